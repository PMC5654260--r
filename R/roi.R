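# Block-entropy ROI detection: frames are scanned with an overlapping
# sliding window; blocks whose gray-level entropy exceeds a threshold mark
# cell-bearing regions, which are refined morphologically and split into
# per-region patches tagged single / touching / overlapped.

#' Shannon entropy of an intensity block
#'
#' `E = -sum_i P_i log(P_i)` over the gray levels occurring in the block,
#' with `P_i` the fraction of block pixels at level `i`. For a full `N x N`
#' block this is the count over `N^2`; clamped edge blocks use their actual
#' pixel count.
#'
#' @param block numeric matrix/vector of intensities in `[0, L-1]`.
#' @param L number of gray levels (default 256).
#' @param base logarithm base; 2 gives bits, so `0 <= E <= log2(L)`.
#' @return scalar entropy.
#' @export
block_entropy <- function(block, L = 256, base = 2) {
  x <- as.vector(block)
  if (length(x) == 0) stop("empty block")
  counts <- tabulate(pmin(pmax(floor(x), 0), L - 1) + 1L, nbins = L)
  p <- counts[counts > 0] / length(x)
  -sum(p * log(p, base = base))
}

#' Sliding-window entropy map of a frame
#'
#' Blocks of size `N x N` are placed on a stride lattice covering the whole
#' frame; windows at the right/bottom edges are clamped to the frame (not
#' padded), so edge blocks are included without injecting artificial levels.
#'
#' @param image grayscale matrix.
#' @param N block size in pixels (default 32; must not exceed either frame
#'   dimension).
#' @param stride lattice step in pixels (default `N/2`).
#' @inheritParams block_entropy
#' @return an `entropy_map`: list with `values` (matrix of entropies, one
#'   per block origin), `row_origins`, `col_origins`, `N`, `stride`, `L`,
#'   `base`, `dim`.
#' @export
entropy_map <- function(image, N = 32, stride = N / 2, L = 256, base = 2) {
  stopifnot(N <= min(dim(image)))
  if (stride <= 0) stop("stride must be positive")
  H <- nrow(image); W <- ncol(image)
  ro <- seq(1, H, by = stride)
  co <- seq(1, W, by = stride)
  vals <- matrix(0, length(ro), length(co))
  for (a in seq_along(ro)) {
    rs <- ro[a]:min(ro[a] + N - 1, H)
    for (b in seq_along(co)) {
      cs <- co[b]:min(co[b] + N - 1, W)
      vals[a, b] <- block_entropy(image[rs, cs], L = L, base = base)
    }
  }
  structure(list(values = vals, row_origins = ro, col_origins = co,
                 N = N, stride = stride, L = L, base = base,
                 dim = c(H, W)),
            class = "entropy_map")
}

#' Threshold an entropy map into a refined ROI mask
#'
#' Pixels covered by any block with entropy `>= tau` become foreground.
#' When the source image is supplied (the default calling pattern), the
#' block-union is refined to cell-shaped regions by an Otsu cut on the
#' intensities inside it, keeping the darker (cell) pixels. Holes are then
#' filled and 8-connected components smaller than the RBC area prior
#' `A_min` are removed (in that order).
#'
#' @param emap an [entropy_map()].
#' @param image optional grayscale matrix enabling intensity refinement.
#' @param tau entropy threshold (default 5.0, in the map's log base).
#' @param A_min area prior in pixels (default 600, i.e. 6*10*10).
#' @param refine_intensity logical; Otsu refinement inside the block union.
#' @return logical ROI mask with attributes `tau` and `A_min`.
#' @export
threshold_and_refine <- function(emap, image = NULL, tau = 5.0, A_min = 600,
                                 refine_intensity = !is.null(image)) {
  stopifnot(inherits(emap, "entropy_map"), tau >= 0)
  H <- emap$dim[1]; W <- emap$dim[2]
  mask <- matrix(FALSE, H, W)
  hot <- which(emap$values >= tau, arr.ind = TRUE)
  for (k in seq_len(nrow(hot))) {
    r0 <- emap$row_origins[hot[k, 1]]
    c0 <- emap$col_origins[hot[k, 2]]
    mask[r0:min(r0 + emap$N - 1, H), c0:min(c0 + emap$N - 1, W)] <- TRUE
  }
  if (refine_intensity && any(mask)) {
    if (is.null(image)) stop("intensity refinement requires the image")
    t <- otsu_threshold(image[mask])
    mask <- mask & (image < t)
    # radius-2 binary closing seals thin rim breaks so pale cell interiors
    # become holes that the next step can fill
    if (any(mask) && !all(mask)) {
      dil <- mask | (cpp_edt(!mask) <= 2)
      mask <- if (all(dil)) dil else dil & (cpp_edt(dil) > 2)
    }
  }
  mask <- cpp_fill_holes(mask)
  lab <- cpp_label_components(mask, 8L)
  if (max(lab) > 0) {
    areas <- tabulate(lab[lab > 0], nbins = max(lab))
    drop <- which(areas < A_min)
    if (length(drop)) mask[lab %in% drop] <- FALSE
  }
  attr(mask, "tau") <- tau
  attr(mask, "A_min") <- A_min
  mask
}

#' Split an ROI mask into per-region patches tagged single/touching/overlapped
#'
#' Each 8-connected component becomes one region with an inclusive bounding
#' box from its min/max pixels. The cell count is estimated from
#' distance-transform seed maxima ([generate_seeds()]): one seed means a
#' single cell; two or more seeds with component solidity (area / convex
#' area) at least `solidity_min` means touching cells; anything else is
#' tagged overlapped (and is discarded by the pipeline).
#'
#' @param mask refined ROI mask from [threshold_and_refine()].
#' @param image grayscale frame (patch crops are taken from it).
#' @param h h-maxima depth for seed detection.
#' @param min_seed_dist minimum seed separation; default derived from the
#'   area prior, `0.5 * sqrt(A_min / pi)`.
#' @param solidity_min touching/overlapped solidity cut (default 0.75).
#' @param A_min area prior used for the seed-distance default.
#' @return list of `roi_region`: `id`, `bbox` (named `r0,r1,c0,c1`, 1-based
#'   inclusive), `mask` (local), `patch` (local crop of `image`), `kind`,
#'   `est_count`, `seeds` (local coordinates).
#' @export
extract_rois <- function(mask, image, h = 2, min_seed_dist = NULL,
                         solidity_min = 0.75, A_min = 600) {
  lab <- cpp_label_components(mask, 8L)
  K <- max(lab)
  if (K == 0) return(list())
  out <- vector("list", K)
  for (k in seq_len(K)) {
    px <- which(lab == k, arr.ind = TRUE)
    rr <- range(px[, 1]); cc <- range(px[, 2])
    local <- lab[rr[1]:rr[2], cc[1]:cc[2], drop = FALSE] == k
    patch <- image[rr[1]:rr[2], cc[1]:cc[2], drop = FALSE]
    dmap <- distance_transform(pad_mask(local))
    seeds <- generate_seeds(dmap, h = h, min_seed_dist = min_seed_dist,
                            A_min = A_min)
    seeds[, c("row", "col")] <- seeds[, c("row", "col")] - 1L  # un-pad
    est <- nrow(seeds)
    kind <- if (est <= 1) "single" else {
      hull <- grDevices::chull(px[, 2], px[, 1])
      ha <- abs(polygon_area(px[hull, 2], px[hull, 1]))
      solidity <- nrow(px) / max(ha, 1)
      if (solidity >= solidity_min) "touching" else "overlapped"
    }
    out[[k]] <- structure(
      list(id = k, bbox = c(r0 = rr[1], r1 = rr[2], c0 = cc[1], c1 = cc[2]),
           mask = local, patch = patch, kind = kind, est_count = est,
           seeds = seeds),
      class = "roi_region")
  }
  out
}

# pad a local mask with a 1-px background frame so the distance transform
# sees background on all sides
pad_mask <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  out <- matrix(FALSE, H + 2, W + 2)
  out[2:(H + 1), 2:(W + 1)] <- mask
  out
}

# shoelace polygon area (signed)
polygon_area <- function(x, y) {
  n <- length(x)
  if (n < 3) return(0)
  j <- c(n, seq_len(n - 1))
  sum(x[j] * y - x * y[j]) / 2
}
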