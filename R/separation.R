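# Separation of touching cells: Euclidean distance-transform peaks give one
# seed per cell; a seeded random walker on the intensity patch assigns every
# foreground pixel the probability of first reaching each seed, and the
# argmax label map partitions the ROI into single-cell masks.

#' Euclidean distance transform of a binary mask
#'
#' Exact distance (pixel centers) from each foreground pixel to the nearest
#' background pixel; background maps to 0.
#' @param mask logical matrix with at least one background pixel.
#' @return numeric matrix of distances.
#' @export
distance_transform <- function(mask) {
  storage.mode(mask) <- "logical"
  if (all(mask)) stop("mask has no background pixel; cannot form a distance")
  cpp_edt(mask)
}

#' Seed points from distance-map maxima
#'
#' Regional maxima of the distance map after h-maxima suppression (peaks
#' shallower than `h` are pruned via morphological reconstruction); maxima
#' closer than `min_seed_dist` are merged to their centroid. Always returns
#' at least one seed.
#'
#' @param dmap distance map from [distance_transform()].
#' @param h maxima depth in pixels (default 2).
#' @param min_seed_dist minimum seed separation in pixels; default
#'   `0.5 * sqrt(A_min / pi)`.
#' @param A_min area prior used for the default separation.
#' @return data.frame with columns `label`, `row`, `col` (1-based).
#' @export
generate_seeds <- function(dmap, h = 2, min_seed_dist = NULL, A_min = 600) {
  if (is.null(min_seed_dist)) min_seed_dist <- 0.5 * sqrt(A_min / pi)
  if (!any(dmap > 0)) stop("distance map has no foreground")
  hmax <- cpp_reconstruct(pmax(dmap - h, 0), dmap)
  eps <- 1e-3
  rec <- cpp_reconstruct(pmax(hmax - eps, 0), hmax)
  rmax <- (hmax - rec) > eps / 2 & dmap > 0
  cand <- NULL
  if (any(rmax)) {
    lab <- cpp_label_components(rmax, 8L)
    K <- max(lab)
    cand <- t(vapply(seq_len(K), function(k) {
      px <- which(lab == k, arr.ind = TRUE)
      peak <- max(dmap[lab == k])
      c(row = mean(px[, 1]), col = mean(px[, 2]), peak = peak)
    }, c(row = 0, col = 0, peak = 0)))
  }
  # a credible cell seed must support an inscribed disc of at least
  # A_min/4 pixels, i.e. peak distance >= min_seed_dist; shallower peaks
  # are debris-scale protrusions
  if (!is.null(cand))
    cand <- cand[cand[, "peak"] >= min_seed_dist, , drop = FALSE]
  if (is.null(cand) || nrow(cand) == 0) {
    p <- which(dmap == max(dmap), arr.ind = TRUE)[1, ]
    cand <- matrix(c(p[1], p[2], max(dmap)), 1, 3,
                   dimnames = list(NULL, c("row", "col", "peak")))
  }
  # single-linkage merge of candidates closer than min_seed_dist
  n <- nrow(cand)
  grp <- seq_len(n)
  if (n > 1) {
    d <- as.matrix(stats::dist(cand[, 1:2, drop = FALSE]))
    repeat {
      merged <- FALSE
      for (i in seq_len(n - 1)) {
        for (j in (i + 1):n) {
          if (grp[i] != grp[j] && d[i, j] < min_seed_dist) {
            grp[grp == grp[j]] <- grp[i]
            merged <- TRUE
          }
        }
      }
      if (!merged) break
    }
  }
  ug <- unique(grp)
  seeds <- t(vapply(ug, function(g) {
    m <- cand[grp == g, , drop = FALSE]
    c(row = sum(m[, "row"] * m[, "peak"]) / sum(m[, "peak"]),
      col = sum(m[, "col"] * m[, "peak"]) / sum(m[, "peak"]))
  }, c(row = 0, col = 0)))
  # snap each seed to the nearest foreground pixel
  fg <- which(dmap > 0, arr.ind = TRUE)
  snap <- t(apply(seeds, 1, function(s) {
    i <- which.min((fg[, 1] - s[1])^2 + (fg[, 2] - s[2])^2)
    fg[i, ]
  }))
  ord <- order(snap[, 1], snap[, 2])
  data.frame(label = seq_along(ord), row = as.integer(snap[ord, 1]),
             col = as.integer(snap[ord, 2]))
}

#' Seeded random-walker segmentation of an ROI
#'
#' Builds a 4-connected lattice graph over the foreground pixels with edge
#' weights `w_ij = exp(-beta * (g_i - g_j)^2)` on intensities normalized to
#' `[0, 1]`, and solves the combinatorial Dirichlet problem: each unseeded
#' pixel's probability of first reaching each seed label is the harmonic
#' extension of the seed indicators (a sparse SPD linear solve). Foreground
#' components that contain no seed are assigned wholly to the nearest seed,
#' with a warning.
#'
#' @param image grayscale patch covering the ROI.
#' @param mask logical ROI mask (same size).
#' @param seeds data.frame with `label`, `row`, `col` (as from
#'   [generate_seeds()]).
#' @param beta edge-weight sharpness on `[0,1]`-scaled intensities
#'   (default 130).
#' @return list with `prob` (matrix `n_foreground x K`, rows sum to 1),
#'   `pixels` (matrix of foreground `row`,`col` matching `prob` rows),
#'   `label_map` (integer matrix, 0 = background), `labels` (seed labels).
#' @export
random_walk_segment <- function(image, mask, seeds, beta = 130) {
  stopifnot(nrow(image) == nrow(mask), ncol(image) == ncol(mask))
  H <- nrow(mask); W <- ncol(mask)
  idx <- matrix(0L, H, W)
  fg <- which(mask)
  idx[fg] <- seq_along(fg)
  nfg <- length(fg)
  K <- nrow(seeds)
  pr <- ((fg - 1) %% H) + 1
  pc <- ((fg - 1) %/% H) + 1
  pixels <- cbind(row = pr, col = pc)
  seed_node <- idx[cbind(seeds$row, seeds$col)]
  if (any(seed_node == 0)) stop("seed not on foreground")
  if (K == 1) {
    prob <- matrix(1, nfg, 1)
    lm <- matrix(0L, H, W)
    lm[fg] <- 1L
    return(list(prob = prob, pixels = pixels, label_map = lm,
                labels = seeds$label))
  }
  g <- image
  rng <- range(g[mask])
  g <- if (diff(rng) > 0) (g - rng[1]) / diff(rng) else g * 0
  # 4-neighbour edges within the mask
  edges_i <- integer(0); edges_j <- integer(0); wts <- numeric(0)
  # vertical neighbours
  has_down <- pr < H
  down <- fg[has_down] + 1L
  ok <- idx[down] > 0
  if (any(ok)) {
    a <- idx[fg[has_down]][ok]; b <- idx[down][ok]
    w <- exp(-beta * (g[fg[has_down]][ok] - g[down][ok])^2) + 1e-6
    edges_i <- c(edges_i, a); edges_j <- c(edges_j, b); wts <- c(wts, w)
  }
  has_right <- pc < W
  right <- fg[has_right] + H
  ok <- idx[right] > 0
  if (any(ok)) {
    a <- idx[fg[has_right]][ok]; b <- idx[right][ok]
    w <- exp(-beta * (g[fg[has_right]][ok] - g[right][ok])^2) + 1e-6
    edges_i <- c(edges_i, a); edges_j <- c(edges_j, b); wts <- c(wts, w)
  }
  # components without a seed -> nearest seed by centroid distance
  comp <- cpp_label_components(mask, 4L)
  comp_of_node <- comp[fg]
  seeded_comps <- unique(comp_of_node[seed_node])
  orphan <- which(!(comp_of_node %in% seeded_comps))
  orphan_label <- integer(0)
  if (length(orphan) > 0) {
    warning("foreground component without a seed; assigning to nearest seed")
    orphan_label <- vapply(orphan, function(v) {
      d2 <- (seeds$row - pr[v])^2 + (seeds$col - pc[v])^2
      which.min(d2)
    }, 0L)
  }
  prob <- matrix(0, nfg, K)
  prob[cbind(seed_node, seq_len(K))] <- 1
  if (length(orphan) > 0)
    prob[cbind(orphan, orphan_label)] <- 1
  solve_nodes <- setdiff(seq_len(nfg), c(seed_node, orphan))
  if (length(solve_nodes) > 0) {
    keep <- (edges_i %in% c(solve_nodes, seed_node)) &
            (edges_j %in% c(solve_nodes, seed_node))
    ei <- edges_i[keep]; ej <- edges_j[keep]; ew <- wts[keep]
    Wm <- Matrix::sparseMatrix(i = c(ei, ej), j = c(ej, ei), x = c(ew, ew),
                               dims = c(nfg, nfg))
    deg <- Matrix::rowSums(Wm)
    u <- solve_nodes
    Luu <- Matrix::Diagonal(x = deg[u]) - Wm[u, u, drop = FALSE]
    S <- matrix(0, K, K); diag(S) <- 1
    B <- as.matrix(Wm[u, seed_node, drop = FALSE] %*% S)
    X <- as.matrix(Matrix::solve(Luu, B))
    prob[u, ] <- X
  }
  lm <- matrix(0L, H, W)
  lm[fg] <- max.col(prob, ties.method = "first")
  list(prob = prob, pixels = pixels, label_map = lm, labels = seeds$label)
}

#' Split a labelled ROI into single-cell masks
#'
#' One mask per walker label; labels smaller than `A_min / 4` are merged
#' into the neighbouring label with the longest shared boundary, so no
#' debris-sized fragment exits this stage. The returned masks partition the
#' ROI foreground exactly.
#'
#' @param label_map integer matrix from [random_walk_segment()] (0 =
#'   background).
#' @param image optional grayscale patch; when given, each cell record
#'   carries its patch crop.
#' @param A_min area prior (fragments below `A_min/4` are merged).
#' @return list of `cell_mask` records: `mask` (local), `bbox` (named,
#'   1-based inclusive, relative to the ROI patch), `area`, `patch`.
#' @export
split_cells <- function(label_map, image = NULL, A_min = 600) {
  lm <- label_map
  K <- max(lm)
  if (K == 0) return(list())
  repeat {
    areas <- tabulate(lm[lm > 0], nbins = max(lm))
    present <- which(areas > 0)
    small <- present[areas[present] < A_min / 4]
    if (length(small) == 0 || length(present) == 1) break
    s <- small[which.min(areas[small])]
    # boundary contact length with each other label (4-neighbour)
    H <- nrow(lm); W <- ncol(lm)
    px <- which(lm == s)
    nb <- c(px[(px - 1) %% H + 1 > 1] - 1L, px[(px - 1) %% H + 1 < H] + 1L,
            px[px > H] - H, px[px <= H * (W - 1)] + H)
    nbl <- lm[nb]
    nbl <- nbl[nbl > 0 & nbl != s]
    if (length(nbl) == 0) break
    target <- as.integer(names(which.max(table(nbl))))
    lm[lm == s] <- target
  }
  labs <- sort(unique(lm[lm > 0]))
  out <- vector("list", length(labs))
  for (i in seq_along(labs)) {
    px <- which(lm == labs[i], arr.ind = TRUE)
    rr <- range(px[, 1]); cc <- range(px[, 2])
    m <- lm[rr[1]:rr[2], cc[1]:cc[2], drop = FALSE] == labs[i]
    out[[i]] <- structure(
      list(mask = m,
           bbox = c(r0 = rr[1], r1 = rr[2], c0 = cc[1], c1 = cc[2]),
           area = nrow(px),
           patch = if (!is.null(image))
             image[rr[1]:rr[2], cc[1]:cc[2], drop = FALSE] else NULL),
      class = "cell_mask")
  }
  out
}

#' Separate one touching ROI region into per-cell patches
#'
#' Convenience wrapper: distance transform on the region mask, seed
#' generation, random-walker segmentation on the intensity patch, and
#' fragment-safe splitting.
#'
#' @param roi an `roi_region` from [extract_rois()].
#' @param beta walker sharpness, see [random_walk_segment()].
#' @param h,min_seed_dist,A_min see [generate_seeds()] / [split_cells()].
#' @return list of `cell_mask` records (bboxes relative to the ROI patch).
#' @export
separate_roi <- function(roi, beta = 130, h = 2, min_seed_dist = NULL,
                         A_min = 600) {
  dmap <- distance_transform(pad_mask(roi$mask))
  seeds <- generate_seeds(dmap, h = h, min_seed_dist = min_seed_dist,
                          A_min = A_min)
  seeds$row <- seeds$row - 1L
  seeds$col <- seeds$col - 1L
  # 3x3 box presmoothing: edge weights should respond to the cell rims,
  # not to single-pixel shot noise (which at beta ~ 130 can isolate a seed)
  rw <- random_walk_segment(box_smooth3(roi$patch), roi$mask, seeds,
                            beta = beta)
  split_cells(rw$label_map, image = roi$patch, A_min = A_min)
}

# 3x3 box filter with replicated borders
box_smooth3 <- function(img) {
  H <- nrow(img); W <- ncol(img)
  p <- img[c(1, 1:H, H), c(1, 1:W, W)]
  acc <- matrix(0, H, W)
  for (di in 0:2) for (dj in 0:2)
    acc <- acc + p[di + 1:H, dj + 1:W]
  acc / 9
}
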