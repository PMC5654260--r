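# Size-invariant patch normalization. A 100x100 pure-background mask is
# cropped once per frame; each variable-size cell patch is pasted centered
# onto a copy of the mask whose intensity has been shifted by the
# corner-median background difference, preserving cell pixels exactly.
# The normalized patch is finally resized to the 78x78 network input.

#' Median of an intensity sequence
#'
#' Sorts the sequence and takes the middle element (odd length) or the mean
#' of the two middle elements (even length). The median of the four corner
#' samples makes the background-difference estimate robust to a single
#' extreme corner (e.g. a cell overhanging one corner).
#'
#' @param x non-empty numeric vector.
#' @return scalar median.
#' @export
intensity_median <- function(x) {
  if (length(x) == 0) stop("empty intensity sequence")
  s <- sort(x)
  n <- length(s)
  if (n %% 2 == 1) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
}

#' Mean intensity in a k x k sample at each of the four image corners
#'
#' @param img numeric matrix.
#' @param extent corner sample side length (default 3; 1 reproduces plain
#'   single-pixel corners).
#' @return numeric vector of 4 corner intensities (TL, TR, BL, BR).
#' @export
corner_samples <- function(img, extent = 3) {
  h <- nrow(img); w <- ncol(img)
  e <- min(extent, h, w)
  c(mean(img[1:e, 1:e]),
    mean(img[1:e, (w - e + 1):w]),
    mean(img[(h - e + 1):h, 1:e]),
    mean(img[(h - e + 1):h, (w - e + 1):w]))
}

#' Background intensity difference between a patch and the reference mask
#'
#' `delta_M = median(G_k) - median(B)` where `G_k` are the four corner
#' intensities of the k-th patch and `B` those of the reference mask.
#' @param patch_corners,mask_corners numeric vectors of length 4.
#' @return signed scalar difference.
#' @export
estimate_delta <- function(patch_corners, mask_corners) {
  stopifnot(length(patch_corners) == 4, length(mask_corners) == 4)
  intensity_median(patch_corners) - intensity_median(mask_corners)
}

#' Shift the normalization mask by the estimated background difference
#'
#' Linear intensity mapping: every mask pixel is shifted by `delta_m` and
#' clipped to `[0, 255]`.
#' @param mask 100x100 background mask.
#' @param delta_m signed shift.
#' @return adapted mask.
#' @export
adapt_mask <- function(mask, delta_m) {
  clamp255(mask + delta_m)
}

#' Paste a cell patch centered on the adapted mask
#'
#' Cell-pixel intensities are preserved exactly; outside the pasted
#' rectangle the adapted mask shows through. Patches larger than the mask
#' are isotropically downscaled to fit 96x96 first (with a warning), so an
#' elongated cell is never cropped.
#'
#' @param patch numeric matrix (the raw cell patch).
#' @param adapted adapted 100x100 mask from [adapt_mask()].
#' @param cell_mask optional logical matrix marking cell pixels in `patch`.
#' @return `normalized_patch` list: `img` (100x100), `cell_mask` (logical
#'   100x100 or NULL), `offset` (top-left paste position, 1-based).
#' @export
compose_patch <- function(patch, adapted, cell_mask = NULL) {
  S <- nrow(adapted)
  stopifnot(S == ncol(adapted))
  if (nrow(patch) > S || ncol(patch) > S) {
    warning("patch exceeds the normalization mask; downscaling to fit")
    sc <- (S - 4) / max(nrow(patch), ncol(patch))
    nh <- max(1, round(nrow(patch) * sc))
    nw <- max(1, round(ncol(patch) * sc))
    patch <- resize_bilinear(patch, nh, nw)
    if (!is.null(cell_mask)) cell_mask <- resize_nearest(cell_mask, nh, nw)
  }
  h <- nrow(patch); w <- ncol(patch)
  r0 <- floor((S - h) / 2) + 1
  c0 <- floor((S - w) / 2) + 1
  img <- adapted
  img[r0:(r0 + h - 1), c0:(c0 + w - 1)] <- patch
  cm <- NULL
  if (!is.null(cell_mask)) {
    cm <- matrix(FALSE, S, S)
    cm[r0:(r0 + h - 1), c0:(c0 + w - 1)] <- cell_mask
  }
  structure(list(img = img, cell_mask = cm, offset = c(r0 = r0, c0 = c0)),
            class = "normalized_patch")
}

#' Normalize a raw cell patch onto the reference background mask
#'
#' Runs the full chain: corner sampling, corner-median background
#' difference, mask adaptation, centered paste.
#' @param patch raw cell patch (numeric matrix).
#' @param norm_mask 100x100 background mask (see
#'   [select_background_mask()]).
#' @param cell_mask optional logical cell mask within `patch`.
#' @param corner_extent corner sample size, see [corner_samples()].
#' @return `normalized_patch` with an extra `delta_m` field.
#' @export
normalize_patch <- function(patch, norm_mask, cell_mask = NULL,
                            corner_extent = 3) {
  dm <- estimate_delta(corner_samples(patch, corner_extent),
                       corner_samples(norm_mask, corner_extent))
  np <- compose_patch(patch, adapt_mask(norm_mask, dm), cell_mask)
  np$delta_m <- dm
  np
}

#' Resize a normalized patch to the network input size
#'
#' Bilinear interpolation from 100x100 to 78x78.
#' @param np a `normalized_patch` or a plain 100x100 matrix.
#' @param size output side length (default 78).
#' @return numeric matrix `size x size`.
#' @export
resize_for_net <- function(np, size = 78) {
  img <- if (inherits(np, "normalized_patch")) np$img else np
  stopifnot(nrow(img) == 100, ncol(img) == 100)
  resize_bilinear(img, size, size)
}

#' Automatically select a pure-background normalization mask from a frame
#'
#' Scans `size x size` windows on a stride lattice and returns the window
#' with minimal gray-level entropy: pure background is the most homogeneous
#' region of a frame, so it minimizes block entropy.
#'
#' @param frame grayscale matrix (at least `size` in both dimensions).
#' @param size mask side length (default 100).
#' @param stride scan stride (default 50).
#' @return numeric `size x size` background crop.
#' @export
select_background_mask <- function(frame, size = 100, stride = 50) {
  H <- nrow(frame); W <- ncol(frame)
  stopifnot(H >= size, W >= size)
  ro <- unique(c(seq(1, H - size + 1, by = stride), H - size + 1))
  co <- unique(c(seq(1, W - size + 1, by = stride), W - size + 1))
  best <- Inf; best_rc <- c(1, 1)
  for (r in ro) {
    for (c in co) {
      e <- block_entropy(frame[r:(r + size - 1), c:(c + size - 1)])
      if (e < best) {
        best <- e
        best_rc <- c(r, c)
      }
    }
  }
  frame[best_rc[1]:(best_rc[1] + size - 1),
        best_rc[2]:(best_rc[2] + size - 1)]
}
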