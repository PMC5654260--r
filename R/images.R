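#' Collapse a multi-channel frame to grayscale
#'
#' Frames may arrive as 1--4 channel arrays (e.g. 4-channel TIFF exports).
#' Multi-channel input is reduced to the rounded mean of the first three
#' channels (a fourth channel, typically alpha, is ignored); single-channel
#' input passes through unchanged.
#'
#' @param frame numeric matrix (single channel) or 3-d array `H x W x C`
#'   with `C <= 4`, intensities in `[0, 255]`.
#' @return integer-valued numeric matrix `H x W`.
#' @export
to_grayscale <- function(frame) {
  if (is.matrix(frame)) return(frame)
  if (!is.array(frame) || length(dim(frame)) != 3)
    stop("frame must be a matrix or an H x W x C array")
  nc <- dim(frame)[3]
  if (nc > 4) stop("frames with more than 4 channels are not supported")
  if (nc == 1) return(frame[, , 1])
  use <- min(nc, 3)
  g <- frame[, , 1]
  for (c in 2:use) g <- g + frame[, , c]
  round(g / use)
}

#' Bilinear image resize
#'
#' @param img numeric matrix.
#' @param out_h,out_w output dimensions in pixels.
#' @return numeric matrix `out_h x out_w`.
#' @export
resize_bilinear <- function(img, out_h, out_w) {
  h <- nrow(img); w <- ncol(img)
  if (h == out_h && w == out_w) return(img)
  # map output pixel centers into input pixel-center coordinates
  ri <- (seq_len(out_h) - 0.5) * h / out_h + 0.5
  ci <- (seq_len(out_w) - 0.5) * w / out_w + 0.5
  r0 <- pmin(pmax(floor(ri), 1), h); r1 <- pmin(r0 + 1, h)
  c0 <- pmin(pmax(floor(ci), 1), w); c1 <- pmin(c0 + 1, w)
  fr <- pmin(pmax(ri - r0, 0), 1); fc <- pmin(pmax(ci - c0, 0), 1)
  a <- img[r0, c0, drop = FALSE]; b <- img[r1, c0, drop = FALSE]
  cc <- img[r0, c1, drop = FALSE]; d <- img[r1, c1, drop = FALSE]
  fr <- matrix(fr, out_h, out_w); fc <- matrix(fc, out_h, out_w, byrow = TRUE)
  a * (1 - fr) * (1 - fc) + b * fr * (1 - fc) + cc * (1 - fr) * fc + d * fr * fc
}

#' Nearest-neighbour resize (for label/mask images)
#' @param img matrix (numeric or logical).
#' @param out_h,out_w output dimensions.
#' @return matrix of the input's storage mode.
#' @export
resize_nearest <- function(img, out_h, out_w) {
  r <- pmin(pmax(ceiling((seq_len(out_h) - 0.5) * nrow(img) / out_h), 1), nrow(img))
  c <- pmin(pmax(ceiling((seq_len(out_w) - 0.5) * ncol(img) / out_w), 1), ncol(img))
  img[r, c, drop = FALSE]
}

#' Otsu threshold of an intensity sample
#'
#' Maximizes between-class variance on a 256-bin histogram. Used to refine
#' the entropy foreground into cell-shaped masks.
#' @param x numeric vector of intensities in `[0, 255]`.
#' @return scalar threshold; pixels `< t` are the dark (cell) class.
#' @export
otsu_threshold <- function(x) {
  counts <- tabulate(pmin(pmax(floor(x), 0), 255) + 1L, nbins = 256L)
  p <- counts / sum(counts)
  omega <- cumsum(p)
  mu <- cumsum(p * (0:255))
  mu_t <- mu[256]
  sb <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sb[!is.finite(sb)] <- 0
  which.max(sb) - 1L + 0.5
}

#' Read / write plain PGM (P2) images
#'
#' Plain-text portable graymap is used for all frame I/O so that outputs
#' and fixtures remain text files; no compiled image library is required.
#' @param path file path.
#' @param img numeric matrix, intensities 0..maxval.
#' @param maxval maximum gray value written to the header.
#' @return `read_pgm` returns a numeric matrix.
#' @export
write_pgm <- function(img, path, maxval = 255) {
  img <- round(pmin(pmax(img, 0), maxval))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(img), nrow(img)), as.character(maxval)), con)
  # row-major per PGM convention
  writeLines(apply(img, 1, paste, collapse = " "), con)
  invisible(path)
}

#' @rdname write_pgm
#' @export
read_pgm <- function(path) {
  toks <- scan(path, what = character(), quiet = TRUE, comment.char = "#")
  if (toks[1] != "P2") stop("only plain (P2) PGM is supported")
  w <- as.integer(toks[2]); h <- as.integer(toks[3])
  vals <- as.numeric(toks[-(1:4)])
  matrix(vals, nrow = h, ncol = w, byrow = TRUE)
}

clamp255 <- function(x) pmin(pmax(x, 0), 255)

# order-independent rolling hash of a config object, for cache keys
config_hash <- function(x) {
  if (!is.null(names(x))) x <- x[order(names(x))]
  bytes <- utf8ToInt(paste(deparse(x), collapse = "\n"))
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}
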