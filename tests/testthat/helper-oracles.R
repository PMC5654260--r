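# Independent oracles and fixture builders shared across the suite.

# dense absorbing-Markov-chain solution of the seeded random walker:
# transition P = D^-1 W over foreground nodes, seeds absorbing; the
# first-arrival probabilities solve (I - Q) X = R. Pure base-R dense
# linear algebra, independent of the sparse-Laplacian implementation.
rw_dense_oracle <- function(image, mask, seeds, beta = 130) {
  H <- nrow(mask); W <- ncol(mask)
  fg <- which(mask)
  nfg <- length(fg)
  idx <- matrix(0L, H, W)
  idx[fg] <- seq_along(fg)
  g <- image
  rng <- range(g[mask])
  g <- if (diff(rng) > 0) (g - rng[1]) / diff(rng) else g * 0
  pr <- ((fg - 1) %% H) + 1
  pc <- ((fg - 1) %/% H) + 1
  Wd <- matrix(0, nfg, nfg)
  for (k in seq_len(nfg)) {
    for (dd in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
      r <- pr[k] + dd[1]; c <- pc[k] + dd[2]
      if (r >= 1 && r <= H && c >= 1 && c <= W && idx[r, c] > 0) {
        j <- idx[r, c]
        Wd[k, j] <- exp(-beta * (g[fg[k]] - g[r + (c - 1) * H])^2) + 1e-6
      }
    }
  }
  K <- nrow(seeds)
  sn <- idx[cbind(seeds$row, seeds$col)]
  un <- setdiff(seq_len(nfg), sn)
  P <- Wd / rowSums(Wd)
  X <- solve(diag(length(un)) - P[un, un, drop = FALSE],
             P[un, sn, drop = FALSE])
  prob <- matrix(0, nfg, K)
  prob[cbind(sn, seq_len(K))] <- 1
  prob[un, ] <- X
  prob
}

# raster disc / ellipse builders (logical masks)
raster_disc <- function(r, pad = 6) {
  G <- 2 * (r + pad) + 1
  ctr <- r + pad + 1
  v <- matrix(seq_len(G) - ctr, G, G)
  u <- t(v)
  u^2 + v^2 <= r^2
}

raster_ellipse <- function(a, b, theta = 0, pad = 6) {
  G <- 2 * (max(a, b) + pad) + 1
  ctr <- max(a, b) + pad + 1
  v <- matrix(seq_len(G) - ctr, G, G)
  u <- t(v)
  ur <- cos(theta) * u + sin(theta) * v
  vr <- -sin(theta) * u + cos(theta) * v
  (ur / a)^2 + (vr / b)^2 <= 1
}

# two discs of radius r joined by a neck; symmetric about the center
raster_dumbbell <- function(r = 13, sep = 14, neck = 3) {
  G <- 2 * (r + sep) + 11
  ctr <- (G + 1) / 2
  v <- matrix(seq_len(G) - ctr, G, G)
  u <- t(v)
  d1 <- (u + sep)^2 + v^2 <= r^2
  d2 <- (u - sep)^2 + v^2 <= r^2
  nk <- abs(v) <= neck & abs(u) <= sep
  d1 | d2 | nk
}

# Mann-Whitney rank statistic AUC oracle
auc_rank_oracle <- function(truth, score, class) {
  pos <- truth == class
  if (!any(pos) || all(pos)) return(NA_real_)
  r <- rank(score)
  (sum(r[pos]) - sum(pos) * (sum(pos) + 1) / 2) /
    (sum(pos) * sum(!pos))
}

# single-cell 78x78 net-input patches via the generator + normalization
make_patch_set <- function(classes, n_per_class, seed_base = 0) {
  patches <- list()
  labels <- character(0)
  for (ci in seq_along(classes)) {
    for (r in seq_len(n_per_class)) {
      mix <- stats::setNames(as.numeric(RBC_CLASSES == classes[ci]),
                             RBC_CLASSES)
      sc <- render_scene(scene_config(
        frame_width = 150, frame_height = 150, n_cells = 1,
        touching_fraction = 0, artifact_count = 0, class_mix = mix,
        seed = seed_base + ci * 1000 + r))
      tc <- sc$truth$cells[[1]]
      bb <- tc$bbox
      patch <- sc$frame[max(1, bb["r0"] - 3):min(150, bb["r1"] + 3),
                        max(1, bb["c0"] - 3):min(150, bb["c1"] + 3)]
      np <- normalize_patch(patch,
                            select_background_mask(sc$frame, stride = 25))
      patches[[length(patches) + 1]] <- resize_for_net(np)
      labels <- c(labels, classes[ci])
    }
  }
  list(patches = patches, labels = labels)
}

# scaled-down architecture used for training benchmarks in the tests
small_net_spec <- function(n_classes = 5, dropout = 0) {
  network_spec(n_classes, conv_filters = c(8, 16, 32),
               conv_kernels = c(5, 5, 4), fc_units = 64, dropout = dropout)
}

# scene with one touching cluster of k cells; returns scene + the ROI
# containing the cluster (largest estimated count) + expected cell count
cluster_fixture <- function(k, seed) {
  sc <- render_scene(scene_config(frame_width = 460, frame_height = 360,
                                  n_cells = k, touching_fraction = 1,
                                  artifact_count = 0, seed = seed))
  em <- entropy_map(sc$frame)
  m <- threshold_and_refine(em, image = sc$frame)
  rois <- extract_rois(m, sc$frame)
  ctr <- t(sapply(sc$truth$cells, `[[`, "center"))
  nin <- vapply(rois, function(roi) {
    r <- round(ctr[, 1]) - roi$bbox["r0"] + 1
    c <- round(ctr[, 2]) - roi$bbox["c0"] + 1
    ok <- r >= 1 & r <= nrow(roi$mask) & c >= 1 & c <= ncol(roi$mask)
    rr <- pmin(pmax(r, 1), nrow(roi$mask))
    cc <- pmin(pmax(c, 1), ncol(roi$mask))
    sum(ok & roi$mask[cbind(rr, cc)])
  }, 0)
  list(scene = sc, roi = rois[[which.max(nin)]], expected = max(nin))
}

# first seed whose rendered cluster actually joins k cells in one ROI
find_cluster_fixture <- function(k, seeds = 1:40) {
  for (s in seeds) {
    fx <- cluster_fixture(k, seed = s)
    if (fx$expected == k) return(fx)
  }
  stop("no seed in range produced a joined ", k, "-cell cluster")
}

# frame-coordinate overlay of a separated cell mask (for IoU scoring)
overlay_cell <- function(cm, roi, H, W) {
  full <- matrix(FALSE, H, W)
  sub <- full[roi$bbox["r0"]:roi$bbox["r1"],
              roi$bbox["c0"]:roi$bbox["c1"]]
  sub[cm$bbox["r0"]:cm$bbox["r1"],
      cm$bbox["c0"]:cm$bbox["c1"]][cm$mask] <- TRUE
  full[roi$bbox["r0"]:roi$bbox["r1"],
       roi$bbox["c0"]:roi$bbox["c1"]] <- sub
  full
}

overlay_truth <- function(tc, H, W) {
  gt <- matrix(FALSE, H, W)
  gt[tc$bbox["r0"]:tc$bbox["r1"],
     tc$bbox["c0"]:tc$bbox["c1"]][tc$mask] <- TRUE
  gt
}
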