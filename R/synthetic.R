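# Synthetic brightfield microscopy scenes with exact per-cell ground truth.
# Cells are rendered as dark-rimmed bodies on a bright, slowly varying
# background; eight morphology classes with class-distinctive geometry and
# interior texture. Touching clusters share a boundary but never overlap
# interiors, so every downstream stage (ROI detection, separation,
# classification, shape factors) can be scored against known truth.

# run expr under a local deterministic RNG, restoring the caller's state
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  eval.parent(substitute(expr))
}

#' Scene configuration for the synthetic microscopy generator
#'
#' Defaults describe the imaging setup the pipeline targets: bright
#' background around gray level 170 with a mild linear drift, Gaussian shot
#' noise, cells 42--54 px across with rims 30--60 gray levels darker than
#' the local background, and a class mix matching the relative abundances
#' seen in pooled sickle-cell patient data.
#'
#' @param frame_width,frame_height frame size in pixels.
#' @param n_cells number of cells to place.
#' @param class_mix named proportions over the 8 classes in [RBC_CLASSES];
#'   must sum to 1.
#' @param touching_fraction fraction of cells placed in touching clusters.
#' @param background_level mean background intensity (0--255).
#' @param background_gradient max linear intensity drift across the frame.
#' @param noise_sd Gaussian pixel noise standard deviation.
#' @param artifact_count number of small debris blobs (area below the ROI
#'   area prior, so they are filtered at default settings).
#' @param cell_size_range characteristic cell diameter range in pixels.
#' @param rim_depth_range per-cell rim darkening below background.
#' @param interior_depth interior darkening below background.
#' @param interior_speckle_sd optical texture inside every cell body
#'   (brightfield RBC interiors are never flat); drives the entropy
#'   contrast that the ROI detector relies on.
#' @param seed RNG seed; fully determines the scene.
#' @return a `scene_config` list.
#' @export
scene_config <- function(frame_width = 1920, frame_height = 1080,
                         n_cells = 30,
                         class_mix = c(Dic = 338, Ech = 123, El = 280,
                                       Grl = 91, Ovl = 118, Ret = 115,
                                       Sk = 115, Sto = 24) / 1204,
                         touching_fraction = 0.25,
                         background_level = 170,
                         background_gradient = 10,
                         noise_sd = 3,
                         artifact_count = 3,
                         cell_size_range = c(42, 54),
                         rim_depth_range = c(30, 60),
                         interior_depth = 15,
                         interior_speckle_sd = 8,
                         seed = 1) {
  stopifnot(length(class_mix) == 8, abs(sum(class_mix) - 1) < 1e-8,
            all(class_mix >= 0),
            background_level >= 0, background_level <= 255,
            noise_sd >= 0, touching_fraction >= 0, touching_fraction <= 1)
  if (is.null(names(class_mix))) names(class_mix) <- RBC_CLASSES
  structure(list(frame_width = frame_width, frame_height = frame_height,
                 n_cells = n_cells, class_mix = class_mix,
                 touching_fraction = touching_fraction,
                 background_level = background_level,
                 background_gradient = background_gradient,
                 noise_sd = noise_sd, artifact_count = artifact_count,
                 cell_size_range = cell_size_range,
                 rim_depth_range = rim_depth_range,
                 interior_depth = interior_depth,
                 interior_speckle_sd = interior_speckle_sd, seed = seed),
            class = "scene_config")
}

# radial boundary in local (u = col, v = row) coords rotated by -orientation
.shape_radius <- function(class, theta, R, pars) {
  switch(class,
    Dic = R * (1 + 0.03 * sin(3 * theta + pars$phi)),
    Grl = R * (1 + 0.02 * sin(2 * theta + pars$phi)),
    Ret = R * (1 + 0.02 * sin(3 * theta + pars$phi)),
    Sto = R * (1 + 0.03 * sin(2 * theta + pars$phi)),
    Ech = R * (0.88 + 0.12 * cos(10 * theta + pars$phi)),
    Ovl = ,
    El = {
      a <- R * sqrt(pars$ratio); b <- R / sqrt(pars$ratio)
      a * b / sqrt((b * cos(theta))^2 + (a * sin(theta))^2)
    },
    stop("unknown RBC class: ", class)
  )
}

#' Generate a single-cell mask with class-distinctive geometry and texture
#'
#' @param shape_class one of [RBC_CLASSES] (`"Dic"`, `"Ech"`, `"El"`,
#'   `"Grl"`, `"Ovl"`, `"Ret"`, `"Sk"`, `"Sto"`).
#' @param size_px characteristic diameter in pixels (>= 8).
#' @param orientation rotation in radians.
#' @param seed optional RNG seed for the per-cell shape jitter.
#' @return list with `mask` (logical matrix, one 8-connected component),
#'   `texture` (signed interior intensity offsets, same size), `class`,
#'   `size_px`, `orientation`.
#' @export
make_cell_mask <- function(shape_class, size_px = 46, orientation = 0,
                           seed = NULL) {
  if (!shape_class %in% RBC_CLASSES)
    stop("unknown RBC class: ", shape_class,
         " (expected one of ", paste(RBC_CLASSES, collapse = ", "), ")")
  stopifnot(size_px >= 8)
  with_local_seed(seed, {
    R <- size_px / 2
    G <- 2L * ceiling(size_px * 0.95) + 1L
    ctr <- (G + 1) / 2
    v <- matrix(seq_len(G) - ctr, G, G)            # row offset
    u <- matrix(seq_len(G) - ctr, G, G, byrow = TRUE)  # col offset
    # rotate into shape frame
    ur <- cos(orientation) * u + sin(orientation) * v
    vr <- -sin(orientation) * u + cos(orientation) * v
    pars <- list(phi = runif(1, 0, 2 * pi),
                 ratio = switch(shape_class, Ovl = runif(1, 1.3, 1.8),
                                El = runif(1, 2.6, 3.4), 1))
    if (shape_class == "Sk") {
      # crescent: large disc minus an offset disc
      R1 <- R * 1.25
      R2 <- R1 * 0.92
      d <- R1 * 0.62
      mask <- (ur^2 + vr^2 <= R1^2) & ((ur - d)^2 + vr^2 > R2^2)
    } else {
      th <- atan2(vr, ur)
      rr <- sqrt(ur^2 + vr^2)
      mask <- rr <= .shape_radius(shape_class, th, R, pars)
    }
    # keep the largest 8-connected component (guards spicule pinch-off)
    lab <- cpp_label_components(mask, 8L)
    if (max(lab) > 1) {
      areas <- tabulate(lab[lab > 0])
      mask <- lab == which.max(areas)
    }
    rr <- sqrt(ur^2 + vr^2)
    texture <- matrix(0, G, G)
    if (shape_class == "Dic") {
      texture <- 26 * exp(-(rr / (0.45 * R))^2)          # pale center
    } else if (shape_class == "Grl") {
      texture <- matrix(rnorm(G * G, 0, 22), G, G)       # speckle
    } else if (shape_class == "Ret") {
      f1 <- runif(2, 0.5, 0.9); f2 <- runif(2, 0.5, 0.9)
      ph <- runif(2, 0, 2 * pi)                           # reticular strands
      s <- sin(f1[1] * ur + f1[2] * vr + ph[1]) *
           sin(f2[1] * ur - f2[2] * vr + ph[2])
      texture <- -28 * (s > 0.45)
    } else if (shape_class == "Sto") {
      texture <- 30 * (abs(vr) < 0.14 * R + 1 & abs(ur) < 0.62 * R)  # slit
    }
    texture[!mask] <- 0
    list(mask = mask, texture = texture, class = shape_class,
         size_px = size_px, orientation = orientation)
  })
}

# Largest integer offset (along a unit direction) at which two local masks
# touch: either 8-adjacent, or with a sliver of overlap small enough that
# the first-owner rasterization rule trims it away. Used to build touching
# clusters whose interiors never overlap.
.contact_offset <- function(maskA, maskB, dir) {
  rA <- (nrow(maskA) + 1) / 2; rB <- (nrow(maskB) + 1) / 2
  dmax <- ceiling((nrow(maskA) + nrow(maskB)) / 2) + 2L
  coordsA <- which(maskA, arr.ind = TRUE)
  coordsB0 <- which(maskB, arr.ind = TRUE)
  keyA <- coordsA[, 1] * 100000 + coordsA[, 2]
  amin <- min(sum(maskA), sum(maskB))
  for (d in seq(dmax, 4L)) {
    dr <- round(dir[1] * d); dc <- round(dir[2] * d)
    # B pixel (i,j) sits at A-frame coords (i - rB + rA + dr, j - rB + rA + dc)
    keyB <- (coordsB0[, 1] - rB + rA + dr) * 100000 +
            (coordsB0[, 2] - rB + rA + dc)
    n_ov <- sum(keyB %in% keyA)
    if (n_ov > 0) {
      if (n_ov <= 0.04 * amin) return(list(d = d, dir = dir))
      return(list(d = d + 1, dir = dir))
    }
    adj <- FALSE
    for (oi in -1:1) {
      for (oj in -1:1) {
        if (any((keyB + oi * 100000 + oj) %in% keyA)) { adj <- TRUE; break }
      }
      if (adj) break
    }
    if (adj) return(list(d = d, dir = dir))
  }
  list(d = 4L, dir = dir)
}

#' Render a synthetic microscopy frame with ground truth
#'
#' The background is `background_level` plus a linear gradient along a
#' random direction plus Gaussian noise. Cells have rims 30--60 gray levels
#' darker than the local background and textured interiors; touching
#' clusters of 2--4 cells share boundaries without interior overlap. Small
#' debris artifacts (below the ROI area prior) are sprinkled in.
#'
#' @param config a [scene_config()].
#' @return a `scene` list: `frame` (numeric matrix), `truth` (list with
#'   per-cell entries `id`, `class`, `center`, `bbox` (1-based inclusive
#'   `r0,r1,c0,c1`), `cluster`, `mask` (local logical matrix), plus
#'   `label_image`), and `config`.
#' @export
render_scene <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  with_local_seed(config$seed, {
    H <- config$frame_height; W <- config$frame_width
    n <- config$n_cells
    # background plane
    ang <- runif(1, 0, 2 * pi)
    gr <- config$background_gradient
    rows <- matrix(seq_len(H) / H, H, W)
    cols <- matrix(seq_len(W) / W, H, W, byrow = TRUE)
    bg <- config$background_level + gr * (cos(ang) * cols + sin(ang) * rows - 0.5)
    frame <- bg
    label <- matrix(0L, H, W)
    truth <- list()
    if (n > 0) {
      classes <- sample(names(config$class_mix), n, replace = TRUE,
                        prob = config$class_mix)
      sizes <- runif(n, config$cell_size_range[1], config$cell_size_range[2])
      cells <- lapply(seq_len(n), function(i)
        make_cell_mask(classes[i], sizes[i], runif(1, 0, pi)))
      # true bounding radius: farthest mask pixel from the local grid center
      radii <- vapply(cells, function(cl) {
        px <- which(cl$mask, arr.ind = TRUE)
        ctr <- (nrow(cl$mask) + 1) / 2
        max(sqrt((px[, 1] - ctr)^2 + (px[, 2] - ctr)^2)) + 1
      }, 0)
      if (sum((2.2 * radii)^2) > 0.8 * H * W)
        stop("cell density too high for the requested frame size")
      # cluster plan
      n_touch <- round(config$touching_fraction * n)
      cluster_of <- integer(n)
      next_cluster <- 0L
      i <- 1L
      while (n_touch >= 2 && i <= n) {
        sz <- min(sample(2:4, 1), n_touch)
        if (sz < 2) break
        next_cluster <- next_cluster + 1L
        cluster_of[i:(i + sz - 1)] <- next_cluster
        n_touch <- n_touch - sz
        i <- i + sz
      }
      # place cluster by cluster / singly with rejection sampling
      centers <- matrix(NA_real_, n, 2)  # (row, col)
      placed_r <- c(); placed_c <- c(); placed_rad <- c()
      place_ok <- function(r, c, rad, ignore = integer(0)) {
        if (r - rad < 2 || r + rad > H - 1 || c - rad < 2 || c + rad > W - 1)
          return(FALSE)
        if (length(placed_r) == 0) return(TRUE)
        keep <- setdiff(seq_along(placed_r), ignore)
        if (length(keep) == 0) return(TRUE)
        all(sqrt((placed_r[keep] - r)^2 + (placed_c[keep] - c)^2) >
              (placed_rad[keep] + rad + 4))
      }
      idx <- 1L
      while (idx <= n) {
        cid <- cluster_of[idx]
        members <- if (cid > 0) which(cluster_of == cid) else idx
        ok <- FALSE
        for (try in 1:300) {
          r0 <- runif(1, max(radii[members]) + 8, H - max(radii[members]) - 8)
          c0 <- runif(1, max(radii[members]) + 8, W - max(radii[members]) - 8)
          pos <- matrix(c(r0, c0), 1, 2)
          good <- place_ok(r0, c0, radii[members[1]])
          if (good && length(members) > 1) {
            # pairwise overlap of two members' masks at integer offsets
            pair_overlap <- function(a, b, dpos) {
              ra <- (nrow(cells[[a]]$mask) + 1) / 2
              rb <- (nrow(cells[[b]]$mask) + 1) / 2
              pa <- which(cells[[a]]$mask, arr.ind = TRUE)
              pb <- which(cells[[b]]$mask, arr.ind = TRUE)
              keyA <- pa[, 1] * 100000 + pa[, 2]
              keyB <- (pb[, 1] - rb + ra + dpos[1]) * 100000 +
                      (pb[, 2] - rb + ra + dpos[2])
              sum(keyB %in% keyA)
            }
            for (m in members[-1]) {
              attached <- FALSE
              for (t2 in 1:40) {
                anchor <- sample(seq_len(nrow(pos)), 1)
                th <- runif(1, 0, 2 * pi)
                co <- .contact_offset(cells[[members[anchor]]]$mask,
                                      cells[[m]]$mask, c(sin(th), cos(th)))
                rr <- pos[anchor, 1] + round(sin(th) * co$d)
                cc <- pos[anchor, 2] + round(cos(th) * co$d)
                if (!place_ok(rr, cc, radii[m])) next
                # must not overlap other already-attached members' interiors
                ok_members <- TRUE
                for (q in setdiff(seq_len(nrow(pos)), anchor)) {
                  ov <- pair_overlap(members[q], m,
                                     round(c(rr - pos[q, 1], cc - pos[q, 2])))
                  amin <- min(sum(cells[[members[q]]]$mask),
                              sum(cells[[m]]$mask))
                  if (ov > 0.04 * amin) { ok_members <- FALSE; break }
                }
                if (ok_members) {
                  pos <- rbind(pos, c(rr, cc))
                  attached <- TRUE
                  break
                }
              }
              if (!attached) { good <- FALSE; break }
            }
          }
          if (good && nrow(pos) == length(members)) { ok <- TRUE; break }
        }
        if (!ok) stop("failed to place all cells after bounded retries; ",
                      "reduce n_cells or enlarge the frame")
        for (k in seq_along(members)) {
          centers[members[k], ] <- pos[k, ]
          placed_r <- c(placed_r, pos[k, 1])
          placed_c <- c(placed_c, pos[k, 2])
          placed_rad <- c(placed_rad, radii[members[k]])
        }
        idx <- max(members) + 1L
      }
      # rasterize in id order; contested pixels keep the first owner
      for (i in seq_len(n)) {
        cl <- cells[[i]]
        G <- nrow(cl$mask)
        r0 <- round(centers[i, 1]) - (G - 1) / 2
        c0 <- round(centers[i, 2]) - (G - 1) / 2
        rs <- r0:(r0 + G - 1); cs <- c0:(c0 + G - 1)
        keep_r <- rs >= 1 & rs <= H; keep_c <- cs >= 1 & cs <= W
        sub <- label[rs[keep_r], cs[keep_c], drop = FALSE]
        mloc <- cl$mask[keep_r, keep_c, drop = FALSE]
        paint <- mloc & sub == 0L
        sub[paint] <- i
        label[rs[keep_r], cs[keep_c]] <- sub
        # intensities: graded rim falling off into a textured interior
        dloc <- cpp_edt(cl$mask)[keep_r, keep_c, drop = FALSE]
        rim_depth <- runif(1, config$rim_depth_range[1],
                           config$rim_depth_range[2])
        fsub <- frame[rs[keep_r], cs[keep_c], drop = FALSE]
        tloc <- cl$texture[keep_r, keep_c, drop = FALSE]
        depth <- config$interior_depth +
          (rim_depth - config$interior_depth) * exp(-((dloc - 1) / 2.2)^2)
        speckle <- matrix(rnorm(length(fsub), 0,
                                config$interior_speckle_sd),
                          nrow(fsub), ncol(fsub))
        # class texture is intracellular: keep the membrane rim clean
        tl <- tloc[paint]
        tl[dloc[paint] <= 3] <- 0
        fsub[paint] <- fsub[paint] - depth[paint] + tl + speckle[paint]
        frame[rs[keep_r], cs[keep_c]] <- fsub
        # ground truth record (frame-cropped mask)
        gmask <- mloc & (label[rs[keep_r], cs[keep_c]] == i)
        px <- which(gmask, arr.ind = TRUE)
        rr <- range(px[, 1]); cc <- range(px[, 2])
        # inner center: distance-transform peak (a centroid can fall
        # outside a crescent-shaped cell)
        dg <- cpp_edt(gmask)
        pk <- which(dg == max(dg), arr.ind = TRUE)[1, ]
        truth[[i]] <- list(
          id = i, class = cl$class,
          center = c(row = unname(pk[1]) + min(rs[keep_r]) - 1,
                     col = unname(pk[2]) + min(cs[keep_c]) - 1),
          bbox = c(r0 = rr[1] + min(rs[keep_r]) - 1,
                   r1 = rr[2] + min(rs[keep_r]) - 1,
                   c0 = cc[1] + min(cs[keep_c]) - 1,
                   c1 = cc[2] + min(cs[keep_c]) - 1),
          cluster = cluster_of[i],
          mask = gmask[rr[1]:rr[2], cc[1]:cc[2], drop = FALSE])
      }
    }
    # debris artifacts on free background
    if (config$artifact_count > 0) {
      for (a in seq_len(config$artifact_count)) {
        for (try in 1:100) {
          ar <- runif(1, 3, 6)
          r <- round(runif(1, ar + 2, H - ar - 2))
          c <- round(runif(1, ar + 2, W - ar - 2))
          rs <- max(1, r - 8):min(H, r + 8)
          cs <- max(1, c - 8):min(W, c + 8)
          if (all(label[rs, cs] == 0L)) {
            rr <- matrix(rs - r, length(rs), length(cs))
            cc <- matrix(cs - c, length(rs), length(cs), byrow = TRUE)
            blob <- rr^2 + cc^2 <= ar^2
            fsub <- frame[rs, cs]
            fsub[blob] <- fsub[blob] - 40
            frame[rs, cs] <- fsub
            break
          }
        }
      }
    }
    if (config$noise_sd > 0)
      frame <- frame + matrix(rnorm(H * W, 0, config$noise_sd), H, W)
    frame <- round(clamp255(frame))
    structure(list(frame = frame,
                   truth = list(cells = truth, label_image = label),
                   config = config),
              class = "scene")
  })
}

#' Replicate a grayscale frame into a 4-channel array
#'
#' Emulates 4-channel TIFF input (RGB + opaque alpha) to exercise the
#' multi-channel to grayscale path.
#' @param frame numeric matrix.
#' @return `H x W x 4` array.
#' @export
as_multichannel <- function(frame) {
  a <- array(frame, c(nrow(frame), ncol(frame), 4))
  a[, , 4] <- 255
  a
}

#' Write a scene to disk as plain-text images plus a JSON manifest
#'
#' @param scene a [render_scene()] result.
#' @param dir output directory (created if missing).
#' @param stem file-name stem.
#' @return the manifest path, invisibly.
#' @export
write_scene <- function(scene, dir, stem = "frame") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_pgm(scene$frame, file.path(dir, paste0(stem, ".pgm")))
  write_pgm(scene$truth$label_image,
            file.path(dir, paste0(stem, "_labels.pgm")),
            maxval = max(1, max(scene$truth$label_image)))
  man <- lapply(scene$truth$cells, function(cl) {
    list(id = cl$id, class = cl$class, cluster = cl$cluster,
         center = unname(cl$center) - 1,      # 0-based in manifests
         bbox = unname(cl$bbox) - 1)
  })
  path <- file.path(dir, paste0(stem, "_manifest.json"))
  jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
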