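# Block-entropy ROI detection.

test_that("to_grayscale handles 1-4 channels and rejects more", {
  m <- matrix(7, 4, 4)
  expect_identical(to_grayscale(m), m)
  a3 <- array(100, c(3, 3, 3))
  expect_true(all(to_grayscale(a3) == 100))
  a4 <- array(0, c(2, 2, 4))
  a4[, , 1] <- 30; a4[, , 2] <- 60; a4[, , 3] <- 90; a4[, , 4] <- 255
  expect_true(all(to_grayscale(a4) == 60))
  expect_error(to_grayscale(array(0, c(2, 2, 5))), "4 channels")
})

test_that("block entropy matches closed forms", {
  expect_identical(block_entropy(matrix(42, 8, 8)), 0)
  two <- matrix(c(0, 255), 16, 16)
  expect_equal(block_entropy(two), 1.0)
  u <- matrix(0:255, 16, 16)
  expect_equal(block_entropy(u), 8.0)
  # bounds on random blocks
  set.seed(1)
  for (i in 1:10) {
    b <- matrix(sample(0:255, 64, replace = TRUE), 8, 8)
    e <- block_entropy(b)
    expect_gte(e, 0)
    expect_lte(e, 8)
  }
})

test_that("entropy map covers the frame and localizes heterogeneity", {
  img <- matrix(128, 128, 128)
  em <- entropy_map(img, N = 32, stride = 16)
  expect_true(all(em$values == 0))
  expect_error(entropy_map(img, N = 32, stride = 0), "stride")

  # one textured cell on constant background: the max-entropy block must
  # overlap the cell (verified against an exhaustive per-origin scan)
  set.seed(4)
  img[40:70, 50:80] <- sample(0:255, 31 * 31, replace = TRUE)
  em <- entropy_map(img, N = 32, stride = 16)
  best <- which(em$values == max(em$values), arr.ind = TRUE)[1, ]
  r0 <- em$row_origins[best[1]]; c0 <- em$col_origins[best[2]]
  expect_true(r0 <= 70 && r0 + 31 >= 40 && c0 <= 80 && c0 + 31 >= 50)
  # exhaustive oracle over the stride lattice
  ex <- max(vapply(em$row_origins, function(r)
    max(vapply(em$col_origins, function(c)
      block_entropy(img[r:min(r + 31, 128), c:min(c + 31, 128)]), 0)), 0))
  expect_equal(max(em$values), ex)

  # halving the stride keeps the coarse map's values at shared origins
  em2 <- entropy_map(img, N = 32, stride = 8)
  shared_r <- match(em$row_origins, em2$row_origins)
  shared_c <- match(em$col_origins, em2$col_origins)
  expect_equal(em2$values[shared_r, shared_c], em$values)
})

test_that("added noise never decreases mean block entropy", {
  base <- matrix(100, 96, 96)
  em0 <- entropy_map(base)
  set.seed(2)
  noisy <- base + matrix(rnorm(96 * 96, 0, 3), 96, 96)
  em1 <- entropy_map(noisy)
  expect_gte(mean(em1$values), mean(em0$values))
})

test_that("threshold_and_refine applies threshold, hole fill, area prior", {
  img <- matrix(128, 64, 64)
  em <- entropy_map(img, N = 16, stride = 16)
  expect_true(all(em$values < 5))
  m <- threshold_and_refine(em, tau = 5, refine_intensity = FALSE)
  expect_false(any(m))

  # two foreground components, 500 and 700 px: only the larger survives
  fake <- structure(list(
    values = matrix(c(9, 0, 0, 0, 9, 0), 1, 6),
    row_origins = 1, col_origins = c(1, 26, 51, 76, 101, 126),
    N = 25, stride = 25, L = 256, base = 2, dim = c(20, 150)),
    class = "entropy_map")
  # block 1 covers rows 1:20 x cols 1:25 = 500 px; block 5 covers
  # 20 x 25 starting at col 101; widen via a second hot block
  fake$values <- matrix(c(9, 0, 0, 0, 9, 9), 1, 6)
  m <- threshold_and_refine(fake, tau = 5, A_min = 600,
                            refine_intensity = FALSE)
  lab <- rbcmorph:::cpp_label_components(m, 8L)
  expect_identical(max(lab), 1L)
  expect_identical(sum(m), 20L * 50L)

  # refinement is idempotent at the mask level (fill + area prune)
  f2 <- rbcmorph:::cpp_fill_holes(m)
  expect_identical(f2, rbcmorph:::cpp_fill_holes(f2))
})

test_that("every ground-truth center lands in foreground on a 12-cell scene", {
  sc <- render_scene(scene_config(frame_width = 760, frame_height = 560,
                                  n_cells = 12, touching_fraction = 0.5,
                                  seed = 7))
  em <- entropy_map(sc$frame)
  m <- threshold_and_refine(em, image = sc$frame)
  ctr <- t(sapply(sc$truth$cells, `[[`, "center"))
  expect_true(all(m[cbind(round(ctr[, 1]), round(ctr[, 2]))]))
})

test_that("extract_rois tags singles and touching clusters correctly", {
  # isolated discocyte: one single region with a tight bbox
  mix <- setNames(as.numeric(RBC_CLASSES == "Dic"), RBC_CLASSES)
  sc <- render_scene(scene_config(frame_width = 200, frame_height = 200,
                                  n_cells = 1, class_mix = mix,
                                  touching_fraction = 0,
                                  artifact_count = 0, seed = 4))
  em <- entropy_map(sc$frame)
  m <- threshold_and_refine(em, image = sc$frame)
  rois <- extract_rois(m, sc$frame)
  expect_length(rois, 1)
  expect_identical(rois[[1]]$kind, "single")
  expect_identical(rois[[1]]$est_count, 1L)
  gt <- sc$truth$cells[[1]]$bbox
  expect_true(all(abs(rois[[1]]$bbox - gt) <= 2))

  # two touching cells: one region, kind touching, estimated count 2
  fx2 <- find_cluster_fixture(2)
  expect_identical(fx2$roi$kind, "touching")
  expect_identical(fx2$roi$est_count, 2L)

  # four touching cells separate into four patches downstream
  fx4 <- find_cluster_fixture(4)
  expect_identical(fx4$roi$est_count, 4L)

  # empty mask -> empty list
  expect_length(extract_rois(matrix(FALSE, 10, 10), matrix(0, 10, 10)), 0)
})

test_that("ROI recall over 20 seeded scenes is at least 0.95", {
  hits <- 0; tot <- 0
  for (s in 1:20) {
    sc <- render_scene(scene_config(frame_width = 512, frame_height = 384,
                                    n_cells = 10, touching_fraction = 0.3,
                                    seed = s))
    em <- entropy_map(sc$frame)
    m <- threshold_and_refine(em, image = sc$frame)
    ctr <- t(sapply(sc$truth$cells, `[[`, "center"))
    hits <- hits + sum(m[cbind(round(ctr[, 1]), round(ctr[, 2]))])
    tot <- tot + nrow(ctr)
  }
  expect_gte(hits / tot, 0.95)
})
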