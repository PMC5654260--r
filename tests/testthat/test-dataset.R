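# Labeling schemes, augmentation, k-fold partitioning.

test_that("label schemes encode the published merge maps", {
  c5 <- label_scheme("coarse5")
  expect_length(c5$classes, 5)
  expect_identical(unname(c5$map[c("Dic", "Ovl")]), c(1L, 1L))
  expect_identical(unname(c5$map[c("El", "Sk")]), c(3L, 3L))
  expect_true(is.na(c5$map["Sto"]))

  r8 <- label_scheme("refined8")
  expect_identical(r8$classes, RBC_CLASSES)
  expect_identical(unname(r8$map), 1:8)

  o6 <- label_scheme("oxydeoxy6")
  expect_length(o6$classes, 6)
  expect_identical(unname(o6$map[c("El.DeOxy", "Sk.DeOxy")]), c(6L, 6L))
})

test_that("augmentation yields 6 exact pixel permutations", {
  set.seed(1)
  p <- matrix(runif(64), 8, 8)
  a <- augment_patch(p)
  expect_length(a, 6)
  expect_identical(names(a),
                   c("orig", "rot90", "rot180", "rot270", "hflip", "vflip"))
  # group identity: rot180 == vflip(hflip)
  expect_identical(a$rot180, p[8:1, 8:1])
  # every variant is a permutation: sorted pixels identical
  for (v in a) expect_identical(sort(as.vector(v)), sort(as.vector(p)))
  # 4-fold rotational symmetry fixes rot90: average p over its rotations
  sym <- p + a$rot90 + a$rot180 + a$rot270
  expect_equal(augment_patch(sym)$rot90, sym)
  expect_error(augment_patch(matrix(0, 3, 4)), "square")
})

test_that("assembly reproduces the published augmented totals", {
  tiny <- function(n) replicate(n, matrix(0, 2, 2), simplify = FALSE)
  # full pooled dataset: 8 classes
  counts1 <- c(Dic = 338, Ech = 123, El = 280, Grl = 91, Ovl = 118,
               Ret = 115, Sk = 115, Sto = 24)
  labels <- rep(names(counts1), counts1)
  ds <- assemble_dataset(tiny(length(labels)), labels, "refined8",
                         augment = TRUE)
  expect_identical(sum(ds$counts), 7224L)
  expect_identical(unname(ds$counts),
                   as.integer(6 * counts1[RBC_CLASSES]))

  # coarse labeling drops stomatocytes: 7224 - 144 = 7080
  expect_message(
    ds5 <- assemble_dataset(tiny(length(labels)), labels, "coarse5",
                            augment = TRUE),
    "dropping")
  expect_identical(sum(ds5$counts), 7080L)

  # oxy/deoxy dataset: merged counts 456,123,395,91,115,81 -> 7566
  labels6 <- c(rep("Dic", 338), rep("Ovl", 118),      # 456 Dic+Ovl
               rep("Ech", 123),
               rep("El", 280), rep("Sk", 115),        # 395 El+Sk
               rep("Grl", 91), rep("Ret", 115),
               rep("El.DeOxy", 50), rep("Sk.DeOxy", 31))  # 81 DeOxy
  ds6 <- assemble_dataset(tiny(length(labels6)), labels6, "oxydeoxy6",
                          augment = TRUE)
  expect_identical(sum(ds6$counts), 7566L)
  expect_identical(unname(ds6$counts),
                   6L * c(456L, 123L, 395L, 91L, 115L, 81L))

  expect_error(assemble_dataset(tiny(2), c("Dic", "Nope"), "refined8"),
               "unknown base label")
})

test_that("k-fold split honours Eq-style exact division and remainders", {
  tiny <- function(n) replicate(n, matrix(0, 2, 2), simplify = FALSE)
  # 115 sources x 6 augmentations = 690 items; 690 / 5 = 138 per fold
  ds <- assemble_dataset(tiny(115), rep("Ret", 115), "refined8",
                         augment = TRUE)
  plan <- kfold_split(ds, k = 5, seed = 1)
  expect_true(all(table(plan$fold) == 138))
  expect_length(table(plan$fold), 5)
  # class of 12 items, k = 5: validation sizes {3,3,2,2,2}
  ds12 <- assemble_dataset(tiny(12), rep("Dic", 12), "refined8",
                           augment = FALSE)
  p12 <- kfold_split(ds12, k = 5, seed = 2)
  expect_identical(sort(as.integer(table(p12$fold)), decreasing = TRUE),
                   c(3L, 3L, 2L, 2L, 2L))
})

test_that("folds partition the dataset with no augmentation leakage", {
  set.seed(4)
  tiny <- replicate(40, matrix(runif(4), 2, 2), simplify = FALSE)
  labels <- rep(c("Dic", "Ech", "El", "Grl"), each = 10)
  ds <- assemble_dataset(tiny, labels, "refined8", augment = TRUE)
  plan <- kfold_split(ds, k = 5, seed = 7)
  # disjoint and exhaustive
  expect_identical(sort(plan$item), seq_along(ds$y))
  expect_identical(sum(table(plan$fold)), length(ds$y))
  # leakage guard: all 6 variants of a source share one fold
  per_source <- tapply(plan$fold, plan$source, function(f)
    length(unique(f)))
  expect_true(all(per_source == 1))
  # train/val complement per fold
  fm <- fold_members(plan, 3)
  expect_identical(sort(c(fm$train, fm$val)), seq_along(ds$y))
  # seed determinism
  expect_identical(kfold_split(ds, k = 5, seed = 7), plan)
  # item-unit mode may split variants
  plan_i <- kfold_split(ds, k = 5, seed = 7, unit = "item")
  expect_identical(sort(plan_i$item), seq_along(ds$y))
  # too-small class is rejected
  ds_small <- assemble_dataset(tiny[1:3], rep("Dic", 3), "refined8",
                               augment = FALSE)
  expect_error(kfold_split(ds_small, k = 5), "at least k")
})
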