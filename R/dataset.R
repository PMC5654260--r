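# Labeling schemes, 6x right-angle data augmentation, and the stratified
# k-fold partition used for cross-validation. Augmented variants of one
# source patch travel together across folds by default (leakage guard).

#' Labeling schemes over the 8 base RBC classes
#'
#' * `coarse5`: Dic+Ovl, Ech, El+Sk, Grl, Ret (stomatocytes are excluded).
#' * `refined8`: the 8 base classes unchanged.
#' * `oxydeoxy6`: `coarse5` plus a sixth class for deoxygenated
#'   elongated/sickle cells (base labels `"El.DeOxy"`, `"Sk.DeOxy"`).
#'
#' @param name one of `"coarse5"`, `"refined8"`, `"oxydeoxy6"`.
#' @return `label_scheme` list: `name`, `classes` (ordered labels), `map`
#'   (named integer vector from base labels to class index; `NA` = dropped).
#' @export
label_scheme <- function(name = c("refined8", "coarse5", "oxydeoxy6")) {
  name <- match.arg(name)
  sch <- switch(name,
    refined8 = list(classes = RBC_CLASSES,
                    map = setNames(seq_len(8), RBC_CLASSES)),
    coarse5 = list(
      classes = c("Dic+Ovl", "Ech", "El+Sk", "Grl", "Ret"),
      map = c(Dic = 1L, Ech = 2L, El = 3L, Grl = 4L, Ovl = 1L, Ret = 5L,
              Sk = 3L, Sto = NA_integer_)),
    oxydeoxy6 = list(
      classes = c("Dic+Ovl (Oxy)", "Ech (Oxy)", "El+Sk (Oxy)", "Grl (Oxy)",
                  "Ret (Oxy)", "El+Sk (DeOxy)"),
      map = c(Dic = 1L, Ech = 2L, El = 3L, Grl = 4L, Ovl = 1L, Ret = 5L,
              Sk = 3L, Sto = NA_integer_,
              El.DeOxy = 6L, Sk.DeOxy = 6L)))
  structure(c(list(name = name), sch), class = "label_scheme")
}

rot90cw <- function(m) t(m[nrow(m):1, , drop = FALSE])

#' Six-fold right-angle augmentation of a square patch
#'
#' Returns the original plus five exact pixel permutations: rotations by
#' 90, 180, 270 degrees and horizontal and vertical reflection. No
#' interpolation is involved, so class-defining texture is untouched.
#'
#' @param patch square numeric matrix.
#' @return named list of 6 matrices
#'   (`orig`, `rot90`, `rot180`, `rot270`, `hflip`, `vflip`).
#' @export
augment_patch <- function(patch) {
  if (nrow(patch) != ncol(patch)) stop("augmentation requires a square patch")
  r1 <- rot90cw(patch)
  r2 <- rot90cw(r1)
  list(orig = patch, rot90 = r1, rot180 = r2, rot270 = rot90cw(r2),
       hflip = patch[, ncol(patch):1, drop = FALSE],
       vflip = patch[nrow(patch):1, , drop = FALSE])
}

#' Assemble patches and base labels into a labeled dataset
#'
#' Base labels are mapped through the scheme (labels mapping to `NA`, e.g.
#' stomatocytes under `coarse5`, are dropped with a message). With
#' `augment = TRUE` each source patch contributes its 6 right-angle
#' variants, so per-class counts are exactly 6x the source counts.
#'
#' @param patches list of equal-size square numeric matrices.
#' @param labels character base labels, one per patch (names in
#'   `scheme$map`).
#' @param scheme a [label_scheme()] (or its name).
#' @param augment logical; apply the 6x augmentation.
#' @return `labeled_dataset`: `x` (array `h x w x n`), `y` (integer class
#'   indices), `source` (source patch ids), `aug` (variant tags), `scheme`,
#'   `counts` (per-class item counts `C(i)`).
#' @export
assemble_dataset <- function(patches, labels, scheme = "refined8",
                             augment = TRUE) {
  if (is.character(scheme)) scheme <- label_scheme(scheme)
  stopifnot(length(patches) == length(labels))
  unknown <- setdiff(unique(labels), names(scheme$map))
  if (length(unknown))
    stop("unknown base label(s): ", paste(unknown, collapse = ", "))
  mapped <- scheme$map[labels]
  if (anyNA(mapped)) {
    dropped <- unique(labels[is.na(mapped)])
    message("dropping ", sum(is.na(mapped)), " patch(es) with label(s) ",
            paste(dropped, collapse = ", "), " not in scheme ", scheme$name)
  }
  keep <- which(!is.na(mapped))
  xs <- list(); ys <- integer(0); src <- integer(0); tags <- character(0)
  for (i in keep) {
    vars <- if (augment) augment_patch(patches[[i]])
            else list(orig = patches[[i]])
    xs <- c(xs, vars)
    ys <- c(ys, rep(as.integer(mapped[i]), length(vars)))
    src <- c(src, rep(i, length(vars)))
    tags <- c(tags, names(vars))
  }
  h <- nrow(xs[[1]]); w <- ncol(xs[[1]])
  x <- array(unlist(xs, use.names = FALSE), c(h, w, length(xs)))
  counts <- tabulate(ys, nbins = length(scheme$classes))
  names(counts) <- scheme$classes
  structure(list(x = x, y = ys, source = src, aug = tags, scheme = scheme,
                 counts = counts),
            class = "labeled_dataset")
}

#' Stratified k-fold partition with augmentation leakage guard
#'
#' Within each class, grouping units (source patches by default, so all
#' augmented variants of a patch land in the same fold) are shuffled by the
#' seed and dealt into k validation subsets whose sizes differ by at most
#' one; a class with exact multiples gives exactly `C(i)/k` per fold. Each
#' fold's training set is the complement of its validation set.
#'
#' @param ds a `labeled_dataset`.
#' @param k number of folds (default 5).
#' @param seed shuffle seed.
#' @param unit `"source"` (leakage-guarded, default) or `"item"`
#'   (paper-literal: augmented variants may split across folds).
#' @return `fold_plan`: data.frame `item`, `class`, `source`, `fold`, with
#'   attributes `k`, `seed`, `unit`.
#' @export
kfold_split <- function(ds, k = 5, seed = 42, unit = c("source", "item")) {
  unit <- match.arg(unit)
  n <- length(ds$y)
  fold <- integer(n)
  with_local_seed(seed, {
    for (cl in sort(unique(ds$y))) {
      items <- which(ds$y == cl)
      groups <- if (unit == "source") unique(ds$source[items]) else items
      if (length(groups) < k)
        stop("class ", cl, " has ", length(groups), " ", unit,
             " unit(s); need at least k = ", k)
      groups <- sample(groups)
      base <- length(groups) %/% k
      rem <- length(groups) %% k
      sizes <- base + as.integer(seq_len(k) <= rem)
      sizes <- sizes[sample(k)]   # remainder folds in shuffled order
      gf <- rep(seq_len(k), times = sizes)
      for (gi in seq_along(groups)) {
        members <- if (unit == "source")
          items[ds$source[items] == groups[gi]] else groups[gi]
        fold[members] <- gf[gi]
      }
    }
  })
  structure(data.frame(item = seq_len(n), class = ds$y, source = ds$source,
                       fold = fold),
            k = k, seed = seed, unit = unit, class = c("fold_plan",
                                                       "data.frame"))
}

#' Training/validation index sets for one fold
#'
#' @param plan a [kfold_split()] result.
#' @param j fold number in `1..k`.
#' @return list with integer vectors `train` and `val`.
#' @export
fold_members <- function(plan, j) {
  stopifnot(j >= 1, j <= attr(plan, "k"))
  list(train = plan$item[plan$fold != j], val = plan$item[plan$fold == j])
}
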