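# End-to-end orchestration: frames -> ROIs -> separated cells ->
# normalized patches -> (optional) dataset/training/prediction -> shape
# report, with a run manifest of per-stage counts.

#' Pipeline configuration
#'
#' Stage parameters default to the published operating point where one is
#' printed: entropy threshold 5.0, area prior 600 px, batch size 20,
#' weight decay 0.01, dropout 0.5, 78x78 input, k = 5 folds, 60 epochs.
#' Unpublished parameters (block size, stride, walker beta, h-maxima
#' depth) use the package defaults documented on their functions.
#'
#' @param tau entropy threshold.
#' @param block_size,stride entropy window parameters.
#' @param A_min RBC area prior in pixels.
#' @param beta random-walker edge sharpness.
#' @param h h-maxima depth for seeding.
#' @param scheme labeling scheme name.
#' @param k folds for cross-validation.
#' @param train a [train_config()].
#' @param net_filters,net_kernels,net_fc CNN architecture knobs (defaults
#'   match [network_spec()]).
#' @param seed master seed for dataset shuffling.
#' @return `pipeline_config` list.
#' @export
pipeline_config <- function(tau = 5.0, block_size = 32, stride = 16,
                            A_min = 600, beta = 130, h = 2,
                            scheme = "refined8", k = 5,
                            train = train_config(),
                            net_filters = c(32, 64, 128),
                            net_kernels = c(5, 5, 4), net_fc = 256,
                            seed = 42) {
  structure(list(tau = tau, block_size = block_size, stride = stride,
                 A_min = A_min, beta = beta, h = h, scheme = scheme,
                 k = k, train = train, net_filters = net_filters,
                 net_kernels = net_kernels, net_fc = net_fc, seed = seed),
            class = "pipeline_config")
}

#' Extract, separate and normalize all cells of one frame
#'
#' Runs grayscale conversion, entropy ROI detection, single/touching
#' triage, random-walker separation of touching regions, and patch
#' normalization against a background mask selected from the frame.
#' Overlapped regions are discarded.
#'
#' @param frame grayscale matrix or multi-channel array.
#' @param config a [pipeline_config()].
#' @return list: `cells` (each with `patch`, `mask`, `bbox` in frame
#'   coordinates, `roi_id`, `net_input` 78x78), `counts` (named stage
#'   counts), `rois` (the `roi_region` list), `norm_mask`.
#' @export
process_frame <- function(frame, config = pipeline_config()) {
  g <- to_grayscale(frame)
  emap <- entropy_map(g, N = config$block_size, stride = config$stride)
  mask <- threshold_and_refine(emap, image = g, tau = config$tau,
                               A_min = config$A_min)
  rois <- extract_rois(mask, g, h = config$h, A_min = config$A_min)
  norm_mask <- select_background_mask(g)
  cells <- list()
  n_single <- 0L; n_touch <- 0L; n_over <- 0L
  for (roi in rois) {
    if (roi$kind == "single") {
      n_single <- n_single + 1L
      cells[[length(cells) + 1]] <- list(
        patch = roi$patch, mask = roi$mask, bbox = roi$bbox,
        roi_id = roi$id)
    } else if (roi$kind == "touching") {
      n_touch <- n_touch + 1L
      for (cm in separate_roi(roi, beta = config$beta, h = config$h,
                              A_min = config$A_min)) {
        bbox <- c(r0 = unname(roi$bbox["r0"] + cm$bbox["r0"] - 1),
                  r1 = unname(roi$bbox["r0"] + cm$bbox["r1"] - 1),
                  c0 = unname(roi$bbox["c0"] + cm$bbox["c0"] - 1),
                  c1 = unname(roi$bbox["c0"] + cm$bbox["c1"] - 1))
        cells[[length(cells) + 1]] <- list(
          patch = cm$patch, mask = cm$mask, bbox = bbox, roi_id = roi$id)
      }
    } else {
      n_over <- n_over + 1L
    }
  }
  for (i in seq_along(cells)) {
    np <- normalize_patch(cells[[i]]$patch, norm_mask, cells[[i]]$mask)
    cells[[i]]$normalized <- np
    cells[[i]]$net_input <- resize_for_net(np)
  }
  list(cells = cells,
       counts = c(rois = length(rois), single = n_single,
                  touching = n_touch, overlapped = n_over,
                  patches = length(cells)),
       rois = rois, norm_mask = norm_mask)
}

# majority ground-truth label of a cell (by its mask pixels in the frame
# label image); 0 votes -> NA
.truth_label <- function(cell, label_image, truth_cells) {
  rs <- cell$bbox["r0"]:cell$bbox["r1"]
  cs <- cell$bbox["c0"]:cell$bbox["c1"]
  ids <- label_image[rs, cs][cell$mask]
  ids <- ids[ids > 0]
  if (length(ids) == 0) return(NA_character_)
  truth_cells[[as.integer(names(which.max(table(ids))))]]$class
}

#' Run the full pipeline on a set of synthetic scenes
#'
#' Extraction, separation and normalization run per frame; extracted cells
#' are labeled from the scenes' ground truth, assembled into an augmented
#' dataset, split train/holdout by source cell, and a CNN is trained and
#' evaluated. Returns a run manifest with per-stage counts, the model, and
#' predictions.
#'
#' @param scenes list of [render_scene()] scenes.
#' @param config a [pipeline_config()].
#' @param train_fraction fraction of source cells used for training.
#' @param epochs training epochs (overrides `config$train$epochs`).
#' @param classify train/evaluate the CNN (set `FALSE` for extraction-only
#'   runs).
#' @return `run_manifest` list: `counts`, `per_frame`, `config_hash`,
#'   optionally `model`, `holdout_accuracy`, `predictions`,
#'   `class_distribution`, `shape` (shape-factor table).
#' @export
run_pipeline <- function(scenes, config = pipeline_config(),
                         train_fraction = 0.8, epochs = NULL,
                         classify = TRUE) {
  per_frame <- list()
  all_cells <- list()
  for (fi in seq_along(scenes)) {
    pf <- process_frame(scenes[[fi]]$frame, config)
    for (cell in pf$cells) {
      cell$frame <- fi
      cell$label <- .truth_label(cell, scenes[[fi]]$truth$label_image,
                                 scenes[[fi]]$truth$cells)
      all_cells[[length(all_cells) + 1]] <- cell
    }
    per_frame[[fi]] <- pf$counts
  }
  counts <- Reduce(`+`, per_frame)
  counts <- c(frames = length(scenes), counts)
  manifest <- list(counts = counts, per_frame = per_frame,
                   config_hash = config_hash(unclass(config)))
  labeled <- !vapply(all_cells, function(x) is.na(x$label), TRUE)
  manifest$n_labeled <- sum(labeled)
  if (classify && sum(labeled) >= 10) {
    cells <- all_cells[labeled]
    patches <- lapply(cells, function(x) x$net_input)
    labels <- vapply(cells, function(x) x$label, "")
    ds <- assemble_dataset(patches, labels, scheme = config$scheme,
                           augment = TRUE)
    # train/holdout split by source cell (no augmented leakage)
    srcs <- unique(ds$source)
    with_local_seed(config$seed, {
      tr_src <- sample(srcs, max(1, round(train_fraction * length(srcs))))
    })
    tr <- which(ds$source %in% tr_src)
    ho <- setdiff(seq_along(ds$y), tr)
    spec <- network_spec(length(ds$scheme$classes),
                         conv_filters = config$net_filters,
                         conv_kernels = config$net_kernels,
                         fc_units = config$net_fc)
    cfg <- config$train
    if (!is.null(epochs)) cfg$epochs <- epochs
    model <- train_cnn(ds$x[, , tr, drop = FALSE], ds$y[tr], spec, cfg)
    manifest$model <- model
    if (length(ho) > 0) {
      pr <- predict_cnn(model, ds$x[, , ho, drop = FALSE])
      manifest$holdout_accuracy <- mean(pr$labels == ds$y[ho])
    }
    # predict every extracted cell once (un-augmented patch)
    xall <- array(unlist(patches), c(78, 78, length(patches)))
    pa <- predict_cnn(model, xall)
    manifest$predictions <- data.frame(
      cell = seq_along(cells),
      frame = vapply(cells, function(x) x$frame, 0L),
      true_class = labels,
      pred_class = ds$scheme$classes[pa$labels])
    manifest$class_distribution <-
      report_class_distribution(ds$scheme$classes[pa$labels])
    manifest$shape <- shape_report(lapply(cells, function(x) x$mask),
                                   classes = ds$scheme$classes[pa$labels])
  }
  structure(manifest, class = "run_manifest")
}

#' Histogram table of predicted class counts
#'
#' @param predictions character or factor vector of predicted classes.
#' @param group optional grouping key (e.g. density fraction); one value
#'   per prediction.
#' @return data.frame of counts per class (per group when given).
#' @export
report_class_distribution <- function(predictions, group = NULL) {
  if (is.null(group)) {
    tab <- table(predictions)
    return(data.frame(class = names(tab), count = as.integer(tab),
                      stringsAsFactors = FALSE))
  }
  stopifnot(length(group) == length(predictions))
  tab <- table(group, predictions)
  df <- as.data.frame(tab, stringsAsFactors = FALSE)
  names(df) <- c("group", "class", "count")
  df
}
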