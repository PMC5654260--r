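# A small convolutional classifier: three conv/ReLU/max-pool stages, a
# dropout - fully-connected - dropout head, softmax + cross-entropy loss,
# trained with plain mini-batch SGD (optional momentum) and inverted
# dropout. Convolution and pooling run in compiled code (im2col + BLAS).

#' Network architecture specification
#'
#' Layer order is fixed: C1-P2-C3-P4-C5-P6-D7-F8-D9-output. Convolutions
#' use valid padding; pools are non-overlapping max windows; dropout rate
#' `p` applies to D7 (after flatten) and D9 (after F8).
#'
#' @param n_classes output dimension (5, 6 or 8 in the shipped schemes).
#' @param input_size input side length (default 78).
#' @param conv_filters filter counts for C1, C3, C5.
#' @param conv_kernels kernel sizes for C1, C3, C5.
#' @param pool pooling window (default 2).
#' @param fc_units F8 width (default 256).
#' @param dropout dropout rate p (default 0.5).
#' @return `network_spec` list including the per-stage spatial dimensions
#'   and the flattened feature size.
#' @export
network_spec <- function(n_classes, input_size = 78,
                         conv_filters = c(32, 64, 128),
                         conv_kernels = c(5, 5, 4),
                         pool = 2, fc_units = 256, dropout = 0.5) {
  stopifnot(length(conv_filters) == length(conv_kernels),
            n_classes >= 2, dropout >= 0, dropout < 1)
  dims <- list()
  s <- input_size
  chans <- 1
  for (i in seq_along(conv_filters)) {
    s <- s - conv_kernels[i] + 1
    if (s < 1) stop("kernel ", i, " larger than its input")
    sp <- s %/% pool
    if (sp < 1) stop("pooled size collapsed at stage ", i)
    dims[[i]] <- c(conv = s, pooled = sp)
    s <- sp
    chans <- conv_filters[i]
  }
  structure(list(n_classes = n_classes, input_size = input_size,
                 conv_filters = conv_filters, conv_kernels = conv_kernels,
                 pool = pool, fc_units = fc_units, dropout = dropout,
                 dims = dims, flat = as.integer(s * s * chans)),
            class = "network_spec")
}

#' Seeded scaled-uniform parameter initialization
#'
#' Weights are drawn from `U(-l, l)` with `l = sqrt(6 / fan_in)` per layer;
#' biases start at zero.
#' @param spec a [network_spec()].
#' @param seed RNG seed.
#' @return parameter list (`conv` stages, `fc`, `out`).
#' @export
init_params <- function(spec, seed = 42) {
  with_local_seed(seed, {
    cin <- 1
    conv <- list()
    for (i in seq_along(spec$conv_filters)) {
      k <- spec$conv_kernels[i]; f <- spec$conv_filters[i]
      lim <- sqrt(6 / (k * k * cin))
      w <- array(runif(k * k * cin * f, -lim, lim), c(k, k, cin, f))
      conv[[i]] <- list(w = w, b = numeric(f))
      cin <- f
    }
    lim <- sqrt(6 / spec$flat)
    fc <- list(w = matrix(runif(spec$flat * spec$fc_units, -lim, lim),
                          spec$flat, spec$fc_units),
               b = numeric(spec$fc_units))
    lim <- sqrt(6 / spec$fc_units)
    out <- list(w = matrix(runif(spec$fc_units * spec$n_classes, -lim, lim),
                           spec$fc_units, spec$n_classes),
                b = numeric(spec$n_classes))
    list(conv = conv, fc = fc, out = out)
  })
}

#' Softmax squashing of a score vector
#'
#' `Q'_i = exp(q_i) / sum_j exp(q_j)`, computed shift-invariantly
#' (the row maximum is subtracted before exponentiation, so arbitrary
#' score magnitudes cannot overflow).
#' @param q numeric vector of scores, or a matrix with one score vector
#'   per row.
#' @return probabilities of the same shape; rows sum to 1.
#' @export
softmax <- function(q) {
  if (is.matrix(q)) {
    z <- exp(q - apply(q, 1, max))
    return(z / rowSums(z))
  }
  z <- exp(q - max(q))
  z / sum(z)
}

#' Cross-entropy between predicted probabilities and a one-hot target
#'
#' `D(Q', Q) = -sum_i Q_i log(Q'_i)` with natural log; for a one-hot target
#' this is `-log` of the probability at the true class, clamped at 1e-12.
#' @param probs probability vector.
#' @param target one-hot vector of the same length, or a single class
#'   index.
#' @return non-negative scalar loss.
#' @export
cross_entropy <- function(probs, target) {
  if (length(target) == 1) {
    i <- as.integer(target)
  } else {
    stopifnot(length(target) == length(probs), sum(target) == 1)
    i <- which(target == 1)
  }
  -log(max(probs[i], 1e-12))
}

# forward pass; x is (h, w, 1, N) scaled to [0,1]. When train=TRUE dropout
# masks are drawn from the current RNG stream and a cache is returned.
cnn_forward <- function(spec, params, x, train = FALSE) {
  if (dim(x)[1] != spec$input_size || dim(x)[2] != spec$input_size)
    stop("input patches are ", dim(x)[1], "x", dim(x)[2],
         " but the network expects ", spec$input_size, "x", spec$input_size)
  N <- dim(x)[4]
  cache <- list(a0 = x)
  a <- x
  for (i in seq_along(params$conv)) {
    z <- cpp_conv_fwd(a, params$conv[[i]]$w, params$conv[[i]]$b)
    r <- z
    r[r < 0] <- 0
    pl <- cpp_maxpool_fwd(r, spec$pool)
    cache[[paste0("z", i)]] <- z
    cache[[paste0("idx", i)]] <- pl$idx
    cache[[paste0("rdim", i)]] <- dim(r)
    cache[[paste0("in", i)]] <- a
    a <- pl$y
  }
  f <- matrix(a, spec$flat, N)
  p <- spec$dropout
  if (train && p > 0) {
    m7 <- matrix((runif(length(f)) >= p) / (1 - p), nrow(f), ncol(f))
    f <- f * m7
    cache$m7 <- m7
  }
  zf <- crossprod(params$fc$w, f) + params$fc$b
  hf <- zf
  hf[hf < 0] <- 0
  if (train && p > 0) {
    m9 <- matrix((runif(length(hf)) >= p) / (1 - p), nrow(hf), ncol(hf))
    hf <- hf * m9
    cache$m9 <- m9
  }
  scores <- crossprod(params$out$w, hf) + params$out$b   # n_classes x N
  cache$f <- f
  cache$zf <- zf
  cache$hf <- hf
  cache$pooled_dim <- dim(a)
  list(scores = scores, cache = if (train) cache else NULL,
       cache_eval = cache)
}

# softmax cross-entropy loss and full parameter gradients for a batch.
# y: integer class labels (1-based). Returns mean loss and grads.
cnn_loss_grads <- function(spec, params, x, y, cache = NULL) {
  N <- dim(x)[4]
  if (is.null(cache)) {
    fw <- cnn_forward(spec, params, x, train = FALSE)
    cache <- fw$cache_eval
    scores <- fw$scores
  } else {
    scores <- crossprod(params$out$w, cache$hf) + params$out$b
  }
  pr <- t(softmax(t(scores)))           # n x N
  loss <- mean(-log(pmax(pr[cbind(y, seq_len(N))], 1e-12)))
  dz <- pr
  dz[cbind(y, seq_len(N))] <- dz[cbind(y, seq_len(N))] - 1
  dz <- dz / N
  grads <- list(conv = vector("list", length(params$conv)))
  grads$out <- list(w = cache$hf %*% t(dz), b = rowSums(dz))
  dhf <- params$out$w %*% dz
  if (!is.null(cache$m9)) dhf <- dhf * cache$m9
  dzf <- dhf
  dzf[cache$zf <= 0] <- 0
  grads$fc <- list(w = cache$f %*% t(dzf), b = rowSums(dzf))
  df <- params$fc$w %*% dzf
  if (!is.null(cache$m7)) df <- df * cache$m7
  da <- array(df, cache$pooled_dim)
  for (i in rev(seq_along(params$conv))) {
    dr <- cpp_maxpool_bwd(da, cache[[paste0("idx", i)]],
                          as.integer(cache[[paste0("rdim", i)]]))
    dzc <- dr
    dzc[cache[[paste0("z", i)]] <= 0] <- 0
    bw <- cpp_conv_bwd(cache[[paste0("in", i)]], params$conv[[i]]$w, dzc)
    grads$conv[[i]] <- list(w = bw$dw, b = bw$db)
    if (i > 1) da <- bw$dx
  }
  list(loss = loss, grads = grads, probs = t(pr),
       pred = max.col(t(pr), ties.method = "first"))
}

#' Training configuration
#'
#' Defaults follow the published operating point: learning rate 0.01
#' (0.03 for faster decay), batch size 20, weight decay 0.01, 60 epochs.
#' Weight decay enters the loss as `0.5 * wd * ||W||^2` over weight
#' matrices (not biases).
#' @param lr learning rate (> 0).
#' @param batch_size mini-batch size (>= 1).
#' @param weight_decay L2 penalty coefficient.
#' @param epochs number of passes over the training set.
#' @param momentum SGD momentum (default 0 = plain SGD).
#' @param seed RNG seed driving initialization, shuffling and dropout.
#' @return `train_config` list.
#' @export
train_config <- function(lr = 0.01, batch_size = 20, weight_decay = 0.01,
                         epochs = 60, momentum = 0, seed = 42) {
  stopifnot(lr > 0, batch_size >= 1, epochs >= 1, momentum >= 0,
            momentum < 1)
  structure(list(lr = lr, batch_size = batch_size,
                 weight_decay = weight_decay, epochs = epochs,
                 momentum = momentum, seed = seed),
            class = "train_config")
}

# elementwise parameter update helpers
.map_params <- function(p, g, fn) {
  for (i in seq_along(p$conv)) {
    p$conv[[i]]$w <- fn(p$conv[[i]]$w, g$conv[[i]]$w, TRUE)
    p$conv[[i]]$b <- fn(p$conv[[i]]$b, g$conv[[i]]$b, FALSE)
  }
  p$fc$w <- fn(p$fc$w, g$fc$w, TRUE)
  p$fc$b <- fn(p$fc$b, g$fc$b, FALSE)
  p$out$w <- fn(p$out$w, g$out$w, TRUE)
  p$out$b <- fn(p$out$b, g$out$b, FALSE)
  p
}

#' Train the CNN with mini-batch SGD
#'
#' Minimizes mean softmax cross-entropy plus `0.5 * weight_decay * ||W||^2`
#' with inverted dropout. The history records, per epoch, the mean batch
#' loss and the running training error (1 - accuracy accumulated over the
#' epoch's batches). If the loss diverges to NaN training aborts and the
#' last finite-loss parameters are returned with a warning.
#'
#' @param x patch array `h x w x n`, intensities 0--255 (scaled to `[0,1]`
#'   internally).
#' @param y integer class labels (1-based).
#' @param spec a [network_spec()].
#' @param config a [train_config()].
#' @param verbose print per-epoch progress.
#' @return `rbc_cnn` model: `spec`, `params`, `config`, `history`
#'   (data.frame `epoch`, `loss`, `train_error`).
#' @export
train_cnn <- function(x, y, spec, config = train_config(), verbose = FALSE) {
  stopifnot(length(dim(x)) == 3, dim(x)[3] == length(y),
            max(y) <= spec$n_classes)
  n <- length(y)
  params <- init_params(spec, seed = config$seed)
  vel <- NULL
  history <- data.frame(epoch = integer(0), loss = numeric(0),
                        train_error = numeric(0))
  last_good <- params
  diverged <- FALSE
  with_local_seed(config$seed + 1L, {
    for (ep in seq_len(config$epochs)) {
      if (diverged) break
      ord <- sample(n)
      losses <- c()
      correct <- 0
      for (b0 in seq(1, n, by = config$batch_size)) {
        ids <- ord[b0:min(b0 + config$batch_size - 1, n)]
        xb <- array(x[, , ids, drop = FALSE] / 255,
                    c(dim(x)[1], dim(x)[2], 1, length(ids)))
        fw <- cnn_forward(spec, params, xb, train = TRUE)
        lg <- cnn_loss_grads(spec, params, xb, y[ids], cache = fw$cache)
        if (!is.finite(lg$loss)) {
          warning("loss diverged at epoch ", ep,
                  "; returning last good parameters")
          params <- last_good
          diverged <- TRUE
          break
        }
        losses <- c(losses, lg$loss)
        correct <- correct + sum(lg$pred == y[ids])
        wd <- config$weight_decay
        if (config$momentum > 0) {
          if (is.null(vel))
            vel <- .map_params(params, params, function(p, g, isw) p * 0)
          mu <- config$momentum
          vel <- local({
            v <- vel
            for (i in seq_along(v$conv)) {
              v$conv[[i]]$w <- mu * v$conv[[i]]$w -
                config$lr * (lg$grads$conv[[i]]$w + wd * params$conv[[i]]$w)
              v$conv[[i]]$b <- mu * v$conv[[i]]$b -
                config$lr * lg$grads$conv[[i]]$b
            }
            v$fc$w <- mu * v$fc$w - config$lr * (lg$grads$fc$w + wd * params$fc$w)
            v$fc$b <- mu * v$fc$b - config$lr * lg$grads$fc$b
            v$out$w <- mu * v$out$w - config$lr * (lg$grads$out$w + wd * params$out$w)
            v$out$b <- mu * v$out$b - config$lr * lg$grads$out$b
            v
          })
          params <- local({
            p <- params
            for (i in seq_along(p$conv)) {
              p$conv[[i]]$w <- p$conv[[i]]$w + vel$conv[[i]]$w
              p$conv[[i]]$b <- p$conv[[i]]$b + vel$conv[[i]]$b
            }
            p$fc$w <- p$fc$w + vel$fc$w
            p$fc$b <- p$fc$b + vel$fc$b
            p$out$w <- p$out$w + vel$out$w
            p$out$b <- p$out$b + vel$out$b
            p
          })
        } else {
          lr <- config$lr
          params <- local({
            p <- params
            for (i in seq_along(p$conv)) {
              p$conv[[i]]$w <- p$conv[[i]]$w -
                lr * (lg$grads$conv[[i]]$w + wd * p$conv[[i]]$w)
              p$conv[[i]]$b <- p$conv[[i]]$b - lr * lg$grads$conv[[i]]$b
            }
            p$fc$w <- p$fc$w - lr * (lg$grads$fc$w + wd * p$fc$w)
            p$fc$b <- p$fc$b - lr * lg$grads$fc$b
            p$out$w <- p$out$w - lr * (lg$grads$out$w + wd * p$out$w)
            p$out$b <- p$out$b - lr * lg$grads$out$b
            p
          })
        }
        last_good <- params
      }
      if (diverged) break
      history[nrow(history) + 1, ] <- list(ep, mean(losses),
                                           1 - correct / n)
      if (verbose)
        message(sprintf("epoch %d: loss %.4f, train error %.4f",
                        ep, mean(losses), 1 - correct / n))
    }
  })
  structure(list(spec = spec, params = params, config = config,
                 history = history),
            class = "rbc_cnn")
}

#' Predict labels and class probabilities for patches
#'
#' Deterministic evaluation mode (dropout off). Ties in the probability
#' vector resolve to the lowest class index; predictions are independent of
#' how items are batched.
#'
#' @param model an `rbc_cnn` from [train_cnn()].
#' @param x patch array `h x w x n` (0--255) or a single matrix.
#' @param batch_size evaluation batch size.
#' @return list: `labels` (integer), `probs` (matrix `n x n_classes`).
#' @export
predict_cnn <- function(model, x, batch_size = 128) {
  if (is.matrix(x)) x <- array(x, c(dim(x), 1))
  n <- dim(x)[3]
  probs <- matrix(0, n, model$spec$n_classes)
  for (b0 in seq(1, n, by = batch_size)) {
    ids <- b0:min(b0 + batch_size - 1, n)
    xb <- array(x[, , ids, drop = FALSE] / 255,
                c(dim(x)[1], dim(x)[2], 1, length(ids)))
    fw <- cnn_forward(model$spec, model$params, xb, train = FALSE)
    probs[ids, ] <- softmax(t(fw$scores))
  }
  list(labels = max.col(probs, ties.method = "first"), probs = probs)
}

#' Save / load a model checkpoint as JSON
#'
#' The checkpoint holds the architecture, training configuration and raw
#' weight arrays in a single versioned JSON file (text-only storage).
#' @param model an `rbc_cnn`.
#' @param path file path.
#' @return `load_model` returns the restored `rbc_cnn`.
#' @export
save_model <- function(model, path) {
  ser <- list(version = 1L,
              spec = unclass(model$spec),
              config = unclass(model$config),
              history = model$history,
              params = rapply(model$params, function(a)
                list(dim = dim(a), data = as.vector(a)), how = "list"))
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  ser <- jsonlite::read_json(path, simplifyVector = FALSE)
  num <- function(x) as.numeric(unlist(x))
  spec <- network_spec(n_classes = num(ser$spec$n_classes),
                       input_size = num(ser$spec$input_size),
                       conv_filters = num(ser$spec$conv_filters),
                       conv_kernels = num(ser$spec$conv_kernels),
                       pool = num(ser$spec$pool),
                       fc_units = num(ser$spec$fc_units),
                       dropout = num(ser$spec$dropout))
  config <- train_config(lr = num(ser$config$lr),
                         batch_size = num(ser$config$batch_size),
                         weight_decay = num(ser$config$weight_decay),
                         epochs = num(ser$config$epochs),
                         momentum = num(ser$config$momentum),
                         seed = num(ser$config$seed))
  restore <- function(x) {
    if (is.list(x) && "data" %in% names(x)) {
      v <- num(x$data)
      d <- unlist(x$dim)
      if (length(d) > 1) return(array(v, d))
      return(v)
    }
    lapply(x, restore)
  }
  params <- restore(ser$params)
  history <- do.call(rbind, lapply(ser$history, function(h)
    data.frame(epoch = num(h$epoch), loss = num(h$loss),
               train_error = num(h$train_error))))
  structure(list(spec = spec, params = params, config = config,
                 history = history),
            class = "rbc_cnn")
}
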