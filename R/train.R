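#' Training configuration
#'
#' Optimization hyperparameters for [train_mstnet()]. The defaults follow
#' the reference recipe: Adam, batch size 100, 150 epochs, initial learning
#' rate 0.01 decayed once every 5 epochs. The decay factor `gamma` and the
#' L2 coefficient `l2_lambda` have no published reference values; the
#' defaults 0.5 and 1e-4 are package choices and both are surfaced here.
#'
#' @param batch_size Segments per optimization step.
#' @param epochs Number of passes over the training set.
#' @param lr_base Initial learning rate.
#' @param gamma Learning-rate decay factor per block, see [lr_schedule()].
#' @param decay_every Epochs per decay block.
#' @param l2_lambda L2 weight-penalty coefficient, see [l2_penalty()].
#' @param beta1,beta2,eps Adam moment coefficients and stabilizer
#'   (conventional defaults).
#' @param val_frac Fraction of the training segments held out for the
#'   validation-loss curve (0 disables the hold-out).
#' @param init_output_bias Initialize the output-layer bias at the mean of
#'   the training labels so optimization starts at the label scale.
#' @param shuffle Reshuffle the training order every epoch.
#' @param recalibrate_bn After the final epoch, recompute the
#'   batch-normalization running statistics in one pass over the training
#'   set, so evaluation-mode statistics describe the final weights instead
#'   of lagging behind them ("precise" batch-norm).
#' @param seed Integer seed governing the hold-out split, shuffling, and
#'   (through [build_mstnet()] callers) initialization.
#' @return A `train_config` list.
#' @export
train_config <- function(batch_size = 100, epochs = 150, lr_base = 0.01,
                         gamma = 0.5, decay_every = 5, l2_lambda = 1e-4,
                         beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                         val_frac = 0.1, init_output_bias = TRUE,
                         shuffle = TRUE, recalibrate_bn = TRUE, seed = 1L) {
  stopifnot(batch_size >= 1, epochs >= 1, lr_base > 0,
            gamma > 0, gamma <= 1, l2_lambda >= 0,
            val_frac >= 0, val_frac < 1)
  structure(list(batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 lr_base = lr_base, gamma = gamma,
                 decay_every = as.integer(decay_every),
                 l2_lambda = l2_lambda, beta1 = beta1, beta2 = beta2,
                 eps = eps, val_frac = val_frac,
                 init_output_bias = isTRUE(init_output_bias),
                 shuffle = isTRUE(shuffle),
                 recalibrate_bn = isTRUE(recalibrate_bn),
                 seed = as.integer(seed)),
            class = "train_config")
}

# One full-set forward pass with unit batch-norm momentum: the running
# statistics become the exact statistics of the final weights.
.bn_refresh <- function(model, X) {
  for (nm in names(model$layers)) {
    if (identical(model$layers[[nm]]$type, "bn")) model$layers[[nm]]$mom <- 1
  }
  layers <- .mstnet_forward(model, X, training = TRUE)$layers
  for (nm in names(layers)) {
    if (identical(layers[[nm]]$type, "bn")) layers[[nm]]$mom <- 0.1
  }
  layers
}

.adam_init <- function(layers) {
  st <- list()
  for (nm in names(layers)) {
    ly <- layers[[nm]]
    pn <- switch(ly$type, conv = , dense = c("W", "b"),
                 bn = c("gamma", "beta"), NULL)
    if (is.null(pn)) next
    st[[nm]] <- lapply(stats::setNames(pn, pn), function(p) {
      list(m = 0 * ly[[p]], v = 0 * ly[[p]])
    })
  }
  st
}

#' Train the network with Adam
#'
#' Minimizes the joint multi-task MSE plus the L2 weight penalty with Adam,
#' shuffling segments every epoch under the run seed and applying the
#' stepped learning-rate schedule. The run is deterministic for a fixed
#' seed and single-threaded BLAS.
#'
#' @param model A freshly built (or partially trained) `mstnet`.
#' @param segments Non-empty list of `bp_segment` objects.
#' @param config A [train_config()].
#' @return An `mstbp_fit`: list with the trained `model` and a `history`
#'   data frame (one row per epoch: learning rate, mean training-batch loss,
#'   validation loss, wall-clock seconds). Training loss is the data term
#'   (mmHg^2); the L2 penalty enters the gradients but is reported
#'   separately via [l2_penalty()].
#' @export
train_mstnet <- function(model, segments, config = train_config()) {
  stopifnot(inherits(model, "mstnet"), inherits(config, "train_config"))
  if (!length(segments)) stop("empty training set", call. = FALSE)
  xy <- .segments_to_xy(segments)
  if (any(!is.finite(xy$Y))) stop("non-finite labels", call. = FALSE)
  n_all <- ncol(xy$X)

  set.seed(config$seed)
  val_idx <- integer(0)
  if (config$val_frac > 0) {
    n_val <- floor(config$val_frac * n_all)
    if (n_val >= 1 && n_val < n_all) val_idx <- sample.int(n_all, n_val)
  }
  tr_idx <- setdiff(seq_len(n_all), val_idx)

  if (config$init_output_bias) {
    model$layers$out_fc$b <- rowMeans(xy$Y[, tr_idx, drop = FALSE])
  }

  adam <- .adam_init(model$layers)
  step <- 0L
  history <- data.frame(epoch = integer(0), lr = numeric(0),
                        train_loss = numeric(0), val_loss = numeric(0),
                        seconds = numeric(0))

  for (epoch in seq_len(config$epochs)) {
    t0 <- proc.time()[["elapsed"]]
    lr <- lr_schedule(config$lr_base, config$gamma, epoch - 1L,
                      config$decay_every)
    order_idx <- if (config$shuffle) sample(tr_idx) else tr_idx
    batch_starts <- seq(1, length(order_idx), by = config$batch_size)
    batch_losses <- numeric(length(batch_starts))

    for (bi in seq_along(batch_starts)) {
      idx <- order_idx[batch_starts[bi]:
                         min(batch_starts[bi] + config$batch_size - 1L,
                             length(order_idx))]
      Xb <- xy$X[, idx, drop = FALSE]
      Yb <- xy$Y[, idx, drop = FALSE]
      fw <- .mstnet_forward(model, Xb, training = TRUE)
      model$layers <- fw$layers # batch-norm running stats
      loss <- sum((fw$scores - Yb)^2) / length(idx)
      if (!is.finite(loss)) {
        stop(sprintf("non-finite training loss at epoch %d (diverged); try a smaller learning rate",
                     epoch), call. = FALSE)
      }
      batch_losses[bi] <- loss
      dScores <- 2 * (fw$scores - Yb) / length(idx)
      grads <- .mstnet_backward(model, fw$cache, dScores)
      step <- step + 1L
      bc1 <- 1 - config$beta1^step
      bc2 <- 1 - config$beta2^step
      for (nm in names(grads)) {
        ly <- model$layers[[nm]]
        for (pn in names(grads[[nm]])) {
          g <- grads[[nm]][[pn]]
          if (config$l2_lambda > 0 && pn == "W" &&
              ly$type %in% c("conv", "dense")) {
            g <- g + 2 * config$l2_lambda * ly[[pn]]
          }
          st <- adam[[nm]][[pn]]
          st$m <- config$beta1 * st$m + (1 - config$beta1) * g
          st$v <- config$beta2 * st$v + (1 - config$beta2) * g * g
          ly[[pn]] <- ly[[pn]] -
            lr * (st$m / bc1) / (sqrt(st$v / bc2) + config$eps)
          adam[[nm]][[pn]] <- st
        }
        model$layers[[nm]] <- ly
      }
    }

    if (epoch == config$epochs && config$recalibrate_bn) {
      model$layers <- .bn_refresh(model, xy$X[, tr_idx, drop = FALSE])
    }
    val_loss <- NA_real_
    if (length(val_idx)) {
      sc <- .mstnet_forward(model, xy$X[, val_idx, drop = FALSE],
                            training = FALSE)$scores
      val_loss <- sum((sc - xy$Y[, val_idx, drop = FALSE])^2) / length(val_idx)
    }
    history <- rbind(history, data.frame(
      epoch = epoch, lr = lr, train_loss = mean(batch_losses),
      val_loss = val_loss, seconds = proc.time()[["elapsed"]] - t0
    ))
  }

  structure(list(model = model, history = history, config = config),
            class = "mstbp_fit")
}

#' @export
print.mstbp_fit <- function(x, ...) {
  h <- x$history
  cat(sprintf("<mstbp_fit> %d epochs; final train loss %.4g mmHg^2%s\n",
              nrow(h), h$train_loss[nrow(h)],
              if (is.finite(h$val_loss[nrow(h)])) {
                sprintf(", val loss %.4g", h$val_loss[nrow(h)])
              } else ""))
  invisible(x)
}

#' K-fold cross-validation split
#'
#' Randomly partitions `1..n` into `k` folds of near-equal size (differing
#' by at most one); each index appears in exactly one test fold.
#'
#' @param x Number of segments, or a list whose length is used.
#' @param k Number of folds.
#' @param seed Integer seed for the shuffle.
#' @return List of `k` elements, each `list(train = ..., test = ...)` of
#'   sorted integer indices.
#' @export
kfold_split <- function(x, k = 5, seed = 1L) {
  n <- if (is.list(x)) length(x) else as.integer(x)
  if (n < k) stop(sprintf("need at least k = %d items, got %d", k, n),
                  call. = FALSE)
  set.seed(as.integer(seed))
  shuffled <- sample.int(n)
  fold_of <- rep(seq_len(k), length.out = n)
  lapply(seq_len(k), function(f) {
    test <- sort(shuffled[fold_of == f])
    list(train = setdiff(seq_len(n), test), test = test)
  })
}

#' Five-fold cross-validation of the full estimator
#'
#' Trains a fresh network on each fold's training segments and evaluates on
#' the held-out fold; the averaged report is the unweighted mean of the
#' per-fold metrics. Splitting is at the segment level (an optional
#' subject-grouped split, stricter than the reference protocol, is available
#' via `group_by_subject`).
#'
#' @param segments List of `bp_segment` objects.
#' @param model_config An [mstnet_config()].
#' @param train_cfg A [train_config()].
#' @param k Number of folds.
#' @param seed Seed fanned out to the split, per-fold initialization, and
#'   training shuffles.
#' @param n_subjects Subject count passed to the AAMI check; defaults to
#'   the number of distinct source subjects in `segments`.
#' @param group_by_subject Keep all segments of a subject in the same fold.
#' @return An `mstbp_cv`: `folds` (list of `eval_report`), `average`
#'   (data frame of per-task metrics averaged over folds), `splits`.
#' @export
cross_validate <- function(segments, model_config, train_cfg, k = 5,
                           seed = 1L, n_subjects = NULL,
                           group_by_subject = FALSE) {
  stopifnot(length(segments) >= k)
  if (group_by_subject) {
    subj <- vapply(segments, function(s) s$source$subject_id, character(1))
    groups <- unique(subj)
    gsplit <- kfold_split(length(groups), k, seed)
    splits <- lapply(gsplit, function(sp) {
      test <- which(subj %in% groups[sp$test])
      list(train = setdiff(seq_along(segments), test), test = test)
    })
  } else {
    splits <- kfold_split(length(segments), k, seed)
  }
  reports <- vector("list", k)
  for (f in seq_len(k)) {
    cfg_f <- train_cfg
    cfg_f$seed <- as.integer(seed + f)
    model <- build_mstnet(model_config, seed = seed + f)
    fit <- train_mstnet(model, segments[splits[[f]]$train], cfg_f)
    reports[[f]] <- evaluate_model(fit$model, segments[splits[[f]]$test],
                                   n_subjects = n_subjects)
  }
  num_cols <- c("n", "r", "me", "mae", "sd", "cp5", "cp10", "cp15")
  avg <- reports[[1]]$metrics[, c("task", num_cols)]
  for (col in num_cols) {
    avg[[col]] <- rowMeans(vapply(reports, function(r) r$metrics[[col]],
                                  numeric(nrow(avg))))
  }
  structure(list(folds = reports, average = avg, splits = splits),
            class = "mstbp_cv")
}

#' @export
print.mstbp_cv <- function(x, ...) {
  cat(sprintf("<mstbp_cv> %d folds; averaged metrics:\n", length(x$folds)))
  print(x$average, row.names = FALSE, digits = 4)
  invisible(x)
}
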