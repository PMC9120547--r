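#' Architecture configuration of the multi-scale multi-task network
#'
#' Collects every architectural hyperparameter of the three-stream 1D CNN.
#' The defaults reproduce the reference architecture: a shared stem
#' (kernel-15 convolution, max-pool 3), three streams with kernel sizes 5,
#' 7 and 9, four modules of two convolutions per stream with a
#' 64/128/256/512 filter ladder, global average pooling, a 512-wide
#' fully-connected layer per stream (3 x 512 = 1536 concatenated features),
#' a 256-wide shared head, and a 3-neuron output emitting SBP, DBP and MAP
#' jointly.
#'
#' @param input_channels Number of input channels (ECG and PPG).
#' @param input_length Samples per segment (8 s at 125 Hz).
#' @param stem_filters Filter count of the shared stem convolution.
#' @param stem_kernel,stem_pool Stem kernel size and max-pool size (pooling
#'   is non-overlapping: stride equals the pool size).
#' @param stream_kernels Integer vector of per-stream kernel sizes; its
#'   length is the stream count.
#' @param modules_per_stream,convs_per_module Module grid of each stream.
#' @param module_filters Filter count per module
#'   (`length == modules_per_stream`).
#' @param module_stride Temporal stride of the first convolution of each
#'   module (later convolutions use stride 1 with same-length padding).
#' @param stream_fc Width of the per-stream fully-connected layer.
#' @param head_fc Width of the shared head layer.
#' @param outputs Output neurons; fixed at 3 (SBP, DBP, MAP).
#' @return An `mstnet_config` list.
#' @examples
#' cfg <- mstnet_config()
#' length(cfg$stream_kernels) * cfg$stream_fc # 1536 concatenated features
#' @export
mstnet_config <- function(input_channels = 2, input_length = 1000,
                          stem_filters = 32, stem_kernel = 15, stem_pool = 3,
                          stream_kernels = c(5, 7, 9),
                          modules_per_stream = 4, convs_per_module = 2,
                          module_filters = c(64, 128, 256, 512),
                          module_stride = 2,
                          stream_fc = 512, head_fc = 256, outputs = 3) {
  stopifnot(input_channels >= 1, input_length >= 1, stem_filters >= 1,
            length(stream_kernels) >= 1, modules_per_stream >= 1,
            convs_per_module >= 1, stream_fc >= 1, head_fc >= 1,
            module_stride >= 1)
  if (length(module_filters) != modules_per_stream) {
    stop("'module_filters' must have one entry per module", call. = FALSE)
  }
  if (outputs != 3) {
    stop("the network emits exactly the three tasks SBP, DBP, MAP", call. = FALSE)
  }
  structure(list(
    input_channels = as.integer(input_channels),
    input_length = as.integer(input_length),
    stem_filters = as.integer(stem_filters),
    stem_kernel = as.integer(stem_kernel),
    stem_pool = as.integer(stem_pool),
    stream_kernels = as.integer(stream_kernels),
    modules_per_stream = as.integer(modules_per_stream),
    convs_per_module = as.integer(convs_per_module),
    module_filters = as.integer(module_filters),
    module_stride = as.integer(module_stride),
    stream_fc = as.integer(stream_fc), head_fc = as.integer(head_fc),
    outputs = as.integer(outputs)
  ), class = "mstnet_config")
}

#' Build the multi-scale multi-task network
#'
#' Instantiates all layers with Kaiming (fan-in) initialization and records
#' a shape trace. Every convolution is followed by batch normalization and a
#' ReLU; each stream ends in global average pooling (temporal length 1) and
#' a `stream_fc`-wide fully-connected layer, the streams concatenate into
#' the shared head, and the output layer has three neurons.
#'
#' @param config An [mstnet_config()].
#' @param seed Optional integer seed for the weight initialization.
#' @return An `mstnet` model object; see [count_parameters()] and
#'   [predict.mstnet()].
#' @examples
#' m <- build_mstnet(mstnet_config(module_filters = c(8, 16, 32, 64),
#'                                 stream_fc = 64, head_fc = 64), seed = 1)
#' m$concat_width # 192
#' @export
build_mstnet <- function(config, seed = NULL) {
  stopifnot(inherits(config, "mstnet_config"))
  if (!is.null(seed)) set.seed(as.integer(seed))
  cf <- config
  layers <- list()
  trace <- data.frame(layer = character(0), channels = integer(0),
                      length = integer(0))
  note <- function(nm, C, L) {
    trace <<- rbind(trace, data.frame(layer = nm, channels = C, length = L))
  }
  note("input", cf$input_channels, cf$input_length)

  fail_short <- function(cond) {
    if (cond) {
      stop(sprintf(
        "input_length %d too short for the pooling/stride plan (needs >= %d)",
        cf$input_length, .min_input_length(cf)
      ), call. = FALSE)
    }
  }

  layers$stem_conv <- .make_conv(cf$input_channels, cf$stem_filters,
                                 cf$stem_kernel, 1L, cf$input_length)
  layers$stem_bn <- .make_bn(cf$stem_filters, layers$stem_conv$L_out)
  note("stem_conv", cf$stem_filters, layers$stem_conv$L_out)
  fail_short(layers$stem_conv$L_out < cf$stem_pool)
  pool <- .make_pool(cf$stem_pool, cf$stem_filters, layers$stem_conv$L_out)
  layers$stem_pool <- pool
  note("stem_pool", cf$stem_filters, pool$L_out)

  for (s in seq_along(cf$stream_kernels)) {
    K <- cf$stream_kernels[s]
    C <- cf$stem_filters
    L <- pool$L_out
    for (m in seq_len(cf$modules_per_stream)) {
      C_out <- cf$module_filters[m]
      for (q in seq_len(cf$convs_per_module)) {
        stride <- if (q == 1) cf$module_stride else 1L
        fail_short(.conv_out_len(L, K, stride, (K - 1) %/% 2) < 1)
        nm <- sprintf("s%d_m%d_c%d", s, m, q)
        cv <- .make_conv(C, C_out, K, as.integer(stride), L)
        layers[[paste0(nm, "_conv")]] <- cv
        layers[[paste0(nm, "_bn")]] <- .make_bn(C_out, cv$L_out)
        if (s == 1) note(nm, C_out, cv$L_out)
        C <- C_out
        L <- cv$L_out
      }
    }
    layers[[sprintf("s%d_fc", s)]] <- .make_dense(C, cf$stream_fc)
    if (s == 1) note("stream_gap_fc", cf$stream_fc, 1L)
  }
  concat_width <- length(cf$stream_kernels) * cf$stream_fc
  layers$head_fc <- .make_dense(concat_width, cf$head_fc)
  layers$out_fc <- .make_dense(cf$head_fc, cf$outputs, act_scale = 1)
  note("concat", concat_width, 1L)
  note("head_fc", cf$head_fc, 1L)
  note("output", cf$outputs, 1L)

  structure(list(config = cf, layers = layers, trace = trace,
                 concat_width = concat_width),
            class = "mstnet")
}

# Smallest input length for which the layer plan stays non-empty.
.min_input_length <- function(cf) {
  ok <- function(L) {
    L1 <- .conv_out_len(L, cf$stem_kernel, 1L, (cf$stem_kernel - 1) %/% 2)
    if (L1 < cf$stem_pool) return(FALSE)
    Lc <- L1 %/% cf$stem_pool
    for (m in seq_len(cf$modules_per_stream)) {
      for (q in seq_len(cf$convs_per_module)) {
        stride <- if (q == 1) cf$module_stride else 1L
        K <- max(cf$stream_kernels)
        Lc <- .conv_out_len(Lc, K, stride, (K - 1) %/% 2)
        if (Lc < 1) return(FALSE)
      }
    }
    TRUE
  }
  L <- 1L
  while (!ok(L)) L <- L + 1L
  L
}

#' @export
print.mstnet <- function(x, ...) {
  cat(sprintf("<mstnet> %d streams (kernels %s), %s parameters\n",
              length(x$config$stream_kernels),
              paste(x$config$stream_kernels, collapse = "/"),
              format(count_parameters(x), big.mark = ",")))
  print(x$trace, row.names = FALSE)
  invisible(x)
}

# Forward pass over the flat layer list. X: (C*L) x n. Returns scores 3 x n
# plus the per-layer caches and (in training mode) updated batch-norm state.
.mstnet_forward <- function(model, X, training = FALSE) {
  cf <- model$config
  ly <- model$layers
  cache <- list()

  fc <- .conv_forward(ly$stem_conv, X)
  cache$stem_conv <- fc$cache
  fb <- .bn_forward(ly$stem_bn, fc$out, training)
  cache$stem_bn <- fb$cache
  if (training) ly$stem_bn <- fb$layer
  fr <- .relu_forward(fb$out)
  cache$stem_relu <- fr$cache
  fp <- .pool_forward(ly$stem_pool, fr$out)
  cache$stem_pool <- fp$cache
  stem_out <- fp$out

  feats <- vector("list", length(cf$stream_kernels))
  for (s in seq_along(cf$stream_kernels)) {
    h <- stem_out
    for (m in seq_len(cf$modules_per_stream)) {
      for (q in seq_len(cf$convs_per_module)) {
        nm <- sprintf("s%d_m%d_c%d", s, m, q)
        fc <- .conv_forward(ly[[paste0(nm, "_conv")]], h)
        cache[[paste0(nm, "_conv")]] <- fc$cache
        fb <- .bn_forward(ly[[paste0(nm, "_bn")]], fc$out, training)
        cache[[paste0(nm, "_bn")]] <- fb$cache
        if (training) ly[[paste0(nm, "_bn")]] <- fb$layer
        fr <- .relu_forward(fb$out)
        cache[[paste0(nm, "_relu")]] <- fr$cache
        h <- fr$out
      }
    }
    last <- ly[[sprintf("s%d_m%d_c%d_conv", s, cf$modules_per_stream,
                        cf$convs_per_module)]]
    fg <- .gap_forward(h, last$L_out, last$C_out)
    cache[[sprintf("s%d_gap", s)]] <- list(L = last$L_out, C = last$C_out,
                                           n = fg$cache)
    fd <- .dense_forward(ly[[sprintf("s%d_fc", s)]], fg$out)
    cache[[sprintf("s%d_fc", s)]] <- fd$cache
    fr <- .relu_forward(fd$out)
    cache[[sprintf("s%d_fc_relu", s)]] <- fr$cache
    feats[[s]] <- fr$out
  }
  concat <- do.call(rbind, feats)

  fd <- .dense_forward(ly$head_fc, concat)
  cache$head_fc <- fd$cache
  fr <- .relu_forward(fd$out)
  cache$head_relu <- fr$cache
  fo <- .dense_forward(ly$out_fc, fr$out)
  cache$out_fc <- fo$cache

  list(scores = fo$out, cache = cache, layers = ly, concat_width = nrow(concat))
}

# Backward pass; dScores: outputs x n. Returns named list of gradients
# parallel to the parameterized layers.
.mstnet_backward <- function(model, cache, dScores) {
  cf <- model$config
  ly <- model$layers
  grads <- list()

  bo <- .dense_backward(ly$out_fc, cache$out_fc, dScores)
  grads$out_fc <- bo$grads
  dh <- .relu_backward(cache$head_relu, bo$dX)
  bh <- .dense_backward(ly$head_fc, cache$head_fc, dh)
  grads$head_fc <- bh$grads
  dconcat <- bh$dX

  d_stem <- NULL
  for (s in seq_along(cf$stream_kernels)) {
    rows <- ((s - 1) * cf$stream_fc + 1):(s * cf$stream_fc)
    dfeat <- dconcat[rows, , drop = FALSE]
    dfeat <- .relu_backward(cache[[sprintf("s%d_fc_relu", s)]], dfeat)
    bd <- .dense_backward(ly[[sprintf("s%d_fc", s)]],
                          cache[[sprintf("s%d_fc", s)]], dfeat)
    grads[[sprintf("s%d_fc", s)]] <- bd$grads
    gp <- cache[[sprintf("s%d_gap", s)]]
    dh <- .gap_backward(bd$dX, gp$L, gp$C, gp$n)
    for (m in rev(seq_len(cf$modules_per_stream))) {
      for (q in rev(seq_len(cf$convs_per_module))) {
        nm <- sprintf("s%d_m%d_c%d", s, m, q)
        dh <- .relu_backward(cache[[paste0(nm, "_relu")]], dh)
        bb <- .bn_backward(ly[[paste0(nm, "_bn")]],
                           cache[[paste0(nm, "_bn")]], dh)
        grads[[paste0(nm, "_bn")]] <- bb$grads
        bc <- .conv_backward(ly[[paste0(nm, "_conv")]],
                             cache[[paste0(nm, "_conv")]], bb$dX)
        grads[[paste0(nm, "_conv")]] <- bc$grads
        dh <- bc$dX
      }
    }
    d_stem <- if (is.null(d_stem)) dh else d_stem + dh
  }

  dp <- .pool_backward(ly$stem_pool, cache$stem_pool, d_stem)
  dr <- .relu_backward(cache$stem_relu, dp$dX)
  bb <- .bn_backward(ly$stem_bn, cache$stem_bn, dr)
  grads$stem_bn <- bb$grads
  bc <- .conv_backward(ly$stem_conv, cache$stem_conv, bb$dX)
  grads$stem_conv <- bc$grads
  grads
}

# Convert a list of bp_segment to the internal (C*L) x n layout and 3 x n
# label matrix.
.segments_to_xy <- function(segments) {
  stopifnot(length(segments) >= 1)
  X <- vapply(segments, function(s) as.vector(t(s$x)), numeric(length(segments[[1]]$x)))
  Y <- vapply(segments, function(s) c(s$labels$sbp, s$labels$dbp, s$labels$map),
              numeric(3))
  list(X = matrix(X, ncol = length(segments)),
       Y = matrix(Y, nrow = 3))
}

#' Predict blood pressure for segments
#'
#' Runs the network forward in evaluation mode (batch normalization uses its
#' running statistics). The three tasks are emitted simultaneously by one
#' pass.
#'
#' @param object A built (and usually trained) `mstnet`.
#' @param segments List of `bp_segment` objects, or a single 2 x L input
#'   matrix (rows ECG, PPG), or a pre-assembled `(C*L) x n` matrix.
#' @param ... Unused.
#' @return An n x 3 matrix with columns `sbp`, `dbp`, `map` (mmHg).
#' @export
predict.mstnet <- function(object, segments, ...) {
  cf <- object$config
  X <- if (is.list(segments)) {
    .segments_to_xy(segments)$X
  } else if (is.matrix(segments) &&
             nrow(segments) == cf$input_channels &&
             ncol(segments) == cf$input_length) {
    matrix(as.vector(t(segments)), ncol = 1)
  } else if (is.matrix(segments) &&
             nrow(segments) == cf$input_channels * cf$input_length) {
    segments
  } else {
    stop(sprintf("expected segments with %d channels of %d samples",
                 cf$input_channels, cf$input_length), call. = FALSE)
  }
  out <- t(.mstnet_forward(object, X, training = FALSE)$scores)
  colnames(out) <- c("sbp", "dbp", "map")
  out
}

#' Joint multi-task mean squared error
#'
#' The training loss: the mean over segments of the summed squared errors of
#' the three tasks,
#' `(1/n) * sum_i [(sbp_i - sbp'_i)^2 + (dbp_i - dbp'_i)^2 + (map_i - map'_i)^2]`,
#' in mmHg^2. Zero exactly when the predictions equal the references.
#'
#' @param pred,ref n x 3 matrices (or length-3 vectors) of predictions and
#'   reference labels.
#' @return Non-negative scalar.
#' @examples
#' multitask_mse(c(121, 81, 95), c(120, 80, 94)) # 3
#' @export
multitask_mse <- function(pred, ref) {
  if (is.vector(pred)) pred <- matrix(pred, nrow = 1)
  if (is.vector(ref)) ref <- matrix(ref, nrow = 1)
  if (!all(dim(pred) == dim(ref)) || ncol(pred) != 3) {
    stop("'pred' and 'ref' must both be n x 3", call. = FALSE)
  }
  sum((pred - ref)^2) / nrow(pred)
}

#' L2 weight penalty
#'
#' `lambda * sum(w^2)` over the convolution and fully-connected weight
#' matrices. Biases and batch-normalization scale/shift parameters are
#' excluded: the penalty constrains the mapping's weights, and shrinking
#' normalization statistics is not a regularization of model complexity.
#'
#' @param model An `mstnet`.
#' @param l2_lambda Non-negative coefficient.
#' @return Scalar penalty added to the training loss.
#' @export
l2_penalty <- function(model, l2_lambda) {
  stopifnot(inherits(model, "mstnet"))
  if (l2_lambda < 0) stop("'l2_lambda' must be >= 0", call. = FALSE)
  if (l2_lambda == 0) return(0)
  ssq <- 0
  for (ly in model$layers) {
    if (ly$type %in% c("conv", "dense")) ssq <- ssq + sum(ly$W^2)
  }
  l2_lambda * ssq
}

#' Stepped learning-rate decay
#'
#' `lr = lr_base * gamma^floor(epoch / decay_every)`: the learning rate is
#' constant within each block of `decay_every` epochs and decays by the
#' factor `gamma` between blocks.
#'
#' @param lr_base Initial learning rate (0.01 in the reference training
#'   recipe).
#' @param gamma Decay factor in (0, 1].
#' @param epoch Zero-based epoch counter.
#' @param decay_every Block length in epochs.
#' @return The learning rate for `epoch`.
#' @examples
#' lr_schedule(0.01, 0.1, 5) # 0.001
#' @export
lr_schedule <- function(lr_base, gamma, epoch, decay_every = 5) {
  if (any(epoch < 0)) stop("'epoch' must be >= 0", call. = FALSE)
  if (gamma <= 0 || gamma > 1) stop("'gamma' must lie in (0, 1]", call. = FALSE)
  lr_base * gamma^(epoch %/% decay_every)
}

#' Count trainable parameters
#'
#' Total number of trainable scalars (convolution and dense weights and
#' biases, batch-normalization scales and shifts). The per-layer shape trace
#' is attached as attribute `"trace"`.
#'
#' @param model An `mstnet`.
#' @return Integer count.
#' @export
count_parameters <- function(model) {
  stopifnot(inherits(model, "mstnet"))
  total <- 0
  for (ly in model$layers) {
    total <- total + switch(ly$type,
      conv = length(ly$W) + length(ly$b),
      dense = length(ly$W) + length(ly$b),
      bn = length(ly$gamma) + length(ly$beta),
      0
    )
  }
  structure(as.integer(total), trace = model$trace)
}
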