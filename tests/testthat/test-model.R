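test_that("default architecture: 3-wide output and 1536-wide concatenation", {
  m <- build_mstnet(mstnet_config(), seed = 1)
  X <- matrix(stats::rnorm(2 * 1000 * 4), ncol = 4)
  fw <- mstbp:::.mstnet_forward(m, X, training = FALSE)
  expect_identical(dim(fw$scores), c(3L, 4L))
  expect_true(all(is.finite(fw$scores)))
  expect_identical(fw$concat_width, 1536L)
  expect_identical(m$concat_width, 3L * 512L)
  tr <- m$trace
  expect_identical(tr$channels[tr$layer == "concat"], 1536L)
  expect_identical(tr$channels[tr$layer == "output"], 3L)
})

test_that("concat width scales as streams x stream_fc across configs", {
  cfgs <- list(
    mstnet_config(module_filters = c(8, 16, 32, 64), stream_fc = 64),
    mstnet_config(stream_kernels = c(7), module_filters = c(8, 16, 32, 64),
                  stream_fc = 32),
    tiny_config()
  )
  for (cfg in cfgs) {
    m <- build_mstnet(cfg, seed = 2)
    n <- 2L
    fw <- mstbp:::.mstnet_forward(m, matrix(stats::rnorm(2 * cfg$input_length * n),
                                            ncol = n))
    expect_identical(fw$concat_width,
                     length(cfg$stream_kernels) * as.integer(cfg$stream_fc))
    expect_identical(dim(fw$scores), c(3L, n))
  }
  expect_identical(build_mstnet(mstnet_config(module_filters = c(8, 16, 32, 64),
                                              stream_fc = 64), seed = 1)$concat_width,
                   192L)
})

test_that("config invariants are enforced", {
  expect_error(mstnet_config(module_filters = c(64, 128)), "one entry per module")
  expect_error(mstnet_config(outputs = 2), "three tasks")
  expect_error(build_mstnet(mstnet_config(input_length = 2)), "too short")
})

test_that("evaluation-mode forward is deterministic and row-consistent", {
  m <- build_mstnet(tiny_config(), seed = 3)
  x1 <- stats::rnorm(2000)
  X <- cbind(x1, stats::rnorm(2000), x1)
  p <- predict(m, X)
  expect_identical(dim(p), c(3L, 3L))
  expect_identical(colnames(p), c("sbp", "dbp", "map"))
  expect_identical(p[1, ], p[3, ]) # identical inputs -> identical rows
  expect_identical(predict(m, X), p)
  expect_error(predict(m, matrix(0, 5, 7)), "expected segments")
})

test_that("multitask loss matches its definition and a loop oracle", {
  expect_identical(multitask_mse(c(120, 80, 93), c(120, 80, 93)), 0)
  expect_equal(multitask_mse(c(121, 81, 94), c(120, 80, 93)), 3)
  pred <- rbind(c(1, 0, 0), c(0, 2, 0)) + 100
  ref <- matrix(100, 2, 3)
  expect_equal(multitask_mse(pred, ref), (1 + 4) / 2)
  set.seed(4)
  P <- matrix(stats::runif(30, 60, 180), 10, 3)
  Y <- matrix(stats::runif(30, 60, 180), 10, 3)
  oracle <- 0
  for (i in 1:10) {
    for (j in 1:3) oracle <- oracle + (P[i, j] - Y[i, j])^2
  }
  expect_equal(multitask_mse(P, Y), oracle / 10, tolerance = 1e-12)
  expect_error(multitask_mse(P, Y[1:5, ]), "n x 3")
})

test_that("L2 penalty covers exactly the conv/dense weights", {
  m <- build_mstnet(tiny_config(), seed = 5)
  expect_identical(l2_penalty(m, 0), 0)
  ssq <- 0
  for (ly in m$layers) {
    if (!is.null(ly$type) && ly$type %in% c("conv", "dense")) {
      ssq <- ssq + sum(ly$W^2)
    }
  }
  expect_equal(l2_penalty(m, 0.5), 0.5 * ssq, tolerance = 1e-12)
  # monotone in |w|: growing one weight grows the penalty
  m2 <- m
  m2$layers$head_fc$W[1] <- m2$layers$head_fc$W[1] + 10
  expect_gt(l2_penalty(m2, 1e-4), l2_penalty(m, 1e-4))
  expect_error(l2_penalty(m, -1), ">= 0")
})

test_that("learning-rate schedule decays once per 5-epoch block", {
  expect_equal(lr_schedule(0.01, 0.1, 0), 0.01)
  expect_equal(lr_schedule(0.01, 0.1, 4), 0.01)
  expect_equal(lr_schedule(0.01, 0.1, 5), 0.001)
  expect_equal(lr_schedule(0.01, 0.5, 12), 0.01 * 0.5^2)
  expect_equal(lr_schedule(0.01, 1, 137), 0.01)
  expect_error(lr_schedule(0.01, 0.5, -1), ">= 0")
  expect_error(lr_schedule(0.01, 1.5, 0), "gamma")
})

test_that("parameter count matches closed forms and is monotone in width", {
  # a single dense layer has out*in + out parameters
  d <- mstbp:::.make_dense(1536, 256)
  expect_identical(length(d$W) + length(d$b), 1536L * 256L + 256L)
  m1 <- build_mstnet(mstnet_config(module_filters = c(8, 16, 32, 64),
                                   stream_fc = 64), seed = 1)
  m2 <- build_mstnet(mstnet_config(module_filters = c(8, 16, 32, 64),
                                   stream_fc = 128), seed = 1)
  expect_gt(as.integer(count_parameters(m2)), as.integer(count_parameters(m1)))
  expect_s3_class(attr(count_parameters(m1), "trace"), "data.frame")
})

test_that("network gradients agree with finite differences", {
  cfg <- mstnet_config(input_length = 64, stem_filters = 3, stem_kernel = 5,
                       stream_kernels = c(3, 5), modules_per_stream = 2,
                       module_filters = c(4, 6), stream_fc = 5, head_fc = 4)
  set.seed(7)
  m <- build_mstnet(cfg, seed = 7)
  X <- matrix(stats::rnorm(2 * 64 * 3), ncol = 3)
  Y <- matrix(stats::runif(9, 60, 180), 3, 3)
  loss_fn <- function(model) {
    sc <- mstbp:::.mstnet_forward(model, X, training = TRUE)$scores
    sum((sc - Y)^2) / ncol(X)
  }
  fw <- mstbp:::.mstnet_forward(m, X, training = TRUE)
  grads <- mstbp:::.mstnet_backward(m, fw$cache, 2 * (fw$scores - Y) / ncol(X))
  eps <- 1e-6
  for (nm in names(grads)) {
    for (pn in names(grads[[nm]])) {
      i <- sample(length(m$layers[[nm]][[pn]]), 1)
      mp <- m; mp$layers[[nm]][[pn]][i] <- mp$layers[[nm]][[pn]][i] + eps
      mn <- m; mn$layers[[nm]][[pn]][i] <- mn$layers[[nm]][[pn]][i] - eps
      num <- (loss_fn(mp) - loss_fn(mn)) / (2 * eps)
      expect_equal(grads[[nm]][[pn]][i], num, tolerance = 1e-3,
                   label = sprintf("grad %s$%s", nm, pn))
    }
  }
})

test_that("ReLU zeroes negative pre-activations exactly", {
  r <- mstbp:::.relu_forward(matrix(c(-2, -0.1, 0, 0.1, 2), 1))
  expect_identical(r$out, matrix(c(0, 0, 0, 0.1, 2), 1))
})
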