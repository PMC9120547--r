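# Brute-force loop oracles, intentionally independent of the vectorized
# implementations.
oracle_metrics <- function(y, z) {
  n <- length(y)
  me <- 0; mae_v <- 0
  for (i in seq_len(n)) {
    me <- me + (y[i] - z[i]) / n
    mae_v <- mae_v + abs(z[i] - y[i]) / n
  }
  dbar <- 0
  for (i in seq_len(n)) dbar <- dbar + (z[i] - y[i]) / n
  ssd <- 0
  for (i in seq_len(n)) ssd <- ssd + (z[i] - y[i] - dbar)^2
  ybar <- sum(y) / n; zbar <- sum(z) / n
  num <- 0; dy <- 0; dz <- 0
  for (i in seq_len(n)) {
    num <- num + (z[i] - zbar) * (y[i] - ybar)
    dy <- dy + (y[i] - ybar)^2
    dz <- dz + (z[i] - zbar)^2
  }
  list(me = me, mae = mae_v, sd = sqrt(ssd / (n - 1)), r = num / sqrt(dy * dz))
}

oracle_cp <- function(abs_err, thr) {
  cnt <- 0
  for (e in abs_err) if (e <= thr) cnt <- cnt + 1
  100 * cnt / length(abs_err)
}

test_that("closed-form metric cases behave as defined", {
  expect_identical(mean_error(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(mean_error(c(100, 100), c(98, 104)), -1)
  expect_equal(mean_error(c(98, 104), c(100, 100)), 1) # antisymmetry
  y <- c(100, 110, 120)
  expect_equal(mae(y, y + 3), 3)
  expect_equal(error_sd(y, y + 3), 0)
  expect_equal(pearson_r(y, y + 3), 1)
  expect_equal(pearson_r(y, -y), -1)
  expect_error(pearson_r(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_error(mae(1:3, 1:4), "mismatch")
  expect_error(error_sd(1, 1), "at least 2")
})

test_that("metrics and cumulative percentages match loop oracles over many draws", {
  set.seed(2024)
  for (trial in 1:200) {
    n <- sample(2:40, 1)
    y <- stats::runif(n, 60, 180)
    z <- y + stats::rnorm(n, sd = stats::runif(1, 0.1, 15))
    o <- oracle_metrics(y, z)
    expect_equal(mean_error(y, z), o$me, tolerance = 1e-12)
    expect_equal(mae(y, z), o$mae, tolerance = 1e-12)
    expect_equal(error_sd(y, z), o$sd, tolerance = 1e-12)
    expect_equal(pearson_r(y, z), o$r, tolerance = 1e-12)
    e <- abs(z - y)
    bh <- bhs_grade(e)
    for (thr in c(5, 10, 15)) {
      expect_equal(bh$cp[[as.character(thr)]], oracle_cp(e, thr),
                   tolerance = 1e-12)
    }
    # invariants: mae >= |me|; cumulative percentages non-decreasing
    expect_gte(mae(y, z) + 1e-12, abs(mean_error(y, z)))
    expect_true(all(diff(bh$cp) >= 0))
  }
})

test_that("literal printed SD variant differs by double-counting the bias", {
  y <- c(100, 120, 140)
  z <- y + c(4, 6, 8) # constant bias 6 plus spread
  d <- z - y
  expect_equal(error_sd(y, z), stats::sd(d), tolerance = 1e-12)
  expect_equal(error_sd(y, z, literal = TRUE),
               sqrt(sum((d - mean(y - z))^2) / 2), tolerance = 1e-12)
  expect_gt(error_sd(y, z, literal = TRUE), error_sd(y, z))
})

test_that("AAMI verdicts respect the published thresholds inclusively", {
  expect_true(aami_check(0.007, 5.81, 514)$pass)
  expect_false(aami_check(5.1, 7, 100)$pass)
  expect_true(aami_check(0, 8.0, 85)$pass) # bounds inclusive
  expect_true(aami_check(-5, 8, 85)$pass)
  expect_false(aami_check(0, 8.01, 500)$pass)
  expect_false(aami_check(0, 5, 84)$pass)
  m <- aami_check(1, 6, 100)$margins
  expect_equal(unname(m), c(4, 2, 15))
  # monotonicity in each argument
  expect_true(aami_check(2, 6, 100)$pass)
  expect_false(aami_check(6, 6, 100)$pass)
})

test_that("BHS grading matches the published table on constructed vectors", {
  a <- bhs_grade(rep(0, 100))
  expect_identical(a$grade, "A")
  expect_equal(unname(a$cp), c(100, 100, 100))

  b <- bhs_grade(c(rep(4, 59), rep(9, 30), rep(14, 10), 20))
  expect_equal(unname(b$cp), c(59, 89, 99))
  expect_identical(b$grade, "B") # fails A at 5 mmHg (59 < 60), meets B

  d <- bhs_grade(rep(16, 100))
  expect_equal(unname(d$cp), c(0, 0, 0))
  expect_identical(d$grade, "D")
  expect_error(bhs_grade(numeric(0)), "empty")
})

test_that("improving any single error never lowers the BHS grade", {
  set.seed(31)
  grade_rank <- c(A = 4, B = 3, C = 2, D = 1)
  for (trial in 1:40) {
    e <- stats::runif(50, 0, 20)
    g0 <- grade_rank[[bhs_grade(e)$grade]]
    i <- sample(50, 1)
    e[i] <- e[i] * stats::runif(1)
    expect_gte(grade_rank[[bhs_grade(e)$grade]], g0)
  }
})

test_that("Bland-Altman limits behave as defined and cover ~95% of Gaussian errors", {
  y <- c(100, 110, 120, 130)
  expect_equal(bland_altman(y, y)[c("mean_diff", "lower", "upper")],
               list(mean_diff = 0, lower = 0, upper = 0))
  ba0 <- bland_altman(c(100, 100, 120, 120), c(102, 98, 122, 118))
  expect_equal(ba0$mean_diff, 0)
  set.seed(77)
  yy <- stats::runif(10000, 80, 180)
  zz <- yy + stats::rnorm(10000, sd = 5)
  ba <- bland_altman(yy, zz)
  expect_equal(ba$fraction_within, 0.95, tolerance = 0.01)
  expect_equal(ba$upper - ba$lower, 2 * 1.96 * stats::sd(zz - yy),
               tolerance = 1e-12)
})

test_that("evaluate_model composes the standalone metrics and serializes", {
  segs <- make_segments(6, seed = 41)
  m <- build_mstnet(tiny_config(), seed = 2)
  rep <- evaluate_model(m, segs, n_subjects = 90)
  Y <- t(mstbp:::.segments_to_xy(segs)$Y)
  Z <- predict(m, segs)
  for (i in 1:3) {
    expect_equal(rep$metrics$me[i], mean_error(Y[, i], Z[, i]), tolerance = 1e-12)
    expect_equal(rep$metrics$mae[i], mae(Y[, i], Z[, i]), tolerance = 1e-12)
    expect_equal(rep$metrics$sd[i], error_sd(Y[, i], Z[, i]), tolerance = 1e-12)
    expect_equal(rep$metrics$aami_pass[i],
                 aami_check(rep$metrics$me[i], rep$metrics$sd[i], 90)$pass)
  }
  expect_identical(rep$metrics$n, rep(length(segs), 3L))
  # histograms cover [-20, 20] in 1-mmHg bins
  expect_identical(nrow(rep$histograms$sbp), 40L)
  # serialization produces the expected files
  dir <- withr::local_tempdir()
  write_eval_report(rep, dir)
  expect_true(all(file.exists(file.path(dir, c("report.csv", "report.txt",
                                               "hist_sbp.csv")))))

  # a perfect (stubbed) estimator: zero errors, grade A
  rep2 <- mstbp:::.build_report(Y, Y, n_subjects = 90)
  expect_true(all(rep2$metrics$mae == 0))
  expect_true(all(rep2$metrics$sd == 0))
  expect_true(all(rep2$metrics$bhs_grade == "A"))
  expect_true(all(rep2$metrics$aami_pass))
  expect_true(rep2$aami_pass)
})
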