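#' Mean error (reference minus estimate)
#'
#' `ME = sum(y_i - z_i) / n`, the signed bias of the estimates relative to
#' the reference values. Note the orientation: a positive ME means the
#' estimates run low.
#'
#' @param ref,est Equal-length non-empty numeric vectors (mmHg).
#' @return Scalar ME in mmHg.
#' @export
mean_error <- function(ref, est) {
  .check_pair(ref, est, min_n = 1)
  mean(ref - est)
}

#' Mean absolute error
#'
#' `MAE = sum(|z_i - y_i|) / n`.
#'
#' @inheritParams mean_error
#' @return Scalar MAE in mmHg.
#' @export
mae <- function(ref, est) {
  .check_pair(ref, est, min_n = 1)
  mean(abs(est - ref))
}

#' Standard deviation of the estimation errors
#'
#' The sample standard deviation (n - 1 denominator) of the signed
#' differences `z_i - y_i` about their own mean — the dispersion term used
#' in device-validation tables and Bland-Altman limits. The printed
#' reference formula subtracts the oppositely-signed ME from `z_i - y_i`;
#' that literal variant (which double-counts the bias) is available with
#' `literal = TRUE` for audit.
#'
#' @inheritParams mean_error
#' @param literal Use the literal printed formula instead of centring the
#'   differences on their own mean.
#' @return Scalar SD in mmHg.
#' @export
error_sd <- function(ref, est, literal = FALSE) {
  .check_pair(ref, est, min_n = 2)
  d <- est - ref
  centre <- if (literal) mean(ref - est) else mean(d)
  sqrt(sum((d - centre)^2) / (length(d) - 1))
}

#' Pearson correlation between reference and estimated values
#'
#' The product-moment correlation of the centred vectors:
#' `sum((z - mean(z)) * (y - mean(y)))` divided by the root of the product
#' of their summed squares.
#'
#' @inheritParams mean_error
#' @return Scalar in \[-1, 1\].
#' @export
pearson_r <- function(ref, est) {
  .check_pair(ref, est, min_n = 2)
  yc <- ref - mean(ref)
  zc <- est - mean(est)
  den <- sqrt(sum(yc^2) * sum(zc^2))
  if (den == 0) stop("correlation undefined for a constant vector", call. = FALSE)
  sum(zc * yc) / den
}

.check_pair <- function(ref, est, min_n) {
  if (length(ref) != length(est)) stop("length mismatch", call. = FALSE)
  if (length(ref) < min_n) {
    stop(sprintf("need at least %d paired values", min_n), call. = FALSE)
  }
  invisible(NULL)
}

#' AAMI device-validation check
#'
#' Passes when the absolute mean error is at most 5 mmHg, the error SD is
#' at most 8 mmHg, and at least 85 subjects contributed — all bounds
#' inclusive, as the standard prints them.
#'
#' @param me Mean error in mmHg.
#' @param sd Error standard deviation in mmHg.
#' @param n_subjects Number of subjects.
#' @return List with `pass` and the per-criterion `margins` (positive =
#'   satisfied, with room to spare).
#' @examples
#' aami_check(0.007, 5.81, 514)$pass
#' @export
aami_check <- function(me, sd, n_subjects) {
  stopifnot(is.finite(me), is.finite(sd), is.finite(n_subjects))
  margins <- c(me = 5 - abs(me), sd = 8 - sd, subjects = n_subjects - 85)
  list(pass = all(margins >= 0), margins = margins)
}

#' BHS grading of absolute errors
#'
#' Cumulative percentages of absolute errors within 5, 10 and 15 mmHg,
#' graded A/B/C against the published thresholds (a grade requires all
#' three of its thresholds); anything below grade C is reported as D.
#'
#' @param abs_errors Non-empty vector of absolute errors in mmHg.
#' @return List with `cp` (named percentages at 5/10/15 mmHg) and `grade`.
#' @examples
#' bhs_grade(rep(0, 10))$grade # "A"
#' @export
bhs_grade <- function(abs_errors) {
  if (!length(abs_errors)) stop("empty error vector", call. = FALSE)
  if (any(abs_errors < 0)) stop("absolute errors must be >= 0", call. = FALSE)
  cp <- 100 * c(`5` = mean(abs_errors <= 5), `10` = mean(abs_errors <= 10),
                `15` = mean(abs_errors <= 15))
  thresholds <- list(A = c(60, 85, 95), B = c(50, 75, 90), C = c(40, 65, 80))
  grade <- "D"
  for (g in c("A", "B", "C")) {
    if (all(cp >= thresholds[[g]])) { grade <- g; break }
  }
  list(cp = cp, grade = grade)
}

#' Bland-Altman agreement summary
#'
#' Differences `d_i = z_i - y_i`; reports their mean, the 95% limits of
#' agreement `mean(d) +/- 1.96 * sd(d)`, and the fraction of points inside
#' the limits.
#'
#' @inheritParams mean_error
#' @return List with `mean_diff`, `lower`, `upper`, `fraction_within`.
#' @export
bland_altman <- function(ref, est) {
  .check_pair(ref, est, min_n = 2)
  d <- est - ref
  m <- mean(d)
  s <- sqrt(sum((d - m)^2) / (length(d) - 1))
  lower <- m - 1.96 * s
  upper <- m + 1.96 * s
  list(mean_diff = m, lower = lower, upper = upper,
       fraction_within = mean(d >= lower & d <= upper))
}

#' Evaluate a trained model on test segments
#'
#' Runs the network in evaluation mode and assembles, per task (SBP, DBP,
#' MAP): Pearson r, ME, MAE, error SD, the BHS cumulative percentages and
#' grade, the AAMI verdict, a Bland-Altman summary, and an error histogram
#' (1-mmHg bins over \[-20, 20\] mmHg). The correlation is reported as `NA`
#' when either vector is constant (e.g. a perfect or degenerate estimator).
#'
#' @param model A trained `mstnet`.
#' @param segments Non-empty list of `bp_segment` test objects.
#' @param n_subjects Subject count for the AAMI check; defaults to the
#'   number of distinct source subjects in `segments`.
#' @return An `eval_report`.
#' @export
evaluate_model <- function(model, segments, n_subjects = NULL) {
  stopifnot(inherits(model, "mstnet"))
  if (!length(segments)) stop("empty test set", call. = FALSE)
  Z <- predict(model, segments)
  Y <- t(.segments_to_xy(segments)$Y)
  colnames(Y) <- c("sbp", "dbp", "map")
  if (is.null(n_subjects)) {
    n_subjects <- length(unique(vapply(segments, function(s) {
      s$source$subject_id
    }, character(1))))
  }
  .build_report(Y, Z, n_subjects)
}

.build_report <- function(Y, Z, n_subjects) {
  tasks <- c("sbp", "dbp", "map")
  metrics <- data.frame(task = tasks, n = nrow(Y), r = NA_real_,
                        me = NA_real_, mae = NA_real_, sd = NA_real_,
                        cp5 = NA_real_, cp10 = NA_real_, cp15 = NA_real_,
                        bhs_grade = NA_character_, aami_pass = NA)
  ba <- list()
  hist_list <- list()
  breaks <- seq(-20, 20, by = 1)
  for (i in seq_along(tasks)) {
    y <- Y[, i]
    z <- Z[, i]
    metrics$me[i] <- mean_error(y, z)
    metrics$mae[i] <- mae(y, z)
    if (length(y) >= 2) {
      metrics$sd[i] <- error_sd(y, z)
      metrics$r[i] <- tryCatch(pearson_r(y, z), error = function(e) NA_real_)
    }
    bh <- bhs_grade(abs(z - y))
    metrics$cp5[i] <- bh$cp[["5"]]
    metrics$cp10[i] <- bh$cp[["10"]]
    metrics$cp15[i] <- bh$cp[["15"]]
    metrics$bhs_grade[i] <- bh$grade
    if (is.finite(metrics$sd[i])) {
      metrics$aami_pass[i] <- aami_check(metrics$me[i], metrics$sd[i],
                                         n_subjects)$pass
    }
    if (length(y) >= 2) ba[[tasks[i]]] <- bland_altman(y, z)
    d <- z - y
    inside <- d[d >= -20 & d <= 20]
    hist_list[[tasks[i]]] <- data.frame(
      lower = utils::head(breaks, -1), upper = breaks[-1],
      count = as.vector(table(cut(inside, breaks, include.lowest = TRUE))),
      row.names = NULL
    )
    attr(hist_list[[tasks[i]]], "n_outside") <- sum(d < -20 | d > 20)
  }
  structure(list(metrics = metrics, bland_altman = ba,
                 histograms = hist_list, n_subjects = n_subjects,
                 aami_pass = all(metrics$aami_pass %in% TRUE)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> n = %d segments, %d subject(s)\n",
              x$metrics$n[1], x$n_subjects))
  print(x$metrics, row.names = FALSE, digits = 4)
  cat(sprintf("AAMI overall: %s\n", if (x$aami_pass) "pass" else "fail"))
  invisible(x)
}

#' Write an evaluation report to disk
#'
#' Emits `report.csv` (the per-task metric table), `report.txt` (the
#' printed summary) and one `hist_<task>.csv` per error histogram.
#'
#' @param report An `eval_report`.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_eval_report <- function(report, dir) {
  stopifnot(inherits(report, "eval_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, "report.csv")
  utils::write.csv(report$metrics, paths, row.names = FALSE)
  txt <- file.path(dir, "report.txt")
  sink(txt); print(report); sink()
  paths <- c(paths, txt)
  for (task in names(report$histograms)) {
    p <- file.path(dir, sprintf("hist_%s.csv", task))
    utils::write.csv(report$histograms[[task]], p, row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
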