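#' Percent change between two timepoints
#'
#' \code{100 * (post - pre) / pre}; the pre-to-post change in ROI-mean MWF
#' expressed in percent. Vectorized over both arguments.
#'
#' @param pre,post Values at the two timepoints; \code{pre} must be
#'   non-zero.
#' @return Percent change.
#' @export
percent_change <- function(pre, post) {
  if (any(pre == 0)) stop("percent change undefined for pre = 0")
  100 * (post - pre) / pre
}

#' One-sample t-test from summary statistics
#'
#' Computes \code{t = (mean - null) / (sd / sqrt(n))} with \code{n - 1}
#' degrees of freedom and a two-tailed p-value from the Student t
#' distribution; the test applied to group-mean percent-change values
#' against a null of no change.
#'
#' @param mean Sample mean.
#' @param sd Sample standard deviation (> 0, Bessel-corrected).
#' @param n Sample size (>= 2).
#' @param null Null-hypothesis mean (default 0).
#' @return An object of class \code{"t_test_summary"}: \code{t}, \code{df},
#'   \code{p}, \code{mean}, \code{sd}, \code{n}.
#' @examples
#' one_sample_t_from_summary(8.30, 13.90, 16)   # t = 2.39, df = 15
#' @export
one_sample_t_from_summary <- function(mean, sd, n, null = 0) {
  stopifnot(is.numeric(mean), is.numeric(sd), is.numeric(n))
  if (sd <= 0) stop("sd must be positive")
  if (n < 2) stop("need n >= 2")
  t <- (mean - null) / (sd / sqrt(n))
  df <- n - 1
  p <- 2 * stats::pt(-abs(t), df)
  structure(list(t = t, df = df, p = p, mean = mean, sd = sd, n = n,
                 null = null),
            class = "t_test_summary")
}

#' @export
print.t_test_summary <- function(x, ...) {
  cat(sprintf("One-sample t-test: t(%g) = %.3f, two-tailed p = %.4g\n",
              x$df, x$t, x$p))
  cat(sprintf("  mean %.4g (sd %.4g, n %d) vs null %g\n",
              x$mean, x$sd, as.integer(x$n), x$null))
  invisible(x)
}

#' One-sample t-test from raw values
#'
#' Identical to \code{\link{one_sample_t_from_summary}} applied to the
#' sample mean and Bessel-corrected standard deviation.
#'
#' @param values Numeric vector (n >= 2, non-zero variance).
#' @param null Null-hypothesis mean.
#' @return A \code{"t_test_summary"}.
#' @export
one_sample_t <- function(values, null = 0) {
  values <- as.numeric(values)
  n <- length(values)
  if (n < 2) stop("need at least 2 values")
  s <- stats::sd(values)
  if (s == 0) stop("degenerate sample: zero variance")
  one_sample_t_from_summary(mean(values), s, n, null)
}

#' Two-tailed p-value for a Pearson correlation
#'
#' Significance from the coefficient and sample size alone:
#' \code{t = r * sqrt((n - 2) / (1 - r^2))} referred to the Student t
#' distribution with \code{n - 2} degrees of freedom, two-tailed.
#'
#' @param r Pearson coefficient, |r| < 1.
#' @param n Number of pairs (>= 3).
#' @return Two-tailed p-value.
#' @examples
#' cor_p_value(-0.615, 16)   # 0.011
#' @export
cor_p_value <- function(r, n) {
  stopifnot(abs(r) < 1, n >= 3)
  t <- r * sqrt((n - 2) / (1 - r^2))
  2 * stats::pt(-abs(t), n - 2)
}

#' Pearson correlation with significance
#'
#' @param x,y Equal-length numeric vectors (n >= 3), neither constant.
#' @return An object of class \code{"correlation_result"}: \code{r},
#'   \code{n}, \code{p} (two-tailed, from \code{\link{cor_p_value}}).
#' @export
pearson <- function(x, y) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 3) stop("need at least 3 pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("degenerate input: constant vector")
  r <- stats::cor(x, y)
  p <- if (abs(r) >= 1) 0 else cor_p_value(r, n)
  structure(list(r = r, n = n, p = p), class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Pearson correlation: r = %.3f (n = %d), two-tailed p = %.4g\n",
              x$r, x$n, x$p))
  invisible(x)
}

#' Intraclass correlation coefficient (two-way, single measure)
#'
#' Test-retest / interrater reliability from the two-way ANOVA mean
#' squares of a complete subjects-by-measurements matrix. With MSR the
#' between-subjects, MSC the between-measurements and MSE the residual
#' mean square over n subjects and k measurements:
#' \describe{
#'   \item{absolute agreement, ICC(A,1):}{(MSR - MSE) / (MSR + (k-1) MSE +
#'     (k/n) (MSC - MSE)) — sensitive to systematic offsets between
#'     sessions or raters.}
#'   \item{consistency, ICC(C,1):}{(MSR - MSE) / (MSR + (k-1) MSE) —
#'     ignores a constant offset.}
#' }
#' Absolute agreement is the default, the conventional choice for
#' test-retest of a quantitative measure.
#'
#' @param ratings Numeric matrix, one row per subject, one column per
#'   measurement (session or rater). Missing cells are an error; no
#'   imputation is performed.
#' @param type \code{"agreement"} (default) or \code{"consistency"}.
#' @return An object of class \code{"icc_result"}: \code{icc}, \code{form},
#'   \code{n_subjects}, \code{n_raters_or_sessions}, and the mean squares.
#' @examples
#' m <- cbind(c(.041, .124, .169, .059, .153, .172),
#'            c(.044, .126, .165, .056, .144, .169))
#' icc(m)
#' @export
icc <- function(ratings, type = c("agreement", "consistency")) {
  type <- match.arg(type)
  ratings <- as.matrix(ratings)
  if (anyNA(ratings)) stop("missing cells are not allowed (no imputation)")
  n <- nrow(ratings); k <- ncol(ratings)
  if (n < 2 || k < 2) stop("need >= 2 subjects and >= 2 measurements")
  grand <- mean(ratings)
  rowm <- rowMeans(ratings); colm <- colMeans(ratings)
  ssr <- k * sum((rowm - grand)^2)
  ssc <- n * sum((colm - grand)^2)
  sst <- sum((ratings - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  val <- if (type == "agreement") {
    (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
  } else {
    (msr - mse) / (msr + (k - 1) * mse)
  }
  structure(list(icc = val,
                 form = paste0("two-way, single-measure, ",
                               if (type == "agreement") "absolute-agreement"
                               else "consistency"),
                 n_subjects = n, n_raters_or_sessions = k,
                 ms = c(msr = msr, msc = msc, mse = mse)),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC = %.3f (%s; %d subjects x %d measurements)\n",
              x$icc, x$form, x$n_subjects, x$n_raters_or_sessions))
  invisible(x)
}
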