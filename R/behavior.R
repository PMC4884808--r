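#' Read a behavioral trial log
#'
#' Expects columns \code{session}, \code{block}, \code{trial},
#' \code{movement_time_s} (or \code{movement_time}) and \code{success}.
#'
#' @param path CSV file.
#' @return A data frame with columns \code{session}, \code{block},
#'   \code{trial}, \code{movement_time} (seconds), \code{success} (logical).
#' @export
read_trials <- function(path) {
  df <- utils::read.csv(path)
  if ("movement_time_s" %in% names(df) && !"movement_time" %in% names(df))
    names(df)[names(df) == "movement_time_s"] <- "movement_time"
  need <- c("session", "block", "trial", "movement_time", "success")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("trial log missing columns: ", paste(miss, collapse = ", "))
  df$success <- as.logical(df$success)
  validate_trials(df)
  df[need]
}

validate_trials <- function(df) {
  if (is.unsorted(df$trial, strictly = TRUE))
    stop("trial index must be strictly increasing")
  if (any(df$movement_time <= 0)) stop("movement times must be positive")
  invisible(df)
}

# Profiled SSE: for fixed alpha the model MT = A + B exp(-alpha N) is linear
# in (A, B); returns the conditional least-squares solution with A clamped
# at its lower bound of 0 when the unconstrained optimum is negative.
profile_ab <- function(alpha, N, MT) {
  x <- exp(-alpha * N)
  if (stats::sd(x) < 1e-14) {          # alpha ~ 0: A and B are confounded
    A <- mean(MT); B <- 0
  } else {
    cf <- stats::lm.fit(cbind(1, x), MT)$coefficients
    A <- cf[1]; B <- cf[2]
    if (A < 0) {                        # constrained refit on the boundary
      A <- 0
      B <- sum(x * MT) / sum(x * x)
    }
  }
  r <- MT - A - B * x
  list(A = unname(A), B = unname(B), sse = sum(r * r))
}

#' Fit the exponential skill-acquisition curve
#'
#' Nonlinear least-squares fit of the motor-learning model
#' \deqn{E(MT)_N = A + B e^{-\alpha N}}
#' to a movement-time series: \code{A} is the movement time at performance
#' plateau (asymptote, seconds), \code{B} the overall change in movement
#' time from the start of training to plateau (positive when performance
#' improves), and \code{alpha} the rate of skill acquisition per trial.
#'
#' Because the model is linear in (A, B) given \code{alpha}, the fit
#' profiles the sum of squared errors over \code{alpha} alone: a
#' multi-start grid (spanning 5e-4 to 0.1 by default) followed by local
#' refinement with \code{\link[stats]{optimize}}, with \code{A} bounded
#' below by 0 and \code{alpha} constrained to [0, 1]. This is considerably
#' more robust than general nonlinear optimization, which is notoriously
#' sensitive to the \code{alpha} start on exponentials.
#'
#' When the flag is set (the default), only successful trials enter the
#' fit, and \code{N} counts the trials actually fitted, sequentially from
#' 1. Series with no detectable decay (e.g. constant movement times)
#' return \code{B} near 0 with the \code{unidentifiable} flag set; the
#' reported \code{alpha} is then arbitrary.
#'
#' @param series Trial data frame (see \code{\link{read_trials}}) or a bare
#'   numeric vector of movement times.
#' @param use_successful_only Fit only trials with \code{success == TRUE}.
#' @param N Optional explicit trial indices (one per fitted trial); default
#'   is the sequential counter 1, 2, ... over the fitted trials.
#' @param alpha_grid Multi-start grid of rate initializations.
#' @return An object of class \code{"learning_curve"} with
#'   \code{coefficients} (A, B, alpha), \code{residual_sse},
#'   \code{n_trials}, \code{unidentifiable}, and the fitted series.
#' @examples
#' N <- 1:500
#' mt <- 1 + 2 * exp(-0.01 * N)
#' fit <- fit_exponential(mt)
#' coef(fit)
#' @export
fit_exponential <- function(series, use_successful_only = TRUE, N = NULL,
                            alpha_grid = c(5e-4, 1e-3, 5e-3, 1e-2, 5e-2, 1e-1)) {
  if (is.data.frame(series)) {
    validate_trials(series)
    keep <- if (use_successful_only) which(series$success) else seq_len(nrow(series))
    MT <- series$movement_time[keep]
  } else {
    MT <- as.numeric(series)
    if (any(MT <= 0)) stop("movement times must be positive")
  }
  n <- length(MT)
  if (n < 3) stop("insufficient data: need at least 3 usable trials, got ", n)
  if (is.null(N)) N <- seq_len(n)
  if (length(N) != n) stop("N must have one index per fitted trial")

  sse_tot <- sum((MT - mean(MT))^2)
  if (sse_tot < 1e-24 * n) {            # exactly flat series
    return(new_learning_curve(A = mean(MT), B = 0, alpha = 0, sse = 0,
                              N = N, MT = MT, unidentifiable = TRUE))
  }
  alpha_grid <- sort(unique(pmin(pmax(alpha_grid, 1e-8), 1)))
  prof <- lapply(alpha_grid, profile_ab, N = N, MT = MT)
  sse <- vapply(prof, `[[`, numeric(1), "sse")
  i <- which.min(sse)
  lo <- if (i > 1) alpha_grid[i - 1] else alpha_grid[i] / 10
  hi <- if (i < length(alpha_grid)) alpha_grid[i + 1] else min(1, alpha_grid[i] * 10)
  opt <- stats::optimize(function(a) profile_ab(a, N, MT)$sse,
                         lower = lo, upper = hi, tol = 1e-10)
  cand <- list(list(alpha = alpha_grid[i], fit = prof[[i]]),
               list(alpha = opt$minimum, fit = profile_ab(opt$minimum, N, MT)))
  best <- cand[[which.min(vapply(cand, function(c) c$fit$sse, numeric(1)))]]
  alpha <- best$alpha; fit <- best$fit

  # identifiability: does the exponential term explain anything beyond a
  # constant model?
  unident <- (sse_tot - fit$sse) < 1e-8 * sse_tot ||
    abs(fit$B) * stats::sd(exp(-alpha * N)) < 1e-8 * stats::sd(MT)
  new_learning_curve(A = fit$A, B = fit$B, alpha = alpha, sse = fit$sse,
                     N = N, MT = MT, unidentifiable = unident)
}

new_learning_curve <- function(A, B, alpha, sse, N, MT, unidentifiable) {
  structure(list(coefficients = c(A = A, B = B, alpha = alpha),
                 residual_sse = sse, n_trials = length(N),
                 unidentifiable = unidentifiable,
                 N = N, movement_time = MT,
                 fitted.values = A + B * exp(-alpha * N)),
            class = "learning_curve")
}

#' @export
print.learning_curve <- function(x, digits = 4, ...) {
  cat("Exponential learning curve: MT(N) = A + B * exp(-alpha * N)\n")
  print(signif(x$coefficients, digits))
  cat(sprintf("trials: %d, residual SSE: %.4g\n", x$n_trials, x$residual_sse))
  if (x$unidentifiable)
    cat("warning: no detectable decay; alpha is not identifiable\n")
  invisible(x)
}

#' @export
summary.learning_curve <- function(object, ...) {
  cf <- object$coefficients
  dfres <- object$n_trials - 3L
  sigma <- if (dfres > 0) sqrt(object$residual_sse / dfres) else NA_real_
  structure(list(coefficients = cf, sigma = sigma,
                 residual_sse = object$residual_sse,
                 n_trials = object$n_trials,
                 unidentifiable = object$unidentifiable),
            class = "summary.learning_curve")
}

#' @export
print.summary.learning_curve <- function(x, ...) {
  cat("Exponential learning curve fit\n")
  cat(sprintf("  A (plateau MT)   : %.4g s\n", x$coefficients["A"]))
  cat(sprintf("  B (overall change): %.4g s\n", x$coefficients["B"]))
  cat(sprintf("  alpha (rate)     : %.4g per trial\n", x$coefficients["alpha"]))
  cat(sprintf("  residual SD      : %.4g s on %d trials\n", x$sigma, x$n_trials))
  if (x$unidentifiable) cat("  alpha flagged unidentifiable\n")
  invisible(x)
}

#' @export
coef.learning_curve <- function(object, ...) object$coefficients

#' @export
fitted.learning_curve <- function(object, ...) object$fitted.values

#' @export
residuals.learning_curve <- function(object, ...)
  object$movement_time - object$fitted.values

#' @export
predict.learning_curve <- function(object, newdata = NULL, ...) {
  N <- if (is.null(newdata)) object$N
       else if (is.data.frame(newdata)) newdata$N
       else as.numeric(newdata)
  cf <- object$coefficients
  cf["A"] + cf["B"] * exp(-cf["alpha"] * N)
}

#' @export
simulate.learning_curve <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  dfres <- max(object$n_trials - 3L, 1L)
  sigma <- sqrt(object$residual_sse / dfres)
  mu <- object$fitted.values
  as.data.frame(replicate(nsim, mu + stats::rnorm(length(mu), 0, sigma)))
}

#' @export
plot.learning_curve <- function(x, ...) {
  graphics::plot(x$N, x$movement_time, xlab = "trial N",
                 ylab = "movement time (s)", col = "grey50", ...)
  graphics::lines(x$N, x$fitted.values, lwd = 2)
  invisible(x)
}

#' Fit early and late training bins separately
#'
#' Splits the series into an early bin (training sessions 1-9) and a late
#' bin (session 10), renumbers trials within each bin starting at 1, and
#' fits the exponential learning curve to each, so early- and late-phase
#' acquisition rates can be compared. A bin with fewer than 3 usable trials
#' yields a captured insufficient-data error in its slot rather than
#' aborting the other bin.
#'
#' @param series Trial data frame with a \code{session} column.
#' @param early_sessions,late_sessions Session numbers defining the bins.
#' @param ... Passed to \code{\link{fit_exponential}}.
#' @return List with elements \code{early} and \code{late}; each either a
#'   \code{"learning_curve"} fit or the condition object raised for that
#'   bin.
#' @export
bin_fit <- function(series, early_sessions = 1:9, late_sessions = 10, ...) {
  stopifnot(is.data.frame(series), "session" %in% names(series))
  fit_bin <- function(sessions) {
    sub <- series[series$session %in% sessions, , drop = FALSE]
    if (nrow(sub) == 0)
      return(simpleError(paste("no trials in sessions",
                               paste(range(sessions), collapse = "-"))))
    sub$trial <- seq_len(nrow(sub))
    tryCatch(fit_exponential(sub, ...), error = identity)
  }
  list(early = fit_bin(early_sessions), late = fit_bin(late_sessions))
}
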