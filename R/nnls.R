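#' Logarithmic T2 analysis grid
#'
#' T2 values at which spectral amplitudes are estimated. The default 40
#' log-spaced points from 15 ms to 2000 ms span the three water pools
#' resolved by multicomponent T2 relaxation imaging: myelin water
#' (15-40 ms), intra/extracellular water (40-200 ms) and CSF (> 1500 ms).
#'
#' @param n Number of grid points (>= 3).
#' @param t2_min Smallest T2 in ms (>= 1).
#' @param t2_max Largest T2 in ms (>= 2000, so the long pool is covered).
#' @return Strictly increasing numeric vector of T2 values (ms).
#' @export
t2_grid <- function(n = 40, t2_min = 15, t2_max = 2000) {
  stopifnot(n >= 3, t2_min >= 1, t2_max >= 2000, t2_min < t2_max)
  exp(seq(log(t2_min), log(t2_max), length.out = n))
}

#' T2 spectrum container
#'
#' Non-negative amplitudes over a T2 grid; the object estimated per voxel
#' by (regularized) NNLS.
#'
#' @param grid T2 grid (ms), strictly increasing.
#' @param amplitudes Non-negative finite weights, same length as grid.
#' @return An object of class \code{"t2_spectrum"}.
#' @export
t2_spectrum <- function(grid, amplitudes) {
  stopifnot(length(grid) == length(amplitudes),
            !is.unsorted(grid, strictly = TRUE),
            all(is.finite(amplitudes)), all(amplitudes >= 0))
  structure(list(grid = as.numeric(grid), amplitudes = as.numeric(amplitudes)),
            class = "t2_spectrum")
}

#' @export
print.t2_spectrum <- function(x, ...) {
  tot <- sum(x$amplitudes)
  cat(sprintf("T2 spectrum on %d-point grid (%.3g-%.3g ms), total amplitude %.4g\n",
              length(x$grid), min(x$grid), max(x$grid), tot))
  if (tot > 0) {
    pk <- x$grid[which.max(x$amplitudes)]
    cat(sprintf("  dominant T2 %.1f ms\n", pk))
  }
  invisible(x)
}

#' @export
plot.t2_spectrum <- function(x, ...) {
  graphics::plot(x$grid, x$amplitudes, type = "h", log = "x",
                 xlab = "T2 (ms)", ylab = "amplitude", ...)
  invisible(x)
}

# Lawson-Hanson active-set NNLS: minimize ||A x - b||^2 subject to x >= 0.
# Returns list(x, chi2). The KKT conditions hold at convergence: x >= 0,
# gradient w = A'(b - A x) satisfies w <= tol on the zero set and |w| <= tol
# on the positive set.
nnls_lh <- function(A, b, tol = NULL, max_iter = NULL) {
  n <- ncol(A)
  w <- drop(crossprod(A, b))            # gradient at x = 0
  gscale <- max(abs(w))                 # scale-equivariant tolerance
  if (is.null(tol)) tol <- 1e-10 * gscale
  if (gscale == 0) return(list(x = numeric(n), chi2 = sum(b * b)))
  if (is.null(max_iter)) max_iter <- 3L * n
  x <- numeric(n)
  P <- logical(n)
  iter <- 0L
  while (any(!P) && any(w[!P] > tol) && iter < max_iter) {
    iter <- iter + 1L
    j <- which(!P)[which.max(w[!P])]
    P[j] <- TRUE
    repeat {
      z <- numeric(n)
      Ap <- A[, P, drop = FALSE]
      z[P] <- qr.coef(qr(Ap), b)
      z[P][is.na(z[P])] <- 0            # rank-deficient passive set
      if (all(z[P] > 0)) break
      neg <- P & (z <= 0)
      alpha <- suppressWarnings(min(x[neg] / (x[neg] - z[neg]), na.rm = TRUE))
      if (!is.finite(alpha)) alpha <- 0
      x <- x + alpha * (z - x)
      P <- P & (x > 1e-12 * max(x))
      x[!P] <- 0
      if (!any(P)) break
    }
    x <- z
    x[!P] <- 0
    w <- drop(crossprod(A, b - A %*% x))
  }
  r <- b - A %*% x
  list(x = x, chi2 = sum(r * r))
}

#' Non-negative least squares spectrum estimate
#'
#' Solves min ||basis x - signal||^2 subject to x >= 0 with the
#' Lawson-Hanson active-set algorithm and returns the amplitude vector as a
#' \code{\link{t2_spectrum}}. An all-zero signal yields the zero spectrum.
#'
#' @param basis Decay basis from \code{\link{decay_basis}} (rows = echoes,
#'   columns = grid T2s), or any numeric matrix.
#' @param signal An \code{\link{echo_train}} or numeric vector with one
#'   value per basis row.
#' @return A \code{t2_spectrum}; attribute \code{chi2} holds the residual
#'   sum of squares.
#' @export
nnls_solve <- function(basis, signal) {
  y <- signal_vector(signal)
  if (length(y) != nrow(basis))
    stop("signal length (", length(y), ") does not match basis rows (",
         nrow(basis), ")")
  fit <- nnls_lh(basis, y)
  grid <- attr(basis, "t2_grid")
  if (is.null(grid)) grid <- seq_len(ncol(basis))
  out <- t2_spectrum(grid, fit$x)
  attr(out, "chi2") <- fit$chi2
  out
}

#' Regularized non-negative least squares
#'
#' Minimum-energy (Tikhonov) regularized NNLS: solves
#' min ||basis x - signal||^2 + mu^2 ||x||^2, x >= 0, with the penalty
#' weight mu chosen by bisection as the largest value whose data misfit
#' chi2(mu) = ||basis x - signal||^2 does not exceed
#' \code{chi2_factor} times the unregularized minimum. This returns the
#' smoothest spectrum consistent with the data at the prescribed misfit
#' inflation, the standard stabilization in multicomponent T2 analysis.
#'
#' @inheritParams nnls_solve
#' @param chi2_factor Allowed misfit inflation, >= 1. The default 1.02
#'   permits a 2 percent chi-square increase. \code{chi2_factor = 1}
#'   reproduces the unregularized solution exactly.
#' @param rel_tol Relative tolerance on the achieved chi2 in the bisection.
#' @return A \code{t2_spectrum} with attributes \code{chi2} (achieved data
#'   misfit), \code{chi2_min} (unregularized misfit) and \code{mu} (penalty
#'   weight).
#' @export
regularized_nnls <- function(basis, signal, chi2_factor = 1.02,
                             rel_tol = 1e-3) {
  if (!is.numeric(chi2_factor) || length(chi2_factor) != 1L || chi2_factor < 1)
    stop("chi2_factor must be a scalar >= 1")
  y <- signal_vector(signal)
  if (length(y) != nrow(basis))
    stop("signal length does not match basis rows")
  grid <- attr(basis, "t2_grid")
  if (is.null(grid)) grid <- seq_len(ncol(basis))
  base_fit <- nnls_lh(basis, y)
  chi2_min <- base_fit$chi2
  wrap <- function(x, chi2, mu) {
    out <- t2_spectrum(grid, x)
    attr(out, "chi2") <- chi2
    attr(out, "chi2_min") <- chi2_min
    attr(out, "mu") <- mu
    out
  }
  energy0 <- sum(base_fit$x^2)
  if (chi2_factor == 1 || chi2_min <= .Machine$double.eps * sum(y * y) ||
      energy0 == 0)
    return(wrap(base_fit$x, chi2_min, 0))
  target <- chi2_factor * chi2_min
  n <- ncol(basis)
  aug <- function(mu) {
    A <- rbind(basis, diag(mu, n))
    fit <- nnls_lh(A, c(y, numeric(n)))
    r <- y - basis %*% fit$x
    list(x = fit$x, chi2 = sum(r * r))
  }
  # bracket: find mu_hi with chi2 > target (chi2 is non-decreasing in mu);
  # the seed scales like the signal, keeping the search scale-equivariant
  mu_lo <- 0; sol_lo <- list(x = base_fit$x, chi2 = chi2_min)
  mu_hi <- sqrt(chi2_min / energy0)
  hi <- aug(mu_hi)
  k <- 0L
  while (hi$chi2 <= target && k < 60L) {
    mu_lo <- mu_hi; sol_lo <- hi
    mu_hi <- mu_hi * 2; hi <- aug(mu_hi)
    k <- k + 1L
  }
  if (hi$chi2 <= target)           # penalty saturates below target
    return(wrap(hi$x, hi$chi2, mu_hi))
  for (i in 1:60) {
    mu <- (mu_lo + mu_hi) / 2
    s <- aug(mu)
    if (s$chi2 <= target) { mu_lo <- mu; sol_lo <- s } else mu_hi <- mu
    if (abs(s$chi2 - target) <= rel_tol * target) break
  }
  wrap(sol_lo$x, sol_lo$chi2, mu_lo)
}
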