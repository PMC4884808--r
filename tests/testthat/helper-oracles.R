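# Independent oracles used across the test suite. These deliberately share
# no code with the package internals.

# Brute-force isochromat (Bloch rotation-matrix) simulation of a CPMG train:
# n_spins uniformly dephased spins, 90 degree excitation about x with
# refocusing about x on magnetization excited along the pulse axis (CPMG
# condition), ideal crushers emulated by the uniform intra-voxel dephasing.
isochromat_cpmg <- function(t2, angle_deg, esp, n, t1 = 1000, n_spins = 10000) {
  phi <- (seq_len(n_spins) - 1) / n_spins * 2 * pi
  a <- angle_deg * pi / 180
  E2 <- exp(-esp / 2 / t2); E1 <- exp(-esp / 2 / t1)
  Mx <- rep(1, n_spins); My <- numeric(n_spins); Mz <- numeric(n_spins)
  cphi <- cos(phi); sphi <- sin(phi); ca <- cos(a); sa <- sin(a)
  amp <- numeric(n)
  for (e in seq_len(n)) {
    Mx <- Mx * E2; My <- My * E2; Mz <- Mz * E1
    tmp <- Mx * cphi - My * sphi; My <- Mx * sphi + My * cphi; Mx <- tmp
    tmp <- My * ca - Mz * sa; Mz <- My * sa + Mz * ca; My <- tmp
    tmp <- Mx * cphi - My * sphi; My <- Mx * sphi + My * cphi; Mx <- tmp
    Mx <- Mx * E2; My <- My * E2; Mz <- Mz * E1
    amp[e] <- sqrt(mean(Mx)^2 + mean(My)^2)
  }
  amp
}

# Exhaustive active-set NNLS oracle: enumerates all 2^n support sets, solves
# the unconstrained least-squares problem on each, keeps feasible solutions
# and returns the best. Exact for small n.
brute_force_nnls <- function(A, b) {
  n <- ncol(A)
  best <- numeric(n); bestf <- sum(b * b)
  for (s in seq_len(2^n) - 1L) {
    act <- as.logical(bitwAnd(s, 2^(seq_len(n) - 1L)))
    x <- numeric(n)
    if (any(act)) {
      z <- qr.coef(qr(A[, act, drop = FALSE]), b)
      z[is.na(z)] <- 0
      if (any(z < 0)) next
      x[act] <- z
    }
    f <- sum((b - A %*% x)^2)
    if (f < bestf - 1e-12) { bestf <- f; best <- x }
  }
  best
}

# Three-pool decay builder used by the recovery tests: returns the noiseless
# echo train with the given myelin fraction (T2 20 ms), CSF fraction fixed
# at 0.05 (T2 2000 ms), remainder intra/extracellular (T2 80 ms).
three_pool_signal <- function(mwf, flip, seq = seq_params(), csf = 0.05) {
  mwf * epg_decay(20, flip, seq)$amplitudes +
    (1 - mwf - csf) * epg_decay(80, flip, seq)$amplitudes +
    csf * epg_decay(2000, flip, seq)$amplitudes
}

# Rician corruption of a noiseless magnitude signal.
add_rician <- function(signal, sigma) {
  sqrt((signal + rnorm(length(signal), 0, sigma))^2 +
         rnorm(length(signal), 0, sigma)^2)
}

# Shared EPG dictionaries for the default config, computed once per test run.
default_bases <- local({
  cache <- NULL
  function(config = mwf_config(), seq = seq_params()) {
    if (is.null(cache))
      cache <<- lapply(config$angles, function(a) decay_basis(config$grid, a, seq))
    cache
  }
})
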