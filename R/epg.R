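#' Multi-echo sequence parameters
#'
#' Container for the CPMG/GRASE acquisition timing used by the extended
#' phase graph (EPG) signal model. Defaults correspond to a 32-echo 3D
#' GRASE protocol with 10 ms echo spacing (echo times 10, 20, ..., 320 ms)
#' and TR 1000 ms; T1 is fixed at 1000 ms and only affects the echo train
#' through magnetization stored longitudinally by imperfect refocusing
#' pulses.
#'
#' @param echo_spacing Echo spacing in ms (> 0).
#' @param n_echoes Number of echoes (>= 1).
#' @param excitation_angle Excitation flip angle in degrees; fixed at 90
#'   (ideal excitation) in this model and validated as such.
#' @param t1 Longitudinal relaxation time in ms (> 0).
#' @return An object of class \code{"seq_params"}.
#' @examples
#' sp <- seq_params()
#' echo_times(sp)
#' @export
seq_params <- function(echo_spacing = 10, n_echoes = 32,
                       excitation_angle = 90, t1 = 1000) {
  stopifnot(is.numeric(echo_spacing), length(echo_spacing) == 1L,
            is.finite(echo_spacing), echo_spacing > 0)
  stopifnot(is.numeric(n_echoes), length(n_echoes) == 1L,
            n_echoes >= 1, n_echoes == round(n_echoes))
  if (!isTRUE(all.equal(excitation_angle, 90)))
    stop("excitation_angle is fixed at 90 degrees in this model")
  stopifnot(is.numeric(t1), length(t1) == 1L, is.finite(t1), t1 > 0)
  structure(list(echo_spacing = echo_spacing, n_echoes = as.integer(n_echoes),
                 excitation_angle = 90, t1 = t1),
            class = "seq_params")
}

#' Echo times of a sequence
#' @param seq A \code{seq_params} object.
#' @return Numeric vector of echo times in ms.
#' @export
echo_times <- function(seq) {
  stopifnot(inherits(seq, "seq_params"))
  seq$echo_spacing * seq_len(seq$n_echoes)
}

#' Echo train container
#'
#' Pairs echo times with measured or simulated decay amplitudes for one
#' voxel.
#'
#' @param echo_times Strictly increasing vector of echo times (ms).
#' @param amplitudes Finite signal amplitudes, same length.
#' @return An object of class \code{"echo_train"}.
#' @export
echo_train <- function(echo_times, amplitudes) {
  stopifnot(length(echo_times) == length(amplitudes),
            all(is.finite(echo_times)), all(is.finite(amplitudes)),
            all(diff(echo_times) > 0))
  structure(list(echo_times = as.numeric(echo_times),
                 amplitudes = as.numeric(amplitudes)),
            class = "echo_train")
}

#' @export
print.echo_train <- function(x, ...) {
  cat("Echo train:", length(x$echo_times), "echoes,",
      sprintf("TE %g-%g ms\n", min(x$echo_times), max(x$echo_times)))
  invisible(x)
}

# Extract a plain amplitude vector from an echo_train or numeric input.
signal_vector <- function(signal) {
  if (inherits(signal, "echo_train")) signal$amplitudes else as.numeric(signal)
}

#' EPG decay curve for a single T2 species
#'
#' Simulates the multi-echo spin-echo decay of a single T2 component under
#' imperfect refocusing pulses with the extended phase graph (EPG)
#' formalism. The configuration-state vector (transverse states F_k over
#' dephasing orders -K..K and longitudinal states Z_k over 0..K, with
#' K = n_echoes + 1) is propagated through, per echo interval: relaxation
#' over half an echo spacing, gradient dephasing (order shift), the
#' refocusing rotation, a second dephasing shift and half-interval
#' relaxation. The readout is the magnitude of the zero-order transverse
#' state, matching magnitude MRI data. Excitation is an ideal 90 degree
#' pulse in CPMG phase (magnetization along the refocusing axis), so at a
#' refocusing angle of exactly 180 degrees the train is purely
#' mono-exponential, exp(-TE/T2).
#'
#' T1 relaxation acts on the stored longitudinal states; regrowth towards
#' equilibrium during the train is not modeled (the standard convention in
#' myelin-water EPG fitting, where TR-related saturation is absorbed into
#' the overall amplitude).
#'
#' @param t2 Transverse relaxation time in ms (> 0).
#' @param refocus_angle Refocusing flip angle in degrees, in (0, 180].
#' @param seq A \code{\link{seq_params}} object.
#' @return An \code{\link{echo_train}} with amplitudes normalized to unit
#'   initial magnetization (all in [0, 1]).
#' @examples
#' # perfect refocusing: pure exponential decay
#' tr <- epg_decay(100, 180, seq_params(n_echoes = 3))
#' all.equal(tr$amplitudes, exp(-c(10, 20, 30) / 100))
#' @export
epg_decay <- function(t2, refocus_angle, seq = seq_params()) {
  stopifnot(inherits(seq, "seq_params"))
  if (!is.numeric(t2) || length(t2) != 1L || !is.finite(t2) || t2 <= 0)
    stop("t2 must be a positive finite scalar (ms)")
  if (!is.numeric(refocus_angle) || length(refocus_angle) != 1L ||
      refocus_angle <= 0 || refocus_angle > 180)
    stop("refocus_angle must lie in (0, 180] degrees")
  n <- seq$n_echoes
  amp <- epg_amplitudes(t2, refocus_angle, seq$echo_spacing, n, seq$t1)
  echo_train(echo_times(seq), amp)
}

# Core EPG recursion (no validation). Returns the n-echo amplitude vector.
# States: F over dephasing orders -K..K (complex), Z over orders 0..K.
# Refocusing rotation about the x axis with magnetization excited along x
# (CPMG condition); the rotation matrix is the standard configuration-state
# operator for a pulse of angle a at phase 0.
epg_amplitudes <- function(t2, refocus_angle, esp, n, t1) {
  K <- n + 1L                      # orders beyond the echo count are unreachable
  a <- refocus_angle * pi / 180
  cs2 <- cos(a / 2)^2
  sn2 <- sin(a / 2)^2
  sa <- sin(a)
  ca <- cos(a)
  E2 <- exp(-esp / 2 / t2)
  E1 <- exp(-esp / 2 / t1)

  nf <- 2L * K + 1L                # F index: k = idx - K - 1
  i0 <- K + 1L                     # position of order 0
  Fst <- complex(nf)
  Z <- complex(K + 1L)
  Fst[i0] <- 1 + 0i                # unit magnetization along the pulse axis

  pos <- i0:(i0 + K)               # F_k, k = 0..K
  neg <- i0:(i0 - K)               # F_{-k}, k = 0..K
  amp <- numeric(n)
  for (e in seq_len(n)) {
    # half interval: relax then dephase (operators commute)
    Fst <- Fst * E2
    Z <- Z * E1
    Fst <- c(0i, Fst[-nf])
    # refocusing pulse: mix (F_k, Conj(F_{-k}), Z_k) for each order k >= 0
    Fp <- Fst[pos]
    Fmc <- Conj(Fst[neg])
    newFp <- cs2 * Fp + sn2 * Fmc - 1i * sa * Z
    newFm <- Conj(sn2 * Fp + cs2 * Fmc + 1i * sa * Z)
    newZ <- -0.5i * sa * Fp + 0.5i * sa * Fmc + ca * Z
    Fst[pos] <- newFp
    Fst[neg[-1L]] <- newFm[-1L]
    Z <- newZ
    # second half interval
    Fst <- Fst * E2
    Z <- Z * E1
    Fst <- c(0i, Fst[-nf])
    amp[e] <- Mod(Fst[i0])
  }
  amp
}

#' Decay basis matrix over a T2 grid
#'
#' Assembles the dictionary used by the non-negative least-squares spectrum
#' fit: one column per grid T2 value, one row per echo, each column the EPG
#' decay of that T2 species at the given refocusing angle.
#'
#' @param grid Strictly increasing vector of T2 values in ms (see
#'   \code{\link{t2_grid}}).
#' @param refocus_angle Refocusing flip angle in degrees, in (0, 180].
#' @param seq A \code{\link{seq_params}} object.
#' @return A numeric matrix (n_echoes x length(grid)) with attributes
#'   \code{t2_grid}, \code{refocus_angle} and \code{echo_times}.
#' @export
decay_basis <- function(grid, refocus_angle, seq = seq_params()) {
  stopifnot(length(grid) >= 1L, all(grid > 0), !is.unsorted(grid, strictly = TRUE))
  B <- vapply(grid,
              function(t2) epg_decay(t2, refocus_angle, seq)$amplitudes,
              numeric(seq$n_echoes))
  B <- matrix(B, nrow = seq$n_echoes)
  attr(B, "t2_grid") <- as.numeric(grid)
  attr(B, "refocus_angle") <- refocus_angle
  attr(B, "echo_times") <- echo_times(seq)
  B
}
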