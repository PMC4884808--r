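# Run expr with a temporarily seeded RNG, restoring the caller's state so
# that generators are pure functions of their spec.
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  expr
}

#' Specification of a synthetic multi-echo phantom
#'
#' Describes a labelled block phantom with known per-class T2 pools, a
#' smooth spatially varying refocusing flip-angle field, and a noise model.
#' The default geometry stacks one 8 x 8 x 4 block per tissue class along
#' z, small enough that a full-volume fit runs in seconds; the default
#' classes are white matter (pool fractions 0.12 / 0.83 / 0.05 at T2 = 20 /
#' 80 / 2000 ms, i.e. true MWF 0.12), grey matter (0.03 / 0.92 / 0.05) and
#' CSF (pure 2000 ms). The default flip field ramps linearly from 140 to
#' 180 degrees along x, emulating smooth B1 droop.
#'
#' @param classes Named list of pool tables; each a data frame (or
#'   two-column matrix) with columns \code{t2} (ms) and \code{fraction},
#'   fractions summing to 1.
#' @param block_shape Voxel dimensions of each class block.
#' @param flip_range Flip-angle ramp endpoints (degrees) along x, or a
#'   single value for a uniform field.
#' @param snr First-echo signal-to-noise ratio (mean in-phantom first-echo
#'   signal divided by the noise standard deviation); \code{Inf} disables
#'   noise.
#' @param noise_model \code{"rician"} (default; magnitude of the complex
#'   signal with independent Gaussian noise on both channels, the realistic
#'   model for magnitude MRI) or \code{"gaussian"} (additive, clamped at 0
#'   to respect magnitude non-negativity).
#' @param seed Integer RNG seed; the phantom is a pure function of the
#'   spec.
#' @return An object of class \code{"phantom_spec"}.
#' @export
phantom_spec <- function(classes = list(
                           wm = data.frame(t2 = c(20, 80, 2000),
                                           fraction = c(0.12, 0.83, 0.05)),
                           gm = data.frame(t2 = c(20, 80, 2000),
                                           fraction = c(0.03, 0.92, 0.05)),
                           csf = data.frame(t2 = 2000, fraction = 1)),
                         block_shape = c(8, 8, 4),
                         flip_range = c(140, 180),
                         snr = 500,
                         noise_model = c("rician", "gaussian"),
                         seed = 1L) {
  noise_model <- match.arg(noise_model)
  stopifnot(length(classes) >= 1, !is.null(names(classes)),
            length(block_shape) == 3L, all(block_shape >= 1),
            snr > 0, length(flip_range) %in% c(1L, 2L),
            all(flip_range > 0), all(flip_range <= 180))
  for (nm in names(classes)) {
    cl <- as.data.frame(classes[[nm]])
    stopifnot(all(c("t2", "fraction") %in% names(cl)), all(cl$t2 > 0),
              all(cl$fraction >= 0))
    if (abs(sum(cl$fraction) - 1) > 1e-12)
      stop("pool fractions of class '", nm, "' must sum to 1")
    classes[[nm]] <- cl
  }
  if (length(flip_range) == 1L) flip_range <- rep(flip_range, 2L)
  structure(list(classes = classes, block_shape = as.integer(block_shape),
                 flip_range = flip_range, snr = snr,
                 noise_model = noise_model, seed = as.integer(seed)),
            class = "phantom_spec")
}

true_mwf_of_class <- function(cl, bounds = partition_bounds()) {
  sum(cl$fraction[cl$t2 >= bounds$short_lo & cl$t2 <= bounds$short_hi])
}

#' Generate a synthetic multi-echo phantom with known truth
#'
#' Builds the 4D magnitude volume voxel by voxel: the noiseless signal at
#' echo i is the pool-fraction-weighted sum of EPG decays of the class's T2
#' species at that voxel's true refocusing angle, normalized to unit proton
#' density. Noise is then added per the spec's model with standard
#' deviation sigma = (mean in-phantom first-echo signal) / snr. The paired
#' truth object carries the per-voxel ground-truth MWF (summed fraction of
#' pools with 15 <= T2 <= 40 ms), flip angle, label map and pool tables, so
#' recovery error of the full fitting pipeline can be measured exactly.
#' Bit-reproducible for a given spec.
#'
#' @param spec A \code{\link{phantom_spec}}.
#' @param seq A \code{\link{seq_params}}.
#' @return A list of class \code{"mwf_phantom"}: \code{volume}
#'   (\code{\link{multiecho_volume}}) and \code{truth} (list with 3D arrays
#'   \code{mwf}, \code{flip_angle}, \code{label}, plus \code{classes} and
#'   \code{sigma}).
#' @export
make_phantom <- function(spec = phantom_spec(), seq = seq_params()) {
  stopifnot(inherits(spec, "phantom_spec"))
  ncls <- length(spec$classes)
  bs <- spec$block_shape
  dims <- c(bs[1], bs[2], bs[3] * ncls)
  label <- array(0L, dims)
  for (c in seq_len(ncls))
    label[, , (c - 1L) * bs[3] + seq_len(bs[3])] <- c
  flip <- array(rep(seq(spec$flip_range[1], spec$flip_range[2],
                        length.out = bs[1]), times = prod(dims[2:3])), dims)

  ne <- seq$n_echoes
  data <- array(0, c(dims, ne))
  nvox <- prod(dims)
  cache <- new.env(parent = emptyenv())
  decay_cached <- function(t2, ang) {
    key <- paste0(format(t2, digits = 12), "@", format(ang, digits = 12))
    if (is.null(cache[[key]]))
      cache[[key]] <- epg_amplitudes(t2, ang, seq$echo_spacing, ne, seq$t1)
    cache[[key]]
  }
  for (v in which(label > 0)) {
    cl <- spec$classes[[label[v]]]
    ang <- flip[v]
    sig <- numeric(ne)
    for (p in seq_len(nrow(cl)))
      sig <- sig + cl$fraction[p] * decay_cached(cl$t2[p], ang)
    data[v + nvox * (seq_len(ne) - 1L)] <- sig
  }

  sigma <- 0
  if (is.finite(spec$snr)) {
    first <- data[, , , 1]
    sigma <- mean(first[label > 0]) / spec$snr
    data <- with_seed(spec$seed, {
      if (spec$noise_model == "rician") {
        re <- data + stats::rnorm(length(data), 0, sigma)
        im <- array(stats::rnorm(length(data), 0, sigma), dim(data))
        sqrt(re^2 + im^2)
      } else {
        pmax(data + stats::rnorm(length(data), 0, sigma), 0)
      }
    })
  }

  truth_mwf <- array(NA_real_, dims)
  for (c in seq_len(ncls))
    truth_mwf[label == c] <- true_mwf_of_class(spec$classes[[c]])
  flip_out <- flip
  flip_out[label == 0L] <- NA_real_
  structure(list(volume = multiecho_volume(data, echo_times(seq)),
                 truth = list(mwf = truth_mwf, flip_angle = flip_out,
                              label = label, classes = spec$classes,
                              sigma = sigma),
                 spec = spec),
            class = "mwf_phantom")
}

#' @export
print.mwf_phantom <- function(x, ...) {
  cat("Synthetic multi-echo phantom\n  ")
  print(x$volume)
  cat(sprintf("  classes: %s; SNR %g (%s noise)\n",
              paste(names(x$spec$classes), collapse = ", "),
              x$spec$snr, x$spec$noise_model))
  invisible(x)
}

#' Specification of a synthetic training log
#'
#' Emulates the visuomotor training schedule: 10 sessions of 5 blocks of
#' 200 movements (10,000 movements in total), with movement times following
#' the exponential learning law \code{A + B exp(-alpha N)} plus Gaussian
#' noise, and success drawn Bernoulli at a fixed rate (default 0.813, a
#' realistic interception success level for this task).
#'
#' @param A,B,alpha Learning-curve truth: plateau (s), overall change (s),
#'   rate per trial.
#' @param n_sessions,blocks_per_session,movements_per_block Schedule.
#' @param noise_sd Movement-time noise standard deviation (s).
#' @param success_rate Probability a trial is successful.
#' @param seed Integer RNG seed.
#' @return An object of class \code{"behavior_spec"}.
#' @export
behavior_spec <- function(A = 1.0, B = 2.0, alpha = 0.01,
                          n_sessions = 10, blocks_per_session = 5,
                          movements_per_block = 200,
                          noise_sd = 0.2, success_rate = 0.813, seed = 1L) {
  stopifnot(A >= 0, alpha >= 0, n_sessions >= 1, blocks_per_session >= 1,
            movements_per_block >= 1, noise_sd >= 0,
            success_rate >= 0, success_rate <= 1)
  structure(list(A = A, B = B, alpha = alpha,
                 n_sessions = as.integer(n_sessions),
                 blocks_per_session = as.integer(blocks_per_session),
                 movements_per_block = as.integer(movements_per_block),
                 noise_sd = noise_sd, success_rate = success_rate,
                 seed = as.integer(seed)),
            class = "behavior_spec")
}

#' Generate a synthetic movement-time trial log
#'
#' One row per movement: \code{MT_N = A + B exp(-alpha N) + e_N},
#' \code{e ~ N(0, noise_sd)}, with session/block labels following the
#' training schedule and success flags drawn Bernoulli. Movement times are
#' floored at 1 ms so the positivity invariant holds under noise.
#' Deterministic given the spec's seed.
#'
#' @param spec A \code{\link{behavior_spec}}.
#' @return Data frame with columns \code{session}, \code{block},
#'   \code{trial}, \code{movement_time} (s), \code{success}; attribute
#'   \code{truth} stores the generating parameters.
#' @export
make_trials <- function(spec = behavior_spec()) {
  stopifnot(inherits(spec, "behavior_spec"))
  n <- spec$n_sessions * spec$blocks_per_session * spec$movements_per_block
  N <- seq_len(n)
  mu <- spec$A + spec$B * exp(-spec$alpha * N)
  df <- with_seed(spec$seed, {
    mt <- mu + stats::rnorm(n, 0, spec$noise_sd)
    succ <- stats::runif(n) < spec$success_rate
    data.frame(
      session = rep(seq_len(spec$n_sessions),
                    each = spec$blocks_per_session * spec$movements_per_block),
      block = rep(rep(seq_len(spec$blocks_per_session),
                      each = spec$movements_per_block),
                  times = spec$n_sessions),
      trial = N,
      movement_time = pmax(mt, 1e-3),
      success = succ)
  })
  attr(df, "truth") <- c(A = spec$A, B = spec$B, alpha = spec$alpha)
  df
}

#' Generate a synthetic cohort for the group-level statistics
#'
#' Draws per-subject ROI percent changes from normal distributions and a
#' behavioral learning rate correlated with one ROI's change at a chosen
#' true correlation, so the inferential layer (percent change, one-sample
#' t, Pearson) can be exercised end to end with known effect sizes.
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param rois Named list; each element \code{c(mu, sigma)} giving the
#'   percent-change distribution of that ROI.
#' @param baseline Named vector (or single value) of pre-intervention ROI
#'   means from which the post values are derived.
#' @param assoc_roi Name of the ROI whose change is correlated with the
#'   learning rate.
#' @param true_r True correlation between that ROI's percent change and the
#'   learning rate, |true_r| < 1.
#' @param alpha_mean,alpha_sd Marginal distribution of the learning rate.
#' @param seed Integer RNG seed.
#' @return Data frame, one row per subject, with \code{<roi>_pre},
#'   \code{<roi>_post}, \code{<roi>_pct_change} per ROI and \code{alpha}.
#' @export
make_cohort <- function(n_subjects = 16,
                        rois = list(ips = c(mu = 8.30, sigma = 13.90),
                                    pos = c(mu = 6.28, sigma = 9.09)),
                        baseline = 0.10,
                        assoc_roi = names(rois)[1],
                        true_r = -0.6,
                        alpha_mean = 0.01, alpha_sd = 0.003,
                        seed = 1L) {
  stopifnot(n_subjects >= 2, length(rois) >= 1, !is.null(names(rois)),
            assoc_roi %in% names(rois))
  if (abs(true_r) >= 1) stop("|true_r| must be < 1")
  if (length(baseline) == 1L)
    baseline <- stats::setNames(rep(baseline, length(rois)), names(rois))
  with_seed(seed, {
    out <- data.frame(subject = seq_len(n_subjects))
    z_assoc <- NULL
    for (nm in names(rois)) {
      p <- rois[[nm]]
      z <- stats::rnorm(n_subjects)
      if (nm == assoc_roi) z_assoc <- z
      pct <- p[["mu"]] + p[["sigma"]] * z
      pre <- rep(baseline[[nm]], n_subjects)
      out[[paste0(nm, "_pre")]] <- pre
      out[[paste0(nm, "_post")]] <- pre * (1 + pct / 100)
      out[[paste0(nm, "_pct_change")]] <- pct
    }
    z_alpha <- true_r * z_assoc +
      sqrt(1 - true_r^2) * stats::rnorm(n_subjects)
    out$alpha <- alpha_mean + alpha_sd * z_alpha
    out
  })
}

#' Write a trial log to CSV
#'
#' @param trials Data frame from \code{\link{make_trials}}.
#' @param path Output CSV path (column \code{movement_time_s} on disk).
#' @return Invisibly, the path.
#' @export
write_trials <- function(trials, path) {
  out <- trials
  names(out)[names(out) == "movement_time"] <- "movement_time_s"
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Write a phantom volume and its truth sidecar
#'
#' Writes the 4D multi-echo volume as NIfTI and the ground truth (per-voxel
#' MWF and flip angle flattened with the label map, pool tables, noise
#' sigma) as a JSON sidecar.
#'
#' @param phantom An \code{"mwf_phantom"} from \code{\link{make_phantom}}.
#' @param prefix Output path prefix.
#' @return Invisibly, the written paths.
#' @export
write_phantom <- function(phantom, prefix) {
  stopifnot(inherits(phantom, "mwf_phantom"))
  vol_path <- paste0(prefix, "echoes.nii.gz")
  RNifti::writeNifti(RNifti::asNifti(phantom$volume$data), vol_path)
  truth_path <- paste0(prefix, "truth.json")
  tr <- phantom$truth
  jsonlite::write_json(
    list(dim = dim(tr$label), label = as.vector(tr$label),
         mwf = as.vector(tr$mwf), flip_angle = as.vector(tr$flip_angle),
         sigma = tr$sigma,
         classes = lapply(tr$classes, function(cl) as.list(cl)),
         echo_times = phantom$volume$echo_times),
    truth_path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(c(volume = vol_path, truth = truth_path))
}
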