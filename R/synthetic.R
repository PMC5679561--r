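#' Synthetic-subject specification
#'
#' Ground truth and perturbation levels for [generate_model_subject()]. The
#' perturbations emulate the features of real phonation the time-invariant
#' model cannot produce: cycle-to-cycle period perturbation (jitter),
#' cycle-to-cycle amplitude perturbation (shimmer), additive measurement
#' noise, and pixel quantization of the imaging chain.
#'
#' @param fit Ground-truth [fit_vars()] triple.
#' @param sex `"female"` or `"male"` (recorded in metadata).
#' @param noise Additive Gaussian noise s.d. as a fraction of the median
#'   per-cycle peak (0-0.2).
#' @param jitter Per-cycle period perturbation s.d. as a fraction of the
#'   period (0-0.2).
#' @param shimmer Per-cycle amplitude perturbation s.d. as a fraction
#'   (0-0.2).
#' @param px_step Pixel quantization step in cm/px; 0 disables.
#' @param seed Integer seed; recorded in the output metadata.
#' @return Object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(fit, sex = c("female", "male"), noise = 0,
                           jitter = 0, shimmer = 0, px_step = 0, seed = 1) {
  sex <- match.arg(sex)
  stopifnot(inherits(fit, "tmm_fit_vars"))
  for (v in c(noise = noise, jitter = jitter, shimmer = shimmer)) {
    if (!is.finite(v) || v < 0 || v > 0.2)
      stop("noise, jitter and shimmer must lie in [0, 0.2]", call. = FALSE)
  }
  if (px_step < 0) stop("px_step must be >= 0", call. = FALSE)
  structure(list(fit = fit, sex = sex, noise = noise, jitter = jitter,
                 shimmer = shimmer, px_step = px_step, seed = seed),
            class = "synthetic_spec")
}

# Round half away from zero (the quantization convention of the pixel
# chain; base round() rounds half to even).
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Generate a model-based synthetic subject
#'
#' Simulates the two-mass model at the ground-truth parameters, then
#' degrades the steady-state visible-edge trajectories toward realistic
#' recordings: a cycle-wise time warp perturbs each cycle's duration
#' (jitter), each cycle's values are rescaled (shimmer), Gaussian noise is
#' added, values are clamped at zero, and optionally quantized to a pixel
#' grid (after the noise, as in a real imaging chain). With all
#' perturbations zero the output equals the model trajectories sample for
#' sample. Fully reproducible per seed.
#'
#' @param spec A [synthetic_spec()].
#' @param std A `tmm_params` set; its rest geometry is recorded as part of
#'   the ground truth so that recovery studies can fit within the same
#'   model family.
#' @param n_samples,sample_rate Output length and rate (defaults 400 at
#'   4000 Hz, i.e. a 100 ms window).
#' @return A [trajectory_pair()] in cm whose `meta` records the ground
#'   truth (`Ql`, `Qr`, `Ps`, rest geometry, perturbation levels, seed).
#' @export
generate_model_subject <- function(spec, std = standard_parameters(),
                                   n_samples = 400, sample_rate = 4000) {
  stopifnot(inherits(spec, "synthetic_spec"))
  margin_ms <- 1000 / sample_rate * n_samples * 0.6
  sim <- simulate_tmm(spec$fit, std,
                      total_ms = 400 + n_samples * 1000 / sample_rate +
                        margin_ms,
                      transient_ms = 400, output_rate = sample_rate)
  left <- sim$trajectories$left
  right <- sim$trajectories$right
  if (diff(range(left + right)) < 1e-4)
    stop(sprintf("no oscillation at Ps = %.3g cmH2O (below phonation threshold)",
                 spec$fit$Ps), call. = FALSE)

  with_seed(spec$seed, {
    t_ms <- (seq_along(left) - 1) * 1000 / sample_rate
    if (spec$jitter > 0 || spec$shimmer > 0) {
      cs <- cycle_statistics(left + right, sample_rate)
      tc_ms <- (cs$crossings - 1) * 1000 / sample_rate
      n_cyc <- length(tc_ms) - 1
      eps <- pmin(pmax(rnorm(n_cyc, 0, spec$jitter), -0.5), 0.5)
      # warped knot times: cycle k lasts (1 + eps_k) times its duration
      warped <- cumsum(c(tc_ms[1], diff(tc_ms) * (1 + eps)))
      t_out <- warped[1] + (seq_len(n_samples) - 1) * 1000 / sample_rate
      if (max(t_out) > max(warped))
        stop("insufficient simulated duration for the requested jitter",
             call. = FALSE)
      t_src <- approx(warped, tc_ms, xout = t_out)$y
      # cubic-spline resampling: linear interpolation would attenuate the
      # peaks of a 300+ Hz oscillation sampled at 4 kHz by up to several
      # percent, biasing the per-cycle amplitude statistics of the
      # generated subject
      left_o <- spline(t_ms, left, xout = t_src)$y
      right_o <- spline(t_ms, right, xout = t_src)$y
      if (spec$shimmer > 0) {
        cyc <- findInterval(t_out, warped, rightmost.closed = TRUE)
        cyc <- pmin(pmax(cyc, 1L), n_cyc)
        scale_l <- pmax(1 + rnorm(n_cyc, 0, spec$shimmer), 0.5)
        scale_r <- pmax(1 + rnorm(n_cyc, 0, spec$shimmer), 0.5)
        left_o <- left_o * scale_l[cyc]
        right_o <- right_o * scale_r[cyc]
      }
    } else {
      left_o <- left[seq_len(n_samples)]
      right_o <- right[seq_len(n_samples)]
    }
    if (spec$noise > 0) {
      amp_l <- median(cycle_statistics(left_o, sample_rate)$peaks)
      amp_r <- median(cycle_statistics(right_o, sample_rate)$peaks)
      left_o <- left_o + rnorm(n_samples, 0, spec$noise * amp_l)
      right_o <- right_o + rnorm(n_samples, 0, spec$noise * amp_r)
    }
    left_o <- pmax(left_o, 0)
    right_o <- pmax(right_o, 0)
    if (spec$px_step > 0) {
      left_o <- round_half_away(left_o / spec$px_step) * spec$px_step
      right_o <- round_half_away(right_o / spec$px_step) * spec$px_step
    }
    trajectory_pair(left_o, right_o, sample_rate = sample_rate, unit = "cm",
                    meta = list(sex = spec$sex, Ql = spec$fit$Ql,
                                Qr = spec$fit$Qr, Ps = spec$fit$Ps,
                                x01 = std$x01, x02 = std$x02, l = std$l,
                                noise = spec$noise, jitter = spec$jitter,
                                shimmer = spec$shimmer,
                                px_step = spec$px_step, seed = spec$seed,
                                synthetic = "model"))
  })
}

#' Generate an analytic (raised, clipped sinusoid) trajectory pair
#'
#' A model-independent fixture for testing the signal and cost machinery:
#' each side is max(0, offset + A sin(2 pi f0 t + phase)). An offset below
#' the amplitude yields closure-like clipping at zero.
#'
#' @param f0 Fundamental frequency in Hz (50-500).
#' @param amp Length-2 amplitudes (cm), left and right.
#' @param offset Length-1 or 2 baseline offset (cm).
#' @param phase Phase in radians (common to both sides).
#' @param noise Optional additive Gaussian noise s.d. (cm).
#' @param seed Seed for the noise.
#' @param n_samples,sample_rate Output length and rate.
#' @return A [trajectory_pair()] in cm.
#' @export
generate_analytic_pair <- function(f0, amp = c(0.05, 0.05), offset = 0.02,
                                   phase = 0, noise = 0, seed = 1,
                                   n_samples = 400, sample_rate = 4000) {
  if (!is.finite(f0) || f0 < 50 || f0 > 500)
    stop("f0 must lie in [50, 500] Hz", call. = FALSE)
  offset <- rep(offset, length.out = 2)
  t <- (seq_len(n_samples) - 1) / sample_rate
  mk <- function(a, o) pmax(0, o + a * sin(2 * pi * f0 * t + phase))
  left <- mk(amp[1], offset[1])
  right <- mk(amp[2], offset[2])
  if (noise > 0) {
    with_seed(seed, {
      left <- pmax(left + rnorm(n_samples, 0, noise), 0)
      right <- pmax(right + rnorm(n_samples, 0, noise), 0)
    })
  }
  trajectory_pair(left, right, sample_rate = sample_rate, unit = "cm",
                  meta = list(f0 = f0, synthetic = "analytic"))
}

#' Draw physiologically plausible ground-truth parameters
#'
#' Samples a ground-truth (Ql, Qr, Ps) triple from the observed group
#' ranges of [observed_parameter_ranges()]: a group is picked uniformly,
#' Ql and Ps uniformly within the group's range, and Qr derived from a
#' uniformly drawn symmetry quotient within the group's observed Qlr range
#' (random side), clamped to the group's Qr range. Joint drawing within a
#' group keeps every triple inside the phonating region.
#'
#' @param seed Integer seed.
#' @return List with `fit` ([fit_vars()]), `sex` and `group`.
#' @export
draw_subject_truth <- function(seed) {
  rg <- observed_parameter_ranges()
  with_seed(seed, {
    g <- rg[sample.int(nrow(rg), 1), ]
    Ql <- runif(1, g$Ql_min, g$Ql_max)
    Qlr <- runif(1, g$Qlr_min, g$Qlr_max)
    Qr <- if (runif(1) < 0.5) Ql * Qlr else Ql / Qlr
    Qr <- min(max(Qr, g$Qr_min), g$Qr_max)
    Ps <- runif(1, g$Ps_min, g$Ps_max)
    list(fit = fit_vars(Ql, Qr, Ps),
         sex = if (grepl("female", g$group)) "female" else "male",
         group = g$group)
  })
}
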