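#' Left-right symmetry quotient
#'
#' Qlr = max(Ql, Qr) / min(Ql, Qr) >= 1; 1 indicates perfectly symmetric
#' fitted biomechanics, values above ~1.2 increasingly asymmetric dynamics.
#'
#' @param Ql,Qr Positive scaling factors.
#' @return Scalar >= 1.
#' @examples
#' symmetry_quotient(0.8, 1.6)  # 2, order-invariant
#' @export
symmetry_quotient <- function(Ql, Qr) {
  if (!is.finite(Ql) || !is.finite(Qr) || Ql <= 0 || Qr <= 0)
    stop("Ql and Qr must be positive", call. = FALSE)
  max(Ql, Qr) / min(Ql, Qr)
}

#' Relative frequency deviation in percent
#'
#' @param fE Experimental fundamental frequency (Hz, > 0).
#' @param fM Model fundamental frequency (Hz).
#' @return 100 * |fM - fE| / fE.
#' @export
frequency_deviation <- function(fE, fM) {
  if (!is.finite(fE) || fE <= 0) stop("fE must be > 0", call. = FALSE)
  100 * abs(fM - fE) / fE
}

#' Rate a fit against the three success criteria
#'
#' A fitted model is rated successful when (1) the fundamental frequency of
#' each model trajectory deviates at most `max_freq_dev` percent (default
#' 5%) from the corresponding experimental one, on both sides; (2) the
#' model reproduces the closure behavior of the recording (both close or
#' both do not, per [detect_closure()]); and (3) on each side the median
#' model per-cycle peak lies within the min-max band of the experimental
#' per-cycle peaks (a model amplitude inside the recording's own
#' cycle-to-cycle variation).
#'
#' @param T_E,T_M Experimental and (phase-aligned) model
#'   [trajectory_pair()]s.
#' @param max_freq_dev Frequency criterion threshold in percent.
#' @param closure_fraction Passed to [detect_closure()].
#' @return Object of class `success_report` with per-criterion booleans,
#'   `overall` (their conjunction), the per-side frequency deviations and
#'   the amplitude bands involved.
#' @export
assess_success <- function(T_E, T_M, max_freq_dev = 5,
                           closure_fraction = 0.05) {
  check_pair_compat(T_E, T_M)
  fs <- T_E$sample_rate
  dev_l <- frequency_deviation(fundamental_frequency(T_E$left, fs),
                               fundamental_frequency(T_M$left, fs))
  dev_r <- frequency_deviation(fundamental_frequency(T_E$right, fs),
                               fundamental_frequency(T_M$right, fs))
  frequency_ok <- dev_l <= max_freq_dev && dev_r <= max_freq_dev

  closure_ok <- detect_closure(T_E, closure_fraction) ==
    detect_closure(T_M, closure_fraction)

  band <- function(x) cycle_statistics(x, fs)$amp_range
  peak <- function(x) median(cycle_statistics(x, fs)$peaks)
  band_l <- band(T_E$left); band_r <- band(T_E$right)
  peak_l <- peak(T_M$left); peak_r <- peak(T_M$right)
  amplitude_ok <- peak_l >= band_l[1] && peak_l <= band_l[2] &&
    peak_r >= band_r[1] && peak_r <= band_r[2]

  structure(list(frequency_ok = frequency_ok, closure_ok = closure_ok,
                 amplitude_ok = amplitude_ok,
                 overall = frequency_ok && closure_ok && amplitude_ok,
                 freq_dev_l = dev_l, freq_dev_r = dev_r,
                 exp_band_l = band_l, exp_band_r = band_r,
                 model_peak_l = peak_l, model_peak_r = peak_r),
            class = "success_report")
}

#' @export
print.success_report <- function(x, ...) {
  cat(sprintf("Success report: %s\n",
              if (x$overall) "SUCCESS" else "not successful"))
  cat(sprintf("  frequency : %s (dev %.2f%% / %.2f%%)\n", x$frequency_ok,
              x$freq_dev_l, x$freq_dev_r))
  cat(sprintf("  closure   : %s\n", x$closure_ok))
  cat(sprintf("  amplitude : %s (model %.4g in [%.4g, %.4g]; %.4g in [%.4g, %.4g])\n",
              x$amplitude_ok, x$model_peak_l, x$exp_band_l[1],
              x$exp_band_l[2], x$model_peak_r, x$exp_band_r[1],
              x$exp_band_r[2]))
  invisible(x)
}

#' Descriptive group summary of fitted parameters
#'
#' Summarizes a set of successful fits in the conventional group-table
#' shape: per parameter (Gamma, Ps, Ql, Qr, the pooled Q column where left
#' and right values form one sample, and Qlr) the mean, sample standard
#' deviation (0 by convention for n = 1), minimum and maximum. Unsuccessful
#' fits are excluded before summarizing.
#'
#' @param fits List of `fit_result` objects.
#' @param label Group label recorded in the output.
#' @param successful_only Drop fits whose success report is not overall
#'   successful (default `TRUE`).
#' @return `data.frame` with columns `parameter`, `mean`, `sd`, `min`,
#'   `max`, `n`, `group`.
#' @export
summarize_group <- function(fits, label = "group", successful_only = TRUE) {
  stopifnot(is.list(fits))
  if (successful_only)
    fits <- Filter(function(f) isTRUE(f$best$success$overall), fits)
  if (length(fits) == 0)
    stop("no fits to summarize", call. = FALSE)
  pull <- function(fun) vapply(fits, fun, numeric(1))
  vals <- list(
    gamma = pull(function(f) f$best$gamma),
    Ps = pull(function(f) f$best$fit$Ps),
    Ql = pull(function(f) f$best$fit$Ql),
    Qr = pull(function(f) f$best$fit$Qr),
    Qlr = pull(function(f) f$best$Qlr))
  vals$Q_pooled <- c(vals$Ql, vals$Qr)
  rows <- lapply(names(vals), function(nm) {
    v <- vals[[nm]]
    data.frame(parameter = nm, mean = mean(v),
               sd = if (length(v) > 1) sd(v) else 0,
               min = min(v), max = max(v), n = length(v), group = label)
  })
  do.call(rbind, rows)
}

#' Representative fitted-parameter ranges for adult subject groups
#'
#' Observed ranges of the fitted scaling factors, symmetry quotient and
#' subglottal pressure for four adult groups (young/elderly by sex) from
#' in-vivo optimization of the two-mass model against high-speed recordings
#' of healthy young and vocally aged elderly speakers. Used by the
#' synthetic-subject sampler to draw physiologically plausible ground-truth
#' parameters (drawing Q and Ps jointly within one group avoids
#' combinations, such as maximal stiffness with minimal pressure, that lie
#' below the phonation threshold).
#'
#' @return `data.frame` with one row per group: `group`, `Ql_min`,
#'   `Ql_max`, `Qr_min`, `Qr_max`, `Qlr_min`, `Qlr_max`, `Ps_min`,
#'   `Ps_max` (cmH2O).
#' @export
observed_parameter_ranges <- function() {
  data.frame(
    group = c("young_male", "young_female", "elderly_male",
              "elderly_female"),
    Ql_min = c(0.76, 2.03, 1.19, 1.56),
    Ql_max = c(1.99, 3.32, 1.49, 3.70),
    Qr_min = c(0.78, 1.93, 1.15, 1.60),
    Qr_max = c(1.83, 3.05, 2.36, 4.87),
    Qlr_min = c(1.02, 1.01, 1.10, 1.02),
    Qlr_max = c(1.17, 1.24, 1.59, 1.32),
    Ps_min = c(10.10, 13.20, 15.14, 18.70),
    Ps_max = c(32.31, 36.10, 27.00, 45.70))
}
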