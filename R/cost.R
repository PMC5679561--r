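# Wrap phase differences to (-pi, pi].
wrap_phase <- function(d) {
  pi - ((pi - d) %% (2 * pi))
}

l2 <- function(v) sqrt(sum(v^2))

cost_value <- function(value, components) {
  structure(list(value = value, components = components),
            class = "cost_value")
}

#' @export
print.cost_value <- function(x, ...) {
  cat(sprintf("Cost value: %.6g\n", x$value))
  comp <- unlist(x$components)
  for (nm in names(comp)) cat(sprintf("  %-12s %.6g\n", nm, comp[nm]))
  invisible(x)
}

# Default phase/magnitude balancing factor for the frequency-domain costs:
# s such that a maximal phase error (pi per selected bin, norm pi*sqrt(L))
# and a total magnitude error (norm of the experimental magnitudes)
# contribute comparably; averaged over sides.
default_phase_scale <- function(mags_l, mags_r) {
  s_one <- function(m) pi * sqrt(length(m)) / max(l2(m), .Machine$double.eps)
  mean(c(s_one(mags_l), s_one(mags_r)))
}

# Selected experimental/model coefficients for one side. Harmonic selection
# is always computed on the experimental signal; the model coefficients are
# read off at the same bin indices.
side_coefficients <- function(exp_side, mod_side, sample_rate) {
  sel <- select_harmonics(exp_side, sample_rate)
  sp_m <- traj_spectrum(mod_side)
  list(sel = sel, e = sel$coefficients, s = sp_m[sel$indices],
       dom_pos = match(sel$dominant, sel$indices))
}

# Wrapped phase differences between coefficient vectors, with the
# convention that a numerically zero coefficient (below 1e-9 of its side's
# dominant magnitude) carries no phase information: its phase term is 0
# rather than the arbitrary angle of floating-point residue.
phase_diffs <- function(e, s) {
  d <- wrap_phase(Arg(e) - Arg(s))
  dead <- Mod(e) < 1e-9 * max(Mod(e)) | Mod(s) < 1e-9 * max(Mod(s))
  d[dead] <- 0
  d
}

check_pair_compat <- function(T_E, T_M) {
  stopifnot(inherits(T_E, "trajectory_pair"), inherits(T_M, "trajectory_pair"))
  if (length(T_E$left) != length(T_M$left))
    stop("trajectory pairs must have equal length", call. = FALSE)
  if (T_E$sample_rate != T_M$sample_rate)
    stop("trajectory pairs must share the sampling rate", call. = FALSE)
}

#' Frequency-domain cost
#'
#' Compares experimental and model trajectories on the dominant harmonics of
#' the experimental signal (see [select_harmonics()]): per side, the
#' Euclidean distance between the magnitude vectors (weighted by the
#' balancing factor `s`) plus the Euclidean norm of the wrapped phase
#' differences. Constructed to be smooth in the model parameters and
#' comparatively free of local minima.
#'
#' @param T_E,T_M Experimental and model [trajectory_pair()]s of equal
#'   length and sampling rate.
#' @param s Magnitude/phase balancing factor; `NULL` (default) uses a
#'   scale-free choice, `pi * sqrt(n_bins) / ||e||`, averaged over sides, so
#'   that a maximal phase error and a total magnitude error contribute
#'   comparably.
#' @return A `cost_value` (non-negative; 0 iff the selected coefficients
#'   agree).
#' @export
gamma1 <- function(T_E, T_M, s = NULL) {
  check_pair_compat(T_E, T_M)
  fs <- T_E$sample_rate
  cl <- side_coefficients(T_E$left, T_M$left, fs)
  cr <- side_coefficients(T_E$right, T_M$right, fs)
  if (is.null(s)) s <- default_phase_scale(Mod(cl$e), Mod(cr$e))
  comp <- list(
    mag_left = l2(Mod(cl$e) - Mod(cl$s)),
    phase_left = l2(phase_diffs(cl$e, cl$s)),
    mag_right = l2(Mod(cr$e) - Mod(cr$s)),
    phase_right = l2(phase_diffs(cr$e, cr$s)),
    scale = s)
  cost_value(s * comp$mag_left + comp$phase_left +
             s * comp$mag_right + comp$phase_right, comp)
}

#' Time-domain cost
#'
#' Euclidean distance between model and experimental trajectories, summed
#' over sides. Because the oscillation phase of a self-oscillating model is
#' arbitrary, the model pair is first circularly aligned to the experimental
#' pair (one common shift maximizing the summed cross-correlation) unless
#' `align = FALSE`.
#'
#' @inheritParams gamma1
#' @param align Circularly align `T_M` to `T_E` first (default `TRUE`).
#' @return A `cost_value`.
#' @export
gamma2 <- function(T_E, T_M, align = TRUE) {
  check_pair_compat(T_E, T_M)
  if (align) T_M <- align_phase(T_E, T_M)
  comp <- list(left = l2(T_E$left - T_M$left),
               right = l2(T_E$right - T_M$right))
  cost_value(comp$left + comp$right, comp)
}

#' Normalized frequency-domain cost
#'
#' Variant of [gamma1()] in which each side's magnitude vector is divided by
#' its own dominant magnitude (so the dominant harmonic is 1 and only the
#' relative harmonic structure is compared), plus a regularization term: the
#' Euclidean distance, joint over both sides, of the un-normalized dominant
#' (fundamental-frequency) magnitudes, which pins down the absolute
#' amplitude the normalization removed.
#'
#' @inheritParams gamma1
#' @return A `cost_value`.
#' @export
gamma3 <- function(T_E, T_M, s = NULL) {
  check_pair_compat(T_E, T_M)
  fs <- T_E$sample_rate
  cl <- side_coefficients(T_E$left, T_M$left, fs)
  cr <- side_coefficients(T_E$right, T_M$right, fs)
  norm_mags <- function(cc) {
    e_dom <- Mod(cc$e[cc$dom_pos])
    s_dom <- Mod(cc$s[cc$dom_pos])
    en <- Mod(cc$e) / e_dom
    sn <- if (s_dom > .Machine$double.eps) Mod(cc$s) / s_dom
          else rep(0, length(cc$s))
    list(en = en, sn = sn, e_dom = e_dom, s_dom = s_dom)
  }
  nl <- norm_mags(cl); nr <- norm_mags(cr)
  if (is.null(s)) s <- default_phase_scale(nl$en, nr$en)
  reg <- sqrt((nl$e_dom - nl$s_dom)^2 + (nr$e_dom - nr$s_dom)^2)
  comp <- list(
    mag_left = l2(nl$en - nl$sn),
    phase_left = l2(phase_diffs(cl$e, cl$s)),
    mag_right = l2(nr$en - nr$sn),
    phase_right = l2(phase_diffs(cr$e, cr$s)),
    regularization = reg, scale = s)
  cost_value(s * comp$mag_left + comp$phase_left +
             s * comp$mag_right + comp$phase_right + reg, comp)
}

#' Normalized Euclidean selection metric
#'
#' The final figure of merit used to pick the best of the nine
#' optimizer-by-cost runs: the mean over sides of the residual energy
#' relative to the experimental signal energy. 0 corresponds to a perfect
#' fit; a model stuck at zero, or at twice the experimental trajectory,
#' scores exactly 1.
#'
#' @inheritParams gamma2
#' @return Non-negative scalar.
#' @export
gamma_final <- function(T_E, T_M, align = TRUE) {
  check_pair_compat(T_E, T_M)
  el <- sum(T_E$left^2); er <- sum(T_E$right^2)
  if (el == 0 || er == 0)
    stop("zero-energy experimental side", call. = FALSE)
  if (align) T_M <- align_phase(T_E, T_M)
  0.5 * (sum((T_E$left - T_M$left)^2) / el +
         sum((T_E$right - T_M$right)^2) / er)
}

#' Circularly align a model pair to an experimental pair
#'
#' Finds the single circular shift (common to both sides) that maximizes the
#' summed circular cross-correlation between the experimental and model
#' pairs, and applies it to the model pair. Used by the time-domain costs,
#' where the model's steady-state phase is arbitrary.
#'
#' @inheritParams gamma1
#' @return The shifted model `trajectory_pair`.
#' @export
align_phase <- function(T_E, T_M) {
  check_pair_compat(T_E, T_M)
  n <- length(T_E$left)
  cc <- Re(fft(fft(T_E$left) * Conj(fft(T_M$left)) +
               fft(T_E$right) * Conj(fft(T_M$right)), inverse = TRUE)) / n
  tau <- which.max(cc) - 1L
  if (tau == 0L) return(T_M)
  idx <- ((seq_len(n) - 1L - tau) %% n) + 1L
  trajectory_pair(T_M$left[idx], T_M$right[idx],
                  sample_rate = T_M$sample_rate, unit = T_M$unit,
                  px_scale = T_M$px_scale, meta = T_M$meta)
}
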