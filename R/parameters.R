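#' Standard parameter set of the two-mass vocal-fold model
#'
#' Returns the classical reference parameterization of the two-mass model
#' (2MM): per-fold lower and upper masses coupled by springs, with collision
#' springs three times as stiff as the corresponding tissue springs. The
#' internal unit system is cgs-ms (g, cm, ms), in which the pressure unit
#' g cm^-1 ms^-2 equals 10^5 Pa; all values below are usable verbatim in the
#' equations of motion.
#'
#' @param l Vibrating vocal-fold length in cm. The package convention for
#'   converting pixel trajectories assumes 1.0 cm for women and 1.6 cm for
#'   men; the reference set uses 1.4 cm.
#' @param x01,x02 Rest half-gap (cm) of the lower and upper mass. Per-subject
#'   values can be estimated from data via [estimate_rest_geometry()].
#' @param Ps Default subglottal pressure in cmH2O.
#' @return An object of class `tmm_params`: a named list with masses
#'   (`m1`, `m2`, g), stiffnesses (`k1`, `k2`, `kc`, g/ms^2), damping
#'   (`r1`, `r2`, g/ms), collision stiffnesses (`c1` = 3 k1, `c2` = 3 k2),
#'   rest geometry (`x01`, `x02`, cm; `a01`, `a02`, cm^2), lower-mass
#'   thickness `d1` (cm), fold length `l` (cm) and `Ps` (cmH2O).
#' @examples
#' std <- standard_parameters()
#' std$c1 / std$k1  # collision springs are 3x the tissue springs
#' @export
standard_parameters <- function(l = 1.4, x01 = 0.0179, x02 = 0.0179,
                                Ps = 8.0) {
  p <- list(
    m1 = 0.125, m2 = 0.025,
    k1 = 0.08, k2 = 0.008, kc = 0.025,
    r1 = 0.02, r2 = 0.02,
    c1 = 3 * 0.08, c2 = 3 * 0.008,
    x01 = x01, x02 = x02,
    a01 = 2 * l * x01, a02 = 2 * l * x02,
    d1 = 0.25, l = l, Ps = Ps
  )
  class(p) <- "tmm_params"
  validate_parameters(p)
  p
}

validate_parameters <- function(p) {
  pos <- c("m1", "m2", "k1", "k2", "kc", "c1", "c2", "x01", "x02",
           "a01", "a02", "d1", "l", "Ps")
  for (f in pos) {
    if (is.null(p[[f]]) || !is.finite(p[[f]]) || p[[f]] <= 0)
      stop("parameter '", f, "' must be strictly positive", call. = FALSE)
  }
  if (p$r1 < 0 || p$r2 < 0) stop("damping must be non-negative", call. = FALSE)
  if (abs(p$c1 - 3 * p$k1) > 1e-9 * p$k1 ||
      abs(p$c2 - 3 * p$k2) > 1e-9 * p$k2)
    stop("collision stiffness must equal 3x the tissue stiffness",
         call. = FALSE)
  for (i in 1:2) {
    a0 <- p[[paste0("a0", i)]]
    x0 <- p[[paste0("x0", i)]]
    if (abs(a0 - 2 * p$l * x0) > 0.01 * a0)
      stop("rest area a0", i, " inconsistent with 2*l*x0", i,
           " beyond 1%", call. = FALSE)
  }
  invisible(p)
}

#' @export
print.tmm_params <- function(x, ...) {
  cat("Two-mass model parameter set (cgs-ms units)\n")
  cat(sprintf("  masses      m1 = %.4g g, m2 = %.4g g\n", x$m1, x$m2))
  cat(sprintf("  stiffness   k1 = %.4g, k2 = %.4g, kc = %.4g g/ms^2\n",
              x$k1, x$k2, x$kc))
  cat(sprintf("  damping     r1 = %.4g, r2 = %.4g g/ms\n", x$r1, x$r2))
  cat(sprintf("  rest gap    x01 = %.4g cm, x02 = %.4g cm\n", x$x01, x$x02))
  cat(sprintf("  geometry    d1 = %.3g cm, l = %.3g cm\n", x$d1, x$l))
  cat(sprintf("  pressure    Ps = %.4g cmH2O\n", x$Ps))
  invisible(x)
}

#' Fit variables of the inverse problem
#'
#' Bundle the three quantities optimized per subject: the left and right
#' scaling factors and the subglottal pressure. Q scales stiffness up and
#' mass down on its side (higher Q = tenser, lighter fold), the model's
#' expression of laryngeal tension and left-right asymmetry.
#'
#' @param Ql,Qr Dimensionless per-side scaling factors (> 0).
#' @param Ps Subglottal pressure in cmH2O (> 0).
#' @return An object of class `tmm_fit_vars`.
#' @examples
#' fit_vars(Ql = 1.2, Qr = 1.1, Ps = 15)
#' @export
fit_vars <- function(Ql, Qr, Ps) {
  if (!is.finite(Ql) || Ql <= 0) stop("Ql must be > 0", call. = FALSE)
  if (!is.finite(Qr) || Qr <= 0) stop("Qr must be > 0", call. = FALSE)
  if (!is.finite(Ps) || Ps <= 0) stop("Ps must be > 0", call. = FALSE)
  structure(list(Ql = Ql, Qr = Qr, Ps = Ps), class = "tmm_fit_vars")
}

#' @export
print.tmm_fit_vars <- function(x, ...) {
  cat(sprintf("Fit variables: Ql = %.4g, Qr = %.4g, Ps = %.4g cmH2O\n",
              x$Ql, x$Qr, x$Ps))
  invisible(x)
}

# cmH2O -> g cm^-1 ms^-2 (= 10^5 Pa). 1 cmH2O = 98.0665 Pa.
CMH2O_TO_INTERNAL <- 98.0665 / 1e5

#' Apply Q-scaling to the standard parameter set
#'
#' Derives the effective per-side parameters of an asymmetric two-mass model:
#' stiffnesses (tissue, coupling and collision springs) are multiplied by the
#' side's scaling factor Q while masses are divided by it, encoding the
#' assumption that a tenser fold vibrates with less effective mass. Damping
#' and geometry are unchanged; the subglottal pressure is converted from
#' cmH2O to the internal pressure unit (g cm^-1 ms^-2, i.e. 10^5 Pa).
#'
#' @param std A `tmm_params` reference set, see [standard_parameters()].
#' @param fit A `tmm_fit_vars` triple, see [fit_vars()].
#' @return An object of class `tmm_effective`: list with per-side lists
#'   `left` and `right` (fields `m1`, `m2`, `k1`, `k2`, `kc`, `c1`, `c2`,
#'   `r1`, `r2`), shared geometry, and `Ps_internal`.
#' @examples
#' eff <- apply_scaling(standard_parameters(), fit_vars(2, 0.5, 8))
#' eff$left$m1   # 0.125 / 2
#' eff$right$k1  # 0.08 * 0.5
#' @export
apply_scaling <- function(std, fit) {
  stopifnot(inherits(std, "tmm_params"), inherits(fit, "tmm_fit_vars"))
  validate_parameters(std)
  side <- function(Q) {
    list(m1 = std$m1 / Q, m2 = std$m2 / Q,
         k1 = std$k1 * Q, k2 = std$k2 * Q, kc = std$kc * Q,
         c1 = std$c1 * Q, c2 = std$c2 * Q,
         r1 = std$r1, r2 = std$r2)
  }
  structure(list(
    left = side(fit$Ql), right = side(fit$Qr),
    x01 = std$x01, x02 = std$x02, a01 = std$a01, a02 = std$a02,
    d1 = std$d1, l = std$l,
    Ps_internal = fit$Ps * CMH2O_TO_INTERNAL
  ), class = "tmm_effective")
}

# Flatten effective parameters into the fixed vector layout the C++
# integrator expects.
effective_as_vector <- function(eff, smooth_eps = 0) {
  s <- function(q) c(q$m1, q$m2, q$k1, q$k2, q$kc, q$c1, q$c2, q$r1, q$r2)
  c(s(eff$left), s(eff$right),
    eff$x01, eff$x02, eff$a01, eff$a02, eff$d1, eff$l,
    eff$Ps_internal, smooth_eps)
}
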