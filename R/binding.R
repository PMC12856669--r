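# Equilibrium 1:1 binding fits and thermodynamic conversions.

#' Fraction of receptor bound under exact 1:1 mass balance
#'
#' Solves the 1:1 binding quadratic for the complex concentration using the
#' cancellation-free root
#' `RL = 2 R B / (b + sqrt(b^2 - 4 R B))`, `b = R + B + K_d`,
#' and returns `RL / R`.  Reduces to the hyperbolic `B / (B + K_d)` as the
#' receptor concentration goes to zero.
#'
#' @param K_d Dissociation constant, M.
#' @param receptor_total Total receptor concentration, M (> 0).
#' @param binder_total Total binder concentration, M (vectorized, >= 0).
#' @return Fraction bound in `[0, 1]`.
#' @export
fraction_bound_exact <- function(K_d, receptor_total, binder_total) {
  if (any(K_d < 0) || any(receptor_total <= 0))
    stop("K_d >= 0 and receptor_total > 0 required")
  if (any(binder_total < 0)) stop("binder_total must be >= 0")
  b <- receptor_total + binder_total + K_d
  disc <- pmax(b^2 - 4 * receptor_total * binder_total, 0)
  RL <- 2 * receptor_total * binder_total / (b + sqrt(disc))
  pmin(pmax(RL / receptor_total, 0), 1)
}

#' Hyperbolic (no-depletion) bound fraction
#'
#' @param K_d Dissociation constant, M.
#' @param binder_total Total binder concentration, M.
#' @return `binder_total / (binder_total + K_d)`.
#' @export
fraction_bound_hyperbolic <- function(K_d, binder_total) {
  if (any(K_d <= 0)) stop("K_d must be > 0")
  if (any(binder_total < 0)) stop("binder_total must be >= 0")
  binder_total / (binder_total + K_d)
}

#' Construct a titration series
#'
#' @param binder_total Total binder concentrations, M (>= 4 points).
#' @param signal Measured signal (e.g. fluorescence), arbitrary units.
#' @param receptor_total Total receptor concentration, M (> 0).
#' @return A `titration_series` data frame with the receptor concentration
#'   as an attribute.
#' @export
titration_series <- function(binder_total, signal, receptor_total) {
  stopifnot(length(binder_total) == length(signal))
  if (length(binder_total) < 4) stop("a titration needs at least 4 points")
  if (receptor_total <= 0) stop("receptor_total must be > 0")
  if (any(binder_total < 0)) stop("binder concentrations must be >= 0")
  structure(data.frame(binder_M = binder_total, signal = signal),
            receptor_total = receptor_total,
            class = c("titration_series", "data.frame"))
}

#' Fit a 1:1 binding isotherm to a titration
#'
#' Least-squares fit of `F0 + dF * fraction_bound(K_d)` where the bound
#' fraction accounts for receptor depletion (exact mass-balance quadratic)
#' by default; a hyperbolic variant is selectable for comparison.
#' Unidentifiable fits (flat signal, non-convergence) are flagged, never
#' silent.
#'
#' @param series A [titration_series()].
#' @param model `"exact-1:1"` (default, receptor depletion) or
#'   `"hyperbolic"`.
#' @return A list of class `binding_fit` with `K_d_hat`, `K_d_se`, `F0`,
#'   `dF`, `residual_rms`, `model`, `ok`, `message`.
#' @export
fit_titration <- function(series, model = c("exact-1:1", "hyperbolic")) {
  model <- match.arg(model)
  B <- series$binder_M
  y <- series$signal
  R <- attr(series, "receptor_total")
  fail <- function(msg) structure(
    list(K_d_hat = NA_real_, K_d_se = NA_real_, F0 = NA_real_, dF = NA_real_,
         residual_rms = NA_real_, model = model, ok = FALSE, message = msg),
    class = "binding_fit")
  rng <- diff(range(y))
  if (rng == 0 || rng < 1e-10 * max(abs(y), 1e-300))
    return(fail("flat signal: K_d unidentifiable"))

  frac <- if (model == "exact-1:1") {
    function(K_d, B) fraction_bound_exact(K_d, R, B)
  } else {
    function(K_d, B) fraction_bound_hyperbolic(K_d, B)
  }
  F0_0 <- y[which.min(B)]
  dF_0 <- y[which.max(B)] - F0_0
  half <- F0_0 + dF_0 / 2
  Kd_0 <- B[which.min(abs(y - half))]
  if (Kd_0 <= 0) Kd_0 <- stats::median(B[B > 0])

  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ F0 + dF * frac(K_d, B),
      data = list(B = B, y = y),
      start = list(F0 = F0_0, dF = dF_0, K_d = Kd_0),
      lower = c(F0 = -Inf, dF = -Inf, K_d = 1e-15),
      control = minpack.lm::nls.lm.control(maxiter = 300)),
    error = function(e) e)
  if (inherits(fit, "error")) return(fail(conditionMessage(fit)))
  co <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, 3))
  if (co[["K_d"]] <= 2e-15) return(fail("K_d at lower bound: unidentifiable"))
  structure(list(K_d_hat = unname(co[["K_d"]]), K_d_se = unname(se[["K_d"]]),
                 F0 = unname(co[["F0"]]), dF = unname(co[["dF"]]),
                 residual_rms = sqrt(mean(stats::residuals(fit)^2)),
                 model = model, ok = TRUE, message = "converged"),
            class = "binding_fit")
}

#' @export
print.binding_fit <- function(x, ...) {
  if (!x$ok) { cat("Titration fit FAILED:", x$message, "\n"); return(invisible(x)) }
  cat(sprintf("1:1 fit (%s): K_d = %.4g +/- %.2g M; F0 = %.4g; dF = %.4g\n",
              x$model, x$K_d_hat, x$K_d_se, x$F0, x$dF))
  invisible(x)
}

# Gas constant in kcal mol^-1 K^-1 (CODATA value converted to kcal)
.R_KCAL <- 1.987204e-3

#' Binding free energy from a dissociation constant
#'
#' `dG = R T ln(K_d)` against the 1 M standard state, with
#' R = 1.987204e-3 kcal/(mol K).  Negative for sub-molar affinities.
#'
#' @param K_d Dissociation constant, M.
#' @param T Temperature, K (default 298.15, i.e. 25 C).
#' @return Free energy of binding, kcal/mol.
#' @export
deltaG_from_Kd <- function(K_d, T = 298.15) {
  if (any(K_d <= 0) || T <= 0) stop("K_d and T must be > 0")
  .R_KCAL * T * log(K_d)
}

#' Dissociation constant from a binding free energy
#'
#' Inverse of [deltaG_from_Kd()].
#'
#' @param deltaG Free energy of binding, kcal/mol.
#' @param T Temperature, K.
#' @return Dissociation constant, M.
#' @export
Kd_from_deltaG <- function(deltaG, T = 298.15) {
  if (T <= 0) stop("T must be > 0")
  exp(deltaG / (.R_KCAL * T))
}

#' Fold-selectivity between two photostates
#'
#' Ratio of light- to dark-state dissociation constants.  When only a lower
#' bound on `K_d_light` is available (binding too weak to measure), the
#' result is itself a lower bound and is flagged as such.
#'
#' @param K_d_light Light-state dissociation constant or lower bound, M.
#' @param K_d_dark Dark-state dissociation constant, M.
#' @param light_is_lower_bound Logical; TRUE when `K_d_light` is a lower
#'   bound.
#' @return A list `value` (the ratio) and `is_lower_bound`.
#' @export
fold_selectivity <- function(K_d_light, K_d_dark, light_is_lower_bound = FALSE) {
  if (K_d_light <= 0 || K_d_dark <= 0) stop("dissociation constants must be > 0")
  list(value = K_d_light / K_d_dark, is_lower_bound = isTRUE(light_is_lower_bound))
}

#' Concentration from absorbance (Beer-Lambert)
#'
#' @param A Absorbance (dimensionless, >= 0).
#' @param epsilon Molar extinction coefficient, 1/(M cm).
#' @param path Path length, cm (default 1).
#' @return Concentration, M.
#' @export
conc_from_absorbance <- function(A, epsilon, path = 1) {
  if (any(A < 0) || epsilon <= 0 || path <= 0)
    stop("A >= 0 and epsilon*path > 0 required")
  A / (epsilon * path)
}
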