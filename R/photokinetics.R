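# Kinetic model of binder-modulated thermal reversion.
#
# A photoswitchable receptor (e.g. a CBCR GAF domain) is driven to its light
# state and relaxes back thermally with rate k_u when free and k_b when bound
# by a state-selective partner.  Under the coupling assumption
# (phi_switching = 1) the rate ratio equals the ratio of light- and
# dark-state dissociation constants, k_b/k_u = K_d,L/K_d,D, so rate-versus-
# concentration data yield the dark-state affinity.

#' Construct a four-state photoswitch/binder model
#'
#' Parameters of the thermodynamic cycle formed by the dark and light states
#' of a photoreceptor and their complexes with a binder: thermal reversion
#' rates for the unbound (`k_u`) and bound (`k_b`) receptor, and dissociation
#' constants of the binder from the dark (`K_d_dark`) and light (`K_d_light`)
#' states.  The coupling factor `phi_switching` is fixed at 1, under which
#' detailed balance requires `k_b/k_u == K_d_light/K_d_dark`.
#'
#' @param k_u Thermal reversion rate of the unbound receptor, 1/s.
#' @param K_d_dark Dark-state dissociation constant, M.
#' @param K_d_light Light-state dissociation constant, M.
#' @param k_b Thermal reversion rate of the bound receptor, 1/s.  Defaults to
#'   the detailed-balance value `k_u * K_d_light / K_d_dark`.
#' @return An object of class `four_state_model` with fields `k_u`, `k_b`,
#'   `K_d_dark`, `K_d_light`, `phi_switching` and a logical `consistent` flag
#'   (TRUE iff `k_b/k_u` matches `K_d_light/K_d_dark` to 1e-9 relative).
#' @examples
#' m <- four_state_model(k_u = 0.0116, K_d_dark = 3e-6, K_d_light = 1e-3)
#' m$k_b / m$k_u   # equals K_d_light / K_d_dark
#' @export
four_state_model <- function(k_u, K_d_dark, K_d_light,
                             k_b = k_u * K_d_light / K_d_dark) {
  stopifnot(is.numeric(k_u), is.numeric(k_b),
            is.numeric(K_d_dark), is.numeric(K_d_light))
  if (k_u <= 0 || k_b <= 0 || K_d_dark <= 0 || K_d_light <= 0)
    stop("all rates and dissociation constants must be > 0")
  ratio <- K_d_light / K_d_dark
  consistent <- abs(k_b / k_u - ratio) / ratio < 1e-9
  structure(list(k_u = k_u, k_b = k_b,
                 K_d_dark = K_d_dark, K_d_light = K_d_light,
                 phi_switching = 1.0, consistent = consistent),
            class = "four_state_model")
}

#' @export
print.four_state_model <- function(x, ...) {
  cat("Four-state photoswitch/binder model\n")
  cat(sprintf("  k_u       = %.4g /s   (half-life %.3g s)\n",
              x$k_u, half_life(x$k_u)))
  cat(sprintf("  k_b       = %.4g /s\n", x$k_b))
  cat(sprintf("  K_d,D     = %.4g M\n", x$K_d_dark))
  cat(sprintf("  K_d,L     = %.4g M\n", x$K_d_light))
  cat(sprintf("  k_b/k_u   = %.4g  (K_d,L/K_d,D = %.4g; consistent: %s)\n",
              x$k_b / x$k_u, x$K_d_light / x$K_d_dark, x$consistent))
  invisible(x)
}

#' Observed reversion rate at a given free binder concentration
#'
#' Population-weighted thermal reversion rate of the light state under
#' rapid-equilibrium binding: with a fraction `B/(B + K_d_light)` of the
#' light-state receptor bound, the observed rate is
#' `(k_u + k_b * B/K_d_light) / (1 + B/K_d_light)`.
#'
#' @param model A [four_state_model()].
#' @param binder_free Free binder concentration, M (vectorized, >= 0).
#' @return Observed reversion rate(s), 1/s.
#' @export
effective_rate <- function(model, binder_free) {
  stopifnot(inherits(model, "four_state_model"))
  if (any(binder_free < 0)) stop("binder concentration must be >= 0")
  x <- binder_free / model$K_d_light
  (model$k_u + model$k_b * x) / (1 + x)
}

#' Linearized observed rate, k_obs = k_u (1 + B_tot / K_d_dark)
#'
#' Valid when the coupling ratio holds (`k_b/k_u = K_d,L/K_d,D`) and the
#' total binder concentration is far below `K_d_light`, so that the
#' light-state receptor is mostly unbound and binder depletion is
#' negligible.  This is the working form fitted to rate-versus-concentration
#' data.
#'
#' @param k_u Unbound reversion rate, 1/s.
#' @param K_d_dark Dark-state dissociation constant, M.
#' @param binder_total Total binder concentration, M (vectorized, >= 0).
#' @return Predicted observed rate(s), 1/s.
#' @export
linearized_k_obs <- function(k_u, K_d_dark, binder_total) {
  if (any(k_u <= 0) || any(K_d_dark <= 0)) stop("k_u and K_d_dark must be > 0")
  if (any(binder_total < 0)) stop("binder_total must be >= 0")
  k_u * (1 + binder_total / K_d_dark)
}

#' Construct a kinetic decay trace
#'
#' @param times Strictly increasing time points, s (>= 5 points).
#' @param signal Measured signal, arbitrary units.
#' @param binder_total Total binder concentration for this trace, M.
#' @return A `kinetic_trace` object (data frame of time_s, signal, plus the
#'   binder concentration as an attribute).
#' @export
kinetic_trace <- function(times, signal, binder_total = 0) {
  stopifnot(length(times) == length(signal))
  if (length(times) < 5) stop("a kinetic trace needs at least 5 points")
  if (!all(is.finite(times)) || any(diff(times) <= 0))
    stop("times must be finite and strictly increasing")
  if (binder_total < 0) stop("binder_total must be >= 0")
  structure(data.frame(time_s = times, signal = signal),
            binder_total = binder_total, class = c("kinetic_trace", "data.frame"))
}

#' Fit a single-exponential decay A exp(-k t) + c
#'
#' Least-squares fit of a first-order decay to a kinetic trace.  Starting
#' values: offset from the mean of the final 5% of points, rate from a
#' log-linear regression of the baseline-subtracted signal.  Failure (flat
#' signal, non-convergence, or rate pinned at a bound) is flagged, never
#' silent.
#'
#' @param trace A [kinetic_trace()] (any data frame with `time_s`, `signal`
#'   columns is accepted).
#' @return A list of class `exp_fit` with `k_obs`, `amplitude`, `offset`,
#'   `k_obs_se`, `residual_rms`, `binder_total`, `ok` (logical) and
#'   `message`.
#' @export
fit_exponential <- function(trace) {
  t <- trace$time_s
  y <- trace$signal
  b_tot <- attr(trace, "binder_total")
  if (is.null(b_tot)) b_tot <- NA_real_
  fail <- function(msg) structure(
    list(k_obs = NA_real_, amplitude = NA_real_, offset = NA_real_,
         k_obs_se = NA_real_, residual_rms = NA_real_,
         binder_total = b_tot, ok = FALSE, message = msg),
    class = "exp_fit")
  if (length(t) < 5) return(fail("fewer than 5 points"))
  rng <- diff(range(y))
  if (rng == 0 || rng < 1e-12 * max(abs(y), 1e-300))
    return(fail("signal is constant: no decay to fit"))

  n_tail <- max(2L, ceiling(0.05 * length(y)))
  c0 <- mean(utils::tail(y, n_tail))
  a0 <- y[1] - c0
  if (abs(a0) < 1e-6 * rng) a0 <- rng * sign(a0 + .Machine$double.eps)
  # log-linear initialization on the decaying part of the signal
  z <- (y - c0) / a0
  keep <- z > 1e-3
  k0 <- if (sum(keep) >= 2) {
    sl <- stats::coef(stats::lm(log(z[keep]) ~ t[keep]))[2]
    max(-sl, 1e-8)
  } else 1 / max(t)

  fit <- tryCatch(
    minpack.lm::nlsLM(
      signal ~ A * exp(-k * time_s) + c,
      data = data.frame(time_s = t, signal = y),
      start = list(A = a0, k = k0, c = c0),
      lower = c(A = -Inf, k = 1e-12, c = -Inf),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) e)
  if (inherits(fit, "error")) return(fail(conditionMessage(fit)))
  co <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, 3))
  if (co[["k"]] <= 2e-12) return(fail("rate at lower bound: no decay"))
  structure(list(
    k_obs = unname(co[["k"]]), amplitude = unname(co[["A"]]),
    offset = unname(co[["c"]]), k_obs_se = unname(se[["k"]]),
    residual_rms = sqrt(mean(stats::residuals(fit)^2)),
    binder_total = b_tot, ok = TRUE, message = "converged"),
    class = "exp_fit")
}

#' Assemble a rate-versus-concentration series
#'
#' @param binder_total Total binder concentrations, M.
#' @param k_obs Observed reversion rates, 1/s.
#' @param k_obs_se Optional standard errors on `k_obs`, 1/s.
#' @return A `reversion_series` data frame.  A warning is raised when no
#'   binder-free (B = 0) measurement is present.
#' @export
reversion_series <- function(binder_total, k_obs, k_obs_se = NULL) {
  stopifnot(length(binder_total) == length(k_obs))
  if (length(unique(binder_total)) < 2)
    stop("need at least 2 distinct binder concentrations")
  if (!any(binder_total == 0))
    warning("no binder-free (B_tot = 0) point: intercept is an extrapolation")
  if (is.null(k_obs_se)) k_obs_se <- rep(NA_real_, length(k_obs))
  structure(data.frame(binder_total = binder_total, k_obs = k_obs,
                       k_obs_se = k_obs_se),
            class = c("reversion_series", "data.frame"))
}

#' Dark-state affinity from reversion kinetics
#'
#' Fits the linear law `k_obs = k_u (1 + B_tot / K_d,D)` by (weighted) linear
#' regression of observed rate on total binder concentration and inverts it:
#' `k_u` is the intercept and `K_d,D = intercept/slope`.  Standard errors are
#' propagated to `K_d,D` from the regression covariance by first-order error
#' propagation.  Weights are `1/SE^2` when rate standard errors are supplied,
#' uniform otherwise.
#'
#' @param series A [reversion_series()].
#' @param K_d_light Optional light-state dissociation constant, M, used only
#'   to check the validity condition `max(B_tot) << K_d,L`; a warning is
#'   emitted when `max(B_tot)/K_d,L > 0.1`.
#' @return A list of class `affinity_from_kinetics` with `K_d_dark_hat`,
#'   `K_d_dark_se`, `k_u_hat`, `k_u_se`, `slope`, `validity_ratio`, `ok`,
#'   `message`.
#' @export
fit_reversion_series <- function(series, K_d_light = NULL) {
  b <- series$binder_total
  k <- series$k_obs
  se <- series$k_obs_se
  w <- if (!is.null(se) && all(is.finite(se)) && all(se > 0)) 1 / se^2 else NULL
  fit <- stats::lm(k ~ b, weights = w)
  cf <- stats::coef(fit)
  # vcov warns on an exactly-interpolating (noiseless) fit; zero SEs are fine
  V <- suppressWarnings(stats::vcov(fit))
  intercept <- cf[[1]]; slope <- cf[[2]]
  validity <- if (is.null(K_d_light)) NA_real_ else max(b) / K_d_light
  if (!is.na(validity) && validity > 0.1)
    warning(sprintf(
      "max(B_tot)/K_d,L = %.2g > 0.1: linearized rate law may be biased",
      validity))
  if (!is.finite(slope) || slope <= 0)
    return(structure(list(K_d_dark_hat = NA_real_, K_d_dark_se = NA_real_,
                          k_u_hat = intercept, k_u_se = sqrt(V[1, 1]),
                          slope = slope, validity_ratio = validity,
                          ok = FALSE,
                          message = "non-positive slope: binder does not accelerate reversion"),
                     class = "affinity_from_kinetics"))
  Kd <- intercept / slope
  # delta method: var(i/s) = (1/s)^2 Vii + (i/s^2)^2 Vss - 2 (i/s^3) Vis
  g <- c(1 / slope, -intercept / slope^2)
  Kd_se <- sqrt(drop(t(g) %*% V %*% g))
  structure(list(K_d_dark_hat = Kd, K_d_dark_se = Kd_se,
                 k_u_hat = intercept, k_u_se = sqrt(V[1, 1]),
                 slope = slope, validity_ratio = validity,
                 ok = TRUE, message = "converged"),
            class = "affinity_from_kinetics")
}

#' @export
print.affinity_from_kinetics <- function(x, ...) {
  if (!x$ok) { cat("Kinetic affinity fit FAILED:", x$message, "\n"); return(invisible(x)) }
  cat(sprintf("K_d,D = %.4g +/- %.2g M;  k_u = %.4g +/- %.2g /s\n",
              x$K_d_dark_hat, x$K_d_dark_se, x$k_u_hat, x$k_u_se))
  invisible(x)
}

#' Photoswitch selectivity from reversion rates
#'
#' Under the coupling assumption (phi_switching = 1) the ratio of bound to
#' unbound reversion rates equals the ratio of light- to dark-state
#' dissociation constants, so `k_b/k_u` measures fold-selectivity directly.
#'
#' @param k_b Bound reversion rate, 1/s.
#' @param k_u Unbound reversion rate, 1/s.
#' @return Dimensionless ratio `k_b/k_u`, interpreted as `K_d,L/K_d,D`.
#' @export
selectivity_from_rates <- function(k_b, k_u) {
  if (k_b <= 0 || k_u <= 0) stop("rates must be > 0")
  k_b / k_u
}

#' Half-life of a first-order process
#'
#' @param k First-order rate constant, 1/s.
#' @return `ln(2)/k`, s.
#' @export
half_life <- function(k) {
  if (any(k <= 0)) stop("rate must be > 0")
  log(2) / k
}

#' First-order rate from a half-life
#'
#' @param t_half Half-life, s.
#' @return `ln(2)/t_half`, 1/s.
#' @export
rate_from_half_life <- function(t_half) {
  if (any(t_half <= 0)) stop("half-life must be > 0")
  log(2) / t_half
}

#' Light-state decay trace by explicit-association kinetics
#'
#' Validation companion to the rapid-equilibrium [effective_rate()]: instead
#' of assuming instantaneous light-state binding, integrates the two-species
#' system (free and bound light-state receptor) with explicit association
#' rate `k_on` and dissociation rate `k_on * K_d_light`, each species
#' decaying to the dark state with its own rate.  The summed light-state
#' population is returned as the observable.  With a diffusion-scale `k_on`
#' the apparent decay rate converges to the rapid-equilibrium prediction.
#'
#' @param model A [four_state_model()].
#' @param binder_free Free binder concentration, M (held constant: binder in
#'   excess).
#' @param times Output time grid, s.
#' @param k_on Association rate constant, 1/(M s); default 1e6.
#' @return A data frame `time_s`, `signal` (total light-state population,
#'   starting at 1 with the two species pre-equilibrated).
#' @export
reversion_ode_trace <- function(model, binder_free, times, k_on = 1e6) {
  stopifnot(inherits(model, "four_state_model"))
  if (binder_free < 0) stop("binder concentration must be >= 0")
  k_off <- k_on * model$K_d_light
  f_bound <- binder_free / (binder_free + model$K_d_light)
  y0 <- c(Pg = 1 - f_bound, PgB = f_bound)
  rhs <- function(t, y, p) {
    dPg  <- -model$k_u * y["Pg"] - k_on * binder_free * y["Pg"] + k_off * y["PgB"]
    dPgB <- -model$k_b * y["PgB"] + k_on * binder_free * y["Pg"] - k_off * y["PgB"]
    list(c(dPg, dPgB))
  }
  out <- deSolve::ode(y = y0, times = times, func = rhs, parms = NULL)
  data.frame(time_s = out[, "time"],
             signal = out[, "Pg"] + out[, "PgB"])
}
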