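#' Phenomenological growth-physiology laws
#'
#' Constructor for the pair of phenomenological laws that tie single-cell
#' geometry and chromosome-replication timing to growth rate in starving
#' *B. subtilis*:
#' division length \eqn{L(\mu) = a\, e^{-r/\mu} + L_0} (micrometres) and
#' replication-period \eqn{T_{rep}(\mu) = s/\mu + T_0} (hours).
#' Defaults are the fitted coefficients used throughout the package.
#'
#' @param length_amp amplitude \eqn{a} of the division-length law (um).
#' @param length_rate rate constant \eqn{r} of the division-length law (1/h).
#' @param length_offset small-growth limit \eqn{L_0} of division length (um).
#' @param trep_slope hyperbolic coefficient \eqn{s} of the replication-period
#'   law (dimensionless over \eqn{\mu}).
#' @param trep_offset fast-growth limit \eqn{T_0} of the replication period (h).
#' @param area fixed cell cross-sectional area (arbitrary units); cell volume
#'   is `area * division_length(mu)`. Only concentration ratios are meaningful.
#' @return An object of class `growth_law`.
#' @examples
#' law <- growth_law()
#' division_length(0.5, law)
#' replication_period(0.5, law)
#' @export
growth_law <- function(length_amp = 3.466, length_rate = 0.689,
                       length_offset = 3.743, trep_slope = 0.15,
                       trep_offset = 0.78, area = 1) {
  coefs <- c(length_amp = length_amp, length_rate = length_rate,
             length_offset = length_offset, trep_slope = trep_slope,
             trep_offset = trep_offset, area = area)
  if (any(!is.finite(coefs)) || any(coefs <= 0))
    stop("all growth-law coefficients must be positive and finite")
  structure(as.list(coefs), class = "growth_law")
}

#' @export
print.growth_law <- function(x, ...) {
  cat("Growth-physiology laws:\n")
  cat(sprintf("  L(mu)    = %.3f * exp(-%.3f/mu) + %.3f um\n",
              x$length_amp, x$length_rate, x$length_offset))
  cat(sprintf("  Trep(mu) = %.2f/mu + %.2f h\n", x$trep_slope, x$trep_offset))
  cat(sprintf("  V(mu)    = %.3g * L(mu)\n", x$area))
  invisible(x)
}

check_mu <- function(mu) {
  if (any(!is.finite(mu)) || any(mu <= 0))
    stop("growth rate `mu` must be positive and finite")
  mu
}

#' Cell length at division as a function of growth rate
#'
#' Evaluates \eqn{L(\mu) = a\,e^{-r/\mu} + L_0}: starving cells divide at
#' shorter lengths as growth slows, approaching `length_offset` as
#' \eqn{\mu \to 0}. Vectorised over `mu`. The exponential underflows cleanly
#' at tiny `mu`, so no special branch is required beyond domain checking.
#'
#' @param mu growth rate (1/h), positive.
#' @param law a [growth_law()].
#' @return division length (um).
#' @export
division_length <- function(mu, law = growth_law()) {
  check_mu(mu)
  law$length_amp * exp(-law$length_rate / mu) + law$length_offset
}

#' Duration of the DNA replication period as a function of growth rate
#'
#' Evaluates \eqn{T_{rep}(\mu) = s/\mu + T_0} (hours): replication takes
#' longer in slowly growing cells, approaching `trep_offset` at fast growth.
#'
#' @inheritParams division_length
#' @return replication period (h).
#' @export
replication_period <- function(mu, law = growth_law()) {
  check_mu(mu)
  law$trep_slope / mu + law$trep_offset
}

#' Growth-rate-dependent cell volume
#'
#' `V(mu) = area * L(mu)` with a fixed cross-sectional area.
#'
#' @inheritParams division_length
#' @return cell volume (arbitrary units).
#' @export
cell_volume <- function(mu, law = growth_law()) {
  law$area * division_length(mu, law)
}

#' Stable-protein accumulation model
#'
#' Describes a protein produced at a growth-independent rate `production`
#' and removed by first-order degradation/deactivation at rate `k_deg` plus
#' dilution by exponential volume growth at rate \eqn{\mu}. Its steady-state
#' concentration is
#' \deqn{C(\mu) = P / (V(\mu)\,(k_{deg} + \mu)),}
#' which is strictly decreasing in \eqn{\mu}: growth slowdown alone makes
#' stable proteins accumulate.
#'
#' @param production production rate P (molecules/min), growth independent.
#' @param k_deg degradation/deactivation rate (1/h), `>= 0`.
#' @param law a [growth_law()] supplying the volume law `V(mu)`; pass `NULL`
#'   for unit volume.
#' @return An object of class `stable_protein_model`.
#' @export
stable_protein_model <- function(production = 10, k_deg = 0.12,
                                 law = growth_law()) {
  if (production < 0) stop("`production` must be >= 0")
  if (k_deg < 0) stop("`k_deg` must be >= 0")
  structure(list(production = production, k_deg = k_deg, law = law),
            class = "stable_protein_model")
}

#' Steady-state concentration of a stable protein
#'
#' Evaluates \eqn{C(\mu) = P/(V(\mu)(k_{deg}+\mu))}. Growth rate acts as an
#' effective first-order removal constant on all cellular proteins, so the
#' concentration rises as growth slows; a shrinking volume at low \eqn{\mu}
#' amplifies the effect.
#'
#' @param model a [stable_protein_model()].
#' @param mu growth rate (1/h); `mu = 0` is allowed only when `k_deg > 0`.
#' @return concentration (molecules per volume unit).
#' @export
steady_state_concentration <- function(model, mu) {
  if (any(!is.finite(mu)) || any(mu < 0))
    stop("`mu` must be finite and >= 0")
  if (model$k_deg == 0 && any(mu == 0))
    stop("concentration diverges at mu = 0 with k_deg = 0")
  V <- if (is.null(model$law)) 1 else cell_volume(pmax(mu, .Machine$double.xmin),
                                                  model$law)
  # V(mu) -> area * length_offset as mu -> 0+, so the pmax guard only protects
  # exp(-r/mu) from 0/0 warnings; the limit itself is finite.
  model$production / (V * (model$k_deg + mu))
}

#' Normalised fold change of a stable protein across growth rates
#'
#' Concentration from [steady_state_concentration()] normalised by its value
#' at the reference growth rate `mu_ref` (default \eqn{\ln 2} per hour, one
#' doubling per hour). For the model law the normalised curve is independent
#' of the production rate, so fold-change data taken at different induction
#' levels collapse onto a single curve.
#'
#' @inheritParams steady_state_concentration
#' @param mu_ref normalisation growth rate (1/h).
#' @return dimensionless fold change `C(mu)/C(mu_ref)`.
#' @export
normalized_fold_change <- function(model, mu, mu_ref = log(2)) {
  steady_state_concentration(model, mu) /
    steady_state_concentration(model, mu_ref)
}

#' Worked steady-state copy number with dilution set by the generation time
#'
#' Back-of-the-envelope steady state used to illustrate stable-protein
#' accumulation: with no degradation, unit volume, and an effective dilution
#' rate equal to the inverse generation time, the steady-state copy number is
#' simply `production * generation_time`. A protein made at 10 molecules/min
#' reaches 600 copies at a 60-min generation time and 3,000 copies at 300 min.
#' This arithmetic (dilution = 1/generation time) is deliberately kept
#' separate from the \eqn{C(\mu)} law, whose \eqn{\mu} is a natural-log
#' elongation rate (\eqn{\ln 2 /} doubling time).
#'
#' @param production production rate (molecules/min).
#' @param generation_time generation time (min), positive.
#' @return steady-state copy number (molecules/cell).
#' @examples
#' worked_copy_number(10, 60)   # 600
#' worked_copy_number(10, 300)  # 3000
#' @export
worked_copy_number <- function(production, generation_time) {
  if (any(production < 0)) stop("`production` must be >= 0")
  if (any(generation_time <= 0)) stop("`generation_time` must be > 0")
  production * generation_time
}

#' Fit the degradation rate of a stable protein from fold-change data
#'
#' Nonlinear least squares of the normalised accumulation curve
#' \eqn{C(\mu)/C(\ln 2)} to (growth rate, fold change) observations, with the
#' degradation rate `k_deg` as the single free parameter (bounded below by 0).
#' The standard error comes from the Jacobian at the optimum (observed
#' curvature); no weighting is applied.
#'
#' @param points data frame (or matrix) with columns `mu` (1/h) and
#'   `fold_change` (positive, normalised at `mu_ref`).
#' @param law a [growth_law()] supplying the volume law.
#' @param mu_ref normalisation growth rate (1/h).
#' @param start starting value for `k_deg` (1/h).
#' @return list of class `fit_result` with `estimate`, `standard_error`,
#'   `residual_norm`, `n_points`, and `half_life_h` (= ln 2 / estimate).
#' @export
fit_degradation_rate <- function(points, law = growth_law(),
                                 mu_ref = log(2), start = 0.1) {
  points <- as.data.frame(points)
  if (!all(c("mu", "fold_change") %in% names(points)))
    stop("`points` needs columns `mu` and `fold_change`")
  if (nrow(points) < 3) stop("need at least 3 points")
  if (length(unique(points$mu)) < 2)
    stop("k_deg is not identifiable: all `mu` values identical")
  if (any(points$fold_change <= 0)) stop("fold changes must be > 0")
  check_mu(points$mu)

  curve_fn <- function(k, mu) {
    m <- stable_protein_model(production = 1, k_deg = k, law = law)
    normalized_fold_change(m, mu, mu_ref = mu_ref)
  }
  # fitted on the log scale: fold-change noise is multiplicative, so log
  # residuals are homoscedastic and the Jacobian-based standard error is
  # calibrated
  fit <- minpack.lm::nlsLM(
    log(fold_change) ~ log(curve_fn(k, mu)),
    data = points, start = list(k = start),
    lower = 0, upper = Inf,
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )
  est <- unname(coef(fit)["k"])
  se <- unname(summary(fit)$coefficients["k", "Std. Error"])
  structure(list(estimate = est, standard_error = se,
                 residual_norm = sqrt(sum(residuals(fit)^2)),
                 n_points = nrow(points),
                 half_life_h = log(2) / est),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("k_deg = %.4g +/- %.3g /h (half-life %.2f h), n = %d\n",
              x$estimate, x$standard_error, x$half_life_h, x$n_points))
  invisible(x)
}
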