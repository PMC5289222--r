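#' Colony-level nutrient-depletion model
#'
#' Batch Monod growth on a finite nutrient pool:
#' `dN/dt = mu(S) N`, `dS/dt = -mu(S) N / Y`,
#' `mu(S) = mu_max S / (K_s + S)`. An optional nutrient bolus (the
#' glucose-addition perturbation) is added to `S0` at time zero. The
#' `mu_law` closure can be swapped without code change.
#'
#' @param mu_max maximal growth rate (1/h).
#' @param K_s half-saturation nutrient level (nutrient units).
#' @param Y yield (cells per nutrient unit).
#' @param S0 initial nutrient.
#' @param N0 initial population.
#' @param bolus extra nutrient added at t = 0.
#' @param mu_law function `(S, model) -> mu`; defaults to Monod.
#' @return object of class `colony_model`.
#' @export
colony_model <- function(mu_max = 0.7, K_s = 0.3, Y = 1, S0 = 1, N0 = 0.01,
                         bolus = 0, mu_law = NULL) {
  if (any(c(mu_max, K_s, Y, S0, N0) <= 0) || bolus < 0)
    stop("colony parameters must be positive (bolus >= 0)")
  if (is.null(mu_law))
    mu_law <- function(S, model) model$mu_max * S / (model$K_s + S)
  structure(list(mu_max = mu_max, K_s = K_s, Y = Y, S0 = S0, N0 = N0,
                 bolus = bolus, mu_law = mu_law), class = "colony_model")
}

#' Simulate colony growth into starvation
#'
#' Integrates the nutrient-depletion model; the population growth rate
#' `mu(t)` is monotone nonincreasing because nutrients are only consumed.
#' Adding a bolus delays the time at which `mu` falls below any fixed
#' threshold but steepens the decline once the enlarged population
#' exhausts the pool.
#'
#' @param model a [colony_model()].
#' @param horizon simulation horizon (h).
#' @param dt output step (h).
#' @return data frame of class `colony_sim`: `t`, `N`, `S`, `mu`.
#' @export
simulate_colony <- function(model, horizon = 40, dt = 0.05) {
  rhs <- function(t, y, p) {
    mu <- model$mu_law(max(y[["S"]], 0), model)
    list(c(N = mu * y[["N"]], S = -mu * y[["N"]] / model$Y))
  }
  y0 <- c(N = model$N0, S = model$S0 + model$bolus)
  times <- seq(0, horizon, by = dt)
  sol <- deSolve::lsoda(y0, times, rhs, NULL, rtol = 1e-9, atol = 1e-12)
  if (attr(sol, "istate")[1] < 0) stop("colony integrator failed")
  out <- as.data.frame(sol)
  names(out) <- c("t", "N", "S")
  out$S <- pmax(out$S, 0)
  out$mu <- model$mu_law(out$S, model)
  structure(out, class = c("colony_sim", "data.frame"), model = model)
}

#' @export
print.colony_sim <- function(x, ...) {
  cat(sprintf("Colony simulation: %.0f h, N %.3g -> %.3g, mu %.2f -> %.3g /h\n",
              max(x$t), x$N[1], x$N[nrow(x)], x$mu[1], x$mu[nrow(x)]))
  invisible(x)
}

#' Time at which the colony growth rate crosses a threshold
#'
#' @param sim a [simulate_colony()] result.
#' @param mu_star threshold growth rate (1/h).
#' @return crossing time (h), linear interpolation; `NA` if never crossed.
#' @export
threshold_crossing_time <- function(sim, mu_star) {
  below <- sim$mu <= mu_star
  if (!any(below) || all(below)) return(NA_real_)
  i <- which(below)[1]
  if (i == 1) return(sim$t[1])
  stats::approx(sim$mu[(i - 1):i], sim$t[(i - 1):i], xout = mu_star)$y
}

#' Growth-threshold prediction of per-generation sporulating fractions
#'
#' The deferral predictor: within each generation, the predicted
#' sporulating fraction is the fraction of cell cycles whose mean growth
#' rate lies at or below the threshold. When fate labels are supplied the
#' observed fraction is reported alongside.
#'
#' @param records per-cycle table with `generation` and `mean_mu` columns,
#'   optionally `fate`.
#' @param mu_star growth threshold (1/h).
#' @return data frame of class `deferral_prediction`: `generation`,
#'   `predicted`, `observed` (NA without labels), `n`.
#' @export
predict_deferral <- function(records, mu_star) {
  if (nrow(records) == 0) stop("`records` must not be empty")
  grp <- split(records, records$generation)
  out <- do.call(rbind, lapply(grp, function(g) {
    data.frame(generation = g$generation[1],
               predicted = mean(g$mean_mu <= mu_star),
               observed = if ("fate" %in% names(g))
                 mean(g$fate == "spore") else NA_real_,
               n = nrow(g))
  }))
  rownames(out) <- NULL
  structure(out[order(out$generation), ],
            class = c("deferral_prediction", "data.frame"))
}

#' @export
print.deferral_prediction <- function(x, ...) {
  cat("Predicted sporulating fraction by generation:\n")
  print(format(as.data.frame(x), digits = 3), row.names = FALSE)
  invisible(x)
}
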