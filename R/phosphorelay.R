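#' Kinetic parameters of the sporulation phosphorelay model
#'
#' Parameter container for the deterministic model of the
#' KinA -> Spo0F -> Spo0B -> Spo0A phosphotransfer cascade. Transcription and
#' translation are lumped into one production rate per protein, scaled by
#' instantaneous gene dosage, divided by the growth-rate-dependent cell
#' volume, and (for native promoters) modulated by Spo0A~P through Hill
#' activation with a basal floor. KinA autophosphorylation is
#' substrate-inhibited by total Spo0F through a Hill-type term
#' \eqn{1/(1+(F_{tot}/K_I)^{n_I})} — the negative feedback that converts the
#' transient kinA:0F dosage imbalance into a 0A~P overshoot pulse at
#' replication completion. All concentrations are nM; time is hours; volume
#' is normalised to 1 at \eqn{\mu = \ln 2} per hour.
#'
#' Default rate constants are the package calibration: with them, at the
#' reference slow growth rate of 0.2/h, a +10% change in KinA production
#' changes the peak 0A~P by about +25% and a +10% change in 0F production by
#' about -18% (see `scripts/calibrate.R` for the procedure).
#'
#' @param v_kinA,v_0F,v_0B,v_0A maximal production rates (nM/h) of KinA,
#'   Spo0F, Spo0B, Spo0A at unit dosage and unit volume.
#' @param basal_kinA,basal_0F,basal_0A basal fraction of each 0A~P-activated
#'   promoter (spo0B is constitutive).
#' @param K_kinA,K_0F,K_0A half-activation 0A~P concentrations (nM).
#' @param K_0F_rep,n_0F_rep half-repression 0A~P concentration (nM) and Hill
#'   coefficient of the low-affinity repression of the spo0F promoter at
#'   high 0A~P.
#' @param n_kinA,n_0F,n_0A promoter Hill coefficients (>= 1).
#' @param kinA_feedback `"native"` keeps the 0A~P activation of kinA;
#'   `"none"` makes kinA production constitutive (used to show the feedback
#'   is dispensable for pulsing).
#' @param ka KinA autophosphorylation rate (1/h).
#' @param K_dim,n_auto scale (nM) and effective cooperativity of KinA
#'   oligomerisation: autophosphorylation flux is
#'   `ka * K_dim * (K/K_dim)^n_auto`, superlinear in the KinA monomer
#'   concentration because the active kinase is an oligomer.
#' @param K_I,n_I substrate-inhibition constant (nM, on total 0F) and Hill
#'   coefficient of KinA autophosphorylation.
#' @param kt1,kt2,kt3 forward phosphotransfer rate constants (1/nM/h) for
#'   KinA~P->0F, 0F~P->0B, 0B~P->0A.
#' @param kr1,kr2,kr3 reverse phosphotransfer rate constants (1/nM/h).
#' @param kph Spo0A~P dephosphorylation rate (1/h).
#' @param kdp_f Spo0F~P drain/dephosphorylation rate (1/h).
#' @param kdeg_F first-order removal rate (1/h) of Spo0F protein
#'   (Rap-phosphatase-family-mediated turnover). Fast relative to dilution,
#'   it lets 0F track its gene-dosage steps within a cell cycle — the source
#'   of pulse contrast — and makes the 0F level nearly growth-independent,
#'   while stable KinA keeps the dilution-set accumulation that drives the
#'   amplitude increase at slow growth.
#' @param v_hsp_kinA,v_hsp_0F production rates (nM/h) of inducible-promoter
#'   gene copies at unit inducer level.
#' @return object of class `phosphorelay_params` (a named list).
#' @export
phosphorelay_params <- function(v_kinA = 20, v_0F = 600, v_0B = 60,
                                v_0A = 150,
                                basal_kinA = 0.9, basal_0F = 1,
                                basal_0A = 0.3,
                                K_kinA = 300, K_0F = 20, K_0A = 100,
                                K_0F_rep = Inf, n_0F_rep = 2,
                                n_kinA = 2, n_0F = 2, n_0A = 2,
                                kinA_feedback = c("native", "none"),
                                ka = 22, K_dim = 100, n_auto = 2.385, K_I = 1200, n_I = 3,
                                kt1 = 0.2, kt2 = 0.2, kt3 = 0.2,
                                kr1 = 0.02, kr2 = 0.02, kr3 = 0.02,
                                kph = 30, kdp_f = 10, kdeg_F = 0,
                                v_hsp_kinA = 20, v_hsp_0F = 56) {
  kinA_feedback <- match.arg(kinA_feedback)
  p <- as.list(environment())
  num <- unlist(p[vapply(p, is.numeric, logical(1))])
  if (any(num < 0)) stop("all rates and constants must be >= 0")
  if (any(c(n_kinA, n_0F, n_0A, n_I) < 1)) stop("Hill coefficients must be >= 1")
  structure(p, class = "phosphorelay_params")
}

#' @export
print.phosphorelay_params <- function(x, ...) {
  cat("Phosphorelay parameters (nM, h):\n")
  cat(sprintf("  production v = [kinA %.3g, 0F %.3g, 0B %.3g, 0A %.3g]\n",
              x$v_kinA, x$v_0F, x$v_0B, x$v_0A))
  cat(sprintf("  autophosphorylation ka = %.3g /h, 0F inhibition K_I = %.3g nM (n = %g)\n",
              x$ka, x$K_I, x$n_I))
  cat(sprintf("  kinA feedback: %s\n", x$kinA_feedback))
  invisible(x)
}

#' Strain configuration for phosphorelay simulations
#'
#' Wires chromosomal locus positions, promoter types and the inducer
#' schedule for the modelled strains:
#' \describe{
#'   \item{WT}{native arrangement: *spo0F* oriC-proximal, *kinA*
#'     ter-proximal, native (0A~P-regulated) promoters.}
#'   \item{iTrans-0F}{native-promoter *spo0F* translocated to the terminus
#'     plus an IPTG-inducible copy near oriC; dosage-driven pulsing becomes
#'     inducer-dependent.}
#'   \item{inducible-KinA}{*kinA* expressed from an inducible promoter (no
#'     0A~P feedback) at its ter-proximal locus; production scales with
#'     `inducer_level` times `v_hsp_kinA`.}
#'   \item{dsda}{label-only sda deletion; behaves identically to WT in this
#'     model.}
#' }
#'
#' @param name strain name.
#' @param inducer_level relative inducer (IPTG) level, `>= 0`; 1 means the
#'   full `v_hsp_*` rate.
#' @param inducer_at time (h) at which the inducer is added.
#' @param loci optional named origin-distance override.
#' @return object of class `strain_config` with a locus map and a per-gene
#'   list of promoter copies.
#' @export
strain_config <- function(name = c("WT", "iTrans-0F", "inducible-KinA", "dsda"),
                          inducer_level = 1, inducer_at = 0, loci = NULL) {
  name <- match.arg(name)
  if (inducer_level < 0) stop("`inducer_level` must be >= 0")
  base <- default_loci()
  genes <- list(
    kinA = list(list(locus = "kinA", type = "native")),
    spo0F = list(list(locus = "spo0F", type = "native")),
    spo0B = list(list(locus = "spo0B", type = "native")),
    spo0A = list(list(locus = "spo0A", type = "native"))
  )
  if (name == "iTrans-0F") {
    # relocated native 0F sits in the same terminus-proximal region as kinA,
    # so without inducer the kinA:0F dosage ratio never leaves 1:1
    base <- c(base, spo0F_ter = unname(base["kinA"]))
    base["spo0F"] <- 34 / 180  # inducible copy occupies the oriC-proximal site
    genes$spo0F <- list(list(locus = "spo0F_ter", type = "native"),
                        list(locus = "spo0F", type = "inducible"))
  } else if (name == "inducible-KinA") {
    genes$kinA <- list(list(locus = "kinA", type = "inducible"))
  }
  if (!is.null(loci)) base[names(loci)] <- loci
  structure(list(name = name, loci = base, genes = genes,
                 inducer_level = inducer_level, inducer_at = inducer_at),
            class = "strain_config")
}

#' @export
print.strain_config <- function(x, ...) {
  cat(sprintf("Strain %s (inducer %.3g from t = %g h)\n",
              x$name, x$inducer_level, x$inducer_at))
  invisible(x)
}

relay_species <- c("K", "Kp", "F", "Fp", "B", "Bp", "A", "Ap")

hill_act <- function(ap, basal, K, n) basal + (1 - basal) * ap^n / (K^n + ap^n)

# volume normalised to 1 at mu = ln 2 per hour
relay_volume <- function(mu, law) {
  division_length(mu, law) / division_length(log(2), law)
}

# per-gene production rate (nM/h) at dosage `dos` per copy, volume V,
# inducer level ind, current Ap. Native spo0F transcription scales with
# growth rate (gene-expression machinery scaling, normalised to 1 at
# mu = ln 2), which makes the steady 0F level growth-independent: 0F
# homeostasis against dilution, while stable KinA accumulates as growth
# slows. Inducible-promoter copies are growth-independent.
relay_production <- function(gene, copies, dos, ap, V, ind, mu, params) {
  total <- 0
  for (i in seq_along(copies)) {
    cp <- copies[[i]]
    rate <- if (cp$type == "inducible") {
      ind * switch(gene, kinA = params$v_hsp_kinA, spo0F = params$v_hsp_0F,
                   stop("no inducible rate for gene ", gene))
    } else {
      switch(gene,
        kinA = params$v_kinA *
          (if (params$kinA_feedback == "native")
             hill_act(ap, params$basal_kinA, params$K_kinA, params$n_kinA)
           else 1),
        spo0F = params$v_0F * (mu * V / log(2)) *
          hill_act(ap, params$basal_0F, params$K_0F, params$n_0F) /
          (1 + (ap / params$K_0F_rep)^params$n_0F_rep),
        spo0B = params$v_0B,
        spo0A = params$v_0A * hill_act(ap, params$basal_0A, params$K_0A, params$n_0A))
    }
    total <- total + dos[[i]] * rate
  }
  total / V
}

# ODE right-hand side; parms carries mu_fn, law, params, strain genes,
# per-gene dosage (list of per-copy dosages) and inducer level (constants
# within one integration segment).
relay_rhs <- function(t, y, parms) {
  p <- parms$params
  mu <- parms$mu_fn(t)
  V <- relay_volume(mu, parms$law)
  y <- pmax(y, 0)
  K <- y[1]; Kp <- y[2]; F <- y[3]; Fp <- y[4]
  B <- y[5]; Bp <- y[6]; A <- y[7]; Ap <- y[8]

  prod <- vapply(names(parms$genes), function(g)
    relay_production(g, parms$genes[[g]], parms$dosage[[g]], Ap, V,
                     parms$inducer, mu, p), numeric(1))

  Ftot <- F + Fp
  # KinA autophosphorylates as a cooperatively assembled dimer/tetramer:
  # flux goes as (K/K_dim)^n_auto (unsaturated assembly regime), and is
  # substrate-inhibited by total 0F
  auto <- p$ka * p$K_dim * (K / p$K_dim)^p$n_auto /
    (1 + (Ftot / p$K_I)^p$n_I)
  pt1 <- p$kt1 * Kp * F - p$kr1 * K * Fp
  pt2 <- p$kt2 * Fp * B - p$kr2 * F * Bp
  pt3 <- p$kt3 * Bp * A - p$kr3 * B * Ap

  dK  <- prod[["kinA"]] - auto + pt1 - mu * K
  dKp <- auto - pt1 - mu * Kp
  dF  <- prod[["spo0F"]] - pt1 + pt2 + p$kdp_f * Fp - (mu + p$kdeg_F) * F
  dFp <- pt1 - pt2 - p$kdp_f * Fp - (mu + p$kdeg_F) * Fp
  dB  <- prod[["spo0B"]] - pt2 + pt3 - mu * B
  dBp <- pt2 - pt3 - mu * Bp
  dA  <- prod[["spo0A"]] - pt3 + p$kph * Ap - mu * A
  dAp <- pt3 - p$kph * Ap - mu * Ap
  list(c(dK, dKp, dF, dFp, dB, dBp, dA, dAp))
}

relay_integrate <- function(y0, times, parms, rtol = 1e-8, atol = 1e-8) {
  sol <- deSolve::lsoda(y0, times, relay_rhs, parms,
                        rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1] < 0)
    stop(sprintf("phosphorelay integrator failed near t = %.3f h", max(sol[, 1])))
  if (min(sol[, -1]) < -1e-5)
    stop("negative concentration beyond tolerance in phosphorelay solution")
  sol[, -1][sol[, -1] < 0] <- 0
  sol
}

#' Fixed point of the phosphorelay at frozen dosage and growth rate
#'
#' Integrates the model with all gene dosages pinned (default 1:1) and a
#' constant growth rate until the state stops changing; used as the initial
#' condition for event-driven simulations and as an oracle for the
#' frozen-dosage control.
#'
#' @param params a [phosphorelay_params()].
#' @param strain a [strain_config()].
#' @param mu constant growth rate (1/h).
#' @param dosage copy number applied to every gene copy.
#' @param law a [growth_law()].
#' @param y0 optional starting state.
#' @param t_max integration horizon (h).
#' @return named steady-state concentration vector (nM).
#' @export
relay_fixed_point <- function(params, strain = strain_config("WT"), mu,
                              dosage = 1, law = growth_law(), y0 = NULL,
                              t_max = 400) {
  parms <- list(params = params, law = law, genes = strain$genes,
                mu_fn = function(t) rep_len(mu, length(t)),
                dosage = lapply(strain$genes, function(cp)
                  rep(dosage, length(cp))),
                inducer = strain$inducer_level)
  if (is.null(y0)) y0 <- stats::setNames(rep(1, 8), relay_species)
  sol <- relay_integrate(y0, c(0, t_max / 2, t_max), parms)
  stats::setNames(sol[nrow(sol), relay_species], relay_species)
}

# inducer level at time t for a strain (0 before inducer_at)
inducer_at_time <- function(strain, t) {
  if (t >= strain$inducer_at) strain$inducer_level else 0
}

#' Simulate the phosphorelay over a cell-cycle schedule
#'
#' Event-driven deterministic simulation: the ODE system is integrated
#' between schedule events with piecewise-constant gene dosages taken from
#' the schedule's dosage timeline; every species is diluted at \eqn{\mu(t)}
#' and produced into the volume \eqn{V(\mu(t))}. Concentrations are
#' continuous across symmetric divisions (volume and copy number halve
#' together). Inducer switch-on times are added as extra integration
#' breakpoints.
#'
#' @param strain a [strain_config()].
#' @param params a [phosphorelay_params()].
#' @param traj a [growth_trajectory()].
#' @param schedule a [build_schedule()] result built with `strain$loci`;
#'   computed automatically when omitted.
#' @param y0 initial state; defaults to the frozen fixed point at
#'   \eqn{\mu(0)}.
#' @param dt dense output step (h) for peak detection.
#' @param law a [growth_law()].
#' @param birth_length initial cell length (um), used when `schedule` is
#'   omitted.
#' @param pin_dosage keep every gene at copy number 1 throughout (control
#'   run without dosage-driven pulsing); schedule events still bound the
#'   integration segments.
#' @return object of class `phosphorelay_sim`: data frame with time, the 8
#'   species (nM), total KinA/0F, per-gene kinA and spo0F dosage, `mu` and
#'   `volume`; the schedule is attached as an attribute.
#' @export
simulate_phosphorelay <- function(strain, params, traj, schedule = NULL,
                                  y0 = NULL, dt = 0.01, law = growth_law(),
                                  birth_length = 2.5, pin_dosage = FALSE) {
  if (is.null(schedule))
    schedule <- build_schedule(traj, law, birth_length = birth_length,
                               horizon = traj$duration, loci = strain$loci)
  timeline <- dosage_timeline(schedule, strain$loci)
  brk <- sort(unique(c(0, schedule$time,
                       if (strain$inducer_at > 0 &&
                           strain$inducer_at < max(schedule$time))
                         strain$inducer_at)))
  brk <- brk[brk <= max(schedule$time)]
  if (is.null(y0))
    y0 <- relay_fixed_point(params, strain, traj$fn(0), law = law)

  rows <- vector("list", length(brk) - 1)
  y <- y0
  for (i in seq_len(length(brk) - 1)) {
    t0 <- brk[i]; t1 <- brk[i + 1]
    if (t1 - t0 < 1e-9) next
    mid <- (t0 + t1) / 2
    parms <- list(
      params = params, law = law, genes = strain$genes,
      mu_fn = traj$fn,
      dosage = lapply(names(strain$genes), function(g)
        vapply(strain$genes[[g]], function(cp)
          if (pin_dosage) 1 else dosage_at(timeline, cp$locus, mid),
          numeric(1))),
      inducer = inducer_at_time(strain, mid))
    names(parms$dosage) <- names(strain$genes)
    times <- unique(c(seq(t0, t1, by = dt), t1))
    sol <- relay_integrate(y, times, parms)
    y <- stats::setNames(sol[nrow(sol), relay_species], relay_species)
    seg <- as.data.frame(sol)
    names(seg) <- c("time", relay_species)
    seg$dosage_kinA <- dosage_at(timeline, "kinA", mid)
    seg$dosage_spo0F <- dosage_at(timeline, "spo0F", mid)
    rows[[i]] <- seg
  }
  out <- do.call(rbind, rows)
  out <- out[!duplicated(out$time), ]
  out$mu <- traj$fn(out$time)
  out$volume <- relay_volume(out$mu, law)
  out$KinA_total <- out$K + out$Kp
  out$F_total <- out$F + out$Fp
  rownames(out) <- NULL
  structure(out, class = c("phosphorelay_sim", "data.frame"),
            schedule = schedule, strain = strain, params = params)
}

#' @export
print.phosphorelay_sim <- function(x, ...) {
  sched <- attr(x, "schedule")
  n_cyc <- if (is.null(sched)) NA else max(sched$cycle)
  cat(sprintf("Phosphorelay simulation: %.1f h, %s cycles, peak 0A~P %.1f nM\n",
              max(x$time), format(n_cyc), max(x$Ap)))
  invisible(x)
}

#' @export
plot.phosphorelay_sim <- function(x, y, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  graphics::plot(x$time, x$mu, type = "l", xlab = "time (h)",
                 ylab = "growth rate (1/h)", ...)
  graphics::plot(x$time, x$Ap, type = "l", col = "firebrick",
                 xlab = "time (h)", ylab = "0A~P (nM)", ...)
  div <- attr(x, "schedule")
  graphics::abline(v = div$time[div$kind == "division"], lty = 3,
                   col = "grey60")
  invisible(x)
}

#' Per-cycle Spo0A~P pulse records
#'
#' Extracts, for every completed cell cycle of a simulation, the peak 0A~P
#' concentration on the dense solver output, its time, the cycle-mean growth
#' rate, and the peak total KinA level.
#'
#' @param sim a [simulate_phosphorelay()] result.
#' @param schedule schedule (defaults to the one attached to `sim`).
#' @return data frame of class `pulse_records` with one row per cycle:
#'   `cycle`, `peak_Ap`, `t_peak`, `mean_mu`, `peak_KinA`, `mean_Ap`.
#' @export
pulse_amplitudes <- function(sim, schedule = attr(sim, "schedule")) {
  sched <- as.data.frame(schedule)
  births <- sched[sched$kind == "birth", ]
  divs <- sched[sched$kind == "division", ]
  cycles <- intersect(births$cycle, divs$cycle)
  if (length(cycles) == 0)
    return(structure(data.frame(), class = c("pulse_records", "data.frame")))
  recs <- lapply(cycles, function(cy) {
    t0 <- births$time[births$cycle == cy]
    t1 <- divs$time[divs$cycle == cy]
    w <- sim$time >= t0 & sim$time <= t1
    if (!any(w)) return(NULL)
    i <- which.max(sim$Ap[w])
    data.frame(cycle = cy,
               peak_Ap = sim$Ap[w][i],
               t_peak = sim$time[w][i],
               mean_mu = mean(sim$mu[w]),
               peak_KinA = max(sim$KinA_total[w]),
               mean_Ap = mean(sim$Ap[w]))
  })
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  structure(out, class = c("pulse_records", "data.frame"))
}

# one steady-state cycle structure at constant mu: returns event breakpoints
# (relative to birth) and per-segment dosage map; division deferred to
# replication completion when Trep exceeds the mass-doubling time.
steady_cycle <- function(strain, mu, law) {
  trep <- replication_period(mu, law)
  t_len <- log(2) / mu
  T <- max(t_len, trep)
  dup <- sort(strain$loci[unique(unlist(lapply(strain$genes, function(cp)
    vapply(cp, `[[`, character(1), "locus"))))]) * trep
  brk <- sort(unique(c(0, unname(dup), trep, T)))
  brk <- brk[brk <= T + 1e-12]
  list(T = T, trep = trep, brk = brk,
       dup_times = dup)
}

# integrate one constant-mu cycle from state y; returns final state, peak Ap,
# peak KinA over the cycle
relay_cycle_step <- function(y, strain, params, mu, law, cyc, dt, inducer) {
  peak <- -Inf; peakK <- -Inf
  for (i in seq_len(length(cyc$brk) - 1)) {
    t0 <- cyc$brk[i]; t1 <- cyc$brk[i + 1]
    if (t1 - t0 < 1e-9) next
    mid <- (t0 + t1) / 2
    dosage <- lapply(names(strain$genes), function(g)
      vapply(strain$genes[[g]], function(cp) {
        d <- strain$loci[[cp$locus]] * cyc$trep
        if (mid >= d) 2 else 1
      }, numeric(1)))
    names(dosage) <- names(strain$genes)
    parms <- list(params = params, law = law, genes = strain$genes,
                  mu_fn = function(t) rep_len(mu, length(t)),
                  dosage = dosage, inducer = inducer)
    times <- unique(c(seq(t0, t1, by = dt), t1))
    sol <- relay_integrate(y, times, parms)
    y <- stats::setNames(sol[nrow(sol), relay_species], relay_species)
    peak <- max(peak, max(sol[, "Ap"]))
    peakK <- max(peakK, max(sol[, "K"] + sol[, "Kp"]))
  }
  list(y = y, peak = peak, peak_KinA = peakK)
}

#' Steady per-cycle 0A~P pulse amplitude at constant growth rate
#'
#' Simulates repeated identical cell cycles at a constant growth rate until
#' successive pulse peaks agree to within `tol` (relative), and returns the
#' converged peak — the model's periodic steady state at that growth rate.
#'
#' @param params a [phosphorelay_params()].
#' @param strain a [strain_config()].
#' @param mu constant growth rate (1/h).
#' @param law a [growth_law()].
#' @param tol relative convergence tolerance on successive peaks.
#' @param max_cycles cap on the number of cycles.
#' @param dt dense output step (h).
#' @return list with `peak` (nM), `peak_KinA` (nM), `cycles` used, and
#'   `converged` flag.
#' @export
steady_pulse <- function(params, strain = strain_config("WT"), mu,
                         law = growth_law(), tol = 0.005, max_cycles = 80,
                         dt = 0.01) {
  check_mu(mu)
  cyc <- steady_cycle(strain, mu, law)
  y <- relay_fixed_point(params, strain, mu, law = law)
  prev <- NA_real_
  res <- NULL
  for (n in seq_len(max_cycles)) {
    res <- relay_cycle_step(y, strain, params, mu, law, cyc, dt,
                            strain$inducer_level)
    y <- res$y
    if (n >= 3 && is.finite(prev) && prev > 0 &&
        abs(res$peak - prev) / prev < tol) {
      return(list(peak = res$peak, peak_KinA = res$peak_KinA,
                  cycles = n, converged = TRUE))
    }
    prev <- res$peak
  }
  list(peak = res$peak, peak_KinA = res$peak_KinA,
       cycles = max_cycles, converged = FALSE)
}

#' Pulse-amplitude-versus-growth-rate curve
#'
#' Periodic steady-state 0A~P pulse peak as a function of growth rate over a
#' grid. The curve is monotone decreasing — slow growth means less dilution,
#' smaller volume, more KinA, and longer post-replication 1:1 dosage windows,
#' all of which raise the pulse — and is ultrasensitive in the threshold
#' region.
#'
#' @param params a [phosphorelay_params()].
#' @param strain a [strain_config()].
#' @param mu_grid growth rates (1/h).
#' @param ... passed to [steady_pulse()].
#' @return data frame of class `amplitude_curve` with `mu`, `peak_Ap`,
#'   `peak_KinA`, `converged`.
#' @export
amplitude_vs_growth <- function(params, strain = strain_config("WT"),
                                mu_grid, ...) {
  rows <- lapply(mu_grid, function(m) {
    r <- steady_pulse(params, strain, m, ...)
    data.frame(mu = m, peak_Ap = r$peak, peak_KinA = r$peak_KinA,
               converged = r$converged)
  })
  out <- do.call(rbind, rows)
  structure(out, class = c("amplitude_curve", "data.frame"))
}

#' @export
plot.amplitude_curve <- function(x, y, ...) {
  graphics::plot(x$mu, x$peak_Ap, type = "b", log = "y",
                 xlab = "growth rate (1/h)", ylab = "peak 0A~P (nM)", ...)
  invisible(x)
}

#' Growth-rate threshold at a fixed 0A~P cutoff
#'
#' The growth rate at which an amplitude-versus-growth curve crosses a fixed
#' 0A~P amplitude threshold (log-linear interpolation); cells growing slower
#' than this rate exceed the sporulation threshold.
#'
#' @param curve an [amplitude_vs_growth()] result.
#' @param ap_threshold 0A~P cutoff (nM).
#' @return growth rate (1/h), `NA` if the curve never crosses.
#' @export
growth_threshold_from_curve <- function(curve, ap_threshold) {
  cv <- curve[order(curve$mu), ]
  above <- cv$peak_Ap >= ap_threshold
  if (all(above) || all(!above)) return(NA_real_)
  i <- max(which(above))  # curve decreasing in mu
  if (i == nrow(cv)) return(NA_real_)
  x1 <- cv$mu[i]; x2 <- cv$mu[i + 1]
  y1 <- log(cv$peak_Ap[i]); y2 <- log(cv$peak_Ap[i + 1])
  x1 + (log(ap_threshold) - y1) * (x2 - x1) / (y2 - y1)
}

#' KinA-level threshold at a fixed 0A~P cutoff
#'
#' The peak total KinA level at the growth rate where the 0A~P pulse
#' amplitude crosses the sporulation cutoff. Under the model this KinA
#' threshold is set by relay biochemistry alone, so it is (nearly)
#' independent of the KinA production rate, whereas the growth-rate
#' threshold is not.
#'
#' @inheritParams growth_threshold_from_curve
#' @return KinA level (nM) at the crossing, `NA` if no crossing.
#' @export
kina_threshold_from_curve <- function(curve, ap_threshold) {
  mu_star <- growth_threshold_from_curve(curve, ap_threshold)
  if (is.na(mu_star)) return(NA_real_)
  cv <- curve[order(curve$mu), ]
  exp(stats::approx(cv$mu, log(cv$peak_KinA), xout = mu_star)$y)
}

#' Sensitivity of the pulse amplitude to a gene's production rate
#'
#' Percent change in the periodic steady-state 0A~P pulse peak when one
#' gene's production rate is multiplied by `1 + delta`, at a reference
#' growth rate in the pulsing regime.
#'
#' @param params a [phosphorelay_params()].
#' @param strain a [strain_config()].
#' @param mu_ref reference growth rate (1/h).
#' @param target one of `"kinA"`, `"spo0F"`, `"spo0B"`, `"spo0A"`.
#' @param delta fractional perturbation in `(-0.5, 0.5)`.
#' @param ... passed to [steady_pulse()].
#' @return percent change `100 * (peak_perturbed - peak_base)/peak_base`.
#' @export
relay_sensitivity <- function(params, strain = strain_config("WT"),
                              mu_ref = 0.2, target = "kinA", delta = 0.1,
                              ...) {
  if (abs(delta) >= 0.5) stop("`delta` must be in (-0.5, 0.5)")
  base <- steady_pulse(params, strain, mu_ref, ...)
  if (base$peak < 1e-9) stop("base pulse peak is ~0; sensitivity undefined")
  if (delta == 0) return(0)
  field <- switch(target, kinA = "v_kinA", spo0F = "v_0F",
                  spo0B = "v_0B", spo0A = "v_0A",
                  stop("unknown target gene: ", target))
  pert <- params
  pert[[field]] <- pert[[field]] * (1 + delta)
  # inducible copies share the gene's perturbation
  hsp <- switch(target, kinA = "v_hsp_kinA", spo0F = "v_hsp_0F", NULL)
  if (!is.null(hsp)) pert[[hsp]] <- pert[[hsp]] * (1 + delta)
  per <- steady_pulse(pert, strain, mu_ref, ...)
  100 * (per$peak - base$peak) / base$peak
}
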