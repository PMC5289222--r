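# helper: per-cycle pulse contrast (peak / within-cycle trough) of the last
# complete cycle of a constant-growth simulation
last_cycle_contrast <- function(strain, params = default_params, mu = 0.2,
                                duration = 40, ...) {
  traj <- growth_trajectory(mu, duration = duration)
  sim <- simulate_phosphorelay(strain, params, traj, ...)
  sched <- attr(sim, "schedule")
  t0 <- max(sched$time[sched$kind == "birth"])
  w <- sim$time >= t0
  max(sim$Ap[w]) / min(sim$Ap[w])
}

test_that("phosphotransfer steps conserve phosphoryl groups in the RHS", {
  p <- default_params
  parms <- list(params = p, law = default_law, genes = wt$genes,
                mu_fn = function(t) rep_len(0.3, length(t)),
                dosage = lapply(wt$genes, function(cp) rep(1, length(cp))),
                inducer = 1)
  set.seed(5)
  for (i in 1:20) {
    y <- stats::setNames(runif(8, 1, 500), growthrelay:::relay_species)
    d <- growthrelay:::relay_rhs(0, y, parms)[[1]]
    dphos <- d[2] + d[4] + d[6] + d[8]  # Kp + Fp + Bp + Ap
    auto <- p$ka * p$K_dim * (y[1] / p$K_dim)^p$n_auto /
      (1 + ((y[3] + y[4]) / p$K_I)^p$n_I)
    expected <- auto - p$kdp_f * y[4] - p$kph * y[8] -
      0.3 * (y[2] + y[4] + y[6] + y[8])
    expect_equal(unname(dphos), unname(expected), tolerance = 1e-9)
  }
})

test_that("frozen-dosage system reaches the fixed point of a plain integration", {
  mu <- 0.25
  fp <- relay_fixed_point(default_params, wt, mu)
  # independent oracle: integrate the same frozen ODE directly with deSolve
  p <- default_params
  V <- growthrelay:::relay_volume(mu, default_law)
  oracle_rhs <- function(t, y, parms) {
    K <- y[1]; Kp <- y[2]; F <- y[3]; Fp <- y[4]
    B <- y[5]; Bp <- y[6]; A <- y[7]; Ap <- y[8]
    act <- function(ap, b, K0, n) b + (1 - b) * ap^n / (K0^n + ap^n)
    prodK <- p$v_kinA * act(Ap, p$basal_kinA, p$K_kinA, p$n_kinA) / V
    prodF <- p$v_0F * (mu * V / log(2)) *
      act(Ap, p$basal_0F, p$K_0F, p$n_0F) /
      (1 + (Ap / p$K_0F_rep)^p$n_0F_rep) / V
    prodB <- p$v_0B / V
    prodA <- p$v_0A * act(Ap, p$basal_0A, p$K_0A, p$n_0A) / V
    auto <- p$ka * p$K_dim * (K / p$K_dim)^p$n_auto /
      (1 + ((F + Fp) / p$K_I)^p$n_I)
    pt1 <- p$kt1 * Kp * F - p$kr1 * K * Fp
    pt2 <- p$kt2 * Fp * B - p$kr2 * F * Bp
    pt3 <- p$kt3 * Bp * A - p$kr3 * B * Ap
    list(c(prodK - auto + pt1 - mu * K,
           auto - pt1 - mu * Kp,
           prodF - pt1 + pt2 + p$kdp_f * Fp - (mu + p$kdeg_F) * F,
           pt1 - pt2 - p$kdp_f * Fp - (mu + p$kdeg_F) * Fp,
           prodB - pt2 + pt3 - mu * B,
           pt2 - pt3 - mu * Bp,
           prodA - pt3 + p$kph * Ap - mu * A,
           pt3 - p$kph * Ap - mu * Ap))
  }
  sol <- deSolve::lsoda(stats::setNames(rep(1, 8),
                                        growthrelay:::relay_species),
                        c(0, 400), oracle_rhs, NULL,
                        rtol = 1e-10, atol = 1e-10)
  oracle <- sol[nrow(sol), -1]
  expect_equal(unname(fp), unname(oracle), tolerance = 1e-6)
})

test_that("pinned-dosage control has flat 0A~P: peaks equal cycle means", {
  traj <- growth_trajectory(0.25, duration = 30)
  sim <- simulate_phosphorelay(wt, default_params, traj, pin_dosage = TRUE)
  pr <- as.data.frame(pulse_amplitudes(sim))
  last <- tail(pr, 2)
  expect_true(all(abs(last$peak_Ap / last$mean_Ap - 1) < 0.01))
})

test_that("states stay non-negative across parameter sets and trajectories", {
  set.seed(11)
  cases <- list(
    list(params = default_params, traj = declining_traj),
    list(params = phosphorelay_params(v_kinA = 40, kph = 60),
         traj = growth_trajectory(0.5, duration = 10)),
    list(params = phosphorelay_params(v_0F = 300, kdp_f = 3),
         traj = growth_trajectory(mu = c(0.3, 0.1), time = c(0, 15),
                                  duration = 15))
  )
  for (cs in cases) {
    sim <- simulate_phosphorelay(wt, cs$params, cs$traj)
    expect_gte(min(as.matrix(as.data.frame(sim)[growthrelay:::relay_species])),
               0)
  }
})

test_that("pulse amplitudes grow as growth slows along a declining trajectory", {
  pr <- wt_declining_pulses
  expect_gte(nrow(pr), 4)
  # drop the first cycle (initial-condition transient); require a strong,
  # essentially monotone ramp as cycle-mean growth falls
  ramp <- pr[-1, ]
  expect_true(all(diff(ramp$mean_mu) < 0))
  expect_true(all(diff(ramp$peak_Ap) > 0))
})

test_that("0A~P falls during replication and rises after completion", {
  sim <- wt_declining_sim
  sched <- attr(sim, "schedule")
  df <- as.data.frame(sched)
  cycles <- unique(df$cycle[df$kind == "division"])
  for (cy in tail(cycles, 3)) {
    t0 <- df$time[df$kind == "birth" & df$cycle == cy]
    comp <- df$time[df$kind == "replication_completion" & df$cycle == cy]
    div <- df$time[df$kind == "division" & df$cycle == cy]
    ap_at <- function(t) sim$Ap[which.min(abs(sim$time - t))]
    w <- sim$time >= t0 & sim$time <= div
    t_min <- sim$time[w][which.min(sim$Ap[w])]
    expect_lte(t_min - t0, comp - t0 + 0.05)  # trough within replication
    expect_gt(ap_at(div), ap_at(comp))        # pulse rise after completion
  }
})

test_that("steady pulse peaks decrease with growth rate (two-point check)", {
  slow <- steady_pulse(default_params, wt, 0.15)
  fast <- steady_pulse(default_params, wt, 0.45)
  expect_true(slow$converged && fast$converged)
  expect_gt(slow$peak, fast$peak)
  expect_gt(slow$peak_KinA, fast$peak_KinA)
})

test_that("amplitude-growth curve is monotone and ultrasensitive", {
  cv <- amplitude_vs_growth(default_params, wt,
                            mu_grid = c(0.12, 0.2, 0.35, 0.55))
  expect_true(all(cv$converged))
  expect_true(all(diff(cv$peak_Ap) < 0))
  slopes <- abs(diff(log(cv$peak_Ap)) / diff(log(cv$mu)))
  expect_gt(max(slopes), 1)
})

test_that("0F substrate inhibition carries the 0F effects on pulsing", {
  no_inh <- phosphorelay_params(K_I = Inf)
  # without the inhibition term the pulse peak no longer cares about 0F
  s_0F <- relay_sensitivity(no_inh, wt, 0.2, "spo0F", 0.1, tol = 1e-3)
  expect_lt(abs(s_0F), 3)
  # and the chromosomal arrangement of 0F stops mattering: the wild-type
  # and terminus-translocated (iTrans-0F, uninduced) configurations become
  # equally modulated, whereas with inhibition they differ strongly
  st0 <- strain_config("iTrans-0F", inducer_level = 0)
  gap_no_inh <- abs(last_cycle_contrast(wt, params = no_inh) -
                      last_cycle_contrast(st0, params = no_inh))
  gap_base <- abs(last_cycle_contrast(wt) - last_cycle_contrast(st0))
  expect_lt(gap_no_inh, 0.3 * gap_base)
})

test_that("kinA transcriptional feedback is dispensable for pulsing", {
  nofb <- phosphorelay_params(kinA_feedback = "none")
  expect_gt(last_cycle_contrast(wt, params = nofb), 1.1)
  slow <- steady_pulse(nofb, wt, 0.15)
  fast <- steady_pulse(nofb, wt, 0.45)
  expect_gt(slow$peak, fast$peak)
})

test_that("sensitivity is zero at zero perturbation and errors on dead relays", {
  expect_identical(relay_sensitivity(default_params, wt, 0.2, "kinA",
                                     delta = 0), 0)
  dead <- phosphorelay_params(ka = 0)
  expect_error(relay_sensitivity(dead, wt, 0.2, "kinA", 0.1), "undefined")
  expect_error(relay_sensitivity(default_params, wt, 0.2, "kinA", 0.6),
               "delta")
})

test_that("iTrans-0F without inducer shows no cycle-coordinated pulses", {
  st0 <- strain_config("iTrans-0F", inducer_level = 0)
  traj <- growth_trajectory(0.2, duration = 40)
  sim <- simulate_phosphorelay(st0, default_params, traj)
  pr <- tail(as.data.frame(pulse_amplitudes(sim)), 1)
  expect_lt(pr$peak_Ap / pr$mean_Ap, 1.2)
  # the wild-type arrangement modulates 0A~P much more strongly
  expect_gt(last_cycle_contrast(wt) - 1,
            2 * (last_cycle_contrast(st0) - 1))
})

test_that("late 0F induction gives an immediate full-amplitude response", {
  st_late <- strain_config("iTrans-0F", inducer_level = 1, inducer_at = 20)
  traj <- growth_trajectory(0.15, duration = 40)
  sim <- simulate_phosphorelay(st_late, default_params, traj)
  pr <- as.data.frame(pulse_amplitudes(sim))
  post <- pr[pr$t_peak > 20 + 1, ]
  asym <- steady_pulse(default_params,
                       strain_config("iTrans-0F", inducer_level = 1), 0.15)
  expect_gte(post$peak_Ap[1], 0.9 * asym$peak)
})
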