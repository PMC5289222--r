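test_that("generation is byte-deterministic under a fixed seed", {
  cfg <- generator_config(seed = 99)
  t1 <- sample_lineage(cfg); t2 <- sample_lineage(cfg)
  expect_identical(as.data.frame(t1), as.data.frame(t2))
  r1 <- suppressWarnings(render_timelapse(t1))
  r2 <- suppressWarnings(render_timelapse(t2))
  expect_identical(as.data.frame(r1), as.data.frame(r2))
})

test_that("zero noise and a flat mean give identical, non-sporulating cells", {
  cfg <- generator_config(generations = 4, mu0 = 0.5, decline = 0,
                          mu_floor = 0.4999, sd_log = 1e-9,
                          rho_md = 0, rho_ss = 0, noise_length = 0,
                          noise_fluor = 0, noise_growth = 0, seed = 3)
  tree <- sample_lineage(cfg)
  expect_true(all(tree$fate == "vegetative"))
  expect_lt(diff(range(tree$true_mu)), 1e-6)
})

test_that("infeasible correlation pairs are rejected", {
  expect_error(generator_config(rho_md = 0.8, rho_ss = 0.3),
               "infeasible")
  expect_silent(generator_config(rho_md = 0.41, rho_ss = 0.36))
})

test_that("mother-daughter and sister correlations hit their targets", {
  # flat mean so the generation trend does not inflate correlations
  cfg <- generator_config(generations = 13, mu0 = 0.6, decline = 0,
                          mu_floor = 0.599, mu_star = 0.01, seed = 31)
  tree <- sample_lineage(cfg)
  pp <- lineage_pairs(tree)
  expect_gt(nrow(pp$mother_daughter), 4000)
  rho_md <- cor(pp$mother_daughter$mu_mother, pp$mother_daughter$mu_daughter,
                method = "spearman")
  rho_ss <- cor(pp$sisters$mu_1, pp$sisters$mu_2, method = "spearman")
  expect_lt(abs(rho_md - 0.41), 0.05)
  expect_lt(abs(rho_ss - 0.36), 0.05)
})

test_that("noise-free rendering lets the pipeline recover true growth rates", {
  cfg <- generator_config(generations = 5, noise_length = 0,
                          noise_fluor = 0, noise_growth = 0, seed = 12)
  tree <- sample_lineage(cfg)
  traces <- suppressWarnings(render_timelapse(tree))
  rec <- analyze_timelapse(traces, tree)
  m <- merge(rec, as.data.frame(tree)[, c("cell_id", "true_mu")],
             by = "cell_id")
  expect_lt(max(abs(m$mean_mu - m$true_mu)), 0.01)
})

test_that("constitutive reporter yields no per-cycle activity peaks", {
  cfg <- generator_config(generations = 4, mu0 = 0.3, decline = 0,
                          mu_floor = 0.299, sd_log = 1e-9, mu_star = 0.01,
                          noise_length = 0, noise_fluor = 0,
                          noise_growth = 0, seed = 17)
  tree <- sample_lineage(cfg)
  tr <- suppressWarnings(render_timelapse(tree, cfg))
  for (id in unique(tr$cell_id)[1:4]) {
    one <- tr[tr$cell_id == id, ]
    if (nrow(one) < 6) next
    act <- promoter_activity(one$t_h, one$fluor_const, one$length_um)
    sm <- suppressWarnings(smooth_and_peak(act)$smoothed)
    expect_lt(max(sm) / mean(sm), 1.2)
  }
  # whereas the pulsatile channel of the same cells is strongly peaked
  one <- tr[tr$cell_id == unique(tr$cell_id)[2], ]
  actp <- promoter_activity(one$t_h, one$fluor_pulse, one$length_um)
  smp <- suppressWarnings(smooth_and_peak(actp)$smoothed)
  expect_gt(max(smp) / mean(pmax(smp, 1e-9)), 1.5)
})

test_that("pulse amplitudes anti-correlate with growth rate", {
  # two-rate check: recovered amplitudes ordered inversely with mu
  cfg <- generator_config(generations = 3, mu0 = 0.5, decline = 0,
                          mu_floor = 0.499, sd_log = 1e-9, mu_star = 0.01,
                          noise_length = 0, noise_fluor = 0,
                          noise_growth = 0, seed = 8)
  slow_cfg <- generator_config(generations = 3, mu0 = 0.2, decline = 0,
                               mu_floor = 0.199, sd_log = 1e-9,
                               mu_star = 0.01, noise_length = 0,
                               noise_fluor = 0, noise_growth = 0, seed = 8)
  rec_fast <- analyze_timelapse(
    suppressWarnings(render_timelapse(tr <- sample_lineage(cfg))), tr)
  rec_slow <- analyze_timelapse(
    suppressWarnings(render_timelapse(ts <- sample_lineage(slow_cfg))), ts)
  expect_gt(min(rec_slow$peak_pulse), max(rec_fast$peak_pulse))

  # default colony: strong negative rank correlation, emulating the
  # single-cell anticorrelation seen in starving colonies
  st <- spearman_test(colony_records$mean_mu, colony_records$peak_pulse)
  expect_lte(st$rho, -0.5)
})

test_that("fluorescence is inherited: daughters start with half the mother total", {
  cfg <- generator_config(generations = 3, mu0 = 0.4, decline = 0,
                          mu_floor = 0.399, sd_log = 1e-9, mu_star = 0.01,
                          noise_length = 0, noise_fluor = 0,
                          noise_growth = 0, seed = 5)
  tree <- sample_lineage(cfg)
  tr <- suppressWarnings(render_timelapse(tree))
  kid <- tree$cell_id[!is.na(tree$parent_id)][1]
  parent <- tree$parent_id[tree$cell_id == kid]
  f_end <- tail(tr$fluor_const[tr$cell_id == parent], 1)
  f_start <- tr$fluor_const[tr$cell_id == kid][1]
  expect_equal(f_start, f_end / 2, tolerance = 1e-9)
})

test_that("newick export is well formed and covers every cell", {
  nwk <- lineage_newick(colony_tree)
  expect_match(nwk, ";$")
  expect_equal(lengths(regmatches(nwk, gregexpr("c[0-9]+:", nwk))),
               nrow(colony_tree))
})
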