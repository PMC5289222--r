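# shared objects built once per test run
default_law <- growth_law()
default_params <- phosphorelay_params()
wt <- strain_config("WT")

# one WT simulation over a declining growth trajectory, reused by several
# phosphorelay tests
declining_traj <- growth_trajectory(mu = c(0.55, 0.12), time = c(0, 30),
                                    duration = 30)
wt_declining_sim <- simulate_phosphorelay(wt, default_params, declining_traj)
wt_declining_pulses <- as.data.frame(pulse_amplitudes(wt_declining_sim))

# one default synthetic colony and its quantification, reused across the
# generator / analysis / classifier / population tests
colony_tree <- sample_lineage(generator_config(seed = 7))
colony_traces <- suppressWarnings(render_timelapse(colony_tree))
colony_records <- analyze_timelapse(colony_traces, colony_tree)
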