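#' Configuration for the synthetic time-lapse generator
#'
#' Defines the statistical structure of generated single-cell lineages:
#' per-cycle growth rates decline over generations with lognormal
#' heterogeneity, are inherited mother-to-daughter with an AR(1)-type term,
#' and sisters share part of their deviation; fate is set by a growth-rate
#' threshold. Defaults emulate starving *B. subtilis* microcolonies on
#' sporulation medium: the mean growth rate relaxes from 0.65/h toward a
#' deep-starvation floor of 0.22/h, crossing the sporulation threshold
#' (0.25/h) around generation 4-5 so the sporulating fraction rises from
#' near zero to a ~2/3 plateau; mother-daughter rank correlation ~0.41,
#' sister correlation ~0.36, 20-min frames, 2% length and 5% fluorescence
#' measurement noise.
#'
#' @param generations number of generations to simulate.
#' @param mu0 initial mean growth rate (1/h).
#' @param decline per-generation decline rate of the mean growth rate.
#' @param mu_floor asymptotic mean growth rate (1/h): the generation-g mean
#'   is `mu_floor + (mu0 - mu_floor) * exp(-decline * g)`, emulating growth
#'   settling just below the sporulation threshold in deep starvation (which
#'   caps the late-generation sporulating fraction below 1).
#' @param sd_log standard deviation of log growth-rate deviations.
#' @param rho_md target mother-daughter correlation of log growth rates.
#' @param rho_ss target sister-sister correlation of log growth rates.
#' @param mu_star sporulation growth threshold (1/h): a cycle whose true
#'   growth rate is at or below it becomes a spore.
#' @param frame_dt imaging frame interval (h); 20 min.
#' @param noise_length,noise_fluor multiplicative lognormal measurement CVs.
#' @param noise_growth within-cycle growth fluctuation: sd of the lognormal
#'   factor applied to each frame's true elongation increment. It decouples
#'   the measured cycle-mean growth rate from the true rate that sets fate,
#'   reproducing the imperfect growth-based fate prediction seen in real
#'   colonies; set to 0 for exact recovery.
#' @param reporter `"pulsatile"` for a 0A~P-driven promoter channel plus a
#'   constitutive channel, `"constitutive"` for the constitutive channel
#'   only.
#' @param seed integer seed; every generator call is deterministic given it.
#' @return object of class `generator_config`.
#' @export
generator_config <- function(generations = 9, mu0 = 0.65, decline = 0.6,
                             mu_floor = 0.22,
                             sd_log = 0.25, rho_md = 0.41, rho_ss = 0.36,
                             mu_star = 0.25, frame_dt = 1 / 3,
                             noise_length = 0.02, noise_fluor = 0.05,
                             noise_growth = 0.28,
                             reporter = c("pulsatile", "constitutive"),
                             seed = 1L) {
  reporter <- match.arg(reporter)
  if (rho_md < 0 || rho_md >= 1 || rho_ss < 0 || rho_ss >= 1)
    stop("correlation targets must lie in [0, 1)")
  if (rho_ss < rho_md^2 - 1e-12)
    stop("infeasible correlation pair: sister correlation below the ",
         "mother-daughter-implied bound rho_md^2")
  if (noise_length < 0 || noise_fluor < 0 || noise_growth < 0)
    stop("noise CVs must be >= 0")
  if (mu0 <= 0 || mu_star <= 0 || mu_floor <= 0 || mu_floor >= mu0)
    stop("need 0 < mu_floor < mu0 and mu_star > 0")
  structure(list(generations = generations, mu0 = mu0, decline = decline,
                 mu_floor = mu_floor,
                 sd_log = sd_log, rho_md = rho_md, rho_ss = rho_ss,
                 mu_star = mu_star, frame_dt = frame_dt,
                 noise_length = noise_length, noise_fluor = noise_fluor,
                 noise_growth = noise_growth,
                 reporter = reporter, seed = as.integer(seed)),
            class = "generator_config")
}

#' Sample a single-cell lineage tree with declining, heritable growth rates
#'
#' Grows a binary lineage from one founder cell. Each cell's log growth-rate
#' deviation from its generation mean is `a * (mother's deviation) + shared
#' sister term + independent term`, with `a = rho_md` and the shared-term
#' variance chosen so the sister correlation equals `rho_ss`; deviations are
#' stationary with variance `sd_log^2`. A cell whose growth rate falls at or
#' below `mu_star` becomes a spore (terminal, with end time 2 h after its
#' last vegetative frame span); vegetative cells divide symmetrically into
#' two daughters. Cycle durations follow the division-length law: a cell
#' born at length L divides when it reaches `division_length(mu)`.
#'
#' @param config a [generator_config()].
#' @param law a [growth_law()].
#' @return data frame of class `lineage_tree`: one row per cell with
#'   `cell_id`, `parent_id`, `generation`, `birth_time`, `end_time`,
#'   `birth_length`, `true_mu`, `fate` (`"vegetative"` or `"spore"`).
#' @export
sample_lineage <- function(config = generator_config(), law = growth_law()) {
  set.seed(config$seed)
  a <- config$rho_md
  var_shared <- max(config$rho_ss - a^2, 0) * config$sd_log^2
  var_indep <- (1 - a^2) * config$sd_log^2 - var_shared
  if (var_indep < 0)
    stop("infeasible correlation pair: rho_ss too close to 1 given rho_md")

  gen_mean <- function(g)
    config$mu_floor + (config$mu0 - config$mu_floor) * exp(-config$decline * g)

  rows <- list()
  next_id <- 1L
  # queue entries: parent id, generation, birth time, birth length,
  # mother's log deviation, sister-shared innovation
  queue <- list(list(parent = NA_integer_, gen = 0L, t0 = 0,
                     L0 = 2.5, dev_m = 0, shared = NA_real_))
  while (length(queue) > 0) {
    cell <- queue[[1]]; queue <- queue[-1]
    shared <- if (is.na(cell$shared)) stats::rnorm(1, 0, sqrt(var_shared))
              else cell$shared
    dev <- a * cell$dev_m + shared + stats::rnorm(1, 0, sqrt(max(var_indep, 0)))
    mu <- gen_mean(cell$gen) * exp(dev)
    fate <- if (mu <= config$mu_star) "spore" else "vegetative"
    Ldiv <- division_length(mu, law)
    duration <- log(Ldiv / cell$L0) / mu
    # guard degenerate case of a cell born longer than its division length
    if (!is.finite(duration) || duration <= 0) duration <- log(2) / mu
    end <- if (fate == "spore") cell$t0 + duration + 2 else cell$t0 + duration
    id <- next_id; next_id <- next_id + 1L
    rows[[id]] <- data.frame(
      cell_id = id, parent_id = cell$parent, generation = cell$gen,
      birth_time = cell$t0, end_time = end, birth_length = cell$L0,
      true_mu = mu, fate = fate, stringsAsFactors = FALSE)
    if (fate == "vegetative" && cell$gen + 1L < config$generations) {
      sh <- stats::rnorm(1, 0, sqrt(var_shared))
      for (k in 1:2) {
        queue[[length(queue) + 1L]] <- list(
          parent = id, gen = cell$gen + 1L, t0 = cell$t0 + duration,
          L0 = Ldiv / 2, dev_m = dev, shared = sh)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("lineage_tree", "data.frame"), config = config)
}

#' @export
print.lineage_tree <- function(x, ...) {
  cat(sprintf("Lineage tree: %d cells over %d generations, %.1f%% spores\n",
              nrow(x), max(x$generation) + 1,
              100 * mean(x$fate == "spore")))
  invisible(x)
}

#' Mother-daughter and sister pairs of a lineage tree
#'
#' Convenience extraction of the growth-rate pairs used for heritability
#' statistics.
#'
#' @param tree a [sample_lineage()] result.
#' @return list with data frames `mother_daughter` (`mu_mother`,
#'   `mu_daughter`, `daughter_fate`) and `sisters` (`mu_1`, `mu_2`).
#' @export
lineage_pairs <- function(tree) {
  kids <- tree[!is.na(tree$parent_id), ]
  md <- data.frame(
    mu_mother = tree$true_mu[match(kids$parent_id, tree$cell_id)],
    mu_daughter = kids$true_mu,
    daughter_fate = kids$fate)
  sis <- split(kids$true_mu, kids$parent_id)
  sis <- sis[vapply(sis, length, integer(1)) == 2L]
  ss <- data.frame(mu_1 = vapply(sis, `[`, numeric(1), 1),
                   mu_2 = vapply(sis, `[`, numeric(1), 2))
  rownames(ss) <- NULL
  list(mother_daughter = md, sisters = ss)
}

#' Default phenomenological pulse-amplitude law for the generator
#'
#' Decreasing Hill function mapping a cycle's growth rate to its promoter
#' activity pulse amplitude (arbitrary units/h), standing in for the
#' phosphorelay amplitude-versus-growth curve when a full ODE run is not
#' needed. A fitted [amplitude_vs_growth()] curve can be supplied to
#' [render_timelapse()] instead.
#'
#' @param mu growth rate (1/h).
#' @param amp_max amplitude at zero growth.
#' @param mu50 half-amplitude growth rate (1/h).
#' @param h Hill steepness.
#' @return pulse amplitude (a.u./h).
#' @export
pulse_amplitude_law <- function(mu, amp_max = 100, mu50 = 0.3, h = 4) {
  amp_max / (1 + (mu / mu50)^h)
}

#' Render fluorescence time-lapse traces from a lineage tree
#'
#' Produces frame-sampled observations that emulate segmented microscopy
#' output. Length grows exponentially at the cell's true growth rate with
#' multiplicative measurement noise. Total fluorescence integrates promoter
#' activity times cell length and halves at division (each daughter
#' inherits half). The pulsatile channel fires once per cycle: a smooth
#' activity bump starting at the cycle's replication completion
#' (`replication_period(mu)` after birth) with amplitude `amplitude_fn(mu)`;
#' the constitutive channel has constant activity per unit length. Cycles
#' spanning fewer than 2 frames are dropped with a warning.
#'
#' @param tree a [sample_lineage()] result.
#' @param config the [generator_config()] (defaults to the tree's).
#' @param law a [growth_law()].
#' @param amplitude_fn function mapping growth rate to pulse amplitude;
#'   default [pulse_amplitude_law()].
#' @param const_activity constitutive channel activity (a.u./h per um).
#' @return data frame of class `timelapse_traces`: long format with
#'   `cell_id`, `frame`, `t_h`, `length_um`, `fluor_pulse`, `fluor_const`.
#' @export
render_timelapse <- function(tree, config = attr(tree, "config"),
                             law = growth_law(),
                             amplitude_fn = pulse_amplitude_law,
                             const_activity = 10) {
  set.seed(config$seed + 1L)
  dt <- config$frame_dt
  ord <- order(tree$birth_time, tree$cell_id)
  # fluorescence inherited at division: track end-of-cycle totals
  end_fluor <- list()
  rows <- vector("list", nrow(tree))
  dropped <- 0L
  for (i in ord) {
    cell <- tree[i, ]
    t_end <- if (cell$fate == "spore") cell$end_time - 2 else cell$end_time
    frames <- seq(cell$birth_time, t_end, by = dt)
    if (length(frames) < 2) { dropped <- dropped + 1L; next }
    tt <- frames - cell$birth_time
    # true elongation with within-cycle growth fluctuations (mean-one
    # lognormal factor per frame increment), then measurement noise
    sg <- config$noise_growth
    fluct <- exp(stats::rnorm(length(tt) - 1, -sg^2 / 2, sg))
    len_true <- cell$birth_length *
      exp(c(0, cumsum(cell$true_mu * diff(tt) * fluct)))
    len_obs <- len_true * exp(stats::rnorm(length(tt), 0, config$noise_length))

    init <- if (!is.na(cell$parent_id) &&
                !is.null(end_fluor[[as.character(cell$parent_id)]])) {
      end_fluor[[as.character(cell$parent_id)]] / 2
    } else c(pulse = 0, const = 5)

    trep <- replication_period(cell$true_mu, law)
    amp <- amplitude_fn(cell$true_mu)
    # activity bump after replication completion: smooth 1-h half-cosine
    act_pulse <- function(t) {
      w <- 1
      ifelse(t > trep & t < trep + w,
             amp * 0.5 * (1 - cos(2 * pi * (t - trep) / w)), 0)
    }
    dtau <- diff(tt)
    mids <- (tt[-1] + tt[-length(tt)]) / 2
    len_mid <- cell$birth_length * exp(cell$true_mu * mids)
    fl_pulse <- init[["pulse"]] + c(0, cumsum(act_pulse(mids) * len_mid * dtau))
    fl_const <- init[["const"]] + c(0, cumsum(const_activity * len_mid * dtau))
    end_fluor[[as.character(cell$cell_id)]] <-
      c(pulse = fl_pulse[length(fl_pulse)], const = fl_const[length(fl_const)])

    nse <- exp(stats::rnorm(length(tt), 0, config$noise_fluor))
    rows[[i]] <- data.frame(
      cell_id = cell$cell_id, frame = seq_along(tt), t_h = frames,
      length_um = len_obs,
      fluor_pulse = if (config$reporter == "pulsatile") fl_pulse * nse else 0,
      fluor_const = fl_const * nse)
  }
  if (dropped > 0)
    warning(sprintf("%d cycle(s) shorter than 2 frames dropped", dropped))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("timelapse_traces", "data.frame"),
            config = config, law = law)
}

#' Export a lineage tree topology as a Newick string
#'
#' Branch lengths are cycle durations (h); spores are terminal tips, and
#' cells truncated by the end of the simulated window appear as tips too.
#'
#' @param tree a [sample_lineage()] result.
#' @param file optional path; when given the string is written there.
#' @return the Newick string, invisibly when `file` is given.
#' @export
lineage_newick <- function(tree, file = NULL) {
  children <- split(tree$cell_id, factor(tree$parent_id,
                                         levels = tree$cell_id))
  build <- function(id) {
    row <- tree[tree$cell_id == id, ]
    bl <- row$end_time - row$birth_time
    kids <- children[[as.character(id)]]
    if (is.null(kids) || length(kids) == 0)
      sprintf("c%d:%.6g", id, bl)
    else
      sprintf("(%s)c%d:%.6g", paste(vapply(kids, build, character(1)),
                                    collapse = ","), id, bl)
  }
  root <- tree$cell_id[is.na(tree$parent_id)]
  nwk <- paste0(build(root), ";")
  if (!is.null(file)) { writeLines(nwk, file); return(invisible(nwk)) }
  nwk
}
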