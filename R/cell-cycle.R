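#' Growth-rate trajectory over absolute time
#'
#' A piecewise description of the single-cell growth rate \eqn{\mu(t)} (1/h)
#' that drives cell-cycle scheduling and the phosphorelay model. Either a
#' constant rate, or a sampled curve interpolated linearly (with constant
#' extrapolation at the ends).
#'
#' @param mu growth rate values (1/h); a scalar for a constant trajectory.
#' @param time sample times (h), required when `mu` has length > 1.
#' @param duration trajectory duration (h); defaults to `max(time)` or, for a
#'   constant trajectory, must be given.
#' @return object of class `growth_trajectory`: a list with `fn(t)` returning
#'   \eqn{\mu(t)} and `duration`.
#' @examples
#' traj <- growth_trajectory(mu = c(0.6, 0.1), time = c(0, 30))
#' traj$fn(15)
#' @export
growth_trajectory <- function(mu, time = NULL, duration = NULL) {
  if (any(!is.finite(mu)) || any(mu <= 0))
    stop("mu(t) must be positive and finite everywhere")
  if (length(mu) == 1L) {
    if (is.null(duration)) stop("constant trajectory needs a `duration`")
    fn <- function(t) rep_len(mu, length(t))
  } else {
    if (is.null(time) || length(time) != length(mu))
      stop("`time` must match `mu` in length")
    if (is.unsorted(time, strictly = TRUE)) stop("`time` must be increasing")
    if (is.null(duration)) duration <- max(time)
    fn <- stats::approxfun(time, mu, rule = 2)
  }
  if (duration <= 0) stop("`duration` must be > 0")
  structure(list(fn = fn, duration = duration), class = "growth_trajectory")
}

# cumulative integral of mu(t) on [0, duration] as an interpolating function;
# dense trapezoid grid (step ~ 0.002 h) keeps event times well inside the
# 1e-9 h detection tolerance used downstream for root refinement.
cumulative_growth <- function(traj, n = NULL) {
  if (is.null(n)) n <- max(2000L, ceiling(traj$duration / 0.002))
  tt <- seq(0, traj$duration, length.out = n)
  mm <- traj$fn(tt)
  dt <- diff(tt)
  M <- c(0, cumsum(dt * (mm[-1] + mm[-length(mm)]) / 2))
  stats::approxfun(tt, M, rule = 2)
}

#' Default chromosomal locus map for the phosphorelay genes
#'
#' Origin distances are the fraction of a replication arm traversed before a
#' locus is copied, on a 360-degree map with bidirectional forks meeting at
#' 180 degrees: *spo0F* at 326 deg (oriC-proximal, 34/180) and *kinA* at
#' 126 deg (ter-proximal, 126/180). *spo0B* and *spo0A* are treated as
#' mid-arm loci.
#'
#' @return named numeric vector of origin distances in `[0, 1]`.
#' @export
default_loci <- function() {
  c(spo0F = 34 / 180, kinA = 126 / 180, spo0B = 0.5, spo0A = 0.55)
}

#' Build a cell-cycle event schedule from a growth trajectory
#'
#' Event-driven scheduling of divisions, replication rounds and per-locus
#' duplications. Each cycle starts with a birth; replication initiates at
#' birth and completes `replication_period(mu)` later (evaluated at the
#' birth-time growth rate); a locus at origin distance `d` is duplicated at
#' `initiation + d * Trep`. Length grows exponentially at \eqn{\mu(t)};
#' division fires when length reaches `division_length(mu(t))`, but never
#' before replication completion (zero D-period), so at fast growth the
#' replication period can occupy the whole cycle. Division is symmetric.
#'
#' @param traj a [growth_trajectory()].
#' @param law a [growth_law()].
#' @param birth_length initial cell length (um).
#' @param horizon simulation horizon (h), at most the trajectory duration.
#' @param loci named origin-distance vector, as [default_loci()].
#' @return object of class `cell_cycle_schedule`: data frame of ordered
#'   events `(time, kind, locus, cycle)` with per-cycle birth lengths and the
#'   inputs attached as attributes. Only completed cycles (birth through
#'   division) are emitted.
#' @export
build_schedule <- function(traj, law = growth_law(), birth_length = 2.5,
                           horizon = traj$duration, loci = default_loci()) {
  stopifnot(inherits(traj, "growth_trajectory"))
  if (horizon <= 0 || horizon > traj$duration + 1e-12)
    stop("`horizon` must be in (0, trajectory duration]")
  if (birth_length <= 0) stop("`birth_length` must be > 0")
  if (length(loci) == 0) stop("locus map must not be empty")

  M <- cumulative_growth(traj)
  events <- list()
  birth_lengths <- numeric()
  t_birth <- 0
  L_birth <- birth_length
  cycle <- 0L
  repeat {
    cycle <- cycle + 1L
    mu_b <- traj$fn(t_birth)
    trep <- replication_period(mu_b, law)
    ev <- data.frame(
      time = c(t_birth, t_birth,
               t_birth + sort(unname(loci)) * trep,
               t_birth + trep),
      kind = c("birth", "replication_initiation",
               rep("locus_duplication", length(loci)),
               "replication_completion"),
      locus = c(NA, NA, names(sort(loci)), NA),
      cycle = cycle, stringsAsFactors = FALSE
    )
    # division: length condition, deferred until replication completion
    g <- function(t) (M(t) - M(t_birth)) -
      log(division_length(traj$fn(t), law) / L_birth)
    t_lo <- t_birth + trep
    if (t_lo >= horizon) break
    t_div <- if (g(t_lo) >= 0) t_lo else {
      if (g(horizon) < 0) NA_real_ else
        stats::uniroot(g, c(t_lo, horizon), tol = 1e-9)$root
    }
    if (is.na(t_div) || t_div > horizon) break
    ev <- rbind(ev, data.frame(time = t_div, kind = "division",
                               locus = NA, cycle = cycle,
                               stringsAsFactors = FALSE))
    events[[cycle]] <- ev
    birth_lengths[cycle] <- L_birth
    L_birth <- (L_birth * exp(M(t_div) - M(t_birth))) / 2
    t_birth <- t_div
  }
  if (length(events) == 0)
    stop("horizon too short: no complete cell cycle")
  out <- do.call(rbind, events)
  out <- out[order(out$time, match(out$kind, c(
    "division", "birth", "replication_initiation", "locus_duplication",
    "replication_completion"))), ]
  rownames(out) <- NULL
  structure(out, class = c("cell_cycle_schedule", "data.frame"),
            birth_lengths = birth_lengths, loci = loci,
            law = law, trajectory = traj)
}

#' @export
print.cell_cycle_schedule <- function(x, ...) {
  n_cyc <- max(x$cycle)
  cat(sprintf("Cell-cycle schedule: %d complete cycles, %d events, %.2f h\n",
              n_cyc, nrow(x), max(x$time)))
  invisible(x)
}

#' Per-locus gene-dosage step functions
#'
#' Converts a schedule into right-continuous copy-number step functions: each
#' locus has 1 copy from birth until its duplication event, 2 copies until
#' division, then 1 again in the daughter. With the default locus map the
#' oriC-proximal *spo0F* is duplicated before ter-proximal *kinA* in every
#' round, so the kinA:0F dosage ratio steps 1:1 -> 1:2 -> 1:1 each cycle.
#'
#' @param schedule a [build_schedule()] result.
#' @param loci named origin-distance vector; defaults to the schedule's map.
#' @return object of class `dosage_timeline`: list with per-locus breakpoint
#'   tables and an evaluator; use [dosage_at()] to query copy numbers.
#' @export
dosage_timeline <- function(schedule, loci = attr(schedule, "loci")) {
  if (length(loci) == 0) stop("locus map must not be empty")
  sched <- as.data.frame(schedule)
  births <- sched[sched$kind == "birth", c("time", "cycle")]
  divs <- sched[sched$kind == "division", c("time", "cycle")]
  steps <- lapply(names(loci), function(nm) {
    dup <- sched[sched$kind == "locus_duplication" & sched$locus == nm, ]
    # breakpoints: duplication -> 2, division -> 1 (right-continuous)
    data.frame(time = c(births$time[1], rbind(dup$time, divs$time)),
               copies = c(1, rbind(rep(2, nrow(dup)), rep(1, nrow(divs)))))
  })
  names(steps) <- names(loci)
  structure(list(steps = steps, loci = loci,
                 end_time = max(sched$time)),
            class = "dosage_timeline")
}

#' Evaluate a dosage timeline
#'
#' Right-continuous copy number of `locus` at times `t`.
#'
#' @param timeline a [dosage_timeline()].
#' @param locus locus name.
#' @param t times (h).
#' @return integer copy numbers (1 or 2).
#' @export
dosage_at <- function(timeline, locus, t) {
  st <- timeline$steps[[locus]]
  if (is.null(st)) stop("unknown locus: ", locus)
  idx <- findInterval(t, st$time)
  ifelse(idx == 0, 1, st$copies[pmax(idx, 1L)])
}
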