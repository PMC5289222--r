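#' Instantaneous growth rate from a length trace
#'
#' Forward-difference log-derivative of cell length,
#' \eqn{\mu(t) = (\log L(t+\Delta t) - \log L(t)) / \Delta t} (natural log),
#' one value per frame except the last.
#'
#' @param t_h frame times (h), equally spaced.
#' @param length_um cell lengths (um), positive.
#' @return numeric vector of length `length(t_h) - 1` (1/h).
#' @export
instantaneous_growth <- function(t_h, length_um) {
  if (length(t_h) < 2) stop("need at least 2 frames")
  if (any(length_um <= 0)) stop("lengths must be positive")
  diff(log(length_um)) / diff(t_h)
}

#' Cycle-mean growth rate, truncated for sporulating cells
#'
#' Mean of the instantaneous growth rate over the cell cycle. For cycles
#' ending in sporulation the average runs only up to the asymmetric
#' division, taken as the reporter-activation time when available and
#' otherwise 2 h before the appearance of the phase-bright forespore.
#'
#' @param t_h frame times (h).
#' @param length_um cell lengths (um).
#' @param fate `"vegetative"` or `"spore"`.
#' @param forespore_time time (h) the forespore becomes visible (spores).
#' @param reporter_time optional asymmetric-division reporter activation
#'   time (h); takes precedence over `forespore_time - 2`.
#' @return mean growth rate (1/h).
#' @export
cycle_mean_growth <- function(t_h, length_um, fate = "vegetative",
                              forespore_time = NULL, reporter_time = NULL) {
  mu <- instantaneous_growth(t_h, length_um)
  tm <- t_h[-length(t_h)]
  if (identical(fate, "spore")) {
    cutoff <- if (!is.null(reporter_time)) reporter_time
              else if (!is.null(forespore_time)) forespore_time - 2
              else stop("spore cycle needs `forespore_time` or `reporter_time`")
    keep <- tm < cutoff
    if (!any(keep)) stop("truncation window is empty")
    mu <- mu[keep]
  }
  mean(mu)
}

#' Promoter activity (protein production rate) from a fluorescence trace
#'
#' The production rate of a fluorescent reporter inferred from total
#' fluorescence: the time derivative of total fluorescence per unit cell
#' length (central differences in the interior, one-sided at the ends).
#' With `dilution_correction = TRUE` the term
#' \eqn{\mu(t) \cdot F(t) / L(t)} is added, compensating dilution when the
#' trace stores concentration-like signal; the default derivative-only mode
#' treats total fluorescence as cumulative production, which it is for a
#' stable reporter in a growing cell.
#'
#' @param t_h frame times (h).
#' @param fluor total fluorescence per cell (a.u.).
#' @param length_um cell lengths (um).
#' @param dilution_correction add the dilution term (default `FALSE`).
#' @return activity series (a.u./h per um), one value per frame.
#' @export
promoter_activity <- function(t_h, fluor, length_um,
                              dilution_correction = FALSE) {
  n <- length(t_h)
  if (length(fluor) != n || length(length_um) != n)
    stop("misaligned series: t, fluorescence and length must match")
  if (n < 2) stop("need at least 2 frames")
  dFdt <- numeric(n)
  dFdt[1] <- (fluor[2] - fluor[1]) / (t_h[2] - t_h[1])
  dFdt[n] <- (fluor[n] - fluor[n - 1]) / (t_h[n] - t_h[n - 1])
  if (n > 2) {
    i <- 2:(n - 1)
    dFdt[i] <- (fluor[i + 1] - fluor[i - 1]) / (t_h[i + 1] - t_h[i - 1])
  }
  act <- dFdt / length_um
  if (dilution_correction) {
    mu <- c(instantaneous_growth(t_h, length_um), NA)
    mu[n] <- mu[n - 1]
    act <- act + mu * fluor / length_um
  }
  act
}

#' Savitzky-Golay smoothing specification
#'
#' @param window odd window length in frames.
#' @param order polynomial order, less than `window`.
#' @return list of class `smoother_spec`.
#' @export
smoother_spec <- function(window = 5, order = 3) {
  if (window %% 2 != 1 || window <= order)
    stop("`window` must be odd and greater than `order`")
  structure(list(window = window, order = order), class = "smoother_spec")
}

#' Smooth an activity series and extract its per-cycle peak
#'
#' Savitzky-Golay filtering (third-order polynomial over five frames by
#' default) followed by the maximum of the smoothed series. Series shorter
#' than the window fall back to the raw maximum with a warning.
#'
#' @param activity activity series.
#' @param spec a [smoother_spec()].
#' @return list with `peak`, `peak_index`, and the `smoothed` series.
#' @export
smooth_and_peak <- function(activity, spec = smoother_spec()) {
  if (length(activity) < spec$window) {
    warning("series shorter than smoothing window; using raw maximum")
    i <- which.max(activity)
    return(list(peak = activity[i], peak_index = i, smoothed = activity))
  }
  sm <- signal::sgolayfilt(activity, p = spec$order, n = spec$window)
  i <- which.max(sm)
  list(peak = sm[i], peak_index = i, smoothed = sm)
}

#' Quantify a synthetic (or identically formatted) time-lapse dataset
#'
#' The full per-cycle pipeline: instantaneous growth rates, cycle-mean
#' growth (with the sporulation truncation rule), promoter activity,
#' Savitzky-Golay smoothing and per-cycle peak extraction for each
#' fluorescence channel, one record per cell cycle.
#'
#' @param traces a [render_timelapse()] table.
#' @param lineage the matching [sample_lineage()] table (supplies fates,
#'   generations and forespore times).
#' @param spec a [smoother_spec()].
#' @param dilution_correction passed to [promoter_activity()].
#' @param channels fluorescence channel columns to quantify.
#' @return data frame of class `cycle_records`: `cell_id`, `generation`,
#'   `mean_mu`, one `peak_<channel>` column per channel, `fate`.
#' @export
analyze_timelapse <- function(traces, lineage, spec = smoother_spec(),
                              dilution_correction = FALSE,
                              channels = c("fluor_pulse", "fluor_const")) {
  channels <- intersect(channels, names(traces))
  recs <- lapply(split(traces, traces$cell_id), function(tr) {
    tr <- tr[order(tr$t_h), ]
    if (nrow(tr) < 2) return(NULL)
    li <- lineage[lineage$cell_id == tr$cell_id[1], ]
    mean_mu <- cycle_mean_growth(tr$t_h, tr$length_um, fate = li$fate,
                                 forespore_time = li$end_time)
    peaks <- vapply(channels, function(ch) {
      act <- promoter_activity(tr$t_h, tr[[ch]], tr$length_um,
                               dilution_correction = dilution_correction)
      suppressWarnings(smooth_and_peak(act, spec)$peak)
    }, numeric(1))
    out <- data.frame(cell_id = li$cell_id, generation = li$generation,
                      mean_mu = mean_mu, fate = li$fate)
    for (ch in channels) out[[paste0("peak_", sub("fluor_", "", ch))]] <-
      peaks[[ch]]
    out
  })
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  structure(out, class = c("cycle_records", "data.frame"))
}

#' Bin per-cycle records by generation or by time
#'
#' Generation mode groups records by generation number; time mode divides
#' the experiment span into fixed-width bins (2 h by default) and assigns
#' each cell cycle to every bin it overlaps. Summaries are the mean and sd
#' of cycle-mean growth rates, the record count, and the sporulating
#' fraction.
#'
#' @param records a [analyze_timelapse()] table; time mode additionally
#'   needs `birth_time` and `end_time` columns (join from the lineage).
#' @param by `"generation"` or `"time"`.
#' @param width time-bin width (h).
#' @return data frame with `bin`, `mean_mu`, `sd_mu`, `n`,
#'   `sporulating_fraction`.
#' @export
bin_records <- function(records, by = c("generation", "time"), width = 2) {
  by <- match.arg(by)
  if (nrow(records) == 0) stop("`records` must not be empty")
  if (by == "generation") {
    grp <- split(records, records$generation)
    bins <- as.numeric(names(grp))
  } else {
    if (!all(c("birth_time", "end_time") %in% names(records)))
      stop("time binning needs `birth_time` and `end_time` columns")
    edges <- seq(0, max(records$end_time) + width, by = width)
    bins <- edges[-length(edges)]
    grp <- lapply(seq_along(bins), function(i) {
      lo <- edges[i]; hi <- edges[i + 1]
      records[records$birth_time < hi & records$end_time > lo, ]
    })
  }
  out <- do.call(rbind, lapply(seq_along(grp), function(i) {
    g <- grp[[i]]
    if (nrow(g) == 0)
      return(data.frame(bin = bins[i], mean_mu = NA_real_, sd_mu = NA_real_,
                        n = 0L, sporulating_fraction = NA_real_))
    data.frame(bin = bins[i], mean_mu = mean(g$mean_mu),
               sd_mu = stats::sd(g$mean_mu), n = nrow(g),
               sporulating_fraction = mean(g$fate == "spore"))
  }))
  rownames(out) <- NULL
  out
}
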