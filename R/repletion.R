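## Focus-formation (repletion) kinetics: brightest-pixel time courses,
## fraction of cells with foci, the steady-state focus-fraction
## adjustment, initial-rate fits and strain fold-differences.

#' Simulate a repletion time course
#'
#' Emits per-cell brightest-pixel intensities and focus presence across
#' sampling times and replicates, with linearly growing planted signal:
#' intensity grows at `intensity_slope` counts/min above `baseline`, and
#' the fraction of cells with a detectable focus grows at
#' `fraction_slope` per min (capped at `max_fraction`, the strain's
#' steady-state focus fraction).
#'
#' @param times_min sampling times in minutes (sorted, unique).
#' @param intensity_slope brightest-pixel intensity gain, counts/min.
#' @param fraction_slope growth rate of the fraction of cells with a
#'   focus, per min.
#' @param n_cells cells per time point and replicate.
#' @param n_replicates independent replicate experiments.
#' @param baseline intensity at time 0.
#' @param noise_sd per-cell intensity noise sd (counts).
#' @param max_fraction steady-state focus fraction of the strain.
#' @param focus_coupled when `TRUE`, the intensity gain accrues only in
#'   cells that currently have a focus, so the population mean is diluted
#'   by focus-less cells — the situation the steady-state focus-fraction
#'   adjustment corrects for. Default `FALSE` (every cell gains signal).
#' @param seed integer seed.
#' @return data frame: `replicate_id`, `time_min`, `cell_id`,
#'   `brightest_intensity`, `has_focus`.
#' @export
sim_repletion <- function(times_min = c(0, 10, 20, 30, 40, 60),
                          intensity_slope = 10, fraction_slope = 0.045,
                          n_cells = 500, n_replicates = 3,
                          baseline = 100, noise_sd = 20,
                          max_fraction = 0.99, focus_coupled = FALSE,
                          seed = 1L) {
  if (is.unsorted(times_min, strictly = TRUE))
    stop_input("'times_min' must be strictly increasing")
  withr::with_seed(seed, {
    grid <- expand.grid(cell_id = seq_len(n_cells), time_min = times_min,
                        replicate_id = seq_len(n_replicates))
    p <- pmin(max_fraction, pmax(0, fraction_slope * grid$time_min))
    grid$has_focus <- stats::runif(nrow(grid)) < p
    gain <- if (focus_coupled) as.numeric(grid$has_focus) else 1
    grid$brightest_intensity <- baseline +
      gain * intensity_slope * grid$time_min +
      stats::rnorm(nrow(grid), sd = noise_sd)
    grid[, c("replicate_id", "time_min", "cell_id",
             "brightest_intensity", "has_focus")]
  })
}

#' Aggregate per-cell measurements into a repletion time course
#'
#' Per replicate and time point, computes the mean brightest-pixel
#' intensity and the fraction of cells with a focus; replicates are then
#' combined as mean of replicate means with SEM = sd(replicate means) /
#' sqrt(n replicates).
#'
#' @param measurements data frame as produced by [sim_repletion()] (or
#'   assembled from focus tables): columns `replicate_id`, `time_min`,
#'   `brightest_intensity`, `has_focus`.
#' @return data frame of class `timecourse`: `time_min`,
#'   `mean_brightest_intensity`, `sem`, `fraction_cells_with_focus`,
#'   `fraction_sem`, `n_cells`, `n_replicates`.
#' @export
build_timecourse <- function(measurements) {
  need <- c("replicate_id", "time_min", "brightest_intensity", "has_focus")
  if (!all(need %in% names(measurements)))
    stop_input("measurements must have columns %s",
               paste(need, collapse = ", "))
  times <- unique(measurements$time_min)
  if (length(times) < 2L) stop_input("need measurements at >= 2 time points")
  if (is.unsorted(times, strictly = TRUE))
    stop_input("time points must be sorted and unique")
  if ("cell_id" %in% names(measurements) &&
      anyDuplicated(measurements[c("replicate_id", "time_min", "cell_id")]))
    stop_input("duplicate (replicate, time, cell) measurements")

  per_rep <- stats::aggregate(
    cbind(brightest_intensity, has_focus) ~ replicate_id + time_min,
    data = measurements, FUN = mean)
  n_cells <- stats::aggregate(cell_count ~ time_min,
                              data = transform(measurements, cell_count = 1),
                              FUN = sum)

  out <- do.call(rbind, lapply(times, function(t) {
    sub <- per_rep[per_rep$time_min == t, ]
    k <- nrow(sub)
    sem <- function(x) if (k > 1L) stats::sd(x) / sqrt(k) else 0
    data.frame(
      time_min = t,
      mean_brightest_intensity = mean(sub$brightest_intensity),
      sem = sem(sub$brightest_intensity),
      fraction_cells_with_focus = mean(sub$has_focus),
      fraction_sem = sem(sub$has_focus),
      n_cells = n_cells$cell_count[n_cells$time_min == t],
      n_replicates = k)
  }))
  class(out) <- c("timecourse", "data.frame")
  out
}

#' Adjust a time course by the steady-state focus fraction
#'
#' Different strains plateau at different fractions of focus-containing
#' cells (e.g. nearly all cells for a wild-type strain versus roughly
#' half for an ATPase-impaired mutant). Dividing the intensity signal by
#' the strain's steady-state focus fraction expresses it per
#' focus-competent cell, making slopes comparable across strains.
#'
#' @param timecourse a `timecourse` data frame.
#' @param steady_state_fraction the strain's steady-state focus fraction,
#'   in (0, 1].
#' @return the adjusted time course; the factor used is recorded in
#'   attribute `"focus_fraction_adjustment"`.
#' @export
adjust_by_focus_fraction <- function(timecourse, steady_state_fraction) {
  if (!is.numeric(steady_state_fraction) ||
      length(steady_state_fraction) != 1L ||
      !is.finite(steady_state_fraction) || steady_state_fraction <= 0)
    stop_config("'steady_state_fraction' must be a number > 0")
  if (steady_state_fraction > 1)
    stop_config("'steady_state_fraction' must be <= 1")
  timecourse$mean_brightest_intensity <-
    timecourse$mean_brightest_intensity / steady_state_fraction
  timecourse$sem <- timecourse$sem / steady_state_fraction
  attr(timecourse, "focus_fraction_adjustment") <- steady_state_fraction
  timecourse
}

#' Initial rate of focus formation
#'
#' Ordinary least-squares slope of the chosen metric versus time over the
#' initial (linear) window.
#'
#' @param timecourse a `timecourse` data frame.
#' @param window_min `c(min, max)` fit window in minutes (inclusive);
#'   default 0-20, the typical initial linear phase.
#' @param metric `"brightest_pixel"` or `"focus_fraction"`.
#' @return list with `slope` (per min), `se`, `n_points`, `window_min`,
#'   `metric`.
#' @export
fit_initial_rate <- function(timecourse, window_min = c(0, 20),
                             metric = c("brightest_pixel",
                                        "focus_fraction")) {
  metric <- match.arg(metric)
  col <- switch(metric, brightest_pixel = "mean_brightest_intensity",
                focus_fraction = "fraction_cells_with_focus")
  sub <- timecourse[timecourse$time_min >= window_min[1L] &
                      timecourse$time_min <= window_min[2L], ]
  if (nrow(sub) < 2L)
    stop_input("fewer than 2 time points in window [%g, %g] min",
               window_min[1L], window_min[2L])
  fit <- stats::lm(sub[[col]] ~ sub$time_min)
  sm <- suppressWarnings(summary(fit))$coefficients
  list(slope = unname(sm[2L, 1L]),
       se = unname(sm[2L, 2L]),
       n_points = nrow(sub), window_min = window_min, metric = metric)
}

#' Fold-difference in focus-formation rate between strains
#'
#' Ratio of the reference strain's initial rate to the test strain's,
#' per metric. The fit window may differ per series (a slow strain is
#' typically sampled longer, so its linear phase spans a wider window).
#'
#' @param timecourse_ref,timecourse_test `timecourse` data frames.
#' @param metric `"brightest_pixel"` or `"focus_fraction"`.
#' @param window_ref,window_test fit windows in minutes.
#' @return list with `fold` (rate_ref / rate_test), `rate_ref`,
#'   `rate_test`, `metric`.
#' @export
rate_fold_difference <- function(timecourse_ref, timecourse_test,
                                 metric = c("brightest_pixel",
                                            "focus_fraction"),
                                 window_ref = c(0, 20),
                                 window_test = window_ref) {
  metric <- match.arg(metric)
  r_ref <- fit_initial_rate(timecourse_ref, window_ref, metric)
  r_test <- fit_initial_rate(timecourse_test, window_test, metric)
  if (!is.finite(r_test$slope) || r_test$slope <= 1e-10)
    stop_input("test-series slope is not positive; fold undefined")
  list(fold = r_ref$slope / r_test$slope,
       rate_ref = r_ref$slope, rate_test = r_test$slope, metric = metric)
}
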