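## Sister-locus cohesion timing from time-lapse focus tracks: replisome
## disappearance, persistent sister separation under a K-consecutive-
## frame rule, the replication-timing offset, and population curves.

#' Cohesion-scoring parameters
#'
#' @param K number of consecutive separated frames required to call the
#'   split persistent (default 3).
#' @param offset_min constant added to the measured replisome-to-split
#'   interval (default 7 min). The locus replicates a couple of minutes
#'   before replication terminates and the sliding clamp takes ~5 min to
#'   unload afterwards, so the raw interval underestimates the time since
#'   locus replication by ~7 min.
#' @param min_separation_px when per-frame focus centroids are available,
#'   minimum inter-focus distance (pixels) for a frame to count as
#'   separated (default 2).
#' @return object of class `cohesion_params`.
#' @export
cohesion_params <- function(K = 3, offset_min = 7, min_separation_px = 2) {
  if (!is.numeric(K) || length(K) != 1L || K < 1 || K != round(K))
    stop_config("'K' must be an integer >= 1")
  assert_scalar_number(offset_min, "offset_min", lower = 0)
  assert_scalar_number(min_separation_px, "min_separation_px", lower = 0)
  structure(list(K = as.integer(K), offset_min = offset_min,
                 min_separation_px = min_separation_px),
            class = "cohesion_params")
}

#' Specify a synthetic segregation time-lapse
#'
#' Each simulated cell carries a replisome channel whose focus
#' disappears at a per-cell time, and a locus channel showing one focus
#' until a true (persistent) sister split and two thereafter. The true
#' split occurs `delay_min` after replisome disappearance (negative
#' delays allowed: sister loci can separate before clamp unloading
#' completes). Transient pre-split separations and post-split re-mergers
#' are planted as short runs, always shorter than the persistence length
#' `K` and placed so they cannot change the persistent-split call, which
#' keeps truth labels unambiguous.
#'
#' @param n_cells number of tracks.
#' @param frame_interval_min imaging interval (default 5 min).
#' @param n_frames frames per track (default 24, i.e. 2 h at 5 min).
#' @param replisome_end_min replisome disappearance time: a single
#'   number or a `function(n)` returning draws (minutes, continuous).
#' @param delay_min true split delay after replisome disappearance: a
#'   single number or a `function(n)` (minutes; may be negative).
#' @param transient_split_prob per-frame probability of starting a
#'   transient pre-split separation run.
#' @param transient_merge_prob per-frame probability of starting a
#'   transient post-split re-merger run.
#' @param K persistence length the transients must stay below.
#' @param seed integer seed.
#' @return object of class `sim_timelapse_spec`.
#' @export
sim_timelapse_spec <- function(n_cells = 50, frame_interval_min = 5,
                               n_frames = 24,
                               replisome_end_min = function(n)
                                 stats::runif(n, 30, 70),
                               delay_min = 2,
                               transient_split_prob = 0.10,
                               transient_merge_prob = 0.05,
                               K = 3, seed = 1L) {
  assert_scalar_number(frame_interval_min, "frame_interval_min", lower = 0,
                       strict_lower = TRUE)
  assert_scalar_number(n_frames, "n_frames", lower = 2)
  assert_scalar_number(transient_split_prob, "transient_split_prob", 0, 1)
  assert_scalar_number(transient_merge_prob, "transient_merge_prob", 0, 1)
  structure(list(n_cells = as.integer(n_cells),
                 frame_interval_min = frame_interval_min,
                 n_frames = as.integer(n_frames),
                 replisome_end_min = replisome_end_min,
                 delay_min = delay_min,
                 transient_split_prob = transient_split_prob,
                 transient_merge_prob = transient_merge_prob,
                 K = as.integer(K), seed = as.integer(seed)),
            class = "sim_timelapse_spec")
}

#' Generate synthetic segregation tracks
#'
#' @param spec a [sim_timelapse_spec()].
#' @return list of class `sim_timelapse` with `tracks` (long data frame:
#'   `cell_id`, `frame`, `time_min`, `replisome_count`, `locus_count`)
#'   and `truth` (per cell: `replisome_end_min`, `true_split_min`,
#'   `measured_min`, `delay_min_true`), plus the `spec`.
#' @export
generate_timelapse <- function(spec) {
  stopifnot(inherits(spec, "sim_timelapse_spec"))
  dt <- spec$frame_interval_min
  times <- (seq_len(spec$n_frames) - 1L) * dt
  withr::with_seed(spec$seed, {
    E <- draw_from(spec$replisome_end_min, spec$n_cells, "replisome_end_min")
    D <- draw_from(spec$delay_min, spec$n_cells, "delay_min")

    tracks <- vector("list", spec$n_cells)
    truth <- data.frame(cell_id = seq_len(spec$n_cells),
                        replisome_end_min = NA_real_,
                        true_split_min = NA_real_,
                        measured_min = NA_real_,
                        delay_min_true = D)
    for (i in seq_len(spec$n_cells)) {
      ## events are observed at the first frame at or after they occur
      e_idx <- match(TRUE, times >= E[i])
      s_idx <- match(TRUE, times >= E[i] + D[i])
      if (is.na(e_idx) || is.na(s_idx) ||
          s_idx > spec$n_frames - spec$K + 1L || s_idx < 2L)
        stop_config(
          "cell %d: planted events do not fit in the track; widen n_frames or narrow the distributions", i)

      repl <- as.integer(times < times[e_idx])
      locus <- ifelse(seq_along(times) >= s_idx, 2L, 1L)

      ## transient pre-split separations: runs < K, ending at least one
      ## frame before the true split so they cannot join it
      f <- 1L
      while (f <= s_idx - 2L) {
        if (stats::runif(1) < spec$transient_split_prob) {
          len <- min(1L + stats::rgeom(1L, 0.5), spec$K - 1L,
                     s_idx - 1L - f)
          if (len >= 1L) {
            locus[f:(f + len - 1L)] <- 2L
            f <- f + len + 1L
            next
          }
        }
        f <- f + 1L
      }
      ## transient post-split re-mergers: only after the first K
      ## separated frames, runs < K
      f <- s_idx + spec$K
      while (f <= spec$n_frames) {
        if (stats::runif(1) < spec$transient_merge_prob) {
          len <- min(1L + stats::rgeom(1L, 0.5), spec$K - 1L,
                     spec$n_frames - f + 1L)
          locus[f:(f + len - 1L)] <- 1L
          f <- f + len + 1L
          next
        }
        f <- f + 1L
      }

      truth$replisome_end_min[i] <- times[e_idx]
      truth$true_split_min[i] <- times[s_idx]
      truth$measured_min[i] <- times[s_idx] - times[e_idx]
      tracks[[i]] <- data.frame(cell_id = i, frame = seq_along(times),
                                time_min = times, replisome_count = repl,
                                locus_count = locus)
    }
    structure(list(tracks = do.call(rbind, tracks), truth = truth,
                   spec = spec), class = "sim_timelapse")
  })
}

#' Time of replisome focus disappearance
#'
#' The replisome is called terminated at the first frame of the terminal
#' focus-free run, i.e. the first frame from which the focus is absent
#' through the end of the track. Isolated dropouts followed by
#' reappearance (focus blinking) do not terminate the replisome.
#'
#' @param replisome_count integer vector of per-frame focus counts.
#' @param time_min frame times.
#' @return time in minutes, or `NA_real_` if the focus never disappears
#'   (censored).
#' @export
call_replisome_end <- function(replisome_count, time_min) {
  if (length(replisome_count) != length(time_min))
    stop_input("counts and times differ in length")
  present <- replisome_count > 0
  if (!any(present)) stop_input("replisome focus present in no frame")
  last <- max(which(present))
  if (last == length(present)) return(NA_real_)
  time_min[last + 1L]
}

#' Time of persistent sister-locus separation
#'
#' A frame counts as separated when two or more locus foci are observed
#' (and, when centroids are supplied, the largest pairwise distance is at
#' least `min_separation_px`). The segregation time is the first frame of
#' the first run of at least `K` consecutive separated frames; shorter
#' (transient) runs are ignored.
#'
#' @param locus_count per-frame locus focus counts.
#' @param time_min frame times.
#' @param params a [cohesion_params()].
#' @param centroids optional list (one element per frame) of centroid
#'   matrices with columns (row, col).
#' @return time in minutes, or `NA_real_` if no qualifying run exists
#'   (censored).
#' @export
call_segregation <- function(locus_count, time_min,
                             params = cohesion_params(),
                             centroids = NULL) {
  if (length(locus_count) != length(time_min))
    stop_input("counts and times differ in length")
  sep <- locus_count >= 2
  if (!is.null(centroids)) {
    far <- vapply(centroids, function(m) {
      m <- as_centroid_matrix(m)
      if (nrow(m) < 2L) return(FALSE)
      max(stats::dist(m)) >= params$min_separation_px
    }, logical(1))
    sep <- sep & far
  }
  r <- rle(sep)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  hit <- which(r$values & r$lengths >= params$K)
  if (length(hit) == 0L) return(NA_real_)
  time_min[starts[hit[1L]]]
}

#' Cohesion time of one cell track
#'
#' measured = segregation time - replisome end time (negative allowed:
#' sister loci may separate before clamp unloading completes);
#' cohesion = measured + offset. Censored if either event is censored.
#'
#' @param track data frame for one cell: columns `time_min`,
#'   `replisome_count`, `locus_count` (optionally `cell_id`).
#' @param params a [cohesion_params()].
#' @return one-row data frame (`cohesion_call`): `cell_id`,
#'   `replisome_end_min`, `segregation_min`, `measured_interval_min`,
#'   `cohesion_time_min`, `censored`.
#' @export
cohesion_time <- function(track, params = cohesion_params()) {
  e <- call_replisome_end(track$replisome_count, track$time_min)
  s <- call_segregation(track$locus_count, track$time_min, params)
  censored <- is.na(e) || is.na(s)
  measured <- if (censored) NA_real_ else s - e
  data.frame(
    cell_id = if ("cell_id" %in% names(track)) track$cell_id[1L] else NA,
    replisome_end_min = e, segregation_min = s,
    measured_interval_min = measured,
    cohesion_time_min = if (censored) NA_real_ else
      measured + params$offset_min,
    censored = censored)
}

#' Cohesion calls for a set of tracks
#'
#' @param tracks long data frame with `cell_id` plus the per-frame
#'   columns of [cohesion_time()].
#' @param params a [cohesion_params()].
#' @return data frame with one `cohesion_call` row per cell.
#' @export
cohesion_calls <- function(tracks, params = cohesion_params()) {
  out <- do.call(rbind, lapply(split(tracks, tracks$cell_id),
                               cohesion_time, params = params))
  rownames(out) <- NULL
  out[order(out$cell_id), , drop = FALSE]
}

#' Population segregation curve and half-segregation time
#'
#' Cumulative fraction of cells segregated versus cohesion time, as a
#' step curve at frame resolution; `t50` is the first time at which the
#' cumulative fraction reaches 0.5. Censored cells are excluded from the
#' denominator by default.
#'
#' @param calls data frame of cohesion calls.
#' @param censored_as_never count censored cells in the denominator as
#'   never segregating? Default `FALSE` (exclude).
#' @return list with `curve` (data frame `cohesion_time_min`,
#'   `fraction_segregated`), `t50_min`, `n_used`, `n_censored`.
#' @export
population_segregation <- function(calls, censored_as_never = FALSE) {
  t <- calls$cohesion_time_min[!calls$censored]
  if (length(t) == 0L) stop_input("all calls are censored")
  denom <- if (censored_as_never) nrow(calls) else length(t)
  x <- sort(unique(t))
  frac <- vapply(x, function(v) sum(t <= v) / denom, numeric(1))
  t50 <- x[match(TRUE, frac >= 0.5)]
  list(curve = data.frame(cohesion_time_min = x,
                          fraction_segregated = frac),
       t50_min = t50, n_used = length(t),
       n_censored = sum(calls$censored))
}
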