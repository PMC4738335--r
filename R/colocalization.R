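## Per-cell shortest centroid distances between two channels, percent
## colocalization at a physical threshold (2 pixels = 258 nm by default),
## a random-pixel null, and cumulative distance distributions.

#' Shortest centroid distance between two focus sets of one cell
#'
#' Minimum Euclidean distance over all pairs of channel-A and channel-B
#' centroids, converted to nanometres.
#'
#' @param foci_a,foci_b numeric matrices with columns (row, col), in pixel
#'   units; one row per focus.
#' @param pixel_size_nm physical pixel size.
#' @return distance in nm, or `NA_real_` ("no-focus" sentinel; the cell
#'   must then be excluded, never counted as distance 0).
#' @export
min_centroid_distance <- function(foci_a, foci_b, pixel_size_nm = 129) {
  foci_a <- as_centroid_matrix(foci_a)
  foci_b <- as_centroid_matrix(foci_b)
  if (nrow(foci_a) == 0L || nrow(foci_b) == 0L) return(NA_real_)
  d2 <- outer(foci_a[, 1L], foci_b[, 1L], "-")^2 +
    outer(foci_a[, 2L], foci_b[, 2L], "-")^2
  sqrt(min(d2)) * pixel_size_nm
}

as_centroid_matrix <- function(x) {
  if (is.data.frame(x)) x <- cbind(x$row, x$col)
  if (is.null(x)) return(matrix(numeric(), ncol = 2L))
  if (!is.matrix(x)) x <- matrix(x, ncol = 2L)
  x[stats::complete.cases(x), , drop = FALSE]
}

#' Percent colocalization at a distance threshold
#'
#' Computes, per cell, the shortest centroid distance between the two
#' channels and the percentage of cells with distance at or below the
#' threshold (inclusive). Cells lacking a focus in either channel are
#' excluded from the denominator by default, i.e. the percentage is
#' conditional on cells that have foci; set `conditional = FALSE` to
#' count them as non-colocalized instead.
#'
#' @param foci focus table (as from [detect_foci()] or a generator truth
#'   table reshaped to focus-table form): columns `cell_id`, `channel`,
#'   `row`, `col`.
#' @param channel_a,channel_b the two channel names to compare.
#' @param threshold_nm colocalization radius (default 258 nm = 2 pixels
#'   at 129 nm/pixel).
#' @param pixel_size_nm physical pixel size.
#' @param conditional exclude cells lacking foci from the denominator?
#' @return object of class `coloc_result`: list with `n_cells_used`,
#'   `n_cells_total`, `distances_nm` (named by cell id), `threshold_nm`,
#'   `percent_colocalized`.
#' @export
colocalization_fraction <- function(foci, channel_a = "A", channel_b = "B",
                                    threshold_nm = 258,
                                    pixel_size_nm = 129,
                                    conditional = TRUE) {
  need <- c("cell_id", "channel", "row", "col")
  if (!all(need %in% names(foci)))
    stop_input("focus table must have columns %s",
               paste(need, collapse = ", "))
  ids <- unique(foci$cell_id)
  if (length(ids) == 0L) stop_input("focus table covers no cells")
  dist_of <- vapply(ids, function(id) {
    a <- foci[foci$cell_id == id & foci$channel == channel_a, ]
    b <- foci[foci$cell_id == id & foci$channel == channel_b, ]
    min_centroid_distance(a, b, pixel_size_nm)
  }, numeric(1))
  names(dist_of) <- ids
  used <- !is.na(dist_of)
  if (!any(used))
    stop_input("no cell has foci in both channels '%s' and '%s'",
               channel_a, channel_b)
  n_hit <- sum(dist_of[used] <= threshold_nm)
  denom <- if (conditional) sum(used) else length(ids)
  structure(list(
    n_cells_used = sum(used), n_cells_total = length(ids),
    distances_nm = dist_of[used], threshold_nm = threshold_nm,
    percent_colocalized = 100 * n_hit / denom,
    conditional = conditional
  ), class = "coloc_result")
}

#' @export
print.coloc_result <- function(x, ...) {
  cat(sprintf(
    "coloc_result: %.1f%% of cells at <= %g nm (%d/%d cells used%s)\n",
    x$percent_colocalized, x$threshold_nm, x$n_cells_used,
    x$n_cells_total,
    if (x$conditional) ", conditional on foci" else ""))
  invisible(x)
}

#' Random-pixel null distribution of centroid distances
#'
#' For each cell that has at least one channel-A focus, draws pixel
#' positions uniformly from the cell mask and records the distance from
#' the nearest A centroid to each drawn pixel centre. This is the
#' baseline against which observed colocalization percentages are judged:
#' it answers "how often would a uniformly placed marker fall within the
#' threshold by chance, given the cell geometry".
#'
#' @param cells list of `cell_region` objects (or a label matrix).
#' @param foci focus table providing the channel-A centroids.
#' @param channel_a channel whose centroids anchor the distances.
#' @param n_draws_per_cell uniform pixel draws per cell (default 10).
#' @param threshold_nm colocalization radius.
#' @param pixel_size_nm physical pixel size.
#' @param seed integer seed for the draws.
#' @return list with `null_distances_nm` (pooled across cells) and
#'   `null_percent` (fraction at or below threshold, in percent).
#' @export
random_pixel_null <- function(cells, foci, channel_a = "A",
                              n_draws_per_cell = 10, threshold_nm = 258,
                              pixel_size_nm = 129, seed = 1L) {
  if (is.matrix(cells)) cells <- regions_from_labels(cells, pixel_size_nm)
  withr::with_seed(seed, {
    dists <- lapply(cells, function(cell) {
      a <- foci[foci$cell_id == cell$cell_id &
                  foci$channel == channel_a, , drop = FALSE]
      a <- as_centroid_matrix(a)
      if (nrow(a) == 0L) return(NULL)
      j <- sample.int(length(cell$rows), n_draws_per_cell, replace = TRUE)
      pr <- cell$rows[j]; pc <- cell$cols[j]
      d2 <- outer(a[, 1L], pr, "-")^2 + outer(a[, 2L], pc, "-")^2
      ## distance from the nearest A focus to each drawn pixel centre
      sqrt(apply(d2, 2L, min)) * pixel_size_nm
    })
    d <- unlist(dists, use.names = FALSE)
    if (length(d) == 0L)
      stop_input("no cell has a focus in channel '%s'", channel_a)
    list(null_distances_nm = d,
         null_percent = 100 * mean(d <= threshold_nm))
  })
}

#' Empirical cumulative distribution of distances
#'
#' Right-continuous ECDF over the supplied distances; evaluated at the
#' colocalization threshold it equals the colocalized fraction.
#'
#' @param distances_nm numeric vector of per-cell distances.
#' @return data frame (`distance_nm`, `cum_fraction`), with the ECDF
#'   function attached as attribute `"ecdf"`.
#' @export
distance_ecdf <- function(distances_nm) {
  distances_nm <- distances_nm[!is.na(distances_nm)]
  if (length(distances_nm) == 0L) stop_input("no distances supplied")
  f <- stats::ecdf(distances_nm)
  x <- sort(unique(distances_nm))
  structure(data.frame(distance_nm = x, cum_fraction = f(x)), ecdf = f)
}

#' Turn a generator truth table into a focus table
#'
#' Convenience bridge from the `sim_cells` truth (planted positions) to
#' the focus-table layout consumed by the colocalization stage, as if
#' detection were perfect.
#'
#' @param truth the `truth` data frame of a `sim_cells` object.
#' @return focus table with channels `"A"` and `"B"`.
#' @export
truth_focus_table <- function(truth) {
  a <- truth[truth$has_a, c("cell_id", "a_row", "a_col")]
  b <- truth[truth$has_b, c("cell_id", "b_row", "b_col")]
  names(a) <- names(b) <- c("cell_id", "row", "col")
  a$channel <- "A"; b$channel <- "B"
  out <- rbind(a, b)
  out$frame_id <- 1L
  out$amplitude <- NA_real_; out$sd_px <- NA_real_; out$qc <- "ok"
  rownames(out) <- NULL
  out[, c("cell_id", "frame_id", "channel", "row", "col",
          "amplitude", "sd_px", "qc")]
}
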