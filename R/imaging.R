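## Focus detection in segmented cells: sub-pixel 2D Gaussian fitting of
## candidate peaks, and the per-cell brightest pixel used as a one-pixel
## focus proxy.

#' Build cell regions from a label image
#'
#' @param labels integer matrix; 0 = background, k > 0 = cell k.
#' @param pixel_size_nm physical pixel size.
#' @return list of `cell_region` objects (cell ids are the label values).
#' @export
regions_from_labels <- function(labels, pixel_size_nm = 129) {
  ids <- sort(unique(labels[labels > 0]))
  lapply(ids, function(id) {
    idx <- which(labels == id, arr.ind = TRUE)
    structure(list(cell_id = id, rows = idx[, 1L], cols = idx[, 2L],
                   pixel_size_nm = pixel_size_nm),
              class = "cell_region")
  })
}

#' Fit a symmetric 2D Gaussian spot in an image window
#'
#' Least-squares fit of `offset + A * exp(-((r-r0)^2+(c-c0)^2)/(2*sd^2))`
#' to an image patch. Returns a sub-pixel centroid in window coordinates.
#' A fit never throws on valid input: if the optimizer fails to converge,
#' the initializing pixel is returned with `qc = "weak"`.
#'
#' @param window numeric matrix, the image patch.
#' @param init integer `c(row, col)` of the coarse peak inside the window;
#'   defaults to the brightest pixel.
#' @param noise_sd local noise sd used for the weak-spot test; defaults
#'   to the median absolute deviation of the window.
#' @param weak_k amplitude threshold in units of `noise_sd` below which
#'   the spot is flagged `weak` (default 3).
#' @param min_sd_px fits narrower than this are flagged `weak` (default
#'   0.7 px): a diffraction-limited spot cannot be narrower than roughly
#'   a pixel at ~130 nm pixels, so narrower "spots" are noise spikes.
#' @return list with `row`, `col` (sub-pixel, window coordinates),
#'   `amplitude`, `sd_px`, `offset`, `qc` (`"ok"`, `"edge"` or `"weak"`).
#' @export
fit_spot_gaussian <- function(window, init = NULL, noise_sd = NULL,
                              weak_k = 3, min_sd_px = 0.7) {
  if (!is.matrix(window) || !is.numeric(window))
    stop_input("'window' must be a numeric matrix")
  if (is.null(init)) {
    init <- which(window == max(window), arr.ind = TRUE)[1L, ]
  }
  if (is.null(noise_sd)) noise_sd <- stats::mad(window)
  med <- stats::median(window)

  fallback <- list(row = as.numeric(init[[1L]]), col = as.numeric(init[[2L]]),
                   amplitude = max(window[init[[1L]], init[[2L]]] - med, 0),
                   sd_px = NA_real_, offset = med, qc = "weak")

  df <- data.frame(
    r = as.vector(row(window)), c = as.vector(col(window)),
    z = as.vector(window)
  )
  start <- list(r0 = as.numeric(init[[1L]]), c0 = as.numeric(init[[2L]]),
                A = max(window[init[[1L]], init[[2L]]] - med, noise_sd, 1),
                s = 1.3, b = med)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      z ~ b + A * exp(-((r - r0)^2 + (c - c0)^2) / (2 * s^2)),
      data = df, start = start,
      lower = c(r0 = 0.5, c0 = 0.5, A = 0, s = 0.3, b = -Inf),
      upper = c(r0 = nrow(window) + 0.5, c0 = ncol(window) + 0.5,
                A = Inf, s = max(dim(window)), b = Inf),
      control = minpack.lm::nls.lm.control(maxiter = 100)),
    error = function(e) NULL)
  if (is.null(fit)) return(fallback)

  p <- as.list(stats::coef(fit))
  qc <- "ok"
  if (p$A < weak_k * noise_sd || p$s < min_sd_px) qc <- "weak"
  else if (p$r0 < 2 || p$r0 > nrow(window) - 1 ||
           p$c0 < 2 || p$c0 > ncol(window) - 1) qc <- "edge"
  list(row = p$r0, col = p$c0, amplitude = p$A, sd_px = p$s,
       offset = p$b, qc = qc)
}

## 8-neighbour local maxima among given pixel positions of a frame.
is_local_max <- function(frame, rows, cols) {
  nr <- nrow(frame); nc <- ncol(frame)
  val <- frame[cbind(rows, cols)]
  ok <- rep(TRUE, length(rows))
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    r2 <- rows + dr; c2 <- cols + dc
    inb <- r2 >= 1 & r2 <= nr & c2 >= 1 & c2 <= nc
    nb <- rep(-Inf, length(rows))
    nb[inb] <- frame[cbind(r2[inb], c2[inb])]
    ## strict comparison on one half of the neighbourhood, non-strict on
    ## the other: a flat-topped peak yields exactly one candidate
    if (dr > 0 || (dr == 0 && dc > 0)) ok <- ok & (val >= nb)
    else ok <- ok & (val > nb)
  }
  ok
}

#' Detect foci in segmented cells
#'
#' Candidate peaks are in-mask local maxima exceeding the cell background
#' (median of mask pixels) plus `k` times the local noise sd (MAD of mask
#' pixels). Each candidate is refined by [fit_spot_gaussian()] in a
#' window around the peak; candidates whose refined centroids fall closer
#' than one fitted sd of the brighter spot are merged, keeping the higher
#' amplitude.
#'
#' @param frame numeric intensity matrix.
#' @param cells list of `cell_region` objects, or an integer label matrix.
#' @param channel channel name recorded in the output.
#' @param k candidate threshold in noise sd units (default 3).
#' @param window_px fitting window side length (odd, default 9).
#' @param keep_weak keep foci flagged `weak`/`edge`? Default `FALSE`.
#' @param frame_id frame identifier recorded in the output.
#' @return data frame (focus table): `cell_id`, `frame_id`, `channel`,
#'   `row`, `col` (sub-pixel, frame coordinates), `amplitude`, `sd_px`,
#'   `qc`. Zero rows for cells without foci.
#' @export
detect_foci <- function(frame, cells, channel = "A", k = 3, window_px = 9,
                        keep_weak = FALSE, frame_id = 1L) {
  if (is.matrix(cells)) cells <- regions_from_labels(cells)
  if (length(cells) == 0L)
    return(empty_focus_table())
  half <- window_px %/% 2
  res <- lapply(cells, function(cell) {
    vals <- frame[cbind(cell$rows, cell$cols)]
    bg <- stats::median(vals)
    noise <- stats::mad(vals)
    thr <- bg + k * noise
    cand <- which(vals > thr &
                    is_local_max(frame, cell$rows, cell$cols))
    if (length(cand) == 0L) return(NULL)
    cand <- cand[order(vals[cand], decreasing = TRUE)]
    fits <- lapply(cand, function(j) {
      r0 <- cell$rows[j]; c0 <- cell$cols[j]
      ## clamp the window inside the frame, keeping its size
      rlo <- min(max(1L, r0 - half), nrow(frame) - 2L * half)
      clo <- min(max(1L, c0 - half), ncol(frame) - 2L * half)
      win <- frame[rlo:(rlo + 2L * half), clo:(clo + 2L * half)]
      f <- fit_spot_gaussian(win, init = c(r0 - rlo + 1L, c0 - clo + 1L),
                             noise_sd = noise)
      data.frame(cell_id = cell$cell_id, frame_id = frame_id,
                 channel = channel,
                 row = f$row + rlo - 1, col = f$col + clo - 1,
                 amplitude = f$amplitude, sd_px = f$sd_px, qc = f$qc)
    })
    tab <- do.call(rbind, fits)
    ## merge unresolved doublets: greedy by amplitude, exclusion radius =
    ## fitted sd of the accepted (brighter) focus
    tab <- tab[order(tab$amplitude, decreasing = TRUE), , drop = FALSE]
    keep <- logical(nrow(tab))
    for (i in seq_len(nrow(tab))) {
      acc <- which(keep)
      if (length(acc) == 0L) { keep[i] <- TRUE; next }
      d <- sqrt((tab$row[acc] - tab$row[i])^2 +
                  (tab$col[acc] - tab$col[i])^2)
      rad <- ifelse(is.na(tab$sd_px[acc]), 1, tab$sd_px[acc])
      keep[i] <- all(d >= rad)
    }
    tab[keep, , drop = FALSE]
  })
  out <- do.call(rbind, res)
  if (is.null(out)) return(empty_focus_table())
  if (!keep_weak) out <- out[out$qc == "ok", , drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_focus_table <- function() {
  data.frame(cell_id = integer(), frame_id = integer(),
             channel = character(), row = numeric(), col = numeric(),
             amplitude = numeric(), sd_px = numeric(), qc = character())
}

#' Brightest pixel per cell
#'
#' Returns the single highest-intensity pixel within each cell mask.
#' Exactly one pixel per cell, always; intensity ties are broken by
#' lexicographic (row, col) order.
#'
#' @inheritParams detect_foci
#' @return data frame: `cell_id`, `frame_id`, `channel`, `row`, `col`
#'   (integer pixel coordinates), `intensity`.
#' @export
brightest_pixel <- function(frame, cells, channel = "A", frame_id = 1L) {
  if (is.matrix(cells)) cells <- regions_from_labels(cells)
  rows <- lapply(cells, function(cell) {
    if (length(cell$rows) == 0L) stop_input("cell %s has an empty mask",
                                            cell$cell_id)
    vals <- frame[cbind(cell$rows, cell$cols)]
    top <- which(vals == max(vals))
    top <- top[order(cell$rows[top], cell$cols[top])][1L]
    data.frame(cell_id = cell$cell_id, frame_id = frame_id,
               channel = channel, row = cell$rows[top],
               col = cell$cols[top], intensity = vals[top])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
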