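## Synthetic rod-shaped cells with two-channel foci at a controlled
## colocalization fraction, plus a renderer that turns planted foci into
## multi-channel images. Ground truth is emitted alongside so downstream
## detection/colocalization stages can be scored against known answers.

#' Specify a synthetic two-channel imaging experiment
#'
#' Defines the geometry, optics and ground-truth structure of a simulated
#' field of rod-shaped (spherocylindrical) bacterial cells carrying one
#' focus per channel. A fraction `coloc_fraction` of cells that have foci
#' in both channels place the channel-B focus on top of the channel-A
#' focus (plus isotropic Gaussian jitter); the rest place it uniformly in
#' the cell, at least 2 pixels away from the A focus so truth labels are
#' unambiguous at the standard 2-pixel colocalization threshold.
#'
#' @param n_cells number of cells in the field.
#' @param cell_length_um,cell_width_um physical cell dimensions
#'   (pole-to-pole length and diameter), in micrometres.
#' @param pixel_size_nm camera pixel size in nanometres. The default 129
#'   makes 2 pixels equal 258 nm, the conventional colocalization radius.
#' @param coloc_fraction probability that a two-focus cell is truly
#'   colocalized.
#' @param coloc_jitter_sd_nm isotropic standard deviation (per axis, nm)
#'   of the displacement between colocalized A and B foci.
#' @param focus_fraction probability that a cell has a focus, per channel;
#'   a single value or a named vector `c(A = , B = )`.
#' @param psf_sigma_px point-spread-function sigma in pixels used when
#'   rendering foci as symmetric 2D Gaussians.
#' @param focus_amplitude peak intensity of a rendered focus above
#'   background (camera counts).
#' @param background_mean mean background intensity (camera counts).
#' @param noise_model `"poisson"` (photon-limited, default) or
#'   `"gaussian"` (additive, useful for fitting tests), or `"none"`.
#' @param noise_sd Gaussian read-noise sd, used when
#'   `noise_model = "gaussian"`.
#' @param seed integer seed; identical specs give identical output.
#' @return an object of class `sim_imaging_spec`.
#' @export
sim_imaging_spec <- function(n_cells = 2000,
                             cell_length_um = 2.5,
                             cell_width_um = 1.0,
                             pixel_size_nm = 129,
                             coloc_fraction = 0.86,
                             coloc_jitter_sd_nm = 40,
                             focus_fraction = c(A = 1, B = 1),
                             psf_sigma_px = 1.3,
                             focus_amplitude = 200,
                             background_mean = 100,
                             noise_model = c("poisson", "gaussian", "none"),
                             noise_sd = 10,
                             seed = 1L) {
  noise_model <- match.arg(noise_model)
  assert_scalar_number(n_cells, "n_cells", lower = 1)
  assert_scalar_number(pixel_size_nm, "pixel_size_nm", lower = 0,
                       strict_lower = TRUE)
  assert_scalar_number(coloc_fraction, "coloc_fraction", 0, 1)
  assert_scalar_number(coloc_jitter_sd_nm, "coloc_jitter_sd_nm", lower = 0)
  assert_scalar_number(psf_sigma_px, "psf_sigma_px", lower = 0,
                       strict_lower = TRUE)
  assert_scalar_number(background_mean, "background_mean", lower = 0)
  assert_scalar_number(focus_amplitude, "focus_amplitude", lower = 0)
  if (length(focus_fraction) == 1L)
    focus_fraction <- c(A = unname(focus_fraction), B = unname(focus_fraction))
  if (is.null(names(focus_fraction))) names(focus_fraction) <- c("A", "B")
  for (f in focus_fraction)
    assert_scalar_number(f, "focus_fraction", 0, 1)

  length_px <- cell_length_um * 1000 / pixel_size_nm
  width_px <- cell_width_um * 1000 / pixel_size_nm
  if (length_px < 3 || width_px < 3)
    stop_config(
      "cell dimensions below 3 pixels (length %.2f px, width %.2f px)",
      length_px, width_px)

  structure(list(
    n_cells = as.integer(n_cells),
    cell_length_um = cell_length_um, cell_width_um = cell_width_um,
    pixel_size_nm = pixel_size_nm,
    coloc_fraction = coloc_fraction,
    coloc_jitter_sd_nm = coloc_jitter_sd_nm,
    focus_fraction = focus_fraction,
    psf_sigma_px = psf_sigma_px,
    focus_amplitude = focus_amplitude,
    background_mean = background_mean,
    noise_model = noise_model, noise_sd = noise_sd,
    length_px = length_px, width_px = width_px,
    seed = as.integer(seed)
  ), class = "sim_imaging_spec")
}

## Distance from points (rows, cols) to the medial axis segment of a
## horizontally oriented capsule centred at (cy, cx).
capsule_axis_dist <- function(r, c, cy, cx, half_axis) {
  dc <- pmin(pmax(c - cx, -half_axis), half_axis)
  sqrt((c - cx - dc)^2 + (r - cy)^2)
}

## Rejection-sample one point uniformly inside a capsule, optionally
## eroded by `margin` pixels from the membrane.
sample_in_capsule <- function(cy, cx, half_axis, radius, margin = 0) {
  rad <- radius - margin
  if (rad <= 0) stop_input("capsule margin leaves no interior to sample")
  repeat {
    c <- stats::runif(1, cx - half_axis - rad, cx + half_axis + rad)
    r <- stats::runif(1, cy - rad, cy + rad)
    if (capsule_axis_dist(r, c, cy, cx, half_axis) <= rad)
      return(c(row = r, col = c))
  }
}

#' Generate a field of synthetic cells with planted foci
#'
#' Lays cells out on a non-overlapping tile grid, builds a label image of
#' spherocylinder masks and plants per-channel focus positions with known
#' colocalization status.
#'
#' @param spec a [sim_imaging_spec()].
#' @return an object of class `sim_cells`: a list with elements
#'   `cells` (list of `cell_region` objects), `labels` (integer label
#'   matrix, 0 = background), `truth` (data frame with one row per cell:
#'   planted focus positions per channel, `has_a`/`has_b`, and the logical
#'   `colocalized` ground-truth label, `NA` where either focus is absent)
#'   and the originating `spec`.
#' @export
generate_cells <- function(spec) {
  stopifnot(inherits(spec, "sim_imaging_spec"))
  withr::with_seed(spec$seed, {
    pad <- 3
    tile_h <- ceiling(spec$width_px) + 2 * pad
    tile_w <- ceiling(spec$length_px) + 2 * pad
    grid_cols <- ceiling(sqrt(spec$n_cells))
    grid_rows <- ceiling(spec$n_cells / grid_cols)
    labels <- matrix(0L, nrow = grid_rows * tile_h, ncol = grid_cols * tile_w)

    radius <- spec$width_px / 2
    half_axis <- (spec$length_px - spec$width_px) / 2
    if (half_axis < 0) half_axis <- 0

    cells <- vector("list", spec$n_cells)
    truth <- data.frame(
      cell_id = seq_len(spec$n_cells),
      a_row = NA_real_, a_col = NA_real_,
      b_row = NA_real_, b_col = NA_real_,
      has_a = FALSE, has_b = FALSE, colocalized = NA
    )

    for (i in seq_len(spec$n_cells)) {
      gr <- (i - 1L) %/% grid_cols
      gc <- (i - 1L) %% grid_cols
      cy <- gr * tile_h + tile_h / 2 + 0.5
      cx <- gc * tile_w + tile_w / 2 + 0.5
      rr <- (gr * tile_h + 1L):((gr + 1L) * tile_h)
      cc <- (gc * tile_w + 1L):((gc + 1L) * tile_w)
      sub <- expand.grid(row = rr, col = cc)
      inside <- capsule_axis_dist(sub$row, sub$col, cy, cx, half_axis) <= radius
      px <- sub[inside, , drop = FALSE]
      labels[cbind(px$row, px$col)] <- i

      cells[[i]] <- structure(list(
        cell_id = i, rows = px$row, cols = px$col,
        center_row = cy, center_col = cx,
        half_axis_px = half_axis, radius_px = radius,
        pixel_size_nm = spec$pixel_size_nm
      ), class = "cell_region")

      has_a <- stats::runif(1) < spec$focus_fraction[["A"]]
      has_b <- stats::runif(1) < spec$focus_fraction[["B"]]
      truth$has_a[i] <- has_a
      truth$has_b[i] <- has_b

      a <- if (has_a) sample_in_capsule(cy, cx, half_axis, radius, 1.5)
      if (has_a) {
        truth$a_row[i] <- a[["row"]]; truth$a_col[i] <- a[["col"]]
      }
      if (!has_b) next

      if (has_a && stats::runif(1) < spec$coloc_fraction) {
        jit_px <- spec$coloc_jitter_sd_nm / spec$pixel_size_nm
        repeat {
          b <- a + stats::rnorm(2, sd = jit_px)
          if (capsule_axis_dist(b[["row"]], b[["col"]], cy, cx,
                                half_axis) <= radius - 0.5) break
        }
        truth$colocalized[i] <- TRUE
      } else {
        ## uniform placement; if an A focus exists, resample until the B
        ## focus is strictly more than 2 px away so the truth label is
        ## unambiguous at the 2-pixel threshold
        repeat {
          b <- sample_in_capsule(cy, cx, half_axis, radius, 1.5)
          if (!has_a) break
          if (sqrt(sum((b - a)^2)) > 2) break
        }
        if (has_a) truth$colocalized[i] <- FALSE
      }
      truth$b_row[i] <- b[["row"]]; truth$b_col[i] <- b[["col"]]
    }

    structure(list(cells = cells, labels = labels, truth = truth,
                   spec = spec), class = "sim_cells")
  })
}

#' @export
print.sim_cells <- function(x, ...) {
  cat(sprintf("sim_cells: %d cells on a %d x %d px grid (%g nm/px)\n",
              length(x$cells), nrow(x$labels), ncol(x$labels),
              x$spec$pixel_size_nm))
  both <- x$truth$has_a & x$truth$has_b
  cat(sprintf("  truth colocalized: %d / %d two-focus cells (%.1f%%)\n",
              sum(x$truth$colocalized[both]), sum(both),
              100 * mean(x$truth$colocalized[both])))
  invisible(x)
}

## Additively render one symmetric 2D Gaussian into a frame.
add_gaussian <- function(frame, row0, col0, amplitude, sigma) {
  half <- ceiling(5 * sigma)
  rr <- max(1L, floor(row0) - half):min(nrow(frame), ceiling(row0) + half)
  cc <- max(1L, floor(col0) - half):min(ncol(frame), ceiling(col0) + half)
  g <- amplitude * exp(-(outer((rr - row0)^2, (cc - col0)^2, "+")) /
                         (2 * sigma^2))
  frame[rr, cc] <- frame[rr, cc] + g
  frame
}

#' Render planted foci as multi-channel images
#'
#' Each planted focus becomes a symmetric 2D Gaussian of sd
#' `psf_sigma_px` and peak `focus_amplitude` on a constant background,
#' with Poisson or Gaussian camera noise. Rendering is deterministic
#' given the spec seed.
#'
#' @param sim a `sim_cells` object from [generate_cells()].
#' @param channels channels to render (default both).
#' @return named list of numeric intensity matrices, class `sim_frames`.
#' @export
render_images <- function(sim, channels = c("A", "B")) {
  stopifnot(inherits(sim, "sim_cells"))
  spec <- sim$spec
  withr::with_seed(spec$seed + 1L, {
    out <- lapply(channels, function(ch) {
      frame <- matrix(spec$background_mean, nrow = nrow(sim$labels),
                      ncol = ncol(sim$labels))
      cols <- if (ch == "A") c("a_row", "a_col") else c("b_row", "b_col")
      for (i in seq_len(nrow(sim$truth))) {
        r0 <- sim$truth[[cols[1]]][i]
        if (is.na(r0)) next
        frame <- add_gaussian(frame, r0, sim$truth[[cols[2]]][i],
                              spec$focus_amplitude, spec$psf_sigma_px)
      }
      switch(spec$noise_model,
        none = frame,
        poisson = matrix(stats::rpois(length(frame), pmax(frame, 0)),
                         nrow = nrow(frame)),
        gaussian = frame + matrix(stats::rnorm(length(frame),
                                               sd = spec$noise_sd),
                                  nrow = nrow(frame)))
    })
    names(out) <- channels
    structure(out, class = "sim_frames")
  })
}
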