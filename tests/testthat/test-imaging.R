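test_that("spot fitting recovers a noiseless centroid to 1e-3 px", {
  win <- gauss_window(11, row0 = 6, col0 = 6)
  f <- fit_spot_gaussian(win, noise_sd = 1)
  expect_equal(f$row, 6, tolerance = 1e-3)
  expect_equal(f$col, 6, tolerance = 1e-3)
  expect_equal(f$qc, "ok")

  win2 <- gauss_window(11, row0 = 5.3, col0 = 4.7)
  f2 <- fit_spot_gaussian(win2, noise_sd = 1)
  expect_equal(f2$row, 5.3, tolerance = 1e-3)
  expect_equal(f2$col, 4.7, tolerance = 1e-3)
  expect_equal(f2$amplitude, 200, tolerance = 1e-2)
  expect_equal(f2$sd_px, 1.5, tolerance = 1e-2)
})

test_that("a flat window is flagged weak, never an exception", {
  f <- fit_spot_gaussian(matrix(100, 9, 9))
  expect_equal(f$qc, "weak")
  f2 <- fit_spot_gaussian(matrix(rnorm(81, 100, 1), 9, 9))
  expect_equal(f2$qc, "weak")
})

test_that("detect_foci finds planted foci with sub-pixel accuracy", {
  spec <- sim_imaging_spec(n_cells = 30, focus_fraction = c(A = 1, B = 0),
                           noise_model = "gaussian", noise_sd = 10,
                           seed = 8)
  sim <- generate_cells(spec)
  fr <- render_images(sim, channels = "A")$A
  det <- detect_foci(fr, sim$cells, channel = "A")
  counts <- table(factor(det$cell_id, levels = seq_len(30)))
  expect_true(all(counts == 1))
  err <- sqrt((det$row - sim$truth$a_row[det$cell_id])^2 +
                (det$col - sim$truth$a_col[det$cell_id])^2)
  expect_true(all(err < 0.2))
})

test_that("two well-separated foci in one cell are both found", {
  sim <- generate_cells(sim_imaging_spec(
    n_cells = 1, focus_fraction = c(A = 0, B = 0), noise_model = "none",
    seed = 1))
  cell <- sim$cells[[1]]
  fr <- matrix(100, nrow(sim$labels), ncol(sim$labels))
  r0 <- cell$center_row; c0 <- cell$center_col
  fr <- mukcoloc:::add_gaussian(fr, r0, c0 - 3, 200, 1.3)
  fr <- mukcoloc:::add_gaussian(fr, r0, c0 + 3, 200, 1.3)
  ## noise floor for candidate threshold comes from the mask MAD, which
  ## is 0 for a noise-free frame; add tiny jitter
  set.seed(2); fr <- fr + matrix(rnorm(length(fr), 0, 1), nrow(fr))
  det <- detect_foci(fr, list(cell))
  expect_equal(nrow(det), 2L)
  expect_equal(sort(det$col), sort(c(c0 - 3, c0 + 3)), tolerance = 0.1)
})

test_that("a blank frame yields no foci anywhere", {
  sim <- generate_cells(sim_imaging_spec(n_cells = 10, seed = 2))
  fr <- matrix(100, nrow(sim$labels), ncol(sim$labels))
  set.seed(3); fr <- fr + matrix(rnorm(length(fr), 0, 5), nrow(fr))
  det <- detect_foci(fr, sim$cells)
  expect_equal(nrow(det), 0L)
})

test_that("detection is equivariant under integer frame translation", {
  sim <- generate_cells(sim_imaging_spec(
    n_cells = 4, focus_fraction = c(A = 1, B = 0),
    noise_model = "gaussian", noise_sd = 8, seed = 9))
  fr <- render_images(sim, channels = "A")$A
  det0 <- detect_foci(fr, sim$cells)
  dr <- 7L; dc <- 11L
  big <- matrix(100, nrow(fr) + 20L, ncol(fr) + 20L)
  big[dr + seq_len(nrow(fr)), dc + seq_len(ncol(fr))] <- fr
  cells_shift <- lapply(sim$cells, function(cl) {
    cl$rows <- cl$rows + dr; cl$cols <- cl$cols + dc; cl
  })
  det1 <- detect_foci(big, cells_shift)
  expect_equal(nrow(det1), nrow(det0))
  expect_equal(det1$row, det0$row + dr, tolerance = 1e-6)
  expect_equal(det1$col, det0$col + dc, tolerance = 1e-6)
})

test_that("detection recall and precision reach 0.95 at SNR >= 10", {
  spec <- sim_imaging_spec(n_cells = 500, focus_fraction = c(A = 1, B = 0),
                           noise_model = "poisson", seed = 11)
  sim <- generate_cells(spec)
  fr <- render_images(sim, channels = "A")$A
  det <- detect_foci(fr, sim$cells)
  hit <- vapply(seq_len(500), function(i) {
    d <- det[det$cell_id == i, ]
    nrow(d) > 0 && any(sqrt((d$row - sim$truth$a_row[i])^2 +
                              (d$col - sim$truth$a_col[i])^2) <= 1)
  }, logical(1))
  recall <- mean(hit)
  precision <- sum(hit) / max(1L, nrow(det))
  expect_gte(recall, 0.95)
  expect_gte(precision, 0.95)
})

test_that("brightest pixel is unique per cell with lexicographic ties", {
  fr <- matrix(0, 6, 6)
  cell <- structure(list(cell_id = 1L,
                         rows = rep(1:6, times = 6),
                         cols = rep(1:6, each = 6),
                         pixel_size_nm = 129), class = "cell_region")
  fr[3, 4] <- 9; fr[5, 2] <- 9   # tie: (3,4) beats (5,2) on row order
  bp <- brightest_pixel(fr, list(cell))
  expect_equal(nrow(bp), 1L)
  expect_equal(c(bp$row, bp$col), c(3, 4))
  expect_equal(bp$intensity, 9)

  fr2 <- matrix(0, 6, 6); fr2[4, 2] <- 9; fr2[4, 5] <- 9
  bp2 <- brightest_pixel(fr2, list(cell))
  expect_equal(c(bp2$row, bp2$col), c(4, 2))  # col breaks the tie
})

test_that("brightest pixel lands on the planted focus", {
  spec <- sim_imaging_spec(n_cells = 40, focus_fraction = c(A = 1, B = 0),
                           noise_model = "gaussian", noise_sd = 10,
                           seed = 12)
  sim <- generate_cells(spec)
  fr <- render_images(sim, channels = "A")$A
  bp <- brightest_pixel(fr, sim$cells)
  expect_equal(nrow(bp), 40L)
  d <- sqrt((bp$row - sim$truth$a_row)^2 + (bp$col - sim$truth$a_col)^2)
  expect_true(all(d <= 1.5))
})
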