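fake_mask <- function(mask) {
  structure(list(mask = mask, min_frames_per_pixel = 2,
                 min_component_px = 1), class = "vessel_mask")
}

fake_angiogram <- function(counts, n_frames = 20) {
  structure(list(counts = counts, n_frames = n_frames,
                 params = angiogram_params()), class = "angiogram")
}

test_that("angiogram binarization is monotone in min_frames", {
  zero <- fake_angiogram(matrix(0L, 10, 10))
  expect_false(any(binarize_angiogram(zero, 2)$mask))

  set.seed(1)
  counts <- matrix(sample(0:20, 400, replace = TRUE), 20, 20)
  m1 <- binarize_angiogram(fake_angiogram(counts), 1, min_component_px = 1)
  mN <- binarize_angiogram(fake_angiogram(counts), 20, min_component_px = 1)
  expect_true(all(m1$mask >= mN$mask))
  expect_error(binarize_angiogram(fake_angiogram(counts), 0), "min_frames")
})

test_that("small components are removed from the vessel mask", {
  counts <- matrix(0L, 30, 30)
  counts[5:20, 10] <- 10L      # 16-px vertical vessel
  counts[25, 25] <- 10L        # single-pixel speckle
  m <- binarize_angiogram(fake_angiogram(counts), 2, min_component_px = 5)
  expect_true(all(m$mask[5:20, 10]))
  expect_false(m$mask[25, 25])
})

test_that("axial band is located at the true artery and vein rows", {
  sim <- small_video(6, seed = 21)
  lay <- sim$truth$layout
  ang <- build_angiogram(sim$stack)
  band <- locate_axial_band(binarize_angiogram(ang))
  expect_lte(abs(band[["row_top"]] - lay$axial_artery_row),
             lay$axial_width_px + 5)
  expect_lte(abs(band[["row_bottom"]] - lay$axial_vein_row),
             lay$axial_width_px + 5)
})

test_that("masks without two axial channels raise the qc error", {
  empty <- fake_mask(matrix(FALSE, 50, 80))
  expect_error(locate_axial_band(empty), "no axial flow detected")
  one <- matrix(FALSE, 50, 80); one[25, ] <- TRUE
  expect_error(locate_axial_band(fake_mask(one)),
               class = "axial_flow_error")
})

test_that("ISV counting handles trivial masks", {
  empty <- fake_mask(matrix(FALSE, 60, 80))
  res <- count_isvs(empty, c(40, 55))
  expect_identical(res$isv_count, 0L)

  m <- matrix(FALSE, 60, 80)
  m[5:55, 30:35] <- TRUE
  res1 <- count_isvs(fake_mask(m), c(40, 55))
  expect_identical(res1$isv_count, 1L)
  expect_equal(res1$isv_column_positions, 32L, tolerance = 1)

  expect_error(count_isvs(fake_mask(m), c(50, 70)), "band")
})

test_that("ISV count is invariant to horizontal mask translation", {
  m <- matrix(FALSE, 60, 120)
  for (cc in c(20, 50, 80)) m[5:55, cc:(cc + 2)] <- TRUE
  base <- count_isvs(fake_mask(m), c(40, 55))
  shifted <- m[, c(106:120, 1:105)]  # shift right by 15 px
  tr <- count_isvs(fake_mask(shifted), c(40, 55))
  expect_identical(base$isv_count, tr$isv_count)
})

test_that("components far from the scan line do not change the count", {
  m <- matrix(FALSE, 60, 120)
  for (cc in c(20, 50, 80)) m[5:55, cc:(cc + 2)] <- TRUE
  with_blob <- m
  with_blob[57:59, 100:110] <- TRUE
  expect_identical(count_isvs(fake_mask(m), c(40, 55))$isv_count,
                   count_isvs(fake_mask(with_blob), c(40, 55))$isv_count)
})

test_that("arterial and venous ISVs are labelled by their ventral reach", {
  sim <- small_video(6, seed = 31)
  res <- quantify_angiogram(build_angiogram(sim$stack), side = "both")
  expect_identical(res$isv_count, 6L)
  expect_identical(res$isv_types, sim$truth$layout$isv_types)
})

test_that("ISV count is recovered exactly on small synthetic videos", {
  for (seed in 1:3) {
    K <- c(4L, 6L, 9L)[seed]
    sim <- small_video(K, seed = 40 + seed)
    res <- quantify_angiogram(build_angiogram(sim$stack))
    expect_identical(res$isv_count, K)
  }
})

test_that("recovery error is at most 1 ISV at doubled pixel noise", {
  errs <- vapply(1:4, function(seed) {
    sim <- small_video(7, seed = 50 + seed, noise_sd = 0.02)
    abs(quantify_angiogram(build_angiogram(sim$stack))$isv_count - 7)
  }, numeric(1))
  expect_lte(median(errs), 1)
})

test_that("videos without circulation are flagged, not errored", {
  lay <- make_vessel_layout(5, image_shape = c(100, 300), seed = 1)
  sim <- simulate_flow_video(lay, flow_sim_config(particle_density = 0,
                                                  seed = 2))
  res <- quantify_angiogram(build_angiogram(sim$stack))
  expect_identical(res$isv_count, 0L)
  expect_true("no axial flow detected" %in% res$qc_flags)
})

test_that("control CV is the sample SD over the mean", {
  expect_equal(control_cv(c(10, 10, 10))$cv, 0)
  cs <- control_cv(c(8, 10, 12))
  expect_equal(cs$sd, 2)
  expect_equal(cs$mean, 10)
  expect_equal(cs$cv, 0.2)
  # scale invariance
  expect_equal(control_cv(c(8, 10, 12) * 7)$cv, 0.2)
  expect_error(control_cv(5), "2 control values")
  expect_error(control_cv(c(0, 0)), "mean")
})
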