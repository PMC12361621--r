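line_set <- function(x = seq(10, 50, by = 10), y = 20, jitter = 0) {
  cand <- tibble::tibble(x_px = x, y_px = y + jitter * sin(x),
                         value = 1, prominence = 1)
  order_along_bundle(curate(cand, pixel_size_nm = 15))
}

circle_set <- function(R = 50, n = 9, span = 2.0, centre = c(60, 60)) {
  th <- seq(-pi / 2 - span / 2, -pi / 2 + span / 2, length.out = n)
  cand <- tibble::tibble(x_px = centre[1] + R * cos(th),
                         y_px = centre[2] + R * sin(th),
                         value = 1, prominence = 1)
  order_along_bundle(curate(cand, pixel_size_nm = 15))
}

test_that("a collinear bundle yields a straight, zero-curvature spline", {
  curve <- fit_spline(line_set())
  expect_lt(max(abs(curve$curvature)), 1e-9)
  expect_lt(max(abs(curve$samples$y_px - 20)), 1e-9)
  # arc-length parameterization: uniform sample spacing to 1%
  d <- sqrt(diff(curve$samples$x_px)^2 + diff(curve$samples$y_px)^2)
  expect_lt(max(abs(d - 1)), 0.01)
  # unit normals orthogonal to tangents
  sm <- curve$samples
  expect_lt(max(abs(sm$tx * sm$nx + sm$ty * sm$ny)), 1e-9)
  expect_equal(sqrt(sm$nx^2 + sm$ny^2), rep(1, nrow(sm)), tolerance = 1e-9)
})

test_that("centres on a circle produce curvature 1/R at interior samples", {
  R <- 80
  curve <- fit_spline(circle_set(R = R, n = 17, span = 1.2, centre = c(100, 100)))
  sm <- curve$samples
  # natural end conditions corrupt curvature near the spline ends; the
  # effect decays within a few knot spacings, so judge the central half
  inner <- sm$s_px > 0.25 * curve$arc_length_px &
    sm$s_px < 0.75 * curve$arc_length_px
  expect_lt(max(abs(abs(curve$curvature[inner]) - 1 / R)) * R, 0.02)
  # the interior normal points toward the circle centre
  mid <- which.min(abs(sm$s_px - curve$arc_length_px / 2))
  to_centre <- c(100 - sm$x_px[mid], 100 - sm$y_px[mid])
  to_centre <- to_centre / sqrt(sum(to_centre^2))
  expect_gt(sum(to_centre * c(sm$nx[mid], sm$ny[mid])), 0.99)
})

test_that("the spline interpolates every control point to < 0.25 px", {
  set.seed(7)
  cand <- tibble::tibble(x_px = seq(5, 65, by = 10),
                         y_px = 30 + 3 * sin(seq(5, 65, by = 10) / 9),
                         value = 1, prominence = 1)
  s <- order_along_bundle(curate(cand, pixel_size_nm = 15))
  curve <- fit_spline(s, step_px = 0.1)
  for (i in seq_len(nrow(s$centers))) {
    d <- sqrt((curve$samples$x_px - s$centers$x_px[i])^2 +
                (curve$samples$y_px - s$centers$y_px[i])^2)
    expect_lt(min(d), 0.25)
  }
})

test_that("unfolding a straight bundle reproduces the axis-aligned crop", {
  set.seed(21)
  ch1 <- matrix(runif(40 * 70), 40, 70)
  ch2 <- matrix(runif(40 * 70), 40, 70)
  img <- image2c(ch1, ch2, pixel_size_nm = 15)
  curve <- fit_spline(line_set(x = seq(10, 50, 10), y = 20))
  u <- unfold(img, curve, half_width_nm = 10 * 15)
  expect_equal(dim(u$actin), c(21, 41))
  crop1 <- ch1[11:31, 11:51]
  crop2 <- ch2[11:31, 11:51]
  expect_lt(max(abs(u$actin - crop1)), 1e-6 * diff(range(ch1)))
  expect_lt(max(abs(u$protein - crop2)), 1e-6 * diff(range(ch2)))
})

test_that("transverse sampling arithmetic matches the contract", {
  img <- image2c(matrix(1, 60, 80), matrix(1, 60, 80), pixel_size_nm = 15)
  curve <- fit_spline(line_set(y = 30))
  u <- unfold(img, curve, half_width_nm = 300)
  expect_equal(nrow(u$actin), 41)
  expect_true(0 %in% u$transverse_offsets_nm)
  expect_equal(diff(u$transverse_offsets_nm), rep(15, 40))
})

test_that("a band at constant offset from a curved spline unfolds to a flat ridge", {
  g <- make_geometry("OHC", n_cilia_per_row = 7, arc_radius_nm = 2000)
  sim <- render(g, band_only_preset(0.5, n_rows = 3),
                render_settings(seed = 2, noise = FALSE))
  px <- sim$image$pixel_size_nm
  tr <- sim$truth$true_centers[sim$truth$true_centers$row == 1, ]
  cand <- tibble::tibble(x_px = tr$x_nm / px, y_px = tr$y_nm / px,
                         value = 1, prominence = 1)
  set <- order_along_bundle(curate(cand, pixel_size_nm = px))
  curve <- fit_spline(set)
  u <- unfold(sim$image, curve, half_width_nm = 600)
  # per-column ridge position of the protein channel
  inner_cols <- seq(10, ncol(u$protein) - 10)
  ridge <- u$transverse_offsets_nm[apply(u$protein[, inner_cols], 2, which.max)]
  expect_true(all(abs(ridge - 250) <= px))
})

test_that("transverse profiles are max-normalized with origin at the spline", {
  img <- image2c(matrix(3, 50, 70), matrix(7, 50, 70), pixel_size_nm = 15)
  curve <- fit_spline(line_set(y = 25))
  u <- unfold(img, curve, half_width_nm = 150)
  p <- transverse_profile(u)
  expect_true(all(p$actin == 1))
  expect_true(all(p$protein == 1))
  expect_true(all(diff(p$distance_nm) > 0))
  expect_true(0 %in% p$distance_nm)

  sim <- render(small_ihc(), preset_library("IHC_ADGRV1_extra"),
                render_settings(seed = 4, noise = FALSE))
  fit <- analyze_sim(sim)
  expect_equal(max(fit$profile$actin), 1)
  expect_equal(max(fit$profile$protein), 1)
  # noise-free 2-row bundle: actin maxima at 0 and the row spacing
  pk <- call_peaks(fit$profile, "actin")
  pos <- sort(pk$position_nm[pk$kind == "peak"])
  expect_equal(length(pos), 2)
  expect_lt(abs(pos[1]), 15)
  expect_lt(abs(pos[2] - 500), 15)
})

test_that("reversing the centre order mirrors the bundle but not the profile", {
  sim <- render(small_ihc(), preset_library("IHC_PDZD7"),
                render_settings(seed = 6, noise = FALSE))
  px <- sim$image$pixel_size_nm
  tr <- sim$truth$true_centers[sim$truth$true_centers$row == 1, ]
  fwd <- tibble::tibble(x_px = tr$x_nm / px, y_px = tr$y_nm / px,
                        value = 1, prominence = 1)
  rev_ <- fwd[rev(seq_len(nrow(fwd))), ]
  pr <- lapply(list(fwd, rev_), function(cand) {
    set <- curate(cand, pixel_size_nm = px)
    curve <- fit_spline(set)
    transverse_profile(unfold(sim$image, curve, half_width_nm = 900))
  })
  expect_equal(pr[[1]]$distance_nm, pr[[2]]$distance_nm)
  # columns sample the curve from opposite ends, so agreement is to the
  # along-bundle averaging resolution, not machine precision
  expect_equal(pr[[1]]$actin, pr[[2]]$actin, tolerance = 0.01)
  expect_equal(pr[[1]]$protein, pr[[2]]$protein, tolerance = 0.01)
})

test_that("samples outside the image are flagged invalid with a warning", {
  img <- image2c(matrix(1, 30, 70), matrix(1, 30, 70), pixel_size_nm = 15)
  curve <- fit_spline(line_set(y = 5))
  expect_warning(u <- unfold(img, curve, half_width_nm = 20 * 15),
                 "partial-coverage")
  expect_false(all(u$valid))
  p <- transverse_profile(u)
  expect_true(all(p$n_valid > 0))
})
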