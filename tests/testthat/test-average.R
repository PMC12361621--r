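frames_from_pts <- function(x, y, px = 15, hint = "down") {
  cand <- tibble::tibble(x_px = x, y_px = y, value = 1, prominence = 1)
  set <- order_along_bundle(curate(cand, pixel_size_nm = px))
  list(set = set, curve = fit_spline(set, interior_hint = hint))
}

test_that("collinear triples are degenerate with a chord-perpendicular normal", {
  f <- frames_from_pts(c(0, 10, 20, 30, 40), rep(8, 5))
  fr <- local_frames(f$set, f$curve)
  expect_true(all(fr$degenerate))
  # outward for hint "down" is up: angle -90 degrees
  expect_equal(fr$normal_angle_deg, rep(-90, 5), tolerance = 1e-6)
})

test_that("circumcircle normals point through the circle centre", {
  R <- 60; centre <- c(70, 75)
  th <- seq(-2.2, -0.9, length.out = 8)
  f <- frames_from_pts(centre[1] + R * cos(th), centre[2] + R * sin(th))
  fr <- local_frames(f$set, f$curve)
  expect_false(any(fr$degenerate))
  for (i in seq_len(nrow(fr))) {
    a <- fr$normal_angle_deg[i] * pi / 180
    # backward ray from the cilium along -normal must pass near the centre
    v <- c(cos(a), sin(a))
    p <- c(fr$x_px[i], fr$y_px[i])
    tpar <- sum((centre - p) * -v)
    miss <- sqrt(sum((p - v * tpar - centre)^2))
    expect_lt(miss, R / 100)
  }
})

test_that("a symmetric isoceles triple bisects the apex angle", {
  f <- frames_from_pts(c(-12, 0, 12), c(0, 5, 0) + 20)
  fr <- local_frames(f$set, f$curve)
  apex <- fr[fr$x_px == 0, ]
  expect_equal(abs(apex$normal_angle_deg), 90, tolerance = 1e-6)
})

test_that("zero-rotation extraction equals the axis-aligned crop", {
  set.seed(13)
  ch1 <- matrix(runif(60 * 80), 60, 80)
  img <- image2c(ch1, ch1 * 2, pixel_size_nm = 15)
  f <- frames_from_pts(c(20, 35, 50), rep(30, 3))
  fr <- local_frames(f$set, f$curve)
  st <- extract_aligned(img, fr, roi_size_px = 11)
  crop <- ch1[26:36, 31:41]   # centred on (35, 30), 0-based coords
  expect_lt(max(abs(st$actin[, , 2] - crop)), 1e-6)
})

test_that("extraction undoes a rotation of the image (NCC > 0.99)", {
  # smooth test pattern
  xs <- 0:120; ys <- 0:120
  blob <- function(cx, cy, s) outer(exp(-(ys - cy)^2 / (2 * s^2)),
                                    exp(-(xs - cx)^2 / (2 * s^2)))
  base <- blob(70, 50, 6) + 0.6 * blob(50, 70, 10) + 0.3 * blob(60, 60, 18)
  img0 <- image2c(base, base, pixel_size_nm = 15)
  theta <- 25 * pi / 180
  centre <- c(60, 60)
  grid <- expand.grid(x = xs, y = ys)
  ct <- cos(theta); st_ <- sin(theta)
  xr <- centre[1] + ct * (grid$x - centre[1]) - st_ * (grid$y - centre[2])
  yr <- centre[2] + st_ * (grid$x - centre[1]) + ct * (grid$y - centre[2])
  rot <- matrix(hairbundle:::bilinear_sample(base, xr, yr), 121, 121,
                byrow = TRUE)
  rot[is.na(rot)] <- 0
  imgR <- image2c(rot, rot, pixel_size_nm = 15)

  fr0 <- tibble::tibble(index = 1L, x_px = 60, y_px = 60, nb1 = 1L, nb2 = 1L,
                        normal_angle_deg = -90, degenerate = FALSE)
  class(fr0) <- c("cilium_frames", class(fr0))
  attr(fr0, "pixel_size_nm") <- 15
  attr(fr0, "mean_intra_spacing_px") <- 10
  frR <- fr0
  frR$normal_angle_deg <- -90 - theta * 180 / pi
  roiA <- extract_aligned(img0, fr0, roi_size_px = 41)$actin[, , 1]
  roiB <- extract_aligned(imgR, frR, roi_size_px = 41)$actin[, , 1]
  expect_gt(hairbundle:::ncc(c(roiA), c(roiB)), 0.99)
})

test_that("extraction validates the ROI size", {
  img <- image2c(matrix(1, 30, 30), matrix(1, 30, 30), 15)
  f <- frames_from_pts(c(5, 15, 25), rep(15, 3))
  fr <- local_frames(f$set, f$curve)
  expect_error(extract_aligned(img, fr, roi_size_px = 4), "odd")
})

test_that("stack averaging obeys identity and law-of-large-numbers checks", {
  template <- outer(exp(-((0:20) - 10)^2 / 30), exp(-((0:20) - 10)^2 / 30))
  n <- 16; sigma <- 0.05
  mk_stack <- function(rois) {
    arr <- simplify2array(rois)
    structure(list(actin = arr, protein = arr,
                   valid = array(TRUE, dim(arr)), roi_size_px = 21,
                   pixel_size_nm = 15, index = seq_along(rois)),
              class = "aligned_stack")
  }
  same <- average_stack(mk_stack(replicate(5, template, simplify = FALSE)))
  expect_equal(same$actin, template)
  one <- average_stack(mk_stack(list(template)))
  expect_equal(one$actin, template)
  set.seed(31)
  noisy <- replicate(n, template + matrix(rnorm(441, 0, sigma), 21, 21),
                     simplify = FALSE)
  avg <- average_stack(mk_stack(noisy))
  res_sd <- stats::sd(avg$actin - template)
  expect_lt(abs(res_sd - sigma / sqrt(n)) / (sigma / sqrt(n)), 0.2)
  empty <- structure(list(actin = array(0, c(21, 21, 0)),
                          protein = array(0, c(21, 21, 0)),
                          valid = array(FALSE, c(21, 21, 0)),
                          roi_size_px = 21, pixel_size_nm = 15,
                          index = integer(0)), class = "aligned_stack")
  expect_error(average_stack(empty), "empty-stack")
})

test_that("background subtraction modes behave per contract", {
  base <- matrix(2.5, 21, 21)
  avg <- structure(list(actin = base, protein = base * 2,
                        counts = matrix(5, 21, 21), roi_size_px = 21,
                        pixel_size_nm = 15, n = 5), class = "stack_average")
  auto <- subtract_background(avg, "auto_region")
  expect_true(all(auto$actin == 0))
  expect_equal(unname(auto$background_values["actin"]), 2.5)
  rec0 <- subtract_background(avg, "recalled_value", value = c(0, 0))
  expect_equal(rec0$actin, base)
  expect_error(subtract_background(avg, "recalled_value", value = c(-1, 0)),
               "parameter error")
  roi <- matrix(FALSE, 21, 21); roi[9:13, 9:13] <- TRUE
  expect_warning(subtract_background(avg, "user_roi", region = roi),
                 "central stereocilium")
})

test_that("an injected background offset is recovered by auto mode", {
  b <- 7.3
  set.seed(5)
  img <- matrix(rnorm(41 * 41, b, 0.5), 41, 41)
  # bundle signal only in the lower half; upper quarter is background
  img[25:41, ] <- img[25:41, ] + 50
  avg <- structure(list(actin = img, protein = img,
                        counts = matrix(1, 41, 41), roi_size_px = 41,
                        pixel_size_nm = 15, n = 1), class = "stack_average")
  res <- subtract_background(avg, "auto_region")
  se <- 0.5 / sqrt(sum(res$region))
  expect_lt(abs(res$background_values[["actin"]] - b), 2 * se + 0.05)
})

test_that("mode-3 background recall reproduces mode-1 subtraction bit-exactly", {
  sim <- render(small_ihc(), preset_library("IHC_ADGRV1_extra"),
                render_settings(seed = 8))
  fit <- analyze_sim(sim)
  a0 <- average_stack(fit$stack)
  auto <- subtract_background(a0, "auto_region")
  path <- tempfile(fileext = ".json")
  export_background(auto, path)
  recalled <- subtract_background(a0, "recalled_value",
                                  value = read_background(path))
  expect_identical(auto$actin, recalled$actin)
  expect_identical(auto$protein, recalled$protein)
})

test_that("axial profiles of a radially symmetric average are symmetric", {
  template <- outer(exp(-((0:20) - 10)^2 / 40), exp(-((0:20) - 10)^2 / 40))
  avg <- structure(list(actin = template, protein = template,
                        counts = matrix(1, 21, 21), roi_size_px = 21,
                        pixel_size_nm = 15, n = 1,
                        background_values = c(actin = 0, protein = 0),
                        background_mode = "recalled_value"),
                   class = "average_stereocilium")
  ax <- axial_profiles(avg)
  h <- ax[ax$axis == "horizontal", ]
  v <- ax[ax$axis == "vertical", ]
  expect_lt(max(abs(h$actin - v$actin)), 0.05 * max(h$actin))
  expect_equal(h$distance_nm[which.max(h$actin)], 0)
})

test_that("aligned averages keep interior rows strictly below the centre", {
  sim <- render(small_ohc(), preset_library("OHC_ADGRV1_extra"),
                render_settings(seed = 2))
  fit <- analyze_sim(sim)
  avg <- fit$average
  k <- avg$roi_size_px; q <- (k + 1) / 2
  margin <- ceiling(k / 8)
  below <- sum(avg$actin[(q + margin):k, ], na.rm = TRUE)
  above <- sum(avg$actin[1:(q - margin), ], na.rm = TRUE)
  expect_gt(below, 3 * above)
})

test_that("excluding kinked stereocilia improves the average's fidelity", {
  g <- make_geometry("IHC", n_cilia_per_row = 7, kink = TRUE, kink_nm = 150)
  marker <- labeling_preset("mk",
    local_marker = list(u_nm = 60, w_nm = 40, amplitude = 1),
    amplitude_ratio = 0.8)
  sim <- render(g, marker, render_settings(seed = 9))
  px <- sim$image$pixel_size_nm
  fit_all <- analyze_sim(sim)
  # identify the displaced (kinked) cilia among the ordered centres
  tr <- sim$truth$true_centers[sim$truth$true_centers$row == 1, ]
  kinked <- tr[rank(tr$y_nm) <= 2, ]   # displaced outward = smallest y
  cenok <- fit_all$centers$centers
  kink_idx <- cenok$index[sapply(seq_len(nrow(cenok)), function(i) {
    min(sqrt((kinked$x_nm / px - cenok$x_px[i])^2 +
               (kinked$y_nm / px - cenok$y_px[i])^2)) < 4
  })]
  # fixed ROI size so both averages live on the same grid
  avg_for <- function(set) {
    frames <- local_frames(set, fit_all$curve)
    a0 <- average_stack(extract_aligned(sim$image, frames, roi_size_px = 41))
    subtract_background(a0, "recalled_value", value = c(0, 0))
  }
  set_all <- fit_all$centers
  set_excl <- order_along_bundle(curate(set_all, rejected = kink_idx,
                                        pixel_size_nm = px))
  tmpl <- marker_template(41, px, u_nm = 60, w_nm = 40, fwhm_nm = 50)
  cor_all <- hairbundle:::ncc(c(avg_for(set_all)$protein), c(tmpl))
  cor_excl <- hairbundle:::ncc(c(avg_for(set_excl)$protein), c(tmpl))
  expect_gt(cor_excl, cor_all)
})
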