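make_disc_image <- function(centres_px, nr = 80, nc = 120, radius = 6,
                            pixel_size_nm = 15) {
  ch <- matrix(0, nr, nc)
  for (i in seq_len(nrow(centres_px))) {
    dd <- outer((0:(nr - 1) - centres_px[i, 2])^2,
                (0:(nc - 1) - centres_px[i, 1])^2, "+")
    ch[dd <= radius^2] <- ch[dd <= radius^2] + 1
  }
  image2c(ch, ch * 0, pixel_size_nm = pixel_size_nm)
}

test_that("smoothing respects the mask and the zero-sigma identity", {
  img <- make_disc_image(cbind(c(30, 60, 90), c(40, 40, 40)))
  mask <- matrix(FALSE, 80, 120)
  mask[20:60, 10:110] <- TRUE
  s0 <- smooth_in_mask(img, mask, sigma_px = 0)
  expect_equal(s0, img$actin * mask)
  # constant value inside the mask stays constant away from the boundary
  cimg <- image2c(matrix(5, 80, 120), matrix(0, 80, 120), 15)
  s2 <- smooth_in_mask(cimg, mask, sigma_px = 2)
  expect_equal(s2[30:50, 20:100], matrix(5, 21, 81), tolerance = 1e-9)
  expect_true(all(s2[!mask] == 0))
  expect_error(smooth_in_mask(img, matrix(FALSE, 80, 120)), "mask error")
})

test_that("an isolated bright pixel blurs to the requested sigma", {
  ch <- matrix(0, 61, 61); ch[31, 31] <- 100
  img <- image2c(ch, ch * 0, 15)
  mask <- matrix(TRUE, 61, 61)
  s <- smooth_in_mask(img, mask, sigma_px = 2)
  w <- colSums(s) / sum(s)
  mu <- sum(w * (0:60))
  sd_fit <- sqrt(sum(w * ((0:60) - mu)^2))
  expect_lt(abs(sd_fit - 2) / 2, 0.05)
})

test_that("find_centers recovers well-separated discs and handles blanks", {
  mask <- matrix(TRUE, 80, 120)
  expect_equal(nrow(find_centers(matrix(0, 80, 120), mask, prominence = 0.1)), 0)
  truth <- cbind(x = c(15, 40, 65, 90, 105), y = c(40, 42, 40, 38, 40))
  img <- make_disc_image(truth)
  sm <- smooth_in_mask(img, mask, 2)
  found <- find_centers(sm, mask, prominence = 0.2)
  expect_equal(nrow(found), 5)
  ord <- order(found$x_px)
  expect_true(all(abs(found$x_px[ord] - truth[, "x"]) <= 1))
  expect_true(all(abs(found$y_px[ord] - truth[, "y"]) <= 1))
})

test_that("the prominence threshold separates merged from split maxima", {
  # two Gaussians: saddle height is known analytically on the joining line;
  # the weaker summit's prominence is peak - saddle, the stronger one keeps
  # its full height, so a threshold between the two leaves one detection
  xg <- 0:60
  g1 <- outer(exp(-((0:40) - 20)^2 / 18), exp(-(xg - 26)^2 / 18))
  g2 <- outer(exp(-((0:40) - 20)^2 / 18), exp(-(xg - 34)^2 / 18))
  m <- g1 + g2
  mask <- matrix(TRUE, 41, 61)
  peak_v <- max(m)
  saddle_v <- m[21, 31]
  prom_low <- peak_v - saddle_v          # ~0.21
  expect_lt(prom_low, 0.5)
  two <- find_centers(m, mask, prominence = prom_low * 0.5, sigma_px = 0)
  one <- find_centers(m, mask, prominence = 0.5, sigma_px = 0)
  expect_equal(nrow(two), 2)
  expect_equal(nrow(one), 1)
})

test_that("curation flags but never deletes, and is idempotent", {
  cand <- tibble::tibble(x_px = c(1, 10, 20, 30), y_px = rep(0, 4),
                         value = 1:4, prominence = 1:4)
  s0 <- curate(cand, pixel_size_nm = 15)
  expect_true(all(s0$centers$included))
  suppressWarnings(s1 <- curate(cand, rejected = c(2L, 3L),
                                pixel_size_nm = 15))
  expect_equal(nrow(s1$centers), 4)
  expect_equal(sum(s1$centers$included), 2)
  suppressWarnings(s2 <- curate(s1, rejected = c(2L, 3L)))
  expect_equal(s1$centers$included, s2$centers$included)
  expect_error(curate(cand, rejected = 9L), "outside")
})

test_that("curation to two points succeeds but downstream stages refuse", {
  cand <- tibble::tibble(x_px = c(0, 10, 20), y_px = c(0, 0, 0),
                         value = c(1, 1, 1), prominence = c(1, 1, 1))
  expect_warning(s <- curate(cand, rejected = 2L, pixel_size_nm = 15),
                 "included centres")
  expect_equal(sum(s$centers$included), 2)
  expect_error(order_along_bundle(s), "insufficient-points")
  expect_error(fit_spline(s), "insufficient-points")
})

test_that("ordering recovers a shuffled line and starts at an extremity", {
  pts <- tibble::tibble(x_px = c(50, 10, 30, 20, 40, 0),
                        y_px = c(0.3, 0.1, -0.2, 0, 0.2, 0),
                        value = 1, prominence = 1)
  set.seed(4)
  for (i in 1:5) {
    sh <- pts[sample(nrow(pts)), ]
    s <- order_along_bundle(curate(sh, pixel_size_nm = 15))
    xs <- s$centers$x_px
    expect_true(identical(xs, sort(xs)) || identical(xs, rev(sort(xs))))
  }
  # for 3 points, the one with the largest distance sum is never the middle
  tri <- tibble::tibble(x_px = c(0, 3, 10), y_px = c(0, 1, 0),
                        value = 1, prominence = 1)
  s <- order_along_bundle(curate(tri, pixel_size_nm = 15))
  sums <- c(0 + 10, 3 + 7, 10 + 7)  # rough distance sums
  expect_false(s$centers$x_px[2] == 10)
})

test_that("greedy ordering matches the exhaustive shortest-path oracle", {
  skip_if_not_installed("e1071")
  set.seed(99)
  for (rep in 1:25) {
    n <- sample(4:8, 1)
    pts <- random_arc_points(n)
    cand <- tibble::tibble(x_px = pts[, 1], y_px = pts[, 2],
                           value = 1, prominence = 1)
    sh <- cand[sample(n), ]
    s <- order_along_bundle(curate(sh, pixel_size_nm = 15))
    got <- as.matrix(s$centers[, c("x_px", "y_px")])
    best <- shortest_path_bruteforce(pts)
    want <- pts[best, ]
    same <- isTRUE(all.equal(got, want, check.attributes = FALSE)) ||
      isTRUE(all.equal(got, want[nrow(want):1, ], check.attributes = FALSE))
    expect_true(same)
  }
})

test_that("detection has full recall and no spurious maxima on synthetic bundles", {
  hits <- 0; spurious <- 0; total <- 0
  for (seed in 1:20) {
    sim <- render(small_ihc(), preset_library("IHC_ADGRV1_extra"),
                  render_settings(seed = seed))
    px <- sim$image$pixel_size_nm
    sm <- smooth_in_mask(sim$image, sim$mask, 2)
    found <- find_centers(sm, sim$mask)
    tr <- sim$truth$true_centers
    tr <- tr[tr$row == 1, ]
    total <- total + nrow(tr)
    for (i in seq_len(nrow(tr))) {
      d <- sqrt((found$x_px - tr$x_nm[i] / px)^2 +
                  (found$y_px - tr$y_nm[i] / px)^2)
      if (min(d) <= 2) hits <- hits + 1
    }
    spurious <- spurious + max(0, nrow(found) - nrow(tr))
  }
  expect_equal(hits, total)
  expect_equal(spurious, 0)
})

test_that("ordering is reversal-symmetric", {
  pts <- random_arc_points(7)
  cand <- tibble::tibble(x_px = pts[, 1], y_px = pts[, 2],
                         value = 1, prominence = 1)
  s <- order_along_bundle(curate(cand, pixel_size_nm = 15))
  rev_cand <- s$centers[rev(seq_len(nrow(s$centers))), ]
  s2 <- order_along_bundle(curate(rev_cand, pixel_size_nm = 15))
  a <- as.matrix(s$centers[, c("x_px", "y_px")])
  b <- as.matrix(s2$centers[, c("x_px", "y_px")])
  expect_true(isTRUE(all.equal(a, b, check.attributes = FALSE)) ||
                isTRUE(all.equal(a, b[nrow(b):1, ], check.attributes = FALSE)))
})
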