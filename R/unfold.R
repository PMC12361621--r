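#' Fit the bundle spline through ordered stereocilium centres
#'
#' An interpolating natural cubic spline is fit through the included,
#' ordered centres (chord-length parameterization), then resampled to
#' uniform arc length. Per-sample unit tangents and interior-pointing unit
#' normals are attached; positive transverse offsets point toward the
#' bundle interior (rows 2, 3), as judged from the mean signed curvature.
#' For near-straight bundles (`max |curvature| * arc length <` the
#' straightness threshold) the curvature side is unreliable and the
#' explicit `interior_hint` decides instead.
#'
#' @param set an ordered `stereocilia_set` (see [order_along_bundle()]).
#' @param step_px arc-length sampling step in pixels.
#' @param interior_hint `"down"`, `"up"`, or a length-2 vector: the image
#'   direction of the bundle interior, used only for near-straight bundles.
#' @param straight_threshold net turning angle (radians) below which the
#'   bundle counts as straight and the hint is used; 0.3 tolerates the
#'   tangent noise of detected centres while any truly curved bundle turns
#'   by far more.
#' @return object of class `bundle_curve`: `samples` tibble
#'   (`s_px`, `x_px`, `y_px`, `tx`, `ty`, `nx`, `ny`), `arc_length_px`,
#'   `control_points`, `mean_intra_spacing_px`, `pixel_size_nm`.
#' @export
fit_spline <- function(set, step_px = 1, interior_hint = "down",
                       straight_threshold = 0.3) {
  stopifnot(inherits(set, "stereocilia_set"))
  cen <- set$centers[set$centers$included, ]
  if (nrow(cen) < 3) {
    stop("insufficient-points error: spline needs at least 3 included centres")
  }
  hint <- if (is.character(interior_hint)) {
    switch(match.arg(interior_hint, c("down", "up")),
           down = c(0, 1), up = c(0, -1))
  } else {
    stopifnot(length(interior_hint) == 2)
    interior_hint / sqrt(sum(interior_hint^2))
  }
  x <- cen$x_px; y <- cen$y_px
  tknot <- c(0, cumsum(sqrt(diff(x)^2 + diff(y)^2)))
  sx <- stats::splinefun(tknot, x, method = "natural")
  sy <- stats::splinefun(tknot, y, method = "natural")

  # dense evaluation, then inversion of arc length to a uniform grid
  tt <- seq(0, max(tknot), length.out = max(200L, ceiling(max(tknot) * 8)))
  dx <- sx(tt, deriv = 1); dy <- sy(tt, deriv = 1)
  sp <- sqrt(dx^2 + dy^2)
  s_dense <- c(0, cumsum((sp[-1] + sp[-length(sp)]) / 2 * diff(tt)))
  arc_len <- max(s_dense)
  s_grid <- seq(0, arc_len, by = step_px)
  t_of_s <- stats::approx(s_dense, tt, xout = s_grid, ties = "ordered")$y

  xg <- sx(t_of_s); yg <- sy(t_of_s)
  dxg <- sx(t_of_s, deriv = 1); dyg <- sy(t_of_s, deriv = 1)
  d2x <- sx(t_of_s, deriv = 2); d2y <- sy(t_of_s, deriv = 2)
  spd <- sqrt(dxg^2 + dyg^2)
  tx <- dxg / spd; ty <- dyg / spd
  kappa <- (dxg * d2y - dyg * d2x) / spd^3   # signed curvature, normal (-ty, tx)

  # interior side: toward the global bend of the control-point chain, or
  # the hint when the bundle is (near-)straight. The bend is estimated by a
  # quadratic fit in the principal-axis frame, which is robust to the local
  # wiggle of noisy centres; pointwise spline curvature is not.
  bend <- chain_bend(x, y)
  mean_n <- c(mean(-ty), mean(tx))
  flip <- if (bend$turning < straight_threshold) {
    if (sum(mean_n * hint) >= 0) 1 else -1
  } else {
    if (sum(mean_n * bend$toward) >= 0) 1 else -1
  }
  nx <- -ty * flip; ny <- tx * flip

  if (polyline_self_intersects(xg, yg)) {
    warning("geometry warning: bundle spline self-intersects; continuing")
  }
  structure(
    list(samples = tibble::tibble(s_px = s_grid, x_px = xg, y_px = yg,
                                  tx = tx, ty = ty, nx = nx, ny = ny),
         arc_length_px = arc_len,
         control_points = cen[, c("index", "x_px", "y_px")],
         mean_intra_spacing_px = set$mean_intra_spacing_px,
         pixel_size_nm = set$pixel_size_nm,
         curvature = kappa),
    class = "bundle_curve")
}

#' @export
print.bundle_curve <- function(x, ...) {
  cat(sprintf("<bundle_curve> %d control points, arc length %.1f px, %d samples\n",
              nrow(x$control_points), x$arc_length_px, nrow(x$samples)))
  invisible(x)
}

polyline_self_intersects <- function(x, y) {
  n <- length(x) - 1
  if (n < 3) return(FALSE)
  # coarse check on a subsampled polyline to keep this O(m^2) small
  keep <- unique(c(seq(1, n + 1, by = max(1L, n %/% 80)), n + 1))
  xs <- x[keep]; ys <- y[keep]
  m <- length(keep) - 1
  for (i in seq_len(m - 2)) {
    for (j in (i + 2):m) {
      if (seg_int_xy(xs, ys, i, j)) return(TRUE)
    }
  }
  FALSE
}

seg_int_xy <- function(x, y, i, j) {
  p <- c(x[i], y[i]); r <- c(x[i + 1] - x[i], y[i + 1] - y[i])
  q <- c(x[j], y[j]); s <- c(x[j + 1] - x[j], y[j + 1] - y[j])
  rxs <- r[1] * s[2] - r[2] * s[1]
  if (abs(rxs) < 1e-12) return(FALSE)
  qp <- q - p
  t <- (qp[1] * s[2] - qp[2] * s[1]) / rxs
  u <- (qp[1] * r[2] - qp[2] * r[1]) / rxs
  t > 0 && t < 1 && u > 0 && u < 1
}

#' Unfold (straighten) both channels along the bundle spline
#'
#' For each arc-length sample the image is interpolated (bilinearly by
#' default) along the normal line at transverse offsets from
#' `-half_width_nm` to `+half_width_nm` in pixel-size steps. Both channels
#' undergo the identical deformation. Offset 0 is the spline; positive
#' offsets point toward the bundle interior. Distances along the bundle are
#' distorted by the straightening (space expands or compresses); transverse
#' distances are preserved.
#'
#' @param img an [image2c()].
#' @param curve a [fit_spline()] result.
#' @param half_width_nm transverse half-width; default 2.5x the mean
#'   intra-row spacing, which covers 2- and 3-row bundles with margin.
#' @param interp `"bilinear"` or `"bicubic"` (bicubic falls back to
#'   bilinear with a note; bilinear avoids ringing on noisy counts).
#' @return object of class `unfolded_bundle`: channel matrices
#'   (rows = transverse offsets, columns = arc samples), `valid` mask,
#'   `transverse_offsets_nm`, `pixel_size_nm`.
#' @export
unfold <- function(img, curve, half_width_nm = NULL, interp = "bilinear") {
  stopifnot(inherits(img, "image2c"), inherits(curve, "bundle_curve"))
  interp <- match.arg(interp, c("bilinear", "bicubic"))
  if (interp == "bicubic") {
    message("bicubic interpolation not implemented; using bilinear")
  }
  px <- img$pixel_size_nm
  half_width_nm <- half_width_nm %||% (2.5 * curve$mean_intra_spacing_px * px)
  if (!(half_width_nm > 0)) stop("half_width_nm must be positive")
  k <- ceiling(half_width_nm / px)
  offsets_nm <- (-k:k) * px
  sm <- curve$samples
  n_s <- nrow(sm)
  xq <- outer(offsets_nm / px, sm$nx) + matrix(sm$x_px, 2 * k + 1, n_s, byrow = TRUE)
  yq <- outer(offsets_nm / px, sm$ny) + matrix(sm$y_px, 2 * k + 1, n_s, byrow = TRUE)
  actin <- matrix(bilinear_sample(img$actin, c(xq), c(yq)), 2 * k + 1, n_s)
  protein <- matrix(bilinear_sample(img$protein, c(xq), c(yq)), 2 * k + 1, n_s)
  valid <- !is.na(actin)
  if (!all(valid)) {
    warning("partial-coverage warning: ", sum(!valid),
            " unfolded samples fall outside the image and are flagged invalid")
  }
  structure(list(actin = actin, protein = protein, valid = valid,
                 transverse_offsets_nm = offsets_nm, pixel_size_nm = px,
                 name = img$name),
            class = "unfolded_bundle")
}

#' @export
print.unfolded_bundle <- function(x, ...) {
  cat(sprintf("<unfolded_bundle> %d transverse x %d arc samples @ %g nm (offsets %g..%g nm)\n",
              nrow(x$actin), ncol(x$actin), x$pixel_size_nm,
              min(x$transverse_offsets_nm), max(x$transverse_offsets_nm)))
  invisible(x)
}

#' Transverse intensity profile of an unfolded bundle
#'
#' Per transverse offset, the mean over valid along-bundle samples is
#' taken for each channel; each channel is then normalized to its own
#' maximum, so the profile maxima equal 1. Distance 0 is the spline through
#' the outer-row centres. Offsets with no valid sample are dropped and
#' flagged in the `gaps` attribute.
#'
#' @param u an [unfold()] result.
#' @return tibble of class `transverse_profile` with columns `distance_nm`,
#'   `actin`, `protein`, `n_valid`.
#' @export
transverse_profile <- function(u) {
  stopifnot(inherits(u, "unfolded_bundle"))
  n_valid <- rowSums(u$valid)
  if (all(n_valid == 0)) stop("no valid columns to average")
  rmean <- function(ch) {
    v <- rowSums(ifelse(u$valid, ch, 0)) / pmax(n_valid, 1)
    v[n_valid == 0] <- NA_real_
    v
  }
  a <- rmean(u$actin); p <- rmean(u$protein)
  keep <- n_valid > 0
  norm <- function(v) if (max(v, na.rm = TRUE) > 0) v / max(v, na.rm = TRUE) else v
  out <- tibble::tibble(distance_nm = u$transverse_offsets_nm[keep],
                        actin = norm(a[keep]), protein = norm(p[keep]),
                        n_valid = n_valid[keep])
  attr(out, "gaps") <- u$transverse_offsets_nm[!keep]
  attr(out, "pixel_size_nm") <- u$pixel_size_nm
  class(out) <- c("transverse_profile", class(out))
  out
}
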