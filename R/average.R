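#' Local orientation frames from circumcircles
#'
#' For each included stereocilium, the circle through it and its two
#' closest included neighbours defines the locally orthogonal direction:
#' the outward normal points from the circumcentre through the stereocilium
#' and is flipped, if needed, to point away from the bundle interior (the
#' side opposite the curve's interior normal). Collinear triples
#' (circumradius beyond 1e4 x the mean spacing) fall back to the
#' perpendicular of the neighbour chord and are flagged `degenerate`.
#'
#' @param set an ordered `stereocilia_set`.
#' @param curve the fitted [fit_spline()] curve (supplies the interior
#'   side).
#' @param neighbor_mode `"nearest"` (default) or `"adjacent"`: whether the
#'   two closest centres or the two order-adjacent centres define the
#'   circle (they coincide for interior cilia of a well-ordered row).
#' @return tibble of class `cilium_frames`: `index`, `x_px`, `y_px`,
#'   `nb1`, `nb2`, `normal_angle_deg` (direction of the outward normal in
#'   image coordinates), `degenerate`.
#' @export
local_frames <- function(set, curve, neighbor_mode = c("nearest", "adjacent")) {
  stopifnot(inherits(set, "stereocilia_set"), inherits(curve, "bundle_curve"))
  neighbor_mode <- match.arg(neighbor_mode)
  cen <- set$centers[set$centers$included, ]
  n <- nrow(cen)
  if (n < 3) {
    stop("insufficient-points error: local frames need at least 3 included centres")
  }
  pts <- as.matrix(cen[, c("x_px", "y_px")])
  dm <- as.matrix(stats::dist(pts))
  sm <- curve$samples
  out <- purrr::map_dfr(seq_len(n), function(i) {
    nb <- if (neighbor_mode == "nearest") {
      order(dm[i, ])[2:3]
    } else {
      nb <- c(i - 1, i + 1)
      nb[nb < 1] <- i + 2; nb[nb > n] <- i - 2
      nb
    }
    p <- pts[i, ]; a <- pts[nb[1], ]; b <- pts[nb[2], ]
    cc <- circumcenter(p, a, b)
    spacing <- set$mean_intra_spacing_px
    # interior direction at the nearest curve sample
    j <- which.min((sm$x_px - p[1])^2 + (sm$y_px - p[2])^2)
    interior <- c(sm$nx[j], sm$ny[j])
    if (is.null(cc) || sqrt(sum((cc - p)^2)) > 1e4 * spacing) {
      chord <- b - a
      nrm <- c(-chord[2], chord[1])
      nrm <- nrm / sqrt(sum(nrm^2))
      if (sum(nrm * interior) > 0) nrm <- -nrm   # outward = away from interior
      deg <- TRUE
    } else {
      nrm <- (p - cc) / sqrt(sum((p - cc)^2))
      if (sum(nrm * interior) > 0) nrm <- -nrm
      deg <- FALSE
    }
    tibble::tibble(index = cen$index[i],
                   x_px = unname(p[1]), y_px = unname(p[2]),
                   nb1 = cen$index[nb[1]], nb2 = cen$index[nb[2]],
                   normal_angle_deg = unname(atan2(nrm[2], nrm[1]) * 180 / pi),
                   degenerate = deg)
  })
  class(out) <- c("cilium_frames", class(out))
  attr(out, "pixel_size_nm") <- set$pixel_size_nm
  attr(out, "mean_intra_spacing_px") <- set$mean_intra_spacing_px
  out
}

# Circumcentre of three points, or NULL if collinear to machine precision.
circumcenter <- function(p, a, b) {
  d <- 2 * (p[1] * (a[2] - b[2]) + a[1] * (b[2] - p[2]) + b[1] * (p[2] - a[2]))
  if (abs(d) < 1e-9) return(NULL)
  p2 <- sum(p^2); a2 <- sum(a^2); b2 <- sum(b^2)
  ux <- (p2 * (a[2] - b[2]) + a2 * (b[2] - p[2]) + b2 * (p[2] - a[2])) / d
  uy <- (p2 * (b[1] - a[1]) + a2 * (p[1] - b[1]) + b2 * (a[1] - p[1])) / d
  c(ux, uy)
}

#' Extract rotation-normalized single-stereocilium ROIs
#'
#' Each region of interest is the image resampled (bilinearly, about the
#' exact sub-pixel centre) on a square grid centred on the stereocilium and
#' rotated so the outward normal points up; interior rows therefore appear
#' below the centre. Both channels use the identical geometry. Samples
#' falling outside the image are flagged invalid.
#'
#' @param img an [image2c()].
#' @param frames a [local_frames()] result.
#' @param roi_size_px odd ROI side length; default rounds
#'   `roi_scale * mean inter-cilium distance` to odd.
#' @param roi_scale ROI size as a multiple of the inter-cilium distance
#'   (default 2: the average cilium sits centred with parts of its
#'   neighbours on both sides).
#' @return object of class `aligned_stack`: 3-D arrays `actin`, `protein`,
#'   `valid` of dimension `roi x roi x n`, plus `roi_size_px` and
#'   `pixel_size_nm`.
#' @export
extract_aligned <- function(img, frames, roi_size_px = NULL, roi_scale = 2) {
  stopifnot(inherits(img, "image2c"), inherits(frames, "cilium_frames"))
  if (is.null(roi_size_px)) {
    roi_size_px <- round_to_odd(roi_scale * attr(frames, "mean_intra_spacing_px"))
  }
  if (roi_size_px %% 2 == 0 || roi_size_px < 5) {
    stop("parameter error: roi_size_px must be odd and >= 5 (got ",
         roi_size_px, ")")
  }
  h <- (roi_size_px - 1) / 2
  grid <- expand.grid(u = -h:h, v = -h:h)   # u right, v down in the ROI
  n <- nrow(frames)
  acts <- array(NA_real_, c(roi_size_px, roi_size_px, n))
  prots <- array(NA_real_, c(roi_size_px, roi_size_px, n))
  valid <- array(FALSE, c(roi_size_px, roi_size_px, n))
  for (i in seq_len(n)) {
    theta <- (frames$normal_angle_deg[i] + 90) * pi / 180
    ct <- cos(theta); st <- sin(theta)
    xq <- frames$x_px[i] + ct * grid$u - st * grid$v
    yq <- frames$y_px[i] + st * grid$u + ct * grid$v
    a <- bilinear_sample(img$actin, xq, yq)
    p <- bilinear_sample(img$protein, xq, yq)
    # grid is (u fast, v slow) -> matrix[v + h + 1, u + h + 1] via byrow fill
    acts[, , i] <- matrix(a, roi_size_px, roi_size_px, byrow = TRUE)
    prots[, , i] <- matrix(p, roi_size_px, roi_size_px, byrow = TRUE)
    valid[, , i] <- !is.na(acts[, , i])
    if (!any(valid[, , i])) {
      warning("stereocilium ", frames$index[i],
              " lies fully outside the image; its ROI is all-invalid")
    }
  }
  structure(list(actin = acts, protein = prots, valid = valid,
                 roi_size_px = roi_size_px,
                 pixel_size_nm = attr(frames, "pixel_size_nm"),
                 index = frames$index),
            class = "aligned_stack")
}

#' @export
print.aligned_stack <- function(x, ...) {
  cat(sprintf("<aligned_stack> %d ROIs of %d x %d px\n",
              dim(x$actin)[3], x$roi_size_px, x$roi_size_px))
  invisible(x)
}

#' Average an aligned stack per channel
#'
#' Per-pixel mean over valid samples; validity counts are recorded so later
#' stages can weight or mask. Warns if any pixel of the central half of the
#' ROI has no valid sample.
#'
#' @param stack an [extract_aligned()] result.
#' @return list of class `stack_average`: `actin`, `protein` (mean
#'   rasters), `counts`, `roi_size_px`, `pixel_size_nm`, `n`.
#' @export
average_stack <- function(stack) {
  stopifnot(inherits(stack, "aligned_stack"))
  n <- dim(stack$actin)[3]
  if (n == 0) stop("empty-stack error: no ROIs to average")
  counts <- apply(stack$valid, c(1, 2), sum)
  msum <- function(ch) {
    s <- apply(ifelse(stack$valid, ch, 0), c(1, 2), sum)
    out <- s / pmax(counts, 1)
    out[counts == 0] <- NA_real_
    out
  }
  k <- stack$roi_size_px
  q <- (k + 1) / 2; hw <- floor(k / 4)
  central <- counts[(q - hw):(q + hw), (q - hw):(q + hw)]
  if (any(central == 0)) {
    warning("central half of the averaged ROI has pixels with no valid sample")
  }
  structure(list(actin = msum(stack$actin), protein = msum(stack$protein),
                 counts = counts, roi_size_px = k,
                 pixel_size_nm = stack$pixel_size_nm, n = n),
            class = "stack_average")
}

#' Background subtraction of the averaged stereocilium
#'
#' Three modes, matching the interactive workflow's options:
#' `auto_region` measures the mean of an automatically chosen sub-region
#' where only background is expected — the upper quarter of the projection
#' (outside the hair bundle, since interior rows point down), eroded 2 px
#' from the borders; `user_roi` measures a caller-supplied region;
#' `recalled_value` subtracts per-channel scalars recorded by a previous
#' analysis (useful to normalize control conditions). Subtracted values are
#' stored and exportable via [export_background()] for mode-3 recall.
#'
#' @param avg an [average_stack()] result.
#' @param mode one of `"auto_region"`, `"user_roi"`, `"recalled_value"`.
#' @param region logical matrix (ROI-sized) for `user_roi`.
#' @param value numeric `c(actin, protein)` background for
#'   `recalled_value`; must be non-negative.
#' @return object of class `average_stereocilium`: subtracted `actin` and
#'   `protein` rasters (clipped at 0), `background_mode`,
#'   `background_values`, the background `region` used (if any), `counts`,
#'   `roi_size_px`, `pixel_size_nm`, `n`.
#' @export
subtract_background <- function(avg, mode = c("auto_region", "user_roi",
                                              "recalled_value"),
                                region = NULL, value = NULL) {
  stopifnot(inherits(avg, "stack_average"))
  mode <- match.arg(mode)
  k <- avg$roi_size_px
  if (mode == "auto_region") {
    region <- matrix(FALSE, k, k)
    region[3:max(3, floor(k / 4)), 3:(k - 2)] <- TRUE
  } else if (mode == "user_roi") {
    if (is.null(region)) stop("user_roi mode needs a region matrix")
    stopifnot(all(dim(region) == c(k, k)))
    region <- region > 0
    q <- (k + 1) / 2
    rr <- which(region, arr.ind = TRUE)
    if (any(((rr[, 1] - q)^2 + (rr[, 2] - q)^2) <= (k / 4)^2)) {
      warning("background region overlaps the central stereocilium disc")
    }
  } else {
    if (is.null(value) || length(value) != 2) {
      stop("recalled_value mode needs value = c(actin, protein)")
    }
    if (any(value < 0)) stop("parameter error: recalled background must be >= 0")
  }
  bg <- if (mode == "recalled_value") {
    c(actin = unname(value[1]), protein = unname(value[2]))
  } else {
    c(actin = mean(avg$actin[region], na.rm = TRUE),
      protein = mean(avg$protein[region], na.rm = TRUE))
  }
  structure(list(actin = pmax(avg$actin - bg["actin"], 0),
                 protein = pmax(avg$protein - bg["protein"], 0),
                 background_mode = mode, background_values = bg,
                 region = if (mode != "recalled_value") region else NULL,
                 counts = avg$counts, roi_size_px = k,
                 pixel_size_nm = avg$pixel_size_nm, n = avg$n),
            class = "average_stereocilium")
}

#' @export
print.average_stereocilium <- function(x, ...) {
  cat(sprintf("<average_stereocilium> %d x %d px, n = %d, background %s (actin %.2f, protein %.2f)\n",
              x$roi_size_px, x$roi_size_px, x$n, x$background_mode,
              x$background_values[1], x$background_values[2]))
  invisible(x)
}

#' Export / reuse recorded background values
#'
#' Writes the per-channel background subtracted from an averaged
#' stereocilium to a JSON sidecar so a later run can recall it (mode 3 of
#' [subtract_background()]); the round trip is bit-exact.
#'
#' @param avg an [subtract_background()] result.
#' @param path JSON file path.
#' @return for `export_background`, `path` invisibly; for
#'   `read_background`, the numeric `c(actin, protein)` vector.
#' @export
export_background <- function(avg, path) {
  stopifnot(inherits(avg, "average_stereocilium"))
  jsonlite::write_json(
    list(mode = avg$background_mode,
         actin = avg$background_values[["actin"]],
         protein = avg$background_values[["protein"]]),
    path, auto_unbox = TRUE, digits = I(17))   # 17 sig. digits: bit-exact
  invisible(path)
}

#' @rdname export_background
#' @export
read_background <- function(path) {
  b <- jsonlite::read_json(path, simplifyVector = TRUE)
  c(actin = as.numeric(b$actin), protein = as.numeric(b$protein))
}

#' Axial intensity profiles of the averaged stereocilium
#'
#' The horizontal profile (central row of the averaged image) reads the
#' intra-row direction; the vertical profile (central column) reads the
#' inter-row direction, with the bundle interior at positive distances.
#' Optionally each is averaged over a 3-pixel-wide band.
#'
#' @param avg an [subtract_background()] (or [average_stack()]) result.
#' @param band_px 1 (single line) or 3 (3-pixel band mean).
#' @return tibble with columns `axis` (`"horizontal"`/`"vertical"`),
#'   `distance_nm` (0 at the central stereocilium), `actin`, `protein`.
#' @export
axial_profiles <- function(avg, band_px = 1) {
  stopifnot(band_px %in% c(1, 3))
  k <- avg$roi_size_px
  q <- (k + 1) / 2
  rows <- (q - (band_px - 1) / 2):(q + (band_px - 1) / 2)
  d <- ((1:k) - q) * avg$pixel_size_nm
  horiz <- function(ch) colMeans(ch[rows, , drop = FALSE], na.rm = TRUE)
  vert <- function(ch) rowMeans(ch[, rows, drop = FALSE], na.rm = TRUE)
  dplyr::bind_rows(
    tibble::tibble(axis = "horizontal", distance_nm = d,
                   actin = horiz(avg$actin), protein = horiz(avg$protein)),
    tibble::tibble(axis = "vertical", distance_nm = d,
                   actin = vert(avg$actin), protein = vert(avg$protein)))
}
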