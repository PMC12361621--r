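#' Call maxima (and shoulders) on a 1-D intensity profile
#'
#' Local maxima are ranked by topographic prominence (height above the
#' highest saddle to any higher maximum, on the max-normalized profile),
#' thresholded, separated by at least `min_separation_nm` (the less
#' prominent of two close maxima is dropped), and refined by parabolic
#' interpolation of the three samples around each maximum. Maxima at the
#' profile endpoints are excluded. Shoulders — bumps that do not form a
#' local maximum — are detected as local minima of the Savitzky-Golay
#' smoothed second derivative (negative-curvature maxima) away from any
#' called peak, and are reported separately, never counted as peaks.
#'
#' @param distance_nm numeric distance axis (strictly increasing, uniform),
#'   or a [transverse_profile()] tibble (then `intensity` names the channel
#'   column).
#' @param intensity numeric profile values, or (for a profile tibble) the
#'   channel name `"actin"`/`"protein"`.
#' @param min_prominence prominence threshold on the max-normalized
#'   profile; default 0.1.
#' @param min_separation_nm minimum peak separation; a sensible default is
#'   the PSF FWHM (50 nm).
#' @param detect_shoulders logical.
#' @param shoulder_sensitivity fraction of the strongest negative curvature
#'   a shoulder must reach.
#' @return tibble of class `peak_set` with columns `kind`
#'   (`"peak"`/`"shoulder"`), `position_nm`, `prominence` (normalized; for
#'   shoulders the relative curvature strength), `value` (normalized
#'   height); attribute `channel` when called on a profile tibble.
#' @examples
#' d <- seq(0, 1000, by = 10)
#' y <- exp(-(d - 300)^2 / 5000) + 0.6 * exp(-(d - 700)^2 / 5000)
#' call_peaks(d, y)
#' @export
call_peaks <- function(distance_nm, intensity = NULL, min_prominence = 0.1,
                       min_separation_nm = 50, detect_shoulders = TRUE,
                       shoulder_sensitivity = 0.5) {
  channel <- NA_character_
  if (is.data.frame(distance_nm)) {
    prof <- distance_nm
    channel <- if (is.character(intensity)) intensity else "protein"
    intensity <- prof[[channel]]
    distance_nm <- prof$distance_nm
  }
  stopifnot(length(distance_nm) == length(intensity))
  ok <- is.finite(intensity)
  d <- distance_nm[ok]; y <- intensity[ok]
  empty <- tibble::tibble(kind = character(), position_nm = numeric(),
                          prominence = numeric(), value = numeric())
  if (length(y) < 3 || max(y) <= 0 || diff(range(y)) == 0) {
    return(structure(empty, class = c("peak_set", class(empty)),
                     channel = channel))
  }
  y <- y / max(y)
  step <- stats::median(diff(d))
  pp <- peak_prominences(y)
  pp <- pp[pp$index > 1 & pp$index < length(y), , drop = FALSE]  # no endpoints
  pp <- pp[pp$prominence >= min_prominence, , drop = FALSE]

  # enforce separation: keep the more prominent of any close pair
  if (nrow(pp) > 1) {
    ordp <- order(-pp$prominence, pp$index)
    keep <- logical(nrow(pp))
    kept_pos <- numeric(0)
    for (i in ordp) {
      p <- d[pp$index[i]]
      if (!length(kept_pos) || all(abs(kept_pos - p) >= min_separation_nm)) {
        keep[i] <- TRUE
        kept_pos <- c(kept_pos, p)
      }
    }
    pp <- pp[keep, , drop = FALSE]
  }
  peaks <- if (nrow(pp)) {
    # sharp maxima: parabolic vertex of the 3 surrounding samples.
    # broad (dome/plateau) maxima, e.g. the projection of a filled disc:
    # the 3-point fit is noise-dominated on the flat top, so the position
    # is the intensity-weighted centroid of the contiguous near-top run.
    pos <- vapply(pp$index, function(i) {
      thr <- 0.97 * y[i]
      lo <- i; while (lo > 1 && y[lo - 1] >= thr &&
                        abs(d[lo - 1] - d[i]) <= min_separation_nm) lo <- lo - 1
      hi <- i; while (hi < length(y) && y[hi + 1] >= thr &&
                        abs(d[hi + 1] - d[i]) <= min_separation_nm) hi <- hi + 1
      if (hi - lo + 1 > 3) {
        w <- y[lo:hi] - thr
        sum(d[lo:hi] * w) / sum(w)
      } else {
        d[i] + step * parabolic_offset(y[i - 1], y[i], y[i + 1])
      }
    }, numeric(1))
    tibble::tibble(kind = "peak", position_nm = pos,
                   prominence = pp$prominence, value = y[pp$index])
  } else empty

  shoulders <- empty
  if (detect_shoulders && length(y) >= 11) {
    w <- round_to_odd(max(9, 2 * min_separation_nm / step))
    w <- min(w, round_to_odd(length(y) / 3))
    if (w >= 5) {
      d2 <- signal::sgolayfilt(y, p = 3, n = w, m = 2, ts = step)
      negc <- -d2
      cand <- which(diff(sign(diff(negc))) == -2) + 1   # local maxima of -d2
      cand <- cand[negc[cand] > 0]
      cand <- cand[y[cand] >= min_prominence & y[cand] <= 0.95]
      if (nrow(peaks)) {
        cand <- cand[vapply(cand, function(i) {
          all(abs(peaks$position_nm - d[i]) >= min_separation_nm)
        }, logical(1))]
      }
      # keep only features within reach of the strongest curvature away
      # from the called peaks (sharp peak flanks would otherwise dominate)
      if (length(cand)) {
        ref <- max(negc[cand])
        cand <- cand[negc[cand] >= shoulder_sensitivity * ref]
        shoulders <- tibble::tibble(
          kind = "shoulder", position_nm = d[cand],
          prominence = negc[cand] / ref, value = y[cand])
      }
    }
  }
  out <- dplyr::arrange(dplyr::bind_rows(peaks, shoulders), .data$position_nm)
  structure(out, class = c("peak_set", class(empty)), channel = channel)
}

#' Row positions and inter-row spacing from actin maxima
#'
#' The transverse positions of the actin maxima are the stereocilia row
#' positions; consecutive differences are the inter-row spacings. The first
#' row is expected at the profile origin (the spline through the outer-row
#' centres); a warning is raised if it is more than one pixel away.
#'
#' @param actin_peaks a [call_peaks()] result for the actin channel.
#' @param pixel_size_nm pixel size, for the origin check.
#' @return tibble of class `row_spacing` with columns `row`, `position_nm`,
#'   `spacing_to_next_nm` (NA for the last row).
#' @export
row_positions <- function(actin_peaks, pixel_size_nm = NULL) {
  pk <- actin_peaks[actin_peaks$kind == "peak", ]
  if (nrow(pk) < 2) {
    stop("spacing-undefined error: fewer than 2 actin maxima")
  }
  pos <- sort(pk$position_nm)
  if (!is.null(pixel_size_nm) && abs(pos[1]) > pixel_size_nm) {
    warning("first actin row is ", round(abs(pos[1]), 1),
            " nm from the profile origin (more than one pixel)")
  }
  out <- tibble::tibble(row = seq_along(pos), position_nm = pos,
                        spacing_to_next_nm = c(diff(pos), NA_real_))
  class(out) <- c("row_spacing", class(out))
  out
}

#' Protein peak positions as fractions of the inter-row space
#'
#' For a protein peak at position p between adjacent rows at r_i < r_(i+1),
#' the fraction is (p - r_i) / (r_(i+1) - r_i), measured from the outer
#' member of the bounding pair toward the interior. Peaks within
#' `snap_nm` of a row position are classified intra-row with fraction 0 at
#' that row; peaks beyond the outermost rows by at most half a spacing are
#' snapped to the nearest row likewise; anything farther is flagged
#' out-of-range. Fractions are kept at full precision and rounded only in
#' the `percent` column (one decimal).
#'
#' @param protein_peaks a [call_peaks()] result (shoulders are carried
#'   through with their own fractions but flagged by `kind`).
#' @param rows a [row_positions()] result.
#' @param snap_nm half-width of the intra-row snap window.
#' @return tibble: `kind`, `position_nm`, `prominence`, `row_lo`, `row_hi`,
#'   `fraction`, `percent`, `out_of_range`.
#' @examples
#' rows <- row_positions(call_peaks(seq(-100, 700, 10),
#'   exp(-(seq(-100, 700, 10))^2 / 2000) +
#'   exp(-(seq(-100, 700, 10) - 500)^2 / 2000)))
#' @export
fraction_of_interrow <- function(protein_peaks, rows, snap_nm = 50) {
  stopifnot(inherits(rows, "row_spacing"))
  rp <- rows$position_nm
  half <- mean(diff(rp)) / 2
  purrr::map_dfr(seq_len(nrow(protein_peaks)), function(i) {
    p <- protein_peaks$position_nm[i]
    near <- which.min(abs(rp - p))
    res <- tibble::tibble(kind = protein_peaks$kind[i], position_nm = p,
                          prominence = protein_peaks$prominence[i],
                          row_lo = NA_integer_, row_hi = NA_integer_,
                          fraction = NA_real_, percent = NA_real_,
                          out_of_range = FALSE)
    if (abs(rp[near] - p) <= snap_nm) {          # intra-row
      res$row_lo <- res$row_hi <- near
      res$fraction <- 0
      res$percent <- 0
    } else if (p >= rp[1] && p <= rp[length(rp)]) {
      lo <- max(which(rp <= p))
      f <- (p - rp[lo]) / (rp[lo + 1] - rp[lo])
      res$row_lo <- lo; res$row_hi <- lo + 1L
      res$fraction <- f
      res$percent <- round(100 * f, 1)
    } else if (abs(rp[near] - p) <= half) {      # just outside the outermost row
      res$row_lo <- res$row_hi <- near
      res$fraction <- 0
      res$percent <- 0
    } else {
      res$out_of_range <- TRUE
    }
    res
  })
}
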