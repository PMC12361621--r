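#' Rendering settings for the synthetic generator
#'
#' @param pixel_size_nm physical sampling, nm per pixel (5-50; the
#'   instrument regime is 10-25 nm).
#' @param psf_fwhm_nm full width at half maximum of the Gaussian point
#'   spread function (30-100; the instrument regime is 40-60 nm).
#' @param photons_per_peak expected photon count at the brightest actin
#'   pixel; sets the Poisson scale.
#' @param read_noise_sd standard deviation of the additive Gaussian
#'   (read-out) noise, in counts.
#' @param seed integer RNG seed; identical settings give bit-identical
#'   images.
#' @param noise if `FALSE`, the noise-free (pre-Poisson) rasters are
#'   returned unquantized.
#' @return object of class `render_settings`.
#' @export
render_settings <- function(pixel_size_nm = 15, psf_fwhm_nm = 50,
                            photons_per_peak = 200, read_noise_sd = 2,
                            seed = 1L, noise = TRUE) {
  if (!(pixel_size_nm >= 5 && pixel_size_nm <= 50)) {
    stop("invalid settings: pixel_size_nm must be in [5, 50]")
  }
  if (!(psf_fwhm_nm >= 30 && psf_fwhm_nm <= 100)) {
    stop("invalid settings: psf_fwhm_nm must be in [30, 100]")
  }
  if (!(photons_per_peak > 0)) {
    stop("invalid settings: photons_per_peak must be positive")
  }
  if (read_noise_sd < 0) stop("invalid settings: read_noise_sd must be >= 0")
  structure(list(pixel_size_nm = pixel_size_nm, psf_fwhm_nm = psf_fwhm_nm,
                 photons_per_peak = photons_per_peak,
                 read_noise_sd = read_noise_sd, seed = as.integer(seed),
                 noise = isTRUE(noise)),
            class = "render_settings")
}

FWHM_TO_SD <- 1 / (2 * sqrt(2 * log(2)))

# Dense centreline paths (step ~ pixel/3) for each channel-2 structure.
# Each element: list(x, y, amp, width_nm, length_nm, point = FALSE).
preset_paths <- function(geom, preset, cen, ds) {
  paths <- list()
  s <- geom$row_spacing_nm
  arc <- is.finite(geom$arc_radius_nm)

  ring_r <- geom$cilium_radius_nm + preset$ring_radius_offset_nm
  for (k in preset$ring_rows) {
    rows <- cen[cen$row == k, ]
    for (i in seq_len(nrow(rows))) {
      a0 <- atan2(-rows$oy[i], -rows$ox[i])   # bundle-interior direction
      half <- preset$ring_span_deg / 2 * pi / 180
      th <- seq(a0 - half, a0 + half, by = ds / ring_r)
      paths[[length(paths) + 1]] <- list(
        x = rows$x_nm[i] + ring_r * cos(th),
        y = rows$y_nm[i] + ring_r * sin(th),
        amp = preset$ring_amplitude, width_nm = 40,
        length_nm = ring_r * 2 * half, point = FALSE)
    }
  }

  for (k in preset$intrarow_bridges) {
    rows <- cen[cen$row == k, ]
    for (i in seq_len(nrow(rows) - 1)) {
      p0 <- c(rows$x_nm[i], rows$y_nm[i])
      p1 <- c(rows$x_nm[i + 1], rows$y_nm[i + 1])
      d <- p1 - p0
      len <- sqrt(sum(d^2))
      u <- d / len
      trim <- geom$cilium_radius_nm
      if (len <= 2 * trim + ds) next
      tt <- seq(trim, len - trim, by = ds)
      paths[[length(paths) + 1]] <- list(
        x = p0[1] + tt * u[1], y = p0[2] + tt * u[2],
        amp = preset$bridge_amplitude, width_nm = 40,
        length_nm = len - 2 * trim, point = FALSE)
    }
  }

  if (nrow(preset$interrow_bands)) {
    n <- geom$n_cilia_per_row
    a <- geom$intra_spacing_nm
    for (b in seq_len(nrow(preset$interrow_bands))) {
      bd <- preset$interrow_bands[b, ]
      if (bd$row_to > geom$n_rows) {
        stop("preset band joins row ", bd$row_to,
             " but the geometry has only ", geom$n_rows, " rows")
      }
      if (arc) {
        rk <- geom$arc_radius_nm - (bd$row_from - 1) * s - bd$offset_fraction * s
        half <- ((n - 1) / 2 + 0.5) * a / geom$arc_radius_nm
        th <- seq(-pi / 2 - half, -pi / 2 + half, by = ds / rk)
        paths[[length(paths) + 1]] <- list(
          x = rk * cos(th), y = rk * sin(th),
          amp = bd$amplitude, width_nm = bd$width_nm,
          length_nm = rk * 2 * half, point = FALSE)
      } else {
        yb <- (bd$row_from - 1) * s + bd$offset_fraction * s
        r1 <- cen[cen$row == 1, ]
        xx <- seq(min(r1$x_nm) - a / 2, max(r1$x_nm) + a / 2, by = ds)
        paths[[length(paths) + 1]] <- list(
          x = xx, y = rep(yb, length(xx)),
          amp = bd$amplitude, width_nm = bd$width_nm,
          length_nm = diff(range(xx)), point = FALSE)
      }
    }
  }

  if (!is.null(preset$local_marker)) {
    mk <- preset$local_marker
    r1 <- cen[cen$row == 1, ]
    for (i in seq_len(nrow(r1))) {
      paths[[length(paths) + 1]] <- list(
        x = r1$x_nm[i] + mk$u_nm * r1$tx[i] + mk$w_nm * r1$ox[i],
        y = r1$y_nm[i] + mk$u_nm * r1$ty[i] + mk$w_nm * r1$oy[i],
        amp = mk$amplitude, width_nm = 0, length_nm = 0, point = TRUE)
    }
  }
  paths
}

#' Render a synthetic two-channel STED-like hair-bundle image
#'
#' Channel 1 carries the actin signal (filled discs for every
#' stereocilium); channel 2 carries the preset's protein pattern. Both are
#' convolved with the Gaussian PSF, scaled so the brightest actin pixel has
#' an expected `photons_per_peak` counts (channel 2 additionally scaled by
#' the preset's `amplitude_ratio`), Poisson-sampled, degraded with Gaussian
#' read noise and quantized to integer counts. Line-like label structures
#' are drawn with their stated Gaussian cross-section so a structure's
#' `amplitude` is directly its expected profile peak density relative to
#' other structures. With finite preset `granularity`, structures are
#' drawn as Poisson point processes of puncta instead of continuous lines.
#'
#' The raster is auto-sized around the bundle with `pad_nm` of margin, and a
#' row-1 mask (the analyst's "brush" over the outer row) is emitted
#' alongside the exact ground truth.
#'
#' @param geom a [make_geometry()] object.
#' @param preset a [labeling_preset()], or a preset name looked up in
#'   [preset_library()].
#' @param settings a [render_settings()] object.
#' @param pad_nm margin around the bundle; must be at least one PSF FWHM
#'   plus the cilium radius.
#' @param dim_px optional fixed raster size `c(ny, nx)`; an error if the
#'   geometry plus margin does not fit.
#' @param mask_radius_nm brush radius of the emitted row-1 mask.
#' @return an object of class `synthetic_bundle`: a list with elements
#'   `image` ([image2c()]), `truth` (ground-truth object), `mask` (logical
#'   matrix), plus the generating `geometry`, `preset` and `settings`.
#' @examples
#' sim <- render(make_geometry("IHC", n_cilia_per_row = 4),
#'               preset_library("IHC_PDZD7"),
#'               render_settings(seed = 7))
#' dim(sim$image$actin)
#' @export
render <- function(geom, preset, settings = render_settings(),
                   pad_nm = 1200, dim_px = NULL, mask_radius_nm = NULL) {
  stopifnot(inherits(geom, "bundle_geometry"))
  if (is.character(preset)) preset <- preset_library(preset)
  stopifnot(inherits(preset, "labeling_preset"),
            inherits(settings, "render_settings"))
  if (pad_nm < settings$psf_fwhm_nm + geom$cilium_radius_nm) {
    stop("geometry error: pad_nm leaves less than one PSF FWHM of margin ",
         "around the stereocilia")
  }
  px <- settings$pixel_size_nm
  withr::with_seed(settings$seed, {
    cen0 <- geometry_centers(geom)
    shift <- c(pad_nm - min(cen0$x_nm), pad_nm - min(cen0$y_nm))
    cen <- cen0
    cen$x_nm <- cen0$x_nm + shift[1]
    cen$y_nm <- cen0$y_nm + shift[2]
    nx <- ceiling((max(cen$x_nm) + pad_nm) / px) + 1
    ny <- ceiling((max(cen$y_nm) + pad_nm) / px) + 1
    if (!is.null(dim_px)) {
      if (dim_px[1] < ny || dim_px[2] < nx) {
        stop("geometry error: raster ", dim_px[1], "x", dim_px[2],
             " px is too small for the bundle plus margin (needs ",
             ny, "x", nx, ")")
      }
      ny <- dim_px[1]; nx <- dim_px[2]
    }

    # channel 1: filled actin discs
    ch1 <- matrix(0, ny, nx)
    rad_px <- geom$cilium_radius_nm / px
    for (i in seq_len(nrow(cen))) {
      cx <- cen$x_nm[i] / px; cy <- cen$y_nm[i] / px
      xs <- max(0, floor(cx - rad_px - 1)):min(nx - 1, ceiling(cx + rad_px + 1))
      ys <- max(0, floor(cy - rad_px - 1)):min(ny - 1, ceiling(cy + rad_px + 1))
      dd <- outer((ys - cy)^2, (xs - cx)^2, "+")
      ch1[ys + 1, xs + 1] <- ch1[ys + 1, xs + 1] + (dd <= rad_px^2)
    }
    sigma_psf_px <- settings$psf_fwhm_nm * FWHM_TO_SD / px
    ch1 <- gaussian_blur(ch1, sigma_psf_px)

    # channel 2: line-like structures, grouped by total blur width
    # (paths are built in the layout frame of geometry_centers(), where
    # arc rows are concentric about the origin, then shifted onto the raster)
    ds <- px / 3
    paths <- preset_paths(geom, preset, cen0, ds)
    paths <- lapply(paths, function(p) {
      p$x <- p$x + shift[1]
      p$y <- p$y + shift[2]
      p
    })
    ch2 <- matrix(0, ny, nx)
    if (length(paths)) {
      sig_tot <- vapply(paths, function(p) {
        sqrt((settings$psf_fwhm_nm * FWHM_TO_SD)^2 +
               (p$width_nm * FWHM_TO_SD)^2)
      }, numeric(1))
      groups <- split(seq_along(paths), round(sig_tot, 6))
      for (g in groups) {
        acc <- matrix(0, ny, nx)
        for (j in g) {
          p <- paths[[j]]
          if (p$point) {
            w <- p$amp * 2 * pi * (sig_tot[j] / px)^2
            xs <- p$x / px; ysp <- p$y / px
          } else {
            lambda <- p$amp * sqrt(2 * pi) * sig_tot[j]
            m <- length(p$x)
            if (is.finite(preset$granularity)) {
              npunct <- stats::rpois(1, preset$granularity * p$length_nm / 1000)
              if (npunct == 0) next
              idx <- sort(sample.int(m, npunct, replace = TRUE))
              xs <- p$x[idx] / px; ysp <- p$y[idx] / px
              w <- rep(lambda * p$length_nm / npunct / px^2, npunct)
            } else {
              xs <- p$x / px; ysp <- p$y / px
              w <- rep(lambda * ds / px^2, m)
            }
          }
          acc <- acc + splat_points(ny, nx, xs, ysp, w)
        }
        ch2 <- ch2 + gaussian_blur(acc, sig_tot[g[1]] / px)
      }
    }

    # photon scaling: brightest actin pixel = photons_per_peak counts
    if (max(ch1) > 0) ch1 <- ch1 / max(ch1) * settings$photons_per_peak
    if (max(ch2) > 0) {
      ch2 <- ch2 / max(ch2) * settings$photons_per_peak * preset$amplitude_ratio
    }
    if (settings$noise) {
      nzr <- function(ch) {
        v <- stats::rpois(length(ch), ch) +
          stats::rnorm(length(ch), 0, settings$read_noise_sd)
        matrix(pmax(0, round(v)), nrow(ch), ncol(ch))
      }
      ch1 <- nzr(ch1)
      ch2 <- nzr(ch2)
    }

    img <- image2c(ch1, ch2, pixel_size_nm = px,
                   name = paste0("synthetic_", geom$cell_type, "_", preset$name,
                                 "_seed", settings$seed))

    mask_radius_nm <- mask_radius_nm %||% (0.6 * geom$intra_spacing_nm)
    mask <- matrix(FALSE, ny, nx)
    r1 <- cen[cen$row == 1, ]
    mrad <- mask_radius_nm / px
    for (i in seq_len(nrow(r1))) {
      cx <- r1$x_nm[i] / px; cy <- r1$y_nm[i] / px
      xs <- max(0, floor(cx - mrad)):min(nx - 1, ceiling(cx + mrad))
      ys <- max(0, floor(cy - mrad)):min(ny - 1, ceiling(cy + mrad))
      dd <- outer((ys - cy)^2, (xs - cx)^2, "+")
      mask[ys + 1, xs + 1] <- mask[ys + 1, xs + 1] | (dd <= mrad^2)
    }

    bands <- preset$interrow_bands
    band_off <- if (nrow(bands)) {
      (bands$row_from - 1) * geom$row_spacing_nm +
        bands$offset_fraction * geom$row_spacing_nm
    } else numeric()
    truth <- structure(
      list(true_centers = cen[, c("index", "row", "x_nm", "y_nm")],
           true_row_spacing_nm = geom$row_spacing_nm,
           true_intra_spacing_nm = geom$intra_spacing_nm,
           preset = preset,
           true_band_offsets_nm = band_off,
           seed = settings$seed),
      class = "synthetic_truth")

    structure(list(image = img, truth = truth, mask = mask,
                   geometry = geom, preset = preset, settings = settings),
              class = "synthetic_bundle")
  })
}

#' @export
print.synthetic_bundle <- function(x, ...) {
  cat(sprintf("<synthetic_bundle> %s / %s, %dx%d px @ %g nm, seed %d\n",
              x$geometry$cell_type, x$preset$name,
              nrow(x$image$actin), ncol(x$image$actin),
              x$settings$pixel_size_nm, x$settings$seed))
  invisible(x)
}

#' Write a synthetic bundle to disk
#'
#' Writes the two-channel TIFF (with its pixel-size sidecar), the row mask,
#' the ground-truth table (`truth.csv`: index, row, x_nm, y_nm) and the run
#' parameters (`params.yaml`).
#'
#' @param sim a [render()] result.
#' @param dir output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_synthetic <- function(sim, dir) {
  stopifnot(inherits(sim, "synthetic_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_image(sim$image, file.path(dir, "image.tif"))
  write_mask(sim$mask, file.path(dir, "mask.tif"))
  utils::write.csv(sim$truth$true_centers, file.path(dir, "truth.csv"),
                   row.names = FALSE)
  yaml::write_yaml(
    list(cell_type = sim$geometry$cell_type, preset = sim$preset$name,
         seed = sim$settings$seed,
         pixel_size_nm = sim$settings$pixel_size_nm,
         psf_fwhm_nm = sim$settings$psf_fwhm_nm,
         photons_per_peak = sim$settings$photons_per_peak,
         read_noise_sd = sim$settings$read_noise_sd,
         row_spacing_nm = sim$geometry$row_spacing_nm,
         intra_spacing_nm = sim$geometry$intra_spacing_nm,
         band_offsets_nm = as.list(sim$truth$true_band_offsets_nm)),
    file.path(dir, "params.yaml"))
  invisible(dir)
}
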