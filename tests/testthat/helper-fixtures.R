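# Shared fixtures: small, fast synthetic bundles and oracle helpers.

small_ihc <- function(...) make_geometry("IHC", n_cilia_per_row = 5, ...)
small_ohc <- function(...) make_geometry("OHC", n_cilia_per_row = 6, ...)

# single inter-row band, continuous, no rings/bridges
band_only_preset <- function(f, width_nm = 60, n_rows = 2) {
  labeling_preset(paste0("band", f),
                  interrow_bands = data.frame(row_from = 1, row_to = 2,
                                              offset_fraction = f,
                                              amplitude = 1,
                                              width_nm = width_nm),
                  granularity = Inf, amplitude_ratio = 0.8)
}

# most prominent inter-row protein peak between rows 1 and 2, as a fraction
dominant_inter_fraction <- function(fit) {
  fr <- tidy(fit)
  fr <- fr[fr$kind == "peak" & !fr$out_of_range &
             !is.na(fr$fraction) & fr$fraction > 0 & fr$row_lo == 1, ]
  if (!nrow(fr)) return(NA_real_)
  fr$fraction[which.max(fr$prominence)]
}

# analysis of a rendered bundle using the generator's own mask
analyze_sim <- function(sim, ...) {
  suppressWarnings(analyze_bundle(sim$image, sim$mask, ...))
}

# analytic PSF-blurred point template at local-frame offsets (u right,
# w outward/up) on an ROI grid, for alignment-fidelity checks
marker_template <- function(roi_size_px, pixel_size_nm, u_nm, w_nm, fwhm_nm) {
  q <- (roi_size_px + 1) / 2
  sig <- fwhm_nm / (2 * sqrt(2 * log(2))) / pixel_size_nm
  col0 <- q + u_nm / pixel_size_nm
  row0 <- q - w_nm / pixel_size_nm
  outer(exp(-((1:roi_size_px) - row0)^2 / (2 * sig^2)),
        exp(-((1:roi_size_px) - col0)^2 / (2 * sig^2)))
}

# expected average marker pattern for a row of cilia on an arc of radius R:
# every cilium carries a marker at (u, w) in its own frame; the ROI of each
# cilium also sees its neighbours' markers. Built analytically from the
# geometry, independent of the package's resampling code.
marker_template_arc <- function(roi_size_px, pixel_size_nm, R_nm, spacing_nm,
                                n_cilia, u_nm, w_nm, fwhm_nm) {
  q <- (roi_size_px + 1) / 2
  sig <- fwhm_nm / (2 * sqrt(2 * log(2))) / pixel_size_nm
  step <- spacing_nm / R_nm
  th <- (seq_len(n_cilia) - (n_cilia + 1) / 2) * step
  pos <- cbind(R_nm * sin(th), -R_nm * cos(th))   # arc below its centre
  tan_i <- cbind(cos(th), sin(th))
  out_i <- cbind(sin(th), -cos(th))               # radially outward (up)
  markers <- pos + u_nm * tan_i + w_nm * out_i
  tmpl <- matrix(0, roi_size_px, roi_size_px)
  half_nm <- (q - 1) * pixel_size_nm
  for (i in seq_len(n_cilia)) {
    for (j in seq_len(n_cilia)) {
      rel <- markers[j, ] - pos[i, ]
      uu <- sum(rel * tan_i[i, ])
      ww <- sum(rel * out_i[i, ])
      if (abs(uu) > half_nm + 4 * fwhm_nm || abs(ww) > half_nm + 4 * fwhm_nm) next
      col0 <- q + uu / pixel_size_nm
      row0 <- q - ww / pixel_size_nm
      tmpl <- tmpl + outer(
        exp(-((1:roi_size_px) - row0)^2 / (2 * sig^2)),
        exp(-((1:roi_size_px) - col0)^2 / (2 * sig^2)))
    }
  }
  tmpl / n_cilia
}

# least-squares circle (algebraic) -- independent oracle for exact points
ls_circle_fit <- function(x, y) {
  A <- cbind(2 * x, 2 * y, 1)
  co <- qr.solve(crossprod(A), crossprod(A, x^2 + y^2))
  c(cx = co[1], cy = co[2], r = sqrt(co[3] + co[1]^2 + co[2]^2))
}

# brute-force shortest open Hamiltonian path via full enumeration
shortest_path_bruteforce <- function(pts) {
  n <- nrow(pts)
  dm <- as.matrix(stats::dist(pts))
  perms <- e1071::permutations(n)
  len <- rep(0, nrow(perms))
  for (i in seq_len(n - 1)) {
    len <- len + dm[cbind(perms[, i], perms[, i + 1])]
  }
  perms[which.min(len), ]
}

# random arc configuration with spacing variation < 2x (simple open chain)
random_arc_points <- function(n) {
  r <- stats::runif(1, 30, 120)
  span <- stats::runif(1, 0.8, 2.2)
  base <- seq(0, span, length.out = n)
  jit <- stats::runif(n, -0.2, 0.2) * span / (n - 1)
  th <- base + jit
  cbind(x = r * cos(th), y = r * sin(th))
}
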