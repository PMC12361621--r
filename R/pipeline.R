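#' Run the full analysis on an in-memory image
#'
#' Chains the pipeline stages — smoothing and centre detection inside the
#' row mask, curation, ordering, spline fitting, unfolding, transverse
#' profiling, circumcircle frames, aligned extraction, averaging,
#' background subtraction, axial profiling, and peak/fraction readout —
#' and returns every intermediate product. This is the in-memory engine
#' behind [run_pipeline()].
#'
#' @param img an [image2c()].
#' @param mask logical row mask over the outer stereocilia row.
#' @param sigma_px detection blur SD in pixels.
#' @param prominence detection prominence threshold or `"auto"`.
#' @param exclude_detect candidate indices to drop before ordering (the
#'   first manual curation point).
#' @param exclude_average ordered-centre indices to drop from averaging
#'   only (the second curation point, e.g. the kinked central segment).
#' @param half_width_nm transverse half-width of the unfolded image.
#' @param roi_scale ROI size in units of the inter-cilium distance.
#' @param background background mode for [subtract_background()].
#' @param background_value per-channel scalars for `recalled_value` mode.
#' @param background_region region matrix for `user_roi` mode.
#' @param interior_hint interior side for near-straight bundles.
#' @param min_prominence,min_separation_nm peak-calling parameters.
#' @param snap_nm intra-row snap window for fractions.
#' @param band_px axial profile band width (1 or 3).
#' @param refine_centers sub-pixel centre refinement flag.
#' @return object of class `bundle_analysis`: a list with `centers`
#'   (stereocilia set), `curve`, `unfolded`, `profile`, `frames`, `stack`,
#'   `average`, `axial`, `actin_peaks`, `protein_peaks`, `rows`,
#'   `fractions`, `axial_peaks`, and the effective `params`.
#' @examples
#' sim <- render(make_geometry("IHC", n_cilia_per_row = 5),
#'               preset_library("IHC_PDZD7"), render_settings(seed = 3))
#' fit <- analyze_bundle(sim$image, sim$mask)
#' tidy(fit)
#' @export
analyze_bundle <- function(img, mask,
                           sigma_px = 2, prominence = "auto",
                           exclude_detect = integer(),
                           exclude_average = integer(),
                           half_width_nm = NULL, roi_scale = 2,
                           background = "auto_region",
                           background_value = NULL, background_region = NULL,
                           interior_hint = "down",
                           min_prominence = 0.1, min_separation_nm = 50,
                           snap_nm = min_separation_nm, band_px = 1,
                           refine_centers = TRUE) {
  stopifnot(inherits(img, "image2c"))
  px <- img$pixel_size_nm

  sm <- smooth_in_mask(img, mask, sigma_px)
  cand <- find_centers(sm, mask, prominence = prominence, sigma_px = sigma_px,
                       refine = refine_centers)
  if (nrow(cand) < 3) {
    stop("detect stage: only ", nrow(cand), " candidate centres found")
  }
  set <- curate(cand, rejected = exclude_detect, pixel_size_nm = px)
  set <- order_along_bundle(set)

  curve <- fit_spline(set, interior_hint = interior_hint)
  unf <- unfold(img, curve, half_width_nm = half_width_nm)
  prof <- transverse_profile(unf)

  avg_set <- if (length(exclude_average)) {
    order_along_bundle(curate(set, rejected = exclude_average,
                              pixel_size_nm = px))
  } else set
  frames <- local_frames(avg_set, curve)
  stack <- extract_aligned(img, frames, roi_scale = roi_scale)
  avg0 <- average_stack(stack)
  avg <- subtract_background(avg0, mode = background,
                             region = background_region,
                             value = background_value)
  axial <- axial_profiles(avg, band_px = band_px)

  actin_pk <- call_peaks(prof, "actin", min_prominence = min_prominence,
                         min_separation_nm = min_separation_nm)
  protein_pk <- call_peaks(prof, "protein", min_prominence = min_prominence,
                           min_separation_nm = min_separation_nm)
  rows <- tryCatch(row_positions(actin_pk, pixel_size_nm = px),
                   error = function(e) NULL)
  fractions <- if (!is.null(rows)) {
    fraction_of_interrow(protein_pk, rows, snap_nm = snap_nm)
  } else NULL
  axial_pk <- dplyr::bind_rows(
    horizontal = call_peaks(
      axial$distance_nm[axial$axis == "horizontal"],
      axial$protein[axial$axis == "horizontal"],
      min_prominence = min_prominence,
      min_separation_nm = min_separation_nm),
    vertical = call_peaks(
      axial$distance_nm[axial$axis == "vertical"],
      axial$protein[axial$axis == "vertical"],
      min_prominence = min_prominence,
      min_separation_nm = min_separation_nm),
    .id = "axis")

  structure(
    list(centers = set, curve = curve, unfolded = unf, profile = prof,
         frames = frames, stack = stack, average = avg, axial = axial,
         actin_peaks = actin_pk, protein_peaks = protein_pk,
         rows = rows, fractions = fractions, axial_peaks = axial_pk,
         params = list(sigma_px = sigma_px, prominence = prominence,
                       exclude_detect = exclude_detect,
                       exclude_average = exclude_average,
                       half_width_nm = half_width_nm, roi_scale = roi_scale,
                       background = background,
                       min_prominence = min_prominence,
                       min_separation_nm = min_separation_nm,
                       snap_nm = snap_nm, band_px = band_px,
                       refine_centers = refine_centers),
         name = img$name),
    class = "bundle_analysis")
}

#' @export
print.bundle_analysis <- function(x, ...) {
  cat(sprintf("<bundle_analysis> '%s': %d centres (%d included), %s actin rows, %d protein peaks\n",
              x$name, nrow(x$centers$centers), sum(x$centers$centers$included),
              if (is.null(x$rows)) "?" else nrow(x$rows),
              sum(x$protein_peaks$kind == "peak")))
  if (!is.null(x$fractions)) {
    inter <- x$fractions[x$fractions$kind == "peak" & !x$fractions$out_of_range &
                           x$fractions$fraction > 0, ]
    if (nrow(inter)) {
      cat("  inter-row protein peaks at",
          paste0(inter$percent, "%", collapse = ", "),
          "of the inter-row space\n")
    }
  }
  invisible(x)
}

#' Pipeline run configuration
#'
#' A flat key-value configuration (one YAML document) validated against
#' documented ranges; unknown keys are rejected. CLI flags override config
#' values, and the effective set is logged with the run.
#'
#' @param image,mask input file paths (two-channel TIFF and mask).
#' @param out_dir output directory.
#' @param pixel_size_nm optional pixel-size override.
#' @param sigma_px,prominence,half_width_nm,roi_scale,min_prominence,min_separation_nm,band_px
#'   stage parameters, as in [analyze_bundle()].
#' @param exclude_detect,exclude_average index lists referencing
#'   `centers.csv` order (the two manual curation points).
#' @param background,recall_file background mode and the JSON to recall
#'   values from (for `recalled_value`).
#' @param interior_hint interior side for near-straight bundles.
#' @param integer_centers parity flag: disable sub-pixel refinement.
#' @param seed seed recorded for synthetic runs.
#' @return validated config list of class `run_config`.
#' @export
run_config <- function(image = NULL, mask = NULL, out_dir = "hairbundle_run",
                       pixel_size_nm = NULL, sigma_px = 2,
                       prominence = "auto", exclude_detect = integer(),
                       exclude_average = integer(), half_width_nm = NULL,
                       roi_scale = 2, background = "auto_region",
                       recall_file = NULL, interior_hint = "down",
                       min_prominence = 0.1, min_separation_nm = 50,
                       band_px = 1, integer_centers = FALSE, seed = NULL) {
  cfg <- list(image = image, mask = mask, out_dir = out_dir,
              pixel_size_nm = pixel_size_nm, sigma_px = sigma_px,
              prominence = prominence,
              exclude_detect = as.integer(exclude_detect),
              exclude_average = as.integer(exclude_average),
              half_width_nm = half_width_nm, roi_scale = roi_scale,
              background = background, recall_file = recall_file,
              interior_hint = interior_hint,
              min_prominence = min_prominence,
              min_separation_nm = min_separation_nm, band_px = band_px,
              integer_centers = isTRUE(integer_centers), seed = seed)
  validate_run_config(cfg)
}

validate_run_config <- function(cfg) {
  known <- names(formals(run_config))
  extra <- setdiff(names(cfg), known)
  if (length(extra)) {
    stop("validation error: unknown config keys: ", paste(extra, collapse = ", "))
  }
  if (!is.null(cfg$sigma_px) && cfg$sigma_px < 0) {
    stop("validation error: sigma_px must be >= 0")
  }
  if (!identical(cfg$prominence, "auto") &&
      (!is.numeric(cfg$prominence) || cfg$prominence < 0)) {
    stop("validation error: prominence must be 'auto' or a non-negative number")
  }
  if (!is.null(cfg$roi_scale) && cfg$roi_scale <= 0) {
    stop("validation error: roi_scale must be positive")
  }
  if (!is.null(cfg$half_width_nm) && cfg$half_width_nm <= 0) {
    stop("validation error: half_width_nm must be positive")
  }
  if (!cfg$background %in% c("auto_region", "user_roi", "recalled_value")) {
    stop("validation error: unknown background mode '", cfg$background, "'")
  }
  if (!is.null(cfg$min_prominence) &&
      (cfg$min_prominence < 0 || cfg$min_prominence > 1)) {
    stop("validation error: min_prominence must be in [0, 1]")
  }
  if (!cfg$band_px %in% c(1, 3)) {
    stop("validation error: band_px must be 1 or 3")
  }
  structure(cfg, class = "run_config")
}

#' @rdname run_config
#' @param path YAML file to read.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(run_config, raw)
}

#' Run the complete headless pipeline on files
#'
#' Executes detect, unfold, average and peaks on the configured image, and
#' persists every stage's output as an independent intermediate file:
#' `centers.csv`, the unfolded per-channel TIFFs, `transverse_profile.csv`,
#' the aligned `stack_*.tif` and `average.tif`, the recallable
#' `background.json`, `axial_profiles.csv`, `peaks.csv`, a `report.txt`
#' summary and `pipeline_log.txt` with all effective parameters. A rerun
#' with an identical configuration and inputs is bit-identical. With
#' `from_stage`, earlier stages are not recomputed; their saved artifacts
#' are re-read instead.
#'
#' @param cfg a [run_config()] (or path to its YAML).
#' @param from_stage `"detect"`, `"unfold"`, `"average"` or `"peaks"`.
#' @return the output directory, invisibly; stage errors propagate with
#'   the stage name, leaving earlier artifacts in place.
#' @export
run_pipeline <- function(cfg, from_stage = "detect") {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  cfg <- validate_run_config(cfg)
  stages <- c("detect", "unfold", "average", "peaks")
  from_stage <- match.arg(from_stage, stages)
  start <- match(from_stage, stages)
  out <- cfg$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  logf <- character(0)

  img <- read_image(cfg$image, pixel_size_nm = cfg$pixel_size_nm)
  mask <- read_mask(cfg$mask, dim_px = dim(img$actin))
  px <- img$pixel_size_nm

  with_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  # --- detect ---------------------------------------------------------
  centers_path <- file.path(out, "centers.csv")
  if (start <= 1) {
    set <- with_stage("detect", {
      smo <- smooth_in_mask(img, mask, cfg$sigma_px)
      cand <- find_centers(smo, mask, prominence = cfg$prominence,
                           sigma_px = cfg$sigma_px,
                           refine = !cfg$integer_centers)
      s <- curate(cand, rejected = cfg$exclude_detect, pixel_size_nm = px)
      order_along_bundle(s)
    })
    tab <- dplyr::mutate(set$centers, order = dplyr::row_number())
    utils::write.csv(tab, centers_path, row.names = FALSE)
    logf <- c(logf, sprintf(
      "detect: sigma_px=%g prominence=%s n_centers=%d n_excluded=%d",
      cfg$sigma_px, format(cfg$prominence), nrow(tab), sum(!tab$included)))
  } else {
    tab <- utils::read.csv(centers_path)
    set <- new_stereocilia_set(tibble::as_tibble(tab), px)
  }

  # --- unfold ---------------------------------------------------------
  profile_path <- file.path(out, "transverse_profile.csv")
  if (start <= 2) {
    res <- with_stage("unfold", {
      curve <- fit_spline(set, interior_hint = cfg$interior_hint)
      unf <- unfold(img, curve, half_width_nm = cfg$half_width_nm)
      list(curve = curve, unf = unf, prof = transverse_profile(unf))
    })
    curve <- res$curve; unf <- res$unf; prof <- res$prof
    w16 <- function(m, path) {
      m[is.na(m)] <- 0
      tiff::writeTIFF(pmin(pmax(round(m), 0), 65535) / 65535, path,
                      bits.per.sample = 16L, compression = "none")
    }
    w16(unf$actin, file.path(out, "unfolded_actin.tif"))
    w16(unf$protein, file.path(out, "unfolded_protein.tif"))
    utils::write.csv(
      data.frame(distance_nm = prof$distance_nm, actin_norm = prof$actin,
                 protein_norm = prof$protein, n_valid = prof$n_valid),
      profile_path, row.names = FALSE)
    p <- autoplot.transverse_profile(prof)
    ggplot2::ggsave(file.path(out, "transverse_profile.pdf"), p,
                    width = 6, height = 4)
    logf <- c(logf, sprintf("unfold: arc_length_px=%.1f half_width_nm=%g",
                            curve$arc_length_px,
                            max(unf$transverse_offsets_nm)))
  } else {
    curve <- fit_spline(set, interior_hint = cfg$interior_hint)
    prof_df <- utils::read.csv(profile_path)
    prof <- tibble::tibble(distance_nm = prof_df$distance_nm,
                           actin = prof_df$actin_norm,
                           protein = prof_df$protein_norm,
                           n_valid = prof_df$n_valid)
    class(prof) <- c("transverse_profile", class(prof))
  }

  # --- average --------------------------------------------------------
  axial_path <- file.path(out, "axial_profiles.csv")
  if (start <= 3) {
    avg <- with_stage("average", {
      avg_set <- if (length(cfg$exclude_average)) {
        order_along_bundle(curate(set, rejected = cfg$exclude_average,
                                  pixel_size_nm = px))
      } else set
      frames <- local_frames(avg_set, curve)
      stack <- extract_aligned(img, frames, roi_scale = cfg$roi_scale)
      a0 <- average_stack(stack)
      value <- if (cfg$background == "recalled_value") {
        read_background(cfg$recall_file)
      } else NULL
      a <- subtract_background(a0, mode = cfg$background, value = value)
      w16s <- function(arr, path) {
        pages <- lapply(seq_len(dim(arr)[3]), function(i) {
          m <- arr[, , i]; m[is.na(m)] <- 0
          pmin(pmax(round(m), 0), 65535) / 65535
        })
        tiff::writeTIFF(pages, path, bits.per.sample = 16L,
                        compression = "none")
      }
      w16s(stack$actin, file.path(out, "stack_actin.tif"))
      w16s(stack$protein, file.path(out, "stack_protein.tif"))
      m2 <- function(m) { m[is.na(m)] <- 0; m / max(m, 1e-12) }
      tiff::writeTIFF(list(m2(a$actin), m2(a$protein)),
                      file.path(out, "average.tif"),
                      bits.per.sample = 16L, compression = "none")
      export_background(a, file.path(out, "background.json"))
      a
    })
    axial <- axial_profiles(avg, band_px = cfg$band_px)
    utils::write.csv(axial, axial_path, row.names = FALSE)
    logf <- c(logf, sprintf(
      "average: n_rois=%d background=%s bg_actin=%.3f bg_protein=%.3f",
      avg$n, avg$background_mode, avg$background_values[1],
      avg$background_values[2]))
  } else {
    axial <- tibble::as_tibble(utils::read.csv(axial_path))
  }

  # --- peaks ----------------------------------------------------------
  with_stage("peaks", {
    actin_pk <- call_peaks(prof, "actin", min_prominence = cfg$min_prominence,
                           min_separation_nm = cfg$min_separation_nm)
    protein_pk <- call_peaks(prof, "protein",
                             min_prominence = cfg$min_prominence,
                             min_separation_nm = cfg$min_separation_nm)
    rows <- row_positions(actin_pk, pixel_size_nm = px)
    fr <- fraction_of_interrow(protein_pk, rows,
                               snap_nm = cfg$min_separation_nm)
    pk_tab <- dplyr::bind_rows(
      dplyr::mutate(tibble::as_tibble(actin_pk), channel = "actin",
                    row_lo = NA, row_hi = NA, fraction_pct = NA),
      dplyr::mutate(tibble::as_tibble(protein_pk), channel = "protein",
                    row_lo = fr$row_lo, row_hi = fr$row_hi,
                    fraction_pct = fr$percent))
    utils::write.csv(pk_tab[, c("channel", "kind", "position_nm", "prominence",
                                "row_lo", "row_hi", "fraction_pct")],
                     file.path(out, "peaks.csv"), row.names = FALSE)
    rep <- c(sprintf("image: %s", img$name),
             sprintf("actin rows at: %s nm",
                     paste(round(rows$position_nm, 1), collapse = ", ")),
             sprintf("inter-row spacing: %s nm",
                     paste(round(stats::na.omit(rows$spacing_to_next_nm), 1),
                           collapse = ", ")),
             sprintf("protein peaks (%% of inter-row space): %s",
                     paste0(fr$percent[fr$kind == "peak"], collapse = ", ")))
    writeLines(rep, file.path(out, "report.txt"))
    logf <- c(logf, sprintf("peaks: n_actin=%d n_protein=%d n_shoulders=%d",
                            sum(actin_pk$kind == "peak"),
                            sum(protein_pk$kind == "peak"),
                            sum(protein_pk$kind == "shoulder")))
  })

  cfgl <- cfg; class(cfgl) <- NULL
  yaml::write_yaml(cfgl[!vapply(cfgl, is.null, logical(1))],
                   file.path(out, "params.yaml"))
  cat(logf, sep = "\n",
      file = file.path(out, "pipeline_log.txt"), append = start > 1)
  cat("\n", file = file.path(out, "pipeline_log.txt"), append = TRUE)
  invisible(out)
}
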