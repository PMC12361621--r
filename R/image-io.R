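#' Two-channel co-registered image container
#'
#' The pipeline's sole image input: an actin channel and a protein channel
#' acquired simultaneously (line-interleaved), so both share one pixel grid.
#'
#' @param actin,protein non-negative numeric matrices of identical size.
#' @param pixel_size_nm physical pixel size in nanometres.
#' @param name identifier used in outputs.
#' @return object of class `image2c`.
#' @export
image2c <- function(actin, protein, pixel_size_nm, name = "image") {
  if (!is.matrix(actin) || !is.matrix(protein) ||
      !identical(dim(actin), dim(protein))) {
    stop("channel error: actin and protein must be matrices of identical dimensions")
  }
  if (!(pixel_size_nm > 0)) stop("pixel_size_nm must be positive")
  if (min(actin) < 0 || min(protein) < 0) {
    stop("intensities must be non-negative")
  }
  structure(list(actin = actin, protein = protein,
                 pixel_size_nm = pixel_size_nm, name = name),
            class = "image2c")
}

#' @export
print.image2c <- function(x, ...) {
  cat(sprintf("<image2c> '%s': %d x %d px @ %g nm/px\n", x$name,
              nrow(x$actin), ncol(x$actin), x$pixel_size_nm))
  invisible(x)
}

meta_path <- function(path) paste0(path, ".meta.yaml")

#' Read a two-channel TIFF as an [image2c()]
#'
#' Accepts a two-page TIFF or a single page with two samples per pixel.
#' The pixel size is resolved, in order, from TIFF resolution tags, from the
#' plain-text sidecar written by [write_image()], or from the
#' `pixel_size_nm` argument; if none is available this is an error.
#'
#' @param path TIFF file path.
#' @param pixel_size_nm explicit pixel size override in nm.
#' @param channel_order which page/sample is which; default actin first.
#' @return an [image2c()].
#' @export
read_image <- function(path, pixel_size_nm = NULL,
                       channel_order = c("actin", "protein")) {
  if (!file.exists(path)) stop("no such image file: ", path)
  channel_order <- match.arg(channel_order[1], c("actin", "protein"))
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE, as.is = TRUE)
  strip <- function(m) matrix(as.numeric(m), nrow(m), ncol(m))
  chans <- list()
  for (p in pages) {
    d <- dim(p)
    if (length(d) == 2) {
      chans[[length(chans) + 1]] <- strip(p)
    } else if (length(d) == 3 && d[3] == 2) {
      chans[[length(chans) + 1]] <- strip(p[, , 1])
      chans[[length(chans) + 1]] <- strip(p[, , 2])
    } else {
      stop("channel-count error: ", path, " has a page with ", d[3],
           " samples per pixel; expected exactly 2 channels")
    }
  }
  if (length(chans) != 2) {
    stop("channel-count error: ", path, " resolves to ", length(chans),
         " channels; expected exactly 2")
  }
  ps <- pixel_size_nm
  if (is.null(ps)) {
    xres <- attr(pages[[1]], "x.resolution")
    unit <- attr(pages[[1]], "resolution.unit") %||% "inch"
    if (!is.null(xres) && xres > 0) {
      unit_nm <- switch(unit, inch = 2.54e7, cm = 1e7, 2.54e7)
      ps <- unit_nm / xres
    }
  }
  if (is.null(ps) && file.exists(meta_path(path))) {
    ps <- yaml::read_yaml(meta_path(path))$pixel_size_nm
  }
  if (is.null(ps)) {
    stop("metadata error: no pixel size in TIFF tags or sidecar for ", path,
         "; pass pixel_size_nm= explicitly")
  }
  if (channel_order == "protein") chans <- rev(chans)
  image2c(chans[[1]], chans[[2]], pixel_size_nm = ps,
          name = sub("\\.[^.]*$", "", basename(path)))
}

#' Write an [image2c()] as a two-page 16-bit TIFF
#'
#' Integer count data round-trips exactly through [read_image()]. A
#' plain-text sidecar (`<path>.meta.yaml`) records the pixel size and
#' channel order.
#'
#' @param img an [image2c()].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  stopifnot(inherits(img, "image2c"))
  mx <- max(img$actin, img$protein)
  if (mx > 65535) stop("intensities exceed 16-bit range; rescale first")
  tiff::writeTIFF(list(img$actin / 65535, img$protein / 65535), path,
                  bits.per.sample = 16L, compression = "none")
  yaml::write_yaml(list(pixel_size_nm = img$pixel_size_nm,
                        channels = c("actin", "protein"),
                        name = img$name),
                   meta_path(path))
  invisible(path)
}

#' Read a row mask
#'
#' Either a raster (TIFF, nonzero pixels are in the mask) or a polygon CSV
#' with columns `x_px`, `y_px` (0-based vertex coordinates), rasterized with
#' the even-odd rule over pixel centres.
#'
#' @param path mask file.
#' @param dim_px raster size `c(ny, nx)`; required for polygon input.
#' @return logical matrix.
#' @export
read_mask <- function(path, dim_px = NULL) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    if (is.null(dim_px)) stop("polygon masks need dim_px = c(ny, nx)")
    poly <- utils::read.csv(path)
    stopifnot(all(c("x_px", "y_px") %in% names(poly)))
    grid <- expand.grid(x = 0:(dim_px[2] - 1), y = 0:(dim_px[1] - 1))
    inside <- point_in_polygon(grid$x, grid$y, poly$x_px, poly$y_px)
    matrix(inside, dim_px[1], dim_px[2], byrow = TRUE)
  } else {
    m <- tiff::readTIFF(path, as.is = TRUE)
    if (length(dim(m)) == 3) m <- m[, , 1]
    m > 0
  }
}

#' @rdname read_mask
#' @param mask logical matrix to write.
#' @export
write_mask <- function(mask, path) {
  tiff::writeTIFF((mask * 1) / 255, path, bits.per.sample = 8L,
                  compression = "none")
  invisible(path)
}

# Even-odd (crossing number) point-in-polygon test, vectorized over points.
point_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    cross <- (vy[i] > py) != (vy[j] > py)
    xint <- (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i]
    inside <- xor(inside, cross & (px < xint))
    j <- i
  }
  inside
}

#' Validate a row mask against an image
#'
#' A valid mask is nonempty, matches the image dimensions, and forms a
#' single connected component after morphological closing (one selected
#' row).
#'
#' @param mask logical matrix.
#' @param img optional [image2c()] to check dimensions against.
#' @return `mask`, invisibly; errors otherwise.
#' @export
validate_mask <- function(mask, img = NULL) {
  if (!is.matrix(mask)) stop("mask error: mask must be a matrix")
  mask <- mask > 0
  if (!any(mask)) stop("mask error: mask is empty")
  if (!is.null(img) && !identical(dim(mask), dim(img$actin))) {
    stop("mask error: mask dimensions do not match the image")
  }
  ncomp <- label_components(morph_close(mask))$n
  if (ncomp != 1) {
    stop("mask error: mask has ", ncomp,
         " connected components after closing; select a single row")
  }
  invisible(mask)
}
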