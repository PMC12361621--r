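#' Define a synthetic hair-bundle geometry
#'
#' Builds the stereocilia layout of an inner (IHC) or outer (OHC) hair-cell
#' bundle. Row 1 is the outer row; higher row indices lie toward the bundle
#' interior. OHC bundles place their rows on concentric arcs (the U-shaped
#' bundle), IHC bundles on straight parallel lines. All distances are in
#' nanometres. Defaults are plausible for P5 mouse cochlea and are not
#' measurements of any particular cell; every field can be overridden.
#'
#' @param cell_type `"IHC"` or `"OHC"`.
#' @param n_rows number of stereocilia rows (2 or 3).
#' @param row_spacing_nm centre-to-centre distance between adjacent rows.
#' @param intra_spacing_nm centre-to-centre distance within a row.
#' @param arc_radius_nm radius of the arc carrying row 1; `Inf` for a
#'   straight row.
#' @param n_cilia_per_row stereocilia per row (at least 3).
#' @param cilium_radius_nm radius of the actin disc of one stereocilium.
#' @param stagger `"aligned"` or `"staircase"` registration of rows;
#'   staircase shifts each deeper row by half the intra-row spacing.
#' @param kink if `TRUE`, the two central row-1 stereocilia are displaced
#'   outward, emulating the atypical central ("kinked") segment of real
#'   bundles that users exclude from averaging.
#' @param kink_nm outward displacement of the kinked stereocilia.
#' @return an object of class `bundle_geometry`.
#' @examples
#' make_geometry("OHC")
#' make_geometry("IHC", n_cilia_per_row = 5)
#' @export
make_geometry <- function(cell_type = c("IHC", "OHC"),
                          n_rows = NULL,
                          row_spacing_nm = 500,
                          intra_spacing_nm = 450,
                          arc_radius_nm = NULL,
                          n_cilia_per_row = 9,
                          cilium_radius_nm = 150,
                          stagger = NULL,
                          kink = FALSE,
                          kink_nm = 120) {
  cell_type <- match.arg(cell_type)
  n_rows <- n_rows %||% if (cell_type == "OHC") 3L else 2L
  arc_radius_nm <- arc_radius_nm %||% if (cell_type == "OHC") 2000 else Inf
  stagger <- stagger %||% if (cell_type == "OHC") "staircase" else "aligned"
  stagger <- match.arg(stagger, c("aligned", "staircase"))

  if (!n_rows %in% c(2L, 3L)) {
    stop("invalid geometry: n_rows must be 2 or 3 (got ", n_rows, ")")
  }
  if (n_cilia_per_row < 3) {
    stop("invalid geometry: n_cilia_per_row must be >= 3 (got ",
         n_cilia_per_row, ")")
  }
  if (!(row_spacing_nm > 2 * cilium_radius_nm)) {
    stop("invalid geometry: row_spacing_nm must exceed 2 * cilium_radius_nm ",
         "(rows would overlap)")
  }
  if (is.finite(arc_radius_nm) &&
      !(arc_radius_nm > n_cilia_per_row * intra_spacing_nm / pi)) {
    stop("invalid geometry: arc_radius_nm must exceed ",
         "n_cilia_per_row * intra_spacing_nm / pi (arc too short for the row)")
  }
  if (intra_spacing_nm <= 2 * cilium_radius_nm) {
    stop("invalid geometry: intra_spacing_nm must exceed 2 * cilium_radius_nm")
  }
  structure(
    list(cell_type = cell_type, n_rows = as.integer(n_rows),
         row_spacing_nm = row_spacing_nm, intra_spacing_nm = intra_spacing_nm,
         arc_radius_nm = arc_radius_nm,
         n_cilia_per_row = as.integer(n_cilia_per_row),
         cilium_radius_nm = cilium_radius_nm, stagger = stagger,
         kink = isTRUE(kink), kink_nm = kink_nm),
    class = "bundle_geometry"
  )
}

#' @export
print.bundle_geometry <- function(x, ...) {
  cat(sprintf(
    "<bundle_geometry> %s: %d rows x %d cilia, intra %g nm, rows %g nm apart, %s, arc R = %g nm%s\n",
    x$cell_type, x$n_rows, x$n_cilia_per_row, x$intra_spacing_nm,
    x$row_spacing_nm, x$stagger, x$arc_radius_nm,
    if (x$kink) ", kinked centre" else ""))
  invisible(x)
}

#' Stereocilium centres and local axes of a geometry
#'
#' Lays the bundle out in an un-translated nm frame: straight bundles run
#' along x with the interior toward +y; arc bundles sit on concentric
#' circles about the origin with the interior toward the arc centre.
#' `tx, ty` give the along-row tangent and `ox, oy` the outward unit normal
#' (away from the bundle interior) at each stereocilium.
#'
#' @param geom a [make_geometry()] object.
#' @return tibble with columns `index`, `row`, `x_nm`, `y_nm`, `tx`, `ty`,
#'   `ox`, `oy`.
#' @export
geometry_centers <- function(geom) {
  stopifnot(inherits(geom, "bundle_geometry"))
  n <- geom$n_cilia_per_row
  a <- geom$intra_spacing_nm
  s <- geom$row_spacing_nm
  rows <- purrr::map_dfr(seq_len(geom$n_rows), function(k) {
    off <- if (geom$stagger == "staircase" && k > 1) (k - 1) * 0.5 else 0
    if (is.finite(geom$arc_radius_nm)) {
      rk <- geom$arc_radius_nm - (k - 1) * s
      step <- a / rk
      th <- -pi / 2 + (seq_len(n) - (n + 1) / 2 + off) * step
      tibble::tibble(
        row = k,
        x_nm = rk * cos(th), y_nm = rk * sin(th),
        tx = -sin(th), ty = cos(th),
        ox = cos(th), oy = sin(th))
    } else {
      x <- (seq_len(n) - (n + 1) / 2 + off) * a
      tibble::tibble(
        row = k,
        x_nm = x, y_nm = (k - 1) * s,
        tx = 1, ty = 0, ox = 0, oy = -1)
    }
  })
  if (geom$kink) {
    mid <- order(abs(seq_len(n) - (n + 1) / 2))[1:2]
    sel <- which(rows$row == 1)[mid]
    rows$x_nm[sel] <- rows$x_nm[sel] + geom$kink_nm * rows$ox[sel]
    rows$y_nm[sel] <- rows$y_nm[sel] + geom$kink_nm * rows$oy[sel]
  }
  dplyr::mutate(rows, index = dplyr::row_number(), .before = 1)
}
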