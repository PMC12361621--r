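#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a bundle analysis into its peak-fraction table
#'
#' One row per protein peak or shoulder with its position, prominence,
#' bounding rows and position as a fraction of the inter-row space.
#'
#' @param x a [analyze_bundle()] result.
#' @param ... unused.
#' @return a tibble.
#' @export
tidy.bundle_analysis <- function(x, ...) {
  if (is.null(x$fractions)) {
    return(tibble::tibble(kind = character(), position_nm = numeric(),
                          prominence = numeric(), row_lo = integer(),
                          row_hi = integer(), fraction = numeric(),
                          percent = numeric(), out_of_range = logical()))
  }
  tibble::as_tibble(x$fractions)
}

#' One-row summary of a bundle analysis
#'
#' @param x a [analyze_bundle()] result.
#' @param ... unused.
#' @return a one-row tibble: centre counts, spacing estimates and peak
#'   counts.
#' @export
glance.bundle_analysis <- function(x, ...) {
  px <- x$centers$pixel_size_nm
  tibble::tibble(
    n_centers = nrow(x$centers$centers),
    n_included = sum(x$centers$centers$included),
    mean_intra_spacing_nm = x$centers$mean_intra_spacing_px * px,
    n_rows = if (is.null(x$rows)) NA_integer_ else nrow(x$rows),
    row_spacing_nm = if (is.null(x$rows)) NA_real_ else {
      mean(x$rows$spacing_to_next_nm, na.rm = TRUE)
    },
    n_protein_peaks = sum(x$protein_peaks$kind == "peak"),
    n_shoulders = sum(x$protein_peaks$kind == "shoulder"),
    arc_length_nm = x$curve$arc_length_px * px)
}

#' @export
tidy.peak_set <- function(x, ...) tibble::as_tibble(x)
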