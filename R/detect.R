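#' Gaussian-smooth the actin channel inside the row mask
#'
#' Smoothing is used only to stabilize centre detection; all later
#' intensity measurements are made on the raw pixels. The image is masked
#' first (outside set to zero) and then blurred, so nothing outside the
#' selected row leaks into the detection.
#'
#' @param img an [image2c()].
#' @param mask logical row mask, same size as the channels.
#' @param sigma_px blur standard deviation in pixels (default 2, the
#'   macro's value); 0 returns the masked raw channel.
#' @return numeric matrix: blurred actin, zero outside the mask.
#' @export
smooth_in_mask <- function(img, mask, sigma_px = 2) {
  stopifnot(inherits(img, "image2c"), sigma_px >= 0)
  validate_mask(mask, img)
  masked <- img$actin * (mask > 0)
  out <- gaussian_blur(masked, sigma_px)
  out * (mask > 0)
}

#' Find stereocilium centres as prominent local maxima
#'
#' Detects all local maxima inside the mask whose topographic prominence
#' (height above the highest saddle connecting them to a higher maximum)
#' exceeds the threshold. Maxima closer together than `2 * sigma_px` are
#' merged to their intensity-weighted centroid, and positions are refined
#' to sub-pixel accuracy by a quadratic fit of the 3x3 neighbourhood
#' (disable with `refine = FALSE` for strict integer-pixel parity with the
#' original interactive macro).
#'
#' @param smoothed matrix from [smooth_in_mask()].
#' @param mask logical row mask.
#' @param prominence threshold; `"auto"` (default) uses 3x the robust noise
#'   SD (median absolute deviation scaled to SD) of the masked smoothed
#'   pixels.
#' @param sigma_px the smoothing scale used, which sets the merge radius.
#' @param refine sub-pixel refinement flag.
#' @return tibble with columns `x_px`, `y_px`, `value`, `prominence`
#'   (possibly empty).
#' @export
find_centers <- function(smoothed, mask, prominence = "auto", sigma_px = 2,
                         refine = TRUE) {
  stopifnot(is.matrix(smoothed))
  mask <- mask > 0
  vals <- smoothed[mask]
  if (identical(prominence, "auto")) {
    prominence <- 3 * stats::mad(vals)
  }
  stopifnot(prominence >= 0)
  pk <- persistence_maxima_2d(smoothed, mask)
  pk <- pk[pk$prominence > prominence, , drop = FALSE]
  empty <- tibble::tibble(x_px = numeric(), y_px = numeric(),
                          value = numeric(), prominence = numeric())
  if (!nrow(pk)) return(empty)

  # merge duplicates closer than 2 * sigma_px (plateaus split by noise)
  merge_r <- 2 * max(sigma_px, .5)
  ord <- order(-pk$value)
  keep <- rep(TRUE, nrow(pk))
  group <- seq_len(nrow(pk))
  for (i in ord) {
    if (!keep[i]) next
    d2 <- (pk$x - pk$x[i])^2 + (pk$y - pk$y[i])^2
    close <- which(keep & d2 <= merge_r^2 & seq_len(nrow(pk)) != i)
    close <- close[pk$value[close] <= pk$value[i]]
    if (length(close)) {
      keep[close] <- FALSE
      group[close] <- i
    }
  }
  merged <- lapply(which(keep), function(i) {
    members <- which(group == i | seq_len(nrow(pk)) == i)
    w <- pk$value[members]
    list(x = sum(pk$x[members] * w) / sum(w),
         y = sum(pk$y[members] * w) / sum(w),
         value = pk$value[i], prominence = max(pk$prominence[members]))
  })
  out <- tibble::tibble(
    x_px = vapply(merged, `[[`, numeric(1), "x"),
    y_px = vapply(merged, `[[`, numeric(1), "y"),
    value = vapply(merged, `[[`, numeric(1), "value"),
    prominence = vapply(merged, `[[`, numeric(1), "prominence"))

  if (refine) {
    nr <- nrow(smoothed); nc <- ncol(smoothed)
    for (i in seq_len(nrow(out))) {
      xi <- round(out$x_px[i]); yi <- round(out$y_px[i])
      # a maximum on a near-flat plateau (blurred uniform disc) is placed at
      # the plateau's intensity-weighted centroid, as the interactive
      # maxima finder does; an isolated sharp maximum keeps its pixel
      plat <- plateau_region(smoothed, mask, xi, yi, frac = 0.9)
      if (nrow(plat) > 9) {
        w <- smoothed[cbind(plat$r, plat$c)]
        xi <- round(sum((plat$c - 1) * w) / sum(w))
        yi <- round(sum((plat$r - 1) * w) / sum(w))
        out$x_px[i] <- sum((plat$c - 1) * w) / sum(w)
        out$y_px[i] <- sum((plat$r - 1) * w) / sum(w)
      }
      if (xi >= 1 && xi <= nc - 2 && yi >= 1 && yi <= nr - 2 &&
          nrow(plat) <= 9) {
        r <- yi + 1; c <- xi + 1
        out$x_px[i] <- xi + parabolic_offset(
          smoothed[r, c - 1], smoothed[r, c], smoothed[r, c + 1])
        out$y_px[i] <- yi + parabolic_offset(
          smoothed[r - 1, c], smoothed[r, c], smoothed[r + 1, c])
      }
    }
  }
  dplyr::arrange(out, .data$x_px, .data$y_px)
}

# Connected region of near-peak pixels (>= frac * peak value) around a
# maximum, grown inside the mask; used to centre plateau maxima.
plateau_region <- function(img, mask, x0, y0, frac = 0.985) {
  nr <- nrow(img); nc <- ncol(img)
  r0 <- y0 + 1; c0 <- x0 + 1
  thr <- img[r0, c0] * frac
  seen <- matrix(FALSE, nr, nc)
  queue <- list(c(r0, c0))
  seen[r0, c0] <- TRUE
  rows <- integer(0); cols <- integer(0)
  while (length(queue)) {
    p <- queue[[length(queue)]]
    queue[[length(queue)]] <- NULL
    rows <- c(rows, p[1]); cols <- c(cols, p[2])
    for (dr in -1:1) for (dc in -1:1) {
      rr <- p[1] + dr; cc <- p[2] + dc
      if (rr < 1 || rr > nr || cc < 1 || cc > nc) next
      if (seen[rr, cc] || !mask[rr, cc] || img[rr, cc] < thr) next
      seen[rr, cc] <- TRUE
      queue[[length(queue) + 1]] <- c(rr, cc)
    }
  }
  data.frame(r = rows, c = cols)
}

# Topographic prominence of 2-D local maxima restricted to a mask
# (persistence of the superlevel-set filtration, 8-connectivity).
persistence_maxima_2d <- function(img, mask) {
  nr <- nrow(img)
  idx <- which(mask)
  if (!length(idx)) {
    return(data.frame(x = numeric(), y = numeric(),
                      value = numeric(), prominence = numeric()))
  }
  vals <- img[idx]
  pos <- integer(length(img)); pos[idx] <- seq_along(idx)  # image idx -> local
  ord <- idx[order(-vals, idx)]
  comp <- integer(length(idx))
  parent <- integer(0); peak_val <- numeric(0); peak_at <- integer(0)
  prom <- numeric(0)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  off <- c(-1L, 1L, -nr, nr, -nr - 1L, -nr + 1L, nr - 1L, nr + 1L)
  for (p in ord) {
    y <- (p - 1L) %% nr + 1L
    nbr <- p + off
    # drop vertical wrap-around at matrix top/bottom edges
    bad <- (y == 1L & (nbr - p) %in% c(-1L, -nr - 1L, nr - 1L)) |
           (y == nr & (nbr - p) %in% c(1L, -nr + 1L, nr + 1L))
    nbr <- nbr[!bad & nbr >= 1 & nbr <= length(img)]
    nbr <- nbr[pos[nbr] != 0L]
    nbr <- nbr[comp[pos[nbr]] != 0L]
    roots <- unique(vapply(nbr, function(q) find(comp[pos[q]]), integer(1)))
    if (!length(roots)) {
      k <- length(parent) + 1L
      parent[k] <- k
      peak_val[k] <- img[p]
      peak_at[k] <- p
      prom[k] <- NA_real_
      comp[pos[p]] <- k
    } else if (length(roots) == 1L) {
      comp[pos[p]] <- roots
    } else {
      win <- roots[order(-peak_val[roots], peak_at[roots])][1]
      for (r in setdiff(roots, win)) {
        prom[r] <- peak_val[r] - img[p]
        parent[r] <- win
      }
      comp[pos[p]] <- win
    }
  }
  alive <- which(parent == seq_along(parent))
  prom[alive] <- peak_val[alive] - min(vals)
  data.frame(x = (peak_at - 1L) %/% nr,       # 0-based px coords
             y = (peak_at - 1L) %% nr,
             value = peak_val, prominence = prom)
}

#' Curate detected centres into a stereocilia set
#'
#' Marks rejected detections as excluded without deleting them, preserving
#' provenance in saved tables. Curation is idempotent: applying the same
#' rejection set twice equals applying it once.
#'
#' @param candidates tibble from [find_centers()] (or a stereocilia set to
#'   re-curate).
#' @param rejected integer indices (1-based, in candidate order) to exclude.
#' @param pixel_size_nm pixel size carried into the set.
#' @return object of class `stereocilia_set`: a list with the `centers`
#'   tibble (`index`, `x_px`, `y_px`, `value`, `included`), the pixel size,
#'   and `mean_intra_spacing_px` over consecutive included centres.
#' @export
curate <- function(candidates, rejected = integer(), pixel_size_nm = NULL) {
  if (inherits(candidates, "stereocilia_set")) {
    pixel_size_nm <- pixel_size_nm %||% candidates$pixel_size_nm
    cen <- candidates$centers
    cen$included <- TRUE
  } else {
    cen <- tibble::as_tibble(candidates)
    cen$included <- TRUE
  }
  if (!"index" %in% names(cen)) {
    cen <- dplyr::mutate(cen, index = dplyr::row_number(), .before = 1)
  }
  if (length(rejected)) {
    if (!all(rejected %in% cen$index)) {
      stop("rejected indices outside the candidate set: ",
           paste(setdiff(rejected, cen$index), collapse = ", "))
    }
    cen$included[cen$index %in% rejected] <- FALSE
  }
  n_inc <- sum(cen$included)
  if (n_inc == 0) stop("insufficient-points error: no centres left")
  if (n_inc < 3) {
    warning("only ", n_inc, " included centres; spline and circle fits need 3")
  }
  new_stereocilia_set(cen, pixel_size_nm)
}

new_stereocilia_set <- function(cen, pixel_size_nm) {
  inc <- cen[cen$included, ]
  spacing <- if (nrow(inc) >= 2) {
    mean(sqrt(diff(inc$x_px)^2 + diff(inc$y_px)^2))
  } else NA_real_
  structure(list(centers = cen, pixel_size_nm = pixel_size_nm,
                 mean_intra_spacing_px = spacing),
            class = "stereocilia_set")
}

#' @export
print.stereocilia_set <- function(x, ...) {
  cat(sprintf("<stereocilia_set> %d centres (%d included), mean spacing %.1f px\n",
              nrow(x$centers), sum(x$centers$included),
              x$mean_intra_spacing_px))
  invisible(x)
}

#' Order centres along the bundle
#'
#' Reorders the included centres to start from one extremity of the hair
#' bundle and proceed by nearest unvisited neighbour, so consecutive
#' elements are closest neighbours. The extremity is the centre whose
#' second-nearest included neighbour is farthest (a chain endpoint); ties
#' break deterministically on lowest (y, then x). For centres on a simple
#' open curve with less than two-fold spacing variation this equals the
#' shortest Hamiltonian path.
#'
#' @param set a `stereocilia_set` (from [curate()]).
#' @return the set with included centres reordered (excluded centres are
#'   kept, flagged, after them) and spacing recomputed.
#' @export
order_along_bundle <- function(set) {
  stopifnot(inherits(set, "stereocilia_set"))
  cen <- set$centers
  inc <- which(cen$included)
  if (length(inc) < 3) {
    stop("insufficient-points error: ordering needs at least 3 included centres")
  }
  pts <- as.matrix(cen[inc, c("x_px", "y_px")])
  n <- nrow(pts)
  dm <- as.matrix(stats::dist(pts))
  second_nn <- apply(dm, 1, function(d) sort(d)[3])  # sorted: self, 1st NN, 2nd NN
  cand <- which(second_nn == max(second_nn))
  if (length(cand) > 1) {
    cand <- cand[order(pts[cand, 2], pts[cand, 1])]
  }
  start <- cand[1]
  path <- integer(n)
  visited <- rep(FALSE, n)
  path[1] <- start; visited[start] <- TRUE
  for (k in 2:n) {
    d <- dm[path[k - 1], ]
    d[visited] <- Inf
    nxt <- which(d == min(d))
    if (length(nxt) > 1) nxt <- nxt[order(pts[nxt, 2], pts[nxt, 1])]
    path[k] <- nxt[1]
    visited[nxt[1]] <- TRUE
  }
  new_order <- c(inc[path], which(!cen$included))
  cen <- cen[new_order, ]
  new_stereocilia_set(cen, set$pixel_size_nm)
}
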