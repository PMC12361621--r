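# Small numeric helpers shared across the pipeline. Images are numeric
# matrices indexed [row = y, col = x]; continuous pixel coordinates are
# 0-based with the origin at the centre of the top-left pixel, x rightward,
# y downward. Physical coordinates are nanometres (nm = px * pixel_size_nm).

round_to_odd <- function(x) {
  k <- round(x)
  k + (k %% 2 == 0) * ifelse(x >= k, 1, -1)
}

#' Separable Gaussian blur of a matrix
#'
#' Dense zero-padded convolution with a truncated (4 sigma) Gaussian kernel,
#' applied along rows and columns. `sigma = 0` returns the input unchanged.
#'
#' @param img numeric matrix.
#' @param sigma standard deviation in pixels.
#' @return blurred matrix of the same dimensions.
#' @keywords internal
gaussian_blur <- function(img, sigma) {
  stopifnot(is.matrix(img), sigma >= 0)
  if (sigma == 0) return(img)
  op <- function(n) {
    m <- ceiling(4 * sigma)
    k <- stats::dnorm(-m:m, sd = sigma)
    k <- k / sum(k)
    d <- outer(seq_len(n), seq_len(n), "-")
    K <- matrix(0, n, n)
    sel <- abs(d) <= m
    K[sel] <- k[d[sel] + m + 1]
    K
  }
  op(nrow(img)) %*% img %*% t(op(ncol(img)))
}

#' Bilinear sampling of a matrix at continuous pixel coordinates
#'
#' @param img numeric matrix.
#' @param x,y 0-based pixel coordinates (x = column, y = row direction).
#' @return numeric vector; `NA` where (x, y) falls outside the raster.
#' @keywords internal
bilinear_sample <- function(img, x, y) {
  nr <- nrow(img); nc <- ncol(img)
  ok <- x >= 0 & x <= nc - 1 & y >= 0 & y <= nr - 1 & is.finite(x) & is.finite(y)
  out <- rep(NA_real_, length(x))
  if (!any(ok)) return(out)
  xs <- x[ok]; ys <- y[ok]
  x0 <- pmin(floor(xs), nc - 2); y0 <- pmin(floor(ys), nr - 2)
  fx <- xs - x0; fy <- ys - y0
  i00 <- cbind(y0 + 1, x0 + 1)
  v <- img[i00] * (1 - fx) * (1 - fy) +
    img[cbind(y0 + 1, x0 + 2)] * fx * (1 - fy) +
    img[cbind(y0 + 2, x0 + 1)] * (1 - fx) * fy +
    img[cbind(y0 + 2, x0 + 2)] * fx * fy
  out[ok] <- v
  out
}

# Bilinear "splat": spread point masses w at continuous pixel coordinates
# onto the 4 surrounding pixel centres of an nr x nc accumulator.
splat_points <- function(nr, nc, x, y, w) {
  keep <- x > -1 & x < nc & y > -1 & y < nr
  x <- x[keep]; y <- y[keep]; w <- w[keep]
  m <- matrix(0, nr, nc)
  if (!length(x)) return(m)
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  add <- function(ix, iy, ww) {
    sel <- ix >= 0 & ix <= nc - 1 & iy >= 0 & iy <= nr - 1 & ww > 0
    if (!any(sel)) return(invisible())
    lin <- iy[sel] + 1 + ix[sel] * nr
    acc <- rowsum(ww[sel], lin)
    m[as.integer(rownames(acc))] <<- m[as.integer(rownames(acc))] + acc[, 1]
    invisible()
  }
  add(x0,     y0,     w * (1 - fx) * (1 - fy))
  add(x0 + 1, y0,     w * fx * (1 - fy))
  add(x0,     y0 + 1, w * (1 - fx) * fy)
  add(x0 + 1, y0 + 1, w * fx * fy)
  m
}

# 3x3 binary dilation / erosion by matrix shifts (used for mask closing).
shift_mat <- function(m, dy, dx, fill = FALSE) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  ys <- max(1, 1 + dy):min(nr, nr + dy)
  xs <- max(1, 1 + dx):min(nc, nc + dx)
  out[ys, xs] <- m[ys - dy, xs - dx]
  out
}

dilate3 <- function(m) {
  out <- m
  for (dy in -1:1) for (dx in -1:1) {
    if (dy || dx) out <- out | shift_mat(m, dy, dx)
  }
  out
}

erode3 <- function(m) {
  out <- m
  for (dy in -1:1) for (dx in -1:1) {
    if (dy || dx) out <- out & shift_mat(m, dy, dx, fill = TRUE)
  }
  out
}

morph_close <- function(m) erode3(dilate3(m))

# Connected-component labelling (8-connectivity) of a logical matrix.
label_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  idx <- which(mask)
  cur <- 0L
  for (seed in idx) {
    if (lab[seed] != 0L) next
    cur <- cur + 1L
    queue <- seed
    lab[seed] <- cur
    while (length(queue)) {
      p <- queue[[length(queue)]]
      queue <- queue[-length(queue)]
      y <- (p - 1L) %% nr + 1L
      x <- (p - 1L) %/% nr + 1L
      for (dy in -1:1) for (dx in -1:1) {
        yy <- y + dy; xx <- x + dx
        if (yy < 1 || yy > nr || xx < 1 || xx > nc) next
        q <- (xx - 1L) * nr + yy
        if (mask[q] && lab[q] == 0L) {
          lab[q] <- cur
          queue <- c(queue, q)
        }
      }
    }
  }
  list(labels = lab, n = cur)
}

# Vertex of the parabola through (-1, yl), (0, yc), (1, yr); returns the
# sub-sample offset in [-0.5, 0.5] (clamped), 0 for a degenerate fit.
parabolic_offset <- function(yl, yc, yr) {
  den <- 2 * (2 * yc - yl - yr)
  if (!is.finite(den) || abs(den) < .Machine$double.eps * 100) return(0)
  max(-0.5, min(0.5, (yr - yl) / den))
}

#' Prominence (topographic persistence) of local maxima of a 1-D signal
#'
#' A maximum's prominence is its height above the highest saddle connecting
#' it to any higher maximum; the global maximum's prominence is its height
#' above the signal minimum. Plateaus are resolved to their first index.
#'
#' @param y numeric vector.
#' @return data.frame with columns `index` and `prominence`, sorted by index.
#' @keywords internal
peak_prominences <- function(y) {
  n <- length(y)
  if (n == 0) return(data.frame(index = integer(), prominence = numeric()))
  ord <- order(-y, seq_len(n))
  comp <- integer(n)              # component id per processed index, 0 = unseen
  parent <- integer(0)            # union-find over components
  peak_val <- numeric(0)
  peak_idx <- integer(0)
  prom <- numeric(0)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (p in ord) {
    nb <- p + c(-1L, 1L)
    nb <- nb[nb >= 1 & nb <= n]
    nb <- nb[comp[nb] != 0L]
    roots <- unique(vapply(nb, function(q) find(comp[q]), integer(1)))
    if (!length(roots)) {
      k <- length(parent) + 1L
      parent[k] <- k
      peak_val[k] <- y[p]
      peak_idx[k] <- p
      prom[k] <- NA_real_
      comp[p] <- k
    } else if (length(roots) == 1L) {
      comp[p] <- roots
    } else {
      win <- roots[order(-peak_val[roots], peak_idx[roots])][1]
      for (r in setdiff(roots, win)) {
        prom[r] <- peak_val[r] - y[p]
        parent[r] <- win
      }
      comp[p] <- win
    }
  }
  alive <- which(parent == seq_along(parent))
  prom[alive] <- peak_val[alive] - min(y)
  out <- data.frame(index = peak_idx, prominence = prom)
  out[order(out$index), , drop = FALSE]
}

# Global bend of a point chain: rotate onto the principal axis, fit a
# quadratic, and convert its curvature into a total turning angle. Returns
# the turning (radians, >= 0) and the image-frame unit vector toward the
# bend (curvature centre) side; robust to pointwise noise, unlike spline
# curvature or algebraic circle fits on near-linear data.
chain_bend <- function(x, y) {
  cx <- x - mean(x); cy <- y - mean(y)
  ev <- eigen(stats::cov(cbind(cx, cy)), symmetric = TRUE)$vectors
  u <- ev[, 1]; nvec <- c(-u[2], u[1])
  t <- cx * u[1] + cy * u[2]
  w <- cx * nvec[1] + cy * nvec[2]
  fit <- stats::lm.fit(cbind(1, t, t^2), w)$coefficients
  a <- fit[3]
  if (!is.finite(a)) return(list(turning = 0, toward = nvec))
  span <- diff(range(t))
  list(turning = abs(2 * a) * span,
       toward = nvec * if (a >= 0) 1 else -1)
}

# Normalized cross-correlation between two equally sized numeric vectors,
# ignoring positions that are NA in either.
ncc <- function(a, b) {
  ok <- is.finite(a) & is.finite(b)
  a <- a[ok] - mean(a[ok]); b <- b[ok] - mean(b[ok])
  s <- sqrt(sum(a^2) * sum(b^2))
  if (s == 0) return(NA_real_)
  sum(a * b) / s
}
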