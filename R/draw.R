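# Anti-aliased raster primitives.
#
# All drawing uses 0-based pixel coordinates: origin at the top-left corner,
# x rightward, y downward. A canvas is a numeric matrix with rows = y and
# columns = x, values in [0, 1].

blank_canvas <- function(size = CANVAS_SIZE, value = 0) {
  matrix(value, size, size)
}

# Composite a coverage matrix `cov` (values in [0,1]) of gray `value` onto the
# sub-rectangle of img given by 1-based row/col ranges.
composite_patch <- function(img, rows, cols, cov, value) {
  patch <- img[rows, cols, drop = FALSE]
  img[rows, cols] <- patch * (1 - cov) + value * cov
  img
}

# Pixel-center grids over a bounding box (0-based coordinates).
bbox_grid <- function(x0, x1, y0, y1, size) {
  cx0 <- max(0L, floor(x0)); cx1 <- min(size - 1L, ceiling(x1))
  cy0 <- max(0L, floor(y0)); cy1 <- min(size - 1L, ceiling(y1))
  if (cx0 > cx1 || cy0 > cy1) return(NULL)
  list(rows = (cy0:cy1) + 1L, cols = (cx0:cx1) + 1L,
       xg = matrix(rep(cx0:cx1, each = cy1 - cy0 + 1L), cy1 - cy0 + 1L),
       yg = matrix(rep(cy0:cy1, times = cx1 - cx0 + 1L), cy1 - cy0 + 1L))
}

#' Fill an (optionally rotated) ellipse with anti-aliased edges
#' @keywords internal
fill_ellipse <- function(img, cx, cy, rx, ry, value, angle = 0, alpha = 1) {
  rx <- max(rx, 0.4); ry <- max(ry, 0.4)
  r <- max(rx, ry)
  g <- bbox_grid(cx - r - 1, cx + r + 1, cy - r - 1, cy + r + 1, nrow(img))
  if (is.null(g)) return(img)
  dx <- g$xg - cx; dy <- g$yg - cy
  if (angle != 0) {
    ca <- cos(angle); sa <- sin(angle)
    tx <- dx * ca + dy * sa; ty <- -dx * sa + dy * ca
    dx <- tx; dy <- ty
  }
  # approximate signed distance: (|q| - 1) scaled by the smaller radius
  q <- sqrt((dx / rx)^2 + (dy / ry)^2)
  sd <- (q - 1) * min(rx, ry)
  cov <- clamp(0.5 - sd, 0, 1) * alpha
  composite_patch(img, g$rows, g$cols, cov, value)
}

#' Fill a thick line segment (capsule) with anti-aliased edges
#' @keywords internal
fill_capsule <- function(img, x0, y0, x1, y1, radius, value, alpha = 1) {
  radius <- max(radius, 0.4)
  g <- bbox_grid(min(x0, x1) - radius - 1, max(x0, x1) + radius + 1,
                 min(y0, y1) - radius - 1, max(y0, y1) + radius + 1, nrow(img))
  if (is.null(g)) return(img)
  vx <- x1 - x0; vy <- y1 - y0
  len2 <- vx^2 + vy^2
  px <- g$xg - x0; py <- g$yg - y0
  t <- if (len2 > 0) clamp((px * vx + py * vy) / len2, 0, 1) else 0
  dx <- px - t * vx; dy <- py - t * vy
  sd <- sqrt(dx^2 + dy^2) - radius
  cov <- clamp(0.5 - sd, 0, 1) * alpha
  composite_patch(img, g$rows, g$cols, cov, value)
}

#' Fill a simple polygon, anti-aliased by analytic scanline coverage
#'
#' Even-odd fill: every pixel row is sampled by two sub-rows, and within each
#' span the x-coverage of the boundary pixels is computed exactly.
#'
#' @param xs,ys polygon vertices, 0-based pixel coordinates
#' @keywords internal
fill_polygon <- function(img, xs, ys, value, alpha = 1) {
  size <- nrow(img)
  y_lo <- max(0L, floor(min(ys))); y_hi <- min(size - 1L, ceiling(max(ys)))
  if (y_lo > y_hi) return(img)
  nrow_box <- y_hi - y_lo + 1L
  subys <- rep(y_lo:y_hi, each = 2) + c(-0.25, 0.25)
  n <- length(xs)
  x2 <- xs[c(2:n, 1)]; y2 <- ys[c(2:n, 1)]
  rows_all <- integer(0); xi_all <- numeric(0)
  for (e in seq_len(n)) {
    if (ys[e] == y2[e]) next
    ylo <- min(ys[e], y2[e]); yhi <- max(ys[e], y2[e])
    # crossings are the sub-rows in [ylo, yhi); subys is sorted
    i0 <- findInterval(ylo, subys, left.open = TRUE) + 1L
    i1 <- findInterval(yhi, subys, left.open = TRUE)
    if (i0 <= i1) {
      hit <- i0:i1
      xi <- xs[e] + (subys[hit] - ys[e]) * (x2[e] - xs[e]) / (y2[e] - ys[e])
      rows_all <- c(rows_all, hit); xi_all <- c(xi_all, xi)
    }
  }
  if (!length(rows_all)) return(img)
  o <- order(rows_all, xi_all, method = "radix")
  rows_all <- rows_all[o]; xi_all <- xi_all[o]
  pos <- sequence(rle(rows_all)$lengths)
  a_idx <- which(pos %% 2 == 1)
  b_idx <- a_idx + 1L
  ok <- b_idx <= length(xi_all)
  a_idx <- a_idx[ok]; b_idx <- b_idx[ok]
  a <- xi_all[a_idx]; b <- xi_all[b_idx]
  prow <- (rows_all[a_idx] - 1L) %/% 2L + 1L
  k0 <- as.integer(pmax(0, floor(a - 0.5)))
  k1 <- as.integer(pmin(size - 1, ceiling(b + 0.5)))
  keep <- k0 <= k1
  a <- a[keep]; b <- b[keep]; prow <- prow[keep]
  k0 <- k0[keep]; k1 <- k1[keep]
  if (!length(a)) return(img)
  len <- k1 - k0 + 1L
  ks <- sequence(len) - 1L + rep.int(k0, len)
  covx <- pmin(rep.int(b, len), ks + 0.5) - pmax(rep.int(a, len), ks - 0.5)
  covx[covx < 0] <- 0
  covx[covx > 1] <- 1
  # accumulate coverage per pixel (a pixel is visited by up to two sub-rows
  # and by adjacent spans sharing a boundary pixel)
  idx <- rep.int(prow, len) + ks * nrow_box
  o <- sort.int(idx, index.return = TRUE, method = "radix")
  iv <- o$x
  cs <- cumsum(0.5 * covx[o$ix])
  last <- which(c(iv[-1L] != iv[-length(iv)], TRUE))
  tot <- cs[last] - c(0, cs[last[-length(last)]])
  cov <- matrix(0, nrow_box, size)
  cov[iv[last]] <- pmin(tot, 1)
  cov <- cov * alpha
  rows <- (y_lo:y_hi) + 1L
  img[rows, ] <- img[rows, ] * (1 - cov) + value * cov
  img
}

# Mirror a raster horizontally (exact pixel flip).
flip_horizontal <- function(img) img[, rev(seq_len(ncol(img))), drop = FALSE]

# Mirror 0-based x coordinates on a canvas of the given width.
flip_x <- function(x, size = CANVAS_SIZE) (size - 1) - x
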