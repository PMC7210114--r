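# Piecewise-affine image warping on a landmark triangulation.
#
# The triangulation is computed once on the mean landmarks (plus canvas-corner
# anchors so the whole canvas is covered) by the Bowyer-Watson incremental
# Delaunay algorithm; warps then move the triangle vertices while keeping the
# topology fixed, and each output pixel is sampled from the source image
# through the affine map of its containing triangle.

#' Delaunay triangulation of a 2-D point set (Bowyer-Watson)
#'
#' @param pts numeric matrix with columns x, y
#' @return integer matrix, one row per triangle (vertex indices into `pts`)
#' @export
delaunay_triangulation <- function(pts) {
  n <- nrow(pts)
  stopifnot(n >= 3)
  # super-triangle enclosing all points
  cx <- mean(range(pts[, 1])); cy <- mean(range(pts[, 2]))
  # far enough out that only hull triangles with near-degenerate (practically
  # collinear) vertex triples can keep a super vertex inside their circumcircle
  d <- max(diff(range(pts[, 1])), diff(range(pts[, 2]))) * 1e4 + 1e4
  P <- rbind(pts, c(cx - 2 * d, cy - d), c(cx + 2 * d, cy - d), c(cx, cy + 2 * d))
  tris <- matrix(c(n + 1L, n + 2L, n + 3L), 1)
  circum <- function(tri) {
    a <- P[tri[1], ]; b <- P[tri[2], ]; c <- P[tri[3], ]
    dd <- 2 * (a[1] * (b[2] - c[2]) + b[1] * (c[2] - a[2]) + c[1] * (a[2] - b[2]))
    if (abs(dd) < 1e-12) return(c(Inf, Inf, Inf))
    ux <- ((a[1]^2 + a[2]^2) * (b[2] - c[2]) + (b[1]^2 + b[2]^2) * (c[2] - a[2]) +
             (c[1]^2 + c[2]^2) * (a[2] - b[2])) / dd
    uy <- ((a[1]^2 + a[2]^2) * (c[1] - b[1]) + (b[1]^2 + b[2]^2) * (a[1] - c[1]) +
             (c[1]^2 + c[2]^2) * (b[1] - a[1])) / dd
    c(ux, uy, (a[1] - ux)^2 + (a[2] - uy)^2)
  }
  cc <- matrix(circum(tris[1, ]), 1)
  for (i in seq_len(n)) {
    p <- P[i, ]
    bad <- which((p[1] - cc[, 1])^2 + (p[2] - cc[, 2])^2 <= cc[, 3] + 1e-9)
    # boundary of the cavity: edges of bad triangles not shared by two of them
    edges <- NULL
    for (t in bad) {
      tri <- tris[t, ]
      edges <- rbind(edges, tri[c(1, 2)], tri[c(2, 3)], tri[c(3, 1)])
    }
    key <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
    keep <- edges[key %in% names(which(table(key) == 1)), , drop = FALSE]
    tris <- tris[-bad, , drop = FALSE]
    cc <- cc[-bad, , drop = FALSE]
    newt <- cbind(keep, i)
    tris <- rbind(tris, newt)
    cc <- rbind(cc, t(apply(newt, 1, circum)))
  }
  drop_rows <- apply(tris, 1, function(t) any(t > n))
  tris <- tris[!drop_rows, , drop = FALSE]
  storage.mode(tris) <- "integer"
  tris
}

# Canvas corner (and edge-midpoint) anchor points appended to landmark sets so
# the triangulation covers the full canvas.
canvas_anchors <- function(size = CANVAS_SIZE) {
  s <- size - 1
  cbind(x = c(0, s, 0, s, s / 2, s / 2, 0, s),
        y = c(0, 0, s, s, 0, s, s / 2, s / 2))
}

#' Warp an image by piecewise-affine landmark mapping
#'
#' Every output pixel inside a triangle of the destination landmark
#' configuration is bilinearly sampled from the source image at the location
#' given by that triangle's affine map to the source configuration. Canvas
#' anchors are added so the warp is defined everywhere.
#'
#' @param img source raster
#' @param src_pts,dst_pts landmark coordinates (same count and order)
#' @param triangles optional precomputed triangulation over
#'   `rbind(dst-basis, anchors)`; when `NULL`, computed on `dst_pts`
#' @return warped raster of the same size
#' @export
warp_image <- function(img, src_pts, dst_pts, triangles = NULL) {
  stopifnot(nrow(src_pts) == nrow(dst_pts))
  size <- nrow(img)
  anch <- canvas_anchors(size)
  src <- rbind(src_pts, anch)
  dst <- rbind(dst_pts, anch)
  if (is.null(triangles)) triangles <- delaunay_triangulation(dst)
  n_tri <- nrow(triangles)
  # pixels claimed by several triangles (possible when a destination triangle
  # degenerates or folds over a neighbor) go to the triangle that contains
  # them most centrally, which keeps the warp consistent with the inverse
  # per-triangle affine queries
  best <- rep.int(-Inf, size * size)
  sx <- numeric(size * size); sy <- numeric(size * size)
  for (t in seq_len(n_tri)) {
    tri <- triangles[t, ]
    dx <- dst[tri, 1]; dy <- dst[tri, 2]
    det <- (dy[2] - dy[3]) * (dx[1] - dx[3]) + (dx[3] - dx[2]) * (dy[1] - dy[3])
    if (abs(det) < 1e-9) {
      stop("degenerate (collinear) triangle in the destination triangulation")
    }
    cx0 <- max(0L, floor(min(dx))); cx1 <- min(size - 1L, ceiling(max(dx)))
    cy0 <- max(0L, floor(min(dy))); cy1 <- min(size - 1L, ceiling(max(dy)))
    if (cx0 > cx1 || cy0 > cy1) next
    nr <- cy1 - cy0 + 1L; nc <- cx1 - cx0 + 1L
    xg <- rep(cx0:cx1, each = nr)
    yg <- rep.int(cy0:cy1, nc)
    l1 <- ((dy[2] - dy[3]) * (xg - dx[3]) + (dx[3] - dx[2]) * (yg - dy[3])) / det
    l2 <- ((dy[3] - dy[1]) * (xg - dx[3]) + (dx[1] - dx[3]) * (yg - dy[3])) / det
    l3 <- 1 - l1 - l2
    score <- pmin(l1, l2, l3)
    idx <- xg * size + yg + 1L
    todo <- score >= -1e-9 & score > best[idx]
    if (!any(todo)) next
    idx <- idx[todo]
    best[idx] <- score[todo]
    sxs <- src[tri, 1]; sys <- src[tri, 2]
    sx[idx] <- l1[todo] * sxs[1] + l2[todo] * sxs[2] + l3[todo] * sxs[3]
    sy[idx] <- l1[todo] * sys[1] + l2[todo] * sys[2] + l3[todo] * sys[3]
  }
  # pixels missed by numerical gaps fall back to the identity
  out <- img
  hit <- which(best > -Inf)
  if (length(hit)) out[hit] <- sample_bilinear(img, sx[hit], sy[hit])
  out
}
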