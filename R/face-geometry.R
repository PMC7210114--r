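# Parametric face geometry.
#
# A face is assembled from seven elementary parts (hair, face outline, eyes,
# irises, eyebrows, mouth, nose) whose geometry is controlled by 19 named
# parameters, each on a [-5, +5] scale where 0 is the average face and +/-5
# are the extremes. The same geometry engine drives both the cartoon stimuli
# and the procedurally rendered annotated faces; every landmark the package
# reports is an exact control point of the rendered primitives.

#' Names of the 19 facial geometry parameters
#' @return character vector of length 19
#' @export
cartoon_param_names <- function() {
  c("face_aspect_ratio", "face_direction", "assembly_height",
    "hair_length", "hair_thickness",
    "eyebrow_slant", "eyebrow_width", "eyebrow_height",
    "inter_eye_distance", "eye_eccentricity", "eye_size", "iris_size",
    "gaze_direction",
    "nose_base", "nose_altitude",
    "mouth_nose_distance", "mouth_size", "mouth_top", "mouth_bottom")
}

#' Supported view labels
#' @return character vector of the 8 views
#' @export
face_views <- function() {
  c("frontal", "left_half_profile", "right_half_profile",
    "left_profile", "right_profile", "up", "down", "back")
}

N_LANDMARKS <- 95L

# Identities for face-space training are rendered at a reduced scale so that
# landmark excursions of +/- 3 SD along any face-space dimension stay on the
# canvas (reconstruction rejects off-canvas landmarks).
IDENTITY_SCALE <- 0.85

# Number of landmarks per face part (sums to 95).
landmark_schema <- function() {
  c(outline = 25L, hairline = 10L, eye_left = 8L, eye_right = 8L,
    iris_left = 1L, iris_right = 1L, brow_left = 6L, brow_right = 6L,
    nose = 9L, mouth = 12L, interior = 9L)
}

# View-dependent affine factors: `kо`/`ki` are horizontal compressions of the
# outline and of the inner features, `dxi` a lateral shift of inner features,
# `dyi` a vertical shift; `mirror` marks views rendered by flipping the
# corresponding right-side view.
view_params <- function(view) {
  switch(view,
    frontal            = list(ko = 1.00, ki = 1.00, dxi = 0.000, dyi = 0.000,
                              mirror = FALSE, back = FALSE),
    right_half_profile = list(ko = 0.92, ki = 0.78, dxi = 0.055, dyi = 0.000,
                              mirror = FALSE, back = FALSE),
    left_half_profile  = list(base = "right_half_profile", mirror = TRUE),
    right_profile      = list(ko = 0.80, ki = 0.55, dxi = 0.100, dyi = 0.000,
                              mirror = FALSE, back = FALSE),
    left_profile       = list(base = "right_profile", mirror = TRUE),
    up                 = list(ko = 1.00, ki = 0.96, dxi = 0.000, dyi = -0.055,
                              mirror = FALSE, back = FALSE),
    down               = list(ko = 1.00, ki = 0.96, dxi = 0.000, dyi = 0.055,
                              mirror = FALSE, back = FALSE),
    back               = list(ko = 1.00, ki = 1.00, dxi = 0.000, dyi = 0.000,
                              mirror = FALSE, back = TRUE),
    stop("unknown view '", view, "'; supported views: ",
         paste(face_views(), collapse = ", "))
  )
}

# Smooth deformation basis: fixed low-frequency fields whose coefficients give
# each synthetic identity landmark variation beyond the 19 geometry knobs.
N_DEFORM <- 30L
DEFORM_AMPLITUDE <- 2.2  # pixels at unit coefficient

# Smooth shading basis: fixed low-frequency intensity fields whose
# coefficients give each identity texture variation beyond the tone knobs, so
# the appearance covariance of a training set has full rank with healthy
# scales in every retained principal component.
N_SHADE <- 32L
SHADE_AMPLITUDE <- 0.16  # relative intensity modulation at unit coefficient

shade_field <- function(xg, yg, coef, size = CANVAS_SIZE) {
  x <- xg / size; y <- yg / size
  mod <- 0
  for (j in seq_along(coef)) {
    if (coef[j] == 0) next
    fx <- 0.5 + ((j - 1) %% 4)        # cycles per canvas: 0.5 .. 3.5
    fy <- 0.5 + ((j - 1) %/% 4 %% 4)
    ph <- (j * 0.57) %% 1
    mod <- mod + coef[j] * cos(2 * pi * (fx * x + fy * y + ph))
  }
  mod * SHADE_AMPLITUDE / sqrt(max(1, length(coef)))
}

deform_field <- function(pts, coef, size = CANVAS_SIZE) {
  if (is.null(coef) || all(coef == 0)) return(pts)
  x <- pts[, 1] / size; y <- pts[, 2] / size
  dx <- numeric(nrow(pts)); dy <- numeric(nrow(pts))
  for (j in seq_along(coef)) {
    if (coef[j] == 0) next
    fx <- 0.5 + ((j - 1) %% 3)        # cycles per canvas: 0.5, 1.5, 2.5
    fy <- 0.5 + ((j - 1) %/% 3 %% 3)
    phx <- (j * 0.7) %% 1; phy <- (j * 0.41) %% 1
    dx <- dx + coef[j] * cos(2 * pi * (fx * x + fy * y + phx))
    dy <- dy + coef[j] * sin(2 * pi * (fy * x + fx * y + phy))
  }
  s <- DEFORM_AMPLITUDE / sqrt(max(1, length(coef)))
  cbind(pts[, 1] + s * dx, pts[, 2] + s * dy)
}

# Build all control points for one face. `p` holds the 19 geometry parameters
# in [-5, 5]; `deform` an optional coefficient vector for the smooth
# deformation basis. Mirrored (left) views are handled by the caller.
face_geometry <- function(p, view = "frontal", deform = NULL,
                          size = CANVAS_SIZE, scale = 1) {
  stopifnot(length(p) == 19)
  if (any(!is.finite(p)) || any(p < -5 | p > 5)) {
    stop("geometry parameters must be finite and within [-5, 5]")
  }
  vp <- view_params(view)
  if (!is.null(vp$base)) vp <- c(view_params(vp$base), mirror = TRUE)
  u <- p / 5
  S <- size
  cx <- S / 2; cy <- 0.54 * S

  # outline (aspect ratio)
  rx <- 0.30 * S * (1 + 0.22 * u[1]) * vp$ko
  ry <- 0.38 * S * (1 - 0.22 * u[1])

  # inner-feature transform: face direction + assembly height + view
  kxi <- (1 - 0.25 * abs(u[2])) * vp$ki
  dxi <- 0.10 * S * u[2] * vp$ko + vp$dxi * S
  dyi <- -0.07 * S * u[3] + vp$dyi * S
  ix <- function(x) cx + (x - cx) * kxi + dxi
  iy <- function(y) y + dyi

  ang <- seq(0, 2 * pi, length.out = 26)[-26] - pi / 2
  outline <- cbind(cx + rx * cos(ang), cy + ry * sin(ang))

  # hair: rim around the upper outline, clipped below y_clip
  th <- (0.035 + 0.030 * (u[5] + 1)) * S
  hair_scale_x <- 1 + th / rx; hair_scale_y <- 1 + th / ry
  hair <- cbind(cx + (outline[, 1] - cx) * hair_scale_x,
                cy + (outline[, 2] - cy) * hair_scale_y)
  y_clip <- (cy - ry) + (0.30 + 0.30 * (u[4] + 1)) * 2 * ry

  hang <- seq(-pi * 0.76, -pi * 0.24, length.out = 10)
  hairline <- cbind(cx + rx * 0.90 * cos(hang), cy + ry * 0.90 * sin(hang))

  # eyes
  eye_y <- iy(cy - 0.11 * S)
  esep <- 0.125 * S * (1 + 0.8 * u[9])
  es <- 0.045 * S * (1 + 0.45 * u[11])
  erx <- es * (1 + 0.30 * u[10]) * kxi
  ery <- es * (1 - 0.30 * u[10])
  exl <- ix(cx - esep); exr <- ix(cx + esep)

  # irises with lateral gaze, kept inside the eye whites
  ri <- es * (0.42 + 0.18 * u[12])
  ri <- min(ri, 0.85 * min(erx, ery))
  gz <- 0.7 * u[13] * (erx - ri)

  # eyebrows
  brow_y <- eye_y - 0.050 * S - 0.022 * S * u[8] - ery
  bl <- 0.055 * S * (1 + 0.40 * u[7]) * kxi
  ba <- 0.35 * u[6]
  brow_pts <- function(bx, mir) {
    tt <- seq(-1, 1, length.out = 6)
    cbind(bx + tt * bl * cos(ba), brow_y - mir * tt * bl * sin(ba))
  }
  brow_l <- brow_pts(exl, -1)
  brow_r <- brow_pts(exr, +1)

  # nose: triangle from bridge apex to the base
  nose_top <- c(ix(cx), iy(cy - 0.055 * S))
  nlen <- 0.10 * S * (1 + 0.35 * u[15])
  nw <- 0.035 * S * (1 + 0.50 * u[14]) * kxi
  nose_base_y <- nose_top[2] + nlen
  nose <- rbind(
    nose_top,
    c(nose_top[1] - nw, nose_base_y), c(nose_top[1], nose_base_y + 1.5),
    c(nose_top[1] + nw, nose_base_y),
    (nose_top + c(-nw, nlen) / 2), (nose_top + c(nw, nlen) / 2),
    c(nose_top[1], nose_top[2] - 0.02 * S),
    c(nose_top[1], nose_top[2] - 0.04 * S),
    c(nose_top[1], nose_top[2] - 0.06 * S))

  # mouth: upper and lower lip around the mouth center
  mouth_y <- nose_base_y + 0.055 * S * (1 + 0.5 * u[16])
  mw <- 0.070 * S * (1 + 0.45 * u[17]) * kxi
  mt <- 0.013 * S * (1 + 0.60 * u[18])
  mb <- 0.017 * S * (1 + 0.60 * u[19])
  mang <- seq(0, 2 * pi, length.out = 13)[-13]
  mouth <- cbind(ix(cx) + mw * cos(mang),
                 mouth_y + (mt + mb) * 0.8 * sin(mang))

  geom <- list(
    size = S, cx = cx, cy = cy, rx = rx, ry = ry, view = view, vp = vp,
    outline = outline, hair = hair, y_clip = y_clip, hairline = hairline,
    eye = list(l = c(exl, eye_y), r = c(exr, eye_y), rx = erx, ry = ery),
    iris = list(l = c(exl + gz, eye_y), r = c(exr + gz, eye_y), r_px = ri),
    brow = list(l = brow_l, r = brow_r, radius = 0.011 * S),
    nose = nose, mouth = mouth,
    mouth_y = mouth_y, mw = mw, mt = mt, mb = mb
  )

  # apply the per-identity smooth deformation to every control point
  if (!is.null(deform)) {
    geom$outline <- deform_field(geom$outline, deform, S)
    geom$hair <- deform_field(geom$hair, deform, S)
    geom$hairline <- deform_field(geom$hairline, deform, S)
    ec <- deform_field(rbind(geom$eye$l, geom$eye$r), deform, S)
    shift_l <- ec[1, ] - geom$eye$l; shift_r <- ec[2, ] - geom$eye$r
    geom$eye$l <- ec[1, ]; geom$eye$r <- ec[2, ]
    geom$iris$l <- geom$iris$l + shift_l
    geom$iris$r <- geom$iris$r + shift_r
    geom$brow$l <- sweep(geom$brow$l, 2, shift_l, `+`)
    geom$brow$r <- sweep(geom$brow$r, 2, shift_r, `+`)
    geom$nose <- deform_field(geom$nose, deform, S)
    geom$mouth <- deform_field(geom$mouth, deform, S)
  }
  if (scale != 1) geom <- scale_geometry(geom, scale)
  geom$landmarks <- geometry_landmarks(geom)
  geom
}

# Shrink/grow a face geometry about the mirror-symmetric canvas center
# ((S-1)/2 in both axes, so left/right views stay exact pixel mirrors).
scale_geometry <- function(geom, scale) {
  pc <- (geom$size - 1) / 2
  tp <- function(m) {
    if (is.null(dim(m))) m <- matrix(m, 1)
    cbind(pc + (m[, 1] - pc) * scale, pc + (m[, 2] - pc) * scale)
  }
  geom$cx <- pc + (geom$cx - pc) * scale
  geom$cy <- pc + (geom$cy - pc) * scale
  geom$rx <- geom$rx * scale; geom$ry <- geom$ry * scale
  geom$y_clip <- pc + (geom$y_clip - pc) * scale
  geom$outline <- tp(geom$outline); geom$hair <- tp(geom$hair)
  geom$hairline <- tp(geom$hairline)
  geom$eye$l <- as.numeric(tp(geom$eye$l)); geom$eye$r <- as.numeric(tp(geom$eye$r))
  geom$eye$rx <- geom$eye$rx * scale; geom$eye$ry <- geom$eye$ry * scale
  geom$iris$l <- as.numeric(tp(geom$iris$l)); geom$iris$r <- as.numeric(tp(geom$iris$r))
  geom$iris$r_px <- geom$iris$r_px * scale
  geom$brow$l <- tp(geom$brow$l); geom$brow$r <- tp(geom$brow$r)
  geom$brow$radius <- geom$brow$radius * scale
  geom$nose <- tp(geom$nose); geom$mouth <- tp(geom$mouth)
  geom$mouth_y <- pc + (geom$mouth_y - pc) * scale
  geom$mw <- geom$mw * scale; geom$mt <- geom$mt * scale
  geom$mb <- geom$mb * scale
  geom
}

# Landmarks are exact control points of the rendered primitives, in the fixed
# schema of landmark_schema() (95 points).
geometry_landmarks <- function(geom) {
  eang <- seq(0, 2 * pi, length.out = 9)[-9]
  eye_pts <- function(c0) cbind(c0[1] + geom$eye$rx * cos(eang),
                                c0[2] + geom$eye$ry * sin(eang))
  interior <- rbind(
    c(geom$cx, geom$cy - 0.30 * geom$ry),          # forehead center
    c(geom$cx - 0.78 * geom$rx, geom$cy - 0.38 * geom$ry),  # temples
    c(geom$cx + 0.78 * geom$rx, geom$cy - 0.38 * geom$ry),
    c(geom$cx - 0.62 * geom$rx, geom$cy + 0.22 * geom$ry),  # cheeks
    c(geom$cx + 0.62 * geom$rx, geom$cy + 0.22 * geom$ry),
    c(geom$cx - 0.35 * geom$rx, geom$cy + 0.62 * geom$ry),  # jaw
    c(geom$cx + 0.35 * geom$rx, geom$cy + 0.62 * geom$ry),
    c(geom$cx, geom$cy + 0.85 * geom$ry),          # chin
    c(geom$nose[9, 1], geom$nose[9, 2] - 0.05 * geom$size)  # nasion
  )
  lm <- rbind(
    geom$outline, geom$hairline,
    eye_pts(geom$eye$l), eye_pts(geom$eye$r),
    matrix(geom$iris$l, 1), matrix(geom$iris$r, 1),
    geom$brow$l, geom$brow$r,
    geom$nose, geom$mouth, interior
  )
  stopifnot(nrow(lm) == N_LANDMARKS)
  dimnames(lm) <- list(NULL, c("x", "y"))
  lm
}

# Default gray levels of the parts.
default_tones <- function() {
  list(bg = 0, skin = 0.55, hair = 0.25, brow = 0.15, eye_white = 0.90,
       iris = 0.08, nose = 0.42, mouth = 0.22)
}

# Rasterize a face geometry. `texture` optionally holds smooth shading knobs
# (gradient_x, gradient_y, wave_amp) applied inside the face outline.
render_face_geometry <- function(geom, tones = default_tones(),
                                 texture = NULL) {
  S <- geom$size
  img <- blank_canvas(S, tones$bg)
  if (geom$vp$back) {
    # back of the head: hair fills the whole head silhouette
    img <- fill_polygon(img, geom$hair[, 1], geom$hair[, 2], tones$hair)
    return(img)
  }
  img <- fill_polygon(img, geom$hair[, 1], geom$hair[, 2], tones$hair)
  # clip hair below the hair-length line
  yc <- geom$y_clip
  img <- fill_polygon(img, c(-2, S + 1, S + 1, -2), c(yc, yc, S + 1, S + 1),
                      tones$bg)
  img <- fill_polygon(img, geom$outline[, 1], geom$outline[, 2], tones$skin)

  if (!is.null(texture)) {
    xg <- matrix(rep(0:(S - 1), each = S), S)
    yg <- matrix(rep(0:(S - 1), times = S), S)
    q <- sqrt(((xg - geom$cx) / geom$rx)^2 + ((yg - geom$cy) / geom$ry)^2)
    mask <- clamp(0.5 - (q - 0.98) * min(geom$rx, geom$ry), 0, 1)
    mod <- texture$gradient_x * (xg - geom$cx) / S +
      texture$gradient_y * (yg - geom$cy) / S +
      texture$wave_amp * cos(2 * pi * 2.5 * xg / S) *
        cos(2 * pi * 1.5 * yg / S)
    if (!is.null(texture$shading)) {
      mod <- mod + shade_field(xg, yg, texture$shading, S)
    }
    img <- clamp(img * (1 + mask * mod), 0, 1)
  }

  for (side in c("l", "r")) {
    b <- geom$brow[[side]]
    img <- fill_capsule(img, b[1, 1], b[1, 2], b[6, 1], b[6, 2],
                        geom$brow$radius, tones$brow)
    e <- geom$eye[[side]]
    img <- fill_ellipse(img, e[1], e[2], geom$eye$rx, geom$eye$ry,
                        tones$eye_white)
    i0 <- geom$iris[[side]]
    img <- fill_ellipse(img, i0[1], i0[2], geom$iris$r_px, geom$iris$r_px,
                        tones$iris)
  }
  img <- fill_polygon(img, geom$nose[c(1, 2, 3, 4), 1],
                      geom$nose[c(1, 2, 3, 4), 2], tones$nose)
  img <- fill_ellipse(img, mean(geom$mouth[, 1]), geom$mouth_y - geom$mt * 0.4,
                      geom$mw, geom$mt, tones$mouth)
  img <- fill_ellipse(img, mean(geom$mouth[, 1]), geom$mouth_y + geom$mb * 0.7,
                      geom$mw * 0.9, geom$mb, tones$mouth)
  img
}
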