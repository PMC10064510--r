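# Internal geometry and RNG helpers shared across modules.
# Polygons are n x 2 matrices of continuous pixel coordinates (x, y),
# 0-based, origin at the top-left image corner; pixel (i, j) of the image
# matrix covers [i-1, i) x [j-1, j) and has centre (i - 0.5, j - 0.5).

#' @noRd
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  force(code)
}

#' Signed polygon area by the shoelace formula (positive if counter-clockwise
#' in a y-down frame is irrelevant; callers take abs()).
#' @noRd
polygon_area <- function(poly) {
  x <- poly[, 1]
  y <- poly[, 2]
  xn <- c(x[-1], x[1])
  yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

#' Area, centroid and central second moments of a simple polygon, computed
#' from the exact Green's-theorem integrals of a uniform lamina. Used to fit
#' moment ellipses to polygons without rasterizing.
#' @return list(area, cx, cy, mxx, myy, mxy) with central second moments per
#'   unit area (i.e. covariance of the uniform density over the polygon).
#' @noRd
polygon_moments <- function(poly) {
  x <- poly[, 1]
  y <- poly[, 2]
  xn <- c(x[-1], x[1])
  yn <- c(y[-1], y[1])
  cross <- x * yn - xn * y
  a <- sum(cross) / 2
  if (abs(a) < .Machine$double.eps * 100) {
    return(list(area = 0, cx = NA_real_, cy = NA_real_,
                mxx = NA_real_, myy = NA_real_, mxy = NA_real_))
  }
  cx <- sum((x + xn) * cross) / (6 * a)
  cy <- sum((y + yn) * cross) / (6 * a)
  # raw second moments about the origin
  ixx <- sum((x^2 + x * xn + xn^2) * cross) / 12
  iyy <- sum((y^2 + y * yn + yn^2) * cross) / 12
  ixy <- sum((x * yn + 2 * x * y + 2 * xn * yn + xn * y) * cross) / 24
  list(
    area = abs(a), cx = cx, cy = cy,
    mxx = ixx / a - cx^2,
    myy = iyy / a - cy^2,
    mxy = ixy / a - cx * cy
  )
}

#' Moment ellipse of a simple polygon: centre, full major/minor axis lengths
#' and orientation (radians, major axis from +x). For a true ellipse the
#' covariance eigenvalues are (a/2)^2 and (b/2)^2, hence axes = 4*sqrt(lambda).
#' @noRd
polygon_ellipse <- function(poly) {
  m <- polygon_moments(poly)
  if (m$area <= 0) {
    return(list(cx = NA_real_, cy = NA_real_, major = NA_real_,
                minor = NA_real_, angle = NA_real_, area = 0))
  }
  cov <- matrix(c(m$mxx, m$mxy, m$mxy, m$myy), 2, 2)
  e <- eigen(cov, symmetric = TRUE)
  lam <- pmax(e$values, 0)
  v <- e$vectors[, 1]
  list(
    cx = m$cx, cy = m$cy,
    major = 4 * sqrt(lam[1]),
    minor = 4 * sqrt(lam[2]),
    angle = atan2(v[2], v[1]),
    area = m$area
  )
}

#' Vertices of an ellipse as an n-gon in pixel coordinates.
#' @noRd
ellipse_polygon <- function(cx, cy, a, b, theta = 0, n = 64L) {
  t <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  ct <- cos(theta)
  st <- sin(theta)
  ex <- a * cos(t)
  ey <- b * sin(t)
  cbind(cx + ex * ct - ey * st, cy + ex * st + ey * ct)
}

#' Even-odd ray-casting point-in-polygon test.
#' @noRd
point_in_polygon <- function(px, py, poly) {
  x <- poly[, 1]
  y <- poly[, 2]
  n <- length(x)
  j <- n
  inside <- FALSE
  for (i in seq_len(n)) {
    if (((y[i] > py) != (y[j] > py)) &&
        (px < (x[j] - x[i]) * (py - y[i]) / (y[j] - y[i]) + x[i])) {
      inside <- !inside
    }
    j <- i
  }
  inside
}

#' Tight axis-aligned bounds of a polygon as a half-open pixel box.
#' @noRd
polygon_bbox <- function(poly) {
  c(
    x = min(poly[, 1]), y = min(poly[, 2]),
    w = max(poly[, 1]) - min(poly[, 1]),
    h = max(poly[, 2]) - min(poly[, 2])
  )
}

#' @noRd
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Quantize an intensity matrix to 8-bit levels on [0, 1]; rendering is
#' defined to be 8-bit grayscale so that determinism is bit-exact.
#' @noRd
quantize8 <- function(img) {
  round(clamp(img, 0, 1) * 255) / 255
}

#' @noRd
stop_stomapipe <- function(msg, class) {
  stop(structure(
    class = c(class, "stomapipe_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}
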