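# Spherical eye model and chart conventions.
#
# Retinal positions are expressed in eye-centered angular coordinates
# (degrees of visual angle): longitude is temporal-positive along the
# disc-fovea axis, latitude superior-positive, fovea-side pole at the
# origin. The chart is azimuthal-equidistant: a point (lon, lat) lies at
# angular eccentricity sqrt(lon^2 + lat^2) from the fovea, in the
# direction atan2(lat, lon). Areas are measured on a sphere whose radius
# is tied to the mm-per-degree conversion constant.

#' Default retinal scale (mm per degree of visual angle)
#'
#' Conversion between degrees of visual angle and millimetres of retinal
#' arc for the schematic emmetropic eye. The spherical model radius is
#' derived from it as `mm_per_degree * 180 / pi` (about 16.68 mm), so that
#' small angular extents convert to retinal millimetres consistently with
#' the area model.
#'
#' @return A single number, millimetres per degree.
#' @export
rq_mm_per_degree <- function() 0.291

#' Spherical model radius implied by a mm-per-degree scale
#'
#' @param mm_per_degree Retinal scale in mm per degree of visual angle.
#' @return Sphere radius in mm.
#' @export
rq_eye_radius <- function(mm_per_degree = rq_mm_per_degree()) {
  mm_per_degree * 180 / pi
}

# chart (lon, lat in degrees) -> unit vectors on the sphere,
# x = temporal, y = superior, z = out of the posterior pole (fovea at z=1)
rq_chart_to_xyz <- function(p) {
  p <- rbind(p)
  ecc <- sqrt(p[, 1]^2 + p[, 2]^2) * pi / 180
  phi <- atan2(p[, 2], p[, 1])
  phi[ecc == 0] <- 0
  cbind(x = sin(ecc) * cos(phi), y = sin(ecc) * sin(phi), z = cos(ecc))
}

rq_xyz_to_chart <- function(v) {
  v <- rbind(v)
  ecc <- acos(pmin(1, pmax(-1, v[, 3]))) * 180 / pi
  phi <- atan2(v[, 2], v[, 1])
  cbind(lon = ecc * cos(phi), lat = ecc * sin(phi))
}

# geodesic distance in degrees between unit vectors and one unit vector
rq_angular_dist <- function(xyz, center_xyz) {
  d <- xyz %*% center_xyz
  acos(pmin(1, pmax(-1, d))) * 180 / pi
}

#' Stereographic projection of retinal points onto the image plane
#'
#' Azimuthal stereographic (conformal) projection of the spherical eye
#' model onto the plane tangent at the posterior pole, projecting from the
#' antipodal (anterior) point. The fovea maps to the origin; a point at
#' eccentricity theta maps to planar radius `2 R tan(theta / 2)`.
#'
#' @param p Retinal point(s): numeric vector `c(lon, lat)` in degrees, or a
#'   two-column matrix with one point per row.
#' @param eye_radius Sphere radius in mm.
#' @return Matrix with columns `X`, `Y` (mm in the projection plane).
#' @export
project_to_plane <- function(p, eye_radius = rq_eye_radius()) {
  v <- rq_chart_to_xyz(p)
  if (any(v[, 3] <= -1 + 1e-12)) {
    stop("point at the projection antipode cannot be projected")
  }
  s <- 2 * eye_radius / (1 + v[, 3])
  cbind(X = s * v[, 1], Y = s * v[, 2])
}

#' Inverse stereographic projection back to retinal coordinates
#'
#' @param xy Planar point(s) in mm: vector `c(X, Y)` or two-column matrix.
#' @param eye_radius Sphere radius in mm.
#' @return Matrix with columns `lon`, `lat` (degrees).
#' @export
project_from_plane <- function(xy, eye_radius = rq_eye_radius()) {
  xy <- rbind(xy)
  t2 <- (xy[, 1]^2 + xy[, 2]^2) / (4 * eye_radius^2)
  z <- (1 - t2) / (1 + t2)
  s <- 1 / (eye_radius * (1 + t2))
  rq_xyz_to_chart(cbind(xy[, 1] * s, xy[, 2] * s, z))
}

# local area-correction factor: dA_sphere = w(X, Y) dA_plane
rq_plane_weight <- function(X, Y, eye_radius) {
  (1 + (X^2 + Y^2) / (4 * eye_radius^2))^-2
}

# planar points (mm) -> unit sphere vectors
rq_plane_to_xyz <- function(xy, eye_radius) {
  xy <- rbind(xy)
  t2 <- (xy[, 1]^2 + xy[, 2]^2) / (4 * eye_radius^2)
  s <- 1 / (eye_radius * (1 + t2))
  cbind(xy[, 1] * s, xy[, 2] * s, (1 - t2) / (1 + t2))
}

# --- triangle quadrature template -------------------------------------------
# Midpoint (3-point, degree-2) rule on each of n^2 congruent subtriangles.
# Returns the (3 n^2) x 3 matrix of barycentric coordinates; each
# consecutive triple belongs to one subtriangle of area |T| / n^2.
rq_tri_template_env <- new.env(parent = emptyenv())

rq_tri_template <- function(n) {
  key <- as.character(n)
  tpl <- rq_tri_template_env[[key]]
  if (!is.null(tpl)) return(tpl)
  rows <- list()
  for (i in 0:(n - 1)) {
    for (j in 0:(n - 1 - i)) {
      a <- c(i, j); b <- c(i + 1, j); cc <- c(i, j + 1)
      rows[[length(rows) + 1]] <- rbind((a + b) / 2, (b + cc) / 2, (cc + a) / 2)
      if (j < n - 1 - i) { # downward triangle
        d <- c(i + 1, j + 1)
        rows[[length(rows) + 1]] <-
          rbind((b + cc) / 2, (b + d) / 2, (cc + d) / 2)
      }
    }
  }
  ij <- do.call(rbind, rows) / n
  tpl <- cbind(1 - ij[, 1] - ij[, 2], ij[, 1], ij[, 2])
  rq_tri_template_env[[key]] <- tpl
  tpl
}

rq_polygon_check <- function(poly) {
  poly <- rbind(poly)
  if (nrow(poly) < 3 || !all(is.finite(poly))) {
    stop("invalid geometry: polygon needs >= 3 finite vertices")
  }
  poly
}

# simple-polygon check: no two non-adjacent edges properly intersect
rq_polygon_is_simple <- function(poly) {
  n <- nrow(poly)
  if (n <= 3) return(TRUE)
  b <- poly[c(2:n, 1), , drop = FALSE]
  pr <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  adj <- (pr[, 2] == pr[, 1] + 1) | (pr[, 1] == 1 & pr[, 2] == n)
  pr <- pr[!adj, , drop = FALSE]
  p1 <- poly[pr[, 1], , drop = FALSE]; p2 <- b[pr[, 1], , drop = FALSE]
  p3 <- poly[pr[, 2], , drop = FALSE]; p4 <- b[pr[, 2], , drop = FALSE]
  d1 <- (p4[, 1] - p3[, 1]) * (p1[, 2] - p3[, 2]) -
    (p4[, 2] - p3[, 2]) * (p1[, 1] - p3[, 1])
  d2 <- (p4[, 1] - p3[, 1]) * (p2[, 2] - p3[, 2]) -
    (p4[, 2] - p3[, 2]) * (p2[, 1] - p3[, 1])
  d3 <- (p2[, 1] - p1[, 1]) * (p3[, 2] - p1[, 2]) -
    (p2[, 2] - p1[, 2]) * (p3[, 1] - p1[, 1])
  d4 <- (p2[, 1] - p1[, 1]) * (p4[, 2] - p1[, 2]) -
    (p2[, 2] - p1[, 2]) * (p4[, 1] - p1[, 1])
  !any(d1 * d2 < 0 & d3 * d4 < 0)
}

#' Lesion surface area on the spherical eye model
#'
#' Projects the polygon stereographically onto the image plane (edges are
#' interpreted as straight segments in that plane) and integrates the
#' local area-correction factor over the planar polygon, yielding the
#' surface area on the curved retina in mm^2.
#'
#' @param poly Two-column matrix of vertices (`lon`, `lat`, degrees).
#' @param eye_radius Sphere radius in mm; defaults to the radius implied by
#'   [rq_mm_per_degree()].
#' @param check If `TRUE`, reject self-intersecting polygons.
#' @return Surface area in mm^2 (non-negative).
#' @export
polygon_area_mm2 <- function(poly, eye_radius = rq_eye_radius(), check = TRUE) {
  poly <- rq_polygon_check(poly)
  xy <- project_to_plane(poly, eye_radius)
  # degenerate: all vertices coincide
  if (max(abs(sweep(xy, 2, xy[1, ]))) < 1e-12) return(0)
  if (check && !rq_polygon_is_simple(xy)) {
    stop("invalid geometry: polygon is self-intersecting")
  }
  n <- nrow(xy)
  ctr <- colMeans(xy)
  v1 <- xy
  v2 <- xy[c(2:n, 1), , drop = FALSE]
  # signed areas of fan triangles (ctr, v1, v2)
  s <- 0.5 * ((v1[, 1] - ctr[1]) * (v2[, 2] - ctr[2]) -
                (v2[, 1] - ctr[1]) * (v1[, 2] - ctr[2]))
  max_edge <- max(sqrt(rowSums((v2 - v1)^2)),
                  sqrt(rowSums(sweep(v1, 2, ctr)^2)))
  ndiv <- max(1L, min(24L, ceiling(max_edge / (0.2 * eye_radius))))
  tpl <- rq_tri_template(ndiv)
  total <- 0
  for (k in seq_len(n)) {
    if (s[k] == 0) next
    pts <- tpl %*% rbind(ctr, v1[k, ], v2[k, ])
    w <- rq_plane_weight(pts[, 1], pts[, 2], eye_radius)
    # each subtriangle contributes (s / ndiv^2) * mean of its 3 midpoints
    total <- total + (s[k] / ndiv^2) * sum(w) / 3
  }
  abs(total)
}

# Batch polygon areas for many small lesions (level-1 fan quadrature).
# polys: list of two-column chart matrices. Accurate to well under 0.1%
# for lesions up to a few degrees across.
rq_batch_polygon_area <- function(polys, eye_radius = rq_eye_radius()) {
  if (!length(polys)) return(numeric(0))
  out <- numeric(length(polys))
  nv <- vapply(polys, nrow, 1L)
  tpl1 <- rq_tri_template(1L)
  for (n in unique(nv)) {
    idx <- which(nv == n)
    arr <- array(unlist(polys[idx], use.names = FALSE), dim = c(n, 2, length(idx)))
    # project all vertices at once
    flat <- matrix(aperm(arr, c(1, 3, 2)), ncol = 2)
    xy <- project_to_plane(flat, eye_radius)
    X <- matrix(xy[, 1], nrow = n)  # n x m
    Y <- matrix(xy[, 2], nrow = n)
    cx <- colMeans(X); cy <- colMeans(Y)
    X2 <- X[c(2:n, 1), , drop = FALSE]
    Y2 <- Y[c(2:n, 1), , drop = FALSE]
    s <- 0.5 * (sweep(X, 2, cx) * sweep(Y2, 2, cy) -
                  sweep(X2, 2, cx) * sweep(Y, 2, cy))
    acc <- 0
    for (q in 1:3) {
      qx <- tpl1[q, 1] * rep(cx, each = n) + tpl1[q, 2] * as.vector(X) +
        tpl1[q, 3] * as.vector(X2)
      qy <- tpl1[q, 1] * rep(cy, each = n) + tpl1[q, 2] * as.vector(Y) +
        tpl1[q, 3] * as.vector(Y2)
      acc <- acc + rq_plane_weight(qx, qy, eye_radius)
    }
    out[idx] <- abs(colSums(matrix(as.vector(s) * acc / 3, nrow = n)))
  }
  out
}
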