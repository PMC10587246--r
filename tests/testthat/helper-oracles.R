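# Independent oracles: Monte-Carlo geometry checks and brute-force rank
# statistics. These deliberately re-derive the arithmetic (chart/sphere
# conversions, point-in-polygon) rather than calling package internals.

or_chart_to_xyz <- function(p) {
  p <- rbind(p)
  ecc <- sqrt(p[, 1]^2 + p[, 2]^2) * pi / 180
  phi <- atan2(p[, 2], p[, 1])
  phi[ecc == 0] <- 0
  cbind(sin(ecc) * cos(phi), sin(ecc) * sin(phi), cos(ecc))
}

# even-odd ray-crossing point-in-polygon (planar)
or_pip <- function(poly_xy, pts) {
  n <- nrow(poly_xy)
  inside <- rep(FALSE, nrow(pts))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly_xy[i, 1]; yi <- poly_xy[i, 2]
    xj <- poly_xy[j, 1]; yj <- poly_xy[j, 2]
    crosses <- ((yi > pts[, 2]) != (yj > pts[, 2])) &
      (pts[, 1] < (xj - xi) * (pts[, 2] - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

or_plane_project <- function(chart, R) {
  v <- or_chart_to_xyz(chart)
  s <- 2 * R / (1 + v[, 3])
  cbind(s * v[, 1], s * v[, 2])
}

or_plane_to_xyz <- function(xy, R) {
  t2 <- (xy[, 1]^2 + xy[, 2]^2) / (4 * R^2)
  s <- 1 / (R * (1 + t2))
  cbind(xy[, 1] * s, xy[, 2] * s, (1 - t2) / (1 + t2))
}

# Monte-Carlo point-assignment oracle: per-field and outside fractions of
# a lesion polygon, from n random sphere-uniform points inside it.
mc_field_fractions <- function(poly, layout, n = 1e5) {
  R <- layout$eye_radius
  xy <- or_plane_project(poly, R)
  lo <- apply(xy, 2, min); hi <- apply(xy, 2, max)
  pts <- cbind(stats::runif(n, lo[1], hi[1]), stats::runif(n, lo[2], hi[2]))
  keep <- or_pip(xy, pts)
  pts <- pts[keep, , drop = FALSE]
  w <- (1 + (pts[, 1]^2 + pts[, 2]^2) / (4 * R^2))^-2
  v <- or_plane_to_xyz(pts, R)
  centers <- or_chart_to_xyz(cbind(layout$fields$center_lon,
                                   layout$fields$center_lat))
  ang <- acos(pmin(pmax(v %*% t(centers), -1), 1)) * 180 / pi
  nearest <- max.col(-ang, ties.method = "first")
  in_union <- ang[cbind(seq_len(nrow(ang)), nearest)] <=
    layout$field_radius_deg
  wtot <- sum(w)
  frac <- vapply(1:7, function(f) sum(w[in_union & nearest == f]) / wtot, 0)
  list(per_field_fraction = frac, outside_fraction = 1 - sum(frac))
}

# Monte-Carlo spherical-surface integration of a polygon's area:
# uniform sampling on the bounding spherical cap.
mc_polygon_area <- function(poly, R, n = 1e6) {
  ctr <- colMeans(poly)
  vc <- or_chart_to_xyz(ctr)[1, ]
  vv <- or_chart_to_xyz(poly)
  cap_r <- max(acos(pmin(pmax(vv %*% vc, -1), 1))) * 1.05 + 1e-4
  # orthonormal frame at the cap center
  up <- if (abs(vc[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- up - sum(up * vc) * vc; e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(vc[2] * e1[3] - vc[3] * e1[2],
          vc[3] * e1[1] - vc[1] * e1[3],
          vc[1] * e1[2] - vc[2] * e1[1])
  cz <- stats::runif(n, cos(cap_r), 1)
  phi <- stats::runif(n, 0, 2 * pi)
  sz <- sqrt(1 - cz^2)
  v <- outer(cz, vc) + outer(sz * cos(phi), e1) + outer(sz * sin(phi), e2)
  # project to the plane and test against the polygon's planar edges
  s <- 2 * R / (1 + v[, 3])
  pts <- cbind(s * v[, 1], s * v[, 2])
  xy <- or_plane_project(poly, R)
  inside <- or_pip(xy, pts)
  cap_area <- 2 * pi * R^2 * (1 - cos(cap_r))
  cap_area * mean(inside)
}

# brute-force Kruskal-Wallis H from the rank formula with tie correction
kw_H_oracle <- function(groups) {
  x <- unlist(groups, use.names = FALSE)
  g <- rep(seq_along(groups), vapply(groups, length, 1L))
  N <- length(x)
  r <- rank(x)
  rbar <- tapply(r, g, mean)
  ns <- tabulate(g)
  h <- 12 / (N * (N + 1)) * sum(ns * (rbar - (N + 1) / 2)^2)
  ties <- table(x)
  h / (1 - sum(ties^3 - ties) / (N^3 - N))
}

# ---- hand-built fixtures ----------------------------------------------------

make_circle_poly <- function(center, r_deg, n = 24) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(lon = center[1] + r_deg * cos(th), lat = center[2] + r_deg * sin(th))
}

make_test_eye <- function(types = character(0), centers = NULL,
                          radii = 0.4, eye_id = "test", laterality = "OD",
                          disc = c(-15.5, 1.5), flags = list()) {
  k <- length(types)
  radii <- rep_len(radii, k)
  polys <- lapply(seq_len(k), function(i) {
    make_circle_poly(centers[i, ], radii[i])
  })
  fl <- list(poor_quality = FALSE, rvo = FALSE, interfering = FALSE,
             questionable = FALSE, non_dr_abnormality = FALSE)
  fl[names(flags)] <- flags
  structure(
    list(
      eye_id = eye_id, laterality = laterality, disc_center = disc,
      fovea_center = c(0, 0), flags = fl,
      lesions = tibble::tibble(
        lesion_id = seq_len(k), lesion_type = types, poly = polys
      ),
      designed_icdr = NULL
    ),
    class = "eye_record"
  )
}

# an eye firing the hemorrhage 4-2-1 criterion: `per_quadrant` small
# hemorrhages placed well inside every fovea-centered quadrant
make_421_eye <- function(per_quadrant = 25, extra_types = character(0),
                         extra_centers = NULL) {
  lay <- build_field_layout(c(-15.5, 1.5), c(0, 0), "OD")
  offs <- as.matrix(expand.grid(t = seq(3, 11, 2), s = seq(3, 11, 2)))
  centers <- NULL
  for (sgn_t in c(1, -1)) {
    for (sgn_s in c(1, -1)) {
      pts <- t(apply(offs[seq_len(per_quadrant), , drop = FALSE], 1,
                     function(o) {
        lay$fovea_center + sgn_t * o[1] * lay$temporal_dir +
          sgn_s * o[2] * lay$superior_dir
      }))
      centers <- rbind(centers, pts)
    }
  }
  types <- rep("H", nrow(centers))
  if (length(extra_types)) {
    types <- c(types, extra_types)
    centers <- rbind(centers, extra_centers)
  }
  make_test_eye(types, centers, radii = 0.35)
}
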