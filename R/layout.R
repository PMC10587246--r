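# ETDRS seven-standard-field layout built from disc/fovea landmarks.

#' Default tangency table for the seven-field arrangement
#'
#' Placement of field centers relative to the two landmarks, in units of
#' the field radius along the disc-fovea (temporal) axis and its superior
#' perpendicular. The defaults encode the standard ETDRS arrangement:
#' field 1 on the disc, field 2 on the fovea, field 3 temporal to the
#' fovea with its nasal edge at the fovea, and fields 4-7 in the four
#' quadrants around the disc, tangent to the axis lines through the disc
#' center (4/5 superior/inferior temporal, 6/7 superior/inferior nasal).
#'
#' @return A tibble with columns `field`, `anchor` ("disc"/"fovea"),
#'   `along` and `perp` (multiples of the field radius).
#' @export
etdrs_tangency_table <- function() {
  tibble::tibble(
    field = 1:7,
    anchor = c("disc", "fovea", "fovea", "disc", "disc", "disc", "disc"),
    along = c(0, 0, 1, 1, 1, -1, -1),
    perp = c(0, 0, 0, 1, -1, 1, -1)
  )
}

#' Build the ETDRS seven-standard-field layout for one eye
#'
#' Places the seven 30-degree-diameter circular fields from the optic-disc
#' and fovea landmarks. Field membership downstream is by geodesic
#' distance on the spherical model: a point belongs to field `f`'s circle
#' when its angular distance to the field center is at most the field
#' radius. Left-eye (OS) layouts are the longitude mirror image of
#' right-eye (OD) layouts by construction, since the temporal axis is
#' derived from the landmarks themselves.
#'
#' @param disc_center,fovea_center Numeric `c(lon, lat)` in degrees.
#' @param laterality `"OD"` (right) or `"OS"` (left).
#' @param field_radius_deg Field radius in degrees (default 15, i.e.
#'   30-degree-diameter fields).
#' @param mm_per_degree Retinal scale; also fixes the spherical radius.
#' @param tangency Field placement table, see [etdrs_tangency_table()].
#' @return An object of class `field_layout`.
#' @export
build_field_layout <- function(disc_center, fovea_center,
                               laterality = c("OD", "OS"),
                               field_radius_deg = 15,
                               mm_per_degree = rq_mm_per_degree(),
                               tangency = etdrs_tangency_table()) {
  laterality <- match.arg(laterality)
  disc_center <- as.numeric(disc_center)
  fovea_center <- as.numeric(fovea_center)
  sep <- sqrt(sum((disc_center - fovea_center)^2))
  if (!is.finite(sep) || sep < 1e-6) {
    stop("landmark error: disc and fovea centers coincide")
  }
  # temporal = from disc towards (and beyond) the fovea
  temporal <- (fovea_center - disc_center) / sep
  # OD: disc is nasal, i.e. at more negative longitude than the fovea
  if (laterality == "OD" && disc_center[1] >= fovea_center[1]) {
    stop("landmark error: OD disc must be nasal (negative longitude side)")
  }
  if (laterality == "OS" && disc_center[1] <= fovea_center[1]) {
    stop("landmark error: OS disc must be nasal (positive longitude side)")
  }
  superior <- c(-temporal[2], temporal[1])
  if (superior[2] < 0) superior <- -superior
  anchors <- list(disc = disc_center, fovea = fovea_center)
  centers <- t(vapply(seq_len(nrow(tangency)), function(i) {
    anchors[[tangency$anchor[i]]] +
      field_radius_deg * (tangency$along[i] * temporal +
                            tangency$perp[i] * superior)
  }, numeric(2)))
  fields <- tibble::tibble(
    field = tangency$field,
    center_lon = centers[, 1],
    center_lat = centers[, 2],
    radius_deg = field_radius_deg
  )
  structure(
    list(
      fields = fields,
      laterality = laterality,
      mm_per_degree = mm_per_degree,
      eye_radius = rq_eye_radius(mm_per_degree),
      field_radius_deg = field_radius_deg,
      disc_center = disc_center,
      fovea_center = fovea_center,
      temporal_dir = temporal,
      superior_dir = superior,
      centers_xyz = rq_chart_to_xyz(centers)
    ),
    class = "field_layout"
  )
}

#' @export
print.field_layout <- function(x, ...) {
  cat(sprintf(
    "ETDRS 7-field layout (%s), field radius %g deg, %g mm/deg\n",
    x$laterality, x$field_radius_deg, x$mm_per_degree
  ))
  print(x$fields)
  invisible(x)
}

# For unit sphere vectors (n x 3): in-union flag and assigned field.
# Every point of the union is assigned to exactly one field: the nearest
# field center, ties broken towards the lowest field index.
rq_assign_points <- function(layout, xyz) {
  d <- xyz %*% t(layout$centers_xyz)          # cosines, n x 7
  ang <- acos(pmin(pmax(d, -1), 1)) * 180 / pi
  nearest <- max.col(-ang, ties.method = "first")
  in_union <- ang[cbind(seq_len(nrow(ang)), nearest)] <= layout$field_radius_deg
  list(field = nearest, in_union = in_union)
}

# Quadrant of chart points: fovea-centered, axes = disc-fovea axis and its
# perpendicular. 1 = superotemporal, 2 = superonasal, 3 = inferotemporal,
# 4 = inferonasal. Points exactly on an axis count as nasal/inferior.
rq_quadrant_of <- function(layout, chart) {
  chart <- rbind(chart)
  rel <- sweep(chart, 2, layout$fovea_center)
  t_comp <- rel %*% layout$temporal_dir
  s_comp <- rel %*% layout$superior_dir
  ifelse(s_comp > 0, ifelse(t_comp > 0, 1L, 2L), ifelse(t_comp > 0, 3L, 4L))
}

rq_quadrant_names <- function() {
  c("superotemporal", "superonasal", "inferotemporal", "inferonasal")
}

# Planar bounding box (stereographic plane, mm) that covers all 7 circles.
rq_layout_bbox <- function(layout, pad = 1.02) {
  th <- seq(0, 2 * pi, length.out = 97)[-97]
  pts <- do.call(rbind, lapply(seq_len(7), function(f) {
    rq_circle_chart(layout, f, th)
  }))
  xy <- project_to_plane(pts, layout$eye_radius)
  rbind(apply(xy, 2, min), apply(xy, 2, max)) * pad
}

# chart points on the rim of field f (geodesic circle on the sphere)
rq_circle_chart <- function(layout, f, theta) {
  c_xyz <- layout$centers_xyz[f, ]
  r <- layout$field_radius_deg * pi / 180
  # orthonormal frame at the center
  up <- if (abs(c_xyz[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- up - sum(up * c_xyz) * c_xyz
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(
    c_xyz[2] * e1[3] - c_xyz[3] * e1[2],
    c_xyz[3] * e1[1] - c_xyz[1] * e1[3],
    c_xyz[1] * e1[2] - c_xyz[2] * e1[1]
  )
  pts <- cos(r) * matrix(c_xyz, length(theta), 3, byrow = TRUE) +
    sin(r) * (outer(cos(theta), e1) + outer(sin(theta), e2))
  rq_xyz_to_chart(pts)
}

#' Surface area of the seven-field union region
#'
#' Deterministic midpoint quadrature on the stereographic plane with the
#' spherical area-correction weight; a point is in the union when its
#' geodesic distance to at least one field center is within the field
#' radius.
#'
#' @param layout A `field_layout`.
#' @param grid_n Grid resolution per axis (default 400).
#' @return Area in mm^2.
#' @export
layout_union_area <- function(layout, grid_n = 400) {
  bb <- rq_layout_bbox(layout)
  xs <- seq(bb[1, 1], bb[2, 1], length.out = grid_n + 1)
  ys <- seq(bb[1, 2], bb[2, 2], length.out = grid_n + 1)
  xm <- (xs[-1] + xs[-length(xs)]) / 2
  ym <- (ys[-1] + ys[-length(ys)]) / 2
  cell <- diff(xs)[1] * diff(ys)[1]
  pts <- cbind(rep(xm, times = grid_n), rep(ym, each = grid_n))
  xyz <- rq_plane_to_xyz(pts, layout$eye_radius)
  asg <- rq_assign_points(layout, xyz)
  w <- rq_plane_weight(pts[, 1], pts[, 2], layout$eye_radius)
  sum(w[asg$in_union]) * cell
}

#' Export the field layout as a GeoJSON FeatureCollection
#'
#' Each field circle is written as a 64-segment polygon in retinal-degree
#' coordinates (marker `"retinal-degrees"` in the collection metadata).
#'
#' @param layout A `field_layout`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_layout_geojson <- function(layout, path) {
  th <- seq(0, 2 * pi, length.out = 65)
  feats <- lapply(seq_len(7), function(f) {
    ring <- rq_circle_chart(layout, f, th)
    ring[65, ] <- ring[1, ]
    list(
      type = "Feature",
      properties = list(field = f),
      geometry = list(
        type = "Polygon",
        coordinates = list(lapply(seq_len(nrow(ring)), function(i) {
          c(ring[i, 1], ring[i, 2])
        }))
      )
    )
  })
  obj <- list(
    type = "FeatureCollection",
    crs_note = "retinal-degrees",
    laterality = layout$laterality,
    features = feats
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = 10)
  invisible(path)
}
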