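# Fractional polygon-field overlap.
#
# The seven circles overlap; for counting, every point of their union is
# assigned to exactly one field (nearest field center, ties to the lowest
# index), so per-field lesion areas partition the lesion's in-union area.
# With no polygon-clipping dependency available, the overlap integrals are
# evaluated by deterministic midpoint quadrature on the stereographic
# plane with the spherical area weight.

# Shared per-lesion integration: field fractions, outside fraction,
# quadrant fractions (of total lesion mass, clipped to the union), and
# exact surface area. `quad_n` is the quadrature grid resolution.
rq_lesion_assign <- function(poly, layout, quad_n = 96, check = TRUE) {
  poly <- rq_polygon_check(poly)
  R <- layout$eye_radius
  area <- polygon_area_mm2(poly, R, check = check)
  if (area == 0) {
    return(list(
      field_fraction = numeric(7), outside_fraction = 1,
      quadrant_fraction = numeric(4), area_mm2 = 0
    ))
  }
  xy <- project_to_plane(poly, R)
  bb <- rbind(apply(xy, 2, min), apply(xy, 2, max))
  xs <- seq(bb[1, 1], bb[2, 1], length.out = quad_n + 1)
  ys <- seq(bb[1, 2], bb[2, 2], length.out = quad_n + 1)
  xm <- (xs[-1] + xs[-length(xs)]) / 2
  ym <- (ys[-1] + ys[-length(ys)]) / 2
  pts <- cbind(rep(xm, times = quad_n), rep(ym, each = quad_n))
  bnd <- rbind(xy, xy[1, ])
  inside <- mgcv::in.out(bnd, pts)
  if (!any(inside)) {
    # polygon thinner than the grid: fall back to vertex majority
    v_xyz <- rq_chart_to_xyz(poly)
    asg <- rq_assign_points(layout, v_xyz)
    f <- numeric(7)
    if (any(asg$in_union)) {
      tab <- tabulate(asg$field[asg$in_union], 7)
      f <- tab / nrow(poly)
    }
    quad <- tabulate(rq_quadrant_of(layout, poly)[asg$in_union], 4) / nrow(poly)
    return(list(
      field_fraction = f, outside_fraction = 1 - sum(f),
      quadrant_fraction = quad, area_mm2 = area
    ))
  }
  pin <- pts[inside, , drop = FALSE]
  w <- rq_plane_weight(pin[, 1], pin[, 2], R)
  xyz <- rq_plane_to_xyz(pin, R)
  asg <- rq_assign_points(layout, xyz)
  wtot <- sum(w)
  ff <- numeric(7)
  qf <- numeric(4)
  iu <- asg$in_union
  if (any(iu)) {
    for (f in unique(asg$field[iu])) {
      ff[f] <- sum(w[iu & asg$field == f]) / wtot
    }
    quad <- rq_quadrant_of(layout, rq_xyz_to_chart(xyz[iu, , drop = FALSE]))
    wq <- w[iu]
    for (q in unique(quad)) qf[q] <- sum(wq[quad == q]) / wtot
  }
  list(
    field_fraction = ff,
    outside_fraction = 1 - sum(ff),
    quadrant_fraction = qf,
    area_mm2 = area
  )
}

#' Fractional overlap of a lesion polygon with the seven fields
#'
#' Splits the lesion across fields 1-7 and the region outside the
#' seven-field union. Fractions are the share of the lesion's surface
#' area falling in each field's assignment region (nearest field center
#' within the union, ties to the lowest index); per-field areas are the
#' fractions scaled by the lesion's exact surface area, so they always
#' partition it.
#'
#' @param poly Two-column vertex matrix (`lon`, `lat`, degrees).
#' @param layout A `field_layout`.
#' @param quad_n Quadrature grid resolution per axis (default 96).
#' @return A list of class `overlap_result` with `per_field_area` (mm^2,
#'   length 7), `outside_area`, `per_field_fraction`, `outside_fraction`
#'   and `total_area_mm2`.
#' @export
field_overlap <- function(poly, layout, quad_n = 96) {
  a <- rq_lesion_assign(poly, layout, quad_n = quad_n)
  structure(
    list(
      per_field_area = a$field_fraction * a$area_mm2,
      outside_area = a$outside_fraction * a$area_mm2,
      per_field_fraction = a$field_fraction,
      outside_fraction = a$outside_fraction,
      total_area_mm2 = a$area_mm2
    ),
    class = "overlap_result"
  )
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf("lesion area %.4f mm^2; per-field fractions:\n", x$total_area_mm2))
  print(round(stats::setNames(c(x$per_field_fraction, x$outside_fraction),
                              c(paste0("F", 1:7), "outside")), 4))
  invisible(x)
}

# Conservative fast-path test: is the lesion's bounding cap wholly inside
# one field-assignment region (and the union)? Returns the field index or
# NA. `centers_ang` is the vector of angular distances from the lesion's
# bounding-cap center to the 7 field centers, `brad` the cap radius (deg).
rq_fast_field <- function(layout, centers_ang, brad) {
  f <- which.min(centers_ang)
  if (centers_ang[f] + brad > layout$field_radius_deg) return(NA_integer_)
  others <- centers_ang[-f]
  if (all(centers_ang[f] + 2 * brad < others)) f else NA_integer_
}
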