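# Lazily computed shared cohorts for the heavier end-to-end tests.

.fixture_env <- new.env(parent = emptyenv())

# 1000-eye cohort (200 per ICDR level), graded by the engine
graded_cohort_fixture <- function() {
  if (is.null(.fixture_env$graded)) {
    cfg <- cohort_config(eyes_per_level = rep(200L, 5), seed = 101L)
    coh <- generate_cohort(cfg)
    gr <- grade_cohort(coh$eyes, quad_n = 48)
    .fixture_env$graded <- list(cfg = cfg, coh = coh, gr = gr)
  }
  .fixture_env$graded
}

# 2500-eye cohort (500 per level) for distribution calibration; never graded
calibration_cohort_fixture <- function() {
  if (is.null(.fixture_env$calib)) {
    cfg <- cohort_config(eyes_per_level = rep(500L, 5), seed = 202L)
    .fixture_env$calib <- list(cfg = cfg, coh = generate_cohort(cfg))
  }
  .fixture_env$calib
}

# per-eye lesion counts with centers inside the seven-field union, and
# the per-lesion measured areas, for one lesion type
eye_type_measurements <- function(eye, type) {
  pl <- eye$lesions[eye$lesions$lesion_type == type, ]
  if (!nrow(pl)) return(list(count = 0, areas = numeric(0)))
  lay <- build_field_layout(eye$disc_center, eye$fovea_center, eye$laterality)
  ctr <- t(vapply(pl$poly, colMeans, numeric(2)))
  centers <- or_chart_to_xyz(cbind(lay$fields$center_lon,
                                   lay$fields$center_lat))
  ang <- acos(pmin(pmax(or_chart_to_xyz(ctr) %*% t(centers), -1), 1)) * 180 / pi
  in_union <- apply(ang, 1, min) <= lay$field_radius_deg
  list(
    count = sum(in_union),
    areas = retquant:::rq_batch_polygon_area(pl$poly[in_union])
  )
}
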