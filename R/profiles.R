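# Default per-severity lesion distributions.

#' The twelve lesion classes
#'
#' Intraretinal hemorrhage (H), microaneurysm (MA), hard exudate (HE),
#' cotton wool spot (CWS), intraretinal microvascular abnormality (IRMA),
#' venous loop (VL), venous beading (VB), neovascularization elsewhere
#' (NVE) and of the disc (NVD), preretinal/vitreous hemorrhage (PRH/VH),
#' and fibrous proliferation of the disc (PFD) and elsewhere (PFE).
#'
#' @return Character vector of lesion-type codes.
#' @export
rq_lesion_types <- function() {
  c("H", "MA", "HE", "CWS", "IRMA", "VL", "VB",
    "NVE", "NVD", "PRH/VH", "PFD", "PFE")
}

rq_pdr_types <- function() c("NVE", "NVD", "PRH/VH")

#' Default severity profiles (per-level lesion count and area distributions)
#'
#' One row per (ICDR level, lesion type): the expected lesion count within
#' the seven-field region, its standard deviation, and the mean/SD of the
#' per-lesion surface area (mm^2). The defaults encode the published
#' per-ICDR-level distributions of a large multicenter ultra-widefield
#' cohort; level 0 (no DR) is all zeros, level 1 (mild NPDR) has
#' microaneurysms only. Per-lesion area means are total-area means divided
#' by count means; per-lesion area SDs default to the mean (unit
#' coefficient of variation). Fibrous proliferation (PFD/PFE) was not
#' reported and defaults to zero at every level.
#'
#' @return A tibble with columns `level`, `lesion_type`, `mean_count`,
#'   `sd_count`, `mean_area_per_lesion`, `sd_area_per_lesion`.
#' @export
severity_profiles <- function() {
  # per level: list of type = c(mean_count, sd_count, mean_total_area)
  cells <- list(
    `0` = list(),
    `1` = list(MA = c(6.33, 6.51, 0.06)),
    `2` = list(
      VL = c(0.01, 0.09, 0.01), H = c(26.47, 27.57, 1.43),
      MA = c(20.12, 21.90, 0.17), HE = c(39.55, 87.89, 1.79),
      CWS = c(2.21, 4.72, 0.59)
    ),
    `3` = list(
      VL = c(0.04, 0.25, 0.01), H = c(78.67, 65.23, 5.45),
      MA = c(40.86, 36.30, 0.36), HE = c(65.80, 91.01, 1.79),
      CWS = c(3.74, 6.21, 0.84), IRMA = c(0.82, 1.42, 0.19),
      VB = c(0.29, 0.66, 0.19)
    ),
    `4` = list(
      VL = c(0.19, 0.66, 0.03), H = c(40.96, 40.97, 3.11),
      MA = c(27.52, 26.76, 0.22), HE = c(48.64, 99.46, 1.94),
      CWS = c(1.23, 3.51, 0.85), IRMA = c(0.63, 1.51, 0.23),
      `PRH/VH` = c(0.34, 1.40, 1.79), NVE = c(1.79, 6.95, 3.28),
      VB = c(0.23, 0.72, 0.15), NVD = c(0.35, 0.75, 6.05)
    )
  )
  rows <- list()
  for (lev in 0:4) {
    cl <- cells[[as.character(lev)]]
    for (ty in rq_lesion_types()) {
      v <- cl[[ty]]
      if (is.null(v)) v <- c(0, 0, 0)
      mapl <- if (v[1] > 0) v[3] / v[1] else 0
      rows[[length(rows) + 1]] <- tibble::tibble(
        level = lev, lesion_type = ty,
        mean_count = v[1], sd_count = v[2],
        mean_area_per_lesion = mapl, sd_area_per_lesion = mapl
      )
    }
  }
  dplyr::bind_rows(rows)
}

rq_validate_profiles <- function(profiles) {
  need <- c("level", "lesion_type", "mean_count", "sd_count",
            "mean_area_per_lesion", "sd_area_per_lesion")
  if (!all(need %in% names(profiles))) {
    stop("profiles must have columns: ", paste(need, collapse = ", "))
  }
  if (any(!is.finite(profiles$mean_count) | profiles$mean_count < 0) ||
      any(!is.finite(profiles$sd_count) | profiles$sd_count < 0) ||
      any(profiles$mean_area_per_lesion < 0) ||
      any(profiles$sd_area_per_lesion < 0)) {
    stop("invalid dispersion or area parameters: profile means/SDs must be ",
         "finite and non-negative")
  }
  for (lev in 0:4) {
    have <- profiles$lesion_type[profiles$level == lev]
    miss <- setdiff(rq_lesion_types(), have)
    if (length(miss)) {
      stop("profile missing for level ", lev, ": ", paste(miss, collapse = ", "))
    }
  }
  invisible(profiles)
}
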