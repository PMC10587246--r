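# Per-eye fractional lesion frequency and surface area.
#
# A lesion's frequency contribution to a field is its area fraction
# falling in that field's assignment region, so per-field frequencies may
# be non-integer while summing (with the outside mass) to the raw lesion
# count. Most lesions are small and wholly inside one assignment region;
# those take an exact fast path, and only field- or quadrant-straddling
# lesions go through quadrature.

#' Quantify one eye's lesions over the seven fields
#'
#' Computes, per field (1-7) and lesion type, the fractional frequency
#' and surface area (mm^2), plus the mass falling outside the seven-field
#' union (`field = "outside"`). Fibrous proliferation rows (PFD/PFE) are
#' quantified but marked non-reportable. The result carries a quadrant
#' summary as attribute `"quadrants"` (see [quadrant_summary()]).
#'
#' @param eye An `eye_record`.
#' @param layout The eye's `field_layout`; built from the eye's landmarks
#'   when omitted.
#' @param quad_n Quadrature resolution for straddling lesions.
#' @param on_invalid `"drop"` (default) to drop self-intersecting or
#'   degenerate lesion polygons with a warning, `"error"` to fail.
#' @return A tibble of class `lesion_metrics` with columns `eye_id`,
#'   `field`, `lesion_type`, `frequency`, `area_mm2`, `reportable`.
#' @export
quantify_eye <- function(eye, layout = NULL, quad_n = 96,
                         on_invalid = c("drop", "error")) {
  on_invalid <- match.arg(on_invalid)
  if (is.null(layout)) {
    layout <- build_field_layout(eye$disc_center, eye$fovea_center,
                                 eye$laterality)
  }
  geo <- rq_eye_geometry(eye, layout, quad_n, on_invalid)
  tbl <- geo$per_lesion
  if (nrow(tbl) == 0) {
    out <- tibble::tibble(
      eye_id = character(0), field = character(0), lesion_type = character(0),
      frequency = numeric(0), area_mm2 = numeric(0), reportable = logical(0)
    )
  } else {
    long <- list()
    for (f in 1:7) {
      long[[f]] <- tibble::tibble(
        field = paste0("F", f), lesion_type = tbl$lesion_type,
        frequency = tbl$field_fraction[, f],
        area_mm2 = tbl$field_fraction[, f] * tbl$area_mm2
      )
    }
    long[[8]] <- tibble::tibble(
      field = "outside", lesion_type = tbl$lesion_type,
      frequency = tbl$outside_fraction,
      area_mm2 = tbl$outside_fraction * tbl$area_mm2
    )
    out <- dplyr::bind_rows(long)
    out <- dplyr::summarise(
      dplyr::group_by(out, .data$field, .data$lesion_type),
      frequency = sum(.data$frequency), area_mm2 = sum(.data$area_mm2),
      .groups = "drop"
    )
    out <- out[out$frequency > 0 | out$area_mm2 > 0, ]
    out <- tibble::tibble(eye_id = eye$eye_id, out,
                          reportable = !(out$lesion_type %in% c("PFD", "PFE")))
  }
  class(out) <- c("lesion_metrics", class(out))
  attr(out, "quadrants") <- rq_quadrant_table(eye, layout, geo)
  attr(out, "raw_counts") <- geo$raw_counts
  out
}

# per-lesion geometry shared by quantification and grading
rq_eye_geometry <- function(eye, layout, quad_n = 96,
                            on_invalid = c("drop", "error")) {
  on_invalid <- match.arg(on_invalid)
  les <- eye$lesions
  # validate up front so invalid polygons never take the fast path
  if (nrow(les)) {
    bad <- !vapply(seq_len(nrow(les)), function(i) {
      p <- les$poly[[i]]
      is.matrix(p) && nrow(p) >= 3 && all(is.finite(p)) &&
        max(abs(sweep(p, 2, p[1, ]))) > 1e-9 && rq_polygon_is_simple(p)
    }, TRUE)
    if (any(bad)) {
      msg <- sprintf(
        "eye %s: invalid lesion geometry for lesion(s) %s", eye$eye_id,
        paste(les$lesion_id[bad], collapse = ", ")
      )
      if (on_invalid == "error") stop(msg)
      warning(msg, ", dropped", call. = FALSE)
      les <- les[!bad, ]
    }
  }
  n <- nrow(les)
  raw_counts <- table(factor(les$lesion_type, levels = rq_lesion_types()))
  if (n == 0) {
    return(list(
      per_lesion = tibble::tibble(
        lesion_type = character(0),
        field_fraction = matrix(numeric(0), 0, 7),
        outside_fraction = numeric(0),
        quadrant_fraction = matrix(numeric(0), 0, 4),
        area_mm2 = numeric(0)
      ),
      raw_counts = raw_counts
    ))
  }
  # chart bounding data per lesion
  ctr <- t(vapply(les$poly, colMeans, numeric(2)))
  brad <- vapply(seq_len(n), function(i) {
    max(sqrt(rowSums(sweep(les$poly[[i]], 2, ctr[i, ])^2)))
  }, 0)
  ctr_xyz <- rq_chart_to_xyz(ctr)
  dists <- acos(pmin(pmax(ctr_xyz %*% t(layout$centers_xyz), -1), 1)) * 180 / pi
  rel <- sweep(ctr, 2, layout$fovea_center)
  tcomp <- as.vector(rel %*% layout$temporal_dir)
  scomp <- as.vector(rel %*% layout$superior_dir)
  ff <- matrix(0, n, 7)
  of <- numeric(n)
  qf <- matrix(0, n, 4)
  area <- rep(NA_real_, n)
  drop_mask <- rep(FALSE, n)
  fr <- layout$field_radius_deg
  # fast path: lesion bounding cap wholly within one field-assignment
  # region and one quadrant (conservative, chart radius bounds the
  # geodesic radius), or wholly outside the union
  f_near <- max.col(-dists, ties.method = "first")
  dmin <- dists[cbind(seq_len(n), f_near)]
  d2 <- dists
  d2[cbind(seq_len(n), f_near)] <- Inf
  dsec <- do.call(pmin, as.data.frame(d2))
  field_ok <- (dmin + brad <= fr) & (dsec - dmin > 2 * brad)
  quad_ok <- abs(tcomp) > brad & abs(scomp) > brad
  wholly_out <- dmin - brad > fr
  fast_in <- field_ok & quad_ok
  fast <- fast_in | (wholly_out & !fast_in)
  slow <- which(!fast)
  if (any(fast_in)) {
    ff[cbind(which(fast_in), f_near[fast_in])] <- 1
    qs <- rq_quadrant_of(layout, ctr[fast_in, , drop = FALSE])
    qf[cbind(which(fast_in), as.integer(qs))] <- 1
  }
  of[wholly_out & !fast_in] <- 1
  if (any(fast)) {
    area[fast] <- rq_batch_polygon_area(les$poly[fast], layout$eye_radius)
  }
  of[fast] <- 1 - rowSums(ff[fast, , drop = FALSE])
  for (i in slow) {
    res <- tryCatch(
      rq_lesion_assign(les$poly[[i]], layout, quad_n = quad_n),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      msg <- sprintf("eye %s lesion %s (%s): %s", eye$eye_id,
                     les$lesion_id[i], les$lesion_type[i],
                     conditionMessage(res))
      if (on_invalid == "error") stop(msg) else {
        warning(msg, call. = FALSE)
        drop_mask[i] <- TRUE
        next
      }
    }
    ff[i, ] <- res$field_fraction
    of[i] <- res$outside_fraction
    qf[i, ] <- res$quadrant_fraction
    area[i] <- res$area_mm2
  }
  keep <- !drop_mask
  list(
    per_lesion = tibble::tibble(
      lesion_type = les$lesion_type[keep],
      field_fraction = ff[keep, , drop = FALSE],
      outside_fraction = of[keep],
      quadrant_fraction = qf[keep, , drop = FALSE],
      area_mm2 = area[keep]
    ),
    raw_counts = raw_counts
  )
}

rq_quadrant_table <- function(eye, layout, geo, rules = grading_rules()) {
  tbl <- geo$per_lesion
  qn <- rq_quadrant_names()
  h_mass <- ma_mass <- numeric(4)
  vb_pres <- irma_prom <- logical(4)
  if (nrow(tbl)) {
    for (q in 1:4) {
      h_mass[q] <- sum(tbl$quadrant_fraction[tbl$lesion_type == "H", q])
      ma_mass[q] <- sum(tbl$quadrant_fraction[tbl$lesion_type == "MA", q])
      vb <- tbl$lesion_type == "VB"
      vb_pres[q] <- any(tbl$quadrant_fraction[vb, q] >=
                          rules$vb_quadrant_presence)
      ir <- tbl$lesion_type == "IRMA" &
        tbl$area_mm2 >= rules$irma_prominence_mm2
      irma_prom[q] <- any(tbl$quadrant_fraction[ir, q] >=
                            rules$vb_quadrant_presence)
    }
  }
  tibble::tibble(
    quadrant = qn,
    h_count = round_half_up(h_mass, 0),
    ma_count = round_half_up(ma_mass, 0),
    vb_present = vb_pres,
    irma_prominent = irma_prom
  )
}

#' Quadrant summary of grade-relevant lesion configuration
#'
#' Fovea-centered quadrants (axes: disc-fovea axis and its
#' perpendicular), clipped to the seven-field union. Hemorrhage and
#' microaneurysm counts are the quadrant's fractional masses rounded
#' half-up; venous beading and prominent IRMA are presence flags.
#'
#' @param eye An `eye_record`.
#' @param layout Optional `field_layout`.
#' @param rules Grading thresholds, see [grading_rules()].
#' @return A tibble with one row per quadrant.
#' @export
quadrant_summary <- function(eye, layout = NULL, rules = grading_rules()) {
  if (is.null(layout)) {
    layout <- build_field_layout(eye$disc_center, eye$fovea_center,
                                 eye$laterality)
  }
  geo <- rq_eye_geometry(eye, layout)
  rq_quadrant_table(eye, layout, geo, rules)
}

#' Per-eye seven-field totals from a metrics table
#'
#' @param metrics A `lesion_metrics` tibble (one or more eyes, bound
#'   together).
#' @return Tibble with `eye_id`, `lesion_type`, `frequency`, `area_mm2`
#'   summed over fields 1-7 (outside mass excluded).
#' @export
metrics_totals <- function(metrics) {
  m <- metrics[metrics$field != "outside", ]
  dplyr::summarise(
    dplyr::group_by(m, .data$eye_id, .data$lesion_type),
    frequency = sum(.data$frequency), area_mm2 = sum(.data$area_mm2),
    .groups = "drop"
  )
}

#' Remove excluded eyes and account for every exclusion
#'
#' Drops eyes flagged poor-quality, RVO or interfering-pathology (the
#' last also covers ungradable Protocol AA levels 81/85/90 when grades
#' are supplied) and reports counts per reason.
#'
#' @param eyes List of `eye_record`s.
#' @param grades Optional severity-grade tibble with `eye_id`, `aa_level`.
#' @return List with `included` (eye list) and `accounting` (tibble of
#'   `reason`, `n`; reasons `assessed`, the three exclusion reasons, and
#'   `included`).
#' @export
apply_exclusions <- function(eyes, grades = NULL) {
  ids <- vapply(eyes, `[[`, "", "eye_id")
  poor <- vapply(eyes, function(e) isTRUE(e$flags$poor_quality), TRUE)
  rvo <- vapply(eyes, function(e) isTRUE(e$flags$rvo), TRUE) & !poor
  interf <- vapply(eyes, function(e) isTRUE(e$flags$interfering), TRUE)
  if (!is.null(grades)) {
    ung <- grades$eye_id[as.character(grades$aa_level) %in% c("81", "85", "90")]
    interf <- interf | ids %in% ung
  }
  interf <- interf & !poor & !rvo
  keep <- !(poor | rvo | interf)
  list(
    included = eyes[keep],
    accounting = tibble::tibble(
      reason = c("assessed", "poor_quality", "rvo", "interfering", "included"),
      n = c(length(eyes), sum(poor), sum(rvo), sum(interf), sum(keep))
    )
  )
}

#' Per-severity summary of lesion metrics (mean, SD, median, n)
#'
#' Groups seven-field eye totals by severity level on the requested scale
#' and summarises each (level, lesion type, metric) cell. Eyes present in
#' `grades` but absent from `metrics` count as zero for every lesion
#' type. PFD/PFE rows are not reported; empty severity groups yield no
#' rows rather than zeros.
#'
#' @param metrics Combined `lesion_metrics` tibble.
#' @param grades Tibble with `eye_id` and the severity columns `icdr`
#'   and/or `aa_level`.
#' @param scale `"icdr"` or `"aa"`.
#' @param suppress_area_types Lesion types whose area column is reported
#'   as `NA` (venous abnormality areas are often deemed not meaningful);
#'   frequencies are always reported.
#' @return Tibble with `level`, `lesion_type`, `metric`, `mean`, `sd`,
#'   `median`, `n`.
#' @export
summarize_by_severity <- function(metrics, grades, scale = c("icdr", "aa"),
                                  suppress_area_types = NULL) {
  scale <- match.arg(scale)
  col <- if (scale == "icdr") "icdr" else "aa_level"
  if (!col %in% names(grades)) stop("grades lack column ", col)
  g <- grades[!is.na(grades[[col]]), c("eye_id", col)]
  names(g)[2] <- "level"
  tot <- metrics_totals(metrics)
  types <- setdiff(rq_lesion_types(), c("PFD", "PFE"))
  full <- expand.grid(
    eye_id = g$eye_id, lesion_type = types,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  full <- dplyr::left_join(full, tot, by = c("eye_id", "lesion_type"))
  full$frequency[is.na(full$frequency)] <- 0
  full$area_mm2[is.na(full$area_mm2)] <- 0
  full <- dplyr::inner_join(full, g, by = "eye_id")
  out <- list()
  for (metric in c("frequency", "area")) {
    v <- if (metric == "frequency") full$frequency else full$area_mm2
    d <- dplyr::summarise(
      dplyr::group_by(tibble::tibble(level = full$level,
                                     lesion_type = full$lesion_type,
                                     value = v),
                      .data$level, .data$lesion_type),
      mean = mean(.data$value), sd = stats::sd(.data$value),
      median = stats::median(.data$value), n = dplyr::n(),
      .groups = "drop"
    )
    d$metric <- metric
    d$sd[is.na(d$sd) & d$n == 1] <- 0
    if (metric == "area" && length(suppress_area_types)) {
      hide <- d$lesion_type %in% suppress_area_types
      d$mean[hide] <- NA_real_
      d$sd[hide] <- NA_real_
      d$median[hide] <- NA_real_
    }
    out[[metric]] <- d
  }
  res <- dplyr::bind_rows(out)
  res[order(res$lesion_type, res$metric, res$level),
      c("level", "lesion_type", "metric", "mean", "sd", "median", "n")]
}
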