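# Annotation interchange and pipeline orchestration.
#
# Lesions are exchanged as GeoJSON FeatureCollections (one Polygon
# feature per lesion, property `lesion_type`), with coordinates in
# retinal degrees (marker "retinal-degrees" in the collection metadata,
# to avoid any geographic misreading) and a JSON landmarks sidecar.

#' Write one eye's annotations and landmarks
#'
#' @param eye An `eye_record`.
#' @param annotation_path GeoJSON output path.
#' @param landmarks_path Landmarks JSON output path.
#' @return Invisibly, the annotation path.
#' @export
write_eye <- function(eye, annotation_path, landmarks_path) {
  feats <- lapply(seq_len(nrow(eye$lesions)), function(i) {
    poly <- eye$lesions$poly[[i]]
    ring <- rbind(poly, poly[1, ])
    list(
      type = "Feature",
      properties = list(lesion_type = eye$lesions$lesion_type[i],
                        lesion_id = eye$lesions$lesion_id[i]),
      geometry = list(
        type = "Polygon",
        coordinates = list(lapply(seq_len(nrow(ring)), function(r) {
          ring[r, ]
        }))
      )
    )
  })
  jsonlite::write_json(
    list(type = "FeatureCollection", crs_note = "retinal-degrees",
         eye_id = eye$eye_id, features = feats),
    annotation_path, auto_unbox = TRUE, digits = NA
  )
  jsonlite::write_json(
    list(eye_id = eye$eye_id,
         disc_center = eye$disc_center, fovea_center = eye$fovea_center,
         laterality = eye$laterality, flags = eye$flags),
    landmarks_path, auto_unbox = TRUE, digits = NA
  )
  invisible(annotation_path)
}

#' Read one eye from annotation and landmark files
#'
#' @param annotation_path GeoJSON FeatureCollection of lesion polygons.
#' @param landmarks_path Landmarks JSON (disc_center, fovea_center,
#'   laterality, flags).
#' @return An `eye_record`.
#' @export
read_eye <- function(annotation_path, landmarks_path) {
  if (!file.exists(annotation_path)) stop("missing file: ", annotation_path)
  if (!file.exists(landmarks_path)) stop("missing file: ", landmarks_path)
  ann <- jsonlite::read_json(annotation_path)
  lm <- jsonlite::read_json(landmarks_path)
  for (fld in c("disc_center", "fovea_center", "laterality")) {
    if (is.null(lm[[fld]])) stop("missing landmark field: ", fld)
  }
  lat <- as.character(lm$laterality)
  if (!lat %in% c("OD", "OS")) stop("laterality must be OD or OS")
  feats <- ann$features
  types <- character(0)
  polys <- list()
  for (ft in feats) {
    ty <- ft$properties$lesion_type
    if (is.null(ty) || !ty %in% rq_lesion_types()) {
      stop("unknown lesion_type: ", if (is.null(ty)) "<missing>" else ty)
    }
    ring <- ft$geometry$coordinates[[1]]
    m <- do.call(rbind, lapply(ring, function(p) as.numeric(unlist(p))))
    if (nrow(m) >= 2 && all(abs(m[1, ] - m[nrow(m), ]) < 1e-12)) {
      m <- m[-nrow(m), , drop = FALSE]
    }
    if (nrow(m) < 3) stop("polygon with fewer than 3 distinct vertices")
    colnames(m) <- c("lon", "lat")
    types <- c(types, ty)
    polys[[length(polys) + 1]] <- m
  }
  flags <- list(poor_quality = FALSE, rvo = FALSE, interfering = FALSE,
                questionable = FALSE, non_dr_abnormality = FALSE)
  for (nm in names(flags)) {
    if (!is.null(lm$flags[[nm]])) flags[[nm]] <- isTRUE(lm$flags[[nm]])
  }
  structure(
    list(
      eye_id = if (!is.null(ann$eye_id)) as.character(ann$eye_id) else
        sub("\\.geojson$", "", basename(annotation_path)),
      laterality = lat,
      disc_center = as.numeric(unlist(lm$disc_center)),
      fovea_center = as.numeric(unlist(lm$fovea_center)),
      flags = flags,
      lesions = tibble::tibble(
        lesion_id = seq_along(polys),
        lesion_type = types, poly = polys
      ),
      designed_icdr = NULL
    ),
    class = "eye_record"
  )
}

#' Write a cohort to a directory
#'
#' One `<eye_id>.geojson` + `<eye_id>_landmarks.json` pair per eye, plus
#' `truth.csv` when truth records are given.
#'
#' @param eyes List of `eye_record`s.
#' @param dir Output directory (created if needed).
#' @param truth Optional truth tibble from [generate_cohort()].
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(eyes, dir, truth = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (eye in eyes) {
    write_eye(eye,
              file.path(dir, paste0(eye$eye_id, ".geojson")),
              file.path(dir, paste0(eye$eye_id, "_landmarks.json")))
  }
  if (!is.null(truth)) {
    utils::write.csv(truth, file.path(dir, "truth.csv"), row.names = FALSE)
  }
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir Directory of annotation/landmark pairs.
#' @return List with `eyes` and `truth` (NULL when absent).
#' @export
read_cohort <- function(dir) {
  ann <- sort(list.files(dir, pattern = "\\.geojson$", full.names = TRUE))
  eyes <- lapply(ann, function(a) {
    read_eye(a, sub("\\.geojson$", "_landmarks.json", a))
  })
  tf <- file.path(dir, "truth.csv")
  truth <- if (file.exists(tf)) {
    tibble::as_tibble(utils::read.csv(tf, colClasses = c(
      eye_id = "character", designed_aa_level = "character"
    )))
  } else NULL
  list(eyes = eyes, truth = truth)
}

#' Run the full simulate-quantify-grade-stats pipeline
#'
#' Generates (or loads) a cohort, applies exclusions, quantifies and
#' grades every included eye, summarises metrics by severity on both
#' scales, runs the severity comparisons, and writes all outputs as CSV
#' plus a JSON run log. Identical config and seed give identical
#' outputs.
#'
#' @param config A [cohort_config()].
#' @param out_dir Output directory.
#' @param input_dir Optional annotation directory; when given, eyes are
#'   read from disk instead of simulated.
#' @param exclusions Counts `c(poor_quality, rvo, interfering)` injected
#'   before filtering (simulate mode only).
#' @param quad_n Quadrature resolution.
#' @return Invisibly, a list with all in-memory results.
#' @export
run_pipeline <- function(config = cohort_config(), out_dir,
                         input_dir = NULL, exclusions = c(0, 0, 0),
                         quad_n = 96) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)
  if (is.null(input_dir)) {
    coh <- generate_cohort(config)
    eyes <- inject_exclusions(coh$eyes, exclusions[1], exclusions[2],
                              exclusions[3])
    truth <- coh$truth
  } else {
    coh <- read_cohort(input_dir)
    eyes <- coh$eyes
    truth <- coh$truth
  }
  exc <- apply_exclusions(eyes)
  gr <- grade_cohort(exc$included, rules = config$rules, quad_n = quad_n)
  grades <- gr$grades
  metrics <- gr$metrics
  summary_icdr <- summarize_by_severity(metrics, grades, "icdr")
  summary_aa <- summarize_by_severity(metrics, grades, "aa")
  stats_icdr <- severity_stats(metrics, grades, "icdr")
  level_counts <- table(factor(grades$icdr, levels = 0:4))
  shares <- cohort_shares(as.integer(level_counts))
  accounting <- rbind(
    exc$accounting,
    tibble::tibble(reason = paste0("icdr_", 0:4), n = as.integer(level_counts))
  )
  kappa <- NULL
  if (!is.null(truth) && "grader2_icdr" %in% names(truth)) {
    paired <- dplyr::inner_join(grades[grades$gradable, c("eye_id", "icdr")],
                                truth[, c("eye_id", "grader2_icdr")],
                                by = "eye_id")
    if (nrow(paired)) {
      kappa <- cohen_kappa(paired$icdr, paired$grader2_icdr)
    }
  }
  utils::write.csv(metrics, file.path(out_dir, "metrics.csv"),
                   row.names = FALSE)
  utils::write.csv(grades, file.path(out_dir, "grades.csv"),
                   row.names = FALSE)
  utils::write.csv(summary_icdr, file.path(out_dir, "summary_icdr.csv"),
                   row.names = FALSE)
  utils::write.csv(summary_aa, file.path(out_dir, "summary_aa.csv"),
                   row.names = FALSE)
  utils::write.csv(stats_icdr$tests, file.path(out_dir, "stats_icdr.csv"),
                   row.names = FALSE)
  utils::write.csv(stats_icdr$pairwise,
                   file.path(out_dir, "stats_icdr_pairwise.csv"),
                   row.names = FALSE)
  acct <- accounting
  acct$share_pct <- NA_real_
  acct$share_pct[match(paste0("icdr_", 0:4), acct$reason)] <- shares
  utils::write.csv(acct, file.path(out_dir, "accounting.csv"),
                   row.names = FALSE)
  cfg_tmp <- tempfile()
  saveRDS(config[setdiff(names(config), "plans")], cfg_tmp)
  log <- list(
    seed = config$seed,
    config_hash = unname(tools::md5sum(cfg_tmp)),
    n_assessed = length(eyes),
    n_included = length(exc$included),
    kappa = if (is.null(kappa)) NULL else kappa$kappa,
    timestamp_free = TRUE
  )
  unlink(cfg_tmp)
  jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(
    eyes = eyes, truth = truth, grades = grades, metrics = metrics,
    summary_icdr = summary_icdr, summary_aa = summary_aa,
    stats_icdr = stats_icdr, accounting = acct, shares = shares,
    kappa = kappa
  ))
}
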