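# ICDR and DRCR Protocol AA rule engines.
#
# The study's grading was done by trained human graders against the
# ETDRS reference photographs; the full standard-photo comparison cannot
# be formalized from severity tables alone. These engines encode an
# explicit, simplified rule set whose thresholds are configuration
# constants: they are documented conventions, not the study's exact
# internal criteria.

#' Grading thresholds
#'
#' @param h_quadrant_threshold Hemorrhage count per quadrant that the
#'   4-2-1 rule must exceed in all four quadrants (default 20; counts are
#'   fractional quadrant masses rounded half-up).
#' @param irma_prominence_mm2 Surface area (mm^2) above which an IRMA
#'   lesion counts as "prominent" (default 0.05).
#' @param presence_eps Minimum in-union fractional frequency for a lesion
#'   type to count as present (default 0.01).
#' @param vb_quadrant_presence Minimum share of a lesion's mass in a
#'   quadrant for quadrant-level presence (default 0.05).
#' @param aa_field_presence Minimum per-field fractional frequency for a
#'   field to count as involved in the Protocol AA extent tiers
#'   (default 0.5).
#' @param nve_moderate_area_mm2 Total NVE area separating mild from
#'   moderate PDR in the simplified Protocol AA tiers (default 0.5).
#' @return Named list of thresholds.
#' @export
grading_rules <- function(h_quadrant_threshold = 20,
                          irma_prominence_mm2 = 0.05,
                          presence_eps = 0.01,
                          vb_quadrant_presence = 0.05,
                          aa_field_presence = 0.5,
                          nve_moderate_area_mm2 = 0.5) {
  list(
    h_quadrant_threshold = h_quadrant_threshold,
    irma_prominence_mm2 = irma_prominence_mm2,
    presence_eps = presence_eps,
    vb_quadrant_presence = vb_quadrant_presence,
    aa_field_presence = aa_field_presence,
    nve_moderate_area_mm2 = nve_moderate_area_mm2
  )
}

# in-union total frequency per type from a lesion_metrics tibble (one eye)
rq_type_presence <- function(metrics, rules) {
  tot <- metrics_totals(metrics)
  freq <- stats::setNames(rep(0, length(rq_lesion_types())), rq_lesion_types())
  if (nrow(tot)) freq[tot$lesion_type] <- tot$frequency
  list(freq = freq, present = freq > rules$presence_eps)
}

rq_check_gradable <- function(eye) {
  f <- eye$flags
  if (isTRUE(f$poor_quality) || isTRUE(f$interfering) || isTRUE(f$rvo)) {
    reason <- if (isTRUE(f$poor_quality)) "poor image quality"
      else if (isTRUE(f$rvo)) "retinal vein occlusion"
      else "interfering pathology"
    stop("eye ", eye$eye_id, " is not gradable: ", reason)
  }
  invisible(TRUE)
}

# number of 4-2-1 criteria met, with the fired rule ids
rq_421 <- function(quads, rules) {
  fired <- character(0)
  n <- 0
  if (all(quads$h_count > rules$h_quadrant_threshold)) {
    n <- n + 1; fired <- c(fired, "421:hemorrhages_all_quadrants")
  }
  if (sum(quads$vb_present) >= 2) {
    n <- n + 1; fired <- c(fired, "421:venous_beading_2_quadrants")
  }
  if (sum(quads$irma_prominent) >= 1) {
    n <- n + 1; fired <- c(fired, "421:prominent_irma")
  }
  list(n = n, fired = fired)
}

#' Grade an eye on the ICDR scale (0-4)
#'
#' Rule order: proliferative lesions (NVE, NVD, preretinal/vitreous
#' hemorrhage, or fibrous proliferation) give level 4; otherwise a fired
#' 4-2-1 criterion gives 3; otherwise microaneurysms only give 1 (as does
#' a questionable-DR flag); any other DR lesion gives 2; no lesions give
#' 0.
#'
#' @param eye An `eye_record` (must be gradable).
#' @param metrics The eye's `lesion_metrics` (from [quantify_eye()]).
#' @param quads Quadrant summary (from [quadrant_summary()] or the
#'   metrics attribute).
#' @param rules Grading thresholds.
#' @return List with `icdr` (integer) and `rule_trace` (character).
#' @export
grade_icdr <- function(eye, metrics, quads = attr(metrics, "quadrants"),
                       rules = grading_rules()) {
  rq_check_gradable(eye)
  pres <- rq_type_presence(metrics, rules)$present
  if (any(pres[c("NVE", "NVD", "PRH/VH", "PFD", "PFE")])) {
    which_p <- names(which(pres[c("NVE", "NVD", "PRH/VH", "PFD", "PFE")]))
    return(list(icdr = 4L,
                rule_trace = paste0("pdr:", paste(which_p, collapse = "+"))))
  }
  crit <- rq_421(quads, rules)
  if (crit$n >= 1) return(list(icdr = 3L, rule_trace = crit$fired))
  non_ma <- pres[setdiff(names(pres), "MA")]
  if (pres[["MA"]] && !any(non_ma)) {
    return(list(icdr = 1L, rule_trace = "npdr:ma_only"))
  }
  if (any(non_ma)) {
    return(list(icdr = 2L, rule_trace = paste0(
      "npdr:lesions_", paste(names(which(non_ma)), collapse = "+"))))
  }
  if (isTRUE(eye$flags$questionable)) {
    return(list(icdr = 1L, rule_trace = "npdr:questionable"))
  }
  list(icdr = 0L, rule_trace = "no_dr")
}

#' Grade an eye on the DRCR Protocol AA scale
#'
#' Simplified deterministic tier table. Non-proliferative tiers are keyed
#' to the number of fields 2-7 with involvement at the extent threshold
#' (35: at most 2 fields; 43: 3-4; 47: 5-6) and to the 4-2-1 criteria
#' count (53: one criterion; 53E: two or more). Proliferative tiers: 60
#' inactive (fibrous proliferation only), 61 mild (small NVE), 65
#' moderate (larger NVE), 71/75 high risk (NVD, or NVE with
#' preretinal/vitreous hemorrhage, or such hemorrhage alone). Ungradable
#' eyes return 81/85/90 by failure reason.
#'
#' @inheritParams grade_icdr
#' @return List with `aa_level` (character) and `rule_trace`.
#' @export
grade_protocol_aa <- function(eye, metrics, quads = attr(metrics, "quadrants"),
                              rules = grading_rules()) {
  f <- eye$flags
  if (isTRUE(f$poor_quality)) {
    return(list(aa_level = "90", rule_trace = "cannot_grade:poor_quality"))
  }
  if (isTRUE(f$interfering)) {
    return(list(aa_level = "85", rule_trace = "cannot_grade:interfering"))
  }
  if (isTRUE(f$rvo)) {
    return(list(aa_level = "81", rule_trace = "cannot_grade:rvo"))
  }
  tp <- rq_type_presence(metrics, rules)
  pres <- tp$present
  nvd <- pres[["NVD"]]; nve <- pres[["NVE"]]; prh <- pres[["PRH/VH"]]
  fib <- pres[["PFD"]] || pres[["PFE"]]
  if (nvd || nve || prh || fib) {
    if (nvd || (nve && prh) || (prh && !nve && !nvd)) {
      return(list(aa_level = "71/75", rule_trace = "pdr:high_risk"))
    }
    if (nve) {
      tot <- metrics_totals(metrics)
      nve_area <- sum(tot$area_mm2[tot$lesion_type == "NVE"])
      if (nve_area >= rules$nve_moderate_area_mm2) {
        return(list(aa_level = "65", rule_trace = "pdr:moderate_nve"))
      }
      return(list(aa_level = "61", rule_trace = "pdr:mild_nve"))
    }
    return(list(aa_level = "60", rule_trace = "pdr:inactive_fibrosis"))
  }
  crit <- rq_421(quads, rules)
  if (crit$n >= 2) return(list(aa_level = "53E", rule_trace = crit$fired))
  if (crit$n == 1) return(list(aa_level = "53", rule_trace = crit$fired))
  non_ma <- pres[setdiff(names(pres), "MA")]
  if (any(non_ma)) {
    # extent: fields 2-7 with any DR-lesion involvement at threshold
    m <- metrics[metrics$field %in% paste0("F", 2:7), ]
    by_field <- dplyr::summarise(
      dplyr::group_by(m, .data$field), freq = sum(.data$frequency),
      .groups = "drop"
    )
    nf <- sum(by_field$freq >= rules$aa_field_presence)
    lvl <- if (nf <= 2) "35" else if (nf <= 4) "43" else "47"
    return(list(aa_level = lvl,
                rule_trace = sprintf("npdr:extent_%d_fields", nf)))
  }
  if (pres[["MA"]]) return(list(aa_level = "20", rule_trace = "ma_only"))
  if (isTRUE(f$questionable)) {
    return(list(aa_level = "14", rule_trace = "questionable"))
  }
  if (isTRUE(f$non_dr_abnormality)) {
    return(list(aa_level = "12", rule_trace = "non_dr_abnormality"))
  }
  list(aa_level = "10", rule_trace = "dr_absent")
}

#' ICDR level compatible with a Protocol AA level
#'
#' The category mapping used for scale-consistency checks and designed
#' truth: 0 with {10, 12}; 1 with {14, 15, 20}; 2 with {35, 43, 47};
#' 3 with {53, 53E}; 4 with {60, 61, 65, 71/75}.
#'
#' @param icdr Integer vector 0-4.
#' @param aa_level Character vector of Protocol AA levels.
#' @return Logical vector.
#' @export
icdr_aa_consistent <- function(icdr, aa_level) {
  sets <- list(
    `0` = c("10", "12"), `1` = c("14", "15", "20"),
    `2` = c("35", "43", "47"), `3` = c("53", "53E"),
    `4` = c("60", "61", "65", "71", "75", "71/75")
  )
  mapply(function(i, a) a %in% sets[[as.character(i)]], icdr,
         as.character(aa_level))
}

#' Grade every eye in a cohort on both scales
#'
#' @param eyes List of `eye_record`s.
#' @param rules Grading thresholds.
#' @param quad_n Quadrature resolution passed to [quantify_eye()].
#' @return List with `grades` (tibble: `eye_id`, `icdr`, `aa_level`,
#'   `gradable`, `rule_trace`) and `metrics` (combined `lesion_metrics`).
#' @export
grade_cohort <- function(eyes, rules = grading_rules(), quad_n = 96) {
  rows <- vector("list", length(eyes))
  mets <- vector("list", length(eyes))
  for (i in seq_along(eyes)) {
    eye <- eyes[[i]]
    layout <- build_field_layout(eye$disc_center, eye$fovea_center,
                                 eye$laterality)
    m <- quantify_eye(eye, layout, quad_n = quad_n)
    mets[[i]] <- m
    fl <- eye$flags
    if (isTRUE(fl$poor_quality) || isTRUE(fl$interfering) || isTRUE(fl$rvo)) {
      aa <- grade_protocol_aa(eye, m, rules = rules)
      rows[[i]] <- tibble::tibble(
        eye_id = eye$eye_id, icdr = NA_integer_, aa_level = aa$aa_level,
        gradable = FALSE, rule_trace = paste(aa$rule_trace, collapse = ";")
      )
      next
    }
    quads <- attr(m, "quadrants")
    gi <- grade_icdr(eye, m, quads, rules)
    ga <- grade_protocol_aa(eye, m, quads, rules)
    rows[[i]] <- tibble::tibble(
      eye_id = eye$eye_id, icdr = gi$icdr, aa_level = ga$aa_level,
      gradable = TRUE,
      rule_trace = paste(unique(c(gi$rule_trace, ga$rule_trace)),
                         collapse = ";")
    )
  }
  list(grades = dplyr::bind_rows(rows), metrics = dplyr::bind_rows(mets))
}

#' Contingency table and kappa between two grade sets
#'
#' @param grades_a,grades_b Tibbles with `eye_id` and a severity column
#'   (`icdr` by default).
#' @param column Severity column to compare.
#' @return List with `table` (k x k contingency) and `kappa`
#'   (a [cohen_kappa()] result).
#' @export
concordance <- function(grades_a, grades_b, column = "icdr") {
  if (!setequal(grades_a$eye_id, grades_b$eye_id)) {
    stop("mismatched eye sets between graders")
  }
  b <- grades_b[match(grades_a$eye_id, grades_b$eye_id), ]
  la <- grades_a[[column]]
  lb <- b[[column]]
  lev <- sort(unique(c(la, lb)))
  tab <- table(factor(la, levels = lev), factor(lb, levels = lev))
  list(table = tab, kappa = cohen_kappa(la, lb))
}
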