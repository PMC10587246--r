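lay <- build_field_layout(c(-15.5, 1.5), c(0, 0), "OD")

test_that("an eye without lesions quantifies to an empty (all-zero) table", {
  eye <- make_test_eye()
  m <- quantify_eye(eye, lay)
  expect_equal(nrow(m), 0)
  quads <- attr(m, "quadrants")
  expect_equal(quads$h_count, rep(0, 4))
  expect_false(any(quads$vb_present))
})

test_that("a single contained MA contributes frequency 1 and its own area", {
  eye <- make_test_eye("MA", rbind(c(2, 1)), radii = 0.2)
  m <- quantify_eye(eye, lay)
  tot <- metrics_totals(m)
  expect_equal(tot$frequency, 1, tolerance = 1e-9)
  a_true <- polygon_area_mm2(eye$lesions$poly[[1]])
  expect_equal(tot$area_mm2, a_true, tolerance = 1e-9)
  expect_equal(m$field[m$frequency > 0], "F2")
})

test_that("a lesion straddling F2/F3 splits its count to match the MC oracle", {
  eye <- make_test_eye("H", rbind(c(7.4, 0)), radii = 2)
  m <- quantify_eye(eye, lay)
  f2 <- m$frequency[m$field == "F2"]
  f3 <- m$frequency[m$field == "F3"]
  expect_gt(f2, 0.2); expect_gt(f3, 0.2)
  mc <- mc_field_fractions(eye$lesions$poly[[1]], lay, 1e5)
  expect_lt(abs(f2 - mc$per_field_fraction[2]), 0.01)
  expect_lt(abs(f3 - mc$per_field_fraction[3]), 0.01)
  expect_equal(f2 + f3, sum(m$frequency), tolerance = 1e-9)
})

test_that("fractional frequencies conserve the raw lesion count", {
  cfg <- cohort_config(eyes_per_level = c(0, 0, 3, 3, 3), seed = 61)
  coh <- generate_cohort(cfg)
  for (e in coh$eyes) {
    m <- quantify_eye(e, quad_n = 48)
    raw <- attr(m, "raw_counts")
    tot <- tapply(m$frequency, m$lesion_type, sum) # includes outside rows
    for (ty in names(tot)) {
      expect_lt(abs(tot[[ty]] - raw[[ty]]), 1e-6)
    }
  }
})

test_that("adding a lesion never decreases any total metric", {
  eye1 <- make_test_eye(c("H", "MA"), rbind(c(3, 2), c(-4, 5)), radii = 0.5)
  eye2 <- make_test_eye(c("H", "MA", "HE"),
                        rbind(c(3, 2), c(-4, 5), c(6, -6)), radii = 0.5)
  t1 <- metrics_totals(quantify_eye(eye1, lay))
  t2 <- metrics_totals(quantify_eye(eye2, lay))
  j <- merge(t1, t2, by = "lesion_type", all = TRUE)
  j[is.na(j)] <- 0
  expect_true(all(j$frequency.y >= j$frequency.x - 1e-12))
  expect_true(all(j$area_mm2.y >= j$area_mm2.x - 1e-12))
})

test_that("fibrous proliferation is quantified but flagged non-reportable", {
  eye <- make_test_eye(c("PFD", "MA"), rbind(c(-15.5, 1.5), c(2, 2)),
                       radii = c(1, 0.2))
  m <- quantify_eye(eye, lay)
  expect_false(any(m$reportable[m$lesion_type == "PFD"]))
  expect_true(all(m$reportable[m$lesion_type == "MA"]))
  expect_gt(sum(m$frequency[m$lesion_type == "PFD"]), 0.9)
})

test_that("invalid lesion polygons are dropped with a warning or raise", {
  bow <- cbind(c(0, 1, 1, 0), c(0, 1, 0, 1)) + 3
  eye <- make_test_eye("MA", rbind(c(2, 1)), radii = 0.2)
  eye$lesions <- dplyr::bind_rows(
    eye$lesions,
    tibble::tibble(lesion_id = 2L, lesion_type = "H", poly = list(bow))
  )
  expect_warning(m <- quantify_eye(eye, lay), "invalid lesion geometry")
  expect_false("H" %in% m$lesion_type)
  expect_error(quantify_eye(eye, lay, on_invalid = "error"),
               "invalid lesion geometry")
})

test_that("exclusion filtering keeps the accounting in balance", {
  cfg <- cohort_config(eyes_per_level = c(2, 2, 2, 2, 2), seed = 62)
  coh <- generate_cohort(cfg)
  set.seed(2)
  eyes <- inject_exclusions(coh$eyes, 2, 1, 1)
  res <- apply_exclusions(eyes)
  acc <- res$accounting
  n <- function(r) acc$n[acc$reason == r]
  expect_equal(n("assessed"), 10)
  expect_equal(n("included"), 6)
  expect_equal(n("assessed"),
               n("included") + n("poor_quality") + n("rvo") + n("interfering"))
  # no flags: identity
  res0 <- apply_exclusions(coh$eyes)
  expect_length(res0$included, 10)
  # all flagged: empty cohort, accounting still sums
  eyes_all <- inject_exclusions(coh$eyes, 10, 0, 0)
  resa <- apply_exclusions(eyes_all)
  expect_length(resa$included, 0)
  expect_equal(resa$accounting$n[resa$accounting$reason == "poor_quality"], 10)
})

test_that("severity summaries behave under singletons and duplication", {
  eyes <- list(
    make_test_eye("MA", rbind(c(2, 1)), radii = 0.3, eye_id = "a"),
    make_test_eye(c("H", "H"), rbind(c(3, 2), c(-4, 4)), radii = 0.4,
                  eye_id = "b")
  )
  metrics <- dplyr::bind_rows(lapply(eyes, quantify_eye, layout = lay))
  grades <- tibble::tibble(eye_id = c("a", "b"), icdr = c(1L, 2L))
  s <- summarize_by_severity(metrics, grades, "icdr")
  ma <- s[s$lesion_type == "MA" & s$metric == "frequency" & s$level == 1, ]
  expect_equal(ma$mean, 1, tolerance = 1e-9)
  expect_equal(ma$sd, 0)
  expect_equal(ma$n, 1L)
  expect_false(any(s$lesion_type %in% c("PFD", "PFE")))
  # duplicating every eye leaves means and medians unchanged
  metrics2 <- metrics
  metrics2$eye_id <- paste0(metrics2$eye_id, "dup")
  grades2 <- grades; grades2$eye_id <- paste0(grades2$eye_id, "dup")
  sdup <- summarize_by_severity(rbind(metrics, metrics2),
                                rbind(grades, grades2), "icdr")
  j <- merge(s, sdup, by = c("level", "lesion_type", "metric"))
  expect_equal(j$mean.x, j$mean.y, tolerance = 1e-12)
  expect_equal(j$median.x, j$median.y, tolerance = 1e-12)
  expect_equal(j$n.y, 2L * j$n.x)
  # venous area suppression is a reporting option only
  ssup <- summarize_by_severity(metrics, grades, "icdr",
                                suppress_area_types = c("VB", "VL"))
  expect_true(all(is.na(
    ssup$mean[ssup$metric == "area" & ssup$lesion_type %in% c("VB", "VL")]
  )))
})
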