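lay <- build_field_layout(c(-15.5, 1.5), c(0, 0), "OD")

grade_one <- function(eye) {
  m <- quantify_eye(eye, lay)
  list(
    icdr = grade_icdr(eye, m),
    aa = grade_protocol_aa(eye, m),
    m = m
  )
}

test_that("no lesions grade as no DR on both scales", {
  g <- grade_one(make_test_eye())
  expect_equal(g$icdr$icdr, 0L)
  expect_equal(g$aa$aa_level, "10")
  expect_equal(g$icdr$rule_trace, "no_dr")
})

test_that("microaneurysms only grade mild NPDR / level 20 at any count", {
  for (k in c(1, 7)) {
    centers <- cbind(runif(k, -8, 8), runif(k, -8, 8))
    g <- grade_one(make_test_eye(rep("MA", k), centers, radii = 0.2))
    expect_equal(g$icdr$icdr, 1L)
    expect_equal(g$aa$aa_level, "20")
  }
})

test_that("any non-MA lesion lifts the grade to moderate NPDR", {
  g <- grade_one(make_test_eye(c("MA", "HE"), rbind(c(2, 2), c(-5, 3)),
                               radii = 0.4))
  expect_equal(g$icdr$icdr, 2L)
  expect_true(g$aa$aa_level %in% c("35", "43", "47"))
})

test_that("the 4-2-1 hemorrhage rule fires severe NPDR, neovascularization fires PDR", {
  eye421 <- make_421_eye(25)
  g <- grade_one(eye421)
  expect_equal(g$icdr$icdr, 3L)
  expect_true(any(grepl("hemorrhages", g$icdr$rule_trace)))
  expect_true(g$aa$aa_level %in% c("53", "53E"))
  # adding one NVE escalates to PDR
  eye_pdr <- make_421_eye(25, extra_types = "NVE",
                          extra_centers = rbind(c(18, 8)))
  g2 <- grade_one(eye_pdr)
  expect_equal(g2$icdr$icdr, 4L)
  # 21 per quadrant is just over threshold; 20 is not
  g20 <- grade_one(make_421_eye(20))
  expect_equal(g20$icdr$icdr, 2L)
  g21 <- grade_one(make_421_eye(21))
  expect_equal(g21$icdr$icdr, 3L)
})

test_that("proliferative tiers follow the simplified Protocol AA table", {
  # NVD with preretinal hemorrhage: high risk
  g <- grade_one(make_test_eye(c("NVD", "PRH/VH"),
                               rbind(c(-15.5, 1.5), c(5, 5)), radii = 1))
  expect_equal(g$aa$aa_level, "71/75")
  expect_equal(g$icdr$icdr, 4L)
  # small NVE alone: mild PDR
  g2 <- grade_one(make_test_eye("NVE", rbind(c(10, 8)), radii = 0.5))
  expect_equal(g2$aa$aa_level, "61")
  # large NVE alone: moderate PDR
  g3 <- grade_one(make_test_eye("NVE", rbind(c(10, 8)), radii = 3))
  expect_equal(g3$aa$aa_level, "65")
  # fibrous proliferation alone: inactive PDR
  g4 <- grade_one(make_test_eye("PFD", rbind(c(-15.5, 1.5)), radii = 1))
  expect_equal(g4$aa$aa_level, "60")
  expect_equal(g4$icdr$icdr, 4L)
})

test_that("questionable DR maps into the mild group; flags drive 81/85/90", {
  gq <- grade_one(make_test_eye(flags = list(questionable = TRUE)))
  expect_equal(gq$icdr$icdr, 1L)
  expect_equal(gq$aa$aa_level, "14")
  eye_bad <- make_test_eye(flags = list(poor_quality = TRUE))
  m <- quantify_eye(eye_bad, lay)
  expect_error(grade_icdr(eye_bad, m), "not gradable")
  expect_equal(grade_protocol_aa(eye_bad, m)$aa_level, "90")
  eye_int <- make_test_eye(flags = list(interfering = TRUE))
  expect_equal(grade_protocol_aa(eye_int, quantify_eye(eye_int, lay))$aa_level,
               "85")
})

test_that("grading is deterministic and monotone under lesion addition", {
  eye <- make_421_eye(23)
  g1 <- grade_one(eye)
  g2 <- grade_one(eye)
  expect_identical(g1$icdr, g2$icdr)
  expect_identical(g1$aa, g2$aa)
  # adding lesions can only escalate: MA-only -> +HE -> +NVE
  e1 <- make_test_eye("MA", rbind(c(2, 2)), radii = 0.3)
  e2 <- make_test_eye(c("MA", "HE"), rbind(c(2, 2), c(5, -4)), radii = 0.3)
  e3 <- make_test_eye(c("MA", "HE", "NVE"),
                      rbind(c(2, 2), c(5, -4), c(10, 6)), radii = 0.3)
  gr <- vapply(list(e1, e2, e3), function(e) grade_one(e)$icdr$icdr, 0L)
  expect_true(all(diff(gr) >= 0))
})

test_that("engine ICDR/AA pairs respect the scale-consistency mapping", {
  cfg <- cohort_config(eyes_per_level = c(3, 3, 3, 3, 3), seed = 71)
  coh <- generate_cohort(cfg)
  gr <- grade_cohort(coh$eyes, quad_n = 48)
  expect_true(all(icdr_aa_consistent(gr$grades$icdr, gr$grades$aa_level)))
  expect_true(all(nzchar(gr$grades$rule_trace)))
})

test_that("concordance builds the contingency table and kappa", {
  a <- tibble::tibble(eye_id = letters[1:6], icdr = c(0, 1, 2, 3, 4, 2))
  cc <- concordance(a, a)
  expect_true(all(cc$table[row(cc$table) != col(cc$table)] == 0))
  expect_equal(cc$kappa$kappa, 1)
  b <- a; b$icdr <- c(1, 2, 3, 4, 0, 3)
  cc2 <- concordance(a, b)
  expect_equal(sum(diag(cc2$table)), 0)
  expect_error(concordance(a, b[-1, ]), "mismatched")
})
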