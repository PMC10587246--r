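test_that("level-0 eyes carry no lesions of any class", {
  cfg <- cohort_config(eyes_per_level = c(30, 0, 0, 0, 0), seed = 51)
  coh <- generate_cohort(cfg)
  expect_true(all(vapply(coh$eyes, function(e) nrow(e$lesions) == 0, TRUE)))
})

test_that("mild-NPDR eyes contain microaneurysms only, at least one", {
  cfg <- cohort_config(eyes_per_level = c(0, 40, 0, 0, 0), seed = 52)
  coh <- generate_cohort(cfg)
  for (e in coh$eyes) {
    expect_gt(nrow(e$lesions), 0)
    expect_true(all(e$lesions$lesion_type == "MA"))
  }
})

test_that("identical seeds give bit-identical cohorts, different seeds differ", {
  cfg <- cohort_config(eyes_per_level = c(1, 1, 1, 1, 1), seed = 53)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a, b)
  cfg2 <- cohort_config(eyes_per_level = c(1, 1, 1, 1, 1), seed = 54)
  c2 <- generate_cohort(cfg2)
  pa <- a$eyes[[3]]$lesions$poly[[1]]
  pc <- c2$eyes[[3]]$lesions$poly[[1]]
  expect_false(isTRUE(all.equal(pa, pc)))
})

test_that("cohort size and truth records follow eyes_per_level", {
  cfg <- cohort_config(eyes_per_level = c(2, 2, 2, 2, 2), seed = 55)
  coh <- generate_cohort(cfg)
  expect_length(coh$eyes, 10)
  expect_equal(nrow(coh$truth), 10)
  expect_equal(as.integer(table(coh$truth$designed_icdr)), rep(2L, 5))
  expect_true(all(icdr_aa_consistent(coh$truth$designed_icdr,
                                     coh$truth$designed_aa_level)))
})

test_that("zero grader error reproduces the designed labels exactly", {
  cfg <- cohort_config(eyes_per_level = c(3, 3, 3, 3, 3), seed = 56,
                       grader_error_rate = 0)
  coh <- generate_cohort(cfg)
  expect_identical(coh$truth$grader2_icdr, coh$truth$designed_icdr)
  kap <- cohen_kappa(coh$truth$grader2_icdr, coh$truth$designed_icdr)
  expect_equal(kap$kappa, 1)
})

test_that("per-lesion area draws recover the configured per-lesion mean", {
  cfg <- cohort_config(eyes_per_level = c(0, 200, 0, 0, 0), seed = 57)
  coh <- generate_cohort(cfg)
  areas <- unlist(lapply(coh$eyes, function(e) {
    if (!nrow(e$lesions)) return(NULL)
    retquant:::rq_batch_polygon_area(e$lesions$poly)
  }))
  target <- 0.06 / 6.33 # configured mild-NPDR per-MA area
  se <- sd(areas) / sqrt(length(areas))
  expect_lt(abs(mean(areas) - target), 3 * se + 0.001)
})

test_that("invalid profile parameters are rejected", {
  prof <- severity_profiles()
  prof$sd_count[prof$level == 3 & prof$lesion_type == "H"] <- -1
  expect_error(cohort_config(profiles = prof), "invalid dispersion")
  prof2 <- severity_profiles()[-1, ]
  expect_error(cohort_config(profiles = prof2), "missing")
  expect_error(generate_eye(7), "unknown ICDR level")
})

test_that("exclusion injection flags exactly the requested eyes", {
  cfg <- cohort_config(eyes_per_level = c(2, 2, 2, 2, 2), seed = 58)
  coh <- generate_cohort(cfg)
  set.seed(1)
  eyes <- inject_exclusions(coh$eyes, 1, 1, 1)
  nfl <- vapply(eyes, function(e) {
    e$flags$poor_quality + e$flags$rvo + e$flags$interfering
  }, 0)
  expect_equal(sum(nfl), 3)
  expect_identical(inject_exclusions(coh$eyes, 0, 0, 0), coh$eyes)
  expect_error(inject_exclusions(coh$eyes, 9, 9, 9), "exceed")
})
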