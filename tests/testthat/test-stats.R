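test_that("identical constant groups give H = 0 and p = 1", {
  kw <- kruskal_wallis(list(rep(3, 5), rep(3, 4), rep(3, 6)))
  expect_equal(kw$H, 0)
  expect_equal(kw$p, 1)
  expect_equal(kw$df, 2)
  expect_error(kruskal_wallis(list(1:3)), "2 groups")
  expect_error(kruskal_wallis(list(1:3, numeric(0))), "empty")
})

test_that("H matches the brute-force rank statistic over all n = 6 partitions", {
  vals_list <- list(c(2.1, 3.7, 1.4, 5.9, 4.2, 8.8),
                    c(1, 2, 2, 3, 3, 3)) # with ties
  for (vals in vals_list) {
    picks <- utils::combn(6, 3)
    for (j in seq_len(ncol(picks))) {
      g1 <- vals[picks[, j]]
      g2 <- vals[-picks[, j]]
      expect_equal(kruskal_wallis(list(g1, g2))$H,
                   kw_H_oracle(list(g1, g2)), tolerance = 1e-12)
    }
  }
  # the spec's worked pair
  expect_equal(kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6)))$H,
               kw_H_oracle(list(c(1, 2, 3), c(4, 5, 6))), tolerance = 1e-12)
})

test_that("H is invariant under strictly monotone transformations", {
  set.seed(81)
  g <- list(rnorm(8), rnorm(9, 1), rnorm(7, -1))
  h1 <- kruskal_wallis(g)$H
  h2 <- kruskal_wallis(lapply(g, function(v) exp(v)))$H
  h3 <- kruskal_wallis(lapply(g, function(v) 5 * v - 2))$H
  expect_equal(h1, h2, tolerance = 1e-12)
  expect_equal(h1, h3, tolerance = 1e-12)
  # duplicating all observations keeps H non-negative and ordering intact
  gd <- lapply(g, rep, times = 2)
  expect_gte(kruskal_wallis(gd)$H, 0)
})

test_that("Dunn-Bonferroni: null pairs give z = 0, separation gives significance", {
  d0 <- dunn_bonferroni(list(c(1, 2, 3, 4), c(1, 2, 3, 4)))
  expect_equal(d0$z[1, 2], 0)
  expect_equal(d0$p_adjusted[1, 2], 1)
  d1 <- dunn_bonferroni(list(1:10, 101:110, 201:210))
  expect_true(all(d1$p_adjusted[upper.tri(d1$p_adjusted)] < 0.05))
  # Bonferroni monotonicity on random inputs
  set.seed(82)
  for (r in 1:20) {
    g <- lapply(1:4, function(i) rnorm(sample(4:10, 1), sample(0:2, 1)))
    d <- dunn_bonferroni(g)
    ok <- d$p_adjusted >= d$p_raw - 1e-15
    expect_true(all(ok[upper.tri(ok)]))
  }
})

test_that("Cohen's kappa matches hand evaluation and the independent oracle", {
  expect_equal(cohen_kappa(1:5, 1:5)$kappa, 1)
  # contingency [[10,5],[5,10]]: kappa = (20/30 - 1/2)/(1 - 1/2) = 1/3
  a <- rep(c("x", "x", "y", "y"), c(10, 5, 5, 10))
  b <- rep(c("x", "y", "x", "y"), c(10, 5, 5, 10))
  k <- cohen_kappa(a, b)
  expect_equal(k$kappa, 1 / 3, tolerance = 1e-12)
  expect_equal(k$observed_agreement, 20 / 30, tolerance = 1e-12)
  # cross-check against e1071 on random tables
  skip_if_not_installed("e1071")
  set.seed(83)
  for (r in 1:10) {
    la <- sample(0:3, 60, replace = TRUE)
    lb <- ifelse(runif(60) < 0.6, la, sample(0:3, 60, replace = TRUE))
    tab <- table(factor(la, levels = 0:3), factor(lb, levels = 0:3))
    expect_equal(cohen_kappa(la, lb)$kappa,
                 e1071::classAgreement(tab)$kappa, tolerance = 1e-12)
  }
})

test_that("kappa is bounded by observed agreement and detects degeneracy", {
  set.seed(84)
  la <- sample(1:3, 100, replace = TRUE)
  lb <- sample(1:3, 100, replace = TRUE)
  k <- cohen_kappa(la, lb)
  expect_lte(k$kappa, k$observed_agreement + 1e-12)
  expect_lte(abs(k$kappa), 1)
  expect_error(cohen_kappa(rep("a", 5), rep("a", 5)), "undefined kappa")
  expect_error(cohen_kappa(1:3, 1:4), "unequal")
})

test_that("a label permutation destroying agreement drives kappa to zero", {
  set.seed(85)
  la <- sample(0:4, 4000, replace = TRUE)
  lb <- sample(la) # independent pairing by shuffling
  expect_lt(abs(cohen_kappa(la, lb)$kappa), 0.05)
})

test_that("cohort shares reproduce printed half-up percentages", {
  sh <- cohort_shares(c(721, 33, 365, 95, 306))
  expect_equal(sh, c(47.4, 2.2, 24.0, 6.3, 20.1))
  expect_equal(cohort_shares(c(0, 12, 0)), c(0, 100, 0))
  expect_equal(cohort_shares(rep(1, 4)), rep(25, 4))
  expect_error(cohort_shares(c(0, 0)), "zero total")
  expect_equal(round_half_up(6.25, 1), 6.3) # base round() would give 6.2
  expect_equal(round_half_up(c(2.171, 24.013, 20.125), 1), c(2.2, 24.0, 20.1))
})

test_that("severity_stats runs the battery per lesion metric family", {
  cfg <- cohort_config(eyes_per_level = c(0, 4, 4, 4, 4), seed = 86)
  coh <- generate_cohort(cfg)
  gr <- grade_cohort(coh$eyes, quad_n = 48)
  st <- severity_stats(gr$metrics, gr$grades, "icdr")
  expect_true(all(c("H", "df", "p") %in% names(st$tests)))
  expect_true(all(st$tests$df == 3))
  expect_true(all(st$pairwise$p_adjusted >= 0 & st$pairwise$p_adjusted <= 1))
  h_row <- st$tests[st$tests$lesion_type == "H" &
                      st$tests$metric == "frequency", ]
  expect_gt(h_row$H, 0)
})
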