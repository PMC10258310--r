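test_that("signed-rank exact p matches hand enumeration and wilcox.test", {
  # all-positive differences 1..5: W = 15, two-sided p = 2/32
  res <- paired_wilcoxon(c(2, 4, 6, 8, 10), c(1, 2, 3, 4, 5))
  expect_equal(res$statistic, 15)
  expect_equal(res$p_value, 0.0625, tolerance = 1e-12)
  expect_equal(res$method, "wilcoxon_signed_rank_exact")

  set.seed(101)
  for (i in 1:25) {
    n <- sample(4:8, 1)
    x <- round(rnorm(n), 1)
    y <- round(rnorm(n), 1)
    if (all(x == y)) next
    res <- paired_wilcoxon(x, y)
    expect_equal(res$p_value, signed_rank_oracle(x, y), tolerance = 1e-12)
    # symmetry: swapping pair order preserves the two-sided p
    expect_equal(paired_wilcoxon(y, x)$p_value, res$p_value,
                 tolerance = 1e-12)
    d <- (x - y)[x != y]
    if (!any(duplicated(abs(d)))) {
      ref <- wilcox.test(x, y, paired = TRUE, exact = TRUE)
      expect_equal(res$p_value, ref$p.value, tolerance = 1e-10)
    }
  }
})

test_that("signed-rank contracts: zero differences dropped, degenerate errors", {
  expect_error(paired_wilcoxon(c(1, 2, 3), c(1, 2, 3)), "zero")
  expect_error(paired_wilcoxon(1:3, 1:2), "equal length")
  # zero differences are dropped before ranking
  res <- paired_wilcoxon(c(5, 5, 1, 2, 3, 4), c(5, 5, 2, 4, 6, 8))
  expect_equal(res$n, 4)
})

test_that("signed-rank normal approximation is close to the exact branch", {
  set.seed(55)
  x <- rnorm(11); y <- rnorm(11)
  exact <- paired_wilcoxon(x, y, exact_limit = 12)
  approx <- paired_wilcoxon(x, y, exact_limit = 5)
  expect_equal(approx$method, "wilcoxon_signed_rank_normal")
  expect_lt(abs(exact$p_value - approx$p_value), 0.05)
})

test_that("Mann-Whitney exact p matches enumeration, examples and wilcox.test", {
  res <- mann_whitney(c(1, 2), c(10, 11))
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1 / 3, tolerance = 1e-12)

  ident <- mann_whitney(c(1, 2, 3), c(1, 2, 3))
  expect_equal(ident$p_value, 1, tolerance = 1e-9)

  set.seed(202)
  for (i in 1:25) {
    na <- sample(2:5, 1); nb <- sample(2:5, 1)
    a <- round(rnorm(na), 1); b <- round(rnorm(nb), 1)
    res <- mann_whitney(a, b)
    expect_equal(res$p_value, mann_whitney_oracle(a, b), tolerance = 1e-12)
    expect_equal(mann_whitney(b, a)$p_value, res$p_value, tolerance = 1e-12)
    if (!any(duplicated(c(a, b)))) {
      ref <- wilcox.test(a, b, exact = TRUE)
      expect_equal(res$p_value, ref$p.value, tolerance = 1e-10)
    }
  }
  expect_error(mann_whitney(numeric(0), 1:3), "at least 2")
})

test_that("Mann-Whitney holds its nominal type-I error under the null", {
  set.seed(777)
  rejections <- replicate(2000, {
    a <- rnorm(8); b <- rnorm(8)
    mann_whitney(a, b)$p_value < 0.05
  })
  expect_gte(mean(rejections), 0.03)
  expect_lte(mean(rejections), 0.07)
})

test_that("Spearman correlation matches rank-Pearson oracle", {
  x <- c(3, 1, 4, 1.5, 9, 2.6)
  expect_equal(spearman(x, x * 2 + 1)$statistic, 1)
  expect_equal(spearman(x, -x)$statistic, -1)

  set.seed(9)
  x <- rnorm(20); y <- 0.5 * x + rnorm(20)
  res <- spearman(x, y)
  expect_equal(res$statistic, cor(rank(x), rank(y)), tolerance = 1e-12)
  expect_equal(res$statistic,
               unname(cor.test(x, y, method = "spearman")$estimate),
               tolerance = 1e-12)
  expect_equal(res$n, 20)

  expect_warning(flat <- spearman(rep(1, 6), rnorm(6)), "constant")
  expect_true(is.na(flat$statistic))
  expect_error(spearman(1:3, 1:3), "at least 4")
})

test_that("frequency table reproduces cohort percentage arithmetic", {
  records <- data.frame(
    patient_id = sprintf("P%02d", 1:64),
    sex = rep(c("male", "female"), c(55, 9)),
    hbv_related = rep(c("yes", "no"), c(59, 5)))
  tab <- frequency_table(records)
  expect_equal(tab$percent[tab$variable == "sex" & tab$category == "male"],
               85.9)
  expect_equal(tab$percent[tab$variable == "hbv_related" &
                             tab$category == "yes"], 92.2)
  # percentages sum to ~100 per variable (rounding slack)
  for (v in unique(tab$variable))
    expect_lt(abs(sum(tab$percent[tab$variable == v]) - 100), 0.2)

  one <- frequency_table(data.frame(patient_id = "P1", sex = "male"))
  expect_equal(one$percent, 100.0)
})

test_that("categorical test routes to Fisher or chi-square as specified", {
  diag_tab <- matrix(c(10, 0, 0, 10), 2)
  res <- categorical_test(diag_tab)
  expect_equal(res$method, "fisher_exact")
  expect_equal(res$p_value, fisher_oracle(diag_tab), tolerance = 1e-12)

  homog <- matrix(c(5, 5, 5, 5), 2)
  expect_equal(categorical_test(homog)$p_value, 1, tolerance = 1e-9)

  big <- matrix(50, 2, 2)
  res_big <- categorical_test(big)
  expect_equal(res_big$method, "chi_square")
  expect_equal(res_big$statistic, 0, tolerance = 1e-12)

  set.seed(14)
  for (i in 1:20) {
    tab <- matrix(rpois(4, 3), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    res <- categorical_test(tab)
    if (res$method == "fisher_exact")
      expect_equal(res$p_value, fisher_oracle(tab), tolerance = 1e-9)
  }
  expect_error(categorical_test(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)),
               "margin")
})

test_that("BH adjustment follows the step-up rule", {
  expect_equal(adjust_bh(0.02), 0.02)
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjust_bh(rep(0.3, 5)), rep(0.3, 5))
  p <- c(0.001, 0.02, 0.5)
  q <- adjust_bh(p)
  expect_true(all(q >= p))
})

test_that("Kaplan-Meier estimates match the hand product-limit computation", {
  cohort <- data.frame(patient_id = c("a", "b", "c", "d"), f = c(0, 0, 1, 1),
                       os_months = c(5, 10, 7, 14), os_event = 1)
  km <- km_logrank(cohort, "f", "OS")
  # low group has event times (5, 10): S(5) = 1/2, S(10) = 0
  expect_equal(km$low$survival, c(0.5, 0), tolerance = 1e-12)

  # all censored: survival stays at 1 and the log-rank p is undefined
  cens <- data.frame(patient_id = sprintf("p%d", 1:8), f = rep(c(0, 1), 4),
                     os_months = 1:8, os_event = 0)
  km_c <- km_logrank(cens, "f", "OS")
  expect_true(all(km_c$low$survival == 1))
  expect_true(all(km_c$high$survival == 1))
  expect_true(is.na(km_c$test$p_value))
})

test_that("KM with no censoring equals the empirical survival function", {
  set.seed(4)
  t_ev <- sort(sample(1:50, 12))
  cohort <- data.frame(patient_id = sprintf("p%d", 1:12),
                       f = rep(c(0, 1), 6),
                       os_months = t_ev, os_event = 1)
  km <- km_logrank(cohort, "f", "OS")
  for (g in c("low", "high")) {
    cv <- km[[g]]
    grp_times <- cohort$os_months[(cohort$f > km$cut) == (g == "high")]
    emp <- vapply(cv$times, function(tt) mean(grp_times > tt), numeric(1))
    expect_equal(cv$survival, emp, tolerance = 1e-12)
  }
})

test_that("log-rank is label-symmetric and null for identical groups", {
  d <- data.frame(patient_id = sprintf("p%d", 1:12),
                  f = rep(c(0, 1), each = 6),
                  os_months = rep(c(3, 6, 9, 12, 15, 18), 2),
                  os_event = rep(c(1, 1, 0, 1, 0, 1), 2))
  km <- km_logrank(d, "f", "OS")
  expect_lt(abs(km$test$statistic), 1e-9)
  expect_equal(km$test$p_value, 1, tolerance = 1e-6)

  flip <- d; flip$f <- 1 - flip$f
  expect_equal(km_logrank(flip, "f", "OS")$test$statistic,
               km$test$statistic, tolerance = 1e-9)
})

test_that("median split sends ties to the low group and validates columns", {
  d <- data.frame(patient_id = sprintf("p%d", 1:6),
                  f = c(1, 2, 2, 2, 3, 4),
                  os_months = c(5, 8, 12, 20, 25, 30),
                  os_event = c(1, 1, 0, 1, 1, 0))
  km <- km_logrank(d, "f", "OS")
  expect_equal(km$cut, 2)
  expect_equal(sum(d$f <= 2), max(km$low$at_risk))
  expect_error(km_logrank(d, "missing_col", "OS"), "missing_col")
})

test_that("cohort table pivots long features into per-patient columns", {
  feats <- data.frame(patient_id = rep(c("P1", "P2"), each = 2),
                      tissue = rep(c("tumor", "non_tumor"), 2),
                      chain = "TRB", isotype_view = "all", level = "CDR3aa",
                      metric = "nsde", value = c(0.9, 0.8, 0.7, 0.6))
  clin <- data.frame(patient_id = c("P1", "P2"), os_months = c(10, 20),
                     os_event = c(1, 0))
  wide <- cohort_table(feats, clin)
  expect_equal(nrow(wide), 2)
  expect_equal(wide$TRB_all_tumor_CDR3aa_nsde, c(0.9, 0.7))
  expect_equal(wide$TRB_all_non_tumor_CDR3aa_nsde, c(0.8, 0.6))
})
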