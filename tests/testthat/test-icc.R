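test_that("ICC(1,1) matches a direct ANOVA computation", {
  set.seed(31)
  for (rep in 1:5) {
    panel <- matrix(rnorm(5 * 3, mean = rep(rnorm(5, sd = 2), 3)), 5, 3)
    fit <- icc_1_1(panel)
    expect_equal(fit$estimate, oracle_icc_aov(panel), tolerance = 1e-12)
  }
  # the 3x2 hand table: identical repeats, distinct subjects
  hand <- matrix(c(1, 1, 2, 2, 3, 3), nrow = 3, byrow = TRUE)
  expect_identical(icc_1_1(hand)$estimate, 1)
})

test_that("ICC recovers the variance-component ratio", {
  set.seed(7)
  n <- 200
  subj <- rnorm(n, sd = 3)  # sigma_b^2 = 9
  panel <- cbind(subj + rnorm(n), subj + rnorm(n))  # sigma_w^2 = 1
  fit <- icc_1_1(panel)
  expect_lt(abs(fit$estimate - 0.9), 0.05)
  expect_lte(fit$estimate, 1)
})

test_that("degenerate panels are flagged, not silently scored", {
  same <- matrix(5, 4, 3)
  fit <- icc_1_1(same)
  expect_true(fit$undefined)
  rec <- icc_record(same)
  expect_equal(rec$label, "indeterminate")
  expect_match(rec$reason, "zero total variance")
  expect_error(icc_1_1(matrix(1, 1, 3)), ">= 2")
  expect_error(icc_1_1(matrix(c(1, NA, 2, 3), 2, 2)), "non-finite")
})

test_that("negative ICC estimates are retained", {
  # within-variance far larger than between-variance
  set.seed(13)
  panel <- matrix(rnorm(40, sd = 5), 4, 10) + rnorm(4, sd = 0.01)
  fit <- icc_1_1(panel)
  expect_lt(fit$estimate, 0.2)
  expect_gte(fit$estimate, -1)
})

test_that("the confidence interval brackets the estimate", {
  set.seed(5)
  for (rep in 1:10) {
    subj <- rnorm(12, sd = 2)
    panel <- matrix(subj, 12, 4) + matrix(rnorm(48), 12, 4)
    fit <- icc_1_1(panel)
    ci <- icc_ci(fit$msb, fit$msw, fit$n, fit$k)
    expect_lte(ci$lower, fit$estimate)
    expect_gte(ci$upper, fit$estimate)
    expect_gte(ci$lower, -1)
    expect_lte(ci$upper, 1)
  }
})

test_that("CI width shrinks as repeated measurements increase", {
  # fixed variance ratio sigma_b^2 / sigma_w^2 = 8; the expected mean
  # squares under the one-way model are MSB = k sigma_b^2 + sigma_w^2 and
  # MSW = sigma_w^2
  widths <- vapply(c(2, 4, 8, 16, 32), function(k) {
    ci <- icc_ci(msb = k * 8 + 1, msw = 1, n = 20, k = k)
    ci$upper - ci$lower
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
})

test_that("MSW = 0 degenerates the interval to [1, 1]", {
  ci <- icc_ci(msb = 4, msw = 0, n = 5, k = 2)
  expect_equal(ci$lower, 1)
  expect_equal(ci$upper, 1)
})

test_that("robustness classification implements the three-state CI rule", {
  expect_equal(classify_robustness(0.92, 0.98), "robust")
  expect_equal(classify_robustness(0.20, 0.50), "non_robust")
  expect_equal(classify_robustness(0.85, 0.95), "indeterminate")
  expect_equal(classify_robustness(0.90, 0.95), "robust")   # lower == thr
  expect_equal(classify_robustness(NA, NA), "indeterminate")
})

test_that("classification is monotone in the lower bound", {
  lowers <- seq(-1, 0.99, by = 0.01)
  labels <- vapply(lowers, function(lo) classify_robustness(lo, 0.995),
                   character(1))
  robust_idx <- which(labels == "robust")
  # once robust, always robust as the lower bound rises
  expect_true(all(diff(robust_idx) == 1))
  expect_false("non_robust" %in% labels[robust_idx[1]:length(labels)])
})

test_that("perturbation ICCs average estimates and bounds element-wise", {
  p1 <- matrix(c(1, 1.1, 2, 2.1, 3, 3.1, 4, 4.2), 4, 2, byrow = TRUE)
  p2 <- p1 + matrix(rnorm(8, sd = 0.05), 4, 2)
  r1 <- icc_record(p1)
  r2 <- icc_record(p2)
  avg <- perturbation_icc(p1, p2)
  expect_equal(avg$estimate, mean(c(r1$estimate, r2$estimate)))
  expect_equal(avg$lower, mean(c(r1$lower, r2$lower)))
  expect_equal(avg$upper, mean(c(r1$upper, r2$upper)))
  # averaging two identical panels is the identity
  same <- perturbation_icc(p1, p1)
  expect_equal(same$estimate, r1$estimate)
  expect_equal(same$lower, r1$lower)
  # one undefined panel poisons the average with a flag
  bad <- perturbation_icc(p1, matrix(1, 4, 2))
  expect_true(bad$undefined)
  expect_equal(bad$label, "indeterminate")
})

test_that("comparison categories implement the nine-cell mapping", {
  expect_equal(compare_conditions("+", "+")$category, "true_positive")
  expect_equal(compare_conditions("-", "-")$category, "true_negative")
  expect_equal(compare_conditions("-", "+")$category, "false_positive")
  expect_equal(compare_conditions("+", "-")$category, "false_negative")
  z <- compare_conditions("0", "+")
  expect_equal(z$category, "indeterminate")
  expect_equal(z$substate, "T0P+")
  # long-form labels map identically
  expect_equal(compare_conditions("robust", "non_robust")$category,
               "false_negative")
  for (t in c("+", "-", "0")) for (p in c("+", "-", "0")) {
    r <- compare_conditions(t, p)
    expect_equal(r$substate, paste0("T", t, "P", p))
    if (t == "0" || p == "0") expect_equal(r$category, "indeterminate")
  }
})
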