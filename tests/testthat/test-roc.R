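test_that("empirical AUC equals the brute-force pair count", {
  expect_equal(empirical_auc(c(3, 4, 1, 2), c(1, 1, 0, 0)), 1)
  expect_equal(empirical_auc(rep(5, 6), rep(c(0, 1), 3)), 0.5)
  expect_equal(empirical_auc(c(2, 3, 1, 3), c(1, 1, 0, 0)), 0.625)
  withr::local_seed(77)
  for (i in 1:30) {
    n <- sample(10:200, 1)
    s <- sample(0:30, n, replace = TRUE)
    l <- rbinom(n, 1, 0.4)
    if (length(unique(l)) < 2) next
    o <- sample(c("higher_is_positive", "lower_is_positive"), 1)
    expect_equal(empirical_auc(s, l, o), brute_auc(s, l, o))
  }
  expect_error(empirical_auc(1:4, rep(1, 4)), "both outcome classes")
})

test_that("AUC respects orientation and label flips on tie-free data", {
  withr::local_seed(78)
  for (i in 1:20) {
    n <- 60
    s <- sample(seq_len(1000), n)  # distinct scores, no ties
    l <- rbinom(n, 1, 0.5)
    if (length(unique(l)) < 2) next
    a <- empirical_auc(s, l, "higher_is_positive")
    expect_equal(empirical_auc(s, l, "lower_is_positive"), 1 - a)
    expect_equal(empirical_auc(s, 1 - l, "higher_is_positive"), 1 - a)
  }
})

test_that("DeLong variance and paired test agree with an independent implementation", {
  library(pROC)
  withr::local_seed(5150)
  l <- rbinom(150, 1, 0.45)
  s1 <- rnorm(150) + l
  s2 <- rnorm(150) + 0.6 * l
  r1 <- pROC::roc(l, s1, quiet = TRUE, direction = "<")
  r2 <- pROC::roc(l, s2, quiet = TRUE, direction = "<")
  mine <- delong_auc_ci(s1, l)
  expect_equal(mine$auc, as.numeric(pROC::auc(r1)))
  expect_equal(mine$var_auc, pROC::var(r1, method = "delong"))
  pt <- pROC::roc.test(r1, r2, method = "delong", paired = TRUE)
  mt <- delong_paired_test(s1, s2, l)
  expect_equal(mt$p_value, pt$p.value)
  expect_equal(abs(mt$statistic), abs(as.numeric(pt$statistic)))
})

test_that("degenerate separation collapses the CI to the point estimate", {
  s <- c(1, 2, 3, 10, 11, 12)
  l <- c(0, 0, 0, 1, 1, 1)
  expect_warning(ci <- delong_auc_ci(s, l), "degenerate")
  expect_equal(ci$auc, 1)
  expect_equal(c(ci$ci_low, ci$ci_high), c(1, 1))
  expect_true(ci$degenerate)
})

test_that("DeLong logit CI agrees with a stratified bootstrap CI", {
  withr::local_seed(42)
  n <- 100
  s <- sample(1:10, n, TRUE)
  l <- rbinom(n, 1, plogis((s - 5.5) * 0.5))
  d <- delong_auc_ci(s, l)
  b <- delong_auc_ci(s, l, ci_method = "bootstrap", n_boot = 2000)
  expect_lt(abs(d$ci_low - b$ci_low), 0.05)
  expect_lt(abs(d$ci_high - b$ci_high), 0.05)
})

test_that("paired test is exact under identity and rank-preserving transforms", {
  withr::local_seed(901)
  l <- rbinom(80, 1, 0.4)
  s <- rnorm(80) + l
  same <- delong_paired_test(s, s, l)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  mono <- delong_paired_test(s, exp(2 * s) + 5, l)
  expect_equal(mono$estimate, 0)
  expect_equal(mono$p_value, 1)
  # opposite orientations cancel when the second score is negated
  flip <- delong_paired_test(s, -s, l, "higher_is_positive", "lower_is_positive")
  expect_equal(flip$p_value, 1)
})

test_that("paired DeLong p agrees with a label-preserving bootstrap on a small fixture", {
  withr::local_seed(7)
  n <- 40
  lab <- rep(c(0, 1), 20)
  sa <- rnorm(n) + lab * 1.1
  sb <- rnorm(n) + lab * 0.5
  pt <- delong_paired_test(sa, sb, lab)
  boot_d <- replicate(10000, {
    i <- c(sample(which(lab == 1), 20, TRUE), sample(which(lab == 0), 20, TRUE))
    empirical_auc(sa[i], lab[i]) - empirical_auc(sb[i], lab[i])
  })
  p_boot <- 2 * min(mean(boot_d <= 0), mean(boot_d >= 0))
  expect_lt(abs(pt$p_value - p_boot), 0.03)
})

test_that("roc_curve exposes monotone se/sp arrays and tidiers", {
  withr::local_seed(300)
  l <- rbinom(120, 1, 0.5)
  s <- sample(0:20, 120, TRUE) + 3 * l
  r <- roc_curve(s, l, scale = "incns")
  expect_s3_class(r, "coma_roc")
  # higher thresholds: fewer predicted positive, se non-increasing, sp non-decreasing
  expect_true(all(diff(r$se_at) <= 0))
  expect_true(all(diff(r$sp_at) >= 0))
  expect_true(r$ci95[1] <= r$auc && r$auc <= r$ci95[2])
  td <- tidy(r)
  expect_named(td, c("scale", "threshold", "se", "sp"))
  gl <- glance(r)
  expect_equal(gl$auc, r$auc)
  expect_s3_class(autoplot(r), "ggplot")
})
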