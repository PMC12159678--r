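# Contribution model, log ratio, driver regression, comparisons.

test_that("zscore standardizes with the sample sd and rejects constants", {
  expect_equal(zscore(c(1, 2, 3)), c(-1, 0, 1))
  set.seed(3)
  for (i in 1:10) {
    x <- rnorm(sample(5:50, 1), sd = runif(1, 0.1, 10))
    z <- zscore(x)
    expect_lt(abs(mean(z)), 1e-12)
    expect_equal(z, (x - mean(x)) / sd(x))
  }
  expect_error(zscore(rep(2, 5), "cn"), "cn")
  expect_error(zscore(3), "at least 2")
})

test_that("the contribution fit recovers noiseless mixtures exactly", {
  ch <- simulate_cohort(cohort_spec(noise_sd = 0), seed = 21)
  fit <- fit_contribution_model(ch$samples)
  expect_equal(fit$a, ch$truth$a_star, tolerance = 1e-8)
  expect_equal(fit$b, ch$truth$b_star, tolerance = 1e-8)
  expect_equal(fit$c, ch$truth$gene_offset, tolerance = 1e-8)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
})

test_that("a gene tracking only the long transcript yields a ~ 1, b ~ 0", {
  set.seed(22)
  d <- data.frame(tpm_long = rlnorm(300, 1, 0.8),
                  tpm_short = rlnorm(300, 1, 0.8))
  d$tpm_gene <- 20 + zscore(d$tpm_long)
  fit <- fit_contribution_model(d)
  expect_equal(fit$a, 1, tolerance = 0.05)
  expect_equal(fit$b, 0, tolerance = 0.05)
})

test_that("the OLS solution equals a generic pseudo-inverse oracle", {
  set.seed(23)
  d <- simulate_cohort(seed = 23)$samples
  fit <- fit_contribution_model(d)
  X <- cbind(1, zscore(d$tpm_long), zscore(d$tpm_short))
  beta <- solve(crossprod(X), crossprod(X, d$tpm_gene))
  expect_equal(fit$c, beta[1L], tolerance = 1e-10)
  expect_equal(fit$a, beta[2L], tolerance = 1e-10)
  expect_equal(fit$b, beta[3L], tolerance = 1e-10)
})

test_that("collinear predictors are refused", {
  d <- data.frame(tpm_long = 1:20)
  d$tpm_short <- d$tpm_long * 2
  d$tpm_gene <- d$tpm_long + 5
  expect_error(fit_contribution_model(d), "collinear")
})

test_that("the log ratio is symmetric, monotone and matches direct arithmetic", {
  fit <- structure(list(a = 0.5, b = 0.5, c = 0, r_squared = 1, n = 10,
                        scale_outcome = FALSE),
                   class = "contribution_fit")
  d <- data.frame(tpm_long = 10, tpm_short = 10)
  expect_equal(contribution_log_ratio(fit, d, 1e-9)$log_ratio, 0)

  fit11 <- structure(list(a = 1, b = 1, c = 0, r_squared = 1, n = 10,
                          scale_outcome = FALSE),
                     class = "contribution_fit")
  d2 <- data.frame(tpm_long = 20, tpm_short = 5)
  expect_equal(contribution_log_ratio(fit11, d2, 0.01)$log_ratio,
               log2(20.01 / 5.01))

  # swapping transcripts and coefficients flips the sign
  fit_ab <- structure(list(a = 0.7, b = 0.3, c = 0, r_squared = 1,
                           n = 10, scale_outcome = FALSE),
                      class = "contribution_fit")
  fit_ba <- structure(list(a = 0.3, b = 0.7, c = 0, r_squared = 1,
                           n = 10, scale_outcome = FALSE),
                      class = "contribution_fit")
  d3 <- data.frame(tpm_long = c(4, 50), tpm_short = c(9, 2))
  d3s <- data.frame(tpm_long = d3$tpm_short, tpm_short = d3$tpm_long)
  expect_equal(contribution_log_ratio(fit_ab, d3, 0.01)$log_ratio,
               -contribution_log_ratio(fit_ba, d3s, 0.01)$log_ratio)

  # monotone: increasing in tpm_long, decreasing in tpm_short
  lr <- function(l, s) contribution_log_ratio(
    fit_ab, data.frame(tpm_long = l, tpm_short = s), 0.01)$log_ratio
  expect_true(all(diff(lr(seq(1, 50, length.out = 20), 10)) > 0))
  expect_true(all(diff(lr(10, seq(1, 50, length.out = 20))) < 0))

  # degenerate coefficients flagged but still computed
  fit_neg <- structure(list(a = -0.2, b = 0.5, c = 0, r_squared = 1,
                            n = 10, scale_outcome = FALSE),
                       class = "contribution_fit")
  res <- contribution_log_ratio(fit_neg, d3, 0.01)
  expect_true(all(res$degenerate))
  expect_true(all(is.finite(res$log_ratio)))
})

test_that("driver regression codes amplification at the cutoff and recovers planted effects", {
  set.seed(24)
  n <- 400
  d <- data.frame(copy_number = c(3.0, 2.99,
                                  runif(n - 2, 1.5, 4.5)),
                  tnf_score = rnorm(n), ifn_score = rnorm(n))
  amp <- as.integer(d$copy_number >= 3)
  expect_equal(amp[1:2], c(1L, 0L))
  d$tpm_gene <- 2 * amp + rnorm(n, sd = 0.1)
  fit <- fit_driver_model(d)
  est_z <- fit$estimate[fit$term == "amplified"]
  # undo the outcome z-scaling analytically to compare with the truth
  expect_equal(est_z * sd(d$tpm_gene), 2, tolerance = 0.1)
  expect_lt(fit$p_value[fit$term == "amplified"], 1e-6)
})

test_that("an all- or never-amplified cohort drops the indicator with a warning", {
  set.seed(25)
  d <- data.frame(copy_number = runif(50, 1, 2),
                  tnf_score = rnorm(50), ifn_score = rnorm(50),
                  tpm_gene = rnorm(50, 10))
  expect_warning(fit <- fit_driver_model(d), "constant")
  expect_false("amplified" %in% fit$term)
})

test_that("group comparisons behave at their fixed points", {
  x <- c(1, 2, 3, 4, 1, 2, 3, 4)
  g <- rep(c("a", "b"), each = 4)
  res <- group_compare(x, groups = g, test = "student_t")
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  mono <- group_compare(c(1, 5, 9, 20), y = c(2, 7, 11, 40),
                        test = "spearman")
  expect_equal(mono$estimate, 1)
  paired <- group_compare(c(2, 3, 5), y = c(1, 2, 3), test = "paired_t")
  expect_equal(paired$estimate, 4 / 3)
  expect_error(group_compare(x, groups = rep("a", 8),
                             test = "student_t"), "2 groups")
})
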