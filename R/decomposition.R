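# Contribution decomposition: how much of the composite gene signal is
# driven by each of two overlapping transcripts.
#
# Model: assuming gene expression derives solely from the long and the
# short transcript,  a*long + b*short + c = gene.  The model is fitted
# by OLS on standardized predictors; the fitted coefficients act as
# normalization factors, and the per-sample statistic is
# log2(a*tpm_long / b*tpm_short) with a pseudocount guard.

#' Z-score a numeric vector
#'
#' Sample standard deviation (n - 1 denominator).
#'
#' @param values numeric vector, length >= 2, non-constant.
#' @param name label used in error messages.
#' @return vector with mean 0 and sd 1.
#' @export
zscore <- function(values, name = deparse(substitute(values))) {
  if (length(values) < 2L)
    stop("zscore: '", name, "' needs at least 2 values")
  s <- stats::sd(values)
  if (!is.finite(s) || s == 0)
    stop("zscore: '", name, "' is constant (sd = 0)")
  (values - mean(values)) / s
}

.check_samples <- function(samples, cols) {
  stopifnot(is.data.frame(samples))
  miss <- setdiff(cols, names(samples))
  if (length(miss))
    stop("sample table missing column(s): ", paste(miss, collapse = ", "))
  bad <- cols[vapply(cols, function(cl)
    any(!is.finite(samples[[cl]])), TRUE)]
  if (length(bad))
    stop("non-finite values in column(s): ", paste(bad, collapse = ", "))
  invisible(samples)
}

#' Fit the two-transcript contribution model
#'
#' Ordinary least squares of the composite gene TPM on the z-scored
#' TPMs of the two transcripts, with intercept.  Standardizing the
#' predictors puts the two coefficients on a common scale so they can
#' act as per-transcript normalization factors.  By default the outcome
#' is centered through the intercept but not rescaled; rescaling it
#' (`scale_outcome = TRUE`) divides both coefficients by the same
#' constant, which cancels from the downstream contribution ratio.
#'
#' @param samples data.frame with columns `tpm_long`, `tpm_short`,
#'   `tpm_gene` (and anything else, e.g. `group`).
#' @param fit_on optional logical/integer index restricting the rows
#'   used for fitting (the default fits on the pooled cohort).
#' @param scale_outcome also z-score the outcome.
#' @return object of class `contribution_fit`: list with `a` (long
#'   coefficient), `b` (short), `c` (intercept), `r_squared`, `n`, and
#'   `scale_outcome`.
#' @export
fit_contribution_model <- function(samples, fit_on = NULL,
                                   scale_outcome = FALSE) {
  .check_samples(samples, c("tpm_long", "tpm_short", "tpm_gene"))
  if (!is.null(fit_on)) samples <- samples[fit_on, , drop = FALSE]
  n <- nrow(samples)
  if (n < 3L) stop("contribution model needs n >= 3 samples")
  zl <- zscore(samples$tpm_long, "tpm_long")
  zs <- zscore(samples$tpm_short, "tpm_short")
  if (abs(stats::cor(zl, zs)) > 1 - 1e-12)
    stop("tpm_long and tpm_short are perfectly collinear")
  y <- if (scale_outcome) zscore(samples$tpm_gene, "tpm_gene")
       else samples$tpm_gene
  fit <- stats::lm(y ~ zl + zs)
  cf <- stats::coef(fit)
  ssr <- sum(stats::residuals(fit)^2)
  sst <- sum((y - mean(y))^2)
  structure(list(a = unname(cf["zl"]), b = unname(cf["zs"]),
                 c = unname(cf["(Intercept)"]),
                 r_squared = if (sst > 0) 1 - ssr / sst else NA_real_,
                 n = n, scale_outcome = scale_outcome),
            class = "contribution_fit")
}

#' @export
print.contribution_fit <- function(x, ...) {
  cat("<contribution_fit> n = ", x$n,
      "\n  a (long)  = ", format(x$a, digits = 4),
      "\n  b (short) = ", format(x$b, digits = 4),
      "\n  c         = ", format(x$c, digits = 4),
      "\n  R^2       = ", format(x$r_squared, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Per-sample log2 contribution ratio
#'
#' The fitted coefficients are applied as normalization factors to each
#' sample's transcript TPMs; the statistic is
#' `log2((a * tpm_long + eps) / (b * tpm_short + eps))`.  Positive
#' values mean the long transcript dominates the composite signal in
#' that sample; negative values, the short one.  Samples fitted with a
#' non-positive coefficient are flagged degenerate (the ratio is still
#' computed under the pseudocount guard) and excluded from group
#' summaries by default.
#'
#' @param fit a `contribution_fit`.
#' @param samples sample data.frame (same columns as the fit input; a
#'   `group` column, if present, is carried through).
#' @param epsilon pseudocount in TPM units guarding zeros (> 0).
#' @return data.frame of class `contribution_result` with columns
#'   `sample_id` (if present), `group` (if present), `normalized_long`,
#'   `normalized_short`, `log_ratio`, `degenerate`.
#' @export
contribution_log_ratio <- function(fit, samples, epsilon = 0.01) {
  stopifnot(inherits(fit, "contribution_fit"), epsilon > 0)
  .check_samples(samples, c("tpm_long", "tpm_short"))
  degenerate <- fit$a <= 0 || fit$b <= 0
  out <- data.frame(
    normalized_long = fit$a * samples$tpm_long,
    normalized_short = fit$b * samples$tpm_short)
  # a non-positive coefficient would put a negative value inside the
  # log; the ratio clamps the normalized terms at zero so the
  # pseudocount keeps it finite
  out$log_ratio <- log2((pmax(out$normalized_long, 0) + epsilon) /
                        (pmax(out$normalized_short, 0) + epsilon))
  out$degenerate <- degenerate
  for (cl in c("group", "sample_id"))
    if (cl %in% names(samples)) out[[cl]] <- samples[[cl]]
  class(out) <- c("contribution_result", "data.frame")
  out
}

#' Group summaries of the contribution ratio
#'
#' @param result a `contribution_result` with a `group` column.
#' @param include_degenerate include samples flagged degenerate.
#' @return data.frame with per-group `n`, `mean` and `median` log ratio.
#' @export
summarize_contributions <- function(result, include_degenerate = FALSE) {
  stopifnot("group" %in% names(result))
  if (!include_degenerate) result <- result[!result$degenerate, ,
                                            drop = FALSE]
  sp <- split(result$log_ratio, result$group)
  data.frame(group = names(sp),
             n = lengths(sp),
             mean = vapply(sp, mean, 0),
             median = vapply(sp, stats::median, 0),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Multivariable driver regression
#'
#' Regresses a z-scored expression outcome on a binary locus
#' amplification indicator (copy number at or above the cutoff) plus
#' z-scored continuous covariates (for the study design: per-sample
#' pathway enrichment scores for TNF-receptor and IFN-gamma signaling,
#' consumed as inputs).  Two-sided p-values come from the t
#' distribution of the OLS coefficients.
#'
#' @param samples data.frame with the outcome column, `copy_number`,
#'   and the covariate columns.
#' @param outcome name of the outcome column (e.g. `"tpm_gene"`).
#' @param covariates character vector of continuous covariate columns.
#' @param amplification_cutoff copy number at or above which a sample is
#'   coded amplified (default 3).
#' @return object of class `driver_fit`: data.frame with columns
#'   `term`, `estimate`, `std_error`, `statistic`, `p_value`; attribute
#'   `outcome`.  A cohort that is all-amplified or none-amplified drops
#'   the indicator with a warning.
#' @export
fit_driver_model <- function(samples, outcome = "tpm_gene",
                             covariates = c("tnf_score", "ifn_score"),
                             amplification_cutoff = 3) {
  .check_samples(samples, c(outcome, "copy_number", covariates))
  amp <- as.integer(samples$copy_number >= amplification_cutoff)
  y <- zscore(samples[[outcome]], outcome)
  X <- lapply(covariates, function(cl) zscore(samples[[cl]], cl))
  names(X) <- covariates
  if (length(unique(amp)) < 2L) {
    warning("amplification indicator is constant (",
            if (amp[1L] == 1L) "all" else "no",
            " samples amplified); dropped from the model")
    df <- data.frame(y = y, X)
  } else {
    df <- data.frame(y = y, amplified = amp, X)
  }
  fit <- stats::lm(y ~ ., data = df)
  sm <- summary(fit)$coefficients
  out <- data.frame(term = rownames(sm),
                    estimate = sm[, 1L], std_error = sm[, 2L],
                    statistic = sm[, 3L], p_value = sm[, 4L],
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "outcome") <- outcome
  class(out) <- c("driver_fit", "data.frame")
  out
}

#' Two-group and correlation comparisons
#'
#' The comparison toolkit used throughout the analysis: a two-tailed
#' pooled-variance Student t test between two groups, a paired t test
#' on matched measurements, or a Spearman rank correlation (average
#' ranks for ties, p-value from the t approximation).
#'
#' @param x numeric vector of values.
#' @param groups for `student_t`: a two-level grouping of `x`.
#' @param y for `paired_t` and `spearman`: the second vector.
#' @param test one of `"student_t"`, `"paired_t"`, `"spearman"`.
#' @return list of class `group_comparison` with `statistic`,
#'   `p_value`, `estimate` (mean difference or correlation) and
#'   `method`.
#' @export
group_compare <- function(x, groups = NULL, y = NULL,
                          test = c("student_t", "paired_t", "spearman")) {
  test <- match.arg(test)
  res <- switch(test,
    student_t = {
      if (is.null(groups)) stop("student_t needs a grouping vector")
      groups <- as.factor(droplevels(as.factor(groups)))
      if (nlevels(groups) != 2L)
        stop("student_t needs exactly 2 groups, got ", nlevels(groups))
      if (any(table(groups) < 2L)) stop("each group needs n >= 2")
      ht <- stats::t.test(x ~ groups, var.equal = TRUE)
      list(statistic = unname(ht$statistic), p_value = ht$p.value,
           estimate = unname(diff(rev(ht$estimate))),
           method = "two-sided pooled-variance t test")
    },
    paired_t = {
      if (is.null(y) || length(y) != length(x))
        stop("paired_t needs y of the same length as x")
      ht <- stats::t.test(x, y, paired = TRUE)
      list(statistic = unname(ht$statistic), p_value = ht$p.value,
           estimate = unname(ht$estimate), method = "paired t test")
    },
    spearman = {
      if (is.null(y) || length(y) != length(x))
        stop("spearman needs y of the same length as x")
      if (length(x) < 3L) stop("spearman needs n >= 3")
      ht <- suppressWarnings(
        stats::cor.test(x, y, method = "spearman", exact = FALSE))
      list(statistic = unname(ht$statistic), p_value = ht$p.value,
           estimate = unname(ht$estimate),
           method = "Spearman rank correlation (t approximation)")
    })
  class(res) <- "group_comparison"
  res
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("<group_comparison> ", x$method,
      "\n  estimate  = ", format(x$estimate, digits = 4),
      "\n  statistic = ", format(x$statistic, digits = 4),
      "\n  p value   = ", format(x$p_value, digits = 4), "\n", sep = "")
  invisible(x)
}
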