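#' Age-covaried (partial) correlation between thickness and an outcome
#'
#' Residualizes both the regional thickness and the outcome on age by ordinary
#' least squares and correlates the residuals; the p-value uses the
#' t-transform with n - 3 degrees of freedom (one df spent on the covariate).
#' The reported `r_squared` is exactly the square of the partial correlation.
#'
#' @param thickness_region per-subject thickness of one region (mm).
#' @param outcome per-subject outcome score.
#' @param ages per-subject ages (years).
#' @param region,outcome_name optional labels carried into the result.
#' @return one-row data frame: region, outcome, partial_r, r_squared,
#'   p_value, n.
#' @export
partial_correlation_age <- function(thickness_region, outcome, ages,
                                    region = NA_character_,
                                    outcome_name = NA_character_) {
  n <- length(thickness_region)
  stopifnot(length(outcome) == n, length(ages) == n)
  if (n < 5L) stop("need n >= 5 subjects", call. = FALSE)
  if (stats::var(thickness_region) == 0) {
    stop("constant input: thickness_region", call. = FALSE)
  }
  if (stats::var(outcome) == 0) stop("constant input: outcome", call. = FALSE)
  if (stats::var(ages) == 0) stop("constant input: ages", call. = FALSE)
  rx <- stats::lm.fit(cbind(1, ages), thickness_region)$residuals
  ry <- stats::lm.fit(cbind(1, ages), outcome)$residuals
  if (stats::var(rx) == 0 || stats::var(ry) == 0) {
    stop("input is an exact linear function of age; partial correlation undefined",
         call. = FALSE)
  }
  r <- stats::cor(rx, ry)
  df <- n - 3L
  tval <- abs(r) * sqrt(df / max(1 - r^2, .Machine$double.eps))
  p <- if (r^2 >= 1) 0 else 2 * stats::pt(-tval, df)
  data.frame(region = region, outcome = outcome_name, partial_r = r,
             r_squared = r^2, p_value = p, n = n,
             stringsAsFactors = FALSE)
}

#' Two-sample t-test on one region's thickness
#'
#' Classical unpaired two-sample t-test (pooled variance by default; set
#' `welch = TRUE` for the unequal-variance variant). The sign of the statistic
#' follows `mean(group A) - mean(group B)`, A being the first factor level.
#'
#' @param thickness_region per-subject thickness of one region.
#' @param labels two-level factor/character of group membership.
#' @param welch use Welch's correction instead of pooled variance.
#' @param region optional label carried into the result.
#' @return one-row data frame: region, t_statistic, p_value, mean_a, mean_b,
#'   group_a, group_b.
#' @export
group_ttest <- function(thickness_region, labels, welch = FALSE,
                        region = NA_character_) {
  labels <- if (is.factor(labels)) labels else factor(labels, levels = unique(labels))
  stopifnot(nlevels(labels) == 2L, length(labels) == length(thickness_region))
  if (any(table(labels) < 2L)) {
    stop("each group needs at least 2 subjects", call. = FALSE)
  }
  lev <- levels(labels)
  xa <- thickness_region[labels == lev[1L]]
  xb <- thickness_region[labels == lev[2L]]
  tt <- stats::t.test(xa, xb, var.equal = !welch)
  data.frame(region = region, t_statistic = unname(tt$statistic),
             p_value = tt$p.value, mean_a = mean(xa), mean_b = mean(xb),
             group_a = lev[1L], group_b = lev[2L],
             stringsAsFactors = FALSE)
}

.outcome_vector <- function(cohort, outcome) {
  cl <- cohort$clinical
  switch(outcome,
         pci = cl$pci_score,
         wpai_percent = wpai_to_percent(cl$wpai_ability_raw),
         years_since_surgery = cl$years_since_surgery,
         years_since_last_treatment = cl$years_since_last_treatment,
         stop("unknown outcome: ", outcome, call. = FALSE))
}

#' Age-covaried association scan over all regions
#'
#' Computes the partial (age-covaried) correlation between every region's
#' thickness and one outcome, ranks regions by p-value and flags those with
#' p < `alpha` (uncorrected, by design; `fdr = TRUE` switches the flag to
#' Benjamini-Hochberg adjusted p-values and adds a `p_adjusted` column).
#'
#' @param cohort an `mcn_cohort` (or any list with `thickness` matrix and
#'   `clinical` data frame carrying `age` plus the outcome columns).
#' @param outcome one of `"pci"`, `"wpai_percent"`, `"years_since_surgery"`,
#'   `"years_since_last_treatment"`.
#' @param alpha significance level for the flag.
#' @param fdr apply Benjamini-Hochberg correction across the 66 regions.
#' @return data frame of per-region association results, ranked by p-value,
#'   with a logical `significant` column.
#' @export
scan_all_regions <- function(cohort, outcome, alpha = 0.05, fdr = FALSE) {
  y <- .outcome_vector(cohort, outcome)
  if (anyNA(y)) stop("outcome '", outcome, "' has missing values", call. = FALSE)
  if (stats::var(y) == 0) stop("outcome '", outcome, "' is constant", call. = FALSE)
  ages <- cohort$clinical$age
  th <- cohort$thickness
  res <- do.call(rbind, lapply(seq_len(ncol(th)), function(j) {
    partial_correlation_age(th[, j], y, ages, region = colnames(th)[j],
                            outcome_name = outcome)
  }))
  res <- res[order(res$p_value), ]
  if (fdr) {
    res$p_adjusted <- stats::p.adjust(res$p_value, method = "BH")
    res$significant <- res$p_adjusted < alpha
  } else {
    res$significant <- res$p_value < alpha
  }
  rownames(res) <- NULL
  res
}
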