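#' Remove the linear age effect from regional thickness
#'
#' Fits, for every region, an ordinary least-squares regression of thickness
#' on age over all supplied subjects, and returns the residuals. The fit is
#' always applied regardless of its significance; the per-region fit p-value
#' is stored for transparency. Residualization is performed on the pooled
#' cohort so that downstream group comparisons are not artifacts of separate
#' age fits (fit per group yourself by subsetting first if you want the
#' sensitivity variant).
#'
#' @param thickness subjects x regions numeric matrix.
#' @param ages per-subject ages (years), length `nrow(thickness)`.
#' @return object of class `mcn_resid`: list with `residuals` (same shape as
#'   `thickness`), `fit` (data frame: region, intercept, age_coef, p_value),
#'   and `ages`.
#' @examples
#' m <- matrix(2 + 0.01 * c(20, 30, 40), 3, 2,
#'             dimnames = list(paste0("s", 1:3), c("a", "b")))
#' r <- residualize_age(m, c(20, 30, 40))
#' max(abs(r$residuals))  # ~0: thickness exactly linear in age
#' @export
residualize_age <- function(thickness, ages) {
  stopifnot(is.matrix(thickness), is.numeric(ages))
  n <- nrow(thickness)
  if (length(ages) != n) stop("length(ages) must match nrow(thickness)", call. = FALSE)
  if (n < 3L) stop("need at least 3 subjects to residualize age", call. = FALSE)
  if (stats::var(ages) == 0) {
    stop("age is constant; skip residualization for this sample", call. = FALSE)
  }
  X <- cbind(1, ages)
  fit <- stats::lm.fit(X, thickness)
  coefs <- fit$coefficients
  resid <- thickness - X %*% coefs
  # per-region p-value of the age coefficient (t on n - 2 df)
  sxx <- sum((ages - mean(ages))^2)
  df <- n - 2L
  sigma2 <- colSums(resid^2) / df
  se <- sqrt(sigma2 / sxx)
  tval <- coefs[2L, ] / se
  pval <- 2 * stats::pt(-abs(tval), df)
  pval[se == 0] <- NA_real_
  out <- list(
    residuals = resid,
    fit = data.frame(region = colnames(thickness),
                     intercept = coefs[1L, ],
                     age_coef = coefs[2L, ],
                     p_value = pval,
                     row.names = NULL,
                     stringsAsFactors = FALSE),
    ages = ages
  )
  class(out) <- "mcn_resid"
  out
}

#' Classify cognitive impairment from a battery of Z-scores
#'
#' Applies the International Cognition and Cancer Task Force style rule: a
#' subject is impaired when at least two standardized test scores lie at or
#' below -2 Z. The boundary value -2.0 counts toward impairment.
#'
#' @param z_scores non-empty numeric vector of standardized test scores.
#' @return `"impaired"` or `"non-impaired"`.
#' @examples
#' classify_impairment(c(-2.0, -2.3, 0.1, 1.0))  # impaired
#' classify_impairment(c(-2.0, -1.99, -1.5))     # non-impaired
#' @export
classify_impairment <- function(z_scores) {
  if (!is.numeric(z_scores) || length(z_scores) == 0L || anyNA(z_scores)) {
    stop("z_scores must be a non-empty numeric vector without NAs", call. = FALSE)
  }
  if (sum(z_scores <= -2) >= 2L) "impaired" else "non-impaired"
}

#' Express a raw WPAI non-work ability score as a percentage
#'
#' The raw ability score lives on a 0-10 scale (higher = worse functioning);
#' the reporting convention expresses it as a percentage of that scale.
#'
#' @param raw numeric in \[0, 10\] (vectorized).
#' @return `raw * 10`, percent.
#' @export
wpai_to_percent <- function(raw) {
  if (!is.numeric(raw) || anyNA(raw) || any(raw < 0 | raw > 10)) {
    stop("raw WPAI ability score must lie in [0, 10]", call. = FALSE)
  }
  raw * 10
}
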