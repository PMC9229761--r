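#' Pearson correlation with two-sided p-value
#'
#' Product-moment correlation between two sequences with the classical
#' t-transform p-value on n - 2 degrees of freedom (two-sided).
#'
#' @param x,y numeric vectors of equal length, n >= 4, non-constant.
#' @return list with elements `r` and `p`.
#' @export
pearson_r <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y))
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length", call. = FALSE)
  if (n < 4L) stop("need n >= 4 observations", call. = FALSE)
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("zero variance input", call. = FALSE)
  }
  r <- stats::cor(x, y)
  list(r = r, p = .r_to_p(r, n))
}

# two-sided p for a Pearson r at sample size n (t on n - 2 df)
.r_to_p <- function(r, n) {
  df <- n - 2L
  r2 <- pmin(r^2, 1)
  tval <- abs(r) * sqrt(df / pmax(1 - r2, .Machine$double.eps))
  p <- 2 * stats::pt(-tval, df)
  p[r2 >= 1] <- 0
  p
}

#' Build a morphometric correlation network
#'
#' Evaluates the interregional Pearson correlation of age-residualized
#' thickness between every pair of regions cross-sectionally across subjects,
#' with two-sided p-values and a significance mask at level `alpha`
#' (uncorrected, by design; apply [stats::p.adjust()] to `$p` yourself for a
#' corrected variant).
#'
#' @param resid an `mcn_resid` from [residualize_age()], or a plain
#'   subjects x regions numeric matrix.
#' @param alpha two-sided significance level for the edge mask.
#' @return object of class `mcn`: list with `r`, `p` (region x region
#'   matrices), `sig_mask` (logical, diagonal excluded), `n_subjects`,
#'   `alpha`, `regions`.
#' @export
build_mcn <- function(resid, alpha = 0.05) {
  X <- if (inherits(resid, "mcn_resid")) resid$residuals else resid
  stopifnot(is.matrix(X), alpha > 0, alpha < 1)
  n <- nrow(X)
  if (n < 4L) stop("need at least 4 subjects to build an MCN", call. = FALSE)
  sds <- apply(X, 2L, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance region(s): ",
         paste(colnames(X)[sds == 0], collapse = ", "), call. = FALSE)
  }
  r <- stats::cor(X)
  p <- .r_to_p(r, n)
  diag(p) <- 0
  sig <- p < alpha
  diag(sig) <- FALSE
  out <- list(r = r, p = p, sig_mask = sig, n_subjects = n, alpha = alpha,
              regions = colnames(X))
  class(out) <- "mcn"
  out
}

#' Edge-wise Fisher r-to-z comparison of two MCNs
#'
#' For every region pair, the group-difference statistic
#' `z = (atanh(r_a) - atanh(r_b)) / sqrt(1/(n_a-3) + 1/(n_b-3))`. Positive
#' entries mean a stronger (more positive) correlation in group A. Exact
#' correlations of magnitude 1 are clamped to 1 - 1e-7 with a warning, since
#' atanh diverges there.
#'
#' @param mcn_a,mcn_b `mcn` objects with matching regions, each built from at
#'   least 4 subjects.
#' @return object of class `mcn_edgez`: list with `z` (region x region,
#'   zero diagonal), `n1`, `n2`.
#' @export
edge_z_compare <- function(mcn_a, mcn_b) {
  stopifnot(inherits(mcn_a, "mcn"), inherits(mcn_b, "mcn"))
  if (!identical(mcn_a$regions, mcn_b$regions)) {
    stop("MCNs cover different region sets", call. = FALSE)
  }
  n1 <- mcn_a$n_subjects
  n2 <- mcn_b$n_subjects
  if (n1 < 4L || n2 < 4L) stop("both groups need n >= 4", call. = FALSE)
  clamp <- function(r) {
    off <- r[upper.tri(r)]
    if (any(abs(off) >= 1 - .Machine$double.eps^0.5)) {
      warning("correlation(s) of magnitude 1 clamped before atanh", call. = FALSE)
    }
    pmin(pmax(r, -(1 - 1e-7)), 1 - 1e-7)   # diagonal excluded from the result
  }
  z <- (atanh(clamp(mcn_a$r)) - atanh(clamp(mcn_b$r))) /
    sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  diag(z) <- 0
  out <- list(z = z, n1 = n1, n2 = n2)
  class(out) <- "mcn_edgez"
  out
}

# shared fast path: pick the top-|r| significant edges at a target density.
# Returns a 2-column matrix of (i, j) upper-triangle indices.
.top_edges <- function(r, sig, density, warn = TRUE) {
  nr <- nrow(r)
  n_pairs <- nr * (nr - 1L) / 2L
  m <- floor(density * n_pairs)
  ut <- which(upper.tri(r) & sig, arr.ind = TRUE)
  if (m > nrow(ut)) {
    if (warn) {
      warning("density ", density, " requests ", m, " edges but only ",
              nrow(ut), " pairs are significant; keeping all significant edges",
              call. = FALSE)
    }
    m <- nrow(ut)
  }
  if (m == 0L) return(ut[0, , drop = FALSE])
  absr <- abs(r[ut])
  ord <- order(-absr, ut[, 1L], ut[, 2L])   # ties: smaller index pair first
  ut[ord[seq_len(m)], , drop = FALSE]
}

#' Binarize an MCN at a target connection density
#'
#' Keeps the `floor(density * P)` significant region pairs of largest absolute
#' correlation (P = number of distinct pairs, 2145 for 66 regions); negative
#' correlations are eligible edges. Ties in |r| are broken toward the smaller
#' region-index pair for determinism. If fewer pairs are significant than
#' requested, all significant edges are kept with a warning.
#'
#' @param mcn an `mcn`.
#' @param density target edge density in (0, 1].
#' @return symmetric 0/1 adjacency matrix with zero diagonal, dimnames =
#'   regions, with the signs of the retained correlations in attribute
#'   `"edge_sign"`.
#' @export
binarize_by_density <- function(mcn, density) {
  stopifnot(inherits(mcn, "mcn"))
  if (!is.numeric(density) || length(density) != 1L ||
      density <= 0 || density > 1) {
    stop("density must lie in (0, 1]", call. = FALSE)
  }
  keep <- .top_edges(mcn$r, mcn$sig_mask, density)
  nr <- length(mcn$regions)
  adj <- matrix(0, nr, nr, dimnames = list(mcn$regions, mcn$regions))
  sgn <- adj
  if (nrow(keep)) {
    adj[keep] <- 1
    sgn[keep] <- sign(mcn$r[keep])
    adj <- adj + t(adj)
    sgn <- sgn + t(sgn)
  }
  attr(adj, "edge_sign") <- sgn
  adj
}
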