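#' Configuration for the full analysis pipeline
#'
#' A single validated configuration object is the source of truth for a run:
#' every random draw (small-world nulls, permutations, optional simulation)
#' traces to a named seed here, so re-running the same config reproduces all
#' numbers exactly.
#'
#' @param alpha edge-significance level for MCN construction.
#' @param densities density grid for the small-world / centrality sweep.
#' @param robustness_density single density for the robustness analysis.
#' @param n_null small-world null graphs per density.
#' @param n_perm robustness permutations.
#' @param seeds named list: `null` (small-world ensembles), `permutation`.
#' @param fdr,welch,recompute_attack,per_group_residualization analysis flags
#'   (see the stage functions).
#' @param outcomes outcome names passed to [scan_all_regions()].
#' @return object of class `mcn_pipeline_config`.
#' @export
pipeline_config <- function(alpha = 0.05,
                            densities = seq(0.05, 0.50, by = 0.05),
                            robustness_density = 0.20,
                            n_null = 100L,
                            n_perm = 1000L,
                            seeds = list(null = 11L, permutation = 42L),
                            fdr = FALSE,
                            welch = FALSE,
                            recompute_attack = FALSE,
                            per_group_residualization = FALSE,
                            outcomes = c("pci", "wpai_percent",
                                         "years_since_surgery",
                                         "years_since_last_treatment")) {
  if (!is.numeric(densities) || any(densities <= 0) || any(densities > 1)) {
    stop("densities must lie in (0, 1]", call. = FALSE)
  }
  if (robustness_density <= 0 || robustness_density > 1) {
    stop("robustness_density must lie in (0, 1]", call. = FALSE)
  }
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)", call. = FALSE)
  if (!all(c("null", "permutation") %in% names(seeds))) {
    stop("seeds must name `null` and `permutation`", call. = FALSE)
  }
  cfg <- list(alpha = alpha, densities = densities,
              robustness_density = robustness_density,
              n_null = as.integer(n_null), n_perm = as.integer(n_perm),
              seeds = lapply(seeds, as.integer),
              fdr = fdr, welch = welch,
              recompute_attack = recompute_attack,
              per_group_residualization = per_group_residualization,
              outcomes = outcomes)
  class(cfg) <- "mcn_pipeline_config"
  cfg
}

.mcn_summary <- function(mcn) {
  ut <- upper.tri(mcn$r)
  list(n_subjects = mcn$n_subjects,
       alpha = mcn$alpha,
       n_significant_edges = sum(mcn$sig_mask[ut]),
       n_negative_significant = sum(mcn$sig_mask[ut] & mcn$r[ut] < 0),
       mean_abs_r = mean(abs(mcn$r[ut])))
}

.group_stack <- function(mcn, cfg) {
  sweep <- lapply(seq_along(cfg$densities), function(i) {
    d <- cfg$densities[i]
    adj <- suppressWarnings(binarize_by_density(mcn, d))
    sw <- suppressWarnings(small_world(adj, n_null = cfg$n_null,
                                       null_seed = cfg$seeds$null + i))
    list(density = d,
         metrics = node_metrics(adj, density = d),
         cp = sw$cp, lp = sw$lp, gamma = sw$gamma, lambda = sw$lambda,
         sigma = sw$sigma)
  })
  metrics_all <- do.call(rbind, lapply(sweep, `[[`, "metrics"))
  hubs <- predominant_nodes(metrics_all)
  list(
    small_world = data.frame(
      density = vapply(sweep, `[[`, numeric(1), "density"),
      cp = vapply(sweep, `[[`, numeric(1), "cp"),
      lp = vapply(sweep, `[[`, numeric(1), "lp"),
      gamma = vapply(sweep, `[[`, numeric(1), "gamma"),
      lambda = vapply(sweep, `[[`, numeric(1), "lambda"),
      sigma = vapply(sweep, `[[`, numeric(1), "sigma")
    ),
    predominant_nodes = hubs$regions,
    node_metrics_mean = hubs$metrics
  )
}

#' Run the full morphometric-correlation-network pipeline
#'
#' Executes every stage on a cohort: pooled age residualization, per-group and
#' pooled MCN construction, edge-wise Fisher-z group comparison, the
#' small-world / centrality density sweep with predominant-node calls, the
#' targeted-attack robustness comparison with its group-label permutation
#' test, and the ROI-wise outcome association scans. All randomness is
#' governed by the seeds in `config`; two runs with the same cohort and
#' config return identical reports.
#'
#' @param cohort an `mcn_cohort` (from [simulate_cohort()] or assembled from
#'   [read_thickness_table()] / [read_clinical_table()] output via
#'   [as_cohort()]).
#' @param config an [pipeline_config()].
#' @param out_dir optional directory; when given, the report is written to
#'   `report.json` (plus `associations.csv` and `residual_thickness.tsv`).
#' @return object of class `mcn_report` (nested list; see the vignette).
#' @export
run_full_pipeline <- function(cohort, config = pipeline_config(),
                              out_dir = NULL) {
  stopifnot(inherits(config, "mcn_pipeline_config"))
  cohort <- as_cohort(cohort)
  groups <- factor(ifelse(cohort$clinical$impaired == "yes",
                          "impaired", "nonimpaired"),
                   levels = c("impaired", "nonimpaired"))
  if (any(table(groups) < 4L)) {
    stop("stage preprocess: need at least 4 subjects per impairment group",
         call. = FALSE)
  }
  ages <- cohort$clinical$age

  resid <- residualize_age(cohort$thickness, ages)
  res_mat <- resid$residuals
  if (config$per_group_residualization) {
    for (g in levels(groups)) {
      idx <- groups == g
      res_mat[idx, ] <- residualize_age(cohort$thickness[idx, , drop = FALSE],
                                        ages[idx])$residuals
    }
  }

  mcn_by_group <- lapply(stats::setNames(nm = levels(groups)), function(g) {
    build_mcn(res_mat[groups == g, , drop = FALSE], alpha = config$alpha)
  })
  mcn_pooled <- build_mcn(res_mat, alpha = config$alpha)

  ez <- edge_z_compare(mcn_by_group[[1L]], mcn_by_group[[2L]])
  ut <- which(upper.tri(ez$z), arr.ind = TRUE)
  top <- ut[order(-abs(ez$z[ut]))[seq_len(10L)], , drop = FALSE]
  edge_z_extremes <- data.frame(
    region_a = mcn_pooled$regions[top[, 1L]],
    region_b = mcn_pooled$regions[top[, 2L]],
    z = ez$z[top], stringsAsFactors = FALSE)

  stacks <- lapply(mcn_by_group, .group_stack, cfg = config)
  stack_pooled <- .group_stack(mcn_pooled, config)

  perm <- permutation_test(res_mat, groups,
                           alpha = config$alpha,
                           density = config$robustness_density,
                           n_perm = config$n_perm,
                           seed = config$seeds$permutation,
                           recompute = config$recompute_attack)

  assoc <- list()
  for (oc in config$outcomes) {
    y <- tryCatch(.outcome_vector(cohort, oc), error = function(e) NULL)
    if (is.null(y) || anyNA(y) || stats::var(y) == 0) next
    assoc[[oc]] <- scan_all_regions(cohort, oc, alpha = config$alpha,
                                    fdr = config$fdr)
  }

  report <- list(
    package_version = as.character(utils::packageVersion("mcnet")),
    config = unclass(config),
    n_subjects = nrow(cohort$thickness),
    groups = as.list(table(groups)),
    mcn_summary = lapply(c(mcn_by_group, list(pooled = mcn_pooled)),
                         .mcn_summary),
    edge_z_extremes = edge_z_extremes,
    small_world = lapply(stacks, `[[`, "small_world"),
    small_world_pooled = stack_pooled$small_world,
    predominant_nodes = lapply(stacks, `[[`, "predominant_nodes"),
    predominant_nodes_pooled = stack_pooled$predominant_nodes,
    robustness = list(
      density = config$robustness_density,
      fractions = perm$fractions,
      curve_impaired = perm$curve_a,
      curve_nonimpaired = perm$curve_b,
      observed_diff = perm$observed_diff,
      critical_low = perm$critical_low,
      critical_high = perm$critical_high,
      significant_fractions = perm$significant_fractions,
      n_perm = perm$n_perm, n_redrawn = perm$n_redrawn
    ),
    associations = assoc
  )
  class(report) <- "mcn_report"

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(report_to_json(report),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    if (length(assoc)) {
      utils::write.csv(do.call(rbind, assoc),
                       file.path(out_dir, "associations.csv"),
                       row.names = FALSE)
    }
    write_thickness_table(res_mat, file.path(out_dir,
                                             "residual_thickness.tsv"))
  }
  report
}

# plain-list view of a report for JSON serialization
#' @keywords internal
report_to_json <- function(report) {
  rapply(unclass(report), how = "replace", f = function(x) x)
}

#' Assemble a cohort from thickness and clinical tables
#'
#' Joins a thickness matrix and a clinical table into the cohort container the
#' pipeline consumes, checking that both cover the same subjects and aligning
#' the clinical rows to the thickness row order.
#'
#' @param x an existing `mcn_cohort` (returned unchanged), or a
#'   subjects x regions thickness matrix.
#' @param clinical clinical data frame (see [read_clinical_table()]).
#' @return an `mcn_cohort`.
#' @export
as_cohort <- function(x, clinical = NULL) {
  if (inherits(x, "mcn_cohort")) return(x)
  stopifnot(is.matrix(x), is.data.frame(clinical))
  ids <- rownames(x)
  if (!setequal(ids, clinical$subject_id)) {
    stop("thickness and clinical tables cover different subjects", call. = FALSE)
  }
  clinical <- clinical[match(ids, clinical$subject_id), ]
  rownames(clinical) <- NULL
  out <- list(clinical = clinical, thickness = x,
              group_of = stats::setNames(
                ifelse(clinical$impaired == "yes", "impaired", "nonimpaired"),
                ids),
              truth = NULL)
  class(out) <- "mcn_cohort"
  out
}

#' @export
print.mcn_report <- function(x, ...) {
  cat("Morphometric correlation network report\n")
  cat("  subjects:", x$n_subjects,
      sprintf("(%s)", paste(names(x$groups), unlist(x$groups),
                            sep = "=", collapse = ", ")), "\n")
  for (g in names(x$mcn_summary)) {
    s <- x$mcn_summary[[g]]
    cat(sprintf("  MCN %-12s n=%d, %d significant edges (%d negative)\n",
                g, s$n_subjects, s$n_significant_edges,
                s$n_negative_significant))
  }
  sf <- x$robustness$significant_fractions
  cat("  robustness: permutation-significant at",
      if (length(sf)) paste0(length(sf), " fractions (min ",
                             format(min(sf), digits = 3), ")")
      else "no fractions", "\n")
  cat("  predominant nodes (pooled):",
      paste(x$predominant_nodes_pooled, collapse = ", "), "\n")
  invisible(x)
}

#' Plot a robustness permutation result
#'
#' Base-graphics line plot of the two group attack curves (top) and the
#' observed per-fraction difference with its pointwise permutation band
#' (bottom).
#'
#' @param x an `mcn_permutation`.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.mcn_permutation <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1.5, 1))
  on.exit(graphics::par(op))
  graphics::matplot(x$fractions, cbind(x$curve_a, x$curve_b), type = "l",
                    lty = 1, col = c("firebrick", "steelblue"),
                    xlab = "fraction of nodes removed",
                    ylab = "relative size of largest component", ...)
  graphics::legend("topright", legend = x$groups, lty = 1, bty = "n",
                   col = c("firebrick", "steelblue"))
  graphics::matplot(x$fractions,
                    cbind(x$observed_diff, x$critical_low, x$critical_high),
                    type = "l", lty = c(1, 2, 2),
                    col = c("black", "grey50", "grey50"),
                    xlab = "fraction of nodes removed",
                    ylab = sprintf("difference (%s - %s)",
                                   x$groups[1], x$groups[2]))
  graphics::abline(h = 0, col = "grey80")
  invisible(x)
}
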