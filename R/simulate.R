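#' Configuration for the synthetic cortical-thickness cohort generator
#'
#' Defines the statistical structure the downstream analyses assume: a linear
#' age effect on per-region mean thickness, group-dependent modular (block
#' compound-symmetric) interregional correlation, and outcome scores linearly
#' linked to chosen regions' thickness plus noise. Defaults emulate the study
#' cohort: 12 subjects per impairment group, ages spanning 22-70 years, a
#' 2.5 mm baseline thickness thinning at 0.005 mm/year, 66 regions partitioned
#' into 6 modules, and residual thickness noise of 0.1 mm.
#'
#' `rho_within`/`rho_between` may be a single value (both groups) or a named
#' vector with entries `impaired` and `nonimpaired`. `mean_offset` optionally
#' adds a per-region mm offset to one group's mean thickness (named list of
#' length-1-or-66 vectors), emulating regional group thickness differences.
#'
#' @param n_per_group subjects per impairment group.
#' @param seed integer master seed; identical configs reproduce bit-identical
#'   cohorts.
#' @param age_range two-element numeric, years.
#' @param baseline_thickness scalar or 66-vector, mm.
#' @param age_slope mm per year (negative = thinning).
#' @param n_modules number of correlation modules partitioning the 66 regions
#'   (contiguous blocks; remainder regions join the last module).
#' @param rho_within within-module interregional correlation per group.
#' @param rho_between between-module correlation per group.
#' @param noise_sd residual thickness standard deviation, mm.
#' @param outcome_links list of links, each
#'   `list(region=, outcome=, slope=, noise_sd=)` with `outcome` one of
#'   `"pci"`, `"wpai"`, `"years_since_surgery"`, `"years_since_last_treatment"`;
#'   `slope` is outcome units per mm of (centered) regional thickness.
#' @param mean_offset optional named list (`impaired`/`nonimpaired`) of mm
#'   offsets added to group mean thickness.
#' @param impairment_mode `"group"` assigns the impairment label from group
#'   membership; `"zscores"` simulates a 10-test neuropsychological battery
#'   per subject and labels through [classify_impairment()].
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_per_group = 12L,
                       seed = 1L,
                       age_range = c(22, 70),
                       baseline_thickness = 2.5,
                       age_slope = -0.005,
                       n_modules = 6L,
                       rho_within = 0.6,
                       rho_between = 0.1,
                       noise_sd = 0.1,
                       outcome_links = list(
                         list(region = "l STG", outcome = "pci",
                              slope = 100, noise_sd = 16),
                         list(region = "l PCUN", outcome = "wpai",
                              slope = -15, noise_sd = 2.4)
                       ),
                       mean_offset = NULL,
                       impairment_mode = c("group", "zscores")) {
  impairment_mode <- match.arg(impairment_mode)
  groups <- c("impaired", "nonimpaired")
  expand <- function(x, what) {
    if (length(x) == 1L) x <- stats::setNames(rep(x, 2L), groups)
    if (is.null(names(x))) names(x) <- groups
    if (!all(groups %in% names(x))) {
      stop("`", what, "` needs entries for both groups", call. = FALSE)
    }
    x[groups]
  }
  stopifnot(n_per_group >= 1, length(age_range) == 2L,
            age_range[1] < age_range[2], n_modules >= 1, n_modules <= 66,
            noise_sd > 0)
  cfg <- list(
    n_per_group = as.integer(n_per_group),
    seed = as.integer(seed),
    age_range = as.numeric(age_range),
    baseline_thickness = baseline_thickness,
    age_slope = age_slope,
    n_modules = as.integer(n_modules),
    rho_within = expand(rho_within, "rho_within"),
    rho_between = expand(rho_between, "rho_between"),
    noise_sd = noise_sd,
    outcome_links = outcome_links,
    mean_offset = mean_offset,
    impairment_mode = impairment_mode
  )
  for (g in groups) {
    R <- block_correlation(66L, cfg$n_modules, cfg$rho_within[[g]],
                           cfg$rho_between[[g]])
    ev <- min(eigen(R, symmetric = TRUE, only.values = TRUE)$values)
    if (ev < -1e-8) {
      stop("implied 66x66 correlation matrix for group '", g,
           "' is not positive semi-definite", call. = FALSE)
    }
  }
  class(cfg) <- "sim_config"
  cfg
}

#' Module membership for a contiguous block partition
#' @keywords internal
module_assignment <- function(n_regions, n_modules) {
  size <- n_regions %/% n_modules
  m <- rep(seq_len(n_modules), each = size)
  if (length(m) < n_regions) {           # remainder joins the last module
    m <- c(m, rep(n_modules, n_regions - length(m)))
  }
  m
}

#' Block compound-symmetric correlation matrix
#'
#' Correlation `rho_within` between regions of the same module, `rho_between`
#' across modules, unit diagonal.
#' @keywords internal
block_correlation <- function(n_regions, n_modules, rho_within, rho_between) {
  if (!(rho_within >= rho_between && rho_between >= 0 && rho_within < 1)) {
    stop("need rho_within >= rho_between >= 0 and rho_within < 1", call. = FALSE)
  }
  m <- module_assignment(n_regions, n_modules)
  same <- outer(m, m, "==")
  R <- ifelse(same, rho_within, rho_between)
  diag(R) <- 1
  R
}

.sim_one_group <- function(cfg, group, atlas, keys, id_offset) {
  n <- cfg$n_per_group
  ages <- round(stats::runif(n, cfg$age_range[1], cfg$age_range[2]))
  R <- block_correlation(66L, cfg$n_modules, cfg$rho_within[[group]],
                         cfg$rho_between[[group]])
  noise <- MASS::mvrnorm(n, mu = rep(0, 66L), Sigma = R * cfg$noise_sd^2)
  noise <- matrix(noise, nrow = n)
  base <- rep(cfg$baseline_thickness, length.out = 66L)
  off <- cfg$mean_offset[[group]]
  if (!is.null(off)) base <- base + rep(off, length.out = 66L)
  age_c <- ages - mean(cfg$age_range)
  thick <- matrix(base, n, 66L, byrow = TRUE) +
    outer(age_c, rep(cfg$age_slope, 66L)) + noise
  thick <- pmin(pmax(thick, 0.5), 6)     # physiological clamp, mm
  dimnames(thick) <- list(sprintf("sub%03d", id_offset + seq_len(n)), keys)
  list(ages = ages, thickness = thick)
}

.sim_outcome_noise <- function(n, links, thickness, keys, atlas) {
  # returns per-outcome linked signal (centered) and the link noise draws
  out <- list(pci = rep(0, n), wpai = rep(0, n),
              years_since_surgery = rep(0, n),
              years_since_last_treatment = rep(0, n))
  for (lk in links) {
    key <- atlas_region_keys(atlas)[atlas_lookup(atlas, lk$region)$index + 1L]
    th <- thickness[, key]
    out[[lk$outcome]] <- out[[lk$outcome]] +
      lk$slope * (th - mean(th)) + stats::rnorm(n, 0, lk$noise_sd)
  }
  out
}

#' Simulate a synthetic two-group cortical-thickness cohort
#'
#' Draws per-subject regional thickness with the configured age slope and
#' group-dependent modular correlation, clinical covariates matching the study
#' population's marginals (sex ratio, tumor location/grade frequencies,
#' log-normal time since surgery), and cognitive/functional outcomes linearly
#' linked to the configured regions' thickness. Fully deterministic given
#' `config$seed`.
#'
#' @param config a [sim_config()].
#' @return an object of class `mcn_cohort`: list with elements `clinical`
#'   (data frame), `thickness` (2n x 66 matrix in atlas order), `group_of`
#'   (named character vector), and `truth` (the config).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  atlas <- load_atlas()
  keys <- atlas_region_keys(atlas)
  with_seed(config$seed, {
    gi <- .sim_one_group(config, "impaired", atlas, keys, 0L)
    gn <- .sim_one_group(config, "nonimpaired", atlas, keys, config$n_per_group)
    thickness <- rbind(gi$thickness, gn$thickness)
    n <- nrow(thickness)
    ages <- c(gi$ages, gn$ages)
    group <- rep(c("impaired", "nonimpaired"), each = config$n_per_group)

    link <- .sim_outcome_noise(n, config$outcome_links, thickness, keys, atlas)
    yss <- pmax(stats::rlnorm(n, log(5.5), 0.55) + link$years_since_surgery, 0.25)
    yslt <- pmax(pmin(yss * stats::runif(n, 0.6, 0.95) +
                        link$years_since_last_treatment, yss), 0)
    pci <- pmin(pmax(round(43.7 + link$pci + stats::rnorm(n, 0, 2)), 0), 72)
    wpai <- pmin(pmax(round(2.6 + link$wpai + stats::rnorm(n, 0, 0.5), 1), 0), 10)

    impaired <- ifelse(group == "impaired", "yes", "no")
    battery <- NULL
    if (config$impairment_mode == "zscores") {
      mu <- ifelse(group == "impaired", -1.6, 0)
      battery <- t(vapply(mu, function(m) stats::rnorm(10L, m, 1),
                          numeric(10L)))
      rownames(battery) <- rownames(thickness)
      impaired <- ifelse(apply(battery, 1L, classify_impairment) == "impaired",
                         "yes", "no")
    }

    clinical <- data.frame(
      subject_id = rownames(thickness),
      age = ages,
      sex = sample(c("M", "F"), n, replace = TRUE, prob = c(2 / 3, 1 / 3)),
      tumor_side = sample(c("L", "R"), n, replace = TRUE),
      tumor_location = sample(.tumor_location_codes, n, replace = TRUE,
                              prob = c(13, 3, 5, 1, 1, 1)),
      who_grade = sample(c("II", "III", "IV"), n, replace = TRUE,
                         prob = c(7, 12, 5)),
      idh_status = sample(c("mutant", "wild-type", "unknown"), n,
                          replace = TRUE, prob = c(18, 2, 3)),
      years_since_surgery = round(yss, 2),
      years_since_last_treatment = round(yslt, 2),
      impaired = impaired,
      pci_score = pci,
      wpai_ability_raw = wpai,
      stringsAsFactors = FALSE
    )
    cohort <- list(clinical = clinical, thickness = thickness,
                   group_of = stats::setNames(group, rownames(thickness)),
                   battery = battery, truth = config)
    class(cohort) <- "mcn_cohort"
    cohort
  })
}

#' Simulate a pair of cohorts with no group effect
#'
#' Draws two cohorts from the identical generator (the `impaired` group's
#' correlation parameters applied to both groups of both cohorts), providing
#' the null setting for type-I-error studies of the robustness permutation
#' test.
#'
#' @param config a [sim_config()]; `n_per_group` must be at least 4, the
#'   minimum the correlation/permutation machinery supports.
#' @param seed integer seed for the pair (overrides `config$seed`).
#' @return list with elements `a` and `b`, each an `mcn_cohort`.
#' @export
simulate_null_pair <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_per_group < 4L) {
    stop("need n >= 4 per group for permutation/Fisher machinery", call. = FALSE)
  }
  cfg <- config
  cfg$rho_within[] <- config$rho_within[["impaired"]]
  cfg$rho_between[] <- config$rho_between[["impaired"]]
  cfg$mean_offset <- NULL
  cfg$seed <- as.integer(seed)
  a <- simulate_cohort(cfg)
  cfg$seed <- as.integer(seed) + 500000L
  b <- simulate_cohort(cfg)
  list(a = a, b = b)
}

#' Write a simulated cohort to disk
#'
#' Emits `thickness.tsv` (wide TSV), `clinical.csv`, and `truth.json` (the
#' generator configuration) under `dir`.
#'
#' @param cohort an `mcn_cohort`.
#' @param dir output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "mcn_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_thickness_table(cohort$thickness, file.path(dir, "thickness.tsv"))
  utils::write.csv(cohort$clinical, file.path(dir, "clinical.csv"),
                   row.names = FALSE, quote = FALSE)
  truth <- cohort$truth
  class(truth) <- NULL
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
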