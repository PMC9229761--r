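#' Read a wide regional cortical-thickness table
#'
#' Reads a tab-delimited wide table in the FreeSurfer `aparcstats2table
#' --hemi both --meas thickness` dialect: one row per subject, a subject-id
#' first column (any header), and one `lh_<region>_thickness` /
#' `rh_<region>_thickness` column per atlas region (the `_thickness` suffix is
#' optional). Columns are reordered to atlas index order; row order is kept.
#' Non-atlas columns (e.g. `eTIV`, `BrainSegVolNotVent`, the per-hemisphere
#' `MeanThickness` columns) are dropped with a warning.
#'
#' @param path TSV file path.
#' @param atlas an `mcn_atlas`; defaults to the packaged registry.
#' @return numeric matrix, subjects x 66, rownames = subject ids, colnames =
#'   canonical region keys in atlas order.
#' @export
read_thickness_table <- function(path, atlas = load_atlas()) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (ncol(tab) < 2L) stop("thickness table has no region columns", call. = FALSE)
  ids <- tab[[1L]]
  if (anyDuplicated(ids)) {
    stop("duplicate subject id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  keys <- atlas_region_keys(atlas)
  have <- names(tab)[-1L]
  # map on-disk headers to canonical keys, tolerating a missing suffix
  canon <- ifelse(grepl("_thickness$", have), have, paste0(have, "_thickness"))
  col_for <- match(keys, canon)
  if (anyNA(col_for)) {
    stop("missing region column(s): ",
         paste(keys[is.na(col_for)], collapse = ", "), call. = FALSE)
  }
  extra <- setdiff(have, have[col_for])
  if (length(extra)) {
    warning("ignoring non-atlas column(s): ", paste(extra, collapse = ", "),
            call. = FALSE)
  }
  mat <- matrix(NA_real_, nrow(tab), length(keys),
                dimnames = list(ids, keys))
  for (j in seq_along(keys)) {
    raw <- tab[[col_for[j] + 1L]]
    val <- suppressWarnings(as.numeric(raw))
    if (anyNA(val)) {
      bad <- which(is.na(val))[1L]
      stop("non-numeric thickness value '", raw[bad], "' at row ", bad,
           ", column ", have[col_for[j]], call. = FALSE)
    }
    mat[, j] <- val
  }
  if (any(mat <= 0) || any(mat >= 10)) {
    stop("thickness values outside the sanity range (0, 10) mm", call. = FALSE)
  }
  mat
}

#' Write a thickness matrix as a wide TSV
#'
#' Inverse of [read_thickness_table()]; emits the same wide tab-delimited
#' dialect so written tables round-trip exactly (within numeric formatting,
#' 15 significant digits).
#'
#' @param mat subjects x regions numeric matrix with dimnames.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_thickness_table <- function(mat, path) {
  stopifnot(is.matrix(mat), !is.null(rownames(mat)), !is.null(colnames(mat)))
  df <- data.frame(subject = rownames(mat),
                   format(mat, digits = 15, trim = TRUE, scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.tumor_location_codes <- c("FC", "PC", "TC", "OC", "FPC", "FTC")

#' Read a clinical covariate table
#'
#' Reads a CSV of per-subject clinical covariates: demographics, tumor
#' location/grade/IDH status, treatment history times, the dichotomous
#' cognitive-impairment label, and (optionally) the FACT-Cog Perceived
#' Cognitive Impairment score (`pci_score`, 0-72, higher = better) and the raw
#' WPAI non-work ability score (`wpai_ability_raw`, 0-10, higher = worse).
#' The packaged fixture `table1_clinical.csv` transcribes the study cohort of
#' 24 glioma survivors verbatim.
#'
#' @param path CSV file path; defaults to the packaged cohort fixture.
#' @return data frame of validated clinical records, one row per subject.
#' @export
read_clinical_table <- function(path = system.file("extdata",
                                                   "table1_clinical.csv",
                                                   package = "mcnet")) {
  cl <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(subject_id = "character"))
  required <- c("subject_id", "age", "sex", "tumor_side", "tumor_location",
                "who_grade", "years_since_surgery",
                "years_since_last_treatment", "impaired")
  miss <- setdiff(required, names(cl))
  if (length(miss)) {
    stop("clinical table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(cl$subject_id)) stop("duplicate subject ids", call. = FALSE)
  bad_loc <- setdiff(unique(cl$tumor_location), .tumor_location_codes)
  if (length(bad_loc)) {
    stop("unknown tumor-location code(s): ", paste(bad_loc, collapse = ", "),
         call. = FALSE)
  }
  stopifnot(all(cl$sex %in% c("M", "F")),
            all(cl$who_grade %in% c("II", "III", "IV")),
            all(cl$impaired %in% c("yes", "no")))
  if ("idh_status" %in% names(cl) &&
      !all(cl$idh_status %in% c("mutant", "wild-type", "unknown"))) {
    stop("unknown IDH status code", call. = FALSE)
  }
  if (any(cl$age < 18)) {
    warning("age below 18 present; cohort inclusion requires adults",
            call. = FALSE)
  }
  if (any(cl$years_since_surgery < 0) ||
      any(cl$years_since_last_treatment < 0) ||
      any(cl$years_since_last_treatment > cl$years_since_surgery + 1e-9)) {
    stop("treatment times invalid: need 0 <= years_since_last_treatment <= years_since_surgery",
         call. = FALSE)
  }
  if (!"pci_score" %in% names(cl)) cl$pci_score <- NA_real_
  if (!"wpai_ability_raw" %in% names(cl)) cl$wpai_ability_raw <- NA_real_
  ok <- is.na(cl$pci_score) | (cl$pci_score >= 0 & cl$pci_score <= 72)
  if (!all(ok)) stop("pci_score outside [0, 72]", call. = FALSE)
  ok <- is.na(cl$wpai_ability_raw) |
    (cl$wpai_ability_raw >= 0 & cl$wpai_ability_raw <= 10)
  if (!all(ok)) stop("wpai_ability_raw outside [0, 10]", call. = FALSE)
  cl
}
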