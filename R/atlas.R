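#' The 66-region bilateral Desikan-Killiany cortical registry
#'
#' Loads the packaged atlas registry: 66 cortical regions of interest, 33 per
#' hemisphere, from the gyral-based Desikan-Killiany parcellation (the
#' banks-of-the-superior-temporal-sulcus label is not part of this 33-region
#' bilateral set). Each region carries its canonical FreeSurfer label name,
#' hemisphere, a short figure-style abbreviation (e.g. `"l STG"` for the left
#' superior temporal gyrus) and an annotation naming the large-scale functional
#' network (default mode / salience / language / other) it is conventionally
#' assigned to. The network annotation is used for report grouping only and
#' never enters any computation.
#'
#' @return A data frame of class `mcn_atlas` with columns `index` (0-65),
#'   `hemisphere` (`"left"`/`"right"`), `name`, `abbreviation`,
#'   `network_label`, ordered by `index`.
#' @examples
#' atlas <- load_atlas()
#' nrow(atlas)                     # 66
#' table(atlas$hemisphere)         # 33 / 33
#' atlas_lookup(atlas, "l STG")$name
#' @export
load_atlas <- function() {
  path <- system.file("extdata", "atlas_dk66.csv", package = "mcnet")
  if (!nzchar(path) || !file.exists(path)) {
    stop("packaged atlas registry not found; broken installation", call. = FALSE)
  }
  atlas <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("index", "hemisphere", "name", "abbreviation", "network_label")
  if (!all(required %in% names(atlas))) {
    stop("atlas registry is corrupt: missing columns ",
         paste(setdiff(required, names(atlas)), collapse = ", "), call. = FALSE)
  }
  atlas <- atlas[order(atlas$index), required]
  if (nrow(atlas) != 66L || !identical(atlas$index, 0:65)) {
    stop("atlas registry is corrupt: indices must be exactly 0..65", call. = FALSE)
  }
  hemis <- table(atlas$hemisphere)
  if (!identical(sort(names(hemis)), c("left", "right")) ||
      any(hemis != 33L)) {
    stop("atlas registry is corrupt: expected 33 regions per hemisphere",
         call. = FALSE)
  }
  if (anyDuplicated(paste(atlas$hemisphere, atlas$name)) ||
      anyDuplicated(atlas$abbreviation)) {
    stop("atlas registry is corrupt: duplicated region labels", call. = FALSE)
  }
  rownames(atlas) <- NULL
  class(atlas) <- c("mcn_atlas", "data.frame")
  atlas
}

#' Canonical thickness-table column keys for the atlas
#'
#' @param atlas an `mcn_atlas` from [load_atlas()].
#' @return character vector of 66 keys, `"lh_<name>_thickness"` /
#'   `"rh_<name>_thickness"`, in atlas index order.
#' @export
atlas_region_keys <- function(atlas = load_atlas()) {
  hemi <- ifelse(atlas$hemisphere == "left", "lh", "rh")
  paste0(hemi, "_", atlas$name, "_thickness")
}

#' Look up an atlas region by any accepted key
#'
#' Accepts the figure-style abbreviation (`"l STG"`), the FreeSurfer-style
#' column key (`"lh_superiortemporal_thickness"` or `"lh_superiortemporal"`),
#' or a `"<hemisphere> <name>"` pair such as `"left superiortemporal"`.
#'
#' @param atlas an `mcn_atlas`.
#' @param key region identifier (see Details).
#' @return one-row data frame for the matching region.
#' @export
atlas_lookup <- function(atlas, key) {
  stopifnot(is.character(key), length(key) == 1L)
  keys <- atlas_region_keys(atlas)
  hit <- which(atlas$abbreviation == key)
  if (!length(hit)) hit <- which(keys == key)
  if (!length(hit)) hit <- which(sub("_thickness$", "", keys) == key)
  if (!length(hit)) {
    hit <- which(paste(atlas$hemisphere, atlas$name) == key)
  }
  if (!length(hit)) {
    stop("unknown atlas region: '", key, "'", call. = FALSE)
  }
  atlas[hit, , drop = FALSE]
}
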