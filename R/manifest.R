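# Sample manifest: which samples are untreated controls, which are RNase R
# treated, and the fold cutoffs that define resistant / sensitive calls.

MANIFEST_PRESETS <- list(
  jeck   = list(resistant_min_fold = 5, sensitive_max_fold = 1),
  mercer = list(resistant_min_fold = 2, sensitive_max_fold = 0.7)
)

#' Construct a sample manifest
#'
#' The manifest pairs every sample with its treatment (untreated `control`
#' vs `rnaser`) and carries the fold-enrichment cutoffs used to classify
#' candidates: fold >= `resistant_min_fold` is RNase R resistant, fold <
#' `sensitive_max_fold` is sensitive (depleted), anything in between is
#' unchanged. Two presets are shipped: `"jeck"` (5 and 1), appropriate for
#' deep RNase R enrichment experiments, and `"mercer"` (2 and 0.7) for
#' datasets with a milder treatment effect.
#'
#' @param sample_ids Character vector of unique sample identifiers.
#' @param treatments Character vector, one of `"control"`/`"rnaser"` per
#'   sample; at least one of each is required.
#' @param preset `"jeck"`, `"mercer"`, or `NULL` to use explicit cutoffs.
#' @param resistant_min_fold,sensitive_max_fold Explicit cutoffs; ignored
#'   when `preset` is given. Must satisfy
#'   `sensitive_max_fold < resistant_min_fold` and `resistant_min_fold > 1`.
#' @return An object of class `circ_manifest`.
#' @examples
#' circ_manifest(c("c1", "c2", "r1", "r2"),
#'               c("control", "control", "rnaser", "rnaser"),
#'               preset = "jeck")
#' @export
circ_manifest <- function(sample_ids, treatments, preset = NULL,
                          resistant_min_fold = 5, sensitive_max_fold = 1) {
  sample_ids <- as.character(sample_ids)
  treatments <- as.character(treatments)
  if (length(sample_ids) != length(treatments))
    stop("sample_ids and treatments must have the same length")
  if (anyDuplicated(sample_ids))
    stop("duplicated sample ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  bad <- setdiff(treatments, c("control", "rnaser"))
  if (length(bad) > 0L)
    stop("invalid treatment(s): ", paste(unique(bad), collapse = ", "),
         "; must be 'control' or 'rnaser'")
  if (!any(treatments == "control"))
    stop("manifest must contain at least one control sample")
  if (!any(treatments == "rnaser"))
    stop("manifest must contain at least one rnaser sample")
  if (!is.null(preset)) {
    if (!preset %in% names(MANIFEST_PRESETS))
      stop("unknown preset '", preset, "'; available: ",
           paste(names(MANIFEST_PRESETS), collapse = ", "))
    cut <- MANIFEST_PRESETS[[preset]]
    resistant_min_fold <- cut$resistant_min_fold
    sensitive_max_fold <- cut$sensitive_max_fold
  }
  stopifnot(is.numeric(resistant_min_fold), length(resistant_min_fold) == 1L,
            is.numeric(sensitive_max_fold), length(sensitive_max_fold) == 1L)
  if (resistant_min_fold <= 1)
    stop("resistant_min_fold must be > 1 (got ", resistant_min_fold, ")")
  if (sensitive_max_fold >= resistant_min_fold)
    stop("sensitive_max_fold (", sensitive_max_fold,
         ") must be < resistant_min_fold (", resistant_min_fold, ")")
  if (sensitive_max_fold <= 0)
    stop("sensitive_max_fold must be > 0")
  structure(
    list(
      samples = data.frame(sample_id = sample_ids, treatment = treatments,
                           stringsAsFactors = FALSE),
      resistant_min_fold = as.numeric(resistant_min_fold),
      sensitive_max_fold = as.numeric(sensitive_max_fold)
    ),
    class = "circ_manifest"
  )
}

#' Read a sample manifest from YAML
#'
#' Expected layout:
#' ```yaml
#' samples:
#'   - {id: ctrl1, treatment: control}
#'   - {id: rnaser1, treatment: rnaser}
#' cutoffs:
#'   preset: jeck        # or resistant_min_fold / sensitive_max_fold
#' ```
#'
#' @param path Path to the YAML manifest.
#' @return A `circ_manifest`.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw$samples)) stop("manifest must contain a 'samples' list")
  ids <- vapply(raw$samples, function(s) as.character(s$id %||% s$sample_id),
                character(1))
  trt <- vapply(raw$samples, function(s) as.character(s$treatment), character(1))
  cut <- raw$cutoffs %||% list(preset = "jeck")
  circ_manifest(ids, trt,
                preset = cut$preset,
                resistant_min_fold = cut$resistant_min_fold %||% 5,
                sensitive_max_fold = cut$sensitive_max_fold %||% 1)
}

#' Write a manifest to YAML
#'
#' @param manifest A `circ_manifest`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  stopifnot(inherits(manifest, "circ_manifest"))
  obj <- list(
    samples = lapply(seq_len(nrow(manifest$samples)), function(i) {
      list(id = manifest$samples$sample_id[i],
           treatment = manifest$samples$treatment[i])
    }),
    cutoffs = list(resistant_min_fold = manifest$resistant_min_fold,
                   sensitive_max_fold = manifest$sensitive_max_fold)
  )
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' Samples of one treatment arm
#'
#' @param manifest A `circ_manifest`.
#' @return Character vector of sample ids.
#' @export
control_samples <- function(manifest) {
  stopifnot(inherits(manifest, "circ_manifest"))
  manifest$samples$sample_id[manifest$samples$treatment == "control"]
}

#' @rdname control_samples
#' @export
treated_samples <- function(manifest) {
  stopifnot(inherits(manifest, "circ_manifest"))
  manifest$samples$sample_id[manifest$samples$treatment == "rnaser"]
}

#' @export
print.circ_manifest <- function(x, ...) {
  cat("<circ_manifest> ", nrow(x$samples), " samples (",
      length(control_samples(x)), " control, ",
      length(treated_samples(x)), " rnaser); cutoffs: resistant >= ",
      x$resistant_min_fold, ", sensitive < ", x$sensitive_max_fold, "\n",
      sep = "")
  invisible(x)
}
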