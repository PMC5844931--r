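# Merging one algorithm's per-sample call lists into a single candidate
# table and applying the candidate-level filters.

#' Merge per-sample candidate lists for one algorithm
#'
#' Prediction is run separately per sample; this merges the per-sample
#' outputs into one candidate per distinct junction carrying the full
#' per-sample count vector, with count 0 for samples where the junction was
#' not reported. Tool score columns are combined across samples by taking
#' the best supporting evidence (max for numeric scores, any() for logical
#' flags); annotations keep the first non-missing value.
#'
#' @param per_sample Named list mapping sample id to a `circ_candidates`
#'   table (each holding that sample's counts); names must be manifest
#'   sample ids.
#' @param manifest A [circ_manifest()]; its sample order fixes the count
#'   columns of the result (samples without a list entry get all-zero
#'   counts).
#' @param match_strand Junction match policy: `FALSE` (default) merges on
#'   (chrom, start, end), `TRUE` additionally on strand. Junctions merged
#'   strand-blind with conflicting strands are reported as `*`.
#' @param algorithm Label for the merged table; defaults to the first
#'   element's algorithm.
#' @return A `circ_candidates` table with one count column per manifest
#'   sample.
#' @export
merge_samples <- function(per_sample, manifest, match_strand = FALSE,
                          algorithm = NULL) {
  stopifnot(inherits(manifest, "circ_manifest"), is.list(per_sample))
  if (length(per_sample) == 0L) stop("per_sample is empty")
  ids <- names(per_sample)
  if (is.null(ids) || any(!nzchar(ids)))
    stop("per_sample must be a named list keyed by sample id")
  unknown <- setdiff(ids, manifest$samples$sample_id)
  if (length(unknown) > 0L)
    stop("sample id(s) not in manifest: ", paste(unknown, collapse = ", "),
         "; manifest samples are: ",
         paste(manifest$samples$sample_id, collapse = ", "))
  algorithm <- algorithm %||% algorithm_name(per_sample[[1]]) %||% "merged"

  pieces <- lapply(ids, function(sid) {
    x <- per_sample[[sid]]
    stopifnot(inherits(x, "circ_candidates"))
    cnt <- sample_ids(x)
    if (length(cnt) != 1L)
      stop("per-sample table for '", sid, "' must carry exactly one count ",
           "column (it has ", length(cnt), ")")
    df <- as.data.frame(x)
    names(df)[names(df) == cnt] <- ".count"
    df$.sample <- sid
    df
  })
  all_rows <- do.call(rbind_fill, pieces)
  key <- junction_key(all_rows, match_strand)
  first <- !duplicated(key)
  idx <- match(key, key[first])
  k <- sum(first)

  out <- all_rows[first, c("chrom", "start", "end", "strand"), drop = FALSE]
  rownames(out) <- NULL
  if (!match_strand) {
    # conflicting strand reports collapse to unknown
    consistent <- unname(tapply(all_rows$strand, idx, function(s) {
      s <- unique(s[s != "*"])
      if (length(s) == 1L) s else "*"
    }))
    out$strand <- consistent
  }
  samples <- manifest$samples$sample_id
  counts <- matrix(0L, nrow = k, ncol = length(samples))
  for (j in seq_along(samples)) {
    rows <- which(all_rows$.sample == samples[j])
    if (length(rows) > 0L) {
      s <- rowsum(as.numeric(all_rows$.count[rows]), idx[rows])
      counts[as.integer(rownames(s)), j] <- s[, 1]
    }
  }
  for (j in seq_along(samples)) out[[samples[j]]] <- as.integer(counts[, j])

  for (sc in setdiff(names(all_rows),
                     c("chrom", "start", "end", "strand", ".count", ".sample"))) {
    v <- all_rows[[sc]]
    out[[sc]] <- if (is.numeric(v)) {
      agg <- unname(tapply(v, idx, function(z)
        if (all(is.na(z))) NA_real_ else max(z, na.rm = TRUE)))
      if (is.integer(v)) as.integer(agg) else as.numeric(agg)
    } else if (is.logical(v)) {
      unname(tapply(v, idx, function(z)
        if (all(is.na(z))) NA else any(z, na.rm = TRUE)))
    } else {
      unname(tapply(v, idx, function(z) {
        z <- z[!is.na(z)]
        if (length(z) == 0L) NA_character_ else z[1]
      }))
    }
  }
  res <- new_candidates(out, algorithm, samples)
  attr(res, "match_strand") <- match_strand
  res
}

rbind_fill <- function(...) {
  dfs <- list(...)
  cols <- unique(unlist(lapply(dfs, names)))
  dfs <- lapply(dfs, function(d) {
    for (cc in setdiff(cols, names(d))) d[[cc]] <- NA
    d[, cols, drop = FALSE]
  })
  do.call(rbind, dfs)
}

#' Candidate filter parameters
#'
#' Defaults implement the standard candidate filters for RNase R benchmark
#' data: at least `min_reads_one_untreated` back-splice reads in at least
#' one untreated (control) sample; a junction posterior probability of at
#' least `min_posterior` where the tool reports one (candidates at exactly
#' the threshold are kept); removal of all mitochondrial candidates and of
#' circular intronic RNA (ciRNA) candidates. `min_anchor_quality` is off by
#' default; setting it to 40 reproduces the find_circ refinement that
#' requires both anchors at the maximal mapping quality.
#'
#' @param min_reads_one_untreated Integer >= 1; default 3.
#' @param min_posterior Posterior probability threshold in \[0, 1\];
#'   default 0.9.
#' @param drop_chrM Remove candidates on mitochondrial chromosomes?
#' @param drop_ciRNA Remove candidates flagged `is_ciRNA`?
#' @param min_anchor_quality Optional integer; when set, both
#'   `anchor_qual_a` and `anchor_qual_b` must reach it.
#' @param chrM_names Chromosome names treated as mitochondrial.
#' @return A list of class `circ_filter_params`.
#' @export
filter_params <- function(min_reads_one_untreated = 3L,
                          min_posterior = 0.9,
                          drop_chrM = TRUE,
                          drop_ciRNA = TRUE,
                          min_anchor_quality = NULL,
                          chrM_names = c("chrM", "MT", "chrMT")) {
  stopifnot(min_reads_one_untreated >= 1,
            min_posterior >= 0, min_posterior <= 1,
            is.logical(drop_chrM), is.logical(drop_ciRNA))
  if (!is.null(min_anchor_quality))
    stopifnot(is.numeric(min_anchor_quality), length(min_anchor_quality) == 1L)
  structure(list(min_reads_one_untreated = as.integer(min_reads_one_untreated),
                 min_posterior = min_posterior,
                 drop_chrM = drop_chrM,
                 drop_ciRNA = drop_ciRNA,
                 min_anchor_quality = min_anchor_quality,
                 chrM_names = chrM_names),
            class = "circ_filter_params")
}

#' Apply candidate filters to a merged candidate table
#'
#' Retains candidates that pass all of: (i) max read count over control
#' samples >= `min_reads_one_untreated` (per-sample, not summed); (ii)
#' posterior probability absent or >= `min_posterior`; (iii) not on a
#' mitochondrial chromosome; (iv) not a ciRNA; (v) when
#' `min_anchor_quality` is set, `min(anchor_qual_a, anchor_qual_b)` >= that
#' value. Relative order is preserved and the operation is idempotent. The
#' returned table carries an `"exclusions"` attribute counting removals by
#' the first failing rule, in the order listed above.
#'
#' @param candidates Merged `circ_candidates` (see [merge_samples()]).
#' @param manifest A [circ_manifest()] identifying the control samples.
#' @param params A [filter_params()] object.
#' @return Filtered `circ_candidates`; possibly empty.
#' @export
apply_filters <- function(candidates, manifest, params = filter_params()) {
  stopifnot(inherits(candidates, "circ_candidates"),
            inherits(manifest, "circ_manifest"),
            inherits(params, "circ_filter_params"))
  ctrl <- intersect(sample_ids(candidates), control_samples(manifest))
  if (length(ctrl) == 0L)
    stop("candidates carry no control-sample count columns")
  n <- nrow(candidates)
  cnt <- as.matrix(as.data.frame(candidates)[, ctrl, drop = FALSE])
  pass_reads <- apply(cnt, 1, max) >= params$min_reads_one_untreated
  if (n == 0L) pass_reads <- logical(0)

  post <- candidates[["posterior_probability"]]
  pass_post <- if (is.null(post)) rep(TRUE, n) else
    is.na(post) | post >= params$min_posterior
  pass_chrM <- if (params$drop_chrM)
    !(candidates$chrom %in% params$chrM_names) else rep(TRUE, n)
  cirna <- candidates[["is_ciRNA"]]
  pass_cirna <- if (params$drop_ciRNA && !is.null(cirna))
    !(cirna %in% TRUE) else rep(TRUE, n)
  qa <- candidates[["anchor_qual_a"]]
  qb <- candidates[["anchor_qual_b"]]
  pass_anchor <- if (!is.null(params$min_anchor_quality) &&
                     !is.null(qa) && !is.null(qb)) {
    q <- pmin(qa, qb)
    is.na(q) | q >= params$min_anchor_quality
  } else rep(TRUE, n)

  keep <- pass_reads & pass_post & pass_chrM & pass_cirna & pass_anchor
  # attribute each exclusion to the first failing rule
  rule <- rep(NA_character_, n)
  rule[!pass_anchor] <- "anchor_quality"
  rule[!pass_cirna] <- "ciRNA"
  rule[!pass_chrM] <- "chrM"
  rule[!pass_post] <- "posterior"
  rule[!pass_reads] <- "min_reads"
  excl <- table(factor(rule[!keep],
                       levels = c("min_reads", "posterior", "chrM",
                                  "ciRNA", "anchor_quality")))

  out <- candidates[keep, , drop = FALSE]
  rownames(out) <- NULL
  out <- new_candidates(as.data.frame(out), algorithm_name(candidates),
                        sample_ids(candidates))
  attr(out, "match_strand") <- match_policy(candidates)
  attr(out, "exclusions") <- c(as.list(excl), kept = sum(keep))
  attr(out, "filter_params") <- params
  out
}
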