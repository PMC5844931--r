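# Mature spliced-length estimation from host transcript models, and the
# length vs RNase R sensitivity association.
#
# A circRNA is assumed to retain the internal splicing pattern of its host
# transcript: its mature length is the summed length of the host exons
# lying between the back-splice coordinates. A junction matches a
# transcript only when its start coincides exactly with an exon start and
# its end with an exon end (both 0-based half-open) — harmonization has
# already fixed coordinate conventions, so no tolerance window is applied.

new_transcript_models <- function(df) {
  stopifnot(is.data.frame(df),
            all(c("transcript_id", "chrom", "strand", "start", "end") %in%
                  names(df)))
  df <- df[order(df$transcript_id, df$start), , drop = FALSE]
  if (any(df$start >= df$end)) stop("exon with start >= end")
  # exons of one transcript must not overlap
  by_tx <- split(seq_len(nrow(df)), df$transcript_id)
  for (idx in by_tx) {
    if (length(idx) > 1L &&
        any(df$start[idx][-1] < df$end[idx][-length(idx)]))
      stop("overlapping exons in transcript ", df$transcript_id[idx[1]])
  }
  rownames(df) <- NULL
  structure(df, class = c("transcript_models", "data.frame"))
}

#' Read transcript models (GTF or BED12)
#'
#' GTF input is parsed with `rtracklayer`; exon features are grouped by
#' `transcript_id`. BED12 input (genePred-like: one transcript per row
#' with block sizes/starts) is also accepted. Exons are returned 0-based
#' half-open, matching the junction convention.
#'
#' @param path Path to a `.gtf`/`.gff` file or a 12-column BED file.
#' @param format `"auto"` (by extension), `"gtf"` or `"bed12"`.
#' @return A `transcript_models` data frame with columns `transcript_id`,
#'   `chrom`, `strand`, `start`, `end` (one row per exon).
#' @export
read_transcript_models <- function(path, format = c("auto", "gtf", "bed12")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("transcript model file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.g[tf]f[0-9]?(\\.gz)?$", path, ignore.case = TRUE))
      "gtf" else "bed12"
  }
  if (format == "gtf") {
    gr <- rtracklayer::import(path, format = "gff")
    gr <- gr[!is.na(S4Vectors::mcols(gr)$type) &
               as.character(S4Vectors::mcols(gr)$type) == "exon"]
    if (length(gr) == 0L) stop("no exon features in ", path)
    df <- data.frame(
      transcript_id = as.character(S4Vectors::mcols(gr)$transcript_id),
      chrom = as.character(GenomicRanges::seqnames(gr)),
      strand = as.character(GenomicRanges::strand(gr)),
      start = GenomicRanges::start(gr) - 1L,  # GTF is 1-based inclusive
      end = GenomicRanges::end(gr),
      stringsAsFactors = FALSE)
  } else {
    bed <- utils::read.delim(path, header = FALSE, comment.char = "#",
                             stringsAsFactors = FALSE)
    if (ncol(bed) < 12L) stop("BED12 input requires 12 columns")
    rows <- lapply(seq_len(nrow(bed)), function(i) {
      sizes <- as.integer(strsplit(as.character(bed[i, 11]), ",")[[1]])
      offs <- as.integer(strsplit(as.character(bed[i, 12]), ",")[[1]])
      data.frame(transcript_id = as.character(bed[i, 4]),
                 chrom = as.character(bed[i, 1]),
                 strand = as.character(bed[i, 6]),
                 start = as.integer(bed[i, 2]) + offs,
                 end = as.integer(bed[i, 2]) + offs + sizes,
                 stringsAsFactors = FALSE)
    })
    df <- do.call(rbind, rows)
  }
  new_transcript_models(df)
}

#' Transcripts whose exon boundaries carry a back-splice junction
#'
#' A transcript matches when it lies on the junction's chromosome and some
#' exon start equals `junction$start` while some exon end equals
#' `junction$end` (the two splice sites involved in backsplicing). An empty
#' result means the back-splice uses unannotated splice sites (a de novo
#' candidate).
#'
#' @param junction List or one-row data frame with `chrom`, `start`, `end`
#'   (0-based half-open).
#' @param models A `transcript_models` table.
#' @return `transcript_models` subset holding all exons of the matched
#'   transcripts (possibly empty).
#' @export
match_transcripts <- function(junction, models) {
  stopifnot(inherits(models, "transcript_models"))
  on_chrom <- models$chrom == junction$chrom
  sub <- models[on_chrom, , drop = FALSE]
  if (nrow(sub) == 0L) return(models[0, , drop = FALSE])
  by_tx <- split(seq_len(nrow(sub)), sub$transcript_id)
  hit <- vapply(by_tx, function(idx) {
    any(sub$start[idx] == junction$start) &&
      any(sub$end[idx] == junction$end)
  }, logical(1))
  out <- sub[sub$transcript_id %in% names(by_tx)[hit], , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("transcript_models", "data.frame"))
}

#' Mature spliced length of a circRNA under one transcript model
#'
#' Sum of the model's exon segments clipped to the junction interval.
#' Always <= the genomic span; equals it exactly for single-exon circles.
#'
#' @param junction List or one-row data frame with `chrom`, `start`, `end`.
#' @param model Exon table (a `transcript_models` subset) of one
#'   transcript that matches the junction.
#' @return Integer number of nucleotides.
#' @export
mature_length <- function(junction, model) {
  stopifnot(is.data.frame(model))
  if (length(unique(model$transcript_id)) != 1L)
    stop("model must contain exactly one transcript")
  if (!any(model$start == junction$start) ||
      !any(model$end == junction$end) ||
      unique(model$chrom) != junction$chrom)
    stop("transcript does not match the junction's splice sites; use ",
         "match_transcripts() first")
  lo <- pmax(model$start, junction$start)
  hi <- pmin(model$end, junction$end)
  as.integer(sum(pmax(hi - lo, 0)))
}

#' Average mature length over matching isoforms
#'
#' Unweighted arithmetic mean of [mature_length()] over all transcripts
#' matched by [match_transcripts()]; `NA` when no isoform matches.
#'
#' @inheritParams match_transcripts
#' @return Numeric length in nt, or `NA`.
#' @export
average_isoform_length <- function(junction, models) {
  matched <- match_transcripts(junction, models)
  if (nrow(matched) == 0L) return(NA_real_)
  ids <- unique(matched$transcript_id)
  mean(vapply(ids, function(tx) {
    mature_length(junction, matched[matched$transcript_id == tx, ,
                                    drop = FALSE])
  }, numeric(1)))
}

#' Mature lengths for every candidate of a call set
#'
#' Batch version of [average_isoform_length()]: splice sites are indexed
#' once (hash maps from `chrom:coordinate` to transcript ids), then each
#' junction is resolved in O(matched isoforms). Agrees exactly with the
#' per-junction functions.
#'
#' @param callset A `circ_callset` (or `circ_candidates`) table.
#' @param models A `transcript_models` table.
#' @return Numeric vector aligned with the rows of `callset`; `NA` for
#'   junctions at unannotated splice sites.
#' @export
annotate_lengths <- function(callset, models) {
  stopifnot(inherits(callset, "circ_candidates"),
            inherits(models, "transcript_models"))
  s_tx <- list2env(split(models$transcript_id,
                         paste0(models$chrom, ":", models$start)))
  e_tx <- list2env(split(models$transcript_id,
                         paste0(models$chrom, ":", models$end)))
  exon_s <- list2env(split(models$start, models$transcript_id))
  exon_e <- list2env(split(models$end, models$transcript_id))
  get0l <- function(env, k) get0(k, envir = env, ifnotfound = NULL)
  vapply(seq_len(nrow(callset)), function(i) {
    js <- callset$start[i]; je <- callset$end[i]
    txs <- intersect(
      unique(get0l(s_tx, paste0(callset$chrom[i], ":", js))),
      unique(get0l(e_tx, paste0(callset$chrom[i], ":", je))))
    if (length(txs) == 0L) return(NA_real_)
    mean(vapply(txs, function(tx) {
      lo <- pmax(get0l(exon_s, tx), js)
      hi <- pmin(get0l(exon_e, tx), je)
      sum(pmax(hi - lo, 0))
    }, numeric(1)))
  }, numeric(1))
}

#' Association between mature length and RNase R sensitivity
#'
#' Rank correlation (Spearman by default) between mature length and log2
#' fold enrichment. A negative coefficient means longer circles are more
#' depleted by RNase R. For Spearman/Kendall a fold of 0 is rank-safe; for
#' Pearson a moderated log-fold `log2((treated + 0.5) / (control + 0.5))`
#' is used instead.
#'
#' @param callset A `circ_callset`.
#' @param lengths Numeric vector of mature lengths aligned with `callset`
#'   rows (e.g. from [annotate_lengths()]); `NA` entries are dropped.
#' @param method `"spearman"` (default), `"kendall"` or `"pearson"`.
#' @return List with `estimate` (correlation), `p.value`, `method`, `n`;
#'   `estimate`/`p.value` are `NA` when all lengths are equal.
#' @export
length_sensitivity_association <- function(callset, lengths,
                                           method = c("spearman", "kendall",
                                                      "pearson")) {
  stopifnot(inherits(callset, "circ_callset"),
            length(lengths) == nrow(callset))
  method <- match.arg(method)
  ok <- !is.na(lengths)
  if (sum(ok) < 3L)
    stop("need at least 3 candidates with defined mature lengths")
  len <- lengths[ok]
  if (length(unique(len)) == 1L)
    return(list(estimate = NA_real_, p.value = NA_real_, method = method,
                n = length(len)))
  lfold <- if (method == "pearson") {
    log2((callset$treated_expression[ok] + 0.5) /
           (callset$control_expression[ok] + 0.5))
  } else {
    log2(callset$fold[ok])  # -Inf for fold 0 is rank-safe
  }
  ct <- suppressWarnings(stats::cor.test(len, lfold, method = method,
                                         exact = FALSE))
  list(estimate = unname(ct$estimate), p.value = ct$p.value,
       method = method, n = length(len))
}
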