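# Expression, RNase R fold enrichment and resistance classification.

#' Classify candidates by RNase R resistance
#'
#' Expression is the sum of back-splice reads over the untreated (control)
#' samples; treated expression sums over all RNase R samples. The fold is
#' treated/control and the class is: `resistant` if fold >=
#' `resistant_min_fold`, `sensitive` if fold < `sensitive_max_fold`, else
#' `unchanged`. Boundaries follow the enrichment convention: fold exactly at
#' the resistant cutoff is resistant, fold exactly at the sensitive cutoff
#' (e.g. 1 under the jeck preset) is unchanged — a candidate with treated
#' equal to control is never called sensitive. Throughout the package,
#' `sensitive` is the operational false positive and `resistant` the
#' operational true positive.
#'
#' No library-size normalization is applied by default (raw junction reads
#' are summed); `scale_factors` provides an optional per-sample multiplier
#' hook for datasets that need one.
#'
#' @param candidates Filtered `circ_candidates` (every candidate must have
#'   control expression > 0, which the >=3-read filter guarantees).
#' @param manifest A [circ_manifest()] supplying treatments and cutoffs.
#' @param scale_factors Optional named numeric vector of per-sample scale
#'   factors applied to counts before summing.
#' @return A `circ_callset`: the candidate table plus columns
#'   `control_expression`, `treated_expression`, `fold` and `resistance`.
#' @examples
#' m <- circ_manifest(c("c1", "c2", "r1", "r2"),
#'                    c("control", "control", "rnaser", "rnaser"),
#'                    preset = "jeck")
#' x <- data.frame(chrom = "chr1", start = 100L, end = 800L, strand = "+",
#'                 c1 = 5L, c2 = 5L, r1 = 40L, r2 = 10L)
#' cs <- classify_candidates(
#'   circompare:::new_candidates(x, "demo", c("c1", "c2", "r1", "r2")), m)
#' cs$fold        # 5 -> resistant
#' @export
classify_candidates <- function(candidates, manifest, scale_factors = NULL) {
  stopifnot(inherits(candidates, "circ_candidates"),
            inherits(manifest, "circ_manifest"))
  ctrl <- control_samples(manifest)
  trt <- treated_samples(manifest)
  missing <- setdiff(c(ctrl, trt), sample_ids(candidates))
  if (length(missing) > 0L)
    stop("candidates lack count columns for manifest sample(s): ",
         paste(missing, collapse = ", "), "; run merge_samples() first")
  df <- as.data.frame(candidates)
  cm <- as.matrix(df[, ctrl, drop = FALSE])
  tm <- as.matrix(df[, trt, drop = FALSE])
  if (!is.null(scale_factors)) {
    stopifnot(!is.null(names(scale_factors)))
    for (s in ctrl) cm[, s] <- cm[, s] * scale_factors[[s]]
    for (s in trt) tm[, s] <- tm[, s] * scale_factors[[s]]
  }
  control_expression <- rowSums(cm)
  treated_expression <- rowSums(tm)
  if (any(control_expression == 0))
    stop("candidate(s) with zero control expression; apply_filters() with ",
         "the minimum-read rule must be run before classification")
  fold <- treated_expression / control_expression
  resistance <- ifelse(fold >= manifest$resistant_min_fold, "resistant",
                       ifelse(fold < manifest$sensitive_max_fold,
                              "sensitive", "unchanged"))
  key <- junction_key(df, match_policy(candidates))
  if (anyDuplicated(key))
    stop("junctions are not unique under the active match policy; ",
         "merge per-sample lists with merge_samples() first")
  df$control_expression <- control_expression
  df$treated_expression <- treated_expression
  df$fold <- fold
  df$resistance <- resistance
  structure(df,
            algorithm = algorithm_name(candidates),
            sample_ids = sample_ids(candidates),
            match_strand = match_policy(candidates),
            cutoffs = c(resistant_min_fold = manifest$resistant_min_fold,
                        sensitive_max_fold = manifest$sensitive_max_fold),
            class = c("circ_callset", "circ_candidates", "data.frame"))
}

#' @export
print.circ_callset <- function(x, ...) {
  tab <- table(factor(x$resistance,
                      levels = c("resistant", "unchanged", "sensitive")))
  cat("<circ_callset> algorithm=", algorithm_name(x) %||% "?", ", ",
      nrow(x), " candidates (", tab[["resistant"]], " resistant, ",
      tab[["unchanged"]], " unchanged, ", tab[["sensitive"]],
      " sensitive)\n", sep = "")
  invisible(x)
}

resistance_levels <- c("resistant", "unchanged", "sensitive")

#' Stratify a call set by resistance class
#'
#' @param callset A `circ_callset` from [classify_candidates()].
#' @return Data frame with one row per class (`resistant`, `unchanged`,
#'   `sensitive`): `n` and `fraction`; fractions sum to 1.
#' @export
stratify <- function(callset) {
  stopifnot(inherits(callset, "circ_callset"))
  if (nrow(callset) == 0L) stop("cannot stratify an empty call set")
  tab <- table(factor(callset$resistance, levels = resistance_levels))
  data.frame(resistance = resistance_levels,
             n = as.integer(tab),
             fraction = as.numeric(tab) / nrow(callset),
             stringsAsFactors = FALSE)
}

#' Sensitive (false positive) fraction among the top expressed candidates
#'
#' Candidates are ranked by control expression, descending, with ties
#' broken by (chrom, start, end) for determinism; the fraction of RNase R
#' sensitive candidates among the first `min(n, size)` is returned.
#'
#' @param callset A `circ_callset`.
#' @param n Number of top candidates to consider (default 100).
#' @return A fraction in \[0, 1\].
#' @export
top_n_sensitive_fraction <- function(callset, n = 100L) {
  stopifnot(inherits(callset, "circ_callset"))
  if (nrow(callset) == 0L) stop("empty call set")
  if (!is.numeric(n) || length(n) != 1L || n < 1)
    stop("n must be a positive integer")
  ord <- order(-callset$control_expression, callset$chrom, callset$start,
               callset$end)
  top <- ord[seq_len(min(as.integer(n), nrow(callset)))]
  mean(callset$resistance[top] == "sensitive")
}

#' Expression summary per resistance class
#'
#' Medians and quartiles of control expression (raw read-count scale) per
#' class; classes with no members get `NA` summaries (absent, not zero).
#'
#' @param callset A `circ_callset`.
#' @param log2_summarize Summarize on the log2 scale? Medians/quartiles are
#'   back-transformed so they are always reported on the raw count scale
#'   (quantiles commute with monotone transforms up to interpolation).
#' @return Data frame with columns `resistance`, `n`, `q1`, `median`, `q3`.
#' @export
expression_by_class <- function(callset, log2_summarize = FALSE) {
  stopifnot(inherits(callset, "circ_callset"))
  if (nrow(callset) == 0L) stop("empty call set")
  out <- lapply(resistance_levels, function(cl) {
    v <- callset$control_expression[callset$resistance == cl]
    if (length(v) == 0L)
      return(data.frame(resistance = cl, n = 0L, q1 = NA_real_,
                        median = NA_real_, q3 = NA_real_))
    if (log2_summarize) {
      q <- 2^stats::quantile(log2(v), c(0.25, 0.5, 0.75), names = FALSE)
    } else {
      q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
    }
    data.frame(resistance = cl, n = length(v), q1 = q[1], median = q[2],
               q3 = q[3])
  })
  do.call(rbind, out)
}
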