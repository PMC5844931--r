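`%||%` <- function(x, y) if (is.null(x)) y else x

# Reserved column names that can never be sample ids.
RESERVED_COLUMNS <- c("chrom", "start", "end", "strand", "name", "score",
                      "control_expression", "treated_expression", "fold",
                      "resistance")

# Junction identity under the active match policy. Strand-blind by default:
# several tools report unknown strand, so (chrom, start, end) is the
# portable key; strand-aware matching is opt-in.
junction_key <- function(x, match_strand = FALSE) {
  if (match_strand) {
    paste(x$chrom, x$start, x$end, x$strand, sep = ":")
  } else {
    paste(x$chrom, x$start, x$end, sep = ":")
  }
}

match_policy <- function(x) attr(x, "match_strand") %||% FALSE

check_same_policy <- function(a, b) {
  if (!identical(match_policy(a), match_policy(b)))
    stop("call sets were harmonized under different junction match policies ",
         "(strand-aware vs strand-blind); re-run with a common match_strand")
  invisible(match_policy(a))
}
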