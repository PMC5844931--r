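# Input dialects: how each prediction tool's merged call table is laid out.

# Optional per-candidate score columns the package understands. Anything
# else in an input file is carried along as an opaque annotation.
KNOWN_SCORE_COLUMNS <- c(
  "posterior_probability", # KNIFE: junction posterior, in [0, 1]
  "anchor_qual_a",         # find_circ: anchor mapping qualities, 0-40
  "anchor_qual_b",
  "is_ciRNA",              # CIRCexplorer: circular intronic RNA flag
  "is_annotated_splice"    # candidate uses annotated splice sites
)

#' Describe the layout of one tool's call table
#'
#' A dialect declares how a tool's merged back-splice call table is read:
#' the coordinate basis of its start column, whether it reports strand, and
#' which optional score columns it may carry. On read, `one_based` dialects
#' have 1 subtracted from the start coordinate so that every candidate ends
#' up in the common 0-based half-open convention; the end coordinate is
#' never modified.
#'
#' @param name Identifier for the dialect (usually the tool name).
#' @param start_basis `"zero_based"` or `"one_based"`.
#' @param has_strand Does the table contain a `strand` column?
#' @param score_columns Character vector of optional score columns the tool
#'   may emit; must be a subset of `posterior_probability`, `anchor_qual_a`,
#'   `anchor_qual_b`, `is_ciRNA`, `is_annotated_splice`.
#' @return An object of class `circ_dialect`.
#' @examples
#' circ_dialect("CIRI", start_basis = "one_based")
#' @export
circ_dialect <- function(name,
                         start_basis = c("zero_based", "one_based"),
                         has_strand = TRUE,
                         score_columns = character()) {
  start_basis <- match.arg(start_basis)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name),
            is.logical(has_strand), length(has_strand) == 1L)
  score_columns <- as.character(score_columns)
  bad <- setdiff(score_columns, KNOWN_SCORE_COLUMNS)
  if (length(bad) > 0L) {
    stop("unknown score column(s) for dialect '", name, "': ",
         paste(bad, collapse = ", "), "; known columns are: ",
         paste(KNOWN_SCORE_COLUMNS, collapse = ", "))
  }
  structure(
    list(name = name, start_basis = start_basis,
         has_strand = has_strand, score_columns = score_columns),
    class = "circ_dialect"
  )
}

#' @export
print.circ_dialect <- function(x, ...) {
  cat("<circ_dialect> ", x$name, ": ", x$start_basis,
      if (x$has_strand) ", stranded" else ", unstranded", sep = "")
  if (length(x$score_columns) > 0L)
    cat("; scores:", paste(x$score_columns, collapse = ", "))
  cat("\n")
  invisible(x)
}

#' Read a dialect registry from a YAML file
#'
#' The registry maps tool names to [circ_dialect()] declarations. The file
#' shipped with the package (`extdata/dialects.yaml`) covers the eleven
#' circRNA prediction tools commonly benchmarked against RNase R data;
#' ACFS, circRNA_finder, CIRI, CIRI2, DCC and MapSplice report 1-based
#' starts and are converted on read, the remaining tools (and the
#' harmonized `bed` dialect) are already 0-based.
#'
#' @param path Path to a YAML file; each top-level key is a dialect name.
#' @return Named list of `circ_dialect` objects.
#' @seealso [dialect_registry()]
#' @export
read_dialects <- function(path) {
  if (!file.exists(path)) stop("dialect file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (!is.list(raw) || is.null(names(raw)) || any(!nzchar(names(raw))))
    stop("dialect registry must be a named mapping of dialect declarations")
  out <- lapply(names(raw), function(nm) {
    d <- raw[[nm]]
    circ_dialect(
      name = nm,
      start_basis = d$start_basis %||% "zero_based",
      has_strand = d$has_strand %||% TRUE,
      score_columns = unlist(d$score_columns) %||% character()
    )
  })
  names(out) <- names(raw)
  out
}

#' Shipped dialect registry for the benchmarked prediction tools
#'
#' @param path Path to the registry YAML; defaults to the copy installed
#'   with the package.
#' @return Named list of `circ_dialect` objects, including the harmonized
#'   `bed` dialect used by [write_bed()]/[read_bed()].
#' @examples
#' names(dialect_registry())
#' dialect_registry()[["CIRI"]]
#' @export
dialect_registry <- function(path = system.file("extdata", "dialects.yaml",
                                                package = "circompare")) {
  read_dialects(path)
}
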