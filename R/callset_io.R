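# Reading heterogeneous per-tool call tables into the common candidate
# representation (0-based half-open junctions + per-sample back-splice read
# counts) and writing harmonized BED-like output.

new_candidates <- function(df, algorithm, sample_ids) {
  stopifnot(is.data.frame(df), is.character(algorithm), length(algorithm) == 1L)
  rownames(df) <- NULL
  structure(df,
            algorithm = algorithm,
            sample_ids = as.character(sample_ids),
            class = c("circ_candidates", "data.frame"))
}

#' Sample (count) columns of a candidate table
#'
#' @param x A `circ_candidates` or `circ_callset` object.
#' @return Character vector of sample ids whose counts are stored as columns.
#' @export
sample_ids <- function(x) attr(x, "sample_ids")

#' Algorithm label of a candidate table or call set
#'
#' @param x A `circ_candidates` or `circ_callset` object.
#' @return Length-1 character.
#' @export
algorithm_name <- function(x) attr(x, "algorithm")

is_integer_like <- function(x) {
  x <- x[!is.na(x) & nzchar(x)]
  length(x) > 0L && all(grepl("^[0-9]+$", x))
}

# Convert raw character columns into a typed candidate table. `line_of`
# maps data rows to file line numbers for error messages.
build_candidates <- function(raw, dialect, algorithm, manifest, line_of, path) {
  cols <- names(raw)
  mandatory <- c("chrom", "start", "end")
  if (dialect$has_strand) mandatory <- c(mandatory, "strand")
  missing_cols <- setdiff(mandatory, cols)
  if (length(missing_cols) > 0L)
    stop("file '", path, "' lacks column(s) required by dialect '",
         dialect$name, "': ", paste(missing_cols, collapse = ", "))

  n <- nrow(raw)
  start <- suppressWarnings(as.numeric(raw$start))
  end <- suppressWarnings(as.numeric(raw$end))
  bad <- which(is.na(start) | is.na(end) | start != floor(start) |
                 end != floor(end) | start < 0)
  if (length(bad) > 0L)
    stop("malformed coordinates in '", path, "' at line ", line_of[bad[1]])
  if (dialect$start_basis == "one_based") start <- start - 1
  bad <- which(start >= end)
  if (length(bad) > 0L)
    stop("start >= end after 0-based normalization in '", path,
         "' at line ", line_of[bad[1]])

  strand <- if (dialect$has_strand) {
    s <- raw$strand
    s[s == "."] <- "*"
    bad <- which(!s %in% c("+", "-", "*"))
    if (length(bad) > 0L)
      stop("invalid strand in '", path, "' at line ", line_of[bad[1]])
    s
  } else {
    rep("*", n)
  }

  score_cols <- intersect(dialect$score_columns, cols)
  leftover <- setdiff(cols, c(mandatory, score_cols))
  if (!is.null(manifest)) {
    count_cols <- intersect(leftover, manifest$samples$sample_id)
    rest <- setdiff(leftover, count_cols)
    stray <- rest[vapply(rest, function(cc) is_integer_like(raw[[cc]]),
                         logical(1))]
    if (length(stray) > 0L)
      stop("unknown sample column(s) in '", path, "': ",
           paste(stray, collapse = ", "), "; manifest samples are: ",
           paste(manifest$samples$sample_id, collapse = ", "))
    annot_cols <- rest
  } else {
    count_cols <- leftover[vapply(leftover, function(cc)
      is_integer_like(raw[[cc]]), logical(1))]
    annot_cols <- setdiff(leftover, count_cols)
  }
  if (length(count_cols) == 0L)
    stop("no back-splice read count column found in '", path, "'")
  clash <- intersect(count_cols, RESERVED_COLUMNS)
  if (length(clash) > 0L)
    stop("sample id(s) collide with reserved column names: ",
         paste(clash, collapse = ", "))

  df <- data.frame(chrom = raw$chrom, start = as.integer(start),
                   end = as.integer(end), strand = strand,
                   stringsAsFactors = FALSE)
  for (cc in count_cols) {
    v <- suppressWarnings(as.numeric(raw[[cc]]))
    bad <- which(is.na(v) | v < 0 | v != floor(v))
    if (length(bad) > 0L)
      stop("malformed read count ('", cc, "') in '", path,
           "' at line ", line_of[bad[1]])
    df[[cc]] <- as.integer(v)
  }
  for (sc in score_cols) {
    df[[sc]] <- switch(sc,
      posterior_probability = {
        v <- suppressWarnings(as.numeric(raw[[sc]]))
        if (any(v < 0 | v > 1, na.rm = TRUE))
          stop("posterior_probability outside [0, 1] in '", path, "'")
        v
      },
      anchor_qual_a = ,
      anchor_qual_b = as.integer(suppressWarnings(as.numeric(raw[[sc]]))),
      is_ciRNA = ,
      is_annotated_splice = as.logical(
        ifelse(raw[[sc]] %in% c("1", "TRUE", "True", "true"), TRUE,
               ifelse(raw[[sc]] %in% c("0", "FALSE", "False", "false"),
                      FALSE, NA)))
    )
  }
  for (ac in annot_cols) df[[ac]] <- raw[[ac]]

  collapse_duplicate_rows(
    new_candidates(df, algorithm, count_cols), path)
}

# Same junction on several rows of one file: counts are summed (a merge
# of per-sample runs can legitimately repeat a junction); numeric scores
# keep the max, logical flags any(), annotations the first value.
collapse_duplicate_rows <- function(x, path = "<in-memory>") {
  key <- junction_key(x, match_strand = TRUE)
  if (!anyDuplicated(key)) return(x)
  warning("duplicated junction rows in '", path,
          "' were merged by summing counts", call. = FALSE)
  samples <- sample_ids(x)
  first <- !duplicated(key)
  out <- x[first, , drop = FALSE]
  idx <- match(key, key[first])
  for (cc in samples)
    out[[cc]] <- as.integer(rowsum(as.numeric(x[[cc]]), idx)[, 1])
  # idx enumerates groups in first-occurrence order, so tapply's 1..k group
  # order matches the rows of `out`.
  for (sc in setdiff(names(x), c("chrom", "start", "end", "strand", samples))) {
    v <- x[[sc]]
    if (is.numeric(v)) {
      agg <- unname(tapply(v, idx, function(z)
        if (all(is.na(z))) v[NA_integer_] else max(z, na.rm = TRUE)))
      out[[sc]] <- if (is.integer(v)) as.integer(agg) else as.numeric(agg)
    } else if (is.logical(v)) {
      out[[sc]] <- unname(tapply(v, idx, function(z)
        if (all(is.na(z))) NA else any(z, na.rm = TRUE)))
    }
  }
  new_candidates(as.data.frame(out), algorithm_name(x), samples)
}

#' Read one tool's call table
#'
#' Reads a tab-separated call table laid out according to `dialect` and
#' returns candidates normalized to the 0-based half-open convention
#' (1-based dialects get their start shifted by -1; ends are untouched).
#' Columns are interpreted as: mandatory coordinates (`chrom`, `start`,
#' `end`, plus `strand` for stranded dialects); the dialect's declared score
#' columns; then per-sample read counts. With a manifest, count columns are
#' exactly the columns named after manifest samples and any other
#' integer-valued column is an error; without one, every remaining
#' integer-valued column is taken as a sample. Non-count leftovers are kept
#' verbatim as opaque annotations.
#'
#' @param path Path to a TSV file with a header line.
#' @param dialect A [circ_dialect()], e.g. from [dialect_registry()].
#' @param algorithm Label for the producing algorithm.
#' @param manifest Optional [circ_manifest()] used to validate sample
#'   columns.
#' @return A `circ_candidates` data frame (one row per junction, row order
#'   preserved; duplicated junctions within the file are summed with a
#'   warning).
#' @export
read_callset <- function(path, dialect, algorithm = dialect$name,
                         manifest = NULL) {
  stopifnot(inherits(dialect, "circ_dialect"))
  if (!file.exists(path)) stop("call table not found: ", path)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE,
                           comment.char = "", quote = "",
                           stringsAsFactors = FALSE)
  names(raw)[1] <- sub("^#", "", names(raw)[1])
  build_candidates(raw, dialect, algorithm, manifest,
                   line_of = seq_len(nrow(raw)) + 1L, path = path)
}

#' Write candidates as a harmonized BED-like table
#'
#' Emits a BED6+ TSV: `chrom`, `start`, `end`, `name` (`chrom:start-end`),
#' `score` (`.`), `strand`, then one read-count column per sample (manifest
#' order when a manifest is given), then any score and annotation columns.
#' Coordinates are 0-based half-open and rows are sorted deterministically
#' by (chrom, start, end, strand). An empty candidate list produces a
#' header-only file.
#'
#' @param candidates A `circ_candidates` (or `circ_callset`) table.
#' @param path Output path.
#' @param manifest Optional [circ_manifest()] fixing the count-column order.
#' @return `path`, invisibly.
#' @seealso [read_bed()] for the inverse operation.
#' @export
write_bed <- function(candidates, path, manifest = NULL) {
  stopifnot(inherits(candidates, "circ_candidates"))
  samples <- sample_ids(candidates)
  if (!is.null(manifest)) {
    stopifnot(inherits(manifest, "circ_manifest"))
    ord <- intersect(manifest$samples$sample_id, samples)
    missing <- setdiff(samples, ord)
    if (length(missing) > 0L)
      stop("candidate samples not in manifest: ",
           paste(missing, collapse = ", "))
    samples <- ord
  }
  extra <- setdiff(names(candidates),
                   c("chrom", "start", "end", "strand", samples))
  x <- as.data.frame(candidates)
  x <- x[order(x$chrom, x$start, x$end, x$strand), , drop = FALSE]
  nm <- if (nrow(x) > 0L)
    paste0(x$chrom, ":", x$start, "-", x$end) else character(0)
  out <- data.frame(chrom = x$chrom, start = x$start, end = x$end,
                    name = nm,
                    score = rep(".", nrow(x)), strand = x$strand,
                    stringsAsFactors = FALSE, check.names = FALSE)
  for (cc in c(samples, extra)) out[[cc]] <- x[[cc]]
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste(names(out), collapse = "\t"), con)
  if (nrow(out) > 0L)
    utils::write.table(out, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a harmonized BED-like table written by [write_bed()]
#'
#' The BED `name` and `score` filler columns are regenerated by
#' [write_bed()] and are dropped on read; everything else round-trips.
#'
#' @param path Path to the harmonized table.
#' @param algorithm Label for the producing algorithm.
#' @param manifest Optional [circ_manifest()] used to validate sample
#'   columns.
#' @return A `circ_candidates` table.
#' @export
read_bed <- function(path, algorithm = "bed", manifest = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE,
                           comment.char = "", quote = "",
                           stringsAsFactors = FALSE)
  names(raw)[1] <- sub("^#", "", names(raw)[1])
  raw$name <- NULL
  raw$score <- NULL
  bed <- circ_dialect("bed", "zero_based", TRUE, KNOWN_SCORE_COLUMNS)
  build_candidates(raw, bed, algorithm, manifest,
                   line_of = seq_len(nrow(raw)) + 1L, path = path)
}

#' @export
print.circ_candidates <- function(x, ...) {
  cat("<circ_candidates> algorithm=", algorithm_name(x) %||% "?",
      ", ", nrow(x), " junction(s), samples: ",
      paste(sample_ids(x), collapse = ", "), "\n", sep = "")
  NextMethod()
}
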