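write_tsv <- function(lines, path = tempfile(fileext = ".tsv")) {
  writeLines(lines, path)
  path
}

test_that("shipped dialect registry marks exactly the 1-based tools", {
  reg <- dialect_registry()
  one_based <- names(Filter(function(d) d$start_basis == "one_based", reg))
  expect_setequal(one_based, c("ACFS", "circRNA_finder", "CIRI", "CIRI2",
                               "DCC", "MapSplice"))
  expect_equal(reg$KNIFE$score_columns[1], "posterior_probability")
  expect_true(all(c("anchor_qual_a", "anchor_qual_b") %in%
                    reg$find_circ$score_columns))
  expect_error(circ_dialect("x", score_columns = "not_a_column"),
               "unknown score column")
})

test_that("1-based starts are shifted by -1 on read; ends untouched", {
  p <- write_tsv(c("chrom\tstart\tend\tstrand\tctrl1",
                   "chrX\t139865301\t139866900\t+\t25"))
  x <- read_callset(p, dialect_registry()$CIRI, "CIRI")
  expect_equal(x$start, 139865300L)  # ciRS-7 target convention
  expect_equal(x$end, 139866900L)
  expect_equal(x$ctrl1, 25L)

  p0 <- write_tsv(c("chrom\tstart\tend\tstrand\tctrl1",
                    "chr1\t100\t200\t+\t0"))
  y <- read_callset(p0, dialect_registry()$find_circ, "find_circ")
  expect_equal(y$start, 100L)  # zero-based dialect: identity
  expect_equal(y$end, 200L)
  expect_equal(y$ctrl1, 0L)
})

test_that("malformed input is rejected with a line number", {
  p <- write_tsv(c("chrom\tstart\tend\tstrand\tctrl1",
                   "chr1\t100\t200\t+\t5",
                   "chr1\tabc\t300\t+\t5"))
  expect_error(read_callset(p, dialect_registry()$find_circ), "line 3")

  p2 <- write_tsv(c("chrom\tstart\tend\tstrand\tctrl1",
                    "chr1\t200\t200\t+\t5"))
  expect_error(read_callset(p2, dialect_registry()$find_circ),
               "start >= end")

  p3 <- write_tsv(c("chrom\tstart\tend\tstrand\tctrl1\tmystery",
                    "chr1\t100\t200\t+\t5\t7"))
  expect_error(
    read_callset(p3, dialect_registry()$find_circ, manifest = jeck_manifest),
    "unknown sample column.*ctrl1, ctrl2, rnaser1, rnaser2")
})

test_that("unknown non-count columns survive as opaque annotations", {
  p <- write_tsv(c("chrom\tstart\tend\tstrand\tctrl1\tgene_symbol",
                   "chr1\t100\t200\t+\t5\tFOO"))
  x <- read_callset(p, dialect_registry()$find_circ, manifest = jeck_manifest)
  expect_equal(x$gene_symbol, "FOO")
  expect_equal(sample_ids(x), "ctrl1")
})

test_that("duplicated junction rows in one file are summed with a warning", {
  p <- write_tsv(c("chrom\tstart\tend\tstrand\tctrl1",
                   "chr1\t100\t200\t+\t5",
                   "chr1\t100\t200\t+\t3"))
  expect_warning(x <- read_callset(p, dialect_registry()$find_circ),
                 "summing")
  expect_equal(nrow(x), 1L)
  expect_equal(x$ctrl1, 8L)
})

test_that("write_bed sorts deterministically and round-trips", {
  df <- data.frame(chrom = c("chr2", "chr1"), start = c(5L, 5L),
                   end = c(50L, 50L), strand = c("+", "+"),
                   ctrl1 = c(3L, 7L), ctrl2 = c(0L, 1L),
                   rnaser1 = c(9L, 2L), rnaser2 = c(1L, 1L),
                   stringsAsFactors = FALSE)
  x <- make_candidates(df)
  p <- tempfile(fileext = ".bed")
  write_bed(x, p, jeck_manifest)
  lines <- readLines(p)
  expect_match(lines[2], "^chr1\t")  # chr1 row first
  y <- read_bed(p, "A", jeck_manifest)
  xs <- as.data.frame(x)[order(df$chrom), ]
  rownames(xs) <- NULL
  expect_identical(as.data.frame(y), xs)

  # empty list -> header-only file
  p2 <- tempfile(fileext = ".bed")
  write_bed(x[0, ], p2)
  expect_length(readLines(p2), 1L)
})

test_that("read -> write_bed -> read is the identity for every dialect", {
  reg <- dialect_registry()
  base <- data.frame(chrom = c("chr1", "chr1", "chr2"),
                     start = c(100L, 900L, 40L),
                     end = c(600L, 1400L, 90L),
                     strand = c("+", "-", "+"),
                     ctrl1 = c(4L, 9L, 2L), stringsAsFactors = FALSE)
  for (nm in names(reg)) {
    dia <- reg[[nm]]
    out <- base
    if (dia$start_basis == "one_based") out$start <- out$start + 1L
    for (sc in dia$score_columns) {
      out[[sc]] <- switch(sc,
        posterior_probability = c(0.95, 0.91, 1),
        anchor_qual_a = c(40L, 38L, 40L),
        anchor_qual_b = c(40L, 40L, 35L),
        is_ciRNA = c(FALSE, TRUE, FALSE),
        is_annotated_splice = c(TRUE, TRUE, FALSE))
    }
    p <- tempfile(fileext = ".tsv")
    utils::write.table(out, p, sep = "\t", quote = FALSE, row.names = FALSE)
    x <- read_callset(p, dia, nm)
    p2 <- tempfile(fileext = ".bed")
    write_bed(x, p2)
    y <- read_bed(p2, nm)
    expect_identical(as.data.frame(y), as.data.frame(x), label = nm)
    expect_equal(y$start, base$start, label = nm)  # always 0-based
  }
})

test_that("manifest presets and invariants", {
  expect_equal(jeck_manifest$resistant_min_fold, 5)
  expect_equal(jeck_manifest$sensitive_max_fold, 1)
  expect_equal(mercer_manifest$resistant_min_fold, 2)
  expect_equal(mercer_manifest$sensitive_max_fold, 0.7)
  expect_error(circ_manifest(c("a", "b"), c("control", "control")),
               "rnaser")
  expect_error(circ_manifest(c("a", "b"), c("rnaser", "rnaser")),
               "control")
  expect_error(circ_manifest(c("a", "b"), c("control", "rnaser"),
                             resistant_min_fold = 2,
                             sensitive_max_fold = 3),
               "must be <")
})

test_that("manifest YAML round-trips, including presets", {
  p <- tempfile(fileext = ".yaml")
  writeLines(c("samples:",
               "  - {id: c1, treatment: control}",
               "  - {id: r1, treatment: rnaser}",
               "cutoffs:",
               "  preset: mercer"), p)
  m <- read_manifest(p)
  expect_equal(m$resistant_min_fold, 2)
  expect_equal(m$sensitive_max_fold, 0.7)
  p2 <- tempfile(fileext = ".yaml")
  write_manifest(m, p2)
  m2 <- read_manifest(p2)
  expect_equal(m2, m)
})
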