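models_df <- function(...) {
  circompare:::new_transcript_models(
    do.call(rbind, lapply(list(...), as.data.frame)))
}

tx <- function(id, chrom, exons, strand = "+") {
  data.frame(transcript_id = id, chrom = chrom, strand = strand,
             start = vapply(exons, `[`, numeric(1), 1),
             end = vapply(exons, `[`, numeric(1), 2),
             stringsAsFactors = FALSE)
}

test_that("splice-site matching is exact on both boundaries", {
  mods <- models_df(
    tx("t1", "chr1", list(c(50, 80), c(100, 200), c(300, 400), c(500, 655))),
    tx("t2", "chr1", list(c(120, 200), c(300, 400))),
    tx("t3", "chr2", list(c(100, 200), c(300, 400))))
  # junction spanning exon 2 start .. exon 4 end of t1
  m <- match_transcripts(list(chrom = "chr1", start = 100, end = 655), mods)
  expect_equal(unique(m$transcript_id), "t1")
  # start inside an exon: no match
  m2 <- match_transcripts(list(chrom = "chr1", start = 110, end = 400), mods)
  expect_equal(nrow(m2), 0L)
  # same coordinates on the wrong chromosome: no match
  m3 <- match_transcripts(list(chrom = "chr3", start = 100, end = 200), mods)
  expect_equal(nrow(m3), 0L)
})

test_that("matching agrees with a brute-force boundary scan", {
  set.seed(91)
  mods <- models_df(
    do.call(rbind, lapply(1:30, function(i) {
      n_ex <- sample(1:4, 1)
      starts <- sort(sample(seq(0, 5000, by = 50), n_ex))
      tx(paste0("tx", i), sample(c("chr1", "chr2"), 1),
         lapply(starts, function(s) c(s, s + sample(10:40, 1))))
    })))
  for (rep in 1:40) {
    j <- list(chrom = sample(c("chr1", "chr2"), 1),
              start = sample(seq(0, 5000, by = 50), 1),
              end = sample(seq(10, 5040, by = 10), 1))
    if (j$start >= j$end) next
    got <- unique(match_transcripts(j, mods)$transcript_id)
    want <- character(0)
    for (id in unique(mods$transcript_id)) {
      ex <- mods[mods$transcript_id == id, ]
      if (ex$chrom[1] == j$chrom && any(ex$start == j$start) &&
          any(ex$end == j$end))
        want <- c(want, id)
    }
    expect_setequal(got, want)
  }
})

test_that("mature length sums exon segments inside the junction", {
  single <- models_df(tx("t", "chr1", list(c(100, 655))))
  j <- list(chrom = "chr1", start = 100, end = 655)
  expect_equal(mature_length(j, single), 555L)       # single exon: genomic
  two <- models_df(tx("t", "chr1", list(c(100, 200), c(300, 400))))
  expect_equal(mature_length(list(chrom = "chr1", start = 100, end = 400),
                             two), 200L)
  expect_error(mature_length(list(chrom = "chr1", start = 110, end = 400),
                             two), "does not match")
})

test_that("mature length equals a per-base brute-force count", {
  set.seed(101)
  for (rep in 1:20) {
    n_ex <- sample(1:5, 1)
    bounds <- sort(sample(0:400, 2 * n_ex))
    exons <- split(bounds, rep(seq_len(n_ex), each = 2))
    exons <- Filter(function(e) e[1] < e[2], exons)
    if (length(exons) == 0) next
    mod <- models_df(tx("t", "chr1", exons))
    j <- list(chrom = "chr1", start = min(mod$start), end = max(mod$end))
    covered <- 0L
    for (base in seq(j$start, j$end - 1)) {
      if (any(base >= mod$start & base < mod$end)) covered <- covered + 1L
    }
    expect_equal(mature_length(j, mod), covered)
    expect_lte(mature_length(j, mod), j$end - j$start)  # spliced <= genomic
  }
})

test_that("isoform averaging is the unweighted mean, NA when unmatched", {
  mods <- models_df(
    tx("iso1", "chr1", list(c(0, 400))),
    tx("iso2", "chr1", list(c(0, 100), c(150, 250), c(300, 400))))
  j <- list(chrom = "chr1", start = 0, end = 400)
  # iso1: 400; iso2: 100 + 100 + 100 = 300
  expect_equal(average_isoform_length(j, mods), 350)
  lens <- c(mature_length(j, mods[mods$transcript_id == "iso1", ]),
            mature_length(j, mods[mods$transcript_id == "iso2", ]))
  expect_gte(average_isoform_length(j, mods), min(lens))
  expect_lte(average_isoform_length(j, mods), max(lens))
  expect_true(is.na(average_isoform_length(
    list(chrom = "chr1", start = 7, end = 400), mods)))
})

test_that("annotate_lengths agrees with the per-junction reference", {
  set.seed(111)
  cfg <- synth_config(n_true_circles = 80, n_decoys = 40, seed = 17,
                      channels = list(synth_channel("A", 1, 0.5, "p", 0L)))
  sim <- simulate_experiment(cfg)
  cs <- simulated_callsets(sim)$A
  fast <- annotate_lengths(cs, sim$models)
  slow <- vapply(seq_len(nrow(cs)), function(i) {
    average_isoform_length(list(chrom = cs$chrom[i], start = cs$start[i],
                                end = cs$end[i]), sim$models)
  }, numeric(1))
  expect_equal(fast, slow)
})

test_that("GTF and BED12 readers yield 0-based half-open exons", {
  gtf <- tempfile(fileext = ".gtf")
  writeLines(c(
    paste0("chr1\tsrc\texon\t101\t200\t.\t+\t.\t",
           "gene_id \"g1\"; transcript_id \"t1\";"),
    paste0("chr1\tsrc\texon\t301\t400\t.\t+\t.\t",
           "gene_id \"g1\"; transcript_id \"t1\";"),
    paste0("chr1\tsrc\tCDS\t301\t400\t.\t+\t.\t",
           "gene_id \"g1\"; transcript_id \"t1\";")), gtf)
  m <- read_transcript_models(gtf)
  expect_equal(nrow(m), 2L)           # CDS feature ignored
  expect_equal(m$start, c(100L, 300L))
  expect_equal(m$end, c(200L, 400L))
  bed <- tempfile(fileext = ".bed")
  writeLines("chr1\t100\t400\tt1\t0\t+\t100\t400\t0\t2\t100,100\t0,200", bed)
  m2 <- read_transcript_models(bed)
  expect_equal(m2$start, c(100L, 300L))
  expect_equal(m2$end, c(200L, 400L))
  expect_equal(mature_length(list(chrom = "chr1", start = 100, end = 400),
                             m2), 200L)
})

test_that("length association: sign convention and degenerate input", {
  cs <- make_callset("A", resistant = 1:20, sensitive = 21:40)
  expect_error(length_sensitivity_association(cs, rep(NA_real_, 40)),
               "at least 3")
  const <- length_sensitivity_association(cs, rep(555, 40))
  expect_true(is.na(const$estimate))
  # longer circles given lower folds -> negative correlation
  lens <- seq(200, 2000, length.out = 40)
  cs2 <- cs
  cs2$fold <- 50 / lens * exp(rnorm(40, sd = 0.05))
  a <- length_sensitivity_association(cs2, lens)
  expect_lt(a$estimate, -0.8)
  expect_lt(a$p.value, 1e-6)
})
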