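# Synthetic multi-algorithm circRNA discovery experiments with known
# ground truth: true circles enriched by RNase R, linear decoys depleted,
# detection channels with configurable sensitivity, shared decoy pools
# (correlated false positives) and channel-unique high-count "exotic"
# false positives.

#' Declare one synthetic detection channel
#'
#' A channel emulates one prediction algorithm: it detects each true
#' circle with probability `sensitivity`, picks up each decoy of its
#' `decoy_pool` with probability `decoy_rate` (channels sharing a pool
#' produce correlated false positives, the analogue of two tools built on
#' the same read mapper), and adds `exotic_fp` channel-unique, highly
#' expressed but RNase R depleted junctions.
#'
#' @param name Channel (algorithm) name.
#' @param sensitivity Detection probability for true circles, in \[0, 1\].
#' @param decoy_rate Detection probability for decoys of the channel's
#'   pool, in \[0, 1\].
#' @param decoy_pool Pool identifier; channels with equal ids share decoys.
#' @param exotic_fp Number of channel-unique high-count false positives.
#' @param dialect Dialect name used when the channel's files are written;
#'   `NULL` picks the registry dialect of the same name if present, else
#'   the harmonized `bed` dialect.
#' @param count_jitter Per-channel count thinning in \[0, 1): each read is
#'   kept with probability `1 - count_jitter`, emulating mapper
#'   sensitivity differences. 0 (default) means all channels see identical
#'   counts.
#' @return A list of class `synth_channel`.
#' @export
synth_channel <- function(name, sensitivity, decoy_rate,
                          decoy_pool = "main", exotic_fp = 0L,
                          dialect = NULL, count_jitter = 0) {
  stopifnot(is.character(name), length(name) == 1L,
            sensitivity >= 0, sensitivity <= 1,
            decoy_rate >= 0, decoy_rate <= 1,
            exotic_fp >= 0, count_jitter >= 0, count_jitter < 1)
  structure(list(name = name, sensitivity = sensitivity,
                 decoy_rate = decoy_rate, decoy_pool = decoy_pool,
                 exotic_fp = as.integer(exotic_fp), dialect = dialect,
                 count_jitter = count_jitter),
            class = "synth_channel")
}

#' Default jeck-like channel profile
#'
#' Eleven channels named after commonly benchmarked circRNA prediction
#' tools, with sensitivities and decoy rates spread so that filtered call
#' set sizes span a realistic range; DCC and circRNA_finder share a decoy
#' pool (both are built on the same mapper and err together), Uroborus
#' draws from its own pool.
#'
#' @return List of [synth_channel()] objects.
#' @export
jeck_channels <- function() {
  list(
    synth_channel("ACFS",           0.55, 0.25, "main", 5L),
    synth_channel("CIRCexplorer",   0.60, 0.06, "main", 1L),
    synth_channel("CIRCexplorer2",  0.62, 0.06, "main", 1L),
    synth_channel("circRNA_finder", 0.45, 0.30, "star", 4L),
    synth_channel("CIRI",           0.75, 0.45, "main", 8L),
    synth_channel("CIRI2",          0.70, 0.10, "main", 2L),
    synth_channel("DCC",            0.40, 0.28, "star", 3L),
    synth_channel("find_circ",      0.55, 0.23, "main", 4L),
    synth_channel("KNIFE",          0.65, 0.20, "main", 3L),
    synth_channel("MapSplice",      0.60, 0.07, "main", 1L),
    synth_channel("Uroborus",       0.20, 0.35, "uro",  3L)
  )
}

#' Configuration of a synthetic discovery experiment
#'
#' The defaults emulate a deep RNase R enrichment design: 2 untreated + 2
#' treated samples, negative-binomial back-splice counts (mean 15,
#' dispersion 2) shared by all channels, lognormal enrichment folds for
#' true circles (median 8, comfortably above the 5-fold resistant cutoff),
#' lognormal depletion folds for decoys (median 0.3), lognormal mature
#' lengths with median 555 nt, and the 11-channel [jeck_channels()]
#' profile. `length_decay` couples longer circles to lower folds
#' (multiplicative on the log-fold scale: fold is attenuated by
#' `(length / 555)^-length_decay`) and is off by default.
#'
#' @param n_true_circles,n_decoys Numbers of true circles and of linear
#'   decoys in the junction universe.
#' @param n_control_samples,n_treated_samples Sample-arm sizes.
#' @param count_mean,count_dispersion Negative-binomial mean and `size`
#'   for per-sample control counts.
#' @param enrichment_meanlog,enrichment_sdlog Lognormal parameters of the
#'   treated/control fold for true circles.
#' @param depletion_meanlog,depletion_sdlog Lognormal fold parameters for
#'   decoys (median < 1).
#' @param length_meanlog,length_sdlog Lognormal mature-length parameters
#'   (nt).
#' @param length_decay Coefficient >= 0 coupling length to RNase R
#'   sensitivity; 0 disables it.
#' @param deterministic_counts If `TRUE`, control counts are fixed at
#'   `round(count_mean)` and treated counts at `round(fold * control)`,
#'   giving separable fold supports (useful for confusion-matrix checks).
#' @param chrom_sizes Named vector of toy chromosome sizes; must include a
#'   mitochondrial chromosome if `chrM_fraction > 0`.
#' @param chrM_fraction Fraction of decoys placed on `chrM` (exercises the
#'   mitochondrial filter).
#' @param channels List of [synth_channel()] declarations.
#' @param seed Integer seed; same config + seed gives identical output.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_true_circles = 2500L,
                         n_decoys = 2500L,
                         n_control_samples = 2L,
                         n_treated_samples = 2L,
                         count_mean = 15,
                         count_dispersion = 2,
                         enrichment_meanlog = log(8),
                         enrichment_sdlog = 0.4,
                         depletion_meanlog = log(0.3),
                         depletion_sdlog = 0.5,
                         length_meanlog = log(555),
                         length_sdlog = 0.7,
                         length_decay = 0,
                         deterministic_counts = FALSE,
                         chrom_sizes = c(chr1 = 5e7, chr2 = 4e7,
                                         chr3 = 3e7, chr4 = 2e7,
                                         chrM = 16571),
                         chrM_fraction = 0.01,
                         channels = jeck_channels(),
                         seed = 1L) {
  stopifnot(n_true_circles >= 0, n_decoys >= 0,
            n_control_samples >= 1, n_treated_samples >= 1,
            count_mean > 0, count_dispersion > 0,
            length_decay >= 0, chrM_fraction >= 0, chrM_fraction <= 1,
            length(channels) >= 1)
  if (is.null(names(chrom_sizes)))
    stop("chrom_sizes must be a named vector")
  for (ch in channels) stopifnot(inherits(ch, "synth_channel"))
  nms <- vapply(channels, `[[`, character(1), "name")
  if (anyDuplicated(nms))
    stop("duplicate channel names: ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "))
  pools <- unique(vapply(channels, `[[`, character(1), "decoy_pool"))
  want_decoys <- any(vapply(channels, function(ch) ch$decoy_rate > 0,
                            logical(1)))
  if (want_decoys && n_decoys < length(pools))
    stop("infeasible config: ", length(pools), " decoy pool(s) but only ",
         n_decoys, " decoys")
  names(channels) <- nms
  structure(
    list(n_true_circles = as.integer(n_true_circles),
         n_decoys = as.integer(n_decoys),
         n_control_samples = as.integer(n_control_samples),
         n_treated_samples = as.integer(n_treated_samples),
         count_mean = count_mean, count_dispersion = count_dispersion,
         enrichment_meanlog = enrichment_meanlog,
         enrichment_sdlog = enrichment_sdlog,
         depletion_meanlog = depletion_meanlog,
         depletion_sdlog = depletion_sdlog,
         length_meanlog = length_meanlog, length_sdlog = length_sdlog,
         length_decay = length_decay,
         deterministic_counts = deterministic_counts,
         chrom_sizes = chrom_sizes, chrM_fraction = chrM_fraction,
         channels = channels, seed = as.integer(seed)),
    class = "synth_config")
}

synth_median_length <- function(config) exp(config$length_meanlog)

place_junctions <- function(n, chrom_sizes, spans, chroms = NULL,
                            exclude_chrM = TRUE) {
  if (n == 0L)
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      stringsAsFactors = FALSE))
  if (is.null(chroms)) {
    pool <- names(chrom_sizes)
    if (exclude_chrM) pool <- setdiff(pool, c("chrM", "MT", "chrMT"))
    chroms <- sample(pool, n, replace = TRUE,
                     prob = chrom_sizes[pool] / sum(chrom_sizes[pool]))
  }
  spans <- pmin(spans, as.integer(chrom_sizes[chroms]) - 2L)
  start <- floor(stats::runif(n) * (chrom_sizes[chroms] - spans - 1))
  data.frame(chrom = chroms, start = as.integer(start),
             end = as.integer(start + spans),
             strand = sample(c("+", "-"), n, replace = TRUE),
             stringsAsFactors = FALSE)
}

draw_counts <- function(n, mu, size, deterministic) {
  if (n == 0L) return(integer(0))
  if (deterministic) as.integer(round(mu)) + integer(n) else
    stats::rnbinom(n, mu = mu, size = size)
}

#' Generate a synthetic multi-algorithm discovery experiment
#'
#' Draws the junction universe (true circles, decoys including some on the
#' mitochondrial chromosome, plus per-channel exotic false positives),
#' per-sample back-splice counts shared across channels, per-junction
#' RNase R folds, and the per-channel detection record. Host transcript
#' models for the true circles (roughly half of them two-exon, so mature
#' length < genomic span) are generated alongside for length annotation.
#'
#' @param config A [synth_config()].
#' @param seed Integer seed; defaults to `config$seed`.
#' @return A list of class `circ_simulation` with elements `truth` (the
#'   registry: one row per junction with identity, `is_true_circle`,
#'   `mature_length`, true fold, per-sample counts and per-channel
#'   `detected_*` flags), `channels` (per channel: named list of
#'   per-sample `circ_candidates`), `manifest`, `models`
#'   (`transcript_models` for the true circles), `config` and `seed`.
#' @seealso [simulated_callsets()] to run the pipeline on the result,
#'   [recovery_report()] to compare recovered and configured parameters,
#'   [write_simulation()] to materialize the experiment as files.
#' @export
simulate_experiment <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(as.integer(seed))
  n_true <- as.integer(config$n_true_circles)
  n_dec <- as.integer(config$n_decoys)
  samples_ctrl <- paste0("ctrl", seq_len(config$n_control_samples))
  samples_trt <- paste0("rnaser", seq_len(config$n_treated_samples))
  samples <- c(samples_ctrl, samples_trt)
  manifest <- circ_manifest(samples,
                            c(rep("control", length(samples_ctrl)),
                              rep("rnaser", length(samples_trt))),
                            preset = "jeck")

  # --- true circles: mature lengths, exon structure, placement ----------
  mature <- pmax(150L, as.integer(round(stats::rlnorm(
    n_true, config$length_meanlog, config$length_sdlog))))
  two_exon <- stats::runif(n_true) < 0.5
  intron <- ifelse(two_exon,
                   as.integer(sample(200:2000, max(n_true, 1),
                                     replace = TRUE)[seq_len(n_true)]), 0L)
  span_true <- mature + intron
  true_j <- place_junctions(n_true, config$chrom_sizes, span_true)
  # spans may have been clipped to the chromosome; keep lengths consistent
  mature <- pmin(mature, true_j$end - true_j$start)
  intron <- (true_j$end - true_j$start) - mature

  # --- decoys: some mitochondrial, depleted folds ----------------------
  span_dec <- pmax(150L, as.integer(round(stats::rlnorm(
    n_dec, config$length_meanlog, config$length_sdlog))))
  dec_chroms <- NULL
  if (n_dec > 0L) {
    pool <- setdiff(names(config$chrom_sizes), c("chrM", "MT", "chrMT"))
    dec_chroms <- sample(pool, n_dec, replace = TRUE,
                         prob = config$chrom_sizes[pool] /
                           sum(config$chrom_sizes[pool]))
    m_names <- intersect(c("chrM", "MT", "chrMT"),
                         names(config$chrom_sizes))
    if (config$chrM_fraction > 0 && length(m_names) > 0L) {
      on_m <- stats::runif(n_dec) < config$chrM_fraction
      dec_chroms[on_m] <- m_names[1]
    }
  }
  dec_j <- place_junctions(n_dec, config$chrom_sizes, span_dec,
                           chroms = dec_chroms)

  # --- exotic channel-unique false positives ---------------------------
  n_exo <- vapply(config$channels, `[[`, integer(1), "exotic_fp")
  exo_total <- sum(n_exo)
  exo_span <- pmax(150L, as.integer(round(stats::rlnorm(
    exo_total, config$length_meanlog, config$length_sdlog))))
  exo_j <- place_junctions(exo_total, config$chrom_sizes, exo_span)
  exo_channel <- rep(names(config$channels), n_exo)

  junc <- rbind(true_j, dec_j, exo_j)
  kind <- rep(c("circle", "decoy", "exotic"),
              c(n_true, n_dec, exo_total))
  n_all <- nrow(junc)

  # resolve the rare placement collisions deterministically
  for (iter in 1:100) {
    key <- paste(junc$chrom, junc$start, junc$end, sep = ":")
    dup <- which(duplicated(key))
    if (length(dup) == 0L) break
    shift <- as.integer(sample(1:1000, length(dup), replace = TRUE))
    room <- as.integer(config$chrom_sizes[junc$chrom[dup]]) -
      junc$end[dup] - 1L
    shift <- pmin(shift, pmax(room, 0L))
    junc$start[dup] <- junc$start[dup] + shift
    junc$end[dup] <- junc$end[dup] + shift
  }
  if (anyDuplicated(paste(junc$chrom, junc$start, junc$end, sep = ":")))
    stop("could not place all junctions uniquely; enlarge chrom_sizes")

  # --- counts and folds ------------------------------------------------
  det <- config$deterministic_counts
  ctrl_counts <- matrix(0L, n_all, length(samples_ctrl),
                        dimnames = list(NULL, samples_ctrl))
  for (s in samples_ctrl) {
    mu <- ifelse(kind == "exotic", config$count_mean * 20, config$count_mean)
    ctrl_counts[, s] <- draw_counts(n_all, mu, config$count_dispersion, det)
  }

  fold <- numeric(n_all)
  if (n_true > 0L) {
    f <- stats::rlnorm(n_true, config$enrichment_meanlog,
                       config$enrichment_sdlog)
    if (config$length_decay > 0)
      f <- f * (mature / synth_median_length(config))^(-config$length_decay)
    fold[kind == "circle"] <- f
  }
  n_depleted <- n_dec + exo_total
  if (n_depleted > 0L)
    fold[kind != "circle"] <- stats::rlnorm(
      n_depleted, config$depletion_meanlog, config$depletion_sdlog)

  trt_counts <- matrix(0L, n_all, length(samples_trt),
                       dimnames = list(NULL, samples_trt))
  base_mu <- pmax(rowMeans(ctrl_counts), 0.25)
  for (s in samples_trt) {
    trt_counts[, s] <- if (det)
      as.integer(round(fold * ctrl_counts[, 1])) else
        stats::rnbinom(n_all, mu = fold * base_mu,
                       size = config$count_dispersion)
  }

  # --- detection record ------------------------------------------------
  pools <- unique(vapply(config$channels, `[[`, character(1), "decoy_pool"))
  pool_of <- rep(NA_character_, n_all)
  if (n_dec > 0L)  # round-robin keeps every pool populated
    pool_of[kind == "decoy"] <- pools[(seq_len(n_dec) - 1L) %% length(pools) + 1L]

  detected <- matrix(FALSE, n_all, length(config$channels),
                     dimnames = list(NULL, names(config$channels)))
  channel_counts <- list()
  for (ch in config$channels) {
    hit <- logical(n_all)
    hit[kind == "circle"] <- stats::runif(n_true) < ch$sensitivity
    if (n_dec > 0L) {
      in_pool <- kind == "decoy" & pool_of == ch$decoy_pool
      hit[in_pool] <- stats::runif(sum(in_pool)) < ch$decoy_rate
    }
    if (exo_total > 0L) {
      exo_idx <- n_true + n_dec + seq_len(exo_total)
      hit[exo_idx[exo_channel == ch$name]] <- TRUE
    }
    cnt <- cbind(ctrl_counts, trt_counts)
    if (ch$count_jitter > 0) {
      keep_p <- 1 - ch$count_jitter
      cnt[] <- stats::rbinom(length(cnt), as.vector(cnt), keep_p)
    }
    # a detected junction with no read support in any sample never shows
    # up in the channel's files; its detection flag is cleared
    hit <- hit & rowSums(cnt) > 0
    detected[, ch$name] <- hit
    channel_counts[[ch$name]] <- cnt
  }

  # --- registry --------------------------------------------------------
  truth <- data.frame(junc,
                      key = paste(junc$chrom, junc$start, junc$end,
                                  sep = ":"),
                      is_true_circle = kind == "circle",
                      kind = kind,
                      mature_length = c(as.numeric(mature),
                                        rep(NA_real_, n_dec + exo_total)),
                      true_fold = fold,
                      stringsAsFactors = FALSE)
  truth <- cbind(truth, as.data.frame(ctrl_counts),
                 as.data.frame(trt_counts))
  for (nm in colnames(detected))
    truth[[paste0("detected_", nm)]] <- detected[, nm]

  # --- per-channel per-sample candidate tables -------------------------
  channels_out <- lapply(names(config$channels), function(nm) {
    cnt <- channel_counts[[nm]]
    hit <- detected[, nm]
    per_sample <- lapply(samples, function(s) {
      rows <- which(hit & cnt[, s] > 0)
      df <- data.frame(chrom = junc$chrom[rows], start = junc$start[rows],
                       end = junc$end[rows], strand = junc$strand[rows],
                       stringsAsFactors = FALSE)
      df[[s]] <- as.integer(cnt[rows, s])
      new_candidates(df, nm, s)
    })
    names(per_sample) <- samples
    per_sample
  })
  names(channels_out) <- names(config$channels)

  # --- host transcript models for the true circles ---------------------
  models <- NULL
  if (n_true > 0L) {
    tx <- sprintf("tx_%05d", seq_len(n_true))
    one <- data.frame(transcript_id = tx, chrom = true_j$chrom,
                      strand = true_j$strand, start = true_j$start,
                      end = true_j$end, stringsAsFactors = FALSE)
    has_intron <- intron > 0L
    if (any(has_intron)) {
      l1 <- pmax(1L, as.integer(round(mature[has_intron] / 2)))
      a <- one[has_intron, ]
      first <- data.frame(transcript_id = a$transcript_id, chrom = a$chrom,
                          strand = a$strand, start = a$start,
                          end = a$start + l1, stringsAsFactors = FALSE)
      second <- data.frame(transcript_id = a$transcript_id, chrom = a$chrom,
                           strand = a$strand,
                           start = a$start + l1 + intron[has_intron],
                           end = a$end, stringsAsFactors = FALSE)
      models <- rbind(one[!has_intron, ], first, second)
    } else {
      models <- one
    }
    models <- new_transcript_models(models)
  }

  structure(list(truth = truth, channels = channels_out,
                 manifest = manifest, models = models, config = config,
                 seed = as.integer(seed)),
            class = "circ_simulation")
}

#' @export
print.circ_simulation <- function(x, ...) {
  cat("<circ_simulation> seed=", x$seed, ": ",
      sum(x$truth$is_true_circle), " true circles, ",
      sum(x$truth$kind == "decoy"), " decoys, ",
      sum(x$truth$kind == "exotic"), " exotic FPs; ",
      length(x$channels), " channels, ",
      nrow(x$manifest$samples), " samples\n", sep = "")
  invisible(x)
}

#' Run the harmonize/filter/classify pipeline on a simulation
#'
#' Convenience wrapper: for every channel, merges the per-sample candidate
#' lists, applies the candidate filters and classifies by RNase R
#' resistance.
#'
#' @param sim A `circ_simulation`.
#' @param params [filter_params()] to apply.
#' @param match_strand Junction match policy passed to [merge_samples()].
#' @return Named list of `circ_callset` objects, one per channel.
#' @export
simulated_callsets <- function(sim, params = filter_params(),
                               match_strand = FALSE) {
  stopifnot(inherits(sim, "circ_simulation"))
  out <- lapply(names(sim$channels), function(nm) {
    merged <- merge_samples(sim$channels[[nm]], sim$manifest,
                            match_strand = match_strand, algorithm = nm)
    classify_candidates(apply_filters(merged, sim$manifest, params),
                        sim$manifest)
  })
  names(out) <- names(sim$channels)
  out
}

#' Compare recovered pipeline estimates with the configured truth
#'
#' For every configured channel, reports the recovered sensitivity
#' (fraction of true circles present in the channel's classified call set)
#' against the configured detection probability, and the call set's RNase R
#' sensitive fraction against the registry-true false positive fraction
#' (non-circles in the call set). Classification confusion counts (truth
#' kind x resistance class) per channel are attached as the `"confusion"`
#' attribute.
#'
#' @param sim A `circ_simulation`.
#' @param callsets Named list of `circ_callset` objects covering every
#'   configured channel (e.g. from [simulated_callsets()]).
#' @return Data frame with columns `channel`, `parameter`, `configured`,
#'   `recovered`, `abs_error`.
#' @export
recovery_report <- function(sim, callsets) {
  stopifnot(inherits(sim, "circ_simulation"), is.list(callsets))
  missing <- setdiff(names(sim$channels), names(callsets))
  if (length(missing) > 0L)
    stop("channel(s) missing from pipeline outputs: ",
         paste(missing, collapse = ", "))
  n_true <- sum(sim$truth$is_true_circle)
  circle_keys <- sim$truth$key[sim$truth$is_true_circle]
  rows <- list()
  confusion <- list()
  for (nm in names(sim$channels)) {
    cs <- callsets[[nm]]
    stopifnot(inherits(cs, "circ_callset"))
    keys <- junction_key(cs, match_strand = FALSE)
    s_conf <- sim$config$channels[[nm]]$sensitivity
    s_hat <- if (n_true == 0L) NA_real_ else
      sum(circle_keys %in% keys) / n_true
    idx <- match(keys, sim$truth$key)
    if (anyNA(idx))
      stop("call set for '", nm, "' contains junctions absent from the ",
           "truth registry")
    fp_truth <- mean(!sim$truth$is_true_circle[idx])
    fp_hat <- mean(cs$resistance == "sensitive")
    rows[[length(rows) + 1L]] <- data.frame(
      channel = nm,
      parameter = c("sensitivity", "fp_fraction"),
      configured = c(s_conf, fp_truth),
      recovered = c(s_hat, fp_hat),
      abs_error = abs(c(s_hat - s_conf, fp_hat - fp_truth)),
      stringsAsFactors = FALSE)
    confusion[[nm]] <- table(
      truth = factor(ifelse(sim$truth$is_true_circle[idx], "circle",
                            "decoy"), levels = c("circle", "decoy")),
      class = factor(cs$resistance, levels = resistance_levels))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "confusion") <- confusion
  out
}

#' Write a simulated experiment to disk
#'
#' Materializes the experiment the way a real multi-tool run would look:
#' one directory per channel with one TSV per sample written in the
#' channel's declared dialect (1-based dialects get their start converted
#' back on write), plus `manifest.yaml`, the truth registry
#' (`truth.tsv`) and the host transcript models (`transcripts.gtf`).
#' Output is byte-identical across runs for the same config and seed.
#'
#' @param sim A `circ_simulation`.
#' @param dir Output directory (created if needed).
#' @param registry Dialect registry used to resolve channel dialects.
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir, registry = dialect_registry()) {
  stopifnot(inherits(sim, "circ_simulation"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(sim$channels)) {
    dia_name <- sim$config$channels[[nm]]$dialect %||%
      (if (nm %in% names(registry)) nm else "bed")
    dia <- registry[[dia_name]]
    if (is.null(dia)) stop("unknown dialect '", dia_name, "' for channel ", nm)
    chdir <- file.path(dir, nm)
    dir.create(chdir, showWarnings = FALSE)
    for (s in names(sim$channels[[nm]])) {
      x <- as.data.frame(sim$channels[[nm]][[s]])
      if (dia$start_basis == "one_based") x$start <- x$start + 1L
      if (!dia$has_strand) x$strand <- NULL
      f <- file.path(chdir, paste0(s, ".tsv"))
      con <- file(f, open = "wt")
      writeLines(paste(names(x), collapse = "\t"), con)
      if (nrow(x) > 0L)
        utils::write.table(x, con, sep = "\t", quote = FALSE,
                           row.names = FALSE, col.names = FALSE)
      close(con)
    }
  }
  write_manifest(sim$manifest, file.path(dir, "manifest.yaml"))
  utils::write.table(sim$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(sim$models)) {
    m <- sim$models
    gtf <- sprintf(
      "%s\tcircompare_synth\texon\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; transcript_id \"%s\";",
      m$chrom, m$start + 1L, m$end, m$strand,
      sub("^tx_", "g_", m$transcript_id), m$transcript_id)
    writeLines(gtf, file.path(dir, "transcripts.gtf"))
  }
  invisible(dir)
}
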