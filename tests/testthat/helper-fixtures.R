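# Shared fixtures and independent brute-force oracles.

jeck_manifest <- circ_manifest(
  c("ctrl1", "ctrl2", "rnaser1", "rnaser2"),
  c("control", "control", "rnaser", "rnaser"),
  preset = "jeck")

mercer_manifest <- circ_manifest(
  c("ctrl1", "ctrl2", "rnaser1", "rnaser2"),
  c("control", "control", "rnaser", "rnaser"),
  preset = "mercer")

# junctions identified by integer ids -> disjoint chr1 intervals
junc_df <- function(ids) {
  data.frame(chrom = "chr1", start = ids * 1000L, end = ids * 1000L + 500L,
             strand = "+", stringsAsFactors = FALSE)
}

make_candidates <- function(df, algorithm = "A",
                            samples = c("ctrl1", "ctrl2", "rnaser1",
                                        "rnaser2")) {
  circompare:::new_candidates(df, algorithm, samples)
}

# Classified call set with prescribed resistance classes. Counts are
# chosen so the jeck preset yields fold 5 (resistant, boundary), 2
# (unchanged) and 0.1 (sensitive).
make_callset <- function(algorithm, resistant = integer(),
                         unchanged = integer(), sensitive = integer(),
                         manifest = jeck_manifest) {
  ids <- c(resistant, unchanged, sensitive)
  df <- junc_df(ids)
  df$ctrl1 <- 10L
  df$ctrl2 <- 10L
  df$rnaser1 <- c(rep(100L, length(resistant)), rep(40L, length(unchanged)),
                  rep(2L, length(sensitive)))
  df$rnaser2 <- 0L
  classify_candidates(make_candidates(df, algorithm), manifest)
}

random_classified <- function(algorithm, n, universe = 500L) {
  ids <- sample.int(universe, n)
  cls <- sample(c("resistant", "unchanged", "sensitive"), n, replace = TRUE)
  make_callset(algorithm,
               resistant = ids[cls == "resistant"],
               unchanged = ids[cls == "unchanged"],
               sensitive = ids[cls == "sensitive"])
}

# ---- brute-force oracles (kept independent of the package internals) ----

keys_of <- function(cs) paste(cs$chrom, cs$start, cs$end, sep = ":")

# element-by-element membership count via an explicit loop + hash env
bf_shared_count <- function(keys_a, keys_b) {
  h <- new.env(hash = TRUE, parent = emptyenv())
  for (k in keys_b) assign(k, TRUE, envir = h)
  n <- 0L
  for (k in keys_a) if (isTRUE(get0(k, envir = h))) n <- n + 1L
  n
}

bf_itp <- function(a, b) {
  rk <- keys_of(a)[a$resistance == "resistant"]
  if (length(rk) == 0L) return(NA_real_)
  bf_shared_count(rk, keys_of(b)) / length(rk)
}

bf_itn <- function(a, b) {
  sk <- keys_of(a)[a$resistance == "sensitive"]
  if (length(sk) == 0L) return(NA_real_)
  1 - bf_shared_count(sk, keys_of(b)) / length(sk)
}

bf_score <- function(a, b) (bf_itp(a, b) * bf_itn(a, b))^2

bf_shared_by_k <- function(callsets, k) {
  envs <- lapply(callsets, function(cs) {
    h <- new.env(hash = TRUE, parent = emptyenv())
    for (kk in keys_of(cs)) assign(kk, TRUE, envir = h)
    h
  })
  all_keys <- unique(unlist(lapply(callsets, keys_of)))
  hit <- vapply(all_keys, function(kk) {
    sum(vapply(envs, function(h) isTRUE(get0(kk, envir = h)),
               logical(1))) >= k
  }, logical(1))
  sort(all_keys[hit])
}

bf_rank_overlap <- function(a, b, bins) {
  ord <- order(-a$control_expression, a$chrom, a$start, a$end)
  hit <- keys_of(a)[ord] %in% keys_of(b)
  n <- length(hit)
  vapply(seq_len(bins), function(bb) {
    idx <- which(ceiling(seq_len(n) * bins / n) == bb)
    mean(hit[idx])
  }, numeric(1))
}

bf_pearson <- function(x, y) {
  n <- length(x)
  num <- sum((x - mean(x)) * (y - mean(y)))
  den <- sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  num / den
}
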