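test_that("the published worked example reproduces through the pipeline", {
  # A: 2289 resistant (1551 shared with B) + 1105 sensitive (251 shared)
  a <- make_callset("CIRI", resistant = 1:2289, sensitive = 3001:4105)
  b <- make_callset("ACFS", resistant = c(1:1551, 5001:5100),
                    sensitive = c(3001:3251, 6001:6050))
  itp <- compute_itp(a, b)
  itn <- compute_itn(a, b)
  expect_equal(itp, 1551 / 2289)
  expect_equal(itn, 1 - 251 / 1105)
  expect_equal(round(itp, 2), 0.68)
  expect_equal(round(itn, 2), 0.77)
  expect_equal(round(complementary_score(itp, itn), 2), 0.27)
})

test_that("intersection is commutative and matches brute force", {
  a <- make_callset("A", resistant = 1:30, sensitive = 31:40)
  expect_equal(nrow(intersect_callsets(a, a)), nrow(a))
  b <- make_callset("B", resistant = 101:120)
  expect_equal(nrow(intersect_callsets(a, b)), 0L)
  set.seed(21)
  for (rep in 1:5) {
    x <- random_classified("X", 60)
    y <- random_classified("Y", 60)
    ix <- intersect_callsets(x, y)
    expect_equal(nrow(ix), bf_shared_count(keys_of(x), keys_of(y)))
    expect_equal(nrow(ix), nrow(intersect_callsets(y, x)))
  }
})

test_that("iTP/iTN degenerate and trivial cases", {
  a <- make_callset("A", resistant = 1:10, sensitive = 11:15)
  expect_equal(compute_itp(a, a), 1)      # self preserves everything
  expect_equal(compute_itn(a, a), 0)      # and removes no false positives
  b <- make_callset("B", resistant = 101:110)
  expect_equal(compute_itn(a, b), 1)      # disjoint partner discards all
  no_res <- make_callset("C", sensitive = 1:5)
  expect_true(is.na(compute_itp(no_res, a)))   # undefined, not coerced
  no_sens <- make_callset("D", resistant = 1:5)
  expect_true(is.na(compute_itn(no_sens, a)))
  expect_true(is.na(complementary_score(NA_real_, 0.5)))
  expect_equal(complementary_score(1, 1), 1)
  expect_equal(complementary_score(1, 0), 0)
  expect_error(complementary_score(1.2, 0.5), "0, 1")
})

test_that("mismatched match policies are rejected", {
  df <- junc_df(1:5)
  df$ctrl1 <- 5L; df$ctrl2 <- 5L; df$rnaser1 <- 50L; df$rnaser2 <- 0L
  x <- classify_candidates(make_candidates(df), jeck_manifest)
  y <- classify_candidates(make_candidates(df, "B"), jeck_manifest)
  attr(y, "match_strand") <- TRUE
  expect_error(compute_itp(x, y), "match polic")
})

test_that("pairwise matrix covers all ordered pairs and is order-invariant", {
  set.seed(31)
  css <- lapply(LETTERS[1:5], function(a) random_classified(a, 50))
  m <- pairwise_matrix(css)
  expect_equal(nrow(m), 25L)
  expect_equal(sum(m$row_algorithm != m$col_algorithm), 20L)  # n(n-1)
  m2 <- pairwise_matrix(rev(css))
  key <- function(d) paste(d$row_algorithm, d$col_algorithm)
  expect_equal(m2$score[match(key(m), key(m2))], m$score)
  # every cell equals the unbatched composition
  for (i in sample(nrow(m), 10)) {
    a <- css[[match(m$row_algorithm[i], LETTERS[1:5])]]
    b <- css[[match(m$col_algorithm[i], LETTERS[1:5])]]
    expect_equal(m$iTP[i], compute_itp(a, b))
    expect_equal(m$iTN[i], compute_itn(a, b))
  }
  dup <- css; attr(dup[[2]], "algorithm") <- "A"
  expect_error(pairwise_matrix(dup), "duplicate")
})

test_that("best_complement takes the row argmax with alphabetical ties", {
  a <- make_callset("a", resistant = 1:100, sensitive = 101:120)
  b <- make_callset("b", resistant = 1:100, sensitive = 201:220)
  d <- make_callset("d", resistant = 1:50, sensitive = 301:320)
  cc <- make_callset("c", resistant = 1:100, sensitive = 401:420)
  m <- pairwise_matrix(list(a, b, d, cc))
  best <- best_complement(m, "a")
  # b and c both preserve all resistant and share no sensitive: score 1, tie
  expect_equal(best$partner, "b")
  expect_equal(best$score, 1)
  expect_error(best_complement(m, "nope"), "unknown")
})

test_that("three-wise scores use the consensus-intersection reading", {
  a <- make_callset("a", resistant = 1:20, sensitive = 21:30)
  b <- make_callset("b", resistant = 1:10, sensitive = 21:25)
  b2 <- make_callset("b2", resistant = 1:10, sensitive = 21:25)  # clone of b
  tw <- threewise_scores(list(a, b, b2))
  row <- tw[tw$row_algorithm == "a" & tw$partner1 == "b", ]
  expect_equal(row$iTP, compute_itp(a, b))   # b2 == b: reduces to pairwise
  expect_equal(row$iTN, compute_itn(a, b))
  # partners jointly disjoint from a's sensitive set -> iTN 1
  c1 <- make_callset("c1", resistant = 1:20)
  c2 <- make_callset("c2", resistant = 1:20)
  tw2 <- threewise_scores(list(a, c1, c2))
  expect_equal(tw2$iTN[tw2$row_algorithm == "a"], 1)
  expect_equal(tw2$iTP[tw2$row_algorithm == "a"], 1)
})

test_that("three-wise scores match a brute-force triple loop", {
  set.seed(41)
  css <- lapply(c("p", "q", "r", "s"), function(a) random_classified(a, 40))
  names(css) <- c("p", "q", "r", "s")
  tw <- threewise_scores(css)
  for (i in seq_len(nrow(tw))) {
    a <- css[[tw$row_algorithm[i]]]
    kb <- keys_of(css[[tw$partner1[i]]])
    kc <- keys_of(css[[tw$partner2[i]]])
    rk <- keys_of(a)[a$resistance == "resistant"]
    sk <- keys_of(a)[a$resistance == "sensitive"]
    n_r <- 0L; for (k in rk) if (k %in% kb && k %in% kc) n_r <- n_r + 1L
    n_s <- 0L; for (k in sk) if (k %in% kb && k %in% kc) n_s <- n_s + 1L
    expect_equal(tw$iTP[i], if (length(rk)) n_r / length(rk) else NA_real_)
    expect_equal(tw$iTN[i], if (length(sk)) 1 - n_s / length(sk) else NA_real_)
  }
})

test_that("shared_by_k: union at k=1, monotone, matches brute force", {
  set.seed(51)
  css <- lapply(LETTERS[1:4], function(a) random_classified(a, 60))
  u <- shared_by_k(css, 1)
  expect_equal(nrow(u), length(unique(unlist(lapply(css, keys_of)))))
  sizes <- vapply(1:4, function(k) nrow(shared_by_k(css, k)), integer(1))
  expect_true(all(diff(sizes) <= 0))
  for (k in 1:4) {
    got <- sort(paste(shared_by_k(css, k)$chrom, shared_by_k(css, k)$start,
                      shared_by_k(css, k)$end, sep = ":"))
    expect_equal(got, bf_shared_by_k(css, k))
  }
  expect_error(shared_by_k(css, 0), "between")
  expect_error(shared_by_k(css, 5), "between")
})

test_that("rank_overlap_curve matches brute force and its trivial cases", {
  a <- make_callset("a", resistant = 1:40, sensitive = 41:50)
  sup <- make_callset("sup", resistant = c(1:40, 51:60), sensitive = 41:50)
  expect_true(all(rank_overlap_curve(a, sup, 5)$overlap_fraction == 1))
  b <- make_callset("b", resistant = 5:25)
  one <- rank_overlap_curve(a, b, 1)
  expect_equal(one$overlap_fraction,
               nrow(intersect_callsets(a, b)) / nrow(a))
  set.seed(61)
  for (rep in 1:5) {
    x <- random_classified("x", 57)
    y <- random_classified("y", 57)
    expect_equal(rank_overlap_curve(x, y, 7)$overlap_fraction,
                 bf_rank_overlap(x, y, 7))
  }
})

test_that("score-size correlations match brute-force Pearson", {
  set.seed(71)
  css <- lapply(LETTERS[1:6], function(a)
    random_classified(a, sample(40:90, 1)))
  m <- pairwise_matrix(css)
  sizes <- vapply(css, nrow, integer(1))
  names(sizes) <- LETTERS[1:6]
  tab <- score_count_correlations(m, sizes)
  off <- m[m$row_algorithm != m$col_algorithm, ]
  r_manual <- bf_pearson(as.numeric(sizes[off$row_algorithm]), off$iTP)
  expect_equal(tab$r[tab$metric == "iTP" &
                       tab$size_of == "first_algorithm"], r_manual)
  # exclusion list drops the named algorithm's rows and columns
  tab2 <- score_count_correlations(m, sizes, exclude = "A")
  expect_equal(unique(tab2$n), 20L)
  # constant score -> NA correlations
  m3 <- m; m3$score <- 0.5
  tab3 <- score_count_correlations(m3, sizes)
  expect_true(all(is.na(tab3$r[tab3$metric == "score"])))
  expect_error(score_count_correlations(m[1:2, ], sizes), "at least 3")
})

test_that("partner monotonicity: growing b never hurts iTP or helps iTN", {
  set.seed(81)
  for (rep in 1:10) {
    a <- random_classified("a", 50)
    ids <- sample.int(500, 80)
    b_small <- make_callset("b", resistant = ids[1:30])
    b_large <- make_callset("b", resistant = ids[1:80])
    expect_gte(compute_itp(a, b_large), compute_itp(a, b_small))
    expect_lte(compute_itn(a, b_large), compute_itn(a, b_small))
  }
})

test_that("score is monotone in both indices on [0,1]^2", {
  g <- seq(0, 1, by = 0.25)
  for (itn in g) {
    s <- complementary_score(g, itn)
    expect_true(all(diff(s) >= 0))
  }
  for (itp in g) {
    s <- complementary_score(itp, g)
    expect_true(all(diff(s) >= 0))
  }
})
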