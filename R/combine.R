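# Algorithm complementarity: intersections, iTP / iTN indices, the
# Complementary score (iTP x iTN)^2, pairwise and three-wise matrices,
# consensus sets and rank-overlap diagnostics.
#
# All indices are directional: compute_itp(a, b) asks how much of a's
# signal survives intersection with b, which is not the same question as
# compute_itp(b, a). Candidates classified "unchanged" enter the junction
# universe of the partner but are counted in neither index.

callset_keys <- function(x) junction_key(x, match_policy(x))

res_keys <- function(x) {
  junction_key(x[x$resistance == "resistant", , drop = FALSE],
               match_policy(x))
}

sens_keys <- function(x) {
  junction_key(x[x$resistance == "sensitive", , drop = FALSE],
               match_policy(x))
}

#' Junctions called by both algorithms
#'
#' @param a,b `circ_callset` objects harmonized under the same match
#'   policy.
#' @return Data frame of the shared junctions (coordinates taken from
#'   `a`); commutative as a set of junction identities.
#' @export
intersect_callsets <- function(a, b) {
  stopifnot(inherits(a, "circ_callset"), inherits(b, "circ_callset"))
  check_same_policy(a, b)
  keep <- callset_keys(a) %in% callset_keys(b)
  cols <- c("chrom", "start", "end",
            if (match_policy(a)) "strand" else NULL)
  out <- as.data.frame(a)[keep, cols, drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Index of true positives (iTP)
#'
#' Fraction of `a`'s RNase R resistant candidates that are preserved when
#' intersecting with `b`'s full call set:
#' `|resistant(a) ∩ junctions(b)| / |resistant(a)|`. Undefined (returns
#' `NA`) when `a` has no resistant candidate; the undefined value is never
#' coerced to 0 or 1.
#'
#' @param a,b `circ_callset` objects under the same match policy.
#' @return Numeric in \[0, 1\], or `NA` if undefined.
#' @export
compute_itp <- function(a, b) {
  stopifnot(inherits(a, "circ_callset"), inherits(b, "circ_callset"))
  check_same_policy(a, b)
  rk <- res_keys(a)
  if (length(rk) == 0L) return(NA_real_)
  mean(rk %in% callset_keys(b))
}

#' Index of true negatives (iTN)
#'
#' One minus the fraction of `a`'s RNase R sensitive candidates (the
#' operational false positives) that `b` also calls:
#' `1 - |sensitive(a) ∩ junctions(b)| / |sensitive(a)|` — the fraction of
#' false positives that intersection with `b` discards. Undefined (`NA`)
#' when `a` has no sensitive candidate.
#'
#' @inheritParams compute_itp
#' @return Numeric in \[0, 1\], or `NA` if undefined.
#' @export
compute_itn <- function(a, b) {
  stopifnot(inherits(a, "circ_callset"), inherits(b, "circ_callset"))
  check_same_policy(a, b)
  sk <- sens_keys(a)
  if (length(sk) == 0L) return(NA_real_)
  1 - mean(sk %in% callset_keys(b))
}

#' Complementary score
#'
#' `(iTP * iTN)^2`: a single number in \[0, 1\] scoring the benefit of
#' pairing one algorithm with another — high only when intersection both
#' preserves the resistant candidates and discards the sensitive ones.
#' Directional, like its inputs. `NA` inputs propagate.
#'
#' @param itp,itn Numeric vectors in \[0, 1\] (recycled).
#' @return `(itp * itn)^2`.
#' @examples
#' complementary_score(1551 / 2289, 1 - 251 / 1105)  # ~0.27
#' @export
complementary_score <- function(itp, itn) {
  ok <- is.na(itp) | (itp >= 0 & itp <= 1)
  ok2 <- is.na(itn) | (itn >= 0 & itn <= 1)
  if (!all(ok) || !all(ok2)) stop("itp and itn must lie in [0, 1]")
  (itp * itn)^2
}

check_algorithms <- function(callsets) {
  stopifnot(is.list(callsets), length(callsets) >= 1L)
  algs <- vapply(callsets, function(x) {
    stopifnot(inherits(x, "circ_callset"))
    algorithm_name(x) %||% NA_character_
  }, character(1))
  if (anyNA(algs) || any(!nzchar(algs)))
    stop("every call set must carry an algorithm name")
  if (anyDuplicated(algs))
    stop("duplicate algorithm names: ",
         paste(unique(algs[duplicated(algs)]), collapse = ", "))
  pol <- unique(vapply(callsets, match_policy, logical(1)))
  if (length(pol) != 1L)
    stop("call sets were harmonized under different junction match policies")
  names(callsets) <- algs
  callsets
}

#' Pairwise complementarity matrix
#'
#' Computes iTP, iTN and the Complementary score for every ordered pair of
#' call sets, diagonal included (self-pairing is the degenerate case: iTP
#' is 1 and, whenever the set holds at least one sensitive candidate, iTN
#' and the score are 0 — combining an algorithm with itself removes no
#' false positives). Cells whose indices are undefined are `NA`. Scores
#' are kept at full precision; rounding to 2 decimals is presentation-only
#' (see the `print` method).
#'
#' @param callsets List of `circ_callset` objects with distinct algorithm
#'   names and a common match policy.
#' @return A `circ_pairwise` data frame with columns `row_algorithm`
#'   (the algorithm whose candidates are evaluated), `col_algorithm` (the
#'   partner), `iTP`, `iTN`, `score`.
#' @export
pairwise_matrix <- function(callsets) {
  callsets <- check_algorithms(callsets)
  if (length(callsets) < 2L) stop("need at least two call sets")
  algs <- names(callsets)
  keys <- lapply(callsets, callset_keys)
  rks <- lapply(callsets, res_keys)
  sks <- lapply(callsets, sens_keys)
  grid <- expand.grid(col = algs, row = algs, stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)[, c("row", "col")]
  itp <- mapply(function(r, c) {
    rk <- rks[[r]]
    if (length(rk) == 0L) NA_real_ else mean(rk %in% keys[[c]])
  }, grid$row, grid$col)
  itn <- mapply(function(r, c) {
    sk <- sks[[r]]
    if (length(sk) == 0L) NA_real_ else 1 - mean(sk %in% keys[[c]])
  }, grid$row, grid$col)
  out <- data.frame(row_algorithm = grid$row, col_algorithm = grid$col,
                    iTP = unname(itp), iTN = unname(itn),
                    score = unname(complementary_score(itp, itn)),
                    stringsAsFactors = FALSE)
  structure(out, algorithms = algs,
            class = c("circ_pairwise", "data.frame"))
}

#' @export
print.circ_pairwise <- function(x, digits = 2, ...) {
  cat("<circ_pairwise> ", length(attr(x, "algorithms")),
      " algorithms, ", nrow(x), " ordered pairs\n", sep = "")
  y <- as.data.frame(x)
  y$iTP <- round(y$iTP, digits)
  y$iTN <- round(y$iTN, digits)
  y$score <- round(y$score, digits)
  print(y, ...)
  invisible(x)
}

#' Complementary-score matrix in wide (heatmap) form
#'
#' @param x A `circ_pairwise` result.
#' @param value Which statistic to spread: `"score"`, `"iTP"` or `"iTN"`.
#' @param ... Unused.
#' @return Numeric matrix, rows = evaluated algorithm, columns = partner.
#' @export
as.matrix.circ_pairwise <- function(x, value = c("score", "iTP", "iTN"),
                                    ...) {
  value <- match.arg(value)
  algs <- attr(x, "algorithms")
  m <- matrix(NA_real_, length(algs), length(algs),
              dimnames = list(algs, algs))
  m[cbind(x$row_algorithm, x$col_algorithm)] <- x[[value]]
  m
}

#' Best complementing partner for one algorithm
#'
#' The partner maximizing the Complementary score in that algorithm's row
#' of the pairwise matrix; ties are broken alphabetically by partner name.
#'
#' @param matrix A `circ_pairwise` result.
#' @param algorithm Row algorithm to look up.
#' @return List with elements `partner` and `score`.
#' @export
best_complement <- function(matrix, algorithm) {
  stopifnot(inherits(matrix, "circ_pairwise"))
  if (!algorithm %in% attr(matrix, "algorithms"))
    stop("unknown algorithm: ", algorithm)
  rows <- matrix[matrix$row_algorithm == algorithm & !is.na(matrix$score), ,
                 drop = FALSE]
  if (nrow(rows) == 0L)
    stop("no defined Complementary score in the row of ", algorithm)
  best <- rows[order(-rows$score, rows$col_algorithm), ][1, ]
  list(partner = best$col_algorithm, score = best$score)
}

#' Three-wise complementarity scores
#'
#' For an algorithm `a` and an unordered partner pair \{`b`, `c`\}, the
#' consensus-intersection reading is used: a candidate of `a` is kept only
#' if present in both partners. iTP is then the fraction of `a`'s
#' resistant candidates found in both `b` and `c`; iTN is 1 minus the
#' corresponding fraction of sensitive candidates; the score is
#' `(iTP * iTN)^2`. With `b == c` this reduces to the pairwise result.
#'
#' @param callsets List of >= 3 `circ_callset` objects.
#' @return A `circ_threewise` data frame with columns `row_algorithm`,
#'   `partner1`, `partner2` (alphabetical), `iTP`, `iTN`, `score`.
#' @export
threewise_scores <- function(callsets) {
  callsets <- check_algorithms(callsets)
  if (length(callsets) < 3L) stop("need at least three call sets")
  algs <- names(callsets)
  keys <- lapply(callsets, callset_keys)
  rks <- lapply(callsets, res_keys)
  sks <- lapply(callsets, sens_keys)
  rows <- list()
  for (a in algs) {
    partners <- sort(setdiff(algs, a))
    pairs <- utils::combn(partners, 2)
    for (j in seq_len(ncol(pairs))) {
      b <- pairs[1, j]; c_ <- pairs[2, j]
      in_both <- function(k) (k %in% keys[[b]]) & (k %in% keys[[c_]])
      itp <- if (length(rks[[a]]) == 0L) NA_real_ else
        mean(in_both(rks[[a]]))
      itn <- if (length(sks[[a]]) == 0L) NA_real_ else
        1 - mean(in_both(sks[[a]]))
      rows[[length(rows) + 1L]] <- data.frame(
        row_algorithm = a, partner1 = b, partner2 = c_,
        iTP = itp, iTN = itn,
        score = complementary_score(itp, itn),
        stringsAsFactors = FALSE)
    }
  }
  structure(do.call(rbind, rows), algorithms = algs,
            class = c("circ_threewise", "data.frame"))
}

#' Junctions shared by at least k algorithms
#'
#' `k = 1` gives the union; `k = length(callsets)` the all-algorithm
#' consensus. The result shrinks monotonically in `k`.
#'
#' @param callsets List of `circ_callset` objects.
#' @param k Integer in `[1, length(callsets)]`.
#' @return Data frame of junction coordinates shared by >= `k` call sets.
#' @export
shared_by_k <- function(callsets, k) {
  callsets <- check_algorithms(callsets)
  if (!is.numeric(k) || length(k) != 1L || k < 1 || k > length(callsets))
    stop("k must lie between 1 and the number of call sets (",
         length(callsets), ")")
  keys <- lapply(callsets, callset_keys)
  tab <- table(unlist(keys, use.names = FALSE))
  hit <- names(tab)[tab >= k]
  # report coordinates from the first call set carrying each junction
  pol <- match_policy(callsets[[1]])
  cols <- c("chrom", "start", "end", if (pol) "strand" else NULL)
  seen <- character(0)
  pieces <- lapply(callsets, function(x) {
    kx <- callset_keys(x)
    take <- kx %in% hit & !kx %in% seen & !duplicated(kx)
    seen <<- c(seen, kx[take])
    as.data.frame(x)[take, cols, drop = FALSE]
  })
  out <- do.call(rbind, pieces)
  out <- out[order(out$chrom, out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Overlap with a partner along the expression ranking
#'
#' Ranks `a`'s candidates by control expression (descending, ties broken
#' by coordinates), partitions them into `bins` near-equal rank bins and
#' reports, per bin, the fraction also called by `b`. No smoothing is
#' applied.
#'
#' @param a,b `circ_callset` objects under the same match policy.
#' @param bins Number of rank bins (>= 1).
#' @return Data frame with columns `bin`, `n`, `overlap_fraction`.
#' @export
rank_overlap_curve <- function(a, b, bins = 20L) {
  stopifnot(inherits(a, "circ_callset"), inherits(b, "circ_callset"))
  check_same_policy(a, b)
  if (nrow(a) == 0L) stop("empty call set")
  if (!is.numeric(bins) || length(bins) != 1L || bins < 1)
    stop("bins must be >= 1")
  bins <- as.integer(bins)
  ord <- order(-a$control_expression, a$chrom, a$start, a$end)
  hit <- (callset_keys(a) %in% callset_keys(b))[ord]
  n <- length(hit)
  bin <- ceiling(seq_len(n) * bins / n)
  frac <- vapply(seq_len(bins), function(b) {
    idx <- bin == b
    if (!any(idx)) NA_real_ else mean(hit[idx])
  }, numeric(1))
  data.frame(bin = seq_len(bins),
             n = as.integer(tabulate(bin, bins)),
             overlap_fraction = frac)
}

#' Do the complementarity indices depend on call-set sizes?
#'
#' Pearson correlations (with p-values from [stats::cor.test()]) between
#' each index (iTP, iTN, score) over the off-diagonal cells of a pairwise
#' matrix and the candidate counts of the first (row) and second (column)
#' algorithm of each pair — a diagnostic for size-driven bias of the
#' scores. Supports an exclusion list to re-run without individual
#' algorithms.
#'
#' @param matrix A `circ_pairwise` result.
#' @param sizes Named numeric vector: candidate count per algorithm.
#' @param exclude Character vector of algorithms to drop from the analysis.
#' @return Data frame with columns `metric` (`iTP`/`iTN`/`score`),
#'   `size_of` (`first_algorithm`/`second_algorithm`), `r`, `p`, `n`; `r`
#'   and `p` are `NA` when a variable has zero variance.
#' @export
score_count_correlations <- function(matrix, sizes, exclude = NULL) {
  stopifnot(inherits(matrix, "circ_pairwise"), !is.null(names(sizes)))
  m <- matrix[matrix$row_algorithm != matrix$col_algorithm, , drop = FALSE]
  if (!is.null(exclude))
    m <- m[!(m$row_algorithm %in% exclude | m$col_algorithm %in% exclude), ,
           drop = FALSE]
  missing <- setdiff(unique(c(m$row_algorithm, m$col_algorithm)),
                     names(sizes))
  if (length(missing) > 0L)
    stop("sizes missing for: ", paste(missing, collapse = ", "))
  if (sum(!is.na(m$score)) < 3L)
    stop("need at least 3 defined cells")
  out <- list()
  for (metric in c("iTP", "iTN", "score")) {
    for (which_size in c("first_algorithm", "second_algorithm")) {
      x <- if (which_size == "first_algorithm")
        as.numeric(sizes[m$row_algorithm]) else
          as.numeric(sizes[m$col_algorithm])
      y <- m[[metric]]
      ok <- !is.na(x) & !is.na(y)
      if (sum(ok) < 3L || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
        r <- NA_real_; p <- NA_real_
      } else {
        ct <- stats::cor.test(x[ok], y[ok], method = "pearson")
        r <- unname(ct$estimate); p <- ct$p.value
      }
      out[[length(out) + 1L]] <- data.frame(
        metric = metric, size_of = which_size, r = r, p = p,
        n = sum(ok), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
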