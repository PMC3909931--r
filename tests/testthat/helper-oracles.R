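# Independent brute-force oracles used across the suite. These are kept
# deliberately naive and separate from the package's implementations.

# N50 by direct definition: the largest length L present in the list such
# that contigs of length >= L sum to at least half the total.
oracle_n50 <- function(lengths) {
  total <- sum(lengths)
  cands <- sort(unique(lengths), decreasing = TRUE)
  for (L in cands) {
    if (sum(lengths[lengths >= L]) >= total / 2) return(L)
  }
  stop("unreachable")
}

# Descendant sets by repeated parent lookup: term d is a descendant of a
# iff a appears in d's ancestor chain. Obsolete terms excluded.
oracle_descendants <- function(dag, term_id) {
  anc_of <- function(t) {
    seen <- character(); frontier <- dag$parents[[t]]
    while (length(frontier)) {
      new <- setdiff(frontier, seen)
      seen <- c(seen, new)
      frontier <- unlist(dag$parents[new], use.names = FALSE)
    }
    seen
  }
  ids <- dag$terms$id[!dag$terms$obsolete]
  ids[vapply(ids, function(t) term_id %in% anc_of(t), logical(1))]
}

# Exhaustive enumeration of every local alignment (all start cells, all
# monotone extension sequences, affine gap states), reporting the best
# score. Feasible only for short strings; no pruning.
oracle_local_align <- function(a, b, S, gap_open, gap_extend) {
  av <- strsplit(a, "", fixed = TRUE)[[1L]]
  bv <- strsplit(b, "", fixed = TRUE)[[1L]]
  m <- length(av); n <- length(bv)
  best <- 0
  extend <- function(i, j, score, state) {
    if (score > best) best <<- score
    if (i < m && j < n) {
      extend(i + 1L, j + 1L, score + S[av[i + 1L], bv[j + 1L]], 0L)
    }
    if (j < n) {
      extend(i, j + 1L,
             score - (if (state == 1L) gap_extend else gap_open + gap_extend),
             1L)
    }
    if (i < m) {
      extend(i + 1L, j,
             score - (if (state == 2L) gap_extend else gap_open + gap_extend),
             2L)
    }
  }
  if (m > 0L && n > 0L) {
    for (i in 0:(m - 1L)) for (j in 0:(n - 1L)) extend(i, j, 0, 0L)
  }
  best
}

# Closed-form expected fraction of contigs reaching the coverage
# threshold when n of `total` records are drawn without replacement:
# each contig's sampled aligned count is marginally hypergeometric.
oracle_expected_fraction <- function(aligned, lens, total, n,
                                     read_length, threshold) {
  k_needed <- ceiling(threshold * lens / read_length)
  p <- mapply(function(a, k) {
    if (k <= 0) 1 else 1 - stats::phyper(k - 1, a, total - a, n)
  }, aligned, k_needed)
  mean(p)
}

# Build a minimal alignment record data.frame with given per-contig
# aligned counts plus n_unaligned unmapped records.
make_alignments <- function(counts, n_unaligned = 0L) {
  ref <- rep(names(counts), counts)
  n <- length(ref) + n_unaligned
  data.frame(
    read_id = sprintf("r%05d", seq_len(n)),
    flag = c(rep(0L, length(ref)), rep(4L, n_unaligned)),
    reference_id = c(ref, rep(NA_character_, n_unaligned)),
    stringsAsFactors = FALSE
  )
}

# A small 4-letter substitution matrix with positive diagonal, mixed
# off-diagonal scores.
test_matrix4 <- function() {
  m <- matrix(-2, 4, 4, dimnames = list(c("A", "B", "C", "D"),
                                        c("A", "B", "C", "D")))
  diag(m) <- c(4, 5, 3, 4)
  m["A", "B"] <- m["B", "A"] <- 1
  m["C", "D"] <- m["D", "C"] <- -3
  m
}

random_word <- function(n, alphabet = c("A", "B", "C", "D")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

write_temp <- function(lines, ext = ".txt") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}
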