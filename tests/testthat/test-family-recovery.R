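test_that("six-frame translation covers both strands under the standard code", {
  fr <- six_frame_translate("ATGGCC")
  expect_equal(fr[["F1"]], "MA")
  # reverse complement is GGCCAT; frame R1 reads GGC CAT -> G H
  expect_equal(fr[["R1"]], "GH")
  expect_length(fr, 6L)

  # degenerate input: too short for any codon in any frame
  expect_true(all(six_frame_translate("AT") == ""))
  # ambiguity codes translate to X; stops are kept as *
  expect_equal(six_frame_translate("ATGNNNTAA")[["F1"]], "MX*")
  expect_error(six_frame_translate("ATG!CC"))
})

test_that("local_align matches diagonal sums, floors at zero, handles empties", {
  b62 <- blosum62_stop()
  self <- local_align("MKT", "MKT", b62)
  expect_equal(self$score, b62["M", "M"] + b62["K", "K"] + b62["T", "T"])
  expect_equal(local_align("", "MKT")$score, 0)
  expect_equal(local_align("", "")$score, 0)
  # no positively scoring residue pair -> empty local alignment
  m <- test_matrix4()
  expect_equal(local_align("C", "D", m, 2, 1)$score, 0)
  expect_error(local_align("MZT", "M", m, 2, 1), "missing")
})

test_that("local_align agrees with exhaustive enumeration on short words", {
  m <- test_matrix4()
  set.seed(42)
  checked <- 0L
  while (checked < 25L) {
    la <- sample(1:8, 1); lb <- sample(1:8, 1)
    if (la + lb > 11) next  # keep full enumeration tractable
    a <- random_word(la); b <- random_word(lb)
    for (gp in list(c(2, 1), c(0, 1), c(5, 2))) {
      expect_equal(local_align(a, b, m, gp[1], gp[2])$score,
                   oracle_local_align(a, b, m, gp[1], gp[2]),
                   info = paste(a, b, gp[1], gp[2]))
    }
    checked <- checked + 1L
  }
})

test_that("local_align score is symmetric for symmetric matrices", {
  m <- test_matrix4()
  set.seed(7)
  for (i in 1:30) {
    a <- random_word(sample(2:12, 1)); b <- random_word(sample(2:12, 1))
    expect_equal(local_align(a, b, m, 2, 1)$score,
                 local_align(b, a, m, 2, 1)$score)
  }
})

test_that("local_align scores agree with Biostrings pairwiseAlignment", {
  e <- new.env(); utils::data("BLOSUM62", package = "Biostrings", envir = e)
  b62 <- e$BLOSUM62
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  set.seed(13)
  for (i in 1:15) {
    a <- paste(sample(aa, sample(10:50, 1), TRUE), collapse = "")
    b <- paste(sample(aa, sample(10:50, 1), TRUE), collapse = "")
    expect_equal(
      local_align(a, b, b62, 11, 1)$score,
      Biostrings::score(Biostrings::pairwiseAlignment(
        Biostrings::AAString(a), Biostrings::AAString(b),
        substitutionMatrix = b62, gapOpening = 11, gapExtension = 1,
        type = "local")))
  }
})

test_that("stop symbols never score positively in the default matrix", {
  b62 <- blosum62_stop()
  expect_true(all(b62["*", ] == min(b62)))
  expect_true(all(b62[, "*"] == min(b62)))
})

test_that("planted orthologs are verified and decoys rejected", {
  g <- gen_families(3, members_per_family = 1, ortholog_identity = 0.8,
                    n_decoys = 8, seed = 19)
  rep <- recover_families(g$proteins, g$transcriptome,
                          families = g$families)
  verified <- rep$candidates[rep$candidates$verified, ]
  expect_setequal(paste(verified$query, verified$candidate),
                  paste(g$pairs$protein_id, g$pairs$contig_id))
  expect_false(any(grepl("^decoy", verified$candidate)))
  expect_true(all(rep$families$recovered))
})

test_that("exact copies verify and an empty transcriptome yields no candidates", {
  g <- gen_families(2, 1, ortholog_identity = 1.0, n_decoys = 0, seed = 3)
  rep <- recover_families(g$proteins, g$transcriptome)
  expect_equal(sum(rep$candidates$verified), 2L)

  empty <- recover_families(g$proteins,
                            Biostrings::DNAStringSet(character()))
  expect_equal(nrow(empty$candidates), 0L)
  expect_true(all(!empty$families$recovered))
  expect_error(recover_families(character(), g$transcriptome), "empty")
})

test_that("a chimeric candidate whose reciprocal best is another query fails", {
  g <- gen_families(2, 1, ortholog_identity = 1.0, n_decoys = 0, seed = 8)
  p1 <- g$proteins[[1]]; p2 <- g$proteins[[2]]
  # chimera: short stretch of protein 1 fused to most of protein 2, so the
  # forward search from p1 finds it but its reciprocal best is p2
  chim_pep <- paste0(substr(p1, 1, 30), p2)
  chimera <- with(list(), {
    set.seed(4)
    txstratkit:::reverse_translate(chim_pep)
  })
  tx <- c(as.character(g$transcriptome),
          chimera = chimera)
  rep <- recover_families(g$proteins, Biostrings::DNAStringSet(tx),
                          families = g$families, min_score = 30)
  chim_rows <- rep$candidates[rep$candidates$candidate == "chimera", ]
  p1_row <- chim_rows[chim_rows$query == names(g$proteins)[1], ]
  expect_equal(nrow(p1_row), 1L)
  expect_false(p1_row$verified)
  expect_equal(p1_row$reciprocal_top, names(g$proteins)[2])
})

test_that("verdicts are independent of input FASTA order", {
  g <- gen_families(3, 1, ortholog_identity = 0.7, n_decoys = 6, seed = 5)
  rep1 <- recover_families(g$proteins, g$transcriptome)
  perm_p <- sample(length(g$proteins))
  perm_t <- sample(length(g$transcriptome))
  rep2 <- recover_families(g$proteins[perm_p], g$transcriptome[perm_t])
  key <- function(r) {
    d <- r$candidates[order(r$candidates$query, r$candidates$candidate), ]
    paste(d$query, d$candidate, d$verified)
  }
  expect_identical(key(rep1), key(rep2))
})
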