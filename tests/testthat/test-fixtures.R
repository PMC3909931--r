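test_that("generated transcriptomes are seed-deterministic with valid ORFs", {
  a <- gen_transcriptome(10, c(200, 400), orf_fraction = 1, seed = 5)
  b <- gen_transcriptome(10, c(200, 400), orf_fraction = 1, seed = 5)
  expect_identical(as.character(a$contigs), as.character(b$contigs))
  expect_equal(nrow(a$orf_truth), 10L)
  # each recorded ORF starts with ATG, ends at a stop, no internal stops
  for (i in seq_len(nrow(a$orf_truth))) {
    tr <- a$orf_truth[i, ]
    orf <- substr(as.character(a$contigs[[tr$contig_id]]),
                  tr$orf_start, tr$orf_end)
    pep <- six_frame_translate(orf)[["F1"]]
    expect_equal(substr(pep, 1, 1), "M")
    expect_equal(substr(pep, nchar(pep), nchar(pep)), "*")
    expect_false(grepl("\\*", substr(pep, 1, nchar(pep) - 1)))
  }
  none <- gen_transcriptome(5, c(200, 400), orf_fraction = 0, seed = 5)
  expect_equal(nrow(none$orf_truth), 0L)
  expect_error(gen_transcriptome(5, c(60, 90), orf_fraction = 1, seed = 1),
               "ORF")
})

test_that("generated reads respect the unaligned fraction and count accounting", {
  tx <- gen_transcriptome(8, c(200, 500), 0, seed = 2)$contigs
  r <- gen_reads(tx, 1000, read_length = 40, unaligned_fraction = 0.2,
                 seed = 9)
  expect_equal(sum(r$counts), 800L)
  expect_equal(sum(r$alignments$flag == 4L), 200L)
  all_unaligned <- gen_reads(tx, 100, 40, unaligned_fraction = 1, seed = 1)
  expect_true(all(all_unaligned$alignments$flag == 4L))
  expect_error(gen_reads(tx, 10, read_length = 10000, seed = 1),
               "shortest contig")
})

test_that("aligned counts follow length-proportional multinomial expectations", {
  tx <- gen_transcriptome(6, c(200, 800), 0, seed = 4)$contigs
  lens <- Biostrings::width(tx)
  n_aligned <- 900L
  reps <- 200L
  counts <- sapply(seq_len(reps), function(s) {
    gen_reads(tx, 1000, 40, unaligned_fraction = 0.1, seed = s)$counts
  })
  p <- lens / sum(lens)
  se <- sqrt(n_aligned * p * (1 - p) / reps)
  expect_true(all(abs(rowMeans(counts) - n_aligned * p) <= 3.5 * se))
})

test_that("generated SAM files round-trip through the reader", {
  tx <- gen_transcriptome(5, c(200, 400), 0, seed = 6)$contigs
  r <- gen_reads(tx, 200, 40, unaligned_fraction = 0.15, seed = 7)
  f <- tempfile(fileext = ".sam")
  write_sam(r$alignments, tx, f)
  back <- read_sam(f)
  expect_equal(nrow(back), 200L)
  got <- table(factor(back$reference_id, levels = names(tx)))
  expect_equal(as.integer(got), unname(r$counts))
})

test_that("contaminant injection matches its nominal rate", {
  model <- edwardsiid_lineage_model()
  probs <- c("no_hit" = 0.3,
             stats::setNames(rep(0.1, 7), unique(model$ancestors)))
  n <- 1000L
  g <- gen_hit_tables(sprintf("g%04d", 1:n), model, probs,
                      contamination_rate = 0.1, seed = 13)
  k <- sum(g$truth$contamination)
  se <- sqrt(n * 0.1 * 0.9)
  expect_lt(abs(k - n * 0.1), 3 * se)
  # contaminants hit only distal bins
  hits <- do.call(rbind, g$hits)
  contam <- g$truth$contig_id[g$truth$contamination]
  contam_bins <- unique(hits$bin[hits$query_id %in% contam])
  expect_true(all(contam_bins %in% model$distal_bins))
})

test_that("gen_hit_tables validates stratum probabilities", {
  model <- edwardsiid_lineage_model()
  expect_error(gen_hit_tables("c1", model, c(no_hit = 0.5), seed = 1),
               "sum to 1")
  expect_error(gen_hit_tables("c1", model, c(bogus = 1), seed = 1),
               "ancestor labels")
  empty <- gen_hit_tables(c("c1", "c2"), model, c(no_hit = 1), seed = 1)
  expect_true(all(vapply(empty$hits, nrow, integer(1)) == 0L))
})

test_that("generated ontologies are trees at max_parents 1 and round-trip", {
  g <- gen_ontology(30, max_parents = 1, seed = 3)
  dag <- read_obo(write_temp(g$lines, ".obo"))
  non_roots <- setdiff(dag$terms$id, g$root_id)
  expect_true(all(lengths(dag$parents[non_roots]) == 1L))
  g2 <- gen_ontology(30, max_parents = 4, seed = 4)
  expect_silent(dag2 <- read_obo(write_temp(g2$lines, ".obo")))
  expect_equal(nrow(dag2$terms), 30L)
})

test_that("all generators are byte-deterministic in their seed", {
  f1 <- tempfile(); f2 <- tempfile()
  b1 <- write_fixture_bundle(f1, seed = 77)
  b2 <- write_fixture_bundle(f2, seed = 77)
  files <- list.files(f1, recursive = TRUE)
  expect_identical(files, list.files(f2, recursive = TRUE))
  for (fn in files) {
    expect_identical(readLines(file.path(f1, fn)),
                     readLines(file.path(f2, fn)), info = fn)
  }
})

test_that("every bundle file parses cleanly through the package readers", {
  d <- tempfile()
  b <- write_fixture_bundle(d, seed = 101)
  expect_silent(contigs <- read_fasta(b$paths$contigs))
  expect_silent(aln <- read_sam(b$paths$sam))
  expect_silent(dag <- read_obo(b$paths$obo))
  expect_silent(model <- read_lineage_model(b$paths$model))
  for (p in b$paths$hits) expect_silent(read_hits(p, bin = "x"))
  expect_silent(read_annotations(b$paths$ann_focal, dag))
  expect_silent(read_annotations(b$paths$ec_focal))
  expect_equal(length(contigs), 100L)
  truth_counts <- utils::read.delim(file.path(d, "truth",
                                              "aligned_counts.tsv"))
  got <- table(factor(aln$reference_id, levels = truth_counts$contig_id))
  expect_equal(as.integer(got), truth_counts$aligned_reads)
})
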