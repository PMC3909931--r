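model <- edwardsiid_lineage_model()

test_that("assign_origin follows deepest-hit-wins over the bin order", {
  a <- assign_origin("N. vectensis", model)
  expect_equal(a$origin_label, "Edwardsiidae ancestor")
  expect_equal(a$deepest_bin, "N. vectensis")

  all_bins <- c(model$bins, model$out_of_lineage)
  b <- assign_origin(all_bins, model)
  expect_equal(b$origin_label, "ancestor of Eubacteria + Eukaryota")

  expect_equal(assign_origin(character(), model)$origin_label, "no_hit")
  expect_equal(assign_origin("viruses", model)$origin_label,
               "out_of_lineage_only")
  # a hit pattern spanning animals but no deeper maps to the metazoan branch
  expect_equal(assign_origin(c("Bilateria",
                               "Metazoa excluding Cnidaria and Bilateria"),
                             model)$origin_label, "Metazoa ancestor")
  expect_error(assign_origin("Fungi", model), "Fungi")
})

test_that("origin assignment ignores virus hits when in-lineage hits exist", {
  a <- assign_origin(c("viruses", "N. vectensis"), model)
  expect_equal(a$origin_label, "Edwardsiidae ancestor")
})

test_that("the merged prokaryote-ancestor option pools the deep strata", {
  merged <- edwardsiid_lineage_model(merge_prokaryote_ancestors = TRUE)
  expect_equal(assign_origin("Eubacteria", merged)$origin_label,
               "ancestor of cellular life")
  expect_equal(assign_origin("Archaea", merged)$origin_label,
               "ancestor of cellular life")
})

test_that("contamination flag needs a distal deepest hit and empty intermediates", {
  expect_true(flag_contamination("Eubacteria", model))
  expect_false(flag_contamination(c("Eubacteria", "Eukaryota excluding Metazoa",
                                    "Bilateria", "N. vectensis"), model))
  expect_false(flag_contamination("N. vectensis", model))
  expect_false(flag_contamination(character(), model))
  # distal hit with closer cnidarian hits but empty intermediates still flags
  expect_true(flag_contamination(c("Eubacteria", "N. vectensis"), model))
})

test_that("origin assignment is a pure function of the hit-bin set", {
  set.seed(21)
  all_bins <- c(model$bins, model$out_of_lineage)
  for (i in 1:50) {
    bins <- sample(all_bins, sample(seq_along(all_bins), 1))
    a <- assign_origin(bins, model)
    b <- assign_origin(rev(bins), model)
    c_ <- assign_origin(sample(rep(bins, 2)), model)  # duplicates too
    expect_equal(a$origin_label, b$origin_label)
    expect_equal(a$origin_label, c_$origin_label)
    expect_equal(a$contamination_flag, c_$contamination_flag)
    if (!is.na(a$deepest_bin)) expect_true(a$deepest_bin %in% bins)
  }
})

test_that("summarize_strata uses hit-producing contigs as the denominator", {
  hits <- data.frame(
    query_id = c("c1", "c2", "c3", "c4", "c5", "c6"),
    bin = c("N. vectensis", "N. vectensis", "N. vectensis",
            "Bilateria", "Bilateria", "Bilateria"),
    stringsAsFactors = FALSE)
  asg <- assign_origins(hits, model, contig_ids = sprintf("c%d", 1:10))
  summ <- summarize_strata(asg, model)
  expect_equal(summ$n_hit_producing, 6L)
  expect_equal(summ$n_no_hit, 4L)
  st <- summ$strata
  expect_equal(st$percent[st$ancestor_label == "Edwardsiidae ancestor"], 50)
  expect_equal(st$percent[st$ancestor_label == "Eumetazoa ancestor"], 50)
  expect_equal(sum(st$percent), 100)
})

test_that("all-no-hit input yields absent percentages, not zeros", {
  asg <- assign_origins(
    data.frame(query_id = character(), bin = character()),
    model, contig_ids = c("c1", "c2"))
  summ <- summarize_strata(asg, model)
  expect_equal(summ$n_hit_producing, 0L)
  expect_true(all(is.na(summ$strata$percent)))
  expect_error(summarize_strata(asg[0, ], model), "no assignments")
})

test_that("generated hit tables with zero contamination are recovered exactly", {
  probs <- c("no_hit" = 0.3,
             stats::setNames(rep(0.1, 7), unique(model$ancestors)))
  g <- gen_hit_tables(sprintf("g%03d", 1:200), model, probs,
                      contamination_rate = 0, seed = 77)
  hits <- do.call(rbind, g$hits)
  asg <- assign_origins(hits, model, contig_ids = g$truth$contig_id)
  merged <- merge(asg, g$truth, by = "contig_id")
  clean <- !is.na(merged$stratum)
  expect_gt(sum(clean), 100)
  expect_equal(merged$origin_label[clean], merged$stratum[clean])
  expect_equal(merged$origin_label[!clean], rep("no_hit", sum(!clean)))
  # summary percentages equal the generator's label frequencies exactly
  summ <- summarize_strata(asg, model)
  freq <- table(factor(merged$stratum, levels = summ$strata$ancestor_label))
  expect_equal(summ$strata$count, as.integer(freq))
})

test_that("lineage model config files round-trip", {
  f <- tempfile(fileext = ".tsv")
  write_lineage_model(model, f)
  back <- read_lineage_model(f, focal_name = model$focal_name)
  expect_equal(back$bins, model$bins)
  expect_equal(back$ancestors, model$ancestors)
  expect_equal(back$out_of_lineage, model$out_of_lineage)
  expect_equal(back$distal_bins, model$distal_bins)
  expect_equal(back$intermediate_bins, model$intermediate_bins)
})

test_that("lineage_model validates its invariants", {
  expect_error(lineage_model(character(), character()), "non-empty")
  expect_error(lineage_model(c("a", "a"), c("x", "y")), "unique")
  expect_error(lineage_model("a", "x", out_of_lineage = "a"), "unique")
})
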