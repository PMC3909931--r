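chain_dag <- function() {
  read_obo(write_temp(c(
    "[Term]", "id: GO:A", "name: a", "",
    "[Term]", "id: GO:B", "name: b", "is_a: GO:A", "",
    "[Term]", "id: GO:C", "name: c", "is_a: GO:B", ""), ".obo"))
}

test_that("go_descendants walks chains, leaves and diamonds", {
  dag <- chain_dag()
  expect_setequal(go_descendants(dag, "GO:A"), c("GO:B", "GO:C"))
  expect_length(go_descendants(dag, "GO:C"), 0L)
  expect_error(go_descendants(dag, "GO:X"), "unknown")

  diamond <- read_obo(write_temp(c(
    "[Term]", "id: GO:A", "",
    "[Term]", "id: GO:B", "is_a: GO:A", "",
    "[Term]", "id: GO:C", "is_a: GO:A", "",
    "[Term]", "id: GO:D", "is_a: GO:B", "is_a: GO:C", ""), ".obo"))
  d <- go_descendants(diamond, "GO:A")
  expect_setequal(d, c("GO:B", "GO:C", "GO:D"))
  expect_equal(sum(d == "GO:D"), 1L)  # multi-parent term counted once
  expect_setequal(oracle_descendants(diamond, "GO:A"), d)
})

test_that("children-mode coverage propagates recovery up the subtree", {
  dag <- read_obo(write_temp(c(
    "[Term]", "id: GO:ROOT", "",
    "[Term]", "id: GO:B", "is_a: GO:ROOT", "",
    "[Term]", "id: GO:C", "is_a: GO:ROOT", "",
    "[Term]", "id: GO:B1", "is_a: GO:B", ""), ".obo"))
  ann <- data.frame(contig_id = "c1", label = "GO:B1")
  cov <- subtree_coverage(dag, list(sp = ann), "GO:ROOT", mode = "children")
  expect_equal(cov$n_units_total, 2L)
  expect_equal(cov$n_recovered[["sp"]], 1L)
  expect_true(cov$recovered$sp[["GO:B"]])
  expect_false(cov$recovered$sp[["GO:C"]])

  none <- subtree_coverage(dag, list(sp = ann[0, ]), "GO:ROOT")
  expect_equal(none$n_recovered[["sp"]], 0L)
  expect_equal(none$n_units_total, 2L)  # totals independent of annotations

  # annotations on the start term itself count toward no child unit
  at_root <- data.frame(contig_id = "c1", label = "GO:ROOT")
  cov2 <- subtree_coverage(dag, list(sp = at_root), "GO:ROOT")
  expect_equal(cov2$n_recovered[["sp"]], 0L)
  expect_equal(cov2$n_at_start[["sp"]], 1L)

  expect_error(subtree_coverage(dag, list(), "GO:ROOT", mode = "bogus"))
})

test_that("terms-mode counts directly annotated subtree terms only", {
  dag <- chain_dag()
  ann <- data.frame(contig_id = "c1", label = "GO:C")
  cov <- subtree_coverage(dag, list(sp = ann), "GO:A", mode = "terms")
  expect_equal(cov$n_units_total, 2L)
  expect_equal(cov$n_recovered[["sp"]], 1L)  # GO:C itself; GO:B not
})

test_that("coverage counts match the transitive-closure oracle on random DAGs", {
  for (seed in 1:8) {
    g <- gen_ontology(60, max_parents = 3, seed = seed)
    dag <- read_obo(write_temp(g$lines, ".obo"))
    ann <- gen_annotations(dag, sprintf("c%02d", 1:20), 25, seed = seed + 100)
    for (mode in c("children", "terms")) {
      cov <- subtree_coverage(dag, list(sp = ann), g$root_id, mode = mode)
      units <- if (mode == "children") dag$children[[g$root_id]] else
        oracle_descendants(dag, g$root_id)
      recovered <- vapply(units, function(u) {
        if (mode == "terms") u %in% ann$label else
          u %in% ann$label || any(oracle_descendants(dag, u) %in% ann$label)
      }, logical(1))
      expect_equal(cov$n_units_total, length(units))
      expect_equal(cov$n_recovered[["sp"]], sum(recovered))
    }
  }
})

test_that("recovered counts are monotone under annotation addition", {
  set.seed(33)
  g <- gen_ontology(60, max_parents = 3, seed = 9)
  dag <- read_obo(write_temp(g$lines, ".obo"))
  pool <- setdiff(dag$terms$id, g$root_id)
  for (i in 1:40) {
    base <- gen_annotations(dag, "c1", sample(1:15, 1), seed = i)
    extra <- rbind(base, data.frame(contig_id = "c1",
                                    label = sample(pool, 1)))
    for (mode in c("children", "terms")) {
      a <- subtree_coverage(dag, list(s = base), g$root_id, mode)
      b <- subtree_coverage(dag, list(s = extra), g$root_id, mode)
      expect_gte(b$n_recovered[["s"]], a$n_recovered[["s"]])
    }
  }
})

test_that("obsolete terms join no totals and recover nothing", {
  dag <- read_obo(write_temp(c(
    "[Term]", "id: GO:ROOT", "",
    "[Term]", "id: GO:B", "is_a: GO:ROOT", "",
    "[Term]", "id: GO:OLD", "is_a: GO:ROOT", "is_obsolete: true", ""),
    ".obo"))
  ann <- data.frame(contig_id = "c1", label = "GO:OLD")
  cov <- subtree_coverage(dag, list(sp = ann), "GO:ROOT")
  expect_equal(cov$n_units_total, 1L)
  expect_equal(cov$n_recovered[["sp"]], 0L)
})

test_that("compare_species classifies root children by recovery pattern", {
  dag <- read_obo(write_temp(c(
    "[Term]", "id: GO:ROOT", "name: root", "",
    "[Term]", "id: GO:X", "name: x", "is_a: GO:ROOT", "",
    "[Term]", "id: GO:Y", "name: y", "is_a: GO:ROOT", "",
    "[Term]", "id: GO:X1", "name: x1", "is_a: GO:X", "",
    "[Term]", "id: GO:Y1", "name: y1", "is_a: GO:Y", ""), ".obo"))
  ann_a <- data.frame(contig_id = "c1", label = "GO:X1")
  ann_b <- data.frame(contig_id = "d1", label = c("GO:X1", "GO:Y1"))
  cmp <- compare_species(dag, ann_a, ann_b, species_names = c("el", "nv"))
  expect_equal(nrow(cmp), 2L)
  expect_equal(cmp$classification[cmp$start_term == "GO:X"], "both")
  expect_equal(cmp$classification[cmp$start_term == "GO:Y"], "nv_only")

  same <- compare_species(dag, ann_b, ann_b)
  expect_equal(same$n_recovered_A, same$n_recovered_B)
  expect_error(compare_species(read_obo(write_temp(
    c("format-version: 1.2"), ".obo")), ann_a, ann_b), "empty ontology")
})

test_that("a fixture shaped like a two-species subcategory comparison reproduces its counts", {
  # 20 root children; exactly 17 recovered in at least one species
  lines <- c("[Term]", "id: GO:ROOT", "")
  kids <- sprintf("GO:K%02d", 1:20)
  for (k in kids) lines <- c(lines, "[Term]", paste0("id: ", k),
                             "is_a: GO:ROOT", "")
  dag <- read_obo(write_temp(lines, ".obo"))
  ann_a <- data.frame(contig_id = "c", label = kids[1:14])
  ann_b <- data.frame(contig_id = "d", label = kids[5:17])
  cmp <- compare_species(dag, ann_a, ann_b)
  expect_equal(nrow(cmp), 20L)
  expect_equal(sum(cmp$classification != "neither"), 17L)
})
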