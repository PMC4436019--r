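test_that("expression parsing validates the header and drops bad ratios", {
  rec <- parse_expression("entrez\tsymbol\tlog2_ratio\n7157\tTP53\t2.0")
  expect_equal(nrow(rec), 1L)
  expect_equal(rec$entrez, 7157L)
  expect_equal(rec$symbol, "TP53")

  expect_warning(
    rec2 <- parse_expression("entrez\tsymbol\tlog2_ratio\n1\tA\tNaN\n2\tB\t1.5"),
    class = "pathburst_dropped_records")
  expect_equal(nrow(rec2), 1L)
  expect_equal(attr(rec2, "n_dropped"), 1L)

  expect_error(parse_expression("7157\tTP53\t2.0"),
               class = "pathburst_parse_error")
  expect_error(parse_expression("entrez\tsymbol\n1\tA"), regexp = "log2_ratio")

  # blank entrez is fine
  rec3 <- parse_expression("entrez\tsymbol\tlog2_ratio\n\tMYC\t-2")
  expect_true(is.na(rec3$entrez))

  # linear input transformed on load
  rec4 <- parse_expression("entrez\tsymbol\tlog2_ratio\n1\tA\t4", linear_ratio = TRUE)
  expect_equal(rec4$log2_ratio, 2)
})

test_that("duplicate gene records keep the largest absolute ratio", {
  expect_warning(
    rec <- parse_expression(
      "entrez\tsymbol\tlog2_ratio\n1\tA\t0.5\n1\tA\t-3\n\tb\t1\n\tB\t0.2"),
    class = "pathburst_duplicate_records")
  expect_equal(rec$log2_ratio[rec$symbol == "A"], -3)
  # dedup by symbol is case-insensitive when no entrez is present
  expect_equal(rec$log2_ratio[rec$symbol == "B"], 1)
})

test_that("DE classification is inclusive at the cutoff boundary", {
  expect_equal(as.character(classify_de(c(2, -2, 0.5, 1, -1), cutoff = 1)),
               c("UP", "DOWN", "UNCHANGED", "UP", "DOWN"))
  expect_error(classify_de(1, cutoff = 0), class = "pathburst_value_error")
})

test_that("pathway summaries match a match-and-count oracle", {
  t <- tiny_hierarchy()
  m <- parse_ortholog_map(c("A\tA_T", "B\tB_T", "C\tC_T", "D\tD_T"))
  proj <- project_orthology(t$h, m)
  rec <- parse_expression(
    "entrez\tsymbol\tlog2_ratio\n1\tA\t2\n2\tB\t-1.5\n3\tC\t0.2")
  s1 <- summarize_pathway(t$h, "P1", rec, proj)
  expect_equal(s1$n_up, 1L)
  expect_equal(s1$n_down, 1L)
  expect_equal(s1$n_ortho, 3L)
  expect_equal(s1$de_ratio, 2 / 3)
  # no matched records
  s_empty <- summarize_pathway(t$h, "P2",
    parse_expression("entrez\tsymbol\tlog2_ratio"), proj)
  expect_equal(s_empty$de_ratio, 0)

  # random instances against a nested-loop recount
  for (seed in 1:10) {
    inst <- random_instance(seed)
    genes <- sort(unique(inst$genes$symbol))
    covered <- withr::with_seed(seed + 7, genes[stats::runif(length(genes)) < 0.6])
    mm <- parse_ortholog_map(sprintf("%s\t%s_T", covered, covered))
    pr <- project_orthology(inst$h, mm)
    ratios <- withr::with_seed(seed, stats::rnorm(length(genes), 0, 2))
    rr <- parse_expression(c("entrez\tsymbol\tlog2_ratio",
                             sprintf("\t%s\t%.4f", genes, ratios)))
    smry <- summarize_expression(inst$h, rr, pr)
    for (i in seq_len(nrow(smry))) {
      ortho <- intersect(oracle_subtree_genes(inst, smry$pathway_id[i]), covered)
      r <- ratios[match(ortho, genes)]
      expect_equal(smry$n_up[i], sum(r >= 1))
      expect_equal(smry$n_down[i], sum(r <= -1))
      expect_equal(smry$n_ortho[i], length(ortho))
      expect_true(smry$de_ratio[i] >= 0 && smry$de_ratio[i] <= 1)
      expect_true(smry$n_up[i] + smry$n_down[i] <= smry$n_ortho[i])
    }
  }
})

test_that("DE counts shrink as the cutoff grows and parents dominate children", {
  inst <- random_instance(23, max_pathways = 10, max_genes = 30)
  genes <- sort(unique(inst$genes$symbol))
  m <- parse_ortholog_map(sprintf("%s\t%s_T", genes, genes))
  proj <- project_orthology(inst$h, m)
  ratios <- withr::with_seed(23, stats::rnorm(length(genes), 0, 2))
  rec <- parse_expression(c("entrez\tsymbol\tlog2_ratio",
                            sprintf("\t%s\t%.4f", genes, ratios)))
  prev <- NULL
  for (cutoff in c(0.5, 1, 2)) {
    s <- summarize_expression(inst$h, rec, proj, cutoff = cutoff)
    if (!is.null(prev)) {
      expect_true(all(s$n_up <= prev$n_up))
      expect_true(all(s$n_down <= prev$n_down))
    }
    prev <- s
  }
  s <- prev
  de <- stats::setNames(s$n_up + s$n_down, s$pathway_id)
  for (id in s$pathway_id) {
    kids <- inst$h$children[[id]]
    if (!is.null(kids) && length(kids) > 0) {
      expect_true(de[[id]] >= max(de[kids]))
    }
  }
})

test_that("gene tables compose expression, crosstalk and rate-limiting fields", {
  t <- tiny_hierarchy()
  m <- parse_ortholog_map(c("A\tA_T", "B\tB_T"))
  proj <- project_orthology(t$h, m)
  idx <- crosstalk_index(t$h, 2)
  rl <- parse_rate_limiting("B\t1")
  rec <- parse_expression("entrez\tsymbol\tlog2_ratio\n1\ta\t2\n2\tB\t-0.1\n3\tC\t5")
  tab <- gene_table(t$h, "P1", rec, proj, idx, rl)
  expect_equal(tab$symbol, c("A", "B")) # C not orthologous
  expect_equal(as.character(tab$status), c("UP", "UNCHANGED"))
  expect_equal(tab$n_crosstalk_pathways, c(0L, 2L))
  expect_equal(tab$rate_limiting, c(FALSE, TRUE))
  expect_equal(tab$n_products, c(1L, 2L)) # B sits in two leaf pathways
  expect_equal(nrow(gene_table(t$h, "P3",
    parse_expression("entrez\tsymbol\tlog2_ratio"), proj)), 0L)
  expect_error(gene_table(t$h, "NOPE", rec, proj), class = "pathburst_key_error")
})

test_that("a matched leaf record propagates into every ancestor summary", {
  edges <- parse_relations(c("P1\tP2", "P2\tP3"))
  h <- build_hierarchy(edges, parse_gmt("P3\tleaf\tA"))
  m <- parse_ortholog_map("A\tA_T")
  proj <- project_orthology(h, m)
  rec <- parse_expression("entrez\tsymbol\tlog2_ratio\n1\tA\t3")
  s <- summarize_expression(h, rec, proj)
  expect_true(all(s$n_up == 1L))
  expect_true(all(s$de_ratio == 1))
})
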