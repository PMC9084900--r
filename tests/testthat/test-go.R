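test_that("OBO parsing handles chains, obsoletes, alt ids, and errors", {
  obo <- write_fixture_obo(tempfile(fileext = ".obo"))
  dag <- load_obo(obo)
  expect_equal(nrow(dag$terms), 5)              # obsolete term skipped
  expect_equal(dag$roots, "GO:0000001")
  expect_setequal(dag$parents[["GO:0000004"]], c("GO:0000002", "GO:0000003"))
  expect_equal(unname(dag$alt["GO:0000099"]), "GO:0000004")
  expect_equal(unname(dag$depth["GO:0000005"]), 3L)

  cyc <- tempfile(fileext = ".obo")
  writeLines(c("[Term]", "id: GO:1", "name: a",
               "namespace: biological_process", "is_a: GO:2", "",
               "[Term]", "id: GO:2", "name: b",
               "namespace: biological_process", "is_a: GO:1"), cyc)
  expect_error(load_obo(cyc), "cycle|root")

  nons <- tempfile(fileext = ".obo")
  writeLines(c("[Term]", "id: GO:1", "name: a"), nons)
  expect_error(load_obo(nons), "namespace")
})

test_that("simulated DAGs round-trip through the OBO writer", {
  for (seed in c(2, 17)) {
    dag <- simulate_go_universe(40, max_depth = 5, seed = seed)
    path <- tempfile(fileext = ".obo")
    write_obo(dag, path)
    back <- load_obo(path)
    expect_identical(back$terms, dag$terms)
    expect_identical(back$parents, dag$parents)
    expect_identical(back$depth, dag$depth)
  }
})

test_that("annotation propagation applies the true-path rule", {
  dag <- load_obo(write_fixture_obo(tempfile(fileext = ".obo")))
  anno <- propagate_annotations(
    list(g_root = "GO:0000001", g_leaf = "GO:0000005",
         g_diamond = "GO:0000004", g_alt = "GO:0000099"), dag)
  expect_setequal(anno$propagated$g_root, "GO:0000001")
  expect_setequal(anno$propagated$g_leaf,
                  c("GO:0000005", "GO:0000004", "GO:0000002", "GO:0000003",
                    "GO:0000001"))
  expect_setequal(anno$propagated$g_diamond,
                  c("GO:0000004", "GO:0000002", "GO:0000003", "GO:0000001"))
  # alt id resolves to the diamond term
  expect_setequal(anno$propagated$g_alt, anno$propagated$g_diamond)
  # idempotence: propagating the propagated sets changes nothing
  again <- propagate_annotations(anno$propagated, dag)
  expect_identical(lapply(again$propagated, sort),
                   lapply(anno$propagated, sort))
  expect_error(propagate_annotations(list(g = "GO:9999999"), dag),
               "GO:9999999")
})

test_that("fisher_tail matches exact arithmetic and the log-factorial oracle", {
  expect_equal(fisher_tail(4, 5, 5, 20), 76 / 15504)
  expect_equal(fisher_tail(0, 5, 5, 20), 1)
  # study = universe makes every term's tail probability 1
  expect_equal(fisher_tail(7, 10, 7, 10), 1)
  expect_error(fisher_tail(6, 5, 7, 10), "impossible")
  withr::with_seed(4, {
    for (rep in 1:200) {
      ut <- sample(2:30, 1)
      uc <- sample(0:ut, 1)
      st <- sample(0:ut, 1)
      sc <- sample(0:min(st, uc), 1)
      expect_equal(fisher_tail(sc, st, uc, ut),
                   oracle_fisher_tail(sc, st, uc, ut), tolerance = 1e-12)
    }
  })
})

test_that("elim decorrelates ancestors of a significantly enriched leaf", {
  dag <- load_obo(write_fixture_obo(tempfile(fileext = ".obo")))
  genes <- sprintf("g%02d", 1:50)
  # 10 study genes annotated to the leaf; the rest spread near the root
  direct <- stats::setNames(c(rep("GO:0000005", 10),
                              rep("GO:0000002", 20),
                              rep("GO:0000001", 20)), genes)
  anno <- propagate_annotations(as.list(direct), dag)
  rec <- run_enrichment(study = genes[1:10], universe = genes, anno, dag,
                        method = "elim")
  leaf <- rec[rec$term_id == "GO:0000005", ]
  parent <- rec[rec$term_id == "GO:0000004", ]
  grand <- rec[rec$term_id == "GO:0000002", ]
  expect_lt(leaf$p_classic, 0.05)
  expect_lt(leaf$p_elim, 0.05)
  # ancestors inherit the leaf genes under classic but lose them under elim
  expect_lt(parent$p_classic, 0.05)
  expect_gt(parent$p_elim, 0.05)
  expect_lt(grand$p_classic, 0.05)
  expect_gt(grand$p_elim, 0.05)
  # original counts are reported even for eliminated ancestors
  expect_equal(parent$study_count, 10)
  expect_equal(parent$universe_count, 10)

  expect_error(run_enrichment(character(0), genes, anno, dag), "empty")
  expect_error(run_enrichment("not_a_gene", genes, anno, dag), "subset")
})

test_that("elim is a no-op when nothing reaches the elimination cutoff", {
  dag <- simulate_go_universe(15, max_depth = 3, seed = 6)
  genes <- sprintf("g%02d", 1:30)
  direct <- withr::with_seed(8, stats::setNames(
    lapply(genes, function(g) sample(dag$terms$id, 2)), genes))
  anno <- propagate_annotations(direct, dag)
  study <- withr::with_seed(9, sample(genes, 8))
  rec <- run_enrichment(study, genes, anno, dag, elim_alpha = 1e-12)
  expect_equal(rec$p_elim, rec$p_classic)
})

test_that("significant_terms thresholds strictly and sorts by p", {
  rec <- data.frame(term_id = c("GO:2", "GO:1", "GO:3"),
                    p_classic = c(0.01, 0.05, 0.002),
                    p_elim = c(0.01, 0.05, 0.002))
  expect_equal(significant_terms(rec, alpha = 0.05), c("GO:3", "GO:2"))
  expect_equal(significant_terms(rec[0, ]), character(0))
})

test_that("unannotated genes are dropped from both totals", {
  dag <- simulate_go_universe(5, seed = 2)
  genes <- c("a", "b", "c", "d")
  anno <- propagate_annotations(list(a = dag$terms$id[2],
                                     b = dag$terms$id[2],
                                     c = dag$terms$id[1]), dag)
  rec <- run_enrichment(study = c("a", "d"), universe = genes, anno, dag)
  expect_equal(unique(rec$universe_total), 3)  # "d" has no annotation
  expect_equal(unique(rec$study_total), 1)
})
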