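test_that("GC computation excludes N from the denominator", {
  expect_equal(compute_gc("ATGC"), 0.5)
  expect_equal(compute_gc("GGGG"), 1.0)
  expect_equal(compute_gc("ATGNN"), 1 / 3)
  expect_equal(compute_gc("atgc"), 0.5)
  expect_error(compute_gc("NNN"), "only N")
  expect_error(compute_gc("ATGX"), "A/C/G/T/N")
})

test_that("GC band filter is strict and gated on length", {
  contigs <- data.frame(
    contig_id = c("low", "edge", "short", "high", "edge_hi"),
    length = c(5000L, 5000L, 800L, 5000L, 5000L),
    gc = c(0.23, 0.24, 0.10, 0.43, 0.42))
  rem <- filter_by_gc(contigs)
  expect_equal(rem$reason[rem$contig_id == "low"], "gc_low")
  expect_equal(rem$reason[rem$contig_id == "high"], "gc_high")
  expect_false("edge" %in% rem$contig_id)     # boundary retained
  expect_false("edge_hi" %in% rem$contig_id)
  expect_false("short" %in% rem$contig_id)    # below the 1,000 bp gate
})

test_that("reference coverage averages the longest contigs", {
  one <- data.frame(contig_id = "a", length = 100L, mean_coverage = 12)
  expect_equal(reference_coverage(one), 12)
  two <- data.frame(contig_id = c("a", "b", "c"),
                    length = c(9000L, 8000L, 10L),
                    mean_coverage = c(10, 20, 999))
  expect_equal(reference_coverage(two, n_longest = 2), 15)
  expect_equal(reference_coverage(two, n_longest = 10),
               mean(c(10, 20, 999)))
  expect_error(reference_coverage(two[0, ]), "no contigs")
})

test_that("coverage filter is strict, relative, and gated at 5,000 bp", {
  contigs <- data.frame(contig_id = c("hot", "edge", "short"),
                        length = c(6000L, 6000L, 4000L),
                        mean_coverage = c(33, 32, 100))
  rem <- filter_by_coverage(contigs, reference = 16)
  expect_equal(rem$contig_id, "hot")          # 33 > 2 * 16
  expect_equal(rem$reason, "coverage_high")
  expect_error(filter_by_coverage(contigs, reference = 0), "positive")
})

test_that("two-step best-hit classification follows the bitscore rule", {
  s1 <- data.frame(query_id = c("q1", "q2", "q3"), subject_id = "db1",
                   subject_label = "custom", bitscore = 100, evalue = 1e-20)
  s2 <- data.frame(
    query_id = c("q1", "q2", "q2"),
    subject_id = c("nt1", "nt2", "nt3"),
    subject_label = c("Wolbachia_PPN", "Rickettsia", "Wolbachia_PPN"),
    bitscore = c(300, 500, 480), evalue = c(1e-50, 1e-80, 1e-70))
  cl <- classify_best_hit(s1, s2, target_labels = "Wolbachia_PPN")
  expect_equal(cl$status[cl$query_id == "q1"], "target")
  # q2's best step-2 hit (bitscore 500) is non-target
  expect_equal(cl$status[cl$query_id == "q2"], "nontarget")
  expect_equal(cl$label[cl$query_id == "q2"], "Rickettsia")
  # step-1 evidence alone keeps a query positive
  expect_equal(cl$status[cl$query_id == "q3"], "target")
  # a query absent from step 1 is not classified at all
  expect_false("q9" %in% cl$query_id)

  bad <- s1
  bad$bitscore[2] <- -5
  expect_error(classify_best_hit(bad, s2, "Wolbachia_PPN"), "row 2")
})

test_that("the enrichment stopping rule halts on plateaus and at the cap", {
  expect_true(should_continue_enrichment(100000))
  expect_true(should_continue_enrichment(c(100000, 150000)))
  expect_false(should_continue_enrichment(c(100000, 150000, 150000)))
  expect_false(should_continue_enrichment(c(100000, 150000, 140000)))
  expect_false(should_continue_enrichment(c(100000, 150000, 160000),
                                          max_iterations = 3))
  expect_error(should_continue_enrichment(c(10, -1)), "nonnegative")
})

test_that("triage partitions the input and is order-stable", {
  contigs <- simulate_contig_set(150, 150, seed = 9)
  cls <- data.frame(
    query_id = contigs$contig_id,
    label = ifelse(contigs$true_label == "target", "Wolbachia_PPN", "Other"),
    status = ifelse(contigs$true_label == "target", "target", "nontarget"))
  rep <- triage_contigs(contigs, classification = cls)
  expect_s3_class(rep, "triage_report")
  expect_setequal(c(rep$kept, names(rep$removed)), contigs$contig_id)
  expect_length(intersect(rep$kept, names(rep$removed)), 0)

  # kept set equals the contigs failing no individual rule, regardless of
  # the order the rules were applied in
  ref <- reference_coverage(contigs)
  fail_any <- unique(c(
    cls$query_id[cls$status == "nontarget"],
    filter_by_gc(contigs)$contig_id,
    filter_by_coverage(contigs, ref)$contig_id))
  expect_setequal(rep$kept, setdiff(contigs$contig_id, fail_any))
})

test_that("triage recovers well-separated synthetic mixtures", {
  contigs <- simulate_contig_set(200, 200, seed = 13)
  # hit tables: every contig hits the custom db; step-2 labels are the truth
  # with 2% label noise
  lab <- withr::with_seed(99, {
    truth <- ifelse(contigs$true_label == "target", "Wolbachia_PPN", "Other")
    flip <- runif(nrow(contigs)) < 0.02
    ifelse(flip, ifelse(truth == "Other", "Wolbachia_PPN", "Other"), truth)
  })
  s1 <- data.frame(query_id = contigs$contig_id, subject_id = "custom16S",
                   subject_label = "custom", bitscore = 100, evalue = 1e-30)
  s2 <- data.frame(query_id = contigs$contig_id, subject_id = "nt",
                   subject_label = lab, bitscore = 200, evalue = 1e-40)
  cls <- classify_best_hit(s1, s2, target_labels = "Wolbachia_PPN")
  rep <- triage_contigs(contigs, classification = cls)
  truth <- contigs$true_label[match(rep$kept, contigs$contig_id)]
  recall <- sum(truth == "target") / sum(contigs$true_label == "target")
  precision <- mean(truth == "target")
  expect_gt(recall, 0.9)
  expect_gt(precision, 0.9)
})
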