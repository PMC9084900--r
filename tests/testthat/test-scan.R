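test_that("window layout follows the 1200/600 overlap rule with a tail gate", {
  expect_equal(make_windows(1200), data.frame(start = 0L, end = 1200L))
  expect_equal(make_windows(3000),
               data.frame(start = c(0L, 600L, 1200L, 1800L),
                          end = c(1200L, 1800L, 2400L, 3000L)))
  # 900 bp tail >= 300 is kept
  expect_equal(make_windows(1500),
               data.frame(start = c(0L, 600L), end = c(1200L, 1500L)))
  # short tails below the gate are dropped
  w <- make_windows(1299, window = 1200, step = 1200)
  expect_equal(nrow(w), 1L)
  expect_warning(out <- make_windows(150), "min_tail")
  expect_equal(nrow(out), 0L)
  expect_error(make_windows(1000), "divisible by 3")
})

test_that("genes attach to windows by the 300 bp overlap rule", {
  wins <- data.frame(start = c(0L, 600L), end = c(1200L, 1800L))
  # overlaps 600 and 300 -> assigned to both windows
  a <- assign_genes_to_windows(wins, data.frame(gene_id = "g1", start = 300,
                                                end = 900))
  expect_setequal(a$start, c(0L, 600L))
  # overlap 600 with only the first window available
  a1 <- assign_genes_to_windows(wins[1, ], data.frame(gene_id = "g1",
                                                      start = 300, end = 900))
  expect_equal(a1$start, 0L)
  # overlap 299 -> not assigned
  b <- assign_genes_to_windows(wins[1, ], data.frame(gene_id = "g2",
                                                     start = 901, end = 1200))
  expect_equal(nrow(b), 0L)
  # straddling gene only reaches the window it overlaps by >= 300
  c3 <- assign_genes_to_windows(wins, data.frame(gene_id = "g3", start = 1100,
                                                 end = 1700))
  expect_equal(c3$start, 600L)
})

test_that("gene scores are means over surviving windows, with drop logging", {
  est <- data.frame(start = c(0L, 600L, 1200L), end = c(1200L, 1800L, 2400L),
                    ka = 0.1, ks = c(0.5, 0.5, 3), ratio = c(0.1, 0.3, 0.9),
                    sd = 1, nd = 1, s_sites = 300, n_sites = 900,
                    pass = c(TRUE, TRUE, FALSE))
  asg <- data.frame(gene_id = c("gA", "gA", "gB", "gC"),
                    start = c(0L, 600L, 600L, 1200L),
                    end = c(1200L, 1800L, 1800L, 2400L))
  expect_message(sc <- gene_level_dnds(asg, est), "dropped")
  expect_equal(sc$dnds[sc$gene_id == "gA"], 0.2)
  expect_equal(sc$dnds[sc$gene_id == "gB"], 0.3)
  expect_false("gC" %in% sc$gene_id)
  expect_equal(attr(sc, "dropped"), "gC")
})

test_that("quantile partitions use ceiling sizes and gene-id tie-breaks", {
  scores <- data.frame(gene_id = sprintf("g%02d", 1:10),
                       dnds = seq(0.01, 0.10, by = 0.01), n_windows = 1L)
  p <- partition_quantiles(scores)
  expect_equal(p$top10, "g10")
  expect_equal(sort(p$bottom25), c("g01", "g02", "g03"))
  expect_true(all(p$top10 %in% p$top25))
  expect_true(all(p$bottom10 %in% p$bottom25))

  ties <- data.frame(gene_id = c("b", "a", "d", "c"), dnds = 0.2,
                     n_windows = 1L)
  pt <- partition_quantiles(ties)
  expect_equal(pt$top10, "a")    # ceiling(0.4) = 1, id tie-break
  expect_equal(pt$bottom10, "d")
  expect_error(partition_quantiles(scores[1:3, ]), "at least 4")
})

test_that("raising one gene's score never demotes it to a bottom set", {
  withr::with_seed(7, {
    for (rep in 1:10) {
      n <- sample(6:20, 1)
      scores <- data.frame(gene_id = sprintf("g%02d", 1:n),
                           dnds = runif(n, 0, 0.5), n_windows = 1L)
      p0 <- partition_quantiles(scores)
      g <- sample(scores$gene_id, 1)
      scores$dnds[scores$gene_id == g] <-
        max(scores$dnds) + runif(1, 0.01, 1)
      p1 <- partition_quantiles(scores)
      expect_true(g %in% p1$top10)
      expect_false(g %in% p1$bottom25)
      expect_equal(lengths(p0), lengths(p1))
    }
  })
})

test_that("Ks-saturated windows are flagged but retained in the raw report", {
  aln <- simulate_codon_pair(1000, target_dnds = 0.2, target_ks = 5, seed = 2)
  est <- scan_alignment(aln, partition_spec(ks_cutoff = 2.0))
  expect_true(nrow(est) >= 1)
  expect_true(all(!est$pass))

  ok <- simulate_codon_pair(1000, target_dnds = 0.1, target_ks = 0.4, seed = 2)
  est2 <- scan_alignment(ok, partition_spec(ks_cutoff = 2.0))
  expect_equal(nrow(est2), 4L)   # 3000 bp -> 4 windows
  expect_true(all(est2$pass))

  one <- simulate_codon_pair(400, target_dnds = 0.1, target_ks = 0.4, seed = 3)
  expect_equal(nrow(scan_alignment(one)), 1L)
})

test_that("the linear clock calibration reproduces the published anchors", {
  expect_equal(calibrate_divergence_time(2.8), 216)
  expect_equal(round(calibrate_divergence_time(3.934)), 303)
  expect_equal(calibrate_divergence_time(4.211), 4.211 * 216 / 2.8)
  expect_error(calibrate_divergence_time(-1), "nonnegative")
})
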