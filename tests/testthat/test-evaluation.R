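test_that("keyword scan matches with phage > mobility > tRNA > unknown precedence", {
  v <- keyword_vocabulary()
  expect_equal(scan_gi_feature("phage major capsid protein", v), "phage")
  expect_equal(scan_gi_feature("Prophage integrase", v), "phage")
  expect_equal(scan_gi_feature("site-specific integrase", v), "mobility")
  expect_equal(scan_gi_feature("tRNA-Leu", v), "tRNA")
  expect_equal(scan_gi_feature("hypothetical protein", v), "unknown")
  expect_equal(scan_gi_feature("DNA polymerase III", v), "none")
  # vectorized
  expect_equal(scan_gi_feature(c("phage holin", "unknown function"), v),
               c("phage", "unknown"))
})

test_that("shipped YAML vocabulary equals the built-in defaults", {
  expect_equal(read_keyword_vocabulary(), keyword_vocabulary())
})

test_that("region class clause boundaries: 6 vs 5 phage genes, 50% vs 49% unknown", {
  v <- keyword_vocabulary()
  expect_equal(phispy_region_class(region_fixture(12, 6, 0), v), "PTP")
  expect_equal(phispy_region_class(region_fixture(12, 5, 0), v), "PFP")
  expect_equal(phispy_region_class(region_fixture(10, 0, 5), v), "PTP")
  expect_equal(phispy_region_class(region_fixture(100, 0, 49), v), "PFP")
  expect_equal(phispy_region_class(region_fixture(10, 5, 3), v), "PFP")
  expect_warning(cls <- phispy_region_class(region_fixture(0, 0, 0), v),
                 "empty")
  expect_equal(cls, "PFP")
})

test_that("false negatives are unpredicted runs of >= 6 consecutive phage genes", {
  v <- keyword_vocabulary()
  g6 <- phage_run_genome(6L)
  none <- prediction_set("t", "g", island_table())
  expect_equal(phispy_false_negatives(g6, none, v), 1L)

  # any bp overlap of the run cancels the FN
  run_genes <- g6$genes[10:15, ]
  hit <- prediction_set("t", "g",
                        island_table("c1", run_genes$start[[1]],
                                     run_genes$start[[1]] + 100L))
  expect_equal(phispy_false_negatives(g6, hit, v), 0L)

  expect_equal(phispy_false_negatives(phage_run_genome(5L), none, v), 0L)

  # interleaved non-phage gene breaks the run (strictly consecutive)
  g <- phage_run_genome(7L)
  g$genes$annotation[13] <- "DNA polymerase III"
  g <- genome_annotation("g", g$contigs, g$genes)
  expect_equal(phispy_false_negatives(g, none, v), 0L)
})

test_that("phispy sensitivity is 1 when every phage run is covered by PTP islands", {
  v <- keyword_vocabulary()
  g <- phage_run_genome(6L)
  run <- g$genes[10:15, ]
  preds <- prediction_set("t", "g",
                          island_table("c1", run$start[[1]],
                                       run$end[[nrow(run)]]))
  m <- phispy_metrics(g, preds, v)
  expect_equal(m$PTP, 1L)
  expect_equal(m$PFP, 0L)
  expect_equal(m$PFN, 0L)
  expect_equal(m$sensitivity, 1)
  expect_equal(m$false_positive_pct, 0)
})

test_that("base-pair coverage and any-overlap match hand values and handle NA", {
  t1 <- prediction_set("t", "g", island_table("c1", 0L, 1000L))
  p1 <- prediction_set("p", "g", island_table("c1", 500L, 1500L))
  expect_equal(base_pair_coverage(t1, p1), 50)
  expect_equal(base_pair_coverage(t1, t1), 100)
  disjoint <- prediction_set("p", "g", island_table("c1", 5000L, 6000L))
  expect_equal(base_pair_coverage(t1, disjoint), 0)
  empty <- prediction_set("p", "g", island_table())
  expect_true(is.na(base_pair_coverage(empty, p1)))
  expect_equal(island_any_overlap(t1, p1), 100)
  expect_equal(island_any_overlap(t1, empty), 0)
  t4 <- prediction_set("t", "g",
                       island_table("c1", c(0L, 2000L, 4000L, 6000L),
                                    c(1000L, 3000L, 5000L, 7000L)))
  p2 <- prediction_set("p", "g", island_table("c1", c(900L, 2500L),
                                              c(1100L, 2600L)))
  expect_equal(island_any_overlap(t4, p2), 50)
  expect_error(base_pair_coverage(t1, prediction_set("p", "other",
                                                     island_table())),
               "different genomes")
})

test_that("coverage is invariant to splitting predictor islands into pieces", {
  withr::local_seed(13)
  for (rep in 1:20) {
    target <- random_prediction_set("t", 80000L, sample(1:10, 1))
    pred <- random_prediction_set("p", 80000L, sample(1:10, 1))
    split_isl <- do.call(rbind, lapply(seq_len(nrow(pred$islands)), function(i) {
      s <- pred$islands$start[[i]]; e <- pred$islands$end[[i]]
      if (e - s < 4L) return(data.frame(contig_id = "c1", start = s, end = e))
      m <- s + sample.int(e - s - 1L, 1)
      data.frame(contig_id = "c1", start = c(s, m), end = c(m, e))
    }))
    pred_split <- prediction_set("p", "g1",
                                 island_table(split_isl$contig_id,
                                              split_isl$start, split_isl$end))
    expect_equal(base_pair_coverage(target, pred_split),
                 base_pair_coverage(target, pred))
  }
})

test_that("unique predictions keep only islands untouched by every other tool", {
  tool <- prediction_set("t", "g",
                         island_table("c1", c(0L, 5000L, 20000L),
                                      c(2000L, 9000L, 26000L)))
  otherA <- prediction_set("a", "g", island_table("c1", 1900L, 2500L))
  otherB <- prediction_set("b", "g", island_table("c1", 8999L, 12000L))
  g <- make_tiled_genome("g", n = 30L, len = 800L, gap = 200L,
                         annotations = c(rep("DNA polymerase III", 20),
                                         rep("phage holin", 10)))
  u <- unique_predictions(tool, list(otherA, otherB), g)
  expect_equal(u$islands$start, 20000L)
  # the surviving island covers phage-feature genes
  expect_equal(u$gi_feature_pct, 100)

  # no other tools: everything unique
  u2 <- unique_predictions(tool, list(), g)
  expect_equal(nrow(u2$islands), 3L)
})

test_that("unique predictions match the per-base bitmap oracle on random fixtures", {
  withr::local_seed(31)
  g <- make_tiled_genome("g1", n = 10L)
  for (rep in 1:20) {
    tool <- random_prediction_set("t", 60000L, sample(0:12, 1))
    others <- lapply(1:3, function(i)
      random_prediction_set(paste0("o", i), 60000L, sample(0:8, 1)))
    got <- unique_predictions(tool, others, g)$islands
    want <- oracle_unique(tool, others, 60000L)
    expect_equal(got$start, want$start)
    expect_equal(got$end, want$end)
  }
})

test_that("gene outcomes follow the flank-window definitions at every clause", {
  g <- outcome_genome()
  # called GI with a phage gene 2 positions away -> TP
  out <- gene_outcomes(pred_for(g, 10L, "GI"), g, flank_k = 4L)
  expect_equal(out$outcome, "TP")
  # flank_k = 1 excludes the phage gene -> FP
  out <- gene_outcomes(pred_for(g, 10L, "GI"), g, flank_k = 1L)
  expect_equal(out$outcome, "FP")
  # called GI, clean window, but overlapping another tool's island -> TP
  tool <- prediction_set("t", "g",
                         island_table("c1", g$genes$start[[2]],
                                      g$genes$end[[2]]))
  out <- gene_outcomes(pred_for(g, 2L, "GI"), g, list(tool))
  expect_equal(out$outcome, "TP")
  # called GI, clean window, no overlap -> FP
  out <- gene_outcomes(pred_for(g, 2L, "GI"), g)
  expect_equal(out$outcome, "FP")
  # not called, clean window -> TN ; not called, phage in window -> FN
  out <- gene_outcomes(pred_for(g, c(2L, 10L), "not-GI"), g)
  expect_equal(out$outcome, c("TN", "FN"))
  # window truncates at contig ends without error
  out <- gene_outcomes(pred_for(g, 1L, "not-GI"), g)
  expect_equal(out$outcome, "TN")
})

test_that("ROC is 1 for separating probabilities, symmetric under p -> 1-p", {
  g <- outcome_genome()
  idx <- seq_len(20L)
  phage_window <- abs(idx - 12L) <= 4L
  preds <- pred_for(g, idx, ifelse(phage_window, "GI", "not-GI"))
  preds$probability <- ifelse(phage_window, 0.9, 0.1)
  roc <- roc_curve(preds, g)
  expect_equal(roc$auc, 1)
  expect_equal(roc$points$TPR[roc$points$FPR == 0][1], 0)

  flipped <- preds
  flipped$probability <- 1 - preds$probability
  expect_equal(roc_curve(flipped, g)$auc, 1 - roc$auc)

  # TPR/FPR monotone in threshold
  pts <- roc$points[order(-roc$points$threshold), ]
  expect_true(all(diff(pts$TPR) >= 0))
  expect_true(all(diff(pts$FPR) >= 0))
})

test_that("random probabilities give chance-level AUC; one-class outcomes give NA", {
  withr::local_seed(17)
  n <- 400L
  ann <- sample(c("phage holin", "DNA polymerase III"), n, TRUE)
  g <- make_tiled_genome("g", n = n, len = 800L, gap = 200L,
                         annotations = ann)
  preds <- pred_for(g, seq_len(n), "not-GI")
  aucs <- replicate(10, {
    preds$probability <- runif(n)
    roc_curve(preds, g, flank_k = 0L)$auc
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.05)

  g_all <- make_tiled_genome("g", n = 30L, len = 800L, gap = 200L,
                             annotations = rep("phage holin", 30))
  p <- pred_for(g_all, 1:30, "GI")
  expect_true(is.na(roc_curve(p, g_all)$auc))
})

test_that("base-pair F1 combines the two coverage directions", {
  a <- prediction_set("a", "g", island_table("c1", 0L, 1000L))
  b <- prediction_set("b", "g", island_table("c1", 500L, 1500L))
  f <- bp_f1(a, b)
  expect_equal(f$precision, 0.5)
  expect_equal(f$recall, 0.5)
  expect_equal(f$f1, 0.5)
  expect_equal(bp_f1(a, a)$f1, 1)
})
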