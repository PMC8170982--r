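test_that("simulation honors island counts and span bounds", {
  cfg <- sim_config(n_reference_genomes = 3L, backbone_genes = 60L,
                    island_count = 0L, seed = 5L)
  sim0 <- simulate_genome_set(cfg)
  expect_equal(nrow(sim0$truth$islands), 0L)
  expect_true(all(sim0$truth$gene_labels$label == "not-GI"))

  cfg3 <- sim_config(n_reference_genomes = 3L, backbone_genes = 60L,
                     island_count = 3L, seed = 5L)
  sim3 <- simulate_genome_set(cfg3)
  expect_equal(nrow(sim3$truth$islands), 3L)
  spans <- sim3$truth$islands$end - sim3$truth$islands$start
  expect_true(all(spans >= cfg3$island_span[[1]] &
                    spans <= cfg3$island_span[[2]]))
  # truth islands hold their genes
  for (i in 1:3) {
    ids <- sim3$truth$islands$gene_ids[[i]]
    gg <- sim3$query$genes[match(ids, sim3$query$genes$gene_id), ]
    expect_true(all(gg$start >= sim3$truth$islands$start[[i]] &
                      gg$end <= sim3$truth$islands$end[[i]]))
  }
  expect_error(sim_config(island_span = c(500, 900)), "island_span")
})

test_that("simulation is deterministic and backbone families are conserved 1:1", {
  cfg <- sim_config(n_reference_genomes = 4L, backbone_genes = 50L, seed = 9L)
  s1 <- simulate_genome_set(cfg)
  s2 <- simulate_genome_set(cfg)
  expect_identical(s1$query$genes, s2$query$genes)
  expect_identical(s1$truth, s2$truth)
  dists <- vapply(s1$references, `[[`, numeric(1), "distance")
  expect_true(all(diff(dists) >= 0))

  bb_fams <- grep("^bbfam", unique(s1$query$genes$family_id), value = TRUE)
  expect_length(bb_fams, 50L)
  for (r in s1$references) {
    counts <- table(r$genome$genes$family_id[
      grepl("^bbfam", r$genome$genes$family_id)])
    expect_true(all(counts == 1L))
    expect_setequal(names(counts), bb_fams)
  }
  # islands absent from references at presence_prob 0
  expect_false(any(grepl("^islfam",
                         unlist(lapply(s1$references, function(r)
                           r$genome$genes$family_id)))))
})

test_that("island genes are shorter than backbone genes on average", {
  # pool across seeds for a >1000-gene sample
  lens <- list(island = numeric(), backbone = numeric())
  for (seed in 1:4) {
    sim <- simulate_genome_set(sim_config(n_reference_genomes = 0L,
                                          backbone_genes = 300L, seed = seed))
    g <- sim$query$genes
    gi <- g$gene_id %in% unlist(sim$truth$islands$gene_ids)
    lens$island <- c(lens$island, g$end[gi] - g$start[gi])
    lens$backbone <- c(lens$backbone, g$end[!gi] - g$start[!gi])
  }
  expect_gt(length(lens$island) + length(lens$backbone), 1000L)
  expect_lt(mean(lens$island), mean(lens$backbone))
})

test_that("sporadic islands appear in references at the configured rate", {
  cfg <- sim_config(n_reference_genomes = 12L, backbone_genes = 40L,
                    island_presence_prob = 0.5, seed = 3L)
  sim <- simulate_genome_set(cfg)
  carriers <- vapply(sim$references, function(r)
    any(grepl("^islfam", r$genome$genes$family_id)), logical(1))
  expect_gt(sum(carriers), 0L)
  expect_lt(sum(carriers), length(carriers))
})

test_that("training corpus is balanced, deterministic, and separable by pixel count", {
  cfg <- sim_config(n_reference_genomes = 5L, backbone_genes = 80L, seed = 2L)
  sim <- simulate_genome_set(cfg)
  rcfg <- small_render_config()
  ncfg <- small_neighborhood_config()
  corpus <- generate_training_corpus(sim, ncfg, rcfg, n_per_class = 12L,
                                     seed = 4L)
  labels <- vapply(corpus, `[[`, character(1), "label")
  expect_length(corpus, 24L)
  expect_equal(sum(labels == "GI"), 12L)

  corpus2 <- generate_training_corpus(sim, ncfg, rcfg, n_per_class = 12L,
                                      seed = 4L)
  expect_identical(lapply(corpus2, `[[`, "source_id"),
                   lapply(corpus, `[[`, "source_id"))
  expect_identical(corpus2[[1]]$image$pixels, corpus[[1]]$image$pixels)

  # island images carry far less ink outside the query band
  ink_out <- vapply(corpus, function(ex)
    sum(ink_by_band(ex$image, rcfg)[-1]), numeric(1))
  expect_lt(mean(ink_out[labels == "GI"]),
            0.5 * mean(ink_out[labels == "not-GI"]))

  # shortfall is a named validation error
  expect_error(generate_training_corpus(sim, ncfg, rcfg,
                                        n_per_class = 10000L, seed = 1L),
               "available")
})

test_that("the separability oracle scores the held-out split it is given", {
  cfg <- sim_config(n_reference_genomes = 4L, backbone_genes = 60L, seed = 8L)
  sim <- simulate_genome_set(cfg)
  corpus <- generate_training_corpus(sim, small_neighborhood_config(),
                                     small_render_config(),
                                     n_per_class = 10L, seed = 8L)
  split <- train_val_split(length(corpus), 0.2, seed = 8L)
  orc <- separability_oracle(corpus, split$train, split$val,
                             small_render_config())
  expect_gte(orc$accuracy, 0.95)
})

test_that("simulation files round-trip through standard formats", {
  cfg <- sim_config(n_reference_genomes = 2L, backbone_genes = 30L, seed = 6L)
  sim <- simulate_genome_set(cfg)
  dir <- withr::local_tempdir()
  write_simulation(sim, dir)
  expect_true(file.exists(file.path(dir, "query.gff3")))
  back <- read_simulation(dir)
  expect_equal(back$query$genes$gene_id, sim$query$genes$gene_id)
  expect_equal(back$query$genes$start, sim$query$genes$start)
  expect_equal(back$query$genes$family_id, sim$query$genes$family_id)
  expect_equal(vapply(back$references, `[[`, numeric(1), "distance"),
               vapply(sim$references, `[[`, numeric(1), "distance"))
  truth <- read_prediction_set(file.path(dir, "truth.bed"), "truth", "query")
  expect_equal(truth$islands$start, sim$truth$islands$start)
  expect_equal(truth$islands$end, sim$truth$islands$end)
})
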