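# small canvases keep these unit tests fast; the full-size training study
# lives in the acceptance suite

small_tcfg <- function(...) {
  train_config(backbone = "tiny_cnn", input_shape = c(96L, 96L), seed = 11L,
               ...)
}

render_small <- function(genome, gene_id, refs = list()) {
  render(build_neighborhood(gene_id, genome, refs,
                            small_neighborhood_config()),
         small_render_config())
}

# tiny separable corpus: sporadic genes (no reference rows) vs conserved
small_corpus <- function(n_per_class = 6L) {
  set <- make_comparative_set(nref = 4L)
  conserved <- lapply(seq_len(n_per_class), function(i)
    labeled_example(render_small(set$query, sprintf("query_g%03d", i + 4L),
                                 set$references),
                    "not-GI", sprintf("c%d", i)))
  qs <- make_genome("sporadic", 30000L,
                    seq(2000L, by = 1500L, length.out = n_per_class + 4L),
                    rep(600L, n_per_class + 4L),
                    families = sprintf("isl%03d", seq_len(n_per_class + 4L)))
  sporadic <- lapply(seq_len(n_per_class), function(i)
    labeled_example(render_small(qs, sprintf("sporadic_g%03d", i + 2L),
                                 set$references),
                    "GI", sprintf("s%d", i)))
  c(conserved, sporadic)
}

test_that("model construction honors shape and parameter contracts", {
  m <- build_model(small_tcfg())
  expect_equal(m$input_shape, c(96L, 96L))
  expect_equal(m$n_trainable, length(m$head$w) + 1L)
  expect_equal(m$n_trainable, 33L)
  expect_false(m$trained)
  expect_error(train_config(epochs = 0L), "epochs")
  expect_error(train_config(validation_fraction = 1), "validation_fraction")
})

test_that("pretrained backbone requires a weights file and loads one when given", {
  expect_error(build_model(train_config(backbone = "inception_v3_pretrained")),
               "configuration error")
  # a backbone checkpoint round-trips through the pluggable-weights path
  donor <- build_model(small_tcfg())
  f <- withr::local_tempfile(fileext = ".json")
  save_backbone(donor, f)
  m <- build_model(train_config(backbone = "inception_v3_pretrained",
                                input_shape = c(96L, 96L),
                                weights_path = f))
  expect_equal(m$backbone, "inception_v3_pretrained")
  img <- small_corpus(2L)[[1]]$image
  expect_equal(islandscope:::extract_features(m, list(img)),
               islandscope:::extract_features(donor, list(img)))
})

test_that("training validates its inputs", {
  m <- build_model(small_tcfg())
  ex <- small_corpus(3L)
  single <- ex[vapply(ex, `[[`, character(1), "label") == "GI"]
  expect_error(train(m, single, small_tcfg()), "single class")
  expect_error(train(m, ex, small_tcfg(freeze_backbone = FALSE)),
               "not supported")
})

test_that("loss decreases when fitting duplicated single images", {
  ex <- small_corpus(1L)
  data <- c(rep(ex[1], 5L), rep(ex[2], 5L))
  cfg <- small_tcfg(epochs = 8L, learning_rate = 1e-2)
  fit <- train(build_model(cfg), data, cfg)
  expect_lt(fit$report$train_loss[[nrow(fit$report)]],
            fit$report$train_loss[[1]])
})

test_that("training is reproducible under a fixed seed and learns the corpus", {
  data <- small_corpus(8L)
  cfg <- small_tcfg(epochs = 10L, learning_rate = 1e-2, batch_size = 8L)
  fit1 <- train(build_model(cfg), data, cfg)
  fit2 <- train(build_model(cfg), data, cfg)
  expect_identical(fit1$report, fit2$report)
  expect_identical(fit1$model$head, fit2$model$head)
  expect_gt(fit1$model$metadata$final_val_accuracy, 0.5)
})

test_that("predictions are probabilities, pure, and shape-checked", {
  data <- small_corpus(4L)
  cfg <- small_tcfg(epochs = 5L, learning_rate = 1e-2)
  fit <- train(build_model(cfg), data, cfg)
  imgs <- lapply(data, `[[`, "image")
  p <- predict(fit$model, imgs)
  expect_length(p, length(imgs))
  expect_true(all(p >= 0 & p <= 1))
  expect_equal(predict(fit$model, imgs[c(1, 1)])[1],
               predict(fit$model, imgs[c(1, 1)])[2])
  expect_error(predict(build_model(cfg), imgs), "not been trained")
  big <- structure(list(pixels = array(255L, c(128L, 128L, 3L)),
                        neighborhood_id = "x"), class = "rendered_image")
  expect_error(predict(fit$model, list(big)), "shape")
})

test_that("classify_genes yields one prediction per gene with threshold extremes", {
  set <- make_comparative_set(nref = 3L, n = 50L)
  data <- small_corpus(4L)
  cfg <- small_tcfg(epochs = 3L)
  fit <- train(build_model(cfg), data, cfg)
  preds <- classify_genes(fit$model, set$query, set$references,
                          small_neighborhood_config(),
                          small_render_config(), threshold = 0.5)
  expect_equal(nrow(preds), 50L)
  expect_equal(preds$gene_id, set$query$genes$gene_id)

  hi <- classify_genes(fit$model, set$query, set$references,
                       small_neighborhood_config(), small_render_config(),
                       threshold = 1.1)
  expect_true(all(hi$call == "not-GI"))
  lo <- classify_genes(fit$model, set$query, set$references,
                       small_neighborhood_config(), small_render_config(),
                       threshold = 0)
  expect_true(all(lo$call == "GI"))

  # monotone: raising the threshold never increases GI calls
  n_calls <- vapply(c(0, 0.25, 0.5, 0.75, 1.1), function(th)
    sum(preds$probability >= th), numeric(1))
  expect_true(all(diff(n_calls) <= 0))
})

test_that("checkpoints restore a model that predicts identically", {
  data <- small_corpus(4L)
  cfg <- small_tcfg(epochs = 3L)
  fit <- train(build_model(cfg), data, cfg)
  f <- withr::local_tempfile(fileext = ".json")
  save_model(fit$model, f)
  back <- load_model(f)
  imgs <- lapply(data[1:4], `[[`, "image")
  expect_equal(predict(back, imgs), predict(fit$model, imgs))
  expect_equal(back$metadata$final_val_accuracy,
               fit$model$metadata$final_val_accuracy)
})
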