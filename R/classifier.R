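#' Training configuration for the image classifier
#'
#' Transfer-learning setup: a convolutional backbone turns each rendered
#' neighborhood into a feature vector, and a freshly initialized binary head
#' (global average pooling -> dense sigmoid unit) is trained on those
#' features with minibatch Adam on binary cross-entropy. The `tiny_cnn`
#' backbone (three 3x3 conv blocks with ReLU and 4x average pooling,
#' seeded random weights) ships with the package so no weights download is
#' ever needed; `inception_v3_pretrained` expects an externally supplied
#' backbone checkpoint via `weights_path`.
#'
#' @param backbone "tiny_cnn" or "inception_v3_pretrained".
#' @param freeze_backbone keep backbone weights fixed (default TRUE; only
#'   the head is ever trained — fine-tuning the backbone is unsupported).
#' @param epochs number of passes over the training split (>= 1).
#' @param batch_size minibatch size.
#' @param learning_rate Adam step size.
#' @param validation_fraction held-out fraction in (0, 1).
#' @param seed integer governing the split, shuffles, and backbone init.
#' @param input_shape c(height, width) in pixels of the rendered images.
#' @param weights_path backbone checkpoint JSON (pretrained backbone only).
#' @return list of class `train_config`.
#' @export
train_config <- function(backbone = c("tiny_cnn", "inception_v3_pretrained"),
                         freeze_backbone = TRUE, epochs = 10L,
                         batch_size = 32L, learning_rate = 1e-3,
                         validation_fraction = 0.2, seed = 1L,
                         input_shape = c(299L, 299L), weights_path = NULL) {
  backbone <- match.arg(backbone)
  epochs <- as.integer(epochs)
  if (is.na(epochs) || epochs < 1L)
    stop("validation error: epochs must be >= 1")
  if (!(validation_fraction > 0 && validation_fraction < 1))
    stop("validation error: validation_fraction must be in (0, 1)")
  if (batch_size < 1L) stop("validation error: batch_size must be >= 1")
  structure(list(backbone = backbone, freeze_backbone = isTRUE(freeze_backbone),
                 epochs = epochs, batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 validation_fraction = validation_fraction,
                 seed = as.integer(seed),
                 input_shape = as.integer(input_shape[1:2]),
                 weights_path = weights_path),
            class = "train_config")
}

#' A labeled training example
#'
#' @param image a `rendered_image`.
#' @param label "GI" or "not-GI".
#' @param source_id window or gene id the image came from.
#' @return list of class `labeled_example`.
#' @export
labeled_example <- function(image, label, source_id) {
  if (!label %in% c("GI", "not-GI"))
    stop("validation error: label must be 'GI' or 'not-GI'")
  structure(list(image = image, label = label, source_id = source_id),
            class = "labeled_example")
}

# ---- backbone ---------------------------------------------------------------

#' Build a classifier model
#'
#' Instantiates the backbone and a new, untrained binary classification
#' head. With `freeze_backbone = TRUE` (the default and only supported
#' mode) the trainable parameter count equals the head's parameter count:
#' one weight per backbone feature plus a bias.
#'
#' @param config a [train_config()].
#' @return object of class `model_handle`.
#' @export
build_model <- function(config = train_config()) {
  layers <- switch(config$backbone,
    tiny_cnn = tiny_cnn_layers(config$seed),
    inception_v3_pretrained = {
      wp <- config$weights_path
      if (is.null(wp) || !file.exists(wp))
        stop("configuration error: backbone 'inception_v3_pretrained' needs ",
             "pretrained weights; set `weights_path` in train_config() to a ",
             "backbone checkpoint JSON (a file written by save_backbone(), ",
             "converted from externally trained weights)")
      load_backbone(wp)$layers
    })
  nfeat <- ncol(layers[[length(layers)]]$W)
  structure(list(
    backbone = config$backbone,
    input_shape = config$input_shape,
    layers = layers,
    head = list(w = numeric(nfeat), b = 0),
    feat_mu = numeric(nfeat), feat_sd = rep(1, nfeat),
    n_trainable = nfeat + 1L,
    n_backbone = sum(vapply(layers, function(l) length(l$W) + length(l$b),
                            numeric(1))),
    trained = FALSE,
    metadata = list(seed = config$seed)
  ), class = "model_handle")
}

# three conv blocks: 3->8->16->32 filters, He-initialized from `seed`
tiny_cnn_layers <- function(seed) {
  withr::with_seed(seed, {
    mk <- function(cin, cout) {
      fan <- 9L * cin
      list(W = matrix(stats::rnorm(fan * cout, sd = sqrt(2 / fan)),
                      nrow = fan, ncol = cout),
           b = numeric(cout), pool = 4L)
    }
    list(mk(3L, 8L), mk(8L, 16L), mk(16L, 32L))
  })
}

#' @export
print.model_handle <- function(x, ...) {
  cat(sprintf("<model_handle> backbone %s (%d frozen params), head %d trainable, %s\n",
              x$backbone, x$n_backbone, x$n_trainable,
              if (x$trained) "trained" else "untrained"))
  invisible(x)
}

# im2col gather indices, cached per input geometry
.conv_cache <- new.env(parent = emptyenv())

im2col_idx <- function(h, w, c) {
  key <- paste(h, w, c, sep = "_")
  if (!is.null(.conv_cache[[key]])) return(.conv_cache[[key]])
  oh <- h - 2L; ow <- w - 2L
  base <- as.vector(outer(seq_len(oh), (seq_len(ow) - 1L) * h, `+`))
  off <- as.vector(outer(0:2, as.vector(outer((0:2) * h,
                                              (seq_len(c) - 1L) * h * w,
                                              `+`)), `+`))
  idx <- outer(base, off, `+`)
  .conv_cache[[key]] <- idx
  idx
}

conv_relu <- function(x, W, b) {
  d <- dim(x)
  idx <- im2col_idx(d[[1]], d[[2]], d[[3]])
  out <- matrix(x[idx], nrow = nrow(idx)) %*% W
  out <- pmax(sweep(out, 2, b, `+`), 0)
  array(out, c(d[[1]] - 2L, d[[2]] - 2L, ncol(W)))
}

avgpool <- function(x, p) {
  d <- dim(x)
  th <- d[[1]] %/% p * p; tw <- d[[2]] %/% p * p
  if (p <= 1L || th < p || tw < p) return(x)
  x <- x[seq_len(th), seq_len(tw), , drop = FALSE]
  dim(x) <- c(p, th %/% p, tw, d[[3]])
  x <- colMeans(x)                      # (th/p, tw, f)
  dim(x) <- c(th %/% p, p, tw %/% p, d[[3]])
  x <- aperm(x, c(2, 1, 3, 4))
  colMeans(x)                           # (th/p, tw/p, f)
}

# image -> backbone feature vector (global average pooling at the end)
extract_features <- function(model, images) {
  feats <- vapply(images, function(im) {
    px <- if (inherits(im, "rendered_image")) im$pixels else im
    d <- dim(px)
    if (d[[1]] != model$input_shape[[1]] || d[[2]] != model$input_shape[[2]])
      stop("validation error: image shape ", d[[1]], "x", d[[2]],
           " does not match model input ", model$input_shape[[1]], "x",
           model$input_shape[[2]])
    x <- px / 255
    for (l in model$layers) x <- avgpool(conv_relu(x, l$W, l$b), l$pool)
    colMeans(matrix(x, ncol = dim(x)[[3]]))
  }, numeric(ncol(model$layers[[length(model$layers)]]$W)))
  t(feats)
}

# ---- training ---------------------------------------------------------------

#' Seeded train/validation split
#'
#' The split used by [train()]: a seeded shuffle of `1:n` whose first
#' `max(1, floor(validation_fraction * n))` indices form the validation
#' set. Exposed so that external baselines (e.g. the pixel-count
#' separability oracle) can be evaluated on exactly the same held-out
#' examples as the classifier.
#'
#' @param n number of examples.
#' @param validation_fraction fraction in (0, 1).
#' @param seed the training seed.
#' @return list with integer vectors `train` and `val`.
#' @export
train_val_split <- function(n, validation_fraction, seed) {
  withr::with_seed(derive_seeds(seed, 2L)[[1]], {
    ord <- sample.int(n)
    n_val <- max(1L, floor(validation_fraction * n))
    list(train = ord[-seq_len(n_val)], val = ord[seq_len(n_val)])
  })
}

#' Train the classification head
#'
#' Splits the examples into train/validation by a seeded shuffle, extracts
#' backbone features once (the backbone is frozen), standardizes them on the
#' training split, and fits the dense sigmoid head with minibatch Adam on
#' binary cross-entropy. Fully deterministic for a given seed.
#'
#' @param model a [build_model()] result.
#' @param data list of [labeled_example()]s; at least 2 per class.
#' @param config the [train_config()].
#' @return list with `model` (trained) and `report` (data.frame with one row
#'   per epoch: `epoch`, `train_loss`, `val_accuracy`).
#' @export
train <- function(model, data, config = train_config()) {
  stopifnot(inherits(model, "model_handle"))
  if (!config$freeze_backbone)
    stop("validation error: freeze_backbone = FALSE (backbone fine-tuning) ",
         "is not supported; only the classification head is trainable")
  y <- as.numeric(vapply(data, `[[`, character(1), "label") == "GI")
  if (length(unique(y)) < 2L)
    stop("validation error: training data contains a single class")
  if (min(table(y)) < 2L)
    stop("validation error: need at least 2 examples per class")
  feats <- extract_features(model, lapply(data, `[[`, "image"))
  n <- nrow(feats)
  split <- train_val_split(n, config$validation_fraction, config$seed)
  val_idx <- split$val
  tr_idx <- split$train
  withr::with_seed(derive_seeds(config$seed, 2L)[[2]], {
    mu <- colMeans(feats[tr_idx, , drop = FALSE])
    sd_ <- apply(feats[tr_idx, , drop = FALSE], 2, stats::sd)
    sd_[!is.finite(sd_) | sd_ == 0] <- 1
    Z <- sweep(sweep(feats, 2, mu), 2, sd_, `/`)
    Ztr <- Z[tr_idx, , drop = FALSE]; ytr <- y[tr_idx]
    Zva <- Z[val_idx, , drop = FALSE]; yva <- y[val_idx]
    w <- model$head$w; b <- model$head$b
    mw <- vw <- numeric(length(w)); mb <- vb <- 0
    beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8; t_ <- 0L
    lr <- config$learning_rate
    report <- data.frame(epoch = integer(), train_loss = numeric(),
                         val_accuracy = numeric())
    bce <- function(p, y) -mean(y * log(pmax(p, 1e-12)) +
                                  (1 - y) * log(pmax(1 - p, 1e-12)))
    for (ep in seq_len(config$epochs)) {
      perm <- sample.int(length(ytr))
      for (batch in split(perm, ceiling(seq_along(perm) / config$batch_size))) {
        Zb <- Ztr[batch, , drop = FALSE]; yb <- ytr[batch]
        p <- sigmoid(drop(Zb %*% w) + b)
        gw <- drop(crossprod(Zb, p - yb)) / length(yb)
        gb <- mean(p - yb)
        t_ <- t_ + 1L
        mw <- beta1 * mw + (1 - beta1) * gw; vw <- beta2 * vw + (1 - beta2) * gw^2
        mb <- beta1 * mb + (1 - beta1) * gb; vb <- beta2 * vb + (1 - beta2) * gb^2
        w <- w - lr * (mw / (1 - beta1^t_)) / (sqrt(vw / (1 - beta2^t_)) + eps)
        b <- b - lr * (mb / (1 - beta1^t_)) / (sqrt(vb / (1 - beta2^t_)) + eps)
      }
      ptr <- sigmoid(drop(Ztr %*% w) + b)
      pva <- sigmoid(drop(Zva %*% w) + b)
      report <- rbind(report, data.frame(
        epoch = ep, train_loss = bce(ptr, ytr),
        val_accuracy = mean((pva >= 0.5) == yva)))
    }
  })
  model$head <- list(w = w, b = b)
  model$feat_mu <- mu; model$feat_sd <- sd_
  model$trained <- TRUE
  model$metadata <- list(seed = config$seed, epochs = config$epochs,
                         n_train = length(tr_idx), n_val = length(val_idx),
                         final_val_accuracy = report$val_accuracy[nrow(report)])
  list(model = model, report = report)
}

#' Per-image genomic-island probability
#'
#' @param object a trained `model_handle`.
#' @param images list of `rendered_image`s (or pixel arrays).
#' @param ... unused.
#' @return numeric vector of probabilities in `[0, 1]`, one per image, in
#'   input order.
#' @export
predict.model_handle <- function(object, images, ...) {
  if (!object$trained)
    stop("validation error: model has not been trained")
  if (inherits(images, "rendered_image")) images <- list(images)
  if (!length(images)) return(numeric(0))
  feats <- extract_features(object, images)
  Z <- sweep(sweep(feats, 2, object$feat_mu), 2, object$feat_sd, `/`)
  unname(sigmoid(drop(Z %*% object$head$w) + object$head$b))
}

#' Classify every gene of a genome
#'
#' Builds the compare-region neighborhood of each gene against the reference
#' genomes, renders it, and scores it with the trained model: exactly one
#' prediction per gene, in genome order.
#'
#' @param model a trained `model_handle`.
#' @param genome the query [genome_annotation()].
#' @param reference_genomes list of `list(genome=, distance=)` as for
#'   [build_neighborhood()].
#' @param ncfg a [neighborhood_config()].
#' @param rcfg a [render_config()].
#' @param vocab a [keyword_vocabulary()].
#' @param threshold call a gene "GI" when probability >= threshold.
#' @return data.frame of class `gene_predictions` with columns `gene_id`,
#'   `contig_id`, `start`, `end`, `probability`, `call`.
#' @export
classify_genes <- function(model, genome, reference_genomes,
                           ncfg = neighborhood_config(),
                           rcfg = render_config(),
                           vocab = keyword_vocabulary(), threshold = 0.5) {
  g <- genome$genes
  images <- lapply(g$gene_id, function(id) {
    render(build_neighborhood(id, genome, reference_genomes, ncfg),
           rcfg, vocab)
  })
  p <- predict(model, images)
  out <- data.frame(gene_id = g$gene_id, contig_id = g$contig_id,
                    start = g$start, end = g$end, probability = p,
                    call = ifelse(p >= threshold, "GI", "not-GI"),
                    stringsAsFactors = FALSE)
  class(out) <- c("gene_predictions", "data.frame")
  out
}

# ---- checkpoints ------------------------------------------------------------

#' Save / load a model checkpoint
#'
#' Checkpoints are a single JSON file (versioned schema) holding the
#' backbone layers, head weights, feature standardization, and training
#' metadata; `load_model` restores a model that predicts identically.
#'
#' @param model a `model_handle`.
#' @param path checkpoint path (.json).
#' @export
save_model <- function(model, path) {
  x <- unclass(model)
  x$schema_version <- 1L
  x$layers <- lapply(x$layers, function(l)
    list(W = as.vector(l$W), dim = dim(l$W), b = l$b, pool = l$pool))
  jsonlite::write_json(x, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (is.null(x$schema_version))
    stop("format error: missing key 'schema_version' in checkpoint ", path)
  layers <- if (is.data.frame(x$layers)) {
    lapply(seq_len(nrow(x$layers)), function(i)
      list(W = matrix(x$layers$W[[i]], x$layers$dim[[i]][[1]],
                      x$layers$dim[[i]][[2]]),
           b = x$layers$b[[i]], pool = as.integer(x$layers$pool[[i]])))
  } else {
    lapply(x$layers, function(l)
      list(W = matrix(unlist(l$W), l$dim[[1]], l$dim[[2]]),
           b = unlist(l$b), pool = as.integer(l$pool)))
  }
  structure(list(
    backbone = x$backbone, input_shape = as.integer(x$input_shape),
    layers = layers,
    head = list(w = as.numeric(x$head$w), b = as.numeric(x$head$b)),
    feat_mu = as.numeric(x$feat_mu), feat_sd = as.numeric(x$feat_sd),
    n_trainable = as.integer(x$n_trainable),
    n_backbone = as.numeric(x$n_backbone),
    trained = isTRUE(x$trained), metadata = as.list(x$metadata)
  ), class = "model_handle")
}

#' Save / load a backbone checkpoint
#'
#' The pluggable-backbone interface: a JSON file holding only the conv
#' layers, suitable as `weights_path` for
#' `train_config(backbone = "inception_v3_pretrained")`.
#'
#' @param model a `model_handle` whose layers to export.
#' @param path output path.
#' @export
save_backbone <- function(model, path) {
  jsonlite::write_json(list(
    schema_version = 1L, backbone = model$backbone,
    input_shape = model$input_shape,
    layers = lapply(model$layers, function(l)
      list(W = as.vector(l$W), dim = dim(l$W), b = l$b, pool = l$pool))
  ), path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_backbone
#' @export
load_backbone <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(x$schema_version) || is.null(x$layers))
    stop("format error: not a backbone checkpoint: ", path)
  list(backbone = x$backbone,
       input_shape = as.integer(unlist(x$input_shape)),
       layers = lapply(x$layers, function(l)
         list(W = matrix(unlist(l$W), l$dim[[1]], l$dim[[2]]),
              b = unlist(l$b), pool = as.integer(l$pool))))
}
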