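#' Simulation configuration for synthetic genome sets
#'
#' Emulates the comparative signal the island detector consumes: a query
#' genome and a panel of related genomes share a conserved backbone of
#' single-copy gene families in conserved order (with per-genome jitter in
#' gene lengths and intergenic gaps), while islands planted into the query
#' carry fresh singleton families (sporadic distribution: absent from the
#' references by default), shorter genes, and phage/mobility/unknown
#' annotations.
#'
#' @param n_reference_genomes panel size (default 20).
#' @param backbone_genes conserved genes per genome (default 300).
#' @param backbone_gene_len c(mean, sd) bp of backbone genes (default 900,
#'   200; truncated at 90 bp).
#' @param island_count islands planted in the query (default 3).
#' @param island_span c(min, max) bp of planted island spans (default
#'   10000, 30000; must lie within 1-200 kbp).
#' @param island_gene_len c(mean, sd) bp of island genes (default 500, 150)
#'   — island genes run shorter than backbone genes.
#' @param island_presence_prob probability that a reference genome also
#'   carries a given island (default 0: fully sporadic).
#' @param phage_annotation_frac,unknown_annotation_frac fraction of island
#'   genes annotated with phage keywords / as hypothetical proteins
#'   (defaults 0.4 and 0.4; the remainder get mobility annotations).
#' @param intergenic_gap mean intergenic gap bp (default 120).
#' @param seed integer.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_reference_genomes = 20L, backbone_genes = 300L,
                       backbone_gene_len = c(900, 200), island_count = 3L,
                       island_span = c(10000, 30000),
                       island_gene_len = c(500, 150),
                       island_presence_prob = 0,
                       phage_annotation_frac = 0.4,
                       unknown_annotation_frac = 0.4,
                       intergenic_gap = 120, seed = 1L) {
  if (island_span[[1]] < 1000 || island_span[[2]] > 200000 ||
      island_span[[1]] > island_span[[2]])
    stop("validation error: island_span must lie within [1 kbp, 200 kbp]")
  fr <- c(island_presence_prob, phage_annotation_frac, unknown_annotation_frac)
  if (any(fr < 0 | fr > 1))
    stop("validation error: fractions must be in [0, 1]")
  if (phage_annotation_frac + unknown_annotation_frac > 1)
    stop("validation error: phage + unknown annotation fractions exceed 1")
  structure(list(n_reference_genomes = as.integer(n_reference_genomes),
                 backbone_genes = as.integer(backbone_genes),
                 backbone_gene_len = backbone_gene_len,
                 island_count = as.integer(island_count),
                 island_span = island_span,
                 island_gene_len = island_gene_len,
                 island_presence_prob = island_presence_prob,
                 phage_annotation_frac = phage_annotation_frac,
                 unknown_annotation_frac = unknown_annotation_frac,
                 intergenic_gap = intergenic_gap, seed = as.integer(seed)),
            class = "sim_config")
}

# annotation pools; backbone products deliberately avoid every GI keyword
.backbone_products <- c(
  "DNA gyrase subunit A", "DNA gyrase subunit B", "ribosomal protein L1",
  "ribosomal protein S4", "elongation factor Tu", "RNA polymerase beta subunit",
  "chaperone protein DnaK", "ATP synthase F1 alpha subunit",
  "citrate synthase", "malate dehydrogenase", "enolase",
  "phosphoglycerate kinase", "aminopeptidase N", "signal peptidase I",
  "preprotein translocase SecY", "cell division protein FtsZ",
  "glutamine synthetase", "aspartate aminotransferase",
  "NADH dehydrogenase subunit B", "succinate dehydrogenase flavoprotein")

.phage_products <- c(
  "phage major capsid protein", "phage terminase large subunit",
  "phage portal protein", "phage tail fiber protein",
  "phage baseplate assembly protein", "prophage antirepressor",
  "phage holin", "phage lysin", "phage virion morphogenesis protein")

.mobility_products <- c(
  "site-specific integrase", "IS3 family transposase",
  "tyrosine recombinase XerC", "conjugal transfer protein TraG",
  "mobile element protein")

#' Simulate a query genome, reference panel, and ground truth
#'
#' Deterministic for a given seed. Backbone families are shared across all
#' genomes in conserved order; islands are inserted into the query at seeded
#' backbone positions with fresh singleton families, shorter genes, and
#' GI-style annotations; references carry each island independently with
#' probability `island_presence_prob`. Reference distances are a seeded
#' increasing sequence.
#'
#' @param config a [sim_config()].
#' @return list with `query` (a [genome_annotation()]), `references` (list
#'   of `list(genome=, distance=)`, sorted by distance), and `truth` (list
#'   with `islands`, an [island_table()], and `gene_labels`, a data.frame of
#'   per-gene "GI"/"not-GI" truth for the query genome).
#' @export
simulate_genome_set <- function(config = sim_config()) {
  withr::with_seed(config$seed, {
    nb <- config$backbone_genes
    fam_ids <- sprintf("bbfam_%04d", seq_len(nb))
    fam_products <- sample(.backbone_products, nb, replace = TRUE)
    fam_strands <- sample(c("+", "-"), nb, replace = TRUE, prob = c(0.6, 0.4))

    # island blueprints (shared between query and any reference carrying them)
    islands <- lapply(seq_len(config$island_count), function(i) {
      target <- stats::runif(1, config$island_span[[1]],
                             max(config$island_span[[1]],
                                 config$island_span[[2]] - 2000))
      lens <- integer(); gaps <- integer(); anns <- character()
      span <- 0
      while (span < target) {
        len <- rnorm_trunc(1, config$island_gene_len[[1]],
                           config$island_gene_len[[2]], 90)
        gap <- if (length(lens)) pmax(1, round(stats::rexp(1, 1 / config$intergenic_gap)))
               else 0L
        u <- stats::runif(1)
        ann <- if (u < config$phage_annotation_frac) sample(.phage_products, 1)
               else if (u < config$phage_annotation_frac +
                          config$unknown_annotation_frac) "hypothetical protein"
               else sample(.mobility_products, 1)
        lens <- c(lens, len); gaps <- c(gaps, gap); anns <- c(anns, ann)
        span <- sum(lens) + sum(gaps)
      }
      list(lens = lens, gaps = gaps, anns = anns,
           strands = sample(c("+", "-"), length(lens), replace = TRUE),
           fams = sprintf("islfam_%d_%03d", i, seq_along(lens)))
    })
    insert_after <- sort(sample(seq_len(nb - 1L), config$island_count))

    build_genome <- function(genome_id, with_islands) {
      pos <- 0L
      rows <- list()
      k <- 0L
      add_gene <- function(len, strand, fam, ann, label, gap = NULL) {
        if (is.null(gap))
          gap <- pmax(1, round(stats::rexp(1, 1 / config$intergenic_gap)))
        start <- pos + gap
        k <<- k + 1L
        rows[[length(rows) + 1L]] <<- data.frame(
          gene_id = sprintf("%s_g%04d", genome_id, k),
          contig_id = "contig_1", start = start, end = start + len,
          strand = strand, family_id = fam, annotation = ann, label = label,
          stringsAsFactors = FALSE)
        pos <<- start + len
      }
      for (b in seq_len(nb)) {
        len <- rnorm_trunc(1, config$backbone_gene_len[[1]],
                           config$backbone_gene_len[[2]], 90)
        add_gene(len, fam_strands[[b]], fam_ids[[b]], fam_products[[b]],
                 "not-GI")
        ii <- which(insert_after == b)
        for (i in ii) {
          if (!with_islands[[i]]) next
          isl <- islands[[i]]
          for (j in seq_along(isl$lens)) {
            add_gene(isl$lens[[j]], isl$strands[[j]], isl$fams[[j]],
                     isl$anns[[j]], "GI",
                     gap = if (j > 1L) isl$gaps[[j]] else NULL)
          }
        }
      }
      df <- do.call(rbind, rows)
      contig_len <- pos + 200L
      genes <- gene_table(df$gene_id, genome_id, df$contig_id, df$start,
                          df$end, df$strand, df$family_id, df$annotation)
      list(genome = genome_annotation(genome_id,
                                      c(contig_1 = contig_len), genes),
           labels = df[, c("gene_id", "label")])
    }

    q <- build_genome("query", rep(TRUE, config$island_count))
    refs <- list()
    dists <- sort(stats::runif(config$n_reference_genomes, 0.02, 0.5))
    for (r in seq_len(config$n_reference_genomes)) {
      present <- stats::runif(config$island_count) < config$island_presence_prob
      rg <- build_genome(sprintf("ref_%02d", r), present)
      refs[[r]] <- list(genome = rg$genome, distance = dists[[r]])
    }

    gi <- q$labels$label == "GI"
    qgenes <- q$genome$genes
    truth_islands <- island_table()
    if (any(gi)) {
      gidx <- which(qgenes$gene_id %in% q$labels$gene_id[gi])
      fam_island <- sub("^islfam_(\\d+)_.*$", "\\1",
                        qgenes$family_id[gidx])
      for (i in unique(fam_island)) {
        sel <- gidx[fam_island == i]
        truth_islands <- rbind(truth_islands, island_table(
          "contig_1", min(qgenes$start[sel]), max(qgenes$end[sel]),
          gene_ids = list(qgenes$gene_id[sel])))
      }
      class(truth_islands) <- c("island_table", "data.frame")
    }
    list(query = q$genome, references = refs,
         truth = list(islands = truth_islands, gene_labels = q$labels))
  })
}

#' Render a balanced labeled corpus from simulated genome sets
#'
#' Samples `n_per_class` island genes (label "GI") and `n_per_class`
#' backbone genes (label "not-GI") from the query genome(s), builds and
#' renders each gene's neighborhood against the corresponding reference
#' panel, and returns the shuffled examples. A list of simulated sets may
#' be supplied to pool genes across replicates.
#'
#' @param sims one result of [simulate_genome_set()], or a list of them.
#' @param ncfg a [neighborhood_config()].
#' @param rcfg a [render_config()].
#' @param vocab a [keyword_vocabulary()].
#' @param n_per_class examples per label.
#' @param seed integer controlling sampling and output order.
#' @return list of [labeled_example()]s of length `2 * n_per_class`.
#' @export
generate_training_corpus <- function(sims, ncfg = neighborhood_config(),
                                     rcfg = render_config(),
                                     vocab = keyword_vocabulary(),
                                     n_per_class = 100L, seed = 1L) {
  if (!is.null(sims$query)) sims <- list(sims)
  pool <- do.call(rbind, lapply(seq_along(sims), function(si) {
    lab <- sims[[si]]$truth$gene_labels
    data.frame(sim = si, gene_id = lab$gene_id, label = lab$label,
               stringsAsFactors = FALSE)
  }))
  withr::with_seed(seed, {
    picks <- lapply(c("GI", "not-GI"), function(cl) {
      avail <- which(pool$label == cl)
      if (length(avail) < n_per_class)
        stop("validation error: only ", length(avail), " ", cl,
             " genes available, need ", n_per_class)
      avail[sample.int(length(avail), n_per_class)]
    })
    idx <- sample(unlist(picks))
  })
  lapply(idx, function(i) {
    sim <- sims[[pool$sim[[i]]]]
    nb <- build_neighborhood(pool$gene_id[[i]], sim$query, sim$references,
                             ncfg)
    labeled_example(render(nb, rcfg, vocab), pool$label[[i]],
                    pool$gene_id[[i]])
  })
}

#' Pixel-count separability oracle
#'
#' Classifier-independent baseline used to validate that a rendered corpus
#' is separable before trusting a learned model's accuracy on it: the score
#' of an image is the number of non-background pixels outside the query
#' band (sporadic neighborhoods have empty reference rows, hence little ink
#' there), the decision cutoff is the midpoint of the two class means on
#' the training split, and an image is called "GI" when its score falls
#' below the cutoff.
#'
#' @param examples list of [labeled_example()]s.
#' @param train_idx,val_idx index vectors (e.g. from [train_val_split()]).
#' @param rcfg the [render_config()] the images were rendered with.
#' @return list with `cutoff` and `accuracy` (on `val_idx`).
#' @export
separability_oracle <- function(examples, train_idx, val_idx,
                                rcfg = render_config()) {
  score <- vapply(examples, function(ex)
    sum(ink_by_band(ex$image, rcfg)[-1]), numeric(1))
  label <- vapply(examples, `[[`, character(1), "label")
  m_gi <- mean(score[train_idx][label[train_idx] == "GI"])
  m_bg <- mean(score[train_idx][label[train_idx] == "not-GI"])
  cutoff <- (m_gi + m_bg) / 2
  calls <- ifelse(score[val_idx] < cutoff, "GI", "not-GI")
  list(cutoff = cutoff, accuracy = mean(calls == label[val_idx]))
}

#' Write a simulated genome set as standard files
#'
#' Emits one GFF3 per genome, the ground-truth islands as BED, the per-gene
#' truth labels as TSV, and the reference distances as TSV, so downstream
#' commands consume only standard formats.
#'
#' @param sim a [simulate_genome_set()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_genome_annotation(sim$query, file.path(dir, "query.gff3"))
  dist_df <- data.frame(genome_id = character(), distance = numeric(),
                        path = character())
  for (r in sim$references) {
    f <- paste0(r$genome$genome_id, ".gff3")
    write_genome_annotation(r$genome, file.path(dir, f))
    dist_df <- rbind(dist_df, data.frame(genome_id = r$genome$genome_id,
                                         distance = r$distance, path = f))
  }
  utils::write.table(dist_df, file.path(dir, "distances.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_prediction_set(prediction_set("truth", sim$query$genome_id,
                                      sim$truth$islands),
                       file.path(dir, "truth.bed"))
  utils::write.table(sim$truth$gene_labels, file.path(dir, "truth_genes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read back a simulated genome set written by [write_simulation()]
#'
#' @param dir directory holding query.gff3, ref_*.gff3, distances.tsv.
#' @return list with `query` and `references` as in [simulate_genome_set()].
#' @export
read_simulation <- function(dir) {
  query <- read_genome_annotation(file.path(dir, "query.gff3"),
                                  genome_id = "query")
  dist_df <- utils::read.delim(file.path(dir, "distances.tsv"),
                               stringsAsFactors = FALSE)
  refs <- lapply(seq_len(nrow(dist_df)), function(i) {
    list(genome = read_genome_annotation(file.path(dir, dist_df$path[[i]]),
                                         genome_id = dist_df$genome_id[[i]]),
         distance = dist_df$distance[[i]])
  })
  list(query = query, references = refs)
}
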