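# fixtures built in code: tiny genomes, random interval sets, and the
# independent per-base / brute-force oracles used against the interval and
# island-calling implementations

make_genome <- function(genome_id = "g1", contig_len = 50000L,
                        starts, lens, strands = NULL, families = NULL,
                        annotations = NULL, contig_id = "c1") {
  n <- length(starts)
  if (is.null(strands)) strands <- rep("+", n)
  if (is.null(families)) families <- sprintf("fam%03d", seq_len(n))
  if (is.null(annotations)) annotations <- rep("DNA polymerase III", n)
  genes <- gene_table(sprintf("%s_g%03d", genome_id, seq_len(n)), genome_id,
                      contig_id, starts, starts + lens, strands, families,
                      annotations)
  genome_annotation(genome_id, stats::setNames(contig_len, contig_id), genes)
}

# evenly spaced genes: start_i = gap + (i-1) * (len + gap)
make_tiled_genome <- function(genome_id = "g1", n = 20L, len = 800L,
                              gap = 200L, contig_len = NULL, ...) {
  starts <- gap + (seq_len(n) - 1L) * (len + gap)
  if (is.null(contig_len)) contig_len <- max(starts) + len + gap
  make_genome(genome_id, contig_len, starts, rep(len, n), ...)
}

random_island_table <- function(contig_len, n, contig_id = "c1") {
  if (n == 0L) return(island_table())
  s <- sample.int(contig_len - 1L, n, replace = TRUE) - 1L
  w <- sample.int(max(2L, contig_len %/% 10L), n, replace = TRUE)
  island_table(contig_id, s, pmin(contig_len, s + w))
}

random_prediction_set <- function(tool, contig_len, n, genome_id = "g1") {
  prediction_set(tool, genome_id, random_island_table(contig_len, n))
}

# --- per-base bitmap oracles (single contig) --------------------------------

bitmap_of <- function(islands, contig_len) {
  bm <- logical(contig_len)
  for (i in seq_len(nrow(islands))) {
    if (islands$end[[i]] > islands$start[[i]])
      bm[(islands$start[[i]] + 1L):islands$end[[i]]] <- TRUE
  }
  bm
}

oracle_bp_coverage <- function(target, predictor, contig_len) {
  ti <- target$islands
  if (!nrow(ti)) return(NA_real_)
  pm <- bitmap_of(predictor$islands, contig_len)
  covered <- 0L; total <- 0L
  for (i in seq_len(nrow(ti))) {
    span <- (ti$start[[i]] + 1L):ti$end[[i]]
    covered <- covered + sum(pm[span])
    total <- total + length(span)
  }
  100 * covered / total
}

oracle_any_overlap <- function(target, predictor, contig_len) {
  ti <- target$islands
  if (!nrow(ti)) return(NA_real_)
  pm <- bitmap_of(predictor$islands, contig_len)
  hit <- vapply(seq_len(nrow(ti)), function(i)
    any(pm[(ti$start[[i]] + 1L):ti$end[[i]]]), logical(1))
  100 * mean(hit)
}

oracle_unique <- function(tool, others, contig_len) {
  om <- Reduce(`|`, lapply(others, function(o)
    bitmap_of(o$islands, contig_len)), logical(contig_len))
  ti <- tool$islands
  keep <- vapply(seq_len(nrow(ti)), function(i)
    !any(om[(ti$start[[i]] + 1L):ti$end[[i]]]), logical(1))
  ti[keep, , drop = FALSE]
}

# brute-force enumerator of maximal GI runs over one contig of predictions
oracle_call_islands <- function(preds, min_span, max_gap_genes) {
  out <- island_table()
  for (ctg in unique(preds$contig_id)) {
    p <- preds[preds$contig_id == ctg, , drop = FALSE]
    gi <- which(p$call == "GI")
    if (!length(gi)) next
    groups <- list()
    for (i in gi) {
      if (length(groups) &&
          i - groups[[length(groups)]][length(groups[[length(groups)]])] <=
            max_gap_genes + 1L) {
        groups[[length(groups)]] <- c(groups[[length(groups)]], i)
      } else groups[[length(groups) + 1L]] <- i
    }
    for (r in groups) {
      s <- p$start[r[[1]]]; e <- p$end[r[[length(r)]]]
      if (e - s > min_span)
        out <- rbind(out, island_table(ctg, s, e, list(p$gene_id[r])))
    }
  }
  class(out) <- c("island_table", "data.frame")
  out
}

random_gene_predictions <- function(n, contig_id = "c1") {
  lens <- sample(100:900, n, replace = TRUE)
  gaps <- sample(20:400, n, replace = TRUE)
  ends <- cumsum(lens + gaps)
  starts <- ends - lens
  df <- data.frame(gene_id = sprintf("g%04d", seq_len(n)),
                   contig_id = contig_id, start = starts,
                   end = ends,
                   probability = runif(n),
                   call = sample(c("GI", "not-GI"), n, replace = TRUE),
                   stringsAsFactors = FALSE)
  class(df) <- c("gene_predictions", "data.frame")
  df
}

# a small comparative fixture: query + nref references sharing families
make_comparative_set <- function(nref = 3L, n = 15L, len = 600L, gap = 400L,
                                 query_extra = NULL) {
  query <- make_tiled_genome("query", n = n, len = len, gap = gap)
  refs <- lapply(seq_len(nref), function(i)
    list(genome = make_tiled_genome(sprintf("ref%02d", i), n = n, len = len,
                                    gap = gap),
         distance = i / 10))
  list(query = query, references = refs)
}

# genes with controlled annotation mixes for the region/gene-outcome rules
region_fixture <- function(n, n_phage, n_unknown) {
  ann <- c(rep("phage major capsid protein", n_phage),
           rep("hypothetical protein", n_unknown),
           rep("DNA polymerase III", n - n_phage - n_unknown))
  gene_table(sprintf("g%02d", seq_len(n)), "g", "c1",
             (seq_len(n) - 1L) * 1000L, (seq_len(n) - 1L) * 1000L + 800L,
             "+", annotation = ann)
}

phage_run_genome <- function(run_len, at = 10L, n = 30L) {
  ann <- rep("DNA polymerase III", n)
  ann[at:(at + run_len - 1L)] <- "phage tail fiber protein"
  make_tiled_genome("g", n = n, len = 800L, gap = 200L, annotations = ann)
}

outcome_genome <- function() {
  # 20 genes; gene 12 is the lone phage gene
  ann <- rep("DNA polymerase III", 20)
  ann[12] <- "phage portal protein"
  make_tiled_genome("g", n = 20L, len = 800L, gap = 200L, annotations = ann)
}

pred_for <- function(g, idx, call) {
  df <- data.frame(gene_id = g$genes$gene_id[idx],
                   contig_id = g$genes$contig_id[idx],
                   start = g$genes$start[idx], end = g$genes$end[idx],
                   probability = ifelse(call == "GI", 0.9, 0.1),
                   call = call, stringsAsFactors = FALSE)
  class(df) <- c("gene_predictions", "data.frame")
  df
}

small_render_config <- function() render_config(width = 96L, height = 96L)
small_neighborhood_config <- function() neighborhood_config(region_size = 6000L,
                                                            max_rows = 20L)
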