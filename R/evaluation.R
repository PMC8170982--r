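#' Keyword vocabulary for genomic-island features
#'
#' Case-insensitive substring keywords used to recognize GI-related gene
#' annotations, in the style of prophage-detection tools that verify
#' predictions by annotation keywords. The default lists ship as an editable
#' YAML file (`system.file("extdata", "gi_keywords.yaml", package =
#' "islandscope")`); "integrase" is classed as mobility, not phage.
#'
#' @param phage_keywords,mobility_keywords,tRNA_keywords,
#'   unknown_function_markers character vectors, lowercase, non-empty.
#' @return list of class `keyword_vocabulary`.
#' @export
keyword_vocabulary <- function(
    phage_keywords = c("phage", "prophage", "capsid", "tail", "terminase",
                       "portal", "baseplate", "holin", "lysin", "virion"),
    mobility_keywords = c("integrase", "transposase", "recombinase",
                          "mobile element", "conjugal", "conjugative"),
    tRNA_keywords = c("trna", "transfer rna"),
    unknown_function_markers = c("hypothetical protein", "uncharacterized",
                                 "unknown function",
                                 "putative uncharacterized")) {
  v <- list(phage_keywords = phage_keywords,
            mobility_keywords = mobility_keywords,
            tRNA_keywords = tRNA_keywords,
            unknown_function_markers = unknown_function_markers)
  if (any(lengths(v) == 0))
    stop("validation error: all keyword lists must be non-empty")
  v <- lapply(v, tolower)
  structure(v, class = "keyword_vocabulary")
}

#' Load a keyword vocabulary from YAML
#'
#' @param path YAML file with keys `phage_keywords`, `mobility_keywords`,
#'   `tRNA_keywords`, `unknown_function_markers`. Defaults to the vocabulary
#'   shipped with the package.
#' @return a [keyword_vocabulary()].
#' @export
read_keyword_vocabulary <- function(path = system.file("extdata",
                                                       "gi_keywords.yaml",
                                                       package = "islandscope")) {
  x <- yaml::read_yaml(path)
  keyword_vocabulary(x$phage_keywords, x$mobility_keywords,
                     x$tRNA_keywords, x$unknown_function_markers)
}

#' Classify one annotation string by GI-feature keywords
#'
#' Case-insensitive substring match with precedence phage > mobility >
#' tRNA > unknown; "none" when nothing matches.
#'
#' @param annotation free-text gene annotation (vectorized).
#' @param vocab a [keyword_vocabulary()].
#' @return character vector over `{phage, mobility, tRNA, unknown, none}`.
#' @export
scan_gi_feature <- function(annotation, vocab = keyword_vocabulary()) {
  ann <- tolower(annotation)
  hit <- function(kws) Reduce(`|`, lapply(kws, grepl, x = ann, fixed = TRUE))
  out <- rep("none", length(ann))
  out[hit(vocab$unknown_function_markers)] <- "unknown"
  out[hit(vocab$tRNA_keywords)] <- "tRNA"
  out[hit(vocab$mobility_keywords)] <- "mobility"
  out[hit(vocab$phage_keywords)] <- "phage"
  out
}

# does each annotation carry any phage/mobility/tRNA feature?
.has_gi_feature <- function(annotation, vocab) {
  scan_gi_feature(annotation, vocab) %in% c("phage", "mobility", "tRNA")
}

#' Region-level classification of a predicted island (Phispy-style)
#'
#' A predicted region is a true positive (PTP) when it contains at least six
#' phage-related genes, or when at least half of its genes have unknown
#' functions; otherwise it is a false positive (PFP).
#'
#' @param region_genes gene rows of the predicted island (a `gene_table`
#'   subset).
#' @param vocab a [keyword_vocabulary()].
#' @return "PTP" or "PFP".
#' @export
phispy_region_class <- function(region_genes, vocab = keyword_vocabulary()) {
  if (!nrow(region_genes)) {
    warning("empty predicted region classified as PFP")
    return("PFP")
  }
  feat <- scan_gi_feature(region_genes$annotation, vocab)
  n_phage <- sum(feat == "phage")
  frac_unknown <- mean(feat == "unknown")
  if (n_phage >= 6L || frac_unknown >= 0.5) "PTP" else "PFP"
}

#' Count Phispy-style false negatives
#'
#' A false negative is a maximal run of at least six consecutive
#' phage-related genes with zero bp overlap with any predicted island.
#'
#' @param genome a [genome_annotation()].
#' @param preds a [prediction_set()].
#' @param vocab a [keyword_vocabulary()].
#' @return integer count.
#' @export
phispy_false_negatives <- function(genome, preds,
                                   vocab = keyword_vocabulary()) {
  n_fn <- 0L
  for (ctg in unique(genome$genes$contig_id)) {
    g <- genome$genes[genome$genes$contig_id == ctg, , drop = FALSE]
    is_phage <- scan_gi_feature(g$annotation, vocab) == "phage"
    if (!any(is_phage)) next
    runs <- rle(is_phage)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    isl <- preds$islands[preds$islands$contig_id == ctg, , drop = FALSE]
    for (k in which(runs$values & runs$lengths >= 6L)) {
      rs <- g$start[starts[[k]]]; re <- g$end[ends[[k]]]
      hit <- nrow(isl) && any(isl$start < re & isl$end > rs)
      if (!hit) n_fn <- n_fn + 1L
    }
  }
  n_fn
}

#' Phispy-style metrics for one prediction set
#'
#' Classifies each predicted island as PTP or PFP from the genes it
#' contains, counts PFNs, and derives sensitivity `PTP / (PTP + PFN)` and
#' the false-positive percentage `PFP / (PTP + PFP)`.
#'
#' @param genome a [genome_annotation()].
#' @param preds a [prediction_set()].
#' @param vocab a [keyword_vocabulary()].
#' @return list with `PTP`, `PFP`, `PFN`, `sensitivity`,
#'   `false_positive_pct` (percent scale; `NA` on empty denominators).
#' @export
phispy_metrics <- function(genome, preds, vocab = keyword_vocabulary()) {
  isl <- preds$islands
  cls <- character(nrow(isl))
  for (i in seq_len(nrow(isl))) {
    g <- genome$genes
    inside <- g$contig_id == isl$contig_id[[i]] &
      g$start < isl$end[[i]] & g$end > isl$start[[i]]
    cls[[i]] <- suppressWarnings(
      phispy_region_class(g[inside, , drop = FALSE], vocab))
  }
  ptp <- sum(cls == "PTP"); pfp <- sum(cls == "PFP")
  pfn <- phispy_false_negatives(genome, preds, vocab)
  list(PTP = ptp, PFP = pfp, PFN = pfn,
       sensitivity = if (ptp + pfn > 0) ptp / (ptp + pfn) else NA_real_,
       false_positive_pct = if (ptp + pfp > 0) 100 * pfp / (ptp + pfp)
                            else NA_real_)
}

#' Base-pair coverage of one tool's islands by another's
#'
#' Percentage of the target tool's predicted bases that are intersected by
#' the union of the predictor tool's islands. Overlapping target islands
#' are counted as printed (not merged); an empty target gives `NA`.
#'
#' @param target,predictor [prediction_set()]s over the same genome.
#' @return percent in `[0, 100]`, or `NA`.
#' @export
base_pair_coverage <- function(target, predictor) {
  .check_same_genome(target, predictor)
  tisl <- target$islands
  if (!nrow(tisl)) return(NA_real_)
  total <- sum(tisl$end - tisl$start)
  covered <- 0
  for (ctg in unique(tisl$contig_id)) {
    tt <- tisl[tisl$contig_id == ctg, , drop = FALSE]
    pp <- predictor$islands[predictor$islands$contig_id == ctg, , drop = FALSE]
    if (!nrow(pp)) next
    tr <- IRanges::IRanges(tt$start + 1L, tt$end)
    pr <- IRanges::reduce(IRanges::IRanges(pp$start + 1L, pp$end))
    ov <- IRanges::findOverlaps(tr, pr)
    if (!length(ov)) next
    inter <- IRanges::pintersect(tr[S4Vectors::queryHits(ov)],
                                 pr[S4Vectors::subjectHits(ov)])
    covered <- covered + sum(IRanges::width(inter))
  }
  100 * covered / total
}

#' Percent of target islands touched by any predictor island
#'
#' An island counts as predicted by the other tool when any prediction
#' overlaps it by at least 1 bp.
#'
#' @inheritParams base_pair_coverage
#' @return percent in `[0, 100]`, or `NA` for an empty target.
#' @export
island_any_overlap <- function(target, predictor) {
  .check_same_genome(target, predictor)
  tisl <- target$islands
  if (!nrow(tisl)) return(NA_real_)
  hit <- logical(nrow(tisl))
  for (i in seq_len(nrow(tisl))) {
    pp <- predictor$islands
    hit[[i]] <- any(pp$contig_id == tisl$contig_id[[i]] &
                      pp$start < tisl$end[[i]] & pp$end > tisl$start[[i]])
  }
  100 * mean(hit)
}

.check_same_genome <- function(a, b) {
  if (!identical(a$genome_id, b$genome_id))
    stop("validation error: prediction sets refer to different genomes (",
         a$genome_id, " vs ", b$genome_id, ")")
}

#' Unique predictions of a tool and their GI-feature rate
#'
#' Islands of `tool` with zero bp overlap against every other prediction
#' set, plus the percentage of those islands containing at least one gene
#' with a phage/mobility/tRNA feature.
#'
#' @param tool a [prediction_set()].
#' @param others list of other tools' [prediction_set()]s.
#' @param genome the [genome_annotation()] (for gene content).
#' @param vocab a [keyword_vocabulary()].
#' @return list with `islands` (an [island_table()]) and `gi_feature_pct`
#'   (`NA` when there are no unique islands).
#' @export
unique_predictions <- function(tool, others, genome,
                               vocab = keyword_vocabulary()) {
  isl <- tool$islands
  keep <- rep(TRUE, nrow(isl))
  for (other in others) {
    .check_same_genome(tool, other)
    oo <- other$islands
    for (i in seq_len(nrow(isl))) {
      if (!keep[[i]]) next
      if (any(oo$contig_id == isl$contig_id[[i]] &
                oo$start < isl$end[[i]] & oo$end > isl$start[[i]]))
        keep[[i]] <- FALSE
    }
  }
  uniq <- isl[keep, , drop = FALSE]
  class(uniq) <- c("island_table", "data.frame")
  if (!nrow(uniq))
    return(list(islands = uniq, gi_feature_pct = NA_real_))
  g <- genome$genes
  has_feat <- vapply(seq_len(nrow(uniq)), function(i) {
    inside <- g$contig_id == uniq$contig_id[[i]] &
      g$start < uniq$end[[i]] & g$end > uniq$start[[i]]
    any(.has_gi_feature(g$annotation[inside], vocab))
  }, logical(1))
  list(islands = uniq, gi_feature_pct = 100 * mean(has_feat))
}

# flank context for the gene-level outcome definitions: for each gene of
# `genome`, whether the window of the gene plus flank_k genes on each side
# (truncated at contig ends) contains a phage-feature gene, and the window's
# bp interval
.flank_context <- function(genome, flank_k, vocab) {
  g <- genome$genes
  is_phage <- scan_gi_feature(g$annotation, vocab) == "phage"
  out <- data.frame(gene_id = g$gene_id, contig_id = g$contig_id,
                    phage_in_window = FALSE, win_start = g$start,
                    win_end = g$end, stringsAsFactors = FALSE)
  for (ctg in unique(g$contig_id)) {
    idx <- which(g$contig_id == ctg)
    for (j in seq_along(idx)) {
      lo <- max(1L, j - flank_k); hi <- min(length(idx), j + flank_k)
      win <- idx[lo:hi]
      k <- idx[[j]]
      out$phage_in_window[[k]] <- any(is_phage[win])
      out$win_start[[k]] <- min(g$start[win])
      out$win_end[[k]] <- max(g$end[win])
    }
  }
  out
}

#' Gene-level prediction outcomes
#'
#' For every predicted gene, the window of the gene plus `flank_k` genes on
#' each side (truncated at contig ends) decides the outcome: a gene called
#' GI is a TP when its window contains a phage-related gene or overlaps any
#' other tool's island, else an FP; a gene not called GI is an FN when its
#' window contains a phage-related gene, else a TN.
#'
#' @param preds a `gene_predictions` data.frame.
#' @param genome the [genome_annotation()] the predictions cover.
#' @param other_tools list of [prediction_set()]s (may be empty).
#' @param vocab a [keyword_vocabulary()].
#' @param flank_k flanking genes per side (default 4).
#' @return `preds` with an added `outcome` column over `{TP, FP, TN, FN}`.
#' @export
gene_outcomes <- function(preds, genome, other_tools = list(),
                          vocab = keyword_vocabulary(), flank_k = 4L) {
  ctx <- .flank_context(genome, flank_k, vocab)
  ctx <- ctx[match(preds$gene_id, ctx$gene_id), , drop = FALSE]
  if (anyNA(ctx$gene_id))
    stop("lookup error: prediction for gene absent from genome")
  overlap <- rep(FALSE, nrow(preds))
  for (other in other_tools) {
    oo <- other$islands
    for (i in which(!overlap)) {
      overlap[[i]] <- any(oo$contig_id == ctx$contig_id[[i]] &
                            oo$start < ctx$win_end[[i]] &
                            oo$end > ctx$win_start[[i]])
    }
  }
  called <- preds$call == "GI"
  positive_evidence <- ctx$phage_in_window | overlap
  preds$outcome <- ifelse(called,
                          ifelse(positive_evidence, "TP", "FP"),
                          ifelse(ctx$phage_in_window, "FN", "TN"))
  preds
}

#' Gene-level ROC curve and AUC
#'
#' Re-thresholds the per-gene probabilities at every distinct value,
#' recomputes the outcome definitions of [gene_outcomes()] at each
#' threshold, and reports (threshold, TPR, FPR) points sorted by FPR with
#' the (0,0) and (1,1) endpoints, plus the trapezoid-rule AUC.
#'
#' @inheritParams gene_outcomes
#' @return list with `points` (data.frame `threshold`, `TPR`, `FPR`) and
#'   `auc` (`NA` when either rate is undefined at every threshold).
#' @export
roc_curve <- function(preds, genome, other_tools = list(),
                      vocab = keyword_vocabulary(), flank_k = 4L) {
  ctx <- .flank_context(genome, flank_k, vocab)
  ctx <- ctx[match(preds$gene_id, ctx$gene_id), , drop = FALSE]
  overlap <- rep(FALSE, nrow(preds))
  for (other in other_tools) {
    oo <- other$islands
    for (i in which(!overlap)) {
      overlap[[i]] <- any(oo$contig_id == ctx$contig_id[[i]] &
                            oo$start < ctx$win_end[[i]] &
                            oo$end > ctx$win_start[[i]])
    }
  }
  phage <- ctx$phage_in_window
  evidence <- phage | overlap
  thresholds <- sort(unique(preds$probability))
  pts <- lapply(thresholds, function(th) {
    called <- preds$probability >= th
    tp <- sum(called & evidence)
    fp <- sum(called & !evidence)
    fn <- sum(!called & phage)
    tn <- sum(!called & !phage)
    data.frame(threshold = th,
               TPR = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
               FPR = if (fp + tn > 0) fp / (fp + tn) else NA_real_)
  })
  pts <- do.call(rbind, pts)
  pts <- rbind(data.frame(threshold = Inf, TPR = 0, FPR = 0), pts,
               data.frame(threshold = -Inf, TPR = 1, FPR = 1))
  pts <- pts[stats::complete.cases(pts[, c("TPR", "FPR")]), , drop = FALSE]
  pts <- pts[order(pts$FPR, pts$TPR), , drop = FALSE]
  rownames(pts) <- NULL
  auc <- if (nrow(pts) >= 2L) {
    sum(diff(pts$FPR) * (utils::head(pts$TPR, -1) + utils::tail(pts$TPR, -1)) / 2)
  } else NA_real_
  if (!any(phage) || all(phage)) auc <- NA_real_
  list(points = pts, auc = auc)
}

#' Base-pair precision, recall and F1 between two island sets
#'
#' Convenience wrapper over [base_pair_coverage()]: recall is the fraction
#' of truth bases covered by the predictions, precision the fraction of
#' predicted bases covered by the truth.
#'
#' @param pred,truth [prediction_set()]s on the same genome.
#' @return list with `precision`, `recall`, `f1` (fractions in `[0, 1]`).
#' @export
bp_f1 <- function(pred, truth) {
  recall <- base_pair_coverage(truth, pred) / 100
  precision <- base_pair_coverage(pred, truth) / 100
  f1 <- if (is.na(precision) || is.na(recall) || precision + recall == 0) {
    NA_real_
  } else 2 * precision * recall / (precision + recall)
  list(precision = precision, recall = recall, f1 = f1)
}
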