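#' Island caller configuration
#'
#' @param min_span report a run of GI-called genes only when its genomic
#'   span (last gene end minus first gene start) is strictly greater than
#'   this many bp (default 8000).
#' @param max_gap_genes number of intervening not-GI genes tolerated inside
#'   a run (default 0).
#' @return list of class `caller_config`.
#' @export
caller_config <- function(min_span = 8000L, max_gap_genes = 0L) {
  if (min_span < 0L) stop("validation error: min_span must be >= 0")
  if (max_gap_genes < 0L) stop("validation error: max_gap_genes must be >= 0")
  structure(list(min_span = as.integer(min_span),
                 max_gap_genes = as.integer(max_gap_genes)),
            class = "caller_config")
}

#' Tile a genome into non-overlapping windows
#'
#' Windows tile each contig left to right. A terminal partial window is kept
#' as its own window when it is at least half the window size; otherwise it
#' is merged into the previous window (a contig shorter than the window size
#' is always a single window).
#'
#' @param genome a [genome_annotation()].
#' @param window_size bp (default 10000).
#' @return data.frame with columns `contig_id`, `start`, `end` (0-based
#'   half-open).
#' @export
tile_windows <- function(genome, window_size = 10000L) {
  window_size <- as.integer(window_size)
  if (window_size < 1L) stop("validation error: window_size must be >= 1")
  out <- lapply(names(genome$contigs), function(ctg) {
    len <- genome$contigs[[ctg]]
    n_full <- len %/% window_size
    rem <- len - n_full * window_size
    if (n_full == 0L)
      return(data.frame(contig_id = ctg, start = 0L, end = len))
    starts <- (seq_len(n_full) - 1L) * window_size
    ends <- starts + window_size
    if (rem > 0L) {
      if (rem >= window_size / 2) {
        starts <- c(starts, n_full * window_size)
        ends <- c(ends, len)
      } else {
        ends[n_full] <- len
      }
    }
    data.frame(contig_id = ctg, start = as.integer(starts),
               end = as.integer(ends))
  })
  do.call(rbind, out)
}

#' Label windows by the intersection of two tools' predictions
#'
#' A window is labeled "GI" only when at least `min_frac` of its bases are
#' covered by islands of set A *and* at least `min_frac` by set B — training
#' labels come from fragments both predictors agree on.
#'
#' @param windows output of [tile_windows()].
#' @param setA,setB [prediction_set()]s over the same genome.
#' @param min_frac minimum per-set coverage fraction (default 0.5).
#' @return the `windows` data.frame with an added `label` column
#'   ("GI"/"not-GI") and coverage fractions `frac_a`, `frac_b`.
#' @export
label_windows <- function(windows, setA, setB, min_frac = 0.5) {
  frac <- function(set) {
    cov <- numeric(nrow(windows))
    for (ctg in unique(windows$contig_id)) {
      wi <- which(windows$contig_id == ctg)
      isl <- set$islands[set$islands$contig_id == ctg, , drop = FALSE]
      if (!nrow(isl)) next
      ir <- IRanges::reduce(IRanges::IRanges(isl$start + 1L, isl$end))
      wr <- IRanges::IRanges(windows$start[wi] + 1L, windows$end[wi])
      ov <- IRanges::findOverlaps(wr, ir)
      if (!length(ov)) next
      inter <- IRanges::pintersect(wr[S4Vectors::queryHits(ov)],
                                   ir[S4Vectors::subjectHits(ov)])
      covered <- tapply(IRanges::width(inter), S4Vectors::queryHits(ov), sum)
      cov[wi[as.integer(names(covered))]] <- covered
    }
    cov / (windows$end - windows$start)
  }
  windows$frac_a <- frac(setA)
  windows$frac_b <- frac(setB)
  windows$label <- ifelse(windows$frac_a >= min_frac &
                            windows$frac_b >= min_frac, "GI", "not-GI")
  windows
}

#' Balance a labeled example collection
#'
#' Downsamples the majority class uniformly at random (seeded) to the
#' minority class size and shuffles the result.
#'
#' @param examples data.frame with a `label` column, or a list of
#'   [labeled_example()]s.
#' @param seed integer.
#' @return same type as the input, with equal class counts.
#' @export
curate_balanced <- function(examples, seed) {
  labels <- if (is.data.frame(examples)) examples$label
            else vapply(examples, `[[`, character(1), "label")
  tab <- table(labels)
  if (length(tab) < 2L)
    stop("validation error: both classes must be present to balance ",
         "(have only: ", paste(names(tab), collapse = ", "), ")")
  n_min <- min(tab)
  keep <- withr::with_seed(seed, {
    idx <- unlist(lapply(names(tab), function(cl) {
      i <- which(labels == cl)
      if (length(i) > n_min) sort(sample(i, n_min)) else i
    }))
    sample(idx)
  })
  if (is.data.frame(examples)) examples[keep, , drop = FALSE]
  else examples[keep]
}

#' Merge per-gene calls into islands
#'
#' Maximal runs of GI-called genes (tolerating up to `max_gap_genes`
#' intervening not-GI genes) become candidate islands spanning from the
#' first to the last GI gene; only candidates whose span strictly exceeds
#' `min_span` are reported.
#'
#' @param preds a `gene_predictions` data.frame (from [classify_genes()] or
#'   equivalent), sorted by (contig, start).
#' @param config a [caller_config()].
#' @return an [island_table()] whose `gene_ids` hold the GI-called genes of
#'   each run.
#' @export
call_islands <- function(preds, config = caller_config()) {
  if (nrow(preds)) {
    ord <- order(preds$contig_id, preds$start)
    if (!identical(ord, seq_len(nrow(preds))))
      stop("validation error: predictions must be sorted by (contig, start)")
  }
  out <- island_table()
  for (ctg in unique(preds$contig_id)) {
    p <- preds[preds$contig_id == ctg, , drop = FALSE]
    gi <- which(p$call == "GI")
    if (!length(gi)) next
    run_id <- cumsum(c(1L, diff(gi) > config$max_gap_genes + 1L))
    for (r in split(gi, run_id)) {
      s <- p$start[r[[1]]]; e <- p$end[r[[length(r)]]]
      if (e - s > config$min_span) {
        out <- rbind(out, island_table(ctg, s, e,
                                       gene_ids = list(p$gene_id[r])))
      }
    }
  }
  class(out) <- c("island_table", "data.frame")
  out
}

#' Write per-gene predictions as TSV
#'
#' @param preds a `gene_predictions` data.frame.
#' @param path output path.
#' @export
write_gene_predictions <- function(preds, path) {
  utils::write.table(as.data.frame(preds), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read per-gene predictions from TSV
#'
#' @param path a file written by [write_gene_predictions()].
#' @return a `gene_predictions` data.frame.
#' @export
read_gene_predictions <- function(path) {
  if (!file.exists(path)) stop("I/O error: no such file: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "contig_id", "start", "end", "probability", "call")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("format error: missing column(s): ", paste(miss, collapse = ", "))
  class(df) <- c("gene_predictions", "data.frame")
  df
}
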