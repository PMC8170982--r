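#' Neighborhood construction parameters
#'
#' @param region_size window width in bp centered on the anchor gene's
#'   midpoint (default 10000).
#' @param max_rows maximum number of reference rows displayed (default 20).
#' @return list of class `neighborhood_config`.
#' @export
neighborhood_config <- function(region_size = 10000L, max_rows = 20L) {
  region_size <- as.integer(region_size); max_rows <- as.integer(max_rows)
  if (is.na(region_size) || region_size < 1000L)
    stop("validation error: region_size must be >= 1000")
  if (is.na(max_rows) || max_rows < 1L)
    stop("validation error: max_rows must be >= 1")
  structure(list(region_size = region_size, max_rows = max_rows),
            class = "neighborhood_config")
}

# genes of `genome` on `contig` whose interval intersects the window of
# width rs centered at `mid` (any 1-bp intersection)
.window_genes <- function(genome, contig, mid, rs) {
  g <- genome$genes
  lo <- mid - rs / 2; hi <- mid + rs / 2
  g[g$contig_id == contig & g$start < hi & g$end > lo, , drop = FALSE]
}

.make_row <- function(genome, anchor, distance, flip, rs) {
  mid <- (anchor$start + anchor$end) / 2
  g <- .window_genes(genome, anchor$contig_id, mid, rs)
  off <- g$start - mid
  strand <- g$strand
  if (flip) {
    off <- -off
    strand <- ifelse(strand == "+", "-", "+")
  }
  genes <- data.frame(
    gene_id = g$gene_id, family_id = g$family_id,
    annotation = g$annotation, strand = strand,
    offset = off, length = g$end - g$start,
    flipped = flip, stringsAsFactors = FALSE
  )
  genes <- genes[order(genes$offset, genes$gene_id), , drop = FALSE]
  rownames(genes) <- NULL
  list(genome_id = genome$genome_id, distance = distance,
       anchor_gene_id = anchor$gene_id, flipped = flip, genes = genes)
}

#' Build the compare-region neighborhood of a query gene
#'
#' For each reference genome containing at least one gene of the query's
#' protein family, an anchor gene is chosen (the copy whose midpoint is
#' closest to the contig midpoint, ties broken by lowest gene id) and all
#' genes intersecting the `region_size` window centered on the anchor
#' midpoint are collected with signed bp offsets relative to that midpoint.
#' Rows are sorted by ascending phylogenetic distance (ties broken by
#' genome id) and truncated to `max_rows`. When a reference anchor lies on
#' the strand opposite the query gene, the whole row is mirrored (offsets
#' negated, strands flipped) and flagged `flipped`, so pileups share the
#' query's orientation.
#'
#' @param query_gene_id id of the query gene in `query_genome`.
#' @param query_genome a [genome_annotation()].
#' @param reference_genomes list of `list(genome = <genome_annotation>,
#'   distance = <non-negative numeric>)`. May be empty.
#' @param config a [neighborhood_config()].
#' @return object of class `neighborhood` with elements `query` (the query
#'   gene row), `query_row`, `rows`, `region_size`.
#' @export
build_neighborhood <- function(query_gene_id, query_genome,
                               reference_genomes = list(),
                               config = neighborhood_config()) {
  g <- query_genome$genes
  qi <- which(g$gene_id == query_gene_id)
  if (!length(qi))
    stop("lookup error: unknown gene_id '", query_gene_id, "' in genome ",
         query_genome$genome_id)
  query <- g[qi[[1]], , drop = FALSE]
  class(query) <- "data.frame"
  rownames(query) <- NULL
  rs <- config$region_size
  dists <- vapply(reference_genomes, function(r) as.numeric(r$distance),
                  numeric(1))
  if (any(dists < 0)) stop("validation error: negative distance")
  rows <- list()
  for (r in reference_genomes) {
    anchor <- .pick_anchor(r$genome, query$family_id)
    if (is.null(anchor)) next
    flip <- anchor$strand != query$strand
    rows[[length(rows) + 1L]] <- .make_row(r$genome, anchor,
                                           as.numeric(r$distance), flip, rs)
  }
  if (length(rows)) {
    ord <- order(vapply(rows, `[[`, numeric(1), "distance"),
                 vapply(rows, `[[`, character(1), "genome_id"))
    rows <- rows[ord]
    if (length(rows) > config$max_rows) rows <- rows[seq_len(config$max_rows)]
  }
  structure(list(
    schema_version = 1L,
    neighborhood_id = paste0(query_genome$genome_id, ":", query$gene_id),
    query = query,
    query_row = .make_row(query_genome, query, 0, FALSE, rs),
    rows = rows,
    region_size = rs
  ), class = "neighborhood")
}

.pick_anchor <- function(genome, family_id) {
  g <- genome$genes
  cand <- g[g$family_id == family_id, , drop = FALSE]
  if (!nrow(cand)) return(NULL)
  cmid <- genome$contigs[cand$contig_id] / 2
  d <- abs((cand$start + cand$end) / 2 - cmid)
  cand <- cand[order(d, cand$gene_id), , drop = FALSE]
  cand[1L, , drop = FALSE]
}

#' @export
print.neighborhood <- function(x, ...) {
  cat(sprintf("<neighborhood> %s: %d reference row(s), region %d bp\n",
              x$neighborhood_id, length(x$rows), x$region_size))
  invisible(x)
}

#' Serialize / deserialize a neighborhood as JSON
#'
#' The JSON dialect carries a `schema_version` field and is lossless: all
#' gene fields, offsets (which may be half-integers), distances and flip
#' flags survive the round trip.
#'
#' @param n a `neighborhood`.
#' @return `neighborhood_to_json`: a JSON string; `json_to_neighborhood`:
#'   a `neighborhood`.
#' @export
neighborhood_to_json <- function(n) {
  stopifnot(inherits(n, "neighborhood"))
  jsonlite::toJSON(unclass(n), dataframe = "columns", digits = NA,
                   auto_unbox = TRUE, na = "null")
}

#' @rdname neighborhood_to_json
#' @param text JSON produced by `neighborhood_to_json`.
#' @export
json_to_neighborhood <- function(text) {
  x <- tryCatch(jsonlite::fromJSON(text, simplifyVector = FALSE),
                error = function(e)
                  stop("format error: malformed neighborhood JSON: ",
                       conditionMessage(e), call. = FALSE))
  required <- c("schema_version", "neighborhood_id", "query", "query_row",
                "rows", "region_size")
  miss <- setdiff(required, names(x))
  if (length(miss))
    stop("format error: missing key '", miss[[1]], "' in neighborhood JSON")
  # rebuild a data.frame from the column-oriented JSON object; `types` maps
  # column name -> coercion (NULL columns become typed empty vectors)
  df_from_cols <- function(obj, types) {
    cols <- lapply(names(types), function(nm)
      types[[nm]](unlist(obj[[nm]], use.names = FALSE)))
    names(cols) <- names(types)
    do.call(data.frame, c(cols, list(stringsAsFactors = FALSE)))
  }
  gene_types <- list(gene_id = as.character, family_id = as.character,
                     annotation = as.character, strand = as.character,
                     offset = as.numeric, length = as.integer,
                     flipped = as.logical)
  query_types <- list(gene_id = as.character, genome_id = as.character,
                      contig_id = as.character, start = as.integer,
                      end = as.integer, strand = as.character,
                      family_id = as.character, annotation = as.character)
  fix_row <- function(r) {
    for (k in c("genome_id", "distance", "anchor_gene_id", "flipped", "genes"))
      if (is.null(r[[k]]))
        stop("format error: missing key '", k, "' in neighborhood row")
    list(genome_id = as.character(r$genome_id),
         distance = as.numeric(r$distance),
         anchor_gene_id = as.character(r$anchor_gene_id),
         flipped = as.logical(r$flipped),
         genes = df_from_cols(r$genes, gene_types))
  }
  structure(list(
    schema_version = as.integer(x$schema_version),
    neighborhood_id = as.character(x$neighborhood_id),
    query = df_from_cols(x$query, query_types),
    query_row = fix_row(x$query_row),
    rows = lapply(x$rows, fix_row),
    region_size = as.integer(x$region_size)
  ), class = "neighborhood")
}
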