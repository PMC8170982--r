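#' Construct a gene feature table
#'
#' Genes are kept as a plain data frame with one row per gene. Coordinates
#' are 0-based half-open throughout the package; conversion to and from the
#' 1-based inclusive conventions of GFF3/GenBank happens only at file
#' boundaries.
#'
#' @param gene_id character, unique within a genome.
#' @param genome_id character scalar or vector.
#' @param contig_id character.
#' @param start,end integer bp, 0-based half-open; `start < end`.
#' @param strand "+" or "-".
#' @param family_id protein family identifier; `NA` means no assignment and
#'   is replaced by a singleton family equal to `gene_id`.
#' @param annotation free-text functional annotation (product).
#' @return data.frame with class `gene_table`.
#' @export
gene_table <- function(gene_id = character(), genome_id = character(),
                       contig_id = character(), start = integer(),
                       end = integer(), strand = character(),
                       family_id = NA_character_,
                       annotation = "") {
  n <- length(gene_id)
  rec <- function(x, what) {
    if (length(x) == n) return(x)
    if (length(x) == 1L) return(rep(x, n))
    stop("validation error: ", what, " must have length 1 or ", n)
  }
  df <- data.frame(
    gene_id = as.character(gene_id),
    genome_id = as.character(rec(genome_id, "genome_id")),
    contig_id = as.character(rec(contig_id, "contig_id")),
    start = as.integer(rec(start, "start")),
    end = as.integer(rec(end, "end")),
    strand = as.character(rec(strand, "strand")),
    family_id = as.character(rec(family_id, "family_id")),
    annotation = as.character(rec(annotation, "annotation")),
    stringsAsFactors = FALSE
  )
  if (nrow(df)) {
    df$family_id[is.na(df$family_id)] <- df$gene_id[is.na(df$family_id)]
    validate_gene_table(df)
  }
  class(df) <- c("gene_table", "data.frame")
  df
}

validate_gene_table <- function(df) {
  if (anyDuplicated(df$gene_id))
    stop("validation error: duplicate gene_id: ",
         paste(unique(df$gene_id[duplicated(df$gene_id)]), collapse = ", "))
  bad <- df$start < 0L | df$end <= df$start
  if (any(bad))
    stop("validation error: gene(s) with end <= start or negative start: ",
         paste(df$gene_id[bad], collapse = ", "))
  if (!all(df$strand %in% c("+", "-")))
    stop("validation error: strand must be '+' or '-'")
  invisible(df)
}

#' Construct a genome annotation
#'
#' @param genome_id character scalar.
#' @param contigs named integer vector of contig lengths (bp).
#' @param genes a [gene_table()] data frame; sorted by (contig_id, start).
#' @return object of class `genome_annotation`.
#' @export
genome_annotation <- function(genome_id, contigs, genes) {
  stopifnot(is.character(genome_id), length(genome_id) == 1L)
  contigs <- stats::setNames(as.integer(contigs), names(contigs))
  if (is.null(names(contigs)) || any(!nzchar(names(contigs))))
    stop("validation error: contigs must be a named vector of lengths")
  contigs <- contigs[order(names(contigs))]
  genes <- genes[order(genes$contig_id, genes$start, genes$gene_id), ,
                 drop = FALSE]
  rownames(genes) <- NULL
  validate_gene_table(genes)
  unknown <- setdiff(unique(genes$contig_id), names(contigs))
  if (length(unknown))
    stop("validation error: genes reference unknown contig(s): ",
         paste(unknown, collapse = ", "))
  over <- genes$end > contigs[genes$contig_id]
  if (any(over))
    stop("validation error: gene(s) extend past contig end: ",
         paste(genes$gene_id[over], collapse = ", "))
  structure(list(genome_id = genome_id, contigs = contigs, genes = genes),
            class = "genome_annotation")
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat(sprintf("<genome_annotation> %s: %d contig(s), %d gene(s)\n",
              x$genome_id, length(x$contigs), nrow(x$genes)))
  invisible(x)
}

#' Construct an island table
#'
#' Islands are genomic intervals (0-based half-open) optionally carrying the
#' ids of the genes they were called from.
#'
#' @param contig_id,start,end interval columns.
#' @param gene_ids list column of character vectors (may be empty).
#' @return data.frame with class `island_table`, sorted by (contig, start).
#' @export
island_table <- function(contig_id = character(), start = integer(),
                         end = integer(), gene_ids = NULL) {
  n <- length(contig_id)
  if (is.null(gene_ids)) gene_ids <- rep(list(character()), n)
  df <- data.frame(contig_id = as.character(contig_id),
                   start = as.integer(start), end = as.integer(end),
                   stringsAsFactors = FALSE)
  df$gene_ids <- gene_ids
  if (nrow(df)) {
    if (any(df$end - df$start < 1L))
      stop("validation error: island with non-positive span")
    df <- df[order(df$contig_id, df$start, df$end), , drop = FALSE]
    rownames(df) <- NULL
  }
  class(df) <- c("island_table", "data.frame")
  df
}

#' Construct a prediction set
#'
#' One tool's predicted islands over one genome.
#'
#' @param tool_name,genome_id character scalars.
#' @param islands an [island_table()].
#' @return object of class `prediction_set`.
#' @export
prediction_set <- function(tool_name, genome_id, islands) {
  stopifnot(is.character(tool_name), length(tool_name) == 1L)
  if (!inherits(islands, "island_table"))
    islands <- island_table(islands$contig_id, islands$start, islands$end,
                            islands$gene_ids)
  structure(list(tool_name = tool_name, genome_id = genome_id,
                 islands = islands),
            class = "prediction_set")
}

#' @export
print.prediction_set <- function(x, ...) {
  cat(sprintf("<prediction_set> %s on %s: %d island(s), %d bp\n",
              x$tool_name, x$genome_id, nrow(x$islands),
              sum(x$islands$end - x$islands$start)))
  invisible(x)
}

# islands of a prediction set (or an island_table itself) as an IRangesList
# keyed by contig
.islands_as_ranges <- function(x) {
  isl <- if (inherits(x, "prediction_set")) x$islands else x
  if (!nrow(isl))
    return(IRanges::IRanges())
  IRanges::IRanges(start = isl$start + 1L, end = isl$end)
}

.islands_by_contig <- function(x) {
  isl <- if (inherits(x, "prediction_set")) x$islands else x
  split(isl, isl$contig_id)
}
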