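#' Read an annotated genome (GFF3 or GenBank)
#'
#' Parses gene-level features (CDS, tRNA, gene) into a [genome_annotation()].
#' File coordinates (1-based inclusive in both formats) are converted to the
#' internal 0-based half-open convention, so a GFF3 feature spanning columns
#' 11..20 becomes `start = 10, end = 20` with length `end - start = 10`.
#'
#' @param path file path; `.gz` inputs are read transparently.
#' @param format "gff3" or "genbank"; default guessed from the extension.
#' @param genome_id identifier for the genome; defaults to the file name
#'   without extension.
#' @param family_attr name of the attribute/qualifier carrying the protein
#'   family assignment (default "family"). Genes lacking it are given a
#'   singleton family equal to their `gene_id`.
#' @return a [genome_annotation()].
#' @details Features with strand "." (GFF3) or no strand are treated as "+"
#'   with a warning, since the renderer needs a direction. When a file
#'   contains CDS or tRNA features, bare "gene" features duplicating their
#'   intervals are skipped to avoid double counting.
#' @export
read_genome_annotation <- function(path, format = c("auto", "gff3", "genbank"),
                                   genome_id = NULL, family_attr = "family") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("I/O error: no such file: ", path)
  if (format == "auto") {
    ext <- tolower(sub("\\.gz$", "", basename(path)))
    format <- if (grepl("\\.(gb|gbk|gbff|genbank)$", ext)) "genbank" else "gff3"
  }
  if (is.null(genome_id))
    genome_id <- sub("\\.gz$", "", tools::file_path_sans_ext(basename(path)))
  if (format == "gff3") {
    read_gff3_annotation(path, genome_id, family_attr)
  } else {
    read_genbank_annotation(path, genome_id, family_attr)
  }
}

read_gff3_annotation <- function(path, genome_id, family_attr) {
  gr <- tryCatch(rtracklayer::import(path, format = "gff3"),
                 error = function(e)
                   stop("format error: cannot parse GFF3 '", path, "': ",
                        conditionMessage(e), call. = FALSE))
  keep_types <- c("CDS", "tRNA")
  type <- as.character(gr$type)
  sel <- type %in% keep_types
  if (!any(sel)) sel <- type %in% "gene"
  gr <- gr[sel]
  if (!length(gr))
    stop("format error: no gene/CDS/tRNA features in ", path)
  strand <- as.character(GenomicRanges::strand(gr))
  if (any(strand == "*")) {
    warning("strand '.' treated as '+' for ", sum(strand == "*"),
            " feature(s) in ", path)
    strand[strand == "*"] <- "+"
  }
  mc <- S4Vectors::mcols(gr)
  pick <- function(keys) {
    out <- rep(NA_character_, length(gr))
    for (k in keys) {
      if (k %in% names(mc)) {
        v <- as.character(mc[[k]])
        out[is.na(out) & !is.na(v)] <- v[is.na(out) & !is.na(v)]
      }
    }
    out
  }
  ids <- pick(c("ID", "locus_tag", "Name"))
  if (anyNA(ids)) ids[is.na(ids)] <- sprintf("gene_%05d", which(is.na(ids)))
  fam <- pick(family_attr)
  ann <- pick(c("product", "Note", "description"))
  ann[is.na(ann)] <- ""
  genes <- gene_table(
    gene_id = ids, genome_id = genome_id,
    contig_id = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L, end = GenomicRanges::end(gr),
    strand = strand, family_id = fam, annotation = ann
  )
  sl <- GenomeInfoDb::seqlengths(gr)
  pragma <- .gff3_sequence_regions(path)
  hit <- !is.na(pragma[names(sl)])
  sl[hit] <- pragma[names(sl)[hit]]
  if (any(is.na(sl))) {
    mx <- tapply(genes$end, genes$contig_id, max)
    sl[is.na(sl)] <- mx[names(sl)[is.na(sl)]]
  }
  genome_annotation(genome_id, sl, genes)
}

# contig lengths from "##sequence-region <id> <start> <end>" directives
.gff3_sequence_regions <- function(path) {
  con <- gzfile(path, "rt")
  on.exit(close(con))
  out <- integer()
  repeat {
    l <- readLines(con, n = 1L, warn = FALSE)
    if (!length(l)) break
    if (startsWith(l, "##sequence-region")) {
      f <- strsplit(trimws(l), "\\s+")[[1]]
      if (length(f) >= 4L) out[f[[2]]] <- suppressWarnings(as.integer(f[[4]]))
    } else if (!startsWith(l, "#") && nzchar(l)) break
  }
  out
}

#' Write a genome annotation as GFF3
#'
#' Inverse of [read_genome_annotation()] for the GFF3 format: coordinates are
#' converted back to 1-based inclusive, `ID`, `product` and the family
#' attribute are emitted, and `##sequence-region` pragmas record contig
#' lengths so the round trip preserves them.
#'
#' @param genome a [genome_annotation()].
#' @param path output path.
#' @param family_attr attribute name for the family assignment.
#' @export
write_genome_annotation <- function(genome, path, family_attr = "family") {
  g <- genome$genes
  type <- ifelse(grepl("trna|transfer rna", tolower(g$annotation)),
                 "tRNA", "CDS")
  gr <- GenomicRanges::GRanges(
    seqnames = g$contig_id,
    ranges = IRanges::IRanges(start = g$start + 1L, end = g$end),
    strand = g$strand,
    seqlengths = genome$contigs[sort(names(genome$contigs))]
  )
  gr$source <- "islandscope"
  gr$type <- type
  gr$phase <- ifelse(type == "CDS", 0L, NA_integer_)
  gr$ID <- g$gene_id
  gr$product <- g$annotation
  S4Vectors::mcols(gr)[[family_attr]] <- g$family_id
  rtracklayer::export(gr, path, format = "gff3")
  # rtracklayer does not emit contig-length directives; add them so the
  # round trip preserves contig lengths
  lines <- readLines(path)
  pragma <- sprintf("##sequence-region %s 1 %d", names(genome$contigs),
                    genome$contigs)
  writeLines(c(lines[[1]], pragma, lines[-1]), path)
  invisible(path)
}

# --- GenBank flat-file feature-table parsing --------------------------------
# Minimal reader for annotation-only work: LOCUS length, CDS/tRNA/gene
# features with plain or complement() locations, and /product, /locus_tag
# and family qualifiers. join() locations take the outer span.

read_genbank_annotation <- function(path, genome_id, family_attr) {
  con <- gzfile(path, "rt")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  if (!length(lines) || !grepl("^LOCUS", lines[[1]]))
    stop("format error: line 1: missing LOCUS header in ", path)
  recs <- split(lines, cumsum(grepl("^LOCUS", lines)))
  genes <- list()
  contigs <- integer()
  for (rec in recs) {
    locus <- strsplit(trimws(rec[[1]]), "\\s+")[[1]]
    contig <- locus[[2]]
    clen <- suppressWarnings(as.integer(locus[[3]]))
    if (is.na(clen))
      stop("format error: LOCUS line lacks a length in ", path)
    contigs[contig] <- clen
    fstart <- grep("^FEATURES", rec)
    if (!length(fstart)) next
    fend <- grep("^(ORIGIN|CONTIG|//)", rec)
    fend <- if (length(fend)) min(fend[fend > fstart[[1]]]) - 1L else length(rec)
    block <- rec[(fstart[[1]] + 1L):fend]
    is_key <- grepl("^ {5}\\S", block)
    idx <- cumsum(is_key)
    for (feat in split(block, idx)) {
      head <- strsplit(trimws(feat[[1]]), "\\s+")[[1]]
      key <- head[[1]]
      if (!key %in% c("CDS", "tRNA", "gene")) next
      loc <- paste(head[-1], collapse = "")
      qual_lines <- trimws(feat[-1])
      # continuation lines of a multi-line location carry no leading "/"
      while (length(qual_lines) && !startsWith(qual_lines[[1]], "/")) {
        loc <- paste0(loc, qual_lines[[1]])
        qual_lines <- qual_lines[-1]
      }
      comp <- grepl("complement", loc)
      nums <- as.numeric(regmatches(loc, gregexpr("[0-9]+", loc))[[1]])
      if (length(nums) < 2)
        stop("format error: unparseable location '", loc, "' in ", path)
      start1 <- min(nums); end1 <- max(nums)
      if (end1 < start1)
        stop("validation error: feature end < start in ", path)
      quals <- parse_gb_qualifiers(qual_lines)
      genes[[length(genes) + 1L]] <- data.frame(
        type = key, contig_id = contig, start = start1 - 1, end = end1,
        strand = if (comp) "-" else "+",
        gene_id = quals[["locus_tag"]] %||% quals[["gene"]] %||% NA_character_,
        family_id = quals[[family_attr]] %||% NA_character_,
        annotation = quals[["product"]] %||% quals[["note"]] %||% "",
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(genes))
    stop("format error: no gene/CDS/tRNA features in ", path)
  df <- do.call(rbind, genes)
  if (any(df$type %in% c("CDS", "tRNA"))) {
    kept <- df[df$type != "gene", , drop = FALSE]
    dup <- paste(df$contig_id, df$start, df$end)
    df <- rbind(kept, df[df$type == "gene" &
                           !(dup %in% paste(kept$contig_id, kept$start,
                                            kept$end)), , drop = FALSE])
  }
  miss <- is.na(df$gene_id)
  if (any(miss)) df$gene_id[miss] <- sprintf("gene_%05d", which(miss))
  genes_tab <- gene_table(df$gene_id, genome_id, df$contig_id, df$start,
                          df$end, df$strand, df$family_id, df$annotation)
  genome_annotation(genome_id, contigs, genes_tab)
}

parse_gb_qualifiers <- function(lines) {
  if (!length(lines)) return(list())
  # re-join continuation lines onto their qualifier
  grp <- cumsum(startsWith(lines, "/"))
  lines <- vapply(split(lines, grp), paste, character(1), collapse = " ")
  out <- list()
  for (l in lines) {
    m <- regmatches(l, regexec('^/([A-Za-z_]+)=?"?([^"]*)"?$', l))[[1]]
    if (length(m) == 3) out[[m[[2]]]] <- m[[3]]
  }
  out
}

# --- BED-like prediction sets ----------------------------------------------

#' Read a tool's island predictions from a BED-like file
#'
#' Expects BED3+ (contig, 0-based start, exclusive end, optional name).
#' Islands are returned sorted by (contig, start); overlapping input
#' intervals are preserved as-is, not merged.
#'
#' @param path BED file (optionally gzipped).
#' @param tool_name name of the predicting tool.
#' @param genome_id genome the predictions refer to; defaults to the file
#'   name without extension.
#' @return a [prediction_set()].
#' @export
read_prediction_set <- function(path, tool_name, genome_id = NULL) {
  if (!file.exists(path)) stop("I/O error: no such file: ", path)
  if (is.null(genome_id))
    genome_id <- sub("\\.gz$", "", tools::file_path_sans_ext(basename(path)))
  con <- gzfile(path, "rt")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lines <- lines[!grepl("^(track|browser|#)", lines)]
  if (!length(lines))
    return(prediction_set(tool_name, genome_id, island_table()))
  fields <- strsplit(lines, "\t| +")
  if (any(lengths(fields) < 3))
    stop("format error: BED line with fewer than 3 columns in ", path)
  contig <- vapply(fields, `[[`, character(1), 1L)
  s <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 2L)))
  e <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 3L)))
  if (anyNA(s) || anyNA(e) || any(s != floor(s)) || any(e != floor(e)))
    stop("format error: non-integer coordinates in ", path, " (line ",
         which(is.na(s) | is.na(e) | s != floor(s) | e != floor(e))[1], ")")
  prediction_set(tool_name, genome_id, island_table(contig, s, e))
}

#' Write a prediction set as BED3+
#'
#' @param pred a [prediction_set()].
#' @param path output path. Empty sets produce an empty file.
#' @export
write_prediction_set <- function(pred, path) {
  isl <- pred$islands
  if (!nrow(isl)) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  gr <- GenomicRanges::GRanges(
    seqnames = isl$contig_id,
    ranges = IRanges::IRanges(start = isl$start + 1L, end = isl$end)
  )
  names(gr) <- sprintf("%s_island_%d", pred$tool_name, seq_along(gr))
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}
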