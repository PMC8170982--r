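#' Rendering parameters for neighborhood images
#'
#' The canvas defaults to 299x299 (the input size of the default pretrained
#' backbone) divided into `max_rows_drawn` equal horizontal bands: band 1 is
#' the query row, subsequent bands the distance-sorted reference rows. Genes
#' are drawn as filled arrows; color encodes function: red is reserved for
#' the query gene, green for mobility genes, yellow for tRNA genes, blue for
#' phage-related genes, and every other protein family receives a stable
#' palette color hashed from its family id.
#'
#' @param width,height canvas size in pixels (>= 64).
#' @param max_rows_drawn number of horizontal bands (default 21: query + 20
#'   references).
#' @param background RGB triple 0-255.
#' @param reserved named list of RGB triples for the query/mobility/tRNA/
#'   phage categories.
#' @param palette matrix (n x 3) of RGB triples, n >= 64, for ordinary
#'   families.
#' @param region_size optional expected neighborhood region size; when set,
#'   rendering a neighborhood with a different region size is an error.
#' @return list of class `render_config`.
#' @export
render_config <- function(width = 299L, height = 299L, max_rows_drawn = 21L,
                          background = c(255L, 255L, 255L),
                          reserved = list(query = c(255L, 0L, 0L),
                                          mobility = c(0L, 200L, 0L),
                                          tRNA = c(255L, 215L, 0L),
                                          phage = c(0L, 0L, 255L)),
                          palette = default_palette(),
                          region_size = NULL) {
  width <- as.integer(width); height <- as.integer(height)
  if (width < 64L || height < 64L)
    stop("validation error: width and height must be >= 64")
  cols <- do.call(rbind, lapply(reserved, as.integer))
  if (anyDuplicated(cols) ||
      any(colSums(abs(t(cols) - as.integer(background))) == 0))
    stop("validation error: reserved colors must be pairwise distinct and ",
         "distinct from background")
  if (nrow(palette) < 64L)
    stop("validation error: palette needs >= 64 colors")
  structure(list(width = width, height = height,
                 max_rows_drawn = as.integer(max_rows_drawn),
                 background = as.integer(background),
                 reserved = lapply(reserved, as.integer),
                 palette = palette, region_size = region_size),
            class = "render_config")
}

#' Default family palette
#'
#' 96+ perceptually spread RGB triples generated from the HCL wheel,
#' excluding the reserved query/mobility/tRNA/phage colors and white.
#'
#' @return integer matrix with 3 columns (R, G, B).
#' @export
default_palette <- function() {
  combos <- expand.grid(l = c(40, 60, 80), c = c(45, 75),
                        h = seq(0, 345, by = 15))
  cols <- t(grDevices::col2rgb(grDevices::hcl(combos$h, combos$c, combos$l)))
  cols <- unique(cols)
  reserved <- rbind(c(255, 0, 0), c(0, 200, 0), c(255, 215, 0), c(0, 0, 255),
                    c(255, 255, 255))
  keep <- !apply(cols, 1, function(x) any(colSums(abs(t(reserved) - x)) == 0))
  storage.mode(cols) <- "integer"
  unname(cols[keep, , drop = FALSE])
}

#' Functional category of a gene for rendering
#'
#' The query flag dominates; otherwise the first matching keyword class in
#' the precedence mobility > tRNA > phage decides; genes matching nothing
#' are "other" and take a palette color.
#'
#' @param gene a single gene row (anything with an `annotation` field) or a
#'   character annotation string.
#' @param is_query is this the query gene itself?
#' @param vocab a [keyword_vocabulary()].
#' @return one of "query", "mobility", "tRNA", "phage", "other".
#' @export
gene_category <- function(gene, is_query = FALSE,
                          vocab = keyword_vocabulary()) {
  if (is_query) return("query")
  ann <- tolower(if (is.character(gene)) gene else gene$annotation)
  if (.matches_any(ann, vocab$mobility_keywords)) return("mobility")
  if (.matches_any(ann, vocab$tRNA_keywords)) return("tRNA")
  if (.matches_any(ann, vocab$phage_keywords)) return("phage")
  "other"
}

.matches_any <- function(ann, keywords) {
  any(vapply(keywords, function(k) grepl(k, ann, fixed = TRUE), logical(1)))
}

#' Stable palette color for a protein family
#'
#' Same family id yields the same color in every image (a stable 31-bit
#' string hash modulo the palette size); consulted only for genes whose
#' category is "other".
#'
#' @param family_id character.
#' @param config a [render_config()].
#' @return integer RGB triple.
#' @export
family_color <- function(family_id, config = render_config()) {
  slot <- stable_hash(family_id) %% nrow(config$palette) + 1
  config$palette[slot, ]
}

#' Pixel rows of a horizontal band
#'
#' @param config a [render_config()].
#' @param i band index, 1-based (band 1 = query row).
#' @return integer vector `c(top, bottom)`, 1-based inclusive.
#' @export
band_bounds <- function(config, i) {
  nb <- config$max_rows_drawn
  c(floor((i - 1) * config$height / nb) + 1L, floor(i * config$height / nb))
}

#' Rasterize a neighborhood
#'
#' Deterministic, pure rendering: identical inputs give byte-identical pixel
#' arrays. The canvas is split into `max_rows_drawn` equal bands; band 1
#' holds the query row with the query gene's arrow horizontally centered
#' (its anchor midpoint maps to the canvas center), bands 2.. hold the
#' reference rows in distance order; bands beyond the available rows stay
#' background. The horizontal scale maps `region_size` bp to the full canvas
#' width, so a gene of length L bp spans round(L * width / region_size) +/- 1
#' pixels; arrows point right for "+" and left for "-" (after row flipping)
#' and are clipped at the canvas edges.
#'
#' @param n a [build_neighborhood()] result.
#' @param config a [render_config()].
#' @param vocab a [keyword_vocabulary()] for the reserved color categories.
#' @return object of class `rendered_image`: list with `pixels` (height x
#'   width x 3 integer array, 0-255) and `neighborhood_id`.
#' @export
render <- function(n, config = render_config(),
                   vocab = keyword_vocabulary()) {
  stopifnot(inherits(n, "neighborhood"))
  if (!is.null(config$region_size) && config$region_size != n$region_size)
    stop("validation error: neighborhood region_size (", n$region_size,
         ") does not match render_config region_size (", config$region_size,
         ")")
  h <- config$height; w <- config$width
  # colors are painted into an index matrix (0 = background) and expanded to
  # RGB once at the end, so overdraw never copies the pixel array
  cidx <- matrix(0L, h, w)
  color_tab <- list()
  rows <- c(list(n$query_row), n$rows)
  nb <- min(length(rows), config$max_rows_drawn)
  qid <- n$query$gene_id
  for (i in seq_len(nb)) {
    bb <- band_bounds(config, i)
    r <- rows[[i]]
    g <- r$genes
    if (!nrow(g)) next
    for (j in seq_len(nrow(g))) {
      flip <- g$flipped[[j]]
      s_off <- if (flip) g$offset[[j]] - g$length[[j]] else g$offset[[j]]
      e_off <- s_off + g$length[[j]]
      x0 <- round((s_off + n$region_size / 2) * w / n$region_size)
      x1 <- round((e_off + n$region_size / 2) * w / n$region_size)
      if (x1 <= 0 || x0 >= w) next
      x0 <- max(0L, x0); x1 <- min(w, x1)
      if (x1 <= x0) x1 <- min(w, x0 + 1L)
      cat_ <- gene_category(g$annotation[[j]],
                            is_query = (i == 1L && g$gene_id[[j]] == qid),
                            vocab = vocab)
      col <- if (cat_ == "other") family_color(g$family_id[[j]], config)
             else config$reserved[[cat_]]
      key <- paste(col, collapse = "_")
      k <- match(key, names(color_tab))
      if (is.na(k)) {
        color_tab[[key]] <- as.integer(col)
        k <- length(color_tab)
      }
      for (seg in .arrow_segments(bb[[1]], bb[[2]], x0 + 1L, x1,
                                  right = g$strand[[j]] == "+", h))
        cidx[seg$rows, seg$cols] <- k
    }
  }
  tab <- do.call(rbind, c(list(config$background), unname(color_tab)))
  img <- array(0L, c(h, w, 3L))
  for (k in 1:3) img[, , k] <- matrix(tab[cidx + 1L, k], h, w)
  structure(list(pixels = img, neighborhood_id = n$neighborhood_id),
            class = "rendered_image")
}

# Filled arrow glyph as a list of (rows, cols) paint segments: rectangle
# body of 60% band height plus a triangular head spanning min(25% of the
# arrow length, 8 px).
.arrow_segments <- function(top, bot, c0, c1, right, h) {
  bh <- bot - top + 1L
  cy <- (top + bot) %/% 2L
  body_half <- max(1L, floor(0.3 * bh))
  head_half <- max(body_half, floor(0.45 * bh))
  len <- c1 - c0 + 1L
  hl <- min(round(0.25 * len), 8L)
  segs <- list()
  body <- if (right) {
    if (c1 - hl >= c0) c0:(c1 - hl) else integer(0)
  } else {
    if (c0 + hl <= c1) (c0 + hl):c1 else integer(0)
  }
  if (length(body))
    segs[[1L]] <- list(rows = max(1L, cy - body_half):min(h, cy + body_half),
                       cols = body)
  if (hl >= 1L) {
    for (j in seq_len(hl)) {
      half <- max(1L, round(head_half * (hl - j + 1) / (hl + 1)))
      cc <- if (right) c1 - hl + j else c0 + hl - j
      segs[[length(segs) + 1L]] <-
        list(rows = max(1L, cy - half):min(h, cy + half), cols = cc)
    }
  }
  segs
}

#' Write a rendered image as PNG
#'
#' PNG only: the lossless format keeps re-reads byte-identical to the
#' rendered array.
#'
#' @param image a `rendered_image`.
#' @param path output path ending in .png.
#' @export
write_image_png <- function(image, path) {
  png::writePNG(image$pixels / 255, path)
  invisible(path)
}

#' Count non-background pixels per band
#'
#' Support for the pixel-count separability oracle and rendering tests: for
#' each horizontal band, the number of pixels differing from the background
#' color.
#'
#' @param image a `rendered_image`.
#' @param config the [render_config()] used to render it.
#' @return integer vector of length `max_rows_drawn`.
#' @export
ink_by_band <- function(image, config = render_config()) {
  px <- image$pixels
  bg <- config$background
  nonbg <- px[, , 1] != bg[[1]] | px[, , 2] != bg[[2]] | px[, , 3] != bg[[3]]
  vapply(seq_len(config$max_rows_drawn), function(i) {
    bb <- band_bounds(config, i)
    sum(nonbg[bb[[1]]:bb[[2]], ])
  }, integer(1))
}
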