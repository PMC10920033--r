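# Annotation-priority segmentation of reference-anchored blocks and
# 10-99-base window splitting.

CATEGORY_PRIORITY <- c(CDS = 1, five_prime_UTR = 2, three_prime_UTR = 3,
                       intron = 4, intergenic = 5)

# per-gene category intervals on the reference (0-based half-open):
# CDS and UTRs from the feature table, intron = span minus CDS/UTRs.
gene_category_intervals <- function(gene) {
  out <- list()
  add <- function(cat, start, end) {
    if (length(start))
      out[[length(out) + 1]] <<- data.frame(
        category = cat, start = start, end = end, gene_id = gene$gene_id,
        stringsAsFactors = FALSE)
  }
  f <- gene$features
  for (cat in c("CDS", "five_prime_UTR", "three_prime_UTR")) {
    sel <- f[f$category == cat, , drop = FALSE]
    add(cat, sel$start, sel$end)
  }
  exonic <- f[f$category %in% c("CDS", "five_prime_UTR", "three_prime_UTR"),
              , drop = FALSE]
  span <- IRanges::IRanges(gene$start + 1, gene$end)
  introns <- if (nrow(exonic))
    IRanges::setdiff(span, IRanges::reduce(
      IRanges::IRanges(exonic$start + 1, exonic$end)))
  else span
  add("intron", IRanges::start(introns) - 1, IRanges::end(introns))
  if (length(out)) do.call(rbind, out)
  else data.frame(category = character(), start = numeric(),
                  end = numeric(), gene_id = character(),
                  stringsAsFactors = FALSE)
}

#' Segment alignment blocks by annotation category
#'
#' Partitions each reference-anchored block at every annotation boundary
#' and labels each segment with the highest-priority category among
#' overlapping gene features, in the order CDS, 5'-UTR, 3'-UTR, intron,
#' intergenic. When several genes contribute the winning category all
#' their IDs are kept; when they contribute different categories the
#' higher-priority category and its gene(s) win. Positions outside every
#' gene span are intergenic with no gene ID.
#'
#' @param blocks List of reference-anchored `maf_block` (gap-free
#'   reference row, as from [merge_reference_anchored()]).
#' @param genes List of `gene_model`.
#' @return List of segments: `chrom`, `start`, `end`, `category`,
#'   `gene_ids` (character vector), `seqs` (taxa x columns matrix).
#' @export
assign_annotation <- function(blocks, genes) {
  by_chrom <- split(genes, vapply(genes, function(g) g$chrom, character(1)))
  cat_tabs <- lapply(by_chrom, function(gs)
    do.call(rbind, lapply(gs, gene_category_intervals)))
  segments <- list()
  for (b in blocks) {
    if (grepl("-", b$rows$text[1], fixed = TRUE))
      stop("contract error: reference row must be gap-free for segmentation")
    iv <- block_ref_interval(b)
    chrom <- sub("\\..*$", "", iv$chrom)
    tab <- cat_tabs[[chrom]]
    if (is.null(tab)) tab <- cat_tabs[[iv$chrom]]
    m <- block_matrix(b)
    if (is.null(tab) || !nrow(tab)) {
      segments[[length(segments) + 1]] <- list(
        chrom = iv$chrom, start = iv$start, end = iv$end,
        category = "intergenic", gene_ids = character(0), seqs = m)
      next
    }
    tab <- tab[tab$end > iv$start & tab$start < iv$end, , drop = FALSE]
    bnd <- sort(unique(c(iv$start, iv$end,
                         pmax(tab$start, iv$start), pmin(tab$end, iv$end))))
    prev <- NULL
    for (k in seq_len(length(bnd) - 1)) {
      s <- bnd[k]; e <- bnd[k + 1]
      hit <- tab[tab$start < e & tab$end > s, , drop = FALSE]
      if (nrow(hit)) {
        pr <- min(CATEGORY_PRIORITY[hit$category])
        cat <- names(CATEGORY_PRIORITY)[pr]
        gids <- sort(unique(hit$gene_id[CATEGORY_PRIORITY[hit$category] == pr]))
      } else {
        cat <- "intergenic"; gids <- character(0)
      }
      if (!is.null(prev) && prev$category == cat &&
          identical(prev$gene_ids, gids) && prev$end == s) {
        prev$end <- e
      } else {
        if (!is.null(prev)) segments[[length(segments) + 1]] <- prev
        prev <- list(chrom = iv$chrom, start = s, end = e, category = cat,
                     gene_ids = gids, seqs = NULL)
      }
    }
    if (!is.null(prev)) segments[[length(segments) + 1]] <- prev
    # attach alignment slices
    n <- length(segments)
    for (k in seq_len(n)) {
      sg <- segments[[k]]
      if (is.null(sg$seqs) && sg$chrom == iv$chrom &&
          sg$start >= iv$start && sg$end <= iv$end) {
        cols <- (sg$start - iv$start + 1):(sg$end - iv$start)
        segments[[k]]$seqs <- m[, cols, drop = FALSE]
      }
    }
  }
  segments
}

window_lengths_for <- function(len, every = 60, min_len = 10,
                               min_tail = 20) {
  if (len < min_len) return(integer(0))
  if (len < 100) return(len)
  k <- len %/% every
  r <- len %% every
  if (r == 0) rep(every, k)
  else if (r < min_tail) c(rep(every, k - 1), every + r)
  else c(rep(every, k), r)
}

#' Split annotated segments into 10-99-base windows
#'
#' Segments shorter than 10 reference bases are dropped; segments of
#' 10-99 bases become one window unchanged; longer segments are cut every
#' 60 bases from the 5' (reference-forward) end, except that a final
#' fragment shorter than 20 bases is merged into the preceding window.
#' All emitted windows span 10-99 reference bases.
#'
#' @param segments Output of [assign_annotation()].
#' @param every,min_len,min_tail Splitting parameters (60, 10, 20).
#' @return List of windows: segment fields plus `window_id` and
#'   `testable` (at least two species with data).
#' @export
split_windows <- function(segments, every = 60, min_len = 10,
                          min_tail = 20) {
  windows <- list()
  dropped <- 0L
  for (sg in segments) {
    len <- sg$end - sg$start
    lens <- window_lengths_for(len, every, min_len, min_tail)
    if (!length(lens)) { dropped <- dropped + 1L; next }
    off <- 0
    for (wl in lens) {
      s <- sg$start + off
      e <- s + wl
      seqs <- sg$seqs[, (off + 1):(off + wl), drop = FALSE]
      ndata <- rowSums(matrix(seqs %in% BASES, nrow(seqs)))
      testable <- sum(ndata > 0) >= 2
      windows[[length(windows) + 1]] <- list(
        window_id = sprintf("%s:%d-%d", sg$chrom, s, e),
        chrom = sg$chrom, start = s, end = e, category = sg$category,
        gene_ids = sg$gene_ids, seqs = seqs, testable = testable)
      off <- off + wl
    }
  }
  if (dropped > 0)
    message(dropped, " segment(s) shorter than ", min_len, " bases dropped")
  windows
}

#' Summarise windows as a data frame (BED-like)
#'
#' @param windows Output of [split_windows()].
#' @return `data.frame` with chrom, start, end, window_id, category,
#'   gene_ids (comma-collapsed), testable.
#' @export
windows_table <- function(windows) {
  data.frame(
    chrom = vapply(windows, `[[`, character(1), "chrom"),
    start = vapply(windows, `[[`, numeric(1), "start"),
    end = vapply(windows, `[[`, numeric(1), "end"),
    window_id = vapply(windows, `[[`, character(1), "window_id"),
    category = vapply(windows, `[[`, character(1), "category"),
    gene_ids = vapply(windows, function(w)
      paste(w$gene_ids, collapse = ","), character(1)),
    testable = vapply(windows, `[[`, logical(1), "testable"),
    stringsAsFactors = FALSE)
}
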