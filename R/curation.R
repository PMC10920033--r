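# Alignment curation: ambiguous-base trimming, reference-overlap
# resolution, reference-anchored merging and species-count filtering.

#' Curation parameters
#'
#' @param n_run_fraction_threshold An internal N run longer than this
#'   fraction of the ungapped length of the row containing it causes a
#'   split (default 0.5, i.e. runs occupying >50% of the sequence).
#' @param min_species Minimum species per multiple-alignment block
#'   (default 7 of 8: one missing genome tolerated).
#' @param total_species Number of species in the study set.
#' @return A `curation_config` list.
#' @export
curation_config <- function(n_run_fraction_threshold = 0.5,
                            min_species = 7L, total_species = 8L) {
  stopifnot(n_run_fraction_threshold > 0, n_run_fraction_threshold <= 1,
            min_species >= 1, min_species <= total_species)
  structure(list(n_run_fraction_threshold = n_run_fraction_threshold,
                 min_species = as.integer(min_species),
                 total_species = as.integer(total_species)),
            class = "curation_config")
}

# contiguous column range [from, to] of a block as a new block with
# recomputed strand-relative starts and sizes
subset_block_range <- function(block, from, to) {
  rows <- block$rows
  texts <- strsplit(rows$text, "")
  newrows <- rows
  for (i in seq_len(nrow(rows))) {
    chars <- texts[[i]]
    before <- if (from > 1) sum(chars[seq_len(from - 1)] != "-") else 0
    seg <- chars[from:to]
    newrows$start[i] <- rows$start[i] + before
    newrows$size[i] <- sum(seg != "-")
    newrows$text[i] <- paste(seg, collapse = "")
  }
  maf_block(newrows)
}

maximal_runs <- function(logical_vec) {
  r <- rle(logical_vec)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  cbind(start = starts[r$values], end = ends[r$values])
}

#' Trim edge Ns and split at long internal N runs
#'
#' For a pairwise block: leading/trailing columns in which either row
#' carries an N are removed; an internal maximal N run whose length
#' exceeds `n_run_fraction_threshold` times the ungapped length of the row
#' containing it causes the block to be split at the run, with the run's
#' columns discarded. Blocks emptied by trimming are dropped.
#'
#' @param block Pairwise `maf_block` (2 rows).
#' @param cfg A `curation_config`.
#' @return List of `maf_block` (possibly empty).
#' @export
trim_and_split_n <- function(block, cfg = curation_config()) {
  if (nrow(block$rows) != 2)
    stop("contract error: trim_and_split_n expects a pairwise block")
  m <- block_matrix(block)
  nc <- ncol(m)
  has_n <- m[1, ] == "N" | m[2, ] == "N"
  lo <- 1
  while (lo <= nc && has_n[lo]) lo <- lo + 1
  hi <- nc
  while (hi >= lo && has_n[hi]) hi <- hi - 1
  if (lo > hi) return(list())
  ungapped <- c(sum(m[1, ] != "-"), sum(m[2, ] != "-"))
  # qualifying internal runs (in trimmed range), merged across rows
  cut <- rep(FALSE, nc)
  for (r in 1:2) {
    is_n <- m[r, ] == "N"
    is_n[seq_len(nc) < lo | seq_len(nc) > hi] <- FALSE
    runs <- maximal_runs(is_n)
    if (nrow(runs)) {
      len <- runs[, 2] - runs[, 1] + 1
      for (k in which(len > cfg$n_run_fraction_threshold * ungapped[r]))
        cut[runs[k, 1]:runs[k, 2]] <- TRUE
    }
  }
  keep <- rep(FALSE, nc)
  keep[lo:hi] <- TRUE
  keep <- keep & !cut
  segs <- maximal_runs(keep)
  out <- list()
  for (k in seq_len(nrow(segs))) {
    b <- subset_block_range(block, segs[k, 1], segs[k, 2])
    if (b$ncols > 0 && all(b$rows$size > 0)) out[[length(out) + 1]] <- b
  }
  out
}

# reference positions (0-based) of each column; NA for reference-gap
# (insertion) columns
block_ref_positions <- function(block) {
  chars <- strsplit(block$rows$text[1], "")[[1]]
  pos <- rep(NA_real_, length(chars))
  base <- chars != "-"
  pos[base] <- block$rows$start[1] + cumsum(base)[base] - 1
  pos
}

#' Resolve overlapping pairwise blocks on the reference
#'
#' When several blocks of one target species align the same reference
#' interval, the longer alignment (more columns) is preferred: blocks are
#' accepted in order of decreasing column count (ties broken by smaller
#' reference start) and later blocks have any columns overlapping
#' already-claimed reference positions removed, splitting them where
#' necessary. Resulting reference intervals are pairwise disjoint.
#'
#' @param blocks List of pairwise `maf_block` sharing one target species.
#' @return List of `maf_block` with disjoint reference coverage.
#' @export
resolve_reference_overlaps <- function(blocks) {
  if (!length(blocks)) return(blocks)
  ord <- order(-vapply(blocks, function(b) b$ncols, numeric(1)),
               vapply(blocks, function(b) b$rows$start[1], numeric(1)))
  claimed <- new.env(parent = emptyenv())
  out <- list()
  for (b in blocks[ord]) {
    pos <- block_ref_positions(b)
    keep <- rep(TRUE, length(pos))
    isbase <- !is.na(pos)
    keep[isbase] <- !vapply(as.character(pos[isbase]),
                            function(k) isTRUE(claimed[[k]]), logical(1))
    # insertion columns travel with the nearest preceding reference base
    last_keep <- TRUE
    for (i in seq_along(pos)) {
      if (is.na(pos[i])) keep[i] <- last_keep else last_keep <- keep[i]
    }
    segs <- maximal_runs(keep)
    for (k in seq_len(nrow(segs))) {
      nb <- subset_block_range(b, segs[k, 1], segs[k, 2])
      if (nb$rows$size[1] > 0) out[[length(out) + 1]] <- nb
    }
    for (p in pos[isbase & keep]) claimed[[as.character(p)]] <- TRUE
  }
  ref_starts <- vapply(out, function(b) b$rows$start[1], numeric(1))
  out[order(ref_starts)]
}

#' Merge per-species pairwise blocks into reference-anchored multiple
#' alignments
#'
#' Simplified reference-anchored merge: for every maximal reference
#' interval covered by a constant set of species, one multi-row block is
#' emitted whose columns are the reference positions (the reference row is
#' gap-free); target-insertion columns (reference gaps) are dropped and
#' absent species omitted. Non-reference row coordinates are not
#' propagated (downstream work is reference-anchored); those rows carry
#' `start = 0`.
#'
#' @param per_species Named list (species -> list of pairwise blocks with
#'   disjoint reference coverage, reference row first).
#' @param ref_name Reference species name.
#' @return List of multi-species `maf_block` sorted by reference start.
#' @export
merge_reference_anchored <- function(per_species, ref_name) {
  refbase <- new.env(parent = emptyenv())   # pos -> reference base
  refsrc <- NULL; refsize <- NULL
  cover <- list()                           # species -> pos -> target base
  for (sp in names(per_species)) {
    spmap <- new.env(parent = emptyenv())
    for (b in per_species[[sp]]) {
      if (is.null(refsrc)) { refsrc <- b$rows$src[1]; refsize <- b$rows$srcSize[1] }
      pos <- block_ref_positions(b)
      m <- block_matrix(b)
      isbase <- !is.na(pos)
      pchar <- as.character(pos[isbase])
      rb <- m[1, isbase]
      tb <- m[2, isbase]
      for (i in seq_along(pchar)) {
        prev <- refbase[[pchar[i]]]
        if (!is.null(prev) && prev != rb[i])
          stop("data error: conflicting reference bases at position ",
               pchar[i])
        refbase[[pchar[i]]] <- rb[i]
        spmap[[pchar[i]]] <- tb[i]
      }
    }
    cover[[sp]] <- spmap
  }
  all_pos <- sort(as.numeric(ls(refbase)))
  if (!length(all_pos)) return(list())
  species <- names(per_species)
  cov_mat <- vapply(species, function(sp)
    vapply(as.character(all_pos), function(p) !is.null(cover[[sp]][[p]]),
           logical(1)), logical(length(all_pos)))
  if (length(all_pos) == 1L) cov_mat <- matrix(cov_mat, nrow = 1)
  key <- apply(cov_mat, 1, function(z) paste(as.integer(z), collapse = ""))
  brk <- c(TRUE, diff(all_pos) != 1 | key[-1] != key[-length(key)])
  grp <- cumsum(brk)
  out <- list()
  for (g in unique(grp)) {
    idx <- which(grp == g)
    pos <- all_pos[idx]
    pc <- as.character(pos)
    sp_in <- species[cov_mat[idx[1], ]]
    if (!length(sp_in)) next
    ref_text <- paste(vapply(pc, function(p) refbase[[p]], character(1)),
                      collapse = "")
    rows <- data.frame(
      species = ref_name, src = refsrc, start = pos[1],
      size = length(pos), srcSize = refsize, strand = "+",
      text = ref_text, stringsAsFactors = FALSE)
    for (sp in sp_in) {
      txt <- paste(vapply(pc, function(p) cover[[sp]][[p]], character(1)),
                   collapse = "")
      rows <- rbind(rows, data.frame(
        species = sp, src = sp, start = 0,
        size = nchar(gsub("-", "", txt, fixed = TRUE)),
        srcSize = refsize, strand = "+", text = txt,
        stringsAsFactors = FALSE))
    }
    out[[length(out) + 1]] <- maf_block(rows)
  }
  out
}

#' Filter multiple-alignment blocks by species count
#'
#' Keeps blocks carrying at least `min_species` species (reference
#' included), preserving input order.
#'
#' @param blocks List of `maf_block`.
#' @param cfg A `curation_config`.
#' @return Filtered list.
#' @export
filter_species_count <- function(blocks, cfg = curation_config()) {
  Filter(function(b) nrow(b$rows) >= cfg$min_species, blocks)
}
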