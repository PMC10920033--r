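#' @importFrom utils read.table write.table count.fields
NULL

# ---- genomic intervals -----------------------------------------------------
# Internal convention everywhere: 0-based, half-open, reference forward
# strand. Conversions to/from 1-based formats happen only at I/O boundaries.

#' Construct a genomic interval (0-based, half-open)
#'
#' @param chrom Sequence name.
#' @param start 0-based inclusive start.
#' @param end Exclusive end; must satisfy `0 <= start < end`.
#' @param strand `"+"` or `"-"`.
#' @return A `genomic_interval` list.
#' @export
genomic_interval <- function(chrom, start, end, strand = "+") {
  stopifnot(start >= 0, start < end, strand %in% c("+", "-"))
  structure(list(chrom = as.character(chrom), start = as.numeric(start),
                 end = as.numeric(end), strand = strand),
            class = "genomic_interval")
}

# ---- MAF blocks ------------------------------------------------------------

ALPHABET <- c("A", "C", "G", "T", "N", "-")

sanitize_text <- function(text) {
  text <- toupper(text)
  chars <- unique(strsplit(paste(text, collapse = ""), "")[[1]])
  odd <- setdiff(chars, ALPHABET)
  if (length(odd)) {
    warning("mapping non-standard base code(s) to N: ",
            paste(odd, collapse = ","))
    for (ch in odd) text <- gsub(ch, "N", text, fixed = TRUE)
  }
  text
}

#' Construct an alignment block
#'
#' One MAF block: reference row first, one gapped row per species. Row
#' fields follow MAF: `start` is strand-relative in the source sequence,
#' `size` the ungapped length.
#'
#' @param rows `data.frame` with columns species, src, start, size,
#'   srcSize, strand, text.
#' @param validate Check invariants (row widths equal, size matches
#'   non-gap count, one row per species, reference on + strand).
#' @return A `maf_block` object.
#' @export
maf_block <- function(rows, validate = TRUE) {
  rows <- as.data.frame(rows, stringsAsFactors = FALSE)
  if (validate) {
    nc <- nchar(rows$text)
    if (length(unique(nc)) != 1)
      stop("format error: row text lengths differ within block")
    ungapped <- nchar(gsub("-", "", rows$text, fixed = TRUE))
    if (any(ungapped != rows$size))
      stop("format error: row size does not match non-gap character count")
    if (any(rows$start + rows$size > rows$srcSize))
      stop("format error: row extends past source sequence")
    if (anyDuplicated(rows$species))
      stop("format error: duplicate species within block")
    if (rows$strand[1] != "+")
      stop("format error: reference row must be on + strand")
  }
  structure(list(rows = rows, ncols = nchar(rows$text[1])),
            class = "maf_block")
}

block_ref_interval <- function(block) {
  r <- block$rows[1, ]
  genomic_interval(r$src, r$start, r$start + r$size)
}

# species x ncols character matrix of a block
block_matrix <- function(block) {
  m <- do.call(rbind, strsplit(block$rows$text, ""))
  rownames(m) <- block$rows$species
  m
}

#' Read a MAF file
#'
#' Parses UCSC-dialect MAF ("a"/"s" lines). Sequence text is uppercased;
#' IUPAC codes outside A,C,G,T,N,- are mapped to N with a warning.
#' Negative-strand coordinates are kept strand-relative as in the format.
#'
#' @param path MAF file.
#' @return List of `maf_block`.
#' @export
read_maf <- function(path) {
  lines <- readLines(path)
  blocks <- list()
  cur <- NULL
  flush <- function(cur) {
    if (is.null(cur) || !nrow(cur)) return(NULL)
    maf_block(cur)
  }
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln) || startsWith(ln, "#")) {
      if (!is.null(cur)) { blocks[[length(blocks) + 1]] <- flush(cur); cur <- NULL }
      next
    }
    if (startsWith(ln, "a")) {
      if (!is.null(cur)) blocks[[length(blocks) + 1]] <- flush(cur)
      cur <- data.frame(species = character(), src = character(),
                        start = numeric(), size = numeric(),
                        srcSize = numeric(), strand = character(),
                        text = character(), stringsAsFactors = FALSE)
    } else if (startsWith(ln, "s")) {
      if (is.null(cur)) stop("parse error at line ", i, ": 's' outside block")
      f <- strsplit(ln, "[ \t]+")[[1]]
      if (length(f) != 7)
        stop("parse error at line ", i, ": expected 7 fields on 's' line")
      src <- f[2]
      cur <- rbind(cur, data.frame(
        species = sub("\\..*$", "", src), src = src,
        start = as.numeric(f[3]), size = as.numeric(f[4]),
        srcSize = as.numeric(f[6]), strand = f[5],
        text = sanitize_text(f[7]), stringsAsFactors = FALSE))
    }
    # other line types (i, e, q) ignored
  }
  if (!is.null(cur)) blocks[[length(blocks) + 1]] <- flush(cur)
  Filter(Negate(is.null), blocks)
}

#' Write alignment blocks as MAF
#'
#' @param blocks List of `maf_block`.
#' @param path Output file.
#' @export
write_maf <- function(blocks, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##maf version=1", con)
  for (b in blocks) {
    writeLines("a", con)
    r <- b$rows
    writeLines(sprintf("s %s %d %d %s %d %s", r$src, as.integer(r$start),
                       as.integer(r$size), r$strand, as.integer(r$srcSize),
                       r$text), con)
    writeLines("", con)
  }
  invisible(path)
}

# ---- gene models -----------------------------------------------------------

BIOTYPES <- c("protein_coding", "snRNA", "lncRNA", "miRNA", "rRNA",
              "snoRNA", "scRNA", "other")
NCRNA_BIOTYPES <- c("snRNA", "lncRNA", "miRNA", "rRNA", "snoRNA", "scRNA")

#' Construct a gene model
#'
#' @param gene_id Stable identifier.
#' @param chrom,start,end,strand Gene span (0-based half-open).
#' @param biotype One of protein_coding, snRNA, lncRNA, miRNA, rRNA,
#'   snoRNA, scRNA, other.
#' @param features `data.frame(category, start, end)` with category in
#'   CDS, five_prime_UTR, three_prime_UTR, exon; must lie within the span.
#' @param name Optional display name.
#' @return A `gene_model` object.
#' @export
gene_model <- function(gene_id, chrom, start, end, strand = "+",
                       biotype = "protein_coding",
                       features = NULL, name = gene_id) {
  stopifnot(start >= 0, start < end, strand %in% c("+", "-"))
  if (!biotype %in% BIOTYPES) biotype <- "other"
  if (is.null(features))
    features <- data.frame(category = character(), start = numeric(),
                           end = numeric(), stringsAsFactors = FALSE)
  if (nrow(features)) {
    ok <- features$start >= start & features$end <= end &
      features$start < features$end
    if (!all(ok))
      stop("invariant error: feature outside gene span or empty (gene ",
           gene_id, ")")
  }
  structure(list(gene_id = gene_id, name = name, biotype = biotype,
                 chrom = as.character(chrom), start = as.numeric(start),
                 end = as.numeric(end), strand = strand,
                 features = features),
            class = "gene_model")
}

#' Read gene models from GFF3
#'
#' Parses GFF3 via `rtracklayer`, converting 1-based closed coordinates to
#' the internal 0-based half-open convention. CDS/UTR/exon records are
#' attached to genes through their (possibly transcript-level) Parent
#' chain; records with an unresolvable Parent are skipped with a warning.
#'
#' @param path GFF3 file.
#' @return List of `gene_model`.
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr, stringsAsFactors = FALSE)
  df$start0 <- df$start - 1          # to 0-based half-open
  df$end0 <- df$end
  ids <- if ("ID" %in% names(df)) as.character(df$ID) else rep(NA, nrow(df))
  parents <- if ("Parent" %in% names(df))
    vapply(df$Parent, function(p) if (length(p)) as.character(p[1]) else NA_character_,
           character(1))
  else rep(NA_character_, nrow(df))
  type <- as.character(df$type)
  is_gene <- type %in% c("gene", "ncRNA_gene", "pseudogene")
  gene_rows <- which(is_gene)
  if (!length(gene_rows)) return(list())
  gene_of <- setNames(ids[gene_rows], ids[gene_rows])
  # resolve transcript -> gene
  tx_rows <- which(!is_gene & !is.na(parents) & parents %in% ids[gene_rows])
  for (i in tx_rows) if (!is.na(ids[i])) gene_of[ids[i]] <- parents[i]
  models <- list()
  for (gi in gene_rows) {
    gid <- ids[gi]
    bt <- if ("gene_biotype" %in% names(df) && !is.na(df$gene_biotype[gi]))
      as.character(df$gene_biotype[gi])
    else if ("biotype" %in% names(df) && !is.na(df$biotype[gi]))
      as.character(df$biotype[gi])
    else if (type[gi] == "gene") "protein_coding" else "other"
    nm <- if ("Name" %in% names(df) && !is.na(df$Name[gi]))
      as.character(df$Name[gi]) else gid
    feat_rows <- which(type %in% c("CDS", "five_prime_UTR", "three_prime_UTR",
                                   "exon") &
                         !is.na(parents) &
                         parents %in% names(gene_of)[gene_of == gid])
    feats <- data.frame(category = type[feat_rows],
                        start = df$start0[feat_rows],
                        end = df$end0[feat_rows], stringsAsFactors = FALSE)
    models[[gid]] <- gene_model(gid, as.character(df$seqnames[gi]),
                                df$start0[gi], df$end0[gi],
                                as.character(df$strand[gi]), bt, feats, nm)
  }
  orphan <- which(!is_gene &
                    type %in% c("CDS", "five_prime_UTR", "three_prime_UTR",
                                "exon", "mRNA", "transcript") &
                    (is.na(parents) | !(parents %in% ids)))
  if (length(orphan))
    warning(length(orphan), " feature record(s) with unresolvable Parent skipped")
  unname(models)
}

# ---- Newick ----------------------------------------------------------------

#' Read a rooted tree from a Newick string or file
#'
#' @param text Newick string (or a path when `is_file = TRUE`).
#' @param is_file Treat `text` as a file path.
#' @return An `ape` `phylo` object.
#' @export
read_newick <- function(text, is_file = FALSE) {
  tr <- tryCatch(
    if (is_file) ape::read.tree(text) else ape::read.tree(text = text),
    error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tr) || !inherits(tr, "phylo"))
    stop("parse error: invalid Newick string")
  tr
}

#' Write a tree as Newick
#' @param tree A `phylo`.
#' @param path Output file.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

# ---- BED -------------------------------------------------------------------

#' Write element calls as BED6
#'
#' 0-based half-open, tab-separated: chrom, start, end, name, score,
#' strand.
#'
#' @param calls `data.frame` with columns chrom, start, end, name, score,
#'   strand (missing name/score/strand filled with ".", 0, "+").
#' @param path Output file.
#' @export
write_bed <- function(calls, path) {
  calls <- as.data.frame(calls, stringsAsFactors = FALSE)
  if (!nrow(calls)) { writeLines(character(), path); return(invisible(path)) }
  if (is.null(calls$name)) calls$name <- "."
  if (is.null(calls$score)) calls$score <- 0
  if (is.null(calls$strand)) calls$strand <- "+"
  stopifnot(all(calls$start >= 0), all(calls$start < calls$end))
  out <- sprintf("%s\t%d\t%d\t%s\t%s\t%s", calls$chrom,
                 as.integer(calls$start), as.integer(calls$end),
                 as.character(calls$name), format(calls$score, trim = TRUE),
                 calls$strand)
  writeLines(out, path)
  invisible(path)
}

#' Read a BED6 file
#' @param path BED file.
#' @return `data.frame(chrom, start, end, name, score, strand)`.
#' @export
read_bed <- function(path) {
  if (file.size(path) == 0)
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), name = character(),
                      score = numeric(), strand = character(),
                      stringsAsFactors = FALSE))
  df <- read.table(path, sep = "\t", stringsAsFactors = FALSE,
                   col.names = c("chrom", "start", "end", "name", "score",
                                 "strand")[1:max(count.fields(path, sep = "\t"))])
  df
}

# ---- FASTA -----------------------------------------------------------------

#' Read a FASTA file as a named character vector
#' @param path FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  s <- Biostrings::readBStringSet(path)
  setNames(as.character(s), names(s))
}

#' Write named sequences as FASTA
#' @param seqs Named character vector.
#' @param path Output file.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path)
  invisible(path)
}
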