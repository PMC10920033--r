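# Small fixture builders shared across test files.

mk_row <- function(species, src, start, text, srcSize = 10000,
                   strand = "+") {
  data.frame(species = species, src = src, start = start,
             size = nchar(gsub("-", "", text)), srcSize = srcSize,
             strand = strand, text = text, stringsAsFactors = FALSE)
}

mk_block <- function(...) maf_block(do.call(rbind, list(...)))

# pairwise block: reference row first
mk_pair <- function(sp, ref_start, ref_text, other_text,
                    ref = "refsp", chrom = "chr1")
  mk_block(mk_row(ref, chrom, ref_start, ref_text),
           mk_row(sp, sp, 0, other_text))

mk_gene <- function(id, start, end, features = NULL, strand = "+",
                    biotype = "protein_coding", chrom = "chr1")
  gene_model(id, chrom, start, end, strand, biotype, features)

feat <- function(category, start, end)
  data.frame(category = category, start = start, end = end,
             stringsAsFactors = FALSE)
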