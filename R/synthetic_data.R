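# Synthetic desk-scale datasets: an eight-taxon Anolis-like alignment with
# implanted conserved/accelerated regions, matching gene annotation
# (including ncRNA genes), codon data with controllable usage bias, and
# curation artefacts, plus ground-truth tables.

#' Default eight-taxon study tree
#'
#' Seven ingroup anole lineages (the reference, three trunk-crown and
#' three trunk-ground species) plus an outgroup, with the internal node
#' ancestral to the three hot-open trunk-crown species labelled
#' `TC_open`. Branch lengths default to 0.05 expected substitutions/site
#' and can be overridden per branch.
#'
#' @param branch_length Default length for every branch.
#' @param overrides Named numeric vector of per-branch lengths (names as
#'   in [branch_names()]).
#' @return Rooted `phylo` with 8 tips.
#' @export
default_tree <- function(branch_length = 0.05, overrides = NULL) {
  nw <- paste0(
    "(((((A_porcatus:%L,A_allisoni:%L):%L,A_carolinensis:%L)TC_open:%L,",
    "A_isolepis:%L):%L,((A_homolechis:%L,A_allogus:%L):%L,",
    "A_sagrei:%L):%L):%L,A_frenatus:%L);")
  tr <- read_newick(gsub("%L", format(branch_length), nw, fixed = TRUE))
  if (!is.null(overrides)) {
    nm <- branch_names(tr)
    idx <- match(names(overrides), nm)
    if (anyNA(idx)) stop("unknown branch in overrides: ",
                         paste(names(overrides)[is.na(idx)], collapse = ", "))
    tr$edge.length[idx] <- overrides
  }
  tr
}

#' Default neutral model for simulations
#'
#' Mildly GC-poor stationary frequencies with transition/transversion bias,
#' the kind of composition typical of vertebrate neutral sites.
#'
#' @param ... Passed to [subst_model()] to override defaults.
#' @return A `subst_model`.
#' @export
default_model <- function(...) {
  args <- list(...)
  defaults <- list(pi = c(0.3, 0.2, 0.2, 0.3), exch = c(1, 4, 1, 1, 4, 1))
  do.call(subst_model, utils::modifyList(defaults, args))
}

#' Build a region plan tiling a synthetic reference chromosome
#'
#' Lays out non-overlapping regions of fixed length, interleaving
#' implanted conserved (global scale < 1) and accelerated (branch scale
#' > 1) regions among neutral ones, and cycling annotation categories so
#' every category receives windows. A fraction of intergenic-labelled
#' neutral regions carries a standalone ncRNA gene.
#'
#' @param n_neutral,n_conserved,n_accelerated Region counts by class.
#' @param region_length Length of each region in bases (default 60, the
#'   window size used downstream).
#' @param conserved_scale Global rate scale of conserved regions
#'   (default 0.1).
#' @param accelerated_scale Branch rate scale of accelerated regions
#'   (default 10).
#' @param target_branch Branch accelerated regions are accelerated on.
#' @param categories Annotation categories cycled over regions.
#' @param ncrna_every Every ncrna_every-th genic region hosts an ncRNA
#'   gene instead of a protein-coding one (0 disables).
#' @param gap Intergenic spacer between consecutive regions (keeps gene
#'   spans and flanks from fusing).
#' @param chrom Reference sequence name.
#' @param seed Seed for interleaving the classes.
#' @return A `region_plan` data.frame.
#' @export
region_plan <- function(n_neutral = 600, n_conserved = 200,
                        n_accelerated = 200, region_length = 60,
                        conserved_scale = 0.1, accelerated_scale = 10,
                        target_branch = "A_sagrei",
                        categories = c("CDS", "five_prime_UTR",
                                       "three_prime_UTR", "intron",
                                       "intergenic"),
                        ncrna_every = 10L, gap = 20L, chrom = "chrSim",
                        seed = NULL) {
  stopifnot(conserved_scale < 1, accelerated_scale > 1)
  if (!is.null(seed)) set.seed(seed)
  class_vec <- sample(c(rep("neutral", n_neutral),
                        rep("conserved", n_conserved),
                        rep("accelerated", n_accelerated)))
  n <- length(class_vec)
  cat_vec <- rep_len(categories, n)
  start <- seq(0, by = region_length + gap, length.out = n)
  genic <- cat_vec != "intergenic"
  gene_id <- rep(NA_character_, n)
  gene_id[genic] <- sprintf("gene%04d", cumsum(genic)[genic])
  ncrna <- rep(FALSE, n)
  if (ncrna_every > 0) {
    gi <- which(genic)
    ncrna[gi[seq_along(gi) %% ncrna_every == 0]] <- TRUE
  }
  # ncRNA host regions are genic but carry no CDS/UTR: classify as intron
  cat_vec[ncrna] <- "intron"
  data.frame(chrom = chrom, start = start, end = start + region_length,
             class = class_vec,
             scale = ifelse(class_vec == "conserved", conserved_scale,
                            ifelse(class_vec == "accelerated",
                                   accelerated_scale, 1)),
             target_branch = ifelse(class_vec == "accelerated",
                                    target_branch, NA_character_),
             category = cat_vec, gene_id = gene_id, ncrna = ncrna,
             stringsAsFactors = FALSE)
}

plan_gene_models <- function(plan) {
  genes <- list()
  for (i in which(!is.na(plan$gene_id))) {
    p <- plan[i, ]
    bt <- if (p$ncrna) "lncRNA" else "protein_coding"
    feats <- if (p$category %in% c("CDS", "five_prime_UTR",
                                   "three_prime_UTR"))
      data.frame(category = p$category, start = p$start, end = p$end,
                 stringsAsFactors = FALSE)
    else if (p$ncrna)
      data.frame(category = "exon", start = p$start, end = p$end,
                 stringsAsFactors = FALSE)
    else NULL  # intron-only gene: span with no exonic feature
    genes[[length(genes) + 1]] <- gene_model(
      p$gene_id, p$chrom, p$start, p$end, "+", bt, feats)
  }
  genes
}

write_gff3_genes <- function(genes, path) {
  rows <- list()
  for (g in genes) {
    rows[[length(rows) + 1]] <- GenomicRanges::GRanges(
      g$chrom, IRanges::IRanges(g$start + 1, g$end), strand = g$strand,
      type = "gene", ID = g$gene_id, Name = g$name, Parent = NA_character_,
      gene_biotype = g$biotype, phase = NA_integer_)
    f <- g$features
    for (k in seq_len(nrow(f)))
      rows[[length(rows) + 1]] <- GenomicRanges::GRanges(
        g$chrom, IRanges::IRanges(f$start[k] + 1, f$end[k]),
        strand = g$strand, type = f$category[k],
        ID = sprintf("%s.%s.%d", g$gene_id, f$category[k], k),
        Name = NA_character_, Parent = g$gene_id,
        gene_biotype = NA_character_,
        phase = if (f$category[k] == "CDS") 0L else NA_integer_)
  }
  gr <- do.call(c, rows)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Artefact-injection settings for the synthetic generator
#'
#' @importFrom stats runif
#' @param edge_n_run Length of N runs written onto block edges (0 off).
#' @param internal_n_run Length of internal N runs (0 off).
#' @param n_run_fraction Fraction of blocks receiving an N run.
#' @param missing_species_fraction Fraction of blocks that lose 1-2
#'   non-reference species.
#' @param duplicate_fraction Fraction of blocks duplicated with an
#'   overlapping shifted copy.
#' @return List of settings.
#' @export
artefact_config <- function(edge_n_run = 0L, internal_n_run = 0L,
                            n_run_fraction = 0, missing_species_fraction = 0,
                            duplicate_fraction = 0) {
  list(edge_n_run = edge_n_run, internal_n_run = internal_n_run,
       n_run_fraction = n_run_fraction,
       missing_species_fraction = missing_species_fraction,
       duplicate_fraction = duplicate_fraction)
}

region_block <- function(p, m, tree, ref_name, ref_len) {
  ord <- c(ref_name, setdiff(tree$tip.label, ref_name))
  m <- m[ord, , drop = FALSE]
  rows <- data.frame(
    species = rownames(m),
    src = c(p$chrom, rownames(m)[-1]),
    start = c(p$start, rep(0, nrow(m) - 1)),
    size = ncol(m),
    srcSize = ref_len,
    strand = "+",
    text = apply(m, 1, paste, collapse = ""),
    stringsAsFactors = FALSE)
  maf_block(rows)
}

#' Generate a complete synthetic dataset
#'
#' Simulates each planned region with [simulate_columns()] under its
#' class's rate scaling (global for conserved, branch-restricted for
#' accelerated), emits one reference-anchored block per region, gene
#' models matching the planned annotation categories, and the ground
#' truth. Optional artefact injection adds N runs, drops species from a
#' fraction of blocks, and duplicates blocks with an overlap; artefacts
#' never alter bases outside the injected runs.
#'
#' @param plan A `region_plan` data.frame.
#' @param tree Rooted `phylo` (default [default_tree()]).
#' @param model Neutral `subst_model` (default [default_model()]).
#' @param seed Integer seed; the dataset is a pure function of
#'   (plan, tree, model, seed).
#' @param ref_name Reference species (must be a tip).
#' @param n_neutral_sites Columns of putatively neutral fourfold-
#'   degenerate sites simulated for model fitting.
#' @param artefacts Optional [artefact_config()].
#' @param out_dir When set, MAF/GFF3/truth-TSV files are written there.
#' @return List: `blocks`, `genes`, `truth` (plan), `neutral_sites`
#'   (`fourfold_sites`), `tree`, `model`, `paths` (when written).
#' @export
generate_dataset <- function(plan, tree = default_tree(),
                             model = default_model(), seed = 1,
                             ref_name = "A_carolinensis",
                             n_neutral_sites = 20000,
                             artefacts = NULL, out_dir = NULL) {
  stopifnot(ref_name %in% tree$tip.label)
  if (any(plan$start[-1] < plan$end[-nrow(plan)]))
    stop("generation error: plan regions overlap")
  bad <- plan$class == "accelerated" &
    (is.na(plan$target_branch) | plan$scale <= 1)
  if (any(bad)) stop("generation error: accelerated regions need a target ",
                     "branch and scale > 1")
  if (any(plan$class == "conserved" & plan$scale >= 1))
    stop("generation error: conserved regions need scale < 1")
  set.seed(seed)
  ref_len <- max(plan$end) + 1000
  blocks <- vector("list", nrow(plan))
  for (i in seq_len(nrow(plan))) {
    p <- plan[i, ]
    st <- switch(p$class,
                 neutral = scaled_tree(tree),
                 conserved = scaled_tree(tree, global_scale = p$scale),
                 accelerated = scaled_tree(
                   tree, branch_scales = setNames(p$scale, p$target_branch)))
    m <- simulate_columns(st, model, p$end - p$start)
    blocks[[i]] <- region_block(p, m, tree, ref_name, ref_len)
  }
  if (!is.null(artefacts)) blocks <- inject_artefacts(blocks, artefacts)
  sites <- simulate_columns(tree, model, n_neutral_sites)
  fams <- sample(c("GT", "CG", "GG"), n_neutral_sites, replace = TRUE)
  neutral_sites <- structure(
    list(taxa = tree$tip.label, columns = sites,
         source = data.frame(gene_id = fams,
                             codon_index = seq_len(n_neutral_sites),
                             stringsAsFactors = FALSE)),
    class = "fourfold_sites")
  genes <- plan_gene_models(plan)
  out <- list(blocks = blocks, genes = genes, truth = plan,
              neutral_sites = neutral_sites, tree = tree, model = model,
              ref_name = ref_name, ref_length = ref_len)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(maf = file.path(out_dir, "alignment.maf"),
                  gff3 = file.path(out_dir, "annotation.gff3"),
                  truth = file.path(out_dir, "truth.tsv"),
                  truth_bed = file.path(out_dir, "truth.bed"))
    write_maf(blocks, paths$maf)
    write_gff3_genes(genes, paths$gff3)
    utils::write.table(plan, paths$truth, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    nz <- plan[plan$class != "neutral", , drop = FALSE]
    write_bed(data.frame(chrom = nz$chrom, start = nz$start, end = nz$end,
                         name = nz$class, score = 0, strand = "+"),
              paths$truth_bed)
    out$paths <- paths
  }
  out
}

inject_artefacts <- function(blocks, art) {
  n <- length(blocks)
  put_n <- function(text, at, len) {
    substr(text, at, at + len - 1) <- strrep("N", len)
    text
  }
  if (art$n_run_fraction > 0 && (art$edge_n_run > 0 || art$internal_n_run > 0)) {
    for (i in which(runif(n) < art$n_run_fraction)) {
      b <- blocks[[i]]
      row <- sample(2:nrow(b$rows), 1)
      txt <- b$rows$text[row]
      if (art$edge_n_run > 0 && art$edge_n_run < nchar(txt))
        txt <- put_n(txt, 1, art$edge_n_run)
      if (art$internal_n_run > 0 && art$internal_n_run + 2 < nchar(txt)) {
        at <- sample(2:(nchar(txt) - art$internal_n_run), 1)
        txt <- put_n(txt, at, art$internal_n_run)
      }
      b$rows$text[row] <- txt
      blocks[[i]] <- maf_block(b$rows)
    }
  }
  if (art$missing_species_fraction > 0) {
    for (i in which(runif(n) < art$missing_species_fraction)) {
      b <- blocks[[i]]
      drop <- sample(2:nrow(b$rows), sample(1:2, 1))
      blocks[[i]] <- maf_block(b$rows[-drop, , drop = FALSE])
    }
  }
  if (art$duplicate_fraction > 0) {
    dups <- list()
    for (i in which(runif(n) < art$duplicate_fraction)) {
      b <- blocks[[i]]
      half <- b$ncols %/% 2
      if (half >= 2) dups[[length(dups) + 1]] <- subset_block_range(b, 1, half)
    }
    blocks <- c(blocks, dups)
  }
  blocks
}

#' Generate coding-sequence data with controlled codon-usage bias
#'
#' Draws amino-acid sequences and chooses synonymous codons with
#' probabilities proportional to target RSCU values, producing per-species
#' CDS sets and per-gene codon alignments whose realised RSCU matches the
#' specification (within sampling error, about +/-0.05 at 200 or more
#' genes). Bias is identical across species unless per-species overrides
#' are supplied.
#'
#' @param bias_spec Named numeric vector codon -> target RSCU. Unspecified
#'   codons in an affected family share the family's remaining RSCU mass
#'   evenly; a family's specified mass must not exceed the family size.
#' @param n_genes Number of genes.
#' @param seed Integer seed.
#' @param species Species names.
#' @param gene_length Codons per gene.
#' @param per_species Optional named list species -> bias_spec override.
#' @return List: `cds_by_species` (named list of character vectors),
#'   `codon_alignments` (per-gene named character vectors).
#' @export
generate_biased_codon_data <- function(bias_spec = NULL, n_genes = 200,
                                       seed = 1,
                                       species = default_tree()$tip.label,
                                       gene_length = 200,
                                       per_species = NULL) {
  set.seed(seed)
  fam <- genetic_code_families()
  codon_probs <- function(spec) {
    probs <- list()
    for (aa in names(fam)) {
      f <- fam[[aa]]
      k <- length(f)
      r <- setNames(rep(NA_real_, k), f)
      if (!is.null(spec)) {
        hit <- intersect(names(spec), f)
        if (any(spec[hit] < 0)) stop("contract error: negative target RSCU")
        r[hit] <- spec[hit]
      }
      rest <- sum(r, na.rm = TRUE)
      nfree <- sum(is.na(r))
      if (rest > k + 1e-9)
        stop("contract error: target RSCU mass ", rest,
             " exceeds family size ", k, " for ", aa)
      if (nfree > 0) r[is.na(r)] <- (k - rest) / nfree
      else if (abs(rest - k) > 1e-6)
        stop("contract error: fully specified family ", aa,
             " must sum to ", k)
      probs[[aa]] <- r / k
    }
    probs
  }
  base_probs <- codon_probs(bias_spec)
  aas <- names(fam)
  genes <- lapply(seq_len(n_genes), function(g)
    sample(aas, gene_length, replace = TRUE))
  draw_gene <- function(aa_seq, probs)
    paste(vapply(aa_seq, function(aa) {
      f <- fam[[aa]]
      if (length(f) == 1) f else sample(f, 1, prob = probs[[aa]])
    }, character(1)), collapse = "")
  cds_by_species <- list()
  shared <- lapply(genes, draw_gene, probs = base_probs)
  for (sp in species) {
    if (!is.null(per_species) && sp %in% names(per_species)) {
      pr <- codon_probs(per_species[[sp]])
      cds_by_species[[sp]] <- vapply(genes, draw_gene, character(1),
                                     probs = pr)
    } else {
      cds_by_species[[sp]] <- unlist(shared)
    }
    names(cds_by_species[[sp]]) <- sprintf("g%04d", seq_len(n_genes))
  }
  codon_alignments <- lapply(seq_len(n_genes), function(g)
    vapply(species, function(sp) cds_by_species[[sp]][[g]], character(1)))
  names(codon_alignments) <- sprintf("g%04d", seq_len(n_genes))
  list(cds_by_species = cds_by_species, codon_alignments = codon_alignments)
}
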