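# Stage orchestration: curate -> fit-neutral -> window -> scan -> call ->
# associate -> enrich -> report, from a single config.

#' Pipeline configuration
#'
#' Collects every tunable threshold of the scan pipeline with the study
#' defaults: N-run fraction 0.5 and 7-of-8 species for curation, RSCU
#' bounds 0.6/1.6, window rules 10-99/60/20, FDR 0.05, 5-kb gene flanks,
#' >80% ncRNA overlap.
#'
#' @param paths Named list: `maf`, `gff3`, `tree` (Newick file), `outdir`;
#'   optionally `pairwise_mafs` (named vector species -> pairwise MAF) for
#'   full curation from pairwise alignments.
#' @param simulate `NULL`, or a list of [region_plan()] /
#'   [generate_dataset()] arguments to run on synthetic data.
#' @param curation,rscu,window Parameter lists (see defaults).
#' @param alpha FDR threshold for element calling.
#' @param target_branches Branches tested for acceleration.
#' @param flank_distance,ncrna_min_frac,background_mode Downstream
#'   association/enrichment parameters.
#' @param habitat_pairs Named list of lineage pairs compared for common
#'   accelerated genes.
#' @param use_gamma Fit discrete-gamma rate variation in the neutral model.
#' @param seed Master seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(paths = list(outdir = "results/pipeline"),
                            simulate = list(),
                            curation = list(),
                            rscu = list(low = 0.6, high = 1.6, rule = "any"),
                            window = list(every = 60, min_len = 10,
                                          min_tail = 20),
                            alpha = 0.05,
                            target_branches = c(
                              "A_carolinensis", "A_porcatus", "A_allisoni",
                              "A_isolepis", "A_sagrei", "A_homolechis",
                              "A_allogus", "TC_open"),
                            flank_distance = 5000,
                            ncrna_min_frac = 0.8,
                            background_mode = "exclusive",
                            habitat_pairs = list(
                              hot_open = c("TC_open", "A_sagrei"),
                              cool_shaded = c("A_isolepis", "A_allogus")),
                            use_gamma = FALSE, seed = 1) {
  structure(list(paths = paths, simulate = simulate,
                 curation = do.call(curation_config, curation),
                 rscu = rscu, window = window, alpha = alpha,
                 target_branches = target_branches,
                 flank_distance = flank_distance,
                 ncrna_min_frac = ncrna_min_frac,
                 background_mode = background_mode,
                 habitat_pairs = habitat_pairs,
                 use_gamma = use_gamma, seed = seed),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#' @param path YAML file whose keys mirror [pipeline_config()] arguments.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  args <- yaml::read_yaml(path)
  do.call(pipeline_config, args)
}

#' Curate pairwise alignments into a filtered multiple alignment
#'
#' Applies the bespoke filters in order: edge/internal N handling per
#' block, reference-overlap resolution per species, reference-anchored
#' merging, and the species-count filter.
#'
#' @param per_species Named list: species -> list of pairwise `maf_block`
#'   (reference row first).
#' @param ref_name Reference species name.
#' @param cfg A `curation_config`.
#' @return List of curated multi-species `maf_block`.
#' @export
curate_pairwise <- function(per_species, ref_name,
                            cfg = curation_config()) {
  cleaned <- lapply(per_species, function(blocks) {
    out <- list()
    for (b in blocks) out <- c(out, trim_and_split_n(b, cfg))
    resolve_reference_overlaps(out)
  })
  merged <- merge_reference_anchored(cleaned, ref_name)
  filter_species_count(merged, cfg)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full scan pipeline
#'
#' Executes curate, fit-neutral, window, scan, call, associate, enrich and
#' report in order, writing each stage's artifacts under the configured
#' output directory together with a manifest. Outputs are pure functions
#' of (inputs, config, seed); with `resume = TRUE` the expensive neutral
#' fit and window scan are reloaded from their serialized outputs when
#' present.
#'
#' @param config A `pipeline_config`.
#' @param resume Reuse existing stage outputs in the output directory.
#' @return Invisible list of in-memory stage results (including `report`).
#' @export
run_pipeline <- function(config = pipeline_config(), resume = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  outdir <- config$paths$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  pth <- function(f) file.path(outdir, f)
  set.seed(config$seed)

  # ---- inputs / simulation -------------------------------------------------
  if (length(config$simulate) || is.null(config$paths$maf)) {
    sim_args <- config$simulate
    plan_args <- sim_args[intersect(names(sim_args), names(formals(region_plan)))]
    plan_args$seed <- config$seed
    plan <- do.call(region_plan, plan_args)
    ds_args <- sim_args[intersect(names(sim_args),
                                  names(formals(generate_dataset)))]
    ds_args$plan <- plan
    ds_args$seed <- config$seed
    ds_args$out_dir <- pth("input")
    ds <- do.call(generate_dataset, ds_args)
    blocks <- ds$blocks
    genes <- ds$genes
    tree <- ds$tree
    ref_length <- ds$ref_length
    codon <- generate_biased_codon_data(
      bias_spec = c(CTA = 0.3, TCG = 0.3, CCG = 0.3, ACG = 0.3, GCG = 0.3),
      n_genes = 200, seed = config$seed + 1, species = tree$tip.label)
    sites <- ds$neutral_sites
  } else {
    blocks <- read_maf(config$paths$maf)
    genes <- read_gff3(config$paths$gff3)
    tree <- read_newick(config$paths$tree, is_file = TRUE)
    ref_length <- if (!is.null(config$paths$ref_length))
      config$paths$ref_length else blocks[[1]]$rows$srcSize[1]
    codon <- NULL
    sites <- NULL
    ds <- NULL
  }

  # ---- curate ----------------------------------------------------------
  if (!is.null(config$paths$pairwise_mafs)) {
    per_species <- lapply(config$paths$pairwise_mafs, read_maf)
    blocks <- curate_pairwise(per_species, config$paths$ref_name,
                              config$curation)
  } else {
    blocks <- filter_species_count(blocks, config$curation)
  }
  write_maf(blocks, pth("curated.maf"))

  # ---- fit-neutral -----------------------------------------------------
  families <- NULL
  if (!is.null(codon)) {
    usage <- flag_biased_codons(compute_rscu(codon$cds_by_species),
                                config$rscu$low, config$rscu$high)
    families <- select_unbiased_4d_families(usage, config$rscu$rule)
    if (is.null(sites))
      sites <- extract_4d_sites(codon$codon_alignments, families)
  }
  if (resume && file.exists(pth("neutral_model.json"))) {
    neutral <- read_neutral_model(pth("neutral_model.json"))
  } else {
    fit <- fit_neutral_model(sites, tree, use_gamma = config$use_gamma)
    write_neutral_model(fit, pth("neutral_model.json"))
    neutral <- fit
  }

  # ---- window ----------------------------------------------------------
  segments <- assign_annotation(blocks, genes)
  windows <- split_windows(segments, config$window$every,
                           config$window$min_len, config$window$min_tail)
  write_tsv(windows_table(windows), pth("windows.tsv"))

  # ---- scan ------------------------------------------------------------
  if (resume && file.exists(pth("scan_results.tsv"))) {
    results <- utils::read.table(pth("scan_results.tsv"), sep = "\t",
                                 header = TRUE, stringsAsFactors = FALSE)
  } else {
    results <- scan_windows(windows, neutral, config$target_branches)
    write_tsv(results, pth("scan_results.tsv"))
  }

  # ---- call ------------------------------------------------------------
  calls <- call_elements(results, config$alpha)
  write_tsv(calls, pth("calls.tsv"))
  write_bed(data.frame(chrom = calls$chrom, start = calls$start,
                       end = calls$end,
                       name = ifelse(calls$kind == "AR",
                                     paste0("AR_", calls$branch),
                                     "CE"),
                       score = pmin(1000, round(-10 * log10(
                         pmax(calls$q, 1e-100)))),
                       strand = "+"),
            pth("calls.bed"))

  # ---- associate -------------------------------------------------------
  ces <- calls[calls$kind == "all_branch_CE", , drop = FALSE]
  assoc <- list()
  assoc_counts <- list()
  for (br in unique(calls$branch[calls$kind == "AR"])) {
    ars <- calls[calls$kind == "AR" & calls$branch == br, , drop = FALSE]
    a <- associate_genes(ars, ces, genes, ce_overlap_required = TRUE,
                         flank_distance = config$flank_distance)
    assoc[[br]] <- a
    assoc_counts[[br]] <- data.frame(
      branch = br, category = AR_GENE_CATEGORIES,
      n_genes = vapply(a$sets, length, integer(1)),
      stringsAsFactors = FALSE)
    write_tsv(a$links, pth(sprintf("gene_association_%s.tsv", br)))
  }
  if (length(assoc_counts))
    write_tsv(do.call(rbind, assoc_counts), pth("gene_association_summary.tsv"))

  # ---- common accelerated genes ---------------------------------------
  common <- list()
  for (pair in names(config$habitat_pairs)) {
    brs <- config$habitat_pairs[[pair]]
    if (all(brs %in% names(assoc))) {
      cg <- common_accelerated_genes(assoc[[brs[1]]], assoc[[brs[2]]])
      common[[pair]] <- cg
      write_tsv(cg, pth(sprintf("common_genes_%s.tsv", pair)))
    }
  }

  # ---- enrich + report -------------------------------------------------
  report <- summary_report(blocks, windows, results, calls, genes,
                           ref_length, config$ncrna_min_frac,
                           config$background_mode)
  if (!is.null(families)) report$retained_4d_families <- families
  jsonlite::write_json(report, pth("report.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  manifest <- list(package = "conaccr",
                   version = tryCatch(
                     as.character(utils::packageVersion("conaccr")),
                     error = function(e) "unversioned"),
                   seed = config$seed, alpha = config$alpha,
                   target_branches = config$target_branches,
                   n_blocks = length(blocks), n_windows = length(windows))
  jsonlite::write_json(manifest, pth("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)

  invisible(list(blocks = blocks, genes = genes, neutral = neutral,
                 windows = windows, results = results, calls = calls,
                 assoc = assoc, common = common, report = report,
                 truth = if (!is.null(ds)) ds$truth else NULL,
                 families = families, outdir = outdir))
}
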