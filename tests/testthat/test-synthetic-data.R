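test_that("default_tree has the study topology and supports overrides", {
  tr <- default_tree(0.05)
  expect_setequal(tr$tip.label,
                  c("A_carolinensis", "A_porcatus", "A_allisoni",
                    "A_isolepis", "A_sagrei", "A_homolechis", "A_allogus",
                    "A_frenatus"))
  expect_true(ape::is.rooted(tr))
  expect_true("TC_open" %in% branch_names(tr))
  # TC_open is the ancestor of exactly the three trunk-crown open species
  nm <- branch_names(tr)
  node <- tr$edge[which(nm == "TC_open"), 2]
  desc <- ape::extract.clade(tr, node)$tip.label
  expect_setequal(desc, c("A_carolinensis", "A_porcatus", "A_allisoni"))
  tr2 <- default_tree(0.05, overrides = c(A_sagrei = 0.2))
  expect_equal(tr2$edge.length[nm == "A_sagrei"], 0.2)
  expect_error(default_tree(overrides = c(nope = 1)), "unknown branch")
})

test_that("region_plan tiles without overlap and cycles categories", {
  plan <- region_plan(n_neutral = 20, n_conserved = 5, n_accelerated = 5,
                      seed = 1)
  expect_true(all(plan$start[-1] >= plan$end[-nrow(plan)]))
  expect_setequal(unique(plan$category),
                  c("CDS", "five_prime_UTR", "three_prime_UTR", "intron",
                    "intergenic"))
  expect_equal(sum(plan$class == "conserved"), 5)
  expect_equal(sum(plan$class == "accelerated"), 5)
  expect_true(all(plan$scale[plan$class == "conserved"] < 1))
  expect_true(all(plan$scale[plan$class == "accelerated"] > 1))
  expect_true(all(is.na(plan$gene_id) == (plan$category == "intergenic")))
  expect_true(any(plan$ncrna))
  expect_error(region_plan(conserved_scale = 2))
  expect_error(region_plan(accelerated_scale = 0.5))
})

test_that("generate_dataset validates the plan", {
  plan <- region_plan(n_neutral = 4, n_conserved = 1, n_accelerated = 1,
                      seed = 2)
  bad <- plan
  bad$start[2] <- bad$start[1]  # overlap
  expect_error(generate_dataset(bad, seed = 1, n_neutral_sites = 10),
               "generation error")
  bad2 <- plan
  bad2$target_branch[bad2$class == "accelerated"] <- NA
  expect_error(generate_dataset(bad2, seed = 1, n_neutral_sites = 10),
               "generation error")
})

test_that("generated blocks match the plan and the dataset is reproducible", {
  plan <- region_plan(n_neutral = 8, n_conserved = 3, n_accelerated = 3,
                      seed = 3)
  ds <- generate_dataset(plan, seed = 3, n_neutral_sites = 100)
  expect_length(ds$blocks, nrow(plan))
  b1 <- ds$blocks[[1]]
  expect_identical(b1$rows$species[1], "A_carolinensis")
  expect_identical(b1$rows$src[1], plan$chrom[1])
  expect_equal(b1$rows$start[1], plan$start[1])
  expect_equal(b1$ncols, plan$end[1] - plan$start[1])
  expect_equal(nrow(b1$rows), 8)
  # conserved regions have visibly fewer substitutions than accelerated
  ndiff <- function(b) {
    m <- do.call(rbind, strsplit(b$rows$text, ""))
    sum(apply(m, 2, function(cc) length(unique(cc)) > 1))
  }
  cons <- mean(vapply(ds$blocks[plan$class == "conserved"], ndiff, numeric(1)))
  acc <- mean(vapply(ds$blocks[plan$class == "accelerated"], ndiff, numeric(1)))
  expect_lt(cons, acc)
  # gene models exist exactly for genic plan rows
  expect_length(ds$genes, sum(!is.na(plan$gene_id)))
  ds2 <- generate_dataset(plan, seed = 3, n_neutral_sites = 100)
  expect_identical(lapply(ds$blocks, function(b) b$rows$text),
                   lapply(ds2$blocks, function(b) b$rows$text))
})

test_that("dataset files round-trip through the package readers", {
  plan <- region_plan(n_neutral = 6, n_conserved = 2, n_accelerated = 2,
                      seed = 4)
  dir <- tempfile("ds")
  ds <- generate_dataset(plan, seed = 4, n_neutral_sites = 50, out_dir = dir)
  blocks <- read_maf(ds$paths$maf)
  expect_length(blocks, length(ds$blocks))
  genes <- read_gff3(ds$paths$gff3)
  expect_length(genes, length(ds$genes))
  ids <- sort(vapply(genes, `[[`, character(1), "gene_id"))
  expect_identical(ids, sort(vapply(ds$genes, `[[`, character(1), "gene_id")))
  truth_bed <- read_bed(ds$paths$truth_bed)
  expect_equal(nrow(truth_bed), sum(plan$class != "neutral"))
})

test_that("artefact injection creates work for every curation filter", {
  plan <- region_plan(n_neutral = 30, n_conserved = 0, n_accelerated = 0,
                      ncrna_every = 0, seed = 5)
  art <- artefact_config(edge_n_run = 5, internal_n_run = 8,
                         n_run_fraction = 0.5,
                         missing_species_fraction = 0.3,
                         duplicate_fraction = 0.2)
  ds <- generate_dataset(plan, seed = 5, n_neutral_sites = 10,
                         artefacts = art)
  txt <- unlist(lapply(ds$blocks, function(b) b$rows$text))
  expect_true(any(grepl("N", txt, fixed = TRUE)))
  nsp <- vapply(ds$blocks, function(b) nrow(b$rows), numeric(1))
  expect_true(any(nsp < 8))
  expect_gt(length(ds$blocks), nrow(plan))  # duplicates appended
  # species-count filter removes the short blocks
  kept <- filter_species_count(ds$blocks, curation_config(min_species = 8))
  expect_lt(length(kept), length(ds$blocks))
})

test_that("codon generator hits target RSCU within sampling error", {
  codon <- generate_biased_codon_data(bias_spec = c(GCG = 0.4, GGG = 1.9),
                                      n_genes = 300, seed = 6,
                                      species = c("s1", "s2"),
                                      gene_length = 200)
  tab <- compute_rscu(codon$cds_by_species)
  expect_equal(unname(tab$rscu["s1", "GCG"]), 0.4, tolerance = 0.05)
  expect_equal(unname(tab$rscu["s1", "GGG"]), 1.9, tolerance = 0.08)
  # sequences identical across species unless overridden
  expect_identical(codon$cds_by_species$s1, codon$cds_by_species$s2)
  over <- generate_biased_codon_data(
    bias_spec = NULL, per_species = list(s2 = c(GCG = 0.2)),
    n_genes = 50, seed = 7, species = c("s1", "s2"), gene_length = 100)
  expect_false(identical(over$cds_by_species$s1, over$cds_by_species$s2))
  # over-allocated family mass is a contract error
  expect_error(generate_biased_codon_data(
    bias_spec = c(GCT = 2, GCC = 2, GCA = 1), n_genes = 2, seed = 1,
    species = "s1", gene_length = 10), "contract error")
})
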