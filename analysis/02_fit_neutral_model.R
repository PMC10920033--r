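#!/usr/bin/env Rscript
# Stage 2: codon-usage screening and neutral-model fitting.
# Reads results/input/, writes results/neutral_model.json and
# results/codon_usage.tsv. Run from the repository root.

library(conaccr)
cfg <- yaml::read_yaml("analysis/config.yaml")
meta <- jsonlite::read_json("results/input/meta.json", simplifyVector = TRUE)

cds_by_species <- lapply(
  setNames(meta$species, meta$species),
  function(sp) read_fasta(sprintf("results/input/cds_%s.fa", sp)))

usage <- flag_biased_codons(compute_rscu(cds_by_species))
families <- select_unbiased_4d_families(usage)
message("retained 4D families: ", paste(families, collapse = ", "))

rscu_long <- data.frame(
  species = rep(rownames(usage$rscu), ncol(usage$rscu)),
  codon = rep(colnames(usage$rscu), each = nrow(usage$rscu)),
  rscu = as.vector(usage$rscu),
  bias = as.vector(usage$biased), stringsAsFactors = FALSE)
write.table(rscu_long, "results/codon_usage.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

sites_fa <- read_fasta("results/input/fourfold_sites.fa")
sites <- do.call(rbind, strsplit(sites_fa, ""))
rownames(sites) <- names(sites_fa)
topology <- read_newick("results/input/topology.nwk", is_file = TRUE)

fit <- fit_neutral_model(sites, topology, use_gamma = cfg$use_gamma)
write_neutral_model(fit, "results/neutral_model.json")
message(sprintf("neutral model fitted: lnL = %.2f over %d sites",
                fit$loglik, ncol(sites)))
print(fit$model)
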