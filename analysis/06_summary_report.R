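#!/usr/bin/env Rscript
# Stage 6: alignment coverage, CE extent, annotation-category bases and
# ncRNA enrichment (Fisher) per AR lineage. Reads all earlier stage
# outputs; writes results/report.json. Run from the repository root.

library(conaccr)
cfg <- yaml::read_yaml("analysis/config.yaml")
meta <- jsonlite::read_json("results/input/meta.json", simplifyVector = TRUE)

blocks <- filter_species_count(read_maf("results/input/alignment.maf"),
                               curation_config())
genes <- read_gff3("results/input/annotation.gff3")
neutral <- read_neutral_model("results/neutral_model.json")
segments <- assign_annotation(blocks, genes)
windows <- split_windows(segments)
results <- read.delim("results/scan_results.tsv", stringsAsFactors = FALSE)
calls <- read.delim("results/calls.tsv", stringsAsFactors = FALSE)

report <- summary_report(blocks, windows, results, calls, genes,
                         ref_length = meta$ref_length,
                         ncrna_min_frac = cfg$ncrna_min_frac,
                         background_mode = cfg$background_mode)
jsonlite::write_json(report, "results/report.json", auto_unbox = TRUE,
                     digits = NA, pretty = TRUE)
message(sprintf("coverage %.1f%%, CE %.2f%% of alignment",
                report$coverage_pct, report$ce$pct_of_alignment))
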