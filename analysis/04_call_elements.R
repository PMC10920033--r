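#!/usr/bin/env Rscript
# Stage 4: call all-branch conserved elements and per-branch accelerated
# regions at FDR < alpha. Reads results/scan_results.tsv; writes
# results/calls.tsv and results/calls.bed. Run from the repository root.

library(conaccr)
cfg <- yaml::read_yaml("analysis/config.yaml")

results <- read.delim("results/scan_results.tsv", stringsAsFactors = FALSE)
calls <- call_elements(results, cfg$alpha)
write.table(calls, "results/calls.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write_bed(data.frame(
  chrom = calls$chrom, start = calls$start, end = calls$end,
  name = ifelse(calls$kind == "AR", paste0("AR_", calls$branch), "CE"),
  score = pmin(1000, round(-10 * log10(pmax(calls$q, 1e-100)))),
  strand = "+"), "results/calls.bed")
message(sum(calls$kind == "all_branch_CE"), " CEs and ",
        sum(calls$kind == "AR"), " ARs at FDR < ", cfg$alpha)
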