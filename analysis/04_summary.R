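#!/usr/bin/env Rscript
# Step 4: collate the headline numbers of the workflow into one table.

suppressMessages(library(mxestruct))

fixtures <- jsonlite::read_json("results/01_fixtures.json")
summary3 <- jsonlite::read_json("results/03_report/summary.json")
events <- read.delim("results/02_events.tsv")

dscam <- generate_genome_annotation(list(preset = "dscam_like"), seed = 1)
isoforms <- enumerate_isoforms(dscam$manifest$clusters)

headline <- list(
  dscam_isoforms = isoforms,
  n_genes = summary3$counts$n_genes,
  n_mxe_events = summary3$counts$n_events,
  n_structural_events = summary3$counts$n_structural,
  mean_identity_pct = round(mean(events$identity_pct), 1),
  exposure_wilcoxon_p = summary3$tests$exposure_wilcoxon$p,
  proximity_near_z = summary3$tests$proximity_CSA$z,
  proximity_near_p = summary3$tests$proximity_CSA$p,
  proximity_far_p = summary3$tests$proximity_PPI$p)

jsonlite::write_json(headline, "results/04_summary.json",
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)
cat("Headline numbers:\n")
for (nm in names(headline))
  cat(sprintf("  %-22s %s\n", nm, format(headline[[nm]], digits = 4)))
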