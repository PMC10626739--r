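#!/usr/bin/env Rscript
# Classify pathway completeness and phase dynamics: which signals have both
# a synthesis side and a receptor in the community, how their per-cell
# abundance distributes over the AP/GP/MP assembly phases, and which genera
# dominate each QS protein per phase (the per-protein top-genus map).

suppressMessages({
  library(qscrosstalk)
  library(readr)
  library(dplyr)
  library(tibble)
})

db <- load_reference_db("results/qs_reference.faa", "results/qs_reference.tsv")
spec <- community_spec(seed = 42)
cat_data <- generate_catalog(spec, db)
homologs <- read_tsv("results/homologs.tsv", show_col_types = FALSE)

rel <- relative_abundance(cat_data$counts)
percell <- normalize_by_recA(homologs, rel, recA_gene_ids(cat_data$annotations))

profiles <- pathway_profiles(homologs, percell, reference_signals(db))
write_tsv(profiles, "results/pathway_profiles.tsv")

cat(sprintf(
  "%d of %d signals form complete pathways; %d are incomplete\n",
  sum(profiles$completeness == "complete"), nrow(profiles),
  sum(profiles$completeness == "incomplete")
))
print(count(profiles[profiles$completeness == "complete", ], specificity))

# per-protein top genera across AP1 / GP / MP, for detected references
top_map <- purrr::map_dfr(intersect(db$protein_id, homologs$reference_id), function(pid) {
  tibble(
    reference_id = pid,
    signal = db$signal[db$protein_id == pid],
    role = db$role[db$protein_id == pid],
    AP1 = paste(top_genera(homologs, rel, cat_data$taxonomy,
      phase = "AP1", reference_id = pid
    ), collapse = ","),
    GP = paste(top_genera(homologs, rel, cat_data$taxonomy,
      phase = "GP", reference_id = pid
    ), collapse = ","),
    MP = paste(top_genera(homologs, rel, cat_data$taxonomy,
      phase = "MP", reference_id = pid
    ), collapse = ",")
  )
})
write_tsv(top_map, "results/top_genera_by_phase.tsv")
cat("AgrD (AP1) carried by:", top_map$AP1[top_map$reference_id == "AgrD"], "\n")
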