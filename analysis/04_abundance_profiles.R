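#!/usr/bin/env Rscript
# Normalize abundances: length-corrected relative gene abundance, genus
# succession profiles, and recA-normalized per-cell abundance of every
# (signal, role) homolog group.

suppressMessages({
  library(qscrosstalk)
  library(readr)
  library(tibble)
})

db <- load_reference_db("results/qs_reference.faa", "results/qs_reference.tsv")
spec <- community_spec(seed = 42)
cat_data <- generate_catalog(spec, db)
homologs <- read_tsv("results/homologs.tsv", show_col_types = FALSE)

rel <- relative_abundance(cat_data$counts)
gprof <- genus_profile(rel, cat_data$taxonomy)
write_tsv(
  as_tibble(gprof$values, rownames = "genus"),
  "results/genus_profile.tsv"
)

percell <- normalize_by_recA(
  homologs, rel, recA_gene_ids(cat_data$annotations)
)
write_tsv(
  as_tibble(percell$values, rownames = "signal_role"),
  "results/percell_abundance.tsv"
)

cat(sprintf(
  "Relative abundance: %d genes, columns sum to 1 (max dev %.1e)\n",
  nrow(rel$values), max(abs(colSums(rel$values) - 1))
))
ai2 <- colSums(percell$values[percell$groups$signal == "AI-2", , drop = FALSE])
cat(sprintf(
  "AI-2 homologs average %.2f copies per cell across the time course\n",
  mean(ai2)
))
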