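#!/usr/bin/env Rscript
# Build the directed longitudinal cross-talk network over the complete
# pathways: genus-to-genus edges per signal, labelled forward (sender peaks
# before receiver), reverse (sender peaks after receiver) or intra
# (same-phase), and identify the QS hub genera.

suppressMessages({
  library(qscrosstalk)
  library(readr)
})

db <- load_reference_db("results/qs_reference.faa", "results/qs_reference.tsv")
spec <- community_spec(seed = 42)
cat_data <- generate_catalog(spec, db)
homologs <- read_tsv("results/homologs.tsv", show_col_types = FALSE)

rel <- relative_abundance(cat_data$counts)
gprof <- genus_profile(rel, cat_data$taxonomy)
completeness <- classify_completeness(homologs, reference_signals(db))

network <- build_network(homologs, cat_data$taxonomy, completeness, gprof)
network <- identify_hubs(network, homologs, cat_data$taxonomy)

write_edge_list(network, "results/network_edges.tsv")
write_graphml(network, "results/network.graphml")

print(network)
ai2 <- network$edges[network$edges$signal == "AI-2", ]
cat("\nAI-2 subnetwork (the only signal spanning forward and reverse):\n")
for (i in seq_len(nrow(ai2))) {
  cat(sprintf(
    "  %-13s (%s) -> %-13s (%s)  %s\n",
    ai2$source[i], ai2$source_peak[i],
    ai2$target[i], ai2$target_peak[i], ai2$direction[i]
  ))
}
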