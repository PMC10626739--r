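# Background residue frequencies used for all synthetic protein sequences
# (roughly uniform; exact values do not matter downstream, only determinism).
random_protein <- function(len) {
  paste(sample(AA_ALPHABET20, len, replace = TRUE), collapse = "")
}

# Entry list for the bundled synthetic reference database. Ten signal classes
# carry both synthesis-side and receptor entries (AIP Agr/Fsr-like peptides,
# lantibiotics, class-II bacteriocins, AI-2, RRNPP-type AIPs, DSF, HAQ, AHL,
# AHK, ethanolamine); eleven further signal classes carry a single role each,
# so pathway-completeness classification has both outcomes to find.
synthetic_refdb_entries <- function() {
  e <- function(id, signal, role, step, org, keyword) {
    tibble::tibble(
      protein_id = id, signal = signal, role = role, step = step,
      source_organism = org, domain_keyword = keyword
    )
  }
  dplyr::bind_rows(
    # -- complete pathways (synthase/processor + receptor) -----------------
    e("AgrD", "AIP_Agr-Fsr_Like", "synthase", NA, "Streptococcus pneumoniae", "agrd_propeptide"),
    e("AgrC", "AIP_Agr-Fsr_Like", "receptor", NA, "Streptococcus pneumoniae", "agrc_histidine_kinase"),
    e("NisA", "Lantibiotics", "synthase", 1L, "Lactococcus lactis", "nisin_precursor"),
    e("NisC", "Lantibiotics", "processor", NA, "Lactococcus lactis", "lanc_cyclase"),
    e("NisK", "Lantibiotics", "receptor", NA, "Lactococcus lactis", "nisk_sensor_kinase"),
    e("CbnS", "Bacteriocin-II", "synthase", NA, "Carnobacterium maltaromaticum", "bacteriocin_ii_precursor"),
    e("CbnK", "Bacteriocin-II", "receptor", NA, "Carnobacterium maltaromaticum", "cbnk_sensor_kinase"),
    e("Pfs", "AI-2", "synthase", 1L, "Salmonella enterica", "mtn_nucleosidase"),
    e("LuxS", "AI-2", "synthase", 2L, "Bacteroides vulgatus", "luxs_lyase"),
    e("AibA", "AI-2", "receptor", NA, "Helicobacter pylori", "aiba_ai2_binding"),
    e("LsrB", "AI-2", "receptor", NA, "Escherichia coli", "lsrb_periplasmic_binding"),
    e("LuxP", "AI-2", "receptor", NA, "Vibrio harveyi", "luxp_periplasmic_binding"),
    e("PhrC", "AIP_RRNPP", "synthase", NA, "Bacillus subtilis", "phr_propeptide"),
    e("Rgg", "AIP_RRNPP", "receptor", NA, "Streptococcus pyogenes", "rrnpp_tpr_regulator"),
    e("RpfB", "DSF", "synthase", 1L, "Xanthomonas campestris", "rpfb_fatty_acyl_ligase"),
    e("RpfF", "DSF", "synthase", 2L, "Xanthomonas campestris", "rpff_enoyl_coa_hydratase"),
    e("RpfR", "DSF", "receptor", NA, "Burkholderia cenocepacia", "rpfr_pas_ggdef"),
    e("RpfC", "DSF", "receptor", NA, "Xanthomonas campestris", "rpfc_hybrid_kinase"),
    e("PqsD", "HAQ", "synthase", NA, "Pseudomonas aeruginosa", "pqsd_condensing_enzyme"),
    e("PqsR", "HAQ", "receptor", NA, "Pseudomonas aeruginosa", "pqsr_lysr_regulator"),
    e("LuxI", "AHL", "synthase", NA, "Vibrio fischeri", "luxi_acyl_synthase"),
    e("AinR", "AHL", "receptor", NA, "Vibrio fischeri", "ainr_sensor_kinase"),
    e("CqsA", "AHK", "synthase", NA, "Vibrio cholerae", "cqsa_aminotransferase"),
    e("CqsS", "AHK", "receptor", NA, "Vibrio cholerae", "cqss_sensor_kinase"),
    e("GlpQ", "Ethanolamine", "synthase", NA, "Haemophilus influenzae", "glpq_phosphodiesterase"),
    e("CqsR", "Ethanolamine", "receptor", NA, "Vibrio cholerae", "cqsr_periplasmic_sensor"),
    # -- single-role pathways ----------------------------------------------
    e("QseC", "AI-3", "receptor", NA, "Escherichia coli", "qsec_sensor_kinase"),
    e("TnaA", "Indole", "synthase", NA, "Escherichia coli", "tryptophanase"),
    e("AlbC", "DKPs", "synthase", NA, "Streptomyces noursei", "cdps_synthase"),
    e("PpyS", "Pyrones", "synthase", NA, "Photorhabdus luminescens", "ppys_pyrone_synthase"),
    e("PluR", "Photopyrones", "receptor", NA, "Photorhabdus luminescens", "plur_luxr_pas4"),
    e("PhcB", "PAME", "synthase", NA, "Ralstonia solanacearum", "phcb_methyltransferase"),
    e("ComQ", "ComX", "synthase", NA, "Bacillus subtilis", "comq_isoprenyl_transferase"),
    e("RapB", "CSF", "receptor", NA, "Bacillus subtilis", "rap_phosphatase"),
    e("PuuR", "Putrescine", "receptor", NA, "Escherichia coli", "puur_hth_regulator"),
    e("QseE", "Epinephrine_NE", "receptor", NA, "Escherichia coli", "qsee_sensor_kinase"),
    e("DarB", "DARs", "synthase", NA, "Photorhabdus asymbiotica", "darb_ketosynthase")
  )
}

#' Bundled synthetic QS reference database
#'
#' Builds the package's self-contained reference database: 37 proteins across
#' 21 QS signal classes. Ten signals (AIP_Agr-Fsr_Like, Lantibiotics,
#' Bacteriocin-II, AI-2, AIP_RRNPP, DSF, HAQ, AHL, AHK, Ethanolamine) have
#' entries on both the synthesis side and the receptor side; the remaining
#' eleven have a single role only. Protein names, roles, multi-step synthase
#' structure and source organisms follow the curated QS systems catalogued in
#' the Sigmol and Quorum Peps databases; the amino-acid sequences are
#' synthetic (seeded random proteins), since the package validates its
#' pipeline on generated communities rather than on curated sequence data.
#'
#' @param seed Integer seed controlling the synthetic sequences.
#' @param length_range Integer range of sequence lengths to draw from.
#' @return A `qs_refdb`.
#' @export
synthetic_reference_db <- function(seed = 101L, length_range = c(140L, 260L)) {
  entries <- synthetic_refdb_entries()
  withr::with_seed(as.integer(seed), {
    lens <- sample(seq(length_range[1], length_range[2]), nrow(entries), replace = TRUE)
    entries$sequence <- vapply(lens, random_protein, character(1))
  })
  reference_db(entries)
}
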