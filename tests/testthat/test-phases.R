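test_that("days map onto phases with half-open windows and inclusive end", {
  sc <- phase_scheme()
  expect_equal(assign_phase(0, sc, "fine"), "AP1")
  expect_equal(assign_phase(1, sc, "fine"), "AP2")
  expect_equal(assign_phase(3, sc, "coarse"), "GP")
  expect_equal(assign_phase(7, sc, "coarse"), "MP")
  expect_equal(assign_phase(11, sc, "fine"), "MP") # terminal day inclusive
  expect_equal(assign_phase(2, sc, "coarse"), "GP") # boundary opens GP
  expect_error(assign_phase(12, sc), "range")
  expect_error(assign_phase(-1, sc), "range")
  # total function on 0..11, and fine labels refine coarse labels
  fine <- assign_phase(0:11, sc, "fine")
  coarse <- assign_phase(0:11, sc, "coarse")
  expect_false(anyNA(fine))
  refine <- c(AP1 = "AP", AP2 = "AP", GP = "GP", MP = "MP")
  expect_equal(unname(refine[fine]), coarse)
})

test_that("pathway completeness needs both a synthesis side and a receptor", {
  hom <- tibble::tibble(
    signal = c("AI-2", "AI-2", "AHL", "Lantibiotics"),
    role = c("synthase", "receptor", "synthase", "processor")
  )
  cls <- classify_completeness(hom, c("AI-2", "AHL", "Lantibiotics", "DSF"))
  expect_equal(unname(cls), c("complete", "incomplete", "incomplete", "absent"))
  # a processor plus a receptor completes a pathway (synthesis-side grouping)
  hom2 <- rbind(hom, tibble::tibble(signal = "Lantibiotics", role = "receptor"))
  expect_equal(unname(classify_completeness(hom2, "Lantibiotics")), "complete")
  # monotone: adding homologs never demotes a signal
  ranks <- c(absent = 0, incomplete = 1, complete = 2)
  set.seed(71)
  pool <- tibble::tibble(
    signal = sample(c("AI-2", "AHL", "DSF"), 30, TRUE),
    role = sample(c("synthase", "receptor", "processor"), 30, TRUE)
  )
  for (n in seq(5, 30, by = 5)) {
    before <- classify_completeness(pool[seq_len(n - 4), ], c("AI-2", "AHL", "DSF"))
    after <- classify_completeness(pool[seq_len(n), ], c("AI-2", "AHL", "DSF"))
    expect_true(all(ranks[after] >= ranks[before]))
  }
})

test_that("phase specificity uses dominance, then stability, then abstains", {
  sc <- phase_scheme()
  days <- 0:11
  series_for <- function(means) {
    coarse <- assign_phase(days, sc, "coarse")
    unname(means[coarse])
  }
  ap <- classify_specificity(series_for(c(AP = 5, GP = 1, MP = 0.5)), days, sc)
  expect_equal(ap$label, "AP-specific")
  expect_equal(unname(ap$phase_means), c(5, 1, 0.5))
  flat <- classify_specificity(series_for(c(AP = 1, GP = 1, MP = 1)), days, sc)
  expect_equal(flat$label, "GP-specific") # stable throughout -> GP branch
  borderline <- classify_specificity(
    series_for(c(AP = 1, GP = 1.1, MP = 1.4)), days, sc
  )
  expect_equal(borderline$label, "unclassified")
  expect_equal(
    classify_specificity(series_for(c(AP = 0.1, GP = 0.2, MP = 2)), days, sc)$label,
    "MP-specific"
  )
  expect_error(classify_specificity(numeric(0), integer(0), sc), "empty")
  expect_error(classify_specificity(1:3, c(0, 1, 2), sc), "coarse phase")
})

test_that("the default community reproduces the 10-complete / 11-incomplete split", {
  run <- small_run()
  cls <- classify_completeness(
    run$homologs,
    reference_signals(synthetic_reference_db())
  )
  expect_equal(sum(cls == "complete"), 10L)
  expect_equal(sum(cls == "incomplete"), 11L)
  both_sided <- c(
    "AIP_Agr-Fsr_Like", "Lantibiotics", "Bacteriocin-II", "AI-2", "AIP_RRNPP",
    "DSF", "HAQ", "AHL", "AHK", "Ethanolamine"
  )
  expect_setequal(names(cls)[cls == "complete"], both_sided)
  # phase-matched pathways pick up their expected specificity labels
  profiles <- run$pathways
  expect_equal(
    profiles$specificity[profiles$signal == "AIP_Agr-Fsr_Like"], "AP-specific"
  )
  expect_equal(profiles$specificity[profiles$signal == "AHK"], "MP-specific")
  expect_equal(profiles$specificity[profiles$signal == "AI-2"], "GP-specific")
})

test_that("top-genus ranking matches a brute-force aggregate-and-sort", {
  run <- small_run()
  cat_data <- run$catalog
  rel <- run$abundance
  # the Agr propeptide is a Streptococcus gene: AP1 top genus
  expect_equal(
    top_genera(run$homologs, rel, cat_data$taxonomy,
      phase = "AP1", reference_id = "AgrD"
    ),
    "Streptococcus"
  )
  # brute-force oracle over AI-2 synthase carriers in GP
  got <- top_genera(run$homologs, rel, cat_data$taxonomy,
    phase = "GP", signal = "AI-2", role = "synthase", k = 5
  )
  ids <- run$homologs$gene_id[
    run$homologs$signal == "AI-2" & run$homologs$role == "synthase"
  ]
  gmap <- setNames(cat_data$taxonomy$genus, cat_data$taxonomy$gene_id)
  in_gp <- assign_phase(rel$samples$day, phase_scheme(), "coarse") == "GP"
  sums <- sort(tapply(
    rowSums(rel$values[ids, in_gp, drop = FALSE]),
    gmap[ids], sum
  ), decreasing = TRUE)
  expect_equal(got, names(sums)[seq_along(got)])
  expect_lte(length(got), 5L)
  # fewer genera than k: all of them are returned
  few <- top_genera(run$homologs, rel, cat_data$taxonomy,
    phase = "MP", signal = "AHK", k = 5
  )
  expect_gt(length(few), 0L)
  expect_lte(length(few), 2L) # only Prevotella/Fusobacterium carry AHK
  expect_error(
    top_genera(run$homologs, rel, cat_data$taxonomy,
      phase = "GP", reference_id = "NotARef"
    ),
    "NotARef"
  )
})
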