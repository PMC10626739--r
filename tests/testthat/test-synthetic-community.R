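test_that("trajectories are compositional and peak in the assigned phase", {
  spec <- community_spec(seed = 3)
  traj <- sample_trajectories(spec)
  expect_true(all(abs(colSums(traj$values) - 1) < 1e-9))
  coarse <- assign_phase(traj$samples$day, phase_scheme(), "coarse")
  for (g in names(spec$genera)) {
    means <- vapply(
      c("AP", "GP", "MP"),
      function(p) mean(traj$values[g, coarse == p]), numeric(1)
    )
    expect_equal(names(which.max(means)), unname(spec$genera[[g]]), info = g)
  }
  # the early colonizer dominates AP relative to MP
  strep <- traj$values["Streptococcus", ]
  expect_gt(mean(strep[coarse == "AP"]), mean(strep[coarse == "MP"]))
})

test_that("noise-free trajectories are identical across replicates", {
  spec <- community_spec(trajectory_noise_sd = 0, replicates = 4, seed = 8)
  traj <- sample_trajectories(spec)
  by_day <- split(traj$samples$sample_id, traj$samples$day)
  for (ids in by_day) {
    expect_true(all(traj$values[, ids] == traj$values[, ids[1]]))
  }
})

test_that("the generator is a pure function of spec and seed", {
  spec <- community_spec(
    decoys_per_genus = 1, background_per_genus = 2,
    total_reads_per_sample = 5000, seed = 77
  )
  db <- synthetic_reference_db()
  a <- generate_catalog(spec, db)
  b <- generate_catalog(spec, db)
  expect_identical(a$proteins, b$proteins)
  expect_identical(a$counts$counts, b$counts$counts)
  expect_identical(as.data.frame(a$truth), as.data.frame(b$truth))
  c2 <- generate_catalog(community_spec(
    decoys_per_genus = 1, background_per_genus = 2,
    total_reads_per_sample = 5000, seed = 78
  ), db)
  expect_false(identical(a$counts$counts, c2$counts$counts))
})

test_that("an empty genera list is rejected", {
  expect_error(community_spec(genera = character(0)), "empty")
})

test_that("planted homologs land at the target identity", {
  set.seed(31)
  ref <- random_aa(150)
  # identity case: target 1 leaves the sequence untouched
  h1 <- plant_homolog(ref, 1.0, 1)
  expect_equal(as.character(h1), ref)
  expect_equal(attr(h1, "realized_identity"), 1.0)
  # target 0.6 on a 100-aa reference: local alignment identity in [0.55, 0.65]
  ref100 <- random_aa(100)
  for (sd in 1:5) {
    h <- plant_homolog(ref100, 0.6, sd)
    a <- align_pair(as.character(h), ref100)
    expect_gte(a$identity, 0.55)
    expect_lte(a$identity, 0.65)
    expect_equal(attr(h, "realized_identity"), 0.6)
  }
  # below-threshold plant: realized identity under the 30% retrieval cutoff
  h2 <- plant_homolog(ref, 0.2, 4)
  expect_lt(attr(h2, "realized_identity"), 0.30)
  # determinism and contract errors
  expect_identical(plant_homolog(ref, 0.5, 9), plant_homolog(ref, 0.5, 9))
  expect_error(plant_homolog(ref, 0, 1), "target_identity")
  expect_error(plant_homolog(ref, 1.2, 1), "target_identity")
  expect_error(plant_homolog(random_aa(20), 0.5, 1), ">= 30")
})

test_that("catalog bookkeeping matches the spec", {
  db <- synthetic_reference_db()
  spec <- community_spec(
    genera = c(Streptococcus = "AP"),
    planted = tibble::tibble(
      genus = "Streptococcus", signal = "AI-2", role = "synthase",
      target_identity = 0.9, copies_per_cell = 1
    ),
    decoys_per_genus = 5, background_per_genus = 0,
    total_reads_per_sample = 10000, seed = 12
  )
  cat_data <- generate_catalog(spec, db)
  expect_equal(nrow(cat_data$truth), 7L) # 1 planted + 1 recA + 5 decoys
  expect_equal(sum(cat_data$truth$class == "recA"), 1L)
  expect_equal(sum(cat_data$truth$class == "qs_decoy"), 5L)
  # every gene appears exactly once in every output table
  expect_false(anyDuplicated(cat_data$truth$gene_id) > 0)
  expect_setequal(names(cat_data$proteins), cat_data$truth$gene_id)
  expect_setequal(rownames(cat_data$counts$counts), cat_data$truth$gene_id)
  # a planted genus outside the community is an error
  expect_error(
    community_spec(
      genera = c(Streptococcus = "AP"),
      planted = tibble::tibble(
        genus = "Veillonella", signal = "AI-2", role = "synthase",
        target_identity = 0.9, copies_per_cell = 1
      )
    ),
    "Veillonella"
  )
})

test_that("signal interference reshapes trajectories per the prediction", {
  run <- small_run()
  spec <- community_spec(seed = 5)
  k_spec <- simulate_interference(spec, run$network, "AI-2")
  pred <- predict_interference(run$network, "AI-2")
  expect_identical(unlist(k_spec$interference$effects), pred$effects)
  base <- sample_trajectories(spec)
  pert <- sample_trajectories(k_spec)
  days <- base$samples$day
  # delayed genera peak later; released genera hold more late-day abundance
  mean_day <- function(tr, g) sum(tr$values[g, ] * days) / sum(tr$values[g, ])
  for (g in names(pred$effects)) {
    if (pred$effects[[g]] == "delayed_or_suppressed") {
      expect_gt(mean_day(pert, g), mean_day(base, g))
    }
  }
  strep_late <- function(tr) mean(tr$values["Streptococcus", days >= 5])
  expect_gt(strep_late(pert), strep_late(base))
  expect_error(simulate_interference(spec, run$network, "no-such"), "no-such")
})
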