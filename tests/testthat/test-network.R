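test_that("genus peak phases follow the succession, ties to the earliest phase", {
  run <- small_run()
  peaks <- run$network$peaks
  expect_equal(unname(peaks["Streptococcus"]), "AP")
  expect_equal(unname(peaks["Veillonella"]), "GP")
  expect_equal(unname(peaks["Fusobacterium"]), "MP")
  # constant-abundance genus: earliest phase wins the tie
  flat <- qscrosstalk:::new_abundance(
    matrix(0.5, 2, 12, dimnames = list(c("A", "B"), sprintf("d%d_r1", 0:11))),
    tibble::tibble(sample_id = sprintf("d%d_r1", 0:11), day = 0:11, replicate = 1L),
    "relative"
  )
  expect_equal(unname(genus_peak_phase(flat)["A"]), "AP")
  expect_error(genus_peak_phase(flat, genera = "C"), "absent")
})

test_that("the edge set equals the brute-force synthase x receptor double loop", {
  run <- small_run()
  spec <- community_spec() # same planted design as the run's spec
  expected <- expected_edges_from_spec(spec)
  got <- run$network$edges[, c("signal", "source", "target", "direction")]
  expect_equal(as.data.frame(got), as.data.frame(expected))
  # headline AI-2 cross-talk calls
  ai2 <- got[got$signal == "AI-2", ]
  fwd <- ai2[ai2$direction == "forward", ]
  rev <- ai2[ai2$direction == "reverse", ]
  expect_true(any(fwd$source == "Streptococcus" & fwd$target == "Veillonella"))
  expect_true(any(fwd$source == "Streptococcus" & fwd$target == "Megasphaera"))
  expect_true(any(rev$source == "Fusobacterium" & rev$target == "Streptococcus"))
  # incomplete signals contribute no edges
  expect_false(any(got$signal %in% c("AI-3", "Indole", "DKPs")))
  # direction trichotomy
  expect_true(all(got$direction %in% c("forward", "reverse", "intra")))
})

test_that("edge directions depend only on the order of peak phases", {
  run <- small_run()
  e <- run$network$edges
  rank <- c(AP = 1, GP = 2, MP = 3)
  dr <- rank[e$target_peak] - rank[e$source_peak]
  expect_equal(
    unname(ifelse(dr > 0, "forward", ifelse(dr < 0, "reverse", "intra"))),
    e$direction
  )
})

test_that("hub identification finds the five core generalists and is monotone", {
  run <- small_run()
  expect_setequal(
    run$network$hubs,
    c("Streptococcus", "Veillonella", "Megasphaera", "Prevotella", "Fusobacterium")
  )
  tax <- run$catalog$taxonomy
  hubs_by_min <- lapply(1:6, function(k) {
    identify_hubs(run$network, run$homologs, tax, min_signals = k)$hubs
  })
  for (k in 2:6) {
    expect_true(all(hubs_by_min[[k]] %in% hubs_by_min[[k - 1]]))
  }
  # an edgeless network yields no hubs
  empty <- build_network(
    run$homologs, tax,
    classify_completeness(run$homologs, reference_signals(synthetic_reference_db())),
    run$genus_prof,
    min_genus_abundance = 0.99
  )
  expect_equal(nrow(empty$edges), 0L)
  expect_length(identify_hubs(empty, run$homologs, tax)$hubs, 0L)
})

test_that("blocking AI-2 releases the early colonizer and delays the rest", {
  run <- small_run()
  pred <- predict_interference(run$network, "AI-2")
  expect_equal(unname(pred$effects["Streptococcus"]), "prolonged_or_enhanced")
  for (g in c("Veillonella", "Megasphaera", "Prevotella", "Fusobacterium")) {
    expect_equal(unname(pred$effects[g]), "delayed_or_suppressed", info = g)
  }
  expect_error(predict_interference(run$network, "Nonexistent"), "unknown signal")
})

test_that("a complete signal without qualifying genera predicts no effects", {
  run <- small_run()
  gated <- build_network(
    run$homologs, run$catalog$taxonomy,
    classify_completeness(run$homologs, reference_signals(synthetic_reference_db())),
    run$genus_prof,
    min_genus_abundance = 0.99
  )
  pred <- predict_interference(gated, "AI-2")
  expect_true(all(pred$effects == "none"))
  # and simulate_interference leaves the spec untouched in that case
  spec <- community_spec(seed = 4)
  expect_identical(simulate_interference(spec, gated, "AI-2"), spec)
})

test_that("network exports are readable edge lists and GraphML", {
  run <- small_run()
  tsv <- tempfile(fileext = ".tsv")
  gml <- tempfile(fileext = ".graphml")
  write_edge_list(run$network, tsv)
  back <- readr::read_tsv(tsv, show_col_types = FALSE)
  expect_equal(nrow(back), nrow(run$network$edges))
  write_graphml(run$network, gml)
  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::ecount(g), nrow(run$network$edges))
  expect_setequal(
    igraph::V(g)$name,
    unique(c(run$network$edges$source, run$network$edges$target))
  )
})
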