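toy_counts <- function(counts, lengths) {
  count_table(counts, lengths, tibble::tibble(
    sample_id = colnames(counts),
    day = seq_len(ncol(counts)) - 1L, replicate = 1L
  ))
}

test_that("relative abundance follows the length-corrected closed forms", {
  # a single gene always has abundance 1
  one <- toy_counts(
    matrix(c(10L, 7L), 1, 2, dimnames = list("g1", c("s1", "s2"))),
    c(g1 = 300)
  )
  expect_true(all(relative_abundance(one)$values == 1))
  # counts (100, 100) at lengths (1000, 500) -> abundances (1/3, 2/3)
  two <- toy_counts(
    matrix(c(100L, 100L), 2, 1, dimnames = list(c("g1", "g2"), "s1")),
    c(g1 = 1000, g2 = 500)
  )
  expect_equal(unname(relative_abundance(two)$values[, 1]), c(1 / 3, 2 / 3))
})

test_that("relative abundance equals the naive two-pass oracle and is scale-free", {
  set.seed(61)
  counts <- matrix(rpois(60, 40), 10, 6,
    dimnames = list(paste0("g", 1:10), paste0("s", 1:6))
  )
  lengths <- setNames(sample(300:3000, 10), rownames(counts))
  ct <- toy_counts(counts, lengths)
  rel <- relative_abundance(ct)
  expect_equal(rel$values, naive_relative_abundance(counts, lengths))
  expect_true(all(abs(colSums(rel$values) - 1) < 1e-9))
  # multiplying one sample's counts by a constant changes nothing
  scaled <- counts
  scaled[, 2] <- scaled[, 2] * 7L
  expect_equal(relative_abundance(toy_counts(scaled, lengths))$values, rel$values)
  # a zero-total sample is an error naming the sample
  zero <- counts
  zero[, 3] <- 0L
  expect_error(relative_abundance(toy_counts(zero, lengths)), "s3")
})

test_that("recA normalization reads out copies per cell", {
  counts <- matrix(c(200L, 100L, 300L), 3, 1,
    dimnames = list(c("qs1", "recA1", "bg1"), "s1")
  )
  lengths <- c(qs1 = 600, recA1 = 300, bg1 = 900)
  rel <- relative_abundance(toy_counts(counts, lengths))
  hom <- tibble::tibble(gene_id = "qs1", signal = "AI-2", role = "synthase")
  pc <- normalize_by_recA(hom, rel, "recA1")
  # equal length-corrected abundance -> exactly 1 copy per cell
  expect_equal(unname(pc$values[1, 1]), 1.0)
  # a group with no genes in the table reports 0
  hom2 <- tibble::tibble(
    gene_id = c("qs1", "ghost"), signal = c("AI-2", "AHL"),
    role = c("synthase", "receptor")
  )
  pc2 <- normalize_by_recA(hom2, rel, "recA1")
  expect_equal(unname(pc2$values["AHL|receptor", 1]), 0)
})

test_that("a gene planted at two copies per cell is recovered at both depths", {
  db <- synthetic_reference_db()
  for (depth in c(30000L, 300000L)) {
    spec <- community_spec(
      genera = c(Streptococcus = "AP"),
      days = 0:3, replicates = 2,
      planted = tibble::tibble(
        genus = "Streptococcus", signal = "AI-2", role = "synthase",
        target_identity = 0.9, copies_per_cell = 2
      ),
      decoys_per_genus = 0, background_per_genus = 10,
      total_reads_per_sample = depth, seed = 62
    )
    cat_data <- generate_catalog(spec, db)
    rel <- relative_abundance(cat_data$counts)
    hom <- filter_by_annotation(
      search_homologs(cat_data$proteins, db),
      cat_data$annotations
    )
    pc <- normalize_by_recA(hom, rel, recA_gene_ids(cat_data$annotations))
    est <- mean(pc$values["AI-2|synthase", ])
    # multinomial delta-method error bound on the per-sample ratio, tightened
    # by averaging over the independent samples
    truth <- cat_data$truth
    w <- truth$copies_per_cell * (3 * (nchar(cat_data$proteins) + 1))[truth$gene_id]
    p <- w / sum(w)
    names(p) <- truth$gene_id
    qs_id <- truth$gene_id[truth$class == "qs_true"]
    recA_id <- truth$gene_id[truth$class == "recA"]
    se <- ratio_se(2, depth, p[[qs_id]], p[[recA_id]]) / sqrt(ncol(pc$values))
    expect_lt(abs(est - 2), 3 * se)
  }
})

test_that("genus aggregation conserves column sums and matches group-and-sum", {
  set.seed(63)
  counts <- matrix(rpois(40, 30), 8, 5,
    dimnames = list(paste0("g", 1:8), paste0("s", 1:5))
  )
  lengths <- setNames(sample(300:1200, 8), rownames(counts))
  rel <- relative_abundance(toy_counts(counts, lengths))
  tax <- tibble::tibble(
    gene_id = rownames(counts)[1:6], # two genes left unassigned
    genus = rep(c("A", "B", "C"), each = 2)
  )
  gp <- genus_profile(rel, tax)
  expect_true(all(abs(colSums(gp$values) - 1) < 1e-9))
  expect_true("unclassified" %in% rownames(gp$values))
  for (g in c("A", "B", "C")) {
    ids <- tax$gene_id[tax$genus == g]
    expect_equal(gp$values[g, ], colSums(rel$values[ids, , drop = FALSE]))
  }
  # all genes in one genus -> that genus has abundance 1
  all_one <- genus_profile(rel, tibble::tibble(
    gene_id = rownames(counts), genus = "Solo"
  ))
  expect_true(all(abs(all_one$values["Solo", ] - 1) < 1e-9))
})

test_that("Shannon diversity matches its closed forms", {
  expect_equal(shannon_index(c(1)), 0)
  expect_equal(shannon_index(rep(0.2, 5)), log(5))
  expect_equal(shannon_index(rep(7, 12)), log(12)) # internal renormalization
  expect_equal(shannon_index(c(0.5, 0.25, 0.25)),
    -sum(c(0.5, 0.25, 0.25) * log(c(0.5, 0.25, 0.25))),
    tolerance = 1e-12
  )
  expect_equal(shannon_index(c(0.5, 0.25, 0.25)), 1.0397208, tolerance = 1e-6)
  expect_error(shannon_index(c(0, 0)), "all-zero")
  expect_error(shannon_index(c(-1, 2)), "nonnegative")
})
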