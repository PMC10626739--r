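# Independent oracles and shared fixtures for the test suite.

AA20 <- c(
  "A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
  "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V"
)

random_aa <- function(len) paste(sample(AA20, len, replace = TRUE), collapse = "")

# Exhaustive affine-gap local alignment score (Smith-Waterman with three
# state matrices); a gap of length L costs open + L * ext. Quadratic DP in
# plain R, independent of the package's aligner backend.
sw_oracle_score <- function(q, s, open = 11, ext = 1) {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  mat <- e$BLOSUM62
  qc <- strsplit(q, "", fixed = TRUE)[[1]]
  sc <- strsplit(s, "", fixed = TRUE)[[1]]
  n <- length(qc)
  m <- length(sc)
  M <- matrix(0, n + 1, m + 1)
  X <- matrix(-Inf, n + 1, m + 1)
  Y <- matrix(-Inf, n + 1, m + 1)
  best <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      X[i + 1, j + 1] <- max(M[i, j + 1] - open - ext, X[i, j + 1] - ext)
      Y[i + 1, j + 1] <- max(M[i + 1, j] - open - ext, Y[i + 1, j] - ext)
      M[i + 1, j + 1] <- max(0, max(M[i, j], X[i, j], Y[i, j]) + mat[qc[i], sc[j]])
      best <- max(best, M[i + 1, j + 1], X[i + 1, j + 1], Y[i + 1, j + 1])
    }
  }
  best
}

# Naive two-pass length-normalized relative abundance (loops, no matrix ops).
naive_relative_abundance <- function(counts, lengths) {
  out <- matrix(0, nrow(counts), ncol(counts), dimnames = dimnames(counts))
  for (s in seq_len(ncol(counts))) {
    divided <- numeric(nrow(counts))
    for (g in seq_len(nrow(counts))) {
      divided[g] <- counts[g, s] / lengths[rownames(counts)[g]]
    }
    for (g in seq_len(nrow(counts))) out[g, s] <- divided[g] / sum(divided)
  }
  out
}

# Delta-method standard error of the length-corrected count ratio
# (c1/L1)/(c2/L2) under a multinomial draw of size N with cell
# probabilities p1, p2 (covariance term included).
ratio_se <- function(ratio, N, p1, p2) {
  ratio * sqrt((1 - p1) / (N * p1) + (1 - p2) / (N * p2) + 2 / N)
}

# Ground-truth cross-talk edges implied by a community spec's planted table:
# brute-force double loop over synthesis-side x receptor genera per signal
# that has both sides planted above the retrieval identity threshold.
expected_edges_from_spec <- function(spec) {
  pl <- spec$planted[spec$planted$target_identity >= 0.30, ]
  out <- list()
  for (s in unique(pl$signal)) {
    rows <- pl[pl$signal == s, ]
    syn <- unique(rows$genus[rows$role %in% c("synthase", "processor")])
    rec <- unique(rows$genus[rows$role == "receptor"])
    if (length(syn) == 0 || length(rec) == 0) next
    for (a in syn) {
      for (b in rec) {
        ra <- match(spec$genera[[a]], c("AP", "GP", "MP"))
        rb <- match(spec$genera[[b]], c("AP", "GP", "MP"))
        out[[length(out) + 1]] <- tibble::tibble(
          signal = s, source = a, target = b,
          direction = if (rb > ra) "forward" else if (rb < ra) "reverse" else "intra"
        )
      }
    }
  }
  dplyr::arrange(dplyr::bind_rows(out), signal, source, target)
}

# Shared pipeline runs, cached for the session so several test files can
# inspect the same objects without re-running the search stage.
.run_cache <- new.env(parent = emptyenv())

# Reduced community: full default planted table (all 21 signals), but few
# decoy/background genes and lower depth. Search completes in seconds.
small_run <- function() {
  if (is.null(.run_cache$small)) {
    cfg <- pipeline_config(
      spec = community_spec(
        decoys_per_genus = 2, background_per_genus = 5,
        total_reads_per_sample = 50000
      )
    )
    .run_cache$small <- run_pipeline(cfg)
  }
  .run_cache$small
}

# Full default community (~450 genes at default depth), the validation
# configuration used by the acceptance checks.
default_run <- function() {
  if (is.null(.run_cache$default)) {
    .run_cache$default <- run_pipeline(pipeline_config())
  }
  .run_cache$default
}
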