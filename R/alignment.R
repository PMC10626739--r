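#' Alignment scoring parameters
#'
#' Scoring settings for local protein alignment and for the Karlin-Altschul
#' e-value formula. Defaults mirror the BLASTP defaults for BLOSUM62 with
#' affine gaps (open 11, extend 1); `karlin_lambda` and `karlin_K` are the
#' standard gapped BLOSUM62 constants. A gap of length L costs
#' `gap_open + L * gap_extend`.
#'
#' @param substitution_matrix Name of a substitution matrix bundled with
#'   Biostrings (default `"BLOSUM62"`), or a numeric matrix.
#' @param gap_open,gap_extend Positive gap penalties.
#' @param karlin_lambda,karlin_K Positive Karlin-Altschul constants.
#' @return A list of class `alignment_params`.
#' @export
alignment_params <- function(substitution_matrix = "BLOSUM62",
                             gap_open = 11L, gap_extend = 1L,
                             karlin_lambda = 0.267, karlin_K = 0.041) {
  stopifnot(gap_open > 0, gap_extend > 0, karlin_lambda > 0, karlin_K > 0)
  structure(
    list(
      substitution_matrix = substitution_matrix,
      gap_open = as.integer(gap_open),
      gap_extend = as.integer(gap_extend),
      karlin_lambda = karlin_lambda,
      karlin_K = karlin_K
    ),
    class = "alignment_params"
  )
}

#' Homolog retrieval thresholds
#'
#' The three filters applied to every candidate alignment: minimum fractional
#' identity, minimum subject (reference) coverage, and maximum e-value.
#' Defaults are identity >= 0.30, coverage >= 0.50, e-value <= 1e-5.
#'
#' @param min_identity Minimum identity over aligned columns (gaps counted),
#'   in (0, 1].
#' @param min_coverage Minimum fraction of the covered sequence spanned by
#'   the alignment, in (0, 1].
#' @param max_evalue Maximum e-value (> 0).
#' @param coverage_of Which sequence the coverage filter applies to:
#'   `"subject"` (the reference protein; default, guarantees the functional
#'   domain is spanned) or `"query"` (the catalog gene).
#' @return A list of class `search_thresholds`.
#' @export
search_thresholds <- function(min_identity = 0.30, min_coverage = 0.50,
                              max_evalue = 1e-5,
                              coverage_of = c("subject", "query")) {
  coverage_of <- match.arg(coverage_of)
  stopifnot(
    min_identity > 0, min_identity <= 1,
    min_coverage > 0, min_coverage <= 1,
    max_evalue > 0
  )
  structure(
    list(
      min_identity = min_identity, min_coverage = min_coverage,
      max_evalue = max_evalue, coverage_of = coverage_of
    ),
    class = "search_thresholds"
  )
}

# Internal: run Biostrings local alignment of a set of queries against one
# subject and extract per-pair statistics. Spans are 0-based half-open.
align_set <- function(queries, subject, params) {
  aln <- Biostrings::pairwiseAlignment(
    pattern = queries, subject = Biostrings::AAString(subject),
    type = "local",
    substitutionMatrix = params$substitution_matrix,
    gapOpening = params$gap_open, gapExtension = params$gap_extend
  )
  ncols <- Biostrings::nchar(aln)
  qlen <- Biostrings::width(queries)
  slen <- nchar(subject)
  pat <- Biostrings::pattern(aln)
  sub <- Biostrings::subject(aln)
  tibble::tibble(
    score = Biostrings::score(aln),
    identity = ifelse(ncols > 0, Biostrings::nmatch(aln) / ncols, 0),
    subject_coverage = (BiocGenerics::end(sub) - BiocGenerics::start(sub) + 1) / slen,
    query_coverage = (BiocGenerics::end(pat) - BiocGenerics::start(pat) + 1) / qlen,
    q_start = BiocGenerics::start(pat) - 1L, q_end = BiocGenerics::end(pat),
    s_start = BiocGenerics::start(sub) - 1L, s_end = BiocGenerics::end(sub)
  )
}

#' Local pairwise protein alignment
#'
#' Smith-Waterman local alignment of two amino-acid sequences under affine
#' gap penalties (via the Biostrings dynamic-programming aligner). Identity
#' is computed BLAST-style as exact matches divided by aligned columns,
#' counting gap columns; coverage of each sequence is the fraction of its
#' length inside the aligned span. Spans are reported 0-based, half-open.
#'
#' @param query,subject Amino-acid strings (20 standard residues plus X).
#' @param params An [alignment_params()].
#' @return A one-row tibble with `score`, `identity`, `subject_coverage`,
#'   `query_coverage` and span columns `q_start`, `q_end`, `s_start`, `s_end`.
#' @export
align_pair <- function(query, subject, params = alignment_params()) {
  check_aa(query, "query")
  check_aa(subject, "subject")
  align_set(Biostrings::AAStringSet(query), subject, params)
}

#' Karlin-Altschul e-value of a local alignment score
#'
#' `E = K * m * n * exp(-lambda * S)` with `m` the query length, `n` the
#' total residue count of the search space, and `(lambda, K)` from `params`.
#' Strictly decreasing in the score and linear in both lengths.
#'
#' @param score Alignment score(s), >= 0.
#' @param query_len Query length in residues (> 0).
#' @param db_residues Total residues of the search space (> 0).
#' @param params An [alignment_params()] supplying `karlin_lambda`/`karlin_K`.
#' @return Numeric e-value(s).
#' @export
compute_evalue <- function(score, query_len, db_residues,
                           params = alignment_params()) {
  if (any(query_len <= 0) || any(db_residues <= 0)) {
    stop("query_len and db_residues must be positive", call. = FALSE)
  }
  if (any(score < 0)) stop("score must be >= 0", call. = FALSE)
  params$karlin_K * query_len * db_residues * exp(-params$karlin_lambda * score)
}
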