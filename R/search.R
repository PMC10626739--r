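#' Retrieve QS protein homologs from a gene catalog
#'
#' Aligns every catalog protein against every reference protein with local
#' Smith-Waterman alignment and retains, per gene, the best reference hit
#' that passes all three retrieval thresholds: identity >= `min_identity`,
#' coverage >= `min_coverage` (of the reference by default), and e-value <=
#' `max_evalue`. The best hit is the highest-scoring passing alignment, with
#' ties broken by lower e-value and then by reference database order, so a
#' gene is assigned to exactly one signal and role. The e-value search space
#' (`n` in the Karlin-Altschul formula) is the total residue count of the
#' catalog.
#'
#' @param catalog Named character vector of amino-acid sequences, an
#'   `AAStringSet`, or a path to a protein FASTA file.
#' @param refdb A `qs_refdb`.
#' @param thresholds A [search_thresholds()].
#' @param params An [alignment_params()].
#' @return A tibble with one row per retained gene: `gene_id`,
#'   `reference_id`, `signal`, `role`, `domain_keyword`, `score`,
#'   `identity`, `subject_coverage`, `query_coverage`, `evalue`, span
#'   columns, and `passed_annotation_filter` (`NA` until
#'   [filter_by_annotation()] is applied). The tibble carries an `"all_hits"`
#'   attribute with every threshold-passing alignment for diagnostics.
#' @export
search_homologs <- function(catalog, refdb,
                            thresholds = search_thresholds(),
                            params = alignment_params()) {
  stopifnot(inherits(refdb, "qs_refdb"))
  queries <- as_aa_set(catalog)
  if (length(queries) == 0L) stop("catalog is empty", call. = FALSE)
  db_residues <- sum(Biostrings::width(queries))
  qlen <- Biostrings::width(queries)

  hits <- purrr::map_dfr(seq_len(nrow(refdb)), function(i) {
    stats <- align_set(queries, refdb$sequence[i], params)
    stats$gene_id <- names(queries)
    stats$reference_id <- refdb$protein_id[i]
    stats$signal <- refdb$signal[i]
    stats$role <- refdb$role[i]
    stats$domain_keyword <- refdb$domain_keyword[i]
    stats$ref_order <- i
    stats$evalue <- compute_evalue(stats$score, qlen, db_residues, params)
    stats
  })
  cov <- if (thresholds$coverage_of == "subject") {
    hits$subject_coverage
  } else {
    hits$query_coverage
  }
  passing <- hits[
    hits$identity >= thresholds$min_identity &
      cov >= thresholds$min_coverage &
      hits$evalue <= thresholds$max_evalue, ,
    drop = FALSE
  ]
  best <- passing |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::arrange(
      dplyr::desc(.data$score), .data$evalue, .data$ref_order,
      .by_group = TRUE
    ) |>
    dplyr::slice(1L) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$gene_id)
  best$passed_annotation_filter <- NA
  best <- best[, c(
    "gene_id", "reference_id", "signal", "role", "domain_keyword",
    "score", "identity", "subject_coverage", "query_coverage", "evalue",
    "q_start", "q_end", "s_start", "s_end", "passed_annotation_filter"
  )]
  attr(best, "all_hits") <- passing
  best
}

as_aa_set <- function(catalog) {
  if (inherits(catalog, "AAStringSet")) {
    return(catalog)
  }
  if (is.character(catalog) && length(catalog) == 1L && is.null(names(catalog)) &&
    file.exists(catalog)) {
    seqs <- Biostrings::readAAStringSet(catalog)
    names(seqs) <- sub("\\s.*$", "", names(seqs))
    return(seqs)
  }
  if (is.character(catalog)) {
    if (is.null(names(catalog))) stop("catalog sequences must be named", call. = FALSE)
    return(Biostrings::AAStringSet(catalog))
  }
  stop("catalog must be a named character vector, AAStringSet, or FASTA path",
    call. = FALSE
  )
}

#' Conserved-domain annotation filter
#'
#' Screens alignment-passing homologs against the catalog's free-text
#' functional annotations: a homolog is kept only if its gene's annotation
#' contains the matched reference's domain keyword (case-insensitive
#' substring), the package's surrogate for requiring a conserved domain and
#' an annotation consistent with the reference QS protein.
#'
#' @param homologs A homolog table from [search_homologs()].
#' @param annotations Tibble with columns `gene_id`, `annotation`, covering
#'   every homolog gene (missing entries are an error).
#' @return The retained homologs with `passed_annotation_filter = TRUE`.
#' @export
filter_by_annotation <- function(homologs, annotations) {
  if (nrow(homologs) == 0L) {
    homologs$passed_annotation_filter <- logical(0)
    return(homologs)
  }
  amap <- setNames(annotations$annotation, annotations$gene_id)
  missing <- setdiff(homologs$gene_id, names(amap))
  if (length(missing) > 0L) {
    stop("missing annotation for gene(s): ", paste(head(missing, 5), collapse = ", "),
      call. = FALSE
    )
  }
  keep <- mapply(
    function(gene, keyword) {
      grepl(keyword, amap[[gene]], ignore.case = TRUE, fixed = FALSE)
    },
    homologs$gene_id, homologs$domain_keyword
  )
  out <- homologs[keep, , drop = FALSE]
  out$passed_annotation_filter <- TRUE
  out
}
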