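#' Read-count tables and normalized abundances
#'
#' A `qs_counts` object holds a gene-by-sample matrix of nonnegative integer
#' read counts together with per-gene nucleotide lengths and a sample table
#' carrying `(day, replicate)` for each column. A `qs_abundance` object holds
#' a nonnegative entity-by-sample matrix with normalization `"relative"`
#' (columns sum to 1) or `"per_cell"` (recA-normalized average copies per
#' cell, unbounded above).
#'
#' @name qs_counts
NULL

#' Construct a read-count table
#'
#' @param counts Integer matrix, genes in rows (rownames = gene ids), samples
#'   in columns (colnames = sample ids).
#' @param lengths Named vector of per-gene nucleotide lengths (> 0), covering
#'   all rownames of `counts`.
#' @param samples Data frame with columns `sample_id`, `day`, `replicate`
#'   covering all colnames of `counts`. If `NULL`, day/replicate are parsed
#'   from sample ids of the form `d{day}_r{replicate}`.
#' @return A list of class `qs_counts`.
#' @export
count_table <- function(counts, lengths, samples = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts must have gene rownames and sample colnames", call. = FALSE)
  }
  if (any(counts < 0)) stop("counts must be nonnegative", call. = FALSE)
  missing_len <- setdiff(rownames(counts), names(lengths))
  if (length(missing_len) > 0L) {
    stop("missing gene length(s) for: ", paste(head(missing_len, 3), collapse = ", "),
      call. = FALSE
    )
  }
  lengths <- lengths[rownames(counts)]
  if (any(lengths <= 0)) stop("gene lengths must be positive", call. = FALSE)
  if (is.null(samples)) {
    m <- regmatches(
      colnames(counts),
      regexec("^d(\\d+)_r(\\d+)$", colnames(counts))
    )
    if (any(vapply(m, length, integer(1)) != 3L)) {
      stop("sample ids must look like d{day}_r{rep} when samples is NULL",
        call. = FALSE
      )
    }
    samples <- tibble::tibble(
      sample_id = colnames(counts),
      day = as.integer(vapply(m, `[`, character(1), 2)),
      replicate = as.integer(vapply(m, `[`, character(1), 3))
    )
  }
  samples <- tibble::as_tibble(samples)
  stopifnot(all(colnames(counts) %in% samples$sample_id))
  samples <- samples[match(colnames(counts), samples$sample_id), ]
  structure(
    list(counts = counts, lengths = lengths, samples = samples),
    class = "qs_counts"
  )
}

new_abundance <- function(values, samples, normalization) {
  structure(
    list(
      values = values, samples = tibble::as_tibble(samples),
      normalization = normalization
    ),
    class = "qs_abundance"
  )
}

#' @export
print.qs_abundance <- function(x, ...) {
  cat(sprintf(
    "%s abundance: %d entities x %d samples\n",
    x$normalization, nrow(x$values), ncol(x$values)
  ))
  invisible(x)
}

#' Length-normalized relative gene abundance
#'
#' Divides each gene's read count by its nucleotide length and renormalizes
#' within each sample: `a[g, s] = (c[g, s] / L[g]) / sum_g'(c[g', s] / L[g'])`.
#' Columns of the result sum to one.
#'
#' @param counts A [count_table()].
#' @return A `qs_abundance` with normalization `"relative"`.
#' @export
relative_abundance <- function(counts) {
  stopifnot(inherits(counts, "qs_counts"))
  zero <- colSums(counts$counts) == 0
  if (any(zero)) {
    stop(
      "sample(s) with zero total count: ",
      paste(colnames(counts$counts)[zero], collapse = ", "),
      call. = FALSE
    )
  }
  per_len <- counts$counts / counts$lengths
  rel <- sweep(per_len, 2, colSums(per_len), "/")
  new_abundance(rel, counts$samples, "relative")
}

#' Identify recA gene ids from annotations
#'
#' Returns the gene ids whose free-text annotation mentions recA
#' (case-insensitive), the package's surrogate for single-copy housekeeping
#' gene identification in real catalogs.
#'
#' @param annotations Tibble with columns `gene_id` and `annotation`.
#' @return Character vector of gene ids.
#' @export
recA_gene_ids <- function(annotations) {
  annotations$gene_id[grepl("recA", annotations$annotation, ignore.case = TRUE)]
}

#' recA-normalized per-cell abundance of QS homolog groups
#'
#' Sums the relative abundances of all genes assigned to each
#' `(signal, role)` homolog group and divides by the summed relative
#' abundance of the single-copy housekeeping gene recA in the same sample.
#' The ratio is interpreted as the average number of gene copies per cell.
#' By default the recA denominator is community-wide (all recA genes in the
#' sample); `scope = "per_genus"` instead divides each group's
#' genus-restricted abundance by that genus's own recA.
#'
#' @param homologs A homolog table from [search_homologs()] (columns
#'   `gene_id`, `signal`, `role`).
#' @param rel A relative `qs_abundance` over genes.
#' @param recA_ids Character vector of recA gene ids present in `rel`.
#' @param taxonomy Tibble `gene_id`/`genus`; required for
#'   `scope = "per_genus"`.
#' @param scope `"community"` (default) or `"per_genus"`.
#' @return A `qs_abundance` with normalization `"per_cell"`; rows are
#'   `(signal, role)` groups named `signal|role`, with the group map stored
#'   in the `groups` element.
#' @export
normalize_by_recA <- function(homologs, rel, recA_ids, taxonomy = NULL,
                              scope = c("community", "per_genus")) {
  scope <- match.arg(scope)
  stopifnot(inherits(rel, "qs_abundance"), rel$normalization == "relative")
  recA_ids <- intersect(recA_ids, rownames(rel$values))
  if (length(recA_ids) == 0L) stop("no recA genes found in abundance table", call. = FALSE)
  recA_total <- colSums(rel$values[recA_ids, , drop = FALSE])
  zero <- recA_total == 0
  if (any(zero)) {
    stop(
      "recA abundance is zero in sample(s): ",
      paste(colnames(rel$values)[zero], collapse = ", "),
      call. = FALSE
    )
  }
  groups <- dplyr::distinct(tibble::as_tibble(homologs)[, c("signal", "role")])
  groups <- dplyr::arrange(groups, .data$signal, .data$role)
  if (scope == "per_genus" && is.null(taxonomy)) {
    stop("taxonomy is required for per-genus recA normalization", call. = FALSE)
  }
  vals <- matrix(0,
    nrow = nrow(groups), ncol = ncol(rel$values),
    dimnames = list(
      paste(groups$signal, groups$role, sep = "|"),
      colnames(rel$values)
    )
  )
  for (i in seq_len(nrow(groups))) {
    ids <- homologs$gene_id[
      homologs$signal == groups$signal[i] & homologs$role == groups$role[i]
    ]
    ids <- intersect(ids, rownames(rel$values))
    if (length(ids) == 0L) next
    if (scope == "community") {
      vals[i, ] <- colSums(rel$values[ids, , drop = FALSE]) / recA_total
    } else {
      gmap <- setNames(taxonomy$genus, taxonomy$gene_id)
      for (g in unique(gmap[ids])) {
        gid <- ids[gmap[ids] == g]
        g_recA <- recA_ids[gmap[recA_ids] == g]
        if (length(g_recA) == 0L) {
          stop("no recA gene for genus ", g, call. = FALSE)
        }
        denom <- colSums(rel$values[g_recA, , drop = FALSE])
        vals[i, ] <- vals[i, ] + colSums(rel$values[gid, , drop = FALSE]) / denom
      }
    }
  }
  out <- new_abundance(vals, rel$samples, "per_cell")
  out$groups <- groups
  out
}

#' Aggregate gene abundances to genus profiles
#'
#' Sums member-gene relative abundances per genus; genes without a taxonomy
#' entry are pooled as `"unclassified"`. Column sums are preserved.
#'
#' @param rel A relative `qs_abundance` over genes.
#' @param taxonomy Tibble with columns `gene_id` and `genus`.
#' @return A relative `qs_abundance` over genera.
#' @export
genus_profile <- function(rel, taxonomy) {
  stopifnot(inherits(rel, "qs_abundance"), rel$normalization == "relative")
  gmap <- setNames(taxonomy$genus, taxonomy$gene_id)
  genus <- gmap[rownames(rel$values)]
  genus[is.na(genus)] <- "unclassified"
  agg <- rowsum(rel$values, group = genus)
  new_abundance(agg, rel$samples, "relative")
}

#' Shannon diversity index
#'
#' `H = -sum(p_i * ln p_i)` over positive entries, natural logarithm, with
#' the input renormalized internally to sum to one (computed through the
#' standard community-ecology implementation in vegan).
#'
#' @param p Nonnegative abundance vector.
#' @return The Shannon index (0 for a single taxon; `ln k` for `k` equally
#'   abundant taxa).
#' @export
shannon_index <- function(p) {
  if (any(p < 0) || anyNA(p)) stop("abundances must be nonnegative", call. = FALSE)
  if (sum(p) == 0) stop("cannot compute diversity of an all-zero vector", call. = FALSE)
  as.numeric(vegan::diversity(matrix(p, nrow = 1), index = "shannon"))
}
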