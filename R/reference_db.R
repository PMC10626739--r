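#' QS reference protein databases
#'
#' A QS reference database holds experimentally characterized quorum-sensing
#' proteins, each tied to a signal class (e.g. `"AI-2"`, `"AHL"`) and a
#' functional role: `synthase` (produces the signal), `receptor` (senses it),
#' or `processor` (maturation machinery such as lantibiotic peptide
#' processors, grouped with the synthesis side for pathway-completeness
#' calls). Multi-step synthases carry a `step` number (e.g. Pfs is step 1 and
#' LuxS step 2 of AI-2 synthesis).
#'
#' The database is represented as a tibble of class `qs_refdb` with columns
#' `protein_id`, `signal`, `role`, `step`, `source_organism`,
#' `domain_keyword` and `sequence`. `domain_keyword` is the token the
#' downstream annotation filter looks for in free-text gene annotations, a
#' surrogate for conserved-domain screening.
#'
#' @name qs_refdb
NULL

REFDB_ROLES <- c("synthase", "receptor", "processor")

REFDB_META_COLS <- c(
  "protein_id", "signal", "role", "step", "source_organism", "domain_keyword"
)

#' Construct a QS reference database from entry fields
#'
#' @param entries A data frame with columns `protein_id`, `signal`, `role`,
#'   `step` (integer or `NA`), `source_organism`, `domain_keyword`, and
#'   `sequence`. Row order is preserved and used downstream as the
#'   deterministic tie-break order.
#' @return A validated `qs_refdb` tibble.
#' @export
reference_db <- function(entries) {
  entries <- tibble::as_tibble(entries)
  required <- c(REFDB_META_COLS, "sequence")
  missing_cols <- setdiff(required, names(entries))
  if (length(missing_cols) > 0L) {
    stop("reference DB is missing columns: ", paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  if (nrow(entries) == 0L) stop("reference DB has no entries", call. = FALSE)
  entries$step <- suppressWarnings(as.integer(entries$step))
  bad_role <- setdiff(unique(entries$role), REFDB_ROLES)
  if (length(bad_role) > 0L) {
    stop("unknown role(s): ", paste(bad_role, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(entries[, c("signal", "role", "protein_id")])) {
    stop("(signal, role, protein_id) combinations must be unique", call. = FALSE)
  }
  for (i in seq_len(nrow(entries))) {
    check_aa(entries$sequence[i], sprintf("sequence of '%s'", entries$protein_id[i]))
  }
  entries <- entries[, required]
  class(entries) <- c("qs_refdb", class(tibble::tibble()))
  entries
}

#' @export
print.qs_refdb <- function(x, ...) {
  cat(sprintf(
    "QS reference database: %d proteins, %d signals\n",
    nrow(x), length(reference_signals(x))
  ))
  NextMethod()
}

#' Distinct signal names of a reference database
#'
#' @param db A `qs_refdb`.
#' @return Character vector of distinct signal names, in first-appearance order.
#' @export
reference_signals <- function(db) {
  unique(db$signal)
}

#' Look up reference entries by signal and role
#'
#' @param db A `qs_refdb`.
#' @param signal Signal name, e.g. `"AI-2"`.
#' @param role One of `"synthase"`, `"receptor"`, `"processor"`.
#' @return A tibble of matching entries (possibly empty), in database order.
#' @export
reference_entries <- function(db, signal, role) {
  role <- match.arg(role, REFDB_ROLES)
  db[db$signal == signal & db$role == role, , drop = FALSE]
}

#' Load a QS reference database from FASTA plus metadata
#'
#' Reads a protein FASTA and a tab-separated metadata table (columns
#' `protein_id`, `signal`, `role`, `step`, `source_organism`,
#' `domain_keyword`) and joins them by `protein_id`. Entries are returned in
#' FASTA file order.
#'
#' @param fasta_path Path to a protein FASTA file; record ids must appear in
#'   the metadata table.
#' @param metadata_path Path to the metadata TSV (with header).
#' @return A `qs_refdb`.
#' @export
load_reference_db <- function(fasta_path, metadata_path) {
  seqs <- Biostrings::readAAStringSet(fasta_path)
  if (length(seqs) == 0L) stop("empty reference FASTA: ", fasta_path, call. = FALSE)
  ids <- sub("\\s.*$", "", names(seqs))
  meta <- readr::read_tsv(metadata_path, show_col_types = FALSE, progress = FALSE)
  missing_cols <- setdiff(REFDB_META_COLS, names(meta))
  if (length(missing_cols) > 0L) {
    stop("reference metadata is missing columns: ",
      paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  absent <- setdiff(ids, meta$protein_id)
  if (length(absent) > 0L) {
    stop("no metadata row for FASTA id(s): ", paste(absent, collapse = ", "),
      call. = FALSE
    )
  }
  meta <- meta[match(ids, meta$protein_id), ]
  meta$sequence <- as.character(seqs)
  reference_db(meta)
}

#' Write a QS reference database to FASTA plus metadata
#'
#' Inverse of [load_reference_db()]: writing then loading reproduces the
#' database field-for-field.
#'
#' @param db A `qs_refdb`.
#' @param fasta_path,metadata_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_reference_db <- function(db, fasta_path, metadata_path) {
  seqs <- Biostrings::AAStringSet(setNames(db$sequence, db$protein_id))
  Biostrings::writeXStringSet(seqs, fasta_path)
  readr::write_tsv(db[, REFDB_META_COLS], metadata_path, progress = FALSE)
  invisible(c(fasta = fasta_path, metadata = metadata_path))
}
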