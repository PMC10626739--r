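#' Assembly phase scheme
#'
#' Partitions the sampling days of an assembling community into ordered
#' succession phases with half-open day windows: by default the adapting
#' phase AP over days [0, 2) -- subdivided into AP1 [0, 1) and AP2 [1, 2) --
#' the growing phase GP over [2, 5), and the mature phase MP over [5, 11],
#' with the terminal day included in MP. Fine labels (AP1/AP2/GP/MP) refine
#' the coarse labels (AP/GP/MP) consistently.
#'
#' @param ap_split Day splitting AP1 from AP2.
#' @param ap_end,gp_end Days opening GP and MP respectively.
#' @param last_day Final sampled day (inclusive, assigned to MP).
#' @return A tibble of class `phase_scheme` with columns `phase`, `coarse`,
#'   `start`, `end` (half-open windows in row order).
#' @export
phase_scheme <- function(ap_split = 1, ap_end = 2, gp_end = 5, last_day = 11) {
  stopifnot(0 < ap_split, ap_split < ap_end, ap_end < gp_end, gp_end < last_day)
  out <- tibble::tibble(
    phase = c("AP1", "AP2", "GP", "MP"),
    coarse = c("AP", "AP", "GP", "MP"),
    start = c(0, ap_split, ap_end, gp_end),
    end = c(ap_split, ap_end, gp_end, last_day)
  )
  class(out) <- c("phase_scheme", class(out))
  out
}

COARSE_PHASES <- c("AP", "GP", "MP")

# Order index of a coarse phase (AP < GP < MP).
phase_rank <- function(phase) match(phase, COARSE_PHASES)

#' Assign a sampling day to its assembly phase
#'
#' Windows are half-open `[start, end)`; the terminal day belongs to the last
#' phase (MP under the default scheme).
#'
#' @param day Integer day(s) within `[0, last_day]`.
#' @param scheme A [phase_scheme()].
#' @param granularity `"coarse"` for AP/GP/MP, `"fine"` for AP1/AP2/GP/MP.
#' @return Character vector of phase labels.
#' @export
assign_phase <- function(day, scheme = phase_scheme(),
                         granularity = c("coarse", "fine")) {
  granularity <- match.arg(granularity)
  last_day <- scheme$end[nrow(scheme)]
  if (any(day < 0 | day > last_day)) {
    stop(sprintf("day out of range [0, %s]", last_day), call. = FALSE)
  }
  idx <- vapply(day, function(d) {
    if (d >= last_day) {
      nrow(scheme)
    } else {
      which(d >= scheme$start & d < scheme$end)[1]
    }
  }, integer(1))
  if (granularity == "fine") scheme$phase[idx] else scheme$coarse[idx]
}

#' Classify pathway completeness per signal
#'
#' A QS pathway is `complete` when the community carries homologs of both a
#' synthesis-side protein (synthase or processor) and a receptor for the
#' signal, `incomplete` when only one side is present, and `absent`
#' otherwise. Only pathways with both sides can actually deliver a signal,
#' so downstream network construction is restricted to complete ones.
#'
#' @param homologs Homolog table (columns `signal`, `role`); normally the
#'   annotation-filtered output of [filter_by_annotation()].
#' @param signals Character vector of signals to classify (e.g. all signals
#'   of the reference database).
#' @return Named character vector `signal -> completeness`.
#' @export
classify_completeness <- function(homologs, signals) {
  vapply(signals, function(s) {
    roles <- homologs$role[homologs$signal == s]
    has_syn <- any(roles %in% c("synthase", "processor"))
    has_rec <- any(roles == "receptor")
    if (has_syn && has_rec) {
      "complete"
    } else if (has_syn || has_rec) {
      "incomplete"
    } else {
      "absent"
    }
  }, character(1))
}

#' Classify the phase specificity of an abundance time series
#'
#' Computes mean abundance per coarse phase and labels the series
#' `"<phase>-specific"` for the highest phase when its mean exceeds the
#' second-highest by at least `ratio_threshold`. Series without a dominant
#' phase but with stable abundance across phases -- relative range
#' `(max - min) / mean` of the phase means below `cv_threshold` -- are
#' labelled GP-specific, reflecting pathways that stay active throughout
#' assembly; remaining borderline series are `"unclassified"` rather than
#' forced into a bin.
#'
#' @param values Numeric abundance per sample.
#' @param days Integer day of each sample.
#' @param scheme A [phase_scheme()].
#' @param ratio_threshold Dominance ratio (default 1.5).
#' @param cv_threshold Stability threshold on the relative range of the
#'   phase means (default 0.25).
#' @return List with `label` and named `phase_means` (AP, GP, MP).
#' @export
classify_specificity <- function(values, days, scheme = phase_scheme(),
                                 ratio_threshold = 1.5, cv_threshold = 0.25) {
  if (length(values) == 0L) stop("empty abundance series", call. = FALSE)
  stopifnot(length(values) == length(days))
  coarse <- assign_phase(days, scheme, "coarse")
  if (!all(COARSE_PHASES %in% coarse)) {
    stop("series must cover at least one sample per coarse phase", call. = FALSE)
  }
  means <- vapply(
    COARSE_PHASES, function(p) mean(values[coarse == p]),
    numeric(1)
  )
  ord <- order(means, decreasing = TRUE)
  label <- if (all(means == 0)) {
    "unclassified"
  } else if (means[ord[2]] == 0 ||
    means[ord[1]] / means[ord[2]] >= ratio_threshold) {
    paste0(COARSE_PHASES[ord[1]], "-specific")
  } else if (mean(means) > 0 &&
    (max(means) - min(means)) / mean(means) < cv_threshold) {
    "GP-specific"
  } else {
    "unclassified"
  }
  list(label = label, phase_means = means)
}

#' Per-signal pathway profiles
#'
#' Combines completeness classification with per-cell abundance phase means
#' and phase-specificity labels into one report table. Signals without any
#' per-cell abundance row get `NA` means and an `"unclassified"` label.
#'
#' @param homologs Annotation-filtered homolog table.
#' @param percell A `"per_cell"` `qs_abundance` from [normalize_by_recA()].
#' @param signals Signals to report.
#' @param scheme A [phase_scheme()].
#' @param ratio_threshold,cv_threshold Passed to [classify_specificity()].
#' @return Tibble with columns `signal`, `completeness`, `AP`, `GP`, `MP`,
#'   `specificity`.
#' @export
pathway_profiles <- function(homologs, percell, signals,
                             scheme = phase_scheme(),
                             ratio_threshold = 1.5, cv_threshold = 0.25) {
  stopifnot(inherits(percell, "qs_abundance"), percell$normalization == "per_cell")
  completeness <- classify_completeness(homologs, signals)
  days <- percell$samples$day
  purrr::map_dfr(signals, function(s) {
    rows <- which(percell$groups$signal == s)
    if (length(rows) == 0L) {
      return(tibble::tibble(
        signal = s, completeness = completeness[[s]],
        AP = NA_real_, GP = NA_real_, MP = NA_real_,
        specificity = "unclassified"
      ))
    }
    series <- colSums(percell$values[rows, , drop = FALSE])
    cls <- classify_specificity(series, days, scheme, ratio_threshold, cv_threshold)
    tibble::tibble(
      signal = s, completeness = completeness[[s]],
      AP = cls$phase_means[["AP"]], GP = cls$phase_means[["GP"]],
      MP = cls$phase_means[["MP"]], specificity = cls$label
    )
  })
}

#' Top genera carrying a QS protein in a phase
#'
#' Ranks the genera carrying homologs of a reference protein (or of a
#' `(signal, role)` group) by their summed relative gene abundance over the
#' samples of one assembly phase -- the per-protein, per-phase top-genus maps
#' reported for QS homolog tables. Ties are broken alphabetically; genera
#' with zero abundance in the phase are omitted.
#'
#' @param homologs Homolog table.
#' @param rel Relative `qs_abundance` over genes.
#' @param taxonomy Tibble `gene_id`/`genus`.
#' @param phase Phase label, fine (`"AP1"`) or coarse (`"GP"`).
#' @param scheme A [phase_scheme()].
#' @param reference_id Reference protein id to select homologs of, or `NULL`
#'   to select by `signal`/`role`.
#' @param signal,role Homolog group selector when `reference_id` is `NULL`.
#' @param k Maximum number of genera to return (default 5).
#' @return Character vector of up to `k` genus names, best first.
#' @export
top_genera <- function(homologs, rel, taxonomy, phase, scheme = phase_scheme(),
                       reference_id = NULL, signal = NULL, role = NULL, k = 5L) {
  stopifnot(inherits(rel, "qs_abundance"), rel$normalization == "relative")
  if (!is.null(reference_id)) {
    sel <- homologs$reference_id == reference_id
    if (!any(sel)) stop("unknown reference id: ", reference_id, call. = FALSE)
  } else {
    if (is.null(signal)) stop("supply reference_id or signal", call. = FALSE)
    sel <- homologs$signal == signal
    if (!is.null(role)) sel <- sel & homologs$role == role
    if (!any(sel)) {
      stop("no homologs for signal ", signal, call. = FALSE)
    }
  }
  fine <- assign_phase(rel$samples$day, scheme, "fine")
  coarse <- assign_phase(rel$samples$day, scheme, "coarse")
  in_phase <- fine == phase | coarse == phase
  if (!any(in_phase)) stop("no samples in phase ", phase, call. = FALSE)
  ids <- intersect(homologs$gene_id[sel], rownames(rel$values))
  if (length(ids) == 0L) {
    return(character(0))
  }
  gmap <- setNames(taxonomy$genus, taxonomy$gene_id)
  sums <- rowSums(rel$values[ids, in_phase, drop = FALSE])
  per_genus <- tapply(sums, gmap[ids], sum)
  per_genus <- per_genus[per_genus > 0]
  ord <- order(-per_genus, names(per_genus))
  head(names(per_genus)[ord], k)
}
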