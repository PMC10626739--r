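#' Pipeline configuration
#'
#' A single configuration object drives an end-to-end run: either a
#' [community_spec()] for simulation or a set of input paths for a real
#' catalog (protein FASTA, counts TSV with `gene_id` + `length` columns
#' followed by sample columns, taxonomy TSV, annotation TSV), plus the
#' reference database, retrieval thresholds, alignment scoring, phase
#' scheme, classification and network parameters, the signal to evaluate
#' interference for, a global seed, and an optional output directory.
#'
#' @param refdb A `qs_refdb` (default: the bundled synthetic database).
#' @param spec A [community_spec()], or `NULL` when `paths` is given.
#' @param paths Named list with elements `catalog`, `counts`, `taxonomy`,
#'   `annotations`, or `NULL` when `spec` is given. Exactly one of
#'   `spec`/`paths` must be active.
#' @param thresholds A [search_thresholds()].
#' @param params An [alignment_params()].
#' @param scheme A [phase_scheme()].
#' @param ratio_threshold,cv_threshold Phase-specificity parameters.
#' @param min_genus_abundance,min_signals Network parameters.
#' @param interference_signal Signal whose knockout is predicted (set `NULL`
#'   to skip).
#' @param seed Global seed; overrides `spec$seed` so one integer controls
#'   the whole run.
#' @param output_dir Directory for stage outputs, or `NULL` to skip writing.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(refdb = synthetic_reference_db(),
                            spec = community_spec(), paths = NULL,
                            thresholds = search_thresholds(),
                            params = alignment_params(),
                            scheme = phase_scheme(),
                            ratio_threshold = 1.5, cv_threshold = 0.25,
                            min_genus_abundance = 0.01, min_signals = 2L,
                            interference_signal = "AI-2",
                            seed = NULL, output_dir = NULL) {
  if (!is.null(seed) && !is.null(spec)) spec$seed <- as.integer(seed)
  structure(
    list(
      refdb = refdb, spec = spec, paths = paths,
      thresholds = thresholds, params = params, scheme = scheme,
      ratio_threshold = ratio_threshold, cv_threshold = cv_threshold,
      min_genus_abundance = min_genus_abundance,
      min_signals = as.integer(min_signals),
      interference_signal = interference_signal,
      seed = if (is.null(seed)) spec$seed else as.integer(seed),
      output_dir = output_dir
    ),
    class = "pipeline_config"
  )
}

#' Validate a pipeline configuration
#'
#' Checks configuration invariants without running anything; each issue is a
#' human-readable string naming the offending field. An empty result means
#' the configuration is runnable.
#'
#' @param config A [pipeline_config()].
#' @return Character vector of issues (empty when valid).
#' @export
validate_config <- function(config) {
  issues <- character(0)
  add <- function(msg) issues <<- c(issues, msg)
  if (is.null(config$spec) == is.null(config$paths)) {
    add("exactly one of spec (simulation) or paths (real inputs) must be set")
  }
  if (!inherits(config$refdb, "qs_refdb")) add("refdb: not a qs_refdb")
  th <- config$thresholds
  if (!is.null(th)) {
    if (th$min_identity <= 0 || th$min_identity > 1) {
      add("thresholds$min_identity: must lie in (0, 1]")
    }
    if (th$min_coverage <= 0 || th$min_coverage > 1) {
      add("thresholds$min_coverage: must lie in (0, 1]")
    }
    if (th$max_evalue <= 0) add("thresholds$max_evalue: must be > 0")
  }
  pr <- config$params
  if (!is.null(pr) && (pr$gap_open <= 0 || pr$gap_extend <= 0)) {
    add("params: gap penalties must be positive")
  }
  sc <- config$scheme
  if (!is.null(sc)) {
    if (any(sc$start >= sc$end)) add("scheme: empty or inverted phase window")
    if (nrow(sc) > 1 && any(sc$start[-1] != sc$end[-nrow(sc)])) {
      add("scheme: phase windows must be contiguous and non-overlapping")
    }
    if (sc$start[1] != 0) add("scheme: first window must start at day 0")
  }
  if (config$min_genus_abundance < 0 || config$min_genus_abundance >= 1) {
    add("min_genus_abundance: must lie in [0, 1)")
  }
  if (config$min_signals < 1) add("min_signals: must be >= 1")
  if (!is.null(config$paths)) {
    for (nm in c("catalog", "counts", "taxonomy", "annotations")) {
      p <- config$paths[[nm]]
      if (is.null(p) || !file.exists(p)) {
        add(sprintf("paths$%s: file missing or unreadable", nm))
      }
    }
  }
  issues
}

read_real_inputs <- function(paths) {
  proteins <- as_aa_set(paths$catalog)
  cnt <- readr::read_tsv(paths$counts, show_col_types = FALSE, progress = FALSE)
  lens <- setNames(cnt$length, cnt$gene_id)
  mat <- as.matrix(cnt[, setdiff(names(cnt), c("gene_id", "length"))])
  rownames(mat) <- cnt$gene_id
  list(
    proteins = setNames(as.character(proteins), names(proteins)),
    counts = count_table(mat, lens),
    taxonomy = readr::read_tsv(paths$taxonomy, show_col_types = FALSE, progress = FALSE),
    annotations = readr::read_tsv(paths$annotations, show_col_types = FALSE, progress = FALSE),
    truth = NULL, trajectories = NULL
  )
}

#' Run the full QS cross-talk pipeline
#'
#' Orchestrates one end-to-end run: obtain the gene catalog (simulated from
#' `config$spec` or read from `config$paths`), retrieve QS homologs under
#' the retrieval thresholds, apply the annotation filter, normalize
#' abundances (relative, genus-level, and recA per-cell), classify pathway
#' completeness and phase specificity, build the cross-talk network,
#' identify hubs, and predict the configured signal knockout. Stage outputs
#' are written to `config$output_dir` when set; reruns with the same
#' configuration and seed are bit-identical.
#'
#' @param config A [pipeline_config()]; must validate cleanly.
#' @return A list of class `qs_run_report`: filter-funnel `counts`,
#'   `pathways` (profile table), `top_genus` table, `network`, `prediction`,
#'   `fingerprint` (md5 of the serialized key outputs), and the intermediate
#'   objects (`homologs`, `abundance`, `genus_prof`, `percell`, `catalog`).
#' @export
run_pipeline <- function(config) {
  issues <- validate_config(config)
  if (length(issues) > 0L) {
    stop("invalid configuration:\n  - ", paste(issues, collapse = "\n  - "),
      call. = FALSE
    )
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
        call. = FALSE
      )
    })
  }

  cat_data <- stage("catalog", {
    if (!is.null(config$spec)) {
      generate_catalog(config$spec, config$refdb)
    } else {
      read_real_inputs(config$paths)
    }
  })

  putative <- stage(
    "search",
    search_homologs(cat_data$proteins, config$refdb, config$thresholds, config$params)
  )
  homologs <- stage(
    "annotation_filter",
    filter_by_annotation(putative, cat_data$annotations)
  )

  rel <- stage("relative_abundance", relative_abundance(cat_data$counts))
  gprof <- stage("genus_profile", genus_profile(rel, cat_data$taxonomy))
  percell <- stage("recA_normalization", {
    recA <- recA_gene_ids(cat_data$annotations)
    normalize_by_recA(homologs, rel, recA)
  })

  signals <- reference_signals(config$refdb)
  completeness <- classify_completeness(homologs, signals)
  pathways <- stage("pathway_profiles", pathway_profiles(
    homologs, percell, signals, config$scheme,
    config$ratio_threshold, config$cv_threshold
  ))

  network <- stage("network", {
    net <- build_network(
      homologs, cat_data$taxonomy, completeness, gprof,
      config$scheme, config$min_genus_abundance
    )
    identify_hubs(net, homologs, cat_data$taxonomy, config$min_signals)
  })

  prediction <- NULL
  if (!is.null(config$interference_signal) &&
    config$interference_signal %in% network$signals) {
    prediction <- stage(
      "interference",
      predict_interference(network, config$interference_signal)
    )
  }

  counts <- list(
    n_genes = length(cat_data$proteins),
    n_putative_hits = nrow(putative),
    n_annotation_passing = nrow(homologs),
    n_signals_detected = length(unique(homologs$signal)),
    n_complete = sum(completeness == "complete"),
    n_incomplete = sum(completeness == "incomplete"),
    n_absent = sum(completeness == "absent"),
    n_edges = nrow(network$edges),
    n_hubs = length(network$hubs)
  )

  report <- structure(
    list(
      counts = counts, pathways = pathways, network = network,
      prediction = prediction, homologs = homologs, putative = putative,
      abundance = rel, genus_prof = gprof, percell = percell,
      catalog = cat_data, config_seed = config$seed,
      fingerprint = NA_character_
    ),
    class = "qs_run_report"
  )
  report$fingerprint <- report_fingerprint(report)

  if (!is.null(config$output_dir)) write_report(report, config$output_dir)
  report
}

# md5 over the JSON serialization of the decision-carrying outputs.
report_fingerprint <- function(report) {
  payload <- list(
    counts = report$counts,
    homologs = report$homologs[, c("gene_id", "reference_id", "signal", "role")],
    pathways = report$pathways,
    edges = report$network$edges,
    hubs = report$network$hubs,
    effects = if (!is.null(report$prediction)) report$prediction$effects else NULL
  )
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(payload, tmp, auto_unbox = TRUE, digits = 10)
  unname(tools::md5sum(tmp))
}

#' @export
print.qs_run_report <- function(x, ...) {
  cat("QS pipeline run\n")
  cat(sprintf(
    "  genes %d -> threshold-passing %d -> annotation-passing %d\n",
    x$counts$n_genes, x$counts$n_putative_hits, x$counts$n_annotation_passing
  ))
  cat(sprintf(
    "  signals detected %d (complete %d, incomplete %d, absent %d)\n",
    x$counts$n_signals_detected, x$counts$n_complete,
    x$counts$n_incomplete, x$counts$n_absent
  ))
  cat(sprintf(
    "  network: %d edges, hubs: %s\n",
    x$counts$n_edges, paste(x$network$hubs, collapse = ", ")
  ))
  cat("  fingerprint:", x$fingerprint, "\n")
  invisible(x)
}

write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(report$homologs, file.path(dir, "homologs.tsv"), progress = FALSE)
  readr::write_tsv(report$pathways, file.path(dir, "pathways.tsv"), progress = FALSE)
  write_edge_list(report$network, file.path(dir, "network_edges.tsv"))
  if (nrow(report$network$edges) > 0L) {
    write_graphml(report$network, file.path(dir, "network.graphml"))
  }
  if (!is.null(report$prediction)) {
    readr::write_tsv(
      tibble::tibble(
        genus = names(report$prediction$effects),
        effect = unname(report$prediction$effects)
      ),
      file.path(dir, sprintf("interference_%s.tsv", report$prediction$signal)),
      progress = FALSE
    )
  }
  jsonlite::write_json(
    c(report$counts, list(fingerprint = report$fingerprint)),
    file.path(dir, "run_report.json"),
    auto_unbox = TRUE, digits = 10
  )
  invisible(dir)
}
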