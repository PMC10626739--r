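#' Peak assembly phase of each genus
#'
#' The coarse phase (AP/GP/MP) in which a genus's mean relative abundance is
#' maximal; ties go to the earliest phase, so a constant-abundance genus is
#' assigned AP.
#'
#' @param genus_prof Relative `qs_abundance` over genera (from
#'   [genus_profile()] or [sample_trajectories()]).
#' @param scheme A [phase_scheme()].
#' @param genera Genera to report (default: all rows of the profile); an
#'   unknown genus is an error.
#' @return Named character vector `genus -> coarse phase`.
#' @export
genus_peak_phase <- function(genus_prof, scheme = phase_scheme(), genera = NULL) {
  stopifnot(inherits(genus_prof, "qs_abundance"))
  genera <- genera %||% rownames(genus_prof$values)
  missing <- setdiff(genera, rownames(genus_prof$values))
  if (length(missing) > 0L) {
    stop("genus absent from profile: ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  coarse <- assign_phase(genus_prof$samples$day, scheme, "coarse")
  if (!all(COARSE_PHASES %in% coarse)) {
    stop("profile must cover all coarse phases", call. = FALSE)
  }
  vapply(genera, function(g) {
    means <- vapply(COARSE_PHASES, function(p) {
      mean(genus_prof$values[g, coarse == p])
    }, numeric(1))
    COARSE_PHASES[which.max(means)] # which.max takes the first (earliest) tie
  }, character(1))
}

#' Build the directed QS cross-talk network
#'
#' For every complete QS pathway, draws a directed edge from each genus
#' carrying a synthesis-side homolog of the signal to each genus carrying a
#' receptor homolog: the synthesizer releases the signal, the receptor
#' carrier can sense it. Edges are labelled by comparing the peak assembly
#' phases of the two genera: `forward` when the receiver peaks strictly
#' later than the sender (signal handed down the succession), `reverse` when
#' strictly earlier (late colonizers acting back on earlier ones), `intra`
#' when the phases coincide. Same-genus edges are flagged `self_talk` and
#' excluded from interference propagation. Only genera whose mean relative
#' abundance in their own peak phase reaches `min_genus_abundance`
#' participate.
#'
#' @param homologs Annotation-filtered homolog table.
#' @param taxonomy Tibble `gene_id`/`genus`.
#' @param completeness Named vector from [classify_completeness()].
#' @param genus_prof Relative `qs_abundance` over genera.
#' @param scheme A [phase_scheme()].
#' @param min_genus_abundance Peak-phase mean relative-abundance cutoff for
#'   a genus to enter the network (default 0.01).
#' @return A list of class `qs_network`: `edges` (tibble `signal`, `source`,
#'   `target`, `direction`, `source_peak`, `target_peak`, `self_talk`,
#'   ordered by signal/source/target), `signals` (complete signals),
#'   `peaks`, and `hubs` (filled by [identify_hubs()]).
#' @export
build_network <- function(homologs, taxonomy, completeness, genus_prof,
                          scheme = phase_scheme(), min_genus_abundance = 0.01) {
  gmap <- setNames(taxonomy$genus, taxonomy$gene_id)
  complete_signals <- names(completeness)[completeness == "complete"]
  peaks <- genus_peak_phase(genus_prof, scheme)
  coarse <- assign_phase(genus_prof$samples$day, scheme, "coarse")
  peak_mean <- vapply(rownames(genus_prof$values), function(g) {
    mean(genus_prof$values[g, coarse == peaks[[g]]])
  }, numeric(1))
  qualifying <- names(peak_mean)[peak_mean >= min_genus_abundance]

  edges <- purrr::map_dfr(complete_signals, function(s) {
    rows <- homologs[homologs$signal == s, , drop = FALSE]
    syn_genera <- sort(unique(gmap[rows$gene_id[rows$role %in% c("synthase", "processor")]]))
    rec_genera <- sort(unique(gmap[rows$gene_id[rows$role == "receptor"]]))
    syn_genera <- intersect(syn_genera, qualifying)
    rec_genera <- intersect(rec_genera, qualifying)
    if (length(syn_genera) == 0L || length(rec_genera) == 0L) {
      return(tibble::tibble())
    }
    grid <- tidyr::expand_grid(source = syn_genera, target = rec_genera)
    grid$signal <- s
    grid$source_peak <- unname(peaks[grid$source])
    grid$target_peak <- unname(peaks[grid$target])
    dr <- phase_rank(grid$target_peak) - phase_rank(grid$source_peak)
    grid$direction <- ifelse(dr > 0, "forward", ifelse(dr < 0, "reverse", "intra"))
    grid$self_talk <- grid$source == grid$target
    grid
  })
  if (nrow(edges) > 0L) {
    edges <- edges[, c(
      "signal", "source", "target", "direction",
      "source_peak", "target_peak", "self_talk"
    )]
    edges <- dplyr::arrange(edges, .data$signal, .data$source, .data$target)
  } else {
    edges <- tibble::tibble(
      signal = character(0), source = character(0), target = character(0),
      direction = character(0), source_peak = character(0),
      target_peak = character(0), self_talk = logical(0)
    )
  }
  structure(
    list(
      edges = edges, signals = complete_signals,
      peaks = peaks, hubs = character(0)
    ),
    class = "qs_network"
  )
}

#' @export
print.qs_network <- function(x, ...) {
  cat(sprintf(
    "QS cross-talk network: %d edges over %d complete signals\n",
    nrow(x$edges), length(x$signals)
  ))
  if (nrow(x$edges) > 0L) print(table(x$edges$direction))
  if (length(x$hubs) > 0L) cat("hubs:", paste(x$hubs, collapse = ", "), "\n")
  invisible(x)
}

#' Identify QS hub genera
#'
#' A hub is a QS generalist: a genus that carries both synthesis-side and
#' receptor homologs (across any signals) and participates in at least
#' `min_signals` distinct complete pathways. Hubs relay signals along and
#' against the succession and anchor the longitudinal network.
#'
#' @param network A `qs_network`.
#' @param homologs Annotation-filtered homolog table.
#' @param taxonomy Tibble `gene_id`/`genus`.
#' @param min_signals Minimum number of distinct complete signals (default 2).
#' @return The network with `hubs` filled (sorted genus names).
#' @export
identify_hubs <- function(network, homologs, taxonomy, min_signals = 2L) {
  stopifnot(inherits(network, "qs_network"))
  gmap <- setNames(taxonomy$genus, taxonomy$gene_id)
  h <- tibble::tibble(
    genus = unname(gmap[homologs$gene_id]),
    signal = homologs$signal,
    side = ifelse(homologs$role == "receptor", "receptor", "synthesis")
  )
  in_network <- unique(c(network$edges$source, network$edges$target))
  hubs <- h |>
    dplyr::filter(.data$signal %in% network$signals) |>
    dplyr::group_by(.data$genus) |>
    dplyr::summarise(
      both_sides = dplyr::n_distinct(.data$side) == 2L,
      n_signals = dplyr::n_distinct(.data$signal)
    ) |>
    dplyr::filter(.data$both_sides, .data$n_signals >= min_signals) |>
    dplyr::pull(.data$genus)
  network$hubs <- sort(intersect(hubs, in_network))
  network
}

#' Predict qualitative effects of interfering with a QS signal
#'
#' Propagates the loss of one signal's cross-talk through the network.
#' Forward edges promote their receiver's succession, so genera receiving
#' the signal on a forward edge are predicted `delayed_or_suppressed` when
#' it is blocked, and the delay propagates along forward chains to genera
#' downstream of a delayed genus. Reverse edges act as a brake on earlier
#' colonizers; blocking the signal releases the brake, so a reverse edge's
#' receiver is predicted `prolonged_or_enhanced`. A genus hit by both kinds
#' of edge takes the direct forward-loss effect (`delayed_or_suppressed`):
#' the promotion it loses acts at its own colonization time, before the
#' late-succession brake it also loses would have mattered. Only the
#' earliest colonizers -- reverse-edge receivers with no forward edge into
#' them -- are released. Self-talk edges carry no interspecies effect and
#' are ignored.
#'
#' @param network A `qs_network`.
#' @param signal Signal to block; must be in `network$signals`.
#' @return A list of class `qs_interference`: `signal` and `effects`, a
#'   named character vector over all network genera with values
#'   `delayed_or_suppressed`, `prolonged_or_enhanced` or `none`.
#' @export
predict_interference <- function(network, signal) {
  stopifnot(inherits(network, "qs_network"))
  if (!signal %in% network$signals) {
    stop("unknown signal: ", signal, call. = FALSE)
  }
  genera <- sort(unique(c(
    network$edges$source, network$edges$target,
    names(network$peaks)
  )))
  effects <- setNames(rep("none", length(genera)), genera)
  e <- network$edges[network$edges$signal == signal & !network$edges$self_talk, ,
    drop = FALSE
  ]
  if (nrow(e) > 0L) {
    fwd <- e[e$direction == "forward", , drop = FALSE]
    rev <- e[e$direction == "reverse", , drop = FALSE]
    delayed <- unique(fwd$target)
    repeat { # propagate the delay down forward chains
      more <- unique(fwd$target[fwd$source %in% delayed])
      if (all(more %in% delayed)) break
      delayed <- union(delayed, more)
    }
    released <- setdiff(unique(rev$target), delayed)
    effects[delayed] <- "delayed_or_suppressed"
    effects[released] <- "prolonged_or_enhanced"
  }
  structure(list(signal = signal, effects = effects), class = "qs_interference")
}

#' Export network edges as TSV
#'
#' @param network A `qs_network`.
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_edge_list <- function(network, path) {
  readr::write_tsv(network$edges, path, progress = FALSE)
  invisible(path)
}

#' Export the network as GraphML
#'
#' Builds an igraph graph with one vertex per genus (annotated with its peak
#' phase and hub status) and one edge per cross-talk pair (annotated with
#' signal and direction), written in GraphML for use in network viewers.
#'
#' @param network A `qs_network`.
#' @param path Output `.graphml` path.
#' @return Invisibly, `path`.
#' @export
write_graphml <- function(network, path) {
  genera <- sort(unique(c(network$edges$source, network$edges$target)))
  g <- igraph::graph_from_data_frame(
    network$edges[, c("source", "target", "signal", "direction")],
    directed = TRUE,
    vertices = tibble::tibble(
      name = genera,
      peak_phase = unname(network$peaks[genera]),
      hub = genera %in% network$hubs
    )
  )
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
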