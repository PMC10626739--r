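#' Synthetic succession community specification
#'
#' Describes an in-silico assembling community emulating oral-biofilm-style
#' succession: each genus is assigned the coarse assembly phase in which it
#' peaks (adapting AP, growing GP, mature MP), sampled over a day grid with
#' replicate cultures. The default community carries the five core
#' successional genera (Streptococcus peaking in AP; Veillonella and
#' Megasphaera in GP; Prevotella and Fusobacterium in MP), 12 daily samples
#' (days 0-11) and 8 replicates per day.
#'
#' `planted` lists the QS genes written into the catalog: for each row a gene
#' is derived from a reference protein of that `(signal, role)` at a
#' controlled percent identity, assigned to `genus` with `copies_per_cell`
#' gene copies per cell. Target identities at or above 0.30 are planted true
#' positives; below 0.30 they are planted negatives that the retrieval
#' thresholds must reject. Every genus additionally receives exactly one
#' single-copy recA gene; `decoys_per_genus` residue-shuffled reference
#' sequences and `background_per_genus` random proteins complete the catalog.
#'
#' @param genera Named character vector mapping genus name to its peak coarse
#'   phase (`"AP"`, `"GP"` or `"MP"`).
#' @param days Integer vector of sampling days.
#' @param replicates Number of replicate cultures per day (>= 1).
#' @param total_reads_per_sample Sequencing depth per sample (multinomial
#'   total).
#' @param decoys_per_genus,background_per_genus Per-genus counts of
#'   residue-shuffled decoy genes and random background genes.
#' @param planted Tibble with columns `genus`, `signal`, `role`,
#'   `target_identity`, `copies_per_cell`; defaults to
#'   [default_planted_genes()].
#' @param trajectory_noise_sd Standard deviation of multiplicative lognormal
#'   replicate noise on genus trajectories (0 = noise-free).
#' @param seed Integer seed; all generator output is a pure function of the
#'   spec including this seed.
#' @param interference Internal: effect map installed by
#'   [simulate_interference()]; leave `NULL`.
#' @return A list of class `community_spec`.
#' @export
community_spec <- function(genera = c(
                             Streptococcus = "AP", Veillonella = "GP",
                             Megasphaera = "GP", Prevotella = "MP",
                             Fusobacterium = "MP"
                           ),
                           days = 0:11, replicates = 8L,
                           total_reads_per_sample = 200000L,
                           decoys_per_genus = 8L, background_per_genus = 72L,
                           planted = default_planted_genes(),
                           trajectory_noise_sd = 0.15,
                           seed = 42L, interference = NULL) {
  if (length(genera) == 0L) stop("genera must not be empty", call. = FALSE)
  if (is.null(names(genera)) || any(names(genera) == "")) {
    stop("genera must be a named vector (genus -> peak phase)", call. = FALSE)
  }
  bad_phase <- setdiff(unique(genera), c("AP", "GP", "MP"))
  if (length(bad_phase) > 0L) {
    stop("unknown peak phase(s): ", paste(bad_phase, collapse = ", "), call. = FALSE)
  }
  stopifnot(
    replicates >= 1, total_reads_per_sample > 0,
    decoys_per_genus >= 0, background_per_genus >= 0,
    trajectory_noise_sd >= 0
  )
  planted <- tibble::as_tibble(planted)
  if (nrow(planted) > 0L) {
    req <- c("genus", "signal", "role", "target_identity", "copies_per_cell")
    missing_cols <- setdiff(req, names(planted))
    if (length(missing_cols) > 0L) {
      stop("planted table missing columns: ", paste(missing_cols, collapse = ", "),
        call. = FALSE
      )
    }
    stray <- setdiff(planted$genus, names(genera))
    if (length(stray) > 0L) {
      stop("planted genus not in spec genera: ", paste(unique(stray), collapse = ", "),
        call. = FALSE
      )
    }
    if (any(planted$target_identity <= 0 | planted$target_identity > 1)) {
      stop("target_identity must lie in (0, 1]", call. = FALSE)
    }
    stopifnot(all(planted$copies_per_cell > 0))
  }
  structure(
    list(
      genera = genera, days = as.integer(days), replicates = as.integer(replicates),
      total_reads_per_sample = as.integer(total_reads_per_sample),
      decoys_per_genus = as.integer(decoys_per_genus),
      background_per_genus = as.integer(background_per_genus),
      planted = planted, trajectory_noise_sd = trajectory_noise_sd,
      seed = as.integer(seed), interference = interference
    ),
    class = "community_spec"
  )
}

#' Default planted QS genes
#'
#' The planted-gene table of the default synthetic community. AI-2 is carried
#' by all five core genera on both the synthesis and the receptor side (the
#' community's generalist signal, giving forward edges from the early
#' colonizer into GP/MP genera and reverse edges from late colonizers back to
#' Streptococcus). Each genus additionally participates in at least one more
#' complete pathway, phase-matched to the taxa that typically carry these
#' systems in oral communities: Agr-like AIP, lantibiotics, bacteriocin-II and
#' RRNPP receptors on Streptococcus (AP); HAQ, DSF and RRNPP synthesis on the
#' GP genera; AHL, AHK and ethanolamine on the MP genera. The eleven
#' single-role signals are planted once each so that they are detected but
#' remain incomplete. Two sub-threshold plants (identity < 0.30) are included
#' as planted negatives.
#'
#' @return A tibble with columns `genus`, `signal`, `role`,
#'   `target_identity`, `copies_per_cell`.
#' @export
default_planted_genes <- function() {
  p <- function(genus, signal, role, ident, copies = 1) {
    tibble::tibble(
      genus = genus, signal = signal, role = role,
      target_identity = ident, copies_per_cell = copies
    )
  }
  dplyr::bind_rows(
    # AI-2: both roles in every core genus
    p("Streptococcus", "AI-2", "synthase", 0.85),
    p("Streptococcus", "AI-2", "receptor", 0.70),
    p("Veillonella", "AI-2", "synthase", 0.60),
    p("Veillonella", "AI-2", "receptor", 0.75),
    p("Megasphaera", "AI-2", "synthase", 0.70),
    p("Megasphaera", "AI-2", "receptor", 0.65),
    p("Prevotella", "AI-2", "synthase", 0.80),
    p("Prevotella", "AI-2", "receptor", 0.60),
    p("Fusobacterium", "AI-2", "synthase", 0.55),
    p("Fusobacterium", "AI-2", "receptor", 0.90),
    # AP-phase pathways on the early colonizer
    p("Streptococcus", "AIP_Agr-Fsr_Like", "synthase", 0.90),
    p("Streptococcus", "AIP_Agr-Fsr_Like", "receptor", 0.80),
    p("Streptococcus", "Lantibiotics", "synthase", 0.85),
    p("Streptococcus", "Lantibiotics", "processor", 0.75),
    p("Streptococcus", "Lantibiotics", "receptor", 0.70),
    p("Streptococcus", "Bacteriocin-II", "synthase", 0.80),
    p("Streptococcus", "Bacteriocin-II", "receptor", 0.85),
    p("Streptococcus", "AIP_RRNPP", "receptor", 0.75),
    # GP-phase pathways
    p("Veillonella", "HAQ", "synthase", 0.80),
    p("Megasphaera", "HAQ", "receptor", 0.70),
    p("Veillonella", "DSF", "synthase", 0.65),
    p("Megasphaera", "DSF", "receptor", 0.80),
    p("Megasphaera", "AIP_RRNPP", "synthase", 0.70),
    # MP-phase pathways
    p("Prevotella", "AHL", "synthase", 0.75),
    p("Fusobacterium", "AHL", "receptor", 0.85),
    p("Prevotella", "AHK", "synthase", 0.75),
    p("Fusobacterium", "AHK", "receptor", 0.85),
    p("Fusobacterium", "Ethanolamine", "synthase", 0.80),
    p("Prevotella", "Ethanolamine", "receptor", 0.70),
    # single-role signals: detected but incomplete
    p("Streptococcus", "AI-3", "receptor", 0.90),
    p("Streptococcus", "Indole", "synthase", 0.90),
    p("Veillonella", "DKPs", "synthase", 0.90),
    p("Veillonella", "Pyrones", "synthase", 0.90),
    p("Megasphaera", "Photopyrones", "receptor", 0.90),
    p("Megasphaera", "PAME", "synthase", 0.90),
    p("Prevotella", "ComX", "synthase", 0.90),
    p("Prevotella", "CSF", "receptor", 0.90),
    p("Fusobacterium", "Putrescine", "receptor", 0.90),
    p("Fusobacterium", "Epinephrine_NE", "receptor", 0.90),
    p("Streptococcus", "DARs", "synthase", 0.90),
    # planted negatives well below the 30% identity threshold (local
    # alignments trim mismatching ends, so realized identity sits above the
    # full-length target near the boundary)
    p("Streptococcus", "AI-2", "synthase", 0.20),
    p("Prevotella", "AHL", "receptor", 0.20)
  )
}

# Coarse-phase trajectory parameters: bump centre (day), bump width (days).
# Centres sit at the midpoints of the default phase windows.
phase_bump <- function(phase) {
  switch(phase,
    AP = list(center = 1.0, width = 1.1),
    GP = list(center = 3.5, width = 1.5),
    MP = list(center = 8.0, width = 2.6),
    stop("unknown phase: ", phase, call. = FALSE)
  )
}

# Deterministic child seeds; kept below 2^31.
child_seed <- function(seed, k) (as.integer(seed) + 1009L * as.integer(k)) %% 2147483647L

#' Sample genus succession trajectories
#'
#' Draws the genus-by-sample relative-abundance table of a synthetic
#' community. Each genus follows a Gaussian bump over days centred in its
#' assigned peak phase on top of a small shared baseline; replicate noise is
#' multiplicative lognormal; samples are renormalized to sum to one. Under a
#' signal-interference effect map (see [simulate_interference()]), genera
#' marked `delayed_or_suppressed` have their bump shifted one day later and
#' damped, and genera marked `prolonged_or_enhanced` have their bump widened
#' and amplified.
#'
#' @param spec A [community_spec()].
#' @return A `qs_abundance` object (normalization `"relative"`) with one row
#'   per genus and one column per `(day, replicate)` sample, named
#'   `d{day}_r{replicate}`.
#' @export
sample_trajectories <- function(spec) {
  stopifnot(inherits(spec, "community_spec"))
  genera <- names(spec$genera)
  samples <- tidyr::expand_grid(day = spec$days, replicate = seq_len(spec$replicates))
  samples$sample_id <- sprintf("d%d_r%d", samples$day, samples$replicate)
  baseline <- 0.05
  effects <- spec$interference$effects
  raw <- withr::with_seed(child_seed(spec$seed, 1L), {
    vals <- sapply(seq_len(nrow(samples)), function(j) {
      sapply(genera, function(g) {
        bump <- phase_bump(spec$genera[[g]])
        amp <- 1
        eff <- if (!is.null(effects)) effects[[g]] else NULL
        if (identical(eff, "delayed_or_suppressed")) {
          bump$center <- bump$center + 1
          amp <- 0.6
        } else if (identical(eff, "prolonged_or_enhanced")) {
          bump$width <- bump$width * 1.6
          amp <- 1.5
        }
        mu <- baseline + amp * exp(-(samples$day[j] - bump$center)^2 / (2 * bump$width^2))
        if (spec$trajectory_noise_sd > 0) {
          mu * exp(rnorm(1, 0, spec$trajectory_noise_sd))
        } else {
          mu
        }
      })
    })
    matrix(vals,
      nrow = length(genera),
      dimnames = list(genera, samples$sample_id)
    )
  })
  rel <- sweep(raw, 2, colSums(raw), "/")
  new_abundance(rel, samples[, c("sample_id", "day", "replicate")], "relative")
}

#' Plant a homolog at a controlled percent identity
#'
#' Derives a synthetic homolog from a reference protein by substituting
#' residues at uniformly chosen positions (no indels): exactly
#' `round((1 - target_identity) * L)` positions are replaced by a different
#' residue drawn from the background composition, so the full-length
#' (ungapped) identity to the reference equals the target up to rounding.
#' The realized identity is recorded in the `"realized_identity"` attribute.
#'
#' @param reference_seq Amino-acid string of length >= 30.
#' @param target_identity Target fractional identity in (0, 1].
#' @param seed Integer seed; the result is deterministic given
#'   `(reference_seq, target_identity, seed)`.
#' @return The mutated amino-acid string, with attribute
#'   `realized_identity`.
#' @export
plant_homolog <- function(reference_seq, target_identity, seed) {
  check_aa(reference_seq, "reference_seq")
  if (target_identity <= 0 || target_identity > 1) {
    stop("target_identity must lie in (0, 1]", call. = FALSE)
  }
  L <- nchar(reference_seq)
  if (L < 30L) stop("reference sequence must have length >= 30", call. = FALSE)
  k <- round((1 - target_identity) * L)
  chars <- strsplit(reference_seq, "", fixed = TRUE)[[1]]
  if (k > 0) {
    withr::with_seed(as.integer(seed), {
      pos <- sample.int(L, k)
      for (i in pos) {
        chars[i] <- sample(setdiff(AA_ALPHABET20, chars[i]), 1)
      }
    })
  }
  out <- paste(chars, collapse = "")
  attr(out, "realized_identity") <- (L - k) / L
  out
}

# Residue-shuffled copy of a sequence: preserves composition and length,
# destroys positional homology (the hardest null for a local aligner).
shuffle_residues <- function(seq) {
  paste(sample(strsplit(seq, "", fixed = TRUE)[[1]]), collapse = "")
}

#' Generate a synthetic gene catalog with ground truth
#'
#' Expands a [community_spec()] into the full input set of the pipeline:
#' protein sequences, per-sample read counts, genus taxonomy, free-text
#' functional annotations, and a truth table recording each gene's class
#' (`qs_true`, `qs_decoy`, `recA`, `background`), planted signal/role and
#' realized identity. Read counts per sample are a multinomial draw of
#' `total_reads_per_sample` with per-gene probability proportional to genus
#' abundance x copies per cell x gene length (nucleotides), mirroring the
#' read-count/length confound that gene-length normalization removes.
#' Planted true homologs carry their reference's domain keyword in the
#' annotation text; decoys, planted negatives and background genes carry
#' generic annotations; every genus gets one single-copy recA gene.
#'
#' @param spec A [community_spec()].
#' @param refdb A `qs_refdb` containing every planted `(signal, role)`.
#' @return A list of class `qs_catalog` with elements `proteins` (named
#'   character vector), `counts` (a `qs_counts`), `taxonomy`, `annotations`,
#'   `truth` (tibbles) and `trajectories` (the genus `qs_abundance`).
#' @export
generate_catalog <- function(spec, refdb) {
  stopifnot(inherits(spec, "community_spec"), inherits(refdb, "qs_refdb"))
  traj <- sample_trajectories(spec)
  genera <- names(spec$genera)

  genes <- list()
  add_gene <- function(genus, class, signal, role, target_identity,
                       realized_identity, copies, sequence, annotation) {
    genes[[length(genes) + 1L]] <<- tibble::tibble(
      genus = genus, class = class, signal = signal, role = role,
      target_identity = target_identity, realized_identity = realized_identity,
      copies_per_cell = copies, sequence = sequence, annotation = annotation
    )
  }

  planted <- spec$planted
  if (nrow(planted) > 0L) {
    for (i in seq_len(nrow(planted))) {
      ref <- reference_entries(refdb, planted$signal[i], planted$role[i])
      if (nrow(ref) == 0L) {
        stop(sprintf(
          "no reference entry for planted (%s, %s)",
          planted$signal[i], planted$role[i]
        ), call. = FALSE)
      }
      ref <- ref[1L, ]
      seq <- plant_homolog(
        ref$sequence, planted$target_identity[i],
        child_seed(spec$seed, 100L + i)
      )
      is_true <- planted$target_identity[i] >= 0.30
      add_gene(
        genus = planted$genus[i],
        class = if (is_true) "qs_true" else "qs_decoy",
        signal = planted$signal[i], role = planted$role[i],
        target_identity = planted$target_identity[i],
        realized_identity = attr(seq, "realized_identity"),
        copies = planted$copies_per_cell[i],
        sequence = as.character(seq),
        annotation = if (is_true) {
          sprintf(
            "%s family protein, %s domain, %s-type quorum sensing",
            ref$protein_id, ref$domain_keyword, planted$signal[i]
          )
        } else {
          "hypothetical protein, weak uncharacterized similarity"
        }
      )
    }
  }

  withr::with_seed(child_seed(spec$seed, 2L), {
    for (g in genera) {
      add_gene(
        genus = g, class = "recA", signal = NA_character_, role = NA_character_,
        target_identity = NA_real_, realized_identity = NA_real_, copies = 1,
        sequence = random_protein(350L),
        annotation = "recA recombinase, DNA recombination and repair"
      )
      if (spec$decoys_per_genus > 0L) {
        ref_idx <- rep_len(seq_len(nrow(refdb)), spec$decoys_per_genus)
        for (j in seq_len(spec$decoys_per_genus)) {
          add_gene(
            genus = g, class = "qs_decoy", signal = NA_character_,
            role = NA_character_, target_identity = NA_real_,
            realized_identity = NA_real_, copies = 1,
            sequence = shuffle_residues(refdb$sequence[ref_idx[j]]),
            annotation = "hypothetical protein of unknown function"
          )
        }
      }
      if (spec$background_per_genus > 0L) {
        for (j in seq_len(spec$background_per_genus)) {
          add_gene(
            genus = g, class = "background", signal = NA_character_,
            role = NA_character_, target_identity = NA_real_,
            realized_identity = NA_real_, copies = 1,
            sequence = random_protein(sample(120:350, 1)),
            annotation = "conserved protein of core metabolism"
          )
        }
      }
    }
  })

  truth <- dplyr::bind_rows(genes)
  truth$gene_id <- sprintf("gene_%04d", seq_len(nrow(truth)))
  truth <- truth[, c("gene_id", setdiff(names(truth), "gene_id"))]

  proteins <- setNames(truth$sequence, truth$gene_id)
  nt_len <- setNames(3L * (nchar(truth$sequence) + 1L), truth$gene_id)

  abund <- traj$values[truth$genus, , drop = FALSE]
  weights <- abund * truth$copies_per_cell * nt_len
  counts_mat <- withr::with_seed(child_seed(spec$seed, 3L), {
    apply(weights, 2, function(w) {
      as.integer(rmultinom(1, spec$total_reads_per_sample, w))
    })
  })
  dimnames(counts_mat) <- list(truth$gene_id, colnames(traj$values))

  out <- list(
    proteins = proteins,
    counts = count_table(counts_mat, nt_len, traj$samples),
    taxonomy = truth[, c("gene_id", "genus")],
    annotations = truth[, c("gene_id", "annotation")],
    truth = truth[, c(
      "gene_id", "genus", "class", "signal", "role",
      "target_identity", "realized_identity", "copies_per_cell"
    )],
    trajectories = traj
  )
  attr(out$truth, "applied_interference") <- spec$interference
  class(out) <- "qs_catalog"
  out
}

#' @export
print.qs_catalog <- function(x, ...) {
  cat(sprintf(
    "Synthetic gene catalog: %d genes, %d samples (%s)\n",
    length(x$proteins), nrow(x$counts$samples),
    paste(range(x$counts$samples$day), collapse = "-")
  ))
  print(table(x$truth$class))
  invisible(x)
}

#' Apply a signal-interference scenario to a community spec
#'
#' Encodes blocking of one QS signal (e.g. AI-2 inhibition by a substrate
#' competitor) into the generator: the qualitative per-genus effects are
#' taken from [predict_interference()] on the supplied network, and the
#' returned spec's trajectories implement them -- genera predicted
#' `delayed_or_suppressed` peak one day later with a damped bump, genera
#' predicted `prolonged_or_enhanced` get a widened, amplified bump. The
#' effect map is recorded in the spec (and propagated into the generated
#' truth table), closing the loop between prediction and simulation.
#'
#' @param spec A [community_spec()].
#' @param network A `qs_network` from [build_network()].
#' @param signal Signal to interfere with; must be one of `network$signals`.
#' @return A modified `community_spec` (unchanged if the signal has no
#'   edges in the network).
#' @export
simulate_interference <- function(spec, network, signal) {
  stopifnot(inherits(spec, "community_spec"), inherits(network, "qs_network"))
  if (!signal %in% network$signals) {
    stop("signal not present in network: ", signal, call. = FALSE)
  }
  pred <- predict_interference(network, signal)
  if (all(pred$effects == "none")) {
    return(spec)
  }
  spec$interference <- list(signal = signal, effects = as.list(pred$effects))
  spec
}
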