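---
title: "Methods: longitudinal quorum-sensing cross-talk inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: longitudinal quorum-sensing cross-talk inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Bacteria coordinate density-dependent behavior through quorum sensing (QS):
dedicated synthases release diffusible signals (AI-2, acyl-homoserine
lactones, autoinducing peptides, DSF, HAQ, and others) that cognate
receptors detect. In an assembling multispecies community -- the motivating
system is an in vitro oral biofilm succession, where *Streptococcus*
dominates an adapting phase (AP), *Veillonella* and *Megasphaera* a growing
phase (GP), and *Prevotella* and *Fusobacterium* a mature phase (MP) --
signals synthesized by one genus can be sensed by another that peaks in a
different phase. `qscrosstalk` reconstructs this longitudinal cross-talk
structure from a time-series metagenomic gene catalog: it mines QS homologs,
normalizes their abundance to per-cell copy numbers, classifies pathway
completeness and phase specificity, builds the directed genus-to-genus
network, and predicts qualitative outcomes of blocking a signal.

Because the raw metagenomes of such experiments are large and external
(sequence archives, NCBI databases), the package ships a synthetic community
generator that reproduces the *structure* of the problem -- succession,
planted QS genes at controlled identity, single-copy *recA* markers, decoys
-- with full ground truth, so every inference step is testable end to end.

## Homolog retrieval

Each catalog protein is aligned against every reference protein by local
Smith--Waterman alignment with BLOSUM62 and affine gaps (open 11, extend 1;
a gap of length $L$ costs $11 + L$). Three filters follow the standard
BLASTP-style retrieval contract:

* **identity** $\geq 0.30$, computed BLAST-style as exact matches divided by
  aligned columns, counting gap columns;
* **coverage** $\geq 0.50$ of the *reference* (subject) by default. The
  literature rarely states which sequence a coverage threshold applies to;
  requiring the reference to be spanned guarantees the functional domain is
  present, and `search_thresholds(coverage_of = "query")` exposes the
  alternative;
* **e-value** $\leq 10^{-5}$ from the Karlin--Altschul formula
  $E = K\,m\,n\,e^{-\lambda S}$ with the standard gapped-BLOSUM62 constants
  $\lambda = 0.267$, $K = 0.041$, $m$ the query length and $n$ the total
  residue count of the catalog. On small synthetic catalogs these e-values
  are conservative (the search space is tiny), which only makes the filter
  stricter; the cutoff is configurable for micro-fixtures.

Each gene keeps at most one hit -- the highest-scoring passing alignment,
ties broken by lower e-value and then reference database order -- because
downstream abundance summaries assume a unique signal/role assignment per
gene. A second screen mirrors conserved-domain checking: a hit is kept only
if the gene's free-text annotation contains the matched reference's domain
keyword (case-insensitive). On real catalogs this corresponds to requiring a
consistent CDD/NR annotation; in the generator, true planted homologs carry
the keyword and decoys do not, which is what restores precision to 1 when a
residue-shuffled decoy sneaks past the alignment thresholds.

The alignment backend is the Biostrings dynamic-programming aligner; the
test suite verifies its scores against an independent plain-R
Smith--Waterman implementation on hundreds of random short pairs, so the
scoring convention (including the gap model) is pinned by tests rather than
assumed.

## Abundance normalization

Read counts confound gene length with gene dosage, so relative abundance is
length-corrected within each sample:

$$a_{gs} = \frac{c_{gs}/L_g}{\sum_{g'} c_{g's}/L_{g'}}$$

with $c_{gs}$ the reads of gene $g$ in sample $s$ and $L_g$ its nucleotide
length. Columns sum to one. QS homolog abundance is then expressed per cell
by dividing the summed relative abundance of each (signal, role) group by
the summed relative abundance of *recA*, a universal single-copy
housekeeping gene:

$$\text{copies per cell}(q, s) = \frac{\sum_{g \in q} a_{gs}}{\sum_{r \in \text{recA}} a_{rs}}.$$

The denominator is community-wide by default (one *recA* equivalent per
cell, so the ratio reads as an average copy number over all cells);
`normalize_by_recA(scope = "per_genus")` restricts both numerator and
denominator to each carrier genus, which is the natural choice when asking
about copy numbers *within* a taxon. recA genes are identified from the
annotation table (`recA_gene_ids()`), since gene catalogs do not flag them
intrinsically.

Genus succession profiles are plain sums of member-gene relative abundances,
and diversity is the Shannon index $H = -\sum p_i \ln p_i$ (natural log,
computed through vegan).

## Phase scheme and pathway classification

Sampling days partition into ordered phases with half-open windows: AP1
$[0,1)$, AP2 $[1,2)$, GP $[2,5)$, MP $[5,11]$, the terminal day inclusive.
Prose descriptions of phase boundaries ("day 2 to day 5") are ambiguous at
the joints; half-open windows are the one self-consistent reading, so day 2
is GP and day 11 is MP, and the tests pin those boundary calls.

A signal's pathway is **complete** when the community carries homologs of
both a synthesis-side protein and a receptor, **incomplete** with only one
side, **absent** with neither. Peptide processors (e.g. lantibiotic
cyclases) count as synthesis-side, since they are part of the production
machinery. Only complete pathways can deliver a signal and enter the
network.

Phase specificity of a per-cell abundance series is decided from its three
coarse-phase means: the top phase wins (`"AP-specific"`, etc.) when it
exceeds the runner-up by a dominance ratio of at least 1.5; otherwise a
series whose phase means are stable -- relative range
$(\max - \min)/\text{mean} < 0.25$ -- is labelled GP-specific, reflecting
pathways that stay active throughout assembly rather than peaking; anything
else is honestly `"unclassified"`. The dominance-then-stability structure is
a design choice (the underlying heatmap-style evidence in this literature
states no statistic); the relative range was chosen over a coefficient of
variation because it cleanly separates flat profiles from modestly tilted
ones at the same 0.25 threshold, and both thresholds are exposed as
parameters.

## Network construction and hubs

For every complete signal, an edge runs from each synthesis-carrying genus
to each receptor-carrying genus. Edge direction compares the two genera's
peak phases (the coarse phase maximizing mean relative abundance, ties to
the earliest phase): **forward** if the receiver peaks strictly later,
**reverse** if strictly earlier, **intra** otherwise; same-genus edges are
flagged self-talk and never propagate interference. Genera must reach a mean
relative abundance of 0.01 in their own peak phase to participate
(`min_genus_abundance`), mirroring the practice of reporting only top
genera.

A **hub** is a QS generalist: a genus carrying both synthesis-side and
receptor homologs and participating in at least two distinct complete
pathways (`min_signals = 2`). On the default community this yields exactly
the five successional genera. Neither the hub criterion nor the abundance
cutoff has a canonical definition in the literature; both defaults are
package choices, exposed as parameters.

## Interference prediction

Blocking a signal removes all of its edges. The qualitative consequences
propagate as:

1. receivers of forward edges lose their growth cue:
   `delayed_or_suppressed`, and the delay propagates along forward chains
   (a delayed genus delays its own forward receivers);
2. receivers of reverse edges lose a brake from later colonizers:
   `prolonged_or_enhanced` -- but only if no forward edge points at them.

Rule 2's precedence is the substantive design decision. A genus can be both
a forward receiver (from earlier colonizers) and a reverse receiver (from
later ones); for such a genus the forward loss acts at its own colonization
time, before the late-succession brake would ever have engaged, so the
direct delay dominates. Only the earliest colonizers -- reverse receivers
with no forward edge into them -- are released. On the default AI-2
subnetwork this reproduces the expected outcome of AI-2 inhibition:
*Streptococcus* prolonged and enhanced, all four later genera delayed or
suppressed. The converse precedence (release dominates everywhere) would
mark the GP genera as released, contradicting the delayed *Veillonella*
proliferation such experiments observe.

`simulate_interference()` closes the loop: it installs the *predicted*
effect map into the generator spec, which shifts delayed genera's trajectory
bumps one day later with 0.6-fold damping and widens released genera's bumps
1.6-fold with 1.5-fold amplification. Tests then verify both that the
simulated trajectories actually move as labelled and that the applied map
equals the prediction.

## The synthetic community generator

`community_spec()` defaults define the simulated community conditions used
throughout the tests and the acceptance script:

| parameter | default | meaning |
|---|---|---|
| genera | 5 core genera | Streptococcus→AP, Veillonella/Megasphaera→GP, Prevotella/Fusobacterium→MP |
| days, replicates | 0--11, 8 | 96 samples |
| total reads/sample | 200{,}000 | multinomial depth |
| planted genes | 42 | all 21 signals; AI-2 on both sides of all five genera |
| planted identities | 0.55--0.90 | true positives, spread across the pass band |
| planted negatives | 2 at 0.20 | must be rejected by the thresholds |
| decoys/genus | 8 | residue-shuffled references |
| background/genus | 72 | random proteins, 120--350 aa |
| trajectory noise | 0.15 | lognormal sd across replicates |

Trajectories are Gaussian bumps over days centred in each genus's peak
phase (centres 1.0/3.5/8.0, widths 1.1/1.5/2.6 days) on a 0.05 baseline,
renormalized per sample -- the simplest shape matching unimodal
successional curves. Counts are multinomial with probability proportional
to genus abundance × copies per cell × gene length, reproducing exactly the
length confound the normalization removes; a planted two-copy gene is
recovered at $2.0$ within multinomial error, which the tests bound with a
delta-method standard error.

`plant_homolog()` substitutes residues at uniformly chosen positions (no
indels by default), so realized full-length identity equals the target up
to rounding. Near the 0.30 retrieval threshold, *local* alignment identity
sits above the full-length value because mismatching ends are trimmed;
planted negatives therefore default to 0.20, where rejection is robust
(identity, coverage and e-value all fail). Decoys are residue-shuffled
reference sequences -- composition preserved, positional homology destroyed
-- the hardest null for a local aligner.

The reference database bundled with the package (`synthetic_reference_db()`)
reproduces the *structure* of curated QS references: 37 proteins across 21
signals, ten signals with both roles (including the two-step AI-2 synthesis
Pfs→LuxS and a lantibiotic processor), eleven with one role. Protein names,
roles and source organisms follow the curated QS systems literature; the
sequences themselves are seeded random proteins, which is sufficient --- and
labelled as synthetic --- because every validation question here concerns
the inference machinery, not real protein families.

What the generator does **not** emulate: assembly and gene-calling
artifacts (chimeras, fragmented ORFs), strain-level variation, real domain
architectures (annotation keywords stand in for conserved-domain content),
horizontal transfer, absolute biomass (only relative composition is
modelled), and read-level error. Passing tests therefore demonstrate that
the inference chain is correct *given* a catalog with these properties; on
real data, sensitivity will additionally depend on gene-calling quality and
the curation of the reference database.

## Problem sizes and runtime choices

The default validation community holds 447 genes × 96 samples; a full
search against the 37-protein reference DB runs in well under a minute, and
the complete acceptance run (pipeline, network recovery, interference loop,
copy-number recovery) in under half a minute. Unit tests use reduced
communities (fewer decoys and background genes, depth 50{,}000) so the whole
suite stays fast; the copy-number recovery test runs at depths 30{,}000 and
300{,}000 to show convergence. All randomness flows from a single integer
seed per spec; child seeds are derived arithmetically and kept below
$2^{31}$, and every generator output is a pure function of its spec.

## Known limitations

* Directionality is inferred from peak-phase order, not from observed
  signal transfer; contemporaneous (intra) cross-talk is detected but
  carries no direction.
* The e-value model uses fixed ungapped-approximation constants rather than
  fitting $\lambda, K$ to the scoring system; for threshold behavior at
  these scales the distinction is immaterial, but absolute e-values should
  not be over-interpreted.
* Interference predictions are qualitative three-level labels; the package
  deliberately avoids fitting growth-rate dynamics, for which a gene
  catalog provides no direct evidence.
* With `scope = "community"`, per-cell copy numbers of a taxon-restricted
  gene scale with the carrier's relative abundance; use
  `scope = "per_genus"` for within-taxon copy numbers.
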