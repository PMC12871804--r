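---
title: "Methods: tracing a repeat-borne intronic polyadenylation site"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tracing a repeat-borne intronic polyadenylation site}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ipastrace)
```

# The problem

A polyadenylation signal (PAS) inside an intron truncates a fraction of a
gene's transcripts: cleavage and polyadenylation at the intronic site
(iPAS) produces a short mRNA whose coding sequence runs past the last
shared exon into the intron until the first in-frame stop, acquiring a
short intron-encoded C-terminal peptide and an intron-derived 3'UTR.
Transposable elements are a recurrent source of such signals: the A-rich
3' tail of Alu/SINE elements readily contains or evolves AATAAA hexamers.
`ipastrace` implements the computational chain needed to characterize such
an event end to end: discover the signals in sequence, predict the
truncated isoform, quantify its usage from short- and long-read RNA-seq
summaries, reconstruct when the element and its signals arose on a species
tree, and characterize the truncated protein's interactions by IP-MS
stoichiometry and structural interface mapping.

# PAS discovery and isoform prediction

`scan_pas()` reports *every* occurrence of the motif set, including
mutually overlapping ones — overlapping AATAAA copies sharing adenosines
are exactly what A-rich repeat tails produce, and ordinary regex scans
silently skip them. The default motif set is the canonical `AATAAA` alone;
the twelve common variants are available via `pas_variant_motifs()` but
off by default, because variant hexamers in an A-rich tract are mostly
noise. Soft-masked (lowercase) sequence matches by design: repeat-embedded
signals are the object of study, `N` never matches.

`cluster_hits()` groups hits by transitive closure under a one-base
overlap. This has no tunable threshold: "partially overlapping" is a
topological property, and closure is idempotent and partition-forming
(property-tested).

`predict_cleavage_site()` applies a fixed-offset heuristic: cleavage
20 nt downstream (transcript orientation) of the 3' end of the 5'-most
hexamer in the cluster. The canonical CPSF/CstF spacing motivates the
default; learned cleavage models are deliberately out of scope, so the
offset is exposed as a parameter (`offset_nt`, non-negative integer,
default 20).

`extend_orf_into_intron()` translates the CDS through the last shared
exon, carries any partial codon across the exon/intron boundary, and reads
intronic codons to the first stop. Residues whose codon contains at least
one intronic nucleotide define the tail peptide — a junction-spanning
codon is unique to the truncated isoform, so it counts as tail. Molecular
weight uses standard average (not monoisotopic) residue masses, retains
the initiator Met and assumes no modifications; a single glycine
reproduces free glycine's 75.07 Da within 0.01.

Coordinates are 0-based half-open on the plus-strand genome axis
throughout; 1-based on-disk dialects (GTF, RepeatMasker, STAR junction
tables) are converted at the readers. Strand enters only at operation
time (cleavage-site arithmetic, transcript orientation).

# Short-isoform fraction from junction counts

Junctions upstream of the iPAS are shared by both isoforms; junctions
downstream belong only to the full-length transcript. With
$\psi$ the fraction of transcripts terminating at the iPAS, expected
junction coverage is proportional to 1 upstream and $1-\psi$ downstream,
giving the estimator

$$\hat\psi = \mathrm{clip}\left(1 -
  \frac{\overline{c}_{\mathrm{down}}}{\overline{c}_{\mathrm{up}}},\;
  0, 1\right).$$

Group *means* (not sums) make the estimator immune to unequal group sizes
(four upstream vs five downstream junctions in the ten-exon walkthrough).
Only uniquely mapping reads (STAR column 7) are counted. The unclipped
value is kept in a diagnostic field (`psi_raw`); negative values flag
sampling noise at low $\psi$. Uncertainty comes from a seeded multinomial
bootstrap over all junctions (percentile interval, 2,000 resamples by
default), and the no-truncation null (equal expectation at every
junction) is tested by chi-square goodness of fit, replaced by a
Monte-Carlo multinomial test below 500 total reads where the asymptotics
are doubtful.

This estimator is the maximum-likelihood estimator of the two-weight
multinomial model, which fixes its precision. Because the upstream and
downstream totals sum to the depth $n$ exactly, $\hat\psi$ is a smooth
function of the single binomial count $S_u \sim \mathrm{Bin}(n, p_u)$
with $p_u = k_u / (k_u + (1-\psi) k_d)$, and the delta method gives, at
$n = 10^4$ with $k_u = 4$, $k_d = 5$:
$\mathrm{sd}(\hat\psi) \approx 0.018$ at $\psi = 0.1$, $0.014$ at $0.3$,
$0.010$ at $0.5$ and $0.007$ at $0.7$.
Consequently $P(|\hat\psi - \psi| < 0.03)$ is about 0.90 at $\psi = 0.1$
and only crosses 95% from $\psi \approx 0.3$ upward. No estimator of this
model can do materially better at that depth (the MLE saturates the
information bound), which is why the recovery tests treat the low-$\psi$,
fixed-depth regime as a documented limitation rather than a target.

`pext_like()` computes the proportion-expressed-across-transcripts score
(TPM of transcripts containing an exon over total gene TPM, per tissue),
and `isoform_ratio()` flags tissues outside the 0.5-2-fold co-expression
band. Tissues with zero gene expression are skipped with a warning, never
imputed.

# Long-read collapse and classification

Long reads are reduced to exon chains; the internal junction list is the
identity of an isoform. `collapse_chains()` groups reads by exact junction
chain and then merges terminal ends by single-linkage connected components
within a tolerance (default 50 nt at both ends — standard long-read
collapse practice); the longest-span member represents each group.
`classify_read()` assigns a read to the unique model whose junction chain
it reproduces (junction tolerance 0 by default: splice junctions are
base-exact in spliced alignments) and whose termini match within the
terminal tolerance. Reads whose chain is a junction-subchain of a model
and whose ends stay inside the corresponding model exons are labelled
`ambiguous`, never counted as short-isoform evidence: a truncated
isoform's only distinguishing feature may be its terminus, and 3'
degradation artifacts would otherwise inflate it. Everything else is
`novel`.

# Evolutionary reconstruction

Two characters evolve on the dated species tree: element presence and
PAS count.

**Presence (Dollo).** A retrotransposon insertion is a unique event, so
presence follows Dollo parsimony: one gain on the branch above the most
recent common ancestor of all anchoring tips, and losses on the minimal
branch set covering non-present descendants. Tip states are
`present`, `absent`, or `lost` — the third state marks species where
independent evidence (deletion breakpoints spanning the element's
position) shows the element was ancestrally present and secondarily
removed. A `lost` tip anchors the gain node like a present tip but
receives a loss branch. This three-state coding matters: with the bundled
primate matrix, plain two-state Dollo would place the gain one node too
shallow (Catarrhini) with no losses; the deletion evidence in the New
World monkey lineage is what pushes the insertion to the Simiiformes stem
with one Platyrrhini loss.

**Count (Sankoff).** PAS count evolves under Sankoff parsimony with a
linear cost matrix, $c(i \to j) = |i - j|$ (each substitution creates or
destroys one hexamer); unit costs are available by flag. Tips where the
element is absent carry `NA` and are unconstrained — absence of the
region is not a count of zero. The implementation runs the standard
bottom-up cost-vector pass plus a top-down pass computing, for every
node, the set of states attained in some globally optimal assignment.
Events are reported per branch only where the parent and child optimal
sets are disjoint (the change is certain across all optima); overlapping
but unequal sets are listed separately as possible events. Set-based
certainty is slightly conservative — states in two sets need not co-occur
in one optimal assignment — which errs on the side of reporting fewer
certain events.

`date_event()` brackets an event by its branch ends, `[child age, parent
age]` in Mya; node ages come from the ultrametric input tree (TimeTree-style
ages are inputs, not estimates — no molecular dating is performed). The
bundled tree places the human-chimp split at 6 Mya and the modern
human-Neanderthal ancestor at 0.5 Mya, so the triple-signal gain on the
Homo branch dates to [0.5, 6] Mya and the element insertion on the
Simiiformes stem to [43, 65] Mya.

**What recovery tests can show.** Exact event-branch recovery from tip
states is only possible for identifiable histories: an event on one of
the root's two child branches cannot be polarized without an outgroup,
and nested or sibling compensating events collapse into cheaper
single-change explanations that parsimony rightly prefers. The
simulation-recovery tests therefore condition on identifiable planted
histories (no root-adjacent events, events on non-nested branches with
distinct parents); unconditioned recovery plateaus around 80-87%
regardless of implementation.

# IP-MS: enrichment and stoichiometry

`compute_nsaf()` divides spectral counts by protein length (SAF) and
normalizes each run to sum to one over detected proteins; NSAF columns
are molar-fraction proxies, invariant to uniform count scaling.
`stoichiometry()` divides each protein's NSAF by the bait's within each
replicate run, then averages across runs (bait fixed at 1, SEM =
sd/sqrt(n)). Normalizing per run before averaging (rather than averaging
NSAF first) keeps run-to-run depth differences out of the ratio; the
alternative order is noted as a variant but not implemented.

`enrichment_test()` is the Perseus-style workflow: log2 transform,
per-run median centering, imputation of missing values from a down-shifted
Gaussian (per run: mean $- 1.8\sigma$, width $0.3\sigma$, the Perseus
convention),
Welch's t-test per protein (the safer default when only "t-test" is
specified; Student's by flag), Benjamini-Hochberg adjustment, and a
significance flag at FDR 0.01. Permutation-based FDR with S0 is out of
scope. Proteins missing everywhere are dropped with a warning;
constant-and-identical rows get p = 1; constant-but-different rows are
undefined (p = NA) and never flagged.

Two statistical facts shape what the validation suite asserts at the
routine triplicate design ($n = 3$ runs/group):

* `mean ± 2·SEM` over three replicates is a Student-t interval with 2
  degrees of freedom; its *nominal* coverage ceiling is
  $P(|t_2| < 2) = 0.816$, independent of measurement precision. Coverage
  assertions at triplicate design are therefore made against that bound,
  not against a Gaussian 95%.
* the Welch statistic with three-vs-three samples is heavy-tailed (2-4
  df), so the p-values of even strong (8-fold) spike-ins straddle a BH
  cutoff at FDR 0.01 among ~200 proteins. What is robust — and what the
  tests assert — is the ranking (spikes dominate the smallest p-values),
  the fold-change estimate, and type-I control (the all-null flag rate
  stays below 2% at FDR 0.01).

# Interface mapping from structure

`shrake_rupley()` computes solvent-accessible surface area with a
deterministic golden-spiral quadrature (960 points per atom by default,
probe 1.4 Å) and a uniform spatial grid for neighbor search: identical
inputs give bit-identical areas. Against closed forms, an isolated sphere
is exact to <0.5% and the two-sphere spherical-cap configuration to <1%.
Heavy atoms only by default (cryo-EM models lack hydrogens); alternate
locations resolve to the highest-occupancy conformer; van der Waals radii
come from a bundled Bondi-type element table (unknown elements fall back
to carbon's 1.70 Å).

`buried_fraction()` is (SASA alone − SASA in complex)/SASA alone for a
chain. `residue_interface_map()` attributes burial *pairwise*: for each
partner chain, the target's per-residue SASA with only that partner
present is compared to the target alone. Pairwise (rather than
leave-one-out) attribution is conservative where partners share a burial
site and matches the "main interacting subunit" semantics — the partner
burying the most area wins, exact ties resolve by the declared chain
order, residues burying nothing stay unassigned, and residue numbers
missing from the model form the unresolved mask.

# The synthetic-data generators

Every input dialect the pipeline reads can be generated with recorded
ground truth: a locus with a planted repeat-borne PAS (FASTA +
exon table + repeat BED), STAR-style junction tables under the
two-isoform mixture, character histories on a tree, spectral counts from
a known stoichiometry, long reads from isoform models (BED12), and toy
atomic structures with analytic surface areas (PDB). One global seed fans
out to per-stage child seeds (`child_seed()`), so stages are
independently reproducible and byte-identical under regeneration.

Design choices worth knowing:

* `gen_locus()` *sanitizes* the sequence — every AATAAA outside the
  planted set is disrupted — so the truth sidecar is the complete ground
  truth for a canonical-motif scan even after random mutation. Planted
  hexamers overlap at stride 4 (`AATAAATAAA...`), the geometry that makes
  overlapping signals possible in an A-rich tract.
* `taf8_like_locus()` is the deterministic walkthrough fixture: common
  CDS of 163 residues ending on a codon boundary at exon 5, an
  11-residue designed intronic tail (`VSDEALGLRVV`) before the stop, the
  element 120 nt into the intron, three overlapping hexamers placed so
  the 20-nt offset yields a 240-nt 3'UTR and a 174-residue, ~19 kDa
  protein.
* `gen_junction_counts()` draws a single multinomial of size `depth`
  (weights 1 upstream, $1-\psi$ downstream), with optional
  Dirichlet-style overdispersion. Default depth 10,000 and 4/5 junctions
  mirror a ten-exon gene truncated after exon 5 at bulk RNA-seq depth.
* `gen_spectral_counts()` samples counts proportional to abundance ×
  length over complex members plus low-abundance background proteins;
  triplicate runs at depth 20,000 mirror a routine IP-MS experiment.
* What the generators do *not* emulate: alignment artifacts,
  multi-mapping reads, 3'-bias, inter-sample batch effects, peptide-level
  missingness structure, or real repeat divergence. Passing recovery
  tests therefore demonstrates estimator correctness under the stated
  models, not robustness to upstream artifacts.

# Analysis problem sizes

The shipped analyses and validation runs use: 200 estimator replicates at
depth 10,000 per $\psi$; 1,000 random sequences for the scan oracle; 200
random trees (≤8 tips, ≤4 states) for the exhaustive parsimony oracle;
100 seeds for the all-null FDR simulation (200 proteins each) and 100
replicates for stoichiometry recovery; 960 quadrature points per atom for
SASA. These sizes make every check sharp enough to fail on a real defect
while keeping the full suite fast.

# Known limitations

* The cleavage site is a fixed-offset heuristic; real cleavage is
  heterogeneous and sequence-context dependent.
* Only the canonical AATAAA drives the shipped analyses; variant-signal
  usage is untested against data.
* Parsimony reports branch intervals, not point dates, and cannot decide
  whether the two extra human hexamers arose in one mutational event or
  two.
* The junction estimator assumes uniform coverage across junctions within
  an isoform; strong 3' bias would distort $\hat\psi$.
* Buried-surface values depend on the radii table, probe and quadrature
  density; comparisons across software should fix all three.
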