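---
title: "Detecting and classifying NUMTs: models, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and classifying NUMTs: models, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(numtatlas)
```

## The problem

Nuclear mitochondrial DNA sequences (NUMTs) are fragments of the
mitochondrial genome that have integrated into nuclear chromosomes,
most plausibly through non-homologous end joining at double-strand
breaks. After insertion they are shaped by the surrounding genome:
they can be duplicated together with their flanking nuclear DNA
(duplicate-type NUMTs), or fragmented by transposable-element (TE)
insertion, leaving a chain of co-oriented, syntenic fragments on one
scaffold that descends from a single insertion event (complex NUMTs).
Counting and classifying these copies correctly is what separates "this
genome has many NUMT insertions" from "this genome amplified a few
insertions after the fact" — two very different evolutionary stories.

`numtatlas` implements the full desk-side pipeline: homology search,
classification, genomic-context profiling, and the comparative
statistics used to relate NUMT content to genome properties across
species. A synthetic-genome simulator with planted, truth-tagged
features makes every stage testable end to end without any external
data.

## Homology search

`scan_numts()` aligns the mitochondrial genome against each nuclear
scaffold on both strands with a seed-and-extend local aligner: exact
`word_size`-mer seeds (default 11), ungapped x-drop extension
(default drop 20) to delimit a candidate region, then an optimal gapped
Smith–Waterman (Gotoh) alignment with traceback inside that region.
Because the final step is a full optimal alignment of the region, each
reported hit's raw score equals the Smith–Waterman optimum for its
coordinates — a property the test suite checks against an independent
dynamic-programming implementation on hundreds of random pairs.

Scoring follows megablast-style defaults: match +1, mismatch −2, gap of
length $L$ costs $5 + 2L$. Significance uses the Karlin–Altschul
formula
$$E = K\,m\,n\,e^{-\lambda S},$$
with $\lambda = 1.28$, $K = 0.46$ (the ungapped values for +1/−2
scoring), $m$ the mitochondrial length and $n$ the total nuclear
length. Two deliberate simplifications are documented rather than
hidden:

* the search space is the raw product $m \times n$ with no edge
  correction, so E-values close to a threshold can differ from NCBI
  blastn's;
* alignments that could never pass the `evalue_max` filter (default
  $10^{-4}$) are not enumerated at all. This floor keeps the scan fast
  on AT-rich genomes, where the background seed rate is high; it means
  `scan_numts()` output starts at the significance floor rather than at
  the seed score.

The canonical acceptance filter — E below $10^{-4}$ and nuclear length
of at least 50 bp — is applied by `filter_hits()`. Pipelines that ran
NCBI blastn externally can enter at `read_blast_tab()` (outfmt 6)
instead of `scan_numts()`.

The mitochondrial genome is treated as linear. A NUMT spanning the
circular origin would appear as two hits touching the two termini;
such hits carry a `mito_terminal` flag so users can join them manually.
N bases never match, never seed, and a run of ten or more Ns stops
extension.

## Classification

**Complex clusters** (`cluster_complex()`) chain filtered hits
left-to-right per scaffold under three criteria: consecutive members
separated by less than `max_gap` (default 10 kb) of non-mitochondrial
DNA; consistent strand; and preserved synteny, meaning the
mitochondrial intervals advance along the scaffold for "+" chains and
retreat for "−" chains. Synteny tolerates up to `synteny_slack`
(default 30 bp) of mitochondrial-interval overlap between consecutive
members: local-alignment endpoints jitter a few bases past a
fragmentation junction when flanking TE bases happen to match, and
without the tolerance genuinely single-event fragment chains break.
Fragments that re-use a substantial part of the previous member's
mitochondrial interval — re-duplicated fragments — still break the
chain, because the order of mitochondrial starts must strictly
advance. Chaining is greedy; for the criteria above a greedy pass is
deterministic, linear, and cannot split a valid chain.

**Duplicate families** (`detect_duplicates()`) implement the
flank-homology principle: if one NUMT arose from another by nuclear
duplication, homology extends into the flanking nuclear DNA, and flank
similarity matches NUMT similarity. Pairs whose mitochondrial
intervals overlap by at least half of the shorter one (duplication
preserves the mitochondrial span, so other pairs cannot be duplicates)
are aligned body-vs-body; pairs at or above `dup_min_numt_similarity`
(default 0.80) have their `flank_len` (default 1 kb) flanks aligned
left-vs-left and right-vs-right in mitochondrial orientation, with
flanks swapped and reverse-complemented across opposite-strand pairs.
A link requires a flank alignment of at least `min_flank_homology`
(default 100 bp) contiguous with the NUMT boundary (within
`boundary_slack`, 20 bp) whose identity matches the body identity to
within `similarity_tolerance` (default 0.05). Families are connected
components of the link graph. The numeric defaults quantify a
principle that the field states qualitatively; all are parameters and
all are reported in output.

**Type labels** (`label_types()`): within each family the member most
similar to the mitochondrial genome is taken as the putative original
and labelled `insertion`; the rest are `duplicate`; NUMTs outside any
family are `insertion`. Whether published counts treat one member per
family as an insertion or label whole families duplicate is genuinely
ambiguous, so `mode = "family-duplicate"` exposes the other
convention. Either way the arithmetic identity
`n_insertion + n_duplicate = n_total` holds exactly.

## Genomic context

`at_profile()` tiles the 250 bp flanks and the first/last 50 bp of each
NUMT with 5 bp sliding windows (step 1) and averages per offset over
NUMTs. `classify_position()` assigns each NUMT by 1 bp-overlap
precedence CDS > intron > intergenic, resolving overlapping gene
models by longest-gene precedence, and counts distinct genes hosting
intronic NUMTs. `density_tracks()` computes NUMT and TE coverage in
50 kb tiles over NUMT-bearing scaffolds; the tiles are non-overlapping
by default (the step is configurable) and overlapping annotations are
flattened before coverage is measured. `te_vicinity()` scans 5 kb
flanks for annotated TEs — a TE counts if it overlaps the flank by at
least 1 bp, so an element whose edge gap is 4,999 bp counts and one at
5,000 bp does not — and reports the nearest element's superfamily
(minimum edge distance, ties to larger overlap, then first by
coordinate). Complex clusters are passed as single units via
`cluster_spans()` with `include_interior = TRUE`, since the
fragmenting TEs sit inside the cluster span.

### The flank AT test and its calibration

`flank_at_test()` pairs each NUMT's 10 bp flank AT content with the
mean AT of its host scaffold (computed over the whole scaffold, NUMTs
included — the simplest reading of "scaffold average") and applies a
one-sided Wilcoxon signed-rank test. One subtlety matters: the flank
AT content of one NUMT is an integer count over 20 sites, a lattice
variable. Pairing it against a scaffold mean that falls between
lattice points would convert the entire probability mass at the
reference cell into signed noise and miscalibrate the test badly (in
simulation, null p-values drift to means of 0.35–0.53 depending on
which side of a lattice point the scaffold mean lands). The package
therefore quantizes the reference to the measurement lattice —
differences are `AT count − round(n_sites × scaffold AT)` — which
restores the symmetric null without changing what is compared. With
this, simulated null p-values are uniform (Kolmogorov–Smirnov p ≈ 0.7
over independent 200-seed batches at realistic AT-rich composition)
and power against a strong insertion-site bias is essentially 1 at 100
NUMTs. The residual binomial skew of flank AT at compositions far from
50% AT is a second-order effect and is left uncorrected.

## Comparative statistics

`pgls_fit()` is generalized least squares under a Brownian-motion
covariance: $C_{ij}$ is the shared root-to-MRCA branch length, built
with `ape::vcv()`, and
$\hat\beta = (X^\top C^{-1}X)^{-1}X^\top C^{-1}y$ is computed through
the Cholesky factor of $C$. Pagel's $\lambda$ is fixed at 1 (pure
Brownian motion); reports record that assumption. $R^2$ is
$1 - \mathrm{RSS}/\mathrm{TSS}$ on the whitened scale with TSS about
the GLS mean, and the slope p-value is a t-test with $n-2$ degrees of
freedom. On a star tree with equal branch lengths the whole procedure
collapses to ordinary least squares, which the tests verify at machine
precision; a dense-algebra oracle (covariance by explicit shared-path
enumeration, inversion by `solve()`) checks a fixed 5-tip instance at
$10^{-10}$.

`rank_test()` provides both Wilcoxon variants with *exact, tie-aware*
null distributions computed by dynamic programming over the observed
(average) ranks — up to 25 non-zero differences for the signed-rank
test and total sample size 30 for the rank-sum test — and a
tie-corrected, continuity-corrected normal approximation beyond that.
`spearman_cor()` enumerates all permutations for $n \le 9$ and uses
the t approximation otherwise. Exactness is tested against brute-force
enumeration (all $2^m$ sign vectors; all $\binom{N}{n_1}$ subsets; all
$n!$ permutations). `bin_length_similarity()` produces the binned
length/identity tables (left-closed, right-open, last bin closed).

## The synthetic-genome simulator

`simulate_genome()` is first-class, tested code, not a fixture. It
emulates the statistical structure the analysis assumes:

* an AT-rich linear mitochondrial genome (default 15,800 bp at 78% AT,
  the composition of insect mtDNA) and a multi-scaffold nuclear
  background (default 65% AT);
* insertion-type NUMTs: copies of random mitochondrial segments
  (default length uniform on 100–3,000 bp) mutated by substitutions at
  a per-site rate drawn from `divergence` (default uniform on
  [0, 0.2] — the field reports divergence distributions only as
  histogram bins, so this is a modelling choice, not data);
* AT-biased insertion sites: candidate points scored by the AT
  fraction of the surrounding 20 bp, sampled with weight
  $(\mathrm{AT})^{\texttt{at\_site\_bias}}$. The exponent 0 gives
  uniform placement (used for null calibration), 1 is the mild default,
  and values ≫ 1 reproduce the observed AT enrichment at insertion
  sites;
* duplicate-type NUMTs: a planted NUMT plus `dup_flank_carry` bp
  (default 1 kb) of its nuclear flanks, re-inserted elsewhere after
  `dup_extra_divergence` (default 0.02) further substitution —
  duplicates are placed uniformly since they arise by segmental
  duplication, and they carry their own flanks regardless;
* complex events: one insertion split into 2–3 fragments by TE
  sequences from the library, fragments keeping order and strand and
  sharing a truth `cluster_id`; the fragment gap equals the TE length;
* background TEs, optionally co-located near NUMTs
  (`te_numt_colocation`) to emulate the shared preference of TEs and
  NUMTs for unstable regions;
* gene models with 2–5 exons placed uniformly without overlap; planted
  features never interrupt exons by default (`allow_exonic` exists for
  negative controls), matching the observation that NUMTs are absent
  from coding sequence.

Every feature is an *insertion* into the background (scaffolds grow),
so truth intervals are exact, nothing overlaps, and nothing crosses a
scaffold boundary. Mutations are substitutions only by default for the
same reason. `min_spacing` (default 12 kb) keeps independent planted
events farther apart than the 10 kb complex-chaining threshold, so
only genuinely fragmented events can form clusters. The simulation is
byte-identical given its configuration, including the seed.

What the simulator does *not* emulate — and hence what passing tests
do not show about real genomes: realistic mitochondrial gene content
and codon structure, indels and rearrangements inside NUMTs, nested or
overlapping insertions, tandem duplication, segmental duplications
larger than one NUMT, assembly artefacts, and sequencing error.
Recovery rates on synthetic genomes are therefore upper bounds for
real data.

## Validation at a glance

The test suite (all sizes chosen to keep a full run within minutes on
one core) checks, among others:

* aligner scores equal to an independent Smith–Waterman oracle on 200
  random pairs of up to 2 kb;
* ≥95% recovery of 200 NUMTs (divergence ≤ 0.10, length ≥ 100 bp)
  planted in a 5 Mb genome at ≥80% reciprocal overlap, and zero
  accepted hits on plant-free 1 Mb genomes across 20 seeds;
* exact reconstruction (membership and order) of 30 TE-fragmented
  insertions with gaps of 1–8 kb, and zero clusters when the planted
  gaps are 12 kb;
* ≥90% recovery of planted duplication links with zero false links
  among 100 independent insertions;
* flank-AT-test null uniformity over 200 simulated genomes and power
  > 0.9 under strong site bias;
* PGLS slope recovery within three standard errors over 200
  Brownian-motion simulations on 50-tip trees, with ~95% confidence
  interval coverage;
* exact agreement of the rank tests and Spearman p-values with
  brute-force enumeration for small samples.

`scripts/acceptance.R` re-runs a condensed version of this battery
from scratch and writes the resulting quantities as JSON.

## Known limitations

* The aligner is a heuristic: a hit whose every seed is destroyed by
  divergence (roughly d ≳ 0.25 at the default word size) is invisible,
  and gapped alignments scoring just above the significance floor but
  whose ungapped core sits more than 10 points below it can be missed.
* E-values use ungapped Karlin–Altschul parameters for the gapped
  scoring scheme and no edge correction; counts near the threshold are
  not expected to match NCBI blastn hit-for-hit.
* Duplicate detection compares NUMT pairs; a duplication whose source
  copy has since been deleted appears as an ordinary insertion.
* PGLS assumes pure Brownian motion; no Ornstein–Uhlenbeck or
  $\lambda$-estimation is provided.
* The signed-rank flank test inherits a mild anti-conservativeness
  from flank-AT skewness at extreme compositions (see above); at the
  compositions typical of insect genomes the effect is negligible in
  simulation.
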