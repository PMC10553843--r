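---
title: "Methods: comparative genomics of syntrophic SRB with syntrophr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative genomics of syntrophic SRB with syntrophr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(syntrophr)
```

`syntrophr` analyses annotated genomes of sulfate-reducing bacteria (SRB)
that live in syntrophic partnership with anaerobic methanotrophic archaea
(ANME). The biological question behind each stage is the same: which parts
of the syntrophic lifestyle — direct electron uptake through multiheme
cytochromes and outer-membrane conduits, biofilm polysaccharides, adhesins
— were inherited from the free-living ancestors of these clades, which were
acquired horizontally, and which were lost or remodelled along the way.
This vignette explains the models and rules each stage implements, the
tunable parameters and why their defaults are what they are, what the
synthetic-data generator does and does not emulate, and the numerical
choices a maintainer should know about.

## The cytochrome census

c-type cytochromes attach heme covalently at the CxxCH motif, so the heme
complement of a protein is estimated by counting occurrences of
`C-x-x-C-H` over every 5-residue window. Two decisions matter:

* **Overlaps are counted.** Two motifs may share a cysteine (e.g.
  `CAACHACH` has motifs at positions 1 and 4). Closely spaced heme motifs
  are real in multiheme proteins, and lookahead counting is pinned by a
  brute-force every-window oracle in the tests.
* **`X` never matches C or H.** MAG proteins are gappy; treating unknown
  residues as potential cysteines would inflate heme counts, so `X` is
  only allowed in the wildcard positions.

The motif is configurable (`count_heme_motifs(seq, motif = "CxxxCH")`) but
only `CxxCH` is scanned by default; CXXCK and long-spacer variants are out
of scope.

Counts map to categories with two boundaries: ≥ 4 motifs makes a protein
*multiheme* (inclusive), and strictly more than 5 makes it a *conduit
candidate* — the class whose gene neighborhoods are searched for porins. A
5-heme cytochrome is therefore never a conduit candidate under defaults;
the tests exercise both boundaries explicitly.

**Type clustering.** Field practice groups census hits into "types" by
eye from alignments. That is not reproducible, so
`cluster_cytochrome_types()` replaces it with deterministic greedy centroid
clustering: sequences are processed longest-first (ties broken by gene id),
and a sequence joins the earliest-founded centroid whose global-alignment
identity (matches / alignment columns, BLOSUM62, gap open 11 / extend 1)
reaches the cutoff, else founds a new type. The default cutoff of 0.50 is
a stand-in — no threshold can be recovered from by-eye clustering — and is
exposed as `identity_cutoff`. Because processing order is recomputed
internally, the result is invariant to the order of the input rows.

## The conduit rule

The EET conduit model is a porin (outer-membrane beta-barrel) feeding
electrons to periplasmic/extracellular multiheme cytochromes. The caller
implements the neighborhood rule directly: a cluster is reported for every
barrel gene that has at least one cytochrome with more than 5 CxxCH motifs
within 10 genes on the same contig. Distance is measured in gene ranks
(`gene_index`: the 0-based rank of a CDS along its contig by start
coordinate), strand is ignored, and the 10-gene boundary is inclusive —
distance 10 is a hit, distance 11 is not. Only CDS features are counted in
the rank, which can matter on RNA-dense loci; this is a deliberate,
documented choice.

Clusters are anchored on barrels rather than on cytochromes. The oetABI-type
cassettes place several cytochromes around one porin; anchoring on the
porin reports such a cassette once, while a cytochrome flanked by two
barrels legitimately appears in both clusters.

Barrel evidence is an input table (mirroring the use of a dedicated
predictor whose internals are out of scope). For synthetic data a built-in
screen exists (`predict_barrels()`): length ≥ 300 aa, C-terminal aromatic
(F/W/Y), and a sustained period-2 Kyte-Doolittle alternation — at least 8
windows and ≥ 30% of windows in the same hydrophobic phase. The phase
requirement is what keeps random sequences out: unsigned alternation spikes
occur in ~17% of windows of any protein, so counting them without phase
would label nearly everything long a barrel. This screen exists to make the
simulator self-contained; real analyses should supply predictions.

## Trait searches and the presence matrix

Trait presence is decided by protein homology search reimplemented as
deterministic Smith-Waterman (affine gaps, BLOSUM62, open 11 / extend 1)
plus Karlin-Altschul statistics: `E = K m n exp(-λ S)` with the standard
gapped-BLOSUM62 constants λ = 0.267, K = 0.041, where `m` is the query
length and `n` the total residue count of the searched proteome. No
seeding or masking heuristics are used — every (query, protein) pair is
aligned optimally, which is feasible at the scales this package targets
and keeps the statistic exact. The alignment core is compiled (Rcpp); the
test suite pins it cell-for-cell to an exhaustive dynamic-programming
oracle written independently in R and to a reference implementation.

A trait is present in a genome iff its best hit (lowest E over all queries
and proteins) passes the trait's E-value cutoff *and* covers at least
`min_query_coverage` of the query. Defaults: 1e-30 for conduit components,
1e-5 for ordinary traits, coverage 0.5. The coverage floor is this
package's addition — raw E-value calls accept domain-sized fragments — and
can be set to 0 to mimic E-value-only behavior.

The null model behind the constants assumes natural amino-acid
composition. `random_protein(composition = "natural")` draws from the
Robinson-Robinson background frequencies, and the calibration test checks
that ~1% or fewer of random 300-aa pairs reach E < 0.01. With uniform
letter frequencies the same constants are anti-conservative (about 4% at
E < 0.01) — a known property of composition-sensitive score statistics,
and the reason the null simulations sample natural composition.

**Group-level presence** uses the strict >30% rule: a trait is present in
a clade (fraction over all members) or an order background (fraction over
non-syntrophic members only) iff the fraction strictly exceeds 0.30. Three
hits in ten background genomes is absence; four is presence. The unit of
counting is the genome, not the species; collapsing to species first is
possible via the species-delineation output but is not the default.

## Trait histories

For each trait and syntrophic clade, the verdict is a pure function of the
two presence bits: present in clade and order background → `vertical`;
background only → `loss`; clade only → `horizontal_gain`; neither →
`absent`. The absent cell is never reported as loss — loss requires an
ancestral presence signal in the background. Tree-based corroboration of
horizontal transfers is reduced to an optional, computable flag:
`flag_adaptation()` marks a vertically inherited trait as *adapted* when
the mean best-match identity of clade homologs to background homologs
falls more than `identity_drop` (default 0.10) below the mean pairwise
identity among the background homologs themselves. With a single
background homolog the cohesion term degenerates to 1 and a warning is
emitted. Phylogenetic tree inference itself is a non-goal.

## Species delineation

ANI follows the fragment-alignment (ANIb-style) recipe, chosen because the
95% species boundary was calibrated on fragment methods: the query genome
is chopped into non-overlapping 1,020-bp fragments (a trailing remainder
≥ 100 bp is kept); each fragment is anchored in the subject by exact
15-mer seeds taken every 30 bp, voting for a diagonal (ties to the
smallest); the fragment is aligned fragment-globally against the anchored
window (±100 bp slack; match 2, mismatch −3, gap open 5 / extend 2) and
kept when identity ≥ 30% and fragment coverage ≥ 70%. ANI is the mean
percent identity over passing fragments, coverage the passing fraction.
Requiring a seed is what makes unrelated genomes fail cleanly: two random
20-kb sequences share a given 15-mer with probability ~1e-9 per position
pair, so no fragment anchors, coverage ≈ 0 and ANI is `NA` rather than a
meaningless forced-alignment number. Self-ANI is exactly 100. Because
fragments come from one side, ANI is mildly asymmetric; `pairwise_ani()`
averages both directions before clustering.

16S identity is an ends-free (overlap) global alignment, identity =
matches / alignment columns with terminal gaps excluded; pairs overlapping
fewer than 800 columns are reported `NA` at the pairwise-matrix level
because fragmentary MAG 16S genes should not drive species calls (the
bare `compute_16s_identity()` computes any overlap).

Species are single-linkage connected components over edges at or above the
cutoff — 95.0 ANI or 98.65 16S, boundary inclusive. The two partitions are
reported side by side with their disagreement pairs; no merging rule is
imposed, since any such rule would be an invention.

## The synthetic-data generator

The simulator exists so that every rule above can be tested against known
truth without downloading genomes. It emulates the statistical structure
of a multi-order study: orders containing one syntrophic clade each plus
non-syntrophic background genomes, single-contig genomes with ordered CDS
features, planted cytochromes with exact heme counts, planted conduit
operons and decoys, planted trait histories, and (in the species
generator) nucleotide divergence structure.

Choices that make truth exact rather than approximate:

* **C/H-free background.** Background proteins, motif wildcards, trait
  queries and barrel proteins are drawn from the 18-letter alphabet
  without C and H, so the only CxxCH motifs in a clean-mode genome are the
  planted ones and heme truth is exact. A noisy mode re-admits C/H and
  records the scanner count of the emitted proteins as truth instead.
* **Exact-count trait realization.** Background presence is realized as
  `round(freq × n_background)` genomes chosen at random, not as Bernoulli
  draws, so a planted 0.6/0.1 frequency can never wander across the 0.30
  rule boundary by sampling noise; configurations whose realized counts
  contradict the requested history are rejected before emission.
* **Block geometry for conduits.** Each planted conduit or decoy occupies
  the 21-gene core of its own 45-gene block, so the neighborhood of one
  block's barrel can never reach another block's cytochrome. Decoy kinds:
  barrel with the cytochrome at distance 11-20, barrel with a 5-heme
  near-miss neighbor, and barrel-less cytochrome runs. When counts allow,
  one distance-10 conduit and one distance-11 decoy are planted per
  genome so the boundary is always exercised.
* **Divergence inversion.** The species generator converts requested
  *pairwise* divergences (e.g. within 0.01, between 0.12) to per-copy
  substitution rates by inverting d = 2q(1−q) + (2/3)q², so planted ANI
  expectations (99 within, ~88 between) hold for pairs, not branches.
* **Derived RNG streams.** Every stream is seeded by a hash of
  (master seed, stream key), so regeneration is byte-identical and
  independent of evaluation order; protein-level datasets do not emit
  nucleotide contigs by default because their random DNA carries no
  divergence signal (the species generator is the nucleotide-level tool).

What the generator does **not** emulate: codon structure and
protein/nucleotide consistency, indels, rearrangements, gene gain/loss
within clades, composition biases, contig fragmentation, or annotation
noise in product descriptions. Passing the planted-truth tests therefore
demonstrates that the rules are implemented exactly as specified, not that
they are robust to the messiness of real MAGs; the E-value thresholds are
exercised by mutating planted traits (10% substitutions by default), which
is the one divergence axis the generator does model.

## Problem sizes and runtime

The validation suite uses sizes chosen to make the statistics meaningful
while staying desk-scale: 1,000 random sequences (50-2,000 aa) for the
motif oracle; 50 genomes with 20 true conduits and 20 decoys each for
conduit recovery; 30 independent datasets of 5 orders × 8 genomes with 12
traits for history recovery; 40-kb genomes over substitution rates
0.01-0.10 for ANI accuracy; 9 genomes in 3 planted species at 12 kb for
species recovery; 200 pairs (≤ 60 aa) against the exhaustive DP oracle and
1,000 pairs for the E-value null. `scripts/acceptance.R` recomputes all of
it in a few minutes on one CPU.

## Numerical and degenerate-input conventions

Ties in gene start coordinates break by end, then gene id. Equally optimal
alignments may differ in column counts between implementations; scores are
compared exactly, identities only where the alignment is unambiguous.
Local alignments with no positive-scoring pair return score 0, identity 0,
coverage 0. An order with no non-syntrophic members has an undefined
background (warning, `NA`), and history inference refuses clades mapped to
more than one order. Empty prediction tables warn rather than fail;
unknown labels and duplicate gene ids are errors. All result tables are
written deterministically so that identical configurations yield
byte-identical TSVs.

## Known limitations

The type-clustering cutoff is a reproducibility device, not an estimate of
the by-eye type granularity; counts from it should be read as "at least".
The conduit caller trusts its barrel evidence — false barrel predictions
become false conduits. E-values use fixed gapped constants rather than
per-composition estimation, so they are approximate for strongly biased
proteomes. ANI is defined only where fragments anchor; highly fragmented
or very short genomes reduce coverage before they bias identity. HMM-based
trait definitions are consumed only as externally computed hit tables; the
package does not implement profile HMMs.
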