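---
title: "Comparative mitogenomics with mitocomp: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative mitogenomics with mitocomp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitocomp)
```

## Scope

`mitocomp` analyses annotated insect mitochondrial genomes — the circular,
~16–18 kb, 37-gene molecules (13 protein-coding genes, 22 tRNAs, 2 rRNAs and
one AT-rich control region) typical of green lacewings (Chrysopidae) and
other holometabolan insects. It covers the descriptive layer of a
comparative mitogenomic study (base composition and strand skews, codon
usage, start/stop codons, gene junctions, control-region architecture, tRNA
cloverleaf consistency), the molecular-evolution layer (per-gene nucleotide
diversity, Nei–Gojobori Ka/Ks, Tamura–Nei distances, codon-position
saturation) and a deliberately lightweight phylogenetic layer (supermatrix
assembly, conserved-block filtering, neighbour-joining, and fossil-calibrated
mean-path-length dating). A seeded simulator generates whole annotated
mitogenomes along a phylogeny with known parameters, so that every analysis
stage is testable without any external data.

## Data model

An `mitogenome` couples an uppercase DNA string with an ordered feature
table (canonical gene symbols, 0-based half-open coordinates, `J`/`N`
strand, tRNA anticodons). GenBank's 1-based inclusive coordinates are
converted only at the I/O boundary; `end` may exceed the sequence length to
encode a feature spanning the origin of the circular molecule. This
eliminates off-by-one arithmetic from the junction analysis, which is where
coordinate bugs do real damage.

Gene labels found in the wild (`COI`, `ND4L`, `s-rRNA`, `tRNA-Ser`…) are
collapsed onto one vocabulary by `canonicalize_gene_name()`. Leucine and
serine tRNAs are disambiguated by anticodon — trnL1 = CUN family (anticodon
UAG), trnL2 = UUR (UAA), trnS1 = AGN (GCU/UCU), trnS2 = UCN (UGA) — falling
back to annotation text, and reporting `"unknown"` with a warning rather
than guessing.

## Composition and skew

`AT-skew = (A − T)/(A + T)` and `GC-skew = (G − C)/(G + C)`, computed from
exact counts. Ambiguity codes are tallied separately and excluded from every
denominator, which keeps both skews inside [−1, 1]; a zero denominator
reports a missing value rather than an error. Reports round to two decimals
(matching the precision at which such values are conventionally published);
full precision is kept internally. Both skews negate under reverse
complement, which is the formal version of the heavy/light strand asymmetry
narrative — this is a tested invariant.

## Codon usage under the invertebrate mitochondrial code

All translation uses NCBI table 5 (`TGA` = Trp, `ATA` = Met, `AGA`/`AGG` =
Ser), with the code table itself cross-checked against Biostrings in the
test suite. RSCU for codon *c* in synonymous family *F* is
`count(c) · |F| / Σ count(F)`; six-fold families are split in the
conventional mitochondrial way (Leu1 = UUR, Leu2 = CUN, Ser1 = AGN,
Ser2 = UCN), so every family mean is exactly 1 wherever the family is used
at all. Unused codons in a used family report 0; a family never observed
reports missing values rather than zeros. Terminal stop codons (and
trailing incomplete-stop bases) are excluded from the counts — stops have no
synonymous family and would otherwise distort RSCU. RSCU tables are labelled
in the RNA alphabet, the convention of codon-usage figures.

Stop-codon calling follows length arithmetic: a CDS whose length is a
multiple of 3 must end in TAA/TAG; a CDS one (two) bases over a multiple of
3 must end in `T` (`TA`) and be followed, in transcription direction, by a
tRNA that completes the stop post-transcriptionally (`T-tRNA` / `TA-tRNA`).
For an N-strand gene "following" means the previous feature in genome
coordinates. A trailing base inconsistent with this scheme is an
annotation error and is reported as such, naming the gene.

## Nucleotide diversity and NG86 Ka/Ks

π is the average pairwise proportion of differing sites,
`π = (2/(n(n−1))) Σ_{i<j} d_ij`. Gap handling is pairwise deletion by
default (a site is dropped only for pairs in which either member has a gap
or ambiguity); complete deletion is available as a switch, since published
values depend on this unstated choice more than on anything else.

The Ka/Ks implementation is the Nei–Gojobori (1986) counting method,
written from the method definition:

* **Sites.** Each codon position contributes the fraction of its single-base
  mutations that are synonymous, with mutations creating stop codons
  excluded from the denominator. Site counts for a pair are the average of
  the two sequences' counts; N + S always equals 3 × (compared codons).
* **Differences.** Codons differing at *k* positions are resolved by
  enumerating all *k*! orderings of the changes, discarding orderings that
  pass through a stop codon, and averaging synonymous/nonsynonymous step
  counts with equal weights. If every ordering passes through a stop (a
  corner case), all orderings are used. The per-pair tables are precomputed
  once per session for all 64 × 64 codon pairs and verified against an
  independent recursive enumeration in the tests.
* **Correction.** pN = Nd/N and pS = Sd/S receive the Jukes–Cantor
  correction `d = −(3/4) ln(1 − 4p/3)`; a proportion at or above 3/4 reports
  a missing value with a warning rather than a fabricated distance.
* **Multiple sequences.** The gene-level result is the unweighted mean of
  per-pair Ka and per-pair Ks, with the ratio taken as mean-Ka over mean-Ks.
  The ratio-of-means is used rather than the mean of per-pair ratios because
  the latter explodes whenever one shallow pair has Ks near zero — exactly
  the situation in closely related mitogenomes.

### Validation design for the estimator

The recovery experiment simulates a 500-codon gene under ω = 0.2, κ = 2 on a
six-taxon clock tree and asks NG86 to recover ω. It is run at uniform codon
base frequencies, because that is the regime in which a counting method with
an equal-mutation-rate site definition is a consistent estimator; the test
requires the estimate to land in [0.1, 0.3] in at least 95% of 100 seeded
replicates. Under strongly AT-biased composition (the mitogenome-emulation
default), the same estimator acquires a modest upward bias — a documented
property of NG86-style counting, not of this implementation — so composition
realism and estimator validation are deliberately separated: the AT-rich
defaults exercise every pipeline stage, while the uniform-composition runs
measure the estimator. Either way, purifying-selection simulations
(ω ≤ 0.5 on all genes) always yield Ka/Ks < 1, which is asserted as a
property of the simulator + estimator pair.

## TN93 distances and saturation

The Tamura–Nei (1993) distance uses base frequencies pooled over the two
compared sequences, the two transition classes (A↔G, C↔T) separated, and the
standard closed form; it is cross-checked against `ape::dist.dna` in the
tests. A non-positive logarithm argument (saturation) yields a missing value
flagged `saturated`, never an error. The saturation profile reports, for
every unordered taxon pair and codon position, the observed transition (S)
and transversion (V) proportions against the TN93 distance, with summary
slopes fitted by least squares through the origin — through the origin
because a zero distance implies S = V = 0 by construction. On deep
simulations the position-3 transition signal flattens relative to
position 1, the classic saturation picture that motivates excluding or
down-weighting third positions in phylogenetic inference.

## Genome architecture

`junction_table()` compares consecutive features in genomic order (including
the wrap between the last and first feature of a circular molecule) and
classifies each junction as overlap, abutment, or unassigned region (UR), a
UR being any inter-feature gap of at least 1 bp. Overlap and UR sequences
are reported as J-strand slices. The tiling identity
`Σ feature lengths − Σ overlaps + Σ URs = genome length` is asserted across
simulated genomes.

The control region is located by annotation when present, otherwise as the
longest UR, and characterized by the four standard identification features:
UR status, T-rich runs (≥ 8 nt), A+T content above the whole-genome value,
and repetitive elements. Candidates shorter than 200 bp are flagged
(`short CR candidate`) since real insect control regions run to kilobases.
Microsatellites are maximal perfect tandem runs of primitive 1–6 bp motifs
(default minimum run 10 bp, configurable — published descriptions rarely
state a threshold), reported with the motif in canonical rotation;
primitivity prevents an (AT)n run from also appearing as (ATAT)n/2. Long
direct repeats are found by exact 15-mer seeding on each diagonal, X-drop
ungapped extension (+1 match / −4 mismatch, drop-off 12), a non-overlap cap
at the diagonal offset, and greedy selection by copy length; defaults
(≥ 200 bp copies, ≥ 0.9 identity) match the scale of control-region
duplications reported in lacewings. Inverted repeats are out of scope.

The cloverleaf checker is a pairing-consistency heuristic, not a folding
algorithm: Watson–Crick plus G·U pairs; a 7-bp acceptor stem between the
ends (≤ 1 mismatch); a 5-bp/7-nt anticodon arm whose loop centre should
carry the anticodon; a strict (0-mismatch, 3–4 bp) D-arm search between
acceptor and anticodon arm; and a 4–5 bp T-arm before the 3′ acceptor half.
The strict D-arm criterion is what lets the checker report the metazoan
trnS2 pattern — a D-arm replaced by a simple loop — without false negatives
on the other 21 tRNAs. Thermodynamic structure prediction (tRNA, rRNA
domains/helices) is deliberately not attempted.

## The lite phylogenetic chain

The supermatrix assembler concatenates per-gene alignments in a fixed,
documented order (protein-coding genes alphabetically, then rRNAs), pads
missing taxa with `?`, and keeps exact partition bookkeeping. Partitions are
one contiguous block per gene; codon-position strata are expressed in the
RAxML-style partition file (`start-end\3` notation) as downstream tools
expect, since interleaved positions cannot tile the matrix contiguously.
The `PCGAA` scheme translates codon alignments under table 5 before
concatenation (all-gap codons stay `-`, partially gapped or ambiguous codons
become `X`).

The block filter is a simplified restatement of conserved-block trimming: a
position is conserved when its majority residue exceeds 50% of rows (85%
for "highly conserved"), positions gapped in at least half the rows are
nonconserved ("with half" gap handling), nonconserved runs longer than 8 are
removed, and surviving blocks shorter than 10 positions are removed with
them. The implementation is checked rule-for-rule against an independent
loop-based reimplementation. On indel-free simulated alignments it removes
0% — the filter only bites on ragged real alignments, which is the expected
and tested behaviour.

Tree inference is standard Saitou–Nei neighbour joining (via `ape::nj`),
with taxa sorted for deterministic tie-breaking and negative branch lengths
clamped to zero with a warning. NJ is exact on additive distances, and that
exactness is asserted over random additive trees. Site-heterogeneous
Bayesian/ML inference and relaxed-clock dating are explicitly out of scope;
the package will happily date an externally supplied published topology
instead.

`mpl_date()` implements minimum-age-calibrated mean-path-length dating: the
MPL of a node is its average branch-length distance to descendant tips; the
global rate is `r = min over calibrations of MPL(node)/min_age`, so every
calibrated node age `MPL/r` meets its hard bound and at least one attains it
exactly; all node ages are `MPL/r`, and a parent dated younger than a child
(possible on non-clocklike trees) is raised to the child's age and flagged.
Calibrations are defined by tip sets that must be monophyletic in the tree —
a violation is an error listing the offending tips, because silently dating
a paraphyletic "clade" is how calibration mistakes propagate.

## The simulator

`simulate_mitogenomes()` emulates the study conditions of complete lacewing
mitogenomes, and its defaults are those conditions:

* 37-gene order with the canonical insect arrangement and strand layout
  (9 PCGs + 14 tRNAs on J; 4 PCGs, 8 tRNAs and both rRNAs on N);
* ~79–81% genome A+T, with a strongly AT-rich third codon position and
  control region (per-position composition targets are configurable);
* purifying selection on every PCG — per-gene ω defaults span 0.05 (cox1)
  to 0.55 (atp8), echoing the rank order seen across lacewing PCGs;
* 7-nt overlaps with coding-orientation motifs ATGATAA (atp8–atp6) and
  ATGTTAA (nad4–nad4L), a single shared `A` at atp6–cox3, an incomplete
  `T` stop on nad5, small URs, and a 2 kb control region carrying a (TA)12
  microsatellite, a 250 bp tandem duplication and a T-run.

The ancestral genome is sampled from the composition targets (PCG codons are
drawn position-wise and stop codons rejected); tRNAs are built as canonical
cloverleafs (trnS2 without a D-stem). Evolution along each branch is a
rejection-sampled mutation process: the number of proposals is Poisson with
mean branch length × gene rate × gene length, each proposal draws a new base
with target-frequency × κ-transition weights, proposals creating stop codons
are rejected, nonsynonymous proposals are accepted with probability ω, and
RNA/control-region proposals are always accepted. Branch lengths are
therefore in expected *proposed* mutations per site; realized substitutions
per branch are recorded in the truth record. A rejection scheme was chosen
over a matrix-exponential codon model because exact stop avoidance and
per-feature planting are then trivial, and estimator-recovery properties
only require ω to be well defined on average.

Planted features (start/stop codons, overlap motifs, control-region
repeats, tRNA anticodons) are frozen during evolution, which is what makes
"preserved by construction" literal: the overlap consistency check at
assembly is an assertion, not a hope. No indels are simulated, so per-gene
alignments across taxa are exact by construction — statistic tests are
thereby isolated from aligner behaviour, and the block filter sees nothing
to remove on simulated data. The simulator does **not** model
rearrangement, sequencing error, heteroplasmy, or secondary structure; a
passing test suite says the statistics are computed correctly on clean
data, not that real, ragged, misannotated records will behave.

One fixture-specific simplification: junction sequences are reported as
J-strand slices, so the deterministic fixture genome places nad4/nad4L (and
nad5 with its completing tRNA) on the J strand to make the planted 7-mers
literal J-strand text, while `simulate_mitogenomes()` keeps the realistic
N-strand layout — there the nad4–nad4L junction slice is the reverse
complement of the coding-orientation motif, as it is in real records.

## Numerical choices and degenerate inputs

* Zero denominators (skews, Ks = 0, empty families) are missing values,
  never errors or zeros masquerading as data.
* JC and TN93 corrections return flagged missing values once proportions
  reach their domain boundaries.
* NG86 pathway weighting is equal over stop-free orderings; the all-stop
  corner case falls back to all orderings.
* NJ ties are broken deterministically by taxon-label order; negative branch
  lengths clamp to zero with a warning.
* The whole simulator is a pure function of its seed; report bundles are
  byte-identical across runs with the same config, which is asserted in the
  tests.

## Problem sizes used by the test suite

The suite exercises: 200 random codon pairs against the exhaustive NG86
oracle; 100 seeded replicates of the ω-recovery experiment (500 codons,
6 taxa); 50 simulated complete genomes for the junction-tiling invariant;
50 random additive trees for NJ exactness; 50 random calibration draws plus
a 7-taxon clock-tree recovery for dating; and 20-seed batches for topology
recovery and sampling-error scaling. These sizes keep the full suite around
a minute of compute while leaving the statistical assertions comfortably
away from their thresholds.

## Known limitations

* The GenBank reader targets single-record flatfiles with the feature types
  mitogenome submissions actually use; it is not a general GenBank parser.
* NG86 is a counting method: under strong composition bias or high
  divergence it is biased relative to ML codon models, which are out of
  scope here.
* The block filter is a simplified restatement of conserved-block trimming,
  not a reimplementation of any specific tool's output.
* MPL dating provides point ages under hard minimum bounds only — no rate
  variation across branches, no credible intervals.
* The cloverleaf checker validates annotation consistency; it does not
  predict structure.
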