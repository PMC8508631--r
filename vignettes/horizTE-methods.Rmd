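---
title: "Detecting horizontal transfer of transposable elements: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting horizontal transfer of transposable elements: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Vertical inheritance constrains how similar two sequences from different
species can be: orthologous protein-coding genes of species that
diverged tens of millions of years ago show third-codon-position
identities far below 90% (medians in the 50–65% range for the distances
this package targets). A transposable element shared between two such
species at more than 90% nucleotide identity therefore cannot have been
inherited vertically — it is a candidate horizontal transfer (HT).
`horizTE` turns that argument into a tested pipeline: screen for
excessively similar cross-species sequence, exclude the conserved
sequence classes that violate the neutral baseline for other reasons
(organelle DNA, rDNA, highly conserved genes), collapse redundant
copies, and then *validate* each candidate with two independent lines of
evidence — the relative activity history of the element's paralogs in
each species, and phylogenetic incongruence of its homolog tree.

## The activity-history statistic

For a TE family in one species, all paralogous copies of a short probe
fragment are collected and compared all-to-all. Classical size-weighted
UPGMA is run directly on the percent-identity matrix, merging the most
similar pair first; each internal node stores the identity at which two
clusters merge. The multiset of these **node values** (n − 1 values for
n copies) is the family's relative activity history: a burst of
transposition at some point in the past produces copies that diverge
from that moment on, so a proliferation burst appears as a mode in the
node-value histogram, and node values *below* the species-divergence
threshold indicate activity that predates the relevant speciations.

Donor and recipient follow from the asymmetry of transfer. The donor
lineage hosted the family before the transfer, so its activity history
extends below the 90% threshold (old paralogs); a recipient acquired a
single copy at the transfer and shows only above-threshold activity.

Probes are 260–280 bp (270 by default) because full-length elements
produce split local alignments that fragment the identity matrix. The
probe is taken from the reverse-transcriptase domain when one is
annotated, otherwise from the element's center — the center is a
deterministic stand-in for "an arbitrary position", preferred so that
reruns are bit-identical. Paralog candidates are trimmed to the
probe-hit span so identities are length-comparable, then clustered by
single linkage at >85% identity, and the cluster containing the probe is
kept; this separates the family from unrelated families that happen to
share the search thresholds. Pairs of members with no qualifying hit are
imputed at the minimum observed identity minus one, so unlinked members
merge last without fabricating precision.

## The search engine

Every screening step runs on a seed-and-extend local similarity engine
implemented in C++: exact 12-mer seeds, ungapped x-drop extension
(x-drop 40), scoring match +1 / mismatch −2, identity = matches /
aligned columns. The engine reports ungapped HSPs: the package's entire
divergence model lives in substitution space (the simulator's mutation
operators are substitution-only, and identity thresholds are defined on
gap-free columns), and the alignment-sensitive steps that do need gaps —
protein-guided codon alignment of orthologs, projection of homolog
fragments onto the probe — use full affine-gap dynamic programming from
Biostrings instead. On gap-free divergence the engine's hit identity
equals a full Smith–Waterman local alignment with the same scoring,
which the test suite asserts against Biostrings as an independent
oracle. E-values use the Karlin–Altschul formula with lambda fitted to
the scoring scheme and K = 0.3; since every protocol threshold pairs an
e-value with a score cutoff, the score is the binding filter and the
e-value is advisory. Score thresholds are interpreted in these +1/−2
units, in which a perfect 500 bp match scores 500, so the protocol's
"score > 500, length > 500 bp" retains its intent.

All thresholds are strict inequalities (a hit must *exceed* 90%), and
coordinates are 0-based half-open on forward strands internally, 1-based
inclusive in exported TSV.

## The vertical baseline

Orthologs are paired by reciprocal best hits (single HSP, identity >60,
score >200, e <1e-5). Each CDS is assigned the unique forward reading
frame whose translation has no internal stop codon; if zero or several
frames qualify the sequence is dropped rather than risking a frame
misassignment that would corrupt every downstream codon column (the
terminal codon is exempt, so a trailing stop is allowed). Translations
are aligned globally (BLOSUM62, affine gaps), gaps are mapped back onto
codons, gapped codon columns are removed entirely, and identity is
computed over third positions only. Species-pair summaries come in two
modes: per-gene distributions (box-plot material) and the concatenated
mode, which pools matches over genes and therefore equals the
length-weighted identity of the concatenated third-codon columns. The
species tree is UPGMA on the concatenated matrix under complete deletion
with supports from resampling alignment columns.

## Donor/recipient classification

A species is the **donor** when (i) its activity history reaches below
the identity threshold and (ii) at least one other species' homologs
nest within its homolog diversity. Nestedness is evaluated on patristic
distances of the neighbor-joining homolog tree (p-distance, pairwise
deletion): species *u* nests within species *s* when the closest *u*
homolog is nearer to an *s* homolog than *s*'s two most divergent
homologs are to each other. This rooting-free criterion was chosen over
the more literal "midpoint root, then check the sister clade of a
monophyletic group": TE bursts produce star-like subtrees, and when two
recipients' bursts are mutually as divergent as the donor's old
paralogs, the midpoint can fall between the recipient clusters and the
sister-clade reading then points at another recipient rather than the
donor. The distance criterion expresses the same biology — recipient
copies coalesce inside the donor's pre-transfer diversity — and is
invariant to rooting. The midpoint/sister-clade test remains available
as `nesting_test` for reporting and for trees where it is the natural
reading.

Both evidence types are required: below-threshold activity without
topological support (or vice versa) leaves the species undetermined.
When *no* species shows below-threshold activity the direction is
genuinely unknowable — all recipients of an unsampled donor, or a donor
whose old copies were purged — and every role is undetermined; such an
event is retained as a validated HT only if the homolog tree interleaves
species across branches (`mixed_branch_test`), which protects against
false positives among undetermined events.

## RT-domain composition

RT domains are found by scoring 92-aa windows of all six translation
frames against a position-specific log-odds profile built from a
user-supplied aligned RT protein set (columns with >50% gaps dropped,
then trimmed to the central 92 columns, pseudocount 1 against a uniform
background). Windows never cross in-frame stop codons, so heavily
degraded elements are undercounted — intentionally, as only RT-bearing
copies are counted. The detection threshold is calibrated from a
shuffled-residue null as mean + 6 SD: a genome scan evaluates millions
of windows, and this per-window rate keeps expected false discoveries
near zero while true domains score an order of magnitude above the null
spread. Families are assigned by best local protein alignment against a
labeled reference set; HT-derived copies are flagged by nucleotide
search against validated event elements (score > 200), and
`composition_report` tabulates per-species, per-family totals with the
HT percentage. Layered activity histories (native vs HT-derived members
of one family) expose differential proliferation; a "peak" in the HT
layer requires its modal bin to hold at least three node values and at
least three times the native count in the same bin, so a single
transferred copy never counts as proliferation.

## The simulator

All simulation is parameterised in percent-identity space, the units the
analysis operates in. `mutate_to_identity` substitutes an exact count of
positions, so a copy's identity to its ancestor is the target up to
rounding; independent copies at per-side fraction q have expected mutual
identity (1 − q)² + q²/3 (a doubly-substituted site coincides with
probability 1/3), and the per-side target is solved from the desired
pairwise identity. Ortholog CDS evolve along the species tree as a
Jukes–Cantor chain: per-branch substitution probabilities compose
exactly, so realized pairwise third-codon identity is unbiased for the
programmed value; first and second codon positions evolve at 0.15× the
third-position rate (synonymous-biased divergence), and substitutions
that would create an in-frame stop are redirected.

The default configuration mirrors the data regime the pipeline is built
for: 4 focal + 6 other species; 500 kb genomes in 5 contigs; programmed
third-codon identities of 97.4–99% within the focal clade and 52–80%
elsewhere; 8 HT events at 91–96% transfer identity with 1–3 recipients;
donors carrying 6 pre-transfer paralogs at 86–87.5% mutual identity
(below the 88% scan threshold, above the 85% paralog-cluster threshold);
recipients carrying 3 post-transfer copies at 94–97%; decoys (organelle-
like, rDNA-like, conserved genes) shared by all species at ~97%. The
actively transferring element is itself an aged lineage of its family
(96% to the family ancestor), so a donor's old paralogs sit well below
the retention threshold relative to every transferred copy — without
this age gap the old copies hover at the 90% boundary and can masquerade
as independent candidate regions. Genome backgrounds are independent
random sequence: cross-species identity of non-implanted DNA is then
~25%, so any cross-genome hit above 90% is attributable by construction,
which is exactly what a ground-truth generator must guarantee.

What the simulator does *not* emulate: shared ancestral repeats between
closely related focal species, indels (off by default so identity
definitions stay exact), recombination-driven element removal,
GC/composition bias, and nested insertions. Passing the recovery tests
therefore demonstrates the pipeline's logic under substitution-only
divergence with known truth — not robustness to assembly artifacts or
to TE landscapes of real genomes, where the conserved-sequence decoy
library and the thresholds would need tuning against curated
annotations.

## Numerical choices and degenerate inputs

* UPGMA ties merge the lexicographically smallest label pair;
  deterministic output. Node heights are exact weighted means, tested to
  1e−9 against a brute-force oracle that recomputes every merge from the
  original matrix.
* NJ clamps negative branch lengths to zero, moving the excess to the
  sister branch so the pair sum is preserved; additive matrices are
  reconstructed exactly.
* Percentages are rounded half-up to one decimal (`round_half_up`), so
  boundary cases never depend on banker's rounding.
* Empty inputs are values, not errors: no hits is an empty table, a
  species without the family is an empty paralog set, fewer than two
  paralogs is an empty history whose `has_activity_below` carries an
  `insufficient` flag distinct from "no old activity".
* Elements shorter than the probe length are used whole (with a
  warning); single-copy species fall back to their best-hit fragment and
  are flagged.

## Problem sizes

The shipped tests and the acceptance script run the full pipeline on
five replicate simulations at the default conditions above (~10 species
× 500 kb each), plus miniature fixtures for the qualitative scenarios;
one replicate takes well under a minute on a single core. Ortholog
calibration uses 60 genes of 300 codons across 5 species spanning the
52–80% programmed range. These sizes were chosen so the full validation
cycle stays interactive while every stage still operates far from
degenerate regimes (thousands of windows per scan, dozens of paralogs
per family).

## Known limitations

* Ungapped HSPs understate identity across indel-rich regions; real-data
  use with indel divergence should route candidate verification through
  the gapped projection path.
* The 90% threshold is calibrated for deep inter-family distances;
  between close relatives (species identities near or above 90%) HT
  cannot be separated from introgression, and the package deliberately
  leaves such calls undetermined.
* Role classification assumes the donor's old copies survive in the
  assembly; a donor with purged old activity is reported undetermined,
  never guessed.
* Absolute dating is out of scope: node values are identities, and
  converting them to years would require a mutation rate the method does
  not use.
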