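# horizTE

Detection and validation of horizontally transferred transposable
elements (TEs) across plant genome assemblies.

Horizontal transfer (HT) moves genetic material across the mating
barrier. In plants the most frequently transferred material is the LTR
retrotransposon (superfamilies *Copia* and *Gypsy*), and an HT event
leaves a characteristic signature: a TE shared between distantly related
species at a sequence identity far above the neutral expectation for
those species. `horizTE` implements the complete screening and
validation workflow around that signature, for researchers studying TE
mobility and genome diversification:

1. **Screen** (`screen_candidates`) — a built-in seed-and-extend local
   similarity engine compares focal genomes against other genomes
   (identity > 90%, score > 500, match length > 500 bp, single HSP) and
   isolates candidate regions from the non-focal assemblies.
2. **Filter** (`filter_conserved`) — candidates matching organelle-like,
   ribosomal or conserved-gene decoys are removed.
3. **Collapse** (`collapse_redundant`) — redundant copies are clustered
   by single linkage over the >90%-identity hit graph; one event per
   cluster, the longest member as its element.
4. **Expand** (`expand_events`) — each element is scanned against every
   genome (best hit > 88%); species are retained above 90% identity.
5. **Vertical baseline** (`species_matrix`, `species_tree_upgma`) —
   reciprocal-best-hit orthologs, coding-frame inference (the unique
   stop-free frame), protein-guided codon alignment, and percent
   identity at third codon positions give the species-level neutral
   divergence the 90% threshold is judged against.
6. **Activity history** (`mine_paralogs`, `activity_history`) — a
   260–280 bp probe (RT domain when present) mines each species'
   paralogous copies (score > 60, e < 1e-8; >85% single-linkage
   clusters); the multiset of UPGMA internal-node identities, binned
   at 1%, is the family's relative activity history.
7. **Validate and classify** (`classify_roles`) — a species whose
   activity reaches below the 90% threshold *and* within whose homolog
   diversity other species' copies nest is the donor; species with only
   above-threshold activity are recipients; events without a donor are
   kept only when the homolog tree mixes species across branches.
8. **Composition** (`extract_rt`, `classify_family`,
   `composition_report`) — position-specific scoring of 92-aa RT
   windows over six-frame translations, family classification against a
   reference RT set, and per-family native vs HT-derived counts and
   layered activity histories.

The core statistic throughout is the **UPGMA node value**: classical
(size-weighted) agglomerative clustering run directly in percent-identity
units, where each internal node's merge identity is a divergence point of
the TE family. `upgma_identity` and `node_values` expose it directly.

A fully ground-truthed simulator (`simulate_genomes`) generates
multi-species genome sets — species phylogeny with programmed third-codon
identities, native TE bursts, implanted HT events at controlled transfer
identity, conserved decoys — so every stage can be validated against
known truth; `fixture_suite` provides curated miniature scenarios.

## Worked example

```r
library(horizTE)

sim <- simulate_genomes(simulation_config(seed = 7, genome_length = 6e4,
  n_orthologs = 6, n_private_genes = 2, n_ht_events = 2,
  ht_recipient_counts = c(1L, 2L), ht_donor_side = c("other", "focal"),
  ht_classes = c("Copia", "MuDR"), n_te_families = 1L))
res <- run_pipeline(sim)
res$summary
#> <ht_summary>
#>   events: 2 (Copia:1, MuDR:1)
#>   Copia share of LTR events: 100.0%
#>   donor determined: 2; focal recipient: 1; focal donor: 1
#>   multi-recipient events: 1 (Copia share 0.0%)

as.data.frame(res$assignments[[1]])[, 1:2]
#>   species      role
#> 1  focal1     donor
#> 2  other4 recipient
#> 3  other5 recipient
```

Two implanted events are recovered as two validated HT events. The first
is the multi-recipient transfer out of `focal1`: its activity history
reaches below the 90% identity threshold (old, pre-transfer paralogs)
and the recipients' copies nest within its homolog diversity, so it is
classified as the donor; the two recipient species carry only recent,
post-transfer copies. The summary counts events per TE class and reports
the *Copia* share of LTR-retrotransposon events.

On real data, replace the simulated objects with `read_genome_fasta()`
genomes, CDS FASTA per species, and your own decoy/TE/RT reference
libraries; the stage functions compose exactly as in `run_pipeline`.

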