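# lgtnet

Detection of within-clade lateral genetic transfer (LGT) — both whole-gene
and within-gene — among closely related bacterial strains, with an overlay
on the transcriptional regulatory network (TRN) to compare how global,
neighbour and other regulators evolve.

## The problem

Among strains of a single species (the motivating system is the
*E. coli*–*Shigella* clade), genes are exchanged laterally both as intact
open reading frames and as within-gene fragments.  Treating whole genes as
the unit of transfer misses the fragmentary signal; treating either signal
alone misclassifies families.  `lgtnet` implements the joint procedure:

1. **Reference tree.** From each single-copy gene family's tree, harvest
   every non-trivial bipartition with posterior probability PP ≥ 0.95 and
   build an MRP supertree (matrix representation with parsimony): each
   harvested split is a binary character (taxa absent from the family
   coded `?`), and the reference is the most parsimonious tree over that
   matrix, found by SPR hill climbing from random-addition starts.
2. **Whole-gene signal.** A family is *discordant* when, after pruning the
   reference to the family's taxa and collapsing test edges with
   PP < 0.95, some resolved test split is incompatible with the
   reference.  The number of implied transfer events is the exact **SPR
   edit distance** d(T, R): the minimum number of subtree
   prune-and-regraft operations separating the topologies, computed by
   bidirectional breadth-first search over SPR neighbourhoods after
   distance-preserving common-subtree reduction, with budget `d_max`
   (families beyond the budget are reported UNRESOLVED).
3. **Within-gene signal.** A two-phase recombination detector on the
   codon alignment.  Phase 1 screens with three permutation statistics —
   the pairwise homoplasy index (Φ), the neighbour similarity score
   (NSS), and maximum χ² — passing a family when at least two of the
   three have p < 0.1 against a site-permutation null.  Phase 2 assigns a
   candidate topology to every alignment position by a penalized
   change-point dynamic program over per-site Jukes–Cantor
   log-likelihoods; breakpoints are graded A/B/C by the likelihood weight
   of the flanking segments.  A family is **ORB+** (observable
   recombination breakpoint positive) iff it passes the screen *and*
   phase 2 yields class A–C evidence.
4. **Classification.** discordant × ORB− → whole-gene lateral;
   ORB+ (discordant or not) → within-gene lateral; concordant × ORB− →
   vertical.
5. **Network overlay.** The TRN is a directed gene→gene graph built from
   RegulonDB-style edge lists.  *Global* regulators are the top-k (k =
   20) TFs by out-degree; *neighbour* regulators are non-global TFs
   regulating a chromosomally adjacent gene (rank ± 1, circular);
   everything else is *other*.  The package compares LGT frequencies
   across the three categories (Fisher's exact test), edit distances of
   ORB+ vs ORB− families (Wilcoxon rank-sum), regulatory neighbourhood
   co-transfer, and functional-category enrichment.

A fully seeded synthetic-data module generates species trees, gene
families with planted SPR transfers, mosaic alignments with planted
breakpoints, and scale-free TRNs with chromosomal gene order — so the
whole pipeline is testable at desk scale with known ground truth.

## Worked example

```r
library(lgtnet)
cfg <- pipeline_config(
  seed = 42,
  sim  = sim_config(n_families = 60, n_strains = 15, n_tfs = 30,
                    n_targets = 200, k_global = 5, n_neighbour = 12),
  k_global = 5L)
res <- run_pipeline(cfg)
res$tables$overall
```

```
           orb_pos orb_neg
discordant       4      23
concordant       2      31
total 60; lateral 29 (48.3%); vertical 31; unclassified 0
```

Of 60 simulated families, 29 (48.3%) show evidence of transfer: 23 are
whole-gene lateral (tree discordant with the MRP reference, no internal
breakpoint), 4 carry a breakpoint *and* a discordant tree, and 2 are
cryptic within-gene transfers — breakpoint-positive yet topologically
concordant, the class a whole-gene-only analysis would miss.

```r
table(res$tf_category)
#>    global neighbour     other
#>         5        12        13

res$records[res$records$orb, c("family", "size", "discordant",
                               "edit_distance", "evidence_class")]
#>    family size discordant edit_distance evidence_class
#> 7  fam007   11       TRUE             2              B
#> 8  fam008    7      FALSE             0              B
#> 13 fam013   13       TRUE             1              C
#> 15 fam015   11       TRUE             1              B
#> 28 fam028    9       TRUE             1              B
#> 56 fam056    8      FALSE             0              A
```

Each ORB+ record shows the breakpoint evidence class and the SPR edit
distance of its gene tree from the reference (0 for the two cryptic
families).  Against the generator's ground truth this run recovers the
planted lateral/vertical labels with sensitivity 0.97 and specificity
1.00, and the planted global/neighbour/other TF categories exactly.

Every stage is also an exported function (`harvest_bipartitions`,
`build_mrp_supertree`, `is_discordant`, `spr_edit_distance`,
`incompatibility_screen`, `segment_alignment`, `build_trn`,
`classify_global`, `find_neighbour_regulators`, `summarize_classification`,
…) and can be composed on its own; `run_pipeline()` writes all stage
tables (TSV), a JSON summary and a log of every threshold and seed to
`config$out_dir`.

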