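---
title: "Detecting within-clade lateral transfer: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting within-clade lateral transfer: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lgtnet)
```

This vignette explains the models and procedures behind `lgtnet`, the
parameters that matter, the choices made where the design was genuinely
open, and what the synthetic-data tests do and do not establish about real
data.

## The two signals and their assumptions

The package treats lateral genetic transfer (LGT) within a clade of
closely related strains as leaving two distinguishable footprints in a
single-copy gene family:

* **Whole-gene transfer** rearranges the gene tree relative to the clade's
  vertical history.  The working assumption is that a reliable estimate of
  the vertical history exists (the MRP supertree over all families'
  well-supported bipartitions) and that a topological conflict supported
  at posterior probability (PP) ≥ 0.95 is not noise.  Each subtree
  prune-and-regraft (SPR) operation reconciling the gene tree with the
  reference is interpreted as one transfer event; the *edit distance* is
  the minimum number of such operations.
* **Within-gene transfer** replaces part of a gene by recombination,
  leaving a mosaic alignment whose segments support different topologies.
  The detector assumes segments long enough (tens of codons) and divergent
  enough to shift per-site likelihoods, and that site order is
  exchangeable under the no-recombination null — true when sites evolve
  independently on a single topology.

Families with fewer than four members are excluded throughout: no
unrooted topology test is possible below four leaves, so such families
are `unclassified`, never silently vertical.

## Parameters

| parameter | default | units | role |
|---|---|---|---|
| `pp_threshold` | 0.95 | posterior probability | bipartition harvest for MRP; inclusive (≥) |
| `collapse_threshold` | 0.95 | posterior probability | support collapse before discordance/edit distance; inclusive |
| `screen_alpha` | 0.1 | p-value | per-statistic screen level; pass needs ≥ 2 of 3 below it |
| `n_permutations` | 1000 | count | site-order permutations per screen statistic |
| `phi_window` | 100 | alignment columns | proximity window of the pairwise homoplasy index |
| `penalty` | 15 | log-likelihood units | cost per breakpoint in the change-point program |
| `s_hi`, `s_lo` | 0.95, 0.5 | likelihood weight | flanking-segment support thresholds for evidence classes A/B/C |
| `d_max` | 6 | SPR moves | edit-distance search budget; beyond it a family is UNRESOLVED |
| `max_nodes` | 1e6 | topologies | node cap of the SPR search (the other half of the budget) |
| `k_global` | 20 | TFs | global regulators = top-k by out-degree |
| `enrichment_alpha` | 0.05 | p-value | functional-category flagging level |

The thresholds 0.95, 0.1, 20 and 0.05 are the working constants of the
procedure the package implements; the remaining defaults are this
package's own calibrations, discussed below.

## The MRP search

The supertree minimises parsimony length over the harvested binary
characters.  The search is hill climbing over SPR rearrangements (the
`phangorn` fitch engine scores candidates) from a random-addition
starting tree, repeated for 10 independent restarts, all driven by one
seed.  Equal-score trees are tie-broken by the lexicographically smallest
canonical newick — a deterministic, content-based rule, so reruns with
the same seed are byte-identical.  Duplicate bipartitions harvested from
different families are retained: each occurrence is a character, which is
how repeated signal outweighs conflict.  On compatible inputs the search
provably can reach the generating tree, and the suite checks that it does
for 100 random 8–27-leaf trees.

## Exact SPR edit distance

Unrooted SPR distance is NP-hard, so exactness comes from search, not
formula.  The implementation:

1. restricts both trees to shared taxa (≥ 4 required);
2. collapses common pendant subtrees iteratively (common-cherry
   reduction), which preserves unrooted SPR distance and typically
   shrinks a 27-leaf problem with one or two planted moves to a handful
   of core leaves;
3. runs breadth-first search over SPR neighbourhoods with canonical
   split-set hashing — bidirectional (meet in the middle) when both
   trees are binary.

When the test tree carries polytomies after the support collapse, the
goal changes: the search starts at the binary reference and stops at the
first tree *displaying* every resolved test split, i.e. the distance is
the minimum over all resolutions of the collapsed tree.  Polytomies are
treated as uncertainty, not conflict, consistent with the discordance
rule.

The budget has two faces: `d_max` (6) bounds the distance searched, and
`max_nodes` (1e6) bounds memory and time when the reduced core is large;
exceeding either returns UNRESOLVED rather than a wrong number.  On the
default synthetic cohort about 3% of discordant families are UNRESOLVED,
concentrated at planted distances ≥ 5.

## The permutation screen

Phase 1 computes three statistics on the parsimony-informative sites:

* **Φ (pairwise homoplasy index)** — mean *refined incompatibility* of
  site pairs within `phi_window` columns of one another.  The refined
  incompatibility of two sites is the cyclomatic number (edges − vertices
  + components) of their state-pair graph: the minimum number of extra
  state changes any tree must pay, zero iff the generalised four-gamete
  condition holds.  Recombination makes *nearby* sites more compatible
  than distant ones, so the lower tail is significant.
* **NSS (neighbour similarity score)** — mean agreement between adjacent
  rows of the binary site-compatibility matrix; recombination clusters
  compatible sites (upper tail).
* **Maximum χ²** — over every sequence pair and cut point, the 2×2 χ²
  contrasting mismatch densities left and right of the cut (upper tail
  of the maximum).

Each is judged against a null built by permuting site order (seeded
Mersenne Twister, independent of R's RNG stream).  Two numerical choices
matter:

* **Mid-p rule.**  The statistics are discrete, and ties between the
  observed and permuted values are common; counting ties fully against
  the observed value made the realised level ≈ 0.05 at nominal 0.1.
  Ties therefore count half (Lancaster mid-p), which restores the
  nominal level while keeping p in (0, 1].
* **Degenerate inputs.**  Fewer than two informative sites (e.g. zero
  divergence) cannot be tested: the screen records p = 1 for all three
  statistics and fails the family, by construction rather than by
  accident.

The suite's calibration experiment runs 500 clonal (single-topology)
alignments at divergence 0.3 substitutions/site — high enough that the
statistics are non-degenerate — and checks each statistic's rejection
rate at 0.1 against the exact binomial 99% interval.  At much lower
divergence the null distributions collapse toward point masses and the
tests become conservative (they lose level downward, never upward); that
regime is shown by the zero-divergence degenerate-input test rather than
by the level check.

## Change-point segmentation (phase 2)

For families passing the screen, each candidate topology's branch lengths
are optimised once on the full alignment under Jukes–Cantor (`phangorn`'s
`pml`; phase 2 needs relative, not absolute, fit), giving a matrix of
per-site log-likelihoods.  A dynamic program then chooses a topology per
site, charging `penalty` log-units per change; breakpoints are the
positions where the chosen topology switches (0-based, half-open
segments; positions map back through the column map when the alignment
was trimmed).  The default penalty 15 was fixed by simulation before the
acceptance suite was frozen: at 15, homogeneous 600-bp alignments
produce no spurious switches while planted mid-alignment breakpoints
between topologies two SPR moves apart are recovered within ±50 columns
in ≥ 80% of ORB+ calls.  As penalty → ∞ the program provably returns a
single segment.

Candidate topologies default to the reference restricted to the family,
the family's own tree, and neighbour-joining trees of the alignment
thirds — the mosaic's two true topologies are in this set whenever the
family tree tracks the majority segment.  Per-segment support is the
likelihood weight (softmax over candidates of segment total
log-likelihood); class A requires ≥ `s_hi` on both flanks of a
breakpoint, B one flank ≥ `s_hi` and the other ≥ `s_lo`, C both ≥
`s_lo`.  The cited A/B/C system is defined operationally elsewhere, so
this rule is a documented, parameterised surrogate: the thresholds are
configuration, not constants of nature.

A family is ORB+ iff the screen passed *and* the evidence class is A, B
or C.  Families failing the screen never reach phase 2 — the two-phase
economy is part of the contract, so a breakpoint that only phase 2 could
have seen does not exist for the classification.

## Regulatory network conventions

Edges come from RegulonDB-dialect TSV (regulator, target, effect,
evidence; `#` comments).  Regulator names map to their encoding genes by
lower-casing the first character, with an explicit `gene_map` for
heterodimers (each subunit gene receives the full target set).  RNA and
obsolete genes are excluded by list; unmappable rows are counted and
skipped, never silently dropped.

Chromosomal adjacency is rank ± 1 on the circular gene order, ignoring
strand and intergenic distance — the minimal reading of "immediately
adjacent", and the one a strand-aware variant can only shrink.
Autoregulation alone never makes a neighbour regulator; adjacent TF
pairs regulating only each other are excluded; global regulators with
adjacent targets stay global.  A tie across the top-k out-degree
boundary returns all tied TFs with a warning rather than an arbitrary
cut.  Regulatory neighbourhoods extend from the TF in both directions
and stop at the first unregulated gene.

## The synthetic cohort: what it emulates, and what not

`sim_config()` defaults describe the study conditions the package is
scaled to: 27 strains; 200 families of 4–27 members (sizes drawn with a
0.6 weight on the 20–27 range, mimicking a core-genome-heavy family-size
distribution); 50.3% of families lateral, 12.8% carrying an internal
breakpoint, 68.3% of breakpoint families also emitting a discordant
tree; SPR move counts weighted so most lateral families need one or two
moves; alignments of 200 codons at divergence 0.1 (0.35 for mosaic
families, where detectability requires divergent segments); a TRN of 179
TF genes and 1533 targets whose 20 hubs carry the observed top-20 target
counts, with 93 planted neighbour regulators (runs of 1–14 collinear
targets, weighted toward 1) and two hubs given an adjacent target to
exercise the global-exclusion rule.  Everything is deterministic given
the seed.

The generator emulates topology rearrangement, mosaic alignments and
network structure; it does *not* emulate alignment error, model
misspecification (sequences truly evolve under the likelihood model the
detector fits), rate heterogeneity, gene flow from outside the clade, or
uncertainty in the gene trees themselves (supports are drawn in
[0.95, 1], so planted signal always survives the collapse).  Passing the
end-to-end recovery test therefore demonstrates that the machinery is
correct and calibrated under its own assumptions — not that real
*E. coli* families would be classified with the same sensitivity.  On
real data the screen's power and the collapse threshold interact with
alignment quality in ways only real alignments can probe.

## Problem sizes used by the test suite

Chosen as the package's own desk-scale verification budget: complete SPR
tree spaces at 5–7 leaves (all-pairs against an independent
pendant-subtree-agreement oracle; full searches on all 5-leaf pairs and
seeded samples at 6–7 leaves), 100 random 8–27-leaf MRP recoveries, 500
clonal alignments for the level check, 100 planted mosaics for
breakpoint localisation, and one 200-family end-to-end cohort.

## Known limitations

* Donor/recipient assignment along SPR edit paths is out of scope; the
  edit distance counts events without orienting them.
* The exact search is exponential in the reduced core size; families
  needing many moves on large cores come back UNRESOLVED by design.
* The evidence-class rule is a parameterised surrogate (see above).
* Neighbourhood ordering across the circular origin is reported in rank
  order, which splits a run spanning the origin into two visual blocks
  (membership is unaffected).
* No multiple-testing correction is applied anywhere; every report
  carries the number of tests performed so a reader can apply one.
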