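---
title: "Parsimony phylogenetics of spidroin terminal domains: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Parsimony phylogenetics of spidroin terminal domains: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(silktree)
```

## The problem this package addresses

Spidroins — the structural proteins of spider silk — are built as a long
core of tandem repeats flanked by short, non-repetitive N- and C-terminal
domains.  The repeats are homogenized by concerted evolution, so aligning
them across paralogs violates positional homology; essentially all usable
phylogenetic characters for the gene family therefore come from the two
terminal domains.  Reconstructing the family's history from these domains
involves a chain of analyses that this package implements end to end:

1. **Characterizing the domains**: structural-motif content of the repeat
   regions, hydropathy profiles, identity/conservation statistics, and the
   pairing of N- and C-terminal partial transcripts through their
   near-identical repeat flanks.
2. **Estimating trees by parsimony**: heuristic search with random
   stepwise addition and branch swapping, bootstrap resampling, and Bremer
   decay indices.
3. **Combined versus separate analysis**: concatenating the N and C blocks
   and asking how much support each partition contributes (partitioned
   branch support), how much emerges only in combination (hidden branch
   support), and whether the partitions conflict (partition-homogeneity
   test; supported-conflict screening between annotated trees).
4. **Rooting by reconciliation**: gene trees are unrooted by construction;
   the root is chosen by reconciling every candidate rooting against a
   species tree and minimizing the weighted duplication-loss score.
5. **Mapping motif evolution**: the five classic silk structural motifs
   are scored per exemplar repeat and their gains and losses reconstructed
   on the rooted tree by parsimony.

A synthetic-data generator reproduces the statistical shape of such a
study (sizes, divergence, duplication history, motif grammar) with full
ground truth, so every stage can be validated by recovery experiments.

## Parsimony machinery

Characters are unordered and multistate; gaps, `?`, and the ambiguity
codes `X`/`N` are normalized to missing on input and contribute the full
state set during scoring, so missing data never adds steps.  Tree length
is computed by the two-pass Fitch set algorithm over bitmask state sets
(implemented in C++; trees are scored rooted at a leaf, which leaves the
unrooted length unchanged).  `exhaustive_search()` enumerates all
(2n−5)!! unrooted binary topologies and is limited to 10 taxa;
`heuristic_search()` performs random-order stepwise addition followed by
steepest-descent branch swapping with NNI, SPR or full
tree-bisection-reconnection (TBR, the default) neighborhoods, keeping a
bounded pool of equally parsimonious trees that is swapped to closure.
Every stochastic routine requires an explicit seed and is bit-reproducible
given it.

Bremer decay is computed, per bipartition of the MPT set, as the extra
length of the best tree lacking that bipartition — by filtered exhaustive
scan (automatic up to 8 taxa, where the enumeration is instant) and by
reverse-constraint (penalized-objective) heuristic search beyond.  Partitioned branch support follows the
decomposition logic of combined-data analysis: for node *i* and partition
*j*, the mean length of partition *j* over the shortest anti-constraint
trees minus its mean length over the combined MPTs, with ties averaged —
which is why fractional values arise.  Because partition lengths sum to
the total length, the per-node partition values sum exactly to the Bremer
support; this identity is the primary correctness oracle in the tests.
Separate-analysis support is defined symmetrically as (best length
without the node) − (best length with it), so a node contradicted by a
partition gets a negative value; PHBS and HBS follow by subtraction.

The partition-homogeneity (ILD) test removes invariant characters first,
then permutes the character-to-partition assignment while keeping the
original block sizes.  The statistic is `D = combined best length − sum of
separate best lengths`; the p-value uses the add-one permutation
estimator, with larger `D` counted as more extreme.

## Reconciliation and rooting

`reconcile()` maps each gene-tree node to the last common ancestor of its
descendants' species.  A node is a duplication when its image coincides
with a child's image; each gene edge whose endpoint images are `k`
species-tree edges apart contributes `k − 1` losses below a speciation
and `k` below a duplication.  The weighted score is `1.5·D + 1.0·L` by
default, the standard cost scheme for choosing roots.  `root_search()`
evaluates all `2n − 3` rootings of an unrooted gene tree and reports all
co-optimal rootings rather than tie-breaking silently.

By default the species tree is pruned to the species actually present in
the gene tree: species that were simply not sampled would otherwise
inflate the loss count.  `prune = FALSE` restores the stricter behaviour.
Polytomies are rejected rather than resolved.  The tests verify the LCA
mapping against an independent dynamic program that minimizes the
weighted cost over *all* valid node-to-species mappings, exhaustively
over every rooted gene topology up to 6 leaves crossed with every rooted
species topology up to 5 leaves.

## Motif grammar and ancestral states

The five motifs use the standard coding thresholds: a poly-alanine run of
at least 4; at least 2 consecutive GA (or GS) couplets; at least 2
contiguous GPGX units, where each unit is `GPG` followed by 1–3 residues
from a configurable set defaulting to `{G, Q, Y, S, A}` (the residues seen
in published GPGXX silk motifs); and at least 2 tandem GGX units with X
any residue.  Matching is left-greedy and any missing symbol breaks a
run.  All thresholds and the X-set live in `motif_config()`, so a
different coding is a one-line change.

Ancestral reconstruction treats each motif as an unordered, reversible
binary character (the conventional default; a Dollo assumption would be
defensible for motif origin but loss-and-regain of short repeat motifs is
plausible, so reversibility is the safer default).  Per character we run
a unit-cost minimum-change dynamic program on the rooted tree, extract
the MPR state set per node (nodes with set {0,1} are flagged equivocal),
and resolve ties twice: ACCTRAN places changes as close to the root as
possible, DELTRAN as far as possible.  Both resolutions are exact optimal
reconstructions, so their change counts equal the Fitch length — an
identity the tests assert on random instances.  `list_synapomorphies()`
applies the same machinery to sequence characters and lists a change only
when both optimizations place it on the same branch with the same states.

## The synthetic-data generator

The generator emulates the study conditions the analysis assumes, and its
defaults are fixed accordingly:

* **Species tree**: pure-birth topology, depth rescaled to 1, default 15
  species.
* **Gene family**: duplication rate 0.55 and loss rate 0.2 per unit
  branch length, chosen so the surviving family averages ≈ 25 tips over
  15 species — the sampling density of terminal-domain studies.  The
  simulator records every event, so the surviving tree carries exact
  duplication/speciation labels.
* **Domains**: the N block draws 151–162 aligned residues and the C block
  87–107, evolved by a symmetric amino-acid replacement process (uniform
  exchangeabilities) at 0.75 and 0.95 expected substitutions per site per
  unit length respectively.  Under the default tree these intensities put
  mean pairwise N identity near 38% and C identity near 31% — the
  mid-divergence regime of real terminal domains, with N more conserved.
  No indels are simulated: the real pipeline takes alignments as input,
  so synthetic matrices are born aligned.  This is the main feature of
  real data the generator does not emulate — passing recovery tests say
  nothing about alignment error.
* **Repeats**: per-motif presence evolves by a two-state Markov gain/loss
  process (rates 0.5/0.5); each tip's exemplar repeat is assembled from
  qualifying motif blocks separated by G/A-free spacers, so scanning an
  exemplar returns exactly its true state vector.
* **Paired transcripts**: each tip yields an N and a C partial record
  sharing a high-identity repeat flank; substitutions on the true C copy
  are confined to the flank ends so an intact ≥ 30-residue window always
  remains, decoy paralogs sit near 70% identity (below the pairing
  threshold), and optional near-duplicate paralogs exercise the
  ambiguity-reporting path.

"Nearly identical" repeat flanks are operationalized as ≥ 95% identity
over a ≥ 30-residue window of an ungapped sliding comparison — no
published threshold exists, so both knobs are exposed as arguments.

## Numerical and design choices

* Alignment coordinates are 1-based inclusive throughout.
* Newick support values are carried as internal node labels (the most
  portable dialect); branch lengths are optional and ignored by the
  parsimony machinery.
* FASTA headers follow `id|species|paralog|region`; a sidecar TSV leaf
  map is the alternative metadata route (species and paralog cannot be
  recovered reliably from free-form names).
* MPT pools are canonically ordered by the Newick string of their
  leaf-sorted form, so search output is stable; pools are bounded
  (`keep_max`) to keep plateau swapping tractable.
* Bootstrap resampling draws columns over the whole combined matrix, not
  within partitions, matching standard combined-analysis practice.
* The anti-constraint searches used beyond the exhaustive range optimize
  length plus a large penalty for violating the constraint; the final
  pool always satisfies it.
* Consensus construction keeps splits present in all trees (strict) or in
  more than the cutoff fraction (majority, cutoff ≥ 0.5 so retained
  splits are mutually compatible).

## Problem sizes used in the shipped tests

The validation suite runs entirely on synthetic data at desk scale: Fitch
brute-force checks use 1000 random characters across all unrooted trees
with 4–6 leaves; search validation uses 100 random 7-taxon matrices; the
support-decomposition identities run on 50 random two-partition 6-taxon
matrices; permutation tests use 200 permutations; reconciliation is
verified exhaustively over ~114,000 gene-tree × species-tree pairs plus
100 simulated rooting-recovery replicates; the end-to-end pipeline demo
uses an 8-species study with 60 bootstrap replicates.  These sizes were
chosen to exercise every code path with exact oracles; the same functions
scale to the tens-of-taxa, thousands-of-replicates settings of a real
study by raising the corresponding arguments.

## Known limitations

* Heuristic search offers no guarantee of finding the global optimum on
  large, conflicted matrices (inherent to hill-climbing); use more
  addition replicates.
* Likelihood and Bayesian analyses (model selection, posterior supports,
  topology tests) are out of scope; the conflict screen's posterior arm
  is therefore not implemented — only the bootstrap threshold.
* Reconciliation assumes binary trees and handles duplications and
  losses only (no transfers, no bootstrap-aware rearrangement).
* The NEXUS reader supports a single DATA/CHARACTERS block, not the full
  standard.
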