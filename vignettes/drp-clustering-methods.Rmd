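---
title: "Clustering disulfide-rich peptides by structural similarity: methods and design"
author: "drpclust"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clustering disulfide-rich peptides: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drpclust)
```

## The problem

Disulfide-rich peptides (DRPs) are small polypeptides — here, chains of
fewer than 50 residues carrying one to four disulfide bonds — whose covalent
cross-links confer unusual chemical and proteolytic stability. They are
attractive scaffolds for engineering binders (e.g., by phage display), and a
prerequisite for scaffold selection is a structural census: which distinct
backbone architectures exist among known DRP structures, and which member
best represents each architecture?

`drpclust` implements an automated clustering protocol for this census. Its
five stages are:

1. **Filtering**: keep chains with fewer than 50 resolved residues and one
   to four disulfide bonds; discard exact duplicates (100% sequence
   identity *and* native overlap 1.0).
2. **Native-overlap clustering**: average-linkage agglomerative clustering
   on the native-overlap similarity, merging while the average overlap is at
   least 0.7.
3. **Knottin reclustering**: clusters containing at least four chains
   annotated with the knottin SCOP fold (`g.3`) are pooled and reclustered
   by the *disulfide distance* with a 2.0 Å cutoff, because knottin loops
   vary so much in length that full-chain superposition splits peptides that
   share an essentially identical disulfide core.
4. **Longer-denominator singleton pass**: any chain outside the 25 most
   populated clusters that overlaps some member of a top-25 cluster at
   ≥ 0.7 is moved into that cluster.
5. **Shorter-denominator singleton pass**: the same rule once more, after
   re-ranking, with the shorter chain's length in the overlap denominator,
   so short fragments matching part of a larger scaffold are also absorbed.

Afterwards each cluster's **representative** is the member with the largest
mean native overlap to its co-members, and per-cluster conservation profiles
color each residue from blue (diverse) to yellow (conserved).

## The two metrics

**Native overlap** between chains $a$ and $b$ is the fraction of aligned
C$\alpha$ pairs within 3.5 Å (inclusive) after optimal rigid superposition,

$$\mathrm{NO}(a,b) \;=\; \frac{\left|\{(i,j) \in \mathcal{A} :
\lVert R\,x_i + t - y_j\rVert \le 3.5\,\text{Å}\}\right|}{L},$$

where $\mathcal{A}$ is the order-preserving residue equivalence found by the
aligner and $L$ is the length of the longer chain (the shorter chain in the
second singleton pass). A self-alignment gives exactly 1.0. **Sequence
identity** divides the number of equivalent residues of identical type by
the longer chain's full length.

**Disulfide distance** compares bond geometry only. For bond counts
$n_a, n_b$, every injection of the smaller bond set into the larger is
enumerated, times both cysteine orientations of each mapped bond —
$P(\max, \min)\cdot 2^{\min}$ candidate mappings, e.g. 48 for two three-bond
peptides. For each mapping the $2m$ mapped cysteine C$\alpha$ atoms are
superposed by least squares and the distances of all $4m$ equivalent atoms
(C$\alpha$ and S$\gamma$) are aggregated; the distance is the minimum over
all mappings. Unmapped bonds of the larger set are ignored.

*Aggregation:* the protocol's text describes a sum of distances, but its
cutoff (2.0 Å) is on the scale of a per-atom deviation, and a raw sum over
up to 12 atom pairs is incommensurate with such a threshold. The package
therefore aggregates by the **mean** over the $4m$ atom distances by
default, with `sum` and `rms` selectable (`ss_aggregation`); no report
silently converts between them.

## The pairwise aligner

The alignment underlying native overlap is a sequence-independent iterative
superposition/dynamic-programming procedure:

1. **Seeding.** Each residue is described by its intramolecular C$\alpha$
   distance profile over a 5-residue window (distances to neighbours at
   offsets −2, −1, +1, +2) — a rigid-motion-invariant local shape
   descriptor. Global DP over profile similarity
   $\max(0,\, s_0 - \overline{|\Delta d|})$ with $s_0 = 3$ Å and gap penalty
   1.0 yields the initial correspondence.
2. **Superposition.** The current pairs are superposed by the Kabsch
   algorithm (proper rotations only). The fit is *trimmed iteratively*:
   after each fit, pairs beyond the 3.5 Å contact cutoff are dropped from
   the fitting set (while at least three remain) and the fit is repeated to
   a fixpoint. Without trimming, a genuinely displaced segment drags the
   least-squares frame into a compromise in which neither the core nor the
   displaced segment is fit well.
3. **Re-derivation.** Pairs are recomputed by DP on the inter-structure
   C$\alpha$ distance matrix with cell score $\max(0,\, d_0 - d_{ij})$,
   $d_0 = 7$ Å, gap penalty 1.0. Matches scoring zero (at or beyond $d_0$)
   are removed from the pair set: they are not equivalences.
4. Steps 2–3 repeat until the pair set is unchanged, at most 50 iterations.

DP ties prefer the diagonal move, then the move advancing chain A, so
results are fully deterministic. Degenerate superpositions are defined for
one point (translation only) and two points (minimal rotation about the
common normal), which the one-bond disulfide mappings require.

The alignment layer is implemented natively rather than delegating to an
external structure-alignment program. The downstream metric — a *fraction
of residues within 3.5 Å* — is deliberately robust to aligner details, but
exact numerical parity with alignments produced by other programs is not
claimed.

## Average-linkage clustering with cutoff termination

Every chain starts as a singleton; repeatedly the cluster pair with the best
average inter-cluster score is merged, where the average is the unweighted
mean over all cross-cluster chain pairs (UPGMA-style, *not* the weighted
mean of previous linkage values — the two differ for unequal cluster sizes).
A merge at exactly the cutoff is allowed (≥ for similarities, ≤ for
distances). Ties are broken toward the lexicographically smallest member
ids, making the partition invariant under input order. Average linkage is
reducible, so the linkage trace is monotone and the usual dendrogram-cutting
interpretation applies; `stats::hclust` with `cutree` serves as an
independent oracle in the test suite.

## Parameters

| Parameter | Default | Units | Meaning |
|---|---|---|---|
| `overlap_contact_cutoff` | 3.5 | Å | contact criterion of native overlap |
| `overlap_cluster_cutoff` | 0.7 | fraction | merge/singleton threshold |
| `ss_cluster_cutoff` | 2.0 | Å | knottin reclustering threshold |
| `ss_aggregation` | mean | — | disulfide-distance aggregation |
| `knottin_fold_id` | `g.3` | — | SCOP fold marking knottins |
| `knottin_min_members` | 4 | chains | pooling threshold per cluster |
| `singleton_top_n` | 25 | clusters | snapshot receiving singletons |
| `report_top_n` | 20 | clusters | summary-table depth |
| `max_residues` | 50 (exclusive) | residues | DRP size filter |
| `min_bonds`–`max_bonds` | 1–4 | bonds | DRP bond filter |

The 0.7 and 2.0 Å cutoffs are empirical: looser alternatives (0.6, 2.5 Å)
lump visibly different folds together, stricter ones (0.8, 1.5 Å) fragment
clusters that share an architecture. The package exposes the parameters and
the machinery to sweep them rather than hard-coding that judgment. Bond counting for the 1–4 filter includes inter-chain bonds by
default (`bond_counting = "any_involving_chain"`), so an insulin B chain
whose cysteines all bond across to the A chain still qualifies; only
intra-chain bonds enter the disulfide metric.

## Conservation scoring

Per cluster, a **star multiple alignment** anchors every member on the
representative: one column per representative residue, member residues
paired to it occupy that column, unpaired member residues are dropped.
A progressive multiple structure alignment would add columns for insertions;
the star layout was chosen because the representative is by construction the
most central member and the coloring only needs representative-indexed
columns. The column score is the mean BLOSUM62 value over all unordered
pairs of non-gap residues (pairs involving gaps are excluded; columns with
fewer than two residues take the minimum raw score). Scores are normalized
to z-scores over columns, clamped to $[-2, 2]$ (all zero if the variance
vanishes) — a stated stand-in for AL2CO's normalization, of which only the
output range is documented — and mapped linearly to RGB with $-2 \mapsto$
blue $[0,0,255]$ and $+2 \mapsto$ yellow $[255,255,0]$, rounding half-up so
colors are platform-independent. The emitted PyMOL script carries one
`set_color`/`color` pair per aligned residue.

## The synthetic benchmark

Real PDB-scale evaluation requires a historical database snapshot; the
package instead ships a generator whose fixtures make every pipeline stage
testable and self-validating.

Templates are idealized C$\alpha$ traces (strands as 3.8 Å zigzags, helices
with 1.5 Å rise and 100° twist, loops as half-ellipse arcs whose bulge grows
with loop length) plus S$\gamma$ pseudo-atoms placed on the axis between
bonded C$\alpha$ pairs at 2.05 Å separation. Full side chains, realistic
Ramachandran geometry, and sequence-structure consistency are *not*
emulated — every metric in scope consumes only C$\alpha$ and S$\gamma$
coordinates, and passing tests demonstrate correctness of the protocol's
machinery, not performance on experimental coordinates. Members add
isotropic Gaussian noise (default σ = 0.3 Å per axis, a typical
room-temperature coordinate uncertainty), a random rigid motion, and
loop-length variation; generation is deterministic for a fixed seed with a
fixed RNG (Mersenne-Twister/Inversion), one derived stream per family.

The default benchmark (`defaultBenchmark()`) holds six family
specifications × 10 members: two β-hairpin families of different size, a
helix–loop–helix family, a collapsed-macrocycle (conotoxin-like) family,
and two knottin-core specifications sharing one ground-truth label but
differing in loop length (4 vs 18 residues) so that full-length overlap
stays below 0.7 while the template disulfide distance is far below 2.0 Å —
the situation the knottin reclustering step exists for. Generation verifies
family separation (cross-family overlap ≤ 0.6; same-label variants checked
on noise-free template realizations, since a single noisy pair can stray
past a cutoff that the cluster-level average respects). Three engineered
decoys exercise the singleton passes: a displaced-segment pair (one decoy
absorbed by the longer pass, its partner following only via the re-ranked
second pass) and a truncation absorbed only under the shorter denominator.

Because the benchmark produces only ~7 clusters, the protocol's top-25 gate
would make every cluster "top" and the singleton passes vacuous; benchmark
runs therefore use `singleton_top_n = 5` (the number of true families) as
the study condition, while the package default remains 25.

```{r benchmark, eval = FALSE}
bm <- defaultBenchmark(seed = 1)
res <- runPipeline(bm$chains, folds = bm$folds,
                   cfg = pipelineConfig(singleton_top_n = 5,
                                        report_top_n = 5))
res$partition
```

## Numerical and degenerate-input choices

* NMR multi-model entries use model 1 only; alternate locations resolve to
  the highest-occupancy conformer, ties toward altloc `A`.
* Geometric disulfide detection uses a 2.5 Å S$\gamma$–S$\gamma$ cutoff
  (canonical bond ≈ 2.05 Å plus refinement noise), greedy nearest-first so
  each cysteine joins at most one bond; SSBOND records take precedence, and
  conflicting records keep the geometrically closer pair with a warning.
* "Within 3.5 Å" and both cluster cutoffs are read inclusively.
* Duplicate removal keeps the lexicographically smallest chain id;
  pre-bucketing by exact sequence cannot change the result because 100%
  identity over the longer denominator forces identical sequences.
* Singleton moves are computed against a frozen snapshot of the top
  clusters and applied as one batch, so no within-pass cascade and no
  order dependence; destination ties prefer the higher member overlap, then
  the larger cluster, then the lower rank.
* Fewer than two chains, empty clusters, chains lacking intra-chain bonds
  during knottin pooling, and alignments with no pair within $d_0$ all have
  defined, non-erroring behavior (trivial partition, pass-through with
  warning, empty alignment with overlap 0).

## Known limitations

* The aligner honors a contract (superposition + distance-based DP), not
  any specific external program; cluster counts and overlap values obtained
  on a full structure-database snapshot therefore depend on the aligner and
  are not expected to match other implementations digit for digit.
* PDB input only (no mmCIF); no biological-assembly expansion; HETATM
  records and ligands are ignored.
* The conservation normalization is a documented stand-in (z-score with
  clamping); entropy- or independence-weighted variants are out of scope.
* Synthetic fixtures are C$\alpha$/S$\gamma$ stick models; conclusions
  about experimental structures require running the pipeline on real
  coordinate files.
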