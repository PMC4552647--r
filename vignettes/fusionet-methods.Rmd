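---
title: "Methods: function-based organism classification with fusionet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: function-based organism classification with fusionet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fusionet)
```

# Overview

`fusionet` classifies microorganisms by what their proteomes can *do*
rather than by their evolutionary descent. The pipeline has four
stages: (1) cluster proteins into molecular-function groups from
pairwise alignment results via the HSSP distance and Markov
clustering; (2) summarise each organism as a functional repertoire and
compare repertoires pairwise to obtain a complete weighted organism
network; (3) interrogate that network against a reference taxonomy
(single-linkage cut-off sweeps, a layered hierarchy, Louvain modules);
(4) benchmark any pairwise similarity metric with precision/recall
machinery. This vignette documents the model, its tunable parameters,
the numerical choices, and what the bundled synthetic-data generator
does and does not emulate.

# The HSSP distance and the same-function graph

For an alignment of length $L$ residues and percent identity
$\mathrm{Id} \in [0,100]$:

$$
\mathrm{HSSP}(L, \mathrm{Id}) =
\begin{cases}
-99 & L < 11\\
\mathrm{Id} - 480\,L^{-0.32\,(1 + e^{-L/1000})} & 11 \le L \le 450\\
\mathrm{Id} - 19.5 & L > 450
\end{cases}
$$

The subtracted term is a calibration curve in the length–identity
plane separating protein pairs of identical molecular function from
the rest; the distance is how far an alignment sits above that curve,
so *higher means more similar*. Short alignments ($L<11$) are
uninformative and get the $-99$ sentinel, which can never reach any
sensible threshold — equivalently, "never the same function".

Two conventions the printed form leaves open:

* **$L = 11$** is unassigned by the strict inequalities; we place it
  in the middle branch, the continuity-preserving closure of the
  printed intervals.
* **Branch continuity.** The curve evaluates to $\approx 19.537$ at
  $L = 450$, so the jump to the $\mathrm{Id} - 19.5$ branch is
  $\approx 0.037$ — continuous for practical purposes. Note the curve
  is not perfectly monotone: it attains a minimum slightly below
  $L = 450$ and rises again by a few hundredths, so the distance in
  $L$ at fixed identity is monotone only up to that wobble. We
  implement the formula exactly as printed rather than smoothing it.

Multiple alignments per protein pair (both orientations, multiple
local hits) are consolidated by keeping the **maximum** distance per
unordered pair; self-hits are dropped, but their protein ids are
retained so the full protein universe survives an alignment-only
entry point. Pairs with distance $\ge 10$ — a stringency at which
same-function calls are right about nine times in ten — become edges
of the same-function graph. The comparison is an exact `>=` with no
epsilon: the threshold is a definition, not an estimate.

## Markov clustering

The graph is clustered with a built-in canonical MCL implementation
(no R package on our dependency tier provides one):

* edge weights are the HSSP distances (they carry the confidence
  signal); a switch to binary weights exists for sensitivity analysis;
* each node receives a self-loop equal to its maximum incident edge
  weight (standard practice; keeps attractors stable);
* expansion is matrix squaring, inflation the entrywise power
  (default 1.4, a deliberately conservative, coarse setting) followed
  by column renormalisation;
* entries below $10^{-6}$ are pruned after each inflation; iteration
  stops when the maximum absolute change between successive matrices
  falls below $10^{-8}$, with an error (reporting the residual) after
  100 iterations;
* clusters are the connected components of the limit matrix's
  support; connected components of the input are processed
  independently, which is exact because expansion cannot cross a
  component boundary;
* nodes are ordered lexicographically by protein id before matrix
  construction, and group ids are assigned by each group's smallest
  member, so results are identical across runs, platforms and input
  orderings.

The implementation is verified in the test suite against an
independent dense-matrix MCL oracle written in base R and, on
structured cases (cliques, weakly bridged cliques), against the exact
expected partitions. Scale limit: the dense limit-support readout and
per-component sparse squaring are comfortable up to $\sim 10^5$
proteins per connected component; this package does not attempt
streamed MCL for larger single components.

# Annotation categories

Proteins are `known` (any informative annotation), `hypothetical`
(annotation contains "hypothetical" or "putative", or equals
"protein" or "Uncharacterized protein conserved in bacteria"), or
`unknown` (no annotation at all). Matching is case-insensitive and
trimmed; the trigger terms match as substrings by default because real
annotation strings embed them in many frames ("conserved hypothetical
protein"), with a whole-word switch for stricter reading. A group is
`Kn` with at least one known member, else `Hy` with at least one
hypothetical member, else `Un`; it is `shared` when its members span
two or more organisms, `unique` otherwise.

For the annotation-consistency report, strings are normalised by
lowercasing, whitespace collapsing and stripping trailing EC-number
qualifiers — a documented, reproducible stand-in for the undefined
notion of "similar annotation".

# Repertoires and organism similarity

A repertoire is the set of function groups containing at least one of
the organism's proteins; in-paralogs collapse. Pairwise similarity is
$|A \cap B| / \max(|A|, |B|)$ — the larger repertoire in the
denominator encodes the assumption that similar organisms have similar
repertoire sizes, so a size mismatch is itself evidence of
dissimilarity. The whole-genome baseline counts proteins with any
$\ge 40\%$-identity alignment to the other proteome (no
alignment-length requirement, as only the identity cut-off is
specified for this baseline); the two directional counts are combined
conservatively as their minimum and normalised by the bigger proteome.
Both directional counts are returned as attributes.

Similarities are fractions in $[0,1]$ everywhere internally;
percentages only appear in rendered output. This single convention
avoids factor-of-100 bugs between the "%"-speak of reports and the
arithmetic.

# Network analysis

**Single linkage.** At cut-off $c$, clusters are the connected
components after keeping edges with weight $\ge c$ (the same `>=`
convention as the HSSP threshold). **Overall accuracy** assigns every
cluster its modal taxon and counts the fraction of organisms assigned
correctly; modal ties break to the lexicographically smallest taxon
(a deterministic choice; a "count either" mode is available).
**Coverage** of a taxon is the fraction of its members inside its
major cluster, ties broken by smallest cluster id; overall coverage
counts only taxa with two or more members, since singletons are
trivially covered. The sweep over cut-offs yields per-level lower
bounds (first cut-off with accuracy 1) and upper bounds (last cut-off
with coverage 1).

**Layered hierarchy.** Starting from one all-organism cluster at
similarity 0 and stepping the cut-off upward in 1% increments, each
cluster is refined into its clusters at the next cut-off; sibling
clusters are related by neighbor joining over distances
$1 - \overline{s}_{\text{inter}}$ (one minus the mean inter-cluster
pairwise similarity), and layers are stitched by substituting each
cluster node with its refinement subtree. Two-cluster layers
degenerate to a simple two-branch join (NJ needs three taxa);
organisms still co-clustered at the top cut-off end as a zero-length
polytomy. Because single-linkage partitions nest, refining within a
parent cluster equals restricting the global partition — the
implementation exploits this. The stitched object is a compact
similarity summary, **not** a phylogeny. Hierarchies are compared by
the correlation (Pearson by default, Spearman by flag) of their
leaf-to-leaf step-count matrices; the layer count cancels out of such
topological comparisons.

**Modules.** Louvain community detection runs on the complete network
— no cut-off at all, edge weight alone drives the grouping. The
package's `resolution` behaves like a random-walk time horizon:
*larger values give larger, coarser modules*. Internally this is
standard resolution-scaled modularity with the null-model term scaled
by `1/resolution` (the γ convention of most libraries runs the other
way). This modularity-based form approximates the Markov-stability
variant of Louvain; the exact stability process is not specified
closely enough to pin down, so the package treats resolutions as
qualitatively ordered (coarseness increases with the value) rather
than numerically transferable between tools. Louvain is inherently
order-dependent, so runs are seeded; a consensus mode reruns the
algorithm $k$ times and keeps majority ($>k/2$) co-assignments.
Partitions are compared by the pair-assignment Jaccard index:
co-assigned pairs in both groupings over pairs co-assigned in at least
one — pairs, not organisms, are the unit throughout.

# Evaluation

At a threshold $t$, organism pairs with similarity $\ge t$ are
predicted same-taxon; counts against the reference taxonomy give
$PA = TP/(TP+FP)$ and $PC = TP/(TP+FN)$. The precision/recall curve
sweeps every distinct similarity value, drops points with undefined
$PA$ (no predicted positives), anchors the curve at $PC = 0$ with the
most stringent defined $PA$, and integrates by trapezoid over $PC$ —
hence the AUC depends only on the similarity ranking and is invariant
under strictly monotone transforms. Bootstrap resampling draws 10% of
the **pairs** with replacement (pairs are what the confusion counts
are built from; resampling whole organisms is available by flag for
the alternative reading), 100 times by default, under an explicit
seed. Replicates whose resample is single-class get `NA`. Two AUC
distributions are compared by the two-sided Wilcoxon rank-sum test in
its normal approximation with tie correction; a fully tied comparison
(zero variance) is reported as $p = 1$. P-values are reported raw —
no multiple-testing correction across metric pairs.

# The synthetic-data generator

The generator emulates the statistical structure the analysis assumes:

* a balanced taxonomy (default: 2 phyla × 2 families × 2 species × 2
  organisms = 16 organisms) in which every taxon contributes a core
  pool of functions shared by all organisms below it (defaults, low to
  high: species 6, genus 8, family 10, order 12, class 15, phylum 40),
  plus organism-unique functions at a target 10% of the repertoire —
  mirroring the observation that widely shared functions are the
  well-annotated ones while poorly annotated functions tend to be
  organism-specific;
* per-function annotation categories drawn at rates known 0.5 /
  hypothetical 0.3 / unknown 0.2, with annotation strings that follow
  the trigger-word conventions of the categorizer;
* in-paralogs at rate 0.1 (a second copy of a function with
  probability 0.1), which exercise repertoire collapsing;
* alignments fabricated *backwards* from target HSSP distances:
  same-function pairs draw $L \sim U\{50..400\}$ and a target distance
  $U(15, 60)$, and the identity is solved from the middle-branch curve
  (exercising the formula where it is nonlinear); spurious
  different-function hits target $U(-30, -5)$; one self-hit per
  protein carries the protein universe, as real all-vs-all aligners
  do. Gaussian identity jitter (default 0 — the idealised noise-free
  regime) degrades the separation smoothly: at jitter SD 2 a
  same-function edge needs a $>2.5\sigma$ excursion to be lost.

Because pool sizes are uniform, every organism has the same repertoire
size $R$ and pairwise similarity takes one of seven exact plateau
values depending on the deepest shared taxon (0 across phyla). The
generator reports these plateaus and the midpoints between adjacent
ones as *designed separating cut-offs*: single-linkage at the cut-off
designed for level $\ell$ recovers exactly the level-$\ell$ taxa, so
accuracy and coverage are both 1 there, accuracy stays 1 at any higher
cut-off (partitions nest and stay pure) and coverage stays 1 at any
lower one.

What the generator does **not** emulate: sequence evolution (sequences
are optional random strings; the pipeline's mathematics never reads
them), horizontal gene transfer, plasmids, unbalanced taxonomies,
heterogeneous repertoire sizes, or any correlation between a
function's annotation category and how widely it is shared. Passing
tests therefore demonstrate algorithmic correctness on the assumed
structure, not robustness to the full messiness of real proteomes.

# Problem sizes and numerical conventions in the test suite

The suite runs the full pipeline at 16–24 organisms with ~400–510
planted function groups and ~1,800–2,700 proteins, block networks of
10–30 organisms for module detection, and a 1,374-organism network
(about 943 thousand pairs) for the complete-network construction —
sizes chosen so the whole suite completes in minutes on one core
while still exercising every code path at meaningful scale.
Noise-recovery claims use 10 generator seeds. Reproducibility
conventions: every stochastic routine takes an explicit integer seed
and restores the caller's RNG state; all tie-breaks are lexicographic;
cluster, group and module ids are assigned by each cluster's smallest
member, so ids as well as memberships are stable across platforms.

# Known limitations

* The pipeline starts at alignment output; running the aligner (and
  profile iteration) is out of scope, as are annotation tools —
  annotation tables are consumed, never produced.
* MCL is exact but not streamed; one connected component must fit in
  sparse memory.
* The Louvain resolution is ordinal across tools, not numerically
  portable.
* The layered hierarchy inherits neighbor joining's occasional
  negative branch lengths; step-count comparisons are unaffected.
* The bipartite view performs no layout; it exports nodes and edges
  for external visualisation.
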