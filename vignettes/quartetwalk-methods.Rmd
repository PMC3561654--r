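---
title: "Random-walk quartet phylogenies: model, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Random-walk quartet phylogenies: model, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(quartetwalk)
```

## The reconstruction model

`quartetwalk` builds an unrooted binary phylogeny incrementally. A guide
tree on a subset of taxa is built by neighbour joining and indexed by a
rooted ternary search tree: each internal search node owns a contiguous
region $r(v)$ of the phylogeny and a center $s(v)$ inside it, its three
children correspond to the three directions around $s(v)$, and search-tree
leaves are in bijection with phylogeny edges. Each remaining taxon $x$ is
routed to an edge by a random walk over this index.

A *node query* at phylogeny node $p$ asks $k$ quartet queries
$q(x, a_1, a_2, a_3)$, one representative $a_i$ per direction around $p$.
The oracle answering those queries is pluggable:

* **distance oracle** — the four-point condition on six pairwise
  distances, with ordinary-least-squares edge lengths $(a,b,c,d,e)$ and
  weight $w = e/(a+b+c+d+e)$. Negative external OLS lengths (possible on
  noisy input) are clamped to zero inside the weight only; the raw fit is
  kept for diagnostics. A four-point tie yields $e = 0$ and hence $w = 0$,
  so tied quartets cannot carry a vote.
* **tree-collection oracle** — the majority induced topology among input
  trees containing all four taxa, weighted by $\sqrt{m/N}$ with $m$ the
  supporting trees and $N$ *all* input trees; a quartet no input tree
  covers is ABSENT, and the walk resamples representatives up to ten times
  before counting a zero-weight abstention.
* **noisy oracle** — the true topology with probability $1-p_{\rm err}$,
  else a uniformly wrong one, weight 1. This isolates the walk's behaviour
  from distance estimation and underlies the exact-reconstruction and
  robustness tests.

Votes aggregate by *weighted majority* (sum of weights per direction) or
*winner-takes-all* (single highest-weight quartet). The two schemes
genuinely differ — two 0.3-weight quartets beat one 0.5-weight quartet
under the former and lose under the latter — and the package exposes both
because they trade split-level accuracy (Robinson–Foulds) against
quartet-level accuracy differently.

The walk starts at the root. At an internal node it first checks the at
most two region boundaries: a node query at a boundary node whose winning
direction leaves the region sends the walk to the parent. Otherwise the
center query picks a child; a vote for a direction with no region edges is
also treated as evidence the taxon lies outside, and retreats. At a leaf
(a phylogeny edge), node queries at the edge's internal endpoints confirm
or disconfirm the placement: confirmations increment a counter,
disconfirmations decrement it, the walk moves up only at zero, and the
taxon is inserted once the counter reaches the confidence threshold
$\ell$. The counter is clamped at zero (the walk leaves a leaf exactly
when a disconfirmation finds it at zero), and acceptance-by-counter
($\ge \ell$ consecutive net confirmations) is the default operational
reading of "spending the last $\ell$ steps at the leaf"; a walk that
exhausts its budget is still accepted if its literal trailing $\ell$-step
window sat at one leaf. Boundary checks run before the center vote,
following the order in which the walk's backtracking rule is defined.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `k` | 5 | quartet queries per node query |
| `voting` | `"wm"` | weighted majority; `"wta"` for winner-takes-all |
| `ell` | 30 | confidence threshold (steps at a leaf before insertion) |
| `step_budget` | $\lceil 6\log_2 E\rceil + \ell$ | walk step cap ($E$ = edge count) |
| `repeats` | 1 | independent walks per taxon; 2 requires both to agree |
| `min_pool` | 20 | biased choice: minimum representatives per direction |
| guide `size` | 200 | NJ guide-tree size (fixed rule, capped at $n/2$ for small $n$) |
| guide `c` | 10 | proportional rule $\lceil c\,n^{1/3}\rceil$ when enabled |
| `rounds` | 3 | insertion rounds (first pass + two reinsertion rounds) |
| saturation cap | 10 | distance ceiling, substitutions/site |

The step budget is not part of the underlying algorithm description, which
only bounds the *expected* walk length; a finite cap is needed in practice.
$O(\log n)$ steps plus room for the $\ell$-window motivates the default,
and it is configurable. Reinsertion rounds re-randomize the insertion
order each time; the alternative (reusing the failed order) has no obvious
advantage and worse mixing.

### Biased choice of representatives

Representatives for a node query at search node $y$ are restricted to the
region of the lowest ancestor $y^\*$ at which every direction holds at
least `min_pool = 20` candidate leaves, falling back to the whole
phylogeny at the root. Near the root this changes nothing (pools are
large); deep in the tree it keeps quartets short, where distance
estimation is most reliable. The implementation exploits a structural
fact: every internal phylogeny node is the center of exactly one search
node (edges around a node are only separated by splitting at that node),
so pools at any level are assembled from precomputed per-direction leaf
lists in $O(\mathrm{depth})$ without traversing regions, and are cached
across walks with version stamps that insertions invalidate precisely.

### Distance estimation

Nucleotide distances are the log-corrected Jukes–Cantor transform
$d = -\tfrac34\ln(1-\tfrac43 p)$ of the mismatch fraction $p$ under
pairwise deletion (gaps and ambiguity codes excluded per pair — the
simplest defensible convention, and the simulator emits neither). $p \ge
0.7499$ saturates to the cap of 10 substitutions/site, which keeps
four-point sums finite and drives saturated quartets toward weight 0.
Protein distances follow the Scoredist construction on BLOSUM62: the
pairwise alignment score normalized by its background expectation and by
the mean self-score, $d = -c\,\ln(\sigma_N/\sigma_{UN})$ with the standard BLOSUM62
calibration $c = 1.337$; the background frequencies are named
constants in the code. Distances are memoized; for full nucleotide builds
of a few hundred taxa or more the complete matrix is instead precomputed
in one pass of one-hot crossproducts, which is numerically identical and
much faster when most pairs will be needed anyway. A precomputed PHYLIP
matrix can replace sequences entirely.

### Guide trees

The guide tree is classic neighbour joining (via `ape::nj`) on a uniform
random subset: 200 taxa by default, or $\lceil 10\,n^{1/3}\rceil$ under
the proportional rule. NJ branch lengths are discarded — the walk is
purely topological — and output trees are emitted without lengths by
default, since the algorithm never estimates them globally. In supertree
mode the guide is NJ on path distances measured in the first input tree
(topological distances when lengths are absent), over a random subset of
that tree's taxa; the aggregation procedure itself does not prescribe a
guide construction, so the package reuses the machinery it already trusts
on the input whose taxon set is sampled.

For the noisy test oracle, guide distances are the true tree's path
distances, making the guide exact; this is deliberate, as that oracle
exists to study the walk itself.

## The simulator and what it does (not) show

`yule_tree(n)` draws a pure-birth tree (rate-1 exponential waiting times,
uniform lineage choice) and normalizes its height to 1.
`perturb_and_scale` multiplies each branch by an independent
$U[0.5, 2]$ draw — deviating the tree from ultrametricity — then by
$\kappa f$. The scale-factor grid $f \in \{25, 50, 100, 200\}$ is conventionally
quoted in arbitrary units; the package fixes the calibration
$\kappa = 1/200$, so the grid spans tree heights 0.125 to
1.0 substitutions/site, from short-branch to near-saturation regimes.
`evolve_jc` evolves gap-free sequences under Jukes–Cantor with per-site
rates drawn once per alignment from a mean-1 exponential (the conventional normalization). The simulation grid
used by `coverage_grid` and the acceptance script runs 1000-taxon trees
over $f \in \{25, 50, 100, 200\}$ and lengths $\{250, 1000, 4000\}$, one
tree per cell — a problem size chosen so the whole grid runs in minutes
on one CPU; the coverage average is checked with a tolerance that
reflects both the modest grid size and the calibration uncertainty.

What passing these simulations does *not* show: real alignments violate
Jukes–Cantor (unequal base frequencies, transition bias, indels,
alignment error), quartet errors correlate through shared taxa far more
strongly than the independent-error model assumes, and real guide trees
are themselves estimated. The simulator reproduces the expected
difficulty gradient (shorter sequences and longer branches lower
coverage), not the idiosyncrasies of biological data.

## Numerical choices and degenerate inputs

* Four-point ties break canonically ($WX|YZ < WY|XZ < WZ|XY$) and carry
  weight 0, so determinism never injects bias into votes.
* Vote ties among directions are resolved uniformly with the walk's RNG.
* All-zero (or all-abstained) votes pick a uniform random direction.
* Quartet weights are scale-invariant and confined to $[0,1]$; a
  nonpositive denominator yields 0.
* `attach_leaf` splits the host edge 0.5/0.5 when lengths are present;
  lengths are cosmetic for this algorithm.
* Within one node query the same taxon triple is never reused (resampled
  up to ten times, then deduplicated); across steps sampling is with
  replacement, so the walk cannot run out of queries.
* Newick output is canonical (children ordered by smallest descendant
  label), making byte-identical outputs the determinism criterion.
* The search tree is never rebalanced after insertions; the decomposition
  is centroid-based, so the guide index starts balanced
  (depth $\le 2\log_2 E + 4$ in the property tests), and insertions in
  random order keep it shallow in expectation. Centers are restricted to
  the path between a region's two boundary nodes, which caps every
  boundary set at two — the invariant the walk's boundary checks rely on.

## Known limitations

Branch lengths of the output tree are not estimated. Polytomies beyond
the root trifurcation are rejected rather than resolved. The
winner-takes-all/weighted-majority trade-off is exposed but not tuned
automatically. Supertree inputs with very low pairwise overlap resolve
few quartets and the walk then stalls near the root, reported as low
coverage rather than as an error. Runtime is dominated by node queries;
the implementation is vectorized R with aggressive caching rather than
compiled code, which is ample for the $10^3$–$10^4$-taxon range the test
suite exercises but not tuned for the $10^5$ scale.
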