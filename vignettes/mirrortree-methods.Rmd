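---
title: "Measuring coevolution between protein families with mirrortree"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring coevolution between protein families with mirrortree}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question the method answers

Proteins that physically interact or work in the same molecular machine —
a secretin channel and the pilotin lipoprotein that docks it into the outer
membrane, a ligand and its receptor — are under shared evolutionary
constraints. Over long timescales this coupling leaves a signature: the
phylogenetic trees of the two families resemble each other beyond what the
underlying species phylogeny alone explains. The mirrortree approach turns
that resemblance into a number. Given one representative sequence per
organism for each of two families, it asks: across all pairs of common
organisms, do the evolutionary distances within family 1 co-vary with the
corresponding distances within family 2?

## The statistic

For the $N$ organisms shared by the two families there are
$n = (N^2 - N)/2$ unordered organism pairs. Let $R_i$ be the patristic
distance (sum of branch lengths along the tree path) between the members of
pair $i$ in family 1's tree, and $S_i$ the corresponding distance in family
2's tree. The tree-similarity score is the Pearson correlation

$$
r = \frac{\sum_{i=1}^{n} (R_i - \bar R)(S_i - \bar S)}
         {\sqrt{\sum_{i=1}^{n} (R_i - \bar R)^2 \;
                \sum_{i=1}^{n} (S_i - \bar S)^2}},
$$

implemented literally in `tree_correlation()`. Correlation, not equality,
is the right comparison: the two families can evolve at quite different
absolute rates (r is invariant to positive affine rescaling of either
matrix), and what matters is whether the *pattern* of divergences mirrors.

Position $i$ must refer to the same organism pair in both vectors;
`match_organisms()` enforces this by intersecting the label sets, sorting
them, and flattening both upper triangles in the same order. Fewer than 4
common organisms ($n \le 3$) makes the correlation nearly meaningless and
is rejected (configurable via `min_n`).

## Significance by permutation

The score alone is hard to calibrate: distance matrices have strong
internal structure, so even unrelated families can show sizable $|r|$. The
package therefore tests the null hypothesis that the organism-to-organism
*correspondence* between the matrices is arbitrary, Mantel-style: the
organism labels of the second matrix are permuted as a whole (rows and
columns together, which preserves the multiset of distances and the
within-family structure — the exchangeability the test needs), the
correlation is recomputed $B$ times, and

$$
p = \frac{1 + \#\{\,|r_b| \ge |r_{\mathrm{obs}}|\,\}}{1 + B}.
$$

The add-one correction keeps $p \ge 1/(B+1)$; the default is two-sided on
$|r|$ with a one-sided (`"greater"`) option, and $B$ defaults to 999.
Permuting individual matrix cells instead of whole organisms would destroy
the within-matrix structure and badly inflate significance; it is not
offered.

## From alignments to distance matrices

`p_distance_matrix()` computes, per pair, the fraction of differing
comparable columns. A column is comparable when neither sequence has a gap
(`-`) or unknown residue (`X`) there — `X` is common in public-database
sequences and counts as missing, never as a mismatch. Two gap policies are
offered because reasonable pipelines differ here:

* `complete_deletion` (default): columns containing any gap or `X` are
  removed for everyone, so all pairs see the same columns — the
  conventional choice before a consensus phylogeny;
* `pairwise_deletion`: columns are dropped per pair, retaining more signal
  when gaps are scattered.

They agree exactly on gapless alignments. A pair left with zero comparable
columns is an error naming the pair, not a silent `NaN`.

Raw p-distances compress real divergence as substitutions stack up.
`poisson_correct()` applies the 20-state equal-rates correction
$d = -\tfrac{19}{20}\,\log(1 - \tfrac{20}{19}p)$, the exact inverse of the
substitution model the simulator uses, so simulated branch lengths are
recoverable in expectation. The correction diverges as $p \to 19/20$;
saturated entries are a hard error rather than an infinite distance,
because a tree built from them would be meaningless. Tree building defaults
to corrected distances; raw p-distances remain available
(`correction = "none"`) for comparability with tools that use percent
divergence directly.

## Tree inference and patristic extraction

`nj_tree()` is a from-scratch Saitou–Nei neighbor-joining implementation.
Two details that vary between implementations are pinned down for
reproducibility:

* ties in the Q-criterion minimum are broken by the smallest (row, column)
  index pair;
* a negative estimated branch length is clamped to zero and its deficit
  transferred to the sister branch, preserving the joined pair's path
  length — this matters because patristic sums feed the correlation.

NJ is exact on additive matrices; the test suite verifies topology recovery
(Robinson–Foulds distance 0, with `ape::nj()` as an independent
cross-check) and patristic round-trips to $10^{-9}$ on hundreds of random
trees. `patristic_matrix()` walks the tree as a weighted graph; tests
compare it against an independent depth/most-recent-common-ancestor oracle
and `stats::cophenetic()`.

Branch support comes from `bootstrap_trees()` (column resampling with
replacement, distances and NJ recomputed per replicate; default $B = 100$)
and `consensus_collapse()`, a majority-rule-*extended* consensus: observed
bipartitions are admitted greedily in order of decreasing frequency when
compatible with those already kept, then every internal edge supported by
fewer than `threshold_pct` percent of replicates (default 45) is
contracted. Supports annotate the remaining edges; branch lengths are
per-bipartition replicate means. The greedy order makes the result at a
higher threshold always a contraction of the result at a lower one — a
property the tests check directly.

## The synthetic data generator

No public benchmark exists for calibrated coevolving-family pairs, so the
package ships its own generator; it is first-class, tested code, and every
pipeline property above is demonstrated on its output.

**Species tree.** `simulate_species_tree()` draws a Yule pure-birth tree:
starting from two lineages, while $k$ lineages are alive the next split
arrives after an $\mathrm{Exp}(\lambda k)$ wait in a uniformly chosen
lineage, plus one final wait after the $N$-th lineage. Tree height then has
the closed form $\mathbb{E}[H] = \sum_{k=2}^{N} 1/(\lambda k)$, which the
tests verify by Monte Carlo. Organism labels are assigned to the leaves in
*random* order: assignment in lineage-creation order would leak topology
into the labels, so that two independently drawn trees over the same label
set would share structure and the permutation null would be miscalibrated.
This is a correctness requirement, not a cosmetic choice.

**Sequences.** `evolve_family()` uses the 20-state equal-rates (Poisson)
model: a uniform random root sequence, and along each branch of length $t$
each site substitutes with probability
$\tfrac{19}{20}(1 - e^{-20 t \rho / 19})$ to a uniformly chosen different
residue ($\rho$ is the per-family rate scalar). This is the exact
finite-time transition probability, so per-branch draws compose correctly
and empirical p-distances follow the closed form — checked at several
depths against 3-standard-error binomial bands. An amino-acid
exchangeability matrix (JTT and relatives) would be more realistic
biochemically but adds no testable structure here, and would cost the
closed-form distance inversion that makes the simulator a usable oracle.

**Pairing.** `make_family_pair()` produces the two study conditions:
*coevolving* (both families on the same species tree, with independent
lognormal rate scalars) and *independent* (each family on its own tree over
the same organism labels — the null). `distant_clade = TRUE` grafts a
shared long-branch clade (20% extra organisms, stem three times the tree
height) onto the tree(s), emulating the common practice of enlarging both
families with distant homologs; because the grafted divergences are large
and shared, they add correlated spread to both matrices and the correlation
does not decrease — a simulation observation the tests pin at fixed seeds,
not a theorem.

**Reference configuration and why.** Defaults: $N = 20$ organisms,
$\lambda = 10$, 200 columns, `rate_sigma` 0.3, no gaps. Twenty organisms
with 190 distance pairs is a typical yield for a bacterial protein family
after one-per-organism selection. $\lambda = 10$ gives a mean root-to-tip
depth near 0.26 substitutions/site — enough divergence to carry signal
while keeping even the deepest pairwise paths comfortably inside the
Poisson-correction domain. The lognormal rate scalars (sdlog 0.3) are the
realistic nuisance that makes correlation rather than equality the right
statistic. All stage seeds derive deterministically from one master seed
(`seed + 10007 * offset`, reduced into the 32-bit range), so a
configuration reproduces byte-identical output.

**What the generator does not emulate.** Indel processes (gaps are placed
independently at random cells, not evolved), alignment error, site-rate
heterogeneity, amino-acid exchangeability bias, horizontal transfer,
paralogy mistakes in representative selection, and — importantly — the
background similarity that a shared speciation history induces between
*any* two families of the same organisms. In real data that background
inflates r for non-interacting pairs; later mirrortree variants subtract a
species-tree signal, which is out of scope here. Passing the calibration
and power tests therefore shows the statistic and its null are implemented
correctly and behave as designed under the stated model; it does not show
that a significant r on real families proves physical interaction.

## Numerical and degenerate-input policy

* Distance matrices must be symmetric to $10^{-12}$, finite, non-negative,
  zero-diagonal; violations are input errors.
* Zero variance in either flattened distance vector (e.g. an invariant
  alignment) is a "degenerate statistic" error, distinct from input errors
  (the command-line tool exits 3 vs 2).
* Saturated p-distances ($p \ge 19/20$) fail loudly in `poisson_correct()`.
* Newick is written with 15 significant digits, enough to round-trip branch
  lengths to well below any tolerance used; internal NJ assembly carries 17.
* Coverage filtering is strictly greater-than: a hit at exactly the 0.60
  default is excluded. Representative selection per organism is highest
  bitscore, then highest coverage, then lexicographically smallest subject
  id — stated as a convention, since upstream servers do not document
  theirs.
* The lipobox scanner reports every overlapping `[VL]xxC` match whose
  cysteine falls in the first 40 residues (lipoprotein signal peptides are
  short; the window is a parameter), flags the exact 4-mer `LGCC` as
  canonical, and offers a stricter `[LVI][ASTG][GAS]C` alphabet behind
  `pattern = "extended"`.

## Design choices made where the design was open

* **Patristic, not raw, distances feed the correlation** — tree-derived
  sums are the defined quantity; raw corrected distance matrices can be
  correlated directly by passing them to `mirror_trees()`, which accepts
  matrices as well as trees.
* **NJ throughout, not maximum likelihood.** The mirrortree procedure is
  distance-based by construction; NJ is exact where the method's
  assumptions hold, orders of magnitude cheaper, and fully reproducible.
  ML/Bayesian search is deliberately out of scope.
* **Permutation null.** Analytic nulls for matrix correlations are
  unreliable because the $n$ pairs are not independent (each organism
  appears in $N - 1$ of them); the label permutation respects exactly that
  dependence.
* **Tabular surfaces where data are tabular.** Hit tables, motif hits and
  tidied results are tibbles and pipe well; trees and distance matrices
  stay `ape::phylo` objects and base matrices, the containers the field's
  tooling expects. `tidy()`, `glance()` and `autoplot()` bridge the fitted
  result into data-frame workflows.

## Validation problem sizes

The shipped test suite exercises, among others: 1000 random vector pairs
against a direct evaluation of the correlation formula ($10^{-12}$); 200
random additive matrices of 4–12 leaves for NJ exactness; 500
independent-mode pairs ($N=20$, 200 columns, $B=199$) whose p-values pass a
Kolmogorov–Smirnov uniformity check; 50 + 50 replicates for the
coevolving/independent power comparison; and 1000 random sequences against
a naive quadratic motif-scan oracle. These sizes were chosen to give the
properties real statistical teeth while keeping a full run comfortable on a
laptop.

## Known limitations

Beyond the generator's idealizations listed above: the pipeline consumes
alignments but does not produce them (alignment quality is the caller's
responsibility); no correction is made for shared speciation background, so
r values from real proteomes should be interpreted comparatively, not as
interaction probabilities; and the consensus tree reports support for the
retained bipartitions only — a collapsed polytomy is a statement of
uncertainty, not of hard multifurcation.
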