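---
title: "Likelihood models and design choices for gene-order phylogenetics"
author: "gophylo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Likelihood models and design choices for gene-order phylogenetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gophylo)
```

## The problem

A genome, for our purposes, is a set of chromosomes, each an ordered list of
signed gene (or synteny-block) identifiers; the sign is the strand. Genome
rearrangements — inversions, transpositions, translocations, fusions,
fissions, all expressible as double-cut-and-join (DCJ) operations — permute
that order without changing content, while deletions, insertions and
duplications change content as well. Given the gene orders of extant
species, we want the phylogeny that relates them and the gene orders of
their ancestors.

Working directly in permutation space is hard: a chromosome of $n$ distinct
genes is a single character with $2^n \cdot n!$ states, which defeats both
standard likelihood machinery and the bootstrap. `gophylo` instead follows
the binary-encoding route: decompose each genome into its local junctions.

## Encoding

An *adjacency* $(i,j)$ records that gene $i$ is immediately followed by gene
$j$; reading the reverse strand yields the same junction as $(-j,-i)$, so
the two are canonicalized to a single object (`canonical_adjacency`; the
representative is the ordered form whose first element is smallest under
$o < \dots < -2 < -1 < 1 < 2 < \dots$). A gene at a chromosome end is
adjacent to the extremity marker $o$ (a *telomere*); circular chromosomes
have no telomere and one wrap-around adjacency. Every canonical adjacency
or telomere seen in at least one input genome becomes one presence/absence
character, in first-observation order; one character per gene family
(distinct $|$id$|$, ascending) follows, so that deletions, insertions and
duplications also leave a signal. Column order is deterministic given the
input order, which keeps bootstrap resampling reproducible.

Copy numbers are deliberately collapsed to presence: with duplicated genes
the map from genomes to encodings is many-to-one (the test suite constructs
two distinct gene orders with identical encodings). This is the price of
the encoding; it buys resampleable, independent-ish characters.

## The transition model

Under a uniform DCJ on a genome with $n$ genes and $O(1)$ chromosomes, a
fixed present adjacency is destroyed with probability $2/(n+O(1))$ per
operation (the operation picks 2 of the $n+O(1)$ junction slots; no
rejoining recreates the cut pair), while a fixed absent adjacency — one of
up to $\binom{2n+2}{2}$ possible — is created with probability
$2/(2n^2+O(n))$. Loss is therefore about $2n$ times more likely than gain.
Rather than work per-event, `adjacency_model(n)` embeds the *ratio* in a
reversible two-state continuous-time chain,

$$q_{10} = 2n\, q_{01}, \qquad \pi_1 = \frac{1}{1+2n},$$

normalized so that one unit of branch length equals one expected change per
character at stationarity ($2\pi_0 q_{01} = 1$). Branch lengths then absorb
the event count. Both enumeration facts are kept as executable checks
(`dcj_break_probability`, exhaustive over all one-step outcomes, equals
$2/(n+1)$ on a single linear chromosome; `count_possible_adjacencies`
equals $\binom{2n+2}{2}$).

Design choices here, made where the method is genuinely open:

* **No rate heterogeneity across characters.** Nothing in the derivation
  distinguishes characters, and adding a gamma mixture would introduce a
  parameter the data barely constrain at these sizes.
* **Gene-family columns evolve under the same chain as adjacency columns.**
  A separate gain/loss ratio for gene content would be defensible but has
  no principled value; one model keeps the likelihood coherent.
* **The ratio is fixed, not estimated.** The $2n$ argument supplies it;
  estimating it from typical datasets (tens of taxa) is poorly conditioned.

## Likelihood, distances, tree search

`tree_log_likelihood` runs Felsenstein pruning over independent characters
with the stationary distribution as root prior; per-node, per-character
scaling guards against underflow, and the per-character likelihood is
floored at $10^{-300}$ so that a zero-length branch separating conflicting
states yields a very small finite value rather than $-\infty$ (the
optimizer needs finite comparisons). Because the chain is reversible and
the root prior stationary, the likelihood is invariant to root placement —
asserted by re-rooting in the tests, not assumed.

One numerical point deserves emphasis. With rates of order $n$, the
likelihood as a function of a branch length is sharply peaked near zero and
flat (at the stationary plateau) over most of any search interval; plain
Brent optimization routinely stalls on the plateau. Every 1-D maximization
(branch lengths, pairwise distances) therefore first brackets the maximum
on a geometric grid from $10^{-8}$ to the upper bound (24 points, plus
$t=0$) and only then refines with Brent between the flanking grid points
(tolerance $10^{-6}$ for branches, $10^{-8}$ for distances).

The search pipeline is classical:

1. **Pairwise ML distances** — the $t$ maximizing the two-sequence
   likelihood $\prod_c \pi_{x_c} P_{x_c y_c}(t)$, capped at 5 expected
   changes for saturated pairs.
2. **Neighbor joining** on that matrix (negative branch lengths clamped to
   zero) as the start tree.
3. **NNI hill climbing**: every internal edge yields two rearrangements;
   candidates are scored after re-optimizing the five branch lengths around
   the rearranged edge (one sweep), the best strictly improving candidate
   is accepted and fully re-optimized, and the search stops when no
   candidate improves the log-likelihood by more than $10^{-4}$. Ties are
   broken by the deterministic candidate enumeration order, so the whole
   search is reproducible from the input alone. NNI (rather than SPR/TBR)
   keeps the move set small; the validation study below shows it suffices
   in the regimes the package targets.

**Bootstrap.** Columns are resampled with replacement — adjacency,
telomere and gene-family characters jointly, as one alignment — the search
is re-run per replicate, and each internal edge of the point-estimate tree
is annotated with the percentage of replicates containing the same
bipartition (integer node labels in the Newick output). Supports are
reported on the ML tree; a majority-rule consensus of the replicates is
available via `consensus = TRUE`. The independence assumption behind
column resampling leans on the Dollo-like behavior of adjacencies — once
broken, a junction is unlikely to re-form in the enormous state space — and
the simulator quantifies this: under default settings the measured
re-formation fraction stays below 5%.

## Ancestral inference

Given the (rooted) tree, `marginal_posteriors` combines the downward
conditional likelihoods with upward partial likelihoods to give, per
internal node and character, the posterior probability of presence. An
unrooted input is rooted at the midpoint of its longest path first — the
likelihood does not care, but node identities need a declared root; users
wanting an outgroup root should supply an already-rooted tree.

`infer_gene_content` declares a family ancestral iff its posterior strictly
exceeds 50% (0.50 is absent, 0.51 present); candidate adjacencies (the
encoding's columns only — unseen junctions never become candidates) keep
their posteriors, and candidates touching an absent gene are dropped so the
assembly below stays well-formed.

`build_tsp` reduces assembly to a Travelling Salesperson instance:
vertices are the two extremities (tail/head) of each present gene plus $2L$
chromosome caps, where $L = \max(1, \mathrm{round}(\tfrac12\sum_\text{telomeres}
p))$ (round half up; e.g. telomere mass 3.7 gives two chromosomes). A
candidate adjacency with posterior $p$ costs $-\ln\max(p,\varepsilon)$, any
other extremity pair $-\ln\varepsilon$ (default $\varepsilon = 10^{-6}$),
cap–cap edges are free, and each gene's tail–head edge gets weight $-B$
with $B$ exceeding the sum of all other magnitudes, so every optimal tour
traverses every gene. `solve_tsp` is exact Held–Karp dynamic programming
(provably minimal, up to 18 vertices; implemented in C++ because the
$2^V$ table is not practical in interpreted code) or greedy
nearest-neighbor plus 2-opt (the 2-opt never considers removing a mandatory
edge: no such move can improve, and excluding them avoids precision loss
against the $-B$ magnitudes). `assemble_genome` cuts the tour at caps and
reads each path as one linear chromosome, gene signs following traversal
direction; since direction and cut point are arbitrary, the output is
normalized (majority-positive strand, chromosomes sorted by smallest gene
id) so identical assemblies serialize identically.

The $-\ln p$ edge weight makes the minimal tour the maximum-product
(maximum joint probability, under independence) consistent adjacency set;
$1-p$ would be an alternative but lacks that interpretation. Limitations,
accepted deliberately: ancestral chromosomes are linear only (the cap
construction cannot close circles), and duplicated families contribute a
single copy (presence encoding carries no copy counts).

## The simulator

`evolve_genomes` generates ground truth: the root genome is the identity
order $1..n$ split contiguously into the configured chromosomes, and along
every branch (preorder) a number of events is applied — a fixed count per
branch, a Poisson count with that mean, or Poisson(branch length × rate).
Event kinds are drawn from the configured distribution; DCJ operands are
chosen uniformly over the current adjacencies and telomeres (including
telomere pairs, matching the uniformity assumption the model rests on);
indel/duplication segment lengths are geometric ($p = 0.5$, so short
segments dominate, as in real indel spectra) capped at the chromosome;
inserted genes always receive fresh family ids so no spurious homology can
arise. Every event is logged with replayable operands, and replaying the
log reproduces every node genome exactly (a test).

Defaults: 100 gene families, one linear chromosome, 3 events per branch
with kind probabilities (DCJ 0.9, deletion/insertion/duplication 0.1/3
each). The validation study uses a *fixed* 3 events per branch rather than
Poisson(3): under a Poisson draw about 5% of branches carry zero events and
are unresolvable in principle, so a topology-recovery criterion would
measure the Poisson zero class rather than the method. What the simulator
does *not* emulate — rate variation across lineages, hotspots of breakage,
whole-genome duplication, unequal family sizes — bounds what passing tests
show: they certify the inference machinery under its own model assumptions,
not robustness to their violation on real genomes.

## Validation experiments and problem sizes

`recovery_experiment` (also driven by `scripts/acceptance.R`) runs, per
replicate: a uniform random 12-leaf tree (exponential branch lengths), 100
root genes, 3 events per branch with the default kind mix; ML tree
inference from the leaves alone, scored by Robinson–Foulds distance; and
ancestral reconstruction on the true topology (branch lengths re-estimated
by ML), scored as the fraction of the true ancestor's adjacencies present
in the assembled ancestor at nodes that are parents of leaves — the nodes
where reconstruction is meaningfully constrained. Twenty replicates keep
the study comfortably within a desktop budget while making a 90%
tree-recovery criterion statistically meaningful. The engine-level checks
(pruning vs exhaustive enumeration over internal states, posteriors vs
brute-force Bayes, Held–Karp vs full tour enumeration) run at sizes where
the oracles are exact and fast: 5-leaf trees × 50 characters, 4–6-leaf
trees, ≤ 8-vertex instances.

## Known limitations

* Orthology/copy assignment is out of scope: inputs are assumed to use
  consistent family ids, and duplicates are collapsed to presence.
* The model treats characters as independent; adjacent junctions sharing a
  gene are in truth negatively correlated. The bootstrap inherits this
  approximation.
* NNI-only search can in principle be trapped by distant optima on very
  conflicted data; bootstrap values flag such cases.
* Branch lengths are expected changes per character under the fixed-ratio
  chain, not event counts; they are comparable within an analysis, not
  across datasets with different $n$.
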