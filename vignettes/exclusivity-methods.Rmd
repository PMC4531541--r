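---
title: "Scoring and sampling mutually exclusive alteration sets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring and sampling mutually exclusive alteration sets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(mexsets)
```

## The problem

Tumors of the same cancer type carry different combinations of driver
alterations, but those drivers concentrate in a small number of pathways, and
one hit per pathway is usually enough. Across a cohort this leaves a
signature: alterations in the same pathway tend to be *mutually exclusive* —
few samples carry more than one of them. `mexsets` searches a binary
alteration matrix $A \in \{0,1\}^{m \times n}$ (rows: alterations, columns:
samples) for collections of alteration sets with surprisingly exclusive
alterations, with no pathway or network priors.

## The exclusivity score

For a set $M$ of $k$ alterations the samples are cross-classified into a
$2^k$ contingency table $X_M$: cell $x_v$ counts the samples whose altered
subset of $M$ is exactly $v$. The test statistic is the number of samples
with *exactly one* alteration,

$$T(X_M) = \sum_{j=1}^{k} x_{\{j\}},$$

and the null model holds the margins $x^+_{(j)}$ (the per-alteration sample
counts) fixed, placing each alteration's support uniformly. Under that null a
table has the multivariate hypergeometric probability

$$p_{X} = \frac{\prod_j x^+_{(j)}!\,(n-x^+_{(j)})!}{(n!)^{k-1}\prod_v x_v!},$$

and the score of $M$ is the mid P-value

$$\Phi(M) = \tfrac12\left(\Pr(T \ge T_{obs}) + \Pr(T > T_{obs})\right),$$

which mitigates the conservativeness of discrete exact tests. Conditioning on
the margins is the point of the design: a set dominated by one very frequent
alteration is much less surprising than a set of equally frequent exclusive
alterations with the same coverage, even though coverage-minus-overlap scores
(`dendrix_weight()`) cannot tell them apart. A collection
$\mathbf{M} = (M_1,\dots,M_t)$ scores $\Phi(\mathbf{M}) = \prod_i \Phi(M_i)$,
reflecting independence of exclusivity across sets under the null.

```{r}
# two alterations in 16 and 6 of 53 samples sharing exactly one:
X <- new_contingency_table(c(32, 15, 5, 1))
exact_phi(X)
```

## Computing the score

**Tail enumeration.** $\Pr(T \ge T_{obs})$ sums $p_Y$ over every table $Y$
with the observed margins and $T(Y) \ge T_{obs}$. A $2^k$ table has
$2^k - k - 1$ degrees of freedom once the margins are fixed, carried entirely
by the co-occurring cells ($|v| \ge 2$). The enumeration therefore iterates
over assignments to those cells only, bounded by (i) the remaining
co-occurrence budget $\sum_{|v| \ge 2} |v|\, y_v \le \sum_j x^+_{(j)} -
T_{obs}$ and (ii) the remaining margins; every feasible assignment completes
uniquely to a full table (singleton cells and the empty cell follow from the
margins). Tables at least as exclusive as the observed one are thus
enumerated without visiting the rest of the (exponentially larger) table
space, which is fast exactly where precision matters: strongly exclusive
tables with few co-occurrences. Cells are visited in decreasing $|v|$ so the
heaviest budget consumers are pruned first; the sum is order-invariant. The
core is compiled (`src/tail_enum.cpp`) with all probabilities assembled from
cached log-factorials, so large $n$ cannot overflow.

**Binomial approximation.** With $p_e = \sum_j x^+_{(j)}/n$ (capped at 1),
$\Pr(T \ge T_{obs}) \approx \Pr(\mathrm{Bin}(n, p_e) \ge T_{obs})$. The
approximation is good for sparse tables with many co-occurrences — which are
exactly the tables whose enumeration is largest — and conservative for
strongly exclusive tables with large margins, where $n p_e$ overshoots the
null mean of $T$.

**Permutation approximation.** `permutation_phi()` samples $L$ tables with
the observed margins uniformly (each row's support independently uniform —
only row margins are fixed under this null) and takes the empirical mid
value, floored at $1/(2L)$ so a score entering products and powers is never
zero. Only the per-sample alteration count matters for $T$, and counts cap at
2, so the sampler draws the three count-category occupancies by sequential
hypergeometrics, vectorized over all $L$ replicates.

**Hybrid dispatch (`phi()`).** The binomial value and the co-occurrence count
are computed first. If more than $\kappa$ samples carry co-occurring
alterations, or the binomial P-value already exceeds $\psi$, the binomial
value is kept. Otherwise tail enumeration runs with stopping threshold
$\varepsilon$; on completion the exact mid P-value is returned, and if the
accumulated tail passes $\varepsilon$ first, the permutation estimate with
$L = \lceil 1/\varepsilon \rceil$ samples replaces it.

Defaults, and why:

* $\kappa = 10$ co-occurring samples. Beyond this the enumeration budget
  grows combinatorially while the binomial error shrinks; the frozen test
  panel puts the binomial within a few $10^{-3}$ of exact there.
* $\psi = 0.9$. The $\psi$ branch exists to skip enumeration for tables the
  binomial itself already calls clearly non-exclusive. Because the binomial
  is *conservative* for exclusive tables with large margins (its tail sits
  near 0.5 for a perfectly exclusive set whose margins sum near $n$), a small
  $\psi$ would divert precisely the most interesting sets to the binomial and
  flatten the score; $\psi$ must sit above that saturation plateau. For the
  same reason the branch is disabled when $p_e \ge 1$, where the binomial
  tail is identically 1 and cannot discriminate.
* $\varepsilon = 0.01$, hence $L = 100$. Scores above 0.01 are never
  significant in this setting, so a Monte Carlo estimate with expected
  extreme-table count $\ge 1$ is sufficient there. For $k = 2$ the
  enumeration is at most $n + 1$ tables and always runs to completion, making
  pair scores deterministic.
* $k \ge 8$ always uses the binomial: the $2^k$ cell explosion makes exact
  mode impractical, and sets that large are rarely interpretable anyway.
  Single-alteration "sets" are rejected everywhere; the test is undefined
  for $k = 1$.

Per-set scores are memoized across an MCMC run keyed by the sorted alteration
tuple, since the sampler revisits sets constantly.

## Sampling collections

`mcmc_sample()` runs Metropolis–Hastings over collections of $t$ pairwise
disjoint $k$-sets with stationary distribution $\propto \Phi(\mathbf{M})^
{-\alpha}$. The proposal picks one slot uniformly and a replacement
alteration from outside the slot's set with probability proportional to its
frequency weight (margin $+\,1$); a replacement drawn from another set is
exchanged with the displaced alteration, so disjointness is preserved. The
frequency bias matters: exclusivity signal worth finding lives in recurrent
alterations, and a uniform proposal on a cohort with a long passenger tail
spends almost all its steps there — slowly assembling, and then being unable
to leave, incidental "exclusive" triples of one frequent gene and two rare
passengers that happen not to overlap it. The weighting is paired with the
exact Hastings correction (an exchange is reachable through either displaced
slot, so both routes enter the proposal ratio), leaving the stationary law
exactly $\Phi(\mathbf{M})^{-\alpha}$; the test suite validates this against
exhaustive enumeration of the target on a 6-alteration toy. The chain is
irreducible for $tk < m$. Defaults: $\alpha = 2$ (higher values concentrate
mass on the best collections; subtype-heavy analyses may use 3), burn-in 10%
of iterations, no thinning.

**Significance.** Sampled scores are calibrated against matrices permuted
with row and column sums fixed (degree-preserving checkerboard swaps;
`permute_matrix()`, default 100 attempted swaps per 1-entry). $\Phi^*$ is the
minimum collection score found by an identical search budget on each of $N$
permuted matrices; collections with $\Phi(\mathbf{M}) \le \Phi^*$ have
$P < 1/N$. The permuted-data searches track only their running minimum.

**Subtypes.** Alterations private to a cancer subtype are exclusive with
everything enriched in other subtypes, which fakes pathway structure. Given a
sample→subtype map, one indicator row per subtype is added, altered in every
sample *not* of that subtype; sets exclusive with that row are the ones
concentrated inside the subtype. Two subtype rows are never allowed in the
same set, and subtypes covering zero or all samples are rejected (their rows
are constant). The standard workflow is two runs — with and without subtype
rows — whose sampling frequencies are normalized and averaged before
summarization (`merge_runs()`).

## Summarization

The posterior over collections is summarized by the marginal probability
graph: $p(u,v)$ is the frequency-weighted fraction of significant sampled
collections placing $u$ and $v$ in the *same set* (same collection,
different sets contributes nothing — within-set pairs are what the score
certifies). Modules are the connected components of size ≥ 2 after deleting
edges below $\delta$; components rather than cliques so that overlapping
pathways joined by a cut vertex surface as one module. This decouples the
output from the $t$ and $k$ the chain ran with: a strong 3-set sampled under
$k=4$ shows up as a 3-clique with a rotating fourth vertex of low weight.

$\delta$ is user-supplied or chosen by `auto_delta()`: the midpoint of the
largest gap in the distinct edge weights at or above 0.05, a deterministic
stand-in for per-dataset manual tuning; posterior noise separates from
signal by a wide gap in well-mixed runs. Edges below $10^{-6}$ are never
materialized.

## The simulation benchmark

`simulate_dataset()` generates the implanted-pathway cohorts used for
validation: (1) implanted pathways, each covering $\lceil \gamma n \rceil$
distinct samples with *exactly one* pathway-gene alteration per covered
sample (uniformly chosen, or balanced so within-pathway gene frequencies
differ by at most one when `equal_freq`); (2) five highly altered confounder
genes (per-sample rate 0.3) that are frequent but not exclusive — the trap
that coverage-driven methods fall into; (3) passenger genes altered i.i.d.
at $q = 0.015$. The published designs fix $n = 500$ samples, a single
$k = 3$ pathway for individual-set benchmarks, and for collection benchmarks
$t$ pathways with equal within-pathway frequencies on a large background
with genes under 1% frequency removed; overlapping designs share exactly one
gene between consecutive pathways. The confounder and passenger rates are
this package's own calibration (the field's cohorts put recurrent drivers at
tens of percent and the passenger tail at a few percent); they are exposed
in `simulation_config()`.

What the generator does *not* emulate: correlated passenger rates across
samples (hypermutators), per-gene mutation-rate variation, copy-number
segment structure, or partial (leaky) exclusivity inside a pathway unless
`noise_on_pathway` is set. Passing recovery tests on these cohorts therefore
demonstrates the machinery — score, search, calibration, summarization —
not robustness to every artifact of real cohorts.

Evaluation uses the F-measure of recovered genes against the implanted
pathway, and for collections the adjusted Rand index between the module
partition and the implanted partition over the full gene universe, with one
background label for confounders and passengers (`module_ari()`). The
chance adjustment keeps the shared background block from inflating the
score: predicting nothing or only spurious modules scores near zero,
perfect recovery scores one.

## Problem sizes and numerical choices

The validation suite scales the published experiments to desk size, keeping
every design parameter of the cohorts themselves: single-pathway recovery
runs 5 replicates per coverage at $10^5$ iterations with $N = 3$
permutations ($m = 100$ genes); the overlapping-collection benchmark
($t = 3$, $k = 4$ pathways, $\gamma = (0.75, 0.75, 0.60)$, 1% filter) runs
on an $m = 500$-gene background at $5 \times 10^5$ iterations with
significance filtering off, relying on $\delta$-thresholding. Stationarity
is checked on a fully enumerable toy at $10^6$ iterations with thinning 10 —
thinning because the chi-square comparison assumes near-independent draws
and consecutive chain states are correlated. Degenerate inputs are handled
explicitly: empty posteriors yield empty module sets (with a warning), the
all-ones matrix is its own unique permutation, constant co-occurrence
indicators return $P = 1$ with a warning, and a frequency filter that would
empty the matrix is an error rather than an empty object.

## Limitations

* The score conditions on margins but still assumes samples are
  exchangeable; systematic per-sample mutation-load differences are only
  partly absorbed by the column-sum-preserving permutation null.
* The sampler is a single chain; multimodal posteriors (several unrelated
  strong collections at equal $t$, $k$) are summarized jointly by the graph
  but convergence diagnostics are the user's responsibility at foreign
  problem sizes.
* `auto_delta()` is a heuristic; published analyses hand-tuned $\delta$ per
  dataset, and borderline modules deserve a sweep (`summarize_posterior()`
  recomputes modules at any $\delta$ from a saved posterior).
* Exact scoring beyond $k = 7$ is refused by design.
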