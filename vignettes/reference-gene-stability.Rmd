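---
title: "Reference-gene stability and consensus ranking: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reference-gene stability and consensus ranking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(refstab)
```

## The measurement model

RT-qPCR reports a quantification cycle Cq per (assay, sample); with
amplification efficiency $E$ (fold amplification per cycle), relative
quantities follow $q_{gs} = E_g^{\,\min_{s'} \mathrm{Cq}_{gs'} -
\mathrm{Cq}_{gs}}$, which `cq_to_quantity()` implements. Relative
quantities are only defined up to a per-assay scale factor; we fix the
convention max-per-assay = 1 so quantities lie in $(0, 1]$. Every
statistic downstream is provably invariant to this choice (constants
cancel in log-ratios), and the test suite checks that invariance to
$10^{-12}$.

Efficiency is rarely reported alongside published stability screens; the
default is $E = 2$ (ideal doubling) for every assay, overridable per
assay. Technical replicates are averaged on the Cq (cycle) scale before
transformation, matching common qPCR analysis frameworks. Incomplete
matrices are refused rather than imputed: the pairwise statistic below
has no defined missing-data behaviour, and silent imputation would be
invisible in the reports.

## The stability statistic family

For genes $j, k$ the **pairwise variation** is the sample
($n-1$ denominator) standard deviation over samples of
$\log_2(q_{js}/q_{ks})$. The **M-value** of gene $j$ within a candidate
panel is the mean of its pairwise variations with every partner. Base 2
is the field convention (fold-change doublings); the statistic is
base-invariant up to a constant, but the printed 0.5 acceptability
threshold and 0.15 V-cutoff assume base 2, so the base is fixed.

**Stepwise exclusion** repeatedly removes the highest-M gene
(recomputing M within the shrinking panel) to produce a ranking from
least to most stable. Two conventions deliberately coexist:

* the *reported* `m_values` are full-panel M-values — the form in which
  multi-experiment screens are published and the weights used for
  aggregation;
* the *ranking* uses the stepwise-recomputed values, which is how the
  optimal-subset curves are constructed.

The two surviving genes cannot be distinguished by the statistic — only
their mutual ratio dispersion remains, which is symmetric — so results
carry `final_pair_tied = TRUE` and the final pair is ordered by
full-panel M. Ties at an exclusion step drop the assay later in input
order; all tie-breaks in the package are deterministic and documented,
because reproducibility of a ranking pipeline matters more than any
particular tie convention.

The **normalization factor** NF$_n$ is the per-sample geometric mean of
the $n$ most stable genes' quantities, and $V_{n,n+1} =
\mathrm{sd}_s\,\log_2(\mathrm{NF}_n/\mathrm{NF}_{n+1})$ measures what the
$(n{+}1)$-th gene still changes. The smallest $n$ with $V < 0.15$ (the
published cutoff, the `cutoff` argument) is the recommended panel size;
if no $V$ passes, all genes are recommended.

## Consensus ranking across experiments

Each experiment contributes a ranked list (ascending M) with its
M-values as importance weights. Weights are min–max normalized to
$[0,1]$ *per list* before aggregation: M magnitudes differ ~20-fold
between low- and high-noise experiments, and without normalization the
noisiest experiments would dominate the objective. An all-equal weight
vector normalizes to all zeros — such a list genuinely carries no
preference information.

The distance between a candidate order and a list is the **weighted
Spearman footrule**: with $W(r)$ the normalized weight at position $r$
of the list, $d = \sum_t |W(\mathrm{rank}_\mathrm{list}(t)) -
W(\mathrm{rank}_\mathrm{cand}(t))|$. Only the position-weight profile
matters, so displacing a gene between positions of similar weight is
cheap. The classic unweighted footrule ($\sum_t |\Delta\mathrm{rank}(t)|$) is
exposed via `weighted = FALSE` for comparison; the weighted form is what
published aggregation of M-value lists uses and is the only objective
the optimizers minimize.

Three optimizers minimize the summed distance:

* **Borda count** — ascending mean rank, ties by assay id. Fast,
  deterministic, weight-blind.
* **Brute force** — exhaustive enumeration up to 8 assays; the oracle
  the stochastic route is validated against.
* **Cross-entropy Monte Carlo** — a $k \times k$ position-probability
  matrix, uniform at start, is sampled (sequentially per position,
  without replacement), the elite fraction $\rho$ of samples re-estimates
  it, smoothed by $P \leftarrow wP_\mathrm{new} + (1-w)P$. Defaults:
  $10k^2$ samples/iteration, $\rho = 0.1$, $w = 0.25$, patience 5,
  published defaults of the framework this follows.

Two safeguards make the stochastic route dependable. First, the
best-ever sampled candidate is polished by a deterministic hill climb
over the swap and single-item-insertion neighborhood. The footrule
objective is separable by (item, position) — it is an assignment-type
objective — so local moves are cheap to evaluate via a precomputed cost
matrix; without the polish, the probability matrix can collapse
prematurely onto a local optimum on 11-item instances (patience 5 is
aggressive). Second, the returned consensus is the better of the
polished CE candidate and the Borda baseline, so `ce_aggregate()` never
underperforms the deterministic method. Results record seed, objective
and the per-iteration best-objective trace; identical seeds give
identical output.

On the packaged 19-experiment table the cross-entropy route reaches
objective 46.96 with the Alu-repeat assay first — which the acceptance
suite verifies, along with agreement between CE and brute force on
subsetted instances.

## The packaged screen

`load_table1_fixture()` returns the published 19-experiment × 11-assay
M-value table exactly as printed (checksummed on load), with the
experiment descriptions attached. The raw Cq data behind it were never
deposited, so per-experiment M-values are an *input* here, not something
the package can recompute; what the package reproduces is everything
computed *from* them: ranked lists, weights, consensus, and the mean-M
summary (Alu-Sq: 0.353, below the 0.5 bound). Ties within a printed row
(values are rounded to 2 decimals) are broken by printed column order —
the publication does not state its tie policy, so we chose the
deterministic option closest to the printed layout.

## The synthetic world

`simulate_qpcr()` draws
$$x_{gs} = \mu_g \cdot 2^{c_s} \cdot 2^{\delta_g \mathbf{1}[s\ \mathrm{treated}]} \cdot 2^{\varepsilon_{gs}},
\qquad c_s \sim N(0, \sigma_\mathrm{content}^2),\quad
\varepsilon_{gs} \sim N(0, \sigma_g^2),$$

i.e. log-normal multiplicative noise: $\sigma_g$ is gene $g$'s intrinsic
stability noise (log2 units), $c_s$ a sample-wide mRNA-content factor
shared by all genes, and $\delta_g$ an optional fixed log2 treatment
shift on a designated sample subset — the simplest structure that
reproduces the destabilization of assumed reference genes under
perturbation. Defaults emulate one experiment of a large perturbation
screen: 11 assays × 22 samples (a 418-sample screen spread over 19
experiments), $\sigma_g$ spanning 0.1–0.5 log2 units (yielding M-values
in the published range), $\sigma_\mathrm{content} = 0.5$, half the
samples treated. Cq offsets place simulated cycles in a realistic 15–35
window; they do not affect any statistic.

Under this model the expected M has the closed form
$\mathbb{E}[M_j] \approx \mathrm{mean}_{k \ne j}\sqrt{\sigma_j^2 +
\sigma_k^2}$ (`expected_m()`), which the tests verify empirically to
within 5 % at $n = 1000$ samples. Standard normals are drawn explicitly
and scaled (never `rnorm(n, sd = 0)`, which consumes no RNG draws) so
that paired runs differing only in one SD share all other noise — this
is what makes the shared-content-cancellation test exact to $10^{-12}$.

`simulate_experiment_suite()` jitters each experiment's $\sigma$ vector
multiplicatively ($\sigma \cdot 2^{N(0, h^2)}$), giving related-but-
disagreeing experiments, the situation consensus ranking exists for.

What the generator does **not** emulate: amplification-curve artifacts,
efficiency variation between wells, co-regulation between candidate
genes, heavy-tailed outliers, or the Alu-repeat copy-number mechanism
itself. A green recovery test therefore establishes that the pipeline
recovers a *known log-normal* stability structure — not that any
particular biological assay is stable.

One interpretation choice in the recovery tests: "recovering the most
stable gene" is asserted as membership in the final indistinguishable
pair, not as exact last position. The statistic provably cannot order
the final two genes, and empirically exact-position recovery saturates
near 90 % however widely the $\sigma$ values are separated, while pair
membership is recovered essentially always.

## Numerical choices and limitations

* Sample ($n-1$) standard deviations throughout; matters at small $n$.
* Comparisons of objectives use an absolute $10^{-12}$ tolerance;
  report serialization uses 6 significant digits.
* Degenerate inputs are defined, not errors: exactly proportional
  assays give $M = 0$ and all-zero V-curves with a recommended panel of
  2; all-equal aggregation weights contribute zero distance.
* Minimum sizes are enforced (2 samples for a ratio SD, 3 assays for
  stepwise exclusion) rather than returning vacuous values.
* No confidence intervals on M are provided, and no alternative
  stability models (ANOVA-based or correlation-based) — deliberately
  out of scope.
* Rank aggregation handles full lists only (no top-$k$ partial lists)
  and a single distance family (weighted/unweighted footrule).
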