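---
title: "Gene behaviors-based network enrichment analysis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene behaviors-based network enrichment analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gbnea)
```

# The problem

A phenotype-specific gene network — a directed, weighted graph estimated from
the expression profiles of one group of samples — is hard to interpret on its
own. **gbnea** asks a sharper question: *which functional pathways are
over-represented among the genes whose network behavior differs most between
two phenotypes?* Instead of ranking genes by differential expression (as
classical gene-set enrichment analysis does), it ranks them by how much their
*role in the network* changes — their regulatory output, the sign and
magnitude of their outgoing edges, and the identity of their neighbors — and
then tests pathway membership against that ranking.

# The model

## Phenotype-specific networks

For each phenotype separately, every gene $\ell$ is regressed on all other
genes:

$$y_{i\ell} = \beta_\ell^{\top} x_i + \varepsilon_{i\ell},$$

with the elastic-net objective

$$\hat\beta_\ell = \arg\min_{\beta}\;
  \tfrac12\sum_i (y_{i\ell} - \beta^\top x_i)^2
  + \lambda \sum_j \Big[\tfrac{1-\delta}{2}\beta_j^2 + \delta|\beta_j|\Big],$$

so a nonzero $\hat\beta_{\ell j}$ is a directed edge $j \to \ell$ with weight
$\hat\beta_{\ell j}$. With $\delta = 1$ (the default) this is the lasso. The
regularization $\lambda$ is chosen per target by minimizing

$$\mathrm{BIC} = \frac{\lVert y_\ell - \hat y_\ell\rVert^2}{n\,\sigma^2}
  + \frac{\log n}{n}\,\widehat{df},$$

where $\widehat{df}$ is the number of nonzero coefficients (the standard
lasso degrees-of-freedom estimator).

Choices the objective leaves open, and what this package does:

* **$\sigma^2$ plug-in.** The residual variance $RSS/(n - \widehat{df})$ of
  the least-penalized model on the grid. When that fit is saturated
  ($n - \widehat{df} < 2$) or numerically zero, the sample variance of the
  target is used instead — otherwise a near-interpolating unpenalized fit
  would drive $\sigma^2 \to 0$ and the BIC scale would collapse.
* **Standardization.** Penalization is scale-sensitive. By default regulators
  are standardized to unit variance and the target is centered before
  fitting; coefficients are reported back on the original scale. Set
  `standardize = FALSE` in `regression_config()` to fit the raw objective.
* **$\lambda$ grid.** The relative grid $(0.001, 0.01, 0.1, 0.5, 1)$ is
  scaled per target by $\max_j |X^\top y|$ — the exact value at which the
  lasso solution becomes identically zero — so the grid spans "almost
  unpenalized" to "empty model" on any data scale. $\lambda = 0$ (ordinary
  least squares) joins the grid only when the number of usable regulators is
  below the sample count. Ties in BIC go to the larger $\lambda$ (the
  sparser model).
* **Degenerate inputs.** Zero-variance regulators are excluded and can never
  receive an edge; a constant target yields no edges. A target whose
  coordinate descent fails to converge is retried at a relaxed tolerance and,
  failing that, set to the all-zero solution with a warning — one bad target
  must not abort a large network.

The solver is a covariance-updating coordinate descent on the Gram matrix
$X^\top X$, computed once per phenotype and shared by all targets (and all
permutations touch only their own Gram matrices). Convergence is declared
when the largest variance-weighted squared coefficient change in a sweep
falls below `tol` $\times\, y^\top y$ (default `tol = 1e-5`; tighten to
`1e-12` or beyond when exact coefficients matter more than speed — the
package's own exactness tests do).

## Per-gene behavior statistics

With networks $\hat\beta^C$, $\hat\beta^N$ and per-phenotype mean expression
$\bar x^C_j$, $\bar x^N_j$:

* **Regulatory effect**: $r_j = \sum_\ell |\hat\beta_{\ell j}\,\bar x_j|$ —
  total outgoing influence of gene $j$, computed per phenotype.
* **Effect difference**: $d^{(1)}_j = r^C_j - r^N_j$ (signed).
* **Signed-profile discrepancy**:
  $d^{(2)}_j = \sum_\ell (\hat\beta^C_{\ell j}\bar x^C_j -
  \hat\beta^N_{\ell j}\bar x^N_j)^2$, which also sees sign flips that leave
  $r_j$ unchanged; absent coefficients count as zero.
* **Jaccard neighborhood distance**:
  $d^{JI}_j = 1 - |N^C_j \cap N^N_j| / |N^C_j \cup N^N_j|$, where $N_j$ is
  the set of genes *directly connected* to $j$. "Directly connected" is read
  direction-agnostically (regulators and targets of $j$): restricting to
  out-edges would make the distance degenerate for genes that are pure
  targets. A gene isolated in both networks gets $d^{JI}_j = 0$ — no wiring,
  no phenotype-specific wiring.
* **Weighted statistics**: $Wd^{(t)}_j = d^{JI}_j \cdot d^{(t)}_j$. These are
  the method variants: `d1`/`d2` (GbNEA1R/GbNEA2R) and the Jaccard-weighted
  `Wd1`/`Wd2` (GbNEA1RJ/GbNEA2RJ, the recommended default `Wd1`).

Any stored nonzero coefficient counts as an edge; no extra magnitude
threshold is applied — the lasso already performed selection, and a second
threshold would be an undocumented parameter.

## Enrichment score

Genes are ranked by the chosen signed statistic in descending order (ties
broken lexicographically by identifier, for cross-platform determinism).
Walking down the ranking, a running sum gains
$|Wd_{(j)}|^k / \sum_{g\in V_T}|Wd_g|^k$ at each pathway member ("hit") and
loses $1/(|V| - |V_T|)$ at each non-member ("miss"). The enrichment score
$ES$ is the running-sum value of maximal absolute deviation from zero,
keeping its sign; when the positive and negative extremes tie to within
accumulation error ($10^{-12}$), the positive one is taken. With $k = 0$
this is exactly the classical unweighted two-sample Kolmogorov–Smirnov
statistic (the package's tests verify this against an independent
brute-force oracle); with $k = 1$ hits are weighted by their normalized
statistic. No automatic selection of $k$ is attempted — it is a user
parameter, default 0, matching the unweighted form used in benchmarking.
Pathway genes absent from the network universe are dropped for that test
(the miss denominator is only coherent for the in-universe subset); the
effective size is reported as `n_hits`, and a pathway with no overlap at all
is excluded with a notice.

## Permutation significance

The null is built by reassigning the phenotype labels (preserving group
sizes), re-estimating **both networks from scratch**, and recomputing every
pathway's score — no shortcut nulls (such as gene-label shuffling) are
offered, since the statistic's null distribution depends on the whole
network-estimation pipeline. Observed and permuted scores are normalized
per pathway by dividing positive scores by the mean positive permuted score
and negative scores by the absolute mean negative permuted score, giving
`nES` values comparable across pathways and signs.

**The p-value rule.** Three variants are computed and reported:

* `p_value` (primary): the two-sided magnitude test with add-one smoothing,
  $p = \big(1 + \#\{\pi : |nES_\pi| \ge |nES|\}\big) / (\Pi + 1)$. This is a
  valid permutation p-value at any $\Pi$ (the add-one form), it detects
  enrichment at either end of the ranking, and the magnitude comparison
  across signs is exactly what the nES normalization exists to license.
* `p_gsea`: the sign-matched one-tail count divided by the number of
  same-sign permutations — the classical GSEA convention. At small $\Pi$
  its discreteness makes it slightly anti-conservative (with $\Pi = 50$ and
  ~25 same-sign permutations, the smallest nonzero p is 0.04, so the
  realized level at $\alpha = 0.05$ is ~0.08).
* `p_literal`: the literal sign-matched count divided by $\Pi$. It can reach
  exactly 0 and understates p by roughly the fraction of opposite-sign
  permutations (about a factor of two); it is reported for comparability
  with analyses that print zero p-values.

The primary rule was fixed before any calibration experiment was run; the
package's acceptance checks then verify empirically that its realized
type-I error at $\alpha = 0.05$ sits inside the binomial 95% band on null
data. If a pathway has no same-sign permuted score at all, its `nES` is
undefined and the resolution floor $1/(\Pi+1)$ is reported with a warning.
Benjamini–Hochberg correction (`fdr_q`) is applied across the pathways
tested within one run — that is the family of hypotheses of one phenotype
comparison.

All permutation sub-seeds are derived up front from the single top-level
seed, so results are bit-identical for any `n_workers` and across repeated
runs. A failed permutation is redrawn once with a reserved sub-seed; more
than 10% failures aborts the analysis.

# The synthetic benchmark generator

`simulation_scenario()` describes a linear structural-equation world: a gene
universe in which a designated pathway subset carries phenotype-specific
directed structure (a chain — or a random DAG — of coefficients of magnitude
`effect_size` present in phenotype C and absent or rewired in N) on top of a
background of edges shared by both phenotypes (`background_density` among
non-pathway pairs, moderate random weights). Root genes are standard normal;
every downstream gene is its parents' weighted sum plus Gaussian noise
(`noise_sd`), sampled in topological order. Edges always point from lower to
higher gene index, so structures are acyclic by construction.

Scenario defaults mirror a full-scale two-phenotype cell-line study — 500
genes, an 87-gene pathway, 85 vs 103 samples, 200 permutations, 50
iterations per arm, and a true-negative universe containing 5% of the
pathway's genes — and every size scales down freely. The default
`effect_size = 1` with `noise_sd = 0.2` places the planted signal in the
strong-recovery regime (effect five times the residual noise); these were
chosen once as the generator's study conditions, not tuned to any test
outcome.

`run_simulation_study()` pairs each true-positive iteration (planted
structure, full pathway in the universe) with a true-negative iteration
(no phenotype effect; only `pathway_fraction_in_negative` of the pathway's
members are present in the tested universe, mirroring a network built
off-pathway) and aggregates Accuracy, Precision, Recall, F1 and the
true-negative rate from the confusion counts. When no pathway is ever
called, Precision is undefined and printed as "–".

**What the generator does and does not emulate.** It reproduces the
*structural* premise of the method — phenotype-specific wiring localized to
a pathway against a shared background — under an exactly known truth, which
is what makes recall/specificity benchmarking and null-calibration checks
possible without external data. It does not emulate real expression data:
no heavy tails, no library-size or batch effects, no feedback loops (the
truth is a DAG), no correlated measurement noise, and pathway wiring in real
tissue is denser and weaker than a clean chain. Passing the benchmark
therefore demonstrates correctness of the machinery and sane operating
characteristics in a favorable regime, not performance guarantees on any
particular real dataset.

# Problem sizes used by the packaged checks

The package's own acceptance checks run, among smaller exact checks: a
null-calibration experiment (60 genes, 30 samples per group, 50
permutations, 100 replicates, rejection rate at $\alpha = 0.05$ compared
with the binomial 95% band) and a planted-recovery benchmark (100 genes,
20-gene pathway, 100 samples per group, 50 permutations, 20 iterations per
arm, requiring recall and true-negative rate of at least 0.9 for the
Jaccard-weighted variant). These sizes were chosen as the smallest designs
at which the two properties are statistically meaningful.

# Known limitations

* Per-target regression scales as $O(p^2)$ per coordinate-descent sweep
  after the one-off Gram computation; the permutation null multiplies the
  whole network estimation by $\Pi$. Very large universes call for fewer
  permutations or parallel workers.
* The method inherits everything the network estimator gets wrong: lasso
  networks on correlated genes pick representatives, not complete truth,
  and edge direction is regression convention, not causal proof.
* `d2`-based variants square weighted coefficient differences and can be
  dominated by a single large edge; the benchmark machinery exists precisely
  to compare variants on planted truth.
* Permutation p-values have resolution limited by $\Pi$; with the default
  add-one rule the smallest attainable p is $1/(\Pi+1)$.
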