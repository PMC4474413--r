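---
title: "Statistical dichotomization of gene signatures into novel and common biomarkers"
author: "SigConsensus"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical dichotomization of gene signatures into novel and common biomarkers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SigConsensus)
```

## The problem and the model

Independently derived gene signatures for the same disease rarely agree
gene for gene. The naive reading — any gene absent from all previously
published signatures is "novel" — ignores the number of reference
signatures consulted and their sizes: a gene missing from three small
signatures and a gene missing from seventy large ones are not equally
surprising. SigConsensus replaces the absolute rule with a sampling model.

Fix a biomarker space $D$ (the universe of admissible symbols: all RefGene
symbols, or the genes assayed on a platform), a tested signature $AS_0$
with $n_0$ genes, and $M$ reference signatures $AS_1,\dots,AS_M$, all
restricted to $D$. For each tested gene, its **co-occurrence count** is the
number of distinct reference signatures containing it. The empirical
frequency distribution (EFD) is

$$F_m = O_m / n_0, \qquad m = 0, 1, \dots, M,$$

where $O_m$ is the number of tested genes with count exactly $m$. The
$m = 0$ level (genes in no reference) is part of the distribution, so
$\sum_m O_m = n_0$ exactly; a formulation that starts the sum at $m = 1$
cannot account for the typically large fraction of never-co-occurring
genes, and this package deliberately includes $m = 0$ throughout.

The null asks how much co-occurrence random signatures would produce. In
each of $N$ simulations, $M$ random sets of the matched sizes are drawn
uniformly without replacement from $D$; the match counts against the
tested set are histogrammed ($RO_{j,m}$) and averaged:

$$EF_m = \frac{\sum_{j=1}^N RO_{j,m}}{N \, n_0}.$$

**Independence reading.** Within one simulation, each random set is
internally without replacement (no duplicate symbols inside a set), but
the $M$ sets are drawn independently of one another, so a gene may land
in several random sets at once. The alternative reading — sets mutually
exclusive within a simulation — would make overlap counts above 1
impossible and contradicts the overlap-segment picture the method is
built on. The package adopts independence everywhere, including in the
analytic oracle below.

**Exact oracle.** Under this scheme a fixed tested gene falls in random
set $i$ with probability $p_i = |AS_i| / |D|$, independently across sets,
so its count is Poisson-binomial; by linearity $EF_m$ equals that
probability mass function exactly. `analyticNull()` computes it with the
standard $O(M^2)$ convolution recursion and serves as the independent
check on the Monte-Carlo path (`simulateNull()`); the two are never
collapsed into one code path.

## Comparison, threshold, labels

Both distributions are summarized by their reverse cumulative curves
$R(r) = \sum_{m \ge r} f_m$. Two statistics drive the dichotomization:

* $p_1$: a Kolmogorov–Smirnov comparison. The statistic is the sup
  distance $\max_r |R_F(r) - R_{EF}(r)|$; the p-value uses the asymptotic
  two-sample Kolmogorov formula with effective sizes $n_0$ and
  $N n_0$ (the analytic null is treated as an infinite second sample).
  On a discrete, heavily tied support this classical p-value is
  conservative, so it is always reported with an "approximate (discrete
  data)" note; it gates nothing downstream.
* $p_2(r) = \min(1, R_{EF}(r) / R_F(r))$ for each candidate threshold
  $r \ge 1$: the expected-to-actual tail-mass ratio. It is computed on
  unrounded frequencies (rounding happens only in rendered reports), is
  `NA` when no tested gene reaches level $r$ (never a silent zero), and
  is 0 when the null tail is empty but the observed tail is not.

The chosen threshold $r^\ast$ is the smallest $r$ with defined
$p_2(r) \le \alpha$ (default $\alpha = 0.05$); if none qualifies,
$r^\ast$ is `NA`, every gene is labelled SN, and a warning is emitted. A
user-forced threshold bypasses the search (useful for reproducing a
published cut-off such as a minimum of four reference signatures).

**Tail convention.** A gene is **statistically common (SC)** when its
count is *at least* $r^\ast$, **statistically novel (SN)** otherwise. The
inclusive convention matches the "minimum threshold of $r^\ast$" usage in
the worked examples shipped with the package (count-4 genes are SC at a
minimum threshold of four); the exclusive reading ("more than $r$ times")
would shift every label boundary by one and is not used.

Per-level enrichment ratios $F_m / EF_m$ accompany the labels; where
$EF_m = 0$ the ratio is reported "Not applicable" rather than infinite.
Note that enrichment ratios recomputed from *rounded, printed* expected
columns can disagree in the second significant digit with values computed
from unrounded simulation output; the package always computes on
unrounded internals.

## Tunable parameters

| parameter | default | meaning and rationale |
|---|---|---|
| `N` | 100 | simulations for the null; 100 resolves the structure and shape of the BFD, while 1000–10000 sharpen far-tail estimates at linear cost |
| `seed` | 1 | master seed; per-simulation sub-seeds are derived from it, so growing `N` extends, never rewrites, earlier simulations |
| `alpha` | 0.05 | tail-ratio significance for the threshold search |
| `forcedR` | `NA` | user-imposed $r^\ast$, bypassing the search |
| `keepSims` | `N <= 1000` | retain the $N \times (M{+}1)$ per-simulation histogram matrix (exact standard errors, reproducibility checks) at $O(NM)$ memory |
| `precision` | 2 | decimal places in rendered percentage tables; internal state is never rounded |

The choice of background is itself a modelling decision: restricting $D$
(e.g. to one platform's genes) shifts the whole null rightward, which
`backgroundFamily()` makes visible across $|D| \in \{20000, 10000, 5000,
1000, 500\}$-style families.

## Curve fits to null families

The fitted quantity is the **reverse cumulative** of the null — monotone
and visually comparable across background sizes — not the mass function.
Two three-parameter forms are offered: Weibull tail
$a\,e^{-(m/\lambda)^k}$ and sigmoid $a / (1 + e^{(m - x_0)/s})$. Fitting
is bounded nonlinear least squares (Levenberg–Marquardt, `minpack.lm`),
deterministic given the data, from fixed documented starts: $a = R(0)$,
$\lambda = $ mean match count $+\,0.5$, $k = 1$; $x_0 = $ median support,
$s = 1$. Bounds keep $\lambda, k, s > 0$ and $a \in (0, 1]$ (Weibull).
A null whose reverse cumulative has fewer than three points strictly
inside $(0, 1)$ — e.g. essentially all mass at $m = 0$ — cannot constrain
three parameters and is flagged `wellConstrained = FALSE` rather than
rejected. Fits are ranked by sum of squared residuals with alphabetical
tie-breaks; no formal model selection (AIC/BIC) is attempted.

## The synthetic generator

`syntheticScenario()` emulates the simulated study design used throughout:
a background of 20,000 pseudo-symbols, a 100-gene tested signature, and
ten references of sizes $20, 40, \dots, 200$ — these defaults reproduce
the reference simulation setting, and smaller backgrounds (down to 500)
reproduce the restricted-space families. On top of that,
`makePlantedTgss()` plants verifiable structure: `nCommon` genes inserted
(by appending, so reference sizes grow by at most `nCommon` and all other
members are kept) into `plantDepth` distinct references, and `nNovel`
genes guaranteed absent from every reference. Truth labels cover the
planted genes only: filler genes acquire stochastic counts and have no
planted class, and with `plantDepth = 0` there is no SC guarantee at all.
Null simulations downstream always use the post-augmentation sizes.

What the generator does **not** emulate: realistic gene-symbol
vocabularies, correlated pathway co-membership among references (real
signatures share biology, not just sampling), size-quality correlations,
or curation noise. Passing the planted-recovery tests therefore
demonstrates the statistical machinery, not robustness to the
correlation structure of real literature collections.

## Numerical choices and degenerate inputs

* Symbol normalization is trim-and-uppercase only; alias/accession
  mapping is out of scope and assumed done upstream.
* Duplicate symbols within a set count once (co-occurrence is set
  membership); a reference sharing the tested signature's id is excluded
  from counting (self-exclusion by id, not by content).
* Reference sets left empty after background restriction are skipped with
  a logged notice, not an error; an empty tested signature is an error.
* $p_2$ is clipped at 1; `NA` propagates explicitly.
* Monte-Carlo reproducibility is bit-exact given (seed, N, sizes, |D|),
  and the per-simulation matrix satisfies
  $EF_m = \sum_j RO_{j,m} / (N n_0)$ exactly.
* Rendered tables round at render time only.

## Problem sizes used in the shipped tests

The test suite exercises Monte-Carlo-versus-oracle agreement on
randomized configurations with $M \le 10$, $|D| \le 5000$ and $N = 1000$,
using an exact-binomial band equivalent to $\pm 4$ standard errors
(the discrete tail quantile at the same two-sided level, which avoids
spurious failures on bins whose expected hit count is below one);
planted-signal recovery runs ten seeds at $|D| = 5000$, $M = 10$,
$N = 100$. These sizes were chosen as representative desk-scale versions
of the reference simulation setting.

## Known limitations

* $p_1$ is approximate on discrete supports; a permutation-based
  alternative would be exact but is not implemented.
* The $p_2$ ratio is a descriptive tail comparison, not a calibrated
  hypothesis test; no multiple-testing correction across genes is
  applied.
* The null treats references as independent uniform draws; real
  signature collections are correlated, so SC calls are anti-conservative
  in the presence of heavily overlapping (e.g. derivative) references.
* Results are conditional on the chosen background and reference
  collection; both are user decisions the package records but cannot
  validate.
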