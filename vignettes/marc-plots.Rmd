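---
title: "Meta-analytic rain cloud plots: model, design and simulation choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Meta-analytic rain cloud plots: model, design and simulation choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(marcplot)
library(dplyr)
```

## The problem

Meta-analyses are read not only by meta-analysts but by practitioners and
decision-makers who have never seen a forest plot. The conventional forest
plot double-books the x axis (effect magnitude *and* confidence-interval
width), gives the widest — least precise — intervals the most ink, and
leaves the y axis as an arbitrary study ordering. The Meta-Analytic Rain
Cloud (MARC) plot re-encodes the same data so that the visual hierarchy
matches meta-analytic reasoning: effect size on the x axis, **relative
inverse-variance weight** on the y axis *and* as dot area, and the pooled
effect drawn as a "cloud" of dots spread over its confidence interval — a
frequency-format uncertainty display, which audiences reason about better
than an error bar.

This package computes the underlying quantities (weights, fixed-effects
pooling, cluster-randomized-trial SMD variances), resolves complete plot
layouts as tables of numbers, renders them statically or as self-contained
interactive HTML, simulates realistic meta-analytic datasets, and
reproduces the machinery of a confounded-factorial survey experiment for
evaluating such visualizations.

## Meta-analytic model

All computation assumes a fixed-effects (common-effect) model. For studies
$j = 1, \dots, k$ with standardized mean differences $d_j$ and standard
errors $se_j$:

$$w_j = \frac{1}{se_j^2}, \qquad
  \hat\delta = \frac{\sum_j w_j d_j}{\sum_j w_j}, \qquad
  se(\hat\delta) = \Big(\sum_j w_j\Big)^{-1/2},$$

with a normal (Wald) confidence interval at a configurable `level`
(default 0.95, the forest-plot convention). Relative weights
$w_j / \sum w_j$ sum to one and are the quantity MARC plots encode.
Random-effects pooling, heterogeneity statistics and publication-bias
diagnostics are deliberately out of scope; `pool_fixed()` takes a `method`
tag so a random-effects extension is additive.

```{r}
studies <- tibble::tibble(study_id = c("a", "b"),
                          smd = c(0.1, 0.3), se = c(0.1, 0.2))
compute_weights(studies)
pool_fixed(studies)
```

## CRT effect-size variance

Simulated studies are two-arm cluster-randomized trials (CRTs; e.g.
schools randomized, students measured) with the SMD standardized by the
total (within- plus between-cluster) standard deviation. With equal
cluster size $n$, arm totals $N^T, N^C$ ($N = N^T + N^C$) and intraclass
correlation $\rho$:

$$v \;=\; \frac{N^T+N^C}{N^T N^C}\,\bigl(1+(n-1)\rho\bigr)
  \;+\; \frac{\delta^2}{2h},
  \qquad
  h = \frac{\bigl[(N-2)-2(n-1)\rho\bigr]^2}
        {(N-2)(1-\rho)^2 + n(N-2n)\rho^2 + 2(N-2n)\rho(1-\rho)}.$$

The leading term is the simple-random-sampling variance of a mean
difference inflated by the design effect $1+(n-1)\rho$; $h$ is the
effective degrees of freedom of the total-variance estimate. At
$\rho = 0$ the expression reduces to the familiar
$(N^T+N^C)/(N^T N^C) + \delta^2/(2(N-2))$, and it is non-decreasing in
$\rho$ — both properties are regression-tested.

## The simulator and what it does (not) emulate

`sim_config()` fixes the study conditions:

| parameter | default | meaning |
|---|---|---|
| `delta` | 0.15 | true SMD; a small effect on the education scale |
| `rho` | 0.20 | intraclass correlation; a standard planning value for school-clustered achievement outcomes |
| `size_log_mean` | `log(c(12, 40))` | log-scale medians: clusters per arm, students per cluster |
| `size_log_cov` | sdlog (0.4, 0.5), corr −0.2 | log-scale spread/association of the two sizes |
| `level` | 0.95 | CI level used when pooling simulator output |

Sample sizes are drawn from a correlated bivariate lognormal (via
`MASS::mvrnorm` on the log scale), rounded half-up with a floor of 2
clusters per arm and 2 students per cluster so variances stay finite, and
arms are equal by construction. The lognormal parameters were chosen once
as realistic education-trial sizes (median ~12 schools per arm of ~40
students, right-skewed, with a mild negative association between the
number of clusters and cluster size); they are overridable. Each study's
standard error is then $\sqrt{v}$ from the formula above at the drawn
sizes, and the observed effect is an unbiased draw
$d_j \sim N(\delta, v_j)$ — one effect per study. The seeded RNG stream
is consumed in documented order (all sizes first, then all effects), so
the size draws can be reproduced on their own.

The generator emulates the *sampling* structure of a single-true-effect
meta-analytic literature: no between-study heterogeneity
($\tau^2 = 0$), no publication bias, no covariates, no non-normal
effects. Tests passing on this generator therefore certify the
computation and calibration of the pipeline under a correctly specified
fixed-effects world, not robustness to the messiness of real literatures.

```{r}
datasets <- lapply(c(10, 20, 50, 100),
                   function(k) simulate_meta(sim_config(k = k, seed = k)))
summarize_datasets(datasets)
```

## Layout anatomy and numerical choices

`marc_layout()`, `forest_layout()` and `bar_layout()` return *fully
resolved* geometry — every number visible in any rendering is computed in
the layout, and renderers only map numbers to pixels. This separation is
itself tested (the interactive HTML embeds the layout tables verbatim and
a test parses them back).

MARC specifics:

* Dot **area** (not radius) is proportional to relative weight —
  perceptual best practice for quantity-by-size encodings.
* Color classes are a total function of `sign(smd)`: negative → red
  ("Decreased scores"), positive → blue ("Increased scores"), zero → a
  neutral gray. The palette is colorblind-safe and configurable.
* **v1** uses a single y scale: studies at their relative weights (which
  sum to 1), the summary cloud at $y = 1.0$, the combined weight of all
  studies.
* **v2** moves the cloud to its own pane with an independent vertical
  scale and rescales the study pane to $[0,\ 1.15 \times \max_j
  (w_j/\sum w)]$ (padding factor 1.15; pane height ratio 1:3,
  summary:studies). This keeps large-$k$ study dots from pooling at the
  axis. The pane proportions are the package's own choice — the source
  designs are not dimensioned — and rescaling the study pane never moves
  the cloud (tested).
* The summary cloud uses `n_dots = 50` dots at deterministic normal
  quantiles $i/(G+1)$ of the pooled sampling distribution, truncated to
  the CI, with vertical offsets from a deterministic greedy
  collision-avoiding packing (dots placed center-outward, each taking the
  smallest clear offset). The dot count and placement scheme are
  configurable design choices, not a claim about any one published
  beeswarm construction.
* Hover text: study id, SMD to 2 decimals, and the display's native
  uncertainty quantity — relative weight (1-decimal percent) for MARC,
  raw weight for forest, student count for bar. Formats configurable at
  the layout level.
* Weight-rank ties are broken by input order. Forest and bar rows grow
  with $k$ (`n_rows` metadata), whereas the MARC y axis is continuous, so
  MARC plot height need not grow with $k$.
* `relabel_studies()` provides the seeded label permutation used when the
  same dataset must be shown repeatedly without matchable labels.

```{r, fig.width = 7, fig.height = 5}
autoplot(marc_layout(datasets[[2]], version = "v2"))
```

## The survey-experiment toolkit

`build_design()` reproduces a confounded $4 \times 4$ factorial:
visualization type (MARCv1, MARCv2, BP, FP) crossed with number of
studies $k \in \{10, 20, 50, 100\}$ gives 16 treatment combinations,
confounded into 4 blocks per pattern so each participant views 4
visualizations — one of each type. Three confounding patterns (12 survey
blocks total) keep interactions estimable in some replicates. The default
patterns are built by Latin-square aliasing — pattern $p$ assigns block
$b$, visualization $v$ the $k$ index $(b + m_p v) \bmod 4$ with
multiplier $m_p \in \{1,2,3\}$ — which satisfies the design invariants
(each visualization once per block; blocks partition the combinations
within a pattern); alternative patterns can be supplied as data and are
validated against the same invariants. Participants are assigned evenly
(imbalance ≤ 1) and at random, condition order randomized per
participant. The printed replicate count follows the convention
$\lfloor n/16 \rfloor$ — 10 at $n = 160$ — i.e. complete 16-participant
replicates; each treatment combination is *viewed* about $4n/16$ times.

Scoring: items Q1–Q7 are 0/1, so scores run 0–7; Q8 is exploratory and
never counted. Q5 is a slider on $[-0.5, 0.5]$, correct within a
tolerance of ±0.05 (one tick; configurable), with out-of-range answers
flagged invalid. Participants failing the attention check or finishing
under 3 minutes are marked excluded (rows retained for audit).

Analysis contracts: `analyze_scores()` fits `score ~ viz * k` by two-way
ANOVA and reports all 6 Tukey-adjusted visualization-pair differences
with standardized effects (difference / √MSE); `analyze_durations()` fits
a two-level mixed model `page_duration ~ viz * centered(k) +
(1 | participant)` with a configurable reference visualization, so the
intercept is that visualization's mean duration at an average $k$;
singular fits are reported, not hidden. Both delegate the standard
machinery to `stats::aov`/`stats::TukeyHSD` and `lme4::lmer`; the
package's contribution is the design and scoring computation plus the
contracts and their tests. Significance/confidence levels are parameters
throughout. Synthetic respondents (`simulate_scores()`,
`simulate_durations()`, `simulate_responses()`) exercise the pipeline;
they emulate data *structure*, never any empirical human-subject result.

## Problem sizes used in the test suite

The suite verifies oracle equivalence of pooling on 1000 random datasets
($k \le 100$, tolerance 1e−12), unbiasedness and nominal CI coverage of
the simulator over 2000 replicate meta-analyses at $k = 20$ (3
Monte-Carlo-SE / binomial tolerance), Tukey family-wise type-I error
under a zero-effect simulation over 1000 replicates at $n = 160$, design
balance over 100 seeds, and mixed-model parameter recovery over 60
replicates at $n = 200$. These sizes give Monte-Carlo error small enough
for the stated tolerances while keeping the default run fast.

## Known limitations

* Fixed-effects only; one effect size per study. Multiple effects per
  study would need robust-variance pooling upstream of the layouts.
* The CRT variance formula assumes equal cluster sizes within a study;
  unequal arm totals are accepted but `cluster_size` is then an average.
* The layouts depict statistical uncertainty only; nothing about external
  validity or relevance of evidence.
* The interactive renderer emits plain SVG + JSON HTML; it is
  intentionally dependency-free and does not provide zooming or linked
  brushing.
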