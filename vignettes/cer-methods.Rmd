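---
title: "Event-of-relation causal inference: model, assumptions and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Event-of-relation causal inference: model, assumptions and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cer)
```

## The model

Two ingredients define causality here: a statistical dependence and a
temporal order. For binary event series the package collapses both into a
single counting statistic. Writing $X$ for the candidate effect and $Y$
for the candidate cause on a common sampling grid, the *event of relation*
(ER) at lag $\tau$ is the joint event $\{X_t = 1, Y_{t-\tau} = 1\}$, and
$K_\tau$ is its count over the recording. If $Y$ does not influence $X$,
shifting $Y$'s observation times cannot change the joint probability of
the pair, so all $K_\tau$ estimate the same quantity; if $Y$ drives $X$
after a transmission delay, the count at (and only at) the true delay is
inflated. Since no physical influence is instantaneous, $K_0$ is a valid
null reference: the method asks, lag by lag, whether $K_\tau$ is
compatible with $K_0$.

The comparison is a binomial test, computed via its Poisson
approximation, which is accurate here because $K$ counts rare-ish joint
events over thousands of samples. With $F(k \mid \lambda)$ the Poisson
CDF, the per-lag score is $p_\tau = F(K_\tau \mid K_0)$:

* `increase` tail (default): flag $\tau$ as **positive causality** when
  $p_\tau > 1 - \alpha$ — a cause ordinarily raises its effect's
  probability, and all of the package's benchmarks use this tail;
* `decrease` tail: flag **negative causality** (suppression) when
  $p_\tau < \alpha$;
* `two-sided`: both rules at $\alpha/2$.

The *upper limit* — the smallest count with CDF above $1-\alpha$ given
$K_0$ — is the horizontal dotted line on the lag-profile plots; a
frequency bar crossing it is exactly a flagged lag.

The crucial property is what the statistic does **not** use: no firing
rates, trends or autocorrelations of $X$ or $Y$ are estimated. The pair
$(K_\tau, K_0)$ is a sufficient summary, which is why the test applies
verbatim to non-stationary inputs whose marginal structure defeats
model-based measures.

### Assumptions and their limits

* **Aligned, equally sampled, gap-free binary channels.** Missing values
  are rejected outright: a gap has no event-logic meaning.
* **Temporal resolution finer than the transmission delay.** If cause and
  effect land in the same sample, their coincidences accrue to $K_0$,
  inflating the null reference; association is still visible but the
  direction is undecidable. This is a data-acquisition limit, not a test
  option, so the package keeps lag 0 strictly as the reference.
* **Delays concentrated on few lags.** A causal effect smeared uniformly
  over a very wide delay window adds only a sliver of probability to each
  individual lag and is designed to be (correctly) invisible to a
  per-lag test; in practice an "unusually wide uniform delay" is best
  read as non-causality.

## Tunable parameters

| parameter | default | meaning and rationale |
|---|---|---|
| `alpha` | 0.005 | per-lag significance level. The scan performs `tau_max` tests per direction, so small values are the practical multiplicity control; 0.005 keeps wrong-direction errors near zero in the benchmarks while retaining full power at realistic interaction strengths. |
| `tau_max` | 20 | largest scanned lag (samples). Covers every delay used in the package's benchmark scenarios (≤ 6) with generous margin; raise it only as far as plausible transmission delays require, because family-wise false flags grow with the number of scanned lags. |
| `tail` | `"increase"` | see above; `decrease` targets suppressive links. |
| `min_events` | 5 | guard on $K_0$. With a near-empty reference the Poisson test degenerates ($F(k \mid 0) = 1$ for every $k$, so everything would be "significant"); below the guard the result status is `insufficient-events` and nothing is flagged. |
| `overlap_correction` | `FALSE` | the linear shift supports lag $\tau$ on $n-\tau$ samples, slightly deflating $K_\tau$ relative to $K_0$. The default compares raw counts, which is the convention the benchmarks assume and is accurate while $\tau_{\max} \ll n$; the flag rescales the reference to $K_0 (n-\tau)/n$ for deep scans into short series. |
| `bonferroni` | `FALSE` | optional $\alpha/\tau_{\max}$ correction. Off by default to preserve the method's published operating characteristics; turn it on for wide scans (e.g. `tau_max` ≥ 50) where the multiplicity inflation documented below matters. |

Lags are always in samples; the `dt` metadata on an `event_series` only
converts them to time units for display.

## The simulator

`simulate_network()` implements a discrete interaction model of spiking
nodes: at each sample a node fires spontaneously with probability
$p_t$, and each firing of a source node independently draws a delay $d$
from the link's discrete delay distribution and, with the link's
interaction probability, forces the target to 1 at $t+d$. Collisions are
idempotent (the series stays binary), induced events beyond the end of the
series are discarded, and nodes are processed in topological order so
effects cascade along directed paths (the graph must be acyclic; parallel
links at different delays are allowed). Drawing a delay *per firing*, not
per run, is what makes multi-atom delay distributions show coincidence
mass at all their atoms within a single recording.

Non-stationarity is emulated by a bounded Gaussian random walk on the
firing probability: steps of sd 0.005 per sample, reflected into
[0.05, 0.6], starting at 0.3. The scale was chosen once so that a
10 000-sample trajectory wanders over a large fraction of its range
(clearly non-stationary to a unit-root test) while staying well away from
the degenerate rates 0 and 1; all three numbers are configurable. Two
caveats documented deliberately: reflection at the bounds injects a little
mean reversion, so a small fraction of trajectories is rejected as
stationary by the ADF check — the package's own tests therefore require a
large majority, not unanimity, of unit-root verdicts; and real
physiological rate drift is smoother and often oscillatory, which this
walk does not imitate. More generally the simulator emulates
*conditionally independent Bernoulli* firing with feed-forward induction —
it has no refractoriness, no bursting, no common slow input shared across
nodes — so passing its benchmarks demonstrates calibration and power under
those idealized conditions, not robustness to every failure mode of real
recordings (shared confounders in particular remain detectable as
spurious pairwise links, as in any bivariate method).

## The evaluation taxonomy

`classify_outcome()` reduces one replicate (both scan directions plus the
ground truth) to one of six mutually exclusive labels. For a causal pair:
**strongly correct** — forward detection with *every* flagged lag inside
the true delay support; **weakly correct** — forward detection with some
flagged lag outside it (with distributed delays the test legitimately
flags several lags; "strong" is reserved for flag sets wholly inside the
support); **missing detection** — nothing flagged either way;
**error type I** — any reverse-direction flag, and this label dominates a
simultaneous forward detection so the categories stay exclusive.
Wrong-direction evidence is treated as the worse failure. For a
non-causal pair: **error type II** — any flag at all — else **true
negative**. Causal scenarios cannot produce error type II by construction,
so spurious-detection rates are estimated from companion null scenarios
(interaction probability 0) run under otherwise identical parameters;
that pairing is an explicit design choice of this package.

`run_experiment()` simulates each replicate once, computes the
bidirectional scan once, and re-thresholds the stored per-lag CDF values
at every requested $\alpha$ — the p-values do not depend on $\alpha$, so
one scan serves all levels. The default replicate budget is 2000 per
cell, sized for a desk machine; the package's own acceptance checks use
200–5000 replicates per scenario and run in well under an hour in total.

## Numerical and degenerate-input choices

* The Poisson CDF is evaluated by `stats::ppois` (numerically stable far
  beyond the count scales reached here); the test suite cross-checks it
  against a direct log-space term summation to $10^{-10}$.
* Thresholds are computed in integer count space: the upper limit is the
  smallest $k$ with $F(k \mid K_0) > 1-\alpha$ (strict inequality, so a
  count exactly at the limit is significant by the $p_\tau > 1-\alpha$
  rule); the lower limit is the largest $k$ with $F(k \mid K_0) < \alpha$
  and is `NA` when even $k = 0$ is not significantly small.
* All-zero or near-empty effect series yield `insufficient-events`, never
  an exception; all-one series are tested and simply produce no increase
  flags.
* The ADF implementation uses the with-constant (drift) regression with
  the standard $(n-1)^{1/3}$ lag-order rule; its statistic matches the
  reference implementation in `statsmodels` to $10^{-10}$ on fixed
  series, and p-values are interpolated from the tabulated tau
  distribution, clamped to [0.01, 0.99].
* A deliberate convention: the unit root is the ADF *null*, so
  **failing to reject** (p > 0.05) is what certifies a series as
  non-stationary; rejection certifies stationarity. Informal usage often
  inverts this, so `nonstationarity_check()` states its verdict
  explicitly rather than returning a bare p-value.

## Multiplicity across scanned lags — a documented limitation

The per-lag test is calibrated: under independent stationary pairs the
per-lag rejection rate at level $\alpha$ matches $\alpha$ closely (the
test suite verifies this within three binomial standard errors). No
cross-lag correction is applied by default, so the *family-wise* flag
probability grows with the number of scanned lags and directions,
concentrated by the shared $K_0$ reference into correlated bursts.
The packaged checks quantify both ends: a 10-lag bidirectional scan at
$\alpha = 0.0005$ flags a null pair well under 1% of the time, while the
"wide uniform delay" control — 100 scanned lags at $\alpha = 0.005$ —
comes out entirely flag-free in only about nine replicates in ten. A
single wide-scan run, as in the method's illustrative figures, is
typically clean, but a high clean *rate* over many replicates requires
either a smaller $\alpha$ or the optional Bonferroni flag. This is an
inherent property of per-lag testing, stated here so users scan no wider
than their physics warrants.

## Problem sizes used in the shipped checks

The packaged tests and the acceptance script run, by the package's own
choice of desk-scale budgets: 5000-replicate null calibration
(family-wise false-detection at $\alpha = 0.0005$), 500-replicate
fixed-delay recovery and non-stationary Gaussian-delay detection,
200-replicate wide-uniform control and three-node-chain direction checks,
and a 1000-replicate outcome-rate grid over interaction probabilities
{0.2, 0.4, 0.6, 0.8} × levels {0.05, 0.005, 0.0005}; series length is
5000 samples throughout, matching the benchmark conditions. Larger
budgets sharpen the Monte-Carlo estimates but do not change any verdict
reported by the documentation.
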