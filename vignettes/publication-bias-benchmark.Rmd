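---
title: "Benchmarking publication-bias detectors on simulated meta-analyses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking publication-bias detectors on simulated meta-analyses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(biasbench)
```

## The problem

Publication bias (PB) — the tendency for studies with favourable or
significant findings to be published while null or unfavourable ones stay in
the drawer — distorts pooled estimates in meta-analysis. Detection tools
(funnel-plot inspection, Egger's regression, Begg's rank correlation,
trim-and-fill, and lately multimodal language models shown funnel-plot
images) are hard to evaluate on real data because the ground truth — which
studies went unpublished — is almost never observable. `biasbench` therefore
evaluates detectors on *simulated* meta-analyses where suppression is
applied by construction, so every dataset carries a known label.

The package provides, end to end: the data-generating process, a REML
random-effects fitter whose convergence signal drives dataset regeneration,
deterministic funnel-plot rendering and payload packaging, a pluggable
detector interface with a strict five-run agreement rule, from-scratch
implementations of the three traditional tests, and confusion-matrix scoring
with replication confidence intervals.

## The generative model

Each meta-analysis is drawn from a two-stage normal-normal hierarchy:

$$ y_i \sim N(\mu_i,\ s_i^2), \qquad \mu_i \sim N(\mu,\ \tau^2), \qquad
   s_i \sim \mathrm{Uniform}(1, 4), $$

with true overall effect $\mu = 0$ and between-study variance
$\tau^2 \in \{0, 1\}$ (homogeneous vs. markedly heterogeneous). The wide
uniform on $s_i$ mimics meta-analyses mixing small and large studies; it is
deliberately coarse and, in particular, makes $s_i$ independent of $y_i$'s
underlying truth — real standard errors can correlate with effect sizes, a
feature the generator does not emulate. Under $\tau^2 = 0$ the marginal
variance of $y$ is $E[s^2] = (1^2 + 1\cdot4 + 4^2)/3 = 7$, a closed form
the tests verify by simulation.

A pool of $n + m$ studies is drawn; $m$ are suppressed; the $n$ survivors
form the published meta-analysis that detectors see. The severity grid is
$m/n \in \{0, 1/10, 1/5, 1/3\}$ ("none", "mild", "moderate", "severe") with
$m$ rounded half-up ($n = 15$, severity $1/10$ gives $m = 2$), and
$n \in \{15, 30, 50, 75\}$. Each cell is replicated 100 times by default.
These defaults *are* the benchmark's stated world; they are constructor
arguments, but the package does not second-guess them.

## Selection mechanisms, and why the default is one-sided

Two suppression mechanisms are implemented:

* `selection = "p_value"` — studies are ranked by the significance of their
  result and the least significant are suppressed;
* `selection = "effect_size"` — studies are ranked by effect size and the
  smallest are suppressed.

Each has a directional switch. The default, `favor = "positive"`, suppresses
the *least favourable* results: the largest one-sided p-values toward the
positive direction, or the most negative effects. The alternative,
`favor = "none"`, ranks by two-sided p-value or absolute effect.

The default matters, and was a genuine design decision. With $\mu = 0$ the
symmetric variant removes studies in a sign-invariant way: the funnel is
hollowed out around its centre but never tilted, so the asymmetry statistics
(Egger's intercept, Begg's concordance, trim-and-fill's rank imbalance) keep
exactly their null behaviour at every severity, and the benchmark would be a
study of type-I error only. One-sided suppression — which is also what the
phrase "studies with negative or nonsignificant results are less likely to
be published" describes — is the mechanism that actually produces the
asymmetric funnels the whole exercise is about, with detector power growing
in $n$ and severity. The symmetric variant is retained behind the flag
because hollow-centre suppression is a legitimate robustness probe (it is a
world where asymmetry tests *should* stay silent); only the directional
default is benchmarked.

Ties in the rankings are broken by absolute effect and then generation
index, so a dataset is a deterministic function of its random stream.

## REML fitting and regeneration

The random-effects model is fit by restricted maximum likelihood with
Fisher scoring on $\tau^2$:

* initialisation at the DerSimonian–Laird moment estimate truncated at 0 —
  a cheap, standard warm start;
* proposals truncated at zero (the boundary is a legal estimate, not an
  error);
* step-halving until the restricted log-likelihood does not decrease, which
  makes the likelihood trace monotone (a tested invariant);
* convergence declared when $|\Delta\hat\tau^2| < 10^{-8}$ within 100
  iterations — tight enough that $\hat\tau^2$ is stable far beyond
  reporting precision. Neither tolerance is a claim about the original
  analysis, which does not state its settings.

Hitting the iteration cap yields `converged = FALSE` rather than an error,
because non-convergence is a *reportable state*: the generator discards such
draws and redraws until it has a convergent dataset, counting regenerations
(capped at 1000, then a simulation-failure error names the cell). The tests
verify the maximiser against a dense grid search of the restricted
log-likelihood and parameter recovery ($\hat\tau^2$ within $1 \pm 0.15$ on
average at $n = 75$).

## The traditional detectors

All three are implemented from first principles and checked against
independent oracles (hand normal equations, exhaustive pair enumeration, a
hand-executed rank iteration):

* **Egger**: OLS of $z_i = y_i/s_i$ on $1/s_i$; two-sided t test of the
  intercept on $n-2$ df; flagged when $p < \alpha = 0.05$.
* **Begg**: Kendall concordance between variance-standardised deviates from
  the fixed-effect mean and the variances, normal approximation with
  continuity correction; flagged when $p < 0.05$.
* **Trim-and-fill**: iterative $L_0$ estimator with fixed-effect centring,
  the dominant side chosen by rank sum; flagged when $\hat k_0 > 0$.

The trim-and-fill flag deserves a caveat. The method is an *adjustment*
procedure, not a test; $k_0 > 0$ is the only parameter-free binary rule it
admits, and it is very liberal: by the symmetry of the null rank
distribution (and the max over sides), sampling noise alone pushes the
rounded $L_0$ above zero in a large share of unbiased meta-analyses. The
power benchmark therefore reads very differently per method — Egger and
Begg are conservative and genuinely gain power with $n$ and severity
(tested properties), while trim-and-fill's rate is high everywhere. The
pooled three-test summaries computed by `benchmark_traditional()` and
`scripts/acceptance.R` inherit this: the pooled rate at $n = 15$ sits near
one third rather than the mid-teens, which is what a k0-based flag forces.

## Detectors, payloads and the agreement rule

`payload_for_llm()` is the privacy boundary: a detector sees the 600×600
funnel PNG (base64) and, in combined mode, the published studies' effect
sizes and standard errors — never the suppressed studies, the severity, or
the label. The test suite asserts the leakage guard on the serialised
payload. The funnel style is deliberately minimal and deterministic
(inverted standard-error axis, dashed reference line at the REML estimate,
optional 95% pseudo-confidence wedge, off by default since the original
styling is not reproducible); byte-identical rendering is a tested
contract, which is why rendering goes through a fixed-output raster device.

Stochastic detectors are queried five times per dataset and a verdict is
accepted only when all five parsed answers are identical; anything else is
`inconsistent` (or `unparseable` when no run parses). Parsing is
word-boundary and negation-aware ("no publication bias" counts as absent).
When scoring, non-verdicts count as *incorrect for the true label* (FN
under bias, FP under no bias): a detector that cannot agree with itself has
not identified anything. This convention is a design decision — the
original rule says only that non-identical runs are "not correct" — and it
shapes every metric, so it is centralised in `score_decision()`.

Metrics follow the printed formulas exactly; a metric with a zero
denominator is `NA`, never 0 or 1 (a no-bias cell has no positives, so
sensitivity simply does not exist there). Uncertainty is summarised by
percentile intervals (type-7 quantiles) of replicate-level values — the
construction behind the reported CIs is not stated beyond "derived from 100
replications", so the plain percentile choice is declared here.

## What a green test run does and does not establish

The suite establishes: the generator's moments and selection orderings, the
REML maximiser against grid search, the three tests against brute-force
oracles and their nominal type-I error, determinism of the whole grid from
one seed, perfect scoring with an oracle detector, and the exact arithmetic
of the agreement rule and metric formulas.

It does *not* establish anything about real multimodal models (their
reported accuracies are properties of proprietary systems, out of scope
here — the HTTP adapter can query them but nothing depends on it), nor
that the simulated world matches real meta-analyses: standard errors are
independent of effects, suppression is a deterministic truncation rather
than a probabilistic or multi-layered process, and only the
normal-model effect-size scale is generated.

## Known limitations

* The pooled three-test power summary is dominated by trim-and-fill's
  liberal flag (above); per-method rows in the `PowerReport` are the more
  interpretable output.
* Begg's test enumerates all pairs ($O(n^2)$) — fine at benchmark sizes.
* The regeneration loop conditions the published data on REML convergence;
  at these cell sizes non-convergence is rare, so the induced selection
  effect is negligible, but it is part of the stated design.
* `detector_scripted()` consumes its responses in evaluation order, so its
  confusion matrix depends on the documented cell ordering of `run_grid()`
  (null cells first, then by severity and scenario).
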