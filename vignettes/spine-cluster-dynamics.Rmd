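---
title: "Stochastic weight dynamics in clustered dendritic spines"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stochastic weight dynamics in clustered dendritic spines}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spinedyn)
```

## The model

spinedyn simulates the day-to-day evolution of synaptic weights in small
clusters of dendritic spines. The synaptic weight $W$ is dimensionless and
proportional to spine volume, the usual imaging proxy for synaptic
strength; one discrete time step corresponds to one day, matching the
typical interval between longitudinal spine-imaging sessions. Each cluster
is a chain of $N_{cl}$ synapses (default 10) on one dendritic branch;
clusters are independent of one another.

Every day, each *active* synapse receives one potentiation (LTP) and one
depression (LTD) increment:

$$
VO_W = v_{hi} - (v_{hi} - v_{lo})\frac{W}{W + W_{med}}, \qquad
A_{LTP} = W\, r_1\, VO_W \left(1 - k_{hi}\frac{W}{W + W_{hi}}\right),
\qquad
A_{LTD} = W\, r_2\, VO_W,
$$

and the synchronous update is $W_{new} = W_{old} + A_{LTP} - A_{LTD}$.
The ingredients:

* **Volatility** $VO_W$ falls from $v_{hi} = 4$ at $W = 0$ towards
  $v_{lo} = 0.2$, with the midpoint at $W_{med} = 0.4$. Small spines
  therefore fluctuate much more, in relative terms, than large ones —
  the property that lets strong synapses stay strong for years.
* **Increments** $r_1, r_2$ are independent Gaussian draws with standard
  deviation equal to a quarter of the mean (`sd_ratio = 4`); rare
  negative draws are clamped to zero. The LTD mean is fixed at
  $a_2 = 0.16$.
* **Resource competition**: the LTP mean $a_1$ falls linearly with the
  number $N_{st}$ of *strong* synapses ($W > T_{st} = 0.8$) in the
  cluster, from $x_2 = 0.18$ ($N_{st} = 0$) to $x_1 = 0.144$
  ($N_{st} = N_{cl}$). Maintaining large spines consumes locally shared
  resources (mRNAs, plasticity-related proteins), so a cluster full of
  strong synapses supports less growth. This negative feedback is what
  stabilises the per-cluster strong count.
* **Saturation**: the bracket with $k_{hi} = 0.05$, $W_{hi} = 20$ trims
  LTP by at most 5% at very large $W$, bounding the weights.
* **Silencing**: an active synapse whose updated weight falls below
  $T_{wk} = 0.08$ is reset to a silent state at the basal weight
  $W_{sil} = 0.05$; silent synapses receive no LTP/LTD.
* **Regeneration**: each day a silent synapse reactivates at
  $W_{reset} = 0.4$ with probability
  $P_{ACT} = P_{bas} N_{st} / N_{cl}$ (maximal value $P_{bas} = 0.1$),
  and only if a chain-adjacent synapse is strong — regrowth happens next
  to healthy spines.

### Within-day semantics and reproducibility

The source text of a synchronous-update model leaves the intra-day order
of silencing, regeneration and $N_{st}$ evaluation open. spinedyn fixes
one consistent convention: $N_{st}$ and the per-synapse strong flags are
snapshotted at the start of the day and drive both $a_1$ and the
regeneration gate; LTP/LTD are applied to all day-start-active synapses;
silencing is applied to the updated weights; regeneration applies only to
synapses that were already silent at day start. A synapse can therefore
not be silenced and regenerate within the same day. "Strong" is strict
($W > T_{st}$), as is silencing ($W < T_{wk}$). The standard deviation of
the LTP draw tracks the cluster-dependent mean ($sd_1 = a_1/4$); the
`fixed_ltp` variant instead uses the fixed pair
$a_1 = 0.16,\ sd_1 = 0.04$.

The draw order is part of the contract: per day, clusters in index order;
within a cluster, $r_1$ then $r_2$ per active synapse in index order,
then one uniform per day-start-silent synapse (drawn even when the gate
fails, so the stream layout does not depend on the realised state). The
compiled driver uses R's RNG and is bit-identical to the pure-R
`step_cluster()` reference loop — the test suite asserts exact equality —
and every protocol is fully determined by `(params, seed)`.

Regenerated synapses never count as strong on the day they regenerate
(they re-enter at $W_{reset} < T_{st}$), so no self-counting ambiguity
arises in $P_{ACT}$. The chain is non-periodic: interior synapses have
two neighbours, the endpoints one.

### Variants

`variant = "fixed_ltp"` removes the resource coupling (fixed LTP mean and
sd); `"no_regeneration"` sets $P_{ACT} = 0$; `"exponential_increments"`
replaces the Gaussian draws by exponentials with decay rate constants
$\lambda_1, \lambda_2$ (explored in $[0.5, 3]$), which destabilises the
model — when the rates differ more than about two-fold almost all weights
either run away or collapse to silence.

## Protocols

All protocols operate on 1,000 independent clusters by default and are
reproducible from `(params, seed)`:

* `steady_state_protocol()` — equilibrate, then analyse one day: 80-bin
  natural-log weight histograms, log-normal fit, the daily-increment
  distribution and its peak-excluding normal fit, the
  $\Delta W$-versus-$W$ profile, and the mean relative daily change.
* `perturbation_protocol()` — paired steady states with the mean LTP
  amplitude scaled by a factor.
* `memory_imprint_protocol()` — impose an engram (synapses 1–5 of each
  cluster at $W = 5$, 6–10 at $0.5$) and track the imprinted subset.
* `decorrelation_protocol()` — Pearson correlation of the weight pattern
  against a steady-state reference, sampled every 10 days to 1,500 days,
  with an exponential decay-time fit.
* `cluster_stability_protocol()` — daily per-cluster $N_{st}$ over 2,000
  days and the occupancy of the 4–7 band.

## Numerical and design choices

**Burn-in.** Protocols default to a 50,000-day pre-run before anything is
measured. Because the weight pattern decorrelates with a time constant of
roughly a thousand days, summaries are statistically stationary long
before that; we verified that ensemble summaries at 10,000, 30,000 and
50,000 days agree within Monte-Carlo error, and the test suite and the
acceptance script therefore equilibrate for 10,000 days. The initial
condition (all synapses active at $W = 1$) is likewise erased by burn-in.

**Histogram fits.** `fit_lognormal()` defaults to maximum likelihood on
$\ln W$ of the *active* synapses — a log-normal cannot represent the
silent point mass at $W_{sil}$, so the all-weights scope (available via
`scope = "all"`) mixes in a spike that inflates the fitted width. A
histogram-curve least-squares option mirrors fitting a drawn curve to a
binned histogram; both curve fits use a free amplitude so excluded or
non-log-normal mass cannot bias the shape parameters.

**The near-zero $\Delta W$ spike.** The daily-increment distribution has
a sharp peak at zero contributed by the smallest active synapses, whose
increments are proportional to their (tiny) weights. `fit_normal()` with
`exclude_peak = TRUE` ignores a window of half-width `epsilon = 0.02`
around zero; the default histogram-curve method reproduces what a curve
fit to the plotted histogram does, while the truncated-moment alternative
weights the heavy tails more and returns a somewhat larger sd. The spike
itself is a model prediction: a subpopulation of near-stationary synapses
that imaging studies with limited sensitivity would not resolve.

**Decay-time fitting.** `fit_decay_time_constant()` uses
Levenberg–Marquardt least squares of $R(t) = e^{-t/\tau}$, initialised
from the median of $-t/\ln R(t)$; an additive-offset form
$c + (1-c)e^{-t/\tau}$ is available behind `with_offset = TRUE` for
series that plateau. Degenerate (constant) series are rejected.

**Degenerate states.** A fully silent cluster is a fixed point
($N_{st} = 0 \Rightarrow P_{ACT} = 0$). Protocol summaries that are
undefined in such states (e.g. the mean active weight of a fully
silenced ensemble) are reported as `NA` rather than invented.

## What the simulations show — and what they do not

At the standard parameters the package's own measurements (computed by
the test suite and by `scripts/acceptance.R`; ensemble of 10,000
synapses, 10,000-day equilibration) are: a unimodal, heavy-tailed weight
distribution whose active range spans about 5.4 natural-log units, with
an active-weight log-normal MLE of $\sigma_{\ln W} \approx 1.04$; about
90% of synapses active at any steady-state day; a mean relative daily
weight change of about 6.2%; a daily-increment distribution whose normal
core has sd $\approx 0.07$ plus the near-zero spike; per-cluster strong
counts within 4–7 for about 99% of cluster-days over 2,000 days; an
imprinted engram that still sits at about 1.8× the steady-state mean
weight 700 days after imposition; and a weight-pattern decorrelation
time constant of roughly 1,100 days. A 5% reduction of the mean LTP
amplitude lowers the equilibrium mean weight by about 46%, whereas the
uncoupled fixed-amplitude variant collapses almost completely after a 2%
reduction — the cluster-level resource feedback is what keeps the model
in a regime where parameter variation is survivable at all.

The generator emulates ongoing, activity-independent volume fluctuation
statistics; it does not model induced plasticity events, molecular state,
spatial geometry beyond chain adjacency, or resource pools explicitly
(competition enters only through $a_1(N_{st})$). Passing tests therefore
show that the implementation realises this stochastic process exactly and
that its emergent statistics are stable and reproducible — not that real
spines obey these equations.

Known limitations: with $N_{cl} = 5$ the all-silent cluster state is
absorbing and in principle bimodalises the long-run distribution, but
under the standard parameters cluster death is so rare that the
distribution remains unimodal over any feasible horizon; the
exponential-increment variant admits unbounded weight growth (weights can
overflow on long horizons — it is intended for short qualitative runs);
and reported standard errors for the decay-time fit are conditional on
the exponential form being correct.
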