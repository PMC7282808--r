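---
title: "Hidden-state inference and place-field remapping: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hidden-state inference and place-field remapping: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(statemap)
```

## The model

Hippocampal place cells keep one spatial map per *context*, and remap —
switch maps — when the animal decides it is in a different context. The
package formalizes that decision as Bayesian inference over hidden
states. The animal's assumed internal model is generative: each session
produces an observation, a feature vector $\mathbf{y} = [y_1, \dots,
y_D]$ summarizing the session (cue positions, enclosure shape, running
direction, ...). A hidden state $c$ is drawn from a nonparametric prior
and the observation is drawn from that state's observation distribution
with the state's parameters integrated out. Remapping questions become
partition questions: "did the place fields remap?" becomes "were these
observations generated by the same hidden state?"

Two log-odds quantities carry all the conclusions:

* the **partition evidence ratio**, the difference in unnormalized log
  posterior between two complete partitions of the observations
  (per-state marginal likelihoods plus the partition prior), and
* the **state evidence ratio**, the log odds between two candidate
  assignments (an existing state or a novel one) of a single new
  observation, each weighted by the sequential prior probability.

Strongly positive same-vs-novel ratios correspond to no remapping,
strongly negative ones to global remapping, and values near zero to the
uncertain regime where partial and rate remapping live.

## The partition prior

States follow a Chinese Restaurant Process: observation $t$ joins
existing state $k$ with probability $m_k / (t - 1 + \alpha)$ and opens a
new state with probability $\alpha / (t - 1 + \alpha)$. The closed form
for a whole assignment vector,

$$\log P(\mathbf{c}) = K \log \alpha + \sum_k \log \Gamma(m_k) +
\log \Gamma(\alpha) - \log \Gamma(T + \alpha),$$

is evaluated in log space with `lgamma` and is exactly the product of
the sequential probabilities; summed over all partitions of $T$
observations it equals one (the test suite verifies both by exhaustive
enumeration up to $T = 6$). The concentration parameter defaults to
$\alpha = 0.1$ everywhere except the protocol that explicitly varies it.
$\alpha = 0$ is accepted as the degenerate single-state prior; a
multi-state partition then scores $-\infty$ rather than raising an
error, so evidence ratios against degenerate priors remain
well-defined. The expected number of states after $n$ observations is
exactly $\alpha(\psi(n + \alpha) - \psi(\alpha))$, for which
$\alpha \log n$ is the familiar asymptotic rate; `crp_expected_states()`
reports both, and the tests compare Monte-Carlo state counts against
the exact form (the remainder between the two is an analytic constant,
about $-\alpha\,\psi(\alpha)$, not sampling noise).

## Observation models

**Real-valued features** use a multivariate normal likelihood with a
conjugate normal-Wishart prior: $\mu_0 = \mathbf{0}$, $\kappa_0 = 0.001$
(prior pseudo-count on the mean), $\nu_0 = 0.02$ degrees of freedom, and
scale matrix $T_0 = 0.02\,I$. The posterior predictive is a generalized
Student-t with $\nu_m - d + 1$ degrees of freedom, location $\mu_m$ and
scale $T_m(\kappa_m + 1) / (\kappa_m(\nu_m - d + 1))$; the marginal
likelihood of a set is the chain of one-step predictives, which for this
conjugate family equals the marginalized integral and is
order-invariant. The scatter term in $T_m$ is the centered scatter
matrix (the divide-by-$m$ covariance times $m$), zero for a single
observation.

One numerical choice deserves emphasis. With $\nu_0 = 0.02$ and $d > 1$
the empty-state predictive has $\nu_0 - d + 1 \le 0$ degrees of freedom
— an improper density. We floor the prior degrees of freedom at
$\nu_0^{\mathrm{eff}} = \nu_0 + d - 1$, which is identical to the stated
value in one dimension and the minimal proper correction above it. The
consequence is that in the multi-feature protocols the novel-state
predictive is a proper (if extremely heavy-tailed, df $= 0.02$)
density. In the cue-constellation protocol this makes the all-cues-
changed probe's evidence ratio negative in the median but with
substantial seed-to-seed spread; the graded, monotone ordering of the
ratio across probes (0, 1, 2, 4 cues changed) is the robust signature
and is what the tests assert.

**Circular features** (angles, in degrees at the interface, radians
internally) use a Von Mises likelihood with a normal-gamma prior:
$\kappa \sim \mathrm{Gamma}(a_0 = 0.01,\ b_0 = 0.01)$ and $\mu \mid
\kappa \sim \mathcal{N}(\mu_0 = 0,\ 1/(\kappa_0 \kappa))$ wrapped onto
the circle, with $\kappa_0 = 0.001$ so the location prior is nearly
flat. This family has no closed-form marginal, so marginals and
predictives are computed by trapezoidal quadrature on a grid of 720
equally spaced mean directions times 64 log-spaced concentrations in
$[10^{-3}, 10^3]$. The prior is renormalized over the grid — effectively
a truncation of the $\kappa$ prior to the grid's support — which makes
the quadrature marginal an exact telescope of the one-step predictives
(the chain-rule identity holds to machine precision on the grid) and
makes the empty-state predictive integrate to one. Doubling both grid
resolutions moves protocol-scale marginals by less than $10^{-3}$.
Multivariate circular observations factor as independent per-dimension
models; no protocol requires correlated circular features. Densities
for circular features are reported per degree.

## Rotational reference directions

Circular cue vectors are only defined up to a global rotation of the
reference frame, so before a new observation is compared to a state the
model infers the offset $\phi$ maximizing the joint posterior
predictive of $\mathbf{y} - \phi$ under that state's training
observations. The search is a plain grid at 1° with no continuous
refinement, matching the integer-degree offsets the protocols report;
ties return the smallest qualifying offset, and offsets are reported in
$(-180°, 180°]$. One global offset applies across all circular
dimensions — the offset plays the role of the map's reference
direction, not a per-cue correction. The sign convention follows the
argmax definition: the offset is positive in the direction the cue
rotated (a cue trained at 30° and probed at 120° yields $+90°$). The
novel-state option uses the prior predictive at offset zero; because
the location prior is nearly flat this choice is immaterial, and a test
verifies the full rotation-corrected evidence is invariant when
training and probe rotate together.

In the three cue-card protocols this machinery reproduces the
qualitative experimental dissociation: a card rotated 180° in a cleaned
arena carries the map with it (offset near ±180°, confident same-state
assignment); the same rotation with five lower-fidelity cues left
intact (uniformly placed means, SD 54°) anchors the map near 0° and
moves the evidence ratio toward zero; a 45° rotation with intact cues
is partially accommodated. For the 45° case the multi-seed offset
median sits near 29°, the precision-weighted compromise
$45° \cdot (1/18^2)\,/\,(1/18^2 + 5/54^2) \approx 28.9°$ between the
card and the five extra cues.

## Population model

A single evidence ratio is mapped onto a population of place fields by
letting the per-cell rate-modulation extent ($1 - $ lower/higher firing
rate, in $[0,1]$) follow a Beta distribution: the shape parameter on
the side of the preferred hypothesis is $|\text{ratio}| + 1$ and the
other is 1, so the ratio equals $b - a$. Thresholds at 0.15 and 0.85
split the population into non-remapping, rate-remapping and
completely remapping fractions via the regularized incomplete beta
function — closed form, no sampling. Derived summaries are the mean
extent $a/(a+b)$, the heterogeneity (Beta standard deviation) and the
uncertainty $e^{-|\text{ratio}|}$. Closed-form evaluation means the
Beta(1, 7) fractions are 32.1% rate / 67.9% none rather than rounded
Monte-Carlo variants of the same split that appear in some accounts;
the complete-remap fraction $0.15^7 \approx 1.7\times10^{-6}$ rounds
to 0% either way.

## Simulation protocols and the synthetic generator

Every protocol is a pure function of a configuration (pre-loaded with
the defaults above) and a seed, returning a tidy table with columns
`protocol, condition, step, quantity, value, seed`; reruns are
bit-identical. One observation represents one recording session. The
generator draws from Gaussian, Von Mises, wrapped-normal or uniform
circular distributions, with alternating schedules expressed as a
repeating list of distribution specs. It emulates the *statistics* of
session-level features, not their mechanics: there is no spatial firing
map, no within-session sampling of the arena, and no sensory noise
model beyond the stated feature distributions — so passing tests
establish the inferential behavior of the model under its assumed
feature statistics, not a fit to recorded neural data.

Protocol defaults follow the source setups: 4 Gaussian features
(mean 0, SD 0.2) with 20 training observations and four probes for the
cue-constellation experiment; alternating 1-D Gaussians at $-1$/$+1$
(SD 0.3) for experience-dependent remapping, with both means at 0 for
map stabilization; 10 circular observations, uniform versus alternating
Von Mises ($\mu = 0°, 180°$, $\kappa = 10$), split by the
maximum-margin diameter, for the direction/foraging comparison; the
three cue-rotation manipulations described above (10 training
observations, card SD 18°); morph probes on a grid in $[-1, 1]$
evaluated after 5 and 25 training observations against the five named
hypotheses (S1, S2 vs D1, D2, D3); three 2-D environment generators at
$[1,1]$, $[1,-1]$, $[-1,-1]$ (SD 0.1) under a configurable session
schedule; and the cue-variability contrast (means $[-5,0]$ vs $[0,0]$,
SDs $[2,0.1]$ vs $[0.1,2]$, 20 training observations).

Three quantities are deliberate package choices where the sources give
none. The alternation trajectories run 20 pairs (40 observations) by
default — long enough that the asymptotic preference is unambiguous at
the default parameters. The schedule protocol defaults to four
interleaved white-circle/morph-circle pairs followed by four
morph-square sessions, a minimal version of the pre-training design it
abstracts; the schedule is ordinary user input. The cue-variability
probe defaults to $[-1, 0]$: roughly 2 SD from the variable-feature
training mean but 10 SD from the tight one, which realizes the intended
contrast and is fully configurable.

Two interpretive choices matter when comparing to the experimental
panels. First, the direction/foraging comparison is *comparative*: at
$\kappa = 10$ with ten observations the split two-state likelihood gain
(8–9 nats) almost exactly offsets the CRP two-state penalty (8.75 nats
at $\alpha = 0.1$), so the directional condition's ratio straddles zero
across seeds while sitting far above the uniform condition's; the tests
assert that ordering, which is the robust content of the comparison.
Second, axis flips used in some figure panels for visual alignment with
experimental conventions are a reporting matter; every evidence ratio
in this package names its numerator and denominator explicitly and the
math never flips signs.

## Problem sizes and runtime choices

The test suite enumerates partitions exhaustively only up to $T = 6$
(203 partitions), uses 100 seeds per protocol for trend checks and 50
seeds for the cue-rotation offset distributions, and replicates the
prior's growth-rate check with 2,000 sampled partitions of 1,000
observations. The acceptance script reports the circular median of the
best offsets over 50 replicate runs, the natural location statistic for
angular data whose clean-rotation distribution concentrates at the
±180° wrap point.

## Known limitations

* The exact-enumeration path is exponential (Bell numbers) and
  restricted to ten observations; all protocols compare small named
  hypothesis sets instead, which is faithful to how the comparisons are
  defined but is not a general-purpose posterior approximation (no
  MCMC or particle filtering is provided).
* The Von Mises quadrature truncates the concentration prior to
  $[10^{-3}, 10^3]$; likelihood mass from even flatter or even sharper
  concentration values is folded into the renormalization. Widening the
  range or refining the grid is a constructor argument away.
* Mixed linear-plus-circular feature vectors within a single state
  model are not supported; no protocol requires them.
* The d > 1 degrees-of-freedom floor is a deliberate propriety
  correction; multi-feature evidence ratios are therefore somewhat less
  extreme than an improper-prior evaluation would produce.
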