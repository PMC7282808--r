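# statemap

Bayesian hidden-state inference models of hippocampal place-field
remapping.

Place cells keep one spatial map per context and *remap* — switch maps
— when the animal treats the situation as a new context. `statemap`
implements the view that this decision is probabilistic inference over
unobservable ("hidden") states: sessions yield feature vectors
**y** = [y₁, …, y_D]; states follow a Chinese Restaurant Process prior
with concentration α (default 0.1),

    P(cₜ = k | c₁:ₜ₋₁) = mₖ / (t − 1 + α),   P(new state) = α / (t − 1 + α),

and each state's observation distribution is either multivariate normal
with a conjugate normal-Wishart prior (μ₀ = 0, κ₀ = 0.001, ν₀ = 0.02,
T₀ = 0.02·I; closed-form generalized Student-t predictive) or Von Mises
with a normal-gamma prior (μ₀ = 0, κ₀ = 0.001, a₀ = b₀ = 0.01;
marginalized by quadrature). Remapping is read off two log-odds
statistics:

* **partition evidence ratio** — log odds between two partitions of all
  observations (e.g. "one state" vs "alternating two states");
* **state evidence ratio** — log odds between two assignments of a
  single new observation (an existing state vs a novel one).

Strongly positive same-vs-novel values mean no remapping, strongly
negative mean global remapping, and values near zero mark the uncertain
regime of partial and rate remapping. The package also provides
rotational reference-direction inference for cue-rotation designs (the
offset φ maximizing the posterior predictive of **y** − φ), a Beta
population model translating an evidence ratio into fractions of cells
that do not / rate / completely remap, and seven simulation protocols
that regenerate the corresponding experimental paradigms from a config
and a seed.

It is intended for computational neuroscientists and experimentalists
who want to reason about remapping experiments — which manipulations
should produce global vs partial remapping, and how the answer depends
on experience, cue reliability and per-animal priors — with a small,
fully reproducible model.

## Worked example

Train on 20 sessions of a four-cue environment (each cue value
Gaussian, mean 0, SD 0.2), then probe with constellations in which 0,
1, 2 or all 4 cues moved to 1:

```r
library(statemap)
run_cue_constellation(seed = 1)
#> # A tibble: 4 × 6
#>   protocol          condition step quantity             value  seed
#>   <chr>             <chr>    <dbl> <chr>                <dbl> <int>
#> 1 cue_constellation 0,0,0,0      1 state_evidence_ratio 21.4      1
#> 2 cue_constellation 1,0,0,0      2 state_evidence_ratio  7.26     1
#> 3 cue_constellation 1,0,0,1      3 state_evidence_ratio  0.423    1
#> 4 cue_constellation 1,1,1,1      4 state_evidence_ratio -5.43     1
```

The unchanged probe is confidently assigned to the familiar state
(+21.4: no remapping); moving one or two cues drops the ratio toward
zero (uncertainty — the partial-remapping regime); moving all four
flips the preference to a novel state (−5.4: global remapping). No
single cue controls the map; the constellation does.

An evidence ratio maps onto a population response profile:

```r
remap_profile(-0.5)
#> <remap_profile> evidence ratio -0.5 -> Beta(1.5, 1)
#>  no remap 6% | rate remap 72% | complete remap 22%
```

a population in which 22% of fields completely remap, 72% rate-remap
and 6% keep their fields — heterogeneity characteristic of a ratio near
zero. Other protocols run the same way
(`list_protocols()` names them all), e.g.
`run_cue_rotation(seed = 1)` reports the inferred map rotation and the
same-vs-novel evidence for the three cue-card manipulations, and
`autoplot()` draws any result table.

A thin command-line wrapper is installed with the package:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/statemap.R", package="statemap"))')" \
  run alternation_learning --seed 4 --alpha 0.5 --out results/
Rscript ... list   # protocols and their default parameters
```

Each run writes the result table (CSV + JSON) and a manifest sufficient
to reproduce it exactly.

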