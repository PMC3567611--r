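# p3dif

Observer models of trial-by-trial P300 amplitude fluctuations.

The amplitude of the P300 event-related potential tracks how *surprising*
a stimulus is to the observer. In a serial two-choice task the stimulus
probabilities are never told to the observer — they are learned, trial by
trial. `p3dif` models that learning process and its electrophysiological
readout for researchers in model-based cognitive neurophysiology:

- **DIF**, a digital-filter observer whose subjective probability

  *P<sub>k</sub>(n) = α<sub>L</sub> c<sub>L,k</sub>(n) + α<sub>S</sub>
  c<sub>S,k</sub>(n) + α<sub>Δ</sub> c<sub>Δ,k</sub>(n) + 1/C*

  mixes a short-term one-pole IIR low-pass filter (time constant
  β<sub>S</sub> trials), a long-term IIR low-pass whose forgetting factor
  γ<sub>L,n</sub> = e<sup>−1/β<sub>L,n</sub></sup> sharpens with
  experience, and a fourth-order FIR high-pass tuned to stimulus
  alternations, all driven by the event indicator padded with the uniform
  prior 1/K before the block;
- **MAR**, an ideal Bayesian event counter without forgetting
  (*P<sub>k</sub>(n) = (c̃<sub>k</sub>(n)+1)/(n−1+K)*);
- **SQU**, the classic expectancy model (known global probability +
  decaying short-term count + alternation expectancy).

Each observer's Shannon surprise *I(n) = −log₂ P<sub>s(n)</sub>(n)* (or
the SQU expectancy) becomes the regressor in a three-level hierarchical
linear-Gaussian model of measured amplitudes, fitted by parametric
empirical Bayes (EM over the level variances λ<sup>(1..3)</sup>). The log
model evidence *F* supports log-Bayes-factor comparisons between the
observers; a two-iteration coordinate grid search identifies the DIF
parameters by evidence maximisation; tree tables average amplitudes by
stimulus-history patterns (aa, ba, …, bbba); and a synthetic generator
produces multi-participant datasets with the assumed statistical
structure for parameter- and model-recovery studies.

## Worked example

```r
library(p3dif)
library(dplyr)

# a synthetic 16-participant study generated by the DIF observer:
# two probability categories (0.5/0.5 and 0.3/0.7) x 192 trials,
# six sequence repetitions averaged, single-trial noise 10 uV^2
sim <- simulate_p300(sim_config(seed = 1))

fit_dif <- fit_observer(sim, "DIF")
fit_mar <- fit_observer(sim, "MAR")
fit_dif
#> <peb_fit> F = -10334.55 nats (5 EM iterations)
#>   lambda = (1.655, 0.3802, 2.44e+06)
#>   group: intercept 3.642, slope 1.020; MSE 1.6476, FVE 0.3249

log_bayes_factor(fit_dif, fit_mar)
#> # A tibble: 1 x 2
#>   log_bf evidence
#>    <dbl> <chr>
#> 1   28.2 very strong

tidy(fit_dif) |> filter(level == "group")
#> # A tibble: 2 x 5
#>   level participant term      estimate std.error
#>   <chr>       <int> <chr>        <dbl>     <dbl>
#> 1 group          NA intercept     3.64     0.169
#> 2 group          NA slope         1.02     0.169
```

The generating group parameters were 3.5 µV and 1.0 µV/bit: both sit
well within one posterior SD, the estimated trial variance λ₁ ≈ 1.66
matches the generated 10/6 ≈ 1.67 µV² after repetition averaging, and
the evidence decisively prefers the generating DIF observer over the
forgetting-free counter (log-BF ≈ 28, "very strong" being > 5).
Sequential effects survive in the amplitudes — first-order alternations
run hotter than repetitions:

```r
tree_table(filter(sim$amplitudes, category == 1), sim$sequences[[1]], orders = 0:1)
#> # A tibble: 3 x 4
#>   order pattern  mean count
#>   <int> <chr>   <dbl> <int>
#> 1     0 a        4.71  3072
#> 2     1 aa       4.65  1536
#> 3     1 ba       4.78  1520
```

`autoplot()` methods display observer traces, fitted amplitudes and
grid-search evidence surfaces; `plot_amplitude_responses()` draws the
three filter transfer functions; `plot_tree()` draws tree diagrams.

A command-line wrapper `exec/p300filter` exposes the same pipeline as
subcommands (`simulate`, `trace`, `fit`, `compare`, `gridsearch`,
`tree`); every run writes a manifest with the config hash and seed next
to its outputs.

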