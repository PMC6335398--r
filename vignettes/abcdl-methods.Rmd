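---
title: "Deep-learned SFS summaries for ABC inference of archaic introgression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deep-learned SFS summaries for ABC inference of archaic introgression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(abcdl)
```

## The inference problem

Out-of-Africa human populations carry ancestry from extinct hominins.
Beyond the well-established Neanderthal pulse into all non-Africans and the
Denisovan pulse into Oceanians, frequency-based statistics hint at a third
introgression into Asian and Oceanian populations from an unidentified
archaic group. Competing demographic explanations differ only in subtle ways
— an extra pulse here, a ghost lineage there — and no closed-form likelihood
exists for such models. `abcdl` implements likelihood-free inference for
eight competing models:

* **A** — the backbone: Out-of-Africa split, European versus Asian/Pacific
  split, Asian (East Asian / Andamanese / Indian) and Oceanian
  (Papuan / Australian) sub-splits; one Neanderthal pulse into the common
  Out-of-Africa ancestor; one Denisovan pulse into the Oceanian ancestor; a
  pulse from a deeply diverged hominin (`XD`) into Denisovans; recent
  continuous migrations AFR–EUR, EUR–ASN and PAP–AUS.
* **B** — backbone plus a non-introgressed "basal Eurasian" modern-human
  ghost (`XN`) admixing into Europeans (diluting their Neanderthal ancestry).
* **C** / **D** — a second Neanderthal / Denisovan pulse into the
  Asian-Pacific ancestor.
* **E**–**H** — an archaic ghost `XE` pulses into the Asian-Pacific
  ancestor; `XE` is a Neanderthal sister (E), a Denisova sister (F), an
  outgroup of both (G), or a Neanderthal–Denisova admixture product (H).
  E and F are exactly the H limits with the Denisovan share of `XE` pinned
  at 0 and 1, which `to_simulator_spec()` reproduces structurally.

The raw data summary is the multidimensional joint site frequency spectrum
(SFS): the count of SNPs at every combination of derived-allele counts
across nine sampled populations (seven modern groups, the Altai Neanderthal
and the Denisovan, one diploid each, so every axis has three classes and the
spectrum has $3^9 = 19{,}683$ cells). The method compresses this spectrum
with a small feedforward network into a handful of learned summary
statistics (SS-DL) and runs classical ABC on those.

## The simulator

No coalescent engine with the needed event repertoire exists in the
dependency stack, so the package ships its own structured-coalescent
simulator (Rcpp). Demes carry diploid sizes and a backward migration-rate
matrix; instantaneous events are mass lineage movements (pulses with
probability $f$, splits with probability 1, admixed origins as two ordered
movements), size changes and migration-rate changes. Mutations are dropped
on branches as a Poisson process and reduced on the fly either to the joint
SFS or to per-site genotypes.

**Recombination.** Each genomic region is simulated as independent
non-recombining segments (default 50 kb, configurable per call). The SFS is
insensitive to recombination in expectation, so this approximation affects
only cross-site correlation — equivalently the effective number of
independent genealogies. Where that granularity matters (jackknife standard
errors of D statistics), analyses use 5–10 kb segments, closer to the scale
over which human genealogies decorrelate.

**Mutation-rate jitter.** Each simulation draws one genome-wide rate
$\mu \sim N(1.61\times10^{-8}, 0.13\times10^{-8})$ per bp per generation,
truncated at zero, and each region scales it by its callable fraction,
$\mu_r = \mu\, L_c / L_r$ (a per-region redraw is available via
`mu_per_region`). The default region set is 9,643 regions totalling 651 Mb;
`region_table(scale)` shrinks the count proportionally for desk-scale work.

**Units.** All internal times are generations; configuration given in years
is converted at 29 years per generation. Archaic sampling ages default to 0
(co-sampled with moderns) and are configurable; `to_simulator_spec()`
rejects event times that predate a sample's age.

## Priors and constraints

The priors are wide uniforms on split and pulse times chosen to contain the
published 95% credible intervals with generous margin; effective sizes are
log-uniform on $[10^2, 10^5]$ diploids; archaic pulse fractions uniform on
$[0, 0.2]$; the `XE` origin mixture uniform on $[0, 1]$; migration rates
(stated nowhere in the source material) log-uniform on
$[10^{-6}, 10^{-3}]$ per generation. Ordering constraints (e.g. the
Neanderthal–Denisova split predating the hominin root, every pulse falling
inside the interval during which its target deme exists) are encoded
explicitly and enforced by rejection resampling, so priors stay independent
and no draw is clipped post hoc.

`published_point_estimates()` carries the posterior-mean calibration of the
two best-supported models (F and H) in the literature, completed with
literature-standard effective sizes (African 24k, other moderns 5–10k,
archaic lineages 2.5k, ancestral demes 5–15k diploids) and nominal
$5\times10^{-5}$ migration. These sizes were fixed a priori; the
posterior-predictive D check below inherits whatever misfit they carry.

## The network

A four-layer feedforward net (input, two hidden layers, output) maps the
flattened spectrum to either per-model softmax scores (model choice) or
per-parameter predictions (estimation). Defaults and the reasoning behind
them:

* **Input normalization** — each spectrum is divided by its included-cell
  total (the two corner cells are excluded by policy, since fixed cells are
  dominated by polarization error on real data), then z-scored per cell
  against training statistics. This removes dependence on the total
  segregating-site count, which the mutation-rate jitter randomizes anyway.
  `normalize = "raw"` keeps the totals (still z-scored); single-population
  controls need it, because there the size signal *is* the total.
* **Architecture** — hidden sizes follow geometric compression of the input
  (⌈p/3⌉, ⌈p/9⌉) but are capped at (64, 24): an uncapped first hidden layer
  on the 19,683-cell spectrum would carry $>10^8$ weights, which desk-scale
  training cannot support. ReLU activations, He initialization.
* **Optimizer** — minibatch Adam (lr $10^{-3}$, batch 64) with early
  stopping on an internal 20% held-out split (patience 8). The original
  implementation used resilient propagation; any robust first-order method
  satisfies the contract, which is the held-out metric, not the trajectory.
* **Noise injection** — during training each record is mixed cellwise with
  a reference spectrum, $(1-\alpha)\,\mathrm{sim} + \alpha\,\mathrm{ref}$,
  $\alpha \sim U(0, 0.2)$ redrawn per record per epoch, on raw counts before
  normalization. The reference is the observed "noise half" (below); in pure
  simulation studies the mean of one point-estimate simulation per model
  stands in. With `alpha_max = 0` training is bit-identical to classical
  training. White noise is deliberately not used: SFS cells are strongly
  correlated, violating its independence premise.
* **Regression targets** — z-scored internally; size and migration
  parameters are learned on the log scale (matching their log-uniform
  priors) and back-transformed on prediction. Constant targets are an error.

## The ABC step

Observed cohorts carry two diploids per modern population. One diploid per
population forms the **noise half** (the noise-injection reference), the
other the **target half** (the ABC observation); the single archaic
individuals are shared by both halves. Both halves therefore have the same
one-diploid-per-population axis layout as the simulations.

Rejection retains the `n_accept` simulations nearest the observed SS-DL —
the canonical error threshold is 1,000 of 100,000; reduced runs keep a
proportionally larger acceptance fraction (default 25% at a few hundred
simulations per model) so the downstream regressions have support. Distances
are Euclidean after per-coordinate standardization by the median absolute
deviation (robust to the heavy-tailed summaries the softmax head can
produce; degenerate MADs fall back to the standard deviation, then 1). Ties
at the acceptance boundary break by simulation index, making the step fully
deterministic.

Model posteriors come from a multinomial-logistic regression of the label on
the SS-DL over the accepted set (`nnet::multinom`), evaluated at the
observed summary, falling back to rejection frequencies on degenerate fits.
Parameter posteriors use the classical local-linear adjustment: Epanechnikov
kernel weights on acceptance distance, a weighted linear fit per parameter,
and the adjustment $\theta^* = \theta - b^\top(s - s_{obs})$, applied on a
logit scale for proportions and a log scale for sizes and rates so adjusted
draws respect their bounds. Summaries report the weighted mean and weighted
2.5%/97.5% quantiles.

## D statistics

`patterson_d()` implements the frequency-based statistic
$D = \sum(w-x)(y-z) \,/\, \sum(w+x-2wx)(y+z-2yz)$ with the ancestral
outgroup as a constant-zero frequency column, listwise site deletion per
quadruple, and Busing-style weighted block-jackknife standard errors over
equal-span physical blocks (default 555). The sign convention makes
`D(AFR, ASN, NEAN, Ancestral)` negative when East Asians share excess
derived alleles with the Neanderthal. `fit_introgression()` matches observed
D vectors to simulation means over a grid of pulse fractions via bounded
scalar minimization (one fraction) or L-BFGS-B (two), with common random
numbers across objective evaluations.

## Desk-scale study conditions

The full-scale conditions (651 Mb per simulation, $10^5$ simulations,
networks on the complete spectrum) are far beyond a single-CPU desk run, so
the shipped tests and the acceptance script use reduced configurations,
chosen once:

* **Confusion study** — 8 models, ~2.5 Mb per simulation
  (`scale = 0.0038`), 250 (tests) / 400 (acceptance script) simulations per
  model, 12 pseudo-observed datasets per model, 25% acceptance, hidden
  layers (32, 12). At this
  sequence scale the eight-way classification signal is weak: measured
  held-out accuracies are ~0.18–0.24 (chance 0.125) and rise only to ~0.29
  at 13 Mb, while the pairwise backbone-versus-admixed-ghost contrast
  reaches ~0.6. Diagonal self-assignment probabilities above 0.5, as
  obtained at full scale, are not reachable at desk scale; the package
  reports the honest reduced-scale values.
* **Posterior-predictive D** — 500 replicates of 13 Mb at the model-H point
  estimates (Monte-Carlo standard error ≈ 0.004 per statistic). Sixteen of
  the seventeen quadruples reproduce the published sign and the orderings
  (Oceanian contrasts strongest, dearth-of-African-ancestry contrasts
  positive); absolute agreement inherits the uncertainty of the unpublished
  effective-size calibration.
* **Coverage control** — a single-population size-estimation pipeline
  (1,200 training simulations of 200 kb, 100 pseudo-observed runs) in which
  the 95% credible intervals cover the generating size in ≳90% of runs.

## What the synthetic data do and do not show

`generate_toy_cohort()` emulates the cohort layout of the real panels (two
diploids per modern population, one per archaic, ancestral-allele
annotation, phased genotypes, equal-span jackknife blocks) with known ground
truth. It does not emulate: sequencing or genotyping error, polarization
error from chimpanzee alignment, mapability masks, variable recombination or
mutation-rate landscapes, or linked selection. Passing tests therefore
demonstrate correctness of the machinery and internal calibration under the
model class — not robustness to the artefacts of real resequencing data,
which is precisely the gap the noise-injection mechanism is designed to
soften.

## Numerical choices and degenerate inputs

Zero-fraction pulses are pruned from simulator specs (identical to the
event's absence); an admixed origin with a pinned fraction emits only its
surviving branch. Jackknife delete-one estimates that are undefined (0/0
ratios) are excluded from the variance with a warning; an all-identical
accepted set short-circuits the local-linear adjustment to the unadjusted
draws. Empty cohorts still write valid VCF headers. The engine refuses
configurations whose lineages cannot reach a common ancestor, rather than
looping forever. Manifest hashes serialize configurations in version-2
format so they are pure functions of content.

## Known limitations

* Independent-segment recombination understates linkage at scales above the
  segment length; jackknife standard errors are honest only when blocks are
  at least as coarse as segments.
* The desk-scale confusion study cannot reproduce full-scale model
  separability (see above); treat its diagonals as a lower bound.
* Ghost-population sizes are weakly identified (their held-out regression
  correlations are markedly lower than sampled-population sizes) — an
  expected property, reproduced by the test suite, not a defect.
* Observed-data ingestion assumes biallelic, AA-annotated, diploid VCF
  records; multi-allelic sites and haploid calls are out of scope.
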