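---
title: "Background selection and the inference of population history"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Background selection and the inference of population history}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bgsdemog)
```

## The problem

Demographic inference from polymorphism data almost universally assumes that
the analysed sites are neutral and unaffected by selection at linked sites.
In real genomes, purifying selection on functional elements removes linked
neutral variation (background selection, BGS) and skews the site frequency
spectrum (SFS) towards rare alleles. Both signatures mimic population
growth, so an equilibrium or even a declining population can be confidently
mis-inferred as a growing one. `bgsdemog` provides the machinery to quantify
this bias and a correction: simulators that generate genomes with a
parametric distribution of fitness effects (DFE), analytical predictions of
diversity and of the SFS under size change with BGS, an SFS
model-selection fitter, and an approximate Bayesian computation (ABC)
method that treats the DFE as a nuisance parameter so that demographic
parameters can be estimated from directly selected sites.

## Genome architecture and the DFE

Simulated chromosomes are tiled with identical genes (by default eight
350-bp exons separated by seven introns) and intergenic tracts; intron and
intergenic lengths control the fraction of the genome under direct
selection. The presets `genome5`, `genome10` and `genome20` give roughly 5,
10 and 20% exonic sequence on a ~150 Mb chromosome. The gene count is
`round(target / (gene + intergenic))`, with a leading intergenic tract and
the final tract one base short; these rules give chromosomes of
150,018,599, 150,029,949 and 150,003,699 bp with 2,737, 5,164 and 11,278
genes.

Fitness effects of exonic mutations follow a discrete DFE with four classes
of the scaled selection coefficient `2 * N_anc * s`: effectively neutral
[0, 1), weakly [1, 10), moderately [10, 100) and strongly deleterious
[100, 2 * N_anc), with proportions `f0..f3` and `s` uniform within each
class. `s` is the homozygous fitness reduction; mutations are semidominant
(h = 0.5) and fitness is multiplicative across sites. The size anchoring
the bins is always the *ancestral* population size. Six named presets
(`DFE1`..`DFE6`) cover weak-, moderate- and strong-selection dominated
shapes, a uniform shape, and two neutral+strong bimodal shapes.

```{r}
genome_layout_preset("genome20")
dfe_preset("DFE2", n_anc = 5000)
```

## Simulation engines

Two engines share the same demography objects (piecewise histories with
constant and exponential epochs, plus instantaneous bottleneck "pulses").

The **forward Wright–Fisher engine** is diploid with random mating,
genotype fitnesses `1, 1 - s/2, 1 - s`, and a finite-sites mutation model:
at most one segregating mutation per site, a mutation arising at an
occupied site is redrawn, and back mutation is disallowed. Every run starts
with a burn-in of `10 * N_anc` generations before the demographic epochs;
fixations after the burn-in are recorded so divergence can be computed as
fixations per site per generation. Site collisions are vanishingly rare at
the diversities simulated here and have no effect at the SFS level.

The **neutral coalescent engine** exists for calibration and for the
analytic cross-checks. Recombination is handled by splitting the sequence
into chunks simulated as independent non-recombining loci, with the default
chunk length set so `4*N*r*chunk ≈ 1`. This leaves every mean (diversity,
segregating sites, SFS class proportions) exact and only approximates
linkage across chunk boundaries; it is not suitable for long-range LD
studies, which is why the forward engine is authoritative whenever
selection or fine-scale LD matters. The two engines are
distribution-identical at `r = 0` with a single chunk, which is how their
agreement is tested.

Rescaling by a factor `Q` (`N/Q, sQ, muQ, rQ, t/Q`) preserves `4Nmu`,
`4Nr` and `2Ns` and is applied inside `sim_forward()`; desk-scale work uses
`Q` such that scaled `N` stays in the hundreds.

Two burn-in initialisations are available. The default (`init = "founder"`)
starts from a monomorphic population and runs the full `10 * N_anc`
generations. The speed mode (`init = "coalescent"`) seeds the population
with a neutral-coalescent equilibrium sample of `2 N_anc` haplotypes and
runs a `2 * N_anc`-generation forward burn during which selected-site
frequencies reach mutation–selection balance. The speed mode is appropriate
when direct selection is strong relative to `1/(2N)` and within-region BGS
is weak (short exons); with an appreciable effectively-neutral-to-weak DFE
mass it retains slightly more mid-frequency variation than the full
burn-in, which is why it is off by default and why studies that use it
apply it identically to every data set being compared.

## Analytical theory

**Expected SFS.** For an arbitrary piecewise history the expected number of
sites with `b` derived copies is computed from the classical
time-inhomogeneous coalescent: the expected time during which the sample
has `k` ancestral lineages is a signed combination of the exponential
functionals `e_j = ∫ exp(-C(j,2) Ω(t)) dt`, where `Ω(t) = ∫ dt / (2N(t))`,
and a mutation on a branch while `k` lineages remain subtends `b` leaves
with probability `C(n-b-1, k-2)/C(n-1, k-1)`. Exponential epochs are
discretised into ≥50 piecewise-constant steps on a geometric grid, doubling
until the spectrum changes by less than `1e-4`. The alternating-sign
coefficients limit reliable sample sizes to roughly `n ≤ 50` in double
precision; the default (and tested) sample size is `n = 20`, and a warning
is issued beyond 50. At constant size the computation reduces exactly to
the `1/b` law, which is used as a unit test.

**B as pure rescaling.** BGS enters the theory only by multiplying every
population size by `B = pi/pi0`; it never reshapes the spectrum directly.
Under equilibrium this is exact for diversity; under size change it yields
the *apparent* B:

`Bhat(t) = pi_sel(t) / pi_neu(t)`

where both trajectories are the neutral pairwise-diversity solutions
(`pi(t) = 2 mu E[T2]`) with sizes multiplied by `B0` (the ancestral
equilibrium value) and by 1 respectively. For a step change `N0 -> N1`,

`pi(t) ∝ B [N1 + (N0 - N1) exp(-t / (2 B N1))]`.

Because a smaller effective size responds faster to size change, the
apparent B dips below `B0` for a transient period after a decline and rises
above it after growth, returning to `B0` at both `t = 0` and `t -> ∞`.
This rescaling construction is validated against the forward simulator in
the test suite rather than assumed.

**Equilibrium B.** The classical deterministic prediction
`B = exp(-Σ u t / (t + r(1-t))^2)` (heterozygous effect `t = s/2`,
recombination fraction by the Haldane map) is integrated over the DFE by
16-point Gauss–Legendre quadrature per class. The formula assumes
`2Ns >> 1`; when more than 1% of the DFE mass lies below `2Ns = 10` the
result is flagged (`weak_selection_warning`), and simulation should be
used instead.

## SFS fitting and model selection

Four one-population models are fitted by maximising a multinomial composite
likelihood over SFS classes: equilibrium (k = 1), instantaneous change,
exponential change, and an instantaneous bottleneck (all k = 3). Bounds are
uniform 100–500,000 diploids for sizes, 100–10,000 generations for times,
log-uniform 1e-5–2 for the bottleneck intensity, which is defined as an
instantaneous pulse of pairwise coalescent intensity `I` (a pair coalesces
during the pulse with probability `1 - exp(-I)`). Including the monomorphic
class (the default, with a known per-site mutation rate) makes absolute
sizes identifiable; without it only the SFS shape is used. Optimisation is
bounded, derivative-free multistart (`nlminb` on log-scale parameters,
50 seeded restarts by default); ties in model choice break towards the
smaller AIC and then model order. Model choice uses Akaike weights
`w_i ∝ exp(-Δ_i/2)` with either the standard penalty of 2 per parameter or
a stricter penalty of 25, which compensates for the non-independence of
linked SNPs that otherwise rewards parameter-rich models. After SNP
thinning to a minimum spacing, the monomorphic class is scaled down by the
realised kept fraction so both classes describe the same thinned site set.

## Nuisance-DFE ABC

The correction for selection bias treats the DFE as a nuisance parameter:
reference-table rows draw `(N_anc, N_cur)` uniformly and a DFE from the
lattice of four-class proportion vectors in steps of 0.05 (1,771 shapes),
then forward-simulate a set of unlinked exons under a one-epoch exponential
size change and record 22 summary statistics (means and between-exon
variances of diversity, Watterson's theta, Tajima's D, Fay & Wu's H
absolute and normalised, singletons, haplotype diversity, mean pairwise
r², D and D', and divergence). Observed data are compared by Euclidean
distance on MAD-standardised statistics, the nearest 10% of rows are
accepted, and a single-hidden-layer neural-network regression (width 5,
10 restarts, Epanechnikov weights, log-scale sizes) adjusts the accepted
draws to the observed statistics, falling back to local-linear and then to
rejection-only adjustment on degeneracy; when prior bounds are supplied the
regression works on a logit-rescaled parameter so adjusted draws respect
the prior support. Point estimates are weighted posterior medians. The
defaults mirror a Drosophila-like setting (94 exons of 1.5 kb, mu = 3e-9,
sizes 1e5–1e7, change time 1e6 generations, Q = 320); zero-spread
statistics are dropped from the distance with a warning, and failed
simulation rows are dropped, never imputed.

Two practical notes on the adjustment, from the package's reduced-scale
experiments. First, with reference tables of a few hundred rows (tens of
accepted draws against 22 statistics) the regression step is
variance-dominated: rejection-mode posteriors give the more reliable point
estimates, and the recovery experiment in the test suite reports those.
Second, when observed data violate the model family of the reference table
— the neutral-assumption mode applied to data from selected sites — the
observed statistics can fall outside the table's statistic manifold
entirely (diversity below anything a neutral history inside the prior can
produce). Rejection then collapses onto the nearest prior corner, and only
the regression adjustment, extrapolating along the learned
statistic-parameter gradients, expresses the characteristic bias: current
size inflated relative to ancestral (spurious growth) with both sizes
underestimated.

## Numerical and design choices

* Coordinates are 0-based half-open everywhere; conversions to 1-based
  formats (VCF, multihetsep) are isolated in the writers.
* The coalescent chunk approximation trades long-range LD for speed; means
  are unaffected (see above).
* Fixation bookkeeping in the forward engine scans the population every
  8 generations; fixation times are therefore resolved to that interval.
* The DFE lattice step, neural-net width/restarts, pair caps for LD
  statistics, and all engine parameters are configurable; defaults are
  stated in the function documentation.
* Demography presets (equilibrium N = 10,000; 30-fold exponential growth
  1,000 → 30,000 over 850 generations; ~6-fold step decline
  12,300 → 2,100 at 2,000 generations; 2-fold variants) are package
  defaults in the spirit of published human-history estimates, not
  calibrated reproductions.

## Problem sizes used by the test suite

The package's experiments are exercised at desk scale: calibration targets
use the standard neutral calibration parameters directly (N = 5,000, mu = r = 1e-8, up
to 1 Gb via chunking); the selection experiments run with scaled
populations of a few hundred diploids (Q chosen accordingly), chromosomes
of ~1–2 Mb at 20% functional density for the false-growth experiment, a
300 kb region with a central 100 kb selected block for the apparent-B
experiment, and a reduced ABC recovery experiment: 24 unlinked exons of
1.5 kb (versus 94 at full scale) with per-exon scaled mutation and
recombination rates matching the fly-like setting (`theta` of roughly
5e-3 to 1e-2 per site, `rho` of 20-190 per exon), a uniform size prior of
60-250 scaled diploids, 2-fold exponential changes over 300 generations,
a 400-row nuisance reference table (150 neutral), and the
coalescent-seeded burn-in applied identically to table rows and test
sets. These sizes are the package's own choices for
a single-CPU workflow; the same code runs the full-scale configurations by
changing the arguments.

## What the synthetic data does and does not emulate

The generators reproduce: discrete-DFE purifying selection with
semidominance, human-like exon/intron/intergenic architecture, piecewise
demographies, heterogeneous recombination/mutation maps, centromere and
repeat masking, and SNP thinning. They deliberately omit: positive
selection and sweeps, crossover interference and gene conversion, dominance
other than 0.5, ancestral-state misidentification, genotyping or phasing
error, and population structure. Passing tests therefore demonstrate
correctness of the implemented model, not robustness of inference to these
additional realities.

## Known limitations

* The expected-SFS computation is numerically unreliable beyond `n ≈ 50`
  haplotypes (inherent to the alternating sums); fit SFS data with
  moderate sample sizes or subsample.
* The deterministic equilibrium-B formula overpredicts BGS under weak
  selection (`2Ns < 10`); the flag should be respected.
* The apparent-B construction is a pure rescaling model; interference
  among selected sites and selection-driven SFS distortions are outside
  its scope and show up as (small) systematic deviations from forward
  simulation under strong selection.
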