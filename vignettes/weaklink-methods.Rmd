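---
title: "Models and methods in weaklink"
author: "weaklink authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in weaklink}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(weaklink)
```

# Scope

`weaklink` implements the quantitative analyses used in laboratory-evolution
studies of a "weak-link" enzyme — an inefficient, newly recruited activity
that limits flux through an essential pathway and hence growth. Four
measurement pipelines (turbidostat and plate-reader growth, qPCR copy
number and expression, two-colour competitive fitness, enzyme kinetics)
sit alongside a stochastic simulator of tandem-array
amplification-divergence dynamics, and a synthetic-data module that
generates every input class with known ground truth.

# Growth dynamics

## Turbidostat traces

A turbidostat holds a culture at a target optical density by periodic
dilution, so cells grow exponentially inside each dilution cycle. With
$N_{t_0}$ the OD reading right after a dilution and $N_{t_1}$ the reading
right before the next one,

$$\mu_i = \frac{\ln(N_{t_1,i}/N_{t_0,i})}{t_{1,i} - t_{0,i}},$$

one estimate per cycle, averaged into a daily mean $\bar\mu$ (h$^{-1}$) and
converted to generations per day via $g = 24\,\bar\mu/\ln 2$. Both formulas
are implemented with the natural logarithm; this is the only reading that
yields h$^{-1}$ units, a doubling time of $\ln 2/\mu$, and daily generation
counts on the scale such experiments report (a $\bar\mu$ of 0.27 h$^{-1}$
gives 9.35 generations/day).

Practical choices:

* **Cycle segmentation.** Explicit dilution marks are used when present;
  otherwise boundaries are detected as relative OD drops exceeding 2%
  (configurable). A mark that does not coincide with a local OD drop
  triggers a warning rather than an error, because at fast dilution
  cadences (e.g. one small dilution per minute) the per-cycle drop is
  legitimately smaller than instrument noise.
* **Outliers.** Cycles whose rate lies beyond 4 standard deviations of the
  day's distribution are excluded (configurable, `Inf` disables); brief
  instrument failures otherwise contaminate daily means.
* **Statistical limits.** With 1% multiplicative reading noise and
  one-minute cycles, each cycle spans only ~0.5% of growth, so a single
  per-cycle rate is noise-dominated and only long averages are
  informative. The recovery tests therefore use hour-long synthetic cycles,
  where each cycle carries ~25% growth and the daily mean recovers the true
  rate to well under 2%.

## Plate-reader growth curves

Baseline-subtracted growth curves are fit by nonlinear least squares
(Levenberg–Marquardt, `minpack.lm`) to the modified Gompertz form

$$y(t) = A \exp\!\left\{-\exp\!\left[\frac{\mu_{max} e}{A}(\lambda - t) + 1\right]\right\},$$

in which $\mu_{max}$ is the maximum slope of the curve, $\lambda$ the
intercept of the inflection tangent with the baseline (lag time), and $A$
the maximum growth. The baseline is the mean of the first 5 points after a
width-3 moving-average smoother (both configurable). Initial values come
directly from the tangent geometry: $\mu_{max}^{(0)}$ is the maximum
smoothed slope, $\lambda^{(0)}$ the tangent's baseline intercept,
$A^{(0)}$ the maximum of the curve; all parameters are bounded below by 0.
On noise-free Gompertz data without baseline the fit recovers the
generating parameters to better than $10^{-4}$ relative; with baseline
estimation, exactness is limited by the small true growth inside the
baseline window (order $10^{-4}$ relative on $\mu_{max}$).

# qPCR relative quantification

Primer efficiency is estimated per primer set from a dilution-series
standard curve: the slope $m$ of Ct against $\log_{10}$ quantity gives
$E = 10^{-1/m}$, with $E = 2$ perfect doubling. Efficiencies outside
$(1, 2.2]$ warn; non-negative slopes are errors.

The target quantity in a sample relative to a calibrator, normalised by
reference genes $r$, is

$$n = \frac{E_{tgt}^{\Delta Ct_{tgt}}}{C\left(E_{r}^{\Delta Ct_{r}}\right)},
\qquad \Delta Ct_x = Ct(\text{calibrator}, x) - Ct(\text{sample}, x),$$

so an amplified or over-expressed target ($Ct$ earlier in the sample) gives
$n > 1$. For several reference genes the combination $C$ is the geometric
mean by default — the standard multi-reference normalisation, which keeps
$n$ on the scale of a single typical reference. A plain-product mode is
provided because the literal formula with two references can also be read
as a product; with a single reference the two modes coincide. Replicate
Cts are averaged per (sample, primer) before $\Delta Ct$, with a QC
warning when the replicate range exceeds 0.5 cycles.

# Competitive fitness

From two-colour (e.g. YFP/CFP) counts with $R$ the test/reference ratio and
$t$ the number of generations,

$$w = \frac{\ln\!\big(R(t)/R(0)\big)}{t} + 1,$$

so neutrality gives exactly $w = 1$. The generations input is not fixed by
the assay itself; `estimate_generations()` provides the default reading —
total population doublings across all passages,
$t = \log_2(\text{final} \cdot D / \text{initial})$ — and an explicit value
can always be supplied. Raw $w$ is divided by the $w$ of a
label-vs-label control competition (division, not subtraction, so a
label cost cancels multiplicatively and neutral stays at 1). A Poisson
counting-error standard error is reported by the delta method
($\mathrm{var}\,\ln R \approx \sum 1/n$) and is never used to filter.

# Enzyme kinetics

## Burst-phase progress curves

Semialdehyde substrates equilibrate with unreactive hydrated (and cyclic)
forms; only a small free-aldehyde fraction reacts. In an NADPH-monitored
progress curve the free aldehyde is consumed in a rapid burst and the
linear tail is limited by dehydration, so

$$f(x) = m x + b(1 - e^{-x}) \quad\text{or}\quad f(x) = m x + b$$

with $x$ in seconds, $m$ the linear slope and $b$ the burst magnitude. The
exponential form is taken as printed, with a unit time constant; because
$e^{-x}$ is then a fixed regressor, the fit is ordinary least squares. An
optional third parameter $k$ in $b(1 - e^{-kx})$ is available and off by
default. The linear form is fit only inside a user-given window; absent a
window, the longest suffix of the curve whose straight-line fit has
$R^2 \ge 0.995$ is used. The free fraction is
$\big(b/(\varepsilon \ell)\big) / [S]_{tot}$ with
$\varepsilon_{340} = 6220$ M$^{-1}$cm$^{-1}$ for NADPH (the standard value,
configurable). Negative fitted bursts clamp the fraction to 0 with a
warning.

## Michaelis–Menten and allosteric titrations

Initial rates are fit unweighted, replicates individually, to
$v = V_{max} S/(K_M + S)$; $k_{cat} = V_{max}/[E]_0$, and the standard
error of $k_{cat}/K_M$ uses the full fit covariance. Where the substrate is
mostly hydrated, concentrations must be on the free-aldehyde basis
(total times the burst-derived fraction) before fitting. Effector
titrations are fit to the hyperbolic two-state form

$$v/v_0 = \frac{aL + K_d}{L + K_d},$$

which is exactly 1 at $L = 0$ and approaches the asymptote $a$ at
saturation ($a<1$ inhibitor, $a>1$ activator). Flat responses (fitted
$|a - 1| < 0.02$, or non-convergence) are returned as $a = 1$ with $K_d$
flagged not determined, mirroring how unmeasurably weak regulation is
reported in practice. Derived statistics (fold-changes, percent changes,
the citrulline colorimetric conversion at
$\varepsilon_{464} = 37800$ M$^{-1}$cm$^{-1}$, the two-ATP coupling ratio
of carbamoyl phosphate synthetase) are plain arithmetic helpers, reported
at the field's customary precision (efficiencies 3 significant figures,
fold-changes 2).

# The amplification–divergence simulator

## Model

Each cell carries a tandem array of $k$ gene copies ($1 \le k \le k_{max}$,
default 20), $j$ of them the beneficial mutant allele. The population is a
count vector over all $(k, j)$ classes, evolved in discrete Wright–Fisher
generations (the natural time unit when everything observable is reported
in generations):

1. **Selection.** Expected offspring of class $g$ are proportional to
   $n_g e^{\mu_g \Delta t}$, with $\Delta t = \ln 2 / \max_g \mu_g$ so the
   fittest occupied class doubles per generation. The default fitness map
   is proportional dosage,
   $\mu = \mu_0 (1 + s_{max}\, j/k) - c\,(k-1)$, anchored at the parental
   rate $\mu_0 = 0.24$ h$^{-1}$ and a +75% benefit for a fully mutant
   array; a saturating mode
   ($\mu = \mu_0(1 + s_{max} A/(A + K_{1/2}))$ with per-copy activities) is
   provided because the true dosage-response is not known. The per-copy
   cost $c$ defaults to 0; it enables, but does not assert, cost-driven
   deamplification after a sweep.
2. **Mutation.** Each class emits to $(k, j+1)$ at the per-array rate
   $(k-j)\,\mu_{gene}$ (exact form $1-(1-\mu_{gene})^{k-j}$ when
   $\mu_{gene} > 10^{-3}$). The default $\mu_{gene} = 10^{-6}$ per copy per
   division is the upper literature bound for a ~1 kb gene at
   $10^{-9}$/nt/division.
3. **Recombination.** A fraction `rec_rate` (default 0.01 — homologous
   recombination acts on roughly 1 of every 100 divisions) of each
   $k \ge 2$ class is redrawn through a homogenization kernel: the event
   duplicates the array to a $2k$-copy pool with $2j$ mutant copies, draws
   a copy-number change $\delta \in \{-1, 0, +1\}$ (default probabilities
   0.25/0.50/0.25), and samples the daughter's $j'$ hypergeometrically from
   the pool. This kernel is a modelling choice — the biology constrains
   only the rate and the facts that recombination cannot create or destroy
   allele identity ($j = 0$ and $j = k$ are absorbing under recombination
   alone) — and it is deliberately swappable via `copy_change_probs`.
4. **Resampling.** Multinomial resampling to constant $N$ (default
   $10^5$).

Because mutation and recombination are linear maps on the expected
composition and resampling is a single multinomial draw, the class-based
engine is equal in distribution to an agent-based scheme that resamples at
selection and transitions each cell independently; the test suite verifies
this against an explicitly written agent-based oracle on small instances,
and checks the neutral martingale property, the deterministic haploid
selection recursion ($\Delta\,\mathrm{logit} = \ln(1+s)$ per generation),
and a transition-matrix absorption-time oracle for single-lineage
homogenization.

The default scenario starts amplified (one $(7,1)$ founder cell in a
$(7,0)$ population), reflecting that the initial duplication precedes the
divergence phase being studied; an explicit multi-copy initial state can be
supplied for other designs.

## Reproducibility

Replicates are seeded independently with a deterministic integer derived
from `(seed, replicate)`, so runs are bit-reproducible and replicates can
be computed in any order or subset. (A counter-based generator keyed
additionally by generation would allow intra-replicate jumping; base R's
generators do not support counter mode, and per-replicate derivation
provides the properties that matter here.)

## What the default run shows

With the default parameters, sweeps conditioned on fixation show fully
mutant arrays first appearing around generation 80–120 and population-wide
loss of heterozygosity (every mutant-carrying cell fully mutant) at median
generation ~350 — comfortably inside the ~500 generations over which array
heterozygosity was observed to disappear in vivo. A companion
branching-process calculation fed by the recorded trajectories confirms
the rate argument embodied in the model: a second, independent beneficial
mutation in another copy of an amplified array (opportunity
$\approx$ wild-type copies in carrier arrays $\times\ 10^{-6}$) essentially
never establishes and reaches 1% frequency before recombination has
homogenized the arrays.

# Synthetic data

Every estimator input can be generated with known ground truth:
exponential-growth sawtooth traces with multiplicative lognormal OD noise
(default $\sigma = 1\%$); Gompertz curves with additive noise (0.002 OD);
Ct tables from $Ct = \text{intercept} - \log_E(\text{quantity})$ with
Gaussian Ct noise (0.15 cycles); two-strain deterministic exponential
competitions with multinomially sampled counts ($10^4$ events per
channel); burst progress curves with additive absorbance noise (0.002 A);
Michaelis–Menten and effector-titration rates with proportional noise
(5%), in triplicate. The noise defaults are plausible bench magnitudes,
chosen once; all are configurable. `fixture_suite()` writes one
deterministic fixture per kind plus a JSON manifest of true parameters,
byte-identical for a given seed.

What passing recovery tests do **not** show about real data: the
generators draw independent Gaussian/lognormal/multinomial noise around the
exact model. Real traces have autocorrelated drift, plate effects,
pipetting covariance between replicates, evaporation late in long runs,
and model misspecification (e.g. a genuinely non-unit burst time constant);
none of these are emulated, so recovery here bounds estimator correctness,
not field accuracy.

# Numerical choices and problem sizes

* Nonlinear fits use Levenberg–Marquardt with parameter lower bounds at 0
  and data-driven starts (described per estimator above); non-convergence
  is an error carrying the optimizer message, except for the allosteric
  fit, where it maps to the flagged flat-response result.
* Monte-Carlo test sizes were chosen to keep the default suite fast while
  leaving clear margins: 50–200 replicates per recovery experiment,
  $10^5$ draws for kernel frequencies, 200 simulator replicates for the
  sweep-time summary, 30–100 cells and $\le 4 \times 10^3$ replicates for
  the agent-based comparisons. Tolerances in the tests are 3-sigma bands
  for stochastic checks and optimizer-level ($10^{-4}$–$10^{-6}$) for
  noise-free self-consistency.
* All randomness flows from explicit integer seeds; derived seeds stay
  below $2^{31} - 1$.

# Known limitations

* The simulator is single-locus and ignores clonal interference from other
  beneficial mutations elsewhere in the genome, which the underlying
  experiments clearly exhibit; it is a model of the array dynamics in
  isolation.
* The recombination kernel abstracts inter-chromosomal and intramolecular
  exchange into one event type with a fixed copy-number-change law.
* The qPCR module consumes called Ct values; it does not process raw
  fluorescence, and absolute quantification is out of scope.
* Progress-curve fitting covers the two-phase burst forms only — no global
  ODE fitting of coupled assays.
* Fitness estimation consumes gated label counts; gating and compensation
  belong upstream.
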