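---
title: "Methods: deuterium tracing of reductive dehalogenation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: deuterium tracing of reductive dehalogenation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(deutrace)
```

## The measurement and its model

A reductive dehalogenase replaces one halogen of its substrate with a
hydrogen atom. When the assay water contains D2O, a fraction of the
product molecules carries deuterium at that newly formed position, and at
unit mass resolution this fraction is read off the first isotopologue
peak pair of the product's molecular ion: with A1 the extracted-ion area
at the nominal molecular-ion m/z and B1 the area one unit higher,

$$\mathrm{DD1} = \frac{B1}{A1 + B1}.$$

`deutrace` models the whole chain from a hypothesised labelling history to
the peak areas, so that every analysis step can be tested against a
synthetic ground truth, and so that the inverse questions — what
fractionation factor, what membrane exchange rate — can be answered by
fitting.

### Isotopologue envelopes

Envelopes are computed on integer nominal mass-shift bins (bin width
1 Da), matching unit-resolution quadrupole data; exact-mass fine
structure is deliberately out of scope. The envelope of a formula is the
convolution of its per-element isotope distributions; the element table
(C, H, D, O, N, Cl, Br; IUPAC 2021 masses and abundances) is embedded and
can be overridden through the `tab` argument of every pattern function,
which the tests use to build hypothetical single-isotope elements.
Patterns are truncated at `max_shift = 6` after all convolutions (a
single truncation, so renormalisation does not compound) and the
discarded tail is recorded; for the shipped product formulas the tail is
below 1e-4.

Two identities matter downstream. The dibromophenol ion C6H4Br2O has
nominal molecular-ion m/z 250 and an M+2/M ratio near 1.95 (two bromines);
trichlorobenzene C6H3Cl3 sits at m/z 180. The product ion is modelled as
the free phenol: the acetyl derivative formed during sample preparation
loses its acetyl group under electron ionisation, and the printed m/z
values match the free ion.

The label is a single position — the carbon freed by the halogen — so a
true deuteration fraction $d$ gives the mixture
$(1-d)\,P(\mathrm{C_6H_4Br_2O}) + d\,P(\mathrm{C_6H_3DBr_2O})$, the
deuterated species shifted one bin up. DD1 applied to this mixture
(`predicted_dd1()`) is strictly increasing in $d$ but does not start at
zero: heavy natural isotopes (mostly ^13^C) put about 6.2% of the
dibromophenol envelope into B1 even at $d = 0$. DD1 on raw areas
reproduces the field's estimator exactly; the bias-removing inverse
(`correct_dd1_for_natural_abundance()`, a bisection on the forward model)
is kept separate so corrected and uncorrected values can be reported side
by side.

### The compartment model

Whole cells start with cytoplasmic D2O fraction $x_{in,0}$ in an assay
whose water is at $x_{ext}$. The external pool is treated as an infinite
reservoir (1 mL of assay water against femtolitre-scale cytoplasm), so

$$x(t) = x_{ext} + (x_{in,0} - x_{ext})\,e^{-k_{ex} t}.$$

Product formed at instant $t$ carries D with probability

$$dd_{inst}(t) = \frac{x(t)}{x(t) + \alpha\,(1 - x(t))},$$

where $\alpha$ is an *apparent* H-over-D preference factor. The study
design cannot separate discrimination at membrane transport, at the
proton channel, or at the enzymatic step, so the model collapses them
into one factor; $\alpha = 1$ means no discrimination and $\alpha > 1$
means protons are favoured. Because the quenched assay measures *all*
product accumulated since mixing, the observable at harvest time $T$ is
the time average $dd_{cum}(T) = \frac1T \int_0^T dd_{inst}(t)\,dt$
(production is assumed constant; substrate depletion and saturation
kinetics are non-goals). Crude extracts have no compartments: their
labelling fraction is the overall mixture fraction at all times, which is
why flat extract courses are the experiment's control.

The integral has an elementary closed form — the integrand is
$(x_{ext} + c\,w)/(A + B\,w)$ with $w = e^{-kt}$,
$A = \alpha + (1-\alpha)x_{ext}$, $B = (1-\alpha)c$ — which
`cumulative_product_dd()` evaluates directly, with the special cases
$\alpha = 1$, $k = 0$ and $x_{in,0} = x_{ext}$ handled explicitly. The
test suite checks the closed form against adaptive quadrature of the
integrand to 1e-8, far inside the 1e-6 the analysis needs; the closed
form is also what makes the 50-replication parameter-recovery study in
the acceptance tests cheap.

### Default parameters and what they encode

* `k_ex = log(2)/90` s⁻¹ — a 90 s half-life puts the cytoplasm ~99%
  equilibrated at ten minutes, the window the whole-cell courses close
  over. No direct measurement of membrane water exchange exists for these
  cells; this is a calibration to the observed equilibration time scale,
  not a measured constant, and the fitter treats it as free.
* `alpha = 1.9` — chosen so a 50% D2O assay plateaus near 35% deuteration,
  the behaviour of the D2O-grown whole-cell condition; consistent with the
  16–18% seen at a 20% assay and the mid-50s% at an 80% assay.
* `r = 1.3e6` molecules cell⁻¹ s⁻¹ — the per-cell turnover implied by
  9.0 µM product in 10 s from 4.19×10⁸ cells in 1 mL. Crude-extract
  simulations in `analysis/01_simulate.R` use a tenth of this, matching
  the roughly ten-fold lower specific activity of lysed preparations.
* Assay volume 1.0 mL; no dilution correction for the 10 µL quench acid
  (below 1%).

### The synthetic-data generator

`simulate_assay()` emulates triplicate extracted-ion peak tables for the
four shipped condition presets:

| id | design | pools |
|----|--------|-------|
| c1 | whole cells, H2O-grown | $x_{in,0}=0$, $x_{ext}=0.8$ (200 µL + 800 µL D2O buffer) |
| c2 | whole cells, 80% D2O-grown | $x_{in,0}=0.8$, $x_{ext}=0.5$ (625 µL + 375 µL H2O buffer) |
| c3 | crude extract | uniform 0.20 (buffer at 25%) |
| c4 | crude extract | uniform 0.80 |

Areas are `scale × concentration(µM) × envelope abundance` with
multiplicative mean-one lognormal noise (default CV 10%); each replicate
draws from its own counter-derived seed, so replicate $k$ is reproducible
in isolation and whole tables are byte-identical across re-runs. The
generator reproduces the qualitative shapes the analysis must recognise —
a rising, 80%-bounded whole-cell course; a decaying course flattening
near 35%; time-invariant extract courses — and at zero noise the DD1
pipeline recovers `predicted_dd1(cumulative_product_dd(t))` to 1e-9.

What it does **not** emulate: chromatographic peak shape and integration
error, detector saturation, background subtraction, regioisomer
resolution (regioisomers share a formula, so their areas are summed per
bin — which the analysis side also does), single-cell heterogeneity, or
substrate depletion. Passing tests therefore certify the arithmetic and
the inference machinery, not instrument behaviour. One visible
simplification: the model's earliest time points in the D2O-inside
condition start at the undiluted cytoplasmic value, whereas real first
measurements (quenching, mixing dead time) sit lower.

On the 20%-extract condition the assembled sources disagree (a buffer
"containing 20% D2O" versus an overall 20% content; with a 0% extract
those differ). The preset follows the overall figure — buffer at 25%
giving 20% in the vial — and both numbers remain reachable through
`assay_condition()`.

### Statistics

Consecutive time points are compared with a paired two-sample t-test,
replicates paired by vial index (the pairing the triplicate design
implies; the assay description does not state it, and the output flags
degenerate pairings rather than guessing). The t statistic uses the
n−1 standard deviation of the differences and the two-sided Student tail
with df = n−1; `stats::pt()` supplies the tail to well beyond six digits
and is verified in the tests against numeric integration of the explicit
density. Zero-variance differences are reported with flags (p = 0 for a
non-zero mean, p = 1 for all-zero differences) instead of erroring,
because zero-noise simulations hit them legitimately. No multiple-testing
correction is applied by default, matching conventional reporting of
per-step significance; a Bonferroni option exists.

### Fitting

`fit_exchange_model()` minimises the unweighted sum of squared residuals
between observed DD1 means and the forward model. Replicate means are
equally weighted by default — per-time standard deviations from n = 3 are
too unstable to weight by, though `weights` accepts 1/sd² if wanted. The
optimiser is a coarse grid (log-spaced over $k_{ex} \in [10^{-4}, 1]$ s⁻¹
and $\alpha \in [0.2, 10]$, linear over $x_{in,0} \in [0,1]$; 25/25/11
points) followed by Nelder–Mead simplex refinement on box-transformed
parameters (logistic transform, so estimates respect the bounds by
construction; Brent's method for one free parameter). Grid ties go to the
smaller exchange rate — the smoother model. A course with identical means
and two or more free parameters is flagged non-identifiable rather than
returning an arbitrary point.

Recovery performance under the study conditions (CV 5%, triplicates,
eight time points from 10 s to 45 min) is part of the acceptance suite:
over 50 seeded replications the median relative error of both $k_{ex}$
and $\alpha$ stays within 10% and the 90th percentile within 25%. Fitted
parameter values for simulated courses are internal to this package's
model and are not measurements.

### Problem sizes and determinism

The shipped analyses use triplicates, eight time points per condition,
envelopes to six mass shifts, 10,000 simulated pairs for the type-I-error
check and 50 replications for the recovery study — sizes at which the
full suite runs in well under a minute of numerics per module. Every
random draw descends from a single user-facing seed through the
counter-based replicate scheme, so all tables and fit outputs are exactly
reproducible.

### Worked tour

```{r tour, eval = FALSE}
cond <- condition_preset("c1")
truth <- exchange_params()
peaks <- simulate_assay(cond, truth, noise_model(cv = 0.05, seed = 1))
tc <- dd_timecourse(peaks, cond$product, cond)
consecutive_timepoint_tests(dd_replicates(peaks, cond$product))
fit_exchange_model(tc, cond)
```

The numbered scripts under `analysis/` run this narrative end to end for
all four conditions and write their tables under `results/`;
`run_pipeline()` does the same programmatically with a manifest recording
seed and configuration hash.
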