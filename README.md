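# deutrace

Deuterium-tracing analysis of reductive dehalogenation activity assays.

Strictly anaerobic organohalide-respiring bacteria such as *Dehalococcoides
mccartyi* replace a halogen substituent of their electron acceptor with a
hydrogen atom. Whether that hydrogen arrives as a proton from the cytoplasm
or from the external medium is a bioenergetic question: cytoplasmic origin
means the respiratory complex moves charge across the membrane and
contributes to the proton motive force. Running the dehalogenase activity
assay in deuterated water, with D2O initially inside or outside intact
cells (or uniformly, in crude extracts), turns the question into a
measurable one — the newly formed C–H/C–D bond shows up as a +1 shift of
the product's molecular ion in GC-MS.

`deutrace` implements the quantitative machinery such an experiment needs,
for mass-spectrometry users working at unit resolution:

* **Isotopologue forward model** — envelopes of (halogenated) molecular
  formulas by convolution of element isotope distributions
  (`pattern_for_formula()`), nominal molecular-ion m/z
  (`nominal_molecular_ion_mz()`), and the envelope of a product carrying a
  single labelable position (`labeled_pattern()`).
* **Deuteration degree** — the first-peak-pair statistic
  DD1 = B1/(A1 + B1) on raw extracted-ion areas (`dd1()`,
  `dd_timecourse()`), its theoretical value for a given true label
  fraction (`predicted_dd1()`), and a natural-abundance correction that
  inverts the forward model (`correct_dd1_for_natural_abundance()`).
* **Assay arithmetic** — vial mixing fractions (`mixture_fraction()`),
  cells per assay, specific activity in nkat per cell and turnover in
  molecules per second per cell and per enzyme (`activity()`).
* **Time-point statistics** — paired two-sample t-tests between
  consecutive time points with star annotation (`paired_t_test()`,
  `consecutive_timepoint_tests()`).
* **Compartment model** — first-order cytoplasmic water exchange with an
  apparent H-over-D preference factor α
  (`cytoplasm_fraction()`, `instantaneous_dd()`,
  `cumulative_product_dd()`), least-squares recovery of the exchange rate
  and α from a DD1 time course (`fit_exchange_model()`), and a synthetic
  triplicate peak-table generator for all four assay designs
  (`simulate_assay()`, `condition_preset()`).

The core statistic, for a product ion with nominal molecular-ion mass A1
and its M+1 companion B1:

    DD1 = B1 / (A1 + B1)

and the incorporation model, for a donating water pool with D fraction
x(t) = x_ext + (x_in0 − x_ext)·exp(−k_ex·t):

    dd_inst(t) = x(t) / (x(t) + α·(1 − x(t)))
    dd_cum(T)  = (1/T) ∫₀ᵀ dd_inst(t) dt     (whole cells)

α = 1 means no discrimination; α > 1 means protons are preferred over
deuterons.

## Worked example

Turnover arithmetic from an endpoint measurement — 9.0 µM dibromophenol
after 10 s in a 1 mL assay holding 625 µL of suspension at 6.7×10⁸
cells/mL, with ~100 dehalogenase copies per cell:

```r
library(deutrace)
res <- activity(9.0, 10, 1.0, cells_in_assay(6.7e8, 625), copies_per_cell = 100)
res$kcat_cell
#> [1] 1294311
round_sig(res$kcat_cell, 1);  round_sig(res$kcat_protein, 1)
#> [1] 1e+06
#> [1] 1e+04
```

about a million product molecules per cell per second, ten thousand per
enzyme. Simulating a whole-cell course (H2O inside, 80% D2O outside) and
recovering the model parameters:

```r
cond  <- condition_preset("c1", times_s = c(10, 30, 60, 120, 300, 600, 1500, 2700))
truth <- exchange_params(k_ex = 7.7e-3, alpha = 1.9)
tc <- dd_timecourse(simulate_assay(cond, truth, noise_model(cv = 0.05, seed = 7)),
                    cond$product, cond)
fit_exchange_model(tc, cond)
#> <exchange_fit> converged
#>   k_ex  = 0.00821668
#>   alpha = 1.97278
#>   RSS = 3.446e-04 over 718 model evaluations
```

The DD1 course starts near the natural-abundance floor (~6%), rises as
D2O enters the cytoplasm, and stays below the 80% external reference
because α > 1. The numbered scripts under `analysis/` run the full
narrative — simulate, deuteration time courses, kinetics, time-point
tests, model fit — writing tables under `results/`.

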