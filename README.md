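# ubithresh

Kinetic models of how EGF receptor (EGFR) ubiquitination acquires its
switch-like dose dependence — and why that switch sits where it does.

EGFR ubiquitination requires the E3 ligase Cbl, recruited to the
receptor tail either directly (pY1045) or through Grb2 (pY1068/pY1086).
Measured dose–response curves are hyperbolic for total phosphorylation
(Hill coefficient n_H ≈ 1) but sigmoidal for ubiquitination (n_H ≈ 3),
with a half-maximal dose — the ubiquitination threshold x_T — between 1
and 10 ng/ml EGF in HeLa cells. The threshold gates the internalization
route and hence receptor degradation, so its position and robustness are
system-level properties worth modelling quantitatively.

The package implements three nested ODE models as one mass-action
reaction-network core:

* **MPM** — independent multisite phosphorylation in the free-enzyme
  regime: a lumped chain R_0 ↔ … ↔ R_n with rates
  φ⁺_α = (n−α)·a(x)·k_KIN and φ⁻_α = α·k_PTP, where
  a(x) = xⁿ/(Jⁿ+xⁿ) couples dose to kinase activation. The chain
  solution is Binomial(n, p(t)) — used as an exact test oracle.
* **MPM-B** — MPM plus site-resolved Cbl/Grb2 binding with
  cooperativity by enforced proximity: once one arm of a Cbl:Grb2 pair
  is receptor-bound, ring closure becomes first-order at f_LOC·k_b.
  Ubiquitination is proportional to Cbl-carrying receptors.
* **EAM** — mechanistic early activation (conformational opening, EGF
  binding, reversible dimerization) in receptor-moiety coordinates,
  feeding the same binding layer.

Around them: exact Gillespie simulation of the kinase:tyrosine
Michaelis–Menten scheme (free vs saturated regime contrast), Hill
fitting and threshold extraction, 1% and 10-fold sensitivity analyses,
simulated-annealing + simplex parameter estimation with closed-form
"optimized maxima", a seeded synthetic dose–response generator
emulating the densitometry/ELISA measurements, config-driven runs, and
SBML level-3 export/import of the assembled networks.

## Worked example

Simulate the fitted MPM-B with the measured HeLa copy numbers
(3×10⁵ surface EGFR, 10⁶ Grb2, 5×10³ binding-competent Cbl), read out
2 min after EGF addition:

```r
library(ubithresh)

params <- apply_profile(mpmb_params(), "hela")
grid <- default_dose_grid(n = 12)          # 0.01 - 100 ng/ml, log-spaced

ub <- mpmb_dose_response(params, grid, readout = "Ub")
py <- mpmb_dose_response(params, grid, readout = "pY")

threshold_xt(ub)
#> [1] 1.802725
fit_hill(ub)
#> <hill_fit> n_H = 1.446, x_half = 1.795 ng/ml, plateau = 0.9984 (rss 7.28e-05)
fit_hill(py)
#> <hill_fit> n_H = 1.005, x_half = 2.169 ng/ml, plateau = 1.021 (rss 1.71e-07)

st <- simulate_mpmb(params, egf = 100)
bound_cbl_breakdown(st)
#> singly_bound doubly_bound
#>     77.76848   4451.51666
```

The threshold sits in the published 1–10 ng/ml window, ubiquitination
is visibly steeper than phosphorylation, and above the threshold nearly
all receptor-bound Cbl is doubly bound (pY1045 plus Grb2·pY1068/86) —
the cooperative signature. Setting `params$floc <- 1` (no enforced
proximity) collapses the ubiquitination steepness onto the
phosphorylation curve and removes doubly-bound dominance.

The Y1045-only receptor keeps a hyperbolic, strongly attenuated
response:

```r
ub45 <- mpmb_dose_response(params, grid, mutant = "y1045plus")
100 * (1 - max(ub45$readout) / max(ub$readout))
#> [1] 81.87165
```

Receptor-number effects use the EAM:

```r
p <- eam_params()
eam_threshold(p)                                          # HeLa baseline
#> [1] 2.477001
eam_threshold(apply_scenario(p, eam_scenario("egfr_kd"))) # 4.2-fold knockdown
#> [1] 4.031693
```

The knockdown shifts the ubiquitination curve to the right, as the
10-fold sensitivity screen (`sensitivity_screen()`) predicts: the
kinase rate and the total receptor number are flagged among the few
parameters that move x_T by at least 0.1 decades per decade of
parameter change, while pure scale factors and the abundant species
are not. `dose_receptor_surface()` maps per-receptor phosphorylation
and ubiquitination over 10⁴–10⁷ receptors per cell, showing the
bell-shaped ubiquitination optimum at physiological receptor numbers
and its rescue by Cbl overexpression.

See the methods vignette (`vignettes/ubithresh-methods.Rmd`) for the
model assumptions, parameter provenance, numerical choices and known
limitations.

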