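---
title: "Modelling the EGFR ubiquitination threshold: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the EGFR ubiquitination threshold: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ubithresh)
```

## The system and the question

Engaged EGF receptors are phosphorylated on up to nine cytoplasmic
tyrosines within the first minutes of stimulation.  Three of them —
pY1045, which docks the ubiquitin ligase Cbl directly, and pY1068 and
pY1086, which dock the adaptor Grb2 — are necessary and sufficient for
receptor ubiquitination.  Experimentally, total phosphorylation rises
hyperbolically with EGF dose (Hill coefficient close to 1) while
ubiquitination is switch-like (Hill coefficient close to 3) with a
half-maximal dose, the ubiquitination threshold $x_T$, between 1 and
10 ng/ml in HeLa cells.  Because ubiquitination selects the
internalization route and hence receptor degradation, the position and
sharpness of the threshold set the balance between signalling and
attenuation.

This package implements three nested kinetic models of that system and
the analysis tooling around them:

* **MPM** — multisite phosphorylation: each tyrosine is (de)phosphorylated
  independently in the free-enzyme regime; receptors with equal numbers
  of phosphoryl groups are lumped into a linear chain
  $R_0 \leftrightarrow \dots \leftrightarrow R_n$ with rates
  $\varphi^+_\alpha = (n-\alpha)\,a(x)\,k_\mathrm{KIN}$ and
  $\varphi^-_\alpha = \alpha\, k_\mathrm{PTP}$, where
  $a(x) = x^{n_a}/(J^{n_a} + x^{n_a})$ is a phenomenological Hill
  coupling of EGF dose $x$ to kinase activation.
* **MPM-B** — MPM plus site-resolved binding of Cbl and Grb2 to the
  three adaptor-competent tyrosines, with cooperativity by enforced
  proximity, and ubiquitination proportional to the number of
  Cbl-carrying receptors.
* **EAM** — early activation: the Hill input is replaced by
  conformational opening/closing, EGF binding, and reversible
  dimerization; a tyrosine is a kinase substrate only while its dimer
  partner carries EGF.

All three compile to one generic mass-action reaction network (at most
two reactants and two products per elementary step) integrated with
`deSolve::lsoda`; everything downstream — Hill fits, thresholds,
sensitivities, fitting, SBML round trips — operates on that shared
representation.

## Free-enzyme regime and the stochastic check

The MPM's premise is that kinase and phosphatase act in the free-enzyme
regime: the kinase–substrate complex is short-lived, so each tyrosine
is modified independently and the receptor-level rate is proportional
to the number of available tyrosines.  `gillespie_mm()` runs the exact
stochastic simulation algorithm on the explicit Michaelis–Menten
scheme ($K + S \leftrightarrow C \to K + P$) and
`regime_rate_scan()` contrasts the two regimes: with
$k_\mathrm{off} \gg k_\mathrm{on} n$ the initial phosphorylation rate
is linear in site number through the origin; with a stable complex it
is independent of site number.  The initial rate is operationalized as
the least-squares slope of the ensemble-mean trajectory through the
origin over the first 5% of the simulated window; because trajectory
values are cumulative counts, the slope's Monte-Carlo error is
propagated under an independent-increments covariance rather than
pointwise.  The test suite checks the ensemble mean against the exact
chemical master equation, so the regime contrast is anchored to an
independent solution, not to the ODE limit alone.

A direct consequence of independent, identical sites is that lumped
chain states are binomial, $R_\alpha(t) \sim
\mathrm{Binomial}(n, p(t))$ with $\dot p = a k_\mathrm{KIN}(1-p) -
k_\mathrm{PTP}\, p$; total phosphorylation of a 9-site receptor is
exactly three times that of the 3-site add-back at every dose, and
normalized dose–response curves are independent of site number.  Both
are exploited as exact oracles in the tests.

## The binding layer and cooperativity

Each receptor is resolved by the state of its three adaptor sites:
Y1045 in $\{$Y, pY, pY·Cbl, pY·Cbl·Grb2$\}$; Y1068 and Y1086 each in
$\{$Y, pY, pY·Grb2, pY·Grb2·Cbl$\}$; plus a bridge flag marking a
doubly-bound complex in which one Cbl contacts pY1045 while its Grb2
contacts pY1068 (or pY1086).  With the cytosolic species Cbl, Grb2 and
Cbl:Grb2 this gives 75 species and ~570 elementary reactions for the
3Y+ receptor, generated programmatically and checked against a
brute-force enumeration.

Cooperativity enters as enforced proximity: once one arm of a
Cbl/Grb2 pair is receptor-bound, the remaining ring-closing step is a
first-order reaction at rate $f_\mathrm{LOC} \cdot k_b$, where
$f_\mathrm{LOC}$ is an effective local concentration in molecules per
cell (the fitted default, $2.5 \times 10^9$, corresponds to about two
millimolar — the upper end of the range expected for partners tethered
by a short flexible linker).  A single $f_\mathrm{LOC}$
multiplies all three closure steps, which makes the thermodynamic
cycle exactly consistent between assembly orders; the test suite
verifies flux balance on the closure reactions at equilibrium.
Setting $f_\mathrm{LOC} = 1$ yields the noncooperative variant used as
the contrast condition.

Ubiquitination is a per-receptor property: the signal is $k_{ub}$
times the number of receptors carrying at least one Cbl, with
`bound_cbl_breakdown()` splitting Cbl-carrying receptors into
singly (pY1045 only) and doubly (bridged) bound.

Two rules are worth making explicit.  First, occupied
phosphotyrosines are protected from phosphatases: a pY carrying a
bound SH2 or TKB module cannot be dephosphorylated until the module
releases.  This is the physically standard assumption (the bound
domain occludes the site) and it is also functionally required here:
if dephosphorylation ejected bound adaptors, complex lifetimes would
be slaved to the phosphatase rate, doubly-bound Cbl could never
accumulate over the 2-minute window, and the measured ceiling on the
basal Cbl pool (about 5,000 per cell) would sit an order of magnitude
too high.  Second, both Grb2 sites are kinetically identical but kept
distinct, so site-specific knockouts remain expressible.

## Where the threshold comes from, and what bounds its steepness

In this architecture the switch-like ubiquitination curve arises from
the conjunction of (i) the probabilistic requirement for two
simultaneously phosphorylated tyrosines on the same receptor, which
makes the pool of bridge-competent receptors grow roughly as the
square of per-site occupancy, and (ii) cooperative capture: at the
fitted rates a Cbl visiting a bridge-competent receptor is committed by
the fast ring closure, while visits to receptors exposing only pY1045
are brief.  The defaults place the system in a kinetically fresh
regime at the 2-minute readout — site turnover is slow compared with
the readout window, so captured Cbl accumulates rather than
equilibrating — which is what lets the doubly-bound species dominate
above the threshold while the Y1045-only mutant retains only a small,
hyperbolic signal.

A structural consequence, visible in the shipped defaults, is that the
model's fitted ubiquitination Hill coefficient (about 1.4–1.5, against
phosphorylation at 1.0) undershoots the experimental value of 3: a
two-site coincidence detector with a hyperbolic per-site input cannot
produce an apparent Hill coefficient near 3 at a threshold placed near
or right of the phosphorylation half-max — deep capture saturation
steepens the curve but simultaneously drags the half-crossing to lower
doses.  This gap between model
and measured steepness is intrinsic to this model class, so the
package treats the steepness *contrast* (cooperative versus
noncooperative), not the absolute value 3, as the model-level claim;
the value 3 lives in the synthetic data generator, which emulates the
measurements.

## Cbl as the limiting species

With the measured HeLa copy numbers (3×10⁵ surface EGFR, 10⁶ Grb2,
5×10³ binding-competent Cbl) Cbl is limiting: absolute ubiquitination
scales with Cbl availability while the normalized threshold stays
put — until the basal pool becomes comparable to the number of
bridge-competent docking configurations near the threshold, at which
point saturation distorts the normalized curve and the invariance
breaks.  `cbl_ceiling_scan()` locates that ceiling by scanning basal
Cbl with two-fold modulation and the $|\Delta \log_{10} x_T| < 0.05$
invariance rule.

## The early activation model

The activation layer tracks receptor moieties, not dimers: classes are
closed/extended × ligand-free/-bound × monomer/dimer-member, with only
the extended form dimerization-competent and EGF stabilizing the
extended form through a single factor $\omega$ (EGF dissociates
$\omega$-fold slower from extended receptors, and liganded receptors
close $\omega$-fold slower — a parameterization that satisfies the
ligand×conformation detailed-balance cycle by construction, checked by
`check_cycle_closure()`).  Pairing flux is
$k_\mathrm{dim} M^2$ with multinomial partner assignment, and dimer
members return to the extended monomer pool at $k_\mathrm{dim,off}$;
for this linear structure the moiety description is *exact* for the
activation layer, which the tests verify against an explicit
dimer-pair reference to 10⁻⁸.

Phosphorylation couples to activation through the literal substrate
rule — a moiety is phosphorylated only while its dimer partner carries
EGF — so the mean per-site kinase rate is $k_\mathrm{KIN}\,
\mathrm{DL}/R_T$, implemented as catalysis by the EGF-loaded
dimer-member species DL.  (The alternative rule, in which any dimer
with at least one loaded member phosphorylates both tails, is exposed
as `phospho_rule = "either_bound"`.)  This factorization applies the
population-average activation to every receptor tail and therefore
neglects the correlation between a moiety's own activation history and
its phosphorylation state; on a single-site test system the measured
bias against a joint explicit-dimer reference is about 17% of total
pY.  That accuracy envelope is acceptable here because every EAM claim
used downstream is qualitative or normalized (threshold shifts,
bell-shaped per-receptor surfaces, sensitivity rankings).

Receptor number enters the EAM nonlinearly through dimerization, which
is why the 10-fold sensitivity screen on $x_T$ flags $R_T$ alongside
$k_\mathrm{KIN}$, and why reducing $R_T$ 4.2-fold (the measured
knockdown) shifts the ubiquitination curve right.  At the other
extreme, raising $R_T$ toward tumour-like levels dilutes the limiting
Cbl over more receptors: per-receptor ubiquitination falls even at
saturating EGF while per-receptor phosphorylation does not fall
comparably — the uncoupling regime — and multiplying Cbl restores it.

## Sensitivity analyses

`sensitivity_local()` implements the 1% central-difference coefficient
$\sigma = |\Delta m / m| / |\Delta k / k|$ for curve metrics ($n_H$,
pY₀.₅, $x_T$).  `sensitivity_large()` implements the 10-fold screen:
$S = \max_{\times 10, \div 10} |\log_{10}(x_T'/x_T)| / 1$, i.e. decades
of threshold shift per decade of parameter change, so $S > 1$ means
the response outruns the perturbation; parameters at $S \ge 0.1$ are
reported.  This log-ratio-per-decade form is adopted because it makes
the published interpretation of $S > 1$ literally true; when a
perturbation pushes the threshold off the scanned dose grid the
boundary value is recorded and flagged as saturated rather than
silently dropped.

## Parameter estimation

`fit_parameters()` reproduces the estimation workflow: simulated
annealing (geometric cooling, $T_{k+1} = 0.95\,T_k$, a fixed number of
proposals per temperature, Gaussian steps in log₁₀ space reflected at
finite boxes) followed by Nelder–Mead simplex from the annealing
incumbent; the incumbent sequence is monotone and the simplex stage
can only improve it.  Rates are fitted in log space; measured molecule
counts stay fixed.  Residuals are computed on normalized curves with
per-group scale factors ("optimized maxima") profiled out in closed
form — the ratio of weighted inner products — at every objective
evaluation; sharing one group across the ubiquitination curves (3Y+,
Y1045+, and the Cbl modulation conditions) is what preserves the ~80%
amplitude contrast and the two-fold modulation amplitudes through
normalization.  A flat objective over the annealing sample raises a
non-identifiability flag instead of returning an arbitrary point,
which is exactly what happens if one frees only the output scale
$k_{ub}$ against normalized data.

The default fit problem (`default_mpmb_fit_problem()`) frees the three
dissociation rates of the binding layer inside ±0.15-decade boxes
around the shipped defaults, with association rates pinned at
diffusion-limited values.  The narrow boxes are deliberate, and mirror
how such affinities are determined in practice — within tight,
experimentally constrained ranges.  They are also structurally
necessary: the synthetic ubiquitination truth is steeper (n_H = 3)
than this model can produce, so an unconstrained fit buys residual by
sliding into a shallow-capture regime that loses the model's validated
kinetic properties — above all the basal-Cbl ceiling, which exists
only while Cbl capture near the threshold is deep enough to saturate
the doubly-phosphorylated receptor pool.  The constraint boxes keep
the refit inside that regime while still letting the data adjust the
affinities.

## The synthetic data generator

`generate_dose_response()` stands in for the densitometry/ELISA
measurements: Hill-shaped ground truths on an 8-point log grid from
0.01 to 100 ng/ml, three replicates, multiplicative lognormal noise
with CV 0.10 (positive signals with roughly proportional errors — the
natural reading of densitometry error bars; the replicate correlation
structure is not knowable from published summaries, so replicates are
independent).  Defaults: phosphorylation $n_H = 1$, $x_{1/2} = 2$
ng/ml; 3Y+ ubiquitination $n_H = 3$, $x_T = 3$ ng/ml (inside the
published 1–10 window); Y1045+ ubiquitination hyperbolic at 20% of the
3Y+ plateau (the ~80% reduction); Cbl overexpression/70Z as ×2/×0.5
amplitude with an unmoved threshold.  Normalization to the observed
maximum is applied after the noise, per replicate, reproducing the
slight downward bias of sub-maximal points that real normalized
densitometry has — fitting must tolerate it, and does.

What passing tests on generator data do *not* show: anything about
blot saturation or capture-antibody nonlinearity, about correlated
replicate structure, or about the true (unpublished) kinetic constants
— the binding rates shipped as defaults are the package's own fit to
the generator defaults within literature-plausible boxes, not the
original supplementary values.

## Numerical choices

* Integrator: `lsoda`, rtol 10⁻⁸, atol 10⁻¹⁰ by default (the
  enforced-proximity closures make the binding layer mildly stiff);
  fitting uses rtol 10⁻⁶ for speed, which changes objectives well
  below the noise floor of the data being fitted.
* EGF-free steady states are closed-form (quadratics for the Cbl:Grb2
  solution equilibrium and for the basal conformations/dimer pool),
  and the tests verify the residual of the right-hand side at the
  initial state is below 10⁻⁸ of $R_T$.
* $x_T$ is defined by log-linear interpolation of the normalized curve
  at 0.5; dose-grid density is therefore part of run provenance.
* Hill fits use Levenberg–Marquardt with analytic-free starting
  heuristics (half-crossing for $x_{1/2}$, logit–log slope for $n_H$)
  and bounded parameters; degenerate inputs return an explicit failure
  flag.  A dense grid-search oracle cross-checks the fit on non-Hill
  sigmoids in the tests.
* Problem sizes in the shipped tests: 8–12 dose points per curve,
  SSA at 2,000–5,000 runs, annealing at 6–10 temperatures × 10–20
  proposals with a simplex polish.  These reproduce every qualitative
  and quantitative claim the package makes while keeping the default
  suite fast; all sizes are arguments, and the full-size settings
  (10⁵ SSA runs, 100 proposals per temperature) are one argument away.

## Known limitations

* The mean-field tail factorization in the EAM (bias ~17% on the test
  system, see above); per-receptor joint activation×tail tracking
  would multiply the state space ~6-fold.
* The model's ubiquitination steepness is structurally capped below
  the experimental $n_H \approx 3$ (see the steepness section); the
  cooperative/noncooperative contrast, threshold position, amplitude
  ratios and Cbl ceiling are the model-level claims.
* No Cbl regulatory network (phosphorylation, dimerization,
  deubiquitinases), no ubiquitin chain identity, no trafficking
  downstream of the plasma membrane, and no ligand depletion (doses
  are a constant extracellular bath).
```
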