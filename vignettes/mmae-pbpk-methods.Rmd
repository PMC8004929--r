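---
title: "Whole-body PBPK modeling of the ADC payload MMAE: model, estimation and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Whole-body PBPK modeling of the ADC payload MMAE}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Monomethyl auristatin E (MMAE) is the cytotoxic payload of several approved
antibody-drug conjugates. Once released, free MMAE is cleared from plasma
within hours but persists in tissues, blood cells and tumor for days,
because it binds its intracellular target (tubulin) and partitions strongly
into cells. Plasma concentrations alone therefore say little about
tissue exposure, which is what drives both efficacy and the payload's
characteristic toxicities. `mmaepbpk` implements a whole-body
physiologically based pharmacokinetic (PBPK) model of free MMAE in
tumor-bearing mice, together with the analysis pipeline needed to study it:
noncompartmental analysis (NCA) and partition coefficients, maximum-
likelihood (ML) parameter estimation, predictive-error evaluation,
in vitro-in vivo extrapolation (IVIVE) of hepatic clearance, and a
synthetic biodistribution-study generator so every stage is testable
without access to raw animal data.

## Model structure

The model has 16 tissue compartments (blood, lung, heart, kidney, muscle,
skin, liver, brain, adipose, thymus, bone, small and large intestine,
spleen, pancreas and a lumped "other"/carcass compartment) plus a tumor,
all connected anatomically by blood flow. Arterial blood leaves the lung;
venous blood from the spleen, pancreas and intestines passes through the
liver (hepatic portal routing) before reaching the central venous pool.

Every non-blood tissue is divided into five sub-compartments: vascular
plasma, vascular blood cells, endothelial, interstitial and cellular space.
Three transfer regimes apply:

* **Fast exchange** between plasma, endothelial and interstitial space,
  modeled as flow-limited transfer scaled by a large multiplier
  `G = 1000` on the tissue plasma flow, which makes these three spaces
  effectively instantaneous relative to everything else. Only unbound drug
  (`fu_p = 0.8`) leaves plasma.
* **Permeability-limited exchange** across the blood-cell membrane and the
  tissue cell membrane, governed by permeability-surface area coefficients
  `PS_BC` and `PS_i` (mL/h). Back-flux from a cellular space is driven by
  its unbound concentration, `fu_t = fu_p / Kp`, so each cellular pool
  equilibrates at concentration `Kp * C_plasma`.
* **Hepatic elimination only**: a single intrinsic clearance `CL_int`
  (mL/h) acts on the liver interstitial concentration. This reflects the
  payload's known disposition (CYP3A metabolism plus biliary excretion,
  negligible renal elimination).

The tumor is a Krogh-cylinder, cell-level disposition model: exchange with
central plasma through a vascular pathway (`2 P R_cap / R_krogh^2`) and a
surface pathway (`6 D / R_tumor^2`), both driven by the difference between
plasma concentration and the extracellular concentration in the accessible
void fraction `epsilon`; first-order cellular influx `k_in` and efflux
`k_out`; and second-order binding to a finite tubulin pool
(`k_on`, `k_off`, `C_tubulin` = 2000 nM). Tubulin binding is the only
nonlinear term in the system.

The full system has 81 states: 2 central, 15 tissues x 5 sub-compartments,
3 tumor states and one bookkeeping state for the cumulative amount
eliminated. Because everything except the bilinear binding term is linear,
the package assembles the system once as a dense coefficient matrix
(`build_pbpk_system()`); both the compiled C right-hand side and the pure-R
reference path (`pbpk_rhs()`) evaluate `A y` plus the binding correction,
and the analytic Jacobian is available to the stiff integrator.

### Numerical choices

`G = 1000` with endothelial volumes of ~0.5% of tissue volume produces
exchange rates up to ~4e8 1/h, so the system is very stiff and is
integrated with `deSolve::lsoda` using the user-supplied dense Jacobian.
Default tolerances are `rtol = 1e-8`, `atol = 1e-10` nM for reported
simulations; fitting uses `rtol = 1e-6`, `atol = 1e-8`, which changes the
objective by less than the optimizer's stopping tolerance while being
several-fold faster. Halving the tolerances moves reported observables by
less than 0.01% (grid-independence test). Mass balance (dose = amounts in
all compartments + amount eliminated) holds to well below 0.1% over 168 h.

Two unit decisions matter. Internal state is nM (= pmol/mL), volumes mL,
flows mL/h, time h, amounts pmol, and `MW = 717.98` g/mol converts to the
assay's ng/mL scale. The Krogh geometry is stored in cm with defaults
`R_cap = 8e-4` cm (8 um) and `R_krogh = 75e-4` cm (75 um): cm-scale values
(0.8/7.5 cm) sometimes quoted for this geometry are anatomically
implausible for capillary spacing and inconsistent with the tumor-
disposition literature the model family descends from, so the micron scale
is the default and the cm scale remains available by configuration.

### Tumor state convention

The published tumor equations exchange *amounts* with plasma
(flux x `V_tumor`) while writing the tumor states as concentrations. The
package therefore interprets the three tumor states as concentrations per
*total* tumor volume (amount = `C * V_tumor`), under which the printed
equations conserve mass exactly against the plasma equation; the
extracellular concentration in the accessible space is `C_extra / epsilon`,
which is exactly the driving term in the exchange fluxes. The homogenate
observable for the tumor is then simply the sum of the three states (which
equals the void-fraction-weighted mixture of the per-space concentrations).
An alternative bookkeeping with sub-volumes `epsilon V_tumor` and
`(1 - epsilon) V_tumor` applied directly to the printed equations leaks a
factor `(1 - epsilon)` of the exchange flux and was rejected for that
reason.

## Physiology fixture

No single canonical physiology table exists in print for this model family
(physiological constants are conventionally inherited from platform
antibody PBPK models), so `mmaepbpk` ships a concrete, versioned stand-in
table for a 28 g mouse
(`inst/extdata/physiology_mouse_28g.csv`), assembled from standard rodent
PBPK physiology: total blood 1.72 mL split 55/45 into plasma and blood
cells (hematocrit 0.45, configurable), cardiac output 678 mL/h constructed
to equal the sum of the regional flows exactly, and endothelial volume
fractions of 0.5% throughout. Cellular volume fractions for the observed
tissues are calibrated from the one in-source constraint available: the
ratio of apparent to cellular-space-adjusted partition coefficients per
tissue (e.g. lung 35.3/64.9 implies `f_cellular = 0.544`). A generic
literature-style fraction set ships as an alternative fixture. Every
downstream number that depends on these values is fixture-sensitive, and
the pipeline log records which fixture was used.

## Partition coefficients and NCA

`Kp` is the ratio of tissue to plasma `AUC(0-t)`, computed with the
lin-up/log-down trapezoidal rule (`auc_linlog()`); the cellular-space
adjustment divides by the cellular volume fraction (`adjust_kp()`), since
the payload is assumed to reside mainly in cells. The liver's apparent Kp
understates its partitioning because the liver also eliminates drug; the
CLint-accounted value (25.3 on the adjusted basis) is used in the model by
default and the apparent value (3.80) is available by override. No
correction formula is computed, because none is published; the constant is
treated as an input. Tissues without observed data take the spleen's
adjusted Kp (thymus, intestines — following the autoradiography evidence
of high payload retention in rapidly dividing tissues) or 1 (carcass), and
muscle's PS scaled by tissue weight.

Moment analysis (`moment_analysis()`) uses the standard closed forms:
`CL = dose / AUC(0-inf)`, `Vss = CL * MRT`, `t_half = ln 2 / lambda_z`,
with `lambda_z` from a log-linear regression on the last three positive
points (configurable). BLQ handling in NCA: replicates below the limit of
quantification are dropped from the per-time mean; leading/trailing
all-BLQ times are dropped, embedded ones excluded. IVIVE (`ivive()`)
scales an in vitro intrinsic clearance by hepatocellularity
(135 x 10^6 cells/g) or microsomal protein content (41.9 mg/g) and liver
weight, and divides the resulting metabolic clearance by the metabolic
fraction of total clearance (default 0.4, per the 40/60
metabolic/biliary split reported for this payload). `scale_ps()` performs
the single allometric operation supported (exponent 0.67).

## Synthetic studies and estimation

`generate_study()` emulates the destructive-sampling design: 0.1 mg/kg IV
bolus (3900 pmol at 28 g), terminal sampling at 5 min, 1, 6, 12, 24 and
168 h, three animals per time point, with each animal contributing plasma,
whole blood, 11 tissues and tumor (252 records). Residual error follows
the combined additive-proportional variance model
`V = (sigma1 + sigma2 * Y)^2`, drawn as a zero-truncated normal to mirror
that variance literally (a log-normal with matched CV is available by
flag). The additive and proportional magnitudes are this package's own choices —
no residual-error estimates are available for the original assay — set to
`sigma1 = 0.01` nM (well below the 0.2 ng/mL = 0.28 nM LLOQ) and
`sigma2 = 0.10`, a typical LC-MS/MS assay CV. Records below the LLOQ keep
their value but are flagged, matching how a bioanalytical report would
censor them. The generator is seed-deterministic, and different seeds share
identical noise-free means.

What the generator does *not* emulate: inter-animal physiological
variability (volumes, flows and tumor size are fixed across replicates),
assay batch effects, and any model misspecification — the data come from
the same model family that is fitted back. Passing recovery tests
therefore validates the estimation machinery and identifiability under the
study design, not the biological truth of the model.

`fit_pbpk()` performs naive-pooled ML estimation: every non-BLQ record
enters a Gaussian likelihood with the variance model above (BLQ records
are excluded and counted; the source is silent on its BLQ policy).
Parameters are log-transformed for positivity and minimized with bounded
L-BFGS-B; `sigma1` is fixed (avoiding variance collapse at BLQ-adjacent
predictions) and `sigma2` estimated by default. CV% comes from the inverse
of the numerically differentiated Hessian of the -2LL at the optimum
(covariance `2 H^-1`), mapped to the natural scale by the delta method —
on the log scale, CV% is simply `100 * SE(log theta)`. Singular
information (a parameter that does not influence any observed matrix)
yields NA CV% for the affected parameters. The optimizer stops when
objective improvements fall below ~1e-4, which is the level of integrator
noise in the objective at the fitting tolerances; a tighter criterion only
burns iterations without moving the estimates.

One estimator subtlety deserves a note. With the variance computed from
the model prediction, the `sum log V` term of the likelihood depends on
the parameters and exerts a small pull toward lower predictions; even a
noise-free self-fit then has its optimum displaced by ~1.5% (most visibly
in `CL_int`). This is an inherent property of prediction-weighted ML, not
an optimizer artifact. `neg2ll()` and `fit_pbpk()` therefore also offer
`variance_basis = "observation"`, the standard data-weighted variant whose
weights are parameter-free; the package's noise-free self-consistency test
uses it, while stochastic recovery experiments keep the prediction-based
default.

Because the raw animal data are not deposited, the published estimates are
approached by *parameter recovery* rather than exact replication
(`recovery_experiment()`): synthetic studies are generated at the
published parameter values, refitted from starts displaced by a factor of
2, and the recovered medians across seeds are compared with the generating
values. The estimated set matches the published one: the blood-cell PS,
the PS of the 11 observed tissues, `CL_int` and the tumor influx `k_in`
(14 structural parameters plus `sigma2`). Problem sizes used throughout
the package: 252-record studies, 5 seeds in the acceptance script, 10
seeds in the recovery property test, one noise-free self-consistency fit.

## Known limitations

* All physiological values are stand-ins; absolute simulated
  concentrations (and hence fixture-dependent quantities like simulated
  plasma AUC) inherit that uncertainty. Self-consistency results do not.
* The model is linear outside tumor tubulin binding; at doses well above
  0.1 mg/kg, saturation of tissue partitioning or protein binding would
  not be captured.
* Single IV bolus only; no oral/subcutaneous routes, no multiple dosing,
  no enterohepatic recirculation, no transporter kinetics (the brain's
  efflux transporters are absorbed into its small fitted PS), and no
  tumor growth over the study.
* The NCA-based back-calculation of in vivo `CL_int` under a well-stirred
  assumption is not implemented: the reported reference values for it
  carry mutually inconsistent units, so it is not a reproducible surface.
* Cross-species translation is limited to the single allometric PS
  operation; clearance scale-up would additionally require species
  differences in unbound fraction and renal contribution.
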