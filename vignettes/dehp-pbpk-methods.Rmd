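---
title: "Methods: a whole-body PBPK model for DEHP and MEHP"
author: "dehptk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a whole-body PBPK model for DEHP and MEHP}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dehptk)
```

## The problem

Di(2-ethylhexyl) phthalate (DEHP) is a plasticizer that people encounter
continuously indoors, by three routes: ingestion with food, dermal uptake,
and inhalation. Once absorbed it is hydrolysed — almost exclusively in the
gut wall and the liver — to mono(2-ethylhexyl) phthalate (MEHP), the
metabolite most often blamed for phthalate toxicity, which is then oxidised
further and partly excreted in urine. `dehptk` implements a whole-body
physiologically based pharmacokinetic (PBPK) model that converts an external
exposure on any of the three routes into time courses of DEHP and MEHP
concentration in individual organs.

## Model structure

The body is sixteen compartments: twelve systemically perfused organs
(heart, brain, muscle, skin, liver, gut, spleen, pancreas, bone, kidney,
thymus, and a lumped rest-of-body), the lungs in series on total cardiac
output, arterial and venous blood pools, and a 1-mL urine accumulator.
Every tissue is flow-limited: uptake is instantaneous relative to
perfusion, so an organ with blood flow $Q_i$, volume $V_i$ and
tissue:plasma partition coefficient $K_{p,i}$ obeys

$$V_i \frac{dC_i}{dt} = Q_i \left( C_{art} - \frac{C_i}{K_{p,i}} \right).$$

Gut, spleen and pancreas drain through the liver (portal circulation); the
liver additionally receives a hepatic arterial fraction, and its outflow —
the sum of all four inflows — returns to the venous pool. The venous pool
feeds the lungs, the lungs feed the arterial pool. `validate_topology()`
audits flow conservation at the liver, venous and lung nodes to
$10^{-9} \times$ cardiac output.

Two parallel copies of this transport network are integrated, one per
species, coupled only through metabolism. DEHP does not distribute into the
lumped rest-of-body compartment (that flow passes through unchanged); MEHP
distributes everywhere. Organs without a species-specific partition
coefficient use the species' rest-of-body value; the tabulated fat
coefficients are carried but unused because the body template has no
discrete adipose compartment (adipose mass is inside rest-of-body).

### Blood flows

Organ volumes are the reference-human values built into
`build_default_physiology()`. Blood flows are a package default, not a
measured input: cardiac output 5200 mL/min and ICRP-style reference-adult
fractional flows (kidney 0.19, muscle 0.17, gut 0.15, brain 0.12, hepatic
artery 0.065, skin 0.05, bone 0.05, heart 0.04, spleen 0.03, pancreas 0.01,
thymus 0.0015, rest 0.1235; exact sum 1). Every fraction can be overridden.
Absolute organ concentrations scale roughly inversely with cardiac output
at steady state, so this choice is the dominant systematic uncertainty of
the model.

## Dosing

* **Oral** — daily meals are constant-rate infusions into a gut-lumen
  state, 30 min each; default 1.95 mg/day split 0.5/0.8/0.65 mg at 8, 12
  and 18 h. The lumen is absorbed into gut tissue at `kgut` = 7 h⁻¹.
  (The per-kg figure sometimes quoted alongside this intake is inconsistent
  with the meal masses; the meal masses are taken as definitive.)
* **Dermal** — continuous infusion into skin tissue, default 0.68 mg/h,
  24 h/day; no stratum-corneum diffusion layer.
* **Inhalation** — continuous infusion into lung tissue, default
  0.53 mg/h; no respiratory-tract deposition model.

Dose events are half-open intervals $[t_0, t_0 + \Delta)$; the integrator
restarts at every boundary so discontinuities are localized exactly, and
`cumulative_input()` integrates the piecewise-constant rates in closed
form.

## Metabolism

Twelve Michaelis–Menten reactions, all in gut or liver: microsomal and
cytosolic DEHP→MEHP hydrolysis, and four MEHP-consuming oxidations per
organ whose products (5-OH MEHP, 5-oxo MEHP, 5-cx MEPP, phthalic acid) are
not tracked individually but pooled into a cumulative sink in
MEHP-equivalent mass. Rates use total tissue concentration on the µg/L
scale. Mass converts between species as
$\mathrm{MW}_{\mathrm{MEHP}}/\mathrm{MW}_{\mathrm{DEHP}}$, which makes the
molar balance exact; `mass_balance()` verifies at every output time that

$$\frac{\text{input}}{\mathrm{MW}_D} =
  \frac{\sum A_D + A_{lumen}}{\mathrm{MW}_D} +
  \frac{\sum A_M + A_{urine} + A_{sink}}{\mathrm{MW}_M}$$

to a relative residual below $10^{-6}$ (in practice $\sim 10^{-14}$).

Tabulated maxima are per mg of subcellular protein and are scaled to whole
organs as `vmax × 60 × (mg protein / g tissue) × organ mass`, with tissue
density 1 g/mL. Protein contents are package defaults (liver microsomal
40 mg/g, liver cytosolic 80.7 mg/g, gut 3 mg/g for both fractions) and a
second major source of systematic uncertainty. Two tabulation quirks are
resolved as follows, both overridable: the gut M5 maximum is read on the
µg/min/mg basis of every other reaction (its printed mg/min/mg unit is
taken as a typo), and the liver microsomal hydrolysis Km, which the source
table omits, defaults to the intestinal microsomal value (6956 µg/L) for
the same reaction class.

## Elimination

Urinary excretion removes unbound MEHP from venous blood:
$dA_{urine}/dt = k_{urine} \cdot f_{up} \cdot A_{MEHP,ven}$ with
$k_{urine} = 0.35$ h⁻¹ and $f_{up} = 0.007$. The unbound fraction applies
to elimination only, not to tissue exchange (configurable conceptually via
the model object). A kidney-draining variant is available
(`pbpk_model(urine_from = "kidney")`).

This law has a quantitative consequence worth stating plainly: the implied
urinary clearance is $0.35 \times 0.007 \times 3396\,\mathrm{mL} \approx
8\,\mathrm{mL/h}$, roughly four orders of magnitude below the hepatic
metabolic clearance of MEHP under the default protein scaling. The
simulated urinary fraction of a single oral dose is therefore well below
1% on a molar basis, far less than the several percent observed in human
dosing studies. Reproducing observed urinary recovery would require either
a much larger effective urinary clearance or a much smaller hepatic one;
the package keeps the parameters as tabulated and reports what they imply.

## Numerics

`lsoda` (via **deSolve**) with relative tolerance $10^{-8}$ and absolute
tolerance $10^{-10}$ µg, restarted at each dose boundary; output on a
0.05-h grid by default so sub-hour peak timing is resolvable. Substrate
concentrations are clamped at zero inside the rate laws so solver-level
undershoot cannot feed back; states remain non-negative to well within
tolerance. The model is deterministic; only `sample_parameters()` consumes
randomness. When simulating doses scaled down by many orders of magnitude
(e.g. linearity checks), scale `atol` down too — an absolute tolerance of
$10^{-10}$ µg is meaningless for states of $10^{-12}$ µg.

Reference problem sizes: a 120-h scenario on the 0.05-h grid (2401 output
points, 32 states) integrates in a few seconds; the full summary analysis
(three 120-h scenarios, one 48-h scenario, one 72-h single-dose run)
completes in well under a minute.

## Scenario summaries

* `organ_peaks()` — interior local maxima of a concentration series on the
  output grid; bolus runs show one peak per meal, infusion runs none.
* `equilibrium_concentration()` — mean over the final window (default
  12 h) accepted only if max−min over the window is below 1% of the mean;
  periodic series are flagged, never silently averaged. The combined
  "endocrine" organ is the volume-weighted spleen+pancreas concentration.
* `day_over_day_delta()` — relative change of whole-body burden (all DEHP
  and MEHP amounts, gut lumen included, urine/sink excluded) between
  consecutive 24-h boundaries, in percent. Alternative burden definitions
  (per-organ, concentration-based) can be built from `as.data.frame()`
  output.

A structural note on orderings: at steady state under continuous dosing,
every organ sharing the rest-of-body partition coefficient (lungs, spleen,
pancreas, heart, …) converges to exactly $K_p \times C_{art}$, so their
equilibrium concentrations tie exactly. Reported orderings that separate
spleen+pancreas from lungs by a few percent are within this model's tie.

## Monte Carlo

Each lognormally specified parameter is sampled independently with the
tabulated value as median and geometric SD factor 1.1 or 1.5, truncated to
median × factor^(±1.5) — the stated ±1–1.5 SD range is read as a
truncation bound, the more conservative of its two readings. Default
simulations use medians only; sampling is opt-in
(`sample_parameters(chem, n, seed)`), reproducible under a fixed seed, and
20,000 draws recover each median to well within 3%.

## Molecular-weight bookkeeping

MEHP is 278.3 g/mol in exposure scenarios; the single-dose validation run
(`run_koch_single_dose()`) uses 281 g/mol because that experiment dosed
deuterium-labelled DEHP and measured D4-MEHP. Both are arguments.

## What the built-in scenarios do and do not show

The reference scenarios are idealized study conditions: constant 24 h/day
dermal/inhalation rates, identical meals every day, a static
reference-adult physiology. Passing tests show the transport/metabolism
machinery is internally consistent (molar conservation, flow-limited
equilibria, dose linearity, analytic limits) and that relative organ
patterns — liver-dominant oral DEHP peaks, liver-dominant MEHP under all
routes, shrinking day-over-day accumulation — are robust. They do not show
that absolute concentrations in a real person are captured better than the
uncertainty of the unmeasured inputs (blood flows, protein scaling), which
enter multiplicatively and are documented above.

## Known limitations

* Flow-limited tissues only; no permeability-limited subcompartments.
* No enterohepatic recirculation and no fecal loss of unabsorbed DEHP
  (the lumen holds it until absorbed).
* Downstream metabolites are a lumped sink; their own kinetics (including
  the tabulated but unused blood-uptake constants of the oxidised
  metabolites) are not simulated.
* Single static physiology; no age/sex libraries, no growth.
* The urinary-excretion law, as parameterized, underpredicts urinary MEHP
  recovery by orders of magnitude (see *Elimination*).
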