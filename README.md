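# dehptk — whole-body PBPK simulation of DEHP and its metabolite MEHP

`dehptk` is an R package for exposure scientists and toxicologists who need
to translate an *external* indoor exposure to the plasticizer
di(2-ethylhexyl) phthalate (DEHP) — through food, skin contact or inhaled
air — into *internal* organ-level time courses of DEHP and its primary
hydrolysis metabolite mono(2-ethylhexyl) phthalate (MEHP).

## The model

The body is sixteen compartments: twelve systemically perfused organs plus
a lumped rest-of-body, the lungs in series on total cardiac output,
arterial and venous blood pools, and a urine accumulator. Each tissue is
flow-limited,

$$V_i \frac{dC_i}{dt} = Q_i\left(C_{art} - \frac{C_i}{K_{p,i}}\right),$$

with portal drainage of gut, spleen and pancreas through the liver. DEHP
enters the gut lumen (oral, absorbed at $k_{gut}$), skin (dermal) or lung
tissue (inhalation), and is hydrolysed to MEHP in gut and liver by
saturable Michaelis–Menten reactions, $v = V_{max} C/(K_m + C)$, with
whole-organ $V_{max}$ obtained by protein-content scaling. MEHP is oxidised
onward into a cumulative downstream-metabolite sink and eliminated in
urine as $dA_u/dt = k_{urine} f_{up} A_{MEHP,ven}$. Molar mass balance is
audited at every output time. A lognormal Monte Carlo sampler
(`sample_parameters()`) propagates the tabulated parameter uncertainty;
default runs use medians.

See the methods vignette (`vignettes/dehp-pbpk-methods.Rmd`) for the full
equations, parameter provenance, numerical choices and limitations.

## Worked example

Two days of the reference dietary scenario — 1.95 mg/day as 0.5, 0.8 and
0.65 mg meals at 8, 12 and 18 h, each eaten over 30 min:

```r
library(dehptk)
sim <- run_paper_scenario("oral", days = 2)
sim
#> PBPK simulation: 48 h, 961 time points, dt = 0.05 h
#>   dosed: oral 3.9, dermal 0, inhalation 0 mg
#>   urine MEHP 0.0001369 mg, metabolite sink 2.773 mg at end
#>   worst molar mass-balance residual: 1.33e-13 (relative)

organ_peaks(sim, "liver", "DEHP")
#>   time_h   conc_ug_mL
#> 1    8.5 0.0007780067
#> 2   12.5 0.0012487370
#> 3   18.5 0.0010134319
#> 4   32.5 0.0007782160
#> 5   36.5 0.0012488623
#> 6   42.5 0.0010134898
```

Each meal produces one liver DEHP peak within the hour (the largest after
the biggest, 0.8 mg, midday meal); nearly all of the absorbed dose ends up
in the downstream-metabolite sink within the same day, which is why the
body carries only µg amounts between meals. Continuous routes instead rise
to a flat plateau:

```r
derm <- run_paper_scenario("dermal", days = 5)   # 0.68 mg/h into skin
equilibrium_concentration(derm, "endocrine", "DEHP")$value
#> [1] 0.0543952
```

the volume-weighted spleen+pancreas DEHP equilibrium in µg/mL.
`day_over_day_delta()` quantifies how fast repeated daily exposure
converges to its periodic steady state, and `run_koch_single_dose()`
reproduces the classic single-48.1-mg-oral-dose design, reporting
cumulative urinary MEHP and plasma MEHP.

A thin command-line wrapper is installed at `inst/cli/dehptk`
(`dehptk simulate --route dermal --days 5 --out out/`).

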