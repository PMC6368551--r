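# brinetrace

Geochemical analysis of athalassohaline (MgCl₂-dominated) deep-sea brine
lakes and their seawater–brine interfaces, for marine biogeochemists and
habitability researchers. The package answers three questions about such a
system from tracer profiles and exact-mass lists:

1. **How long have the sediments been in contact with the brine?**
   Pore-water tracer profiles (Mg²⁺, Cl⁻, δD) are fitted with the 1-D
   advection–diffusion model

   ∂C/∂t = Dₛ ∂²C/∂z² − Vₛ ∂C/∂z,

   whose closed-form solution for a constant brine reservoir over an
   initially uniform column is

   C(z,t) = C_bg + (C₀ − C_bg) · ½ [erfc((z − Vₛt)/(2√(D_h t/R_d))) +
   exp(Vₛz/D_h) · erfc((z + Vₛt)/(2√(D_h t/R_d)))],

   evaluated through the scaled complementary error function so it is
   stable at any depth. Inversion for the contact time is a bounded
   log-scale least-squares fit with multi-start, span-standardized joint
   fitting across tracers, and a residual-resampling bootstrap interval.

2. **Where does the halocline stop being habitable?** Interface samples
   are binned into the named layers (UIF/MIF/LIF) by Mg²⁺ concentration; a
   monotone (PCHIP-type) water-activity curve through measured anchors
   locates the depth of the recognized a_w = 0.585 limit for cell division
   and classifies each sample against both the a_w limit and the
   empirically observed 2,970 mM activity limit.

3. **What is the DOM made of?** Negative-mode exact masses ([M−H]⁻) are
   decomposed into CHNOS elemental formulas by exhaustive bounded search
   with chemical-plausibility filters (integer RDBE in [0, 20], H/C, O/C
   windows), then summarized as compound classes (CHO/CHNO/CHOS/CHNOS),
   class ratios, van Krevelen coordinates, sulfur histograms and
   between-sample unique fractions.

Seeded synthetic-data generators (`make_pore_profile()`,
`make_interface_profile()`, `synthetic_dom_formulas()`,
`make_peak_list()`) produce every input under the published parameter
sets, so the full pipeline runs and is tested without any external data.

## Worked example

```r
library(brinetrace)

# a synthetic Mg2+ pore-water profile under the published parameters
# (Ds 2.4e-10 m2/s, Vs 9.51e-11 m/s, brine 4720 / seawater 61 mmol/kg,
# emplacement 2.2e10 s, 2% measurement noise)
p    <- transport_params(Ds = 2.4e-10, Vs = 9.51e-11, C0 = 4720, Cbg = 61)
prof <- make_pore_profile("hephaestus_mg", seed = 42)
prof
#> <tracer_profile> Mg [mmol/kg], 16 depths, 0.1-3.1 m
#>  depth_m    value
#>      0.1 4802.262
#>      0.3 4525.345
#>      0.5 4505.615
#>      0.7 4417.867
#>      0.9 4280.261
#>      1.1 4114.627
#>   ... 10 more rows

bootstrap_age_ci(prof, p, n_boot = 500, seed = 1)
#> <age_estimate> t = 2.26e+10 s = 716.3 yr (rss 0.004111, n 16)
#>   95%-type bootstrap CI: [701.3, 750.8] yr
#>   per-tracer rss: Mg=8.923e+04
```

The fitted contact time, ~716 yr here, recovers the generating 2.2×10¹⁰ s
(697 yr) within the noise; the interval is a residual-resampling bootstrap.

```r
# water-activity structure of the 3-m halocline (70 -> 4720 mM Mg2+)
cv    <- fit_activity_curve(hephaestus_anchors())
iface <- make_interface_profile(n = 61, shape = "logistic")
locate_threshold_depth(iface, cv)$depth_m
#> [1] 1.822242
```

The recognized a_w = 0.585 limit for cell division falls at ~1.8 m —
roughly midway down the interface, so only its upper half lies in the
habitable window.

```r
# formula assignment of a deprotonated exact mass (glucose, [M-H]- at
# m/z 179.0561116)
decompose_mass(neutral_mass_from_mz(179.0561116), element_bounds(ppm_tol = 1))
#>   nC nH nN nO nS neutral_mass    ppm_error cls hc oc rdbe
#> 1  6 12  0  6  0     180.0634 0.0002700714 CHO  2  1    1
```

## Analysis workflow

The numbered drivers under `analysis/` run the full study as a narrative
workflow, writing delimited tables under `results/`:

```sh
Rscript analysis/01_simulate_profiles.R --seed 1   # all synthetic inputs
Rscript analysis/02_fit_ages.R         --seed 1    # contact-time inversion
Rscript analysis/03_interface_habitability.R       # layers, a_w limit
Rscript analysis/04_dom_formulas.R                 # CHNOS assignment
```

Each step's computation lives in the package; the drivers only narrate and
write tables. `run_pipeline()` offers the same stages as a single callable
with a structured, diffable JSON report (`write_report()`).

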