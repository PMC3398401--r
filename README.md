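# gapcanal

Dynamical-systems analysis of gap gene expression canalization in the
early *Drosophila* blastoderm.

Positional information along the fly's anterior-posterior axis starts as
a noisy maternal Bicoid (Bcd) gradient, yet the downstream gap gene
expression borders — the posterior border of the anterior *hunchback*
(*hb*) domain in particular — end up far more precisely placed than the
input. `gapcanal` is for researchers who want to study this variance
*filtration* mechanistically: it implements the four-gene gap circuit
(*hb*, *Kr*, *gt*, *kni*) as a tested, reusable pipeline and explains
border placement in the vocabulary of dynamical systems theory —
attractors, attraction basins, basin boundaries and unstable manifolds.

## The model

The circuit equations for gene *a* in nucleus *i* are

    dv_i^a/dt = R^a χ(t) g( Σ_b T^{ab} v_i^b + m^a v_i^Bcd
                            + Σ_e E^{ae} v_i^e + h^a )
                − λ^a v_i^a
                + D^a(n) [ (v_{i−1}^a − v_i^a) + (v_{i+1}^a − v_i^a) ],

with the sigmoid regulation function `g(u) = (u/√(u²+1) + 1)/2`, mitotic
gating `χ(t)`, nuclear division from cycle 13 (30 nuclei over 35–92 %EL)
into cycle 14A (58 nuclei), and external inputs from Bcd, Cad and Tll.
Dropping diffusion decouples the nuclei into independent 4-D systems (the
"shorted" model), whose equilibria, stability, symbolic 0/X/1 codes,
Bcd–Cad existence domains and saddle manifolds the package computes
directly. Attraction basins restricted to the biological initial segment
Ω = {0 ≤ Hb ≤ 100, Kr = Gt = Kni = 0} are estimated by seeded Monte-Carlo
sampling plus bisection sharpening; *hb* border positions, Bcd response
curves, border-formation mechanism labels (attractor–attractor,
attractor–manifold, ...), basin-transition families and positional
variance / filtration-rate tables follow.

Everything the pipeline consumes can be generated synthetically
(exponential Bcd ensembles with embryo-to-embryo variation, maternal Hb
gradients, Cad/Tll tables, circuit fixtures with verified phase
portraits, analytically solvable toys), so the whole analysis runs
without any external data.

## Worked example

```r
library(gapcanal)

params   <- gen_parameter_fixture("bistable_border")  # verified 1000/0100 bistability
inputs   <- gen_external_inputs()
ensemble <- gen_bcd_ensemble(12, preset = "narrow", seed = 42)
hb0      <- gen_maternal_hb()

run <- run_pipeline(params, ensemble, inputs$cad, hb0,
                    n_samples = 100, seed = 42, mechanisms = FALSE)
print(run)
#> Canalization analysis: 12 profiles, window 37-57 %EL
#>   families: I=12
#>   hb border sd: 0.593 %EL over 12 profiles
#>   Bcd threshold sd: 1.108 %EL
#>   intersection/border correlation: 0.995
```

Each embryo's record pairs its model *hb* border with the intersection of
the maternal Hb gradient and the crossed basin boundary:

```r
head(run$records[, c("profile_id", "A", "border", "intersection",
                     "transition", "family")])
#>   profile_id        A   border intersection transition family
#> 1          1 166.8253 51.87666     51.91211 1000->0100      I
#> 2          2 142.9281 50.63447     50.73477 1000->0100      I
#> 3          3 153.9225 51.14834     51.26523 1000->0100      I
#> ...
```

All twelve gradients cross from the basin of the hb-ON attractor (code
`1000`) into the basin of the Kr-ON attractor (`0100`) — a Family I
(ON→OFF) border. The variance table shows the canalization: the borders
spread about half as much as the Bcd threshold positions that drive them,

```r
run$summary[run$summary$family == "full", ]
#>                 row_label family  n full_range        sd
#> 3  Intersection positions   full 12   1.759375 0.5804918
#> 6     hb border positions   full 12   1.746921 0.5929014
#> 9 Bcd threshold positions   full 12   3.424718 1.1080288

filtration_rate(0.593, 1.108)
#> [1] 0.465
```

i.e. the circuit filtered ~46% of the input positional variance under
these synthetic conditions. The geometric reason — a decreasing maternal
gradient crossing a posteriorly *rising* basin boundary — can be isolated
with `opposite_slope_spread()`.

## Layout

- `R/` — model core (`integrate_full_circuit`, `integrate_shorted_nucleus`),
  phase space (`find_equilibria`, `scan_bcd_cad_plane`,
  `trace_unstable_manifold`), basins (`sample_basin_partition`,
  `basin_boundary_profile`, `intersect_initial_hb`), borders and response
  (`border_position_shorted/full`, `response_curve`, `pattern_mass`,
  `knockout_hb_inputs`), classification, statistics, synthetic
  generators, CSV/JSON IO and the `run_pipeline()` driver.
- `vignettes/gap-gene-canalization.Rmd` — the methods vignette: model
  assumptions, parameter meanings and defaults, numerical choices, what
  the synthetic data do and do not emulate, limitations.
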