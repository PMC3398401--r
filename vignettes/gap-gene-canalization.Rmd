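---
title: "Gap gene circuit dynamics and canalization of the hb border"
author: "gapcanal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gap gene circuit dynamics and canalization of the hb border}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gapcanal)
```

## The model

The early *Drosophila* blastoderm patterns its anterior-posterior (A-P)
axis by reading maternal morphogen gradients — chiefly Bicoid (Bcd) —
through the zygotic gap gene network. `gapcanal` implements the classical
gene-circuit model of the four trunk gap genes *hb*, *Kr*, *gt* and *kni*:
for gene $a$ in nucleus $i$,

$$
\frac{dv_i^a}{dt} \;=\; R^a\,\chi(t)\,
  g\!\left(\textstyle\sum_b T^{ab} v_i^b + m^a v_i^{Bcd}
  + \sum_e E^{ae} v_i^{e} + h^a\right)
  \;-\; \lambda^a v_i^a
  \;+\; D^a(n)\big[(v_{i-1}^a - v_i^a) + (v_{i+1}^a - v_i^a)\big],
$$

with the boundary diffusion terms dropped at the first and last nucleus.
$R^a$ is the maximal synthesis rate, $T^{ab}$ the regulatory weight of gene
$b$ on gene $a$, $m^a$ the Bcd weight, $E^{ae}$ the weights of the external
inputs Caudal (Cad) and Tailless (Tll), $h^a$ a threshold offset,
$\lambda^a$ the decay rate and $D^a(n)$ the per-cycle internuclear exchange
rate. The regulation function is the standard gene-circuit sigmoid

$$ g(u) = \tfrac12\left(\frac{u}{\sqrt{u^2+1}} + 1\right), $$

which is strictly increasing on $(0,1)$ with $g(0)=1/2$ and
$g(u)+g(-u)=1$. Concentrations are on a relative 0–255 scale.

$\chi(t)$ gates synthesis off during mitosis. The time axis starts at the
beginning of cleavage cycle 13 ($t_0 = 0$): interphase 13 occupies
$[0, 16)$ min, mitosis 13 $[16, 21.1)$ min, and cycle 14A
$[21.1, 71.1]$ min, subdivided into eight equal time classes T1–T8 of
6.25 min. These durations follow the timing convention of the gene-circuit
literature and are fully configurable through `mitosis_schedule()`. At the
13→14A transition every nucleus at odd-integer position $p$ (%EL) divides
into daughters at $p$ and $p{+}1$ that copy the parent state; daughters
posterior to the 92 %EL bound are dropped. This lattice convention is the
unique simple one reproducing all four modelled nucleus counts (30 and 58
over 35–92 %EL; 11 and 22 over 37–57 %EL), and those counts are what
`scripts/acceptance.R` recomputes.

After the end of time class T6 ($t = 58.6$ min) the earliest signs of the
mid-blastula transition appear, so the time-dependent Cad input is frozen
at its T6 value and $\chi \equiv 1$: the equations become autonomous.
External-input tables are interpolated linearly between time-class
midpoints with constant extrapolation before the first midpoint; we clamp
queries at the T6 *midpoint* rather than the class end so that evaluation
is continuous in time while still satisfying "any time after T6 evaluates
to the T6 value".

## The shorted model and its phase space

Setting $D^a = 0$ decouples the nuclei into independent four-dimensional
dynamical systems, one per position $x$ (the "shorted" model; Tll does not
act in the 37–57 %EL analysis region and is omitted there). Because the
per-nucleus equations depend on $x$ only through the inputs
$(v^{Bcd}, v^{Cad})$, they extend to real-valued $x$, and equally to any
point of the Bcd–Cad plane.

Equilibria of the autonomous system are found by deterministic multistart
Newton iteration (`find_equilibria()`): a regular grid of starting points
per gene over $[0,\ 1.2\,\max_a R^a/\lambda^a]$ plus a Halton
low-discrepancy set, analytic Jacobian
$J = \mathrm{diag}(R\,g'(u))\,T - \mathrm{diag}(\lambda)$, duplicate roots
merged within 0.5 concentration units, residual tolerance $10^{-9}$.
Stability is read from the Jacobian eigenvalues with a hyperbolicity
tolerance of $10^{-6}$ on real parts. Attractors are coded over
$\{0, X, 1\}$ per gene with thresholds 50/150 (e.g. `1000` = hb-ON,
`0100` = Kr-ON).

`scan_bcd_cad_plane()` maps attractor existence domains on a rectangular
input grid. We deliberately replaced numerical continuation with dense
multistart root-finding plus nearest-state label matching between
neighbouring nodes: it is reproducible, dependency-free and adequate at
the problem sizes used here. Boundary segments between nodes with
different labelled attractor sets are tagged saddle-node when the
disappearing attractor's leading eigenvalue is real and Hopf when it is a
complex pair; co-dimension-2 (Bogdanov–Takens) points appear only as
intersections of such segments, and limit cycles are not continued —
oscillatory attractors are never reached from the biological initial
conditions, so they are excluded from the basin analysis. Because label
matching by nearest state is our operationalization of visual continuity,
ambiguous matches flag the node instead of silently assigning a label.

One-dimensional unstable manifolds of saddles with a single unstable
eigenvalue are traced by integrating the autonomous flow from
$S \pm \epsilon \hat w$, with $\hat w$ the unit unstable eigenvector,
$\epsilon = 0.1$ units and a 500 min horizon.

## Attraction basins on the biological segment

Biologically meaningful initial conditions form the segment
$\Omega = \{0 \le v^{Hb} \le 100,\ v^{Kr}=v^{Gt}=v^{Kni}=0\}$: a maternal
Hb gradient atop zero zygotic expression. `sample_basin_partition()` draws
uniform Hb values on $[0, 100]$, integrates each through the nonautonomous
phase (mitotic gating, time-dependent Cad) and on until the autonomous
vector field drops below $10^{-6}$ in sup-norm (or 1000 min), assigns
endpoints to attractors within a capture radius of 1 unit, and condenses
the sorted labels into disjoint intervals $(c_1, c_2)$. Interval
boundaries are then sharpened by bisection between the innermost opposing
samples, so the reported partition always measures exactly 100 and the
boundary accuracy is set by the bisection tolerance, not by the
Monte-Carlo resolution $100/n$. The production setting uses 10 000 draws;
because bisection supplies the boundary precision, the test and pipeline
default operate at 100–1000 draws. On a one-dimensional bistable toy
system whose separatrix solves the scalar fixed-point equation
$R\,g(Tv + h) = \lambda v$ in closed form, the refined boundary agrees
with the separatrix to $10^{-3}$ (toy runs integrate the autonomous flow
throughout, since mitotic decay would otherwise compose an extra map in
front of the separatrix).

Basin boundaries are interpolated linearly in $x$ across nuclei
(`basin_boundary_profile()`), and `intersect_initial_hb()` locates every
crossing of the maternal gradient with a boundary curve by bisection to
0.001 %EL.

## Borders, mechanisms, families, classes

The *hb* border in a shorted-model solution is the anteriormost downward
half-maximum crossing of a first-order (piecewise-linear) spatial
interpolant; in the full model, whose solutions are smooth in space, it is
the inflection point of a third-order (cubic-spline) interpolant,
bracketed within ±3 %EL of the half-max crossing to avoid spurious cubic
wiggles (falling back to half-max, with a warning, when no inflection
exists). The half-max reference defaults to half the window maximum
because absolute saturation varies between solutions; a fixed reference
level can be supplied instead, which is what parameter sweeps (such as the
*hb* cross-regulation knockout) should use so that level crossings are
comparable across the sweep.

Per Bcd profile the pipeline labels:

* **mechanism** — which attracting set each border nucleus's trajectory is
  near at gastrulation time $\tau$: a point attractor (`A`, within
  $\delta_A = 5$ units) or a traced unstable-manifold branch (`M`, within
  $\delta_M = 5$ units), giving AA/AM/MA/MM. The closeness radii are our
  explicit surrogate for a visual criterion, are configurable, and
  nuclei matching neither are flagged rather than forced.
* **transition and family** — the attractors owning the maternal Hb value
  in the two border nuclei. A switch from an hb-ON to an hb-OFF attractor
  (e.g. `1000→0100` or `1100→0100`) is Family I; a transition between two
  distinct hb-ON attractors (`1100→1000`), where the hb-OFF state at the
  border is supplied by an attracting manifold, is Family II; identical
  owners on both sides mean the border forms without a basin transition
  (a rare, manifold-only case) and are left unclassified. We state the
  family rule at the level of attractor codes because the package labels
  attractors by code rather than by a continuation-assigned identity.
* **solution class** — a rule-based reading of the anterior Kr/gt pattern
  at $\tau$ on the full model: class I has an anterior gt domain (above
  the 128 half-scale level in the 35–50 %EL window) and a proper anterior
  Kr border (upward 128-crossing); class III lacks both the gt domain and
  any anterior Kr expression; class II covers the intermediate defects,
  typically ectopic anterior Kr in place of gt. The window and level are
  documented conventions, configurable in
  `classify_solution_class()`.

## Canalization statistics

`positional_summary()` reports the full range (max − min) and the sample
standard deviation (n − 1 denominator; the estimator choice is a
documented convention) of a set of positions.
`family_stratified_summary()` arranges intersection, border and Bcd
threshold positions by family. The Bcd threshold position of an embryo is
where its own exponential gradient crosses a fixed reference
concentration; the pipeline takes that reference as the median profile's
concentration at the median-model border, which reconstructs the usual
"Bcd threshold" notion and is flagged as a convention. The filtration
rate $1 - \sigma_{out}/\sigma_{in}$ quantifies how much positional
variance the network removes.

Two geometric mechanisms produce the filtration. First, the maternal Hb
gradient decreases with $x$ while the crossed basin boundary increases,
and opposite slopes pin the crossing: `opposite_slope_spread()`
demonstrates on linear families that the intersection spread shrinks by
the factor $|s_0 - s_b|_{\text{co}} / |s_0 - s_b|_{\text{opp}}$ relative
to a co-varying boundary of equal absolute slope. Second, the nonlinear
response of the boundary position to Bcd level (visible in
`response_curve()` output) compresses part of the input range; removing
*hb* cross regulation (`knockout_hb_inputs()`, zeroing the $T^{hb\cdot}$
row) linearizes the response, and on an amplitude-ordered synthetic
ensemble the knockout border position shifts strictly monotonically
posterior with amplitude.

## The synthetic generators

Quantified embryo ensembles and published fitted circuit parameters are
not shipped; the generators produce inputs with the statistical structure
the analysis assumes, and every fixture claim is re-verified inside the
test suite rather than trusted.

* `gen_bcd_ensemble()` draws $(A, l)$ lognormally. The defaults
  ($\bar A = 150$, $\bar l = 0.0665$ /%EL, i.e. a ≈15 %EL decay length)
  were chosen once as a realistic gradient scale. The `wide` preset
  ($A$ cv 0.3, $l$ cv 0.05) emulates the larger amplitude spread of basic
  background-subtraction normalization; the `narrow` preset ($A$ cv 0.08,
  $l$ cv 0) emulates variance-minimizing normalization and by
  construction yields a Bcd threshold-position sd of
  $\mathrm{sdlog}(A)/\bar l \approx 1.2$ %EL.
* `gen_raw_profiles()` adds a shared quadratic staining background,
  optional per-embryo scales/offsets and Gaussian noise on the 5–92 %EL
  axis, returning the generating truth for recovery tests. Exponential
  fitting (log-linear start, nonlinear least-squares polish via
  `minpack.lm`) recovers the truth exactly without noise; with noise the
  fit should be restricted (via `x_range`) to the region where the signal
  clears the noise floor, because the zero-flooring of background
  subtraction otherwise truncates the posterior tail upward and biases
  $\hat l$ low. Profiles whose log-linear fit has $R^2 < 0.9$ are flagged
  nonexponential (the rejection criterion itself is a convention).
* `gen_maternal_hb()` is a decreasing logistic bounded by $\Omega$'s
  range, 50 at its midpoint (default 47 %EL, steepness 5 %EL).
* `gen_external_inputs()` builds a smooth posteriorly increasing Cad
  surface with a mild rise over T1–T8 and a Tll profile that is exactly
  zero anterior of 70 %EL — in particular throughout the analysis window.
* `gen_parameter_fixture("bistable_border")` is a hand-designed circuit
  (mutual hb/Kr repression with weak self-activation, Bcd activating hb,
  Cad activating Kr) whose autonomous phase portrait across the window
  has exactly the attractor pair `1000`/`0100` with a posteriorly rising
  basin boundary that crosses the default maternal gradient inside
  37–57 %EL. `gen_toy_system()` supplies the analytically solvable
  oracles: a 1-D bistable system with separatrix exactly 50 (the
  threshold $h$ is chosen so $g(u(50)) = \lambda\,50/R$ holds
  identically) and a symmetric 2-D mutual-repression system whose saddle
  sits exactly at $(100, 100)$ with eigenvalues
  $-\lambda \pm R\,g'(0)\,|T_{12}|$ along $(1, \mp 1)$.

What the synthetic conditions do **not** emulate: imaging noise statistics
of real embryo databases, nuclear-level quantification noise, correlated
$(A, l)$ variation, maternal patterns of the other gap genes (zero at
cycle-13 start, as in the biology), and the full richness of the fitted
circuits (six attractors, Hopf/Bogdanov–Takens structure, class II/III
anterior defects arising from missing anterior regulators). Passing tests
therefore validate the machinery and the geometric canalization
mechanisms, not the quantitative variance tables of any particular fitted
circuit, whose reproduction requires the original embryo ensemble and
fitted parameter tables.

## Numerical choices

* Integration: `deSolve::lsoda` (adaptive, stiff-capable) for small
  systems, restarted exactly at the $\chi$ discontinuities, the division
  event and the T6 freeze; adaptive `ode45` for large vectorized
  ensembles of independent nuclei, where a stiff solver's Jacobian cost
  would dominate. Default tolerances $10^{-8}$ (relative and absolute).
* States are never clamped; negativity beyond $10^{-6}$ raises a
  diagnostic instead of silent truncation.
* Newton steps are clipped to the search-box diameter; non-converged
  starts are discarded.
* Degenerate inputs: all-identical ensembles normalize with zero
  variance (not an error); flat profiles are flagged nonexponential;
  borders absent from a window raise a typed condition
  (`gapcanal_border_absent`) that the pipeline records as a flag.
* Ties: the median profile breaks distance ties by smallest embryo id;
  interval ownership at an exact basin boundary goes to the lower
  interval.

## Problem sizes

The shipped test suite runs the complete pipeline on a 50-embryo narrow
ensemble at 100 Monte-Carlo draws per partition with bisection refinement
(boundary tolerance 0.01 Hb units), 11 basin nuclei and a 0.25 %EL border
grid — sizes we consider adequate because every stochastic quantity the
assertions touch is bisection-refined or averaged. Production analyses can
raise `n_samples` to the canonical 10 000 and add positions freely; cost
scales linearly in profiles × positions × samples.

## Known limitations

* Parameter fitting (simulated annealing against expression data) is out
  of scope; circuits must be supplied or generated.
* Limit cycles are detected only indirectly (Hopf-tagged boundaries);
  basins are computed for point attractors only.
* The plane-scan label matching can mislabel across a fold if the grid is
  far coarser than the attractor separation; flagged nodes mark where to
  refine.
* Mechanism labels at $\tau$ depend on the closeness radii; slowly
  converging trajectories near basin boundaries legitimately sit between
  `A` and `M` and are re-checked at $\delta/2$ in careful analyses.
* Geometry is one-dimensional (%EL positions); no cylindrical or 3-D
  embryo geometry, and nothing anterior of 35 %EL or posterior of
  92 %EL.
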