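---
title: "Melting thermodynamics and conformer dynamics of DNA four-way junctions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Melting thermodynamics and conformer dynamics of DNA four-way junctions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fourway)
```

## Scope

DNA four-way (Holliday) junctions are branched intermediates of
recombination and repair. Four strands -- labelled X, R, H and B in the
Lilley convention -- pair into four duplex arms that meet at a branch point.
In solution the junction interconverts between an unstacked **open** form
(roughly four-fold symmetric; square-planar at low salt, tetrahedral
variants at high salt) and two antiparallel **stacked** conformers,
**iso-I** and **iso-II**, which differ in their coaxial stacking partners.

`fourway` analyses coarse-grained junction trajectories (three sites per
nucleotide: sugar, phosphate, base) and UV melting data. It covers four
connected tasks:

1. **Topology** -- build the site/base-pair representation of a junction and
   idealized conformer geometries;
2. **Melting** -- estimate the single-strand fraction from frame ensembles or
   absorbance curves, fit the tetramolecular van't Hoff model, and compute
   Debye screening lengths;
3. **Conformers** -- classify frames as open/iso-I/iso-II from core
   inter-base distances, and estimate ensemble populations, transition
   probabilities and inter-duplex angles;
4. **Synthetic data** -- a generator with the statistical structure that the
   analysis assumes, used to validate every estimator end to end.

## The junction topology

Each nucleotide contributes three sites, with no phosphate on the
5'-terminal nucleotide, so a strand of $n$ nucleotides has $3n - 1$ sites.
A junction with 17-bp arms (four 34-nt strands, the "J34" architecture)
therefore has $4 \times 101 = 404$ sites:

```{r topo}
topo <- build_topology(example_j34_sequences(), arm_length = 17)
topo
```

Strands follow the cyclic order X-R-H-B; arm XR pairs the 3' half of X
antiparallel with the 5' half of R, and likewise for RH, HB and BX. The arm
set (XR, RH, HB, BX) is chosen so that the inter-duplex angle between the
XR and RH arms -- the angle reported by FRET experiments on this junction --
is well defined.

The *core markers* are the eight bases flanking the branch point (the
innermost nucleotide of each strand half, overridable in the junction
definition file since marker choices on real junctions are a curation
decision). They form four labelled non-complementary pairs: TT and CC
(spanning strands X and H) and two AG pairs (spanning R and B). The shipped
`inst/extdata/j34_synthetic.yaml` is a *synthetic* stand-in sequence with
this core architecture; the true J34 sequence is published only as a figure
and is not machine-readable, so we do not pretend to reproduce it.

## Conformer classification

In stacked conformers, one diagonal pair of core bases is pinched together
while the other is pushed apart; in the open form all four separations are
comparable and large. Pooled over an equilibrium ensemble, the distance
distributions are bimodal with a minimum near 12 Å, which is used as the
classification cutoff:

* signature~I~ = max(d~TT~, d~CC~), signature~II~ = max(d~AG1~, d~AG2~);
* **iso-I** if signature~I~ < 12 Å ≤ signature~II~; **iso-II** for the
  reverse; **open** if both are long.

The max-aggregation rule (both signature distances must be short) is
deliberately conservative: a frame with one short and one long signature
distance is not confidently stacked. Frames in which *both* signatures are
short are labelled **ambiguous** and reported separately rather than
silently assigned; they are excluded from transition counting (a
carry-forward alternative would be easy to add, but silent assignment would
inflate stacked fractions). A core-distance criterion classifies H-like
shapes with an open centre as open, so it systematically yields a smaller
stacked fraction than end-to-end (FRET-like) criteria -- a property of the
definition, not a defect.

```{r classify}
iso2 <- idealized_geometry(topo, "iso-II", nominal_ida = 43)
core_distances(iso2$coords, topo)
classify_frame(core_distances(iso2$coords, topo))
```

### Idealized geometries

`idealized_geometry()` builds template coordinates per conformer: arms are
straight helical-axis proxies radiating from a common vertex (planar at 90°,
tetrahedral at 109.47°, or two pseudo-duplex axes crossing at the nominal
inter-duplex angle for the stacked forms). Base pairs sit on a regular
lattice (default rise 3.3 Å, lateral base offset 2 Å); the eight core-marker
bases are placed explicitly so the conformer's distance signature holds by
construction (signature pairs at 5 Å, complementary pairs at 18 Å, centroid
at the vertex). These are geometric scaffolds for classification and
rendering, not energy-minimized structures: a physically faithful stacked
junction would offset the two helices laterally, but that cannot satisfy
both the nominal-angle constraint and the long-pair requirement for
arbitrary angles with on-axis arms, and nothing downstream consumes more
than distances and arm directions.

### Inter-duplex angle

The IDA is computed with the vertex at the centroid of the eight core-marker
bases and each arm direction pointing from the vertex to the centroid of the
arm's terminal base pair. These centroid choices are our own convention
(the quantity itself is standard in junction FRET work); they are exact on
the templates (90° planar, 109.47° tetrahedral, the nominal angle for
stacked templates).

## Melting thermodynamics

A junction dissociates into four distinct strands, each at concentration
$C/4$ where $C$ is the total strand concentration. The two-state
tetramolecular mass action law links the single-strand fraction $\alpha$ to
the equilibrium constant:

$$
K(T) \;=\; \exp\!\left(\frac{\Delta S}{R} - \frac{\Delta H}{R\,T}\right)
\;=\; \frac{\alpha^4\,(C/4)^3}{1-\alpha},
$$

with $\Delta H, \Delta S > 0$ in the melting direction, assumed constant
over the transition. The left side is strictly increasing in $\alpha$, so
`vant_hoff_alpha()` finds the unique root in $(0,1)$ by a bracketed solver
(tolerance $10^{-12}$, Newton-polished; far outside the transition the
asymptotic limits $\alpha \approx e^{\text{rhs}/4}$ and
$1-\alpha \approx e^{-\text{rhs}}$ are used to avoid overflow).

Setting $\alpha = 1/2$ at the melting temperature gives
$K(T_M) = (C/4)^3/8$ and the identity

$$
\Delta H \;=\; T_M\,\Delta S - R\,T_M \ln\!\frac{(C/4)^3}{8},
$$

implemented as `enthalpy_entropy_identity()`. `fit_vant_hoff()` recovers
$T_M$ from its fitted parameters through this identity in closed form, so
every fit satisfies it to machine precision; the identity also explains why
$\Delta H$ versus $\Delta S$ "compensation" plots are only approximately
linear (the logarithmic term depends on $C$, and $T_M$ varies).

### Fitting choices

* Only points with $0.1 < \alpha < 0.9$ enter the fit. The window is
  applied **iteratively on the fitted model's** $\alpha$, not on the
  observed values: selecting points by their noisy $\alpha$ couples the
  selection to the noise and biases $\Delta H$ low by about half a percent
  at $\sigma_\alpha = 0.02$, while model-based selection is unbiased. On
  noiseless data the two rules coincide.
* Optimizer: Levenberg-Marquardt trust region (`minpack.lm`), tolerances
  $10^{-10}$, initialized from a two-point van't Hoff line through the
  interpolated $\alpha = 0.25$ and $0.75$ crossings.
* `melting_temperature()` interpolates the $\alpha = 1/2$ crossing
  linearly; non-monotone (noisy) curves are first smoothed by isotonic
  regression, which also resolves multiple crossings.
* Units: kcal/mol, K, Å, mol/L; $R = 1.987204 \times 10^{-3}$
  kcal/(mol K).

### Distance-based $\alpha$ from trajectories

A base-pair bond is intact when the base-site separation is below 10 Å, and
a strand is *single* when strictly more than half of its possible base-pair
links are broken (so exactly half broken is not single). On clean synthetic
frames the resulting $\alpha$ is exactly invariant for cutoffs in 7-12 Å
and broken-fraction thresholds in 0.40-0.60, mirroring the robustness of
the criterion on real trajectories. $\alpha$ is the number of single
strands over all frames divided by $4\times$ the frame count.

### Absorbance curves

`absorbance_to_alpha()` fits linear sloping baselines on user-declared
windows (the standard treatment when only buffer subtraction is specified)
and maps $\alpha = (A - A_\mathrm{low})/(A_\mathrm{up} - A_\mathrm{low})$,
clipped to $[0,1]$. Known baseline coefficients can be passed directly,
making the conversion the exact algebraic inverse of the forward model.

### Debye screening

`debye_length()` evaluates
$\lambda_D = \sqrt{\varepsilon_0 \varepsilon_r k_B T / (2 N_A e^2 I)}$ with
CODATA constants. The default permittivity is a fixed
$\varepsilon_r = 78$; an empirical temperature- and salt-dependent model
(the water/NaCl dielectric fit used by coarse-grained DNA force fields) is
opt-in because its coefficients come from the force-field literature rather
than from anything this package measures. At 300 mM monovalent salt and
300 K both models give $\lambda_D < 6$ Å, the screening regime in which
junction melting becomes insensitive to added salt.

## The synthetic generator and what it does (not) show

The generator replaces a molecular-dynamics engine at desk scale with the
*statistical* structure the analysis consumes:

* **Kinetics** -- an exact continuous-time Markov chain over
  (open, iso-I, iso-II) with the direct iso-I ↔ iso-II rate fixed at zero:
  the open state is the obligatory intermediate. Dwell times are
  exponential (Gillespie sampling); the exact jump path is retained
  alongside the discretized frames, so event-level checks (every
  stacked-to-stacked inter-conversion contains an open dwell) are exact.
  Frame-level direct I↔II transitions can arise only from discretization
  and vanish as $\Delta t \to 0$.
* **Geometry** -- each frame is its state's template plus isotropic Gaussian
  site noise $\sigma$ and a random rigid motion. At $\sigma = 1$ Å the
  template margins (≥ 6 Å to the 12 Å cutoff) make misclassification
  rates negligible (a distance perturbs by roughly
  $\mathcal{N}(0, \sigma\sqrt{2})$ per axis).
* **Melting frames** -- per temperature, frames are melted with probability
  $\alpha(T)$ from the mass-action model; base-pair separations are drawn
  uniformly from [4, 8] Å (intact) or [12, 30] Å (melted), ranges that
  deliberately straddle the 10 Å criterion. An independent per-pair mode
  generates partially melted junctions that exercise the
  more-than-half-broken rule non-trivially. The robustness analysis passes
  explicit ranges clear of the tested 7-12 Å cutoff band ([4, 7) and
  [12, 30)), since draws inside the band would measure the overlap of the
  ranges with the cutoff rather than the estimator.
* **Reproducibility** -- one master seed; member seeds derive from a Lehmer
  step plus member counter (never colliding for a fixed master), and every
  seed is recorded in the objects and file headers.

Default study conditions: 100 members × 2000 ns at 1 ns frame spacing
(frame-save intervals are a free choice; 1 ns resolves the ~0.5 ns open
dwells at the default rates), all-open initial states, with a second-stage
protocol re-seeded from a first-stage population estimate. The default
kinetic model pins the stationary populations at 6/36/58 %
(open/iso-I/iso-II), the high-salt equilibrium composition of this
junction, with a short-lived open state. Ensembles matter because
inter-conversion is slow relative to single trajectories ("broken
ergodicity"): the population estimate averages members with equal weight
and reports the member-to-member standard error.

What passing these tests shows: the estimators are calibrated and
internally consistent on data satisfying their own assumptions. What they
do not show: two-state behaviour, exponential dwells, isotropic noise or
temperature-independent $\Delta H, \Delta S$ in real junction trajectories
-- those are modelling assumptions that real data can violate (partially
melted intermediates, ion-mediated core rearrangements, sequence-dependent
core geometry).

## Numerical and degenerate-input policy

* `vant_hoff_alpha` warns and returns the limiting 0/1 when no bracket is
  numerically possible.
* A kinetic state with zero exit rate is absorbing: the series is constant,
  not an error.
* Transition-matrix rows with no observations are NA and flagged
  `undefined_rows`; states with zero frames are *absent* from IDA
  statistics, not reported as zero.
* Classification at exactly the cutoff counts as "long" (strict `<` for
  short), and strand melting at exactly the threshold counts as "not
  single" (strict `>`), matching the respective definitions.
* Degenerate (zero-length) arm vectors in the IDA are an error rather than
  an arbitrary angle.

## Problem sizes used in the shipped checks

The validation suite runs ensembles of 100 members × 2000 frames for
kinetic recovery, 10 × 4·10^5 fine-spacing frames for the
direct-transition bound, 100 replicate noisy curves (σ~α~ = 0.02, 50
points) for estimator calibration, a 10^4-point grid for the classifier
truth table, and 10^7-point dense grids as the brute-force oracle for the
mass-action solver. These sizes give standard errors comfortably below the
tolerances being checked while keeping the whole suite in the tens of
seconds on a laptop.

## Known limitations

* The conformer surrogate is Markovian with template geometries; it does
  not emulate partially stacked intermediates, branch migration, or
  ion-binding heterogeneity.
* The melting model is strictly two-state; no per-arm nearest-neighbour
  thermodynamics (SantaLucia-style predictions are out of scope).
* The transition matrix is an empirical lag count, not a Markov state
  model; no lag-convergence or spectral analysis is attempted.
* LAMMPS dump support is read-only and limited to orthogonal-box
  `id/x/y/z`-style ATOMS sections.
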