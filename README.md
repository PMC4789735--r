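# fourway

Thermodynamics and conformer dynamics of DNA four-way (Holliday) junctions.

Four-way junctions are branched DNA intermediates of recombination and
repair: four strands (labelled X, R, H, B) pair into four duplex arms that
meet at a branch point. In solution a junction interconverts between an
unstacked **open** form and two antiparallel stacked conformers, **iso-I**
and **iso-II**, with the open state acting as the obligatory intermediate.
`fourway` is an analysis toolkit for coarse-grained junction trajectories
(three sites per nucleotide: sugar, phosphate, base) and UV melting
experiments, aimed at people studying junction stability and conformer
populations with coarse-grained simulation or spectroscopy.

## What it computes

**Melting.** A junction dissociates into four distinct strands, each at
concentration C/4. The two-state tetramolecular van't Hoff model

    K(T) = exp(ΔS/R − ΔH/(R·T)) = α⁴ (C/4)³ / (1 − α)

links the single-strand fraction α to the melting enthalpy and entropy.
The package estimates α from trajectory frames (a base-pair bond is intact
below 10 Å; a strand is single when more than half its links are broken) or
from absorbance curves with sloping baselines, fits (ΔH, ΔS) by
Levenberg–Marquardt least squares inside the 0.1 < α < 0.9 window, and
extracts T_M via the identity ΔH = T_M·ΔS − R·T_M·ln[(C/4)³/8] (α = 1/2 at
T_M). Debye–Hückel screening lengths λ_D = √(ε₀ε_r·k_B·T / 2N_A e² I)
quantify the high-salt regime.

**Conformers.** Frames are classified from the four core inter-base
distances (the TT and CC pairs on strands X/H, the two AG pairs on R/B)
with a 12 Å cutoff: both signature distances short ⇒ stacked isoform, both
diagonals short ⇒ ambiguous, otherwise open. On top of the per-frame labels
the package computes pooled distance distributions, ensemble population
fractions with member-to-member standard errors, lagged transition
matrices, and inter-duplex angles (IDA, the XR–RH arm angle at the junction
vertex).

**Synthetic data.** A seeded generator — an exact continuous-time Markov
chain over the three conformers (direct iso-I↔iso-II rate fixed at zero)
rendered onto idealized geometric templates, plus mass-action melting
frames and absorbance curves — provides ground truth for every estimator.

## Worked example

```r
library(fourway)

topo <- build_topology(example_j34_sequences(), arm_length = 17)
topo
#> Four-way junction topology: 4 strands x 34 nt, 404 sites, 68 base pairs
#> Arms: XR, RH, HB, BX (17 bp each)

# conformer kinetics: 25 members, 2 microseconds each, 1 ns frames
ens <- simulate_ensemble(default_kinetic_model(), n_members = 25,
                         duration = 2000, seed = 11)
population_fractions(ens)
#> Conformer populations over 25 member(s):
#>   open         6.06%  (SE 0.09%)
#>   iso-I       36.45%  (SE 1.02%)
#>   iso-II      57.49%  (SE 1.02%)
#>   ambiguous    0.00%  (SE 0.00%)
transition_matrix(ens)
#> Conformer transition matrix (lag 1 frame(s), 49975 transitions):
#>          open  iso-I iso-II
#> open   0.1778 0.3083 0.5139
#> iso-I  0.0525 0.9075 0.0400
#> iso-II 0.0525 0.0266 0.9209

# melting: distance-based alpha through the full pipeline, then the fit
dS <- 0.1375; Tm <- 340; C <- 6e-7
dH <- enthalpy_entropy_identity(dS, Tm, C)   # 80.004 kcal/mol
truth <- melting_ground_truth(dH, dS, C, seq(310, 370, by = 2))
mf <- simulate_melting_frames(truth, topo, n_frames = 200, seed = 12)
alpha_hat <- sapply(mf, function(e) single_strand_fraction(e$frames, topo))
fit_vant_hoff(melting_curve(truth$temperatures, alpha_hat, C = C))
#> van't Hoff fit (tetramolecular two-state, C = 6e-07 mol/L)
#>   dH  = 79.688 kcal/mol
#>   dS  = 0.13617 kcal/(mol K)
#>   T_M = 340.59 K
#>   16 points in window (0.1, 0.9), residual norm 0.0955

debye_length(300, 0.300)   # 300 K, 300 mM Na+
#> [1] 5.553445
```

The ensemble populations recover the generator's stationary distribution
(6/36/58 % open/iso-I/iso-II) with the quoted member-to-member standard
errors; the small iso-I↔iso-II entries of the transition matrix are pure
1-ns discretization artifacts — the exact jump paths never join the stacked
states directly. The fitted ΔH/ΔS/T_M agree with the generating values
within the binomial noise of 200 frames per temperature, and the screening
length at 300 mM is below 6 Å, the regime where junction melting becomes
salt-insensitive.

A thin command-line interface wraps the same functions
(`inst/exec/fourway`): subcommands `topology`, `debye`, `synthesize`,
`classify`, `populations`, `transitions`, `melt-frames`, `melt-fit`,
`absorbance`, `ida`.

## Package layout

- `R/topology.R`, `R/geometry.R` — junction topology and idealized conformer templates
- `R/melting.R` — α estimation, van't Hoff fit, T_M, Debye lengths
- `R/conformers.R` — classification, populations, transitions, IDA
- `R/synthetic.R` — CTMC/rendering/melting-frame generators
- `R/io.R`, `R/cli.R` — extended-XYZ and LAMMPS-dump readers, CSV/JSON/YAML I/O, CLI
- `vignettes/junction-analysis.Rmd` — the model, its assumptions and design choices
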