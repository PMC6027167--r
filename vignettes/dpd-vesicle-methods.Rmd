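---
title: "Mesoscale modeling of chitosan-coated, capsaicin-loaded nanoliposomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mesoscale modeling of chitosan-coated, capsaicin-loaded nanoliposomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`dpdvesicle` simulates and analyzes a drug-delivery nanocapsule at the
mesoscale: a closed lecithin bilayer vesicle (a nanoliposome) that absorbs a
hydrophobic drug (capsaicin) into its membrane while a polysaccharide
(chitosan) deposits on its outer surface. This vignette explains the model,
the parameters that matter, and the design decisions behind the package, in
the spirit of a methods section.

## The DPD model

Dissipative particle dynamics (DPD) evolves soft beads, each standing for a
group of atoms, under three pairwise forces acting along the line of
centers for separations $r < r_c$:

* a **conservative** soft repulsion $F^C = a_{ij}\,(1 - r/r_c)\,\hat r$,
* a **dissipative** drag $F^D = -\gamma\, (1 - r/r_c)^2 (\hat r \cdot
  \mathbf v_{ij})\, \hat r$,
* a **random** kick $F^R = \sigma\, (1 - r/r_c)\, \theta_{ij}\,
  \hat r / \sqrt{\delta t}$,

with $\theta_{ij} = \theta_{ji}$ a symmetric unit-variance variate redrawn
every step. The weight functions satisfy $w^D = (w^R)^2$ and the amplitudes
$\sigma^2 = 2\gamma k_BT$, which together make the dissipative/random pair a
momentum-conserving thermostat sampling the canonical ensemble — the key
property the test suite verifies (a pure solvent fluid at reduced density 3
holds $k_BT = 1$ within 5% and drifts less than $10^{-8}$ momentum per bead
over the run). Bonded beads additionally feel a harmonic spring
$F = -k_s (r - r_0)\hat r$.

All quantities are reduced: lengths in the cutoff $r_c = 1$, energies in
$k_BT = 1$, masses 1. Physical lengths are recovered with a configurable
`length_scale` (default 0.646 nm per $r_c$, the common three-waters-per-bead
mapping at reduced density 3).

Integration uses the modified velocity-Verlet scheme with velocity
prediction factor $\lambda$: positions advance with the current forces,
velocities are predicted as $v + \lambda\,\delta t\,f$, forces are
recomputed, and velocities corrected with the mean of old and new forces.
Defaults $\delta t = 0.03$, $\lambda = 0.65$, $\gamma = 4.5$ (so
$\sigma = 3$) are the standard choices for reduced-density-3 DPD fluids.

Two numerical conventions worth noting: a coincident pair ($r = 0$) feels
zero force — the direction is undefined and the event has measure zero under
soft potentials; and the per-pair noise is *counter-based*, hashed from
`(seed, step, i, j)` with $i<j$, so $\theta_{ij} = \theta_{ji}$ holds
exactly, runs are bit-reproducible, and a checkpointed state (which carries
its force array) continues an unbroken trajectory identically.

The force loop uses a cell list with counting-sort binning into contiguous
per-cell ranges (an all-pairs fallback engages automatically when any box
edge is under $3 r_c$); the tests verify exact set-equality of the cell-list
pair enumeration against a brute-force oracle.

## Coarse-grained molecules

Nine bead types are used:

| bead | role |
|------|------|
| `L1`, `L2`, `L3` | lecithin head, neck, tail |
| `C1`, `C2`, `C3` | capsaicin head (vanillyl), neck (amide), tail (aliphatic) |
| `G` | chitosan d-glucosamine (GlcN, deacetylated) |
| `A` | chitosan N-acetyl-d-glucosamine (GlucNA, acetylated) |
| `W` | water (three waters per bead) |

The default lecithin is 1 `L1` + 1 `L2` + two tails of 3 `L3` (8 beads,
7 bonds), reflecting the two acyl chains of a phosphatidylcholine; only the
three bead *roles* are fixed by the model — the grouping granularity (beads
per tail, tails per lipid) is a package choice, fully configurable via
`lecithin_topology()`.
Capsaicin is a linear `C1`–`C2`–`C3` trimer, one bead per named group.
Chitosan is one bead per monomer on a linear chain.

Chitosan acetylation patterns are written in the field's block notation and
parsed by `parse_sequence_spec()`; decorative dashes between tokens are
ignored. Two built-in 50-mers share 30% acetylation but differ in pattern:
`S1` spreads isolated GlucNA units quasi-uniformly, `S2` concentrates them
in blocks. Terminology: the package reports the **acetyl fraction**
(GlucNA share); the complementary deacetylated fraction is sometimes also
called "DA" in the literature, so the package standardizes on one
definition and documents it.

## Interaction parameters

The conservative repulsion table follows the compressibility rule
$a_{ii} = 25$ at density 3 and encodes hydrophobic/hydrophilic contrasts as
offsets from the water baseline (`default_interaction_matrix()`):

* tails (`L3`, `C3`) vs. water: 80 — drives bilayer integrity and drug
  partitioning;
* chitosan vs. lecithin head: `G`–`L1` = 20, `A`–`L1` = 22 (below water's
  25, i.e. effectively attractive) — drives surface adsorption;
* `A`–`A` = 23, `A`–`W` = 28 — a mild hydrophobicity of the acetylated
  monomer that allows cooperative association of blocky sequences;
* chitosan vs. tails: 75–80 — the polymer coats the surface but does not
  enter the membrane;
* capsaicin tail vs. lipid tail: 25 (like dissolves like).

These defaults reproduce the qualitative physics (stable vesicle, membrane
uptake of the drug, surface deposition of the polymer) and every entry can
be overridden in the config; they are package defaults, not fitted
constants, and quantitative observables (PMF well depths, EE values) will
shift with them.

## Building the study system

`build_system()` assembles the initial configuration in three stages:

1. **Vesicle** — lipids on two concentric leaflets; outer-leaflet heads on
   the sphere of radius $R_\mathrm{out}$, inner-leaflet heads at
   $R_\mathrm{out} - t$ (bilayer thickness $t$), tails toward the bilayer
   interior, lipid count per leaflet $= \mathrm{round}(4\pi R^2 / a_\ell)$
   with $a_\ell$ the area per lipid. Head positions use a deterministic
   Fibonacci lattice.
2. **Solutes** — each capsaicin and chitosan molecule grows as a bonded
   random walk (step 0.7 $r_c$) started uniformly outside
   $R_\mathrm{out} + 1$, with every bead kept outside the vesicle radius.
3. **Solvent** — `W` beads fill the box uniformly at random to exactly
   `round(3 V)` total beads. Overlaps are permitted (soft potentials); a
   short capped-force relaxation (default 1000 steps at force cap 50)
   removes initial stresses in place of any exclusion test.

The default box is **calibrated to the printed concentrations**: its
physical volume makes 50 solute chains correspond to 6 mM, so 100, 150 and
200 chains are 12, 18 and 24 mM in the same box — `concentration_of()` and
`volume_from_calibration()` are exact inverses. At the default length scale
this gives a cube of ${\sim}37\,r_c$ (about 154,000 beads), with vesicle
defaults ($R_\mathrm{out} = 14$, $t = 3.5$, $a_\ell = 1.25$) chosen so the
relaxed liposome diameter lands near 18 nm.

What the generator emulates: the study's initial condition — a preformed,
monodisperse vesicle with the drug and polymer dispersed at controlled
concentration outside it, at global reduced density 3. What it does not:
spontaneous self-assembly, electrostatics and pH-dependent protonation of
chitosan, polydisperse chain lengths, or thermal area/volume fluctuations of
a pre-relaxed membrane. Passing tests therefore show that the *mechanisms*
(uptake, surface deposition, competitive adsorption) operate in the model;
they do not validate the quantitative mapping onto any particular
experimental formulation.

## Observables

* **Density maps** (`density_map_xy()`): time-averaged bead density on the
  $xy$ plane, restricted to a $z$-slab (default 2 $r_c$ thick) through the
  vesicle center, bins 0.5 $r_c$. Normalization is exact: the integral of
  the map recovers the mean in-slab bead count.
* **Radial profiles** (`radial_density_profile()`): spherical shells
  (default 0.25 $r_c$) around the per-frame lecithin center, computed with
  a circular mean so a vesicle straddling the periodic boundary is handled
  correctly. Valid to half the smallest box edge.
* **PMF** (`pair_gr()` + `pmf_from_gr()`): the potential of mean force
  between molecular centers of mass, $w(r) = -k_BT \ln g(r)$, with $g(r)$
  the minimum-image COM pair correlation (bins 0.1 $r_c$, self-pairs
  excluded) and $w$ anchored to zero over the outermost 10% of sampled
  bins. Bins with $g = 0$ are undefined rather than infinite. This is the
  simplest estimator consistent with reporting PMFs against COM
  separation; constrained force integration would be the next refinement.
  Molecule COMs unwrap each molecule by chaining minimum-image steps
  between consecutive beads before averaging.
* **Vesicle size** (`mean_diameter()`): twice the outermost radius at
  which the lecithin radial density falls to half its peak (linear
  interpolation between shells), with a block-standard-deviation
  uncertainty over frame blocks (default 5). The half-maximum convention
  makes the metric insensitive to the peak height and robust to membrane
  thickening as the drug loads.
* **Encapsulation efficiency**: $EE = (Caps_T - Caps_F)/Caps_T \times
  100$. A capsaicin molecule counts as *free* when its COM lies beyond the
  lecithin outer half-maximum radius plus 1 $r_c$ — the classifier follows
  the measured membrane edge rather than a fixed radius; the offset is
  configurable. Per-frame free counts give the EE mean and spread.

The reported uncertainties are block standard deviations over trajectory
frames; treat them as spread indicators, not calibrated standard errors.

## Desk-scale study conditions

The full calibrated system is too large for routine single-CPU work, so the
package fixes a **reduced preset** (`reduced_experiment()`) that preserves
the design at desk scale: vesicle $R_\mathrm{out} = 6.5$, $t = 3.5$,
$a_\ell = 1.0$ (about 640 lipids), 25 capsaicin, 5 chitosan 50-mers, cubic
box of 18 $r_c$ at density 3 (about 17,500 beads), 1000 capped-force
relaxation steps, $10^5$ production steps with the last 50% analyzed. The
vesicle radius is set by the analysis geometry: the 8-bead lipid forms a
membrane about 5 $r_c$ thick, and the radial profiles and the free-drug
boundary are only valid inside half the box edge, so the membrane's outer
slope must die off well before $L/2$ — at larger radii the aqueous
"far field" annulus vanishes and profile-based observables degrade.
The acceptance checks also use a further-reduced vesicle
($R_\mathrm{out} = 6$, box 15, 25,000 steps) to compare the
lecithin–chitosan PMF at two chain counts, and a flat 200-lipid periodic
bilayer patch (box $10^3$, 20,000 steps) for membrane cohesion. These sizes
are the package's chosen study conditions for its own verification; the
full-scale presets (`cs_sweep_preset()`, `sequence_preset()`) expose the
original four-concentration and two-sequence experiments.

For the cohesion check, a lipid counts as shed when a terminal tail bead
sits beyond the membrane core half-thickness (bead content per area,
$\approx (B/3)/a_\ell$ with $B = 8$ beads per lipid) plus a 1.5 $r_c$
interface margin from the bilayer mid-plane; the default 8-bead lipid forms
a core roughly 5 $r_c$ thick, so thresholds must scale with the topology
rather than assume a thin membrane.

## Worked example

```{r example}
library(dpdvesicle)

cfg <- reduced_experiment(n_chitosan = 5, production_steps = 1e5,
                          rng_seed = 1, output_dir = "results")
res <- run_experiment(cfg, verbose = TRUE)
res$summary
# radial structure: membrane, drug in the shell, polymer on the surface
lapply(res$profiles, function(p) p$r[which.max(p$density)])
# adsorption strength
pmf_well_depth(res$pmf$lecithin_chitosan)
```

## Known limitations

* No electrostatics: chitosan's polycationic character at acidic pH is
  folded into the effective repulsion offsets, so pH- and salt-dependence
  are out of reach.
* The interaction table is a documented default, not a parametrization
  fitted to this chemistry; quantitative EE/size/PMF values depend on it.
* The PMF estimator is $-k_BT\ln g(r)$ between COMs; for strongly
  inhomogeneous geometries (lipids fixed in a shell) it mixes geometric and
  energetic structure.
* Reduced time is not mapped to physical time; run lengths are chosen by
  convergence of the observables, not by microseconds.
* The builder starts from a preformed vesicle; assembly kinetics and the
  equilibrium aggregate are not probed.
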