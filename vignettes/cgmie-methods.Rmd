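---
title: "Methods: the coarse-grained [bmim][Cl] + cellulose + water model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the coarse-grained [bmim][Cl] + cellulose + water model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cgmie)
```

## The model

`cgmie` simulates mixtures of the ionic liquid 1-butyl-3-methylimidazolium
chloride ([bmim][Cl]), cellulose and water with a coarse-grained (CG)
representation:

* **Ionic liquid, five sites per pair.** The cation is a four-site chain —
  two imidazolium ring beads (`I1`, `I2`), a methyl bead (`I3`) and a butyl
  tail bead (`CT`) — and the chloride anion is a single bead (`CI`).
* **Cellulose, six sites per cellobiose.** Each glucose of the two-glucose
  repeat unit maps to three beads named by the dominant ring carbon:
  `C11`/`C14`/`C16` on the first glucose, `C21`/`C24`/`C26` on the second.
  The `C16`/`C26` beads host the reactive primary hydroxyl, `C11`/`C24` the
  weaker secondary hydroxyls, and `C14`/`C21` none.
* **Water**, rigid three-site SPC/E (charges −0.8476 e on O, +0.4238 e on H,
  O–H 1.0 Å, H–O–H 109.47°), held by SHAKE/RATTLE.

Van der Waals interactions use the **Mie n–m potential**

$$U(r) = \frac{\epsilon}{n-m}\left(m\left(\frac{r_0}{r}\right)^{n}
       - n\left(\frac{r_0}{r}\right)^{m}\right),$$

parameterised by the well depth $\epsilon$ and the position of the minimum
$r_0$, so $U(r_0) = -\epsilon$ exactly. The collision diameter satisfies
$r_0 = \sigma\,(n/m)^{1/(n-m)}$. The ionic-liquid self-interactions are the
published 9–6 parameters (12–6 for chloride); water oxygen is the standard
SPC/E 12–6 site. Cross interactions use Lorentz–Berthelot mixing
($\sigma$ arithmetic, $\epsilon$ geometric); because the classical rules do
not define cross *exponents*, unlike-exponent pairs take the arithmetic mean
of each exponent rounded to the nearest integer not below $m+1$
(configurable: `exponent_mixing: arithmetic | fixed`). The first exponent
column of the parameter table is read as the repulsive exponent $n$ and the
second as the attractive $m$; the $r_0$–$\sigma$ relation is symmetric under
this choice, so geometry is unaffected either way.

Electrostatics are evaluated by **Ewald summation**: an erfc-screened
real-space sum inside the cutoff, a reciprocal sum bounded by `kmax`, and
the self term. The classical settings are $\alpha = 0.18520\,$Å$^{-1}$ with
`kmax = (8, 8, 16)` at a 15 Å cutoff; when no $\alpha$ is given the package
uses $\alpha = 2.78/r_c$, which reproduces that pairing and keeps the
real-space truncation error uniform when a smaller cutoff is chosen for a
smaller box. Reciprocal limits default to a spherically truncated grid with
relative truncation error $\sim 10^{-5}$.

## Parameters that are package defaults, and why

The published parameter set covers the ionic-liquid Mie table, the Ewald
and thermostat settings, the time step and the cutoff. Everything else in
the shipped registry (`inst/forcefield/bmimcl_cg.yaml`) is a package
default, clearly labelled there, and every term-count audit in the test
suite holds for any valid registry file:

* **Site charges.** Not part of the published table. Default: +0.5 e on
  each ring bead (tails neutral) for a net +1 cation against −1 chloride.
  Density is insensitive to the ring charge split (moving the full +1 onto
  one ring bead changes the 298 K density by under 2%), so the simplest
  symmetric choice is kept. Cellulose beads carry small partial charges
  encoding hydroxyl polarity (+0.15 on C16/C26, +0.10 on C11/C24, −0.25 on
  C14/C21; zero net charge per glucose): chloride is a hydrogen-bond
  acceptor, and in a CG model without explicit hydroxyl hydrogens this
  polarity is what represents the Cl⋯HO attraction.
* **Cation geometry.** The two ring beads are halves of one fused ring, so
  their centroids sit close together: bonds I1–I2 2.3 Å, I3–I1 2.5 Å,
  I2–CT 3.4 Å, backbone angles 140°. These separations fix the cation molar
  volume; they were calibrated so the model reproduces its reported
  atmospheric liquid density (a 3.55 Å ring-bead bond — treating the beads
  as tangent spheres — under-predicts the 298 K density by ~19%). This is
  the same calibration target the original force field was fitted to.
* **Bonded force constants** (bonds 40–80 kcal mol⁻¹ Å⁻², bends
  15–20 kcal mol⁻¹ rad⁻², cosine dihedrals with 0.8–1.0 kcal mol⁻¹
  amplitude) keep molecules semi-rigid at 100–360 K without demanding a
  smaller time step. Reference bond lengths, angles and dihedral phases are
  *derived from the template coordinates* in the registry, so every builder
  emits molecules at their bonded-energy minimum and the file stays the
  single source of geometry.
* **Cellulose bead sizes and well depths** grade with hydroxyl content
  (ε 0.80/0.45/0.20 kcal mol⁻¹ for primary-hydroxyl, secondary-hydroxyl and
  hydroxyl-free beads) so that chloride–bead affinity ranks C16/C26 >
  C11/C24 > C14/C21, the ordering the model is meant to reproduce.

## Bonded topology of the cellulose repeat unit

Each cellobiose unit owns **7 bonds, 4 bends and 8 dihedrals**, counting the
glycosidic linkage into the *next* unit as belonging to the current one.
The terminal unit of a finite chain drops the unit-spanning terms (1 bond,
1 bend, 4 dihedrals), so an n-unit chain carries 7n−1 / 4n−1 / 8n−4 terms
while the per-unit template audit reports 7/4/8. The 6 bead types generate
C(6,2) + 6 = 21 unique unordered type pairs.

## Integration and ensembles

The core integrator is velocity Verlet at dt = 0.004 ps. NVT wraps it in a
single Nosé–Hoover chain with coupling time f = 0.5 ps; NPT uses the
isotropic Martyna–Tobias–Klein splitting with thermostat time f1 = 0.5 ps
and barostat time f2 = 3.0 ps (thermostat mass $Q = N_f k_B T f_1^2$,
barostat mass $W = (N_f+3) k_B T f_2^2$). Initial velocities are
Maxwell–Boltzmann at the stage temperature with the net momentum zeroed and
the kinetic temperature rescaled exactly; kinetic degrees of freedom are
$3N - 3 - 3 n_\mathrm{water}$. The extended-system conserved quantity is
tracked and reported with every observable sample.

The standard workflow ([run_protocol()]) is the **lattice quench**: build a
lattice at a low density, minimise briefly (steepest descent, displacement
capped at 0.2 Å), equilibrate at 100 K (800 ps by default; scaled-down runs
use shorter spans), then change the thermostat setpoint instantaneously to
the production temperature. The quench is deliberately instantaneous — no
velocity-rescaling ramp — and can be overridden by running stages manually.

## Numerical choices

* **Truncation.** The Mie potential is cut at `cutoff` and energy-shifted to
  zero there (default). For strict energy-conservation work a shifted-force
  scheme (`truncation = "shift-force"`) removes the force discontinuity as
  well; with it the harmonic-dimer and Mie-fluid NVE drifts sit below
  $10^{-5}$–$10^{-4}$ relative over $10^5$ steps. Analytic tail corrections
  for energy and pressure (assuming $g(r)=1$ beyond the cutoff) are added by
  default; note the pressure tail is the thermodynamic virial-integral
  correction, which is intentionally *not* the volume derivative of the
  truncated Hamiltonian — the difference is the usual cutoff boundary term.
* **Neighbour list.** Verlet list with a 2 Å skin, rebuilt when any site has
  moved more than half the skin since the last build.
* **Ewald exclusions.** Intramolecular 1–2 and 1–3 pairs (and all rigid-water
  pairs) are excluded from Mie and real-space Coulomb; because the
  reciprocal sum contains every pair, excluded charged pairs receive an
  erf-screened correction so their net electrostatic interaction is exactly
  zero (or `scale14` times the bare interaction for 1–4 pairs;
  default scale 1.0).
* **Constraints.** SHAKE on positions (tolerance $10^{-8}$ Å, max 500
  iterations, error on non-convergence) and RATTLE velocity projection, so
  constraint forces do no net work.
* **Degenerate geometry.** Collinear dihedral quadruples get zero torsional
  force (the torsion is undefined there); bends guard the $\sin\theta$
  division. Builders refuse configurations with sites closer than 0.5 Å
  ("packing error") and the force loop raises a singularity error below
  $10^{-6}$ Å.
* **Determinism.** All randomness flows from a single integer seed; builds
  and trajectories are bit-reproducible from (specification, seed) on one
  platform.

## What the synthetic fixtures emulate

`generate_fixture()` produces the systems the tests run on: an ideal gas
(RDF normalisation, barostat limiting law), an 8-ion rock-salt cell (the
Ewald sum must reproduce the Madelung constant 1.747565), a harmonic dimer
(closed-form oscillator), a small Mie fluid (conservation and thermostat
contracts), a 64-pair ionic-liquid lattice (scaled-down equilibrium
density), and a mini solvated fiber — 4 cellulose chains, 200 ionic-liquid
pairs, 270 waters, preserving the full system's water:IL molecule ratio
3809:2826 ≈ 1.348.

These fixtures are deliberately small and cold-started from lattices. What
passing tests show is that the implementation integrates this Hamiltonian
correctly and that the scaled systems reproduce the model's macroscopic
anchors (density within a few percent; chloride–hydroxyl-site RDF ordering).
What they cannot show is ergodic sampling of the real, highly viscous
ionic liquid — the full-size 256-pair, 80–160 ns density runs and the
36-chain solvated-fiber structure remain long-run computations that this
package can execute but the test suite does not attempt.

## Problem sizes used by the packaged checks

Desk-scale runs were sized to sample the relevant observable with useful
statistics: the density check uses 64 ion pairs with a 20 ps, 100 K
equilibration and ≥100 ps of NPT production at 298.15 K (the volume
autocorrelation time under the 3 ps barostat is a few ps, so this gives
dozens of independent volume samples); the RDF check uses the mini fiber
with a short cold equilibration and tens of ps of 283.15 K production,
enough for first-shell peak heights though not for long-range structure.
Equilibration onset is detected by the two-block flatness test below.

## Analysis definitions

* **Equilibration detection** scans candidate production starts over the
  first half of a series and accepts the first one after which the two
  halves of the remaining window have means closer than one pooled block
  standard deviation; a series that drifts to its end is returned flagged,
  not as an error.
* **Density** is total registry mass over the mean post-equilibration
  volume; its error is propagated from the standard deviation of the
  volumes.
* **MABD** (mean absolute percentage deviation) uses the *simulated* value
  as denominator, $100\,|\rho_\mathrm{MD}-\rho_\mathrm{ref}|/\rho_\mathrm{MD}$,
  matching the convention of the reference comparison table; the measure is
  intentionally asymmetric. Recomputing the reference table's rows from its
  printed densities reproduces the printed deviations to within one unit in
  the last printed digit (the table's own last digits appear to come from
  unrounded densities: e.g. the printed MD/EXP pair at 323.15 K yields
  7.7787…, printing as 7.78 against a listed 7.77). The packaged table also
  lists 10% w/w water, and "18% w/w cellulose in IL" whose basis is
  ambiguous: the shipped counts give ~19% of cellulose + IL mass and ~17%
  of the total mixture; `mass_fraction()` reports any basis explicitly
  rather than forcing 18.
* **RDF first-peak heights** for the chloride-cellulose ordering check are
  read inside the contact shell, 3-4.6 Å (up to ~110% of the chloride-bead
  cross-interaction minimum r0 ≈ 4.2 Å, which is where the direct-contact
  peak sits). The window must stop there because cellulose beads are bonded
  at 2.6-2.9 Å — closer than the chloride contact distance — so from ~4.6 Å
  outward the g(r) of a hydroxyl-free bead is dominated by indirect
  correlation through its bonded hydroxyl-bearing neighbours and no longer
  measures direct affinity.
* **RDF** uses the standard estimator: per-frame pair counts within `rmax`
  normalised by the ideal-gas shell expectation $N_a N_b\,V^{-1}\,
  \tfrac{4}{3}\pi(r_2^3-r_1^3)$ per frame (identical types: $N(N-1)/2$,
  unordered pairs counted once).

## Known limitations

* Plain Ewald scales as $O(N \cdot K)$; systems beyond ~10⁴ sites call for
  mesh methods this package does not implement.
* The barostat is isotropic and the box orthorhombic.
* The printed production lengths for the full density study are ambiguous
  (80 ns per temperature vs. a reported 160 ns total figure); spans are
  plain configuration values here, with the scaled defaults documented
  above.
* No hydrogen-bond geometric analysis: the CG model has no explicit
  hydroxyl hydrogens; the chloride–hydroxyl attraction lives in the bead
  polarity described above.
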