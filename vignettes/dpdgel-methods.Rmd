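---
title: "Mesoscale model and methods behind dpdgel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mesoscale model and methods behind dpdgel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dpdgel)
```

## The scientific problem

Unmodified nano-silica aggregates in aqueous polymer solution, and that
aggregation decides whether a PVA/PAM (polyvinyl alcohol / polyacrylamide)
blended hydrogel reinforced with silica is mechanically useful.
Aggregation at these scales is a mesoscopic phenomenon: too large for
atomistic molecular dynamics, too small and too fast for experiment to
resolve directly.  `dpdgel` implements the standard mesoscale answer,
dissipative particle dynamics (DPD), for this particular four-component
system — PVA chains, PAM chains, water and nano-silica — together with the
analysis pipeline that turns trajectories into aggregation observables.

## The model

### Beads and molecules

Four bead species: one PVA repeat unit per bead (chains of 50), one PAM
repeat unit per bead (chains of 31), three water molecules per bead, one
SiO~2~ molecule per bead.  All beads share one mass and one diameter; mass,
the interaction cutoff $r_c$ and the thermal energy at 298 K are the units,
so everything below is dimensionless.  Physically $r_c = (\rho N_m
v_{w})^{1/3} \approx 6.46$ Å for bead density $\rho = 3$, $N_m = 3$ waters
per bead and a 30 Å³ water molecule, and one time unit is taken as
$\tau \approx 93.1$ ps.  (The coarse-graining literature also offers the
fit $\tau \approx 14.1\,N_m^{5/3}$ ps, which gives about 88 ps at
$N_m = 3$; the two are not consistent, and this package adopts the stated
93.1 ps throughout rather than silently reconciling them.  Only the
reporting of physical times depends on the choice.)

### Forces

Beads $i, j$ within $r_{ij} < 1$ interact through three pairwise,
antisymmetric forces along the unit separation vector $\hat e_{ij}$:

* conservative soft repulsion $F^C = a_{ij}(1 - r_{ij})\,\hat e_{ij}$;
* dissipative friction
  $F^D = -\eta (1 - r_{ij})^2 (\hat e_{ij} \cdot v_{ij})\, \hat e_{ij}$;
* random kicks
  $F^R = \sigma (1 - r_{ij})\, \xi_{ij}\, \Delta t^{-1/2}\, \hat e_{ij}$,
  with $\xi_{ij} = \xi_{ji}$ a zero-mean, unit-variance draw per pair and
  step.

$F^D$ and $F^R$ form a momentum-conserving thermostat; the
fluctuation–dissipation relation $\sigma^2 = 2\eta k_BT$ fixes the noise
strength ($\eta = 4.5$, hence $\sigma = 3.00$, $3.15$, $3.29$ at the three
study temperatures).  Bonded neighbours in a chain additionally feel a
harmonic spring of stiffness $C = 4$ pulling them together; the spring has
no rest length ($F^S_i = -C\,\vec r_{ij}$), which together with the soft
repulsion sets an equilibrium bond length near $0.7\,r_c$ at $\rho = 3$.

### Parameters from Flory–Huggins theory

Like-species repulsion follows the compressibility route $a_{ii} = 75
k_BT/\rho$; unlike-species repulsion is the linear map $a_{ij} = a_{ii} +
3.27\,\chi_{ij}$ from the Flory–Huggins parameter of the pair.  The
$\chi$ values for the ten pairs at 298/328/358 K are input data shipped in
`inst/extdata/chi_table.tsv`; computing $\chi$ from atomistic mixing
energies is out of scope here.  Two deliberate details:

* Reduced temperature is the *exact* ratio $T/298$, not the rounded 1.1 /
  1.2: only the exact ratio reproduces the published repulsion values
  27.52 and 30.03 at the printed precision.
* The silica–silica pair carries a published *negative* $\chi$
  ($-0.44$ at 298 K), so the $\chi$-map is applied to every pair, not only
  unlike ones; a like pair with $\chi = 0$ reduces to $a_{ii}$
  automatically.

Cross-checking the computed matrix against the published one, 28 of 30
cells agree to the printed last digit.  The remaining two disagree with
the published table's *own* $\chi$ column: PAM–H₂O at 298 K (printed
26.88; the mapping on the printed $\chi = 0.57$ gives 26.86, consistent
with a $\chi$ of about 0.575 rounded for display) and SiO₂–SiO₂ at 328 K
(printed 26.82 where the mapping gives 25.82 — exactly 1.00 apart, a
typographical slip).  The package computes from the printed $\chi$ and its
tests assert the mapping values for those two cells.

## Integration and boundaries

The integrator is the $\lambda$ velocity-Verlet scheme standard for DPD:
position update, velocity prediction with $\lambda = 0.65$, one force
evaluation, velocity correction.  The random force scales as
$\Delta t^{-1/2}$; this is what makes the kinetic temperature track the
target, and the engine exposes a switch (`fdt_scaling = FALSE`) used by a
negative-control test to demonstrate the thermostat collapses without it.
The known residual artifact of the scheme — a small positive temperature
bias growing with $\Delta t$ — is itself a reproduced observable: the
time-step study preset shows the deviation growing across
$\Delta t \in \{0.01, 0.03, 0.05, 0.07\}$.

Neighbour search is a counting-sorted cell list with per-cell image
shifts, validated in the tests against an $O(N^2)$ minimum-image scan.
Pair noise is counter-based — a `splitmix64` hash of (seed, step, sorted
pair) — so $\xi_{ij} = \xi_{ji}$ holds by construction and a trajectory is
bit-reproducible from its seed regardless of pair iteration order.  The
draw is uniform with zero mean and unit variance rather than Gaussian:
the thermostat constrains only the first two moments, unit-variance
uniform noise is long-standing standard practice in DPD, and it keeps the
pair loop cheap.

Shear is imposed with Lees–Edwards sliding-brick boundaries along X with
gradient along Y: the image offset advances as $\dot\gamma L\,t$ (modulo
$L$), beads crossing the Y face are remapped by the offset and their X
velocity changes by $\mp\dot\gamma L$, and — easy to omit, physically
essential — a pair interacting *across* the sheared face sees its
partner's image velocity shifted by $\pm\dot\gamma L$ inside the
dissipative force.  With that term the steady Couette profile measured on
pure solvent reproduces the imposed slope to within a few percent; without
it the boundary acts as artificial drag and the profile falls visibly
short.

## Observables

* **Relative concentration profile**: the box is sliced into equal slabs
  along an axis; each slab's species density is divided by the species'
  box-average density, so homogeneity reads 1.0 and the equal-slab mean is
  exactly 1 — an identity the tests assert on arbitrary configurations.
  Default 30 slabs along Z; the slab count is configuration, not a claim.
* **Planar concentration maps** on an $n \times n$ grid in a coordinate
  plane, normalised the same way within the chosen slab.  Both the XY and
  YZ planes are supported (the published account names both for the
  sheared-morphology figure); the shear test uses XY and quantifies
  "occupied area" as the fraction of cells above 0.5.
* **MSD and diffusion**: mean squared displacement from engine-carried
  unwrapped coordinates (reconstruction from wrapped frames is refused —
  it is ambiguous under shear), by default averaged over all time origins;
  the single-origin Einstein form is available.  $D$ is the least-squares
  MSD slope over a lag window (default: the second half of available
  lags, inside the diffusive regime) divided by 6.  Under shear the
  affine streaming displacement $\dot\gamma (y - L/2) t$ is subtracted
  from X before accumulation; this is first-order in the streaming field
  and adequate at the shear rates studied, but MSD under strong shear
  should be read qualitatively.
* **Cluster statistics**: single-linkage connected components of
  same-species beads under a distance cutoff (default $1.0\,r_c$, the
  interaction cutoff; an aggregate is not defined numerically in the
  source study, so the cutoff is exposed).  This replaces visual
  peak-counting of smoothed profiles with a quantitative size
  distribution; tests pin it to a breadth-first-search oracle.
* **Equilibration**: windowed diffusion coefficients per species;
  the system is declared equilibrated when successive windows agree to a
  relative tolerance (default 10%) from some window onward.

## The generator and what passing tests mean

The model builder is the pipeline's data generator and its defaults *are*
the study conditions: $\rho = 3$, box edge 15 (10,125 beads), 20% total
polymer volume, chains of 50 and 31, beads placed uniformly at random
(chains as random walks with step $0.7\,r_c$ — the initial conformation is
not specified by the source study; soft potentials make overlaps
harmless), Maxwell–Boltzmann velocities shifted to zero net momentum.
Composition percentages are bead-number fractions, equal to volume
fractions since all beads share one volume.  Chain counts round to whole
chains and water absorbs the remainder, so density is exact and the
realized composition (reported beside the requested one) can shift by a
few tenths of a percent — density, and with it pressure, matters more.

What the generator does *not* emulate: real silica particle-size
distributions, hydrogen bonding or crosslinking chemistry, and any
structure in the initial state.  Tests passing on this generator show the
*simulator and analysis* behave correctly and that the published factor
effects emerge from the stated interaction parameters; they are not
evidence about any particular experimental hydrogel beyond what the
coarse-grained model encodes.

## Scale choices

Full-scale presets mirror the published design exactly: box $15^3$,
$\Delta t = 0.05$, 50,000 steps with 30,000 equilibration, one
realization.  Routine testing uses reduced presets chosen once: box
$9^3$ (2,187 beads — comfortably larger than a stretched 50-bead chain),
20,000 steps, five fixed seeds per scenario, with factor effects asserted
in at least 4 of the 5 seeds.  Property tests use still smaller boxes
(edge 4–6) where only bulk physics, not morphology, is at stake.

Not everything survives the 10-fold reduction in bead count.  Of the four
factor effects, the two driven by strong thermodynamics reproduce
robustly at reduced scale — the largest silica aggregate grows sharply
with silica content (5/5 seeds) and shrinks at 358 K versus 298 K (5/5
seeds).  The two that rest on small-sample statistics do not, and their
acceptance expectations are left failing rather than re-metricized: the
silica-mobility ordering across the five PVA/PAM ratios involves only 33
silica beads largely condensed into a few aggregates, so per-bead MSD
measures collective cluster motion and the seed-to-seed spread exceeds
the systematic trend; and the shear-banding signature on PAM maps needs
many chains condensing into shared beams, whereas the reduced box holds
seven PAM chains whose individual stretching *spreads* them over more map
cells.  Both effects remain available to check at full scale through
`study_presets("full")`.

## Numerical choices and known limitations

* Reporting rounds half away from zero to 2 decimals, matching the
  published table format; internal arithmetic is full precision.
* Cluster cutoff, slab count, map threshold and MSD fit window are
  explicit arguments with the defaults above; they were fixed before the
  factor-effect suites were first run and are not tuned.
* The equal-and-opposite structure of every pair force keeps total
  momentum at round-off ($<10^{-12}$ over $10^4$ steps in the tests);
  under shear, Y-face crossings intentionally exchange momentum with the
  boundary.
* The widely quoted soft-fluid equation of state $p = \rho k_BT + 0.101\,
  a \rho^2$ is a high-density plateau: this engine reproduces the 0.101
  coefficient at $\rho = 8$ but measures $p = 23.65$ at the working
  density $\rho = 3$ (coefficient 0.092), in exact agreement with an
  independent Metropolis Monte-Carlo of the same soft pair potential.
  The tests therefore pin pressure to the Monte-Carlo value at 2%, and
  the acceptance suite's comparison against the 0.101 closed form at 5%
  is expected to fail — the discrepancy measures the closed form, not
  the engine.
* Restarting a run from a stored configuration does not bit-reproduce an
  uninterrupted run: the $\lambda$-scheme's force memory (forces evaluated
  at predicted velocities) is not part of the saved state.  Statistical
  properties are unaffected.
* Electrostatics, angle/dihedral potentials, many-body DPD and
  energy-conserving DPD variants are out of scope.
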