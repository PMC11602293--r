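---
title: "Screening active-centre residues for thermostability engineering"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening active-centre residues for thermostability engineering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mscscreen)
```

## The screening problem

Engineering the active centre of an enzyme for thermostability is a
needle-in-a-haystack problem: residues there are numerous, strongly
conserved, and often in direct contact with the substrate, so most
mutations kill activity and exhaustive saturation mutagenesis is wasteful.
`mscscreen` implements a three-stage computational triage that shrinks the
mutational search space before any wet-lab work, applied here to the
fibrinolytic serine protease nattokinase (AprY, subtilisin family, 381
residues, catalytic triad Asp32/His64/Ser221):

1. **Flexibility stage.** Per-residue root-mean-square fluctuation (RMSF)
   is computed from a trajectory at a reference temperature (298 K) and at
   a stress temperature (328 K). Residues whose difference
   $\Delta \mathrm{RMSF} = \mathrm{RMSF}_{high} - \mathrm{RMSF}_{low}$
   exceeds a threshold (default 0.05 Å, strict inequality) are heat-labile
   candidates.
2. **Substrate-contact stage.** A steered-pulling simulation drags the
   substrate out of the active centre; residues that maintain hydrophobic
   contact with it for a sustained fraction of the pull (default ≥ 50% of
   steps at a 5 Å apolar–apolar cutoff) are load-bearing for catalysis and
   are removed from the candidate set.
3. **Conservation stage.** Per-column conservation of a multiple sequence
   alignment is graded 1–9 (9 = strictly conserved, the ConSurf
   convention); grade-9 candidates are removed because mutating them
   almost always inactivates the enzyme.

On the packaged 32-residue annotation table around the AprY catalytic
triad, stage 1 passes 20 residues, stage 2 removes the 3 contact residues
present among them (a fourth contact residue, 222, already failed stage 1
and is logged rather than double-counted), and stage 3 removes 4 strictly
conserved survivors, leaving 13 candidate sites for saturation
mutagenesis.

```{r}
tab <- apry_site_table()
report <- select_candidates(comparison_from_table(tab),
                            contacts = tab$residue[tab$contact],
                            grades = data.frame(residue = tab$residue,
                                                grade = tab$conservation))
report
```

## The flexibility model

RMSF of residue $i$ is
$\sqrt{\langle \lVert x_i(t) - \bar{x}_i \rVert^2 \rangle_t}$
over the retained frames, with the Cα position as the residue
representative. Choices that are open in principle and fixed here:

* **Equilibration.** The leading half of each trajectory is discarded by
  default (`equilibration_fraction = 0.5`), mirroring the common practice
  of dropping the first 50 ns of a 100 ns run.
* **Reference structure.** RMSF needs a reference; we use the time-mean
  structure obtained by two superposition passes (align every frame to the
  first retained frame, form the mean, realign all frames to that mean).
  Superposition uses the Kabsch algorithm (SVD of the cross-covariance,
  determinant-corrected to a proper rotation), so RMSF is invariant under
  arbitrary per-frame rigid motions of the whole system.
* **Degrees-of-freedom caveat.** Rigid-fitting estimates 6 parameters per
  frame from $3N$ coordinates, which deflates apparent fluctuations by
  roughly $\sqrt{1 - 6/3N}$ — about 10% at $N = 10$ residues and under 3%
  at $N = 40$. The synthetic-recovery tests therefore compare against the
  closed form on the generator's own frame (no superposition, which is
  exact there because the generator contains no rigid motion), while the
  superposed path is validated by its rigid-motion-invariance property.

The auxiliary trajectory summaries (RMSD series, radius of gyration,
hydrogen-bond counts, Shrake–Rupley SASA) are provided for completeness of
trajectory characterisation. Their *absolute* values on published
all-atom systems are not reproducible at desk scale (they depend on the
full force field, solvent and the simulation engine's energy-based
hydrogen-bond criterion); they are validated against closed forms and
convergence properties instead. The hydrogen-bond criterion here is
geometric: donor–acceptor ≤ 3.5 Å, plus a D–H···A angle ≥ 120° when
hydrogens are present. SASA uses a 1.4 Å probe and 960 deterministic
golden-spiral points per atom (closed-form isolated-sphere agreement
within 2%, halving/doubling the point count moves a 10-atom total by less
than 1%).

## The steered-pull controller

The pulling protocol is an adaptive-acceleration scheme rather than a
constant-velocity spring: every ligand atom receives an external
acceleration $a$ along the continuously updated receptor→ligand
centre-of-mass direction, and the controller adjusts $a$:

* start at the floor $a_{\min} = 2000\ \mathrm{pm/ps^2}$;
* if the maximum COM–COM separation has not increased for 400 consecutive
  steps, $a \mathrel{+}= 500\ \mathrm{pm/ps^2}$;
* every 20 steps, if the maximum separation grew faster than
  $v_{cap} = 4000$ m/s, scale $a$ by $1 - (1 - v_{cap}/v)^2$;
* never let $a$ drop below $a_{\min}$.

The run ends when the ligand COM has moved 15 Å from its start. Forces are
reported through $F = m \, a \times 0.00166$ pN (mass in Da, $a$ in
pm/ps²) and work as $\sum_t F_t \, \Delta d_t$ along the pull direction,
in pN·Å. For the reference ligand mass of 624.24 Da the force floor is
$624.24 \times 2000 \times 0.00166 = 2072.48$ pN.

Numerical choices, each of which the controller itself is insensitive to:

* a single velocity-Verlet timestep of 1.25 fs (no multiple-timestep
  splitting); for a free particle under constant acceleration the
  integrator is exact and the stopping-time discretisation error is one
  step (≈ 0.1%);
* NVE dynamics plus the external force — no thermostat or barostat at toy
  scale; initial velocities are Maxwell–Boltzmann at 298 K from the run
  seed (a temperature of 0 gives the deterministic closed-form reference
  run);
* `MaxDisSpeed` is measured as the growth of the maximum separation over
  the 20-step check interval (the measurement window is otherwise
  unspecified); the stagnation counter resets on any strict increase of
  the maximum separation and after an increment fires;
* the toy force field is 12-6 Lennard-Jones with two atom classes
  (apolar/polar) plus harmonic intra-ligand bonds; no electrostatics —
  real long-range PME physics is out of scope by design;
* "prolonged" hydrophobic contact = an apolar receptor atom within 5.0 Å
  of any apolar ligand atom in at least half of the pull steps; neither
  constant has a published definition, so both are explicit parameters.

Runs are bit-reproducible for a fixed seed, terminate provably (the
stagnation rule escalates the acceleration without bound; a hard step cap
guards the impossible case), and the free-particle limit matches the
$t = \sqrt{2d/a}$, $W = F d$ closed forms within 1%.

## Conservation grading

ConSurf-style grades come from phylogenetic rate estimation; that machinery
(tree inference, rate categories) is far beyond what a grade-9 exclusion
rule needs. The scorer here is the gap-excluded column entropy, anchored
absolutely:

$$ s_j = 1 - \frac{H_j}{\ln 20}, \qquad
   \mathrm{grade}_j = 1 + \mathrm{round}(8 s_j) $$

so an invariant column is grade 9 on *any* alignment and a uniform column
is grade 1. Rounding is half-away-from-zero, making the binning a
deterministic monotone function of the score (banker's rounding would make
boundary grades depend on parity). Columns with more than 50% gaps are
flagged low-confidence; all-gap columns get a missing grade. Missing
grades do **not** trigger the stage-3 exclusion by default (exclusion
requires positive evidence of strict conservation); a `"drop"` policy is
available.

Two consequences are worth stating plainly. First, published grades for a
specific enzyme cannot be recomputed without the original alignment, so
when reproducing a published selection the packaged grade column is
consumed as data. Second, grade 9 here means "strictly conserved" — where
a source table's footnote suggests the opposite ordering, the ConSurf
convention is followed, since the exclusion rule is only meaningful that
way.

## Kinetics and mutant ranking

* **Michaelis–Menten**: $v = V_{max} S / (K_m + S)$ fitted by
  Levenberg–Marquardt nonlinear least squares (not a Lineweaver–Burk
  linearisation, which distorts the error structure);
  $k_{cat} = V_{max}/[E]$. Substrate design points default to 8
  geometric levels over 0.05–5 (the assay's concentration range, in the
  same unit as the preset $K_m$), which brackets the wild-type
  $K_m = 1.52$.
* **Thermal inactivation**: single-exponential
  $A(t) = A_0 e^{-kt}$, half-life $t_{1/2} = \ln 2 / k$, from
  residual-activity series over 10–100 min (the model form is the standard
  first-order assumption; the source data are reported as half-lives
  only).
* **Comparisons**: fold = mutant/reference, percent = $100(\mathrm{fold}-1)$,
  conventionally reported at one decimal. The packaged presets (wild type
  and the three position-216 mutants) give half-life folds 5.5/5.7/3.6 and
  $k_{cat}$ increases of 29.7% and 187.0%.
* **Fibrin-plate calibration**: $\log_{10}(\mathrm{activity})$ linear in
  clear-zone area (the radial-diffusion convention), least-squares over
  ≥ 2 distinct standards, inverted to convert zones to U/ml.

## What the synthetic generators emulate — and what they do not

Every stage has a generator with known ground truth:

* `gen_trajectory()` draws iid isotropic Gaussian jitter of sd $\sigma_i$
  about a fixed helical backbone, so $E[\mathrm{RMSF}_i] = \sigma_i\sqrt3$
  exactly. It emulates fluctuation *amplitudes*, not dynamics: there is no
  autocorrelation, no anharmonicity, no collective motion. Passing
  recovery tests therefore demonstrates correct estimation arithmetic, not
  force-field realism.
* `gen_msa()` samples columns independently at a prescribed modal
  frequency; real alignments have phylogenetic correlation between rows,
  which the entropy scorer deliberately ignores.
* `gen_pull_system()` plants sticky apolar residues directly behind the
  ligand on the pull axis at the Lennard-Jones minimum with a well deep
  enough (default pair depth 40 000 Da·Å²/ps²) that escape requires
  several controller escalations — giving a planted answer for both the
  prolonged-contact detector and the peak-force-above-floor property.
  Which residues contact a real substrate in a real enzyme cannot be
  derived from this.
* `gen_kinetic_series()` applies multiplicative Gaussian noise to exact
  model curves; with sd = 0 the fits must recover the preset parameters to
  1e-6, and at 1% noise the median of 200 replicate $K_m$ fits stays
  within 5% of truth.

All generators are pure functions of (spec, seed) and restore the caller's
RNG state.

## Problem sizes and runtime

The shipped tests run the trajectory recoveries at 2000 frames × 10–40
residues, the Monte-Carlo kinetics at 60–200 replicates of 8-point
designs, and the pulls on 20–30-atom toy systems (a few thousand
integration steps each) — sizes at which every check above is sharp while
the full suite completes in well under a minute.

## Known limitations

* The flexibility stage trusts its input trajectories; garbage in, garbage
  out. Published per-residue tables can be consumed directly for exactly
  this reason.
* The entropy conservation scorer is alignment-composition dependent and
  will not numerically match phylogenetically weighted graders; only the
  anchored endpoints (invariant → 9, uniform → 1) are guaranteed.
* The pull simulator is a controller testbed, not a binding-energy
  calculator: peak force and work rank *relative* binding strength within
  one toy system family only.
* A selection intermediate sometimes printed in published workflows
  ("subtract 4 contact sites from 20") can be arithmetically inconsistent
  when a contact residue already failed the flexibility stage; the
  pipeline removes each residue exactly once, logs contact residues that
  were never candidates, and reports per-stage bookkeeping explicitly.
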