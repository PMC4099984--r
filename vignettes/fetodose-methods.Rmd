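---
title: "Methods: synthetic pregnant phantom dosimetry for thyroid agents"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic pregnant phantom dosimetry for thyroid agents}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette records the models, assumptions and numerical choices behind
the package, in the order the pipeline runs them. It states no empirical
result that the test suite or `scripts/acceptance.R` does not itself
compute.

## 1. The synthetic phantom

Fetal dosimetry for thyroid agents hinges on two things the anatomy must get
right: organ **masses** (self-dose scales as 1/m) and the **topology** of
the source regions (a 1.3 g fetal thyroid embedded in a fetus inside the
gravid uterus, hollow organs split into wall and contents). It does not
hinge on realistic organ *shapes* for the questions this package answers,
because every downstream algorithm — voxel-centre classification, layer
peeling, mass adjustment, Monte Carlo tracking — is geometry-agnostic.

`build_reference_scene("reference_9mo")` therefore lays out ellipsoids,
capsules and shells in a simplified trunk: maternal source organs at ICRP
110 reference masses (thyroid 17 g, stomach wall 140 g + contents,
small-intestine wall 600 g + contents, liver 1400 g, kidneys, urinary
bladder contents 200 g, salivary glands, residual trunk tissue) and a
20-organ fetus at ICRP 89 reference masses summing to 3471.82 g (within 1 %
of the 3.5 kg reference fetus). All placement coordinates live in
`R/layout.R` so the layout can be reviewed or edited in one file.

Choices worth flagging:

* **Salivary glands.** No reference mass is tabulated for them in the
  comparison table the roster follows; they are a source region
  nonetheless. Default 70 g, split into two neck capsules, configurable in
  the layout.
* **Uteroplacental components.** Nothing constrains the relative placement
  of placenta, amniotic fluid and umbilical cord; the choice here is
  arbitrary and, because the fetal envelope takes painting precedence, the
  placenta and amniotic fluid are truncated to the space the fetus leaves
  (their voxel masses fall well below the nominal targets unless explicitly
  adjusted). They are background tissue for the iodide studies; the
  placenta *is* a source for pertechnetate, where what matters is its
  location next to the fetus, which survives truncation.
* **Fetal skeleton.** Represented as a skull shell, a spine capsule (with
  nested spinal cord) and four limb capsules, sharing one skeletal material
  (1.22 g/cm³ mineralising bone) and jointly carrying the tabulated 204.31 g.
* **Overlap resolution.** Nesting depth wins (contents beat walls, fetal
  organs beat the fetal body); equal-depth overlaps resolve by declaration
  order, later wins. This makes voxelization deterministic and lets
  anatomically embedded structures (gall bladder in liver, eyes carving the
  skull) be declared simply.

## 2. Voxelization and mass adjustment

A voxel belongs to an organ iff its **centre** lies inside the organ's
primitive; points exactly on a boundary classify as inside (closed
surfaces), a deterministic convention with measure-zero effect. This is the
same classification a contour/trim/intersect construction produces, done
here as analytic inside-tests. Hollow organs are nested primitives;
`add_wall_layers()` additionally supports peeling *n* 6-connected surface
layers into a wall label (6-connectivity, because 26-connectivity
over-peels corners).

`adjust_mass()` brings each organ to its reference mass by adding or
removing voxels on its exterior layer, in a fully deterministic order:
descending distance from the (frozen) organ centroid, ties by ascending
linear index. Removed voxels return to the surrounding region's label;
growth claims voxels of the surrounding region 6-adjacent to the organ.
The guarantee is |m − target| ≤ one voxel mass; in practice the loop lands
within half a voxel. `adjust_scene_masses()` runs organs in reverse
painting order (contents before walls before enveloping tissue) and
iterates to a fixed point (≤ 3 rounds), so adjustments cannot undo each
other.

The acceptance script measures the end result: maximum absolute deviation
across fetal organs on a 1 mm grid and across the adjusted maternal organs
on a 2 mm grid. Default spacings follow small-structure needs: 2 mm for the
maternal trunk, 1 mm where fetal organs below ~1 g must resolve.

## 3. Biokinetics

The biokinetic layer is linear compartmental kinetics with physical decay,
`dA/dt = K·A − λ_p·A`, rates per day. Cumulated activities are the exact
linear solve `Ã = (λ_p I − K)⁻¹ A₀` (hours per unit administered); time
stepping (`deSolve::lsoda`) is kept only as the independent oracle in the
tests, which agree to 1e-8. With all excreta explicit, `Σ Ã λ_p = 1`
exactly — the tested conservation law.

The iodide-in-pregnancy structure: blood iodide clears at a total rate
`lambda_blood`; a fraction **F** (the maximum thyroid uptake, the model's
sweep parameter) is trapped by the maternal thyroid, and the remainder
splits between renal excretion, salivary and gastric secretion (recycled
through stomach and small intestine), and a transplacental pool that feeds
the fetal thyroid and returns to maternal blood. Thyroidal iodine returns
as organically bound iodine through a body pool and the liver. Mapping
`blood → thyroid = F · lambda_blood` means the asymptotic no-decay
first-pass uptake equals F, the interpretation adopted here for "maximum
thyroid uptake" (the source literature does not pin the mapping down).

The published pregnancy model does not print its rate constants. The
defaults in `iodide_default_constants()` (and the editable YAML bundle in
`inst/extdata/`) are package choices: conventional iodide kinetics tuned
only to reproduce the qualitative uptake-level trends — maternal thyroid Ã
increasing in F, fetal thyroid, stomach and bladder decreasing (they share
the (1−F) pool), liver increasing (it sits on the organic pathway). The
tests assert exactly these trends plus the conservation and oracle
identities, never the published numeric tables, which ship instead as
fixtures (`load_fixture_activities()`) with their provenance tagged.

Bladder contents use the periodic-voiding treatment: the bladder
accumulates the renal outflow, decays, and empties every 3.5 h (first void
at 3.5 h; both configurable — the convention is stated nowhere in the
source material, so the conventional adult assumption is used).
Oral-versus-IV administration delay is ignored; it only shifts blood
appearance by minutes. Feces are a terminal sink.

`gen_time_activity()` and `fit_rates()` support parameter-recovery
validation: multiplicative lognormal noise of stated CV (mean-1 factors),
least squares on log-activities over a caller-declared identifiable subset.
The acceptance property (CV 5 %, 20 time points, both rates of a two-step
chain within 10 % in ≥ 90 % of 100 seeded replicates) is computed in the
test suite.

## 4. Emission inventories

Decay schemes ship as plain-text CSV fixtures (I-131, I-123, Tc-99m) —
simplified line lists transcribed and rounded from standard ENSDF-derived
compilations, with MD5 checksums frozen in the tests to catch silent edits.
Policies applied before transport:

* **Yield cutoff** at 0.1 % per line (per line, not per group — the finer
  of the two readings), removed yield logged.
* **Auger electrons** represented per group at the group's yield-weighted
  average energy; **conversion electrons** per subshell at the subshell's
  maximum energy. Both policies are idempotent and conserve yield.
* **Beta continua** use the phase-space shape times the nonrelativistic
  point-charge Coulomb factor `F = 2πη/(1−e^(−2πη))`, η = ±Zα·W/p — the
  minimal reading of "the Fermi function"; a relativistic screened factor
  would be a flagged extension. Spectra are binned at 1 keV (sub-percent
  moment accuracy); transport uses the spectrum-mean energy per branch,
  consistent with local/CSDA electron kernels that are linear in energy.
* Daughter-chain ingrowth (the Xe-131m contribution) and positron support
  are omitted; I-123's β+ branch is negligible.

## 5. Transport

The Monte Carlo is deliberately minimal and fully documented rather than a
re-implementation of a general-purpose code:

* **Photons** (1 keV–2 MeV): photoelectric-type absorption plus
  free-electron Klein–Nishina incoherent scattering. Coherent scattering
  and pair production are omitted (sources here are ≤ 723 keV); the
  interaction split assigns the Klein–Nishina coefficient to scattering and
  the remainder of the tabulated total to absorption, so the omitted
  coherent part conservatively terminates histories. Scoring is the
  track-length kerma estimator `t·E·(μ_en/ρ)·ρ` per segment — the heating
  tally under the kerma approximation. Embedded log-log tables cover
  water, soft tissue, bone, lung and air.
* **Electrons**: `local` mode deposits the full energy in the emission
  voxel (self-dose = E/m exactly, a tested closed form); `csda` mode
  spreads the energy uniformly in mass path length along a straight
  sampled direction over the density-scaled CSDA range. At ≤ 606 keV the
  ranges are ~2 mm of tissue, below or near the voxel size, which is why
  local deposition is the default; csda exists for sensitivity checks.
  Bremsstrahlung is ignored (sub-percent at these energies, noted as a
  bias).
* **RNG**: one master seed, counter-based splitmix64 substream per history
  — bit-identical results for identical seeds, independent of execution
  order.
* **Statistics**: per-history scores give the sample standard error per
  region; the energy audit (emitted = transferred + escaped +
  below-cutoff) balances to 1e-6 relative and is asserted per run.
* **Variance reduction**: optional Russian roulette on low-energy scattered
  photons (threshold + survival weight, off by default). With roulette on,
  scores carry statistical weights and the audit balances in expectation
  only; the tests check unbiasedness against the analog run.
* **Mesh tallies** accumulate energy per voxel; `mesh_dose_map()` divides
  by density (masking air) and `render_dose_map()` draws log-scale slices.

Tested physics properties: mean free path against 1/μ (3 MC standard
errors at 1e5 histories), reciprocity of cross-doses between equal organs,
self-dose decreasing with organ mass, kerma ≤ emitted energy, and ~2 %
stability of organ kerma under grid refinement once organs are
mass-adjusted at each spacing (the pipeline always adjusts, so the ladder
isolates transport discretization).

## 6. Dose assembly

`assemble_svalues()` forms `S(T←s) = Σ yield · D_pp` with photon/electron
components retained and MC errors propagated in quadrature;
`organ_doses()` applies the exact unit constant 3600·1e6·1.602176634e-10·1e3
= 576.7836 (mGy/MBq per h·MeV/g). Linearity in Ã and in yields is exact and
tested. The whole-fetus summary is the mass-weighted mean of fetal-region
doses — equivalently total fetal energy over total fetal mass (the audit
identity tested against voxel tallies); the definition is not stated in the
source tables, so it is fixed here and documented. Percent differences in
provenance comparisons are always `100(a−b)/b` with the base named in the
output, because such comparisons are base-ambiguous. When a reference
activity set carries only a whole-fetus entry, the fetus is treated as a
single uniform source region — the comparison scenario that demonstrates
(and the tests assert) the fetal-thyroid self-absorption contrast.

## 7. Problem sizes and runtime choices

The shipped defaults keep every documented computation on one CPU in
seconds to a couple of minutes: full-scene voxelization at 2 mm (~14 M
voxels, ~3 s), fetal sub-scene at 1 mm (~13 M voxels), scene-wide mass
adjustment ~10–20 s, S-value demonstrations at 4 mm with 5000 histories per
emission, 1e5 histories for the attenuation-length and refinement checks.
These sizes are the package's validation choices; production users can turn
all of them up through the exposed arguments.

## 8. Known limitations

* Geometry is schematic: organ shapes, inter-organ distances and hence
  cross-organ S-values are not those of an image-derived phantom; absolute
  organ doses should be read as method demonstrations, not patient
  dosimetry.
* The iodide rate constants are package defaults reproducing trends, not a
  fitted physiological model; absolute cumulated activities differ from
  the published pregnancy tables (which are available as fixtures).
* Photon physics omits coherent scattering and bound-electron effects;
  electron transport has no scattering, energy-loss straggling or
  bremsstrahlung.
* The marrow/endosteal aggregation uses a configurable site-fraction table
  on a schematic skeleton; it demonstrates the weighting, not skeletal
  microdosimetry.
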