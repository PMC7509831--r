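---
title: "Models and methods behind npamyloid"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind npamyloid}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(npamyloid)
```

npamyloid studies how surface-functionalised gold nanoparticles (NPs)
modulate the aggregation of the amyloid-beta peptide. It bundles four
stages that are usually scattered across instrument software and ad hoc
scripts: a coarse-grained Monte Carlo simulator of NP-modulated peptide
aggregation, sigmoidal fitting of thioflavin-T (ThT) fibrillation
kinetics, one-site analysis of isothermal titration calorimetry (ITC)
thermograms, and first-order plasma-elimination fitting. A set of seeded
generators produces synthetic inputs for every tabular stage, so the whole
pipeline is testable without laboratory data. This vignette documents the
models, the tunable parameters and the design choices, in that order of
importance.

## The coarse-grained aggregation model

Peptides are freely jointed chains of `chain_length = 8` hard beads of
diameter 1 sigma with bond length 1 sigma, in a cubic periodic box. The
reduced length unit maps to physical size through `sigma_nm = 0.5`, so a
3.3 nm particle has diameter 6.6 sigma. Energies are in units of kT
(canonical, fixed-temperature ensemble).

Two interactions drive the physics:

* **Inter-chain hydrogen bonds.** Bead pairs on *different* chains closer
  than `hb_cutoff = 1.2` sigma can bond, each bead holding at most
  `max_bonds_per_bead = 2` bonds, a beta-strand-like valence that favours
  linear, fibril-like growth. Each bond contributes `-eps_hb` with
  `eps_hb = 4` kT, strong enough that aggregation proceeds at the default
  densities but weak enough that bonds still break. Bond bookkeeping is
  *judged before each move*: bonds stretched beyond the cutoff break, and
  eligible pairs that come inside the cutoff form, nearest distance first,
  with ties broken by the lowest (chain, bead) index so trajectories are
  reproducible. Setting `eps_hb = 0` disables bond formation entirely,
  giving an exactly non-interacting reference system.
* **Nanoparticle adsorption.** NPs are fixed hard spheres placed uniformly
  at random without mutual overlap. Each carries a square-well shell of
  thickness 0.5 sigma outside the hard core; a bead whose centre lies in
  the shell gains `-adsorption_energy` (2 kT per bead by default). While
  inside a shell a bead is barred from *forming new* bonds
  (`adsorbed_bond_block = TRUE`), expressing the monomer-sequestration
  mechanism: peptide captured on the NP surface is removed from the
  aggregation-competent pool. Existing bonds are not severed by
  adsorption.

A Monte Carlo *step* is one attempted move of one uniformly chosen chain,
which keeps step schedules comparable across system sizes. Move types are
drawn with equal weight by default:

* **pivot** — rigid rotation of a random chain tail about a random bead,
  uniform axis and angle;
* **crankshaft** — rotation of one interior bead about the axis through
  its two neighbours, angle uniform in plus/minus `crankshaft_max_angle`
  (default pi/2 — a local move, distinct from the kink-jump below);
* **kink-jump** — resampling of one interior bead uniformly on the circle
  of points preserving both adjacent bond lengths (when the neighbours are
  collinear with the bead the circle degenerates and the move is a null
  move);
* **translation** — whole-chain displacement, each component uniform in
  plus/minus one bead diameter.

Acceptance is the standard Metropolis rule `min(1, exp(-dE))`, with hard
overlaps (bead-bead closer than one diameter, or a bead centre inside an
NP) rejected outright. The total energy is updated incrementally and can
be checked against a full recomputation every 1000 steps
(`debug_energy = TRUE`); the tests require agreement within 1e-8 kT.

**Observable.** Two chains belong to the same aggregate when connected
through shared inter-chain bonds (transitively). The headline observable
is the mean number of chains per aggregate, averaged over snapshots taken
every `snapshot_stride = 1000` steps across the trailing analysis window —
monomers count as aggregates of size one, which makes the non-interacting
limit exactly 1.0. Whether chains adsorbed on the same NP without mutual
bonds form one aggregate is a modelling question with no unique answer; the
default says no, and `cluster_chains(state, merge_np_contact = TRUE)`
provides the alternative reading.

**Presets and problem sizes.** Three presets cover routine use:

| preset | box (sigma) | chains | relax | production | analysed | replicates |
|---|---|---|---|---|---|---|
| `desk` | 20 | 100 | 1e4 | 1e5 | 1e4 | 5 |
| `sweep` | 62 | 680 | 1e4 | 1e6 | 1e5 | 5 |
| `paper2020` | 77.4 | 1330 | 1e4 | 1e6 | 1e5 | 10 |

`paper2020` is the full published geometry (38.7 nm box). `desk` is a
dense small box for fast experiments. `sweep` is the default base
configuration of `size_sweep()`: its box must exceed twice the largest
swept particle diameter (30 sigma for a 15 nm particle), and its chain
count preserves the full-scale chain number density (about 2.9e-3 chains
per cubic sigma) so aggregation propensity carries over. The desk box is
too small to host particles above 5 nm, which is why the sweep does not
reuse it.

## The size sweep and what it can show

`size_sweep()` implements the experimental dosing rule: every diameter
receives the same *total surface area*, `n = round(S / (pi d^2))`
particles of diameter `d` against a budget `S`. The default budget is the
area of a single particle of the largest swept diameter — the smallest
budget under which every swept diameter still receives at least one
particle (a zero count is an error, not a silent skip). Replicate `r` of
every condition runs with seed `seed + r`, so conditions are paired.

A structural property of this minimal model is worth stating openly. At
matched surface area the total *shell volume* — the capacity of the
sequestration mechanism — is `4 pi t (R^2 + R t + t^2/3) n`, which is
`S t` to leading order but carries a `t/R` correction that *grows* as
particles shrink. The uniform square well also applies no curvature
penalty to binding: a freely jointed chain with 1-sigma bonds can keep
consecutive bead centres inside a 0.5-sigma shell even on a 2 nm particle.
Both features push the model toward "smaller is (slightly) better" at
matched area, opposed only by the larger hard-core volume of big
particles, which crowds chains together. Mechanisms that penalise very
small particles in experiments — curvature-weakened multivalent binding,
ligand-shell packing — are deliberately outside this model, so an interior
optimum in diameter need not emerge from it; conclusions from the sweep
should rest on the NP-versus-control contrast, which the sequestration
mechanism does produce, rather than on fine ranking among adjacent
diameters.

## Fibrillation kinetics

ThT fluorescence time courses are fitted with the Boltzmann sigmoid

    F(t) = F0 + A / (1 + exp(-k (t - t_half)))

with baseline `F0`, amplitude `A` (maximum minus baseline), apparent
aggregation constant `k` (per hour) and half-time `t_half`. The lag time
uses the tangent-at-midpoint convention standard in amyloid kinetics,

    lag = t_half - 2 / k .

Other lag conventions exist; every reported lag in this package means the
expression above, and the identity is exact in every returned fit.
Starting values are data-driven (baseline from the minimum, amplitude from
the range, half-time from the interpolated half-range crossing, rate from
the steepest observed slope via `k = 4 s_max / A`), and fitting is
Levenberg-Marquardt
(`minpack.lm`). A flat curve has no transition to fit and is an error; a
non-converged fit is returned flagged, never as silent success.

Replicates are fitted independently and summarised as means of parameters
(`fit_tht()`, `compare_fits()`), not as fits of averaged curves, which
would understate replicate variance. Inhibition is flagged when, relative
to the control, lag rises, `k` falls and `A` falls. The percent decrease
in maximum intensity is `100 (1 - A_treated / A_control)` on fitted
amplitudes by default; plateau maxima (`F0 + A`) are available via
`method = "plateau"` since published percent decreases do not always say
which was used.

## ITC binding thermodynamics

`one_site_heats()` is the forward model for titrating peptide into an NP
solution: running total concentrations follow a perfusion (overfill)
convention in which each injection of volume `dv` into cell volume `V0`
dilutes existing contents by `(1 - dv/2V0)/(1 + dv/2V0)` and delivers
fresh titrant attenuated by `1/(1 + dv/2V0)`; instrument vendors differ in
this bookkeeping at the second decimal, and at 2 uL against 200 uL the
differences are far below fit noise. Bound titrant comes from the one-site
mass-action closed form (the positive root of the binding quadratic), and
the heat of injection `i` is `dH V0 (Xb_i - Xb_{i-1} f_i)` in
microcalories, with `f_i` the dilution factor, plus an optional constant
per-injection heat-of-dilution offset that `fit_one_site()` estimates by
default since measured titrations rarely return exactly to zero.

The fitter works on `log10 K` internally (the likelihood is far better
behaved in the exponent), does not constrain the stoichiometry `n0` near
one — peptide multilayers on an NP surface make `n0` large — and derives
`dG = -R T ln K` and `dS = (dH - dG)/T` at the thermogram temperature, so
both thermodynamic identities hold to machine precision by construction.
A Wiseman c-value `n0 K [cell]` outside `[1, 1e4]` warns that the isotherm
shape poorly determines the constants; it is a warning, not an error,
because synthetic studies routinely probe that regime on purpose.

The built-in presets (`itc_truth_default()`) anchor their binding
constants to Gibbs energies of -6.7 and -7.3 kcal/mol at 298.15 K with a
negative enthalpy and `n0 = 10`; the enthalpy and stoichiometry are
illustrative emulation values, not measurements.

## Plasma elimination

First-order elimination appears as a straight line in `log10`
concentration: `y = a - b t`. The package fixes the log base at 10 because
only that reading makes published slope-halflife pairs consistent through
`t_half = log10(2)/b` — e.g. a slope of 0.0211 per hour gives 14.27 h,
printing as 14.3 h. Concentrations are averaged per time point before
fitting by default, matching destructive sampling designs (different
animals at each time); `per_time_means = FALSE` fits all points.
A non-positive fitted decay returns a flagged fit with undefined
half-life. `peak_summary()` summarises biodistribution series: per-time
group means, the time of the maximum mean (earliest time on ties) and the
fold-change against the control group at that time.

## Synthetic data

Each generator draws from the corresponding stage model with a stated
noise process and is a pure function of its arguments and seed (the
session RNG stream is saved and restored):

* `gen_tht()` — additive Gaussian noise (sd 2 a.u. by default) around
  sigmoid truths; the default treated groups reduce the control amplitude
  by 60%, 63% and 11% with extended lag and reduced rate, so end-to-end
  demos produce recognisable effect sizes. These are emulation targets,
  not data.
* `gen_itc()` — proportional Gaussian noise (2%) on one-site heats at the
  default titration geometry (twenty 2 uL injections of 138 uM titrant
  into 200 uL of 1.5 uM cell species, 25 C).
* `gen_pk()` — multiplicative lognormal noise (sd 0.1 on the log scale) on
  exponential decay, keeping concentrations positive by construction, with
  4 subjects per time point on a 6/12/24/48 h grid.

What passing tests on these generators show is that the estimators recover
the truth of *their own models* under the stated noise; they say nothing
about fluorescence quenching, inner-filter effects, baseline drift,
incomplete titrations or absorption/distribution phases, none of which the
generators emulate.

## Numerical choices and degenerate inputs

* Determinism: every stochastic routine takes an explicit seed; the
  simulator uses its own 64-bit generator (independent of R's RNG stream),
  and replicate `r` always runs at `seed + r`.
* Excluded volume uses strict inequality with adjacent backbone neighbours
  exempt (they sit exactly at contact by construction).
* Bond-candidate ordering (distance, then lowest chain and bead index)
  makes the saturating bond assignment unique.
* Noise-free round-trip tolerances: 1e-6 relative for the sigmoid, 1e-4
  for the ITC fit (its forward model is itself iterative bookkeeping),
  machine precision for the linear elimination fit.
* Degenerate inputs fail loudly and specifically: flat ThT curve ("no
  transition"), all-zero thermogram (flagged non-convergence), non-positive
  concentrations, packing failures ("density too high", with the achieved
  density), surface-area budgets rounding to zero particles.

## Known limitations

The bead chain has no residue identity, no chirality and no secondary
structure, so enantiomer-specific effects are out of reach by design;
Monte Carlo steps have no calibrated physical time, so simulated
aggregation cannot be compared with ThT kinetics quantitatively; the
one-site ITC model cannot represent cooperative multilayer growth even
though it fits such data operationally; and the sweep's fine size ranking
is limited by the model structure discussed above.
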