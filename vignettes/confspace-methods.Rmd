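---
title: "confspace: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{confspace: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the model and its assumptions, every tunable parameter with its unit and
default, what the synthetic benchmark does and does not establish, the
numerical choices, and known limitations.

## 1. From distance distributions to a differentiable target function

A PELDOR/DEER measurement on one spin-label pair yields a discrete
probability density $\{(r_1,p_1),\dots,(r_N,p_N)\}$ over the inter-label
distance. `confspace` normalizes each to unit trapezoidal area
(`normalize_unit_area()`) and interpolates it with a Fritsch–Carlson
monotone cubic Hermite spline (`make_continuous()`,
`stats::splinefun(method = "monoH.FC")`). The interpolant reproduces every
knot, is shape-preserving (no overshoot below zero or spurious wiggles
between knots), is clamped at zero, defined as zero outside the measured
support $[r_1, r_N]$, and has an analytic first derivative. Any smooth
non-negative interpolant satisfying $P(r_j)\approx p_j$ would serve; the
exact curve family is immaterial to the method's behaviour, and the
monotone cubic is chosen for reproducibility. The density maximum
$p_{\max}$ is evaluated on a 0.01 Å grid, not only at knots, so normalized
probabilities can never exceed 1.

The restraint penalty is

$$T(r) = A \cdot \max\!\left(0,\; 1 - \frac{P(r)}{p_{\max}\, c}\right)$$

- **A** (weighting factor, Å², default **10.0**): the cost of a fully
  improbable distance. Large compared to the steric term, so distance
  restraints dominate the optimization.
- **c** (cutoff, dimensionless, default **0.75**): all distances with
  normalized probability $P(r)/p_{\max} \ge c$ lie on a zero-penalty
  *plateau*, so every sufficiently probable distance is equally acceptable
  and the ensemble is not strained towards the single most probable value.

Outside the measured support $P := 0$, hence $T = A$: distances never
observed experimentally are maximally disfavoured.

## 2. Rigid bodies, pseudo-linker, label sites

The system is two rigid bodies — *stationary* and *moving* — joined by a
flexible linker. Rigid bodies keep their internal geometry exactly (they are
moved only by a rotation and a translation), which realizes by construction
what restraint-based engines enforce with intra-body distance restraints.

The linker is a pseudo-chain: one virtual bond of fixed length per residue
(default **3.8 Å**, the Cα–Cα spacing) plus one bond joining it to each
anchor, with free pseudo-torsions and bounded deflection angles (default
maximum deflection **110°**, i.e. pseudo bond angles ≥ 70°). Its role is to
tether the moving body and limit its reach, which is all the flexible
residues do in this method; full backbone torsions would add cost without
adding information. Crucially, the moving body's **pose is parameterized
through the chain**: the chain starts at the stationary anchor atom, and the
moving body's anchor atom is placed at the chain end, so the chain is closed
for every conformer ever generated and the translation is a derived
quantity. (For this reason the annealing proposals act on rotation and chain
parameters only; explicit translational moves would break the chain.)

Spin labels are virtual points: by default **7 Å** from the labelled
residue's Cα along the Cα→Cβ direction (radially outward from the body
centre for Cα-only models), approximating the distance to the nitroxide
N–O bond centre; explicit points or weighted point clouds may be supplied
instead (clouds collapse to their weighted mean for distance evaluation).
Rotamer-library label modelling is intentionally out of scope; the synthetic
benchmark uses the same label model for truth and recovery, so the
simplification is self-consistent there.

Steric overlap is a soft-sphere quadratic: $k\sum \max(0, d_{\min}-d)^2$
over inter-body sphere pairs, with $k = 1$ and, in the default *coarse*
mode, one 3.0 Å sphere per residue at the Cα (per-element radii
C/N/O/S = 1.7/1.55/1.52/1.8 Å in *atom* mode). A soft in-target term rather
than post-hoc filtering keeps every calculated structure usable.

## 3. The history-dependent sampling protocol

Defaults are the published protocol constants:

| parameter | default | meaning |
|---|---|---|
| `n_iterations` | 250 | iterations |
| `n_calculated` | 100 | structures optimized per iteration |
| `n_selected` | 10 | lowest-target structures kept (top 10%) |
| `sigma_sub` | 2.5 Å | sd of each subtracted Gaussian |
| `A`, `c` | 10 Å², 0.75 | penalty constants |

The ensemble size is $n = n_{\text{iterations}} \times n_{\text{selected}}
= 2500$. After each iteration, for every kept conformer and every restraint
a Gaussian with sd `sigma_sub` and area $1/n$ centred at the conformer's
distance is subtracted from a *working copy* of the distribution, clamping
negative values at zero. Summed over the whole run the subtracted area
equals the unit area of the input, so the working distributions are nearly
flat by the last iterations and sampling has visited every probable
distance in proportion to its probability — the same history-dependent
flattening as metadynamics, applied to a restraint error function.

Working distributions live on a fixed **0.1 Å** grid with linear
interpolation (the spline is used only for the pristine originals);
repeated subtraction of a spline is ill-defined, whereas the gridded state
is closed under the update. $p_{\max}$ is recomputed from the *current*
working distribution after every change, so the plateau tracks the
not-yet-sampled regions. Subtraction happens at the end of an iteration —
all 100 structures of one iteration see the same working distributions.
Ties in the target value are broken by the lower derived-seed index.

Two conventions the protocol leaves open are resolved as follows:

- **Fully flattened restraints.** Once a working distribution's $p_{\max}$
  falls below `flatten_threshold` (default 1e-3) of its original value, its
  penalty term is treated as identically zero. The formula divides by
  $p_{\max}$; near-zero values would otherwise make the penalty ≈ A almost
  everywhere, inverting the intended "flattened ⇒ fully sampled ⇒ free"
  semantics.
- **Out-of-support restoring term.** The capped penalty is constant
  ($T = A$) outside the measured support, so a frustrated optimization run
  — typical late in the protocol when the residual distributions of
  different restraints are hard to satisfy jointly — would feel no force
  pulling it back into the observed range, and occasionally a selected
  conformer violated the support. A quadratic out-of-range term
  (`k_oos`, default 4 Å²/Å², the analogue of an NOE upper/lower-limit
  violation penalty) is therefore added *on top of* A outside the support
  only; the published formula is unchanged on the support. With it, the
  packaged benchmark selects no conformer outside any restraint's support.

### The annealing engine

The optimizer is a bespoke Metropolis simulated annealer over the moving
body's quaternion and the chain parameters, from a random start
("torsions set to random values at the beginning of each calculation"):
`anneal_steps` (default **1000**) steps of geometric cooling from
`anneal_T_start` = 10 Å² to `anneal_T_end` = 0.01 Å², with Gaussian
proposals of sd 15° on rotation/torsion/direction angles and 10° on
deflections (reflected at their bounds). Nothing about this engine tries to
match any particular molecular-dynamics package; it is validated solely by
the reproduction properties below, and the defaults were fixed by those
properties (deeper annealing improves per-structure optimality but not the
ensemble-level reproduction). Per-structure seeds are derived as
`(seed·69069 + iteration·65537 + index·101) mod (2^31−1)`; the C++ engine
uses its own xorshift RNG, so runs are bitwise reproducible and independent
of the standard library's distribution implementations.

## 4. Weighting and density maps

Weighting uses the **original** (not working) distributions — weighting
happens after sampling, and the working copies are exhausted by design.
Each conformer's probability for restraint $i$ is the area of distribution
$i$ in the window $r_i \pm 2.5$ Å (`window_probability()`, composite
Simpson on a ~0.01 Å grid); the per-restraint probabilities are multiplied
(as log-sums, to survive 17+ restraints without underflow) and divided by
the ensemble maximum, so the most probable conformer has relative
probability exactly 1. Zero-probability conformers are retained with
relative probability 0, keeping the bookkeeping size equal to the
protocol's count.

For the density map, conformers (already in the stationary body's frame;
`superpose_on_stationary()` handles externally supplied models via Kabsch
superposition) contribute isotropic 3D Gaussians with **peak amplitude
equal to the relative probability** — amplitude, not integral, is the
natural choice under max-merging, where the map value is a "best relative
probability of finding the moving body here". Defaults: one Gaussian at the
moving body's geometric centre with sd equal to the rigid part's radius of
gyration (a nearly spherical protein is well represented by a single
Gaussian scaled to its size); a per-residue mode (sd 2.2 Å, calibrated so a
globular synthetic body renders the same level-0.5 iso-volume as the single
mode within ~10%) for non-globular bodies. Gaussians are truncated at
3σ, evaluated on a 1 Å grid padded by the truncation radius, and merged by
taking the maximum at each grid point. Maps are written as OpenDX text or
CCP4/MRC-2000 (mode 2, little-endian) volumes sharing the frame of the
multi-model ensemble PDB.

## 5. The synthetic benchmark: what a green test establishes

`make_synthetic_system()` builds two compact random Cα clouds (default 60
residues in a 10 Å ball, ≥ 3 Å separation), a pseudo-linker (default 5
residues), label sites spread over each body's surface by farthest-point
sampling, and `n_states` weighted clash-free truth poses (weights
$\propto 1..n$; states redrawn until some pair's distances differ by > 8 Å
so at least one simulated distribution is bimodal).
`simulate_distributions()` forward-simulates each pair as the
weight-mixture of Gaussians at the per-state distances, sd 2.5 Å by
default — deliberately equal to the subtraction kernel, which makes the
round trip a fixed point in the infinite-sampling limit. Multiplicative
noise is available but the packaged benchmark is noiseless.

The packaged benchmark (2 bodies, 2-state truth, 6 pairs, protocol scaled
to 50 × 20/4, seeds fixed at 42/7) establishes that restrained ensembles
reproduce every input distribution (histogram intersection ≥ 0.7; measured
0.88–0.98) and beat an unrestrained baseline for every pair, and that a
withheld restraint is reproduced better than by a free run. It does **not**
establish: robustness to kernel mismatch (σ_sim ≠ σ_sub), to noisy or
Tikhonov-artefacted experimental distributions, to label-model error
(rotamer distributions vs virtual points), or to more than two bodies.

**Known limitation.** With only 6 pairs and plateau slack of ±~2 Å per
restraint, the pose is underdetermined: leave-one-out margins over the free
baseline are small (the packaged harness withholds the first pair, margin
+0.01 overlap), and for one of the six pairs the withheld distribution is
reproduced no better than the free baseline. This is a property of sparse
distance-only restraints, not of the sampler; the published application
used 17 pairs.

## 6. Numerical conventions

- Internal unit is Å everywhere; input files may be declared nm or Å.
- Degenerate inputs: all-zero densities, non-monotone distance columns,
  < 3 rows, duplicate restraint labels, restraints on undeclared labels and
  same-body label pairs are hard errors; negative densities clamp to 0 with
  a warning; penalty evaluation on a fully flattened distribution signals a
  `confspace_flattened` condition and contributes 0.
- `distribution_overlap()` integrates the pointwise minimum of two
  piecewise-linear densities exactly (cells split at crossings);
  `window_probability()` uses composite Simpson — both so that comparisons
  against independent fine-grid quadrature agree to 1e-6.
- Configurations are JSON (no YAML parser is guaranteed in the supported
  stack); every run writes a manifest sufficient to reproduce it.
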