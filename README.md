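# confspace

Determination and visualization of the accessible conformation space of
multi-domain protein complexes from pulsed EPR (PELDOR/DEER) distance
distributions.

## The problem

PELDOR/DEER experiments measure the dipolar coupling between two nitroxide
spin labels and yield, per label pair, a *probability distribution* P(r) of
the inter-label distance (~18–100 Å). For covalently linked but weakly
interacting domains — ubiquitin conjugated to an E2 enzyme, di-ubiquitin
chains, poly-domain synthetases — no single structure exists: the system
populates a whole conformation space, and the widths and shapes of the
distance distributions encode it. `confspace` turns a set of such
distributions into (i) a structural ensemble whose pairwise label distances
reproduce every input distribution, (ii) per-conformer relative
probabilities, and (iii) a 3D density map of where the moving domain lives
around the stationary one.

## The method

Each unit-area experimental distribution is interpolated by a
shape-preserving cubic (so it has analytic derivatives) and converted into a
penalty term of the sampling target function

```
T(r) = A · max(0, 1 − P(r) / (p_max · c))
```

with weighting factor A = 10 Å² and cutoff c = 0.75: distances whose
normalized probability is at least `c` lie on a zero-penalty *plateau*;
unobserved distances cost the full A. Conformers of two rigid bodies joined
by a flexible pseudo-linker are optimized against the sum of these terms
(plus a soft-sphere steric score) by simulated annealing.

Because an optimizer alone would pile conformers onto the distribution
modes, sampling is made history-dependent, in the spirit of metadynamics:
the protocol runs 250 iterations; each iteration calculates 100 structures
and keeps the 10 with the lowest target value; for every kept structure and
every restraint, a Gaussian (σ = 2.5 Å, area 1/2500) centred at the
structure's distance is subtracted from a *working copy* of that restraint's
distribution (clamped at zero). High-probability regions are thus
progressively flattened and later iterations are driven into the not-yet
sampled parts of each distribution. The result is an ensemble of 2500
structures whose accumulated distance distributions resemble the inputs.

Each conformer is then weighted by the product over restraints of the
original distribution's area in the window r ± 2.5 Å, normalized so the most
probable conformer has relative probability 1. For visualization, conformers
are superposed on the stationary body and the moving body is rendered as
amplitude-scaled 3D Gaussians on a 1 Å grid, merged by taking the maximum at
each grid point, and written as OpenDX or CCP4/MRC volumes (loadable in
PyMOL/ChimeraX together with the multi-model PDB of the ensemble).

A synthetic-data module generates complete ground-truth benchmarks (two
globular bodies, a flexible linker, label sites, weighted truth states, and
forward-simulated Gaussian-mixture distributions), so the entire pipeline is
testable without any experimental input.

## Worked example

```r
library(confspace)

# ground-truth benchmark: 2 bodies, 2-state truth, 6 spin-label pairs
bm    <- make_synthetic_system(n_states = 2, n_label_pairs = 6, seed = 42)
dists <- simulate_distributions(bm$truth, bm$system)     # unit-area mixtures

cfg <- protocol_config(n_iterations = 50, n_calculated = 20,
                       n_selected = 4, rng_seed = 7)     # scaled-down protocol
ens  <- run_protocol(dists, bm$system, cfg)              # 200 conformers
free <- run_protocol(NULL, bm$system, cfg, free = TRUE)  # unrestrained baseline

for (nm in names(dists)) {
  cat(sprintf("%s  restrained %.3f   free %.3f\n", nm,
    distribution_overlap(ensemble_distribution(ens,  nm), dists[[nm]]),
    distribution_overlap(ensemble_distribution(free, nm), dists[[nm]])))
}
```

Output (histogram intersection between the ensemble's distance distribution
and the corresponding input; 1 = perfect reproduction):

```
pair1  restrained 0.922   free 0.427
pair2  restrained 0.876   free 0.388
pair3  restrained 0.962   free 0.681
pair4  restrained 0.959   free 0.470
pair5  restrained 0.952   free 0.562
pair6  restrained 0.984   free 0.429
```

The restrained ensemble reproduces every input distribution (overlap
0.88–0.98), while the free run does not — the synthetic analogue of the
method's published validation. Continuing:

```r
ens  <- assign_relative(ens)                  # max relative probability == 1
grid <- build_density_grid(ens)               # 1 A grid, max-merged Gaussians
write_volume(grid, "density.dx")              # or .mrc
write_ensemble_pdb(ens, "ensemble.pdb")
```

## Command line

```sh
Rscript exec/confspace synth --seed 1 -o fixture/        # synthetic fixture
Rscript exec/confspace run -c fixture/config.json        # full pipeline
Rscript exec/confspace validate -c fixture/config.json   # reproduction + leave-one-out
```

`run` writes `ensemble.pdb`, `ensemble.json`, `weights.tsv`, per-pair
calculated distributions, `density.dx`/`density.mrc` and a reproducibility
manifest. Flags `--seed`, `--iterations`, `--calculated`, `--selected`,
`--sigma-sub`, `--weighting-factor`, `--cutoff` override the configured
protocol. Configurations are JSON; distance files may be declared in nm or
Å per file; everything internal and all outputs are Å.

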