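# Shared fixtures, built in code at test time.

# Independent trapezoid oracle (deliberately separate from the package's).
trapz_oracle <- function(x, y) {
  n <- length(x)
  sum(diff(x) * (y[-1] + y[-n]) / 2)
}

# Small two-body system for fast sampler/geometry tests (12 residues/body).
tiny_system <- function(seed = 5, n_states = 1, pairs = 2, linker = 4) {
  make_synthetic_system(n_states = n_states, linker_length = linker,
                        n_label_pairs = pairs, seed = seed,
                        n_residues = 12, body_radius = 6)
}

# Unit-area Gaussian restraint as a discrete distribution (knots 0.5 A).
gaussian_restraint <- function(mu, sigma = 2.5, label = "g", half_span = 15) {
  r <- seq(mu - half_span, mu + half_span, by = 0.5)
  normalize_unit_area(distance_distribution(r, dnorm(r, mu, sigma), label = label))
}

# Linear-ramp density from 0 at r0 to peak at r1, unit area (exactly
# reproduced by the monotone cubic interpolant).
ramp_restraint <- function(r0 = 20, r1 = 30, label = "ramp") {
  r <- seq(r0, r1, by = 0.5)
  normalize_unit_area(distance_distribution(r, r - r0, label = label))
}

write_tmp_dist <- function(lines) {
  f <- withr::local_tempfile(fileext = ".dat", .local_envir = parent.frame())
  writeLines(lines, f)
  f
}

# Minimal fake conformer carrying only pair distances (enough for the
# subtraction and weighting operations).
fake_conformer <- function(distances, relative = NA_real_) {
  structure(list(quat = c(1, 0, 0, 0), translation = c(0, 0, 0), chain = NULL,
                 pair_distances = distances, target_value = NA_real_,
                 relative_probability = relative),
            class = "conformer")
}

fake_ensemble <- function(conformers, system, labels = NULL,
                          cfg = protocol_config()) {
  structure(list(conformers = conformers,
                 labels = labels %||% names(conformers[[1]]$pair_distances),
                 state = NULL, cfg = cfg, system = system, free = FALSE),
            class = "conf_ensemble")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Three-residue synthetic PDB text (backbone + CB), for reader tests.
tiny_pdb_lines <- function() {
  c("REMARK synthetic test structure",
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C",
    "ATOM      3  CB  ALA A   1       2.000   1.400   0.000  1.00  0.00           C",
    "ATOM      4  CA  ALA A   2       4.000   1.000   0.500  1.00  0.00           C",
    "ATOM      5  CA  ALA A   3       7.500   2.000   1.000  1.00  0.00           C",
    "END")
}
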