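## History-dependent ensemble sampler.
##
## Each iteration optimizes n_calculated conformers by simulated annealing
## against the current *working* distributions, keeps the n_selected lowest
## target-function values, and subtracts from each working distribution one
## Gaussian (sd sigma_sub, area 1/n with n the total ensemble size) per
## selected conformer distance, clamping at zero. High-probability regions
## are thereby progressively flattened so that successive iterations explore
## the remaining, not-yet-sampled parts of each distribution - the same
## history-dependent flattening idea as metadynamics, applied to the
## restraint error function.

#' Protocol configuration
#'
#' Defaults are the published protocol constants: 250 iterations of 100
#' calculated / 10 selected structures (ensemble size 2500), subtraction
#' Gaussians of sd 2.5 Angstrom and area 1/2500, weighting factor A = 10
#' Angstrom^2 and cutoff c = 0.75.
#'
#' @param n_iterations number of iterations (default 250).
#' @param n_calculated structures calculated per iteration (default 100).
#' @param n_selected lowest-target structures kept per iteration (default 10).
#' @param sigma_sub sd of the subtracted Gaussians in Angstrom (default 2.5).
#' @param A penalty weighting factor, Angstrom^2 (default 10).
#' @param c plateau cutoff on normalized probability (default 0.75).
#' @param anneal_steps Metropolis steps per structure (default 1000).
#' @param anneal_T_start,anneal_T_end geometric cooling schedule in target
#'   units, Angstrom^2 (defaults 10 and 0.01).
#' @param rng_seed integer seed; every random draw of the protocol derives
#'   from it.
#' @param steric_mode `"coarse"` (one 3 Angstrom sphere per residue at the
#'   Calpha; default) or `"atom"` (per-element radii).
#' @param k_steric soft-sphere stiffness (default 1).
#' @param k_oos stiffness of the quadratic out-of-support term added on top
#'   of the maximal penalty A when a restrained distance leaves the measured
#'   range entirely (Angstrom^2 per Angstrom^2, default 4); gives the
#'   optimizer a restoring gradient towards observed distances.
#' @param grid_step evaluation grid of the working distributions (Angstrom,
#'   default 0.1).
#' @param flatten_threshold fraction of the original p_max below which a
#'   working distribution is considered fully flattened and its penalty term
#'   is dropped (default 1e-3).
#' @param move_sigma_rot,move_sigma_angle,move_sigma_delta proposal widths in
#'   degrees for rotation axis-angle, chain direction/torsion and deflection
#'   moves (defaults 15, 15, 10).
#' @return A `protocol_config`.
#' @export
protocol_config <- function(n_iterations = 250L, n_calculated = 100L,
                            n_selected = 10L, sigma_sub = 2.5, A = 10.0,
                            c = 0.75, anneal_steps = 1000L,
                            anneal_T_start = 10, anneal_T_end = 0.01,
                            rng_seed = 1L, steric_mode = c("coarse", "atom"),
                            k_steric = 1, k_oos = 4, grid_step = 0.1,
                            flatten_threshold = 1e-3,
                            move_sigma_rot = 15, move_sigma_angle = 15,
                            move_sigma_delta = 10) {
  if (n_selected > n_calculated) stop("n_selected must be <= n_calculated")
  stopifnot(n_iterations >= 1, sigma_sub > 0, A > 0, c > 0, c <= 1,
            anneal_steps >= 1, anneal_T_start > 0, anneal_T_end > 0)
  structure(list(
    n_iterations = as.integer(n_iterations),
    n_calculated = as.integer(n_calculated),
    n_selected = as.integer(n_selected),
    sigma_sub = sigma_sub, A = A, c = c,
    anneal_steps = as.integer(anneal_steps),
    anneal_T_start = anneal_T_start, anneal_T_end = anneal_T_end,
    rng_seed = as.integer(rng_seed), steric_mode = match.arg(steric_mode),
    k_steric = k_steric, k_oos = k_oos, grid_step = grid_step,
    flatten_threshold = flatten_threshold,
    move_sigma_rot = move_sigma_rot, move_sigma_angle = move_sigma_angle,
    move_sigma_delta = move_sigma_delta
  ), class = "protocol_config")
}

ensemble_size <- function(cfg) cfg$n_iterations * cfg$n_selected

# A working distribution: the mutable, gridded copy of an experimental
# distribution from which per-conformer Gaussians are subtracted.
new_working <- function(cd, step) {
  r <- seq(cd$support[1], cd$support[2], by = step)
  p <- cdist_eval(cd, r)
  list(r = r, p = p, p_max = max(p), p_max0 = max(p))
}

working_active <- function(w, threshold) w$p_max > threshold * w$p_max0

#' Initialize the sampling state
#'
#' @param restraints named list of unit-area distributions
#'   ([distance_distribution()] or `continuous_distribution`); names must be
#'   unique and must match restraint labels declared in `system$pairs`.
#' @param system a [conf_system()].
#' @param cfg a [protocol_config()].
#' @return A `sampling_state` holding immutable originals, working copies on
#'   a `cfg$grid_step` grid, and the subtraction history (0).
#' @export
init_state <- function(restraints, system, cfg = protocol_config()) {
  if (length(restraints) == 0) stop("empty restraint list")
  nms <- names(restraints)
  if (is.null(nms) || any(!nzchar(nms))) stop("restraints must be a named list")
  if (anyDuplicated(nms)) stop("duplicate restraint labels: ",
                               paste(unique(nms[duplicated(nms)]), collapse = ", "))
  missing <- setdiff(nms, system$pairs$label)
  if (length(missing)) stop("restraint(s) not declared in system pairs: ",
                            paste(missing, collapse = ", "))
  originals <- lapply(restraints, function(d) {
    if (inherits(d, "distance_distribution")) make_continuous(d)
    else if (inherits(d, "continuous_distribution")) d
    else stop("restraints must be distance_distribution or continuous_distribution")
  })
  working <- lapply(originals, new_working, step = cfg$grid_step)
  structure(list(originals = originals, working = working, system = system,
                 cfg = cfg, history = 0L, iteration = 0L,
                 nominal_subtracted = stats::setNames(numeric(length(nms)), nms),
                 area_log = list()),
            class = "sampling_state")
}

# Per-structure seed, derived reproducibly and kept in 32-bit range. All
# arithmetic is exact in doubles (< 2^53).
derive_seed <- function(seed, iteration, index) {
  as.integer((as.numeric(seed) * 69069 + as.numeric(iteration) * 65537 +
                as.numeric(index) * 101) %% 2147483647)
}

# Penalty of one working distribution at distance r: linear interpolation on
# the grid, dropped entirely once flattened below threshold. Outside the
# measured support P = 0, so the term takes its maximal value A; on top of
# that a quadratic out-of-range term (CYANA-style) grows with the distance
# beyond the support, giving the optimizer a restoring gradient back towards
# experimentally observed distances.
working_penalty <- function(w, r, cfg) {
  if (!working_active(w, cfg$flatten_threshold)) return(0)
  n <- length(w$r)
  if (r < w$r[1] || r > w$r[n]) {
    excess <- max(w$r[1] - r, r - w$r[n])
    return(cfg$A + cfg$k_oos * excess^2)
  }
  P <- stats::approx(w$r, w$p, xout = r)$y
  cfg$A * max(0, 1 - P / (w$p_max * cfg$c))
}

#' Target function of a conformer
#'
#' Sum over restraints of the working-distribution penalty at the conformer's
#' pair distance, plus the soft-sphere steric score. Contributions of fully
#' flattened restraints are zero.
#'
#' @param conformer a `conformer`.
#' @param state a [init_state()] object.
#' @param cfg protocol configuration; defaults to the one in `state`.
#' @return Target value in Angstrom^2.
#' @export
target_function <- function(conformer, state, cfg = state$cfg) {
  pen <- sum(vapply(names(state$working), function(nm) {
    working_penalty(state$working[[nm]], conformer$pair_distances[[nm]], cfg)
  }, 0))
  pen + conformer_steric(state$system, conformer, mode = cfg$steric_mode,
                         k = cfg$k_steric)
}

# Pack system + working distributions into flat structures for the C++
# annealing engine.
pack_for_cpp <- function(system, cfg, working = list()) {
  sa <- body_spheres(system$stationary, cfg$steric_mode)
  sb <- body_spheres(system$moving, cfg$steric_mode)
  lp <- do.call(rbind, system$label_positions)
  lb <- vapply(system$labels, function(s) if (s$body == "moving") 1L else 0L, 1L)
  pair_a <- match(system$pairs$a, names(system$labels)) - 1L
  pair_b <- match(system$pairs$b, names(system$labels)) - 1L
  grids <- lapply(system$pairs$label, function(nm) {
    w <- working[[nm]]
    if (is.null(w)) {
      list(r0 = 0, dr = 1, p = numeric(2), pmax = 1, active = FALSE)
    } else {
      list(r0 = w$r[1], dr = w$r[2] - w$r[1], p = w$p, pmax = w$p_max,
           active = working_active(w, cfg$flatten_threshold))
    }
  })
  list(stat_xyz = sa$xyz, mov_xyz = sb$xyz, stat_radii = sa$radii,
       mov_radii = sb$radii, anchor_s = system$anchor_stationary,
       anchor_m = system$anchor_moving, n_bonds = n_bonds(system),
       bond_length = system$linker$bond_length,
       delta_max = system$linker$delta_max,
       label_body = lb, label_xyz = lp, pair_a = pair_a, pair_b = pair_b,
       grids = grids)
}

cpp_result_to_conformers <- function(res, system, idx = seq_along(res$target)) {
  na <- n_bonds(system) - 1L
  lapply(idx, function(i) {
    chain <- list(alpha = res$alpha[i], beta = res$beta[i],
                  delta = if (na > 0) res$delta[i, seq_len(na)] else numeric(0),
                  phi = if (na > 0) res$phi[i, seq_len(na)] else numeric(0))
    cf <- make_conformer(system, res$quat[i, ], chain)
    cf$target_value <- res$target[i]
    cf
  })
}

#' Optimize a single conformer by simulated annealing
#'
#' Starting from random pose and linker parameters, runs `cfg$anneal_steps`
#' Metropolis steps with geometric cooling and returns the best-visited
#' conformer. A poor optimum is a valid, high-target conformer.
#'
#' @param state a [init_state()] `sampling_state` (or `free_state()`).
#' @param cfg protocol configuration; defaults to the one in `state`.
#' @param seed integer seed for this structure's trajectory; identical seeds
#'   give bitwise-identical trajectories.
#' @return A `conformer` with `target_value` and `pair_distances` set.
#' @export
optimize_structure <- function(state, cfg = state$cfg, seed = cfg$rng_seed) {
  pk <- pack_for_cpp(state$system, cfg, state$working)
  res <- run_structures_cpp(
    pk$stat_xyz, pk$mov_xyz, pk$stat_radii, pk$mov_radii,
    pk$anchor_s, pk$anchor_m, pk$n_bonds, pk$bond_length, pk$delta_max,
    pk$label_body, pk$label_xyz, pk$pair_a, pk$pair_b, pk$grids,
    cfg$A, cfg$c, cfg$k_steric, cfg$k_oos, cfg$anneal_steps,
    cfg$anneal_T_start, cfg$anneal_T_end,
    deg2rad(cfg$move_sigma_rot), deg2rad(cfg$move_sigma_angle),
    deg2rad(cfg$move_sigma_delta), as.integer(seed))
  cpp_result_to_conformers(res, state$system)[[1]]
}

#' Subtract a conformer from the working distributions
#'
#' For each restraint, subtracts a Gaussian centred at the conformer's pair
#' distance with sd `cfg$sigma_sub` and area `1/n` (n = total ensemble size),
#' clamping the result at zero, and recomputes the working p_max.
#'
#' @param state a `sampling_state`.
#' @param conformer a `conformer` carrying distances for every restraint.
#' @param cfg protocol configuration; defaults to the one in `state`.
#' @return The updated `sampling_state` (history incremented).
#' @export
subtract_conformer <- function(state, conformer, cfg = state$cfg) {
  n <- ensemble_size(cfg)
  for (nm in names(state$working)) {
    mu <- conformer$pair_distances[[nm]]
    if (is.null(mu) || is.na(mu)) stop("conformer lacks a distance for restraint '", nm, "'")
    w <- state$working[[nm]]
    w$p <- pmax(0, w$p - stats::dnorm(w$r, mean = mu, sd = cfg$sigma_sub) / n)
    w$p_max <- max(w$p)
    state$working[[nm]] <- w
    state$nominal_subtracted[nm] <- state$nominal_subtracted[nm] + 1 / n
  }
  state$history <- state$history + 1L
  state
}

#' Run one protocol iteration
#'
#' Calculates `cfg$n_calculated` structures (independent derived seeds),
#' selects the `cfg$n_selected` with the lowest target values (ties broken by
#' lower derived-seed index), and subtracts each selected conformer from the
#' working distributions in selection order.
#'
#' @param state a `sampling_state`.
#' @param cfg protocol configuration; defaults to the one in `state`.
#' @param subtract set `FALSE` for free (unrestrained) runs.
#' @return List with `conformers` (selected, ascending target) and `state`.
#' @export
run_iteration <- function(state, cfg = state$cfg, subtract = TRUE) {
  state$iteration <- state$iteration + 1L
  seeds <- vapply(seq_len(cfg$n_calculated), function(i) {
    derive_seed(cfg$rng_seed, state$iteration, i)
  }, 1L)
  pk <- pack_for_cpp(state$system, cfg, state$working)
  res <- run_structures_cpp(
    pk$stat_xyz, pk$mov_xyz, pk$stat_radii, pk$mov_radii,
    pk$anchor_s, pk$anchor_m, pk$n_bonds, pk$bond_length, pk$delta_max,
    pk$label_body, pk$label_xyz, pk$pair_a, pk$pair_b, pk$grids,
    cfg$A, cfg$c, cfg$k_steric, cfg$k_oos, cfg$anneal_steps,
    cfg$anneal_T_start, cfg$anneal_T_end,
    deg2rad(cfg$move_sigma_rot), deg2rad(cfg$move_sigma_angle),
    deg2rad(cfg$move_sigma_delta), seeds)
  sel <- order(res$target, seq_along(res$target))[seq_len(cfg$n_selected)]
  conformers <- cpp_result_to_conformers(res, state$system, sel)
  if (subtract) {
    for (cf in conformers) state <- subtract_conformer(state, cf, cfg)
  }
  state$area_log[[state$iteration]] <- vapply(state$working, function(w) {
    trapz(w$r, w$p)
  }, 0)
  list(conformers = conformers, state = state)
}

# State for free (unrestrained) runs: no working distributions; all restraint
# grids inactive so the target reduces to the steric score, but pair
# distances are still recorded for comparison with experiment.
free_state <- function(system, cfg) {
  structure(list(originals = list(), working = list(), system = system,
                 cfg = cfg, history = 0L, iteration = 0L,
                 nominal_subtracted = numeric(0), area_log = list()),
            class = "sampling_state")
}

#' Run the full sampling protocol
#'
#' @param restraints named list of unit-area distributions (one per spin
#'   pair), or `NULL` with `free = TRUE` for an unrestrained reference run.
#' @param system a [conf_system()].
#' @param cfg a [protocol_config()].
#' @param free if `TRUE`, run without restraints (steric-only target, no
#'   subtraction); the baseline of the validation protocols.
#' @param verbose print one progress line per iteration (iteration index,
#'   best/median target, mean residual working area).
#' @return A `conf_ensemble`: `conformers` (length `n_iterations *
#'   n_selected`), `labels`, the final `state`, `cfg` and `system`.
#' @export
run_protocol <- function(restraints, system, cfg = protocol_config(),
                         free = FALSE, verbose = FALSE) {
  state <- if (free) free_state(system, cfg) else init_state(restraints, system, cfg)
  conformers <- vector("list", ensemble_size(cfg))
  k <- 0L
  for (it in seq_len(cfg$n_iterations)) {
    step <- run_iteration(state, cfg, subtract = !free)
    state <- step$state
    conformers[k + seq_along(step$conformers)] <- step$conformers
    k <- k + length(step$conformers)
    if (verbose) {
      tv <- vapply(step$conformers, `[[`, 0, "target_value")
      area <- if (length(state$working))
        mean(state$area_log[[state$iteration]]) else NA_real_
      message(sprintf("iteration %3d/%d  best %.4g  median %.4g  mean working area %.4g",
                      it, cfg$n_iterations, min(tv), stats::median(tv), area))
    }
  }
  structure(list(conformers = conformers, labels = names(state$originals),
                 state = state, cfg = cfg, system = system, free = free),
            class = "conf_ensemble")
}

#' @export
print.conf_ensemble <- function(x, ...) {
  cat(sprintf("<conf_ensemble: %d conformers, %d restraints%s>\n",
              length(x$conformers), length(x$labels),
              if (x$free) ", free run" else ""))
  invisible(x)
}
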