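## Conformer weighting by the original experimental distributions.
##
## Each experimental distribution is a unit-area probability density; the
## probability assigned to a conformer distance r is the area of the
## distribution in the window r +/- 2.5 A. Per-conformer window probabilities
## are multiplied across restraints (as log-sums, to avoid underflow with
## many restraints) and the products are divided by their maximum so the most
## probable conformer has relative probability exactly 1.

#' Window probability of a distance under an original distribution
#'
#' Integral of the unit-area distribution over `[r - half_width, r +
#' half_width]`, by composite Simpson quadrature on a ~0.01 Angstrom grid,
#' clipped to `[0, 1]`.
#'
#' @param dist a `continuous_distribution` (unit-area original).
#' @param r conformer distance in Angstrom.
#' @param half_width window half-width in Angstrom (default 2.5).
#' @return Probability in `[0, 1]`; 0 if the window misses the support.
#' @export
window_probability <- function(dist, r, half_width = 2.5) {
  stopifnot(inherits(dist, "continuous_distribution"), half_width > 0)
  lo <- max(dist$support[1], r - half_width)
  hi <- min(dist$support[2], r + half_width)
  if (hi <= lo) return(0)
  n <- 2L * max(1L, ceiling((hi - lo) / 0.02))
  x <- seq(lo, hi, length.out = n + 1L)
  min(1, max(0, simpson(x, cdist_eval(dist, x))))
}

#' Joint probability of a conformer
#'
#' Product over restraints of [window_probability()]; computed as a sum of
#' log-probabilities.
#'
#' @param conformer a `conformer` with a distance for every restraint.
#' @param originals named list of `continuous_distribution`s (the unmodified
#'   experimental distributions).
#' @param half_width window half-width in Angstrom (default 2.5).
#' @return Non-negative joint probability (0 if any window misses).
#' @export
joint_probability <- function(conformer, originals, half_width = 2.5) {
  exp(log_joint_probability(conformer, originals, half_width))
}

log_joint_probability <- function(conformer, originals, half_width = 2.5) {
  lw <- vapply(names(originals), function(nm) {
    r <- conformer$pair_distances[[nm]]
    if (is.null(r) || is.na(r)) stop("conformer lacks a distance for restraint '", nm, "'")
    log(window_probability(originals[[nm]], r, half_width))
  }, 0)
  sum(lw)
}

#' Assign relative probabilities to an ensemble
#'
#' Divides each conformer's joint probability by the ensemble maximum, so the
#' most probable conformer has relative probability exactly 1 and all values
#' lie in `[0, 1]`. Conformers whose joint probability is zero are retained
#' with relative probability 0.
#'
#' @param ensemble a `conf_ensemble`.
#' @param originals named list of `continuous_distribution`s; defaults to the
#'   originals stored in the ensemble's sampling state.
#' @param half_width window half-width in Angstrom (default 2.5).
#' @return The ensemble with `relative_probability` set on every conformer
#'   (and a `weights` data.frame attached: model, per-restraint distance and
#'   window probability, joint, relative).
#' @export
assign_relative <- function(ensemble, originals = ensemble$state$originals,
                            half_width = 2.5) {
  stopifnot(inherits(ensemble, "conf_ensemble"))
  if (!length(ensemble$conformers)) stop("empty ensemble")
  if (!length(originals)) stop("no original distributions to weight against")
  lj <- vapply(ensemble$conformers, log_joint_probability, 0,
               originals = originals, half_width = half_width)
  m <- max(lj)
  if (!is.finite(m)) {
    # diagnostic: which restraints annihilate the best conformers
    worst <- table(vapply(ensemble$conformers, function(cf) {
      w <- vapply(names(originals), function(nm) {
        window_probability(originals[[nm]], cf$pair_distances[[nm]], half_width)
      }, 0)
      names(originals)[which.min(w)]
    }, ""))
    stop("all joint probabilities are zero; worst-offending restraint(s): ",
         paste(sprintf("%s (%d conformers)", names(worst), as.integer(worst)),
               collapse = ", "))
  }
  rel <- exp(lj - m)
  rel[!is.finite(lj)] <- 0
  for (i in seq_along(ensemble$conformers)) {
    ensemble$conformers[[i]]$relative_probability <- rel[i]
  }
  wtab <- data.frame(model = seq_along(ensemble$conformers),
                     joint = exp(lj), relative = rel)
  for (nm in names(originals)) {
    wtab[[paste0("dist_", nm)]] <- vapply(ensemble$conformers, function(cf) {
      cf$pair_distances[[nm]]
    }, 0)
    wtab[[paste0("p_", nm)]] <- vapply(ensemble$conformers, function(cf) {
      window_probability(originals[[nm]], cf$pair_distances[[nm]], half_width)
    }, 0)
  }
  ensemble$weights <- wtab
  ensemble
}

#' Write the per-conformer weight table as TSV
#'
#' @param ensemble a weighted `conf_ensemble` (see [assign_relative()]).
#' @param path output path.
#' @export
write_weights <- function(ensemble, path) {
  if (is.null(ensemble$weights)) stop("ensemble has no weights; run assign_relative() first")
  utils::write.table(ensemble$weights, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
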