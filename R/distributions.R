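## Distance probability distributions and their penalty-term representation.
##
## A PELDOR/DEER experiment yields, per spin-label pair, a probability density
## over the inter-label distance.  This module reads such distributions,
## normalizes them to unit area, represents them as smooth non-negative
## interpolants with analytic derivatives, and converts them into the
## restraint penalty term
##     T(r) = A * max(0, 1 - P(r) / (p_max * c))
## which is zero on the "plateau" where the normalized probability
## P(r)/p_max is at least the cutoff c, and rises to A where P(r) = 0.

#' Construct a discrete distance distribution
#'
#' @param r numeric vector of distances in Angstrom, strictly increasing,
#'   length >= 3.
#' @param p numeric vector of probability densities (per Angstrom), same
#'   length as `r`, all non-negative.
#' @param label text identifier of the spin pair.
#' @return An object of class `distance_distribution` with fields `r`, `p`,
#'   `label`.
#' @export
distance_distribution <- function(r, p, label = "") {
  r <- as.numeric(r); p <- as.numeric(p)
  if (length(r) != length(p)) stop("r and p must have the same length")
  if (length(r) < 3) stop("a distance distribution needs at least 3 points")
  if (any(!is.finite(r)) || any(!is.finite(p))) stop("non-finite values in distribution")
  if (any(diff(r) <= 0)) stop("distances must be strictly increasing")
  if (any(p < 0)) stop("negative probability density")
  structure(list(r = r, p = p, label = as.character(label)),
            class = "distance_distribution")
}

#' @export
print.distance_distribution <- function(x, ...) {
  cat(sprintf("<distance_distribution '%s': %d points, %.1f-%.1f A, area %.4g>\n",
              x$label, length(x$r), min(x$r), max(x$r), trapz(x$r, x$p)))
  invisible(x)
}

#' Read a two-column distance distribution file
#'
#' Reads the plain-text dialect emitted by DEER analysis software: two
#' whitespace- or comma-separated numeric columns (distance, probability
#' density); lines starting with `#` or `%` are comments.
#'
#' @param path file path.
#' @param unit unit of the distance column; `"angstrom"` (also `"A"`) or
#'   `"nanometre"` (also `"nm"`). Distances are converted to Angstrom.
#' @param label identifier stored on the returned distribution; defaults to
#'   the file base name.
#' @return A [distance_distribution()]. Densities are returned as read (not
#'   yet normalized); rows with negative density are clamped to zero with a
#'   warning.
#' @export
read_distribution <- function(path, unit = c("angstrom", "nanometre"),
                              label = NULL) {
  unit <- match.arg(gsub("^(a|ang|angstrom)$", "angstrom",
                         gsub("^(nm|nanometer|nanometre)$", "nanometre",
                              tolower(unit[1]))),
                    c("angstrom", "nanometre"))
  if (!file.exists(path)) stop("distribution file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !grepl("^[#%]", lines)]
  if (length(lines) < 3) stop("fewer than 3 data rows in ", path)
  fields <- strsplit(lines, "[,[:space:]]+")
  bad <- vapply(fields, length, 1L) < 2L
  if (any(bad)) stop("malformed row(s) in ", path)
  r <- as.numeric(vapply(fields, `[[`, "", 1L))
  p <- as.numeric(vapply(fields, `[[`, "", 2L))
  if (any(is.na(r)) || any(is.na(p))) stop("non-numeric data in ", path)
  if (any(diff(r) <= 0)) stop("distances in ", path, " are not strictly increasing")
  if (any(p < 0)) {
    warning(sum(p < 0), " negative density value(s) in ", path, " clamped to 0")
    p[p < 0] <- 0
  }
  if (unit == "nanometre") r <- r * 10
  distance_distribution(r, p, label = label %||% sub("\\.[^.]*$", "", basename(path)))
}

#' Write a distance distribution in the two-column dialect
#'
#' @param d a [distance_distribution()].
#' @param path output file path.
#' @export
write_distribution <- function(d, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# distance(A)  probability_density(1/A)  [%s]", d$label), con)
  writeLines(sprintf("%.6f %.10g", d$r, d$p), con)
  invisible(path)
}

#' Normalize a distance distribution to unit area
#'
#' Rescales the density so that its trapezoidal integral over `r` equals 1.
#'
#' @param d a [distance_distribution()].
#' @return The rescaled distribution; shape is preserved up to a scalar.
#' @export
normalize_unit_area <- function(d) {
  stopifnot(inherits(d, "distance_distribution"))
  area <- trapz(d$r, d$p)
  if (area <= 0) stop("distribution '", d$label, "' has no probability mass")
  distance_distribution(d$r, d$p / area, label = d$label)
}

#' Continuous representation of a distance distribution
#'
#' Builds a smooth, shape-preserving piecewise-cubic interpolant
#' (Fritsch-Carlson monotone Hermite, `stats::splinefun(method = "monoH.FC")`)
#' through the knots, clamped to be non-negative and defined as zero outside
#' the measured support. The interpolant reproduces the knots exactly and has
#' an analytic first derivative, so penalty terms derived from it are
#' differentiable.
#'
#' @param d a [distance_distribution()], normally unit-area.
#' @return An object of class `continuous_distribution` with fields `source`,
#'   `support` (c(r_min, r_max)) and `p_max` (maximum density, computed on a
#'   0.01 Angstrom grid so inter-knot overshoot cannot yield normalized
#'   probabilities above 1).
#' @export
make_continuous <- function(d) {
  stopifnot(inherits(d, "distance_distribution"))
  f <- stats::splinefun(d$r, d$p, method = "monoH.FC")
  support <- range(d$r)
  grid <- seq(support[1], support[2], by = 0.01)
  p_max <- max(pmax(0, f(grid)), max(d$p))
  structure(list(source = d, support = support, p_max = p_max, .fun = f),
            class = "continuous_distribution")
}

#' Evaluate a continuous distribution
#'
#' @param cd a [make_continuous()] object.
#' @param r distances (Angstrom); vectorized.
#' @param deriv 0 for the density, 1 for its first derivative.
#' @return Density per Angstrom (or its derivative); zero outside the support,
#'   never negative (derivative is zero where the clamp is active).
#' @export
cdist_eval <- function(cd, r, deriv = 0L) {
  stopifnot(inherits(cd, "continuous_distribution"))
  out <- numeric(length(r))
  inside <- r >= cd$support[1] & r <= cd$support[2]
  if (any(inside)) {
    if (deriv == 0L) {
      out[inside] <- pmax(0, cd$.fun(r[inside]))
    } else {
      v <- cd$.fun(r[inside])
      g <- cd$.fun(r[inside], deriv = 1L)
      g[v <= 0] <- 0
      out[inside] <- g
    }
  }
  out
}

#' @export
print.continuous_distribution <- function(x, ...) {
  cat(sprintf("<continuous_distribution '%s': support %.1f-%.1f A, p_max %.4g>\n",
              x$source$label, x$support[1], x$support[2], x$p_max))
  invisible(x)
}

#' Restraint penalty term derived from a distance distribution
#'
#' Bundles a continuous distribution with the weighting factor `A` and cutoff
#' `c` of the target-function term `T(r) = A * max(0, 1 - P(r)/(p_max * c))`.
#'
#' @param dist a `continuous_distribution`.
#' @param A weighting factor in Angstrom^2 (default 10.0).
#' @param c cutoff threshold on the normalized probability (default 0.75).
#' @return An object of class `penalty_function`.
#' @export
penalty_function <- function(dist, A = 10.0, c = 0.75) {
  stopifnot(inherits(dist, "continuous_distribution"), A > 0, c > 0, c <= 1)
  structure(list(dist = dist, A = A, c = c), class = "penalty_function")
}

#' Evaluate a penalty term and its gradient
#'
#' `T(r) = A * max(0, 1 - P(r)/(p_max * c))`: zero wherever the normalized
#' probability `P(r)/p_max >= c` (the plateau), equal to `A` wherever
#' `P(r) = 0` (including outside the measured support, where unobserved
#' distances are maximally disfavoured).
#'
#' @param pf a [penalty_function()].
#' @param r distances (Angstrom); vectorized.
#' @return List with `value` (Angstrom^2) and `gradient` (dT/dr, Angstrom),
#'   the gradient being 0 on the plateau and outside the support.
#'   If the underlying distribution is fully flattened (`p_max` = 0) a
#'   condition of class `confspace_flattened` is signalled and the term
#'   evaluates to zero (a flattened working distribution means its region has
#'   been fully sampled and exerts no further restraint).
#' @export
penalty <- function(pf, r) {
  stopifnot(inherits(pf, "penalty_function"), all(is.finite(r)))
  if (pf$dist$p_max <= 0) {
    warning(warningCondition(
      "penalty evaluated on a fully flattened distribution; term treated as 0",
      class = "confspace_flattened"))
    return(list(value = numeric(length(r)), gradient = numeric(length(r))))
  }
  P <- cdist_eval(pf$dist, r)
  s <- 1 - P / (pf$dist$p_max * pf$c)
  value <- pf$A * pmax(0, s)
  gradient <- ifelse(s > 0,
                     -pf$A * cdist_eval(pf$dist, r, deriv = 1L) / (pf$dist$p_max * pf$c),
                     0)
  list(value = value, gradient = gradient)
}
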