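# Small numeric helpers shared across modules.

# Trapezoidal integral of y over x (x strictly increasing).
trapz <- function(x, y) {
  n <- length(x)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}

# Composite Simpson quadrature of f sampled on an even number of equal
# intervals; used where ~1e-8 accuracy on smooth integrands is needed.
simpson <- function(x, y) {
  n <- length(x) - 1L
  stopifnot(n >= 2L, n %% 2L == 0L)
  h <- (x[length(x)] - x[1]) / n
  i <- seq_len(n - 1L) + 1L
  w <- ifelse(seq_len(n - 1L) %% 2L == 1L, 4, 2)
  h / 3 * (y[1] + y[length(y)] + sum(w * y[i]))
}

vnorm <- function(v) sqrt(sum(v * v))

unit <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalize a zero vector")
  v / n
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

# Wrap angles (radians) into (-pi, pi].
wrap_angle <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  y[y <= -pi] <- pi
  y
}

## Quaternions are length-4 numerics (w, x, y, z), unit norm.

quat_normalize <- function(q) q / vnorm(q)

quat_to_mat <- function(q) {
  q <- quat_normalize(q)
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3, byrow = TRUE)
}

quat_from_axis_angle <- function(axis, angle) {
  a <- unit(axis)
  c(cos(angle / 2), sin(angle / 2) * a)
}

quat_multiply <- function(a, b) {
  c(a[1] * b[1] - a[2] * b[2] - a[3] * b[3] - a[4] * b[4],
    a[1] * b[2] + a[2] * b[1] + a[3] * b[4] - a[4] * b[3],
    a[1] * b[3] - a[2] * b[4] + a[3] * b[1] + a[4] * b[2],
    a[1] * b[4] + a[2] * b[3] - a[3] * b[2] + a[4] * b[1])
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Deterministic orthonormal frame perpendicular to unit vector d.
# Must match the C++ implementation bit-for-bit in its branch choices.
perp_frame <- function(d) {
  ax <- abs(d[1]); ay <- abs(d[2]); az <- abs(d[3])
  e <- if (ax <= ay && ax <= az) c(1, 0, 0) else if (ay <= az) c(0, 1, 0) else c(0, 0, 1)
  e1 <- unit(e - sum(e * d) * d)
  e2 <- cross3(d, e1)
  list(e1 = e1, e2 = e2)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
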