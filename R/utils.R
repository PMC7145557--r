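# Internal numeric helpers shared across modules.

# Boltzmann constant, kcal/(mol K)
KB_KCAL <- 0.0019872

# Evaluate expr with a temporary RNG state; global .Random.seed is restored.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

logsumexp <- function(x) {
  x <- x[is.finite(x) | x == -Inf]
  m <- max(x)
  if (!is.finite(m)) return(-Inf)
  m + log(sum(exp(x - m)))
}

vnorm <- function(v) sqrt(sum(v * v))

unit <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalize a zero-length vector")
  v / n
}

# Angle (degrees, [0,180]) at vertex v between directions to a and b,
# via atan2 of cross/dot for stability near 0 and 180.
angle_at <- function(v, a, b, tol = 1e-6) {
  u1 <- a - v
  u2 <- b - v
  if (vnorm(u1) < tol || vnorm(u2) < tol)
    stop("degenerate geometry: vertex coincides with an endpoint")
  cr <- c(u1[2] * u2[3] - u1[3] * u2[2],
          u1[3] * u2[1] - u1[1] * u2[3],
          u1[1] * u2[2] - u1[2] * u2[1])
  atan2(vnorm(cr), sum(u1 * u2)) * 180 / pi
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Rotation matrix: angle (radians) about unit axis (Rodrigues).
rotation_about <- function(axis, theta) {
  k <- unit(axis)
  K <- matrix(c(0, -k[3], k[2], k[3], 0, -k[1], -k[2], k[1], 0),
              3, 3, byrow = TRUE)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

# Kabsch optimal superposition of point sets (n x 3), proper rotation only.
# Returns list(rotation, translation) mapping x onto y: y ~ x %*% R + t.
kabsch <- function(x, y) {
  stopifnot(nrow(x) == nrow(y), ncol(x) == 3, ncol(y) == 3)
  if (nrow(x) < 3) stop("need at least 3 paired points for superposition")
  cx <- colMeans(x)
  cy <- colMeans(y)
  H <- t(sweep(x, 2, cx)) %*% sweep(y, 2, cy)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  R <- s$u %*% D %*% t(s$v)
  list(rotation = R, translation = cy - as.numeric(cx %*% R))
}

# Least-squares plane through points (n x 3): list(center, normal).
fit_plane <- function(p) {
  ctr <- colMeans(p)
  sv <- svd(sweep(p, 2, ctr))
  list(center = ctr, normal = sv$v[, 3])
}

# n approximately uniform points on the unit sphere (Fibonacci lattice).
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
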