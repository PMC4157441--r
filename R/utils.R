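# Internal helpers shared across modules.

# Run expr with a locally seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a reproducible sub-seed
#'
#' Deterministic integer hash used wherever one user-facing seed has to drive
#' several independent random draws (restraint selection, velocity assignment,
#' grid-search cells). The rule is a multiply-and-add congruential mix over the
#' base seed and the supplied integer tags, reduced modulo 2^31 - 1; it is
#' stable across platforms and sessions.
#'
#' @param base integer base seed.
#' @param ... further integer tags (e.g. grid indices, repeat number).
#' @return a single integer in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(base, ...) {
  m <- 2147483647
  x <- as.numeric(base) %% m
  for (tag in list(...)) {
    for (t in as.numeric(tag)) {
      # 48271 and 69621 are classic Lehmer multipliers; all arithmetic stays
      # below 2^53 so the double-precision modular reduction is exact.
      x <- (x * 48271 + (t %% m) * 69621 + 1) %% m
    }
  }
  as.integer(x %% (m - 2) + 1)
}

# Rotation matrix from a rotation vector (axis * angle, radians).
rotvec_to_matrix <- function(v) {
  th <- sqrt(sum(v^2))
  if (th < 1e-12) return(diag(3))
  k <- v / th
  K <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# Rotation matrix about an arbitrary axis through a point.
rotate_about_axis <- function(xyz, origin, axis, angle) {
  R <- rotvec_to_matrix(axis / sqrt(sum(axis^2)) * angle)
  sweep(sweep(xyz, 2, origin) %*% t(R), 2, origin, "+")
}

# Plain coordinate RMSD without superposition.
rmsd_xyz <- function(a, b) sqrt(mean(rowSums((a - b)^2)))

# Least-squares superposition of mobile onto fixed by the Horn quaternion
# method; returns the transformed mobile coordinates.
superpose_xyz <- function(mobile, fixed) {
  cm <- colMeans(mobile)
  cf <- colMeans(fixed)
  A <- sweep(mobile, 2, cm)
  B <- sweep(fixed, 2, cf)
  M <- t(A) %*% B
  S <- matrix(0, 4, 4)
  S[1, 1] <- M[1, 1] + M[2, 2] + M[3, 3]
  S[1, 2] <- S[2, 1] <- M[2, 3] - M[3, 2]
  S[1, 3] <- S[3, 1] <- M[3, 1] - M[1, 3]
  S[1, 4] <- S[4, 1] <- M[1, 2] - M[2, 1]
  S[2, 2] <- M[1, 1] - M[2, 2] - M[3, 3]
  S[2, 3] <- S[3, 2] <- M[1, 2] + M[2, 1]
  S[2, 4] <- S[4, 2] <- M[1, 3] + M[3, 1]
  S[3, 3] <- -M[1, 1] + M[2, 2] - M[3, 3]
  S[3, 4] <- S[4, 3] <- M[2, 3] + M[3, 2]
  S[4, 4] <- -M[1, 1] - M[2, 2] + M[3, 3]
  q <- eigen(S, symmetric = TRUE)$vectors[, 1]
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(
    w^2 + x^2 - y^2 - z^2, 2 * (x * y + w * z), 2 * (x * z - w * y),
    2 * (x * y - w * z), w^2 - x^2 + y^2 - z^2, 2 * (y * z + w * x),
    2 * (x * z + w * y), 2 * (y * z - w * x), w^2 - x^2 - y^2 + z^2
  ), 3, 3)
  sweep(A %*% t(R), 2, cf, "+")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
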