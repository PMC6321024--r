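# Geometry and RNG helpers shared across modules.

# All-pairs Euclidean distance between two coordinate matrices (n x 3, m x 3).
cross_dist <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  stopifnot(ncol(a) == 3L, ncol(b) == 3L)
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  sqrt(d2)
}

# Minimum distance between two atom sets.
min_dist <- function(a, b) min(cross_dist(a, b))

# Rotation matrix from a unit quaternion (w, x, y, z).
quat_to_rot <- function(q) {
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3, byrow = TRUE)
}

# n rotation matrices, uniform over SO(3) (random unit quaternions).
random_rotations <- function(n) {
  q <- matrix(rnorm(4 * n), ncol = 4)
  lapply(seq_len(n), function(i) quat_to_rot(q[i, ]))
}

# Rotation about an arbitrary axis through the origin by angle (radians).
axis_rotation <- function(axis, angle) {
  u <- axis / sqrt(sum(axis^2))
  c_ <- cos(angle); s_ <- sin(angle); C <- 1 - c_
  matrix(c(
    u[1]^2 * C + c_,          u[1] * u[2] * C - u[3] * s_, u[1] * u[3] * C + u[2] * s_,
    u[2] * u[1] * C + u[3] * s_, u[2]^2 * C + c_,          u[2] * u[3] * C - u[1] * s_,
    u[3] * u[1] * C - u[2] * s_, u[3] * u[2] * C + u[1] * s_, u[3]^2 * C + c_
  ), nrow = 3, byrow = TRUE)
}

# Evaluate expr with a locally seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Heavy-atom RMSD between two conformations of the same atom list.
coord_rmsd <- function(a, b) {
  stopifnot(nrow(a) == nrow(b))
  sqrt(mean(rowSums((as.matrix(a) - as.matrix(b))^2)))
}

`%||%` <- function(x, y) if (is.null(x)) y else x
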