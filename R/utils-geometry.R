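# Small geometry and chemistry helpers shared across modules.

# Covalent radii (Angstrom) used for distance-based bond inference.
.COVALENT_RADIUS <- c(
  H = 0.31, C = 0.76, N = 0.71, O = 0.66, S = 1.05, P = 1.07,
  F = 0.57, CL = 1.02, BR = 1.20, I = 1.39
)

.BOND_TOLERANCE <- 0.40  # slack added to the radius sum

covalent_radius <- function(elem) {
  r <- .COVALENT_RADIUS[toupper(elem)]
  r[is.na(r)] <- 0.9
  unname(r)
}

#' @noRd
vec_norm <- function(v) sqrt(sum(v^2))

unit_vec <- function(v) v / vec_norm(v)

# Pairwise Euclidean distance matrix between two coordinate matrices (n x 3).
cross_dist <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  sqrt(d2)
}

# Angle (degrees) at vertex `b` of points a-b-c.
angle_deg <- function(a, b, c) {
  u <- a - b; v <- c - b
  cs <- sum(u * v) / (vec_norm(u) * vec_norm(v))
  cs <- max(-1, min(1, cs))
  acos(cs) * 180 / pi
}

# Rotation matrix sending unit vector `from` onto unit vector `to`
# (Rodrigues formula; handles the antiparallel case).
rotation_onto <- function(from, to) {
  from <- unit_vec(from); to <- unit_vec(to)
  v <- c(from[2] * to[3] - from[3] * to[2],
         from[3] * to[1] - from[1] * to[3],
         from[1] * to[2] - from[2] * to[1])
  c2 <- sum(from * to)
  s <- vec_norm(v)
  if (s < 1e-12) {
    if (c2 > 0) return(diag(3))
    # antiparallel: rotate pi about any axis orthogonal to `from`
    ax <- if (abs(from[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    ax <- unit_vec(ax - sum(ax * from) * from)
    return(2 * tcrossprod(ax) - diag(3))
  }
  K <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
  diag(3) + K + K %*% K * ((1 - c2) / s^2)
}

# Any unit vector orthogonal to u.
orthogonal_vec <- function(u) {
  u <- unit_vec(u)
  ax <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  unit_vec(ax - sum(ax * u) * u)
}

# Bond (adjacency) inference from covalent radii on a coordinate matrix.
# Returns a two-column index matrix of bonded pairs (i < j).
infer_bonds <- function(xyz, elem) {
  n <- nrow(xyz)
  if (n < 2) return(matrix(integer(0), ncol = 2))
  d <- cross_dist(xyz, xyz)
  lim <- outer(covalent_radius(elem), covalent_radius(elem), "+") + .BOND_TOLERANCE
  hit <- which(d <= lim & upper.tri(d), arr.ind = TRUE)
  # guard against coincident atoms being "bonded" to everything
  hit[d[hit] > 0.4, , drop = FALSE]
}

is_heavy <- function(elem) toupper(elem) != "H"

`%||%` <- function(a, b) if (is.null(a)) b else a
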