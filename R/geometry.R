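# Vector geometry primitives shared by all modules. Coordinates are in
# Angstrom, angles returned in degrees, dihedrals signed per the IUPAC
# convention (cis = 0, trans = 180, sign from the right-hand rule).

DEG <- pi / 180

vnorm <- function(v) sqrt(sum(v * v))

vunit <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalise a zero-length vector", call. = FALSE)
  v / n
}

vcross <- function(a, b) {
  c(
    a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1]
  )
}

#' Angle at vertex b formed by points a-b-c, in degrees
#' @noRd
vec_angle <- function(a, b, c) {
  u <- vunit(a - b)
  v <- vunit(c - b)
  acos(max(-1, min(1, sum(u * v)))) / DEG
}

#' Signed dihedral angle for four points, in degrees in (-180, 180]
#' @noRd
dihedral4 <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- vcross(b1, b2)
  n2 <- vcross(b2, b3)
  if (vnorm(n1) < 1e-10 || vnorm(n2) < 1e-10) {
    stop("dihedral undefined: collinear atoms", call. = FALSE)
  }
  m1 <- vcross(n1, vunit(b2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  ang <- atan2(y, x) / DEG
  if (ang <= -180) ang <- ang + 360
  ang
}

#' Rodrigues rotation matrix about a unit axis, angle in degrees
#' @noRd
rotation_about_axis <- function(axis, angle_deg) {
  u <- vunit(axis)
  th <- angle_deg * DEG
  ct <- cos(th)
  st <- sin(th)
  ux <- u[1]; uy <- u[2]; uz <- u[3]
  matrix(c(
    ct + ux^2 * (1 - ct),      ux * uy * (1 - ct) - uz * st, ux * uz * (1 - ct) + uy * st,
    uy * ux * (1 - ct) + uz * st, ct + uy^2 * (1 - ct),      uy * uz * (1 - ct) - ux * st,
    uz * ux * (1 - ct) - uy * st, uz * uy * (1 - ct) + ux * st, ct + uz^2 * (1 - ct)
  ), nrow = 3, byrow = TRUE)
}

#' Place a new atom D from internal coordinates (NeRF construction)
#'
#' Given positions of atoms a-b-c, returns the position of d such that
#' |c-d| = bond, angle(b,c,d) = angle and dihedral(a,b,c,d) = dihedral.
#' @noRd
place_atom <- function(a, b, c, bond, angle, dihedral) {
  th <- angle * DEG
  ph <- -dihedral * DEG   # sign matches the IUPAC convention of dihedral4()
  d_local <- bond * c(-cos(th), sin(th) * cos(ph), sin(th) * sin(ph))
  bc <- vunit(c - b)
  n <- vunit(vcross(b - a, bc))
  m <- vcross(n, bc)       # bc, m, n form a right-handed frame
  frame <- cbind(bc, m, n)
  as.numeric(c + frame %*% d_local)
}

# Row-wise helpers over coordinate matrices -------------------------------

#' Pairwise Euclidean distances between the rows of two n x 3 matrices
#' @noRd
cross_dist <- function(A, B) {
  a2 <- rowSums(A^2)
  b2 <- rowSums(B^2)
  d2 <- outer(a2, b2, "+") - 2 * A %*% t(B)
  d2[d2 < 0] <- 0
  sqrt(d2)
}

#' Angles (degrees) at vertex V for rows of matrices: angle(A[i,], V[i,], B[i,])
#' @noRd
row_angle <- function(A, V, B) {
  U1 <- A - V
  U2 <- B - V
  n1 <- sqrt(rowSums(U1^2))
  n2 <- sqrt(rowSums(U2^2))
  cosx <- rowSums(U1 * U2) / (n1 * n2)
  cosx <- pmax(-1, pmin(1, cosx))
  acos(cosx) / DEG
}

#' Signed dihedrals (degrees) for rows of four coordinate matrices
#' @noRd
row_dihedral <- function(P1, P2, P3, P4) {
  B1 <- P2 - P1
  B2 <- P3 - P2
  B3 <- P4 - P3
  N1 <- cbind(
    B1[, 2] * B2[, 3] - B1[, 3] * B2[, 2],
    B1[, 3] * B2[, 1] - B1[, 1] * B2[, 3],
    B1[, 1] * B2[, 2] - B1[, 2] * B2[, 1]
  )
  N2 <- cbind(
    B2[, 2] * B3[, 3] - B2[, 3] * B3[, 2],
    B2[, 3] * B3[, 1] - B2[, 1] * B3[, 3],
    B2[, 1] * B3[, 2] - B2[, 2] * B3[, 1]
  )
  B2u <- B2 / sqrt(rowSums(B2^2))
  M1 <- cbind(
    N1[, 2] * B2u[, 3] - N1[, 3] * B2u[, 2],
    N1[, 3] * B2u[, 1] - N1[, 1] * B2u[, 3],
    N1[, 1] * B2u[, 2] - N1[, 2] * B2u[, 1]
  )
  x <- rowSums(N1 * N2)
  y <- rowSums(M1 * N2)
  ang <- atan2(y, x) / DEG
  ang[ang <= -180] <- ang[ang <= -180] + 360
  ang
}

#' Wrap angles in degrees into (-180, 180]
#' @noRd
wrap_angle <- function(x) {
  out <- (x + 180) %% 360 - 180
  out[out <= -180] <- out[out <= -180] + 360
  out
}
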