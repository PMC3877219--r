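# Back-calculation of trans-hydrogen-bond h3J(NC') scalar couplings and N-H
# residual dipolar couplings, with SVD alignment-tensor fitting and
# Q-factors.

#' Trans-hydrogen-bond h3J(NC') coupling from bond geometry
#'
#' Evaluates the closed form
#' `J = -A * exp(-k (r_HO - r0)) * cos^2(theta1) * (p cos^2(theta2) + q)`
#' (coefficients from the parameter file), where `theta1` is the N-H...O
#' angle and `theta2` the H...O=C angle. The coupling decays exponentially
#' with the hydrogen-bond length, so opened bonds evaluate to ~0 Hz. Records
#' carrying a side-chain acceptor class raise an error: the coupling is
#' defined only across amide-amide hydrogen bonds.
#'
#' @param geom A tibble with columns `r_ho`, `angle_nho`, `angle_hoc` (from
#'   [amide_pair_geometry()] or [detect_hbonds()]).
#' @param params A [shift_params()] object.
#' @return Couplings in Hz (<= 0 under the sign convention).
#' @export
j_coupling <- function(geom, params = shift_params()) {
  if ("acceptor_class" %in% names(geom)) {
    bad <- !geom$acceptor_class %in% "BACKBONE_AMIDE"
    if (any(bad)) {
      stop("h3J(NC') couplings are defined only across amide-amide hydrogen ",
           "bonds (got class ",
           paste(unique(geom$acceptor_class[bad]), collapse = ", "), ")",
           call. = FALSE)
    }
  }
  cf <- params$jcoupling
  -cf$A * exp(-cf$k * (geom$r_ho - cf$r0)) *
    cos(geom$angle_nho * DEG)^2 *
    (cf$p * cos(geom$angle_hoc * DEG)^2 + cf$q)
}

#' Back-calculate h3J(NC') couplings for a structure
#'
#' With `pairs = NULL`, couplings are computed across the amide-amide
#' hydrogen bonds detected in the structure. Supplying an explicit
#' `pairs` table fixes the donor/acceptor list independently of the bond
#' gate, which is what ensemble averaging needs when bonds open and close
#' during sampling (opened bonds contribute ~0 Hz).
#'
#' @param s An `amide_structure`.
#' @param pairs Optional tibble with `donor` and `acceptor` residue numbers
#'   (acceptor = residue owning the carbonyl C=O).
#' @param params A [shift_params()] object.
#' @return A tibble with `donor`, `acceptor`, geometry columns and `j` (Hz).
#' @export
couplings <- function(s, pairs = NULL, params = shift_params()) {
  if (is.null(pairs)) {
    hb <- detect_hbonds(s, params$gate)
    hb <- hb[hb$acceptor_class == "BACKBONE_AMIDE", , drop = FALSE]
    pairs <- tibble::tibble(donor = hb$resno, acceptor = hb$acceptor_resno)
  }
  if (nrow(pairs) == 0) {
    return(tibble::tibble(donor = integer(), acceptor = integer(),
                          r_ho = double(), angle_nho = double(),
                          angle_hoc = double(), dihedral_rho = double(),
                          j = double()))
  }
  geom <- amide_pair_geometry(s, pairs$donor, pairs$acceptor)
  geom$j <- j_coupling(geom, params)
  geom
}

#' Ensemble statistics for h3J(NC') couplings
#'
#' Computes the per-bond mean coupling over conformers and its standard
#' deviation (the root-mean-square deviation from the mean), and, when an
#' experimental table is supplied, the RMSD of the per-bond means against
#' experiment.
#'
#' @param structures A list of `amide_structure` conformers (or one).
#' @param pairs Optional donor/acceptor table; defaults to the amide-amide
#'   bonds detected in the first conformer.
#' @param experimental Optional tibble with `donor`, `acceptor`, `j_exp`
#'   (Hz).
#' @param params A [shift_params()] object.
#' @return A tibble with `donor`, `acceptor`, `mean_j`, `sd_j` (and `j_exp`
#'   when supplied); the overall RMSD to experiment is in attribute
#'   `"rmsd"`.
#' @export
ensemble_couplings <- function(structures, pairs = NULL, experimental = NULL,
                               params = shift_params()) {
  if (inherits(structures, "amide_structure")) structures <- list(structures)
  stopifnot(length(structures) >= 1)
  if (is.null(pairs)) {
    first <- couplings(structures[[1]], params = params)
    pairs <- tibble::tibble(donor = first$donor, acceptor = first$acceptor)
  }
  jm <- vapply(structures,
               function(s) couplings(s, pairs, params)$j,
               numeric(nrow(pairs)))
  jm <- matrix(jm, nrow = nrow(pairs))
  m <- nrow(pairs)
  out <- tibble::tibble(
    donor = pairs$donor, acceptor = pairs$acceptor,
    mean_j = rowMeans(jm),
    sd_j = sqrt(rowMeans((jm - rowMeans(jm))^2))
  )
  if (!is.null(experimental)) {
    out <- dplyr::left_join(out, experimental, by = c("donor", "acceptor"))
    attr(out, "rmsd") <- sqrt(mean((out$mean_j - out$j_exp)^2, na.rm = TRUE))
  }
  out
}

# Unit N-H bond vectors for residues carrying an amide proton
nh_vectors <- function(s) {
  ctx <- structure_context(s)
  xyz <- coords(s)
  d <- ctx$donors
  H <- xyz[ctx$idx$H[d], , drop = FALSE]
  N <- xyz[ctx$idx$N[d], , drop = FALSE]
  V <- H - N
  V <- V / sqrt(rowSums(V^2))
  list(resno = ctx$resnos[d], v = V)
}

# quadratic design row(s) for the 5-parameter Saupe tensor
saupe_design <- function(V) {
  cbind(
    V[, 1]^2 - V[, 3]^2,
    V[, 2]^2 - V[, 3]^2,
    2 * V[, 1] * V[, 2],
    2 * V[, 1] * V[, 3],
    2 * V[, 2] * V[, 3]
  )
}

saupe_names <- c("Sxx", "Syy", "Sxy", "Sxz", "Syz")

#' Reconstruct the symmetric traceless 3x3 Saupe matrix
#'
#' @param saupe Named length-5 vector (`Sxx`, `Syy`, `Sxy`, `Sxz`, `Syz`) or
#'   an `alignment_tensor`.
#' @return A 3x3 symmetric traceless matrix.
#' @export
saupe_matrix <- function(saupe) {
  if (inherits(saupe, "alignment_tensor")) saupe <- saupe$saupe
  s <- unname(saupe)
  matrix(c(
    s[1], s[3], s[4],
    s[3], s[2], s[5],
    s[4], s[5], -s[1] - s[2]
  ), 3, 3, byrow = TRUE)
}

#' Fit an N-H RDC alignment tensor by singular value decomposition
#'
#' Least-squares fit of the five independent Saupe components to observed
#' residual dipolar couplings, solved through the SVD pseudo-inverse of the
#' orientation design matrix. In ensemble mode (the default for a list of
#' conformers) the quadratic orientation terms of each residue are averaged
#' over all conformers first, so a single tensor is fitted to all structures
#' simultaneously. The dipolar scale is absorbed into the tensor, so the
#' components carry Hz units.
#'
#' @param structures An `amide_structure` or list of conformers.
#' @param rdc A tibble with `resno` and `d` (observed RDC, Hz).
#' @param ensemble_mode Average orientations over conformers (default
#'   `TRUE`); with `FALSE` only the first conformer is used.
#' @return An object of class `alignment_tensor` with elements `saupe`,
#'   `rdc` (input plus `d_calc`), `q`, `rmsd`, `n`, `condition`.
#' @export
fit_alignment_tensor <- function(structures, rdc, ensemble_mode = TRUE) {
  if (inherits(structures, "amide_structure")) structures <- list(structures)
  if (!ensemble_mode) structures <- structures[1]
  if (nrow(rdc) < 5) {
    stop("need >= 5 RDCs to determine the 5 Saupe components", call. = FALSE)
  }
  G <- NULL
  for (s in structures) {
    nv <- nh_vectors(s)
    sel <- match(rdc$resno, nv$resno)
    if (anyNA(sel)) {
      stop("RDC residue(s) without resolvable N-H vector: ",
           paste(rdc$resno[is.na(sel)], collapse = ","), call. = FALSE)
    }
    Gi <- saupe_design(nv$v[sel, , drop = FALSE])
    G <- if (is.null(G)) Gi else G + Gi
  }
  G <- G / length(structures)
  sv <- svd(G)
  cond <- sv$d[1] / sv$d[5]
  if (sv$d[5] < 1e-10 * sv$d[1]) {
    stop("rank-deficient orientation design (singular values ",
         paste(signif(sv$d, 3), collapse = ", "),
         "): N-H vectors are too collinear to determine the tensor",
         call. = FALSE)
  }
  saupe <- sv$v %*% ((t(sv$u) %*% rdc$d) / sv$d)
  saupe <- stats::setNames(as.numeric(saupe), saupe_names)
  d_calc <- as.numeric(G %*% saupe)
  out <- list(
    saupe = saupe,
    rdc = tibble::tibble(resno = rdc$resno, d = rdc$d, d_calc = d_calc),
    q = q_factor(d_calc, rdc$d),
    rmsd = sqrt(mean((d_calc - rdc$d)^2)),
    n = nrow(rdc),
    condition = cond,
    ensemble_mode = ensemble_mode,
    n_conformers = length(structures)
  )
  class(out) <- "alignment_tensor"
  out
}

#' @export
print.alignment_tensor <- function(x, ...) {
  cat("<alignment_tensor>", x$n, "RDCs,", x$n_conformers, "conformer(s)\n")
  print(signif(x$saupe, 4))
  cat(sprintf("  Q = %.4g, RMSD = %.4g Hz\n", x$q, x$rmsd))
  invisible(x)
}

#' Back-calculate N-H RDCs from a structure and an alignment tensor
#'
#' @param s An `amide_structure` (or list of conformers, averaged).
#' @param tensor An `alignment_tensor` or named length-5 Saupe vector.
#' @param resno Optional residue subset.
#' @return A tibble with `resno` and `d_calc` (Hz).
#' @export
calc_rdc <- function(s, tensor, resno = NULL) {
  if (inherits(tensor, "alignment_tensor")) tensor <- tensor$saupe
  if (inherits(s, "amide_structure")) s <- list(s)
  G <- NULL
  for (si in s) {
    nv <- nh_vectors(si)
    Gi <- saupe_design(nv$v)
    G <- if (is.null(G)) Gi else G + Gi
  }
  G <- G / length(s)
  out <- tibble::tibble(resno = nh_vectors(s[[1]])$resno,
                        d_calc = as.numeric(G %*% tensor))
  if (!is.null(resno)) out <- out[out$resno %in% resno, , drop = FALSE]
  out
}

#' RDC Q-factor
#'
#' `Q = sqrt( sum (D_calc - D_exp)^2 / sum D_exp^2 )`: the normalized
#' root-mean-square disagreement between back-calculated and experimental
#' RDCs (0 = perfect agreement; 1 for all-zero back-calculation).
#'
#' @param d_calc,d_exp Back-calculated and experimental couplings (Hz), or a
#'   single tibble with columns `d_calc` and `d` as the first argument.
#' @return The dimensionless Q-factor.
#' @export
q_factor <- function(d_calc, d_exp = NULL) {
  if (is.data.frame(d_calc)) {
    d_exp <- d_calc$d
    d_calc <- d_calc$d_calc
  }
  if (length(d_exp) == 0) stop("no RDC records", call. = FALSE)
  if (all(d_exp == 0)) {
    stop("all experimental RDCs are zero; Q-factor undefined", call. = FALSE)
  }
  sqrt(sum((d_calc - d_exp)^2) / sum(d_exp^2))
}

#' Read an h3J(NC') coupling table (CSV: donor, acceptor, j_exp in Hz)
#' @param path File path.
#' @return A tibble with `donor`, `acceptor`, `j_exp`.
#' @export
read_coupling_table <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  names(df)[1:3] <- c("donor", "acceptor", "j_exp")
  df
}

#' Read an N-H RDC table (CSV: resno, d in Hz)
#' @param path File path.
#' @return A tibble with `resno`, `d`.
#' @export
read_rdc_table <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  names(df)[1:2] <- c("resno", "d")
  df
}
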