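# The five additive terms of the amide proton chemical shift model:
# backbone (phi/psi cosine series), primary and secondary hydrogen-bond
# perturbations, tertiary polarization increments, and the point-dipole
# ring-current term. All are pure functions of geometry + parameters.

#' Backbone torsion term of the amide proton shift
#'
#' Evaluates the truncated two-dimensional cosine series at (phi, psi), then
#' applies the affine scaling `a * value + b` that absorbs basis-set and
#' geometry-optimization differences of the underlying parameterization.
#'
#' @param phi,psi Backbone torsions in degrees (vectors, recycled).
#' @param params A [shift_params()] object.
#' @param scale Optional override of `params$scale` (length-2 `c(a, b)`).
#' @return Shift contributions in ppm.
#' @export
backbone_term <- function(phi, psi, params = shift_params(), scale = NULL) {
  if (is.null(scale)) scale <- params$scale
  n <- max(length(phi), length(psi))
  phi <- rep_len(phi, n) * DEG
  psi <- rep_len(psi, n) * DEG
  tab <- params$backbone
  raw <- rep(0, n)
  for (t in seq_len(nrow(tab))) {
    f1 <- if (substr(tab$basis[t], 1, 1) == "c") cos(tab$kphi[t] * phi) else sin(tab$kphi[t] * phi)
    f2 <- if (substr(tab$basis[t], 2, 2) == "c") cos(tab$kpsi[t] * psi) else sin(tab$kpsi[t] * psi)
    raw <- raw + tab$coeff[t] * f1 * f2
  }
  scale[1] * raw + scale[2]
}

#' Ring-current term (point-dipole approximation)
#'
#' Sums `i * B * (1 - 3 cos^2 theta) / r^3` over all aromatic rings, where
#' `r` is the vector from the ring center to the proton and `theta` its angle
#' to the ring normal. Protons on the ring axis (theta = 0) are shielded
#' (negative contribution); in-plane protons are deshielded; the magic angle
#' (54.7356 deg) gives zero.
#'
#' @param h_pos Proton position, length-3 vector (Angstrom), or an n x 3
#'   matrix of positions.
#' @param rings Ring table from [find_rings()].
#' @param params A [shift_params()] object (supplies intensities and
#'   `B = 30.42` ppm A^3).
#' @return Shift contributions in ppm (one per proton; 0 if no rings).
#' @export
ring_current_term <- function(h_pos, rings, params = shift_params()) {
  if (is.null(dim(h_pos))) h_pos <- matrix(h_pos, nrow = 1)
  if (is.null(rings) || nrow(rings) == 0) return(rep(0, nrow(h_pos)))
  out <- rep(0, nrow(h_pos))
  for (k in seq_len(nrow(rings))) {
    ctr <- c(rings$cx[k], rings$cy[k], rings$cz[k])
    nrm <- c(rings$nx[k], rings$ny[k], rings$nz[k])
    inten <- params$ring_intensity[[rings$kind[k]]]
    if (is.null(inten)) stop("no intensity for ring kind ", rings$kind[k], call. = FALSE)
    rv <- sweep(h_pos, 2, ctr)
    rr <- sqrt(rowSums(rv^2))
    if (any(rr < 1e-6)) {
      stop("proton coincident with an aromatic ring center", call. = FALSE)
    }
    cost <- (rv %*% nrm) / rr
    out <- out + inten * params$ring_B * (1 - 3 * cost^2) / rr^3
  }
  as.numeric(out)
}

# closed-form exponential x angular perturbation used for amide-amide
# primary bonds and for secondary bonds
hb_closed_form <- function(r, theta, cf) {
  exp(-cf$k * r) * (cf$a * cos(theta * DEG)^2 + cf$b)
}

#' Primary hydrogen-bond term
#'
#' Dispatches on the acceptor class of each bond record: backbone and
#' side-chain amide carbonyl acceptors use the closed-form
#' exponential-times-angular surface; carboxylate and alcohol acceptors are
#' interpolated from their lookup grids; protons with no acceptor
#' (`"NONE"`, solvent exposed) receive the fixed water-model value
#' (2.07 ppm with the shipped parameter set).
#'
#' @param hb Hydrogen-bond records from [detect_hbonds()] (needs columns
#'   `acceptor_class`, `r_ho`, `angle_hoc`).
#' @param params A [shift_params()] object.
#' @return Shift contributions in ppm, one per record.
#' @export
primary_hb_term <- function(hb, params = shift_params()) {
  cls <- hb$acceptor_class
  out <- numeric(length(cls))
  is_none <- cls == "NONE"
  out[is_none] <- params$primary$none_value
  is_amide <- cls %in% c("BACKBONE_AMIDE", "SIDECHAIN_AMIDE")
  if (any(is_amide)) {
    out[is_amide] <- hb_closed_form(hb$r_ho[is_amide], hb$angle_hoc[is_amide],
                                    params$primary)
  }
  for (g in c("CARBOXYLATE", "ALCOHOL")) {
    sel <- cls == g
    if (any(sel)) {
      out[sel] <- interp_surface(params$grids[[g]], hb$r_ho[sel],
                                 hb$angle_hoc[sel])
    }
  }
  out
}

#' Secondary hydrogen-bond term
#'
#' Contribution from a hydrogen bond accepted by the amide group's own
#' carbonyl oxygen. `NULL` or zero-row input (no such bond) gives 0 ppm.
#'
#' @param hb_to_own_carbonyl A one-or-more-row bond record with `r_ho` and
#'   `angle_hoc` (geometry of the bond landing on the carbonyl), or `NULL`.
#' @param params A [shift_params()] object.
#' @return Shift contribution in ppm (vector; 0 where absent).
#' @export
secondary_hb_term <- function(hb_to_own_carbonyl, params = shift_params()) {
  if (is.null(hb_to_own_carbonyl) || nrow(hb_to_own_carbonyl) == 0) return(0)
  r <- hb_to_own_carbonyl$r_ho
  th <- hb_to_own_carbonyl$angle_hoc
  out <- hb_closed_form(r, th, params$secondary)
  out[is.na(r)] <- 0
  out
}

#' Tertiary polarization term
#'
#' Small additive increments applied when the primary and/or secondary
#' hydrogen-bond partner amide is itself hydrogen-bonded (cooperative
#' polarization of chained amide-amide networks).
#'
#' @param primary_partner_bonded,secondary_partner_bonded Logical vectors.
#' @param params A [shift_params()] object.
#' @return Shift contributions in ppm.
#' @export
tertiary_term <- function(primary_partner_bonded,
                          secondary_partner_bonded = FALSE,
                          params = shift_params()) {
  n <- max(length(primary_partner_bonded), length(secondary_partner_bonded))
  p <- rep_len(as.logical(primary_partner_bonded), n)
  s <- rep_len(as.logical(secondary_partner_bonded), n)
  p * params$tertiary[["PRIMARY_PARTNER_BONDED"]] +
    s * params$tertiary[["SECONDARY_PARTNER_BONDED"]]
}
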