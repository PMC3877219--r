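# Programmatic generators for every test input: ideal secondary-structure
# peptides with exact torsions, two-amide hydrogen-bond geometry scans
# (N-methylacetamide-like model systems), and synthetic observable tables
# with known ground truth.

# Ideal internal coordinates (Angstrom / degrees), standard peptide values.
bb_geom <- list(
  n_ca = 1.458, ca_c = 1.525, c_n = 1.329, c_o = 1.231, n_h = 1.010,
  ang_n_ca_c = 111.2, ang_ca_c_n = 116.2, ang_c_n_ca = 121.7,
  ang_ca_c_o = 120.8, ang_c_n_h = 119.3, omega = 180
)

# Side-chain templates: each atom placed by NeRF from three previously placed
# atoms. Dihedral entries "chi1"/"chi2"/"chi3" are substituted at build time;
# "+180"/"+120" suffixes add an offset to the named torsion.
aa3 <- c(A = "ALA", G = "GLY", S = "SER", T = "THR", D = "ASP", E = "GLU",
         N = "ASN", Q = "GLN", F = "PHE", W = "TRP", H = "HIS", P = "PRO")

sc_atom <- function(name, a, b, c, bond, angle, dihedral) {
  list(name = name, a = a, b = b, c = c, bond = bond, angle = angle,
       dihedral = dihedral)
}

cb <- sc_atom("CB", "N", "C", "CA", 1.521, 110.1, "+122.9")  # improper, L-chirality

sidechain_templates <- list(
  ALA = list(cb),
  GLY = list(),
  SER = list(cb, sc_atom("OG", "N", "CA", "CB", 1.417, 110.8, "chi1")),
  THR = list(cb, sc_atom("OG1", "N", "CA", "CB", 1.433, 109.6, "chi1"),
             sc_atom("CG2", "N", "CA", "CB", 1.521, 110.5, "chi1+120")),
  ASP = list(cb, sc_atom("CG", "N", "CA", "CB", 1.516, 113.8, "chi1"),
             sc_atom("OD1", "CA", "CB", "CG", 1.249, 118.4, "chi2"),
             sc_atom("OD2", "CA", "CB", "CG", 1.249, 118.4, "chi2+180")),
  GLU = list(cb, sc_atom("CG", "N", "CA", "CB", 1.530, 114.1, "chi1"),
             sc_atom("CD", "CA", "CB", "CG", 1.516, 113.8, "chi2"),
             sc_atom("OE1", "CB", "CG", "CD", 1.249, 118.4, "chi3"),
             sc_atom("OE2", "CB", "CG", "CD", 1.249, 118.4, "chi3+180")),
  ASN = list(cb, sc_atom("CG", "N", "CA", "CB", 1.516, 113.8, "chi1"),
             sc_atom("OD1", "CA", "CB", "CG", 1.231, 120.8, "chi2"),
             sc_atom("ND2", "CA", "CB", "CG", 1.328, 116.4, "chi2+180")),
  GLN = list(cb, sc_atom("CG", "N", "CA", "CB", 1.530, 114.1, "chi1"),
             sc_atom("CD", "CA", "CB", "CG", 1.516, 113.8, "chi2"),
             sc_atom("OE1", "CB", "CG", "CD", 1.231, 120.8, "chi3"),
             sc_atom("NE2", "CB", "CG", "CD", 1.328, 116.4, "chi3+180")),
  PHE = list(cb, sc_atom("CG", "N", "CA", "CB", 1.502, 113.8, "chi1"),
             sc_atom("CD1", "CA", "CB", "CG", 1.390, 120.0, "chi2"),
             sc_atom("CD2", "CA", "CB", "CG", 1.390, 120.0, "chi2+180"),
             sc_atom("CE1", "CB", "CG", "CD1", 1.390, 120.0, "180"),
             sc_atom("CE2", "CB", "CG", "CD2", 1.390, 120.0, "180"),
             sc_atom("CZ", "CG", "CD1", "CE1", 1.390, 120.0, "0")),
  HIS = list(cb, sc_atom("CG", "N", "CA", "CB", 1.504, 113.8, "chi1"),
             sc_atom("ND1", "CA", "CB", "CG", 1.378, 122.7, "chi2"),
             sc_atom("CD2", "CA", "CB", "CG", 1.356, 131.0, "chi2+180"),
             sc_atom("CE1", "CB", "CG", "ND1", 1.321, 109.2, "180"),
             sc_atom("NE2", "CB", "CG", "CD2", 1.373, 107.2, "180")),
  TRP = list(cb, sc_atom("CG", "N", "CA", "CB", 1.498, 113.6, "chi1"),
             sc_atom("CD1", "CA", "CB", "CG", 1.365, 126.9, "chi2"),
             sc_atom("CD2", "CA", "CB", "CG", 1.433, 126.7, "chi2+180"),
             sc_atom("NE1", "CB", "CG", "CD1", 1.374, 110.2, "180"),
             sc_atom("CE2", "CB", "CG", "CD2", 1.409, 107.2, "180"),
             sc_atom("CE3", "CG", "CD2", "CE2", 1.398, 122.4, "180"),
             sc_atom("CZ2", "CD2", "CE2", "CZ2_REF", 1.398, 122.4, "NA"),
             sc_atom("CZ3", "CD2", "CE3", "CZ3_REF", 1.382, 118.6, "NA"),
             sc_atom("CH2", "CE3", "CZ3", "CH2_REF", 1.400, 121.1, "NA")),
  PRO = list(cb, sc_atom("CG", "N", "CA", "CB", 1.495, 104.5, "chi1"),
             sc_atom("CD", "CA", "CB", "CG", 1.507, 106.1, "chi2"))
)

sc_dihedral_value <- function(spec, chis) {
  if (grepl("^chi", spec)) {
    base <- chis[[substr(spec, 1, 4)]]
    off <- sub("^chi[0-9]", "", spec)
    if (nzchar(off)) base + as.numeric(off) else base
  } else if (startsWith(spec, "+")) {
    as.numeric(spec)   # improper offset, used directly
  } else {
    as.numeric(spec)
  }
}

#' Build an ideal peptide with exact backbone torsions
#'
#' Constructs a peptide chain atom-by-atom from ideal bond lengths and
#' angles (NeRF internal-coordinate build) so that `backbone_torsions()`
#' recovers the requested phi/psi exactly. Backbone amide hydrogens are
#' placed explicitly (trans to the carbonyl oxygen); the C-terminus carries
#' OXT. Defaults give an ideal alpha-helix.
#'
#' @param n Number of residues (>= 2); ignored when `sequence` is given.
#' @param phi,psi Backbone torsions in degrees; scalars are recycled.
#'   `phi[1]` and `psi[n]` do not exist and are ignored.
#' @param sequence One-letter sequence (string), e.g. `"AAFAA"`. Supported:
#'   A G S T D E N Q F W H P.
#' @param chi1,chi2,chi3 Side-chain torsions in degrees (recycled).
#' @param start_resno First residue number.
#' @param chain Chain identifier.
#' @return An `amide_structure`.
#' @examples
#' helix <- make_peptide(8)                      # ideal alpha-helix
#' sheet <- make_peptide(6, phi = -139, psi = 135)
#' @export
make_peptide <- function(n = NULL, phi = -57, psi = -47, sequence = NULL,
                         chi1 = -60, chi2 = 90, chi3 = -20,
                         start_resno = 1L, chain = "A") {
  if (is.null(sequence)) {
    if (is.null(n) || n < 2) stop("need n >= 2 residues", call. = FALSE)
    sequence <- strrep("A", n)
  }
  letters1 <- strsplit(sequence, "")[[1]]
  n <- length(letters1)
  if (n < 2) stop("need n >= 2 residues", call. = FALSE)
  unknown <- setdiff(letters1, names(aa3))
  if (length(unknown) > 0) {
    stop("unsupported residue letter(s): ", paste(unknown, collapse = ""),
         call. = FALSE)
  }
  resnames <- unname(aa3[letters1])
  phi <- rep_len(phi, n); psi <- rep_len(psi, n)
  chi1 <- rep_len(chi1, n); chi2 <- rep_len(chi2, n); chi3 <- rep_len(chi3, n)
  g <- bb_geom

  atoms <- list()
  add <- function(name, resno, resid, pos, elesy = substr(name, 1, 1)) {
    atoms[[length(atoms) + 1]] <<- list(
      elety = name, resid = resid, resno = resno,
      x = pos[1], y = pos[2], z = pos[3], elesy = elesy
    )
  }
  # coordinate store for placed backbone atoms, keyed "name.i"
  P <- new.env(parent = emptyenv())
  pget <- function(name, i) get(paste0(name, ".", i), envir = P)
  pset <- function(name, i, v) assign(paste0(name, ".", i), v, envir = P)

  for (i in seq_len(n)) {
    resno <- start_resno + i - 1L
    resid <- resnames[i]
    if (i == 1) {
      Npos <- c(0, 0, 0)
      CApos <- c(g$n_ca, 0, 0)
      th <- g$ang_n_ca_c * DEG
      Cpos <- CApos + g$ca_c * c(-cos(th), sin(th), 0)
    } else {
      Npos <- place_atom(pget("N", i - 1), pget("CA", i - 1), pget("C", i - 1),
                         g$c_n, g$ang_ca_c_n, psi[i - 1])
      CApos <- place_atom(pget("CA", i - 1), pget("C", i - 1), Npos,
                          g$n_ca, g$ang_c_n_ca, g$omega)
      Cpos <- place_atom(pget("C", i - 1), Npos, CApos,
                         g$ca_c, g$ang_n_ca_c, phi[i])
    }
    pset("N", i, Npos); pset("CA", i, CApos); pset("C", i, Cpos)
    add("N", resno, resid, Npos, "N")
    if (i > 1 && resid != "PRO") {
      Hpos <- place_atom(pget("O", i - 1), pget("C", i - 1), Npos,
                         g$n_h, g$ang_c_n_h, 180)
      add("H", resno, resid, Hpos, "H")
    }
    add("CA", resno, resid, CApos, "C")
    add("C", resno, resid, Cpos, "C")
    # carbonyl O: anti to the next N (psi + 180); last residue uses its psi too
    Opos <- place_atom(Npos, CApos, Cpos, g$c_o, g$ang_ca_c_o, psi[i] + 180)
    pset("O", i, Opos)
    add("O", resno, resid, Opos, "O")
    if (i == n) {
      add("OXT", resno, resid,
          place_atom(Npos, CApos, Cpos, g$c_o, g$ang_ca_c_o, psi[i]), "O")
    }
    # side chain
    chis <- list(chi1 = chi1[i], chi2 = chi2[i], chi3 = chi3[i])
    placed <- list(N = Npos, CA = CApos, C = Cpos)
    for (atm in sidechain_templates[[resid]]) {
      if (atm$name %in% c("CZ2", "CZ3", "CH2")) next  # handled below for TRP
      dih <- sc_dihedral_value(atm$dihedral, chis)
      pos <- place_atom(placed[[atm$a]], placed[[atm$b]], placed[[atm$c]],
                        atm$bond, atm$angle, dih)
      placed[[atm$name]] <- pos
      add(atm$name, resno, resid, pos, substr(atm$name, 1, 1))
    }
    if (resid == "TRP") {
      # close the six-ring in the indole plane (all dihedrals 0/180)
      placed$CZ2 <- place_atom(placed$CG, placed$CD2, placed$CE2, 1.398, 122.4, 180)
      placed$CZ3 <- place_atom(placed$CG, placed$CD2, placed$CE3, 1.382, 118.6, 180)
      placed$CH2 <- place_atom(placed$CD2, placed$CE2, placed$CZ2, 1.400, 121.1, 0)
      add("CZ2", resno, resid, placed$CZ2, "C")
      add("CZ3", resno, resid, placed$CZ3, "C")
      add("CH2", resno, resid, placed$CH2, "C")
    }
  }

  tab <- dplyr::bind_rows(lapply(atoms, tibble::as_tibble))
  tab$eleno <- seq_len(nrow(tab))
  tab$chain <- chain
  as_structure(tab[, c("eleno", "elety", "resid", "chain", "resno",
                       "x", "y", "z", "elesy")])
}

#' Build a two-amide hydrogen-bond model system at exact geometry
#'
#' Places a donor dipeptide so that its backbone amide proton sits at the
#' requested H...O distance and H...O=C angle from the carbonyl oxygen of an
#' acceptor dipeptide, with the N-H bond pointing straight at the oxygen
#' (N-H...O = `angle_nho`). This emulates the formamide/N-methylacetamide
#' dimer scans used to parameterize hydrogen-bond shift surfaces.
#'
#' @param r_ho H...O distance in Angstrom.
#' @param angle_hoc H...O=C angle in degrees.
#' @param angle_nho N-H...O angle in degrees (default 180, linear bond).
#' @param rho H...O=C-X dihedral in degrees (default 180).
#' @return An `amide_structure` with acceptor residues 1-2 (chain A) and a
#'   donor tripeptide, residues 11-13 (chain B); the probe proton is on the
#'   interior residue 12 (so both of its backbone torsions are defined).
#' @export
make_amide_dimer <- function(r_ho = 1.9, angle_hoc = 150, angle_nho = 180,
                             rho = 180) {
  acc <- make_peptide(2, phi = -140, psi = 140, start_resno = 1L, chain = "A")
  don <- make_peptide(3, phi = -140, psi = 140, start_resno = 11L, chain = "B")
  aat <- acc$atoms
  dat <- don$atoms
  O <- unlist(aat[aat$resno == 1 & aat$elety == "O", c("x", "y", "z")])
  C <- unlist(aat[aat$resno == 1 & aat$elety == "C", c("x", "y", "z")])
  X <- unlist(aat[aat$resno == 1 & aat$elety == "CA", c("x", "y", "z")])
  h_target <- place_atom(X, C, O, r_ho, angle_hoc, rho)

  h0 <- unlist(dat[dat$resno == 12 & dat$elety == "H", c("x", "y", "z")])
  n0 <- unlist(dat[dat$resno == 12 & dat$elety == "N", c("x", "y", "z")])
  d_nh <- vnorm(n0 - h0)
  # desired N position: N-H...O angle = angle_nho, in the H-O-C plane
  u_oh <- vunit(h_target - O)
  if (abs(angle_nho - 180) < 1e-9) {
    n_target <- h_target + d_nh * u_oh
  } else {
    in_plane <- vunit(vcross(vcross(u_oh, C - O), u_oh))
    th <- (180 - angle_nho) * DEG
    n_target <- h_target + d_nh * (cos(th) * u_oh + sin(th) * in_plane)
  }
  # rigid motion: H -> h_target, N-H axis -> target axis (spin about the axis
  # is irrelevant to the bond geometry)
  v_from <- vunit(n0 - h0)
  v_to <- vunit(n_target - h_target)
  ax <- vcross(v_from, v_to)
  if (vnorm(ax) < 1e-12) {
    R <- if (sum(v_from * v_to) > 0) diag(3) else rotation_about_axis(
      vunit(vcross(v_from, c(1, 0, 0) + 1e-3)), 180)
  } else {
    ang <- acos(max(-1, min(1, sum(v_from * v_to)))) / DEG
    R <- rotation_about_axis(ax, ang)
  }
  dxyz <- as.matrix(dat[, c("x", "y", "z")])
  dxyz <- sweep(dxyz, 2, h0) %*% t(R)
  dxyz <- sweep(dxyz, 2, h_target, "+")
  dat$x <- dxyz[, 1]; dat$y <- dxyz[, 2]; dat$z <- dxyz[, 3]

  tab <- dplyr::bind_rows(aat, dat)
  tab$eleno <- seq_len(nrow(tab))
  as_structure(tab)
}

#' Grid of two-amide model systems over bond lengths and angles
#'
#' @param r_values H...O distances (Angstrom).
#' @param angle_values H...O=C angles (degrees).
#' @param ... Passed to [make_amide_dimer()].
#' @return A list of structures, one per (r, angle) node, with attributes
#'   `r_ho` and `angle_hoc` on each element.
#' @export
make_dimer_scan <- function(r_values, angle_values, ...) {
  if (length(r_values) == 0 || length(angle_values) == 0) {
    stop("scan ranges must be nonempty", call. = FALSE)
  }
  grid <- expand.grid(r = r_values, a = angle_values)
  out <- lapply(seq_len(nrow(grid)), function(i) {
    s <- make_amide_dimer(grid$r[i], grid$a[i], ...)
    attr(s, "r_ho") <- grid$r[i]
    attr(s, "angle_hoc") <- grid$a[i]
    s
  })
  out
}

# Synthetic observables -----------------------------------------------------

#' Synthetic experimental shift table from a known structure
#'
#' Forward-models shifts for the structure and adds Gaussian noise, giving a
#' table with known ground truth for recovery tests.
#'
#' @param s An `amide_structure` (the generating conformer).
#' @param params A [shift_params()] object.
#' @param noise_sd Gaussian noise in ppm (0 = exact forward model).
#' @param seed Optional integer seed.
#' @return A tibble with `resno`, `resid`, `shift`; the noise-free truth is
#'   kept in column `truth`.
#' @export
make_synthetic_shifts <- function(s, params = shift_params(), noise_sd = 0,
                                  seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pr <- predict_shifts(s, params)
  tibble::tibble(
    resno = pr$resno, resid = pr$resid,
    shift = pr$total + stats::rnorm(nrow(pr), 0, noise_sd),
    truth = pr$total
  )
}

#' Synthetic N-H RDC table from a known alignment tensor
#'
#' @param s An `amide_structure` or list of conformers.
#' @param tensor Named length-5 Saupe vector; `NULL` draws a random tensor.
#' @param noise_sd Gaussian noise in Hz.
#' @param seed Optional integer seed (controls tensor draw and noise).
#' @return A tibble with `resno`, `d`; the generating tensor is in attribute
#'   `"tensor"` and the noise-free couplings in column `truth`.
#' @export
make_synthetic_rdcs <- function(s, tensor = NULL, noise_sd = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(tensor)) {
    tensor <- stats::setNames(stats::runif(5, -1, 1), saupe_names)
  }
  d0 <- calc_rdc(s, tensor)
  out <- tibble::tibble(
    resno = d0$resno,
    d = d0$d_calc + stats::rnorm(nrow(d0), 0, noise_sd),
    truth = d0$d_calc
  )
  attr(out, "tensor") <- tensor
  out
}

#' Synthetic h3J(NC') coupling table from a structure
#'
#' @param s An `amide_structure`.
#' @param params A [shift_params()] object.
#' @param noise_sd Gaussian noise in Hz.
#' @param seed Optional integer seed.
#' @return A tibble with `donor`, `acceptor`, `j_exp` (and `truth`).
#' @export
make_synthetic_couplings <- function(s, params = shift_params(),
                                     noise_sd = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  jc <- couplings(s, params = params)
  tibble::tibble(
    donor = jc$donor, acceptor = jc$acceptor,
    j_exp = jc$j + stats::rnorm(nrow(jc), 0, noise_sd),
    truth = jc$j
  )
}
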