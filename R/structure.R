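# Protein structure container and readers. A structure is a thin classed list
# around an atom tibble so that downstream code can use ordinary data-frame
# verbs, while geometry kernels work on the bare coordinate matrix.

#' Create a structure object from an atom table
#'
#' @param atoms A data frame with columns `eleno`, `elety` (PDB atom name),
#'   `resid` (three-letter residue name), `chain`, `resno` (1-based residue
#'   number), `x`, `y`, `z` (Angstrom) and `elesy` (element symbol).
#' @param check If `TRUE` (default), verify that every non-proline,
#'   non-N-terminal residue carries an explicit backbone amide hydrogen.
#' @return An object of class `amide_structure`.
#' @export
as_structure <- function(atoms, check = TRUE) {
  req <- c("eleno", "elety", "resid", "chain", "resno", "x", "y", "z", "elesy")
  missing_cols <- setdiff(req, names(atoms))
  if (length(missing_cols) > 0) {
    stop("atom table lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (!all(is.finite(xyz))) stop("non-finite atom coordinates", call. = FALSE)
  s <- structure(
    list(atoms = tibble::as_tibble(atoms)),
    class = "amide_structure"
  )
  if (check) check_amide_hydrogens(s)
  s
}

#' @export
print.amide_structure <- function(x, ...) {
  rn <- unique(x$atoms$resno)
  cat(sprintf("<amide_structure: %d atoms, %d residues>\n",
              nrow(x$atoms), length(rn)))
  invisible(x)
}

#' Coordinate matrix of a structure
#'
#' @param s An `amide_structure`.
#' @return An n x 3 numeric matrix in Angstrom, rows in atom-table order.
#' @export
coords <- function(s) {
  as.matrix(s$atoms[, c("x", "y", "z")])
}

#' Replace the coordinates of a structure
#' @param s An `amide_structure`.
#' @param xyz An n x 3 matrix matching the atom table rows.
#' @return The modified structure.
#' @export
set_coords <- function(s, xyz) {
  stopifnot(nrow(xyz) == nrow(s$atoms), ncol(xyz) == 3)
  s$atoms$x <- xyz[, 1]
  s$atoms$y <- xyz[, 2]
  s$atoms$z <- xyz[, 3]
  s
}

backbone_h_names <- c("H", "HN", "HT1", "H1")

check_amide_hydrogens <- function(s) {
  at <- s$atoms
  resnos <- sort(unique(at$resno))
  chain_of <- vapply(resnos, function(r) at$chain[at$resno == r][1], character(1))
  for (k in seq_along(resnos)[-1]) {
    r <- resnos[k]
    # N-terminal residues of each chain carry no amide proton
    if (resnos[k] - resnos[k - 1] != 1 || chain_of[k] != chain_of[k - 1]) next
    rn <- at$resid[at$resno == r][1]
    if (identical(rn, "PRO")) next
    has_h <- any(at$resno == r & at$elety %in% backbone_h_names)
    if (!has_h) {
      stop(sprintf(
        "no explicit hydrogens: residue %d (%s) lacks a backbone amide H",
        r, rn), call. = FALSE)
    }
    hi <- which(at$resno == r & at$elety %in% backbone_h_names)[1]
    ni <- which(at$resno == r & at$elety == "N")[1]
    if (!is.na(ni)) {
      d <- vnorm(c(at$x[hi] - at$x[ni], at$y[hi] - at$y[ni], at$z[hi] - at$z[ni]))
      if (d < 0.8 || d > 1.2) {
        stop(sprintf(
          "no explicit hydrogens: residue %d (%s) N-H distance %.2f A outside 0.8-1.2 A",
          r, rn, d), call. = FALSE)
      }
    }
  }
  invisible(TRUE)
}

#' Read one conformer from a PDB file
#'
#' Multi-model files (NMR-style ensembles, refinement output) yield one
#' structure per `MODEL` record; `model` selects which (1-based).
#'
#' @param path Path to a PDB file with explicit hydrogens.
#' @param model 1-based model index.
#' @param check Verify explicit amide hydrogens (default `TRUE`).
#' @return An `amide_structure`.
#' @export
read_structure <- function(path, model = 1, check = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  nm <- nrow(pdb$xyz)
  if (model < 1 || model > nm) {
    stop(sprintf("model %d requested but file has %d model(s)", model, nm),
         call. = FALSE)
  }
  at <- pdb$atom
  keep <- at$type %in% c("ATOM", "HETATM") & (is.na(at$alt) | at$alt %in% c("", "A"))
  xyz <- matrix(pdb$xyz[model, ], ncol = 3, byrow = TRUE)
  atoms <- tibble::tibble(
    eleno = at$eleno[keep],
    elety = at$elety[keep],
    resid = at$resid[keep],
    chain = ifelse(is.na(at$chain[keep]), "A", at$chain[keep]),
    resno = at$resno[keep],
    x = xyz[keep, 1], y = xyz[keep, 2], z = xyz[keep, 3],
    elesy = ifelse(is.na(at$elesy[keep]) | at$elesy[keep] == "",
                   substr(trimws(at$elety[keep]), 1, 1), at$elesy[keep])
  )
  as_structure(atoms, check = check)
}

#' Read all conformers of a multi-model PDB file
#'
#' @inheritParams read_structure
#' @return A list of `amide_structure` objects, one per model.
#' @export
read_ensemble <- function(path, check = TRUE) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  lapply(seq_len(nrow(pdb$xyz)), function(m) read_structure(path, m, check))
}

#' Write one or more structures to a (multi-model) PDB file
#'
#' @param structures An `amide_structure` or a list of them sharing one atom
#'   table (an ensemble of conformers).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_structures <- function(structures, path) {
  if (inherits(structures, "amide_structure")) structures <- list(structures)
  s1 <- structures[[1]]
  xyz <- do.call(rbind, lapply(structures, function(s) as.numeric(t(coords(s)))))
  at <- s1$atoms
  bio3d::write.pdb(
    file = path, xyz = xyz,
    resno = at$resno, resid = at$resid, eleno = at$eleno,
    elety = at$elety, chain = at$chain, elesy = at$elesy
  )
  invisible(path)
}

# Backbone torsions --------------------------------------------------------

#' Backbone phi/psi torsion angles
#'
#' @param s An `amide_structure`.
#' @param residue Optional residue number; if omitted, all residues.
#' @return A tibble with columns `resno`, `resid`, `phi`, `psi` (degrees in
#'   (-180, 180], `NA` where an angle is undefined at a terminus).
#' @export
backbone_torsions <- function(s, residue = NULL) {
  ctx <- structure_context(s)
  xyz <- coords(s)
  tor <- torsions_core(xyz, ctx)
  out <- tibble::tibble(
    resno = ctx$resnos, resid = ctx$resnames,
    phi = tor$phi, psi = tor$psi
  )
  if (!is.null(residue)) {
    out <- out[out$resno %in% residue, , drop = FALSE]
    if (nrow(out) == 0) stop("residue not found: ", residue, call. = FALSE)
  }
  out
}

# Aromatic rings -----------------------------------------------------------

ring_atom_sets <- list(
  PHE = list(PHE6 = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
  TYR = list(TYR6 = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
  HIS = list(HIS5 = c("CG", "ND1", "CD2", "CE1", "NE2")),
  TRP = list(
    TRP5 = c("CG", "CD1", "NE1", "CE2", "CD2"),
    TRP6 = c("CD2", "CE2", "CZ2", "CH2", "CZ3", "CE3")
  )
)

#' Locate aromatic rings
#'
#' One ring per PHE/TYR/HIS and two per TRP. The center is the centroid of the
#' ring heavy atoms; the normal is the best-fit plane normal from an SVD of
#' the centered ring coordinates. Residues with incomplete ring atoms are
#' skipped with a warning.
#'
#' @param s An `amide_structure`.
#' @return A tibble with columns `resno`, `kind` (PHE6/TYR6/HIS5/TRP5/TRP6),
#'   `cx`, `cy`, `cz` (center), `nx`, `ny`, `nz` (unit normal).
#' @export
find_rings <- function(s) {
  ctx <- structure_context(s)
  xyz <- coords(s)
  rings_core(xyz, ctx)
}

rings_core <- function(xyz, ctx) {
  rows <- lapply(ctx$rings, function(rg) {
    P <- xyz[rg$idx, , drop = FALSE]
    ctr <- colMeans(P)
    sv <- svd(sweep(P, 2, ctr))
    nrm <- sv$v[, 3]
    tibble::tibble(
      resno = rg$resno, kind = rg$kind,
      cx = ctr[1], cy = ctr[2], cz = ctr[3],
      nx = nrm[1], ny = nrm[2], nz = nrm[3]
    )
  })
  if (length(rows) == 0) {
    return(tibble::tibble(
      resno = integer(), kind = character(),
      cx = double(), cy = double(), cz = double(),
      nx = double(), ny = double(), nz = double()
    ))
  }
  dplyr::bind_rows(rows)
}

# Hydrogen bonds -----------------------------------------------------------

#' Detect hydrogen bonds donated by backbone amide protons
#'
#' For every backbone amide proton (prolines and the N-terminal residue have
#' none and are excluded) the acceptor is the candidate oxygen minimising the
#' H...O distance among those passing the geometric gate (`r_HO <= r_max` and
#' N-H...O angle `>= nho_min`); ties are broken by the larger N-H...O angle.
#' Protons with no acceptor inside the gate are returned with
#' `acceptor_class = "NONE"` (solvent-exposed).
#'
#' Acceptor classes: backbone carbonyl oxygens are `BACKBONE_AMIDE`; ASN/GLN
#' side-chain carbonyls `SIDECHAIN_AMIDE`; ASP/GLU carboxylates and the
#' C-terminal OXT `CARBOXYLATE`; SER/THR/TYR hydroxyls `ALCOHOL`. The
#' donor's own carbonyl and the covalently adjacent carbonyl O(i-1) are never
#' candidates.
#'
#' @param s An `amide_structure`.
#' @param gate List with `r_max` (Angstrom, default 2.5) and `nho_min`
#'   (degrees, default 120).
#' @return A tibble with one row per amide proton: `resno`, `resid`,
#'   `acceptor_resno`, `acceptor_atom`, `acceptor_class`, `r_ho`,
#'   `angle_nho`, `angle_hoc`, `dihedral_rho` (geometry columns `NA` for
#'   class `NONE`).
#' @export
detect_hbonds <- function(s, gate = list(r_max = 2.5, nho_min = 120)) {
  ctx <- structure_context(s)
  xyz <- coords(s)
  hb <- hbonds_core(xyz, ctx, gate)
  tibble::tibble(
    resno = ctx$resnos[ctx$donors],
    resid = ctx$resnames[ctx$donors],
    acceptor_resno = ifelse(hb$acc > 0, ctx$acc$resno[pmax(hb$acc, 1)], NA_integer_),
    acceptor_atom = ifelse(hb$acc > 0, ctx$acc$elety[pmax(hb$acc, 1)], NA_character_),
    acceptor_class = ifelse(hb$acc > 0, ctx$acc$class[pmax(hb$acc, 1)], "NONE"),
    r_ho = ifelse(hb$acc > 0, hb$r, NA_real_),
    angle_nho = ifelse(hb$acc > 0, hb$nho, NA_real_),
    angle_hoc = ifelse(hb$acc > 0, hb$hoc, NA_real_),
    dihedral_rho = ifelse(hb$acc > 0, hb$rho, NA_real_)
  )
}

#' Hydrogen-bond geometry for an explicit amide-amide residue pair
#'
#' Computes the H(donor)...O(acceptor carbonyl) geometry between the backbone
#' amide proton of `donor_resno` and the backbone carbonyl oxygen of
#' `acceptor_resno`, with no distance gate. Used for back-calculating
#' trans-hydrogen-bond couplings across bonds that may open during sampling.
#'
#' @param s An `amide_structure`.
#' @param donor_resno,acceptor_resno Residue numbers (vectors of equal
#'   length). The acceptor residue is the one owning the carbonyl C=O.
#' @return A tibble with `donor`, `acceptor`, `r_ho`, `angle_nho` (theta1),
#'   `angle_hoc` (theta2), `dihedral_rho`.
#' @export
amide_pair_geometry <- function(s, donor_resno, acceptor_resno) {
  stopifnot(length(donor_resno) == length(acceptor_resno))
  ctx <- structure_context(s)
  xyz <- coords(s)
  dp <- match(donor_resno, ctx$resnos)
  ap <- match(acceptor_resno, ctx$resnos)
  if (anyNA(dp) || anyNA(ap)) stop("residue number not in structure", call. = FALSE)
  hi <- ctx$idx$H[dp]; ni <- ctx$idx$N[dp]
  oi <- ctx$idx$O[ap]; ci <- ctx$idx$C[ap]; xi <- ctx$idx$CA[ap]
  if (anyNA(hi) || anyNA(oi) || anyNA(ci)) {
    stop("amide pair geometry needs donor H/N and acceptor C=O atoms", call. = FALSE)
  }
  H <- xyz[hi, , drop = FALSE]; N <- xyz[ni, , drop = FALSE]
  O <- xyz[oi, , drop = FALSE]; C <- xyz[ci, , drop = FALSE]
  X <- xyz[xi, , drop = FALSE]
  tibble::tibble(
    donor = donor_resno,
    acceptor = acceptor_resno,
    r_ho = sqrt(rowSums((H - O)^2)),
    angle_nho = row_angle(N, H, O),
    angle_hoc = row_angle(H, O, C),
    dihedral_rho = row_dihedral(H, O, C, X)
  )
}
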