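# Precomputed index tables ("context") for a structure, plus the geometry
# kernels that operate on a bare coordinate matrix. The exported tidyverse
# surface wraps these; the Metropolis-Hastings loop calls them directly so a
# move costs matrix arithmetic, not data-frame bookkeeping.

sidechain_acceptors <- list(
  ASP = list(elety = c("OD1", "OD2"), carbon = "CG", xatom = "CB", class = "CARBOXYLATE"),
  GLU = list(elety = c("OE1", "OE2"), carbon = "CD", xatom = "CG", class = "CARBOXYLATE"),
  ASN = list(elety = "OD1", carbon = "CG", xatom = "CB", class = "SIDECHAIN_AMIDE"),
  GLN = list(elety = "OE1", carbon = "CD", xatom = "CG", class = "SIDECHAIN_AMIDE"),
  SER = list(elety = "OG",  carbon = "CB", xatom = "CA", class = "ALCOHOL"),
  THR = list(elety = "OG1", carbon = "CB", xatom = "CA", class = "ALCOHOL"),
  TYR = list(elety = "OH",  carbon = "CZ", xatom = "CE1", class = "ALCOHOL")
)

structure_context <- function(s) {
  at <- s$atoms
  resnos <- sort(unique(at$resno))
  n <- length(resnos)
  pos_of <- function(r) match(r, resnos)
  resnames <- vapply(resnos, function(r) at$resid[at$resno == r][1], character(1))

  find_atom <- function(r, names) {
    i <- which(at$resno == r & at$elety %in% names)
    if (length(i) == 0) NA_integer_ else i[1]
  }
  idx <- list(
    N  = vapply(resnos, find_atom, integer(1), names = "N"),
    H  = vapply(resnos, find_atom, integer(1), names = backbone_h_names),
    CA = vapply(resnos, find_atom, integer(1), names = "CA"),
    C  = vapply(resnos, find_atom, integer(1), names = "C"),
    O  = vapply(resnos, find_atom, integer(1), names = "O")
  )

  chains <- vapply(resnos, function(r) at$chain[at$resno == r][1], character(1))
  # is residue p covalently preceded by residue p-1 (same chain, consecutive)?
  prev_ok <- c(FALSE, diff(resnos) == 1 & chains[-1] == chains[-n])

  donors <- which(seq_len(n) > 1 & resnames != "PRO" &
                    !is.na(idx$H) & !is.na(idx$N))

  # acceptor candidate table
  acc_rows <- list()
  for (p in seq_len(n)) {
    r <- resnos[p]
    if (!is.na(idx$O[p]) && !is.na(idx$C[p])) {
      acc_rows[[length(acc_rows) + 1]] <- list(
        o = idx$O[p], c = idx$C[p], x = idx$CA[p], resno = r, pos = p,
        elety = "O", class = "BACKBONE_AMIDE", backbone = TRUE
      )
    }
    oxt <- find_atom(r, "OXT")
    if (!is.na(oxt) && !is.na(idx$C[p])) {
      acc_rows[[length(acc_rows) + 1]] <- list(
        o = oxt, c = idx$C[p], x = idx$CA[p], resno = r, pos = p,
        elety = "OXT", class = "CARBOXYLATE", backbone = FALSE
      )
    }
    sc <- sidechain_acceptors[[resnames[p]]]
    if (!is.null(sc)) {
      ci <- find_atom(r, sc$carbon)
      xi <- find_atom(r, sc$xatom)
      for (nm in sc$elety) {
        oi <- find_atom(r, nm)
        if (!is.na(oi) && !is.na(ci) && !is.na(xi)) {
          acc_rows[[length(acc_rows) + 1]] <- list(
            o = oi, c = ci, x = xi, resno = r, pos = p,
            elety = nm, class = sc$class, backbone = FALSE
          )
        }
      }
    }
  }
  acc <- list(
    o = vapply(acc_rows, `[[`, integer(1), "o"),
    c = vapply(acc_rows, `[[`, integer(1), "c"),
    x = vapply(acc_rows, `[[`, integer(1), "x"),
    resno = vapply(acc_rows, `[[`, integer(1), "resno"),
    pos = vapply(acc_rows, `[[`, integer(1), "pos"),
    elety = vapply(acc_rows, `[[`, character(1), "elety"),
    class = vapply(acc_rows, `[[`, character(1), "class"),
    backbone = vapply(acc_rows, `[[`, logical(1), "backbone")
  )

  # exclusion matrix: donor i never bonds its own backbone carbonyl O(i) nor
  # the covalently adjacent O(i-1)
  nd <- length(donors)
  na_ <- length(acc$o)
  excl <- matrix(FALSE, nd, na_)
  if (nd > 0 && na_ > 0) {
    for (k in seq_len(nd)) {
      p <- donors[k]
      excl[k, ] <- acc$backbone &
        (acc$pos == p | (acc$pos == p - 1 & prev_ok[p]))
    }
  }

  # aromatic rings
  rings <- list()
  for (p in seq_len(n)) {
    sets <- ring_atom_sets[[resnames[p]]]
    if (is.null(sets)) next
    for (kind in names(sets)) {
      ai <- vapply(sets[[kind]], function(a) find_atom(resnos[p], a), integer(1))
      if (anyNA(ai)) {
        warning(sprintf("incomplete %s ring in residue %d; ring skipped",
                        kind, resnos[p]), call. = FALSE)
      } else {
        rings[[length(rings) + 1]] <- list(resno = resnos[p], kind = kind, idx = ai)
      }
    }
  }

  # torsion atom quadruples (NA row where undefined or across a chain break)
  phi_q <- cbind(c(NA_integer_, idx$C[-n]), idx$N, idx$CA, idx$C)
  phi_q[!prev_ok, 1] <- NA_integer_
  next_ok <- c(prev_ok[-1], FALSE)
  psi_q <- cbind(idx$N, idx$CA, idx$C, c(idx$N[-1], NA_integer_))
  psi_q[!next_ok, 4] <- NA_integer_

  list(
    n = n, resnos = resnos, resnames = resnames, idx = idx,
    chains = chains, prev_ok = prev_ok,
    donors = donors, acc = acc, excl = excl, rings = rings,
    phi_q = phi_q, psi_q = psi_q,
    natoms = nrow(at)
  )
}

torsions_core <- function(xyz, ctx) {
  phi <- rep(NA_real_, ctx$n)
  psi <- rep(NA_real_, ctx$n)
  ok_phi <- rowSums(is.na(ctx$phi_q)) == 0
  ok_psi <- rowSums(is.na(ctx$psi_q)) == 0
  if (any(ok_phi)) {
    q <- ctx$phi_q[ok_phi, , drop = FALSE]
    phi[ok_phi] <- row_dihedral(
      xyz[q[, 1], , drop = FALSE], xyz[q[, 2], , drop = FALSE],
      xyz[q[, 3], , drop = FALSE], xyz[q[, 4], , drop = FALSE]
    )
  }
  if (any(ok_psi)) {
    q <- ctx$psi_q[ok_psi, , drop = FALSE]
    psi[ok_psi] <- row_dihedral(
      xyz[q[, 1], , drop = FALSE], xyz[q[, 2], , drop = FALSE],
      xyz[q[, 3], , drop = FALSE], xyz[q[, 4], , drop = FALSE]
    )
  }
  list(phi = phi, psi = psi)
}

# Per-donor acceptor choice. Returns acc (candidate row index, 0 = none) and
# the bond geometry for chosen pairs.
hbonds_core <- function(xyz, ctx, gate = list(r_max = 2.5, nho_min = 120)) {
  nd <- length(ctx$donors)
  out <- list(
    acc = integer(nd), r = rep(NA_real_, nd), nho = rep(NA_real_, nd),
    hoc = rep(NA_real_, nd), rho = rep(NA_real_, nd)
  )
  na_ <- length(ctx$acc$o)
  if (nd == 0 || na_ == 0) return(out)

  H <- xyz[ctx$idx$H[ctx$donors], , drop = FALSE]
  N <- xyz[ctx$idx$N[ctx$donors], , drop = FALSE]
  A <- xyz[ctx$acc$o, , drop = FALSE]

  D <- cross_dist(H, A)
  U <- N - H
  un <- sqrt(rowSums(U^2))
  # cos(N-H...O) for all donor x acceptor pairs
  numer <- U %*% t(A) - rowSums(U * H)
  cosang <- numer / (un * D)
  cosang[cosang > 1] <- 1
  cosang[cosang < -1] <- -1
  ANG <- acos(cosang) / DEG

  pass <- (D <= gate$r_max) & (ANG >= gate$nho_min) & !ctx$excl
  for (k in seq_len(nd)) {
    cand <- which(pass[k, ])
    if (length(cand) == 0) next
    j <- cand[order(D[k, cand], -ANG[k, cand])][1]
    out$acc[k] <- j
    out$r[k] <- D[k, j]
    out$nho[k] <- ANG[k, j]
    Opos <- A[j, ]
    Cpos <- xyz[ctx$acc$c[j], ]
    Xpos <- xyz[ctx$acc$x[j], ]
    out$hoc[k] <- vec_angle(H[k, ], Opos, Cpos)
    # rho is undefined for a linear H...O=C arrangement
    out$rho[k] <- tryCatch(dihedral4(H[k, ], Opos, Cpos, Xpos),
                           error = function(e) NA_real_)
  }
  out
}
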