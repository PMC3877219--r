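# Metropolis-Hastings refinement of hydrogen-bond geometry against
# experimental amide proton shifts. Moves are small Gaussian perturbations
# of backbone (phi, psi) and side-chain chi1 torsions, applied as rigid
# rotations of the downstream atoms; the posterior combines a pluggable
# prior energy with the per-bond-class Gaussian shift likelihood.

# Rotatable-torsion topology: for each torsion, the rotation axis (two atom
# indices) and the indices of the atoms it moves.
torsion_topology <- function(s, ctx) {
  at <- s$atoms
  if (length(unique(at$chain)) > 1) {
    stop("refinement supports single-chain structures", call. = FALSE)
  }
  topo <- list()
  backbone_names <- c("N", "CA", "C", "O", "OXT", backbone_h_names)
  for (p in seq_len(ctx$n)) {
    r <- ctx$resnos[p]
    after <- which(at$resno > r)
    # phi: rotate about N-CA; moves all of residue p except N,H plus residues > p
    if (p > 1 && !is.na(ctx$idx$N[p]) && !is.na(ctx$idx$CA[p])) {
      own <- which(at$resno == r & !(at$elety %in% c("N", backbone_h_names, "CA")))
      topo[[length(topo) + 1]] <- list(
        type = "phi", pos = p, group = "backbone",
        axis = c(ctx$idx$N[p], ctx$idx$CA[p]),
        moving = c(own, after)
      )
    }
    # psi: rotate about CA-C; moves O(p) (+OXT) plus residues > p
    if (p < ctx$n && !is.na(ctx$idx$CA[p]) && !is.na(ctx$idx$C[p])) {
      own <- which(at$resno == r & at$elety %in% c("O", "OXT"))
      topo[[length(topo) + 1]] <- list(
        type = "psi", pos = p, group = "backbone",
        axis = c(ctx$idx$CA[p], ctx$idx$C[p]),
        moving = c(own, after)
      )
    }
    # chi1: rotate about CA-CB; moves the side chain beyond CB
    cb <- which(at$resno == r & at$elety == "CB")
    side <- which(at$resno == r & !(at$elety %in% c(backbone_names, "CB")))
    if (length(cb) == 1 && length(side) > 0 && !is.na(ctx$idx$CA[p])) {
      topo[[length(topo) + 1]] <- list(
        type = "chi1", pos = p, group = "sidechain",
        axis = c(ctx$idx$CA[p], cb),
        moving = side
      )
    }
  }
  topo
}

rotate_about <- function(xyz, axis_idx, moving, angle_deg) {
  a <- xyz[axis_idx[1], ]
  b <- xyz[axis_idx[2], ]
  R <- rotation_about_axis(b - a, angle_deg)
  xyz[moving, ] <- sweep(sweep(xyz[moving, , drop = FALSE], 2, a) %*% t(R),
                         2, a, "+")
  xyz
}

# Energy models -------------------------------------------------------------

#' Default prior energy: soft sterics + hydrogen-bond wells + torsion restraint
#'
#' A deliberately coarse, fast stand-in for a molecular-mechanics prior that
#' preserves the structure of the posterior: (i) a soft-sphere repulsion
#' between heavy atoms of residues at sequence separation >= 2,
#' (ii) a Gaussian attractive well for amide H...O=C pairs centred at
#' typical hydrogen-bond length, and (iii) a harmonic restraint of all
#' phi/psi torsions to the reference structure. Any energy callable with the
#' same signature (`function(xyz, ctx) -> kcal/mol`) can replace it.
#'
#' @param s Reference `amide_structure` (supplies the restraint center).
#' @param k_torsion Torsion restraint constant, kcal/mol/deg^2 (default
#'   0.005, i.e. ~11 deg thermal spread at 300 K).
#' @param steric_eps Soft-sphere prefactor, kcal/mol (default 0.5).
#' @param r_clash Soft-sphere radius, Angstrom (default 2.6).
#' @param hb_depth Hydrogen-bond well depth, kcal/mol (default 1.0).
#' @return A function `(xyz, ctx) -> energy` of class `energy_model`.
#' @export
default_energy_model <- function(s, k_torsion = 0.005, steric_eps = 0.5,
                                 r_clash = 2.6, hb_depth = 1.0) {
  ctx0 <- structure_context(s)
  ref <- torsions_core(coords(s), ctx0)
  heavy <- which(s$atoms$elesy != "H")
  heavy_res <- s$atoms$resno[heavy]
  sep_ok <- abs(outer(heavy_res, heavy_res, "-")) >= 2
  sep_ok[lower.tri(sep_ok, diag = TRUE)] <- FALSE

  fn <- function(xyz, ctx) {
    D <- cross_dist(xyz[heavy, , drop = FALSE], xyz[heavy, , drop = FALSE])
    dd <- D[sep_ok]
    close <- dd < r_clash
    e_steric <- if (any(close)) {
      sum(pmin(steric_eps * ((r_clash / dd[close])^12 - 1), 100))
    } else 0
    e_hb <- 0
    if (length(ctx$donors) > 0 && any(ctx$acc$backbone)) {
      Hm <- xyz[ctx$idx$H[ctx$donors], , drop = FALSE]
      Om <- xyz[ctx$acc$o[ctx$acc$backbone], , drop = FALSE]
      Dho <- cross_dist(Hm, Om)
      keep <- !ctx$excl[, ctx$acc$backbone, drop = FALSE]
      e_hb <- -hb_depth * sum(exp(-((Dho[keep] - 1.95) / 0.3)^2))
    }
    tor <- torsions_core(xyz, ctx)
    dphi <- wrap_angle(tor$phi - ref$phi)
    dpsi <- wrap_angle(tor$psi - ref$psi)
    e_tor <- 0.5 * k_torsion *
      (sum(dphi^2, na.rm = TRUE) + sum(dpsi^2, na.rm = TRUE))
    e_steric + e_hb + e_tor
  }
  structure(fn, class = c("energy_model", "function"))
}

#' Harmonic toy energy in a single backbone torsion
#'
#' `E = 0.5 k (theta - center)^2` for one phi or psi angle; all other
#' degrees of freedom are free. Used to validate the sampler against the
#' closed-form variance `k_B T / k`.
#'
#' @param resno Residue number.
#' @param which `"phi"` or `"psi"`.
#' @param center Restraint center, degrees.
#' @param k Force constant, kcal/mol/deg^2.
#' @return An `energy_model` function.
#' @export
harmonic_torsion_energy <- function(resno, which = "phi", center, k) {
  force(resno); force(which); force(center); force(k)
  fn <- function(xyz, ctx) {
    p <- match(resno, ctx$resnos)
    q <- if (which == "phi") ctx$phi_q[p, ] else ctx$psi_q[p, ]
    th <- dihedral4(xyz[q[1], ], xyz[q[2], ], xyz[q[3], ], xyz[q[4], ])
    0.5 * k * wrap_angle(th - center)^2
  }
  structure(fn, class = c("energy_model", "function"))
}

#' Flat (zero) prior energy
#' @return An `energy_model` function returning 0 for any structure.
#' @export
zero_energy <- function() {
  structure(function(xyz, ctx) 0, class = c("energy_model", "function"))
}

# ---------------------------------------------------------------------------

#' Refine a structure against experimental amide proton shifts
#'
#' Metropolis-Hastings sampling at `temperature` kelvin from the posterior
#' `p(X | D) ~ exp(-E(X)/kT) * L(D | X)`, where the likelihood is Gaussian
#' in the per-residue shift deviations with per-bond-class standard
#' deviations. Moves perturb one randomly chosen torsion by a Gaussian step
#' (mixture of backbone phi/psi and side-chain chi1 moves, default 25%/75%
#' when side-chain torsions exist); rejected moves restore the previous
#' coordinates bit-exactly. Conformers are saved every `save_every` steps.
#'
#' @param s Starting `amide_structure`.
#' @param shifts Experimental shift tibble (`resno`, `shift`), or `NULL` to
#'   sample from the prior alone.
#' @param params A [shift_params()] object.
#' @param sigma A [sigma_model()]; ignored when `shifts` is `NULL`.
#' @param energy_model An `energy_model` function (`(xyz, ctx) -> kcal/mol`);
#'   default [default_energy_model()] referenced to the start structure.
#' @param n_steps Total MH steps.
#' @param save_every Save interval in steps (default 10000).
#' @param temperature Kelvin (default 300).
#' @param moves List: `backbone_frac` (probability of a backbone move when
#'   side-chain torsions exist, default 0.25), `sd_backbone` and
#'   `sd_sidechain` (Gaussian step widths, degrees).
#' @param seed Integer seed; the run is deterministic given the seed.
#' @param frozen_window Steps with zero acceptances that trigger a
#'   frozen-chain warning (default 2000).
#' @return An object of class `shift_refinement`: list with `ensemble`
#'   (saved conformers), `trace` (tibble: step, energy, log_lik,
#'   log_posterior, shift_rmsd, acceptance_rate), `final` (last structure),
#'   `acceptance_rate` and the run configuration.
#' @export
refine_structure <- function(s, shifts = NULL, params = shift_params(),
                             sigma = sigma_model(),
                             energy_model = default_energy_model(s),
                             n_steps = 10000, save_every = 10000,
                             temperature = 300,
                             moves = list(backbone_frac = 0.25,
                                          sd_backbone = 2,
                                          sd_sidechain = 10),
                             seed = 1, frozen_window = 2000) {
  set.seed(seed)
  ctx <- structure_context(s)
  topo <- torsion_topology(s, ctx)
  if (length(topo) == 0) stop("no rotatable torsions", call. = FALSE)
  bb_moves <- which(vapply(topo, function(t) t$group == "backbone", logical(1)))
  sc_moves <- which(vapply(topo, function(t) t$group == "sidechain", logical(1)))
  if (length(sc_moves) == 0) moves$backbone_frac <- 1

  # precompute the experimental match against the donor list
  exp_map <- NULL
  if (!is.null(shifts)) {
    donor_resno <- ctx$resnos[ctx$donors]
    sel <- match(donor_resno, shifts$resno)
    exp_map <- list(donor_idx = which(!is.na(sel)),
                    shift = shifts$shift[sel[!is.na(sel)]])
    if (length(exp_map$donor_idx) == 0) {
      stop("no experimental shifts match the structure", call. = FALSE)
    }
  }
  kT <- BOLTZMANN_KCAL * temperature

  loglik_of <- function(pc) {
    if (is.null(exp_map)) return(list(ll = 0, rmsd = NA_real_))
    i <- exp_map$donor_idx
    tot <- pc$total[i]
    ok <- !is.na(tot)
    dd <- tot[ok] - exp_map$shift[ok]
    sg <- sigma_for_class(sigma, pc$acceptor_class[i][ok])
    list(ll = sum(stats::dnorm(dd, 0, sg, log = TRUE)),
         rmsd = sqrt(mean(dd^2)))
  }

  xyz <- coords(s)
  pc <- if (is.null(exp_map)) NULL else predict_core(xyz, ctx, params)
  lk <- loglik_of(pc)
  E <- energy_model(xyz, ctx)
  lp <- -E / kT + lk$ll
  if (!is.finite(lp)) stop("start structure has zero posterior density", call. = FALSE)

  ensemble <- list()
  trace <- list()
  n_acc <- 0L
  last_acc_step <- 0L
  warned_frozen <- FALSE

  for (step in seq_len(n_steps)) {
    mv <- if (stats::runif(1) < moves$backbone_frac || length(sc_moves) == 0) {
      topo[[sample(bb_moves, 1)]]
    } else {
      topo[[sample(sc_moves, 1)]]
    }
    sd_mv <- if (mv$group == "backbone") moves$sd_backbone else moves$sd_sidechain
    delta <- stats::rnorm(1, 0, sd_mv)
    xyz2 <- rotate_about(xyz, mv$axis, mv$moving, delta)
    pc2 <- if (is.null(exp_map)) NULL else predict_core(xyz2, ctx, params)
    lk2 <- loglik_of(pc2)
    E2 <- energy_model(xyz2, ctx)
    lp2 <- -E2 / kT + lk2$ll
    if (is.finite(lp2) && log(stats::runif(1)) < lp2 - lp) {
      xyz <- xyz2; pc <- pc2; lk <- lk2; E <- E2; lp <- lp2
      n_acc <- n_acc + 1L
      last_acc_step <- step
    }
    if (!warned_frozen && step - last_acc_step >= frozen_window) {
      warning(sprintf("chain frozen: no accepted moves in %d steps", frozen_window),
              call. = FALSE)
      warned_frozen <- TRUE
    }
    if (step %% save_every == 0 || step == n_steps) {
      k <- length(ensemble) + 1L
      ensemble[[k]] <- set_coords(s, xyz)
      trace[[k]] <- tibble::tibble(
        step = step, energy = E, log_lik = lk$ll, log_posterior = lp,
        shift_rmsd = lk$rmsd, acceptance_rate = n_acc / step
      )
    }
  }

  out <- list(
    ensemble = ensemble,
    trace = dplyr::bind_rows(trace),
    final = set_coords(s, xyz),
    acceptance_rate = n_acc / n_steps,
    n_steps = n_steps, save_every = save_every,
    temperature = temperature, seed = seed,
    has_likelihood = !is.null(shifts)
  )
  class(out) <- "shift_refinement"
  out
}

#' @export
print.shift_refinement <- function(x, ...) {
  cat(sprintf(
    "<shift_refinement: %d steps at %g K, %d saved conformer(s), acceptance %.1f%%>\n",
    x$n_steps, x$temperature, length(x$ensemble), 100 * x$acceptance_rate))
  invisible(x)
}
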