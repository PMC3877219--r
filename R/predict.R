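# Per-proton shift assembly, ensemble averaging and scoring against
# experimental shift tables.

# Fast kernel: everything downstream of a coordinate move. Works on plain
# vectors/lists so the sampler can call it tens of thousands of times.
predict_core <- function(xyz, ctx, params) {
  tor <- torsions_core(xyz, ctx)
  hb <- hbonds_core(xyz, ctx, params$gate)
  nd <- length(ctx$donors)
  if (nd == 0) {
    return(list(donors = integer(0), total = numeric(0)))
  }
  safe <- pmax(hb$acc, 1)
  cls <- ifelse(hb$acc > 0, ctx$acc$class[safe], "NONE")

  prim <- primary_hb_term(
    list(acceptor_class = cls, r_ho = hb$r, angle_hoc = hb$hoc), params)

  # secondary: a bond accepted by the donor's own carbonyl O(i-1)
  acc_o <- ifelse(hb$acc > 0, ctx$acc$o[safe], NA_integer_)
  sec <- numeric(nd)
  sec_donor <- rep(NA_integer_, nd)
  for (k in seq_len(nd)) {
    p <- ctx$donors[k]
    if (!ctx$prev_ok[p]) next
    ow <- ctx$idx$O[p - 1]
    if (is.na(ow)) next
    ks <- which(acc_o == ow)
    if (length(ks) == 0) next
    ks <- ks[which.min(hb$r[ks])]
    sec[k] <- hb_closed_form(hb$r[ks], hb$hoc[ks], params$secondary)
    sec_donor[k] <- ks
  }

  # tertiary: is the primary / secondary partner itself hydrogen-bonded?
  donor_of_pos <- match(seq_len(ctx$n), ctx$donors)
  prim_partner <- logical(nd)
  sec_partner <- logical(nd)
  for (k in seq_len(nd)) {
    if (hb$acc[k] > 0 && ctx$acc$backbone[hb$acc[k]]) {
      j <- ctx$acc$pos[hb$acc[k]] + 1  # amide group owning the carbonyl
      if (j <= ctx$n && !is.na(donor_of_pos[j])) {
        prim_partner[k] <- hb$acc[donor_of_pos[j]] > 0
      }
    }
    if (!is.na(sec_donor[k])) {
      q <- ctx$donors[sec_donor[k]]
      if (ctx$prev_ok[q] && !is.na(ctx$idx$O[q - 1])) {
        sec_partner[k] <- any(acc_o == ctx$idx$O[q - 1], na.rm = TRUE)
      }
    }
  }
  tert <- tertiary_term(prim_partner, sec_partner, params)

  phi <- tor$phi[ctx$donors]
  psi <- tor$psi[ctx$donors]
  eligible <- !is.na(phi) & !is.na(psi)
  bb <- rep(NA_real_, nd)
  if (any(eligible)) {
    bb[eligible] <- backbone_term(phi[eligible], psi[eligible], params)
  }

  ring_tbl <- rings_core(xyz, ctx)
  rc <- ring_current_term(xyz[ctx$idx$H[ctx$donors], , drop = FALSE],
                          ring_tbl, params)

  list(
    donors = ctx$donors, eligible = eligible, acceptor_class = cls, hb = hb,
    backbone = bb, primary_hb = prim, secondary_hb = sec, tertiary = tert,
    ring_current = rc, total = bb + prim + sec + tert + rc,
    phi = phi, psi = psi
  )
}

#' Predict backbone amide proton chemical shifts
#'
#' Computes, for every eligible amide proton (explicit H present and both
#' phi and psi defined; prolines and chain termini are excluded), the total
#' DSS-referenced shift as the sum of five additive terms: backbone
#' (phi/psi cosine series), primary hydrogen bond, secondary hydrogen bond,
#' tertiary polarization, and ring current.
#'
#' @param s An `amide_structure`.
#' @param params A [shift_params()] object.
#' @return A tibble with columns `resno`, `resid`, `acceptor_class`,
#'   `backbone`, `primary_hb`, `secondary_hb`, `tertiary`, `ring_current`
#'   and `total` (all ppm).
#' @examples
#' helix <- make_peptide(8)
#' predict_shifts(helix)
#' @export
predict_shifts <- function(s, params = shift_params()) {
  ctx <- structure_context(s)
  pc <- predict_core(coords(s), ctx, params)
  keep <- which(pc$eligible)
  tibble::tibble(
    resno = ctx$resnos[pc$donors[keep]],
    resid = ctx$resnames[pc$donors[keep]],
    acceptor_class = pc$acceptor_class[keep],
    backbone = pc$backbone[keep],
    primary_hb = pc$primary_hb[keep],
    secondary_hb = pc$secondary_hb[keep],
    tertiary = pc$tertiary[keep],
    ring_current = pc$ring_current[keep],
    total = pc$total[keep]
  )
}

#' Average shift predictions over an ensemble of conformers
#'
#' @param structures A list of `amide_structure` conformers (or a single
#'   structure), e.g. from [read_ensemble()] or [refine_structure()].
#' @param params A [shift_params()] object.
#' @return A tibble with per-residue `mean` and population standard
#'   deviation `sd` of the total shift, plus means of the five terms.
#' @export
ensemble_shifts <- function(structures, params = shift_params()) {
  if (inherits(structures, "amide_structure")) structures <- list(structures)
  preds <- purrr::map(structures, predict_shifts, params = params)
  dplyr::bind_rows(preds, .id = "conformer") |>
    dplyr::group_by(.data$resno, .data$resid) |>
    dplyr::summarise(
      mean = mean(.data$total),
      sd = sqrt(sum((.data$total - mean(.data$total))^2) / dplyr::n()),
      backbone = mean(.data$backbone),
      primary_hb = mean(.data$primary_hb),
      secondary_hb = mean(.data$secondary_hb),
      tertiary = mean(.data$tertiary),
      ring_current = mean(.data$ring_current),
      n_conformers = dplyr::n(),
      .groups = "drop"
    )
}

#' Score predicted shifts against an experimental table
#'
#' Rows are matched by residue number; a residue-name mismatch or unmatched
#' rows produce warnings. RMSD and the Pearson correlation are computed over
#' matched residues. With `by_class = TRUE` the result carries one row per
#' acceptor class plus an `"ALL"` row, mirroring the per-bond-class error
#' structure of the shift model.
#'
#' @param predicted Tibble from [predict_shifts()] (columns `resno`, `total`,
#'   optionally `acceptor_class`, `resid`) or any tibble with `resno` and a
#'   shift column named `total` or `shift`.
#' @param experimental Tibble with `resno` and `shift` (ppm), optionally
#'   `resid`.
#' @param by_class Emit per-acceptor-class rows (default `FALSE`).
#' @return A tibble with `rmsd` (ppm), `pearson_r` and `n`.
#' @export
score_shifts <- function(predicted, experimental, by_class = FALSE) {
  pv <- if ("total" %in% names(predicted)) "total" else "shift"
  m <- dplyr::inner_join(
    dplyr::rename(predicted, .pred = dplyr::all_of(pv)),
    dplyr::rename(experimental, .exp = "shift"),
    by = "resno", suffix = c("", ".exp")
  )
  if (nrow(m) < 2) stop("need >= 2 matched residues to score", call. = FALSE)
  un_p <- setdiff(predicted$resno, m$resno)
  un_e <- setdiff(experimental$resno, m$resno)
  if (length(un_p) + length(un_e) > 0) {
    warning("unmatched residues: predicted [", paste(un_p, collapse = ","),
            "] experimental [", paste(un_e, collapse = ","), "]", call. = FALSE)
  }
  if ("resid.exp" %in% names(m) && "resid" %in% names(m)) {
    bad <- which(m$resid != m$resid.exp)
    if (length(bad) > 0) {
      warning("residue name mismatch at resno ",
              paste(m$resno[bad], collapse = ","), call. = FALSE)
    }
  }
  one <- function(d) {
    tibble::tibble(
      rmsd = sqrt(mean((d$.pred - d$.exp)^2)),
      pearson_r = if (nrow(d) >= 2 && stats::sd(d$.pred) > 0 && stats::sd(d$.exp) > 0)
        stats::cor(d$.pred, d$.exp) else NA_real_,
      n = nrow(d)
    )
  }
  if (!by_class || !"acceptor_class" %in% names(m)) {
    return(one(m))
  }
  dplyr::bind_rows(
    dplyr::mutate(one(m), acceptor_class = "ALL"),
    m |>
      dplyr::group_by(.data$acceptor_class) |>
      dplyr::group_modify(~ one(.x)) |>
      dplyr::ungroup()
  ) |>
    dplyr::relocate(dplyr::all_of("acceptor_class"))
}

#' Read an experimental chemical shift table
#'
#' Accepts comma- or whitespace-separated files with columns residue number,
#' residue name, shift (ppm); a header line naming `resno`/`resid`/`shift`
#' is recognised. Shifts outside the physical 3-13 ppm amide window produce
#' a warning.
#'
#' @param path File path.
#' @return A tibble with `resno`, `resid`, `shift`.
#' @export
read_shift_table <- function(path) {
  first <- readLines(path, n = 1)
  sep <- if (grepl(",", first)) "," else ""
  has_header <- grepl("resno|shift", first, ignore.case = TRUE)
  df <- utils::read.table(path, header = has_header, sep = sep,
                          comment.char = "#", stringsAsFactors = FALSE)
  if (!has_header) names(df)[1:3] <- c("resno", "resid", "shift")
  df <- tibble::as_tibble(df[, c("resno", "resid", "shift")])
  if (anyDuplicated(df$resno)) stop("duplicate residue indices in shift table",
                                    call. = FALSE)
  out_of_window <- df$shift < 3 | df$shift > 13
  if (any(out_of_window)) {
    warning(sum(out_of_window),
            " shift(s) outside the physical 3-13 ppm amide window", call. = FALSE)
  }
  df
}
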