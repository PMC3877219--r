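# broom-style tidiers for fitted/simulation objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the Saupe components of an alignment tensor
#'
#' @param x An `alignment_tensor`.
#' @param ... Unused.
#' @return A tibble with `component` and `estimate` (Hz).
#' @exportS3Method generics::tidy
tidy.alignment_tensor <- function(x, ...) {
  tibble::tibble(component = names(x$saupe), estimate = unname(x$saupe))
}

#' One-row fit summary of an alignment tensor
#'
#' @param x An `alignment_tensor`.
#' @param ... Unused.
#' @return A tibble with `q`, `rmsd`, `n`, `condition`, `n_conformers`.
#' @exportS3Method generics::glance
glance.alignment_tensor <- function(x, ...) {
  tibble::tibble(
    q = x$q, rmsd = x$rmsd, n = x$n,
    condition = x$condition, n_conformers = x$n_conformers
  )
}

#' Tidy the Monte Carlo trace of a refinement run
#'
#' @param x A `shift_refinement`.
#' @param ... Unused.
#' @return The trace tibble (step, energy, log_lik, log_posterior,
#'   shift_rmsd, acceptance_rate).
#' @exportS3Method generics::tidy
tidy.shift_refinement <- function(x, ...) {
  x$trace
}

#' One-row summary of a refinement run
#'
#' @param x A `shift_refinement`.
#' @param ... Unused.
#' @return A tibble with steps, saved conformers, acceptance rate, final
#'   energy / shift RMSD and temperature.
#' @exportS3Method generics::glance
glance.shift_refinement <- function(x, ...) {
  last <- x$trace[nrow(x$trace), ]
  tibble::tibble(
    n_steps = x$n_steps,
    n_saved = length(x$ensemble),
    acceptance_rate = x$acceptance_rate,
    final_energy = last$energy,
    final_shift_rmsd = last$shift_rmsd,
    temperature = x$temperature
  )
}
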