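# Bayesian machinery: per-bond-class Gaussian likelihood, Boltzmann prior,
# and a generic Metropolis-Hastings engine. The structural sampler built on
# top of these lives in refine.R.

BOLTZMANN_KCAL <- 0.0019872041  # kcal mol^-1 K^-1

#' Per-bond-class likelihood standard deviations
#'
#' The uncertainty of the shift model depends on the primary hydrogen-bond
#' type: the amide-amide model is the best constrained (0.3 ppm) and the
#' solvent-exposed water model the crudest (1.2 ppm). Defaults (ppm):
#' backbone amide 0.3, side-chain amide 0.5, alcohol/carboxylate 0.8,
#' solvent-exposed or other 1.2.
#'
#' @param backbone_amide,sidechain_amide,alcohol,carboxylate,none Standard
#'   deviations in ppm (all > 0).
#' @return A named numeric vector of class `sigma_model` keyed by acceptor
#'   class.
#' @export
sigma_model <- function(backbone_amide = 0.3, sidechain_amide = 0.5,
                        alcohol = 0.8, carboxylate = 0.8, none = 1.2) {
  sm <- c(
    BACKBONE_AMIDE = backbone_amide,
    SIDECHAIN_AMIDE = sidechain_amide,
    ALCOHOL = alcohol,
    CARBOXYLATE = carboxylate,
    NONE = none
  )
  if (any(sm <= 0)) stop("all sigma values must be > 0", call. = FALSE)
  class(sm) <- "sigma_model"
  sm
}

#' Look up the likelihood sigma for acceptor classes
#'
#' @param sigma A [sigma_model()].
#' @param acceptor_class Character vector of acceptor classes.
#' @return Standard deviations in ppm.
#' @export
sigma_for_class <- function(sigma, acceptor_class) {
  out <- unclass(sigma)[acceptor_class]
  out[is.na(out)] <- unclass(sigma)[["NONE"]]
  unname(out)
}

#' Gaussian log-likelihood of experimental shifts given predictions
#'
#' `sum_i [ -d_i^2 / (2 sigma_i^2) - log(sigma_i sqrt(2 pi)) ]` where `d_i`
#' is the predicted-minus-experimental deviation of residue `i` and
#' `sigma_i` is chosen by the proton's primary-bond acceptor class.
#'
#' @param predicted Tibble from [predict_shifts()] (`resno`,
#'   `acceptor_class`, `total`).
#' @param experimental Tibble with `resno` and `shift` (ppm).
#' @param sigma A [sigma_model()].
#' @return The log-likelihood (a single number).
#' @export
shift_log_likelihood <- function(predicted, experimental,
                                 sigma = sigma_model()) {
  m <- dplyr::inner_join(predicted, experimental, by = "resno",
                         suffix = c("", ".exp"))
  if (nrow(m) < 1) stop("no matched residues", call. = FALSE)
  s <- sigma_for_class(sigma, m$acceptor_class)
  sum(stats::dnorm(m$total - m$shift, mean = 0, sd = s, log = TRUE))
}

#' Log-posterior of a structure state
#'
#' `-E / (k_B T) + log-likelihood`: the Boltzmann prior at temperature `T`
#' (kelvin, default 300) times the Gaussian shift likelihood, on the log
#' scale. With `log_lik = 0` (no data) this reduces to the prior alone.
#'
#' @param energy Prior energy in kcal/mol (finite).
#' @param log_lik Log-likelihood of the data given the structure.
#' @param temperature Temperature in kelvin.
#' @return The unnormalised log-posterior.
#' @export
log_posterior <- function(energy, log_lik = 0, temperature = 300) {
  if (!is.finite(energy)) return(-Inf)
  -energy / (BOLTZMANN_KCAL * temperature) + log_lik
}

#' Generic Metropolis-Hastings sampler
#'
#' Samples from an arbitrary target density using a symmetric proposal:
#' a move is accepted with probability `min(1, exp(delta log-target))`;
#' rejected moves restore the previous state bit-exactly. Used directly for
#' toy systems and as the acceptance rule inside [refine_structure()].
#'
#' @param init Initial state (any R object; numeric states are returned as a
#'   matrix of samples).
#' @param log_target Function `state -> log density` (may return `-Inf`).
#' @param propose Function `state -> new state`; must be symmetric.
#' @param n_steps Number of MH steps.
#' @param seed Optional integer seed for reproducibility.
#' @return A list with `states` (matrix for numeric states, else list),
#'   `log_target` (numeric vector), `accepted` (logical vector) and
#'   `acceptance_rate`.
#' @export
mh_sample <- function(init, log_target, propose, n_steps, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  state <- init
  lt <- log_target(state)
  if (!is.finite(lt)) stop("initial state has zero posterior density", call. = FALSE)
  numeric_state <- is.numeric(init)
  states <- if (numeric_state) {
    matrix(NA_real_, n_steps, length(init))
  } else {
    vector("list", n_steps)
  }
  lts <- numeric(n_steps)
  acc <- logical(n_steps)
  for (i in seq_len(n_steps)) {
    cand <- propose(state)
    lt_cand <- log_target(cand)
    if (is.finite(lt_cand) && log(stats::runif(1)) < lt_cand - lt) {
      state <- cand
      lt <- lt_cand
      acc[i] <- TRUE
    }
    if (numeric_state) states[i, ] <- state else states[[i]] <- state
    lts[i] <- lt
  }
  list(states = states, log_target = lts, accepted = acc,
       acceptance_rate = mean(acc))
}
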