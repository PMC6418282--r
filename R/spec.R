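#' Model specification
#'
#' Selects one of the spatial mark-resight model variants: generalized
#' (joint marking + resighting processes) versus conventional (resighting
#' only), with or without telemetry, one-time activity-centre transiency,
#' the observed-sex identity constraint on latent allocations, and
#' sex-specific detection-function parameters.
#'
#' The default augmentation size `A` follows common practice for these
#' variants: 250 for conventional models, 350 for generalized models with
#' telemetry, 600 for generalized models without telemetry; it can (and in
#' small studies should) be overridden.
#'
#' @param generalized model the marking process jointly (genSMR) rather
#'   than ignoring it (conSMR).
#' @param use_telemetry include telemetry locations of marked individuals.
#' @param use_transience one-time activity-centre relocation between the
#'   marking and resighting periods (truncated bivariate normal, scale
#'   `sigma_t`).
#' @param use_sex_constraint forbid latent-identity matches between
#'   unmarked detections of different observed sexes.
#' @param sex_specific sex-specific `lambda0_M`, `lambda0_R` and `sigma_d`.
#' @param A data-augmentation size (total potential individuals).
#' @return A `model_spec` list.
#' @export
model_spec <- function(generalized = TRUE, use_telemetry = TRUE,
                       use_transience = FALSE, use_sex_constraint = TRUE,
                       sex_specific = FALSE, A = NULL) {
  if (is.null(A)) {
    A <- if (!generalized) 250L else if (use_telemetry) 350L else 600L
  }
  structure(list(generalized = isTRUE(generalized),
                 use_telemetry = isTRUE(use_telemetry),
                 use_transience = isTRUE(use_transience),
                 use_sex_constraint = isTRUE(use_sex_constraint),
                 sex_specific = isTRUE(sex_specific),
                 A = as.integer(A)),
            class = "model_spec")
}

#' MCMC run configuration
#'
#' @param n_iter total sweeps.
#' @param burn_in sweeps discarded (must be < `n_iter`).
#' @param thin retain every `thin`-th post-burn-in sweep.
#' @param seed integer RNG seed, or `NULL` to continue the current stream.
#' @param tune adapt proposal scales during burn-in (frozen afterwards,
#'   preserving detailed balance of the retained chain).
#' @param proposal named list of initial random-walk proposal scales:
#'   `lambda0` and `sigma` (log scale), `s` (km), `sigma_t` (log scale).
#' @param fixed named list of parameters to hold fixed at given values
#'   instead of sampling (any of `lambda0_M`, `lambda0_R`, `sigma_d`,
#'   `sigma_t`, `psi`, `p_sex`); used for validation studies.
#' @param priors named list of prior settings: uniform upper bounds
#'   `lambda0_max`, `sigma_d_max`, `sigma_t_max`; `psi` and `p_sex` carry
#'   Beta(1, 1) priors.
#' @return An `mcmc_config` list.
#' @export
mcmc_config <- function(n_iter = 5000L, burn_in = 1000L, thin = 2L,
                        seed = NULL, tune = TRUE,
                        proposal = list(), fixed = list(), priors = list()) {
  if (burn_in >= n_iter) stop("'burn_in' must be smaller than 'n_iter'")
  if (thin < 1L) stop("'thin' must be >= 1")
  prop <- utils::modifyList(
    list(lambda0 = 0.3, sigma = 0.08, s = NULL, sigma_t = 0.3), proposal)
  pri <- utils::modifyList(
    list(lambda0_max = 10, sigma_d_max = 50, sigma_t_max = 100), priors)
  structure(list(n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 thin = as.integer(thin), seed = seed, tune = isTRUE(tune),
                 proposal = prop, fixed = fixed, priors = pri),
            class = "mcmc_config")
}
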