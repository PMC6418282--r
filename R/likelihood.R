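#' Half-normal detection rate
#'
#' The expected per-occasion detection rate at distance `d` from an
#' activity centre: `lambda0 * exp(-d^2 / (2 * sigma_d^2))`. The same
#' functional form is shared by the marking hazard and the resighting
#' Poisson rate; only the baseline differs by process.
#'
#' @param d distance(s) from activity centre (km, >= 0).
#' @param lambda0 baseline rate at distance zero (>= 0).
#' @param sigma_d spatial scale of the detection function (km, > 0).
#' @return Rate(s), same length as `d`.
#' @export
halfnormal_rate <- function(d, lambda0, sigma_d) {
  if (any(d < 0)) stop("'d' must be non-negative")
  if (lambda0 < 0) stop("'lambda0' must be >= 0")
  if (sigma_d <= 0) stop("'sigma_d' must be > 0")
  lambda0 * exp(-d^2 / (2 * sigma_d^2))
}

#' Convert a per-occasion hazard to a detection probability
#'
#' Complementary log-log link `1 - exp(-rate)`, turning the hazard
#' half-normal marking rate into the binomial success probability per
#' exposure occasion.
#'
#' @param rate non-negative hazard(s).
#' @return Probabilities in `[0, 1)`.
#' @export
hazard_to_prob <- function(rate) {
  if (any(rate < 0)) stop("'rate' must be >= 0")
  -expm1(-rate)
}

sqdist <- function(s, X) {
  # rows of s vs rows of X: n x J matrix of squared Euclidean distances
  outer(s[, 1L], X[, 1L], "-")^2 + outer(s[, 2L], X[, 2L], "-")^2
}

#' Marking-process log-likelihood
#'
#' Binomial log-likelihood of the summed live-trap capture histories:
#' `Y_M[i, j] ~ Binomial(E_M[i, j], 1 - exp(-lambda0_M * exp(-d_ij^2 / (2 sigma_d^2))))`
#' with `d_ij` the distance from individual i's marking-period activity
#' centre to live-trap j. Rows with all-zero histories (augmented
#' individuals with inclusion z = 1) contribute their zero-capture
#' probability.
#'
#' @param Y_M n x J^M matrix of capture counts.
#' @param s_M n x 2 matrix of marking-period activity centres (km).
#' @param lambda0_M baseline marking hazard; scalar or length-n vector.
#' @param sigma_d detection spatial scale (km); scalar or length-n vector.
#' @param E_M n x J^M exposure matrix (trap-days).
#' @param live_coords J^M x 2 live-trap coordinates.
#' @return Scalar log-likelihood.
#' @export
marking_loglik <- function(Y_M, s_M, lambda0_M, sigma_d, E_M, live_coords) {
  Y_M <- as.matrix(Y_M); E_M <- as.matrix(E_M); s_M <- as.matrix(s_M)
  if (any(Y_M > E_M)) stop("marking counts exceed exposure")
  if (any(Y_M < 0)) stop("negative marking counts")
  d2 <- sqdist(s_M, as.matrix(live_coords))
  p <- hazard_to_prob(lambda0_M * exp(-d2 / (2 * sigma_d^2)))
  sum(stats::dbinom(Y_M, size = E_M, prob = p, log = TRUE))
}

#' Resighting-process log-likelihood
#'
#' Poisson log-likelihood of the summed camera-trap counts:
#' `Y_R[i, j] ~ Poisson(E_R[i, j] * lambda0_R * exp(-d_ij^2 / (2 sigma_d^2)))`
#' with `d_ij` from individual i's resighting-period activity centre. With
#' sex-specific detection, supply per-individual `lambda0_R` and `sigma_d`
#' vectors.
#'
#' @param Y_R n x J^R matrix of counts (identified plus currently
#'   allocated latent-identity counts).
#' @param s_R n x 2 resighting-period activity centres (km).
#' @param lambda0_R baseline resighting rate; scalar or length-n vector.
#' @param sigma_d detection spatial scale (km); scalar or length-n vector.
#' @param E_R n x J^R exposure matrix (occasions).
#' @param camera_coords J^R x 2 camera coordinates.
#' @return Scalar log-likelihood.
#' @export
resighting_loglik <- function(Y_R, s_R, lambda0_R, sigma_d, E_R,
                              camera_coords) {
  Y_R <- as.matrix(Y_R); E_R <- as.matrix(E_R); s_R <- as.matrix(s_R)
  if (any(Y_R < 0)) stop("negative resighting counts")
  d2 <- sqdist(s_R, as.matrix(camera_coords))
  mu <- E_R * (lambda0_R * exp(-d2 / (2 * sigma_d^2)))
  sum(stats::dpois(Y_R, lambda = mu, log = TRUE))
}

#' Telemetry log-likelihood
#'
#' Independent bivariate normal log-density of the thinned telemetry
#' locations of each marked individual, centred on its (resighting-period)
#' activity centre with per-axis standard deviation `sigma_d`. Telemetry
#' locations are not truncated to the state space.
#'
#' @param telemetry data frame with columns `individual`, `x`, `y`.
#' @param s n x 2 activity centres; row i is individual i's centre.
#' @param sigma_d spatial scale (km, > 0); scalar or length-n vector.
#' @return Scalar log-likelihood.
#' @export
telemetry_loglik <- function(telemetry, s, sigma_d) {
  if (sigma_d[1L] <= 0 || any(sigma_d <= 0)) stop("'sigma_d' must be > 0")
  if (nrow(telemetry) == 0L) return(0)
  s <- as.matrix(s)
  idx <- telemetry$individual
  if (any(idx < 1L | idx > nrow(s)))
    stop("telemetry refers to an individual without an activity centre")
  sig <- if (length(sigma_d) == 1L) rep(sigma_d, nrow(s)) else sigma_d
  sum(stats::dnorm(telemetry$x, s[idx, 1L], sig[idx], log = TRUE) +
      stats::dnorm(telemetry$y, s[idx, 2L], sig[idx], log = TRUE))
}

#' Truncation mass of the transiency kernel
#'
#' Probability that a bivariate normal with diagonal covariance
#' `sigma_t^2 I` centred at `s_M` falls inside the state-space rectangle:
#' the product of two one-dimensional normal-CDF differences.
#'
#' @param s_M n x 2 matrix of kernel centres.
#' @param sigma_t transiency scale (km, > 0).
#' @param ss a [make_state_space()] object.
#' @return Length-n vector of probabilities.
#' @export
transience_truncmass <- function(s_M, sigma_t, ss) {
  s_M <- rbind(s_M)
  (stats::pnorm(ss$xmax, s_M[, 1L], sigma_t) -
     stats::pnorm(ss$xmin, s_M[, 1L], sigma_t)) *
    (stats::pnorm(ss$ymax, s_M[, 2L], sigma_t) -
       stats::pnorm(ss$ymin, s_M[, 2L], sigma_t))
}

#' Log-density of the truncated activity-centre relocation kernel
#'
#' One-time activity-centre transiency between the marking and resighting
#' periods: `s_R ~ BVN(s_M, sigma_t^2 I)` truncated to the state-space
#' rectangle. The normalizing constant is computed exactly via
#' [transience_truncmass()].
#'
#' @param s_R,s_M n x 2 matrices of resighting- and marking-period centres.
#' @param sigma_t transiency scale (km, > 0).
#' @param ss a [make_state_space()] object.
#' @return Length-n vector of log-densities; `-Inf` where `s_R` falls
#'   outside the rectangle.
#' @export
transience_logdensity <- function(s_R, s_M, sigma_t, ss) {
  if (sigma_t <= 0) stop("'sigma_t' must be > 0")
  s_R <- rbind(s_R); s_M <- rbind(s_M)
  inside <- s_R[, 1L] >= ss$xmin & s_R[, 1L] <= ss$xmax &
    s_R[, 2L] >= ss$ymin & s_R[, 2L] <= ss$ymax
  out <- stats::dnorm(s_R[, 1L], s_M[, 1L], sigma_t, log = TRUE) +
    stats::dnorm(s_R[, 2L], s_M[, 2L], sigma_t, log = TRUE) -
    log(transience_truncmass(s_M, sigma_t, ss))
  out[!inside] <- -Inf
  out
}

#' Bernoulli log-priors for sex and inclusion
#'
#' Sum of independent Bernoulli log-probability masses over the augmented
#' population: `sex_i ~ Bernoulli(p_sex)` (1 = female) and
#' `z_i ~ Bernoulli(psi)` for the data-augmentation inclusion indicators.
#'
#' @param sex binary vector (1 = female).
#' @param p_sex probability that an individual is female.
#' @return Scalar log-probability.
#' @export
sex_logprior <- function(sex, p_sex) {
  if (p_sex < 0 || p_sex > 1) stop("'p_sex' must be in [0, 1]")
  sum(stats::dbinom(sex, 1L, p_sex, log = TRUE))
}

#' @rdname sex_logprior
#' @param z binary inclusion vector.
#' @param psi inclusion probability.
#' @export
inclusion_logprior <- function(z, psi) {
  if (psi <= 0 || psi >= 1) stop("'psi' must be in (0, 1)")
  sum(stats::dbinom(z, 1L, psi, log = TRUE))
}
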