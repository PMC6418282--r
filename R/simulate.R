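#' Simulate a population of activity centres
#'
#' Activity centres are uniform on the rectangular state space; sexes are
#' independent Bernoulli(`p_sex`) draws (1 = female). Abundance is either
#' fixed (`N`) or Poisson with mean `density_per_100km2 * area / 100`.
#'
#' @param ss a [make_state_space()] object.
#' @param density_per_100km2 expected density (individuals / 100 km^2);
#'   mutually exclusive with `N`.
#' @param N fixed abundance.
#' @param p_sex probability an individual is female.
#' @param seed optional RNG seed.
#' @return A `population_truth` list with `N`, `s_M` (N x 2), `s_R`
#'   (initially equal to `s_M`), `sex`, `marked`, `mark_occasion`,
#'   `death_occasion`.
#' @export
simulate_population <- function(ss, density_per_100km2 = NULL, N = NULL,
                                p_sex = 0.33, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (!is.null(density_per_100km2) && !is.null(N))
    stop("supply either 'density_per_100km2' or 'N', not both")
  if (is.null(density_per_100km2) && is.null(N))
    stop("supply 'density_per_100km2' or 'N'")
  if (p_sex < 0 || p_sex > 1) stop("'p_sex' must be in [0, 1]")
  if (!is.null(N)) {
    if (N < 1) stop("'N' must be >= 1")
    N <- as.integer(N)
  } else {
    if (density_per_100km2 <= 0) stop("density must be positive")
    N <- stats::rpois(1L, density_per_100km2 * ss$area / 100)
  }
  s <- cbind(x = stats::runif(N, ss$xmin, ss$xmax),
             y = stats::runif(N, ss$ymin, ss$ymax))
  structure(list(N = N, s_M = s, s_R = s,
                 sex = stats::rbinom(N, 1L, p_sex),
                 marked = logical(N),
                 mark_occasion = rep(NA_integer_, N),
                 death_occasion = rep(Inf, N), ss = ss),
            class = "population_truth")
}

#' Simulate the live-trap marking process
#'
#' Binomial captures with a hazard half-normal per-day capture
#' probability: `Y_M[i, j] ~ Binomial(days_j, 1 - exp(-lambda0_M *
#' exp(-d_ij^2 / (2 sigma_d^2))))`. Individuals with at least one capture
#' form the marked set (optionally capped at `n_M_target` randomly chosen
#' captured individuals; the remainder are treated as never captured).
#'
#' @param truth a `population_truth`.
#' @param live_traps a live-trap [trap_array()]; its operation rows are
#'   summed to per-trap effort days.
#' @param lambda0_M baseline per-day marking hazard.
#' @param sigma_d detection spatial scale (km).
#' @param n_M_target optional cap on the number of marked individuals.
#' @param seed optional RNG seed.
#' @return Updated truth with `marked`, `mark_occasion = 1` for marked
#'   individuals, and attached `Y_M` (n_M x J^M, marked rows only).
#' @export
simulate_marking <- function(truth, live_traps, lambda0_M, sigma_d,
                             n_M_target = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (lambda0_M < 0 || sigma_d <= 0) stop("invalid detection parameters")
  days <- rowSums(live_traps$operation)
  d2 <- sqdist(truth$s_M, live_traps$coords)
  p <- hazard_to_prob(lambda0_M * exp(-d2 / (2 * sigma_d^2)))
  Y <- matrix(stats::rbinom(length(p), size = rep(days, each = truth$N),
                            prob = p), truth$N, length(days))
  captured <- which(rowSums(Y) > 0L)
  if (!is.null(n_M_target) && length(captured) > n_M_target) {
    keep <- sort(sample(captured, n_M_target))
    Y[setdiff(captured, keep), ] <- 0L
    captured <- keep
  }
  truth$marked <- seq_len(truth$N) %in% captured
  truth$mark_occasion[captured] <- 1L
  truth$Y_M <- Y[captured, , drop = FALSE]
  truth$marked_ids <- captured
  truth
}

#' Simulate one-time activity-centre transiency
#'
#' Relocates every individual's resighting-period activity centre by a
#' bivariate normal step of scale `sigma_t`, truncated to the state-space
#' rectangle by rejection. `sigma_t = 0` leaves centres unchanged.
#'
#' @param truth a `population_truth`.
#' @param sigma_t transiency scale (km, >= 0).
#' @param ss state space (defaults to the one stored in `truth`).
#' @param seed optional RNG seed.
#' @return Updated truth with relocated `s_R`.
#' @export
simulate_transience <- function(truth, sigma_t, ss = truth$ss, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (sigma_t < 0) stop("'sigma_t' must be >= 0")
  if (sigma_t == 0) { truth$s_R <- truth$s_M; return(truth) }
  truth$s_R <- rtnorm2_rect(truth$s_M, sigma_t, ss)
  truth
}

# vectorized rejection sampler for BVN(centre, sig^2 I) truncated to rect
rtnorm2_rect <- function(centres, sig, ss) {
  n <- nrow(centres)
  out <- matrix(NA_real_, n, 2L)
  todo <- seq_len(n)
  while (length(todo)) {
    prop <- centres[todo, , drop = FALSE] +
      matrix(stats::rnorm(2L * length(todo), 0, sig), ncol = 2L)
    ok <- prop[, 1L] >= ss$xmin & prop[, 1L] <= ss$xmax &
      prop[, 2L] >= ss$ymin & prop[, 2L] <= ss$ymax
    out[todo[ok], ] <- prop[ok, , drop = FALSE]
    todo <- todo[!ok]
  }
  colnames(out) <- c("x", "y")
  out
}

#' Simulate the camera-trap resighting process
#'
#' Occasion-level Poisson counts with rate `lambda0_R *
#' exp(-d_ij^2 / (2 sigma_d^2))` per operating occasion, using
#' resighting-period activity centres. Detections of individuals while
#' marked keep their identity; all other detections are emitted as
#' identity-free unmarked records whose observed sex equals the true sex
#' with probability `p_sex_observed` and is unknown otherwise. Dead
#' individuals are not detected.
#'
#' @param truth a `population_truth` (after [simulate_marking()] and
#'   optionally [simulate_transience()]).
#' @param cameras a camera [trap_array()] with a J^R x K^R operation
#'   schedule.
#' @param lambda0_R baseline per-occasion resighting rate.
#' @param sigma_d detection spatial scale (km).
#' @param p_sex_observed probability the sex of an unmarked detection is
#'   identified.
#' @param seed optional RNG seed.
#' @return List with `marked_resights` (data frame `individual` (1..n_M),
#'   `trap`, `occasion`) and `U` (data frame `trap`, `occasion`,
#'   `obs_sex` in \{"F","M","U"\}, `true_individual`).
#' @export
simulate_resighting <- function(truth, cameras, lambda0_R, sigma_d,
                                p_sex_observed = 0.52, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (lambda0_R < 0 || sigma_d <= 0) stop("invalid detection parameters")
  if (p_sex_observed < 0 || p_sex_observed > 1)
    stop("'p_sex_observed' must be in [0, 1]")
  op <- cameras$operation
  K <- ncol(op)
  d2 <- sqdist(truth$s_R, cameras$coords)
  lam <- lambda0_R * exp(-d2 / (2 * sigma_d^2))   # N x J
  marked_idx <- match(seq_len(truth$N), truth$marked_ids)  # NA if unmarked
  recs <- vector("list", K)
  for (k in seq_len(K)) {
    alive <- truth$death_occasion > k
    mu <- lam * rep(op[, k], each = truth$N) * alive
    cnt <- stats::rpois(length(mu), mu)
    nz <- which(cnt > 0L)
    if (!length(nz)) next
    i <- ((nz - 1L) %% truth$N) + 1L
    j <- ((nz - 1L) %/% truth$N) + 1L
    recs[[k]] <- data.frame(individual = rep(i, cnt[nz]),
                            trap = rep(j, cnt[nz]), occasion = k)
  }
  recs <- do.call(rbind, recs)
  if (is.null(recs))
    recs <- data.frame(individual = integer(), trap = integer(),
                       occasion = integer())
  is_marked_now <- truth$marked[recs$individual] &
    recs$occasion >= truth$mark_occasion[recs$individual] &
    !is.na(truth$mark_occasion[recs$individual])
  is_marked_now[is.na(is_marked_now)] <- FALSE
  mr <- recs[is_marked_now, , drop = FALSE]
  marked_resights <- data.frame(individual = marked_idx[mr$individual],
                                trap = mr$trap, occasion = mr$occasion)
  um <- recs[!is_marked_now, , drop = FALSE]
  n_u <- nrow(um)
  known <- stats::runif(n_u) < p_sex_observed
  obs_sex <- rep("U", n_u)
  obs_sex[known] <- ifelse(truth$sex[um$individual[known]] == 1L, "F", "M")
  U <- data.frame(trap = um$trap, occasion = um$occasion, obs_sex = obs_sex,
                  true_individual = um$individual)
  list(marked_resights = marked_resights, U = U)
}

#' Simulate telemetry locations for marked individuals
#'
#' For each marked, collared, alive individual and each resighting
#' occasion, emits (with probability `1 - missingness`) one location drawn
#' from a bivariate normal centred on the individual's resighting-period
#' activity centre with per-axis SD `sigma_d`; locations are not truncated
#' to the state space. This emulates GPS fixes already thinned to one
#' location per occasion.
#'
#' @param truth a `population_truth` after [simulate_marking()].
#' @param sigma_d spatial scale (km).
#' @param K_R number of resighting occasions.
#' @param missingness per-occasion probability of no retained fix.
#' @param seed optional RNG seed.
#' @return Data frame `individual` (1..n_M), `occasion`, `x`, `y`.
#' @export
simulate_telemetry <- function(truth, sigma_d, K_R = 17L, missingness = 0.15,
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (sigma_d <= 0) stop("'sigma_d' must be > 0")
  ids <- truth$marked_ids
  if (is.null(ids) || !length(ids))
    return(data.frame(individual = integer(), occasion = integer(),
                      x = numeric(), y = numeric()))
  grid <- expand.grid(m = seq_along(ids), occasion = seq_len(K_R))
  tru_i <- ids[grid$m]
  ok <- grid$occasion >= truth$mark_occasion[tru_i] &
    grid$occasion < truth$death_occasion[tru_i] &
    stats::runif(nrow(grid)) >= missingness
  grid <- grid[ok, , drop = FALSE]
  tru_i <- tru_i[ok]
  data.frame(individual = grid$m, occasion = grid$occasion,
             x = stats::rnorm(nrow(grid), truth$s_R[tru_i, 1L], sigma_d),
             y = stats::rnorm(nrow(grid), truth$s_R[tru_i, 2L], sigma_d))
}

#' Simulate a complete spatial mark-resight dataset
#'
#' Runs the full generative chain -- population, marking, optional
#' transiency, resighting, telemetry -- and assembles an `smr_data` object
#' ready for [run_mcmc()], plus the generating truth. Defaults emulate a
#' large semi-arid puma study: density 0.84 individuals / 100 km^2, a
#' clustered camera array, ~30 live-traps, 17 weekly resighting occasions,
#' and detection parameters `lambda0_M = 0.007` per trap-day,
#' `lambda0_R = 0.019` per occasion, `sigma_d = 6.51` km,
#' `sigma_t = 17.4` km, `p_sex = 0.33`, with sex identified for 52% of
#' unmarked detections.
#'
#' @param live_traps,cameras [trap_array()] objects.
#' @param ss state space; default buffers both arrays by `buffer_km`.
#' @param density_per_100km2,N population size specification (see
#'   [simulate_population()]).
#' @param lambda0_M,lambda0_R,sigma_d,sigma_t,p_sex,p_sex_observed
#'   generating parameters.
#' @param n_M_target optional cap on marked individuals.
#' @param events optional data frame (`individual` = marked index,
#'   `occasion`, `event` in \{"marked","died"\}) of known mid-survey
#'   markings and deaths, applied to the realized marked set.
#' @param telemetry_missingness per-occasion telemetry missingness.
#' @param buffer_km state-space buffer when `ss` is NULL.
#' @param seed optional RNG seed.
#' @return List with elements `data` (class `smr_data`) and `truth`.
#' @export
simulate_smr <- function(live_traps, cameras, ss = NULL,
                         density_per_100km2 = 0.84, N = NULL,
                         lambda0_M = 0.007, lambda0_R = 0.019,
                         sigma_d = 6.51, sigma_t = 17.4, p_sex = 0.33,
                         p_sex_observed = 0.52, n_M_target = NULL,
                         events = NULL, telemetry_missingness = 0.15,
                         buffer_km = 25, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(ss)) ss <- make_state_space(live_traps, cameras,
                                          buffer_km = buffer_km)
  truth <- simulate_population(ss, density_per_100km2 = density_per_100km2,
                               N = N, p_sex = p_sex)
  truth <- simulate_marking(truth, live_traps, lambda0_M, sigma_d,
                            n_M_target = n_M_target)
  if (sigma_t > 0) truth <- simulate_transience(truth, sigma_t, ss)
  n_M <- length(truth$marked_ids)
  K_R <- ncol(cameras$operation)

  # apply known mid-survey markings / deaths to the realized marked set
  if (!is.null(events) && nrow(events) > 0L && n_M > 0L) {
    events <- events[events$individual <= n_M, , drop = FALSE]
    for (r in seq_len(nrow(events))) {
      tid <- truth$marked_ids[events$individual[r]]
      if (events$event[r] == "marked")
        truth$mark_occasion[tid] <- events$occasion[r]
      else if (events$event[r] == "died")
        truth$death_occasion[tid] <- events$occasion[r]
    }
  }

  res <- simulate_resighting(truth, cameras, lambda0_R, sigma_d,
                             p_sex_observed = p_sex_observed)
  tel <- simulate_telemetry(truth, sigma_d, K_R = K_R,
                            missingness = telemetry_missingness)
  exposure <- build_exposure(live_traps$operation, cameras$operation,
                             n_marked = n_M, events = events)
  data <- smr_data(live_traps = live_traps, cameras = cameras,
                   Y_M = truth$Y_M,
                   marked_resights = res$marked_resights,
                   U = res$U, telemetry = tel,
                   sex_marked = truth$sex[truth$marked_ids],
                   exposure = exposure)
  truth$params <- list(lambda0_M = lambda0_M, lambda0_R = lambda0_R,
                       sigma_d = sigma_d, sigma_t = sigma_t, p_sex = p_sex,
                       D = truth$N / ss$area * 100)
  list(data = data, truth = truth)
}

#' Assemble a spatial mark-resight dataset
#'
#' Container for everything a model fit needs: detector arrays, the marked
#' capture histories, identified resightings of marked individuals,
#' identity-free unmarked detection records, thinned telemetry, the sexes
#' of marked individuals, and the exposure/mark-status matrices.
#'
#' @param live_traps live-trap [trap_array()] (may be NULL for
#'   conventional-SMR-only data).
#' @param cameras camera [trap_array()].
#' @param Y_M n_M x J^M summed marking counts.
#' @param marked_resights data frame `individual`, `trap`, `occasion` of
#'   identified detections of marked individuals.
#' @param U data frame `trap`, `occasion`, `obs_sex` ("F"/"M"/"U") of
#'   unmarked detection records; an optional `true_individual` column is
#'   carried along but never used in fitting.
#' @param telemetry data frame `individual`, `occasion`, `x`, `y`.
#' @param sex_marked length-n_M binary or "F"/"M" vector.
#' @param exposure result of [build_exposure()].
#' @return Object of class `smr_data`.
#' @export
smr_data <- function(live_traps = NULL, cameras, Y_M = NULL,
                     marked_resights, U, telemetry = NULL, sex_marked,
                     exposure) {
  if (is.character(sex_marked)) sex_marked <- as.integer(sex_marked == "F")
  n_M <- length(sex_marked)
  if (!is.null(Y_M)) {
    Y_M <- as.matrix(Y_M)
    if (nrow(Y_M) != n_M) stop("Y_M rows must match marked individuals")
    if (any(Y_M > exposure$E_M)) stop("marking counts exceed exposure")
  }
  if (nrow(marked_resights) > 0L &&
      any(marked_resights$individual < 1L | marked_resights$individual > n_M))
    stop("marked_resights refers to unknown individuals")
  if (!all(U$obs_sex %in% c("F", "M", "U")))
    stop("U$obs_sex must be 'F', 'M' or 'U'")
  structure(list(live_traps = live_traps, cameras = cameras, Y_M = Y_M,
                 marked_resights = marked_resights, U = U,
                 telemetry = telemetry, sex_marked = sex_marked,
                 exposure = exposure, n_M = n_M,
                 K_R = ncol(cameras$operation)),
            class = "smr_data")
}

#' @export
print.smr_data <- function(x, ...) {
  cat(sprintf(paste0("<smr_data> %d marked, %d identified resights, ",
                     "%d unmarked records, %d telemetry fixes\n"),
              x$n_M, nrow(x$marked_resights), nrow(x$U),
              if (is.null(x$telemetry)) 0L else nrow(x$telemetry)))
  invisible(x)
}
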