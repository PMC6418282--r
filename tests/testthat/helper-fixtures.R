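# Shared fixtures: a tiny enumerable mark-resight instance and its
# brute-force oracle, plus small array builders used across test files.

tiny_params <- list(lambda0_M = 0.3, lambda0_R = 0.3, sigma_d = 2,
                    psi = 0.6, K = 5L, days = 5L)

tiny_arrays <- function() {
  list(cams = trap_array(rbind(c(4, 5), c(6, 5)), "camera",
                         matrix(1, 2, tiny_params$K)),
       live = trap_array(rbind(c(5, 5)), "live",
                         matrix(tiny_params$days, 1, 1)),
       ss = structure(list(xmin = 0, xmax = 10, ymin = 0, ymax = 10,
                           area = 100), class = "state_space"))
}

# one marked individual (one live capture, one identified resight) plus
# two identity-free unmarked records at different cameras/occasions
tiny_instance <- function(obs_sex = c("U", "U")) {
  ar <- tiny_arrays()
  expo <- build_exposure(ar$live$operation, ar$cams$operation, n_marked = 1)
  dat <- smr_data(live_traps = ar$live, cameras = ar$cams,
                  Y_M = matrix(1, 1, 1),
                  marked_resights = data.frame(individual = 1L, trap = 1L,
                                               occasion = 2L),
                  U = data.frame(trap = c(1L, 2L), occasion = c(1L, 3L),
                                 obs_sex = obs_sex),
                  telemetry = NULL, sex_marked = 1L, exposure = expo)
  c(ar, list(dat = dat))
}

# exact posterior over N for the tiny instance: enumeration over record
# allocations and inclusion states, with activity centres integrated
# numerically over a grid of the state space (independent of the sampler)
tiny_oracle_pN <- function(ngrid = 15L) {
  p <- tiny_params
  ar <- tiny_arrays()
  w <- (ar$ss$xmax - ar$ss$xmin) / ngrid
  gx <- seq(ar$ss$xmin + w / 2, ar$ss$xmax - w / 2, length.out = ngrid)
  grid <- as.matrix(expand.grid(gx, gx))
  d2 <- function(X) outer(grid[, 1], X[, 1], "-")^2 +
    outer(grid[, 2], X[, 2], "-")^2
  hM <- exp(-d2(ar$live$coords) / (2 * p$sigma_d^2))
  hR <- exp(-d2(ar$cams$coords) / (2 * p$sigma_d^2))
  p0M <- dbinom(0, p$days, 1 - exp(-p$lambda0_M * hM[, 1]))
  G <- function(y) mean(p0M * dpois(y[1], p$K * p$lambda0_R * hR[, 1]) *
                          dpois(y[2], p$K * p$lambda0_R * hR[, 2]))
  G0 <- G(c(0, 0))
  q <- p$psi * G0 / (p$psi * G0 + 1 - p$psi)
  pN <- numeric(4)
  for (o1 in 2:4) for (o2 in 2:4) {   # marked individual ineligible (m = 1)
    owners <- unique(c(o1, o2))
    y <- list(`2` = c(0, 0), `3` = c(0, 0), `4` = c(0, 0))
    y[[as.character(o1)]][1] <- y[[as.character(o1)]][1] + 1
    y[[as.character(o2)]][2] <- y[[as.character(o2)]][2] + 1
    nf <- 3L - length(owners)
    W <- prod(vapply(owners, function(i) p$psi * G(y[[as.character(i)]]),
                     0)) * (p$psi * G0 + 1 - p$psi)^nf
    base <- 1L + length(owners)
    for (k in 0:nf)
      pN[base + k] <- pN[base + k] + W * dbinom(k, nf, q)
  }
  pN / sum(pN)
}

# small clustered camera design with live traps inside the camera extent
small_study <- function(n_clusters = 4, n_live = 12, live_days = 22,
                        K = 17, seed = 1) {
  set.seed(seed)
  cams <- make_clustered_design(n_clusters, 3, 3, 3.5, cluster_dx_km = 28,
                                cluster_dy_km = c(36, 45), n_occasions = K)
  ext <- apply(cams$coords, 2, range)
  live <- trap_array(cbind(runif(n_live, ext[1, 1], ext[2, 1]),
                           runif(n_live, ext[1, 2], ext[2, 2])),
                     kind = "live",
                     operation = matrix(live_days, n_live, 1))
  list(cams = cams, live = live)
}
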