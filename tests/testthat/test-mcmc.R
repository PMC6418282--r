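test_that("latent allocation respects sex exclusion, mark status and conservation", {
  # two known-sex records of opposite sex plus unknowns, small instance
  ti <- tiny_instance(obs_sex = c("F", "M"))
  spec <- model_spec(generalized = TRUE, use_telemetry = FALSE,
                     use_transience = FALSE, use_sex_constraint = TRUE,
                     A = 6)
  cfg <- mcmc_config(n_iter = 4000, burn_in = 500, thin = 1, seed = 51,
                     fixed = list(lambda0_M = 0.3, lambda0_R = 0.3,
                                  sigma_d = 2, psi = 0.6),
                     proposal = list(s = 2))
  ch <- run_mcmc(ti$dat, ti$ss, spec, cfg, keep_latent = TRUE)
  la <- ch$latent
  # an unmarked F record and an unmarked M record never share an owner
  expect_false(any(la$alloc[, 1] == la$alloc[, 2]))
  # owners carry the sex their known-sex records require, in every draw
  expect_true(all(la$owner_sex[, 1] == 1L))
  expect_true(all(la$owner_sex[, 2] == 0L))
  # the marked individual (m = 1 throughout) never owns latent records
  expect_false(any(la$alloc == 1L))
  # owners are always included (z = 1)
  expect_true(all(la$z[cbind(rep(seq_len(nrow(la$alloc)), 2),
                             as.vector(la$alloc))] == 1L))
  # abundance never falls below the number of distinct observed individuals
  n_obs <- 1L + apply(la$alloc, 1, function(a) length(unique(a)))
  expect_true(all(ch$draws[, "N"] >= n_obs))
})

test_that("a record at all-marked occasions can only go to augmented individuals", {
  # marked individual unmarked for occasions 1-2 only (marked at 3)
  ar <- tiny_arrays()
  expo <- build_exposure(ar$live$operation, ar$cams$operation, 1,
                         events = data.frame(individual = 1L, occasion = 3L,
                                             event = "marked"))
  dat <- smr_data(live_traps = ar$live, cameras = ar$cams,
                  Y_M = matrix(1, 1, 1),
                  marked_resights = data.frame(individual = 1L, trap = 1L,
                                               occasion = 4L),
                  U = data.frame(trap = c(1L, 1L), occasion = c(2L, 5L),
                                 obs_sex = c("U", "U")),
                  telemetry = NULL, sex_marked = 1L, exposure = expo)
  spec <- model_spec(TRUE, FALSE, FALSE, TRUE, A = 5)
  cfg <- mcmc_config(n_iter = 3000, burn_in = 500, thin = 1, seed = 52,
                     fixed = list(lambda0_M = 0.3, lambda0_R = 0.3,
                                  sigma_d = 2, psi = 0.6),
                     proposal = list(s = 2))
  ch <- run_mcmc(dat, ar$ss, spec, cfg, keep_latent = TRUE)
  # record at occasion 5 (marked individual has code 1): augmented only
  expect_false(any(ch$latent$alloc[, 2] == 1L))
  # record at occasion 2 (code 0) may be owned by the marked individual
  expect_true(any(ch$latent$alloc[, 1] == 1L))
})

test_that("two equally placed eligible owners split a record evenly", {
  # one unknown-sex record, two augmented individuals, symmetric geometry,
  # everything else pinned: long-run ownership frequencies are 1/2 each
  ar <- tiny_arrays()
  expo <- build_exposure(ar$live$operation, ar$cams$operation, 1)
  dat <- smr_data(live_traps = ar$live, cameras = ar$cams,
                  Y_M = matrix(1, 1, 1),
                  marked_resights = data.frame(individual = 1L, trap = 1L,
                                               occasion = 2L),
                  U = data.frame(trap = 1L, occasion = 1L, obs_sex = "U"),
                  telemetry = NULL, sex_marked = 1L, exposure = expo)
  spec <- model_spec(TRUE, FALSE, FALSE, FALSE, A = 3)
  cfg <- mcmc_config(n_iter = 20000, burn_in = 1000, thin = 1, seed = 53,
                     fixed = list(lambda0_M = 0.3, lambda0_R = 0.3,
                                  sigma_d = 2, psi = 0.999),
                     proposal = list(s = 2))
  ch <- suppressWarnings(run_mcmc(dat, ar$ss, spec, cfg,
                                  keep_latent = TRUE))
  f2 <- mean(ch$latent$alloc[, 1] == 2L)
  expect_equal(f2, 0.5, tolerance = 0.05)
})

test_that("degenerate and reproducibility behaviour of the null SCR fitter", {
  d <- make_clustered_design(1, 2, 2, 4, n_occasions = 5)
  ss <- make_state_space(d, buffer_km = 10)
  # zero detections: sampler completes, posterior driven by the prior
  ch0 <- fit_null_scr(matrix(0, 0, 4), d, ss,
                      mcmc_config(n_iter = 400, burn_in = 100, thin = 1,
                                  seed = 54), A = 40)
  expect_equal(nrow(ch0$draws), 300L)
  expect_true(all(ch0$draws[, "N"] >= 0))
  # same data, same seed: bit-identical chains
  sim <- simulate_scr(d, ss, D = 20, lambda0 = 0.3, sigma = 3, seed = 55)
  cfg <- mcmc_config(n_iter = 500, burn_in = 100, thin = 2, seed = 56)
  chA <- fit_null_scr(sim$counts, d, ss, cfg, A = 80)
  chB <- fit_null_scr(sim$counts, d, ss, cfg, A = 80)
  expect_identical(chA$draws, chB$draws)
  # D is N / area * 100 exactly, draw by draw
  expect_equal(chA$draws[, "D"],
               chA$draws[, "N"] / ss$area * 100)
})

test_that("more unmarked detections at a camera do not lower detected-unmarked counts", {
  ar <- tiny_arrays()
  expo <- build_exposure(ar$live$operation, ar$cams$operation, 1)
  base_U <- data.frame(trap = c(1L, 2L), occasion = c(1L, 3L),
                       obs_sex = c("U", "U"))
  more_U <- rbind(base_U,
                  data.frame(trap = 1L, occasion = c(2L, 4L),
                             obs_sex = c("U", "U")))
  fit <- function(U) {
    dat <- smr_data(live_traps = ar$live, cameras = ar$cams,
                    Y_M = matrix(1, 1, 1),
                    marked_resights = data.frame(individual = 1L, trap = 1L,
                                                 occasion = 2L),
                    U = U, telemetry = NULL, sex_marked = 1L,
                    exposure = expo)
    spec <- model_spec(TRUE, FALSE, FALSE, FALSE, A = 8)
    cfg <- mcmc_config(n_iter = 6000, burn_in = 1000, thin = 1, seed = 57,
                       fixed = list(lambda0_M = 0.3, lambda0_R = 0.3,
                                    sigma_d = 2, psi = 0.6),
                       proposal = list(s = 2))
    mean(run_mcmc(dat, ar$ss, spec, cfg)$draws[, "n_UM"])
  }
  expect_gte(fit(more_U), fit(base_U))
})

test_that("data inconsistencies are rejected before sampling", {
  ti <- tiny_instance()
  # identified resight at an occasion where the animal was not yet marked
  ar <- tiny_arrays()
  expo <- build_exposure(ar$live$operation, ar$cams$operation, 1,
                         events = data.frame(individual = 1L, occasion = 4L,
                                             event = "marked"))
  expect_error(
    run_mcmc(smr_data(live_traps = ar$live, cameras = ar$cams,
                      Y_M = matrix(1, 1, 1),
                      marked_resights = data.frame(individual = 1L,
                                                   trap = 1L, occasion = 2L),
                      U = ti$dat$U, telemetry = NULL, sex_marked = 1L,
                      exposure = expo),
             ti$ss, model_spec(A = 5), mcmc_config(n_iter = 10,
                                                   burn_in = 1)),
    "not marked")
  # augmentation must exceed the marked sample
  expect_error(run_mcmc(ti$dat, ti$ss, model_spec(A = 1),
                        mcmc_config(n_iter = 10, burn_in = 1)),
               "exceed")
})
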