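ss10 <- structure(list(xmin = 0, xmax = 100, ymin = 0, ymax = 100,
                       area = 1e4), class = "state_space")

test_that("population generator hits its density, uniformity and sex targets", {
  tr <- simulate_population(ss10, N = 100, p_sex = 0.5, seed = 1)
  expect_equal(tr$N, 100L)
  expect_equal(tr$N / ss10$area * 100, 1.00)        # realized density exact
  expect_true(all(tr$s_M[, 1] >= 0 & tr$s_M[, 1] <= 100))
  expect_error(simulate_population(ss10, density_per_100km2 = 1, N = 10),
               "not both")
  expect_true(all(simulate_population(ss10, N = 50, p_sex = 0,
                                      seed = 2)$sex == 0))
  # female fraction under replication: binomial expectation 0.33
  set.seed(3)
  fr <- replicate(300, mean(simulate_population(ss10, N = 500,
                                                p_sex = 0.33)$sex))
  mc_se <- sqrt(0.33 * 0.67 / 500) / sqrt(300)
  expect_lt(abs(mean(fr) - 0.33), 4 * mc_se)
})

test_that("marking process follows the hazard half-normal binomial model", {
  lt <- trap_array(rbind(c(50, 50)), "live", matrix(1, 1, 1))
  tr <- simulate_population(ss10, N = 200, p_sex = 0.5, seed = 4)
  tr0 <- simulate_marking(tr, lt, lambda0_M = 0, sigma_d = 5)
  expect_equal(sum(tr0$marked), 0L)
  expect_equal(nrow(tr0$Y_M), 0L)
  # per-day capture probability at distance zero
  expect_equal(hazard_to_prob(0.05), 0.04877058, tolerance = 1e-6)
  # Monte-Carlo check of expected captures against the closed form
  set.seed(5)
  tr$s_M[1, ] <- c(50, 50)                 # individual on the trap
  lt20 <- trap_array(rbind(c(50, 50)), "live", matrix(20, 1, 1))
  hits <- replicate(400, {
    t2 <- simulate_marking(tr, lt20, lambda0_M = 0.05, sigma_d = 5)
    t2$Y_M[match(1, t2$marked_ids), 1]
  })
  hits[is.na(hits)] <- 0
  expect_equal(mean(hits), 20 * hazard_to_prob(0.05), tolerance = 0.08)
  # capping the marked set
  t3 <- simulate_marking(tr, lt20, lambda0_M = 2, sigma_d = 30,
                         n_M_target = 10, seed = 6)
  expect_equal(sum(t3$marked), 10L)
})

test_that("transiency relocates centres by the stated truncated kernel", {
  tr <- simulate_population(ss10, N = 400, p_sex = 0.5, seed = 7)
  t0 <- simulate_transience(tr, 0)
  expect_identical(t0$s_R, t0$s_M)
  # interior centres, small sigma_t: per-axis displacement sd ~ sigma_t
  tr$s_M[] <- 50
  t1 <- simulate_transience(tr, 3, seed = 8)
  disp <- t1$s_R - t1$s_M
  expect_equal(sd(disp[, 1]), 3, tolerance = 0.35)
  expect_equal(sd(disp[, 2]), 3, tolerance = 0.35)
  # corner centres: all relocations inside, mean displacement points inward
  tr$s_M[] <- 0
  t2 <- simulate_transience(tr, 10, seed = 9)
  expect_true(all(t2$s_R >= 0 & t2$s_R <= 100))
  expect_gt(mean(t2$s_R[, 1] - t2$s_M[, 1]), 0)
  expect_gt(mean(t2$s_R[, 2] - t2$s_M[, 2]), 0)
})

test_that("resighting emits identified and identity-free records as specified", {
  cams <- trap_array(rbind(c(45, 50), c(55, 50)), "camera", matrix(1, 2, 17))
  tr <- simulate_population(ss10, N = 150, p_sex = 0.4, seed = 10)
  lt <- trap_array(rbind(c(50, 50)), "live", matrix(30, 1, 1))
  tr <- simulate_marking(tr, lt, 0.05, 8)
  r0 <- simulate_resighting(tr, cams, lambda0_R = 0, sigma_d = 8)
  expect_equal(nrow(r0$U), 0L)
  expect_equal(nrow(r0$marked_resights), 0L)
  set.seed(11)
  r1 <- simulate_resighting(tr, cams, lambda0_R = 0.5, sigma_d = 8,
                            p_sex_observed = 0.52)
  # known-sex fraction of unmarked records ~ 0.52
  expect_gt(nrow(r1$U), 50)
  frac <- mean(r1$U$obs_sex != "U")
  expect_lt(abs(frac - 0.52), 4 * sqrt(0.25 / nrow(r1$U)))
  # observed sexes are the true sexes
  kn <- r1$U[r1$U$obs_sex != "U", ]
  expect_true(all((kn$obs_sex == "F") ==
                    (tr$sex[kn$true_individual] == 1)))
  # marked individuals detected while marked are identified, never in U
  expect_false(any(r1$U$true_individual %in% tr$marked_ids))
})

test_that("telemetry locations are unbiased with per-axis scale sigma_d", {
  tr <- simulate_population(ss10, N = 50, p_sex = 0.5, seed = 12)
  lt <- trap_array(rbind(c(50, 50)), "live", matrix(60, 1, 1))
  tr <- simulate_marking(tr, lt, 0.3, 20)
  expect_gt(length(tr$marked_ids), 2)
  # no missingness: exactly K locations per marked individual
  tl <- simulate_telemetry(tr, sigma_d = 4, K_R = 17, missingness = 0,
                           seed = 13)
  expect_true(all(table(tl$individual) == 17))
  expect_true(all(tl$occasion %in% 1:17))
  # many locations for one individual: mean at s_R, sd at sigma_d
  tr2 <- tr; tr2$marked_ids <- tr$marked_ids[1]
  tl2 <- do.call(rbind, lapply(1:60, function(i)
    simulate_telemetry(tr2, sigma_d = 4, K_R = 17, missingness = 0)))
  i1 <- tr$marked_ids[1]
  expect_equal(mean(tl2$x), unname(tr$s_R[i1, 1]), tolerance = 0.5)
  expect_equal(mean(tl2$y), unname(tr$s_R[i1, 2]), tolerance = 0.5)
  expect_equal(sd(tl2$x), 4, tolerance = 0.4)
  # missingness thins per-occasion retention
  tl3 <- simulate_telemetry(tr, sigma_d = 4, K_R = 17, missingness = 0.5,
                            seed = 14)
  expect_lt(nrow(tl3), nrow(tl))
})

test_that("the assembled dataset respects known deaths and mid-survey marking", {
  stdy <- small_study(n_clusters = 2, seed = 15)
  ev <- data.frame(individual = c(1L, 2L), occasion = c(1L, 5L),
                   event = c("died", "marked"))
  sim <- simulate_smr(stdy$live, stdy$cams, density_per_100km2 = 3,
                      lambda0_M = 0.05, lambda0_R = 0.1, sigma_d = 5,
                      sigma_t = 0, events = ev, seed = 16)
  m <- sim$data$exposure$m
  expect_true(all(m[1, ] == 2L))
  expect_equal(unname(m[2, ]), c(rep(0L, 4), rep(1L, 13)))
  # the dead individual has no resights or telemetry
  expect_false(1L %in% sim$data$marked_resights$individual)
  expect_false(1L %in% sim$data$telemetry$individual)
  # individual 2's identified resights all fall at marked occasions
  occ2 <- sim$data$marked_resights$occasion[
    sim$data$marked_resights$individual == 2L]
  expect_true(all(occ2 >= 5))
})
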