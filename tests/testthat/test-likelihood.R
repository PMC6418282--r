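test_that("detection rate and hazard link have their closed forms", {
  expect_equal(halfnormal_rate(0, 0.05, 5), 0.05)
  expect_equal(halfnormal_rate(5, 0.05, 5), 0.05 * exp(-0.5))
  expect_lt(halfnormal_rate(50, 0.05, 5), 1e-21 * 0.05)
  d <- seq(0, 20, by = 0.5)
  expect_true(all(diff(halfnormal_rate(d, 0.1, 3)) <= 0))
  expect_error(halfnormal_rate(-1, 0.05, 5), "non-negative")

  expect_equal(hazard_to_prob(0), 0)
  expect_equal(hazard_to_prob(0.05), 1 - exp(-0.05))
  expect_equal(hazard_to_prob(1e6), 1)
  expect_error(hazard_to_prob(-0.1))
})

test_that("marking log-likelihood matches a brute-force binomial oracle", {
  expect_equal(marking_loglik(matrix(0, 2, 2), rbind(c(0, 0), c(1, 1)), 0,
                              5, matrix(3, 2, 2), rbind(c(0, 0), c(2, 2))),
               0)
  expect_equal(marking_loglik(matrix(1, 1, 1), rbind(c(0, 0)), 0.05, 5,
                              matrix(1, 1, 1), rbind(c(0, 0))),
               log(1 - exp(-0.05)))
  set.seed(42)
  for (rep in 1:5) {
    n <- 4L; J <- 3L
    s <- matrix(runif(2 * n, 0, 10), n, 2)
    X <- matrix(runif(2 * J, 0, 10), J, 2)
    E <- matrix(sample(1:6, n * J, TRUE), n, J)
    lam0 <- runif(1, 0.01, 0.5); sig <- runif(1, 1, 4)
    p <- matrix(NA_real_, n, J)
    for (i in 1:n) for (j in 1:J) {
      dd <- sqrt(sum((s[i, ] - X[j, ])^2))
      p[i, j] <- 1 - exp(-lam0 * exp(-dd^2 / (2 * sig^2)))
    }
    Y <- matrix(rbinom(n * J, E, p), n, J)
    brute <- 0
    for (i in 1:n) for (j in 1:J)
      brute <- brute + dbinom(Y[i, j], E[i, j], p[i, j], log = TRUE)
    expect_equal(marking_loglik(Y, s, lam0, sig, E, X), brute,
                 tolerance = 1e-10)
  }
  expect_error(marking_loglik(matrix(5, 1, 1), rbind(c(0, 0)), 0.1, 5,
                              matrix(2, 1, 1), rbind(c(0, 0))), "exceed")
})

test_that("resighting log-likelihood matches a brute-force Poisson oracle", {
  # lambda0 = 0 with a positive count is impossible
  expect_equal(resighting_loglik(matrix(1, 1, 1), rbind(c(0, 0)), 0, 5,
                                 matrix(17, 1, 1), rbind(c(0, 0))), -Inf)
  expect_equal(resighting_loglik(matrix(2, 1, 1), rbind(c(0, 0)), 0.1, 5,
                                 matrix(17, 1, 1), rbind(c(0, 0))),
               dpois(2, 1.7, log = TRUE))
  set.seed(43)
  for (rep in 1:5) {
    n <- 4L; J <- 3L
    s <- matrix(runif(2 * n, 0, 10), n, 2)
    X <- matrix(runif(2 * J, 0, 10), J, 2)
    E <- matrix(sample(5:17, n * J, TRUE), n, J)
    lam0 <- runif(1, 0.01, 0.3); sig <- runif(1, 1, 4)
    mu <- matrix(NA_real_, n, J)
    for (i in 1:n) for (j in 1:J) {
      dd <- sqrt(sum((s[i, ] - X[j, ])^2))
      mu[i, j] <- E[i, j] * lam0 * exp(-dd^2 / (2 * sig^2))
    }
    Y <- matrix(rpois(n * J, mu), n, J)
    brute <- sum(mapply(function(y, m) dpois(y, m, log = TRUE), Y, mu))
    expect_equal(resighting_loglik(Y, s, lam0, sig, E, X), brute,
                 tolerance = 1e-10)
  }
})

test_that("telemetry log-likelihood is a centred bivariate normal density", {
  s <- rbind(c(3, 4))
  tl <- data.frame(individual = 1L, x = 3, y = 4)
  expect_equal(telemetry_loglik(tl, s, 2), -log(2 * pi * 4))
  # doubling sigma at the centre costs 2 log 2
  expect_equal(telemetry_loglik(tl, s, 2) - telemetry_loglik(tl, s, 4),
               2 * log(2))
  # profile over sigma peaks near the generating value
  set.seed(7)
  tl2 <- data.frame(individual = 1L, x = rnorm(4000, 3, 1.5),
                    y = rnorm(4000, 4, 1.5))
  sig_grid <- seq(0.5, 4, by = 0.05)
  prof <- vapply(sig_grid, function(sg) telemetry_loglik(tl2, s, sg), 0)
  expect_equal(sig_grid[which.max(prof)], 1.5, tolerance = 0.1)
  expect_error(telemetry_loglik(data.frame(individual = 5L, x = 0, y = 0),
                                s, 1), "without an activity centre")
})

test_that("truncated relocation kernel is correctly normalized", {
  ss <- make_state_space(rbind(c(5, 5)), buffer_km = 5)  # [0,10]^2
  # centre far from edges: truncation negligible
  ld <- transience_logdensity(rbind(c(5.2, 5.1)), rbind(c(5, 5)), 0.3, ss)
  free <- dnorm(5.2, 5, 0.3, log = TRUE) + dnorm(5.1, 5, 0.3, log = TRUE)
  expect_equal(ld, free, tolerance = 1e-6)
  # centre exactly at a corner: a quarter of the mass is inside
  expect_equal(transience_truncmass(rbind(c(0, 0)), 1, ss), 0.25)
  # outside the rectangle: impossible
  expect_identical(transience_logdensity(rbind(c(-1, 5)), rbind(c(5, 5)),
                                         2, ss), -Inf)
  # quadrature oracle: exp(logdensity) integrates to 1 over the rectangle
  for (cn in list(c(5, 5), c(1, 2), c(0.2, 9.8))) {
    for (sig_t in c(1, 3, 8)) {
      ng <- 200L
      w <- 10 / ng
      gx <- seq(w / 2, 10 - w / 2, length.out = ng)
      grid <- as.matrix(expand.grid(gx, gx))
      ld <- transience_logdensity(grid, matrix(cn, nrow(grid), 2,
                                               byrow = TRUE), sig_t, ss)
      expect_equal(sum(exp(ld)) * w^2, 1, tolerance = 1e-4)
    }
  }
})

test_that("Bernoulli priors and model-variant likelihood identities hold", {
  expect_equal(sex_logprior(rep(c(0, 1), 5), 0.5), -10 * log(2))
  expect_identical(sex_logprior(c(1, 0), 1), -Inf)
  set.seed(11)
  sex <- rbinom(20, 1, 0.3)
  expect_equal(sex_logprior(sex, 0.3),
               sum(log(ifelse(sex == 1, 0.3, 0.7))))
  z <- rbinom(20, 1, 0.6)
  expect_equal(inclusion_logprior(z, 0.6),
               sum(log(ifelse(z == 1, 0.6, 0.4))))

  # conventional-model likelihood equals the generalized likelihood minus
  # the marking term on identical data
  set.seed(12)
  n <- 5L
  s <- matrix(runif(2 * n, 0, 10), n, 2)
  XR <- matrix(runif(8, 0, 10), 4, 2)
  XM <- matrix(runif(4, 0, 10), 2, 2)
  ER <- matrix(17, n, 4); EM <- matrix(10, n, 2)
  YR <- matrix(rpois(n * 4, 0.5), n, 4)
  YM <- matrix(rbinom(n * 2, 2, 0.2), n, 2)
  gen <- marking_loglik(YM, s, 0.05, 3, EM, XM) +
    resighting_loglik(YR, s, 0.1, 3, ER, XR)
  con <- resighting_loglik(YR, s, 0.1, 3, ER, XR)
  expect_equal(gen - marking_loglik(YM, s, 0.05, 3, EM, XM), con)

  # sex-specific detection with equal parameters reproduces the pooled value
  sexv <- rbinom(n, 1, 0.5)
  lam_vec <- c(0.1, 0.1)[2 - sexv]
  sig_vec <- c(3, 3)[2 - sexv]
  expect_equal(resighting_loglik(YR, s, lam_vec, sig_vec, ER, XR), con)
})
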