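#' Simulate a fully identified SCR dataset on a design
#'
#' Helper for pre-deployment design evaluation: activity centres uniform
#' on the buffered design rectangle, Poisson counts with a half-normal
#' detection function, all identities known.
#'
#' @param traps a [trap_array()].
#' @param ss state space.
#' @param D true density (individuals / 100 km^2); abundance is fixed at
#'   `round(D * area / 100)`.
#' @param lambda0 baseline per-occasion detection rate.
#' @param sigma detection spatial scale (km).
#' @param seed optional RNG seed.
#' @return List with `counts` (detected individuals x J), `N` (true
#'   abundance) and `n_detected`.
#' @export
simulate_scr <- function(traps, ss, D = 1.0, lambda0 = 0.05, sigma = 5.0,
                         seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (D <= 0 || lambda0 < 0 || sigma <= 0) stop("invalid parameters")
  N <- max(1L, round(D * ss$area / 100))
  s <- cbind(stats::runif(N, ss$xmin, ss$xmax),
             stats::runif(N, ss$ymin, ss$ymax))
  E <- rep(rowSums(traps$operation), each = N)
  lam <- lambda0 * exp(-sqdist(s, traps$coords) / (2 * sigma^2))
  Y <- matrix(stats::rpois(length(lam), E * lam), N, nrow(traps$coords))
  det <- which(rowSums(Y) > 0L)
  list(counts = Y[det, , drop = FALSE], N = N, n_detected = length(det))
}

#' Evaluate a survey design by simulation
#'
#' Replicated pre-deployment performance study of a detector design:
#' each replicate simulates a fully identified SCR dataset at the stated
#' density and detection parameters on the design's buffered state space,
#' fits a null SCR model, and records the density point estimate
#' (posterior mode), the posterior CV (posterior SD / posterior mode) and
#' whether the 95% HPDI covers the true density. Aggregates are the mean
#' relative bias of the point estimate with a normal-approximation 95% CI,
#' the mean posterior CV, the RMSE of the point estimate, and the coverage
#' of the nominal 95% intervals with a Wilson 95% CI.
#'
#' @param design a [trap_array()].
#' @param D true density (individuals / 100 km^2).
#' @param lambda0 baseline per-occasion detection rate.
#' @param sigma detection spatial scale (km).
#' @param K number of occasions (overrides the design's operation
#'   schedule with an all-on J x K matrix when not `NULL`).
#' @param n_reps number of replicates (>= 1).
#' @param seed RNG seed; replicate r uses `seed + r`.
#' @param config [mcmc_config()] for the per-replicate fits.
#' @param A augmentation size for the fits.
#' @param buffer_km state-space buffer; default 3 * sigma.
#' @return A `design_study` list: aggregate statistics plus the
#'   per-replicate table.
#' @export
run_design_study <- function(design, D = 1.0, lambda0 = 0.05, sigma = 5.0,
                             K = 17L, n_reps = 100L, seed = 1L,
                             config = mcmc_config(n_iter = 4000L,
                                                  burn_in = 1000L, thin = 3L),
                             A = 300L, buffer_km = 3 * sigma) {
  if (n_reps < 1L) stop("'n_reps' must be >= 1")
  if (!is.null(K))
    design$operation <- matrix(1, nrow(design$coords), K)
  ss <- make_state_space(design, buffer_km = buffer_km)
  reps <- vector("list", n_reps)
  failures <- 0L
  for (r in seq_len(n_reps)) {
    res <- tryCatch({
      sim <- simulate_scr(design, ss, D = D, lambda0 = lambda0,
                          sigma = sigma, seed = seed + r)
      cfg <- config
      cfg$seed <- seed + r
      ch <- fit_null_scr(sim$counts, design, ss, cfg, A = A)
      Dd <- ch$draws[, "D"]
      md <- suppressWarnings(posterior_mode(Dd, integer_valued = FALSE))
      hp <- hpdi(Dd, 0.95)
      data.frame(rep = r, n_detected = sim$n_detected, D_hat = md,
                 post_sd = stats::sd(Dd), post_cv = stats::sd(Dd) / md,
                 hpdi_low = hp[[1L]], hpdi_high = hp[[2L]],
                 covered = hp[[1L]] <= D && D <= hp[[2L]])
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures <- failures + 1L
      warning(sprintf("replicate %d failed: %s", r, conditionMessage(res)))
    } else reps[[r]] <- res
  }
  if (failures > 0.05 * n_reps)
    stop("more than 5% of replicates failed")
  tab <- do.call(rbind, reps)
  rel_err <- (tab$D_hat - D) / D
  nr <- nrow(tab)
  rb <- mean(rel_err)
  rb_ci <- rb + c(-1, 1) * stats::qnorm(0.975) * stats::sd(rel_err) / sqrt(nr)
  cov <- mean(tab$covered)
  wil <- stats::prop.test(sum(tab$covered), nr, correct = FALSE)$conf.int
  structure(list(n_reps = nr, n_failed = failures,
                 relative_bias = rb, relative_bias_ci = rb_ci,
                 mean_cv = mean(tab$post_cv),
                 rmse = sqrt(mean((tab$D_hat - D)^2)),
                 coverage = cov, coverage_ci = as.numeric(wil),
                 D = D, replicates = tab),
            class = "design_study")
}

#' @export
print.design_study <- function(x, ...) {
  cat(sprintf("<design_study> %d replicates (%d failed) at D = %.2f/100 km^2\n",
              x$n_reps, x$n_failed, x$D))
  cat(sprintf("  relative bias %+.3f (95%% CI %.3f to %.3f)\n",
              x$relative_bias, x$relative_bias_ci[1L], x$relative_bias_ci[2L]))
  cat(sprintf("  mean posterior CV %.3f; RMSE %.3f\n", x$mean_cv, x$rmse))
  cat(sprintf("  coverage %.3f (95%% CI %.3f to %.3f)\n",
              x$coverage, x$coverage_ci[1L], x$coverage_ci[2L]))
  invisible(x)
}
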