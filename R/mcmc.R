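#' Fit a spatial mark-resight model by MCMC
#'
#' Metropolis-within-Gibbs sampler for generalized and conventional
#' spatial mark-resight models with data augmentation. One sweep updates,
#' in order: activity centres (per-individual random-walk proposals,
#' accepted rowwise; centres of excluded individuals are refreshed from
#' their prior), the latent identity allocation of unmarked detection
#' records (uniform proposals over eligible individuals, accepted by the
#' record-level Poisson rate ratio), sexes of individuals whose sex is not
#' pinned by data (Gibbs), `p_sex` (conjugate Beta), inclusion indicators
#' `z` for individuals with no data (Gibbs) and `psi` (conjugate Beta),
#' then the detection parameters (log-scale random walks) and, for
#' transient models, `sigma_t` jointly with a rescaling of the
#' relocation steps of augmented individuals that carry no data.
#'
#' A record at occasion k is eligible for individual i only if z_i = 1,
#' the mark-status code of i permits an unmarked detection at k (code 0;
#' augmented individuals are always eligible), and, under the sex
#' constraint, i's sex matches the record's observed sex (unknown-sex
#' records are unconstrained).
#'
#' Priors: uniform on `lambda0` and the sigmas (bounds in
#' [mcmc_config()]), Beta(1, 1) on `psi` and `p_sex`.
#'
#' @param data an [smr_data()] object.
#' @param ss the state space ([make_state_space()]); for conventional
#'   models buffer the cameras only.
#' @param spec a [model_spec()].
#' @param config an [mcmc_config()].
#' @param keep_latent store per-retained-draw latent allocation, owner
#'   sexes and inclusion vectors for chain audits.
#' @return An `smr_chains` object: list with `draws` (matrix, one row per
#'   retained draw; includes `N`, `D`, `n_UM`), `area`, `spec`, `config`,
#'   `accept` rates, and optionally `latent`.
#' @export
run_mcmc <- function(data, ss, spec = model_spec(), config = mcmc_config(),
                     keep_latent = FALSE) {
  if (!is.null(config$seed)) set.seed(config$seed)
  st <- .smr_setup(data, ss, spec, config)
  .smr_run(st, config, keep_latent)
}

# ---------------------------------------------------------------- setup ----

.smr_setup <- function(data, ss, spec, config) {
  gen <- spec$generalized
  trans <- spec$use_transience
  if (trans && !gen) {
    warning("activity-centre transiency requires the generalized model; disabled")
    trans <- FALSE
  }
  tel <- spec$use_telemetry && !is.null(data$telemetry) &&
    nrow(data$telemetry) > 0L
  sexcon <- spec$use_sex_constraint
  ssx <- spec$sex_specific
  A <- spec$A
  nM <- data$n_M
  if (A <= nM) stop("augmentation size A must exceed the number of marked individuals")

  XR <- data$cameras$coords
  JR <- nrow(XR); K <- data$K_R
  opR <- data$cameras$operation

  # exposure, padded to A rows (augmented individuals fully exposed)
  ER <- rbind(as.matrix(data$exposure$E_R),
              matrix(rep(data$exposure$eR_full, each = A - nM), A - nM, JR))
  if (gen) {
    XM <- data$live_traps$coords
    JM <- nrow(XM)
    EM <- rbind(as.matrix(data$exposure$E_M),
                matrix(rep(data$exposure$eM_full, each = A - nM), A - nM, JM))
    YM <- rbind(as.matrix(data$Y_M), matrix(0L, A - nM, JM))
    if (any(YM > EM)) stop("marking counts exceed exposure")
  } else {
    XM <- NULL; JM <- 0L; EM <- NULL; YM <- NULL
  }

  m <- data$exposure$m
  # occasion eligibility for latent unmarked detections
  elig_occ <- matrix(TRUE, A, K)
  if (nM > 0L) elig_occ[seq_len(nM), ] <- m == 0L

  # identified resight counts
  Yfix <- matrix(0, A, JR)
  mr <- data$marked_resights
  if (nrow(mr) > 0L) {
    if (any(m[cbind(mr$individual, mr$occasion)] != 1L))
      stop("identified resighting at an occasion where the individual was not marked")
    for (r in seq_len(nrow(mr)))
      Yfix[mr$individual[r], mr$trap[r]] <- Yfix[mr$individual[r], mr$trap[r]] + 1
  }

  # unmarked records
  U <- data$U
  n_rec <- nrow(U)
  rec_j <- U$trap; rec_k <- U$occasion
  rec_sex <- ifelse(U$obs_sex == "F", 1L, ifelse(U$obs_sex == "M", 0L, NA))
  if (n_rec > 0L) {
    if (any(opR[cbind(rec_j, rec_k)] <= 0))
      stop("unmarked record at a non-operating camera-occasion")
  }

  # telemetry sufficient statistics per marked individual
  ntel <- numeric(A); tsx <- numeric(A); tsy <- numeric(A); tss <- numeric(A)
  if (tel) {
    tl <- data$telemetry
    if (any(tl$individual > nM)) stop("telemetry for an unknown individual")
    ag <- rowsum(cbind(1, tl$x, tl$y, tl$x^2 + tl$y^2), tl$individual)
    ids <- as.integer(rownames(ag))
    ntel[ids] <- ag[, 1L]; tsx[ids] <- ag[, 2L]; tsy[ids] <- ag[, 3L]
    tss[ids] <- ag[, 4L]
  }

  # --- initial values --------------------------------------------------
  fx <- config$fixed
  pri <- config$priors
  sig0 <- if (tel && sum(ntel > 1) > 0) {
    ok <- which(ntel > 1)
    tl <- data$telemetry
    sqrt(mean(unlist(lapply(ok, function(i) {
      w <- tl$individual == i
      c((tl$x[w] - mean(tl$x[w]))^2, (tl$y[w] - mean(tl$y[w]))^2)
    }))))
  } else {
    dd <- stats::dist(XR[sample(JR, min(JR, 40L)), , drop = FALSE])
    if (!length(dd)) 1 else max(1e-2, 0.7 * min(dd))
  }
  sig0 <- min(max(sig0, 1e-2), pri$sigma_d_max * 0.9)
  sigd <- rep(if (!is.null(fx$sigma_d)) fx$sigma_d[1L] else sig0, 2L)
  if (ssx && !is.null(fx$sigma_d) && length(fx$sigma_d) == 2L) sigd <- fx$sigma_d
  lamR <- rep(if (!is.null(fx$lambda0_R)) fx$lambda0_R[1L] else
    max(0.005, (nrow(mr) + n_rec) / max(1, A / 2) / max(1, mean(colSums(opR)))), 2L)
  if (ssx && !is.null(fx$lambda0_R) && length(fx$lambda0_R) == 2L) lamR <- fx$lambda0_R
  lamM <- rep(if (!is.null(fx$lambda0_M)) fx$lambda0_M[1L] else 0.01, 2L)
  if (ssx && !is.null(fx$lambda0_M) && length(fx$lambda0_M) == 2L) lamM <- fx$lambda0_M
  sigt <- if (!is.null(fx$sigma_t)) fx$sigma_t else max(sig0, 5)
  psi <- if (!is.null(fx$psi)) fx$psi else min(0.8, max(0.2, (nM + n_rec) / A))
  psex <- if (!is.null(fx$p_sex)) fx$p_sex else 0.5

  clamp <- function(s) {
    s[, 1L] <- pmin(pmax(s[, 1L], ss$xmin + 1e-6), ss$xmax - 1e-6)
    s[, 2L] <- pmin(pmax(s[, 2L], ss$ymin + 1e-6), ss$ymax - 1e-6)
    s
  }
  sM <- cbind(stats::runif(A, ss$xmin, ss$xmax),
              stats::runif(A, ss$ymin, ss$ymax))
  # marked individuals: centre on their own data
  if (nM > 0L) {
    for (i in seq_len(nM)) {
      pts <- NULL
      if (tel && ntel[i] > 0) pts <- rbind(pts, c(tsx[i], tsy[i]) / ntel[i])
      w <- which(Yfix[i, ] > 0)
      if (length(w)) pts <- rbind(pts, XR[w, , drop = FALSE])
      if (gen) {
        wm <- which(YM[i, ] > 0)
        if (length(wm)) pts <- rbind(pts, XM[wm, , drop = FALSE])
      }
      if (!is.null(pts)) sM[i, ] <- colMeans(pts)
    }
    sM[seq_len(nM), ] <- clamp(sM[seq_len(nM), , drop = FALSE])
  }
  sR <- sM

  # sexes: marked fixed; others random
  sex <- stats::rbinom(A, 1L, 0.5)
  if (nM > 0L) sex[seq_len(nM)] <- data$sex_marked

  # initial allocation: one augmented individual per (trap, obs-sex) group
  alloc <- integer(n_rec)
  z <- integer(A)
  if (nM > 0L) z[seq_len(nM)] <- 1L
  if (n_rec > 0L) {
    grp <- paste(rec_j, ifelse(is.na(rec_sex), "U", rec_sex))
    ug <- unique(grp)
    if (length(ug) > A - nM)
      stop("augmentation size A too small for the observed unmarked records")
    own <- nM + match(grp, ug)
    alloc <- own
    for (g in seq_along(ug)) {
      i <- nM + g
      r1 <- which(grp == ug[g])[1L]
      z[i] <- 1L
      sR[i, ] <- clamp(XR[rec_j[r1], , drop = FALSE] +
                         stats::rnorm(2L, 0, 1))
      sM[i, ] <- sR[i, ]
      sx <- rec_sex[which(grp == ug[g])]
      sx <- sx[!is.na(sx)]
      if (length(sx)) sex[i] <- sx[1L]
    }
  }
  zfree0 <- which(z == 0L)
  z[zfree0] <- stats::rbinom(length(zfree0), 1L, psi)

  CU <- matrix(0, A, JR)
  if (n_rec > 0L)
    for (r in seq_len(n_rec)) CU[alloc[r], rec_j[r]] <- CU[alloc[r], rec_j[r]] + 1
  ocount <- tabulate(alloc, nbins = A)

  # distance matrices and kernels
  D2R <- sqdist(sR, XR)
  D2M <- if (gen) sqdist(sM, XM) else NULL

  nzM <- if (gen) which(YM > 0, arr.ind = TRUE) else NULL

  st <- list(
    gen = gen, trans = trans, tel = tel, sexcon = sexcon, ssx = ssx,
    A = A, nM = nM, JR = JR, JM = JM, K = K, ss = ss, area = ss$area,
    XR = XR, XM = XM, ER = ER, EM = EM, YM = YM, Yfix = Yfix,
    m = m, elig_occ = elig_occ, opR = opR,
    n_rec = n_rec, rec_j = rec_j, rec_k = rec_k, rec_sex = rec_sex,
    eRfull = data$exposure$eR_full, eMfull = data$exposure$eM_full,
    sweep_no = 0L,
    ntel = ntel, tsx = tsx, tsy = tsy, tss = tss,
    lamM = lamM, lamR = lamR, sigd = sigd, sigt = sigt,
    psi = psi, psex = psex,
    sM = sM, sR = sR, sex = sex, z = z, alloc = alloc, CU = CU,
    ocount = ocount, D2R = D2R, D2M = D2M, nzM = nzM,
    fx = fx, pri = pri)
  st <- .refresh_H(st)
  st <- .refresh_nz(st)
  st
}

# cache the nonzero-count index; counts change only in the allocation sweep
.refresh_nz <- function(st) {
  Ytot <- st$Yfix + st$CU
  st$nz <- which(Ytot > 0, arr.ind = TRUE)
  st$yv <- Ytot[st$nz]
  st
}

# recompute kernel matrices and exposure-weighted row sums from scratch
.refresh_H <- function(st) {
  sig_i <- st$sigd[2L - st$sex]
  st$HR <- exp(-st$D2R / (2 * sig_i^2))
  st$rER <- rowSums(st$ER * st$HR)
  if (st$gen) {
    st$HM <- exp(-st$D2M / (2 * sig_i^2))
    st$EmY <- st$EM - st$YM
    st$rEmY <- rowSums(st$EmY * st$HM)
  }
  st
}

# ------------------------------------------------------------------ run ----

.smr_run <- function(st, config, keep_latent) {
  n_iter <- config$n_iter; burn <- config$burn_in; thin <- config$thin
  n_keep <- (n_iter - burn) %/% thin
  pri <- st$pri; fx <- st$fx
  tune <- config$tune

  # proposal scales
  step_lamM <- step_lamR <- config$proposal$lambda0
  step_sig <- config$proposal$sigma
  step_sigt <- config$proposal$sigma_t
  step_ridge <- config$proposal$sigma
  step_s <- if (is.null(config$proposal$s)) st$sigd[1L] else config$proposal$s
  use_ridge <- !st$ssx && is.null(fx$sigma_d) && is.null(fx$lambda0_R)
  acc <- new.env()
  for (nm in c("lamM", "lamR", "sig", "sigt", "sM", "sR", "ridge"))
    assign(nm, c(0, 0), envir = acc)
  bump <- function(nm, a, n = 1) {
    v <- get(nm, envir = acc); assign(nm, v + c(a, n), envir = acc)
  }

  cols <- c(if (st$gen) if (st$ssx) c("lambda0_M_F", "lambda0_M_M") else "lambda0_M",
            if (st$ssx) c("lambda0_R_F", "lambda0_R_M") else "lambda0_R",
            if (st$ssx) c("sigma_d_F", "sigma_d_M") else "sigma_d",
            if (st$trans) "sigma_t",
            "psi", "p_sex", "N", "D", "n_UM")
  draws <- matrix(NA_real_, n_keep, length(cols),
                  dimnames = list(NULL, cols))
  lat <- if (keep_latent)
    list(alloc = matrix(NA_integer_, n_keep, st$n_rec),
         owner_sex = matrix(NA_integer_, n_keep, st$n_rec),
         z = matrix(NA_integer_, n_keep, st$A)) else NULL

  kept <- 0L
  for (it in seq_len(n_iter)) {
    st$sweep_no <- it
    st <- .upd_s(st, step_s, acc, bump)
    if (st$n_rec > 0L) st <- .upd_alloc(st)
    st <- .upd_sex(st)
    if (is.null(fx$p_sex)) {
      nf <- sum(st$sex[st$z == 1L])
      st$psex <- stats::rbeta(1L, 1 + nf, 1 + sum(st$z) - nf)
    }
    st <- .upd_z(st)
    if (is.null(fx$psi))
      st$psi <- stats::rbeta(1L, 1 + sum(st$z), 1 + st$A - sum(st$z))
    if (st$gen && is.null(fx$lambda0_M))
      st <- .upd_lamM(st, step_lamM, bump)
    if (is.null(fx$lambda0_R))
      st <- .upd_lamR(st, step_lamR, bump)
    if (is.null(fx$sigma_d))
      st <- .upd_sigd(st, step_sig, bump)
    if (use_ridge)
      st <- .upd_ridge(st, step_ridge, bump)
    if (st$trans && is.null(fx$sigma_t))
      st <- .upd_sigt(st, step_sigt, bump)

    # adapt proposal scales during burn-in
    if (tune && it <= burn && it %% 50L == 0L) {
      ad <- function(nm, step, target = 0.44) {
        v <- get(nm, envir = acc)
        r <- if (v[2L] > 0) v[1L] / v[2L] else target
        assign(nm, c(0, 0), envir = acc)
        step * exp(min(0.5, max(-0.5, r - target)))
      }
      step_lamM <- ad("lamM", step_lamM)
      step_lamR <- ad("lamR", step_lamR)
      step_sig <- ad("sig", step_sig)
      step_sigt <- ad("sigt", step_sigt)
      step_ridge <- ad("ridge", step_ridge)
      step_s <- ad("sM", step_s, target = 0.3)
      assign("sR", c(0, 0), envir = acc)
    }

    if (it > burn && (it - burn) %% thin == 0L) {
      kept <- kept + 1L
      N <- sum(st$z)
      row <- c(if (st$gen) if (st$ssx) st$lamM else st$lamM[1L],
               if (st$ssx) st$lamR else st$lamR[1L],
               if (st$ssx) st$sigd else st$sigd[1L],
               if (st$trans) st$sigt,
               st$psi, st$psex, N, N / st$area * 100, sum(st$ocount > 0L))
      draws[kept, ] <- row
      if (keep_latent) {
        lat$alloc[kept, ] <- st$alloc
        lat$owner_sex[kept, ] <- st$sex[st$alloc]
        lat$z[kept, ] <- st$z
      }
    }
  }

  if (any(draws[, "N"] > 0.95 * st$A))
    warning("augmentation nearly saturated: some draws had N > 0.95 * A")
  rates <- vapply(c("lamM", "lamR", "sig", "sigt", "sM", "ridge"),
                  function(nm) {
                    v <- get(nm, envir = acc)
                    if (v[2L] > 0) v[1L] / v[2L] else NA_real_
                  }, 0)
  structure(list(draws = draws[seq_len(kept), , drop = FALSE],
                 area = st$area, spec = NULL, config = config,
                 A = st$A, n_M = st$nM, latent = lat, accept = rates,
                 steps = c(lambda0 = step_lamR, sigma = step_sig,
                           sigma_t = step_sigt, s = step_s,
                           ridge = step_ridge)),
            class = "smr_chains")
}

#' @export
print.smr_chains <- function(x, ...) {
  cat(sprintf("<smr_chains> %d retained draws, %d parameters, area %.0f km^2\n",
              nrow(x$draws), ncol(x$draws), x$area))
  invisible(x)
}

# ------------------------------------------------------------- updates ----

# per-row sum of y * f(H[i,j]) over a nonzero index set
.nzsum <- function(idx, vals, A) {
  out <- numeric(A)
  if (length(vals)) {
    ag <- rowsum(vals, idx)
    out[as.integer(rownames(ag))] <- ag
  }
  out
}

.upd_s <- function(st, step_s, acc, bump) {
  ss <- st$ss
  # individuals whose centres carry data get random-walk proposals;
  # included individuals with no data get independence proposals from the
  # prior (their likelihood is nearly flat, so these mix across the whole
  # state space); excluded individuals are refreshed from the prior
  informed <- seq_len(st$A) <= st$nM | st$ocount > 0L | st$ntel > 0
  z1 <- which(st$z == 1L & informed)
  f1 <- which(st$z == 1L & !informed)
  z0 <- which(st$z == 0L)
  n1 <- length(z1)
  lamRi <- st$lamR[2L - st$sex]
  lamMi_all <- if (st$gen) st$lamM[2L - st$sex] else NULL
  sig_i <- st$sigd[2L - st$sex]
  nz <- st$nz
  yv <- st$yv

  inside <- function(s)
    s[, 1L] >= ss$xmin & s[, 1L] <= ss$xmax &
    s[, 2L] >= ss$ymin & s[, 2L] <= ss$ymax

  # independence refresh of data-free included individuals
  if (length(f1)) {
    nf <- length(f1)
    sMp <- cbind(stats::runif(nf, ss$xmin, ss$xmax),
                 stats::runif(nf, ss$ymin, ss$ymax))
    sRp <- if (st$trans) rtnorm2_rect(sMp, st$sigt, ss) else sMp
    sgf <- sig_i[f1]
    d2Rp <- sqdist(sRp, st$XR)
    HRp <- exp(-d2Rp / (2 * sgf^2))
    rERp <- drop(HRp %*% st$eRfull)           # f1 rows are all augmented
    dll <- -lamRi[f1] * (rERp - st$rER[f1])
    if (st$gen) {
      d2Mp <- sqdist(sMp, st$XM)
      HMp <- exp(-d2Mp / (2 * sgf^2))
      rEmYp <- drop(HMp %*% st$eMfull)
      dll <- dll - lamMi_all[f1] * (rEmYp - st$rEmY[f1])
    }
    take <- log(stats::runif(nf)) < dll
    if (any(take)) {
      ti <- f1[take]
      st$sM[ti, ] <- sMp[take, , drop = FALSE]
      st$sR[ti, ] <- sRp[take, , drop = FALSE]
      st$D2R[ti, ] <- d2Rp[take, , drop = FALSE]
      st$HR[ti, ] <- HRp[take, , drop = FALSE]
      st$rER[ti] <- rERp[take]
      if (st$gen) {
        st$D2M[ti, ] <- d2Mp[take, , drop = FALSE]
        st$HM[ti, ] <- HMp[take, , drop = FALSE]
        st$rEmY[ti] <- rEmYp[take]
      }
    }
  }

  if (st$trans) {
    lamMi <- st$lamM[2L - st$sex]
    # (a) marking-period centres
    if (n1 > 0L) {
      prop <- st$sM[z1, , drop = FALSE] +
        matrix(stats::rnorm(2L * n1, 0, step_s), ncol = 2L)
      ok <- inside(prop)
      d2p <- sqdist(prop, st$XM)
      Hp <- exp(-d2p / (2 * sig_i[z1]^2))
      rEmYp <- rowSums(st$EmY[z1, , drop = FALSE] * Hp)
      dll <- -lamMi[z1] * (rEmYp - st$rEmY[z1])
      nzm <- st$nzM
      if (length(nzm)) {
        w <- match(nzm[, 1L], z1)
        keep <- !is.na(w)
        if (any(keep)) {
          i <- nzm[keep, 1L]; j <- nzm[keep, 2L]; wi <- w[keep]
          y <- st$YM[cbind(i, j)]
          num <- log1p(-exp(-lamMi[i] * Hp[cbind(wi, j)]))
          den <- log1p(-exp(-lamMi[i] * st$HM[cbind(i, j)]))
          dll <- dll + .nzsum(wi, y * (num - den), n1)
        }
      }
      # relocation kernel: exponent and truncation constant both move
      dr_new <- rowSums((st$sR[z1, , drop = FALSE] - prop)^2)
      dr_old <- rowSums((st$sR[z1, , drop = FALSE] -
                           st$sM[z1, , drop = FALSE])^2)
      dll <- dll - (dr_new - dr_old) / (2 * st$sigt^2) -
        (log(transience_truncmass(prop, st$sigt, ss)) -
           log(transience_truncmass(st$sM[z1, , drop = FALSE], st$sigt, ss)))
      take <- ok & log(stats::runif(n1)) < dll
      if (any(take)) {
        ti <- z1[take]
        st$sM[ti, ] <- prop[take, , drop = FALSE]
        st$D2M[ti, ] <- d2p[take, , drop = FALSE]
        st$HM[ti, ] <- Hp[take, , drop = FALSE]
        st$rEmY[ti] <- rEmYp[take]
      }
      bump("sM", sum(take), n1)
    }
    # (a3) marked individuals: an additional independence proposal for
    # s_M from the kernel around s_R (the random walk above stays); the
    # acceptance ratio is the truncation-mass ratio times the full
    # marking-likelihood ratio
    mk <- which(seq_len(st$A) <= st$nM & st$z == 1L)
    if (length(mk) && st$sigt > 1e-8) {
      nk <- length(mk)
      prop <- rtnorm2_rect(st$sR[mk, , drop = FALSE], st$sigt, ss)
      d2p <- sqdist(prop, st$XM)
      sgk <- sig_i[mk]
      Hp <- exp(-d2p / (2 * sgk^2))
      rEmYp <- rowSums(st$EmY[mk, , drop = FALSE] * Hp)
      dll <- -lamMi_all[mk] * (rEmYp - st$rEmY[mk]) +
        log(transience_truncmass(st$sM[mk, , drop = FALSE], st$sigt, ss)) -
        log(transience_truncmass(prop, st$sigt, ss))
      nzm <- st$nzM
      if (length(nzm)) {
        w <- match(nzm[, 1L], mk)
        keep <- !is.na(w)
        if (any(keep)) {
          i <- nzm[keep, 1L]; j <- nzm[keep, 2L]; wi <- w[keep]
          y <- st$YM[cbind(i, j)]
          num <- log1p(-exp(-lamMi_all[i] * Hp[cbind(wi, j)]))
          den <- log1p(-exp(-lamMi_all[i] * st$HM[cbind(i, j)]))
          dll <- dll + .nzsum(wi, y * (num - den), nk)
        }
      }
      take <- log(stats::runif(nk)) < dll
      if (any(take)) {
        ti <- mk[take]
        st$sM[ti, ] <- prop[take, , drop = FALSE]
        st$D2M[ti, ] <- d2p[take, , drop = FALSE]
        st$HM[ti, ] <- Hp[take, , drop = FALSE]
        st$rEmY[ti] <- rEmYp[take]
      }
    }
    # (a2) augmented owners have no marking captures, so their
    # marking-period centre is informed almost solely by the relocation
    # kernel: an independence proposal from the kernel around s_R mixes
    # it in one step (acceptance ratio reduces to truncation-mass and
    # zero-capture terms; symmetric normal factors cancel)
    ao <- which(seq_len(st$A) > st$nM & st$z == 1L & st$ocount > 0L)
    if (length(ao)) {
      na <- length(ao)
      prop <- rtnorm2_rect(st$sR[ao, , drop = FALSE], st$sigt, ss)
      d2p <- sqdist(prop, st$XM)
      sga <- sig_i[ao]
      Hp <- exp(-d2p / (2 * sga^2))
      rEmYp <- drop(Hp %*% st$eMfull)
      dll <- -lamMi_all[ao] * (rEmYp - st$rEmY[ao]) +
        log(transience_truncmass(st$sM[ao, , drop = FALSE], st$sigt, ss)) -
        log(transience_truncmass(prop, st$sigt, ss))
      take <- log(stats::runif(na)) < dll
      if (any(take)) {
        ti <- ao[take]
        st$sM[ti, ] <- prop[take, , drop = FALSE]
        st$D2M[ti, ] <- d2p[take, , drop = FALSE]
        st$HM[ti, ] <- Hp[take, , drop = FALSE]
        st$rEmY[ti] <- rEmYp[take]
      }
    }
    # (b) resighting-period centres
    if (n1 > 0L) {
      prop <- st$sR[z1, , drop = FALSE] +
        matrix(stats::rnorm(2L * n1, 0, step_s), ncol = 2L)
      ok <- inside(prop)
      d2p <- sqdist(prop, st$XR)
      Hp <- exp(-d2p / (2 * sig_i[z1]^2))
      rERp <- rowSums(st$ER[z1, , drop = FALSE] * Hp)
      dll <- -lamRi[z1] * (rERp - st$rER[z1])
      if (nrow(nz)) {
        w <- match(nz[, 1L], z1)
        keep <- !is.na(w)
        if (any(keep)) {
          i <- nz[keep, 1L]; j <- nz[keep, 2L]; wi <- w[keep]
          dll <- dll + .nzsum(wi, yv[keep] *
                                (log(Hp[cbind(wi, j)]) -
                                   log(st$HR[cbind(i, j)])), n1)
        }
      }
      if (st$tel) {
        i <- z1
        ssq <- function(s) st$ntel[i] * rowSums(s^2) -
          2 * (s[, 1L] * st$tsx[i] + s[, 2L] * st$tsy[i])
        dll <- dll - (ssq(prop) - ssq(st$sR[i, , drop = FALSE])) /
          (2 * sig_i[i]^2)
      }
      dr_new <- rowSums((prop - st$sM[z1, , drop = FALSE])^2)
      dr_old <- rowSums((st$sR[z1, , drop = FALSE] -
                           st$sM[z1, , drop = FALSE])^2)
      dll <- dll - (dr_new - dr_old) / (2 * st$sigt^2)
      take <- ok & log(stats::runif(n1)) < dll
      if (any(take)) {
        ti <- z1[take]
        st$sR[ti, ] <- prop[take, , drop = FALSE]
        st$D2R[ti, ] <- d2p[take, , drop = FALSE]
        st$HR[ti, ] <- Hp[take, , drop = FALSE]
        st$rER[ti] <- rERp[take]
      }
      bump("sR", sum(take), n1)
    }
    # (c) excluded individuals: refresh from the process prior
    # (their conditional; run every other sweep, which suffices)
    if (length(z0) && st$sweep_no %% 2L == 0L) {
      st$sM[z0, 1L] <- stats::runif(length(z0), ss$xmin, ss$xmax)
      st$sM[z0, 2L] <- stats::runif(length(z0), ss$ymin, ss$ymax)
      st$sR[z0, ] <- rtnorm2_rect(st$sM[z0, , drop = FALSE], st$sigt, ss)
      st <- .refresh_rows(st, z0)
    }
  } else {
    # single shared activity centre
    if (n1 > 0L) {
      prop <- st$sR[z1, , drop = FALSE] +
        matrix(stats::rnorm(2L * n1, 0, step_s), ncol = 2L)
      ok <- inside(prop)
      d2pR <- sqdist(prop, st$XR)
      HpR <- exp(-d2pR / (2 * sig_i[z1]^2))
      rERp <- rowSums(st$ER[z1, , drop = FALSE] * HpR)
      dll <- -lamRi[z1] * (rERp - st$rER[z1])
      if (nrow(nz)) {
        w <- match(nz[, 1L], z1)
        keep <- !is.na(w)
        if (any(keep)) {
          i <- nz[keep, 1L]; j <- nz[keep, 2L]; wi <- w[keep]
          dll <- dll + .nzsum(wi, yv[keep] *
                                (log(HpR[cbind(wi, j)]) -
                                   log(st$HR[cbind(i, j)])), n1)
        }
      }
      if (st$gen) {
        lamMi <- st$lamM[2L - st$sex]
        d2pM <- sqdist(prop, st$XM)
        HpM <- exp(-d2pM / (2 * sig_i[z1]^2))
        rEmYp <- rowSums(st$EmY[z1, , drop = FALSE] * HpM)
        dll <- dll - lamMi[z1] * (rEmYp - st$rEmY[z1])
        nzm <- st$nzM
        if (length(nzm)) {
          w <- match(nzm[, 1L], z1)
          keep <- !is.na(w)
          if (any(keep)) {
            i <- nzm[keep, 1L]; j <- nzm[keep, 2L]; wi <- w[keep]
            y <- st$YM[cbind(i, j)]
            num <- log1p(-exp(-lamMi[i] * HpM[cbind(wi, j)]))
            den <- log1p(-exp(-lamMi[i] * st$HM[cbind(i, j)]))
            dll <- dll + .nzsum(wi, y * (num - den), n1)
          }
        }
      }
      if (st$tel) {
        i <- z1
        ssq <- function(s) st$ntel[i] * rowSums(s^2) -
          2 * (s[, 1L] * st$tsx[i] + s[, 2L] * st$tsy[i])
        dll <- dll - (ssq(prop) - ssq(st$sR[i, , drop = FALSE])) /
          (2 * sig_i[i]^2)
      }
      take <- ok & log(stats::runif(n1)) < dll
      if (any(take)) {
        ti <- z1[take]
        st$sR[ti, ] <- prop[take, , drop = FALSE]
        st$sM[ti, ] <- prop[take, , drop = FALSE]
        st$D2R[ti, ] <- d2pR[take, , drop = FALSE]
        st$HR[ti, ] <- HpR[take, , drop = FALSE]
        st$rER[ti] <- rERp[take]
        if (st$gen) {
          st$D2M[ti, ] <- d2pM[take, , drop = FALSE]
          st$HM[ti, ] <- HpM[take, , drop = FALSE]
          st$rEmY[ti] <- rEmYp[take]
        }
      }
      bump("sM", sum(take), n1)
    }
    if (length(z0) && st$sweep_no %% 2L == 0L) {
      st$sM[z0, 1L] <- stats::runif(length(z0), ss$xmin, ss$xmax)
      st$sM[z0, 2L] <- stats::runif(length(z0), ss$ymin, ss$ymax)
      st$sR[z0, ] <- st$sM[z0, , drop = FALSE]
      st <- .refresh_rows(st, z0)
    }
  }
  st
}

.refresh_rows <- function(st, rows) {
  sig_i <- st$sigd[2L - st$sex[rows]]
  st$D2R[rows, ] <- sqdist(st$sR[rows, , drop = FALSE], st$XR)
  st$HR[rows, ] <- exp(-st$D2R[rows, , drop = FALSE] / (2 * sig_i^2))
  st$rER[rows] <- .erowsum(st, rows, st$HR, st$ER, st$eRfull)
  if (st$gen) {
    st$D2M[rows, ] <- sqdist(st$sM[rows, , drop = FALSE], st$XM)
    st$HM[rows, ] <- exp(-st$D2M[rows, , drop = FALSE] / (2 * sig_i^2))
    st$rEmY[rows] <- .erowsum(st, rows, st$HM, st$EmY, st$eMfull)
  }
  st
}

# exposure-weighted kernel row sums; augmented rows share one exposure
# vector, so they reduce to a matrix-vector product
.erowsum <- function(st, rows, H, E, efull) {
  out <- numeric(length(rows))
  aug <- rows > st$nM
  if (any(aug))
    out[aug] <- drop(H[rows[aug], , drop = FALSE] %*% efull)
  if (any(!aug)) {
    mr <- rows[!aug]
    out[!aug] <- rowSums(E[mr, , drop = FALSE] * H[mr, , drop = FALSE])
  }
  out
}

.upd_alloc <- function(st) {
  lamRi <- st$lamR[2L - st$sex]
  lamh <- lamRi * st$HR                      # A x JR per-occasion rates
  ord <- sample.int(st$n_rec)
  for (r in ord) {
    k <- st$rec_k[r]; j <- st$rec_j[r]; sx <- st$rec_sex[r]
    base <- st$z == 1L & st$elig_occ[, k]
    if (st$sexcon && !is.na(sx)) base <- base & st$sex == sx
    elig <- which(base)
    ne <- length(elig)
    if (ne <= 1L) next
    a <- st$alloc[r]
    b <- elig[sample.int(ne, 1L)]
    if (b == a) next
    lr <- log(lamh[b, j]) - log(lamh[a, j])
    if (is.nan(lr)) next
    if (log(stats::runif(1L)) < lr) {
      st$alloc[r] <- b
      st$CU[a, j] <- st$CU[a, j] - 1
      st$CU[b, j] <- st$CU[b, j] + 1
      st$ocount[a] <- st$ocount[a] - 1L
      st$ocount[b] <- st$ocount[b] + 1L
    }
  }
  .refresh_nz(st)
}

.upd_sex <- function(st) {
  # individuals whose sex is pinned: marked, or owning a known-sex record
  pinned <- logical(st$A)
  if (st$nM > 0L) pinned[seq_len(st$nM)] <- TRUE
  if (st$sexcon && st$n_rec > 0L) {
    kn <- which(!is.na(st$rec_sex))
    pinned[unique(st$alloc[kn])] <- TRUE
  }
  free <- which(!pinned)
  if (!length(free)) return(st)
  if (!st$ssx) {
    st$sex[free] <- stats::rbinom(length(free), 1L, st$psex)
    return(st)
  }
  # sex-specific detection: likelihood-weighted Gibbs draw for z = 1
  f1 <- free[st$z[free] == 1L]
  f0 <- setdiff(free, f1)
  if (length(f0)) st$sex[f0] <- stats::rbinom(length(f0), 1L, st$psex)
  if (length(f1)) {
    llsex <- function(sexval) {
      sg <- st$sigd[2L - sexval]; lR <- st$lamR[2L - sexval]
      H <- exp(-st$D2R[f1, , drop = FALSE] / (2 * sg^2))
      ll <- -lR * rowSums(st$ER[f1, , drop = FALSE] * H)
      cnt <- st$CU[f1, , drop = FALSE] + st$Yfix[f1, , drop = FALSE]
      nzl <- which(cnt > 0, arr.ind = TRUE)
      if (nrow(nzl))
        ll <- ll + .nzsum(nzl[, 1L],
                          cnt[nzl] * (log(lR) + log(H[nzl])), length(f1))
      if (st$gen) {
        lM <- st$lamM[2L - sexval]
        HM <- exp(-st$D2M[f1, , drop = FALSE] / (2 * sg^2))
        ll <- ll - lM * rowSums(st$EmY[f1, , drop = FALSE] * HM)
        # free individuals are unmarked: no positive marking counts
      }
      ll
    }
    lf <- llsex(1L); lm <- llsex(0L)
    pf <- 1 / (1 + exp(log1p(-st$psex) - log(st$psex) + lm - lf))
    newsex <- stats::rbinom(length(f1), 1L, pf)
    ch <- f1[newsex != st$sex[f1]]
    st$sex[f1] <- newsex
    if (length(ch)) st <- .refresh_rows(st, ch)
  }
  st
}

.upd_z <- function(st) {
  cand <- which(seq_len(st$A) > st$nM & st$ocount == 0L)
  if (!length(cand)) return(st)
  lamRi <- st$lamR[2L - st$sex[cand]]
  logL0 <- -lamRi * st$rER[cand]
  if (st$gen) {
    lamMi <- st$lamM[2L - st$sex[cand]]
    logL0 <- logL0 - lamMi * st$rEmY[cand]
  }
  q <- stats::plogis(log(st$psi) - log1p(-st$psi) + logL0)
  st$z[cand] <- stats::rbinom(length(cand), 1L, q)
  st
}

.upd_lamM <- function(st, step, bump) {
  sexes <- if (st$ssx) c(1L, 0L) else NA
  for (sx in sexes) {
    rows <- which(st$z == 1L & (if (st$ssx) st$sex == sx else TRUE))
    cur <- st$lamM[if (st$ssx) 2L - sx else 1L]
    prop <- cur * exp(stats::rnorm(1L, 0, step))
    if (prop > st$pri$lambda0_max) { bump("lamM", 0); next }
    dll <- -(prop - cur) * sum(st$rEmY[rows])
    nzm <- st$nzM
    if (length(nzm)) {
      keep <- nzm[, 1L] %in% rows
      if (any(keep)) {
        h <- st$HM[nzm[keep, , drop = FALSE]]
        y <- st$YM[nzm[keep, , drop = FALSE]]
        dll <- dll + sum(y * (log1p(-exp(-prop * h)) -
                                log1p(-exp(-cur * h))))
      }
    }
    dll <- dll + log(prop / cur)
    if (log(stats::runif(1L)) < dll) {
      if (st$ssx) st$lamM[2L - sx] <- prop else st$lamM[] <- prop
      bump("lamM", 1)
    } else bump("lamM", 0)
  }
  st
}

.upd_lamR <- function(st, step, bump) {
  sexes <- if (st$ssx) c(1L, 0L) else NA
  for (sx in sexes) {
    rows <- which(st$z == 1L & (if (st$ssx) st$sex == sx else TRUE))
    cur <- st$lamR[if (st$ssx) 2L - sx else 1L]
    prop <- cur * exp(stats::rnorm(1L, 0, step))
    if (prop > st$pri$lambda0_max) { bump("lamR", 0); next }
    ytot <- if (st$ssx) sum(st$yv[st$nz[, 1L] %in% rows]) else sum(st$yv)
    dll <- -(prop - cur) * sum(st$rER[rows]) +
      ytot * (log(prop) - log(cur)) + log(prop / cur)
    if (log(stats::runif(1L)) < dll) {
      if (st$ssx) st$lamR[2L - sx] <- prop else st$lamR[] <- prop
      bump("lamR", 1)
    } else bump("lamR", 0)
  }
  st
}

.upd_sigd <- function(st, step, bump) {
  nz <- st$nz
  sexes <- if (st$ssx) c(1L, 0L) else NA
  for (sx in sexes) {
    cur <- st$sigd[if (st$ssx) 2L - sx else 1L]
    prop <- cur * exp(stats::rnorm(1L, 0, step))
    if (prop > st$pri$sigma_d_max) { bump("sig", 0); next }
    grp <- if (st$ssx) which(st$sex == sx) else seq_len(st$A)
    rows <- grp[st$z[grp] == 1L]
    lamRi <- st$lamR[2L - st$sex]
    # decide on the included rows only; excluded rows are refreshed on accept
    HRp <- exp(-st$D2R[rows, , drop = FALSE] / (2 * prop^2))
    rERp <- rowSums(st$ER[rows, , drop = FALSE] * HRp)
    dll <- -sum(lamRi[rows] * (rERp - st$rER[rows]))
    if (nrow(nz)) {
      keep <- nz[, 1L] %in% rows
      if (any(keep)) {
        i <- nz[keep, 1L]; j <- nz[keep, 2L]
        gi <- match(i, rows)
        dll <- dll + sum(st$yv[keep] *
                           (log(HRp[cbind(gi, j)]) - log(st$HR[cbind(i, j)])))
      }
    }
    if (st$gen) {
      lamMi <- st$lamM[2L - st$sex]
      HMp <- exp(-st$D2M[rows, , drop = FALSE] / (2 * prop^2))
      rEmYp <- rowSums(st$EmY[rows, , drop = FALSE] * HMp)
      dll <- dll - sum(lamMi[rows] * (rEmYp - st$rEmY[rows]))
      nzm <- st$nzM
      if (length(nzm)) {
        keep <- nzm[, 1L] %in% rows
        if (any(keep)) {
          i <- nzm[keep, 1L]; j <- nzm[keep, 2L]
          gi <- match(i, rows)
          y <- st$YM[cbind(i, j)]
          dll <- dll + sum(y * (log1p(-exp(-lamMi[i] * HMp[cbind(gi, j)])) -
                                  log1p(-exp(-lamMi[i] * st$HM[cbind(i, j)]))))
        }
      }
    }
    if (st$tel) {
      ti <- intersect(which(st$ntel > 0), grp)
      if (length(ti)) {
        SS <- sum(st$tss[ti] - 2 * (st$sR[ti, 1L] * st$tsx[ti] +
                                      st$sR[ti, 2L] * st$tsy[ti]) +
                    st$ntel[ti] * rowSums(st$sR[ti, , drop = FALSE]^2))
        ntot <- sum(st$ntel[ti])
        dll <- dll - 2 * ntot * (log(prop) - log(cur)) -
          SS / 2 * (1 / prop^2 - 1 / cur^2)
      }
    }
    dll <- dll + log(prop / cur)
    if (is.finite(dll) && log(stats::runif(1L)) < dll) {
      if (st$ssx) st$sigd[2L - sx] <- prop else st$sigd[] <- prop
      st$HR[rows, ] <- HRp
      st$rER[rows] <- rERp
      if (st$gen) { st$HM[rows, ] <- HMp; st$rEmY[rows] <- rEmYp }
      rest <- setdiff(grp, rows)
      if (length(rest)) {
        st$HR[rest, ] <- exp(-st$D2R[rest, , drop = FALSE] / (2 * prop^2))
        st$rER[rest] <- rowSums(st$ER[rest, , drop = FALSE] *
                                  st$HR[rest, , drop = FALSE])
        if (st$gen) {
          st$HM[rest, ] <- exp(-st$D2M[rest, , drop = FALSE] / (2 * prop^2))
          st$rEmY[rest] <- rowSums(st$EmY[rest, , drop = FALSE] *
                                     st$HM[rest, , drop = FALSE])
        }
      }
      bump("sig", 1)
    } else bump("sig", 0)
  }
  st
}

# full observation log-likelihood over included rows at pooled parameter
# values (drops count factorials and binomial coefficients, which cancel
# in every ratio this is used for)
.ll_obs <- function(st, sigd, lamR, lamM) {
  rows <- which(st$z == 1L)
  HR <- exp(-st$D2R[rows, , drop = FALSE] / (2 * sigd^2))
  ll <- -lamR * sum(st$ER[rows, , drop = FALSE] * HR)
  nz <- st$nz
  if (nrow(nz)) {
    gi <- match(nz[, 1L], rows)
    ll <- ll + sum(st$yv * (log(lamR) + log(HR[cbind(gi, nz[, 2L])])))
  }
  if (st$gen) {
    HM <- exp(-st$D2M[rows, , drop = FALSE] / (2 * sigd^2))
    ll <- ll - lamM * sum(st$EmY[rows, , drop = FALSE] * HM)
    nzm <- st$nzM
    if (length(nzm)) {
      gi <- match(nzm[, 1L], rows)
      y <- st$YM[nzm]
      ll <- ll + sum(y * log1p(-exp(-lamM * HM[cbind(gi, nzm[, 2L])])))
    }
  }
  if (st$tel) {
    ti <- which(st$ntel > 0)
    SS <- sum(st$tss[ti] - 2 * (st$sR[ti, 1L] * st$tsx[ti] +
                                  st$sR[ti, 2L] * st$tsy[ti]) +
                st$ntel[ti] * rowSums(st$sR[ti, , drop = FALSE]^2))
    ll <- ll - 2 * sum(st$ntel[ti]) * log(sigd) - SS / (2 * sigd^2)
  }
  ll
}

# same quantity at the current parameters, from the maintained kernels
.ll_obs_cached <- function(st) {
  rows <- st$z == 1L
  ll <- -st$lamR[1L] * sum(st$rER[rows])
  if (nrow(st$nz))
    ll <- ll + sum(st$yv * (log(st$lamR[1L]) + log(st$HR[st$nz])))
  if (st$gen) {
    ll <- ll - st$lamM[1L] * sum(st$rEmY[rows])
    if (length(st$nzM))
      ll <- ll + sum(st$YM[st$nzM] *
                       log1p(-exp(-st$lamM[1L] * st$HM[st$nzM])))
  }
  if (st$tel) {
    ti <- which(st$ntel > 0)
    SS <- sum(st$tss[ti] - 2 * (st$sR[ti, 1L] * st$tsx[ti] +
                                  st$sR[ti, 2L] * st$tsy[ti]) +
                st$ntel[ti] * rowSums(st$sR[ti, , drop = FALSE]^2))
    ll <- ll - 2 * sum(st$ntel[ti]) * log(st$sigd[1L]) -
      SS / (2 * st$sigd[1L]^2)
  }
  ll
}

# joint move along the (sigma_d, lambda0) ridge: expected exposure to
# detection scales roughly with lambda0 * sigma^2, so scale sigma up and
# the baselines down together
.upd_ridge <- function(st, step, bump) {
  eps <- stats::rnorm(1L, 0, step)
  sig_p <- st$sigd[1L] * exp(eps)
  lamR_p <- st$lamR[1L] * exp(-2 * eps)
  lamM_p <- if (st$gen) st$lamM[1L] * exp(-2 * eps) else 0
  if (sig_p > st$pri$sigma_d_max || lamR_p > st$pri$lambda0_max ||
        (st$gen && lamM_p > st$pri$lambda0_max)) {
    bump("ridge", 0); return(st)
  }
  dll <- .ll_obs(st, sig_p, lamR_p, lamM_p) - .ll_obs_cached(st)
  dll <- dll + log(sig_p / st$sigd[1L]) + log(lamR_p / st$lamR[1L]) +
    if (st$gen) log(lamM_p / st$lamM[1L]) else 0
  if (is.finite(dll) && log(stats::runif(1L)) < dll) {
    st$sigd[] <- sig_p
    st$lamR[] <- lamR_p
    if (st$gen) st$lamM[] <- lamM_p
    st <- .refresh_H(st)
    bump("ridge", 1)
  } else bump("ridge", 0)
  st
}

.upd_sigt <- function(st, step, bump) {
  ss <- st$ss
  cur <- st$sigt
  prop <- cur * exp(stats::rnorm(1L, 0, step))
  if (prop > st$pri$sigma_t_max) { bump("sigt", 0); return(st) }
  # augmented individuals carry no marking captures or telemetry, so
  # their relocation steps are resampled from the truncated kernel at
  # the proposed sigma_t as part of the joint proposal: the kernel and
  # truncation factors then cancel exactly against the target, leaving
  # only the (small) zero-detection likelihood corrections. Individuals
  # without detections redraw s_R around s_M; owners of records (whose
  # s_R is data-pinned) redraw s_M around s_R. Only marked individuals
  # anchor sigma_t through data.
  rs <- which(seq_len(st$A) > st$nM & st$z == 0L)
  an <- setdiff(seq_len(st$A), rs)
  dll <- log(prop / cur)                       # log-RW Jacobian
  sRn <- NULL
  if (length(rs)) {
    # excluded individuals carry no likelihood: resampling their s_R
    # from the kernel at the proposed scale cancels all kernel,
    # truncation and proposal factors exactly
    sRn <- rtnorm2_rect(st$sM[rs, , drop = FALSE], prop, ss)
  }
  if (length(an)) {
    r2 <- rowSums((st$sR[an, , drop = FALSE] - st$sM[an, , drop = FALSE])^2)
    Ta <- transience_truncmass(st$sM[an, , drop = FALSE], cur, ss)
    Tp <- transience_truncmass(st$sM[an, , drop = FALSE], prop, ss)
    dll <- dll - 2 * length(an) * (log(prop) - log(cur)) -
      sum(r2) / 2 * (1 / prop^2 - 1 / cur^2) + sum(log(Ta) - log(Tp))
  }
  if (is.finite(dll) && log(stats::runif(1L)) < dll) {
    st$sigt <- prop
    if (length(rs)) {
      st$sR[rs, ] <- sRn
      st <- .refresh_rows(st, rs)
    }
    bump("sigt", 1)
  } else bump("sigt", 0)
  st
}

#' Fit a null spatial capture-recapture model
#'
#' Poisson-count spatial capture-recapture with fully identified detection
#' histories: the machinery of [run_mcmc()] with the latent-identity
#' allocation fixed (no unmarked records), no marking process and no
#' telemetry. Used by the design-evaluation harness.
#'
#' @param counts n x J matrix of per-individual, per-detector counts
#'   summed across occasions (rows are detected individuals).
#' @param traps a [trap_array()] with the operation schedule.
#' @param ss state space.
#' @param config an [mcmc_config()].
#' @param A augmentation size.
#' @return An `smr_chains` object.
#' @export
fit_null_scr <- function(counts, traps, ss, config = mcmc_config(),
                         A = 300L) {
  counts <- as.matrix(counts)
  n <- nrow(counts)
  K <- ncol(traps$operation)
  expo <- build_exposure(matrix(0, 1L, 1L), traps$operation,
                         n_marked = max(n, 1L))
  if (n == 0L) expo$E_R <- expo$E_R[0L, , drop = FALSE]
  # expand summed counts into identified per-occasion records: occasion
  # labels are immaterial here (no latent allocation), spread arbitrarily
  nz <- which(counts > 0, arr.ind = TRUE)
  mrec <- if (nrow(nz)) {
    data.frame(individual = rep(nz[, 1L], counts[nz]),
               trap = rep(nz[, 2L], counts[nz]), occasion = 1L)
  } else data.frame(individual = integer(), trap = integer(),
                    occasion = integer())
  dat <- smr_data(live_traps = NULL, cameras = traps, Y_M = NULL,
                  marked_resights = mrec,
                  U = data.frame(trap = integer(), occasion = integer(),
                                 obs_sex = character()),
                  telemetry = NULL,
                  sex_marked = integer(n),
                  exposure = expo)
  spec <- model_spec(generalized = FALSE, use_telemetry = FALSE,
                     use_transience = FALSE, use_sex_constraint = FALSE,
                     sex_specific = FALSE, A = A)
  run_mcmc(dat, ss, spec, config)
}
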