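# Pre-compiled evaluation design for a dataset: observation vectors plus an
# (observation, dose) pairing so concentrations for the whole cohort are one
# vectorized superposition, and per-subject covariate terms for estimable
# covariate effects.
build_design <- function(dataset, effects = list()) {
  ids <- unique(dataset$ID)
  n <- length(ids)
  obs <- dataset[dataset$EVID == 0 & dataset$MDV == 0, , drop = FALSE]
  dos <- dataset[dataset$EVID == 1, , drop = FALSE]
  obs_sub <- match(obs$ID, ids)
  pair_obs <- integer(0); pair_sub <- integer(0)
  pair_te <- numeric(0); pair_amt <- numeric(0); pair_dur <- numeric(0)
  for (j in seq_len(n)) {
    oi <- which(obs_sub == j)
    di <- which(dos$ID == ids[j])
    if (!length(oi) || !length(di)) next
    te <- outer(obs$TIME[oi], dos$TIME[di], `-`)   # rows obs, cols doses
    keep <- which(te > 0)
    if (!length(keep)) stop("subject ", ids[j], " has no dose before its observations")
    rr <- ((keep - 1) %% length(oi)) + 1
    cc <- ((keep - 1) %/% length(oi)) + 1
    pair_obs <- c(pair_obs, oi[rr])
    pair_sub <- c(pair_sub, rep(j, length(keep)))
    pair_te <- c(pair_te, te[keep])
    pair_amt <- c(pair_amt, dos$AMT[di][cc])
    pair_dur <- c(pair_dur, dos$DUR[di][cc])
  }
  # covariate design: one column per effect, x such that the log-multiplier
  # on the target parameter is u * x (u the unconstrained effect coefficient)
  n_eff <- length(effects)
  X <- matrix(0, n, max(n_eff, 1))
  eff_par <- integer(n_eff)
  sub_first <- match(ids, dataset$ID)
  for (e in seq_len(n_eff)) {
    ce <- effects[[e]]
    v <- dataset[[ce$covariate]][sub_first]
    if (is.null(v) || any(is.na(v))) stop("missing covariate column: ", ce$covariate)
    X[, e] <- if (ce$kind == "power") log(v / ce$cov_median) else v
    eff_par[e] <- match(ce$parameter, c("CL", "Vc", "Vp", "Q"))
  }
  list(ids = ids, n = n, y = obs$DV, n_obs = nrow(obs), obs_sub = obs_sub,
       pair_obs = pair_obs, pair_sub = pair_sub, pair_te = pair_te,
       pair_amt = pair_amt, pair_dur = pair_dur,
       X = X, eff_par = eff_par, n_eff = n_eff)
}

# Model predictions for all observation rows given per-subject log-parameter
# matrix LP (n x 4, columns CL, Vc, Vp, Q on the log scale).
design_conc <- function(design, LP) {
  i <- design$pair_sub
  cc <- conc2_single(design$pair_te, exp(LP[i, 1]), exp(LP[i, 2]),
                     exp(LP[i, 3]), exp(LP[i, 4]),
                     design$pair_amt, design$pair_dur)
  f <- numeric(design$n_obs)
  rs <- rowsum(cc, design$pair_obs)
  f[as.integer(rownames(rs))] <- rs
  f
}

# Baseline log-parameters (typical values + covariate terms), n x 4.
design_lp_base <- function(design, theta, u_cov) {
  LP <- matrix(rep(log(theta), each = design$n), design$n, 4)
  for (e in seq_len(design$n_eff)) {
    LP[, design$eff_par[e]] <- LP[, design$eff_par[e]] + u_cov[e] * design$X[, e]
  }
  LP
}

# Joint -2 log-density pieces. Returns per-subject h(eta) given the eta
# matrix E (n x k), plus fitted values. Includes all 2*pi constants so the
# k = 0 case is the exact Gaussian deviance.
make_h <- function(design, theta, u_cov, eta_par, Oinv, logdet2piO, sp, sa) {
  LP0 <- design_lp_base(design, theta, u_cov)
  force(eta_par)
  function(E) {
    LP <- LP0
    if (length(eta_par)) LP[, eta_par] <- LP[, eta_par, drop = FALSE] + E
    f <- design_conc(design, LP)
    s2 <- sa^2 + (sp * f)^2
    bad_var <- is.finite(f) & s2 <= 0
    if (any(bad_var)) {
      stop("zero predicted variance for subject ",
           design$ids[design$obs_sub[which(bad_var)[1]]])
    }
    r <- design$y - f
    li <- log(2 * pi * s2) + r^2 / s2
    li[!is.finite(li)] <- 1e12   # overflowed prediction: reject in line search
    h <- numeric(design$n)
    rs <- rowsum(li, design$obs_sub)
    h[as.integer(rownames(rs))] <- rs
    if (length(eta_par)) {
      h <- h + rowSums((E %*% Oinv) * E) + logdet2piO
    }
    list(h = h, f = f)
  }
}

# Per-subject gradient and Hessian of h by central finite differences,
# vectorized across subjects. Returns list(g = n x k, H = n x k x k).
h_derivs <- function(hfun, E, h0, k, delta = 1e-4) {
  n <- nrow(E)
  g <- matrix(0, n, k)
  H <- array(0, c(n, k, k))
  hp <- hm <- matrix(0, n, k)
  for (i in seq_len(k)) {
    Ei <- E; Ei[, i] <- Ei[, i] + delta
    hp[, i] <- hfun(Ei)$h
    Ei <- E; Ei[, i] <- Ei[, i] - delta
    hm[, i] <- hfun(Ei)$h
    g[, i] <- (hp[, i] - hm[, i]) / (2 * delta)
    H[, i, i] <- (hp[, i] + hm[, i] - 2 * h0) / delta^2
  }
  if (k > 1) {
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      Eij <- E; Eij[, i] <- Eij[, i] + delta; Eij[, j] <- Eij[, j] + delta
      hij <- hfun(Eij)$h
      H[, i, j] <- H[, j, i] <- (hij - hp[, i] - hp[, j] + h0) / delta^2
    }
  }
  list(g = g, H = H)
}

# Solve H p = -g per subject. Indefinite Hessians (far from the mode) get a
# Levenberg-style diagonal shift large enough to keep the system well
# conditioned, so the step stays a descent direction of moderate length.
newton_step <- function(g, H, k) {
  n <- nrow(g)
  P <- matrix(0, n, k)
  if (k == 1) {
    a <- H[, 1, 1]
    a <- pmax(a, 1e-3 * pmax(abs(a), 1))
    P[, 1] <- -g[, 1] / a
  } else if (k == 2) {
    a <- H[, 1, 1]; b <- H[, 1, 2]; c <- H[, 2, 2]
    disc <- sqrt((a - c)^2 + 4 * b^2)
    lmin <- ((a + c) - disc) / 2
    lmax <- ((a + c) + disc) / 2
    bump <- pmax(-lmin, 0) + 1e-3 * pmax(lmax, 1)
    a <- a + bump; c <- c + bump
    det <- a * c - b^2
    P[, 1] <- -( c * g[, 1] - b * g[, 2]) / det
    P[, 2] <- -(-b * g[, 1] + a * g[, 2]) / det
  } else {
    for (s in seq_len(n)) {
      ev <- eigen(H[s, , ], symmetric = TRUE)
      lam <- pmax(ev$values, 1e-3 * max(abs(ev$values), 1))
      P[s, ] <- -ev$vectors %*% ((t(ev$vectors) %*% g[s, ]) / lam)
    }
  }
  P
}

# Vectorized damped Newton for the per-subject eta modes. Converges on the
# per-subject gradient norm; a stagnation counter guards against line-search
# breakdown far from the mode.
inner_solve <- function(hfun, E0, k, max_iter = 50, tol = 1e-5) {
  E <- E0
  h0 <- hfun(E)$h
  for (it in seq_len(max_iter)) {
    d <- h_derivs(hfun, E, h0, k)
    if (max(abs(d$g)) < tol) break
    P <- newton_step(d$g, d$H, k)
    # trust region: rescale (never clamp) so the direction is preserved
    len <- sqrt(rowSums(P^2))
    P <- P * pmin(2 / pmax(len, 1e-12), 1)
    step <- rep(1, nrow(E))
    Enew <- E + P
    hnew <- hfun(Enew)$h
    for (half in seq_len(12)) {
      worse <- hnew > h0 + 1e-10
      if (!any(worse)) break
      step[worse] <- step[worse] / 2
      Enew[worse, ] <- E[worse, , drop = FALSE] +
        P[worse, , drop = FALSE] * step[worse]
      hnew <- hfun(Enew)$h
    }
    worse <- hnew > h0 + 1e-10  # give up on subjects that never improved
    if (any(worse)) {
      Enew[worse, ] <- E[worse, , drop = FALSE]
      hnew[worse] <- h0[worse]
    }
    moved <- max(abs(Enew - E))
    E <- Enew; h0 <- pmin(hnew, h0)
    if (moved < 1e-9) break  # deterministic stagnation: repeating is futile
  }
  d <- h_derivs(hfun, E, h0, k)
  list(E = E, h = h0, g = d$g, H = d$H)
}

# Laplace-with-interaction objective function value (-2 log marginal
# likelihood). `m` is an unpacked parameter list; E_warm optional warm-start
# eta matrix.
ofv_internal <- function(design, m, E_warm = NULL) {
  k <- length(m$eta_par)
  if (k == 0) {
    hf <- make_h(design, m$theta, m$u_cov, integer(0), NULL, 0,
                 m$sigma_prop, m$sigma_add)
    return(list(ofv = sum(hf(matrix(0, design$n, 0))$h),
                E = matrix(0, design$n, 0), f = NULL))
  }
  O <- m$omega
  ch <- tryCatch(chol(O), error = function(e) NULL)
  if (is.null(ch)) stop("omega is not positive definite")
  Oinv <- chol2inv(ch)
  logdet2piO <- k * log(2 * pi) + 2 * sum(log(diag(ch)))
  hf <- make_h(design, m$theta, m$u_cov, m$eta_par, Oinv, logdet2piO,
               m$sigma_prop, m$sigma_add)
  E0 <- if (is.null(E_warm) || !all(dim(E_warm) == c(design$n, k))) {
    matrix(0, design$n, k)
  } else E_warm
  sol <- inner_solve(hf, E0, k)
  # try a cold start for any subject that looks unconverged
  if (max(abs(sol$g)) > 1e-3 && !is.null(E_warm)) {
    sol2 <- inner_solve(hf, matrix(0, design$n, k), k)
    use2 <- sol2$h < sol$h
    if (any(use2)) {
      sol$E[use2, ] <- sol2$E[use2, , drop = FALSE]
      sol$h[use2] <- sol2$h[use2]
      sol$H[use2, , ] <- sol2$H[use2, , , drop = FALSE]
    }
  }
  # log det(H/2) per subject, eigenvalues clamped for safety
  ld <- numeric(design$n)
  if (k == 1) {
    ld <- log(pmax(sol$H[, 1, 1], 1e-10) / 2)
  } else if (k == 2) {
    a <- sol$H[, 1, 1]; b <- sol$H[, 1, 2]; c <- sol$H[, 2, 2]
    tr <- a + c; disc <- sqrt(pmax((a - c)^2 + 4 * b^2, 0))
    l1 <- pmax((tr + disc) / 2, 1e-10); l2 <- pmax((tr - disc) / 2, 1e-10)
    ld <- log(l1 / 2) + log(l2 / 2)
  } else {
    for (s in seq_len(design$n)) {
      ev <- eigen(sol$H[s, , ], symmetric = TRUE, only.values = TRUE)$values
      ld[s] <- sum(log(pmax(ev, 1e-10) / 2))
    }
  }
  list(ofv = sum(sol$h) - design$n * k * log(2 * pi) + sum(ld),
       E = sol$E, h = sol$h)
}

# ---- parameter packing -----------------------------------------------------

# Unconstrained parameterization: log theta (4), omega via log-Cholesky
# (diagonal logs, off-diagonals raw, row-major lower triangle), log sigmas,
# covariate coefficients u (power exponent, or log of a binary multiplier).
pack_model <- function(pop) {
  k <- nrow(pop$omega)
  p <- log(pop$theta)
  names(p) <- paste0("l", names(pop$theta))
  if (k > 0) {
    L <- t(chol(pop$omega + diag(1e-12, k)))
    v <- numeric(0)
    for (i in seq_len(k)) for (j in seq_len(i)) {
      v <- c(v, if (i == j) log(L[i, j]) else L[i, j])
    }
    names(v) <- paste0("om", seq_along(v))
    p <- c(p, v)
  }
  p <- c(p, lsp = log(max(pop$sigma_prop, 1e-8)),
         lsa = log(max(pop$sigma_add, 1e-8)))
  for (e in seq_along(pop$covariate_effects)) {
    ce <- pop$covariate_effects[[e]]
    u <- if (ce$kind == "power") ce$theta_cov else log(ce$theta_cov)
    p <- c(p, setNames(u, paste0("cov", e)))
  }
  p
}

unpack_model <- function(p, template) {
  k <- nrow(template$omega)
  theta <- exp(p[1:4])
  names(theta) <- names(template$theta)
  idx <- 4
  omega <- matrix(0, k, k, dimnames = dimnames(template$omega))
  if (k > 0) {
    L <- matrix(0, k, k)
    for (i in seq_len(k)) for (j in seq_len(i)) {
      idx <- idx + 1
      L[i, j] <- if (i == j) exp(p[idx]) else p[idx]
    }
    omega <- L %*% t(L)
    dimnames(omega) <- dimnames(template$omega)
  }
  sp <- exp(p[idx + 1]); sa <- exp(p[idx + 2])
  idx <- idx + 2
  n_eff <- length(template$covariate_effects)
  u_cov <- numeric(n_eff)
  if (n_eff > 0) u_cov <- unname(p[idx + seq_len(n_eff)])
  eta_par <- match(rownames(template$omega), c("CL", "Vc", "Vp", "Q"))
  list(theta = theta, omega = omega, sigma_prop = sp, sigma_add = sa,
       u_cov = u_cov, eta_par = eta_par)
}

# Rebuild a population_model from an unpacked parameter list.
model_from_unpacked <- function(m, template) {
  effs <- template$covariate_effects
  for (e in seq_along(effs)) {
    effs[[e]]$theta_cov <- if (effs[[e]]$kind == "power") m$u_cov[e] else exp(m$u_cov[e])
  }
  population_model(theta = m$theta, omega = m$omega,
                   sigma_prop = m$sigma_prop, sigma_add = m$sigma_add,
                   covariate_effects = effs)
}

# Fill in unset covariate medians from the dataset (first record/subject).
resolve_cov_medians <- function(pop, dataset) {
  for (e in seq_along(pop$covariate_effects)) {
    ce <- pop$covariate_effects[[e]]
    if (ce$kind == "power" && is.na(ce$cov_median)) {
      ids <- unique(dataset$ID)
      v <- dataset[[ce$covariate]][match(ids, dataset$ID)]
      pop$covariate_effects[[e]]$cov_median <- median(v)
    }
  }
  pop
}

# ---- public API ------------------------------------------------------------

#' Objective function value of a population model on a dataset
#'
#' Computes \eqn{-2 \log} of the approximate marginal likelihood by the
#' Laplace approximation with interaction (the residual variance is
#' evaluated at individual predictions): per subject the joint
#' \eqn{-2\log}-density is minimized over the random effects and the
#' curvature correction \eqn{\log\det(H/2)} added. With no (or all-zero)
#' `omega` the value is the exact Gaussian \eqn{-2} log-likelihood,
#' including all \eqn{2\pi} constants.
#'
#' @param dataset A [pk_dataset()].
#' @param model A [population_model()] (covariate medians resolved from the
#'   dataset if unset).
#' @return The objective function value (scalar).
#' @export
ofv <- function(dataset, model) {
  stopifnot(inherits(dataset, "pk_dataset"), inherits(model, "population_model"))
  model <- resolve_cov_medians(model, dataset)
  if (nrow(model$omega) > 0 && all(model$omega == 0)) {
    model$omega <- matrix(numeric(0), 0, 0)
  }
  design <- build_design(dataset, model$covariate_effects)
  m <- unpack_model(pack_model(model), model)
  ofv_internal(design, m)$ofv
}

#' Fit a population PK model by approximate marginal maximum likelihood
#'
#' Minimizes the Laplace-with-interaction objective over the free
#' parameters: typical values on the log scale, the IIV covariance through
#' its log-Cholesky factor, log residual SDs, and covariate coefficients.
#' Outer optimization is Nelder-Mead followed by a restarted polish; the
#' inner random-effect modes use a damped Newton iteration vectorized across
#' subjects, warm-started between outer iterations.
#'
#' @param dataset A [pk_dataset()].
#' @param model_spec A [population_model()] holding initial values and the
#'   model structure (omega block pattern, covariate effects).
#' @param fixed Character vector of components to hold at their initial
#'   values: any of `"CL"`, `"Vc"`, `"Vp"`, `"Q"`, `"omega"`,
#'   `"sigma_prop"`, `"sigma_add"`.
#' @param compute_se Compute relative standard errors from the
#'   finite-difference observed information (adds ~2 k^2 objective
#'   evaluations); default `TRUE`.
#' @param control List: `maxit_nm` (first Nelder-Mead iterations, default
#'   500), `maxit_polish` (restart iterations, default 200), `reltol`
#'   (default 1e-8).
#' @return A `fit_result` list: `estimates` ([population_model()]), `ofv`,
#'   `rse` (named, %), `etas` (empirical-Bayes modes, one row per subject),
#'   `shrinkage_eta` (named, %), `shrinkage_eps` (%), `converged`,
#'   `n_subjects`, `n_obs`, `ids`.
#' @export
fit_poppk <- function(dataset, model_spec, fixed = character(),
                      compute_se = TRUE, control = list()) {
  stopifnot(inherits(dataset, "pk_dataset"),
            inherits(model_spec, "population_model"))
  if (length(unique(dataset$ID)) < 2) stop("need at least 2 subjects")
  ctl <- modifyList(list(maxit_nm = 500, max_restarts = 8, tol_restart = 0.01,
                         reltol = 1e-8),
                    control)
  model_spec <- resolve_cov_medians(model_spec, dataset)
  design <- build_design(dataset, model_spec$covariate_effects)
  p0 <- pack_model(model_spec)
  free <- rep(TRUE, length(p0))
  names(free) <- names(p0)
  for (fx in fixed) {
    free[names(p0) %in% switch(fx,
      CL = "lCL", Vc = "lVc", Vp = "lVp", Q = "lQ",
      omega = grep("^om", names(p0), value = TRUE),
      sigma_prop = "lsp", sigma_add = "lsa",
      stop("unknown fixed component: ", fx))] <- FALSE
  }
  env <- new.env()
  env$E_warm <- NULL
  obj <- function(pf) {
    p <- p0; p[free] <- pf
    m <- unpack_model(p, model_spec)
    out <- tryCatch(ofv_internal(design, m, env$E_warm),
                    error = function(e) NULL)
    if (is.null(out) || !is.finite(out$ofv)) return(1e10)
    env$E_warm <- out$E
    out$ofv
  }
  # restarted Nelder-Mead: fresh simplices until the OFV stops improving
  cur <- list(par = p0[free], value = obj(p0[free]))
  improve <- Inf
  for (r in seq_len(ctl$max_restarts)) {
    nxt <- optim(cur$par, obj, method = "Nelder-Mead",
                 control = list(maxit = ctl$maxit_nm, reltol = ctl$reltol))
    improve <- cur$value - nxt$value
    if (nxt$value <= cur$value) cur <- nxt
    if (r > 1 && improve < ctl$tol_restart) break
  }
  o2 <- cur
  converged <- is.finite(o2$value) && improve < ctl$tol_restart
  p_hat <- p0; p_hat[free] <- o2$par
  m_hat <- unpack_model(p_hat, model_spec)
  final <- ofv_internal(design, m_hat)  # cold start: deterministic report
  est <- model_from_unpacked(m_hat, model_spec)

  # empirical-Bayes etas, shrinkage
  k <- length(m_hat$eta_par)
  etas <- final$E
  if (k > 0) colnames(etas) <- rownames(model_spec$omega)
  shr_eta <- if (k > 0) {
    om_sd <- sqrt(diag(m_hat$omega))
    100 * (1 - apply(etas, 2, sd) / om_sd)
  } else numeric(0)
  # epsilon shrinkage from IWRES at individual predictions
  LP <- design_lp_base(design, m_hat$theta, m_hat$u_cov)
  if (k > 0) LP[, m_hat$eta_par] <- LP[, m_hat$eta_par, drop = FALSE] + etas
  f_ind <- design_conc(design, LP)
  iwres <- (design$y - f_ind) /
    sqrt(m_hat$sigma_add^2 + (m_hat$sigma_prop * f_ind)^2)
  shr_eps <- 100 * (1 - sd(iwres))

  rse <- NULL
  if (compute_se) {
    rse <- tryCatch(compute_rse(obj, o2$par, p0, free, model_spec),
                    error = function(e) NULL)
  }
  structure(list(estimates = est, ofv = final$ofv, rse = rse,
                 etas = etas, shrinkage_eta = shr_eta,
                 shrinkage_eps = shr_eps, converged = converged,
                 n_subjects = design$n, n_obs = design$n_obs,
                 ids = design$ids),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("popPK fit: OFV = %.3f (%s), %d subjects / %d observations\n",
              x$ofv, if (x$converged) "converged" else "NOT converged",
              x$n_subjects, x$n_obs))
  print(x$estimates)
  if (length(x$shrinkage_eta)) {
    cat(sprintf("  eta shrinkage (%%): %s;  eps shrinkage: %.1f%%\n",
                paste(sprintf("%s=%.1f", names(x$shrinkage_eta),
                              x$shrinkage_eta), collapse = "  "),
                x$shrinkage_eps))
  }
  invisible(x)
}

# RSE (%) for the reported natural-scale quantities via the inverse observed
# information of the OFV and a numerical delta method. The Hessian step is
# wide (0.01 on the unconstrained scale) so finite-difference noise from the
# inner optimization stays well below the curvature signal.
compute_rse <- function(obj, pf_hat, p0, free, template, step = 0.01) {
  kf <- length(pf_hat)
  H <- matrix(0, kf, kf)
  f0 <- obj(pf_hat)
  for (i in seq_len(kf)) for (j in i:kf) {
    pp <- function(si, sj) {
      p <- pf_hat; p[i] <- p[i] + si * step; p[j] <- p[j] + sj * step
      obj(p)
    }
    H[i, j] <- H[j, i] <- if (i == j) {
      (pp(1, 0) + pp(-1, 0) - 2 * f0) / step^2
    } else {
      (pp(1, 1) - pp(1, -1) - pp(-1, 1) + pp(-1, -1)) / (4 * step^2)
    }
  }
  covu <- 2 * solve((H + t(H)) / 2)
  nat <- function(pf) {
    p <- p0; p[free] <- pf
    m <- unpack_model(p, template)
    k <- nrow(template$omega)
    v <- m$theta
    if (k > 0) {
      v <- c(v, setNames(cv_percent(diag(m$omega)),
                         paste0("IIV_", rownames(template$omega))))
    }
    v <- c(v, sigma_prop = 100 * m$sigma_prop, sigma_add = m$sigma_add)
    if (length(m$u_cov)) v <- c(v, setNames(m$u_cov,
      paste0("cov", seq_along(m$u_cov))))
    v
  }
  v0 <- nat(pf_hat)
  jstep <- 1e-5  # nat() is noise-free, so a small step is fine
  J <- matrix(0, length(v0), kf)
  for (i in seq_len(kf)) {
    p1 <- pf_hat; p1[i] <- p1[i] + jstep
    p2 <- pf_hat; p2[i] <- p2[i] - jstep
    J[, i] <- (nat(p1) - nat(p2)) / (2 * jstep)
  }
  vv <- diag(J %*% covu %*% t(J))
  se <- ifelse(vv > 0, sqrt(vv), NA_real_)  # NA where information is not PD
  setNames(100 * se / abs(v0), names(v0))
}

#' Shrinkage of empirical-Bayes estimates
#'
#' Eta shrinkage is \eqn{100(1 - SD(\hat\eta)/\omega)} per random-effect
#' dimension; epsilon shrinkage is \eqn{100(1 - SD(IWRES))} with IWRES the
#' individually weighted residuals. Both are already computed by
#' [fit_poppk()]; this accessor returns them together.
#'
#' @param fit A `fit_result`.
#' @return List with `eta` (named, %) and `eps` (%).
#' @export
shrinkage <- function(fit) {
  stopifnot(inherits(fit, "fit_result"))
  list(eta = fit$shrinkage_eta, eps = fit$shrinkage_eps)
}

#' Likelihood-ratio thresholds for stepwise covariate modelling
#'
#' Chi-square (1 df) quantiles rounded to two decimals: 3.84 at p = 0.05
#' (forward inclusion) and 10.83 at p = 0.001 (backward elimination).
#'
#' @return Named vector `c(forward = 3.84, backward = 10.83)`.
#' @export
lrt_thresholds <- function() {
  c(forward = round(qchisq(0.95, df = 1), 2),
    backward = round(qchisq(0.999, df = 1), 2))
}

#' Forward-inclusion / backward-elimination decision
#'
#' Forward: include if the OFV drop is at least 3.84. Backward: retain only
#' if removing the effect raises the OFV by strictly more than 10.83.
#'
#' @param delta_ofv OFV difference (reduced minus extended model; positive
#'   means the effect improves the fit).
#' @param step `"forward"` or `"backward"`.
#' @return Logical: include (forward) or retain (backward).
#' @export
lrt_decision <- function(delta_ofv, step = c("forward", "backward")) {
  step <- match.arg(step)
  if (!is.finite(delta_ofv)) stop("delta_ofv must be finite")
  th <- lrt_thresholds()
  if (step == "forward") delta_ofv >= th["forward"] else delta_ofv > th["backward"]
}

eff_label <- function(ce) paste0(ce$covariate, "-on-", ce$parameter)

#' Stepwise covariate search (forward inclusion, backward elimination)
#'
#' Greedy forward selection: each round, every remaining candidate is added
#' alone to the current model and refitted; the candidate with the largest
#' significant OFV drop (>= 3.84) is included. After no candidate qualifies,
#' the included effects are subjected to backward elimination: each is
#' removed in turn, and the effect whose removal raises the OFV the least is
#' dropped unless the rise exceeds 10.83, until all survivors are
#' significant at the stricter level. Candidates whose fits fail to converge
#' are skipped with a warning. Ties break by candidate order.
#'
#' @param dataset A [pk_dataset()].
#' @param base A [population_model()] (structural model without the tested
#'   effects), used for initial values.
#' @param candidates List of [covariate_effect()] objects.
#' @param fixed,control Passed to [fit_poppk()].
#' @return A `covariate_search_result`: `trace` (data.frame of tested
#'   models), `included` (list of effects), `fit` (final `fit_result`).
#' @export
covariate_search <- function(dataset, base, candidates, fixed = character(),
                             control = list()) {
  stopifnot(inherits(base, "population_model"))
  base_fit <- fit_poppk(dataset, base, fixed = fixed, compute_se = FALSE,
                        control = control)
  current <- base_fit
  included <- list()
  remaining <- candidates
  trace <- data.frame(step = character(), effect = character(),
                      ofv = numeric(), delta_ofv = numeric(),
                      decision = character(), stringsAsFactors = FALSE)
  repeat {
    if (!length(remaining)) break
    deltas <- rep(NA_real_, length(remaining))
    fits <- vector("list", length(remaining))
    rows <- rep(NA_integer_, length(remaining))
    for (i in seq_along(remaining)) {
      spec <- current$estimates
      spec$covariate_effects <- c(included, remaining[i])
      f <- tryCatch(fit_poppk(dataset, spec, fixed = fixed,
                              compute_se = FALSE, control = control),
                    error = function(e) NULL)
      if (is.null(f) || !f$converged) {
        warning("forward fit failed for ", eff_label(remaining[[i]]),
                "; candidate skipped")
        next
      }
      fits[[i]] <- f
      deltas[i] <- current$ofv - f$ofv
      trace <- rbind(trace, data.frame(
        step = "forward", effect = eff_label(remaining[[i]]),
        ofv = f$ofv, delta_ofv = deltas[i], decision = "tested"))
      rows[i] <- nrow(trace)
    }
    ok <- which(!is.na(deltas) & vapply(deltas, lrt_decision, TRUE,
                                        step = "forward"))
    if (!length(ok)) break
    best <- ok[which.max(deltas[ok])]
    included <- c(included, remaining[best])
    current <- fits[[best]]
    trace$decision[rows[best]] <- "included"
    remaining <- remaining[-best]
  }
  # backward elimination
  repeat {
    if (length(included) < 1) break
    rises <- rep(NA_real_, length(included))
    fits <- vector("list", length(included))
    rows <- rep(NA_integer_, length(included))
    for (i in seq_along(included)) {
      spec <- current$estimates
      spec$covariate_effects <- included[-i]
      f <- tryCatch(fit_poppk(dataset, spec, fixed = fixed,
                              compute_se = FALSE, control = control),
                    error = function(e) NULL)
      if (is.null(f)) next
      fits[[i]] <- f
      rises[i] <- f$ofv - current$ofv
      trace <- rbind(trace, data.frame(
        step = "backward", effect = eff_label(included[[i]]),
        ofv = f$ofv, delta_ofv = rises[i], decision = "tested"))
      rows[i] <- nrow(trace)
    }
    cand <- which(!is.na(rises))
    if (!length(cand)) break
    weakest <- cand[which.min(rises[cand])]
    if (lrt_decision(rises[weakest], step = "backward")) break  # all retained
    current <- fits[[weakest]]
    trace$decision[rows[weakest]] <- "removed"
    included <- included[-weakest]
  }
  structure(list(trace = trace, included = included, fit = current,
                 base_ofv = base_fit$ofv),
            class = "covariate_search_result")
}

#' @export
print.covariate_search_result <- function(x, ...) {
  cat("Stepwise covariate search\n")
  cat(sprintf("  base OFV: %.2f, final OFV: %.2f\n", x$base_ofv, x$fit$ofv))
  if (length(x$included)) {
    cat("  included:", paste(vapply(x$included, eff_label, ""),
                             collapse = ", "), "\n")
  } else cat("  included: none\n")
  invisible(x)
}
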