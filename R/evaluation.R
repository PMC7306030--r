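# Simulate replicate observation vectors under `model` at the design
# (times, doses, covariates) of `dataset`. Returns an n_obs x n_sim matrix.
simulate_observations <- function(design, model, n_sim) {
  eta_par <- match(rownames(model$omega), c("CL", "Vc", "Vp", "Q"))
  u_cov <- vapply(model$covariate_effects, function(ce) {
    if (ce$kind == "power") ce$theta_cov else log(ce$theta_cov)
  }, numeric(1))
  k <- length(eta_par)
  LP0 <- design_lp_base(design, model$theta, u_cov)
  out <- matrix(0, design$n_obs, n_sim)
  for (s in seq_len(n_sim)) {
    LP <- LP0
    if (k > 0) {
      E <- draw_etas(design$n, model$omega)
      LP[, eta_par] <- LP[, eta_par, drop = FALSE] + E
    }
    f <- design_conc(design, LP)
    out[, s] <- f * (1 + rnorm(design$n_obs, 0, model$sigma_prop)) +
      rnorm(design$n_obs, 0, model$sigma_add)
  }
  out
}

# Time after the most recent dose for each observation row.
time_after_dose <- function(dataset) {
  obs <- dataset[dataset$EVID == 0 & dataset$MDV == 0, , drop = FALSE]
  dos <- dataset[dataset$EVID == 1, , drop = FALSE]
  vapply(seq_len(nrow(obs)), function(i) {
    dt <- dos$TIME[dos$ID == obs$ID[i] & dos$TIME < obs$TIME[i]]
    obs$TIME[i] - max(dt)
  }, numeric(1))
}

#' Nonparametric bootstrap of the population model
#'
#' Resamples subjects with replacement, refits the model to each resampled
#' dataset (initialized at `model_spec`), and summarizes the resample
#' distribution of every reported parameter by its median and 95%
#' percentile interval. Failed or non-converged fits are counted and
#' excluded; the result is flagged when more than half fail.
#'
#' @param dataset A [pk_dataset()].
#' @param model_spec A [population_model()] of initial values (typically the
#'   point estimates).
#' @param n_resamples Number of bootstrap resamples (default 1000).
#' @param seed Integer seed.
#' @param stratify_by_interval If `TRUE`, resample within dose-interval
#'   groups so each resample keeps the design's group sizes.
#' @param control Passed to [fit_poppk()].
#' @return A `bootstrap_result`: `samples` (data.frame, one row per
#'   successful resample), `summary` (median and CI per parameter),
#'   `n_success`, `n_fail`, `flagged`.
#' @export
bootstrap_poppk <- function(dataset, model_spec, n_resamples = 1000,
                            seed = NULL, stratify_by_interval = FALSE,
                            control = list()) {
  stopifnot(inherits(dataset, "pk_dataset"))
  if (!is.null(seed)) set.seed(seed)
  ids <- unique(dataset$ID)
  if (length(ids) < 2) stop("need at least 2 subjects")
  strata <- if (stratify_by_interval) {
    vapply(ids, function(id) {
      dt <- sort(dataset$TIME[dataset$ID == id & dataset$EVID == 1])
      if (length(dt) > 1) min(diff(dt)) else Inf
    }, numeric(1))
  } else rep(1, length(ids))
  samples <- list()
  n_fail <- 0L
  for (b in seq_len(n_resamples)) {
    pick <- unlist(lapply(unique(strata), function(s) {
      pool <- ids[strata == s]
      sample(pool, length(pool), replace = TRUE)
    }))
    boot <- do.call(rbind, lapply(seq_along(pick), function(i) {
      sub <- dataset[dataset$ID == pick[i], , drop = FALSE]
      sub$ID <- i
      sub
    }))
    boot <- pk_dataset(boot)
    f <- tryCatch(fit_poppk(boot, model_spec, compute_se = FALSE,
                            control = control),
                  error = function(e) NULL)
    if (is.null(f) || !f$converged) {
      n_fail <- n_fail + 1L
      next
    }
    est <- f$estimates
    row <- c(est$theta,
             if (nrow(est$omega)) setNames(cv_percent(diag(est$omega)),
                                           paste0("IIV_", rownames(est$omega))),
             sigma_prop = 100 * est$sigma_prop, sigma_add = est$sigma_add)
    samples[[length(samples) + 1]] <- row
  }
  if (!length(samples)) stop("all bootstrap fits failed")
  samples <- as.data.frame(do.call(rbind, samples))
  summ <- data.frame(
    parameter = names(samples),
    median = vapply(samples, median, 0),
    ci_lo = vapply(samples, quantile, 0, probs = 0.025),
    ci_hi = vapply(samples, quantile, 0, probs = 0.975),
    row.names = NULL)
  structure(list(samples = samples, summary = summ,
                 n_success = nrow(samples), n_fail = n_fail,
                 flagged = n_fail > n_resamples / 2),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("Bootstrap: %d successful, %d failed%s\n", x$n_success,
              x$n_fail, if (x$flagged) "  [FLAGGED: >50% failures]" else ""))
  print(x$summary, digits = 4)
  invisible(x)
}

#' Visual predictive check
#'
#' Simulates `n_sim` replicates of the dataset under the model at the
#' original design, bins observations by time after dose, and compares the
#' observed median and 5th/95th percentiles per bin with the simulated 95%
#' confidence bands of the same percentiles.
#'
#' @param dataset A [pk_dataset()].
#' @param model A [population_model()].
#' @param n_sim Simulation replicates (default 1000).
#' @param seed Integer seed.
#' @param bins Numeric vector of bin edges on the time-after-dose axis, or
#'   `NULL` to place edges between the design's nominal sampling times.
#' @param prediction_corrected If `TRUE`, observations and simulations are
#'   scaled by the ratio of the bin-median population prediction to each
#'   row's population prediction (pcVPC). Default `FALSE` (plain VPC).
#' @return A `vpc_result` with element `stats`: one row per bin with
#'   observed percentiles and simulated confidence bands.
#' @export
vpc <- function(dataset, model, n_sim = 1000, seed = NULL, bins = NULL,
                prediction_corrected = FALSE) {
  stopifnot(inherits(dataset, "pk_dataset"), inherits(model, "population_model"))
  if (!is.null(seed)) set.seed(seed)
  model <- resolve_cov_medians(model, dataset)
  design <- build_design(dataset, model$covariate_effects)
  tad <- time_after_dose(dataset)
  if (is.null(bins)) {
    # one bin per nominal sampling occasion: break between TAD quintiles
    br <- unique(quantile(tad, probs = c(0.2, 0.4, 0.6, 0.8)))
    bins <- sort(unique(c(min(tad) - 1e-9, br, max(tad) + 1e-9)))
  }
  grp <- cut(tad, breaks = bins, include.lowest = TRUE)
  y <- design$y
  sims <- simulate_observations(design, model, n_sim)
  if (prediction_corrected) {
    m <- unpack_model(pack_model(model), model)
    pred <- design_conc(design, design_lp_base(design, m$theta, m$u_cov))
    med_pred <- ave(pred, grp, FUN = median)
    corr <- ifelse(pred > 0, med_pred / pred, 1)
    y <- y * corr
    sims <- sims * corr
  }
  pcts <- c(0.05, 0.5, 0.95)
  lev <- levels(grp)
  rows <- lapply(lev, function(g) {
    sel <- which(grp == g)
    if (!length(sel)) {
      warning("empty VPC bin ", g, " dropped")
      return(NULL)
    }
    ob <- quantile(y[sel], pcts)
    sim_p <- apply(sims[sel, , drop = FALSE], 2, quantile, probs = pcts)
    ci <- apply(sim_p, 1, quantile, probs = c(0.025, 0.975))
    data.frame(bin = g, tad_mid = median(tad[sel]), n = length(sel),
               obs_p5 = ob[1], obs_med = ob[2], obs_p95 = ob[3],
               sim_p5_lo = ci[1, 1], sim_p5_hi = ci[2, 1],
               sim_med_lo = ci[1, 2], sim_med_hi = ci[2, 2],
               sim_p95_lo = ci[1, 3], sim_p95_hi = ci[2, 3],
               row.names = NULL)
  })
  structure(list(stats = do.call(rbind, rows), n_sim = n_sim,
                 prediction_corrected = prediction_corrected),
            class = "vpc_result")
}

#' Normalized prediction distribution errors
#'
#' Standard NPDE algorithm: simulate `n_sim` replicate observation vectors
#' per subject, mean-center and decorrelate both observed and simulated
#' vectors with the inverse Cholesky factor of the empirical simulated
#' covariance, rank each decorrelated observation among its simulated
#' counterparts, and transform the percentile (clipped to
#' (1/(2 n_sim), 1 - 1/(2 n_sim))) by the inverse standard-normal CDF.
#' Under a correct model the NPDEs are approximately N(0, 1).
#'
#' @inheritParams vpc
#' @param n_sim Simulation replicates (>= 100; default 1000).
#' @return An `npde_result`: `npde` (per observation), `mean`, `variance`,
#'   `normality` (Shapiro-Wilk statistic and p-value).
#' @export
npde <- function(dataset, model, n_sim = 1000, seed = NULL) {
  stopifnot(inherits(dataset, "pk_dataset"), inherits(model, "population_model"))
  if (n_sim < 100) stop("n_sim must be at least 100")
  if (!is.null(seed)) set.seed(seed)
  model <- resolve_cov_medians(model, dataset)
  design <- build_design(dataset, model$covariate_effects)
  sims <- simulate_observations(design, model, n_sim)
  out <- numeric(design$n_obs)
  for (j in seq_len(design$n)) {
    idx <- which(design$obs_sub == j)
    Yj <- sims[idx, , drop = FALSE]
    Ej <- rowMeans(Yj)
    Vj <- tcrossprod(Yj - Ej) / (n_sim - 1)
    L <- NULL
    ridge <- 0
    for (try in 1:6) {
      L <- tryCatch(t(chol(Vj + diag(ridge, nrow(Vj)))),
                    error = function(e) NULL)
      if (!is.null(L)) break
      ridge <- max(ridge * 10, 1e-8 * mean(diag(Vj)))
    }
    if (is.null(L)) stop("singular simulated covariance for subject ",
                         design$ids[j])
    if (ridge > 0) warning("ridge-regularized simulated covariance for subject ",
                           design$ids[j])
    ys <- forwardsolve(L, design$y[idx] - Ej)
    ss <- forwardsolve(L, Yj - Ej)
    pde <- (rowSums(ss < ys) + 0.5) / (n_sim + 1)
    pde <- pmin(pmax(pde, 1 / (2 * n_sim)), 1 - 1 / (2 * n_sim))
    out[idx] <- qnorm(pde)
  }
  sh <- shapiro.test(out)
  structure(list(npde = out, mean = mean(out), variance = var(out),
                 normality = list(statistic = unname(sh$statistic),
                                  p_value = sh$p.value),
                 n_sim = n_sim),
            class = "npde_result")
}

#' @export
print.npde_result <- function(x, ...) {
  cat(sprintf("NPDE (%d simulations): mean %.3f, variance %.3f, Shapiro-Wilk p = %.3g\n",
              x$n_sim, x$mean, x$variance, x$normality$p_value))
  invisible(x)
}

#' Goodness-of-fit quantities per observation
#'
#' Population predictions (PRED, all etas zero), individual predictions
#' (IPRED, at the empirical-Bayes etas), individually weighted residuals
#' (IWRES), and conditional weighted residuals (CWRES) from a first-order
#' linearization of the individual model around the eta mode, with the
#' residual variance evaluated at individual predictions.
#'
#' @param fit A `fit_result` from [fit_poppk()].
#' @param dataset The [pk_dataset()] the model was fitted to.
#' @return Data.frame: `ID`, `TIME`, `TAD`, `DV`, `PRED`, `IPRED`, `IWRES`,
#'   `CWRES`.
#' @export
gof <- function(fit, dataset) {
  stopifnot(inherits(fit, "fit_result"), inherits(dataset, "pk_dataset"))
  model <- fit$estimates
  m <- unpack_model(pack_model(model), model)
  design <- build_design(dataset, model$covariate_effects)
  k <- length(m$eta_par)
  LP0 <- design_lp_base(design, m$theta, m$u_cov)
  pred <- design_conc(design, LP0)
  E <- fit$etas
  LPi <- LP0
  if (k > 0) LPi[, m$eta_par] <- LPi[, m$eta_par, drop = FALSE] + E
  ipred <- design_conc(design, LPi)
  s2i <- m$sigma_add^2 + (m$sigma_prop * ipred)^2
  iwres <- (design$y - ipred) / sqrt(s2i)
  cwres <- numeric(design$n_obs)
  if (k > 0) {
    delta <- 1e-4
    G <- matrix(0, design$n_obs, k)
    for (c in seq_len(k)) {
      LPp <- LPi; LPp[, m$eta_par[c]] <- LPp[, m$eta_par[c]] + delta
      LPm <- LPi; LPm[, m$eta_par[c]] <- LPm[, m$eta_par[c]] - delta
      G[, c] <- (design_conc(design, LPp) - design_conc(design, LPm)) / (2 * delta)
    }
    for (j in seq_len(design$n)) {
      idx <- which(design$obs_sub == j)
      Gj <- G[idx, , drop = FALSE]
      r <- design$y[idx] - ipred[idx] + as.vector(Gj %*% E[j, ])
      Cov <- Gj %*% model$omega %*% t(Gj) + diag(s2i[idx], length(idx))
      cwres[idx] <- forwardsolve(t(chol(Cov)), r)
    }
  } else {
    cwres <- iwres
  }
  obs <- dataset[dataset$EVID == 0 & dataset$MDV == 0, , drop = FALSE]
  data.frame(ID = obs$ID, TIME = obs$TIME, TAD = time_after_dose(dataset),
             DV = obs$DV, PRED = pred, IPRED = ipred, IWRES = iwres,
             CWRES = cwres, row.names = NULL)
}
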