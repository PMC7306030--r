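#' Covariate effect on a structural parameter
#'
#' A multiplicative covariate-parameter relation. Continuous covariates use
#' a power model normalized to the population median,
#' \eqn{\theta_i = \theta_{pop} (cov_i / cov_m)^{\theta_{cov}}}; binary
#' covariates use a multiplier, \eqn{\theta_i = \theta_{pop}
#' \theta_{cov}^{cov_i}} with \eqn{cov_i \in \{0, 1\}}.
#'
#' @param parameter Which structural parameter the effect scales: one of
#'   `"CL"`, `"Vc"`, `"Vp"`, `"Q"`.
#' @param covariate Covariate column name (e.g. `"EGFR"`, `"SEX"`).
#' @param kind `"power"` (continuous) or `"binary"` (0/1 multiplier).
#' @param theta_cov Exponent (power) or multiplier (binary). Multipliers
#'   must be positive.
#' @param cov_median Population median used for normalization (power kind
#'   only); if `NA` it is taken from the dataset at fit time.
#' @return An object of class `covariate_effect`.
#' @examples
#' covariate_effect("CL", "EGFR", "power", theta_cov = 0.75, cov_median = 58.5)
#' @export
covariate_effect <- function(parameter, covariate, kind = c("power", "binary"),
                             theta_cov = 0, cov_median = NA_real_) {
  kind <- match.arg(kind)
  parameter <- match.arg(parameter, c("CL", "Vc", "Vp", "Q"))
  if (kind == "power" && !is.na(cov_median) && cov_median <= 0) {
    stop("cov_median must be positive for a power effect")
  }
  if (kind == "binary" && theta_cov <= 0) {
    stop("a binary multiplier must be positive")
  }
  structure(list(parameter = parameter, covariate = covariate, kind = kind,
                 theta_cov = theta_cov, cov_median = cov_median),
            class = "covariate_effect")
}

#' Population pharmacokinetic model
#'
#' Fixed effects (typical values), inter-individual variability (IIV) as a
#' log-normal random-effect covariance matrix, a combined
#' proportional-plus-additive residual-error model, and optional covariate
#' effects.
#'
#' @param theta Named numeric vector of typical values with names `CL`,
#'   `Vc`, `Vp`, `Q` (units as [pk_params()]); all positive.
#' @param omega IIV covariance matrix on the log scale, with dimnames naming
#'   the structural parameters carrying a random effect (a subset of
#'   `c("CL","Vc","Vp","Q")`). Must be symmetric positive semi-definite.
#'   May be a 0x0 matrix for a model with no IIV.
#' @param sigma_prop Proportional residual SD (fraction, >= 0).
#' @param sigma_add Additive residual SD (mg/L, >= 0).
#' @param covariate_effects List of [covariate_effect()] objects.
#' @return An object of class `population_model`.
#' @seealso [cipro_final_model()] for the published ciprofloxacin estimates.
#' @export
population_model <- function(theta, omega = matrix(numeric(0), 0, 0),
                             sigma_prop = 0, sigma_add = 0,
                             covariate_effects = list()) {
  theta <- theta[c("CL", "Vc", "Vp", "Q")]
  if (any(is.na(theta)) || any(theta <= 0)) {
    stop("theta must contain positive CL, Vc, Vp, Q")
  }
  omega <- as.matrix(omega)
  if (nrow(omega) != ncol(omega)) stop("omega must be square")
  if (nrow(omega) > 0) {
    if (is.null(rownames(omega))) stop("omega needs dimnames naming parameters")
    if (!all(rownames(omega) %in% names(theta))) {
      stop("omega dimnames must be a subset of CL, Vc, Vp, Q")
    }
    if (max(abs(omega - t(omega))) > 1e-10) stop("omega must be symmetric")
    ev <- eigen(omega, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-10 * max(abs(ev), 1)) {
      stop("omega must be positive semi-definite")
    }
  }
  if (sigma_prop < 0 || sigma_add < 0) stop("residual SDs must be >= 0")
  stopifnot(is.list(covariate_effects))
  structure(list(theta = theta, omega = omega, sigma_prop = sigma_prop,
                 sigma_add = sigma_add, covariate_effects = covariate_effects),
            class = "population_model")
}

#' @export
print.population_model <- function(x, ...) {
  cat("Population PK model (two-compartment, IV infusion)\n")
  cat(sprintf("  theta: CL=%.3g L/h  Vc=%.3g L  Vp=%.3g L  Q=%.3g L/h\n",
              x$theta["CL"], x$theta["Vc"], x$theta["Vp"], x$theta["Q"]))
  if (nrow(x$omega)) {
    cv <- cv_percent(diag(x$omega))
    cat(sprintf("  IIV (CV%%): %s\n",
                paste(sprintf("%s=%.1f", rownames(x$omega), cv),
                      collapse = "  ")))
  } else cat("  IIV: none\n")
  cat(sprintf("  residual error: proportional %.1f%%, additive %.3g mg/L\n",
              100 * x$sigma_prop, x$sigma_add))
  if (length(x$covariate_effects)) {
    for (ce in x$covariate_effects) {
      cat(sprintf("  covariate: %s on %s (%s, theta_cov=%.3g)\n",
                  ce$covariate, ce$parameter, ce$kind, ce$theta_cov))
    }
  }
  invisible(x)
}

#' Ciprofloxacin final-model population estimates
#'
#' The published final-model estimates for intravenous ciprofloxacin in ICU
#' patients: CL 25.4 L/h, Vc 91.1 L, Vp 164 L, Q 91.9 L/h; IIV 67.8% on CL
#' and 51.0% on Vc with an omega block between them; combined residual error
#' with proportional SD 0.153 and additive SD 0.143 mg/L. The CL-Vc
#' correlation was not reported; the default uses 0.5.
#'
#' @param cl_vc_corr Correlation between the CL and Vc random effects.
#' @param iiv_q Optional IIV CV fraction on Q (e.g. 0.3) added as an
#'   independent diagonal element; `NULL` (default) for the Table-2
#'   structure with IIV on CL and Vc only.
#' @return A [population_model()].
#' @examples
#' cipro_final_model()
#' @export
cipro_final_model <- function(cl_vc_corr = 0.5, iiv_q = NULL) {
  om_cl <- 0.678
  om_vc <- 0.510
  omega <- matrix(c(om_cl^2, cl_vc_corr * om_cl * om_vc,
                    cl_vc_corr * om_cl * om_vc, om_vc^2), 2, 2,
                  dimnames = list(c("CL", "Vc"), c("CL", "Vc")))
  if (!is.null(iiv_q)) {
    omega <- rbind(cbind(omega, c(0, 0)), c(0, 0, iiv_q^2))
    dimnames(omega) <- list(c("CL", "Vc", "Q"), c("CL", "Vc", "Q"))
  }
  population_model(theta = c(CL = 25.4, Vc = 91.1, Vp = 164, Q = 91.9),
                   omega = omega, sigma_prop = 0.153, sigma_add = 0.143)
}

# Multiplicative covariate terms for one subject: named multiplier per
# structural parameter. `cov` is a one-row data.frame / named list.
covariate_multipliers <- function(effects, cov) {
  m <- c(CL = 1, Vc = 1, Vp = 1, Q = 1)
  for (ce in effects) {
    x <- cov[[ce$covariate]]
    if (is.null(x) || is.na(x)) stop("missing covariate: ", ce$covariate)
    m[ce$parameter] <- m[ce$parameter] * switch(ce$kind,
      power = {
        if (is.na(ce$cov_median)) stop("cov_median not set for ", ce$covariate)
        (x / ce$cov_median)^ce$theta_cov
      },
      binary = ce$theta_cov^x)
  }
  m
}

#' Individual parameters from population model, covariates and random effects
#'
#' Applies the log-normal IIV model
#' \eqn{P_j = \theta_P \prod(\mathrm{cov\ terms}) \exp(\eta_P)} to obtain one
#' individual's structural parameters. Parameters without a random effect in
#' `pop$omega` use \eqn{\exp(0) = 1}.
#'
#' @param pop A [population_model()].
#' @param cov Named list or one-row data.frame of covariate values (only
#'   needed when `pop` has covariate effects).
#' @param eta Named or positional numeric vector of random effects, one per
#'   row of `pop$omega`.
#' @return A [pk_params()] object.
#' @examples
#' individual_params(cipro_final_model(), eta = c(CL = log(2), Vc = 0))
#' @export
individual_params <- function(pop, cov = list(), eta = NULL) {
  stopifnot(inherits(pop, "population_model"))
  k <- nrow(pop$omega)
  if (is.null(eta)) eta <- rep(0, k)
  if (length(eta) != k) stop("eta must have length ", k, " (rows of omega)")
  ex <- c(CL = 0, Vc = 0, Vp = 0, Q = 0)
  if (k > 0) ex[rownames(pop$omega)] <- eta
  m <- if (length(pop$covariate_effects)) {
    covariate_multipliers(pop$covariate_effects, cov)
  } else c(CL = 1, Vc = 1, Vp = 1, Q = 1)
  p <- pop$theta * m * exp(ex)
  pk_params(p[["CL"]], p[["Vc"]], p[["Vp"]], p[["Q"]])
}

# Draw an n x k matrix of etas ~ MVN(0, omega); omega may be PSD (rank
# deficient allowed via eigen square root).
draw_etas <- function(n, omega) {
  k <- nrow(omega)
  if (k == 0) return(matrix(numeric(0), n, 0))
  e <- eigen(omega, symmetric = TRUE)
  if (min(e$values) < -1e-8 * max(abs(e$values), 1)) {
    stop("omega is not positive semi-definite")
  }
  rt <- e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
  z <- matrix(rnorm(n * k), n, k)
  out <- z %*% rt
  colnames(out) <- rownames(omega)
  out
}

#' Sample individuals from the population model
#'
#' Draws `n` individuals' random effects from \eqn{N(0, \Omega)} and maps
#' them to structural parameters. Reproducible under a fixed seed.
#'
#' @param pop A [population_model()].
#' @param n Number of individuals (>= 1).
#' @param seed Optional integer seed.
#' @param cov Optional data.frame of covariates with `n` rows.
#' @return A list with `eta` (n x k matrix) and `params` (data.frame with
#'   columns CL, Vc, Vp, Q).
#' @export
sample_individuals <- function(pop, n, seed = NULL, cov = NULL) {
  stopifnot(inherits(pop, "population_model"), n >= 1)
  if (!is.null(seed)) set.seed(seed)
  eta <- draw_etas(n, pop$omega)
  ex <- matrix(0, n, 4, dimnames = list(NULL, c("CL", "Vc", "Vp", "Q")))
  if (ncol(eta) > 0) ex[, colnames(eta)] <- eta
  m <- matrix(1, n, 4, dimnames = list(NULL, c("CL", "Vc", "Vp", "Q")))
  if (length(pop$covariate_effects)) {
    if (is.null(cov)) stop("covariates required for a model with effects")
    for (i in seq_len(n)) {
      m[i, ] <- covariate_multipliers(pop$covariate_effects, cov[i, , drop = FALSE])
    }
  }
  params <- sweep(exp(ex) * m, 2, pop$theta, `*`)
  list(eta = eta, params = as.data.frame(params))
}

#' Combined proportional-and-additive residual error
#'
#' Applies the observation model \eqn{y = f (1 + \epsilon_{prop}) +
#' \epsilon_{add}}. In the deterministic form the epsilons are supplied; in
#' the stochastic form they are drawn from \eqn{N(0, \sigma^2)}.
#'
#' @param pred Model-predicted concentration(s), mg/L (>= 0).
#' @param eps_prop,eps_add Residual deviates; if `NULL`, drawn from normal
#'   distributions with SDs `sigma_prop`, `sigma_add`.
#' @param sigma_prop,sigma_add Residual SDs used for the stochastic form.
#' @return Observed concentration(s), mg/L.
#' @examples
#' residual_observe(2, eps_prop = 0.1, eps_add = 0.05)  # 2.25
#' @export
residual_observe <- function(pred, eps_prop = NULL, eps_add = NULL,
                             sigma_prop = 0, sigma_add = 0) {
  if (any(pred < 0)) stop("pred must be non-negative")
  n <- length(pred)
  if (is.null(eps_prop)) eps_prop <- rnorm(n, 0, sigma_prop)
  if (is.null(eps_add)) eps_add <- rnorm(n, 0, sigma_add)
  pred * (1 + eps_prop) + eps_add
}

#' Convert a log-scale variance to a coefficient of variation (%)
#'
#' Uses the standard pharmacometric reporting approximation
#' \eqn{CV\% = 100\sqrt{\omega^2}}.
#'
#' @param omega_sq Variance(s) on the log scale (>= 0).
#' @return CV in percent.
#' @examples
#' cv_percent(0.678^2)  # 67.8
#' @export
cv_percent <- function(omega_sq) {
  if (any(omega_sq < 0)) stop("omega_sq must be >= 0")
  100 * sqrt(omega_sq)
}
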