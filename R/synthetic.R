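# Table-style covariate marginals for the ICU cohort: median with IQR
# (BMI's bracket is a min-max range; flagged by wide = TRUE).
default_covariate_marginals <- function() {
  list(
    AGE  = list(median = 65.5, lo = 56, hi = 71),
    WT   = list(median = 80, lo = 64, hi = 90),
    BMI  = list(median = 26, lo = 17.8, hi = 46.3, wide = TRUE),
    CREA = list(median = 90, lo = 70, hi = 153),
    EGFR = list(median = 58.5, lo = 32, hi = 101),
    ALB  = list(median = 25, lo = 22, hi = 29),
    SEX  = list(p = 25 / 42),   # 1 = male
    RRT  = list(p = 10 / 42)    # 1 = on renal replacement therapy
  )
}

#' Study design for the synthetic ICU cohort
#'
#' Encodes the sparse day-2 sampling design of the intravenous ciprofloxacin
#' ICU study: dose groups of 3 / 25 / 14 subjects on 400 mg q24h / q12h /
#' q8h, 1 h infusions, and five samples in one day-2 dosing interval
#' (pre-dose trough; a peak drawn uniformly 0.25-0.5 h after the end of the
#' infusion; 1 h and 3 h after the infusion; the next pre-dose trough).
#'
#' @param groups Data.frame with columns `dose` (mg), `interval` (h), `n`
#'   (subjects per group).
#' @param infusion_duration Infusion duration, h.
#' @param peak_jitter Range (h after end of infusion) for the peak sample.
#' @param post_infusion_offsets Fixed sample times, h after end of infusion.
#' @param missingness Probability each planned sample is missing; the
#'   default 0.03 reproduces the study's average of ~4.9 of 5 samples.
#' @param covariates List of covariate marginals (median/lo/hi for
#'   continuous, p for binary); see `cipropk:::default_covariate_marginals`.
#' @param egfr_gradient If `TRUE`, eGFR medians differ by dose group
#'   (28 / 52 / 82.5 for q24h / q12h / q8h), emulating the dose-by-renal-
#'   function confounding observed in the study. Off by default.
#' @return An object of class `study_design`.
#' @export
study_design <- function(groups = data.frame(dose = 400,
                                             interval = c(24, 12, 8),
                                             n = c(3, 25, 14)),
                         infusion_duration = 1,
                         peak_jitter = c(0.25, 0.5),
                         post_infusion_offsets = c(1, 3),
                         missingness = 0.03,
                         covariates = default_covariate_marginals(),
                         egfr_gradient = FALSE) {
  stopifnot(all(groups$n >= 0), sum(groups$n) > 0,
            missingness >= 0, missingness < 1,
            infusion_duration > 0, all(groups$interval > infusion_duration))
  structure(list(groups = groups, infusion_duration = infusion_duration,
                 peak_jitter = peak_jitter,
                 post_infusion_offsets = post_infusion_offsets,
                 missingness = missingness, covariates = covariates,
                 egfr_gradient = egfr_gradient),
            class = "study_design")
}

# Sample n covariate values from one marginal: lognormal matched to
# median/IQR (or median/range when wide), Bernoulli for binary.
sample_marginal <- function(marg, n) {
  if (!is.null(marg$p)) return(rbinom(n, 1, marg$p))
  z <- if (isTRUE(marg$wide)) qnorm(0.99) else qnorm(0.75)
  sdlog <- (log(marg$hi) - log(marg$lo)) / (2 * z)
  exp(rnorm(n, log(marg$median), sdlog))
}

#' Generate a synthetic ICU cohort
#'
#' Simulates an observable dataset under a known population model
#' ("truth"): covariates from the design marginals, log-normal random
#' effects, a full dose history from therapy start through day 2,
#' concentrations at the (jittered) sampling template, combined
#' proportional-plus-additive residual error, and censoring of observations
#' below the assay limit (0.04 mg/L, M1: dropped with a recorded count).
#' The hidden truth (per-subject etas and parameters) is attached for
#' recovery testing.
#'
#' @param design A [study_design()].
#' @param truth A [population_model()] used as the generating truth;
#'   defaults to [cipro_final_model()].
#' @param seed Integer seed.
#' @param lloq Censoring limit, mg/L.
#' @return A [pk_dataset()] with attributes `truth` (list: `model`, `eta`,
#'   `params` — one row per subject) and `n_blq` (count of censored
#'   observations).
#' @examples
#' d <- generate_cohort(seed = 1)
#' length(unique(d$ID))  # 42
#' @export
generate_cohort <- function(design = study_design(),
                            truth = cipro_final_model(),
                            seed = NULL, lloq = 0.04) {
  stopifnot(inherits(design, "study_design"),
            inherits(truth, "population_model"))
  if (!is.null(seed)) set.seed(seed)
  n_total <- sum(design$groups$n)
  if (n_total < 1) stop("design has zero subjects")
  g_idx <- rep(seq_len(nrow(design$groups)), design$groups$n)

  # covariates
  cov <- as.data.frame(lapply(design$covariates, sample_marginal, n = n_total))
  if (design$egfr_gradient) {
    med <- c(28, 52, 82.5)[match(design$groups$interval[g_idx], c(24, 12, 8))]
    marg <- design$covariates$EGFR
    sdlog <- (log(marg$hi) - log(marg$lo)) / (2 * qnorm(0.75))
    cov$EGFR <- exp(rnorm(n_total, log(med), sdlog))
  }

  si <- sample_individuals(truth, n_total, cov = cov)
  tinf <- design$infusion_duration
  rows <- vector("list", n_total)
  n_blq <- 0L
  for (i in seq_len(n_total)) {
    tau <- design$groups$interval[g_idx[i]]
    dose <- design$groups$dose[g_idx[i]]
    dose_times <- seq(0, 24, by = tau)      # history through start of day 2
    t0 <- max(dose_times)                   # sampled interval starts here
    peak <- tinf + runif(1, design$peak_jitter[1], design$peak_jitter[2])
    offsets <- c(0, peak, tinf + design$post_infusion_offsets, tau)
    keep <- runif(length(offsets)) >= design$missingness
    if (!any(keep)) keep[1] <- TRUE
    offsets <- offsets[keep]
    times <- t0 + offsets
    p <- si$params[i, ]
    pred <- rep(0, length(times))
    for (td in dose_times) {
      pred <- pred + conc2_single(times - td, p$CL, p$Vc, p$Vp, p$Q, dose, tinf)
    }
    dv <- residual_observe(pred, sigma_prop = truth$sigma_prop,
                           sigma_add = truth$sigma_add)
    ok <- dv >= lloq
    n_blq <- n_blq + sum(!ok)
    dose_df <- data.frame(ID = i, TIME = dose_times, EVID = 1L,
                          AMT = dose, DUR = tinf, DV = NA_real_, MDV = 1L)
    obs_df <- data.frame(ID = i, TIME = times[ok], EVID = 0L, AMT = NA_real_,
                         DUR = NA_real_, DV = dv[ok], MDV = 0L)
    sub <- rbind(dose_df, obs_df)
    sub <- sub[order(sub$TIME, sub$EVID), ]  # pre-dose trough listed first
    sub <- cbind(sub, cov[rep(i, nrow(sub)), , drop = FALSE])
    rows[[i]] <- sub
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out <- pk_dataset(out)
  attr(out, "truth") <- list(model = truth, eta = si$eta, params = si$params)
  attr(out, "n_blq") <- n_blq
  out
}

#' Cohort with a known covariate effect baked into the truth
#'
#' Generates a cohort exactly as [generate_cohort()] but with `effect`
#' appended to the truth model (its `cov_median` filled from the design
#' marginal median if unset), for covariate-selection power and type-I-error
#' studies. The dose-group proportions of `design` are rescaled to
#' `n_subjects`.
#'
#' @param effect A [covariate_effect()]; `theta_cov = 0` (power) reproduces
#'   the null scenario.
#' @param n_subjects Total cohort size.
#' @param design,truth,seed,lloq As in [generate_cohort()].
#' @return A [pk_dataset()] with truth attributes.
#' @export
covariate_effect_scenario <- function(effect, n_subjects,
                                      design = study_design(),
                                      truth = cipro_final_model(),
                                      seed = NULL, lloq = 0.04) {
  stopifnot(inherits(effect, "covariate_effect"))
  if (effect$kind == "power" && is.na(effect$cov_median)) {
    marg <- design$covariates[[effect$covariate]]
    if (is.null(marg$median)) stop("no marginal median for ", effect$covariate)
    effect$cov_median <- marg$median
  }
  g <- design$groups
  n <- round(n_subjects * g$n / sum(g$n))
  n[1] <- n[1] + (n_subjects - sum(n))
  design$groups$n <- pmax(n, 0)
  truth$covariate_effects <- c(truth$covariate_effects, list(effect))
  generate_cohort(design, truth, seed = seed, lloq = lloq)
}
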