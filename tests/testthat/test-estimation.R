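test_that("with no random effects the OFV is the exact Gaussian deviance", {
  th <- c(CL = 25.4, Vc = 91.1, Vp = 164, Q = 91.9)
  truth <- population_model(th, sigma_prop = 0, sigma_add = 0.3)
  des <- small_design(n = 8)
  d <- generate_cohort(des, truth, seed = 31, lloq = 0)
  model <- population_model(th, sigma_prop = 0, sigma_add = 0.3)
  # independent oracle: per-subject closed-form predictions and dnorm
  obs <- d[d$EVID == 0 & d$MDV == 0, ]
  p <- pk_params(th[["CL"]], th[["Vc"]], th[["Vp"]], th[["Q"]])
  ll <- 0
  for (id in unique(d$ID)) {
    sub <- obs[obs$ID == id, ]
    doses <- d[d$ID == id & d$EVID == 1, ]
    pred <- rep(0, nrow(sub))
    for (r in seq_len(nrow(doses))) {
      reg1 <- dosing_regimen(doses$AMT[r], 12, doses$DUR[r], n_doses = 1)
      tt <- pmax(sub$TIME - doses$TIME[r], 0)
      cc <- concentration(p, reg1, tt)
      cc[sub$TIME <= doses$TIME[r]] <- 0
      pred <- pred + cc
    }
    ll <- ll + sum(dnorm(sub$DV, pred, 0.3, log = TRUE))
  }
  expect_equal(ofv(d, model), -2 * ll, tolerance = 1e-8)
})

test_that("OFV is additive over subjects and invariant to relabelling", {
  truth <- reduced_truth()
  d <- generate_cohort(small_design(n = 6), truth, seed = 32)
  o1 <- ofv(d, truth)
  # duplicate every subject under new ids
  d2 <- as.data.frame(d)
  dup <- d2
  dup$ID <- dup$ID + 100
  both <- pk_dataset(rbind(d2, dup))
  expect_equal(ofv(both, truth), 2 * o1, tolerance = 1e-6)
  # relabel and reorder subjects
  shuf <- d2
  shuf$ID <- match(shuf$ID, unique(shuf$ID)) * 7 + 3
  shuf <- shuf[order(-shuf$ID, shuf$TIME, shuf$EVID), ]
  shuf <- shuf[order(shuf$ID, shuf$TIME, shuf$EVID), ]
  expect_equal(ofv(pk_dataset(shuf), truth), o1, tolerance = 1e-8)
})

test_that("near-noiseless rich data recovers the structural parameters", {
  th <- c(CL = 25.4, Vc = 91.1, Vp = 164, Q = 91.9)
  truth <- population_model(th, sigma_prop = 0.005, sigma_add = 0)
  d <- generate_cohort(small_design(n = 20), truth, seed = 33, lloq = 0)
  init <- population_model(th * c(1.3, 0.8, 1.2, 0.7),
                           sigma_prop = 0.02, sigma_add = 0)
  fit <- fit_poppk(d, init, fixed = "sigma_add", compute_se = FALSE)
  expect_true(fit$converged)
  expect_equal(unname(fit$estimates$theta), unname(th), tolerance = 0.01)
})

test_that("refitting from the returned estimates leaves the OFV fixed", {
  truth <- reduced_truth()
  d <- generate_cohort(small_design(n = 12), truth, seed = 34)
  f1 <- fit_poppk(d, truth, compute_se = FALSE)
  f2 <- fit_poppk(d, f1$estimates, compute_se = FALSE,
                  control = quick_control())
  expect_lt(abs(f1$ofv - f2$ofv), 0.01)
})

test_that("shrinkage formulas behave at the degenerate extremes", {
  truth <- reduced_truth()
  d <- generate_cohort(small_design(n = 12), truth, seed = 35)
  fit <- fit_poppk(d, truth, compute_se = FALSE, control = quick_control())
  s <- shrinkage(fit)
  expect_named(s$eta, "CL")
  # five samples per subject is informative: low shrinkage on CL
  expect_lt(s$eta[["CL"]], 20)
  # hand-check against the definition
  expect_equal(s$eta[["CL"]],
               100 * (1 - sd(fit$etas[, "CL"]) /
                        sqrt(fit$estimates$omega["CL", "CL"])))
})

test_that("likelihood-ratio thresholds and decisions match the chi-square quantiles", {
  th <- lrt_thresholds()
  expect_equal(unname(th["forward"]), 3.84)
  expect_equal(unname(th["backward"]), 10.83)
  expect_true(lrt_decision(3.84, "forward"))
  expect_false(lrt_decision(3.83, "forward"))
  expect_false(lrt_decision(10.83, "backward"))  # strict inequality: dropped
  expect_true(lrt_decision(10.84, "backward"))
  expect_false(lrt_decision(0, "forward"))
  expect_false(lrt_decision(0, "backward"))
})

test_that("empty candidate list returns the base model unchanged", {
  truth <- reduced_truth()
  d <- generate_cohort(small_design(n = 8), truth, seed = 36)
  res <- covariate_search(d, truth, list(), control = quick_control())
  expect_equal(nrow(res$trace), 0)
  expect_length(res$included, 0)
  expect_equal(res$fit$ofv, res$base_ofv)
})

test_that("a strong simulated eGFR effect on clearance is selected", {
  eff <- covariate_effect("CL", "EGFR", "power", theta_cov = 0.75)
  d <- covariate_effect_scenario(eff, n_subjects = 50,
                                 truth = reduced_truth(sigma_add = 0),
                                 seed = 37, lloq = 0)
  base <- reduced_truth(sigma_add = 0)
  cands <- list(covariate_effect("CL", "EGFR", "power"),
                covariate_effect("CL", "ALB", "power"))
  res <- suppressWarnings(
    covariate_search(d, base, cands, control = quick_control()))
  labs <- vapply(res$included, cipropk:::eff_label, "")
  expect_true("EGFR-on-CL" %in% labs)
  est <- res$fit$estimates$covariate_effects
  est_egfr <- est[[which(labs == "EGFR-on-CL")]]$theta_cov
  expect_equal(est_egfr, 0.75, tolerance = 0.35)
})
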