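test_that("default design reproduces the cohort size and dose-group split", {
  d <- generate_cohort(seed = 2)
  ids <- unique(d$ID)
  expect_length(ids, 42)
  intervals <- vapply(ids, function(id) {
    dt <- d$TIME[d$ID == id & d$EVID == 1]
    min(diff(sort(unique(dt))))
  }, numeric(1))
  expect_equal(unname(table(intervals)[c("24", "12", "8")]),
               c(3, 25, 14), ignore_attr = TRUE)
})

test_that("zero missingness yields the full five-sample template", {
  des <- study_design(missingness = 0)
  truth <- cipro_final_model()
  truth$sigma_add <- 0   # keep all draws positive so none are censored
  d <- generate_cohort(des, truth, seed = 3, lloq = 0)
  obs_per_subject <- table(d$ID[d$EVID == 0 & d$MDV == 0])
  expect_true(all(obs_per_subject == 5))
  expect_equal(sum(d$EVID == 0 & d$MDV == 0), 210)
})

test_that("sampling times follow the day-2 template", {
  des <- study_design(missingness = 0)
  d <- generate_cohort(des, seed = 13, lloq = 0)
  one <- d[d$ID == 5 & d$EVID == 0, ]          # a q12h subject
  doses <- d[d$ID == 5 & d$EVID == 1, ]
  expect_equal(doses$TIME, c(0, 12, 24))
  offs <- one$TIME - 24
  expect_equal(offs[1], 0)                      # pre-dose trough
  expect_true(offs[2] >= 1.25 && offs[2] <= 1.5) # peak 15-30 min post-infusion
  expect_equal(offs[3:5], c(2, 4, 12))          # +1 h, +3 h, next trough
})

test_that("noiseless generation reproduces typical-value predictions", {
  th <- c(CL = 25.4, Vc = 91.1, Vp = 164, Q = 91.9)
  noiseless <- population_model(th)  # no IIV, no residual error
  des <- study_design(missingness = 0)
  d <- generate_cohort(des, noiseless, seed = 4, lloq = 0)
  obs <- d[d$EVID == 0 & d$MDV == 0, ]
  p <- pk_params(th["CL"], th["Vc"], th["Vp"], th["Q"])
  for (id in c(1, 10, 40)) {
    sub <- obs[obs$ID == id, ]
    doses <- d[d$ID == id & d$EVID == 1, ]
    reg <- dosing_regimen(doses$AMT[1], diff(doses$TIME)[1],
                          doses$DUR[1], n_doses = nrow(doses))
    manual <- concentration(p, reg, sub$TIME)
    expect_equal(sub$DV, manual, tolerance = 1e-10)
  }
})

test_that("covariate marginals reproduce the published cohort medians", {
  marg <- cipropk:::default_covariate_marginals()
  set.seed(9)
  for (nm in c("EGFR", "ALB", "AGE", "WT", "CREA", "BMI")) {
    x <- cipropk:::sample_marginal(marg[[nm]], 1e4)
    expect_equal(median(x), marg[[nm]]$median,
                 tolerance = 0.1 * marg[[nm]]$median, ignore_attr = TRUE)
  }
  sex <- cipropk:::sample_marginal(marg$SEX, 1e4)
  expect_equal(mean(sex), 25 / 42, tolerance = 0.05)
  rrt <- cipropk:::sample_marginal(marg$RRT, 1e4)
  expect_equal(mean(rrt), 10 / 42, tolerance = 0.05)
})

test_that("generation is reproducible and BLQ censoring is recorded", {
  d1 <- generate_cohort(seed = 8)
  d2 <- generate_cohort(seed = 8)
  expect_identical(as.data.frame(d1), as.data.frame(d2))
  expect_true(attr(d1, "n_blq") >= 0)
  expect_true(all(d1$DV[d1$EVID == 0 & d1$MDV == 0] >= 0.04))
  tr <- attr(d1, "truth")
  expect_equal(nrow(tr$params), 42)
  expect_equal(dim(tr$eta), c(42, 2))
})

test_that("covariate-effect scenario bakes the effect into the truth", {
  eff <- covariate_effect("CL", "EGFR", "power", theta_cov = 0.75)
  d <- covariate_effect_scenario(eff, n_subjects = 30,
                                 truth = reduced_truth(), seed = 5)
  expect_length(unique(d$ID), 30)
  tr <- attr(d, "truth")
  expect_equal(tr$model$covariate_effects[[1]]$cov_median, 58.5)
  # subjects with higher eGFR have higher true CL after removing the eta
  ids <- unique(d$ID)
  egfr <- d$EGFR[match(ids, d$ID)]
  cl_noeta <- tr$params$CL / exp(tr$eta[, 1])
  expect_true(all(diff(cl_noeta[order(egfr)]) > 0))
})

test_that("the eGFR-by-dose-group gradient flag shifts group medians", {
  des <- study_design(egfr_gradient = TRUE,
                      groups = data.frame(dose = 400, interval = c(24, 8),
                                          n = c(200, 200)))
  d <- generate_cohort(des, reduced_truth(), seed = 6)
  ids <- unique(d$ID)
  egfr <- d$EGFR[match(ids, d$ID)]
  iv <- vapply(ids, function(id) {
    dt <- d$TIME[d$ID == id & d$EVID == 1]
    min(diff(sort(unique(dt))))
  }, numeric(1))
  expect_lt(median(egfr[iv == 24]), median(egfr[iv == 8]))
})
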