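test_that("bootstrap is seed-reproducible and summarizes resamples", {
  truth <- reduced_truth()
  d <- generate_cohort(small_design(n = 10), truth, seed = 41)
  b1 <- bootstrap_poppk(d, truth, n_resamples = 2, seed = 7,
                        control = quick_control())
  b2 <- bootstrap_poppk(d, truth, n_resamples = 2, seed = 7,
                        control = quick_control())
  expect_identical(b1$samples, b2$samples)
  expect_true(all(b1$summary$ci_lo <= b1$summary$median &
                    b1$summary$median <= b1$summary$ci_hi))
})

test_that("bootstrap of cloned subjects collapses to the point estimate", {
  truth <- reduced_truth()
  one <- generate_cohort(small_design(n = 1), truth, seed = 42)
  clones <- do.call(rbind, lapply(1:8, function(i) {
    sub <- as.data.frame(one)
    sub$ID <- i
    sub
  }))
  d <- pk_dataset(clones)
  b <- bootstrap_poppk(d, truth, n_resamples = 3, seed = 8,
                       control = quick_control())
  # every resample contains exactly the same records, so estimates agree
  expect_lt(max(apply(b$samples, 2, sd), na.rm = TRUE), 1e-6)
})

test_that("bootstrap median clearance is consistent with the point estimate", {
  truth <- reduced_truth()
  d <- generate_cohort(small_design(n = 14), truth, seed = 43)
  fit <- fit_poppk(d, truth, compute_se = FALSE, control = quick_control())
  b <- bootstrap_poppk(d, fit$estimates, n_resamples = 30, seed = 9,
                       control = quick_control())
  expect_lt(b$n_fail / 30, 0.5)
  med <- b$summary$median[b$summary$parameter == "CL"]
  expect_equal(med, fit$estimates$theta[["CL"]], tolerance = 0.15)
})

test_that("VPC under the generating model covers the observed percentiles", {
  truth <- cipro_final_model()
  d <- generate_cohort(seed = 44)
  v1 <- vpc(d, truth, n_sim = 200, seed = 10)
  v2 <- vpc(d, truth, n_sim = 200, seed = 10)
  expect_identical(v1$stats, v2$stats)
  s <- v1$stats
  expect_true(all(s$obs_p5 <= s$obs_med & s$obs_med <= s$obs_p95))
  covered <- s$obs_med >= s$sim_med_lo & s$obs_med <= s$sim_med_hi
  expect_gte(mean(covered), 0.8)  # small-replicate smoke check
})

test_that("degenerate noise-free VPC has zero-width bands on the data", {
  th <- c(CL = 25.4, Vc = 91.1, Vp = 164, Q = 91.9)
  noiseless <- population_model(th)
  d <- generate_cohort(study_design(missingness = 0), noiseless,
                       seed = 45, lloq = 0)
  v <- vpc(d, noiseless, n_sim = 50, seed = 11)
  s <- v$stats
  expect_equal(s$sim_med_lo, s$sim_med_hi, tolerance = 1e-12)
  expect_equal(s$obs_med, s$sim_med_lo, tolerance = 1e-10)
})

test_that("NPDE under the true model is near standard normal", {
  truth <- cipro_final_model()
  d <- generate_cohort(seed = 46)
  r1 <- npde(d, truth, n_sim = 400, seed = 12)
  r2 <- npde(d, truth, n_sim = 400, seed = 12)
  expect_identical(r1$npde, r2$npde)
  n <- length(r1$npde)
  expect_lt(abs(r1$mean), 3 / sqrt(n))
  expect_lt(abs(r1$variance - 1), 3 * sqrt(2 / (n - 1)))
  expect_true(all(is.finite(r1$npde)))
})

test_that("NPDE flags a grossly misspecified model", {
  truth <- cipro_final_model()
  d <- generate_cohort(seed = 47)
  wrong <- truth
  wrong$theta["CL"] <- wrong$theta["CL"] * 10
  r <- npde(d, wrong, n_sim = 300, seed = 13)
  expect_gt(abs(r$mean), 1)
})

test_that("goodness-of-fit residuals behave at the definitions", {
  th <- c(CL = 25.4, Vc = 91.1, Vp = 164, Q = 91.9)
  # noiseless, no-IIV data refitted by construction: residuals vanish
  noiseless <- population_model(th, sigma_prop = 0.001, sigma_add = 0)
  d <- generate_cohort(small_design(n = 6), noiseless, seed = 48, lloq = 0)
  fit <- fit_poppk(d, noiseless, fixed = c("sigma_add"), compute_se = FALSE,
                   control = quick_control())
  g <- gof(fit, d)
  expect_equal(g$IPRED, g$PRED, tolerance = 1e-10)  # no etas in the model
  expect_lt(max(abs(g$CWRES)), 4)
  expect_lt(mean(abs(g$DV - g$IPRED) / g$IPRED), 0.01)
  # with IIV: CWRES centered near zero under the true model
  truth <- cipro_final_model()
  d2 <- generate_cohort(seed = 49)
  fit2 <- fit_poppk(d2, truth, compute_se = FALSE, control = quick_control())
  g2 <- gof(fit2, d2)
  expect_lt(abs(mean(g2$CWRES)), 3 / sqrt(nrow(g2)) + 0.2)
  expect_true(all(c("PRED", "IPRED", "IWRES", "CWRES") %in% names(g2)))
})

test_that("evaluation plots build without error", {
  truth <- cipro_final_model()
  d <- generate_cohort(seed = 50)
  v <- vpc(d, truth, n_sim = 60, seed = 14)
  expect_s3_class(plot_vpc(v), "ggplot")
  fit <- list(estimates = truth,
              etas = attr(d, "truth")$eta,
              converged = TRUE)
  class(fit) <- "fit_result"
  g <- gof(fit, d)
  expect_s3_class(plot_gof(g), "ggplot")
})
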