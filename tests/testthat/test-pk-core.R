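test_that("micro constants match eigenvalues of the disposition matrix", {
  p <- table2_params()
  mc <- micro_constants(p)
  expect_equal(mc$k10, 25.4 / 91.1, tolerance = 1e-12)
  expect_equal(mc$k21, 91.9 / 164, tolerance = 1e-12)
  # independent oracle: eigenvalues of the 2x2 rate matrix
  A <- matrix(c(-(mc$k10 + mc$k12), mc$k21, mc$k12, -mc$k21), 2, 2,
              byrow = TRUE)
  ev <- sort(-eigen(A, only.values = TRUE)$values)
  expect_equal(mc$beta, ev[1], tolerance = 1e-10)
  expect_equal(mc$alpha, ev[2], tolerance = 1e-10)
  expect_equal(mc$beta, 0.0888, tolerance = 1e-3)
  expect_equal(mc$t_half_beta, 7.80, tolerance = 1e-3)
})

test_that("algebraic identities hold for random parameter draws", {
  set.seed(7)
  for (i in 1:25) {
    p <- pk_params(runif(1, 1, 60), runif(1, 10, 200), runif(1, 10, 400),
                   runif(1, 1, 200))
    mc <- micro_constants(p)
    expect_gt(mc$alpha, mc$beta)
    expect_gt(mc$beta, 0)
    expect_equal(mc$alpha * mc$beta, mc$k10 * mc$k21, tolerance = 1e-10)
    expect_equal(mc$alpha + mc$beta, mc$k10 + mc$k12 + mc$k21,
                 tolerance = 1e-10)
  }
})

test_that("vanishing inter-compartmental clearance gives one-compartment kinetics", {
  # as Q -> 0 the eigenvalues tend to (CL/Vc, 0): the fast exponent carries
  # the whole disposition and equals the one-compartment elimination rate
  mc <- micro_constants(pk_params(25.4, 91.1, 164, 1e-8))
  expect_equal(mc$alpha, 25.4 / 91.1, tolerance = 1e-6)
  expect_lt(mc$beta, 1e-9)
})

test_that("parameter validation rejects non-positive values", {
  expect_error(pk_params(0, 91.1, 164, 91.9), "positive")
  expect_error(pk_params(25.4, -1, 164, 91.9), "positive")
  expect_error(dosing_regimen(400, 12, 13), "infusion_duration")
  expect_error(dosing_regimen(-1, 12), "dose")
})

test_that("closed-form concentration matches numerical ODE integration", {
  skip_if_not_installed("deSolve")
  set.seed(11)
  for (i in 1:5) {
    p <- pk_params(runif(1, 5, 50), runif(1, 30, 150), runif(1, 50, 300),
                   runif(1, 20, 150))
    reg <- dosing_regimen(400, 12, runif(1, 0.5, 1), n_doses = 3)
    tt <- c(0.25, 0.5, 0.9, 1.0, 1.5, 3, 7.9, 12.5, 13.2, 24, 30)
    expect_equal(concentration(p, reg, tt), ode_concentration(p, reg, tt),
                 tolerance = 1e-6)
  }
})

test_that("multiple-dose profile is the superposition of shifted single doses", {
  p <- table2_params()
  tt <- seq(0.1, 60, by = 0.7)
  for (n in 2:5) {
    reg_n <- dosing_regimen(400, 12, 1, n_doses = n)
    single <- dosing_regimen(400, 12, 1, n_doses = 1)
    manual <- Reduce(`+`, lapply(seq_len(n) - 1, function(i) {
      c0 <- concentration(p, single, pmax(tt - 12 * i, 0))
      c0[tt - 12 * i <= 0] <- 0
      c0
    }))
    expect_equal(concentration(p, reg_n, tt), manual, tolerance = 1e-12)
  }
})

test_that("zero dose and washout limits are zero", {
  p <- table2_params()
  expect_equal(concentration(p, dosing_regimen(0, 12, 1), c(0, 1, 5)),
               c(0, 0, 0))
  late <- concentration(p, dosing_regimen(400, 12, 1, n_doses = 1), 500)
  expect_lt(late, 1e-10)
})

test_that("single-dose AUC to infinity equals dose over clearance", {
  p <- table2_params()
  reg <- dosing_regimen(400, 12, 1, n_doses = 1)
  tt <- seq(0, 400, length.out = 80001)
  cc <- concentration(p, reg, tt)
  auc <- sum((cc[-1] + cc[-length(cc)]) / 2) * (tt[2] - tt[1])
  expect_equal(auc, 400 / 25.4, tolerance = 1e-3)
})

test_that("steady-state profile integrates to dose/CL per interval and is periodic", {
  p <- table2_params()
  reg <- dosing_regimen(400, 12, 1)
  tt <- seq(0, 12, length.out = 20001)
  cc <- concentration(p, reg, tt)
  auc <- sum((cc[-1] + cc[-length(cc)]) / 2) * (tt[2] - tt[1])
  expect_equal(2 * auc, 800 / 25.4, tolerance = 1e-4)   # daily fAUC identity
  # periodicity: many-dose superposition approaches the analytic steady state
  reg30 <- dosing_regimen(400, 12, 1, n_doses = 30)
  t_obs <- 29 * 12 + c(0.5, 1, 3, 11.9)
  expect_equal(concentration(p, reg30, t_obs),
               concentration(p, reg, c(0.5, 1, 3, 11.9)), tolerance = 1e-6)
})

test_that("steady-state exposure metrics follow the linear-PK identities", {
  p <- table2_params()
  reg <- dosing_regimen(400, 12, 1)
  m <- steady_state_metrics(p, reg)
  expect_equal(m$fAUC24, 0.7 * 800 / 25.4, tolerance = 1e-12)  # ~22.05
  expect_gt(m$fCmax, m$fCmin)
  expect_gt(m$fCmin, 0)
  # fCmax is the profile maximum (brute-force fine grid)
  grid <- concentration(p, reg, seq(0, 12, by = 0.002))
  expect_equal(m$fCmax, 0.7 * max(grid), tolerance = 1e-5)
  # unbound-fraction proportionality
  m1 <- steady_state_metrics(p, reg, fu = 1)
  expect_equal(m1$fAUC24 / m$fAUC24, 1 / 0.7, tolerance = 1e-12)
  # dose linearity
  m2 <- steady_state_metrics(p, dosing_regimen(800, 12, 1))
  expect_equal(m2$fAUC24 / m$fAUC24, 2, tolerance = 1e-12)
  expect_equal(m2$fCmax / m$fCmax, 2, tolerance = 1e-9)
  expect_equal(m2$fCmin / m$fCmin, 2, tolerance = 1e-9)
  expect_error(steady_state_metrics(p, reg, fu = 1.2), "fu")
})
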