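# Shared fixtures: published-model truth, reduced one-eta scenarios for
# fast repeated fitting, and a quick control list for small fits.

table2_params <- function() pk_params(CL = 25.4, Vc = 91.1, Vp = 164, Q = 91.9)

# One-eta (CL only) truth for fast estimation scenarios
reduced_truth <- function(om_cl = 0.678, sigma_prop = 0.153,
                          sigma_add = 0.143) {
  population_model(c(CL = 25.4, Vc = 91.1, Vp = 164, Q = 91.9),
                   omega = matrix(om_cl^2, 1, 1,
                                  dimnames = list("CL", "CL")),
                   sigma_prop = sigma_prop, sigma_add = sigma_add)
}

# Single-group design for fast scenarios
small_design <- function(n = 16, interval = 12, missingness = 0) {
  study_design(groups = data.frame(dose = 400, interval = interval, n = n),
               missingness = missingness)
}

quick_control <- function() list(maxit_nm = 300, max_restarts = 3)

# Numerical ODE solution of the two-compartment infusion model (independent
# oracle for the closed form), via deSolve.
ode_concentration <- function(params, regimen, times) {
  mc <- micro_constants(params)
  n_doses <- if (is.infinite(regimen$n_doses)) {
    stop("ode oracle handles finite dose counts only")
  } else regimen$n_doses
  rate_in <- function(t) {
    r <- 0
    for (i in seq_len(n_doses)) {
      t0 <- (i - 1) * regimen$interval
      if (t > t0 && t <= t0 + regimen$infusion_duration) {
        r <- r + regimen$dose / regimen$infusion_duration
      }
    }
    r
  }
  deriv <- function(t, y, p) {
    list(c(rate_in(t) - (mc$k10 + mc$k12) * y[1] + mc$k21 * y[2],
           mc$k12 * y[1] - mc$k21 * y[2]))
  }
  grid <- sort(unique(c(0, times,
                        seq(0, max(times), by = regimen$infusion_duration / 20))))
  sol <- deSolve::lsoda(c(A1 = 0, A2 = 0), grid, deriv, NULL,
                        rtol = 1e-10, atol = 1e-12)
  approx(sol[, "time"], sol[, "A1"] / params$Vc, xout = times)$y
}
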