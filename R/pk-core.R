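#' Structural pharmacokinetic parameters of a two-compartment model
#'
#' Bundles the four disposition parameters of a two-compartment intravenous
#' model: clearance `CL` (L/h), central volume `Vc` (L), peripheral volume
#' `Vp` (L) and inter-compartmental clearance `Q` (L/h). All must be
#' strictly positive.
#'
#' @param CL Clearance, L/h.
#' @param Vc Central volume of distribution, L.
#' @param Vp Peripheral volume of distribution, L.
#' @param Q Inter-compartmental clearance, L/h.
#' @return An object of class `pk_params`.
#' @examples
#' pk_params(CL = 25.4, Vc = 91.1, Vp = 164, Q = 91.9)
#' @export
pk_params <- function(CL, Vc, Vp, Q) {
  vals <- c(CL = CL, Vc = Vc, Vp = Vp, Q = Q)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all of CL, Vc, Vp, Q must be finite and strictly positive")
  }
  structure(as.list(vals), class = "pk_params")
}

#' @export
print.pk_params <- function(x, ...) {
  cat("Two-compartment PK parameters\n")
  cat(sprintf("  CL = %.3g L/h, Vc = %.3g L, Vp = %.3g L, Q = %.3g L/h\n",
              x$CL, x$Vc, x$Vp, x$Q))
  invisible(x)
}

#' Micro-rate constants and disposition exponents
#'
#' Re-parameterizes (CL, Vc, Vp, Q) as first-order micro constants
#' `k10 = CL/Vc`, `k12 = Q/Vc`, `k21 = Q/Vp` and the bi-exponential
#' disposition exponents `alpha > beta`, the roots of
#' \eqn{s^2 - (k10+k12+k21)s + k10\,k21 = 0}, together with the
#' corresponding half-lives. `t_half_beta` is the terminal half-life.
#'
#' @param params A [pk_params()] object.
#' @return A list of class `micro_constants` with elements `k10`, `k12`,
#'   `k21`, `alpha`, `beta`, `t_half_alpha`, `t_half_beta`.
#' @examples
#' micro_constants(pk_params(25.4, 91.1, 164, 91.9))
#' @export
micro_constants <- function(params) {
  stopifnot(inherits(params, "pk_params"))
  k10 <- params$CL / params$Vc
  k12 <- params$Q / params$Vc
  k21 <- params$Q / params$Vp
  s <- k10 + k12 + k21
  p <- k10 * k21
  disc <- sqrt(max(s * s - 4 * p, 0))
  alpha <- (s + disc) / 2
  beta <- if (alpha > 0) p / alpha else 0 # stable for small beta
  structure(list(k10 = k10, k12 = k12, k21 = k21,
                 alpha = alpha, beta = beta,
                 t_half_alpha = log(2) / alpha,
                 t_half_beta = log(2) / beta),
            class = "micro_constants")
}

#' Intravenous dosing regimen
#'
#' @param dose Dose per administration, mg (non-negative).
#' @param interval Dosing interval, h.
#' @param infusion_duration Zero-order infusion duration, h; must lie in
#'   (0, interval]. Default 1 h.
#' @param n_doses Number of administered doses, or `Inf` for steady state.
#' @return An object of class `dosing_regimen`.
#' @examples
#' dosing_regimen(400, 12)              # 400 mg q12h at steady state
#' dosing_regimen(400, 8, 0.5, n_doses = 4)
#' @export
dosing_regimen <- function(dose, interval, infusion_duration = 1,
                           n_doses = Inf) {
  if (!is.finite(dose) || dose < 0) stop("dose must be >= 0")
  if (!is.finite(interval) || interval <= 0) stop("interval must be > 0")
  if (!is.finite(infusion_duration) || infusion_duration <= 0 ||
      infusion_duration > interval) {
    stop("infusion_duration must lie in (0, interval]")
  }
  if (!(is.infinite(n_doses) || (n_doses == floor(n_doses) && n_doses >= 1))) {
    stop("n_doses must be a positive integer or Inf (steady state)")
  }
  structure(list(dose = dose, interval = interval,
                 infusion_duration = infusion_duration, n_doses = n_doses),
            class = "dosing_regimen")
}

# Concentration from a single zero-order infusion, elapsed time `te` since
# the start of the infusion. Fully vectorized; recycles parameters against
# `te`. Returns 0 for te <= 0.
conc2_single <- function(te, CL, Vc, Vp, Q, amt, dur) {
  k10 <- CL / Vc
  k12 <- Q / Vc
  k21 <- Q / Vp
  s <- k10 + k12 + k21
  p <- k10 * k21
  disc <- sqrt(pmax(s * s - 4 * p, 0))
  alpha <- (s + disc) / 2
  beta <- p / alpha
  r0 <- amt / dur
  A1 <- (alpha - k21) / (alpha * (alpha - beta))
  A2 <- (k21 - beta) / (beta * (alpha - beta))
  t1 <- pmin(te, dur)           # time infused
  t2 <- pmax(te - dur, 0)       # time since end of infusion
  out <- (r0 / Vc) * (A1 * (1 - exp(-alpha * t1)) * exp(-alpha * t2) +
                      A2 * (1 - exp(-beta * t1)) * exp(-beta * t2))
  out[te <= 0] <- 0
  pmax(out, 0)
}

# Steady-state concentration at time `t` in [0, interval] after the start of
# a dose, for repeated infusions every `tau` hours. Vectorized.
conc2_ss <- function(t, CL, Vc, Vp, Q, amt, dur, tau) {
  k10 <- CL / Vc
  k12 <- Q / Vc
  k21 <- Q / Vp
  s <- k10 + k12 + k21
  p <- k10 * k21
  disc <- sqrt(pmax(s * s - 4 * p, 0))
  alpha <- (s + disc) / 2
  beta <- p / alpha
  r0 <- amt / dur
  A1 <- (alpha - k21) / (alpha * (alpha - beta))
  A2 <- (k21 - beta) / (beta * (alpha - beta))
  t1 <- pmin(t, dur)
  t2 <- pmax(t - dur, 0)
  # current dose + geometric accumulation of all earlier doses
  term <- function(A, lam) {
    acc <- exp(-lam * (t + tau - dur)) / (1 - exp(-lam * tau))
    A * ((1 - exp(-lam * t1)) * exp(-lam * t2) + (1 - exp(-lam * dur)) * acc)
  }
  pmax((r0 / Vc) * (term(A1, alpha) + term(A2, beta)), 0)
}

#' Plasma concentration under an intravenous infusion regimen
#'
#' Closed-form total plasma concentration of the two-compartment model under
#' zero-order infusions. For a finite number of doses the solution is the
#' superposition of single-dose solutions administered every
#' `regimen$interval` hours starting at `t = 0`; for `n_doses = Inf` the
#' analytic steady-state (accumulation-factor) form is used and `t` is
#' interpreted as time after the start of a steady-state dose, folded into
#' the dosing interval.
#'
#' @param params A [pk_params()] object.
#' @param regimen A [dosing_regimen()] object.
#' @param t Time, h (non-negative); vectorized.
#' @return Total plasma concentration, mg/L.
#' @examples
#' p <- pk_params(25.4, 91.1, 164, 91.9)
#' concentration(p, dosing_regimen(400, 12, 1), t = c(0.5, 1, 4, 12))
#' @export
concentration <- function(params, regimen, t) {
  stopifnot(inherits(params, "pk_params"), inherits(regimen, "dosing_regimen"))
  if (any(t < 0)) stop("t must be non-negative")
  if (regimen$dose == 0) return(rep(0, length(t)))
  with(regimen, {
    if (is.infinite(n_doses)) {
      conc2_ss(t %% interval, params$CL, params$Vc, params$Vp, params$Q,
               dose, infusion_duration, interval)
    } else {
      out <- numeric(length(t))
      for (i in seq_len(n_doses)) {
        out <- out + conc2_single(t - (i - 1) * interval, params$CL,
                                  params$Vc, params$Vp, params$Q,
                                  dose, infusion_duration)
      }
      out
    }
  })
}

#' Steady-state exposure metrics with free-fraction correction
#'
#' Free (unbound) exposure metrics at steady state: `fAUC24 = fu * 24 /
#' interval * dose / CL` (linear kinetics), `fCmax` the free concentration at
#' the end of a steady-state infusion (the maximum for an intravenous
#' infusion), and `fCmin` the free trough at the end of the interval. The
#' default unbound fraction `fu = 0.7` corresponds to 30% plasma protein
#' binding of ciprofloxacin.
#'
#' @inheritParams concentration
#' @param fu Unbound fraction in (0, 1]; default 0.7.
#' @return A list of class `exposure_metrics` with `fAUC24`, `fCmax`,
#'   `fCmin` (free concentrations, mg/L; fAUC24 in mg*h/L).
#' @examples
#' steady_state_metrics(pk_params(25.4, 91.1, 164, 91.9),
#'                      dosing_regimen(400, 12, 1))
#' @export
steady_state_metrics <- function(params, regimen, fu = 0.7) {
  stopifnot(inherits(params, "pk_params"), inherits(regimen, "dosing_regimen"))
  if (!is.finite(fu) || fu <= 0 || fu > 1) stop("fu must lie in (0, 1]")
  daily_dose <- regimen$dose * 24 / regimen$interval
  cmax <- conc2_ss(regimen$infusion_duration, params$CL, params$Vc,
                   params$Vp, params$Q, regimen$dose,
                   regimen$infusion_duration, regimen$interval)
  cmin <- conc2_ss(regimen$interval, params$CL, params$Vc, params$Vp,
                   params$Q, regimen$dose, regimen$infusion_duration,
                   regimen$interval)
  structure(list(fAUC24 = fu * daily_dose / params$CL,
                 fCmax = fu * cmax, fCmin = fu * cmin),
            class = "exposure_metrics")
}
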