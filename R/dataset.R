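#' Longitudinal PK event dataset
#'
#' Validates and classes a data.frame of NONMEM-style event records. Required
#' columns: `ID` (subject), `TIME` (h), `EVID` (1 dose, 0 observation),
#' `AMT` (mg, dose rows), `DUR` (infusion duration h, dose rows), `DV`
#' (observed concentration mg/L, observation rows), `MDV` (1 if DV missing).
#' Additional columns are carried as covariates (constant within subject).
#'
#' @param df A data.frame of event records.
#' @return The validated data.frame with class `pk_dataset`.
#' @export
pk_dataset <- function(df) {
  req <- c("ID", "TIME", "EVID", "AMT", "DUR", "DV", "MDV")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (any(df$TIME < 0)) stop("TIME must be non-negative")
  if (!all(df$EVID %in% c(0, 1))) stop("EVID must be 0 or 1")
  for (id in unique(df$ID)) {
    sub <- df[df$ID == id, ]
    if (is.unsorted(sub$TIME)) stop("times not sorted within subject ", id)
    if (!any(sub$EVID == 1)) stop("subject ", id, " has no dose record")
    if (!any(sub$EVID == 0 & sub$MDV == 0)) {
      stop("subject ", id, " has no observation")
    }
  }
  obs <- df$EVID == 0 & df$MDV == 0
  if (any(!is.finite(df$DV[obs])) || any(df$DV[obs] <= 0)) {
    stop("observed concentrations must be positive (drop BLQ records first)")
  }
  dose <- df$EVID == 1
  if (any(df$AMT[dose] < 0) || any(df$DUR[dose] <= 0)) {
    stop("dose records need AMT >= 0 and DUR > 0")
  }
  class(df) <- unique(c("pk_dataset", class(df)))
  df
}

#' @export
print.pk_dataset <- function(x, ...) {
  nobs <- sum(x$EVID == 0 & x$MDV == 0)
  cat(sprintf("PK dataset: %d subjects, %d observations, %d dose records\n",
              length(unique(x$ID)), nobs, sum(x$EVID == 1)))
  NextMethod()
}

#' Read a NONMEM-style PK dataset from CSV
#'
#' Accepts `RATE` (mg/h) in place of `DUR`; rows with `DV` below the lower
#' limit of quantification (default 0.04 mg/L, the assay limit) are dropped
#' with a message, following the M1 below-limit policy.
#'
#' @param path CSV file path.
#' @param lloq Lower limit of quantification, mg/L; observation rows with
#'   `DV < lloq` are discarded. Use 0 to keep everything.
#' @return A [pk_dataset()].
#' @export
read_pk_dataset <- function(path, lloq = 0.04) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!"DUR" %in% names(df) && "RATE" %in% names(df)) {
    df$DUR <- ifelse(df$EVID == 1 & df$RATE > 0, df$AMT / df$RATE, NA_real_)
    df$RATE <- NULL
  }
  if (!"MDV" %in% names(df)) df$MDV <- ifelse(df$EVID == 1, 1L, 0L)
  df$DUR[df$EVID != 1] <- NA_real_
  blq <- df$EVID == 0 & df$MDV == 0 & df$DV < lloq
  if (any(blq)) {
    message(sum(blq), " observation(s) below ", lloq,
            " mg/L discarded (M1 policy)")
    df <- df[!blq, ]
  }
  pk_dataset(df)
}

#' Write a PK dataset to NONMEM-style CSV
#'
#' Round-trips with [read_pk_dataset()] (`lloq = 0`).
#'
#' @param dataset A [pk_dataset()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_pk_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "pk_dataset"))
  write.csv(as.data.frame(dataset), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Serialize / load a population model as JSON
#'
#' Flat, unit-explicit parameter file so externally published popPK
#' parameter sets can be loaded (e.g. to drive [simulate_pta()]).
#' Units: theta in L/h (CL, Q) and L (Vc, Vp); omega on the log scale;
#' sigma_prop a fraction; sigma_add mg/L.
#'
#' @param pop A [population_model()].
#' @param path JSON file path.
#' @return `write_model_json` returns `path` invisibly; `read_model_json`
#'   returns a [population_model()].
#' @export
write_model_json <- function(pop, path) {
  stopifnot(inherits(pop, "population_model"))
  obj <- list(
    units = list(CL = "L/h", Vc = "L", Vp = "L", Q = "L/h",
                 sigma_add = "mg/L", sigma_prop = "fraction",
                 omega = "log-scale (co)variance"),
    theta = as.list(pop$theta),
    omega_names = rownames(pop$omega),
    omega = pop$omega,
    sigma_prop = pop$sigma_prop,
    sigma_add = pop$sigma_add,
    covariate_effects = lapply(pop$covariate_effects, function(ce) {
      ce[c("parameter", "covariate", "kind", "theta_cov", "cov_median")]
    }))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  omega <- as.matrix(obj$omega)
  if (length(omega) == 0) omega <- matrix(numeric(0), 0, 0)
  if (!is.null(obj$omega_names)) {
    dimnames(omega) <- list(obj$omega_names, obj$omega_names)
  }
  effs <- list()
  if (!is.null(obj$covariate_effects) && length(obj$covariate_effects)) {
    ce <- obj$covariate_effects
    if (is.data.frame(ce)) ce <- split(ce, seq_len(nrow(ce)))
    effs <- lapply(ce, function(e) {
      covariate_effect(e$parameter, e$covariate, e$kind, e$theta_cov,
                       ifelse(is.null(e$cov_median), NA_real_, e$cov_median))
    })
  }
  population_model(theta = unlist(obj$theta), omega = omega,
                   sigma_prop = obj$sigma_prop, sigma_add = obj$sigma_add,
                   covariate_effects = unname(effs))
}
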