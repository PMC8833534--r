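#' Compute NTCP for one endpoint
#'
#' Evaluates the logistic toxicity model
#' `NTCP = plogis(intercept + sum(beta_oar * Dmean_oar) + baseline)`,
#' where the baseline term is the model's coefficient for the
#' patient's level of the relevant pre-treatment complaint covariate.
#'
#' An OAR with a nonzero dose coefficient but no dose supplied is an
#' error unless `missing_oar = "zero"`, in which case 0 Gy is imputed
#' with a warning (an anatomically absent organ contributes no dose).
#'
#' @param model an [NTCPModel-class].
#' @param dmeans named numeric of mean doses (Gy) keyed by OAR; `NA`
#'   marks a missing dose.
#' @param baseline named list or character vector of baseline
#'   covariate levels, e.g.
#'   `c(baseline_xerostomia = "none", baseline_dysphagia = "minor")`.
#' @param missing_oar `"error"` (default) or `"zero"`.
#' @return The complication probability, strictly inside `(0, 1)`.
#' @export
#' @examples
#' m <- ntcpModel("xerostomia_g2", -2,
#'                dose_betas = c(parotid_left = 0.02),
#'                baseline_covariate = "baseline_xerostomia",
#'                baseline_betas = c(none = 0, minor = 0.5))
#' computeNtcp(m, c(parotid_left = 30),
#'             baseline = c(baseline_xerostomia = "none"))
computeNtcp <- function(model, dmeans, baseline,
                        missing_oar = c("error", "zero")) {
  stopifnot(is(model, "NTCPModel"))
  missing_oar <- match.arg(missing_oar)
  s <- model@intercept
  for (oar in names(model@dose_betas)) {
    beta <- model@dose_betas[[oar]]
    if (beta == 0) next
    d <- if (oar %in% names(dmeans)) dmeans[[oar]] else NA_real_
    if (is.na(d)) {
      if (missing_oar == "error")
        stop("no dose for OAR '", oar, "' required by endpoint ",
             model@endpoint,
             " (set missing_oar = \"zero\" to impute 0 Gy)")
      warning("imputing 0 Gy for missing OAR '", oar, "' in endpoint ",
              model@endpoint)
      d <- 0
    }
    s <- s + beta * d
  }
  lev <- baseline[[model@baseline_covariate]]
  if (is.null(lev) || is.na(lev))
    stop("baseline covariate '", model@baseline_covariate,
         "' not supplied for endpoint ", model@endpoint)
  if (!lev %in% names(model@baseline_betas))
    stop("unknown level '", lev, "' of baseline covariate '",
         model@baseline_covariate, "'")
  s <- s + model@baseline_betas[[lev]]
  plogis(s)
}

#' NTCP profile for one plan
#'
#' Evaluates all four endpoint models against one plan's mean doses.
#'
#' @param models list of the four [NTCPModel-class]s (one per
#'   endpoint).
#' @param dmeans named numeric of mean doses (Gy) keyed by OAR.
#' @param baseline baseline covariate levels (see [computeNtcp()]).
#' @param missing_oar missing-dose policy passed through.
#' @return Named numeric of probabilities over [ntcpEndpoints()].
#' @export
ntcpProfile <- function(models, dmeans, baseline,
                        missing_oar = c("error", "zero")) {
  missing_oar <- match.arg(missing_oar)
  eps <- vapply(models, function(m) m@endpoint, "")
  if (!setequal(eps, ntcpEndpoints()))
    stop("models must cover exactly the four endpoints")
  names(models) <- eps
  vapply(ntcpEndpoints(), function(e)
    computeNtcp(models[[e]], dmeans, baseline, missing_oar),
    numeric(1))
}

#' Delta-NTCP profile between two plans
#'
#' The photon-minus-proton toxicity-risk difference per endpoint, in
#' percentage points.  Negative values (proton worse) are preserved;
#' they simply cannot satisfy any qualification criterion.
#'
#' @param ntcp_vmat,ntcp_impt named numerics over [ntcpEndpoints()]
#'   (probabilities in `(0, 1)`).
#' @return Named numeric: `100 * (NTCP_VMAT - NTCP_IMPT)` per
#'   endpoint.
#' @export
#' @examples
#' deltaProfile(c(dysphagia_g2 = 0.30, xerostomia_g2 = 0.2,
#'                dysphagia_g3 = 0.05, xerostomia_g3 = 0.04),
#'              c(dysphagia_g2 = 0.18, xerostomia_g2 = 0.15,
#'                dysphagia_g3 = 0.03, xerostomia_g3 = 0.05))
deltaProfile <- function(ntcp_vmat, ntcp_impt) {
  eps <- ntcpEndpoints()
  if (!all(eps %in% names(ntcp_vmat)) || !all(eps %in% names(ntcp_impt)))
    stop("both NTCP profiles must cover the four endpoints")
  100 * (ntcp_vmat[eps] - ntcp_impt[eps])
}
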