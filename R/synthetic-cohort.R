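#' Default synthetic NTCP model set
#'
#' Four logistic toxicity models with synthetic illustrative
#' coefficients: the national-protocol coefficients are distributed
#' with the protocol itself and are consumed by this package as
#' configuration, so tests and simulations ship with a clearly
#' synthetic set whose structure matches the protocol's (dysphagia
#' driven by oral cavity and constrictor doses, xerostomia by salivary
#' gland doses, grade >=3 risks roughly an order of magnitude below
#' grade >=2, and an additive baseline-complaint term).
#'
#' @return Named list of four [NTCPModel-class]s keyed by endpoint.
#' @export
defaultNtcpModels <- function() {
  bl2 <- c(none = 0, minor = 0.4, moderate_severe = 0.9)
  bl3 <- c(none = 0, minor = 0.5, moderate_severe = 1.0)
  list(
    dysphagia_g2 = ntcpModel("dysphagia_g2", intercept = -3.1,
      dose_betas = c(oral_cavity = 0.012, pcm_superior = 0.010,
                     pcm_medius = 0.007, pcm_inferior = 0.005),
      baseline_covariate = "baseline_dysphagia", baseline_betas = bl2),
    xerostomia_g2 = ntcpModel("xerostomia_g2", intercept = -2.7,
      dose_betas = c(parotid_left = 0.016, parotid_right = 0.016,
                     submandibular_left = 0.005,
                     submandibular_right = 0.005, oral_cavity = 0.004),
      baseline_covariate = "baseline_xerostomia", baseline_betas = bl2),
    dysphagia_g3 = ntcpModel("dysphagia_g3", intercept = -5.2,
      dose_betas = c(oral_cavity = 0.010, pcm_superior = 0.009,
                     pcm_medius = 0.006, pcm_inferior = 0.004),
      baseline_covariate = "baseline_dysphagia", baseline_betas = bl3),
    xerostomia_g3 = ntcpModel("xerostomia_g3", intercept = -5.0,
      dose_betas = c(parotid_left = 0.013, parotid_right = 0.013,
                     submandibular_left = 0.004,
                     submandibular_right = 0.004, oral_cavity = 0.003),
      baseline_covariate = "baseline_xerostomia", baseline_betas = bl3))
}

#' Cohort simulation specification
#'
#' Defines the generative model of a feature-level synthetic cohort.
#' Per patient and OAR a latent proximity `d70` (mm, distance-like
#' offset of the OAR from the 70 Gy target) and a target-level gap
#' `gap` (mm, offset between the 54.25 and 70 Gy target surfaces) are
#' drawn; overlap percentages follow the monotone-in-margin profiles
#' `pct_in70(m) = 100 * plogis((m - d70) / width)` and
#' `pct_in54_out70(m) = 100 * plogis((m - d70 + gap) / width) -
#' pct_in70(m)`.  Actual mean doses are the per-OAR/modality true
#' linear model evaluated at that modality's true margin plus
#' homoscedastic Gaussian noise, clamped to 0-70 Gy.  Actual
#' qualification labels are computed by running the NTCP models and
#' thresholds on the actual doses.
#'
#' Random numbers are consumed in a fixed, documented order so seeds
#' are portable: (1) `d70` per OAR in canonical order, n draws each;
#' (2) `gap` likewise; (3) VMAT dose noise per OAR; (4) IMPT dose
#' noise per OAR; (5) baseline xerostomia levels; (6) baseline
#' dysphagia levels; (7) tumor locations.
#'
#' @param n_patients cohort size (default 151, the size of a typical
#'   national-selection cohort year).
#' @param seed integer RNG seed.
#' @param geometry data.frame with one row per OAR: `oar`,
#'   `d70_mean`, `d70_sd`, `gap_mean`, `gap_sd`, `width` (mm).
#' @param true_margin data.frame `oar`, `modality`, `margin_mm`: the
#'   margin at which the true dose model operates.
#' @param true_coef data.frame `oar`, `modality`, `intercept`,
#'   `coef_in70`, `coef_in54_out70` (Gy, Gy/%).
#' @param noise_sd data.frame `oar`, `modality`, `sd` (Gy).
#' @param margins feature margins to tabulate (default 0, 3, 5, 7,
#'   10, 15 mm).
#' @param baseline_freqs list with named numeric `xerostomia` and
#'   `dysphagia` level frequencies (each summing to 1).
#' @param location_freqs named numeric of tumor-location frequencies
#'   (summing to 1).
#' @param ntcp_models list of four [NTCPModel-class]s.
#' @param thresholds a [ThresholdConfig-class].
#' @return A list with class `cohortSpec`.
#' @export
cohortSpec <- function(n_patients = 151L, seed = 1L,
                       geometry = defaultCohortGeometry(),
                       true_margin = defaultTrueMargins(),
                       true_coef = defaultTrueCoefficients(),
                       noise_sd = defaultNoiseSd(),
                       margins = c(0, 3, 5, 7, 10, 15),
                       baseline_freqs = list(
                         xerostomia = c(none = 0.60, minor = 0.30,
                                        moderate_severe = 0.10),
                         dysphagia = c(none = 0.50, minor = 0.35,
                                       moderate_severe = 0.15)),
                       location_freqs = c(pharynx = 0.55, larynx = 0.25,
                                          other = 0.20),
                       ntcp_models = defaultNtcpModels(),
                       thresholds = thresholdConfig()) {
  if (n_patients < 1) stop("n_patients must be >= 1")
  for (fr in c(baseline_freqs, list(location = location_freqs)))
    if (abs(sum(fr) - 1) > 1e-8)
      stop("frequency vectors must sum to 1")
  if (any(noise_sd$sd < 0)) stop("noise_sd must be >= 0")
  structure(list(n_patients = as.integer(n_patients),
                 seed = as.integer(seed), geometry = geometry,
                 true_margin = true_margin, true_coef = true_coef,
                 noise_sd = noise_sd, margins = sort(unique(margins)),
                 baseline_freqs = baseline_freqs,
                 location_freqs = location_freqs,
                 ntcp_models = ntcp_models, thresholds = thresholds),
            class = "cohortSpec")
}

#' @describeIn cohortSpec default per-OAR geometry distribution:
#'   constrictors near or inside the targets, parotids lateral,
#'   submandibulars intermediate.
#' @export
defaultCohortGeometry <- function() {
  data.frame(
    oar = canonicalOars(),
    d70_mean = c(6, 13, 13, 5, 5, 3, 6, 10),
    d70_sd   = c(6, 5, 5, 5, 5, 4, 4, 5),
    gap_mean = rep(6, 8), gap_sd = rep(2, 8), width = rep(4, 8),
    stringsAsFactors = FALSE)
}

#' @describeIn cohortSpec default true margins: the penumbra-scale
#'   margins at which the dose-overlap relation is tightest — around
#'   10 mm for photon plans and 5-7 mm for proton plans.
#' @export
defaultTrueMargins <- function() {
  rbind(
    data.frame(oar = canonicalOars(), modality = "VMAT",
               margin_mm = c(15, 7, 7, 10, 10, 10, 10, 10),
               stringsAsFactors = FALSE),
    data.frame(oar = canonicalOars(), modality = "IMPT",
               margin_mm = c(7, 7, 5, 5, 5, 5, 5, 7),
               stringsAsFactors = FALSE))
}

#' @describeIn cohortSpec default true linear dose model: photon plans
#'   carry a sizable out-of-field bath dose (intercept) with moderate
#'   overlap slopes; proton plans have a near-zero intercept and
#'   steeper slopes (dose concentrated where the organ meets the
#'   target).
#' @export
defaultTrueCoefficients <- function() {
  v_int <- c(12, 8, 8, 12, 12, 14, 14, 12)
  rbind(
    data.frame(oar = canonicalOars(), modality = "VMAT",
               intercept = v_int, coef_in70 = 0.55,
               coef_in54_out70 = 0.30, stringsAsFactors = FALSE),
    data.frame(oar = canonicalOars(), modality = "IMPT",
               intercept = 2, coef_in70 = 0.65,
               coef_in54_out70 = 0.32, stringsAsFactors = FALSE))
}

#' @describeIn cohortSpec default residual noise: 3 Gy for photon
#'   doses, 2 Gy for proton doses (the proton dose-overlap relation
#'   is tighter).
#' @export
defaultNoiseSd <- function() {
  rbind(data.frame(oar = canonicalOars(), modality = "VMAT", sd = 3,
                   stringsAsFactors = FALSE),
        data.frame(oar = canonicalOars(), modality = "IMPT", sd = 2,
                   stringsAsFactors = FALSE))
}

.lookup <- function(df, oar, modality, col) {
  v <- df[[col]][df$oar == oar & df$modality == modality]
  if (length(v) != 1L)
    stop("spec table has no unique ", col, " for ", oar, "/", modality)
  v
}

#' Generate a feature-level synthetic cohort
#'
#' Draws a cohort from a [cohortSpec()]: overlap features at every
#' margin, actual VMAT/IMPT mean doses, baseline covariates with
#' tumor location and treatment order, and the actual plan-comparison
#' qualification label obtained by running the NTCP models and
#' thresholds on the actual doses.  Fully reproducible from
#' `spec$seed`; the RNG state of the caller is restored on exit.
#'
#' @param spec a [cohortSpec()].
#' @return List with data.frames `features` (`patient_id`, `oar`,
#'   `margin_mm`, `pct_in70`, `pct_in54_out70`, `absent`), `dmeans`
#'   (`patient_id`, `oar`, `modality`, `dmean`), `covariates`
#'   (`patient_id`, `baseline_xerostomia`, `baseline_dysphagia`,
#'   `tumor_location`, `treatment_order`), `labels` (`patient_id`,
#'   four `delta_*` columns, `actual_qualifies`,
#'   `triggered_criteria`), and the `spec`.
#' @export
#' @examples
#' cohort <- generateCohort(cohortSpec(n_patients = 20, seed = 7))
#' head(cohort$labels)
generateCohort <- function(spec) {
  if (!inherits(spec, "cohortSpec"))
    stop("spec must be created with cohortSpec()")
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, globalenv()))
  set.seed(spec$seed)

  n <- spec$n_patients
  oars <- spec$geometry$oar
  pid <- sprintf("P%03d", seq_len(n))

  # (1) latent proximities, (2) target-level gaps (canonical order)
  d70 <- sapply(seq_along(oars), function(j)
    rnorm(n, spec$geometry$d70_mean[j], spec$geometry$d70_sd[j]))
  gap <- sapply(seq_along(oars), function(j)
    pmax(0.5, rnorm(n, spec$geometry$gap_mean[j],
                    spec$geometry$gap_sd[j])))
  colnames(d70) <- colnames(gap) <- oars

  feat <- list()
  for (j in seq_along(oars)) {
    w <- spec$geometry$width[j]
    for (m in spec$margins) {
      p70 <- 100 * plogis((m - d70[, j]) / w)
      p54 <- 100 * plogis((m - d70[, j] + gap[, j]) / w)
      feat[[length(feat) + 1L]] <- data.frame(
        patient_id = pid, oar = oars[j], margin_mm = m,
        pct_in70 = p70, pct_in54_out70 = p54 - p70, absent = FALSE,
        stringsAsFactors = FALSE)
    }
  }
  features <- do.call(rbind, feat)
  rownames(features) <- NULL

  featAt <- function(oar, margin) {
    f <- features[features$oar == oar & features$margin_mm == margin, ]
    f[match(pid, f$patient_id), c("pct_in70", "pct_in54_out70")]
  }

  # (3) VMAT noise then (4) IMPT noise, canonical OAR order
  dm <- list()
  for (modality in c("VMAT", "IMPT")) {
    for (oar in oars) {
      tm <- .lookup(spec$true_margin, oar, modality, "margin_mm")
      if (!tm %in% spec$margins)
        stop("true margin ", tm, " for ", oar, "/", modality,
             " is not among the tabulated margins")
      co <- spec$true_coef[spec$true_coef$oar == oar &
                             spec$true_coef$modality == modality, ]
      sdv <- .lookup(spec$noise_sd, oar, modality, "sd")
      f <- featAt(oar, tm)
      mu <- co$intercept + co$coef_in70 * f$pct_in70 +
        co$coef_in54_out70 * f$pct_in54_out70
      y <- mu + if (sdv > 0) rnorm(n, 0, sdv) else 0
      dm[[length(dm) + 1L]] <- data.frame(
        patient_id = pid, oar = oar, modality = modality,
        dmean = pmin(pmax(y, 0), 70), stringsAsFactors = FALSE)
    }
  }
  dmeans <- do.call(rbind, dm)
  rownames(dmeans) <- NULL

  # (5)-(7) covariates
  bx <- sample(names(spec$baseline_freqs$xerostomia), n, replace = TRUE,
               prob = spec$baseline_freqs$xerostomia)
  bd <- sample(names(spec$baseline_freqs$dysphagia), n, replace = TRUE,
               prob = spec$baseline_freqs$dysphagia)
  loc <- sample(names(spec$location_freqs), n, replace = TRUE,
                prob = spec$location_freqs)
  covariates <- data.frame(patient_id = pid, baseline_xerostomia = bx,
                           baseline_dysphagia = bd, tumor_location = loc,
                           treatment_order = seq_len(n),
                           stringsAsFactors = FALSE)

  # actual decision labels from the actual doses
  labels <- cohortDecisions(dmeans, covariates, spec$ntcp_models,
                            spec$thresholds)
  names(labels)[names(labels) == "qualifies"] <- "actual_qualifies"

  list(features = features, dmeans = dmeans, covariates = covariates,
       labels = labels, spec = spec)
}

#' Decide qualification for a cohort of actual or predicted doses
#'
#' Evaluates the NTCP models and thresholds for every patient of a
#' long-format dose table containing both modalities.
#'
#' @param dmeans data.frame `patient_id`, `oar`, `modality`, `dmean`.
#' @param covariates data.frame with `patient_id` and the baseline
#'   covariate columns the models need.
#' @param ntcp_models list of four [NTCPModel-class]s.
#' @param thresholds a [ThresholdConfig-class].
#' @param missing_oar missing-dose policy (see [computeNtcp()]).
#' @return data.frame `patient_id`, `delta_<endpoint>` (four columns,
#'   percentage points), `qualifies`, `triggered_criteria`
#'   (semicolon-joined).
#' @export
cohortDecisions <- function(dmeans, covariates, ntcp_models,
                            thresholds = thresholdConfig(),
                            missing_oar = c("error", "zero")) {
  missing_oar <- match.arg(missing_oar)
  pid <- unique(dmeans$patient_id)
  rows <- lapply(pid, function(p) {
    dv <- dmeans[dmeans$patient_id == p & dmeans$modality == "VMAT", ]
    di <- dmeans[dmeans$patient_id == p & dmeans$modality == "IMPT", ]
    cov <- covariates[covariates$patient_id == p, , drop = FALSE]
    if (nrow(cov) != 1L)
      stop("covariates must contain exactly one row for patient ", p)
    bl <- as.list(cov)
    nv <- ntcpProfile(ntcp_models, setNames(dv$dmean, dv$oar), bl,
                      missing_oar)
    ni <- ntcpProfile(ntcp_models, setNames(di$dmean, di$oar), bl,
                      missing_oar)
    delta <- deltaProfile(nv, ni)
    res <- decide(delta, thresholds)
    out <- data.frame(patient_id = p, stringsAsFactors = FALSE)
    for (e in ntcpEndpoints()) out[[paste0("delta_", e)]] <- delta[[e]]
    out$qualifies <- qualifies(res)
    out$triggered_criteria <- paste(triggeredCriteria(res),
                                    collapse = ";")
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
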