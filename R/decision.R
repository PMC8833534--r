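#' Apply the qualification thresholds to a delta-NTCP profile
#'
#' Evaluates the four protocol criteria against a per-endpoint
#' delta-NTCP profile (percentage points, photon minus proton), all
#' with inclusive (`>=`) comparisons:
#' \itemize{
#'   \item `single_g2`: some grade >=2 endpoint gain >= 10 pp;
#'   \item `single_g3`: some grade >=3 endpoint gain >= 5 pp;
#'   \item `sum_g2`: the grade >=2 gains that are individually
#'     >= 5 pp sum to >= 15 pp;
#'   \item `sum_g3`: the grade >=3 gains that are individually
#'     >= 3.75 pp sum to >= 5 pp.
#' }
#' The per-endpoint minimum acts as a contribution filter: an endpoint
#' below the minimum is excluded from the sum rather than voiding the
#' criterion.
#'
#' @param delta named numeric over [ntcpEndpoints()], in percentage
#'   points.
#' @param thresholds a [ThresholdConfig-class] (protocol defaults).
#' @param comparison_mode recorded in the result: `"predicted"` or
#'   `"hybrid"`.
#' @param audit optional list stored in the result for auditing.
#' @return A [DecisionResult-class].
#' @export
#' @examples
#' decide(c(dysphagia_g2 = 12, xerostomia_g2 = 0,
#'          dysphagia_g3 = 0, xerostomia_g3 = 0))
decide <- function(delta, thresholds = thresholdConfig(),
                   comparison_mode = "predicted", audit = list()) {
  stopifnot(is(thresholds, "ThresholdConfig"))
  eps <- ntcpEndpoints()
  if (!all(eps %in% names(delta)) || anyNA(delta[eps]))
    stop("delta must supply all four endpoints: ",
         paste(eps, collapse = ", "))
  delta <- delta[eps]
  g2 <- delta[.g2Endpoints()]
  g3 <- delta[.g3Endpoints()]
  trig <- character()
  if (any(g2 >= thresholds@single_g2)) trig <- c(trig, "single_g2")
  if (any(g3 >= thresholds@single_g3)) trig <- c(trig, "single_g3")
  if (sum(g2[g2 >= thresholds@min_g2]) >= thresholds@sum_g2)
    trig <- c(trig, "sum_g2")
  if (sum(g3[g3 >= thresholds@min_g3]) >= thresholds@sum_g3)
    trig <- c(trig, "sum_g3")
  new("DecisionResult", delta_ntcp = delta,
      qualifies = length(trig) > 0, triggered_criteria = trig,
      comparison_mode = comparison_mode, audit = audit)
}

#' Vectorized qualification over many delta-NTCP profiles
#'
#' Same rule as [decide()], evaluated column-wise over a matrix of
#' profiles (used for cohort scoring and threshold sweeps).
#'
#' @param delta_matrix numeric matrix with one row per profile and one
#'   column per endpoint (column names from [ntcpEndpoints()]).
#' @param thresholds a [ThresholdConfig-class].
#' @return Logical vector: one qualification flag per row.
#' @export
decideBatch <- function(delta_matrix, thresholds = thresholdConfig()) {
  stopifnot(is(thresholds, "ThresholdConfig"))
  eps <- ntcpEndpoints()
  if (!all(eps %in% colnames(delta_matrix)))
    stop("delta_matrix must have the four endpoint columns")
  d <- delta_matrix[, eps, drop = FALSE]
  g2 <- d[, .g2Endpoints(), drop = FALSE]
  g3 <- d[, .g3Endpoints(), drop = FALSE]
  single_g2 <- rowSums(g2 >= thresholds@single_g2) > 0
  single_g3 <- rowSums(g3 >= thresholds@single_g3) > 0
  sum_g2 <- rowSums(g2 * (g2 >= thresholds@min_g2)) >= thresholds@sum_g2
  sum_g3 <- rowSums(g3 * (g3 >= thresholds@min_g3)) >= thresholds@sum_g3
  unname(single_g2 | single_g3 | sum_g2 | sum_g3)
}

#' Run the full decision pipeline for one patient
#'
#' End-to-end composition of the tool's workflow: look up the
#' patient's overlap features at each OAR's selected expansion margin,
#' predict the mean doses for both modalities (or take the actual
#' VMAT doses in hybrid mode), optionally apply a post-hoc IMPT
#' adjustment, evaluate the four NTCP models per plan, form the
#' delta-NTCP profile and apply the thresholds.  All intermediate
#' values are retained in the result's audit slot.
#'
#' @param features data.frame of this patient's overlap features
#'   (columns `oar`, `margin_mm`, `pct_in70`, `pct_in54_out70`,
#'   optionally `absent`), covering every margin used by the selected
#'   models.
#' @param dmean_models named list of selected [DmeanModel-class]s
#'   keyed `oar|modality` (as from [selectAllMargins()]).
#' @param ntcp_models list of the four [NTCPModel-class]s.
#' @param baseline baseline covariate levels (see [computeNtcp()]).
#' @param thresholds a [ThresholdConfig-class].
#' @param mode `"predicted"` (default) compares predicted VMAT with
#'   predicted IMPT; `"hybrid"` compares the supplied actual VMAT
#'   doses with predicted IMPT.
#' @param actual_vmat_dmeans named numeric of actual VMAT mean doses
#'   (Gy), required in hybrid mode.
#' @param adjustment optional [adjustmentSpec()] applied to the
#'   predicted doses of `adjust_modality`.
#' @param adjust_modality modality whose predictions the adjustment
#'   modifies (default `"IMPT"`).
#' @param missing_oar missing-dose policy: `"error"` (default) or
#'   `"zero"`.
#' @return A [DecisionResult-class].
#' @export
runPatient <- function(features, dmean_models, ntcp_models, baseline,
                       thresholds = thresholdConfig(),
                       mode = c("predicted", "hybrid"),
                       actual_vmat_dmeans = NULL, adjustment = NULL,
                       adjust_modality = "IMPT",
                       missing_oar = c("error", "zero")) {
  mode <- match.arg(mode)
  missing_oar <- match.arg(missing_oar)
  if (mode == "hybrid" && is.null(actual_vmat_dmeans))
    stop("hybrid mode requires actual VMAT mean doses")

  oars <- unique(vapply(dmean_models, function(m) m@oar, ""))
  preds <- list()
  sel_models <- list()
  for (modality in .modalities()) {
    dm <- setNames(rep(NA_real_, length(oars)), oars)
    mods <- list()
    for (oar in oars) {
      m <- dmean_models[[paste(oar, modality, sep = "|")]]
      if (is.null(m)) next
      mods[[oar]] <- m
      fe <- features[features$oar == oar &
                       features$margin_mm == m@margin_mm, , drop = FALSE]
      if (nrow(fe) != 1L)
        stop("features must contain exactly one row for OAR '", oar,
             "' at the selected margin ", m@margin_mm, " mm")
      if (!is.null(fe$absent) && isTRUE(fe$absent[1])) next  # stays NA
      dm[[oar]] <- predictDmean(m, fe$pct_in70, fe$pct_in54_out70)
    }
    if (!is.null(adjustment) && modality == adjust_modality)
      dm <- applyAdjustment(dm, mods, adjustment, modality,
                            features = features)
    preds[[modality]] <- dm
    sel_models[[modality]] <- mods
  }
  vmat_dm <- if (mode == "hybrid") actual_vmat_dmeans
    else preds[["VMAT"]]
  impt_dm <- preds[["IMPT"]]

  ntcp_vmat <- ntcpProfile(ntcp_models, vmat_dm, baseline, missing_oar)
  ntcp_impt <- ntcpProfile(ntcp_models, impt_dm, baseline, missing_oar)
  delta <- deltaProfile(ntcp_vmat, ntcp_impt)
  decide(delta, thresholds, comparison_mode = mode,
         audit = list(features = features,
                      predicted_dmeans = preds,
                      vmat_dmeans_used = vmat_dm,
                      impt_dmeans_used = impt_dm,
                      ntcp_vmat = ntcp_vmat, ntcp_impt = ntcp_impt))
}
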