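#' Specify a post-hoc sensitivity adjustment
#'
#' Institutions prioritizing sensitivity (fewer false-negative
#' proton-therapy calls) can bias the predicted doses in favor of
#' qualification by one of three mechanisms: rescaling the predicted
#' IMPT doses by a factor below 1, re-predicting with the
#' lower (IMPT) or upper (VMAT) 95% confidence bound of every model
#' coefficient, or shifting predicted IMPT doses down by a multiple of
#' the model residual SD.  The adjustment can be restricted to a
#' subset of OARs (e.g. the salivary glands, which drive
#' xerostomia-based qualification of laryngeal patients).
#'
#' @param method one of `"rescale"`, `"ci_bound"`, `"sd_shift"`.
#' @param factor multiplicative factor for `rescale` (> 0, e.g. 0.85).
#' @param k_sd number of residual SDs to subtract for `sd_shift`
#'   (e.g. 1).
#' @param pooled_sd optional pooled residual SD in Gy for `sd_shift`;
#'   when `NULL` (default) each OAR uses its own model's residual SD.
#' @param target_oars OAR names the adjustment applies to; default all
#'   eight.
#' @return An `adjustmentSpec` list.
#' @export
#' @examples
#' adjustmentSpec("rescale", factor = 0.85,
#'                target_oars = c("parotid_left", "parotid_right"))
adjustmentSpec <- function(method = c("rescale", "ci_bound", "sd_shift"),
                           factor = NULL, k_sd = NULL, pooled_sd = NULL,
                           target_oars = canonicalOars()) {
  method <- match.arg(method)
  if (method == "rescale") {
    if (is.null(factor) || !is.finite(factor) || factor <= 0)
      stop("rescale adjustment requires a positive 'factor'")
  } else if (method == "sd_shift") {
    if (is.null(k_sd) || !is.finite(k_sd))
      stop("sd_shift adjustment requires 'k_sd'")
    if (!is.null(pooled_sd) && (!is.finite(pooled_sd) || pooled_sd < 0))
      stop("'pooled_sd' must be a non-negative number")
  }
  if (length(bad <- setdiff(target_oars, canonicalOars())))
    stop("unknown target OAR(s): ", paste(bad, collapse = ", "))
  structure(list(method = method, factor = factor, k_sd = k_sd,
                 pooled_sd = pooled_sd, target_oars = target_oars),
            class = "adjustmentSpec")
}

#' Apply a post-hoc adjustment to predicted mean doses
#'
#' @param dmeans named numeric of predicted mean doses (Gy) keyed by
#'   OAR.
#' @param models named list of the selected [DmeanModel-class]s for
#'   this modality, keyed by OAR (required for `ci_bound` and for
#'   per-model `sd_shift`).
#' @param spec an [adjustmentSpec()].
#' @param modality `"VMAT"` or `"IMPT"`; decides the `ci_bound` side
#'   (lower bound for IMPT, upper for VMAT).
#' @param features for `ci_bound` only: data.frame of this patient's
#'   overlap features (columns `oar`, `margin_mm`, `pct_in70`,
#'   `pct_in54_out70`) so doses can be re-predicted from the bound
#'   coefficients at each model's margin.
#' @return Named numeric of adjusted doses, clamped to `[0, 70]` Gy;
#'   OARs outside `spec$target_oars` are returned unchanged.
#' @export
applyAdjustment <- function(dmeans, models, spec, modality,
                            features = NULL) {
  if (!inherits(spec, "adjustmentSpec"))
    stop("spec must be created with adjustmentSpec()")
  modality <- match.arg(modality, .modalities())
  out <- dmeans
  targets <- intersect(names(dmeans), spec$target_oars)
  for (oar in targets) {
    if (is.na(out[[oar]])) next
    if (spec$method == "rescale") {
      out[[oar]] <- dmeans[[oar]] * spec$factor
    } else if (spec$method == "sd_shift") {
      s <- if (!is.null(spec$pooled_sd)) spec$pooled_sd
        else {
          m <- models[[oar]]
          if (is.null(m))
            stop("sd_shift needs the selected model for OAR '", oar, "'")
          m@residual_sd
        }
      out[[oar]] <- dmeans[[oar]] - spec$k_sd * s
    } else {  # ci_bound: re-predict from the bound coefficients
      m <- models[[oar]]
      if (is.null(m))
        stop("ci_bound needs the selected model for OAR '", oar, "'")
      if (is.null(features))
        stop("ci_bound adjustment requires the patient's features")
      side <- if (modality == "IMPT") "lower" else "upper"
      cf <- m@coef_ci95[, side]
      fe <- features[features$oar == oar &
                       features$margin_mm == m@margin_mm, , drop = FALSE]
      if (nrow(fe) != 1L)
        stop("features must contain exactly one row for OAR '", oar,
             "' at margin ", m@margin_mm, " mm")
      out[[oar]] <- cf[["intercept"]] +
        cf[["coef_in70"]] * fe$pct_in70 +
        cf[["coef_in54_out70"]] * fe$pct_in54_out70
    }
  }
  pmin(pmax(out, 0), 70)
}
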