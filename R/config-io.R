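#' Write and read mean-dose models as JSON
#'
#' The model store is a JSON array with one object per model carrying
#' `oar`, `modality`, `margin_mm`, `intercept`, `coef_in70`,
#' `coef_in54_out70`, `r_squared`, `residual_sd`, `coef_ci95`
#' (per-coefficient `[lower, upper]`) and `n_fit`, so fitted or
#' externally supplied coefficient sets are interchangeable
#' configuration.
#'
#' @param models named list of [DmeanModel-class]s (e.g. from
#'   [selectAllMargins()], or `grid@models` for a full grid).
#' @param path JSON file path.
#' @return `writeDmeanModels`: `path` invisibly; `readDmeanModels`: a
#'   named list of [DmeanModel-class]s keyed `oar|modality|margin`.
#' @export
writeDmeanModels <- function(models, path) {
  payload <- lapply(unname(models), function(m) {
    list(oar = m@oar, modality = m@modality, margin_mm = m@margin_mm,
         intercept = m@coefficients[["intercept"]],
         coef_in70 = m@coefficients[["coef_in70"]],
         coef_in54_out70 = m@coefficients[["coef_in54_out70"]],
         r_squared = m@r_squared, residual_sd = m@residual_sd,
         coef_ci95 = list(
           intercept = as.numeric(m@coef_ci95["intercept", ]),
           coef_in70 = as.numeric(m@coef_ci95["coef_in70", ]),
           coef_in54_out70 = as.numeric(m@coef_ci95["coef_in54_out70", ])),
         n_fit = m@n_fit)
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname writeDmeanModels
#' @export
readDmeanModels <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  models <- lapply(raw, function(x) {
    ci <- rbind(intercept = as.numeric(unlist(x$coef_ci95$intercept)),
                coef_in70 = as.numeric(unlist(x$coef_ci95$coef_in70)),
                coef_in54_out70 =
                  as.numeric(unlist(x$coef_ci95$coef_in54_out70)))
    colnames(ci) <- c("lower", "upper")
    new("DmeanModel", oar = x$oar, modality = x$modality,
        margin_mm = as.numeric(x$margin_mm),
        coefficients = c(intercept = as.numeric(x$intercept),
                         coef_in70 = as.numeric(x$coef_in70),
                         coef_in54_out70 = as.numeric(x$coef_in54_out70)),
        r_squared = as.numeric(x$r_squared),
        residual_sd = as.numeric(x$residual_sd),
        coef_ci95 = ci, n_fit = as.integer(x$n_fit))
  })
  names(models) <- vapply(models, function(m)
    .gridKey(m@oar, m@modality, m@margin_mm), "")
  models
}

# selected-model lists are keyed oar|modality for runPatient
.keyByOarModality <- function(models) {
  setNames(models,
           vapply(models, function(m) paste(m@oar, m@modality, sep = "|"),
                  ""))
}

#' Write and read NTCP model configuration (JSON or YAML)
#'
#' Each entry carries `endpoint`, `intercept`, `dose_betas` (OAR ->
#' per-Gy coefficient), `baseline_covariate` and `baseline_betas`
#' (level -> additive coefficient).
#'
#' @param models list of [NTCPModel-class]s.
#' @param path file path (`.json`, `.yaml`/`.yml`).
#' @return `writeNtcpModels`: `path` invisibly; `readNtcpModels`: a
#'   named list of [NTCPModel-class]s keyed by endpoint.
#' @export
writeNtcpModels <- function(models, path) {
  payload <- lapply(unname(models), function(m)
    list(endpoint = m@endpoint, intercept = m@intercept,
         dose_betas = as.list(m@dose_betas),
         baseline_covariate = m@baseline_covariate,
         baseline_betas = as.list(m@baseline_betas)))
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::write_yaml(payload, path)
  else
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  invisible(path)
}

#' @rdname writeNtcpModels
#' @export
readNtcpModels <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = FALSE)
  models <- lapply(raw, function(x)
    ntcpModel(x$endpoint, as.numeric(x$intercept),
              dose_betas = unlist(x$dose_betas),
              baseline_covariate = x$baseline_covariate,
              baseline_betas = unlist(x$baseline_betas)))
  setNames(models, vapply(models, function(m) m@endpoint, ""))
}

#' Write and read threshold configuration (JSON or YAML)
#'
#' @param thresholds a [ThresholdConfig-class].
#' @param path file path (`.json`, `.yaml`/`.yml`).
#' @return `writeThresholds`: `path` invisibly; `readThresholds`: a
#'   [ThresholdConfig-class].
#' @export
writeThresholds <- function(thresholds, path) {
  stopifnot(is(thresholds, "ThresholdConfig"))
  payload <- list(single_g2 = thresholds@single_g2,
                  single_g3 = thresholds@single_g3,
                  sum_g2 = thresholds@sum_g2, min_g2 = thresholds@min_g2,
                  sum_g3 = thresholds@sum_g3, min_g3 = thresholds@min_g3)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::write_yaml(payload, path)
  else
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  invisible(path)
}

#' @rdname writeThresholds
#' @export
readThresholds <- function(path) {
  x <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
  thresholdConfig(single_g2 = x$single_g2, single_g3 = x$single_g3,
                  sum_g2 = x$sum_g2, min_g2 = x$min_g2,
                  sum_g3 = x$sum_g3, min_g3 = x$min_g3)
}

# all floating point CSV output at 6 significant digits so repeated
# runs produce byte-identical artifacts
.writeCsv6 <- function(df, path) {
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(x) signif(x, 6))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
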