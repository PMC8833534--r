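#' Fit a linear mean-dose model for one OAR, modality and margin
#'
#' Ordinary least squares of the actual mean dose on the two overlap
#' percentages computed at a fixed target expansion margin.  The
#' goodness of fit is the in-sample `R^2 = 1 - SS_res / SS_tot`; the
#' residual standard deviation uses the `n - 3` denominator (three
#' estimated coefficients); coefficient confidence intervals are the
#' standard t-based 95% OLS intervals.
#'
#' @param pct_in70,pct_in54_out70 numeric vectors of per-patient
#'   overlap percentages.
#' @param dmean numeric vector of per-patient actual mean doses (Gy).
#' @param oar,modality,margin_mm identifiers stored in the model.
#' @return A [DmeanModel-class].
#' @export
#' @examples
#' x1 <- runif(20, 0, 80); x2 <- runif(20, 0, 20)
#' y <- 5 + 0.6 * x1 + 0.2 * x2
#' fitDmeanModel(x1, x2, y, "parotid_left", "VMAT", 7)
fitDmeanModel <- function(pct_in70, pct_in54_out70, dmean,
                          oar = "unknown", modality = "VMAT",
                          margin_mm = 0) {
  ok <- complete.cases(pct_in70, pct_in54_out70, dmean) &
    is.finite(pct_in70) & is.finite(pct_in54_out70) & is.finite(dmean)
  x1 <- pct_in70[ok]; x2 <- pct_in54_out70[ok]; y <- dmean[ok]
  n <- length(y)
  if (n < 4)
    stop("fit for ", oar, "/", modality, " @ ", margin_mm,
         " mm needs at least 4 complete patients (got ", n, ")")
  if (sd(y) == 0)
    stop("degenerate fit for ", oar, "/", modality, " @ ", margin_mm,
         " mm: response has zero variance, R^2 undefined")
  fit <- lm(y ~ x1 + x2)
  cf <- coef(fit)
  if (anyNA(cf) || fit$rank < 3)
    stop("singular fit for ", oar, "/", modality, " @ ", margin_mm,
         " mm: predictors are collinear")
  sm <- summary(fit)
  ci <- confint(fit, level = 0.95)
  dimnames(ci) <- list(c("intercept", "coef_in70", "coef_in54_out70"),
                       c("lower", "upper"))
  new("DmeanModel", oar = oar, modality = modality,
      margin_mm = as.numeric(margin_mm),
      coefficients = c(intercept = unname(cf[1]),
                       coef_in70 = unname(cf[2]),
                       coef_in54_out70 = unname(cf[3])),
      r_squared = sm$r.squared, residual_sd = sm$sigma,
      coef_ci95 = ci, n_fit = as.integer(n))
}

.gridKey <- function(oar, modality, margin_mm)
  paste(oar, modality, format(margin_mm), sep = "|")

#' Fit the full OAR x margin x modality model grid
#'
#' Fits one [fitDmeanModel()] per combination of OAR, expansion margin
#' and modality: the full product `|oars| * |margins| * |modalities|`
#' of candidate models.  A cell whose fit fails (collinearity, too few
#' patients) is recorded in the grid's `failures` table instead of
#' aborting the rest of the grid.
#'
#' @param features data.frame of per-patient overlap features with
#'   columns `patient_id`, `oar`, `margin_mm`, `pct_in70`,
#'   `pct_in54_out70` (as written by [extractFeatures()] /
#'   [generateCohort()]).
#' @param dmeans data.frame of actual doses with columns `patient_id`,
#'   `oar`, `modality`, `dmean`.
#' @param margins,oars,modalities the grid axes; defaults are taken
#'   from the data.
#' @return A [DmeanModelGrid-class].
#' @export
fitMarginGrid <- function(features, dmeans,
                          margins = sort(unique(features$margin_mm)),
                          oars = intersect(canonicalOars(),
                                           unique(features$oar)),
                          modalities = .modalities()) {
  need_f <- c("patient_id", "oar", "margin_mm", "pct_in70",
              "pct_in54_out70")
  if (length(miss <- setdiff(need_f, names(features))))
    stop("features is missing column(s): ", paste(miss, collapse = ", "))
  need_d <- c("patient_id", "oar", "modality", "dmean")
  if (length(miss <- setdiff(need_d, names(dmeans))))
    stop("dmeans is missing column(s): ", paste(miss, collapse = ", "))

  models <- list()
  fails <- list()
  for (oar in oars) for (mod in modalities) {
    dm <- dmeans[dmeans$oar == oar & dmeans$modality == mod, ]
    for (mar in margins) {
      fe <- features[features$oar == oar & features$margin_mm == mar, ]
      idx <- match(fe$patient_id, dm$patient_id)
      y <- dm$dmean[idx]
      key <- .gridKey(oar, mod, mar)
      res <- tryCatch(
        fitDmeanModel(fe$pct_in70, fe$pct_in54_out70, y,
                      oar = oar, modality = mod, margin_mm = mar),
        error = function(e) e)
      if (inherits(res, "error")) {
        fails[[key]] <- data.frame(oar = oar, modality = mod,
                                   margin_mm = mar,
                                   message = conditionMessage(res),
                                   stringsAsFactors = FALSE)
      } else {
        models[[key]] <- res
      }
    }
  }
  failures <- if (length(fails)) do.call(rbind, c(fails, list(make.row.names = FALSE)))
    else data.frame(oar = character(), modality = character(),
                    margin_mm = numeric(), message = character(),
                    stringsAsFactors = FALSE)
  new("DmeanModelGrid", models = models, failures = failures,
      oars = oars, margins = as.numeric(margins),
      modalities = modalities)
}

#' Tabulate a fitted model grid
#'
#' @param grid a [DmeanModelGrid-class].
#' @return data.frame with one row per fitted cell: identifiers,
#'   coefficients, `r_squared`, `residual_sd`, `n_fit`.
#' @export
modelTable <- function(grid) {
  stopifnot(is(grid, "DmeanModelGrid"))
  if (!length(grid@models))
    return(data.frame(oar = character(), modality = character(),
                      margin_mm = numeric(), intercept = numeric(),
                      coef_in70 = numeric(), coef_in54_out70 = numeric(),
                      r_squared = numeric(), residual_sd = numeric(),
                      n_fit = integer(), stringsAsFactors = FALSE))
  do.call(rbind, lapply(unname(grid@models), function(m) {
    data.frame(oar = m@oar, modality = m@modality,
               margin_mm = m@margin_mm,
               intercept = m@coefficients[["intercept"]],
               coef_in70 = m@coefficients[["coef_in70"]],
               coef_in54_out70 = m@coefficients[["coef_in54_out70"]],
               r_squared = m@r_squared, residual_sd = m@residual_sd,
               n_fit = m@n_fit, stringsAsFactors = FALSE)
  }))
}

#' R-squared heatmap table of a model grid
#'
#' Wide table of in-sample R-squared values (rows OAR x modality,
#' one column per margin) for eyeballing which margin predicts each
#' OAR's dose best.
#'
#' @param grid a [DmeanModelGrid-class].
#' @return data.frame with columns `oar`, `modality`, then one
#'   `margin_<mm>` column per margin.
#' @export
r2Table <- function(grid) {
  tab <- modelTable(grid)
  out <- expand.grid(oar = grid@oars, modality = grid@modalities,
                     stringsAsFactors = FALSE)
  for (m in grid@margins) {
    col <- paste0("margin_", format(m))
    idx <- match(paste(out$oar, out$modality),
                 paste(tab$oar[tab$margin_mm == m],
                       tab$modality[tab$margin_mm == m]))
    out[[col]] <- tab$r_squared[tab$margin_mm == m][idx]
  }
  out
}

#' Select the best expansion margin for one OAR and modality
#'
#' Picks, among the fitted cells of one OAR/modality row of the grid,
#' the model with the highest in-sample R-squared; ties are broken in
#' favor of the smallest margin.
#'
#' @param grid a [DmeanModelGrid-class].
#' @param oar,modality the row to select from.
#' @return The winning [DmeanModel-class].
#' @export
selectMargin <- function(grid, oar, modality) {
  stopifnot(is(grid, "DmeanModelGrid"))
  keys <- vapply(grid@margins, function(m) .gridKey(oar, modality, m), "")
  cand <- grid@models[intersect(keys, names(grid@models))]
  if (!length(cand))
    stop("no successfully fitted model for ", oar, "/", modality)
  r2 <- vapply(cand, function(m) m@r_squared, numeric(1))
  mar <- vapply(cand, function(m) m@margin_mm, numeric(1))
  ord <- order(-r2, mar)
  cand[[ord[1]]]
}

#' Select best-margin models for every OAR and modality
#'
#' @param grid a [DmeanModelGrid-class].
#' @return Named list of [DmeanModel-class] keyed `oar|modality`; rows
#'   where every cell failed are omitted with a warning.
#' @export
selectAllMargins <- function(grid) {
  out <- list()
  for (oar in grid@oars) for (mod in grid@modalities) {
    m <- tryCatch(selectMargin(grid, oar, mod), error = function(e) e)
    if (inherits(m, "error"))
      warning(conditionMessage(m))
    else
      out[[paste(oar, mod, sep = "|")]] <- m
  }
  out
}

#' Predict a mean dose from overlap features
#'
#' Linear prediction from a fitted [DmeanModel-class], clamped to the
#' physically meaningful range 0-70 Gy (the prescription maximum).
#' `NA` features (absent OAR) propagate to an `NA` prediction.
#'
#' @param model a [DmeanModel-class].
#' @param pct_in70,pct_in54_out70 overlap percentages in `[0, 100]`
#'   (vectorized).
#' @return Predicted mean dose(s) in Gy.
#' @export
predictDmean <- function(model, pct_in70, pct_in54_out70) {
  stopifnot(is(model, "DmeanModel"))
  bad <- !is.na(pct_in70) & (pct_in70 < 0 | pct_in70 > 100)
  bad2 <- !is.na(pct_in54_out70) &
    (pct_in54_out70 < 0 | pct_in54_out70 > 100)
  if (any(bad) || any(bad2))
    stop("overlap percentages must lie in [0, 100]")
  cf <- model@coefficients
  pred <- cf[["intercept"]] + cf[["coef_in70"]] * pct_in70 +
    cf[["coef_in54_out70"]] * pct_in54_out70
  pmin(pmax(pred, 0), 70)
}
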