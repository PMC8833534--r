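#' VoxelGrid: a regular 3-D voxel lattice with physical spacing
#'
#' Describes the sampling grid that all structure masks of a patient
#' share: number of voxels per axis, physical spacing in mm, and the
#' physical position (mm) of the center of voxel (1,1,1).
#'
#' @slot shape integer(3), voxels per axis (each >= 1).
#' @slot spacing numeric(3), mm per voxel along each axis (each > 0);
#'   anisotropic spacing (thicker CT slices) is supported.
#' @slot origin numeric(3), mm position of the first voxel center.
#' @export
setClass("VoxelGrid",
  slots = c(shape = "integer", spacing = "numeric", origin = "numeric"))

setValidity("VoxelGrid", function(object) {
  msg <- character()
  if (length(object@shape) != 3L || any(is.na(object@shape)) ||
      any(object@shape < 1L))
    msg <- c(msg, "shape must be three integers >= 1")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    msg <- c(msg, "spacing must be three positive reals (mm)")
  if (length(object@origin) != 3L || any(!is.finite(object@origin)))
    msg <- c(msg, "origin must be three finite reals (mm)")
  if (length(msg)) msg else TRUE
})

#' Construct a VoxelGrid
#'
#' @param shape integer(3): voxels along each axis.
#' @param spacing numeric(3): voxel spacing in mm (default 1 mm
#'   isotropic).
#' @param origin numeric(3): physical position (mm) of the first voxel
#'   center (default the physical origin).
#' @return A [VoxelGrid-class] object.
#' @export
#' @examples
#' voxelGrid(c(64, 64, 40), spacing = c(1, 1, 2))
voxelGrid <- function(shape, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  new("VoxelGrid", shape = as.integer(shape),
      spacing = as.numeric(spacing), origin = as.numeric(origin))
}

#' @describeIn voxelGrid grid dimensions (voxels per axis).
#' @param x a `VoxelGrid`.
#' @export
gridShape <- function(x) x@shape

#' @describeIn voxelGrid voxel spacing in mm.
#' @export
gridSpacing <- function(x) x@spacing

#' @describeIn voxelGrid physical position (mm) of the first voxel
#'   center.
#' @export
gridOrigin <- function(x) x@origin

setMethod("show", "VoxelGrid", function(object) {
  cat(sprintf("VoxelGrid %s voxels, spacing %s mm, origin %s mm\n",
              paste(object@shape, collapse = "x"),
              paste(format(object@spacing), collapse = "x"),
              paste(format(object@origin), collapse = ", ")))
})

#' StructureSet: named binary masks on a shared voxel grid
#'
#' Holds one patient's delineations: the two planning target volumes
#' (`PTV_7000`, `PTV_5425`) and any subset of the eight canonical
#' organs at risk, each as a 3-D logical array on the same
#' [VoxelGrid-class].  `PTV_5425` is stored as its union with
#' `PTV_7000` so that "inside PTV_5425 but outside PTV_7000" is well
#' defined even when the input masks are exclusive rings.  An OAR that
#' is anatomically absent (e.g. a resected gland) is carried as an
#' explicit entry of `absent`, never as a silently empty mask.
#'
#' @slot grid the shared [VoxelGrid-class].
#' @slot masks named list of 3-D logical arrays matching the grid
#'   shape.
#' @slot absent character vector of canonical OAR names flagged as
#'   anatomically absent.
#' @export
setClass("StructureSet",
  slots = c(grid = "VoxelGrid", masks = "list", absent = "character"))

setValidity("StructureSet", function(object) {
  msg <- character()
  nms <- names(object@masks)
  if (is.null(nms) || any(nms == "") || anyDuplicated(nms))
    return("masks must be a uniquely named list")
  allowed <- c(targetNames(), canonicalOars())
  if (length(bad <- setdiff(nms, allowed)))
    msg <- c(msg, paste0("unknown structure name(s): ",
                         paste(bad, collapse = ", ")))
  if (length(miss <- setdiff(targetNames(), nms)))
    msg <- c(msg, paste0("missing required target(s): ",
                         paste(miss, collapse = ", ")))
  shp <- object@grid@shape
  for (nm in nms) {
    m <- object@masks[[nm]]
    if (!is.logical(m) || !identical(dim(m), as.integer(shp))) {
      msg <- c(msg, paste0("mask '", nm,
                           "' is not a logical array of the grid shape"))
      next
    }
    if (nm %in% canonicalOars() && !any(m))
      msg <- c(msg, paste0("OAR mask '", nm,
                           "' is empty; flag it absent instead"))
  }
  if (length(bad <- setdiff(object@absent, canonicalOars())))
    msg <- c(msg, paste0("absent flag for non-canonical name(s): ",
                         paste(bad, collapse = ", ")))
  if (length(both <- intersect(object@absent, nms)))
    msg <- c(msg, paste0("structure(s) both present and flagged absent: ",
                         paste(both, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Construct a StructureSet
#'
#' @param grid a [VoxelGrid-class].
#' @param masks named list of 3-D logical arrays (must include
#'   `PTV_7000` and `PTV_5425`; OAR names from [canonicalOars()]).
#' @param absent character vector of OAR names that are anatomically
#'   absent for this patient.
#' @return A [StructureSet-class]; `PTV_5425` is replaced by its union
#'   with `PTV_7000`.
#' @export
#' @examples
#' g <- voxelGrid(c(8, 8, 8), spacing = c(2, 2, 2))
#' ptv <- array(FALSE, c(8, 8, 8)); ptv[4:5, 4:5, 4:5] <- TRUE
#' oar <- array(FALSE, c(8, 8, 8)); oar[1:2, 1:2, 1:2] <- TRUE
#' ss <- structureSet(g, list(PTV_7000 = ptv, PTV_5425 = ptv,
#'                            parotid_left = oar))
#' structureNames(ss)
structureSet <- function(grid, masks, absent = character()) {
  masks <- lapply(masks, function(m) {
    storage.mode(m) <- "logical"
    m
  })
  if (!is.null(masks$PTV_5425) && !is.null(masks$PTV_7000))
    masks$PTV_5425 <- masks$PTV_5425 | masks$PTV_7000
  new("StructureSet", grid = grid, masks = masks,
      absent = as.character(absent))
}

#' @describeIn structureSet names of the structures present.
#' @param x a `StructureSet`.
#' @export
structureNames <- function(x) names(x@masks)

#' @describeIn structureSet the shared voxel grid.
#' @export
structureGrid <- function(x) x@grid

#' @describeIn structureSet OAR names flagged anatomically absent.
#' @export
absentOars <- function(x) x@absent

#' @describeIn structureSet extract one mask by name.
#' @param name structure name.
#' @export
getMask <- function(x, name) {
  if (!name %in% names(x@masks))
    stop("no structure named '", name, "' in this StructureSet")
  x@masks[[name]]
}

setMethod("show", "StructureSet", function(object) {
  cat("StructureSet on ")
  show(object@grid)
  vox <- vapply(object@masks, sum, numeric(1))
  cat(sprintf("  %d structures: %s\n", length(vox),
              paste(sprintf("%s (%d vox)", names(vox), vox),
                    collapse = ", ")))
  if (length(object@absent))
    cat("  absent OARs:", paste(object@absent, collapse = ", "), "\n")
})

#' DmeanModel: a per-OAR, per-modality linear mean-dose model
#'
#' An ordinary-least-squares model predicting the mean dose (Gy) of one
#' OAR under one modality from the two overlap percentages at a fixed
#' target expansion margin:
#' `Dmean = intercept + coef_in70 * pct_in70 + coef_in54_out70 *
#' pct_in54_out70`.
#'
#' @slot oar OAR name.
#' @slot modality `"VMAT"` or `"IMPT"`.
#' @slot margin_mm expansion margin (mm) at which the predictors were
#'   computed.
#' @slot coefficients named numeric: `intercept` (Gy), `coef_in70` and
#'   `coef_in54_out70` (Gy per percentage point).
#' @slot r_squared in-sample coefficient of determination.
#' @slot residual_sd residual standard deviation, Gy (denominator
#'   `n - 3`).
#' @slot coef_ci95 3 x 2 matrix of t-based 95% confidence bounds for
#'   the coefficients (rows as in `coefficients`, columns
#'   `lower`/`upper`).
#' @slot n_fit number of patients used in the fit.
#' @export
setClass("DmeanModel",
  slots = c(oar = "character", modality = "character",
            margin_mm = "numeric", coefficients = "numeric",
            r_squared = "numeric", residual_sd = "numeric",
            coef_ci95 = "matrix", n_fit = "integer"))

setValidity("DmeanModel", function(object) {
  msg <- character()
  if (!identical(names(object@coefficients),
                 c("intercept", "coef_in70", "coef_in54_out70")))
    msg <- c(msg, "coefficients must be named intercept, coef_in70, coef_in54_out70")
  if (!object@modality %in% .modalities())
    msg <- c(msg, "modality must be VMAT or IMPT")
  if (!is.na(object@r_squared) &&
      (object@r_squared < 0 || object@r_squared > 1))
    msg <- c(msg, "r_squared must lie in [0, 1]")
  if (!is.na(object@residual_sd) && object@residual_sd < 0)
    msg <- c(msg, "residual_sd must be >= 0")
  ci <- object@coef_ci95
  if (!all(dim(ci) == c(3L, 2L))) {
    msg <- c(msg, "coef_ci95 must be a 3 x 2 matrix")
  } else if (!all(is.na(ci)) &&
             (any(ci[, 1] > object@coefficients + 1e-9) ||
              any(ci[, 2] < object@coefficients - 1e-9)))
    msg <- c(msg, "coefficient CIs must bracket the point estimates")
  if (length(msg)) msg else TRUE
})

setMethod("show", "DmeanModel", function(object) {
  cat(sprintf(
    "DmeanModel %s / %s @ %g mm: Dmean = %.3f + %.4f*in70 + %.4f*in54out70  (R2 = %.3f, sigma = %.2f Gy, n = %d)\n",
    object@oar, object@modality, object@margin_mm,
    object@coefficients[["intercept"]],
    object@coefficients[["coef_in70"]],
    object@coefficients[["coef_in54_out70"]],
    object@r_squared, object@residual_sd, object@n_fit))
})

#' DmeanModelGrid: the full OAR x margin x modality model grid
#'
#' Container for the grid of candidate mean-dose models (one per OAR,
#' expansion margin and modality).  Cells whose fit failed are
#' recorded in `failures` rather than aborting the grid.
#'
#' @slot models named list of [DmeanModel-class] objects, keyed
#'   `oar|modality|margin`.
#' @slot failures data.frame with columns `oar`, `modality`,
#'   `margin_mm`, `message` for cells that could not be fitted.
#' @slot oars,margins,modalities the grid axes.
#' @export
setClass("DmeanModelGrid",
  slots = c(models = "list", failures = "data.frame",
            oars = "character", margins = "numeric",
            modalities = "character"))

setMethod("show", "DmeanModelGrid", function(object) {
  cat(sprintf(
    "DmeanModelGrid: %d OARs x %d margins x %d modalities = %d cells (%d fitted, %d failed)\n",
    length(object@oars), length(object@margins),
    length(object@modalities),
    length(object@oars) * length(object@margins) * length(object@modalities),
    length(object@models), nrow(object@failures)))
})

#' NTCPModel: a logistic toxicity model over OAR mean doses
#'
#' One endpoint of the selection protocol, modelled as
#' `NTCP = plogis(intercept + sum(dose_betas * Dmean) + baseline
#' term)`, where the baseline term is the coefficient of the patient's
#' level of one pre-treatment complaint covariate.
#'
#' @slot endpoint one of [ntcpEndpoints()].
#' @slot intercept logistic intercept.
#' @slot dose_betas named numeric, per-Gy coefficients keyed by OAR
#'   name (subset of [canonicalOars()]).
#' @slot baseline_covariate name of the baseline covariate the model
#'   uses (e.g. `"baseline_dysphagia"`).
#' @slot baseline_betas named numeric, additive coefficient per
#'   covariate level (the reference level carries 0).
#' @export
setClass("NTCPModel",
  slots = c(endpoint = "character", intercept = "numeric",
            dose_betas = "numeric", baseline_covariate = "character",
            baseline_betas = "numeric"))

setValidity("NTCPModel", function(object) {
  msg <- character()
  if (!object@endpoint %in% ntcpEndpoints())
    msg <- c(msg, paste0("endpoint must be one of: ",
                         paste(ntcpEndpoints(), collapse = ", ")))
  if (length(bad <- setdiff(names(object@dose_betas), canonicalOars())))
    msg <- c(msg, paste0("dose_betas for unknown OAR(s): ",
                         paste(bad, collapse = ", ")))
  if (is.null(names(object@baseline_betas)) &&
      length(object@baseline_betas))
    msg <- c(msg, "baseline_betas must be named by covariate level")
  if (length(msg)) msg else TRUE
})

#' Construct an NTCPModel
#'
#' @param endpoint one of [ntcpEndpoints()].
#' @param intercept logistic intercept.
#' @param dose_betas named numeric of per-Gy OAR coefficients.
#' @param baseline_covariate name of the baseline complaint covariate.
#' @param baseline_betas named numeric of per-level additive
#'   coefficients (include the reference level with 0).
#' @return An [NTCPModel-class].
#' @export
#' @examples
#' ntcpModel("xerostomia_g2", intercept = -2.4,
#'           dose_betas = c(parotid_left = 0.03, parotid_right = 0.03),
#'           baseline_covariate = "baseline_xerostomia",
#'           baseline_betas = c(none = 0, minor = 0.5))
ntcpModel <- function(endpoint, intercept, dose_betas,
                      baseline_covariate, baseline_betas) {
  new("NTCPModel", endpoint = endpoint,
      intercept = as.numeric(intercept),
      dose_betas = dose_betas,
      baseline_covariate = baseline_covariate,
      baseline_betas = baseline_betas)
}

setMethod("show", "NTCPModel", function(object) {
  cat(sprintf("NTCPModel %s: intercept %.3f; %d OAR dose terms; baseline '%s' (%s)\n",
              object@endpoint, object@intercept,
              length(object@dose_betas), object@baseline_covariate,
              paste(names(object@baseline_betas), collapse = "/")))
})

#' ThresholdConfig: the delta-NTCP qualification thresholds
#'
#' The four protocol criteria for proton-therapy qualification, all
#' compared inclusively (>=), in NTCP percentage points:
#' a single grade >=2 endpoint gain of at least `single_g2`; a single
#' grade >=3 gain of at least `single_g3`; a summed grade >=2 gain of
#' at least `sum_g2` where only endpoints individually at least
#' `min_g2` contribute; and the analogous grade >=3 sum criterion
#' (`sum_g3`, `min_g3`).
#'
#' @slot single_g2,single_g3,sum_g2,min_g2,sum_g3,min_g3 thresholds in
#'   percentage points.
#' @export
setClass("ThresholdConfig",
  slots = c(single_g2 = "numeric", single_g3 = "numeric",
            sum_g2 = "numeric", min_g2 = "numeric",
            sum_g3 = "numeric", min_g3 = "numeric"))

setValidity("ThresholdConfig", function(object) {
  vals <- c(object@single_g2, object@single_g3, object@sum_g2,
            object@min_g2, object@sum_g3, object@min_g3)
  msg <- character()
  if (any(!is.finite(vals)) || any(vals <= 0))
    msg <- c(msg, "all thresholds must be positive")
  if (object@min_g2 > object@sum_g2)
    msg <- c(msg, "min_g2 must not exceed sum_g2")
  if (object@min_g3 > object@sum_g3)
    msg <- c(msg, "min_g3 must not exceed sum_g3")
  if (length(msg)) msg else TRUE
})

#' Construct a ThresholdConfig
#'
#' Defaults are the national-protocol values: 10% for a single
#' grade >=2 endpoint, 5% for a single grade >=3 endpoint, 15% for the
#' grade >=2 sum (minimum 5% each) and 5% for the grade >=3 sum
#' (minimum 3.75% each).
#'
#' @param single_g2,single_g3,sum_g2,min_g2,sum_g3,min_g3 thresholds
#'   in NTCP percentage points.
#' @return A [ThresholdConfig-class].
#' @export
#' @examples
#' thresholdConfig()
thresholdConfig <- function(single_g2 = 10, single_g3 = 5,
                            sum_g2 = 15, min_g2 = 5,
                            sum_g3 = 5, min_g3 = 3.75) {
  new("ThresholdConfig", single_g2 = single_g2, single_g3 = single_g3,
      sum_g2 = sum_g2, min_g2 = min_g2, sum_g3 = sum_g3,
      min_g3 = min_g3)
}

setMethod("show", "ThresholdConfig", function(object) {
  cat(sprintf(
    "ThresholdConfig: single G2 >= %g%%, single G3 >= %g%%, sum G2 >= %g%% (each >= %g%%), sum G3 >= %g%% (each >= %g%%)\n",
    object@single_g2, object@single_g3, object@sum_g2, object@min_g2,
    object@sum_g3, object@min_g3))
})

#' DecisionResult: one patient's qualification decision
#'
#' The delta-NTCP profile (VMAT minus IMPT, percentage points), the
#' qualification flag, the criteria that fired, and an audit trail of
#' the intermediate quantities (features used, predicted doses, NTCP
#' profiles).
#'
#' @slot delta_ntcp named numeric over [ntcpEndpoints()], percentage
#'   points (negative values preserved).
#' @slot qualifies logical: `TRUE` iff at least one criterion fired.
#' @slot triggered_criteria subset of `c("single_g2", "single_g3",
#'   "sum_g2", "sum_g3")`.
#' @slot comparison_mode `"predicted"` (predicted VMAT vs predicted
#'   IMPT) or `"hybrid"` (actual VMAT vs predicted IMPT).
#' @slot audit list of intermediate values for auditing.
#' @export
setClass("DecisionResult",
  slots = c(delta_ntcp = "numeric", qualifies = "logical",
            triggered_criteria = "character",
            comparison_mode = "character", audit = "list"))

setValidity("DecisionResult", function(object) {
  msg <- character()
  if (!setequal(names(object@delta_ntcp), ntcpEndpoints()))
    msg <- c(msg, "delta_ntcp must cover exactly the four endpoints")
  if (object@qualifies != (length(object@triggered_criteria) > 0))
    msg <- c(msg, "qualifies must equal 'some criterion triggered'")
  if (length(bad <- setdiff(object@triggered_criteria,
                            c("single_g2", "single_g3", "sum_g2", "sum_g3"))))
    msg <- c(msg, paste0("unknown criterion: ", paste(bad, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

setMethod("show", "DecisionResult", function(object) {
  d <- object@delta_ntcp[ntcpEndpoints()]
  cat(sprintf("DecisionResult (%s): %s\n", object@comparison_mode,
              if (object@qualifies)
                paste0("QUALIFIES via ",
                       paste(object@triggered_criteria, collapse = ", "))
              else "does not qualify"))
  cat(sprintf("  dNTCP [pp]: %s\n",
              paste(sprintf("%s %.2f", names(d), d), collapse = ", ")))
})

#' @describeIn decide delta-NTCP profile (percentage points) of a
#'   result.
#' @param x a `DecisionResult`.
#' @export
deltaNtcp <- function(x) x@delta_ntcp

#' @describeIn decide qualification flag of a result.
#' @export
qualifies <- function(x) x@qualifies

#' @describeIn decide criteria that fired.
#' @export
triggeredCriteria <- function(x) x@triggered_criteria

#' @describeIn decide audit trail (intermediate doses and NTCP
#'   profiles) of a result.
#' @export
decisionAudit <- function(x) x@audit
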