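#' Expand a binary mask by a physical margin
#'
#' Isotropic 3-D expansion in physical space: the returned mask
#' contains exactly the voxels whose center lies within Euclidean
#' distance `margin_mm` of the center of some voxel of the input mask.
#' Anisotropic voxel spacing is honored per axis, so a 5 mm margin
#' spans fewer slices than in-plane pixels on a thick-slice CT.  The
#' distance field is computed with an exact separable squared Euclidean
#' distance transform.
#'
#' @param mask 3-D logical array matching `grid`.
#' @param grid the [VoxelGrid-class] carrying the physical spacing.
#' @param margin_mm expansion margin in mm, `>= 0`.  Margin 0 returns
#'   the input mask unchanged.
#' @return 3-D logical array of the same shape; always a superset of
#'   the input mask.
#' @export
#' @examples
#' g <- voxelGrid(c(9, 9, 9), spacing = c(2, 2, 2))
#' m <- array(FALSE, c(9, 9, 9)); m[5, 5, 5] <- TRUE
#' sum(expandMask(m, g, 5))   # 81 voxels within 5 mm
expandMask <- function(mask, grid, margin_mm) {
  stopifnot(is(grid, "VoxelGrid"))
  if (!is.array(mask) || length(dim(mask)) != 3L)
    stop("mask must be a 3-D array")
  if (!identical(dim(mask), grid@shape))
    stop("mask shape ", paste(dim(mask), collapse = "x"),
         " does not match grid shape ",
         paste(grid@shape, collapse = "x"))
  if (!is.numeric(margin_mm) || length(margin_mm) != 1L ||
      is.na(margin_mm) || margin_mm < 0)
    stop("margin_mm must be a single non-negative number")
  storage.mode(mask) <- "logical"
  if (margin_mm == 0 || !any(mask)) return(mask)
  d2 <- .cpp_squared_edt(as.vector(mask), grid@shape, grid@spacing)
  # tolerance keeps voxels at exactly the margin distance inside
  out <- array(d2 <= margin_mm^2 + 1e-7, dim = grid@shape)
  out
}

#' Overlap percentages of an OAR with the expanded targets
#'
#' Computes the two geometric predictors of the dose models: the
#' percentage of the OAR volume inside the (expanded) 70 Gy target,
#' and the percentage inside the (expanded) 54.25 Gy target but
#' outside the 70 Gy one.  Volumes are voxel counts (uniform voxel
#' volume), so the shared grid cancels out of the ratios.
#'
#' @param oar_mask 3-D logical array, non-empty.
#' @param ptv70_expanded,ptv54_expanded 3-D logical arrays of the same
#'   shape (already expanded by the margin of interest).
#' @return Named numeric: `pct_in70` and `pct_in54_out70`, each in
#'   `[0, 100]` with `pct_in70 + pct_in54_out70 <= 100`.
#' @export
overlapPercentages <- function(oar_mask, ptv70_expanded, ptv54_expanded) {
  dims <- dim(oar_mask)
  if (!identical(dims, dim(ptv70_expanded)) ||
      !identical(dims, dim(ptv54_expanded)))
    stop("all masks must share the same shape")
  n_oar <- sum(oar_mask)
  if (n_oar == 0)
    stop("empty OAR mask: overlap percentages are undefined")
  in70 <- sum(oar_mask & ptv70_expanded)
  in54_out70 <- sum(oar_mask & ptv54_expanded & !ptv70_expanded)
  c(pct_in70 = 100 * in70 / n_oar,
    pct_in54_out70 = 100 * in54_out70 / n_oar)
}

#' Extract overlap features over a margin grid
#'
#' For each requested margin, expands both targets by that margin and
#' computes [overlapPercentages()] for every canonical OAR of the
#' structure set.  OARs flagged anatomically absent produce rows with
#' `absent = TRUE` and `NA` percentages rather than being dropped.
#'
#' @param structures a [StructureSet-class] containing both targets
#'   and at least one OAR (present or flagged absent).
#' @param margins numeric vector of expansion margins in mm (default
#'   the penumbra-scale grid 0, 3, 5, 7, 10, 15).
#' @param patient_id optional identifier copied into every row.
#' @return data.frame with one row per OAR x margin, columns
#'   `patient_id` (if given), `oar`, `margin_mm`, `pct_in70`,
#'   `pct_in54_out70`, `absent`; ordered by canonical OAR order then
#'   ascending margin.
#' @export
extractFeatures <- function(structures, margins = c(0, 3, 5, 7, 10, 15),
                            patient_id = NULL) {
  stopifnot(is(structures, "StructureSet"))
  if (!length(margins) || any(!is.finite(margins)) || any(margins < 0))
    stop("margins must be a non-empty vector of non-negative numbers")
  nms <- structureNames(structures)
  if (length(miss <- setdiff(targetNames(), nms)))
    stop("structure set is missing target(s): ",
         paste(miss, collapse = ", "))
  oars_present <- intersect(canonicalOars(), nms)
  oars_all <- intersect(canonicalOars(),
                        c(nms, absentOars(structures)))
  if (!length(oars_all))
    stop("structure set contains no canonical OAR")
  grid <- structureGrid(structures)
  ptv70 <- getMask(structures, "PTV_7000")
  ptv54 <- getMask(structures, "PTV_5425")
  margins <- sort(unique(as.numeric(margins)))

  rows <- vector("list", length(margins))
  for (i in seq_along(margins)) {
    m <- margins[i]
    e70 <- expandMask(ptv70, grid, m)
    e54 <- expandMask(ptv54, grid, m)
    p70 <- p54 <- rep(NA_real_, length(oars_all))
    for (j in seq_along(oars_all)) {
      oar <- oars_all[j]
      if (oar %in% oars_present) {
        pct <- overlapPercentages(getMask(structures, oar), e70, e54)
        p70[j] <- pct[["pct_in70"]]
        p54[j] <- pct[["pct_in54_out70"]]
      }
    }
    rows[[i]] <- data.frame(
      oar = oars_all, margin_mm = m, pct_in70 = p70,
      pct_in54_out70 = p54,
      absent = !(oars_all %in% oars_present),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out <- out[order(match(out$oar, canonicalOars()), out$margin_mm), ,
             drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(patient_id))
    out <- cbind(patient_id = patient_id, out)
  out
}
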