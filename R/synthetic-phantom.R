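#' Ellipsoid specification
#'
#' @param center numeric(3), center in physical mm.
#' @param semiaxes numeric(3), semi-axis lengths in mm (> 0).
#' @return A list with class `ellipsoid`.
#' @export
ellipsoid <- function(center, semiaxes) {
  if (length(center) != 3L || any(!is.finite(center)))
    stop("center must be three finite numbers (mm)")
  if (length(semiaxes) != 3L || any(!is.finite(semiaxes)) ||
      any(semiaxes <= 0))
    stop("semiaxes must be three positive numbers (mm)")
  structure(list(center = as.numeric(center),
                 semiaxes = as.numeric(semiaxes)),
            class = "ellipsoid")
}

#' Phantom specification
#'
#' An analytic stand-in for a delineated simulation CT: axis-aligned
#' ellipsoids for the two nested targets and for each OAR, on a
#' [VoxelGrid-class].  Masks are rasterized by the
#' voxel-center-inside-ellipsoid rule, so phantom geometry is exactly
#' reproducible and analytic volumes are available as oracles.
#'
#' @param grid a [VoxelGrid-class].
#' @param ptv70,ptv54 [ellipsoid()]s for `PTV_7000` and `PTV_5425`
#'   (the 70 Gy ellipsoid must lie inside the 54.25 Gy one).
#' @param oars named list of [ellipsoid()]s; names from
#'   [canonicalOars()].
#' @return A list with class `phantomSpec`.
#' @export
phantomSpec <- function(grid, ptv70, ptv54, oars) {
  stopifnot(is(grid, "VoxelGrid"))
  structs <- c(list(PTV_7000 = ptv70, PTV_5425 = ptv54), oars)
  if (length(bad <- setdiff(names(oars), canonicalOars())))
    stop("unknown OAR name(s): ", paste(bad, collapse = ", "))
  lo <- grid@origin
  hi <- grid@origin + (grid@shape - 1L) * grid@spacing
  for (nm in names(structs)) {
    e <- structs[[nm]]
    if (!inherits(e, "ellipsoid"))
      stop("structure '", nm, "' must be an ellipsoid()")
    if (any(e$center - e$semiaxes < lo - grid@spacing / 2) ||
        any(e$center + e$semiaxes > hi + grid@spacing / 2))
      stop("structure '", nm, "' exceeds the grid extent")
  }
  structure(list(grid = grid, ptv70 = ptv70, ptv54 = ptv54,
                 oars = oars), class = "phantomSpec")
}

.rasterizeEllipsoid <- function(e, grid) {
  shp <- grid@shape
  ax <- lapply(1:3, function(k)
    grid@origin[k] + (seq_len(shp[k]) - 1) * grid@spacing[k])
  u1 <- (ax[[1]] - e$center[1]) / e$semiaxes[1]
  u2 <- (ax[[2]] - e$center[2]) / e$semiaxes[2]
  u3 <- (ax[[3]] - e$center[3]) / e$semiaxes[3]
  q <- outer(outer(u1^2, u2^2, `+`), u3^2, `+`)
  array(q <= 1, dim = shp)
}

#' Rasterize a phantom into a StructureSet
#'
#' Deterministic for a fixed spec: a voxel belongs to a structure iff
#' its center lies inside the structure's ellipsoid.
#'
#' @param spec a [phantomSpec()].
#' @return A [StructureSet-class].
#' @export
#' @examples
#' g <- voxelGrid(c(40, 40, 40), spacing = c(2, 2, 2))
#' ps <- phantomSpec(g,
#'   ptv70 = ellipsoid(c(40, 40, 40), c(18, 15, 15)),
#'   ptv54 = ellipsoid(c(40, 40, 40), c(28, 24, 24)),
#'   oars = list(parotid_left = ellipsoid(c(12, 40, 40), c(8, 8, 10))))
#' generatePhantom(ps)
generatePhantom <- function(spec) {
  if (!inherits(spec, "phantomSpec"))
    stop("spec must be created with phantomSpec()")
  masks <- list(PTV_7000 = .rasterizeEllipsoid(spec$ptv70, spec$grid),
                PTV_5425 = .rasterizeEllipsoid(spec$ptv54, spec$grid))
  if (any(masks$PTV_7000 & !masks$PTV_5425))
    stop("PTV_7000 ellipsoid is not contained in PTV_5425")
  for (nm in names(spec$oars)) {
    m <- .rasterizeEllipsoid(spec$oars[[nm]], spec$grid)
    if (!any(m))
      stop("OAR '", nm, "' rasterizes to an empty mask; ",
           "enlarge it or refine the grid")
    masks[[nm]] <- m
  }
  structureSet(spec$grid, masks)
}

#' A ready-made eight-OAR demonstration phantom
#'
#' A coarse head-and-neck-like arrangement: nested target ellipsoids
#' in the midline with the eight canonical OARs at heterogeneous
#' distances — constrictor muscles close to or inside the targets,
#' parotids lateral, submandibulars intermediate — so the overlap
#' features span a wide range across margins.
#'
#' @param spacing voxel spacing in mm (default 2 mm isotropic).
#' @return A [phantomSpec()].
#' @export
demoPhantomSpec <- function(spacing = c(2, 2, 2)) {
  extent <- c(120, 120, 120)
  grid <- voxelGrid(round(extent / spacing) + 1L, spacing = spacing)
  ctr <- extent / 2
  phantomSpec(grid,
    ptv70 = ellipsoid(ctr, c(20, 16, 22)),
    ptv54 = ellipsoid(ctr, c(32, 26, 32)),
    oars = list(
      oral_cavity        = ellipsoid(ctr + c(0, -24, 14), c(16, 12, 10)),
      parotid_left       = ellipsoid(ctr + c(-40, 4, 16), c(9, 9, 12)),
      parotid_right      = ellipsoid(ctr + c(40, 4, 16), c(9, 9, 12)),
      submandibular_left = ellipsoid(ctr + c(-22, -18, 0), c(7, 7, 8)),
      submandibular_right = ellipsoid(ctr + c(22, -18, 0), c(7, 7, 8)),
      pcm_superior       = ellipsoid(ctr + c(0, 10, 18), c(10, 5, 6)),
      pcm_medius         = ellipsoid(ctr + c(0, 12, 0), c(10, 5, 6)),
      pcm_inferior       = ellipsoid(ctr + c(0, 14, -20), c(10, 5, 8))))
}
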