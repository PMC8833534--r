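# Independent oracles and small fixture builders shared across tests.

# Brute-force mask expansion: all-pairs voxel-center Euclidean
# distances in physical mm (usable on small grids only).
bruteExpand <- function(mask, grid, margin_mm) {
  shp <- gridShape(grid); sp <- gridSpacing(grid)
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0) return(mask)
  all_idx <- as.matrix(expand.grid(seq_len(shp[1]), seq_len(shp[2]),
                                   seq_len(shp[3])))
  seed_mm <- sweep(idx, 2, sp, `*`)
  all_mm <- sweep(all_idx, 2, sp, `*`)
  d2min <- apply(all_mm, 1, function(p)
    min(colSums((t(seed_mm) - p)^2)))
  array(d2min <= margin_mm^2 + 1e-7, dim = shp)
}

# Straightforward re-statement of the four qualification criteria,
# written independently of decide()/decideBatch().
oracleDecide <- function(delta, thr = thresholdConfig()) {
  d2 <- c(delta[["dysphagia_g2"]], delta[["xerostomia_g2"]])
  d3 <- c(delta[["dysphagia_g3"]], delta[["xerostomia_g3"]])
  crit <- character()
  if (d2[1] >= thr@single_g2 || d2[2] >= thr@single_g2)
    crit <- c(crit, "single_g2")
  if (d3[1] >= thr@single_g3 || d3[2] >= thr@single_g3)
    crit <- c(crit, "single_g3")
  s2 <- 0
  for (v in d2) if (v >= thr@min_g2) s2 <- s2 + v
  if (s2 >= thr@sum_g2) crit <- c(crit, "sum_g2")
  s3 <- 0
  for (v in d3) if (v >= thr@min_g3) s3 <- s3 + v
  if (s3 >= thr@sum_g3) crit <- c(crit, "sum_g3")
  list(qualifies = length(crit) > 0, criteria = crit)
}

deltaVec <- function(dys_g2 = 0, xer_g2 = 0, dys_g3 = 0, xer_g3 = 0) {
  c(dysphagia_g2 = dys_g2, xerostomia_g2 = xer_g2,
    dysphagia_g3 = dys_g3, xerostomia_g3 = xer_g3)
}

# A hand-built DmeanModel with chosen coefficients (for prediction
# and selection tests that need no fitting).
fakeModel <- function(oar = "parotid_left", modality = "VMAT",
                      margin_mm = 7, coefs = c(5, 0.6, 0.2),
                      r_squared = 0.9, residual_sd = 1,
                      ci_halfwidth = c(1, 0.1, 0.1), n_fit = 50L) {
  cf <- c(intercept = coefs[1], coef_in70 = coefs[2],
          coef_in54_out70 = coefs[3])
  ci <- cbind(lower = cf - ci_halfwidth, upper = cf + ci_halfwidth)
  new("DmeanModel", oar = oar, modality = modality,
      margin_mm = margin_mm, coefficients = cf,
      r_squared = r_squared, residual_sd = residual_sd,
      coef_ci95 = ci, n_fit = n_fit)
}

# Tiny two-structure set: a central PTV cube and one configurable OAR.
tinyStructureSet <- function(shape = c(12, 12, 12),
                             spacing = c(2, 2, 2),
                             oar_name = "parotid_left",
                             oar_idx = 1:3) {
  g <- voxelGrid(shape, spacing = spacing)
  ptv70 <- array(FALSE, shape); ptv70[6:7, 6:7, 6:7] <- TRUE
  ptv54 <- array(FALSE, shape); ptv54[5:8, 5:8, 5:8] <- TRUE
  oar <- array(FALSE, shape); oar[oar_idx, oar_idx, oar_idx] <- TRUE
  masks <- list(PTV_7000 = ptv70, PTV_5425 = ptv54)
  masks[[oar_name]] <- oar
  structureSet(g, masks)
}

# Noiseless cohort spec variant (keeps everything else at defaults).
noiselessSpec <- function(n = 151, seed = 3) {
  sp <- cohortSpec(n_patients = n, seed = seed)
  sp$noise_sd$sd <- 0
  sp
}

trueCoefFor <- function(spec, oar, modality) {
  tc <- spec$true_coef[spec$true_coef$oar == oar &
                         spec$true_coef$modality == modality, ]
  c(tc$intercept, tc$coef_in70, tc$coef_in54_out70)
}

trueMarginFor <- function(spec, oar, modality) {
  spec$true_margin$margin_mm[spec$true_margin$oar == oar &
                               spec$true_margin$modality == modality]
}
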