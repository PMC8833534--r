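test_that("OLS fit recovers exact linear data and matches the normal equations", {
  # exact data -> exact coefficients, R^2 = 1
  set.seed(11)
  x1 <- runif(10, 0, 90); x2 <- runif(10, 0, 10)
  y <- 5 + 0.6 * x1 + 0.2 * x2
  m <- suppressWarnings(fitDmeanModel(x1, x2, y, "oral_cavity", "VMAT", 7))
  expect_equal(unname(m@coefficients), c(5, 0.6, 0.2), tolerance = 1e-10)
  expect_equal(m@r_squared, 1, tolerance = 1e-10)

  # random data -> closed-form normal-equations oracle
  x1 <- runif(50, 0, 100); x2 <- runif(50, 0, 40)
  y <- 10 + 0.4 * x1 + 0.1 * x2 + rnorm(50, 0, 2)
  m <- fitDmeanModel(x1, x2, y, "oral_cavity", "VMAT", 7)
  X <- cbind(1, x1, x2)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  expect_equal(unname(m@coefficients), as.numeric(beta),
               tolerance = 1e-8)
  res <- y - X %*% beta
  expect_equal(m@residual_sd, sqrt(sum(res^2) / (50 - 3)),
               tolerance = 1e-8)
  expect_equal(m@r_squared, 1 - sum(res^2) / sum((y - mean(y))^2),
               tolerance = 1e-8)
  # t-based 95% CIs from the OLS covariance
  s2 <- sum(res^2) / (50 - 3)
  se <- unname(sqrt(diag(s2 * solve(t(X) %*% X))))
  tq <- qt(0.975, 47)
  expect_equal(unname(m@coef_ci95[, "lower"]),
               as.numeric(beta) - tq * se, tolerance = 1e-8)
  expect_equal(unname(m@coef_ci95[, "upper"]),
               as.numeric(beta) + tq * se, tolerance = 1e-8)
})

test_that("degenerate fits are reported as errors, not numbers", {
  x1 <- runif(10, 0, 50); x2 <- runif(10, 0, 50)
  expect_error(fitDmeanModel(x1, x2, rep(30, 10), "oral_cavity",
                             "VMAT", 0),
               "zero variance")
  expect_error(fitDmeanModel(x1[1:3], x2[1:3], c(1, 2, 3),
                             "oral_cavity", "VMAT", 0),
               "at least 4")
  expect_error(fitDmeanModel(x1, 2 * x1, 1 + x1, "oral_cavity",
                             "VMAT", 0),
               "collinear")
})

test_that("margin-grid fitting covers the full product and isolates failures", {
  co <- generateCohort(cohortSpec(n_patients = 40, seed = 21))
  margins <- c(0, 3, 5, 7, 10, 15)
  grid <- fitMarginGrid(co$features, co$dmeans, margins = margins)
  expect_equal(length(grid@models) + nrow(grid@failures),
               8 * 6 * 2)
  expect_equal(nrow(grid@failures), 0)

  # single-cell grid equals a direct fit
  g1 <- fitMarginGrid(co$features, co$dmeans, margins = 7,
                      oars = "parotid_left", modalities = "VMAT")
  expect_equal(length(g1@models), 1)
  f <- co$features[co$features$oar == "parotid_left" &
                     co$features$margin_mm == 7, ]
  d <- co$dmeans[co$dmeans$oar == "parotid_left" &
                   co$dmeans$modality == "VMAT", ]
  direct <- fitDmeanModel(f$pct_in70, f$pct_in54_out70,
                          d$dmean[match(f$patient_id, d$patient_id)],
                          "parotid_left", "VMAT", 7)
  expect_equal(g1@models[[1]]@coefficients, direct@coefficients)

  # a poisoned cell (constant response) is recorded, not fatal
  dm_bad <- co$dmeans
  dm_bad$dmean[dm_bad$oar == "pcm_superior" &
                 dm_bad$modality == "IMPT"] <- 25
  grid_bad <- fitMarginGrid(co$features, dm_bad, margins = margins)
  expect_equal(nrow(grid_bad@failures), 6)   # all margins of that cell
  expect_true(all(grid_bad@failures$oar == "pcm_superior"))
  expect_equal(length(grid_bad@models), 8 * 6 * 2 - 6)
})

test_that("margin selection takes the highest R-squared, smallest margin on ties", {
  r2 <- c(`0` = 0.80, `3` = 0.85, `5` = 0.93, `7` = 0.91,
          `10` = 0.89, `15` = 0.84)
  models <- lapply(names(r2), function(m)
    fakeModel(margin_mm = as.numeric(m), r_squared = r2[[m]]))
  names(models) <- vapply(models, function(m)
    protonSelect:::.gridKey(m@oar, m@modality, m@margin_mm), "")
  grid <- new("DmeanModelGrid", models = models,
              failures = data.frame(), oars = "parotid_left",
              margins = as.numeric(names(r2)), modalities = "VMAT")
  expect_equal(selectMargin(grid, "parotid_left", "VMAT")@margin_mm, 5)

  # tie -> smallest margin
  models_tie <- models
  models_tie[["parotid_left|VMAT|7"]]@r_squared <- 0.93
  grid_tie <- new("DmeanModelGrid", models = models_tie,
                  failures = data.frame(), oars = "parotid_left",
                  margins = as.numeric(names(r2)), modalities = "VMAT")
  expect_equal(selectMargin(grid_tie, "parotid_left", "VMAT")@margin_mm, 5)

  expect_error(selectMargin(grid, "oral_cavity", "VMAT"),
               "no successfully fitted model")
})

test_that("low-noise generative truth puts the best R-squared at the true margin", {
  sp <- cohortSpec(n_patients = 151, seed = 31)
  sp$noise_sd$sd <- 0.1
  co <- generateCohort(sp)
  grid <- fitMarginGrid(co$features, co$dmeans)
  for (oar in c("parotid_left", "pcm_superior")) {
    for (modality in c("VMAT", "IMPT")) {
      sel <- selectMargin(grid, oar, modality)
      expect_equal(sel@margin_mm, trueMarginFor(sp, oar, modality),
                   label = paste(oar, modality))
      r2_all <- vapply(grid@models[grepl(paste0("^", oar, "\\|", modality),
                                         names(grid@models))],
                       function(m) m@r_squared, numeric(1))
      expect_true(all(sel@r_squared >= r2_all))
    }
  }
})

test_that("dose prediction is the clamped linear form", {
  m <- fakeModel(coefs = c(5, 0.6, 0.2))
  expect_equal(predictDmean(m, 0, 0), 5)       # intercept at origin
  expect_equal(predictDmean(m, 50, 25), 40)    # 5 + 30 + 5
  expect_equal(predictDmean(fakeModel(coefs = c(-2, 0, 0)), 0, 0), 0)
  expect_equal(predictDmean(fakeModel(coefs = c(60, 0.5, 0)), 100, 0), 70)
  expect_true(is.na(predictDmean(m, NA, NA)))  # absent OAR propagates
  expect_error(predictDmean(m, 120, 0), "\\[0, 100\\]")
})

test_that("post-hoc adjustments move predicted doses as specified", {
  models <- list(parotid_left = fakeModel(residual_sd = 3.1,
                                          modality = "IMPT"))
  dm <- c(parotid_left = 40)
  # rescale by 0.85 -> 34 Gy
  expect_equal(
    unname(applyAdjustment(dm, models,
                           adjustmentSpec("rescale", factor = 0.85),
                           "IMPT")),
    34)
  # subtract 1 SD of the residuals (3.1 Gy) -> 36.9 Gy
  expect_equal(
    unname(applyAdjustment(dm, models,
                           adjustmentSpec("sd_shift", k_sd = 1),
                           "IMPT")),
    36.9)
  # pooled-SD variant and identity factor
  expect_equal(
    unname(applyAdjustment(dm, models,
                           adjustmentSpec("sd_shift", k_sd = 1,
                                          pooled_sd = 2),
                           "IMPT")),
    38)
  expect_equal(
    unname(applyAdjustment(dm, models,
                           adjustmentSpec("rescale", factor = 1),
                           "IMPT")),
    40)
  # floor at 0 Gy
  expect_equal(
    unname(applyAdjustment(c(parotid_left = 2), models,
                           adjustmentSpec("sd_shift", k_sd = 1),
                           "IMPT")),
    0)
  # non-target OARs unchanged
  dm2 <- c(parotid_left = 40, oral_cavity = 30)
  adj <- applyAdjustment(dm2, models,
                         adjustmentSpec("rescale", factor = 0.85,
                                        target_oars = "parotid_left"),
                         "IMPT")
  expect_equal(unname(adj["oral_cavity"]), 30)
})

test_that("CI-bound adjustment lowers IMPT and raises VMAT predictions", {
  m_impt <- fakeModel(modality = "IMPT", coefs = c(5, 0.6, 0.2),
                      ci_halfwidth = c(1, 0.05, 0.05))
  m_vmat <- fakeModel(modality = "VMAT", coefs = c(5, 0.6, 0.2),
                      ci_halfwidth = c(1, 0.05, 0.05))
  fe <- data.frame(oar = "parotid_left", margin_mm = 7,
                   pct_in70 = 50, pct_in54_out70 = 25)
  base <- predictDmean(m_impt, 50, 25)
  lo <- applyAdjustment(c(parotid_left = base),
                        list(parotid_left = m_impt),
                        adjustmentSpec("ci_bound"), "IMPT",
                        features = fe)
  hi <- applyAdjustment(c(parotid_left = base),
                        list(parotid_left = m_vmat),
                        adjustmentSpec("ci_bound"), "VMAT",
                        features = fe)
  expect_lt(unname(lo), base)
  expect_gt(unname(hi), base)
  # lower bound of all three coefficients at once
  expect_equal(unname(lo), (5 - 1) + 0.55 * 50 + 0.15 * 25)
  expect_error(applyAdjustment(c(parotid_left = base),
                               list(parotid_left = m_impt),
                               adjustmentSpec("ci_bound"), "IMPT"),
               "features")
})

test_that("sensitivity adjustments never increase predicted IMPT doses", {
  co <- generateCohort(cohortSpec(n_patients = 30, seed = 77))
  grid <- fitMarginGrid(co$features, co$dmeans)
  sel <- selectAllMargins(grid)
  impt <- sel[grepl("IMPT", names(sel))]
  models <- setNames(impt, vapply(impt, function(m) m@oar, ""))
  pid <- "P001"
  fe <- co$features[co$features$patient_id == pid, ]
  dm <- vapply(names(models), function(oar) {
    m <- models[[oar]]
    f <- fe[fe$oar == oar & fe$margin_mm == m@margin_mm, ]
    predictDmean(m, f$pct_in70, f$pct_in54_out70)
  }, numeric(1))
  for (adj in list(adjustmentSpec("rescale", factor = 0.85),
                   adjustmentSpec("sd_shift", k_sd = 1),
                   adjustmentSpec("ci_bound"))) {
    out <- applyAdjustment(dm, models, adj, "IMPT", features = fe)
    expect_true(all(out <= dm + 1e-9), label = adj$method)
  }
})

test_that("invalid adjustment specifications are rejected", {
  expect_error(adjustmentSpec("rescale"), "factor")
  expect_error(adjustmentSpec("sd_shift"), "k_sd")
  expect_error(adjustmentSpec("rescale", factor = -1), "factor")
  expect_error(adjustmentSpec("rescale", factor = 1,
                              target_oars = "femur"), "unknown")
  expect_error(adjustmentSpec("shrink"), "arg")
})
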