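test_that("NTCP evaluation follows the logistic model", {
  m <- ntcpModel("xerostomia_g2", intercept = -2,
                 dose_betas = c(parotid_left = 0.05,
                                parotid_right = 0.05),
                 baseline_covariate = "baseline_xerostomia",
                 baseline_betas = c(none = 0, minor = 0.5))
  bl <- c(baseline_xerostomia = "none")
  # all terms cancel -> 0.5
  expect_equal(computeNtcp(m, c(parotid_left = 20, parotid_right = 20),
                           bl), 0.5)
  # intercept only -> 1 / (1 + e^2)
  expect_equal(computeNtcp(m, c(parotid_left = 0, parotid_right = 0),
                           bl),
               1 / (1 + exp(2)))
  # baseline level shifts the linear predictor
  expect_equal(computeNtcp(m, c(parotid_left = 0, parotid_right = 0),
                           c(baseline_xerostomia = "minor")),
               plogis(-1.5))
  # strictly increasing in a positive-beta dose
  doses <- seq(0, 70, by = 5)
  p <- vapply(doses, function(d)
    computeNtcp(m, c(parotid_left = d, parotid_right = 10), bl),
    numeric(1))
  expect_true(all(diff(p) > 0))
  expect_true(all(p > 0 & p < 1))

  expect_error(computeNtcp(m, c(parotid_left = 10, parotid_right = 10),
                           c(baseline_xerostomia = "terrible")),
               "unknown level")
  expect_error(computeNtcp(m, c(parotid_left = 10), bl),
               "no dose")
  expect_warning(
    p0 <- computeNtcp(m, c(parotid_left = 10), bl,
                      missing_oar = "zero"),
    "imputing 0 Gy")
  expect_equal(p0, plogis(-2 + 0.5))
})

test_that("delta profiles are signed percentage-point differences", {
  v <- c(dysphagia_g2 = 0.30, xerostomia_g2 = 0.20,
         dysphagia_g3 = 0.05, xerostomia_g3 = 0.06)
  i <- c(dysphagia_g2 = 0.18, xerostomia_g2 = 0.20,
         dysphagia_g3 = 0.02, xerostomia_g3 = 0.09)
  d <- deltaProfile(v, i)
  expect_equal(unname(d["dysphagia_g2"]), 12)
  expect_equal(unname(d["xerostomia_g2"]), 0)
  expect_equal(unname(d["xerostomia_g3"]), -3)   # proton worse, kept
  expect_equal(unname(deltaProfile(v, v)), rep(0, 4))
  expect_error(deltaProfile(v[-1], i), "four endpoints")
})

test_that("threshold rule reproduces the protocol criteria", {
  # single grade-2 endpoint at 12 pp
  r <- decide(deltaVec(dys_g2 = 12))
  expect_true(qualifies(r))
  expect_identical(triggeredCriteria(r), "single_g2")
  # nothing gained -> no qualification
  expect_false(qualifies(decide(deltaVec())))
  # summed grade-2: 8 + 7.5 = 15.5, each >= 5
  r <- decide(deltaVec(dys_g2 = 8, xer_g2 = 7.5))
  expect_true(qualifies(r))
  expect_identical(triggeredCriteria(r), "sum_g2")
  # summed grade-3: 4.0 + 3.8 = 7.8 >= 5, each >= 3.75
  r <- decide(deltaVec(dys_g3 = 4.0, xer_g3 = 3.8))
  expect_true(qualifies(r))
  expect_identical(triggeredCriteria(r), "sum_g3")
  # 9 + 4: 4 misses the per-endpoint minimum, 9 < 15 and < 10
  expect_false(qualifies(decide(deltaVec(dys_g2 = 9, xer_g2 = 4))))
  # inclusive boundaries
  expect_true(qualifies(decide(deltaVec(xer_g2 = 10))))
  expect_true(qualifies(decide(deltaVec(xer_g3 = 5))))
  expect_false(qualifies(decide(deltaVec(xer_g2 = 9.999))))
  # negative deltas cannot qualify
  expect_false(qualifies(decide(deltaVec(dys_g2 = -20, xer_g2 = -5))))
  expect_error(decide(c(dysphagia_g2 = 1)), "four endpoints")
})

test_that("decision rule matches an exhaustive brute-force evaluator", {
  thr <- thresholdConfig()
  vals <- seq(0, 25, by = 0.5)
  grid <- as.matrix(expand.grid(dysphagia_g2 = vals,
                                xerostomia_g2 = vals,
                                dysphagia_g3 = vals,
                                xerostomia_g3 = vals))
  got <- decideBatch(grid, thr)
  # independent vectorized restatement of the four criteria
  want <- (grid[, "dysphagia_g2"] >= 10) | (grid[, "xerostomia_g2"] >= 10) |
    (grid[, "dysphagia_g3"] >= 5) | (grid[, "xerostomia_g3"] >= 5) |
    (ifelse(grid[, "dysphagia_g2"] >= 5, grid[, "dysphagia_g2"], 0) +
       ifelse(grid[, "xerostomia_g2"] >= 5, grid[, "xerostomia_g2"], 0) >= 15) |
    (ifelse(grid[, "dysphagia_g3"] >= 3.75, grid[, "dysphagia_g3"], 0) +
       ifelse(grid[, "xerostomia_g3"] >= 3.75, grid[, "xerostomia_g3"], 0) >= 5)
  expect_identical(got, unname(want))

  # scalar path including the triggered-criteria sets, on a sample
  set.seed(13)
  idx <- sample(nrow(grid), 400)
  for (i in idx) {
    oracle <- oracleDecide(grid[i, ], thr)
    res <- decide(grid[i, ], thr)
    expect_identical(qualifies(res), oracle$qualifies)
    expect_setequal(triggeredCriteria(res), oracle$criteria)
  }
})

test_that("raising any single delta never revokes qualification", {
  set.seed(17)
  thr <- thresholdConfig()
  for (rep in 1:200) {
    delta <- deltaVec(runif(1, 0, 20), runif(1, 0, 20),
                      runif(1, 0, 8), runif(1, 0, 8))
    base <- qualifies(decide(delta, thr))
    for (e in ntcpEndpoints()) {
      up <- delta; up[e] <- up[e] + runif(1, 0, 10)
      expect_true(!base || qualifies(decide(up, thr)))
    }
  }
})

test_that("custom thresholds are honored and validated", {
  thr <- thresholdConfig(single_g2 = 5, single_g3 = 2.5,
                         sum_g2 = 7.5, min_g2 = 2.5,
                         sum_g3 = 2.5, min_g3 = 1.875)
  expect_true(qualifies(decide(deltaVec(xer_g2 = 5), thr)))
  expect_true(qualifies(decide(deltaVec(dys_g3 = 2.5), thr)))
  expect_error(thresholdConfig(min_g2 = 20), "min_g2")
  expect_error(thresholdConfig(single_g2 = -1), "positive")
})

test_that("the patient pipeline equals manual chaining of its parts", {
  sp <- cohortSpec(n_patients = 30, seed = 55)
  co <- generateCohort(sp)
  grid <- fitMarginGrid(co$features, co$dmeans)
  sel <- selectAllMargins(grid)
  ntcp <- sp$ntcp_models
  pid <- "P007"
  fe <- co$features[co$features$patient_id == pid, ]
  bl <- as.list(co$covariates[co$covariates$patient_id == pid, ])

  res <- runPatient(fe, sel, ntcp, bl, sp$thresholds)

  # manual chain: predict doses at each selected margin, NTCP, delta
  manual_dm <- function(modality) {
    mods <- sel[grepl(paste0("\\|", modality, "$"), names(sel))]
    vapply(mods, function(m) {
      f <- fe[fe$oar == m@oar & fe$margin_mm == m@margin_mm, ]
      predictDmean(m, f$pct_in70, f$pct_in54_out70)
    }, numeric(1)) |> setNames(vapply(mods, function(m) m@oar, ""))
  }
  nv <- ntcpProfile(ntcp, manual_dm("VMAT"), bl)
  ni <- ntcpProfile(ntcp, manual_dm("IMPT"), bl)
  manual <- decide(deltaProfile(nv, ni), sp$thresholds)
  expect_equal(deltaNtcp(res), deltaNtcp(manual))
  expect_identical(qualifies(res), qualifies(manual))
  expect_identical(triggeredCriteria(res), triggeredCriteria(manual))
  # audit trail carries the intermediates
  aud <- decisionAudit(res)
  expect_equal(aud$ntcp_vmat, nv)
  expect_equal(aud$impt_dmeans_used, manual_dm("IMPT"))
})

test_that("hybrid mode swaps only the VMAT dose source", {
  sp <- cohortSpec(n_patients = 20, seed = 56)
  co <- generateCohort(sp)
  grid <- fitMarginGrid(co$features, co$dmeans)
  sel <- selectAllMargins(grid)
  pid <- "P003"
  fe <- co$features[co$features$patient_id == pid, ]
  bl <- as.list(co$covariates[co$covariates$patient_id == pid, ])
  act <- co$dmeans[co$dmeans$patient_id == pid &
                     co$dmeans$modality == "VMAT", ]
  actual_vmat <- setNames(act$dmean, act$oar)

  pred <- runPatient(fe, sel, sp$ntcp_models, bl, sp$thresholds)
  hyb <- runPatient(fe, sel, sp$ntcp_models, bl, sp$thresholds,
                    mode = "hybrid", actual_vmat_dmeans = actual_vmat)
  expect_identical(hyb@comparison_mode, "hybrid")
  # IMPT side identical, VMAT side from the actual plan
  expect_equal(decisionAudit(hyb)$ntcp_impt,
               decisionAudit(pred)$ntcp_impt)
  expect_equal(decisionAudit(hyb)$vmat_dmeans_used,
               actual_vmat[names(decisionAudit(hyb)$vmat_dmeans_used)])
  expect_error(runPatient(fe, sel, sp$ntcp_models, bl, sp$thresholds,
                          mode = "hybrid"),
               "actual VMAT")
})

test_that("missing-organ policy is explicit in the pipeline", {
  sp <- cohortSpec(n_patients = 12, seed = 57)
  co <- generateCohort(sp)
  grid <- fitMarginGrid(co$features, co$dmeans)
  sel <- selectAllMargins(grid)
  pid <- "P002"
  fe <- co$features[co$features$patient_id == pid, ]
  fe$absent[fe$oar == "submandibular_left"] <- TRUE
  bl <- as.list(co$covariates[co$covariates$patient_id == pid, ])
  expect_error(runPatient(fe, sel, sp$ntcp_models, bl, sp$thresholds),
               "submandibular_left")
  warns <- capture_warnings(
    res <- runPatient(fe, sel, sp$ntcp_models, bl, sp$thresholds,
                      missing_oar = "zero"))
  expect_true(any(grepl("imputing 0 Gy", warns)))
  expect_s4_class(res, "DecisionResult")
  expect_true(all(deltaNtcp(res) > -100 & deltaNtcp(res) < 100))
})
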