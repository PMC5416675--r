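test_that("the generator is deterministic and respects value ranges", {
  cfg <- simConfig(nGenes = 300L, nProbes = 300L, seed = 11L)
  a <- simulateCohort(cfg)
  b <- simulateCohort(cfg)
  expect_identical(exprValues(a), exprValues(b))
  expect_identical(betaValues(a), betaValues(b))
  expect_identical(sampleSheet(a), sampleSheet(b))

  expect_true(all(exprValues(a) > 0))
  expect_true(all(betaValues(a) > 0 & betaValues(a) < 1))

  tr <- truthTable(a)
  expect_equal(sum(tr$class == "risk_expr"), 50L)
  expect_equal(sum(tr$class == "risk_meth"), 10L)
  expect_equal(sum(tr$class == "offspring_only"), 40L)
  expect_equal(sum(tr$class == "patient_only"), 10L)
  expect_equal(sum(tr$class == "coupled" & tr$layer == "expression"), 25L)
})

test_that("planted expression effects are recovered from the emitted matrix", {
  cfg <- simConfig(nGenes = 2000L, nRiskExpr = 50L, nOffspringOnly = 0L,
                   nPatientOnly = 0L, nCoupled = 0L, nRiskMeth = 0L,
                   exprEffect = 2.0, noiseSdExpr = 0.3, seed = 21L)
  cohort <- simulateCohort(cfg)
  logE <- log(exprValues(cohort))
  ss <- sampleSheet(cohort)
  planted <- truthTable(cohort)
  planted <- planted$feature_id[planted$class == "risk_expr"]
  diff <- rowMeans(logE[planted, ss$group == "control"]) -
    rowMeans(logE[planted, ss$group == "high_risk"])
  # planted shift is a 2.0 log-unit down-shift in the risk groups
  expect_lt(abs(mean(diff) - 2.0), 0.2)          # mean within 10% of planted
  expect_gt(mean(abs(diff - 2.0) < 0.6), 0.9)    # nearly all genes close
})

test_that("planted delta-beta effects hit the configured magnitude", {
  cfg <- simConfig(nGenes = 220L, nProbes = 200L, nRiskExpr = 0L,
                   nOffspringOnly = 0L, nPatientOnly = 0L, nCoupled = 0L,
                   nRiskMeth = 200L, deltaBetaEffect = 0.35, seed = 31L)
  cohort <- simulateCohort(cfg)
  beta <- betaValues(cohort)
  ss <- sampleSheet(cohort)
  tr <- truthTable(cohort)
  probes <- tr$feature_id[tr$class == "risk_meth"]
  db <- rowMeans(beta[probes, ss$group == "high_risk"]) -
    rowMeans(beta[probes, ss$group == "control"])
  expect_lt(abs(mean(db) - 0.35), 0.05)
  # the same shift is planted in the patient group
  dbP <- rowMeans(beta[probes, ss$group == "patient"]) -
    rowMeans(beta[probes, ss$group == "control"])
  expect_lt(abs(mean(dbP) - 0.35), 0.05)
})

test_that("an infeasible delta beta raises a configuration error", {
  cfg <- simConfig(nGenes = 50L, nProbes = 50L, nRiskMeth = 5L,
                   nRiskExpr = 0L, nOffspringOnly = 0L, nPatientOnly = 0L,
                   nCoupled = 0L, deltaBetaEffect = 0.9, seed = 1L)
  expect_error(simulateCohort(cfg), "infeasible delta beta")
})

test_that("coupled gene/probe pairs correlate strongly at default noise", {
  rs <- numeric(0)
  for (seed in 1:4) {
    cfg <- simConfig(nGenes = 120L, nProbes = 120L, nRiskExpr = 0L,
                     nOffspringOnly = 0L, nPatientOnly = 0L, nRiskMeth = 0L,
                     nCoupled = 25L, seed = seed)
    cohort <- simulateCohort(cfg)
    ann <- probeAnnotation(cohort)
    coupled <- ann[nzchar(ann$genes), ]
    r <- vapply(seq_len(nrow(coupled)), function(i) {
      pearsonCorr(log(exprValues(cohort)[coupled$genes[i], ]),
                  betaValues(cohort)[coupled$probe_id[i], ])$r
    }, numeric(1))
    rs <- c(rs, r)
  }
  expect_length(rs, 100L)
  expect_true(all(rs < 0))                 # repressive coupling direction
  expect_gte(mean(abs(rs) > 0.8), 0.9)
})

test_that("covariates follow the configured group structure", {
  cohort <- simulateCohort(simConfig(nGenes = 200L, nProbes = 150L, seed = 17L))
  ss <- sampleSheet(cohort)
  expect_gt(mean(ss$cohesion[ss$group == "control"]),
            mean(ss$cohesion[ss$group == "patient"]))
  expect_lt(mean(ss$conflict[ss$group == "control"]),
            mean(ss$conflict[ss$group == "patient"]))
})

test_that("truth tables round-trip and join cleanly with DE output", {
  cohort <- simulateCohort(simConfig(nGenes = 100L, nProbes = 80L, seed = 9L,
                                     nRiskExpr = 10L, nRiskMeth = 5L,
                                     nOffspringOnly = 5L, nPatientOnly = 5L,
                                     nCoupled = 5L))
  path <- withr::local_tempfile(fileext = ".tsv")
  tr <- truthTable(cohort)
  writeTruth(tr, path)
  expect_equal(readTruth(path), tr)

  de <- deTest(log(exprValues(cohort)), sampleSheet(cohort),
               "control", "high_risk")
  joined <- merge(de, tr[tr$layer == "expression", ],
                  by = "feature_id")
  expect_equal(nrow(joined), 100L)
  # planted shared effects carry far smaller p-values than nulls
  expect_lt(median(joined$p_value[joined$class == "risk_expr"]),
            median(joined$p_value[joined$class == "null"]))
})
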