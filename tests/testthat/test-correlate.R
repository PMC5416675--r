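test_that("Pearson correlation matches its closed form and cor.test", {
  expect_equal(pearsonCorr(c(1, 2, 3), 2 * c(1, 2, 3) + 1)$r, 1)
  expect_equal(pearsonCorr(c(1, 2, 4), -c(1, 2, 4))$r, -1)
  expect_equal(pearsonCorr(c(1, 2, 4), -c(1, 2, 4))$p_value, 0)

  out <- pearsonCorr(1:4, c(1, 3, 2, 4))
  expect_equal(out$r, 0.8, tolerance = 1e-12)
  expect_equal(out$p_value, 0.2, tolerance = 1e-12)

  set.seed(12)
  for (i in 1:20) {
    n <- sample(3:30, 1)
    x <- rnorm(n); y <- rnorm(n)
    ct <- suppressWarnings(cor.test(x, y))
    mine <- pearsonCorr(x, y)
    expect_equal(mine$r, unname(ct$estimate), tolerance = 1e-12)
    expect_equal(mine$p_value, ct$p.value, tolerance = 1e-12)
  }
})

test_that("Pearson r is symmetric and invariant under positive affine maps", {
  set.seed(5)
  x <- rnorm(15); y <- rnorm(15)
  expect_equal(pearsonCorr(x, y)$r, pearsonCorr(y, x)$r)
  expect_equal(pearsonCorr(3 * x + 7, y)$r, pearsonCorr(x, y)$r,
               tolerance = 1e-12)
  expect_equal(pearsonCorr(x, 0.1 * y - 2)$r, pearsonCorr(x, y)$r,
               tolerance = 1e-12)
  # degenerate inputs
  expect_true(is.na(pearsonCorr(rep(1, 5), rnorm(5))$r))
  expect_true(is.na(pearsonCorr(c(1, 2, NA), c(1, NA, 3))$r))  # n < 3
})

test_that("integration reproduces a brute-force double loop exactly", {
  cohort <- simulateCohort(simConfig(nGenes = 20L, nProbes = 20L,
                                     nRiskExpr = 0L, nOffspringOnly = 0L,
                                     nPatientOnly = 0L, nRiskMeth = 5L,
                                     nCoupled = 5L, seed = 4L))
  expr <- log(exprValues(cohort))
  beta <- betaValues(cohort)
  ann <- probeAnnotation(cohort)
  out <- integrateExpressionMethylation(expr, beta, ann)
  ref <- corrBruteForce(expr, beta, ann)
  merged <- merge(out$pairs, ref, by = c("gene", "probe_id"))
  expect_equal(nrow(merged), nrow(out$pairs))
  expect_equal(merged$r.x, merged$r.y, tolerance = 1e-12)
  expect_setequal(out$genesWithoutProbe,
                  setdiff(rownames(expr), ref$gene))

  # invariant to sample ordering
  perm <- sample(colnames(beta))
  out2 <- integrateExpressionMethylation(expr, beta[, perm], ann)
  expect_equal(out2$pairs$r, out$pairs$r, tolerance = 1e-12)
})

test_that("the |r| > 0.8 filter is strict at the boundary", {
  # r(1:4, c(1,3,2,4)) = 0.8 exactly; affine maps keep it exact
  expr <- smallMatrix("GENE1", sprintf("S%d", 1:4), 1:4)
  beta <- smallMatrix("cg1", sprintf("S%d", 1:4), 0.1 * c(1, 3, 2, 4))
  ann <- simpleAnnotation("cg1", "GENE1")
  out <- integrateExpressionMethylation(expr, beta, ann)
  expect_equal(out$pairs$r, 0.8, tolerance = 1e-12)
  expect_false(out$pairs$selected)

  beta2 <- smallMatrix("cg1", sprintf("S%d", 1:4), 0.1 * c(1, 2, 3.1, 4))
  out2 <- integrateExpressionMethylation(expr, beta2, ann)
  expect_gt(out2$pairs$r, 0.8)
  expect_true(out2$pairs$selected)
})

test_that("gene summaries keep the strongest pair per gene", {
  set.seed(6)
  expr <- smallMatrix("G1", sprintf("S%d", 1:6), rnorm(6))
  beta <- rbind(cgWeak = runif(6),
                cgStrong = plogis(scale(expr["G1", ])[, 1] * 2))
  colnames(beta) <- colnames(expr)
  ann <- simpleAnnotation(c("cgWeak", "cgStrong"), c("G1", "G1"))
  out <- integrateExpressionMethylation(expr, beta, ann)
  expect_equal(nrow(out$pairs), 2L)
  expect_equal(out$geneSummary$probe_id, "cgStrong")
})

test_that("gene-covariate correlations recover the planted sign structure", {
  hits <- 0L; total <- 0L
  for (seed in 1:10) {
    cohort <- simulateCohort(simConfig(nGenes = 60L, nProbes = 20L,
                                       nRiskExpr = 10L, nRiskMeth = 0L,
                                       nOffspringOnly = 0L, nPatientOnly = 0L,
                                       nCoupled = 0L, seed = seed))
    tr <- truthTable(cohort)
    planted <- tr$feature_id[tr$class == "risk_expr"]
    tab <- covariateCorrelation(log(exprValues(cohort)), sampleSheet(cohort),
                                genes = planted,
                                covariates = c("cohesion", "conflict"))
    # expression is reduced in the risk groups, where cohesion is low and
    # conflict high: r should be positive for cohesion, negative for conflict
    hits <- hits + sum(tab$r[tab$covariate == "cohesion"] > 0) +
      sum(tab$r[tab$covariate == "conflict"] < 0)
    total <- total + nrow(tab)
  }
  expect_gte(hits / total, 0.95)

  # a covariate equal to a gene's expression correlates perfectly
  cohort <- simulateCohort(simConfig(nGenes = 10L, nProbes = 5L,
                                     nRiskExpr = 0L, nRiskMeth = 0L,
                                     nOffspringOnly = 0L, nPatientOnly = 0L,
                                     nCoupled = 0L, seed = 3L))
  ss <- sampleSheet(cohort)
  expr <- log(exprValues(cohort))
  ss$mirror <- expr["G00001", ss$sample_id]
  tab <- covariateCorrelation(expr, ss, genes = "G00001",
                              covariates = "mirror")
  expect_equal(tab$r, 1)

  # constant covariates are skipped with a warning
  ss$flat <- 1
  expect_warning(
    covariateCorrelation(expr, ss, genes = "G00001", covariates = "flat"),
    "flat")
})
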