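test_that("concordant features are the sorted intersection", {
  expect_equal(concordantFeatures(c("B", "A"), c("C", "D")), character(0))
  expect_equal(concordantFeatures(c("B", "A", "C"), c("C", "A", "B")),
               c("A", "B", "C"))

  # published-scale list sizes: 128 and 56 sharing 33 planted ids
  shared <- sprintf("SHARED%02d", 1:33)
  listA <- c(shared, sprintf("A%03d", 1:95))    # 128
  listB <- c(shared, sprintf("B%03d", 1:23))    # 56
  expect_length(listA, 128L)
  expect_length(listB, 56L)
  expect_equal(concordantFeatures(listA, listB), sort(shared))
})

test_that("the risk set is the union of E and M evidence with source flags", {
  eGenes <- sprintf("EGENE%02d", 1:33)
  mGenes <- sprintf("MGENE%02d", 1:10)
  allGenes <- sprintf("G%03d", 1:200)
  degA <- fakeDE(allGenes, character(0))
  degA <- rbind(degA, fakeDE(eGenes, eGenes))
  degB <- rbind(fakeDE(allGenes, character(0)), fakeDE(eGenes, eGenes))
  probes <- sprintf("cg%03d", 1:18)
  ann <- simpleAnnotation(probes, rep(mGenes, length.out = 18))
  dmpA <- fakeDMP(sprintf("cg%03d", 1:60), probes)
  dmpB <- fakeDMP(sprintf("cg%03d", 1:60), probes)

  rs <- buildRiskGeneSet(degA, degB, dmpA, dmpB, ann)
  g <- riskGenes(rs)
  expect_equal(nrow(g), 43L)   # 33 E + 10 M, disjoint
  expect_equal(sum(g$source == "E"), 33L)
  expect_equal(sum(g$source == "M"), 10L)
  expect_true(all(nzchar(g$probes[g$source == "M"])))
  expect_true(all(g$probes[g$source == "E"] == ""))

  # swapping the contrast order leaves the membership unchanged
  rs2 <- buildRiskGeneSet(degB, degA, dmpB, dmpA, ann)
  expect_equal(riskGenes(rs2)$symbol, g$symbol)
})

test_that("a gene supported by both layers appears once, flagged E+M", {
  genes <- c("GLUL", "OTHER")
  deg <- fakeDE(genes, "GLUL")
  dmp <- fakeDMP(c("cg1", "cg2"), "cg1")
  ann <- simpleAnnotation(c("cg1", "cg2"), c("GLUL", ""))
  rs <- buildRiskGeneSet(deg, deg, dmp, dmp, ann)
  g <- riskGenes(rs)
  expect_equal(nrow(g), 1L)
  expect_equal(g$source, "E+M")
  expect_equal(g$probes, "cg1")

  empty <- buildRiskGeneSet(fakeDE(genes, character(0)),
                            fakeDE(genes, character(0)),
                            fakeDMP("cg1", character(0)),
                            fakeDMP("cg1", character(0)), ann)
  expect_equal(nrow(riskGenes(empty)), 0L)
})

test_that("direction-aware concordance drops discordant signs", {
  genes <- c("UP_BOTH", "FLIP")
  degA <- fakeDE(genes, genes, direction = 1)
  degB <- fakeDE(genes, genes, direction = c(1, -1))
  dmp <- fakeDMP("cg1", character(0))
  ann <- simpleAnnotation("cg1", "X")
  strict <- buildRiskGeneSet(degA, degB, dmp, dmp, ann)
  expect_equal(riskGenes(strict)$symbol, "UP_BOTH")
  loose <- buildRiskGeneSet(degA, degB, dmp, dmp, ann,
                            config = analysisConfig(requireSameDirection = FALSE))
  expect_setequal(riskGenes(loose)$symbol, genes)
})

test_that("concordant probes without annotation are reported, not counted", {
  deg <- fakeDE("G1", character(0))
  dmp <- fakeDMP(c("cg1", "cg2"), c("cg1", "cg2"))
  ann <- simpleAnnotation(c("cg1", "cg2"), c("", "NLK"))
  rs <- buildRiskGeneSet(deg, deg, dmp, dmp, ann)
  expect_equal(riskGenes(rs)$symbol, "NLK")
  expect_equal(unannotatedProbes(rs), "cg1")
})

test_that("the combined patient-vs-high-risk list deduplicates across layers", {
  degIds <- sprintf("DEG%02d", 1:12)
  otherGenes <- sprintf("MG%02d", 1:30)
  deg <- fakeDE(c(degIds, otherGenes), degIds)
  probes <- sprintf("cg%03d", 1:47)
  ann <- simpleAnnotation(probes, rep(otherGenes, length.out = 47))
  dmp <- fakeDMP(probes, probes)
  combined <- combinedContrastGenes(deg, dmp, ann)
  expect_length(combined, 42L)   # 12 expression + 30 methylation genes

  # a symbol hit on both layers counts once
  annOverlap <- simpleAnnotation(probes, rep(c(degIds, otherGenes)[1:42],
                                             length.out = 47))
  expect_length(combinedContrastGenes(deg, dmp, annOverlap), 42L)

  # no selected probes: the DEG list passes through
  dmpNone <- fakeDMP(probes, character(0))
  expect_equal(combinedContrastGenes(deg, dmpNone, ann), sort(degIds))
})

test_that("group-specific planted genes never enter the risk set", {
  cohort <- simulateCohort(simConfig(seed = 2L))
  res <- runRiskGeneAnalysis(cohort)
  tr <- truthTable(cohort)
  specific <- tr$feature_id[tr$class %in% c("offspring_only", "patient_only")]
  expect_length(intersect(specific, riskGenes(res$riskGeneSet)$symbol), 0L)
  # size bound: |risk set| <= |E| + |M| with equality iff disjoint
  g <- riskGenes(res$riskGeneSet)
  nE <- sum(g$source %in% c("E", "E+M"))
  nM <- sum(g$source %in% c("M", "E+M"))
  expect_lte(nrow(g), nE + nM)
  if (!any(g$source == "E+M")) expect_equal(nrow(g), nE + nM)
})
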