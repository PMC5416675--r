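#' Run the full risk-gene analysis on a cohort
#'
#' End-to-end convenience wrapper: quantile-normalises and log2-transforms
#' the expression layer, runs differential expression and differential
#' methylation for the three contrasts (control vs high-risk, control vs
#' patient, high-risk vs patient), builds the concordance risk-gene set and
#' the combined patient-vs-high-risk gene list, correlates expression with
#' methylation across all annotated pairs and (when covariates are present)
#' with the clinical covariates of the risk genes, and, when a gene-set
#' collection is supplied, tests the risk genes for pathway
#' over-representation.
#'
#' @param cohort An [OmicsCohort-class].
#' @param config An [AnalysisConfig-class].
#' @param collection Optional [GeneSetCollection-class] for enrichment.
#' @param universeSize Optional enrichment universe size (overrides the
#'   collection's).
#' @param normalize Quantile-normalise expression first (default `TRUE`).
#' @param logTransform Analyse expression on the log2 scale (default
#'   `TRUE`, the usual scale for array signal intensities).
#' @return List with elements `de` (per-contrast [deTest()] tables), `dm`
#'   (per-contrast [dmTest()] tables), `riskGeneSet`
#'   ([RiskGeneSet-class]), `combinedPatientVsHighRisk` (gene vector),
#'   `integration` ([integrateExpressionMethylation()] output),
#'   `covariateCorrelations` (or `NULL`), `enrichment` (or `NULL`) and
#'   `config`.
#' @export
#' @examples
#' cohort <- simulateCohort(simConfig(nGenes = 300, nProbes = 300, seed = 3))
#' res <- runRiskGeneAnalysis(cohort)
#' res$riskGeneSet
runRiskGeneAnalysis <- function(cohort, config = analysisConfig(),
                                collection = NULL, universeSize = NULL,
                                normalize = TRUE, logTransform = TRUE) {
  stopifnot(is(cohort, "OmicsCohort"))
  expr <- exprValues(cohort)
  if (normalize) expr <- quantileNormalize(expr)
  if (logTransform) expr <- log2(expr + 1)
  beta <- betaValues(cohort)
  samples <- sampleSheet(cohort)
  ann <- probeAnnotation(cohort)

  contrasts <- list(
    control_vs_high_risk = c("control", "high_risk"),
    control_vs_patient = c("control", "patient"),
    high_risk_vs_patient = c("high_risk", "patient"))
  de <- lapply(contrasts, function(ct)
    deTest(expr, samples, ct[1], ct[2], config = config))
  dm <- lapply(contrasts, function(ct)
    dmTest(beta, samples, ct[1], ct[2], annotation = ann, config = config))

  risk <- buildRiskGeneSet(de$control_vs_high_risk, de$control_vs_patient,
                           dm$control_vs_high_risk, dm$control_vs_patient,
                           ann, config = config)
  combined <- combinedContrastGenes(de$high_risk_vs_patient,
                                    dm$high_risk_vs_patient, ann)
  integration <- integrateExpressionMethylation(expr, beta, ann,
                                                config = config)

  covTab <- NULL
  covCols <- setdiff(colnames(samples), c("sample_id", "group"))
  riskSymbols <- riskGenes(risk)$symbol
  if (length(covCols) && length(riskSymbols))
    covTab <- covariateCorrelation(expr, samples, genes = riskSymbols)

  enr <- NULL
  if (!is.null(collection) && length(riskSymbols))
    enr <- enrichSets(riskSymbols, collection, universeSize = universeSize)

  list(de = de, dm = dm, riskGeneSet = risk,
       combinedPatientVsHighRisk = combined,
       integration = integration,
       covariateCorrelations = covTab,
       enrichment = enr,
       config = config)
}
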