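#' @import methods
NULL

#' Cohort group labels
#'
#' The three-group design anchoring every contrast: healthy controls,
#' unaffected high-risk individuals (e.g. offspring of an affected parent)
#' and patients.
#'
#' @return Character vector of the three recognised group labels, in the
#'   canonical order `control`, `high_risk`, `patient`.
#' @export
#' @examples
#' cohortGroups()
cohortGroups <- function() c("control", "high_risk", "patient")

#' Analysis thresholds for the risk-gene pipeline
#'
#' Bundles every selection threshold used by the differential expression,
#' differential methylation, concordance and correlation-integration stages.
#'
#' @slot deFdr Benjamini-Hochberg FDR level for differential expression
#'   (proportion; default 0.01).
#' @slot deAlpha Nominal per-test level reported in run summaries
#'   (default 0.05). Not used for selection; see the vignette.
#' @slot deNeglog10pCutoff Differential expression requires
#'   \eqn{-\log_{10} p} strictly greater than this value (default 1.5,
#'   i.e. p < 0.0316).
#' @slot dmPCutoff Differential methylation requires p strictly below this
#'   value (default 0.01).
#' @slot dmDeltaBetaCutoff Differential methylation requires
#'   \eqn{|\Delta\beta| \ge} this value (inclusive; default 0.3).
#' @slot corrRCutoff Expression--methylation pairs are retained when
#'   \eqn{|r|} is strictly greater than this value (default 0.8).
#' @slot requireSameDirection Logical; cross-contrast concordance demands a
#'   consistent direction of change in both contrasts (default `TRUE`).
#' @seealso [analysisConfig()]
#' @export
setClass("AnalysisConfig",
  representation(
    deFdr = "numeric",
    deAlpha = "numeric",
    deNeglog10pCutoff = "numeric",
    dmPCutoff = "numeric",
    dmDeltaBetaCutoff = "numeric",
    corrRCutoff = "numeric",
    requireSameDirection = "logical"
  ),
  prototype(
    deFdr = 0.01,
    deAlpha = 0.05,
    deNeglog10pCutoff = 1.5,
    dmPCutoff = 0.01,
    dmDeltaBetaCutoff = 0.3,
    corrRCutoff = 0.8,
    requireSameDirection = TRUE
  )
)

setValidity("AnalysisConfig", function(object) {
  msg <- character()
  prop <- function(x) length(x) == 1L && is.finite(x) && x > 0 && x < 1
  if (!prop(object@deFdr)) msg <- c(msg, "deFdr must be a proportion in (0,1)")
  if (!prop(object@deAlpha)) msg <- c(msg, "deAlpha must be a proportion in (0,1)")
  if (!(length(object@deNeglog10pCutoff) == 1L && is.finite(object@deNeglog10pCutoff) &&
        object@deNeglog10pCutoff >= 0))
    msg <- c(msg, "deNeglog10pCutoff must be a non-negative number")
  if (!prop(object@dmPCutoff)) msg <- c(msg, "dmPCutoff must be a proportion in (0,1)")
  if (!(length(object@dmDeltaBetaCutoff) == 1L && is.finite(object@dmDeltaBetaCutoff) &&
        object@dmDeltaBetaCutoff > 0 && object@dmDeltaBetaCutoff <= 1))
    msg <- c(msg, "dmDeltaBetaCutoff must lie in (0,1]")
  if (!prop(object@corrRCutoff)) msg <- c(msg, "corrRCutoff must lie in (0,1)")
  if (length(object@requireSameDirection) != 1L || is.na(object@requireSameDirection))
    msg <- c(msg, "requireSameDirection must be TRUE or FALSE")
  if (length(msg)) msg else TRUE
})

#' Construct an [AnalysisConfig-class] object
#'
#' @param deFdr,deAlpha,deNeglog10pCutoff,dmPCutoff,dmDeltaBetaCutoff,corrRCutoff,requireSameDirection
#'   See the corresponding slots of [AnalysisConfig-class].
#' @return A validated `AnalysisConfig`.
#' @export
#' @examples
#' analysisConfig()
#' analysisConfig(dmDeltaBetaCutoff = 0.2)
analysisConfig <- function(deFdr = 0.01, deAlpha = 0.05, deNeglog10pCutoff = 1.5,
                           dmPCutoff = 0.01, dmDeltaBetaCutoff = 0.3,
                           corrRCutoff = 0.8, requireSameDirection = TRUE) {
  new("AnalysisConfig",
      deFdr = deFdr, deAlpha = deAlpha,
      deNeglog10pCutoff = deNeglog10pCutoff,
      dmPCutoff = dmPCutoff, dmDeltaBetaCutoff = dmDeltaBetaCutoff,
      corrRCutoff = corrRCutoff, requireSameDirection = requireSameDirection)
}

#' Configuration of the synthetic matched-omics cohort generator
#'
#' Describes a three-group cohort (control / high-risk / patient) with
#' matched expression and methylation layers, planted shared and
#' group-specific effects and methylation--expression coupling. See the
#' vignette for the distributional model.
#'
#' @slot nPerGroup Samples per group (default 6).
#' @slot nGenes,nProbes Total features on each layer.
#' @slot nRiskExpr Genes with a shared expression shift in BOTH risk groups.
#' @slot nRiskMeth Genes carrying a probe with a shared delta-beta shift in
#'   both risk groups.
#' @slot nOffspringOnly,nPatientOnly Group-specific expression effects.
#' @slot nCoupled Genes whose log-expression is a linear function of their
#'   probe's beta value.
#' @slot exprEffect Magnitude of the planted log-signal shift
#'   (natural-log units; applied as a down-shift in the affected groups).
#' @slot deltaBetaEffect Target expected |delta beta| for planted probes
#'   (default 0.35).
#' @slot couplingR Target population |Pearson r| for coupled gene/probe
#'   pairs (default 0.92, giving the sample-level |r| > 0.8 filter
#'   comfortable headroom at 18 samples).
#' @slot noiseSdExpr Residual SD of log-signal.
#' @slot noiseSdMvalue Residual SD of methylation M-values (logit scale).
#' @slot covariateModel Named list of per-covariate group means and SD,
#'   each `list(mean = c(control=, high_risk=, patient=), sd =)`.
#' @slot seed Integer seed; a given configuration is bitwise reproducible.
#' @seealso [simConfig()], [simulateCohort()]
#' @export
setClass("SimConfig",
  representation(
    nPerGroup = "integer", nGenes = "integer", nProbes = "integer",
    nRiskExpr = "integer", nRiskMeth = "integer",
    nOffspringOnly = "integer", nPatientOnly = "integer",
    nCoupled = "integer",
    exprEffect = "numeric", deltaBetaEffect = "numeric",
    couplingR = "numeric", noiseSdExpr = "numeric", noiseSdMvalue = "numeric",
    covariateModel = "list", seed = "integer"
  )
)

setValidity("SimConfig", function(object) {
  msg <- character()
  if (object@nPerGroup < 3L) msg <- c(msg, "nPerGroup must be >= 3")
  nExprPlanted <- object@nRiskExpr + object@nOffspringOnly +
    object@nPatientOnly + object@nCoupled
  if (nExprPlanted > object@nGenes)
    msg <- c(msg, "planted expression classes exceed nGenes")
  if (object@nRiskMeth + object@nCoupled > object@nProbes)
    msg <- c(msg, "planted methylation probes exceed nProbes")
  if (any(c(object@nRiskExpr, object@nRiskMeth, object@nOffspringOnly,
            object@nPatientOnly, object@nCoupled) < 0L))
    msg <- c(msg, "planted counts must be non-negative")
  if (object@exprEffect <= 0) msg <- c(msg, "exprEffect must be > 0")
  if (object@deltaBetaEffect <= 0 || object@deltaBetaEffect >= 1)
    msg <- c(msg, "deltaBetaEffect must lie in (0,1)")
  if (object@couplingR <= 0 || object@couplingR >= 1)
    msg <- c(msg, "couplingR must lie in (0,1)")
  if (object@noiseSdExpr <= 0 || object@noiseSdMvalue <= 0)
    msg <- c(msg, "noise SDs must be > 0")
  if (length(msg)) msg else TRUE
})

#' Construct a [SimConfig-class] object
#'
#' Defaults emulate the study design the pipeline targets: three matched
#' groups of six, array-scale feature counts scaled to a testable size, a
#' planted effect structure in which the high-risk group carries more
#' expression alterations than the patient group, and family-environment
#' covariates whose group means follow the published demographics
#' (cohesion high in controls, conflict reversed).
#'
#' @param nPerGroup,nGenes,nProbes,nRiskExpr,nRiskMeth,nOffspringOnly,nPatientOnly,nCoupled,exprEffect,deltaBetaEffect,couplingR,noiseSdExpr,noiseSdMvalue,covariateModel,seed
#'   See [SimConfig-class].
#' @return A validated `SimConfig`.
#' @export
#' @examples
#' simConfig(nGenes = 500, nProbes = 500, seed = 1)
simConfig <- function(nPerGroup = 6L, nGenes = 2000L, nProbes = 2000L,
                      nRiskExpr = 50L, nRiskMeth = 10L,
                      nOffspringOnly = 40L, nPatientOnly = 10L,
                      nCoupled = 25L,
                      exprEffect = 2.0, deltaBetaEffect = 0.35,
                      couplingR = 0.92,
                      noiseSdExpr = 0.3, noiseSdMvalue = 0.3,
                      covariateModel = defaultCovariateModel(),
                      seed = 1L) {
  new("SimConfig",
      nPerGroup = as.integer(nPerGroup),
      nGenes = as.integer(nGenes), nProbes = as.integer(nProbes),
      nRiskExpr = as.integer(nRiskExpr), nRiskMeth = as.integer(nRiskMeth),
      nOffspringOnly = as.integer(nOffspringOnly),
      nPatientOnly = as.integer(nPatientOnly),
      nCoupled = as.integer(nCoupled),
      exprEffect = exprEffect, deltaBetaEffect = deltaBetaEffect,
      couplingR = couplingR,
      noiseSdExpr = noiseSdExpr, noiseSdMvalue = noiseSdMvalue,
      covariateModel = covariateModel, seed = as.integer(seed))
}

#' Default family-environment covariate model
#'
#' Group means follow the published cohort demographics: family cohesion is
#' highest in controls and lowest in patients, family conflict is reversed,
#' and global functioning collapses in the patient group.
#'
#' @return Named list of covariate models (`mean` per group, `sd`).
#' @export
defaultCovariateModel <- function() {
  list(
    cohesion = list(mean = c(control = 8.16, high_risk = 5.5, patient = 4.66), sd = 1.5),
    conflict = list(mean = c(control = 0.83, high_risk = 4.0, patient = 5.16), sd = 1.5),
    gaf      = list(mean = c(control = 88.3, high_risk = 89.2, patient = 49.8), sd = 4.0)
  )
}

#' Matched expression + methylation cohort
#'
#' The central container: an expression matrix (genes x samples,
#' non-negative signal intensities), a methylation beta-value matrix
#' (probes x samples, values in [0,1]), a sample sheet with group labels
#' and optional continuous covariates, a probe-to-gene annotation table
#' and, for simulated cohorts, a ground-truth table of planted effects.
#'
#' @slot expression Numeric matrix, unique rownames (gene symbols), sample
#'   ids as colnames; values >= 0 or NA.
#' @slot methylation Numeric matrix, unique rownames (probe ids), same
#'   sample ids; values in [0,1] or NA.
#' @slot samples `data.frame` with columns `sample_id`, `group` and any
#'   number of numeric covariate columns.
#' @slot annotation `data.frame` with columns `probe_id`, `genes`
#'   (";"-separated symbols, possibly empty), `chromosome`, `position`
#'   (1-based).
#' @slot truth `data.frame` of planted classes (possibly 0-row): columns
#'   `feature_id`, `layer` ("expression"/"methylation"), `class`, `effect`.
#' @seealso [OmicsCohort()], [simulateCohort()]
#' @export
setClass("OmicsCohort",
  representation(
    expression = "matrix",
    methylation = "matrix",
    samples = "data.frame",
    annotation = "data.frame",
    truth = "data.frame"
  )
)

setValidity("OmicsCohort", function(object) {
  msg <- character()
  ex <- object@expression; be <- object@methylation; ss <- object@samples
  if (anyDuplicated(rownames(ex)))
    msg <- c(msg, "duplicated gene ids in expression matrix")
  if (anyDuplicated(rownames(be)))
    msg <- c(msg, "duplicated probe ids in methylation matrix")
  if (any(ex < 0, na.rm = TRUE))
    msg <- c(msg, "expression values must be >= 0")
  if (any(be < 0 | be > 1, na.rm = TRUE))
    msg <- c(msg, "beta values must lie in [0,1]")
  if (!all(c("sample_id", "group") %in% colnames(ss)))
    msg <- c(msg, "sample sheet must have sample_id and group columns")
  else {
    if (anyDuplicated(ss$sample_id)) msg <- c(msg, "duplicated sample_id")
    if (!all(ss$group %in% cohortGroups()))
      msg <- c(msg, sprintf("group labels must be one of: %s",
                            paste(cohortGroups(), collapse = ", ")))
    if (ncol(ex) && !setequal(colnames(ex), ss$sample_id))
      msg <- c(msg, "expression columns do not match the sample sheet")
    if (ncol(be) && !setequal(colnames(be), ss$sample_id))
      msg <- c(msg, "methylation columns do not match the sample sheet")
  }
  an <- object@annotation
  if (nrow(an)) {
    if (!all(c("probe_id", "genes") %in% colnames(an)))
      msg <- c(msg, "annotation must have probe_id and genes columns")
    else if (anyDuplicated(an$probe_id))
      msg <- c(msg, "duplicated probe_id in annotation")
  }
  if (length(msg)) msg else TRUE
})

#' Construct an [OmicsCohort-class] object
#'
#' @param expression Genes x samples numeric matrix (rownames = gene
#'   symbols, colnames = sample ids).
#' @param methylation Probes x samples numeric matrix of beta values.
#' @param samples Sample sheet `data.frame` (`sample_id`, `group`,
#'   covariates).
#' @param annotation Probe annotation `data.frame` (`probe_id`, `genes`,
#'   `chromosome`, `position`).
#' @param truth Optional ground-truth table for simulated cohorts.
#' @return A validated `OmicsCohort`.
#' @export
OmicsCohort <- function(expression, methylation, samples,
                        annotation = emptyAnnotation(), truth = emptyTruth()) {
  new("OmicsCohort", expression = expression, methylation = methylation,
      samples = samples, annotation = annotation, truth = truth)
}

emptyAnnotation <- function() {
  data.frame(probe_id = character(), genes = character(),
             chromosome = character(), position = integer(),
             stringsAsFactors = FALSE)
}

emptyTruth <- function() {
  data.frame(feature_id = character(), layer = character(),
             class = character(), effect = numeric(),
             stringsAsFactors = FALSE)
}

#' Collection of named gene sets
#'
#' GMT-style gene-set collection with an optional universe (reference-set)
#' size for the hypergeometric enrichment test.
#'
#' @slot sets Named list of character vectors of gene symbols; set names
#'   unique, members deduplicated, every set non-empty.
#' @slot universeSize Number of genes in the enrichment universe, or `NA`
#'   when it is to be supplied (or derived) at test time.
#' @seealso [geneSetCollection()], [readGMT()], [enrichSets()]
#' @export
setClass("GeneSetCollection",
  representation(sets = "list", universeSize = "numeric"),
  prototype(sets = list(), universeSize = NA_real_)
)

setValidity("GeneSetCollection", function(object) {
  msg <- character()
  s <- object@sets
  if (length(s)) {
    if (is.null(names(s)) || anyDuplicated(names(s)) || any(names(s) == ""))
      msg <- c(msg, "gene sets must have unique non-empty names")
    if (any(!vapply(s, is.character, logical(1))))
      msg <- c(msg, "gene sets must be character vectors")
    else {
      if (any(vapply(s, length, integer(1)) < 1L))
        msg <- c(msg, "gene sets must be non-empty")
      if (any(vapply(s, anyDuplicated, integer(1)) > 0L))
        msg <- c(msg, "gene-set members must be deduplicated")
    }
  }
  N <- object@universeSize
  if (length(N) != 1L) msg <- c(msg, "universeSize must be a single number")
  else if (!is.na(N)) {
    if (N < 1 || N != round(N)) msg <- c(msg, "universeSize must be a positive integer")
    if (length(s) && N < max(vapply(s, length, integer(1))))
      msg <- c(msg, "universeSize smaller than the largest gene set")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a [GeneSetCollection-class]
#'
#' @param sets Named list of character vectors; members are deduplicated.
#' @param universeSize Optional universe size (default `NA`).
#' @return A validated `GeneSetCollection`.
#' @export
#' @examples
#' geneSetCollection(list(GR_SIGNALING = c("MED1", "GTF2A1", "HSPA1L", "TAF15")))
geneSetCollection <- function(sets, universeSize = NA_real_) {
  sets <- lapply(sets, function(x) unique(as.character(x)))
  new("GeneSetCollection", sets = sets, universeSize = as.numeric(universeSize))
}

#' Risk-gene set from cross-contrast concordance
#'
#' Genes altered in BOTH control-referenced contrasts, flagged by the
#' evidence layer: `E` (concordant differential expression), `M` (annotated
#' to a probe concordantly differentially methylated) or `E+M`.
#'
#' @slot genes `data.frame` with columns `symbol`, `source` (E/M/E+M) and
#'   `probes` (";"-separated contributing probes for M evidence).
#' @slot unannotatedProbes Concordant probes without a gene annotation;
#'   reported, never silently dropped.
#' @seealso [buildRiskGeneSet()]
#' @export
setClass("RiskGeneSet",
  representation(genes = "data.frame", unannotatedProbes = "character"),
  prototype(
    genes = data.frame(symbol = character(), source = character(),
                       probes = character(), stringsAsFactors = FALSE),
    unannotatedProbes = character()
  )
)

setValidity("RiskGeneSet", function(object) {
  msg <- character()
  g <- object@genes
  if (!all(c("symbol", "source", "probes") %in% colnames(g)))
    msg <- c(msg, "genes table must have symbol, source and probes columns")
  else {
    if (anyDuplicated(g$symbol)) msg <- c(msg, "duplicated risk-gene symbol")
    if (!all(g$source %in% c("E", "M", "E+M")))
      msg <- c(msg, "source must be E, M or E+M")
  }
  if (length(msg)) msg else TRUE
})
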