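#' @include AllGenerics.R
NULL

#' Expression matrix of a cohort
#'
#' @param x An [OmicsCohort-class].
#' @return Genes x samples numeric matrix.
#' @export
setMethod("exprValues", "OmicsCohort", function(x) x@expression)

#' Methylation beta-value matrix of a cohort
#'
#' @param x An [OmicsCohort-class].
#' @return Probes x samples numeric matrix with values in [0,1].
#' @export
setMethod("betaValues", "OmicsCohort", function(x) x@methylation)

#' Sample sheet of a cohort
#'
#' @param x An [OmicsCohort-class].
#' @return `data.frame` with `sample_id`, `group` and covariate columns.
#' @export
setMethod("sampleSheet", "OmicsCohort", function(x) x@samples)

#' Probe-to-gene annotation of a cohort
#'
#' @param x An [OmicsCohort-class].
#' @return `data.frame` with `probe_id`, `genes`, `chromosome`, `position`.
#' @export
setMethod("probeAnnotation", "OmicsCohort", function(x) x@annotation)

#' Ground-truth table of a simulated cohort
#'
#' @param x An [OmicsCohort-class].
#' @return `data.frame` of planted feature classes (0-row for real data).
#' @export
setMethod("truthTable", "OmicsCohort", function(x) x@truth)

#' Member sets of a gene-set collection
#'
#' @param x A [GeneSetCollection-class].
#' @return Named list of character vectors.
#' @export
setMethod("geneSets", "GeneSetCollection", function(x) x@sets)

#' Universe (reference-set) size of a gene-set collection
#'
#' @param x A [GeneSetCollection-class].
#' @return Single number, `NA` when unset.
#' @export
setMethod("universeSize", "GeneSetCollection", function(x) x@universeSize)

#' Risk-gene table
#'
#' @param x A [RiskGeneSet-class].
#' @return `data.frame` with `symbol`, `source` and `probes` columns.
#' @export
setMethod("riskGenes", "RiskGeneSet", function(x) x@genes)

#' Concordant probes lacking a gene annotation
#'
#' @param x A [RiskGeneSet-class].
#' @return Character vector of probe ids.
#' @export
setMethod("unannotatedProbes", "RiskGeneSet", function(x) x@unannotatedProbes)

setMethod("show", "OmicsCohort", function(object) {
  ss <- object@samples
  cat("OmicsCohort\n")
  cat(sprintf("  expression : %d genes x %d samples\n",
              nrow(object@expression), ncol(object@expression)))
  cat(sprintf("  methylation: %d probes x %d samples\n",
              nrow(object@methylation), ncol(object@methylation)))
  grp <- table(factor(ss$group, levels = cohortGroups()))
  cat(sprintf("  groups     : %s\n",
              paste(sprintf("%s=%d", names(grp), grp), collapse = ", ")))
  cov <- setdiff(colnames(ss), c("sample_id", "group"))
  if (length(cov)) cat(sprintf("  covariates : %s\n", paste(cov, collapse = ", ")))
  if (nrow(object@truth))
    cat(sprintf("  truth      : %d planted features\n",
                sum(object@truth$class != "null")))
})

setMethod("show", "GeneSetCollection", function(object) {
  sizes <- vapply(object@sets, length, integer(1))
  cat(sprintf("GeneSetCollection with %d sets", length(sizes)))
  if (length(sizes))
    cat(sprintf(" (sizes %d-%d)", min(sizes), max(sizes)))
  if (!is.na(object@universeSize))
    cat(sprintf(", universe N = %d", as.integer(object@universeSize)))
  cat("\n")
})

setMethod("show", "RiskGeneSet", function(object) {
  g <- object@genes
  cat(sprintf("RiskGeneSet: %d genes (E: %d, M: %d, E+M: %d)\n",
              nrow(g), sum(g$source == "E"), sum(g$source == "M"),
              sum(g$source == "E+M")))
  if (length(object@unannotatedProbes))
    cat(sprintf("  + %d concordant unannotated probes\n",
                length(object@unannotatedProbes)))
})

setMethod("show", "AnalysisConfig", function(object) {
  cat("AnalysisConfig\n")
  cat(sprintf("  DE : BH q <= %g and -log10(p) > %g (alpha = %g)\n",
              object@deFdr, object@deNeglog10pCutoff, object@deAlpha))
  cat(sprintf("  DM : p < %g and |delta beta| >= %g\n",
              object@dmPCutoff, object@dmDeltaBetaCutoff))
  cat(sprintf("  r  : |Pearson r| > %g\n", object@corrRCutoff))
  cat(sprintf("  concordance requires same direction: %s\n",
              object@requireSameDirection))
})

setMethod("show", "SimConfig", function(object) {
  cat(sprintf("SimConfig: %d x 3 samples, %d genes, %d probes (seed %d)\n",
              object@nPerGroup, object@nGenes, object@nProbes, object@seed))
  cat(sprintf("  planted: %d risk-expr, %d risk-meth, %d offspring-only, %d patient-only, %d coupled\n",
              object@nRiskExpr, object@nRiskMeth, object@nOffspringOnly,
              object@nPatientOnly, object@nCoupled))
})
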