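## Cross-contrast concordance: risk genes are features altered in BOTH
## control-referenced contrasts (control vs high-risk and control vs
## patient); the patient-vs-high-risk contrast gets its own combined list.

#' Intersect two selected feature lists
#'
#' @param listA,listB Character vectors of selected feature ids from two
#'   contrasts over the same feature space.
#' @return Sorted character vector of features present in both.
#' @export
#' @examples
#' concordantFeatures(c("B", "A", "C"), c("C", "D", "A"))
concordantFeatures <- function(listA, listB) {
  sort(intersect(listA, listB))
}

# selected features of a result table, optionally requiring the same
# direction of change in a second table
.concordantSelected <- function(resA, resB, idCol, dirCol, sameDirection) {
  selA <- resA[[idCol]][resA$selected]
  selB <- resB[[idCol]][resB$selected]
  shared <- concordantFeatures(selA, selB)
  if (sameDirection && length(shared)) {
    dA <- sign(resA[[dirCol]][match(shared, resA[[idCol]])])
    dB <- sign(resB[[dirCol]][match(shared, resB[[idCol]])])
    shared <- shared[!is.na(dA) & !is.na(dB) & dA == dB]
  }
  shared
}

#' Build the risk-gene set from the two control-referenced contrasts
#'
#' Expression evidence (`E`): genes selected in BOTH differential
#' expression contrasts. Methylation evidence (`M`): genes annotated to at
#' least one probe selected in BOTH differential methylation contrasts —
#' concordance is evaluated at probe level, then mapped to genes. The risk
#' set is the union, with `E+M` flags where both layers agree. By default
#' concordance additionally demands a consistent direction of change
#' (`config@requireSameDirection`). Concordant probes without a gene
#' annotation are reported in [unannotatedProbes()], never counted as
#' genes.
#'
#' @param degControlVsHighRisk,degControlVsPatient [deTest()] result tables
#'   for the two control-referenced expression contrasts.
#' @param dmpControlVsHighRisk,dmpControlVsPatient [dmTest()] result tables
#'   for the two control-referenced methylation contrasts.
#' @param annotation Annotation `data.frame`.
#' @param config An [AnalysisConfig-class].
#' @return A [RiskGeneSet-class].
#' @export
buildRiskGeneSet <- function(degControlVsHighRisk, degControlVsPatient,
                             dmpControlVsHighRisk, dmpControlVsPatient,
                             annotation, config = analysisConfig()) {
  same <- config@requireSameDirection
  eGenes <- .concordantSelected(degControlVsHighRisk, degControlVsPatient,
                                "feature_id", "direction", same)
  mProbes <- .concordantSelected(dmpControlVsHighRisk, dmpControlVsPatient,
                                 "probe_id", "delta_beta", same)
  mapped <- mapProbesToGenes(mProbes, annotation)
  geneList <- annotationGeneList(annotation)[mProbes]
  probesOf <- function(sym) {
    hit <- vapply(geneList, function(g) sym %in% g, logical(1))
    paste(sort(mProbes[hit]), collapse = ";")
  }
  symbols <- sort(union(eGenes, mapped$genes))
  genes <- data.frame(
    symbol = symbols,
    source = ifelse(symbols %in% eGenes & symbols %in% mapped$genes, "E+M",
                    ifelse(symbols %in% eGenes, "E", "M")),
    probes = vapply(symbols, function(s)
      if (s %in% mapped$genes) probesOf(s) else "", character(1)),
    stringsAsFactors = FALSE)
  rownames(genes) <- NULL
  new("RiskGeneSet", genes = genes,
      unannotatedProbes = sort(c(mapped$unannotated, mapped$unknown)))
}

#' Combined gene list for the patient-vs-high-risk contrast
#'
#' Union of the selected differentially expressed genes and the genes
#' annotated to selected differentially methylated probes in a single
#' contrast, deduplicated.
#'
#' @param degResults [deTest()] result table for the contrast.
#' @param dmpResults [dmTest()] result table for the contrast.
#' @param annotation Annotation `data.frame`.
#' @return Sorted character vector of gene symbols.
#' @export
combinedContrastGenes <- function(degResults, dmpResults, annotation) {
  degGenes <- degResults$feature_id[degResults$selected]
  dmProbes <- dmpResults$probe_id[dmpResults$selected]
  sort(union(degGenes, mapProbesToGenes(dmProbes, annotation)$genes))
}
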