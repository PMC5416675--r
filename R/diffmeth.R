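## Differential methylation: per-probe two-group test on beta values with
## the dual p / delta-beta filter, and probe-to-gene mapping.

#' Per-probe two-group differential methylation
#'
#' Group mean betas, delta beta (comparison minus reference), a two-sided
#' Student's t-test on the beta values, and an Illumina-style DiffScore
#' \eqn{10\,\mathrm{sign}(\Delta\beta)(-\log_{10} p)} (reported for
#' reference, never used for selection). Probes use complete observations
#' per group; fewer than two in either group flags the probe untestable
#' (p missing, `selected = FALSE`).
#'
#' @param beta Numeric matrix of beta values, probes x samples.
#' @param samples Sample sheet `data.frame`.
#' @param referenceGroup,comparisonGroup Group labels to contrast.
#' @param annotation Optional annotation `data.frame`; adds a
#'   `gene_symbols` column.
#' @param config An [AnalysisConfig-class].
#' @return `data.frame`, one row per probe in input order: `probe_id`,
#'   `mean_beta_ref`, `mean_beta_cmp`, `delta_beta`, `p_value`,
#'   `diff_score`, `selected` (and `gene_symbols` when annotation given).
#' @export
dmTest <- function(beta, samples, referenceGroup, comparisonGroup,
                   annotation = NULL, config = analysisConfig()) {
  idx <- .contrastIdx(samples, referenceGroup, comparisonGroup, colnames(beta))
  st <- .rowTTest(beta, idx$ref, idx$cmp)
  db <- st$meanCmp - st$meanRef
  res <- data.frame(
    probe_id = rownames(beta),
    mean_beta_ref = st$meanRef,
    mean_beta_cmp = st$meanCmp,
    delta_beta = db,
    p_value = st$p,
    diff_score = 10 * sign(db) * (-log10(st$p)),
    stringsAsFactors = FALSE)
  res$selected <- !is.na(res$p_value) &
    res$p_value < config@dmPCutoff &
    abs(res$delta_beta) >= config@dmDeltaBetaCutoff
  if (!is.null(annotation)) {
    res$gene_symbols <- annotation$genes[match(res$probe_id, annotation$probe_id)]
    res$gene_symbols[is.na(res$gene_symbols)] <- ""
  }
  res
}

#' Select differentially methylated probes
#'
#' Selection requires p strictly below `dmPCutoff` and \eqn{|\Delta\beta|}
#' at least `dmDeltaBetaCutoff` (inclusive boundary).
#'
#' @param results Output of [dmTest()].
#' @param config An [AnalysisConfig-class].
#' @return Character vector of selected probe ids, sorted by p-value
#'   ascending (ties by probe id).
#' @export
selectDMP <- function(results, config = analysisConfig()) {
  sel <- !is.na(results$p_value) &
    results$p_value < config@dmPCutoff &
    abs(results$delta_beta) >= config@dmDeltaBetaCutoff
  hit <- results[sel, , drop = FALSE]
  hit$probe_id[order(hit$p_value, hit$probe_id)]
}

#' Map probes to annotated gene symbols
#'
#' Union of gene symbols across the given probes, deduplicated and sorted.
#' Probes with an empty annotation and probes absent from the annotation
#' table are reported separately, never silently dropped.
#'
#' @param probes Character vector of probe ids.
#' @param annotation Annotation `data.frame` from [readAnnotation()].
#' @return List with `genes` (sorted unique symbols), `unannotated`
#'   (annotated probes with no gene) and `unknown` (probes missing from the
#'   annotation).
#' @export
#' @examples
#' ann <- data.frame(probe_id = c("cg1", "cg2"), genes = c("GLUL", ""),
#'                   chromosome = "chr1", position = c(1L, 2L))
#' mapProbesToGenes(c("cg1", "cg2", "cg9"), ann)
mapProbesToGenes <- function(probes, annotation) {
  probes <- unique(probes)
  known <- probes %in% annotation$probe_id
  geneList <- annotationGeneList(annotation)[probes[known]]
  nGenes <- lengths(geneList)
  list(
    genes = sort(unique(unlist(geneList, use.names = FALSE))),
    unannotated = probes[known][nGenes == 0L],
    unknown = probes[!known])
}
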