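## Expression-methylation correlation integration (eQTM-style) and
## gene-covariate correlation.

#' Pearson correlation with a two-sided t-based p-value
#'
#' Sample Pearson r over pairwise-complete observations; two-sided p from
#' the t-transform \eqn{t = r\sqrt{(n-2)/(1-r^2)}} with n - 2 df. Fewer
#' than 3 complete pairs, or zero variance in either vector, yields a
#' missing result.
#'
#' @param x,y Numeric vectors of equal length.
#' @return List with `r`, `p_value` and `n` (complete pairs used).
#' @export
#' @examples
#' pearsonCorr(1:4, c(1, 3, 2, 4))
pearsonCorr <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  ok <- !is.na(x) & !is.na(y)
  n <- sum(ok)
  if (n < 3L) return(list(r = NA_real_, p_value = NA_real_, n = n))
  x <- x[ok]; y <- y[ok]
  dx <- x - mean(x); dy <- y - mean(y)
  sxx <- sum(dx^2); syy <- sum(dy^2)
  if (sxx == 0 || syy == 0) return(list(r = NA_real_, p_value = NA_real_, n = n))
  r <- sum(dx * dy) / sqrt(sxx * syy)
  r <- max(-1, min(1, r))
  p <- if (abs(r) == 1) 0 else {
    tval <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(tval), n - 2)
  }
  list(r = r, p_value = p, n = n)
}

#' Correlate expression with methylation across all annotated pairs
#'
#' One Pearson correlation per (gene, annotated probe) pair, pooled over
#' ALL samples of the cohort (the three groups analysed jointly). A pair
#' is selected when \eqn{|r|} strictly exceeds `config@corrRCutoff`;
#' correlation p-values are reported but play no role in selection. A
#' gene-level summary keeps, per gene, the pair with maximal \eqn{|r|}.
#'
#' @param expr Expression matrix, genes x samples.
#' @param beta Beta-value matrix, probes x samples (same sample set).
#' @param annotation Annotation `data.frame` linking probes to genes.
#' @param config An [AnalysisConfig-class].
#' @return List with `pairs` (`gene`, `probe_id`, `r`, `n_samples`,
#'   `p_value`, `selected`), `geneSummary` (best pair per gene) and
#'   `genesWithoutProbe` (measured genes absent from the output).
#' @export
integrateExpressionMethylation <- function(expr, beta, annotation,
                                           config = analysisConfig()) {
  shared <- intersect(colnames(expr), colnames(beta))
  if (length(shared) < 3L)
    stop("expression and methylation matrices share fewer than 3 samples")
  geneList <- annotationGeneList(annotation)
  geneList <- geneList[names(geneList) %in% rownames(beta)]
  pairs <- data.frame(
    probe_id = rep(names(geneList), lengths(geneList)),
    gene = unlist(geneList, use.names = FALSE),
    stringsAsFactors = FALSE)
  pairs <- pairs[pairs$gene %in% rownames(expr), , drop = FALSE]
  if (nrow(pairs)) {
    stats <- lapply(seq_len(nrow(pairs)), function(i) {
      pearsonCorr(expr[pairs$gene[i], shared], beta[pairs$probe_id[i], shared])
    })
    pairs$r <- vapply(stats, `[[`, numeric(1), "r")
    pairs$n_samples <- vapply(stats, `[[`, numeric(1), "n")
    pairs$p_value <- vapply(stats, `[[`, numeric(1), "p_value")
  } else {
    pairs$r <- numeric(0); pairs$n_samples <- numeric(0)
    pairs$p_value <- numeric(0)
  }
  pairs$selected <- !is.na(pairs$r) & abs(pairs$r) > config@corrRCutoff
  pairs <- pairs[, c("gene", "probe_id", "r", "n_samples", "p_value", "selected")]
  pairs <- pairs[order(pairs$gene, pairs$probe_id), , drop = FALSE]
  rownames(pairs) <- NULL

  summ <- do.call(rbind, lapply(split(pairs, pairs$gene), function(d) {
    if (all(is.na(d$r))) return(d[1L, , drop = FALSE])
    d[which.max(abs(d$r)), , drop = FALSE]
  }))
  rownames(summ) <- NULL

  list(pairs = pairs,
       geneSummary = summ,
       genesWithoutProbe = setdiff(rownames(expr), pairs$gene))
}

#' Correlate gene expression with continuous covariates
#'
#' Pearson r and p per (gene, covariate) pair across all samples with
#' pairwise-complete data. An all-missing or constant covariate is skipped
#' with a warning.
#'
#' @param expr Expression matrix, genes x samples.
#' @param samples Sample sheet `data.frame` whose non-id/group columns are
#'   covariates.
#' @param genes Genes to correlate (default: all measured genes).
#' @param covariates Covariate columns to use (default: all).
#' @return `data.frame` with `gene`, `covariate`, `r`, `p_value`, `n`.
#' @export
covariateCorrelation <- function(expr, samples, genes = rownames(expr),
                                 covariates = NULL) {
  samples <- validateSampleSheet(samples)
  if (is.null(covariates))
    covariates <- setdiff(colnames(samples), c("sample_id", "group"))
  genes <- intersect(genes, rownames(expr))
  keep <- character()
  for (cv in covariates) {
    v <- samples[[cv]]
    if (sum(!is.na(v)) < 3L || stats::sd(v, na.rm = TRUE) == 0 ||
        is.na(stats::sd(v, na.rm = TRUE))) {
      warning(sprintf("covariate '%s' is constant or nearly all missing; skipped", cv))
    } else keep <- c(keep, cv)
  }
  grid <- expand.grid(gene = genes, covariate = keep,
                      stringsAsFactors = FALSE)
  ord <- match(samples$sample_id, colnames(expr))
  res <- lapply(seq_len(nrow(grid)), function(i) {
    pearsonCorr(expr[grid$gene[i], ord], samples[[grid$covariate[i]]])
  })
  grid$r <- vapply(res, `[[`, numeric(1), "r")
  grid$p_value <- vapply(res, `[[`, numeric(1), "p_value")
  grid$n <- vapply(res, `[[`, numeric(1), "n")
  grid
}
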