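## Differential expression: quantile normalisation, row-wise two-sided
## Student's t-test (pooled variance), BH adjustment and the dual
## FDR / -log10(p) selection rule.

# Vectorised row-wise pooled-variance Student's t between two column sets.
# Missing values are dropped pairwise per row; rows with < minPerGroup
# complete observations in either group, or zero pooled variance, get NA.
.rowTTest <- function(mat, idxRef, idxCmp, minPerGroup = 2L) {
  groupStats <- function(x) {
    ok <- !is.na(x)
    n <- rowSums(ok)
    x0 <- x
    x0[!ok] <- 0
    m <- rowSums(x0) / n
    ss <- rowSums((x0 - ifelse(ok, m, 0))^2)
    v <- ss / pmax(n - 1, 1)
    v[n < 2] <- NA_real_
    list(n = n, mean = m, var = v)
  }
  a <- groupStats(mat[, idxRef, drop = FALSE])
  b <- groupStats(mat[, idxCmp, drop = FALSE])
  df <- a$n + b$n - 2
  sp2 <- ((a$n - 1) * a$var + (b$n - 1) * b$var) / df
  se <- sqrt(sp2 * (1 / a$n + 1 / b$n))
  t <- (b$mean - a$mean) / se
  p <- 2 * stats::pt(-abs(t), df)
  untestable <- a$n < minPerGroup | b$n < minPerGroup
  zeroVar <- !untestable & !is.na(sp2) & sp2 == 0
  t[untestable | zeroVar] <- NA_real_
  p[untestable | zeroVar] <- NA_real_
  meanRef <- a$mean; meanCmp <- b$mean
  meanRef[a$n == 0] <- NA_real_
  meanCmp[b$n == 0] <- NA_real_
  list(meanRef = meanRef, meanCmp = meanCmp, t = t, df = df, p = p,
       untestable = untestable, zeroVar = zeroVar)
}

.contrastIdx <- function(samples, referenceGroup, comparisonGroup, ids) {
  samples <- validateSampleSheet(samples)
  if (referenceGroup == comparisonGroup)
    stop("contrast groups must be distinct")
  for (g in c(referenceGroup, comparisonGroup)) {
    k <- sum(samples$group == g)
    if (k < 2L)
      stop(sprintf("group '%s' has %d sample(s); need at least 2", g, k))
  }
  missing <- setdiff(samples$sample_id, ids)
  if (length(missing))
    stop(sprintf("sample(s) in sheet but not in matrix: %s",
                 paste(missing, collapse = ", ")))
  list(ref = match(samples$sample_id[samples$group == referenceGroup], ids),
       cmp = match(samples$sample_id[samples$group == comparisonGroup], ids))
}

#' Quantile-normalise an expression matrix
#'
#' Forces every sample (column) onto the same distribution: the
#' across-column mean of order statistics. Ties within a column receive the
#' mean of the quantile values they span. Delegates to
#' [limma::normalizeQuantiles()].
#'
#' @param m Numeric matrix, genes x samples, no missing values.
#' @return Matrix of the same shape and dimnames.
#' @export
#' @examples
#' quantileNormalize(cbind(a = c(1, 2, 3), b = c(4, 5, 6)))
quantileNormalize <- function(m) {
  if (anyNA(m))
    stop("quantile normalisation requires a complete matrix; ",
         "impute or filter missing values upstream")
  if (ncol(m) <= 1L) return(m)
  out <- limma::normalizeQuantiles(m, ties = TRUE)
  dimnames(out) <- dimnames(m)
  out
}

#' Per-gene two-group differential expression
#'
#' Two-sided Student's t-test with pooled variance (df = n1 + n2 - 2) per
#' gene, BH q-values across all testable genes, and the dual selection rule
#' of [selectDEG()]. Genes with zero pooled variance (or fewer than two
#' complete observations in a group) are flagged untestable: p and q are
#' missing, `selected` is `FALSE`, and they do not enter the BH
#' multiplicity count.
#'
#' @param m Numeric matrix of (typically log-scale, quantile-normalised)
#'   expression values, genes x samples.
#' @param samples Sample sheet `data.frame`.
#' @param referenceGroup,comparisonGroup Group labels to contrast;
#'   `direction` is the sign of (comparison mean - reference mean).
#' @param config An [AnalysisConfig-class] supplying the selection
#'   thresholds.
#' @return `data.frame`, one row per gene in input order: `feature_id`,
#'   `mean_ref`, `mean_cmp`, `t_statistic`, `p_value`, `q_value`,
#'   `neglog10_p`, `direction`, `selected`.
#' @export
deTest <- function(m, samples, referenceGroup, comparisonGroup,
                   config = analysisConfig()) {
  idx <- .contrastIdx(samples, referenceGroup, comparisonGroup, colnames(m))
  st <- .rowTTest(m, idx$ref, idx$cmp)
  q <- rep(NA_real_, nrow(m))
  ok <- !is.na(st$p)
  q[ok] <- bhAdjust(st$p[ok])
  res <- data.frame(
    feature_id = rownames(m),
    mean_ref = st$meanRef,
    mean_cmp = st$meanCmp,
    t_statistic = st$t,
    p_value = st$p,
    q_value = q,
    neglog10_p = -log10(st$p),
    direction = sign(st$meanCmp - st$meanRef),
    stringsAsFactors = FALSE)
  res$selected <- !is.na(res$q_value) &
    res$q_value <= config@deFdr &
    res$neglog10_p > config@deNeglog10pCutoff
  res
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Step-up adjusted values \eqn{q_{(i)} = \min_{j \ge i} \min(1, m\,p_{(j)}/j)}
#' mapped back to input order (computed via [stats::p.adjust()]). The
#' multiplicity count `m` is the number of non-missing p-values.
#'
#' @param p Numeric vector of p-values in (0, 1]; NA passed through.
#' @return Adjusted values, same length and order.
#' @export
#' @examples
#' bhAdjust(c(0.01, 0.02, 0.03, 0.04))
bhAdjust <- function(p) {
  bad <- which(!is.na(p) & (p <= 0 | p > 1))
  if (length(bad))
    stop(sprintf("p-value(s) outside (0,1] at position(s): %s",
                 paste(bad, collapse = ", ")))
  out <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  out[ok] <- stats::p.adjust(p[ok], method = "BH")
  out
}

#' Select differentially expressed genes
#'
#' A gene is selected when its BH q-value is at most `deFdr` AND
#' \eqn{-\log_{10} p} strictly exceeds `deNeglog10pCutoff` — every printed
#' constraint applied conjunctively (see the vignette for why the nominal
#' alpha plays no selection role).
#'
#' @param results Output of [deTest()].
#' @param config An [AnalysisConfig-class].
#' @return Character vector of selected feature ids, sorted by p-value
#'   ascending (ties by feature id).
#' @export
selectDEG <- function(results, config = analysisConfig()) {
  sel <- !is.na(results$q_value) &
    results$q_value <= config@deFdr &
    results$neglog10_p > config@deNeglog10pCutoff
  hit <- results[sel, , drop = FALSE]
  hit$feature_id[order(hit$p_value, hit$feature_id)]
}
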