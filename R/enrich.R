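## Right-tailed hypergeometric gene-set enrichment (one-sided Fisher) with
## BH adjustment across sets, and inference of the reference-universe size
## from a singleton-pathway p-value.

#' Right tail of the hypergeometric distribution
#'
#' \eqn{P(X \ge k)} for \eqn{X \sim} Hypergeometric(N, K, q): the chance
#' that at least `k` of `q` genes drawn without replacement from an
#' `N`-gene universe fall inside a `K`-gene set. Computed through
#' [stats::phyper()] (log-gamma arithmetic internally). Vectorised over
#' `k` and `K`.
#'
#' @param k Observed overlap(s), `0 <= k <= min(K, q)`.
#' @param K Gene-set size(s).
#' @param q Query size.
#' @param N Universe size; `K, q <= N`.
#' @return Probability in (0, 1]; exactly 1 when `k = 0`.
#' @export
#' @examples
#' hypergeomTail(k = 2, K = 3, q = 4, N = 10)  # 1/3 by enumeration
hypergeomTail <- function(k, K, q, N) {
  n <- max(length(k), length(K), length(q), length(N))
  k <- rep_len(k, n); K <- rep_len(K, n)
  q <- rep_len(q, n); N <- rep_len(N, n)
  if (any(c(k, K, q, N) != round(c(k, K, q, N))))
    stop("hypergeometric parameters must be integers")
  if (any(k < 0) || any(K < 0) || any(q < 0) || any(N < 1))
    stop("hypergeometric parameters must be non-negative (N >= 1)")
  if (any(K > N) || any(q > N))
    stop("K and q must not exceed the universe size N")
  if (any(k > pmin(K, q)))
    stop("overlap k cannot exceed min(K, q)")
  stats::phyper(k - 1, K, N - K, q, lower.tail = FALSE)
}

#' Derive the enrichment universe from a singleton-set p-value
#'
#' For a set of size 1 the right tail has the closed form
#' \eqn{P(X \ge 1) = q/N}; a published singleton-pathway p-value therefore
#' pins the (otherwise unpublished) reference-universe size at
#' \eqn{N = \mathrm{round}(q / p_1)}.
#'
#' @param pSingleton Printed p-value of a size-1 set, in (0, 1).
#' @param q Query size (mapped genes).
#' @return Integer universe size.
#' @export
#' @examples
#' deriveUniverse(0.00198, 41)  # 20707
deriveUniverse <- function(pSingleton, q) {
  if (length(pSingleton) != 1L || !is.finite(pSingleton) ||
      pSingleton <= 0 || pSingleton >= 1)
    stop("pSingleton must be a probability in (0,1)")
  if (length(q) != 1L || q < 1 || q != round(q))
    stop("q must be a positive integer")
  N <- round(q / pSingleton)
  if (N < q) stop("derived universe is smaller than the query")
  as.integer(N)
}

#' Gene-set over-representation of a query list
#'
#' One right-tailed hypergeometric test per set in the collection, BH
#' adjustment across all sets. When `universeGenes` is supplied, query
#' genes outside it are reported as unmapped and excluded from the query
#' size q (and set sizes are restricted to the universe); with a purely
#' numeric universe all query genes count.
#'
#' @param query Character vector of gene symbols (deduplicated internally).
#' @param collection A [GeneSetCollection-class].
#' @param universeSize Universe size N; defaults to
#'   `universeSize(collection)`.
#' @param universeGenes Optional character vector enumerating the universe
#'   ("measured" mode: pass the annotated measured genes).
#' @return List with `table` (`set`, `set_size`, `overlap`,
#'   `overlap_fraction`, `p_value`, `q_value`, `overlap_genes`; rows sorted
#'   by p ascending, ties by set name), `querySize` and `unmappedGenes`.
#' @export
enrichSets <- function(query, collection, universeSize = NULL,
                       universeGenes = NULL) {
  query <- unique(as.character(query))
  if (!length(query)) stop("empty query gene list")
  sets <- geneSets(collection)
  if (!length(sets)) stop("empty gene-set collection")
  unmapped <- character()
  if (!is.null(universeGenes)) {
    universeGenes <- unique(as.character(universeGenes))
    unmapped <- setdiff(query, universeGenes)
    query <- intersect(query, universeGenes)
    if (!length(query))
      stop("no query gene maps to the universe")
    sets <- lapply(sets, intersect, universeGenes)
    sets <- sets[lengths(sets) > 0L]
    if (is.null(universeSize)) universeSize <- length(universeGenes)
  }
  if (is.null(universeSize)) universeSize <- collection@universeSize
  if (is.na(universeSize))
    stop("no universe size: set it on the collection, pass universeSize, ",
         "or provide universeGenes")
  N <- as.integer(round(universeSize))
  q <- length(query)
  if (N < q) stop("universe size smaller than the query size")
  K <- lengths(sets)
  if (any(K > N)) stop("universe size smaller than the largest gene set")
  ov <- lapply(sets, intersect, query)
  k <- lengths(ov)
  tab <- data.frame(
    set = names(sets),
    set_size = as.integer(K),
    overlap = as.integer(k),
    overlap_fraction = k / K,
    p_value = hypergeomTail(k, K, q, N),
    stringsAsFactors = FALSE)
  tab$q_value <- bhAdjust(tab$p_value)
  tab$overlap_genes <- vapply(ov, function(g) paste(sort(g), collapse = ";"),
                              character(1))
  tab <- tab[order(tab$p_value, tab$set), , drop = FALSE]
  rownames(tab) <- NULL
  list(table = tab, querySize = q, unmappedGenes = sort(unmapped))
}
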