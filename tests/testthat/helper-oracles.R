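# Independent oracles used to cross-check the package's statistics.

# Benjamini-Hochberg step-up by its definition:
# q_(i) = min_{j >= i} min(1, m * p_(j) / j) on the sorted scale.
bhBruteForce <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    cand <- vapply(i:m, function(j) min(1, m * p[o[j]] / j), numeric(1))
    q[o[i]] <- min(cand)
  }
  q
}

# Hypergeometric right tail by full enumeration over binomial coefficients.
hyperTailEnum <- function(k, K, q, N) {
  jmax <- min(K, q)
  if (k > jmax) return(0)
  j <- k:jmax
  sum(choose(K, j) * choose(N - K, q - j)) / choose(N, q)
}

# Pearson r for every (gene, probe) annotated pair by a double loop.
corrBruteForce <- function(expr, beta, annotation) {
  out <- list()
  for (i in seq_len(nrow(annotation))) {
    pr <- annotation$probe_id[i]
    if (!pr %in% rownames(beta)) next
    genes <- strsplit(annotation$genes[i], ";", fixed = TRUE)[[1]]
    for (g in genes[nzchar(genes)]) {
      if (!g %in% rownames(expr)) next
      out[[length(out) + 1L]] <- data.frame(
        gene = g, probe_id = pr,
        r = stats::cor(expr[g, ], beta[pr, colnames(expr)]),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
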