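# Small in-code fixtures shared across test files.

smallSampleSheet <- function(nPerGroup = 3L) {
  groups <- rep(cohortGroups(), each = nPerGroup)
  data.frame(sample_id = sprintf("S%02d", seq_along(groups)),
             group = groups, stringsAsFactors = FALSE)
}

smallMatrix <- function(ids, sampleIds, values) {
  matrix(values, nrow = length(ids), ncol = length(sampleIds),
         dimnames = list(ids, sampleIds))
}

# Minimal deTest-shaped result table: selected features get tiny p-values.
fakeDE <- function(allIds, selectedIds, direction = 1) {
  n <- length(allIds)
  sel <- allIds %in% selectedIds
  dirs <- rep_len(direction, n)
  data.frame(
    feature_id = allIds,
    mean_ref = 5, mean_cmp = 5 + dirs * ifelse(sel, 1, 0.001),
    t_statistic = dirs * ifelse(sel, 10, 0.1),
    p_value = ifelse(sel, 1e-6, 0.5),
    q_value = ifelse(sel, 1e-4, 0.6),
    neglog10_p = ifelse(sel, 6, 0.3),
    direction = dirs,
    selected = sel,
    stringsAsFactors = FALSE)
}

# Minimal dmTest-shaped result table.
fakeDMP <- function(allIds, selectedIds, deltaBeta = 0.35) {
  n <- length(allIds)
  sel <- allIds %in% selectedIds
  db <- rep_len(deltaBeta, n) * ifelse(sel, 1, 0.01)
  data.frame(
    probe_id = allIds,
    mean_beta_ref = 0.3, mean_beta_cmp = 0.3 + db,
    delta_beta = db,
    p_value = ifelse(sel, 1e-5, 0.6),
    diff_score = 10 * sign(db) * ifelse(sel, 5, 0.2),
    selected = sel,
    stringsAsFactors = FALSE)
}

simpleAnnotation <- function(probeIds, genes) {
  data.frame(probe_id = probeIds, genes = genes,
             chromosome = "chr1", position = seq_along(probeIds),
             stringsAsFactors = FALSE)
}
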