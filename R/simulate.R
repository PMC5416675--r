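## Synthetic matched-omics cohort generator.
##
## Expression: exp(Normal(mu_g, noiseSdExpr)) per gene, with planted group
## shifts applied on the log scale. Methylation: Normal noise on the
## M-value (logit) scale, mapped back through the inverse logit so betas
## stay inside (0,1); planted delta-beta effects are calibrated on the
## EXPECTED beta scale (the logit-normal mean, not logistic(m)).

# E[logistic(m + sd*Z)], Z ~ N(0,1); vectorised over m
.expectedBeta <- function(m, sd) {
  vapply(m, function(mi) {
    stats::integrate(function(z) stats::plogis(mi + sd * z) * stats::dnorm(z),
                     -Inf, Inf, rel.tol = 1e-10)$value
  }, numeric(1))
}

# Var(logistic(m + sd*Z))
.betaVariance <- function(m, sd) {
  e1 <- .expectedBeta(m, sd)
  e2 <- vapply(m, function(mi) {
    stats::integrate(function(z) stats::plogis(mi + sd * z)^2 * stats::dnorm(z),
                     -Inf, Inf, rel.tol = 1e-10)$value
  }, numeric(1))
  pmax(e2 - e1^2, 0)
}

# logit shift d such that E[beta | m0 + d] - E[beta | m0] = delta
.solveMShift <- function(m0, sd, delta) {
  base <- .expectedBeta(m0, sd)
  if (base + delta >= 1 - 1e-6)
    stop(sprintf(
      "infeasible delta beta: baseline expected beta %.3f cannot be shifted by %.3f",
      base, delta))
  f <- function(d) .expectedBeta(m0 + d, sd) - base - delta
  stats::uniroot(f, lower = 0, upper = 40, tol = 1e-9)$root
}

#' Simulate a matched expression + methylation cohort
#'
#' Generates the three-group cohort structure the risk-gene pipeline
#' assumes: shared ("risk") expression and methylation effects planted with
#' the same sign and magnitude in the high-risk and patient groups,
#' group-specific expression effects, gene/probe pairs with coupled
#' expression and methylation, and group-structured family-environment
#' covariates. A ground-truth table records every planted feature for
#' recovery testing. All randomness flows from `config@seed`; the same
#' configuration yields bitwise-identical output.
#'
#' @param config A [SimConfig-class].
#' @return An [OmicsCohort-class] whose [truthTable()] holds the planted
#'   classes (`null`, `risk_expr`, `offspring_only`, `patient_only`,
#'   `coupled` on the expression layer; `null`, `risk_meth`, `coupled` on
#'   the methylation layer) and effect sizes.
#' @export
#' @examples
#' cohort <- simulateCohort(simConfig(nGenes = 200, nProbes = 200, seed = 7))
#' cohort
simulateCohort <- function(config) {
  stopifnot(is(config, "SimConfig"))
  validObject(config)
  if (exists(".Random.seed", envir = globalenv())) {
    oldSeed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", oldSeed, envir = globalenv()), add = TRUE)
  }
  set.seed(config@seed)

  n <- config@nPerGroup
  groups <- rep(cohortGroups(), each = n)
  sampleIds <- sprintf("S%02d", seq_along(groups))
  isHR <- groups == "high_risk"
  isPT <- groups == "patient"

  ## ---- gene classes ----
  nG <- config@nGenes
  geneIds <- sprintf("G%05d", seq_len(nG))
  geneClass <- rep("null", nG)
  idx <- 0L
  take <- function(k) {
    out <- idx + seq_len(k); idx <<- idx + k; out
  }
  iRisk <- take(config@nRiskExpr)
  iOff <- take(config@nOffspringOnly)
  iPat <- take(config@nPatientOnly)
  iCoup <- take(config@nCoupled)
  iMeth <- take(config@nRiskMeth)   # genes hosting planted probes (null expression)
  geneClass[iRisk] <- "risk_expr"
  geneClass[iOff] <- "offspring_only"
  geneClass[iPat] <- "patient_only"
  geneClass[iCoup] <- "coupled"

  ## ---- probes: one per methylation-planted gene, one per coupled gene,
  ##      remaining probes unannotated ----
  nP <- config@nProbes
  probeIds <- sprintf("cg%08d", seq_len(nP))
  probeClass <- rep("null", nP)
  pMeth <- seq_len(config@nRiskMeth)
  pCoup <- config@nRiskMeth + seq_len(config@nCoupled)
  probeClass[pMeth] <- "risk_meth"
  probeClass[pCoup] <- "coupled"
  probeGene <- rep("", nP)
  probeGene[pMeth] <- geneIds[iMeth]
  probeGene[pCoup] <- geneIds[iCoup]

  ## ---- methylation layer (M-value scale) ----
  sdM <- config@noiseSdMvalue
  baseBeta <- stats::runif(nP, 0.05, 0.95)
  baseBeta[pMeth] <- stats::runif(length(pMeth), 0.15, 0.35)
  baseBeta[pCoup] <- stats::runif(length(pCoup), 0.30, 0.70)
  m0 <- stats::qlogis(baseBeta)
  M <- matrix(m0, nP, length(sampleIds))
  shift <- numeric(nP)
  if (length(pMeth)) {
    shift[pMeth] <- vapply(m0[pMeth], .solveMShift, numeric(1),
                           sd = sdM, delta = config@deltaBetaEffect)
    M[pMeth, isHR | isPT] <- M[pMeth, isHR | isPT] + shift[pMeth]
  }
  M <- M + matrix(stats::rnorm(nP * length(sampleIds), 0, sdM),
                  nP, length(sampleIds))
  beta <- stats::plogis(M)
  dimnames(beta) <- list(probeIds, sampleIds)

  ## ---- expression layer (log-signal scale) ----
  sdE <- config@noiseSdExpr
  mu <- stats::rnorm(nG, 6, 1)
  L <- matrix(mu, nG, length(sampleIds))
  L[iRisk, isHR | isPT] <- L[iRisk, isHR | isPT] - config@exprEffect
  L[iOff, isHR] <- L[iOff, isHR] - config@exprEffect
  L[iPat, isPT] <- L[iPat, isPT] - config@exprEffect
  L <- L + matrix(stats::rnorm(nG * length(sampleIds), 0, sdE),
                  nG, length(sampleIds))

  ## coupled genes: log-expression is a linear function of the probe's beta,
  ## residual SD solved from the logit-normal beta SD so the population
  ## Pearson correlation has magnitude couplingR (negative slope: the
  ## canonical repressive direction of promoter methylation)
  slope <- -4
  coupleSigma <- numeric(length(iCoup))
  if (length(iCoup)) {
    sdBeta <- sqrt(.betaVariance(m0[pCoup], sdM))
    eBeta <- .expectedBeta(m0[pCoup], sdM)
    coupleSigma <- abs(slope) * sdBeta *
      sqrt(1 / config@couplingR^2 - 1)
    for (j in seq_along(iCoup)) {
      a <- mu[iCoup[j]] - slope * eBeta[j]
      L[iCoup[j], ] <- a + slope * beta[pCoup[j], ] +
        stats::rnorm(length(sampleIds), 0, coupleSigma[j])
    }
  }
  expr <- exp(L)
  dimnames(expr) <- list(geneIds, sampleIds)

  ## ---- covariates ----
  samples <- data.frame(sample_id = sampleIds, group = groups,
                        stringsAsFactors = FALSE)
  for (cv in names(config@covariateModel)) {
    mod <- config@covariateModel[[cv]]
    samples[[cv]] <- stats::rnorm(length(groups), mod$mean[groups], mod$sd)
  }

  ## ---- annotation & truth ----
  annotation <- data.frame(
    probe_id = probeIds,
    genes = probeGene,
    chromosome = "chr1",
    position = seq_len(nP) * 1000L,
    stringsAsFactors = FALSE)

  geneEffect <- numeric(nG)
  geneEffect[c(iRisk, iOff, iPat)] <- -config@exprEffect
  geneEffect[iCoup] <- slope
  probeEffect <- numeric(nP)
  probeEffect[pMeth] <- config@deltaBetaEffect
  truth <- rbind(
    data.frame(feature_id = geneIds, layer = "expression",
               class = geneClass, effect = geneEffect,
               stringsAsFactors = FALSE),
    data.frame(feature_id = probeIds, layer = "methylation",
               class = probeClass, effect = probeEffect,
               stringsAsFactors = FALSE))

  OmicsCohort(expression = expr, methylation = beta, samples = samples,
              annotation = annotation, truth = truth)
}

#' Write a ground-truth table
#'
#' One row per feature; round-trip safe through [readTruth()].
#'
#' @param truth Truth `data.frame` (see [truthTable()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeTruth <- function(truth, path) writeResultTable(truth, path)

#' Read a ground-truth table written by [writeTruth()]
#'
#' @param path Path to the truth file.
#' @return `data.frame`.
#' @export
readTruth <- function(path) readResultTable(path)
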