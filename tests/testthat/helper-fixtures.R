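# Shared fixtures, memoised so expensive simulations run once per suite.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (is.null(.fixtures[[name]])) assign(name, force(expr), envir = .fixtures)
  .fixtures[[name]]
}

# default-conditions cohort used across modules
refCohort <- function() {
  fixture("refCohort", generateCohort(simulationConfig(seed = 11)))
}

# zero-perturbation, zero-score-noise cohort (closed-loop checks)
cleanCohort <- function() {
  fixture("cleanCohort", generateCohort(simulationConfig(
    seed = 5, centeringShiftSd = 0, scalingMultRange = c(1, 1),
    scoreNoiseSd = 0)))
}

# default-perturbation, zero-score-noise cohort (factor recovery)
recoveryCohort <- function() {
  fixture("recoveryCohort",
          generateCohort(simulationConfig(seed = 42, scoreNoiseSd = 0)))
}

# small strictly positive intensity matrix over the full panel union
makeRawMatrix <- function(n, seed = 1) {
  set.seed(seed)
  genes <- colnames(panelMatrix(refCohort()))
  m <- matrix(2^rnorm(n * length(genes), 8, 1.5), n,
              dimnames = list(sprintf("T%02d", seq_len(n)), genes))
  m
}

prosignaLogMatrix <- function(cohort) {
  normalizeHousekeeping(panelMatrix(cohort), loadPanel("prosigna"))
}

# validation-set performance of a Prosigna training result
prosignaValidation <- function(res, cohort, valIds) {
  pred <- applyTrained(res, cohort)
  est <- scores(pred)[valIds]
  truth <- trueScores(cohort, "ROR_PT")[valIds]
  c(mse = mean((est - truth)^2), r = stats::cor(est, truth))
}
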