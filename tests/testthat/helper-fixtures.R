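## Shared fixtures, built once per test run and memoized. All inputs are
## generated in code; nothing is read from disk.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  v <- .fixtures[[name]]
  if (is.null(v)) {
    v <- builder()
    .fixtures[[name]] <- v
  }
  v
}

## calibrated wall parameters (deterministic)
wallFixture <- function() fixture("wall", function() homeostaticCalibration())

## a sampled, calibrated profile shared across physics tests
profileFixture <- function() fixture("profile", function() {
  sampleInsultProfile(gridSpec(), grfKernel(), seed = 101L)
})

## small end-to-end dataset: 4 profiles x 3 mixture weights = 12 records
tinyDatasetFixture <- function() fixture("tiny_se", function() {
  generateTAADataset(n_profiles = 4L, combos = c(0, 0.3, 0.6),
                     base_seed = 11L, params = wallFixture(),
                     n_train = 9L)
})

## finite-difference gradient checker used by the operator tests
gradCheckWorst <- function(model, x, y, loss = "relative_l2",
                           n_probe = 4L, eps = 1e-6, seed = 99L) {
  ns <- asNamespace("TAAinvert")
  fw <- ns$modelForward(model, x, TRUE)
  lg <- ns$lossGrad(fw$y, y, loss)
  grads <- ns$modelBackward(model, fw$cache, lg$grad)
  worst <- 0
  set.seed(seed)
  for (nm in names(model@params)) {
    np <- length(model@params[[nm]])
    for (i in sample(np, min(n_probe, np))) {
      m2 <- model
      m2@params[[nm]][i] <- m2@params[[nm]][i] + eps
      lp <- ns$lossGrad(ns$modelForward(m2, x, FALSE)$y, y, loss)$loss
      m2@params[[nm]][i] <- m2@params[[nm]][i] - 2 * eps
      lm <- ns$lossGrad(ns$modelForward(m2, x, FALSE)$y, y, loss)$loss
      num <- (lp - lm) / (2 * eps)
      ana <- grads[[nm]][i]
      ## denominator floored at 1e-5: below that the central-difference
      ## truncation error itself dominates the comparison
      worst <- max(worst, abs(num - ana) / max(abs(num), abs(ana), 1e-5))
    }
  }
  worst
}
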