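test_that("relative L2 error matches its closed forms", {
  truth <- matrix(rnorm(25), 5, 5)
  expect_equal(relativeL2(truth, truth), 0)
  expect_equal(relativeL2(matrix(0, 5, 5), truth), 1)
  ## unit-norm perturbation of size eps gives exactly eps / ||truth||
  set.seed(1)
  pert <- matrix(rnorm(25), 5, 5)
  pert <- pert / sqrt(sum(pert^2))
  eps <- 0.037
  expect_equal(relativeL2(truth + eps * pert, truth),
               eps / sqrt(sum(truth^2)))
  expect_error(relativeL2(truth, matrix(0, 5, 5)), "zero norm")
})

test_that("relative L2 agrees with an independent double-loop summation", {
  set.seed(7)
  for (rep in 1:20) {
    pred <- matrix(rnorm(25), 5, 5)
    truth <- matrix(rnorm(25), 5, 5)
    num <- 0; den <- 0
    for (i in 1:5) for (j in 1:5) {
      num <- num + (pred[i, j] - truth[i, j])^2
      den <- den + truth[i, j]^2
    }
    expect_equal(relativeL2(pred, truth), sqrt(num) / sqrt(den),
                 tolerance = 1e-12)
  }
})

test_that("error maps are signed and norm-consistent", {
  truth <- matrix(rnorm(16), 4, 4)
  expect_equal(absoluteErrorMap(truth, truth), matrix(0, 4, 4))
  expect_equal(absoluteErrorMap(truth + 0.3, truth), matrix(0.3, 4, 4))
  pred <- truth + matrix(rnorm(16, sd = 0.1), 4, 4)
  emap <- absoluteErrorMap(pred, truth)
  ## Cauchy-Schwarz: mean |error| <= relL2 * ||truth|| / sqrt(N)
  expect_lte(mean(abs(emap)),
             relativeL2(pred, truth) * sqrt(sum(truth^2)) / sqrt(16) + 1e-12)
})

test_that("insult-filtered error restricts to the masked region", {
  profile <- matrix(c(1, 0.6, 0.5, 0.2, 0, 0, 0.4, 0.1, 0), 3, 3)
  truth <- matrix(1:9 / 10, 3, 3)
  pred <- truth + matrix(c(0.1, -0.2, 0.05, rep(0.5, 6)), 3, 3)
  ## hand computation over the three masked nodes (profile >= 0.5)
  manual <- sqrt(0.1^2 + 0.2^2 + 0.05^2) / sqrt(0.1^2 + 0.2^2 + 0.3^2)
  expect_equal(filteredError(pred, truth, profile), manual)
  expect_equal(filteredError(truth, truth, profile), 0)
  ## threshold 0 is the unfiltered error
  expect_equal(filteredError(pred, truth, profile, threshold = 0),
               relativeL2(pred, truth))
  expect_error(filteredError(pred, truth, matrix(0, 3, 3)), "empty")
})

test_that("condition comparison builds ratios and a ranking", {
  rep1 <- list(arch = "unet", channels = 1L, encoding = "grayscale",
               e_ce = 0.08, e_delta = 0.12, e_ce_filt = 0.07,
               e_delta_filt = 0.1)
  rep2 <- modifyList(rep1, list(channels = 2L, e_ce = 0.04, e_delta = 0.06))
  cmp <- suppressMessages(compareConditions(list(rep1, rep2)))
  expect_equal(cmp$ratios$ratio, 2)
  expect_equal(nrow(cmp$table), 2)
  ## identical reports in both conditions give unit ratios
  cmp1 <- suppressMessages(
    compareConditions(list(rep1, modifyList(rep1, list(channels = 2L)))))
  expect_equal(cmp1$ratios$ratio, 1)
  expect_error(suppressMessages(compareConditions(list(rep1))),
               "missing channel condition")
})
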