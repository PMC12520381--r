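test_that("dilatation normalizes by the mean end-row radius", {
  g <- gridSpec()
  r <- matrix(1, 41, 41)
  expect_equal(dilatationField(r, g), matrix(1, 41, 41))
  r2 <- r
  r2[20, 21] <- 2
  d <- dilatationField(r2, g)
  expect_equal(d[20, 21], 2)
  expect_equal(d[1, 1], 1)
  expect_error(dilatationField(matrix(0, 41, 41), g), "zero mean end radius")
})

test_that("distensibility is the fractional systolic-diastolic radius change", {
  r <- matrix(1, 3, 3)
  expect_equal(distensibilityField(r, r), matrix(0, 3, 3))
  expect_equal(distensibilityField(r * 1.05442, r)[1, 1], 0.05442)
  expect_error(distensibilityField(r * 0.9, r), "negative distensibility")
})

test_that("bilinear resampling is exact where it should be", {
  g <- gridSpec()
  co <- gridCoords(g)
  vals <- matrix(rnorm(41 * 41), 41, 41)
  ## source grid equals target grid: bitwise identity
  expect_identical(resampleToGrid(vals, co$theta, co$z, g), vals)
  ## constant field from a coarser source stays constant
  th_s <- 2 * pi * (0:19) / 20
  z_s <- seq(0, 1, length.out = 15)
  expect_equal(resampleToGrid(matrix(3.7, 20, 15), th_s, z_s, g),
               matrix(3.7, 41, 41))
  ## bilinear interpolation reproduces fields linear in z exactly
  lin <- outer(rep(1, 20), 2 * z_s - 0.5)
  got <- resampleToGrid(lin, th_s, z_s, g)
  expect_equal(got, outer(rep(1, 41), 2 * co$z - 0.5), tolerance = 1e-12)
  ## insufficient axial coverage is rejected
  expect_error(resampleToGrid(matrix(1, 20, 5), th_s,
                              seq(0.2, 0.8, length.out = 5), g),
               "coverage")
})

test_that("grayscale quantization follows the stated rounding and range rules", {
  expect_equal(as.vector(encodeGrayscale(matrix(c(0.9, 1.35, 1.8), 1),
                                         0.9, 1.8)),
               c(0L, 128L, 255L))
  expect_error(encodeGrayscale(matrix(1), 1, 1), "hi > lo")
  ## round-trip within half a quantization step for random values
  set.seed(3)
  x <- matrix(runif(1000, 0, 0.08), 50, 20)
  gmat <- encodeGrayscale(x, 0, 0.08)
  back <- decodeGrayscale(gmat, 0, 0.08)
  expect_lte(max(abs(back - x)), 0.08 / 510 + 1e-12)
  ## clipping is counted
  expect_equal(attr(encodeGrayscale(matrix(c(-1, 0.5), 1), 0, 1), "n_clipped"), 1)
})

test_that("train/test split is a seeded disjoint partition", {
  ids <- sprintf("r%03d", 1:500)
  sp <- splitDataset(ids, n_train = 450L, seed = 5L)
  expect_length(sp$train, 450L)
  expect_length(sp$test, 50L)
  expect_length(intersect(sp$train, sp$test), 0L)
  expect_setequal(c(sp$train, sp$test), ids)
  expect_identical(sp, splitDataset(ids, 450L, seed = 5L))
  expect_false(identical(sp$test, splitDataset(ids, 450L, seed = 6L)$test))
  expect_error(splitDataset(ids, 500L), "below")
})

test_that("the dataset container round-trips and rejects corrupted inputs", {
  se <- tinyDatasetFixture()
  path <- file.path(tempdir(), "tiny_taa.rds")
  writeTAADataset(se, path)
  back <- readTAADataset(path)
  expect_identical(SummarizedExperiment::assay(back, "theta_ce"),
                   SummarizedExperiment::assay(se, "theta_ce"))
  expect_identical(SummarizedExperiment::assay(back, "d_gray"),
                   SummarizedExperiment::assay(se, "d_gray"))
  expect_identical(SummarizedExperiment::colData(back),
                   SummarizedExperiment::colData(se))
  expect_true(file.exists(paste0(path, ".manifest.csv")))
  ## missing split column -> rejected
  bad <- se
  SummarizedExperiment::colData(bad)$split <- NULL
  saveRDS(bad, path)
  expect_error(readTAADataset(path), "split")
  ## grayscale assay corrupted to non-8-bit values -> rejected
  bad2 <- se
  SummarizedExperiment::assay(bad2, "d_gray")[1, 1] <- 300
  saveRDS(bad2, path)
  expect_error(readTAADataset(path), "8-bit|\\[0, 255\\]")
  expect_error(readTAADataset(file.path(tempdir(), "nope.rds")), "no such")
})

test_that("generated datasets satisfy the construction invariants", {
  se <- tinyDatasetFixture()
  cd <- SummarizedExperiment::colData(se)
  expect_equal(ncol(se), 4L * 3L)
  expect_equal(sum(cd$split == "train"), 9L)
  ## calibration closure: every record near the dilatation target
  expect_true(all(abs(cd$dmax - 1.5) <= 0.01))
  ## cap respect over all nodes and records
  expect_lte(max(SummarizedExperiment::assay(se, "theta_ce")), 0.48)
  expect_lte(max(SummarizedExperiment::assay(se, "theta_delta")), 0.28)
  ## distensibility suppression inside every lesion
  Dmin <- apply(SummarizedExperiment::assay(se, "D_heat"), 2, min)
  expect_true(all(Dmin < 0.05442))
  ## grayscale ranges are dataset-wide and recorded
  gr <- S4Vectors::metadata(se)$gray_ranges
  expect_equal(gr, defaultGrayRanges())
  ## determinism: regeneration reproduces ground truth bit-for-bit
  se2 <- generateTAADataset(n_profiles = 4L, combos = c(0, 0.3, 0.6),
                            base_seed = 11L, params = wallFixture(),
                            n_train = 9L)
  expect_identical(SummarizedExperiment::assay(se, "theta_ce"),
                   SummarizedExperiment::assay(se2, "theta_ce"))
  expect_identical(SummarizedExperiment::assay(se, "d_gray"),
                   SummarizedExperiment::assay(se2, "d_gray"))
})

test_that("operator data tensors expose maps but never the ground truth", {
  se <- tinyDatasetFixture()
  d2 <- operatorData(se, channels = 2L, encoding = "grayscale",
                     subset = "train")
  expect_equal(dim(d2$x), c(41, 41, 2, 9))
  expect_equal(dim(d2$y), c(41, 41, 2, 9))
  ## grayscale inputs rescaled to [0, 1]
  expect_gte(min(d2$x), 0)
  expect_lte(max(d2$x), 1)
  ## channel 1 is the dilatation map, not an insult field
  g <- S4Vectors::metadata(se)$grid
  tr_idx <- trainIndices(se)
  expect_equal(d2$x[, , 1, 1],
               mapMatrix(se, "d_gray", tr_idx[1]) / 255)
  d1 <- operatorData(se, channels = 1L, encoding = "heat", subset = "test")
  expect_equal(dim(d1$x)[3], 1L)
  expect_equal(d1$x[, , 1, 1], mapMatrix(se, "d_heat", testIndices(se)[1]))
})
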