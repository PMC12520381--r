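#' Generate the synthetic TAA map dataset
#'
#' Runs the full data-generation pipeline: sample spatially correlated
#' normalized insult profiles from the Gaussian random field, assign each
#' profile the configured mixture-weight combinations, calibrate each
#' combination's scale so the simulated lesion reaches the aneurysmal
#' maximum dilatation (default 1.5), simulate the equilibrated vessel, and
#' assemble dilatation/distensibility maps in heat and grayscale encodings
#' together with the ground-truth insult fields and a train/test split.
#' The result is a pure function of `(base_seed, configuration)`.
#'
#' @param n_profiles Number of unique spatial profiles (default 100).
#' @param combos Mixture weights, one record per profile per weight
#'   (default `c(0, 0.15, 0.30, 0.45, 0.60)`, spanning pure mechanosensing
#'   to the most elastic-fiber-dominated combination that can still reach
#'   the dilatation target under the wall model).
#' @param base_seed Integer base seed; per-profile seeds are derived from it.
#' @param params Calibrated \linkS4class{WallParams}; `NULL` runs
#'   [homeostaticCalibration()] with defaults.
#' @param grid A \linkS4class{GridSpec}.
#' @param kernel A \linkS4class{GRFKernel}.
#' @param target_dmax,tol Calibration target and tolerance for the
#'   per-record maximum dilatation.
#' @param t0 Profile support floor (see [normalizeProfile()]).
#' @param gray_ranges Dataset-wide grayscale ranges, see
#'   [defaultGrayRanges()].
#' @param n_train Training-set size; `NULL` takes 90% of the records
#'   (450 of the default 500).
#' @param max_resample Maximum profile resampling attempts on calibration
#'   failure before aborting.
#' @param verbose Print progress.
#' @return A \linkS4class{TAAMapExperiment}.
#' @export
generateTAADataset <- function(n_profiles = 100L,
                               combos = c(0, 0.15, 0.30, 0.45, 0.60),
                               base_seed = 1L, params = NULL,
                               grid = gridSpec(), kernel = grfKernel(),
                               target_dmax = 1.5, tol = 0.01, t0 = 0.3,
                               gray_ranges = defaultGrayRanges(),
                               n_train = NULL, max_resample = 10L,
                               verbose = FALSE) {
  stopifnot(n_profiles >= 1L, length(combos) >= 1L)
  if (is.null(params)) params <- homeostaticCalibration()
  fac <- grfFactor(grid, kernel)
  seed_pool <- matrix(deriveSeeds(base_seed, n_profiles * (max_resample + 1L)),
                      nrow = n_profiles)
  n_nodes <- grid@n_theta * grid@n_z
  n_rec <- n_profiles * length(combos)
  assay_names <- c("insult_profile", "theta_ce", "theta_delta",
                   "r_dia", "r_sys", "h", "sigma_tt", "sigma_zz",
                   "shear_analog", "d_heat", "D_heat", "d_gray", "D_gray")
  assays <- lapply(assay_names, function(a) matrix(0, n_nodes, n_rec))
  names(assays) <- assay_names
  cd <- data.frame(profile_id = character(n_rec), combo_id = character(n_rec),
                   w = numeric(n_rec), s = numeric(n_rec),
                   dmax = numeric(n_rec), seed = integer(n_rec),
                   stringsAsFactors = FALSE)
  rec <- 0L
  for (i in seq_len(n_profiles)) {
    profile <- NULL
    for (attempt in seq_len(max_resample + 1L)) {
      seed_i <- seed_pool[i, attempt]
      cand <- sampleInsultProfile(grid, kernel, seed_i, t0 = t0,
                                  profile_id = sprintf("p%03d", i),
                                  factor = fac)
      scales <- tryCatch(
        lapply(combos, function(w)
          calibrateScale(cand, w, params, grid,
                         target_dmax = target_dmax, tol = tol)),
        error = function(e) NULL)
      if (!is.null(scales)) { profile <- cand; break }
      if (verbose)
        message("profile ", i, ": calibration failed for seed ", seed_i,
                ", resampling with replacement seed ",
                seed_pool[i, min(attempt + 1L, max_resample + 1L)])
    }
    if (is.null(profile))
      stop("pipeline error: profile ", i, " failed calibration after ",
           max_resample, " resampling attempts")
    for (k in seq_along(combos)) {
      rec <- rec + 1L
      w <- combos[k]
      s <- as.numeric(scales[[k]])
      pair <- makeInsultPair(profile, w, s, combo_id = sprintf("c%d", k))
      vf <- simulateTAA(pair, params, grid)
      d <- dilatationField(vf@r_dia, grid)
      D <- distensibilityField(vf@r_sys, vf@r_dia)
      assays$insult_profile[, rec] <- as.vector(profile@field)
      assays$theta_ce[, rec] <- as.vector(pair@theta_ce)
      assays$theta_delta[, rec] <- as.vector(pair@theta_delta)
      assays$r_dia[, rec] <- as.vector(vf@r_dia)
      assays$r_sys[, rec] <- as.vector(vf@r_sys)
      assays$h[, rec] <- as.vector(vf@h)
      assays$sigma_tt[, rec] <- as.vector(vf@sigma_tt)
      assays$sigma_zz[, rec] <- as.vector(vf@sigma_zz)
      assays$shear_analog[, rec] <- as.vector(vf@shear_analog)
      assays$d_heat[, rec] <- as.vector(d)
      assays$D_heat[, rec] <- as.vector(D)
      assays$d_gray[, rec] <- as.vector(encodeGrayscale(d, gray_ranges$d[1],
                                                        gray_ranges$d[2]))
      assays$D_gray[, rec] <- as.vector(encodeGrayscale(D, gray_ranges$D[1],
                                                        gray_ranges$D[2]))
      cd$profile_id[rec] <- profile@profile_id
      cd$combo_id[rec] <- sprintf("c%d", k)
      cd$w[rec] <- w
      cd$s[rec] <- s
      cd$dmax[rec] <- attr(scales[[k]], "dmax")
      cd$seed[rec] <- profile@seed
    }
    if (verbose && i %% 10L == 0L) message("profile ", i, "/", n_profiles)
  }
  record_ids <- sprintf("%s_%s", cd$profile_id, cd$combo_id)
  if (is.null(n_train)) n_train <- as.integer(round(0.9 * n_rec))
  spl <- splitDataset(record_ids, n_train = n_train,
                      seed = deriveSeeds(base_seed + 1L, 1L))
  cd$split <- ifelse(record_ids %in% spl$train, "train", "test")
  co <- gridCoords(grid)
  rd <- S4Vectors::DataFrame(theta = as.vector(co$theta_grid),
                             z = as.vector(co$z_grid),
                             theta_hat = as.vector(co$theta_grid) / (2 * pi),
                             z_hat = as.vector(co$z_grid) / grid@L)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = assays,
    rowData = rd,
    colData = S4Vectors::DataFrame(cd, row.names = record_ids),
    metadata = list(grid = grid, kernel = kernel, params = params,
                    gray_ranges = gray_ranges, base_seed = base_seed,
                    target_dmax = target_dmax, tol = tol, t0 = t0,
                    combos = combos, split_seed = spl$seed))
  as(se, "TAAMapExperiment")
}

#' Train / test record indices of a dataset
#'
#' @param se A \linkS4class{TAAMapExperiment}.
#' @return Integer indices.
#' @export
trainIndices <- function(se) which(SummarizedExperiment::colData(se)$split == "train")

#' @rdname trainIndices
#' @export
testIndices <- function(se) which(SummarizedExperiment::colData(se)$split == "test")

#' Extract one record's map or field as a matrix
#'
#' @param se A \linkS4class{TAAMapExperiment}.
#' @param assay Assay name (e.g. `"d_heat"`, `"theta_ce"`).
#' @param record Record index or id.
#' @return Matrix (n_theta x n_z).
#' @export
mapMatrix <- function(se, assay, record) {
  g <- S4Vectors::metadata(se)$grid
  matrix(SummarizedExperiment::assay(se, assay)[, record], g@n_theta, g@n_z)
}

#' Persist / load a TAA map dataset
#'
#' The container (a \linkS4class{TAAMapExperiment}) is stored as a single
#' serialized R object; [readTAADataset()] validates the class, required
#' assays, split and grayscale integrity before returning, and rejects
#' corrupted containers. A plain-text CSV manifest of the records is written
#' alongside for inspection.
#'
#' @param se A \linkS4class{TAAMapExperiment}.
#' @param path File path (conventionally `.rds`).
#' @param manifest Write `<path>.manifest.csv` with per-record metadata.
#' @return `writeTAADataset`: `path`, invisibly. `readTAADataset`: the
#'   validated \linkS4class{TAAMapExperiment}.
#' @export
writeTAADataset <- function(se, path, manifest = TRUE) {
  stopifnot(is(se, "TAAMapExperiment"))
  validObject(se)
  saveRDS(se, path)
  if (manifest) {
    cd <- as.data.frame(SummarizedExperiment::colData(se))
    utils::write.csv(cbind(record_id = rownames(cd), cd),
                     paste0(path, ".manifest.csv"), row.names = FALSE)
  }
  invisible(path)
}

#' @rdname writeTAADataset
#' @export
readTAADataset <- function(path) {
  if (!file.exists(path)) stop("format error: no such dataset: ", path)
  obj <- readRDS(path)
  if (!is(obj, "TAAMapExperiment"))
    stop("format error: ", path, " does not hold a TAAMapExperiment")
  v <- validObject(obj, test = TRUE)
  if (!isTRUE(v)) stop("format error in ", path, ": ", paste(v, collapse = "; "))
  obj
}

#' Assemble network input/target arrays from a dataset
#'
#' Builds the arrays consumed by [trainOperator()] / [predictInsults()]:
#' inputs are the dilatation map (channel 1) and optionally the
#' distensibility map (channel 2) in the requested encoding, targets are the
#' two ground-truth insult fields. Grayscale inputs are rescaled to ``[0, 1]``
#' here (the network boundary); heat inputs stay physical. Ground-truth
#' insult fields are never part of the input tensor.
#'
#' @param se A \linkS4class{TAAMapExperiment}.
#' @param channels 1 (dilatation only) or 2 (dilatation + distensibility).
#' @param encoding `"grayscale"` or `"heat"`.
#' @param subset `"train"`, `"test"` or `"all"`.
#' @return List with `x` array `(n_theta, n_z, channels, n)`, `y` array
#'   `(n_theta, n_z, 2, n)`, `profile` array `(n_theta, n_z, n)` of the
#'   normalized insult templates (for filtered evaluation), record `ids`,
#'   and the per-record mixture weights `w`.
#' @export
operatorData <- function(se, channels = 2L, encoding = c("grayscale", "heat"),
                         subset = c("train", "test", "all")) {
  encoding <- match.arg(encoding)
  subset <- match.arg(subset)
  channels <- as.integer(channels)
  stopifnot(channels %in% c(1L, 2L))
  idx <- switch(subset, train = trainIndices(se), test = testIndices(se),
                all = seq_len(ncol(se)))
  g <- S4Vectors::metadata(se)$grid
  nt <- g@n_theta; nz <- g@n_z; n <- length(idx)
  getA <- function(a) SummarizedExperiment::assay(se, a)[, idx, drop = FALSE]
  if (encoding == "grayscale") {
    d <- getA("d_gray") / 255
    D <- getA("D_gray") / 255
  } else {
    d <- getA("d_heat")
    D <- getA("D_heat")
  }
  x <- array(0, c(nt, nz, channels, n))
  x[, , 1L, ] <- array(as.matrix(d), c(nt, nz, n))
  if (channels == 2L) x[, , 2L, ] <- array(as.matrix(D), c(nt, nz, n))
  y <- array(0, c(nt, nz, 2L, n))
  y[, , 1L, ] <- array(as.matrix(getA("theta_ce")), c(nt, nz, n))
  y[, , 2L, ] <- array(as.matrix(getA("theta_delta")), c(nt, nz, n))
  list(x = x, y = y,
       profile = array(as.matrix(getA("insult_profile")), c(nt, nz, n)),
       ids = colnames(se)[idx],
       w = SummarizedExperiment::colData(se)$w[idx],
       channels = channels, encoding = encoding)
}
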