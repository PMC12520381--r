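#' Gaussian-random-field kernel constructor
#'
#' Defaults (correlation length 1 radian circumferentially, a quarter of the
#' vessel length axially) yield single-lobe lesions after thresholding.
#'
#' @param variance Marginal variance (>= 0).
#' @param length_theta Circumferential correlation length in radians.
#' @param length_z Axial correlation length in z units.
#' @return A \linkS4class{GRFKernel}.
#' @export
grfKernel <- function(variance = 1, length_theta = 1.0, length_z = 0.25) {
  new("GRFKernel", variance = variance, length_theta = length_theta,
      length_z = length_z, family = "squared_exponential")
}

## Covariance factor (lower Cholesky) of the kernel on the grid, with
## escalating jitter. theta distance is chordal (2 sin(dtheta/2)) so the
## covariance is exactly periodic.
grfFactor <- function(grid, kernel, max_jitter = 1e-4) {
  co <- gridCoords(grid)
  th <- as.vector(co$theta_grid)
  zz <- as.vector(co$z_grid)
  dth <- outer(th, th, function(a, b) 2 * sin((a - b) / 2))
  dz <- outer(zz, zz, "-")
  K <- kernel@variance *
    exp(-(dth^2) / (2 * kernel@length_theta^2) - (dz^2) / (2 * kernel@length_z^2))
  jitter <- 1e-10
  repeat {
    L <- tryCatch(t(chol(K + diag(jitter, nrow(K)))), error = function(e) NULL)
    if (!is.null(L)) return(L)
    jitter <- jitter * 10
    if (jitter > max_jitter)
      stop("covariance factorization failed even at maximum jitter")
  }
}

#' Normalize a raw field into an insult profile
#'
#' Shift-and-scale the raw field so its minimum maps to 0 and its maximum to
#' 1. A floor threshold `t0` (fraction of the normalized range, default 0.3)
#' is then removed by the continuous rescale
#' `max(0, (x - t0)) / (1 - t0)`, which zeroes the far field while keeping
#' the profile continuous and its maximum exactly 1, producing a compact
#' localized lesion. Degenerate fields (range below `tol`) map to the zero
#' profile (no insult).
#'
#' @param raw Numeric matrix of finite values.
#' @param t0 Support floor as a fraction of the normalized range, in `[0, 1)`.
#' @param tol Degeneracy tolerance on the raw range.
#' @param z_taper Optional per-column (axial) window in `[0, 1]` applied
#'   after the min-max normalization and before the floor; used to make
#'   lesions vanish at the clamped vessel ends so the end rows stay
#'   non-aneurysmal (the dilatation normalization reference).
#' @param profile_id,seed Metadata stored on the result.
#' @return An \linkS4class{InsultProfile}.
#' @examples
#' normalizeProfile(matrix(c(0, 5, 10, 0), 2), t0 = 0)@field
#' @export
normalizeProfile <- function(raw, t0 = 0.3, tol = 1e-12, z_taper = NULL,
                             profile_id = "profile", seed = NA_integer_) {
  if (!all(is.finite(raw))) stop("raw field must be finite")
  if (t0 < 0 || t0 >= 1) stop("t0 must be in [0, 1)")
  rng <- range(raw)
  if (diff(rng) < tol) {
    f <- matrix(0, nrow(raw), ncol(raw))
  } else {
    f <- (raw - rng[1]) / diff(rng)
    if (!is.null(z_taper)) {
      stopifnot(length(z_taper) == ncol(f))
      f <- f * rep(z_taper, each = nrow(f))
      mx <- max(f)
      if (mx < tol) f[] <- 0 else f <- f / mx
    }
    if (t0 > 0 && max(f) > 0) f <- pmax(f - t0, 0) / (1 - t0)
  }
  new("InsultProfile", field = f, profile_id = as.character(profile_id),
      seed = as.integer(seed))
}

#' Sample a normalized insult profile from the Gaussian random field
#'
#' Draws a zero-mean Gaussian field with the kernel's covariance on the
#' periodic cylindrical grid (dense Cholesky factorization), then applies
#' [normalizeProfile()]. Deterministic given `(seed, grid, kernel)`.
#'
#' @param grid A \linkS4class{GridSpec}.
#' @param kernel A \linkS4class{GRFKernel}.
#' @param seed Integer seed.
#' @param t0 Support floor passed to [normalizeProfile()].
#' @param end_taper Apply the axial half-sine window `sin(pi * z/L)` so the
#'   lesion vanishes at the clamped vessel ends (default TRUE).
#' @param profile_id Identifier for the result.
#' @param factor Optional precomputed covariance factor (as produced
#'   internally); supply it when sampling many profiles on one grid/kernel to
#'   avoid refactorizing.
#' @return An \linkS4class{InsultProfile}.
#' @export
sampleInsultProfile <- function(grid, kernel, seed, t0 = 0.3,
                                end_taper = TRUE,
                                profile_id = paste0("p", seed), factor = NULL) {
  stopifnot(is(grid, "GridSpec"), is(kernel, "GRFKernel"))
  raw <- sampleGRF(grid, kernel, seed, factor = factor)
  taper <- if (end_taper) sin(pi * gridCoords(grid)$z_hat) else NULL
  normalizeProfile(raw, t0 = t0, z_taper = taper,
                   profile_id = profile_id, seed = seed)
}

#' Sample the raw (un-normalized) Gaussian random field
#'
#' @inheritParams sampleInsultProfile
#' @return Numeric matrix (n_theta x n_z) with the kernel's covariance.
#' @export
sampleGRF <- function(grid, kernel, seed, factor = NULL) {
  n <- grid@n_theta * grid@n_z
  if (kernel@variance == 0) return(matrix(0, grid@n_theta, grid@n_z))
  if (is.null(factor)) factor <- grfFactor(grid, kernel)
  z <- withSeed(seed, rnorm(n))
  matrix(factor %*% z, grid@n_theta, grid@n_z)
}

#' Combine a profile into the two-contributor insult pair
#'
#' @param profile An \linkS4class{InsultProfile}.
#' @param w Mixture weight in `[0, 1]`; 1 = pure elastic-fiber insult.
#' @param s Scale > 0; requires `s*w <= 1` and `s*(1-w) <= 1` so the caps
#'   (0.48 for elastic-fiber integrity, 0.28 for mechanosensing) are respected.
#' @param combo_id Identifier for the combination.
#' @return An \linkS4class{InsultPair}.
#' @examples
#' p <- normalizeProfile(matrix(c(0, 1), 1), t0 = 0)
#' makeInsultPair(p, w = 0.5, s = 1)
#' @export
makeInsultPair <- function(profile, w, s, combo_id = sprintf("w%g", w)) {
  stopifnot(is(profile, "InsultProfile"))
  if (w < 0 || w > 1) stop("mixture weight w must be in [0, 1]")
  if (s <= 0) stop("scale s must be positive")
  if (s * w > 1 + 1e-12 || s * (1 - w) > 1 + 1e-12)
    stop("cap violation: require s*w <= 1 and s*(1-w) <= 1")
  new("InsultPair",
      theta_ce = s * w * .CAP_CE * profile@field,
      theta_delta = s * (1 - w) * .CAP_DELTA * profile@field,
      w = w, s = s, profile_id = profile@profile_id,
      combo_id = as.character(combo_id))
}

#' Maximum admissible scale for a mixture weight
#'
#' The largest `s` for which both caps are respected: `1 / max(w, 1 - w)`.
#' @param w Mixture weight in `[0, 1]`.
#' @return Numeric scale.
#' @export
maxScale <- function(w) 1 / max(w, 1 - w)

#' Calibrate the insult scale to a target maximum dilatation
#'
#' Bisection on the scale `s` over `(0, s_max]` until the simulated
#' per-record maximum dilatation is within `tol` of `target_dmax`
#' (default 1.5, the aneurysmal threshold). Monotonicity of the maximum
#' dilatation in `s` is asserted during the search.
#'
#' @param profile An \linkS4class{InsultProfile}; must be non-degenerate.
#' @param w Mixture weight.
#' @param sim_params Calibrated \linkS4class{WallParams}.
#' @param grid A \linkS4class{GridSpec}.
#' @param target_dmax Target maximum dilatation (default 1.5).
#' @param tol Dilatation tolerance (default 0.01).
#' @param max_iter Bisection iteration cap.
#' @return The calibrated scale (numeric scalar), with attribute `"dmax"`.
#' @export
calibrateScale <- function(profile, w, sim_params, grid = gridSpec(),
                           target_dmax = 1.5, tol = 0.01, max_iter = 60L) {
  stopifnot(is(profile, "InsultProfile"), tol > 0)
  if (max(profile@field) == 0)
    stop("calibration error: zero insult profile '", profile@profile_id,
         "' cannot reach the dilatation target")
  s_max <- maxScale(w)
  ## diastolic-radius-only evaluation: identical per-node model as
  ## simulateTAA, skipping the systolic solve and stress diagnostics, and
  ## solving only inside the insult support (the far field is baseline)
  f <- profile@field
  idx <- which(f > 0)
  st0 <- solveEquilibratedNode(0, 0, sim_params)
  r0d <- as.numeric(pressurizeVessel(st0, sim_params@P_dia, sim_params))
  dmax_of <- function(s) {
    st <- solveEquilibratedNode(s * w * .CAP_CE * f[idx],
                                s * (1 - w) * .CAP_DELTA * f[idx], sim_params)
    r <- matrix(r0d, nrow(f), ncol(f))
    r[idx] <- pressurizeVessel(st, sim_params@P_dia, sim_params)
    max(dilatationField(smoothTheta(r, sim_params@smooth_width), grid))
  }
  d_hi <- dmax_of(s_max)
  if (d_hi < target_dmax - tol)
    stop("calibration error: profile '", profile@profile_id, "' (w=", w,
         ") reaches dmax=", signif(d_hi, 4), " < target ", target_dmax,
         " at the cap-saturating scale")
  lo <- 0; hi <- s_max; d_lo <- 1
  s <- s_max; d_s <- d_hi
  for (i in seq_len(max_iter)) {
    if (abs(d_s - target_dmax) <= tol) break
    if (d_s > target_dmax) { hi <- s; d_hi <- d_s } else { lo <- s; d_lo <- d_s }
    if (d_lo > d_hi + tol)
      stop("numerical error: dmax not monotone in scale within the bracket")
    s <- (lo + hi) / 2
    d_s <- dmax_of(s)
  }
  if (abs(d_s - target_dmax) > tol)
    stop("calibration error: bisection did not converge for profile '",
         profile@profile_id, "'")
  structure(s, dmax = d_s)
}
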