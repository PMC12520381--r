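#' Dilatation map from a diastolic radius field
#'
#' Local inner radius normalized by the average inner radius at the vessel
#' ends (the first and last `n_end_rows` axial node rows), evaluated at
#' diastolic pressure.
#'
#' @param r_dia Radius matrix (n_theta x n_z).
#' @param grid The \linkS4class{GridSpec}.
#' @param n_end_rows Axial rows at each end entering the normalization
#'   (default 1).
#' @return Dilatation matrix d.
#' @export
dilatationField <- function(r_dia, grid, n_end_rows = 1L) {
  stopifnot(n_end_rows >= 1L, ncol(r_dia) == grid@n_z)
  ends <- c(seq_len(n_end_rows), grid@n_z - seq_len(n_end_rows) + 1L)
  r_end <- mean(r_dia[, ends])
  if (!is.finite(r_end) || abs(r_end) < 1e-12)
    stop("data error: zero mean end radius")
  r_dia / r_end
}

#' Distensibility map
#'
#' Pointwise \eqn{\mathcal{D} = (r_S - r_D)/r_D}, the fractional radius
#' change between systolic and diastolic loading.
#'
#' @param r_sys,r_dia Radius matrices at systole / diastole.
#' @return Distensibility matrix.
#' @export
distensibilityField <- function(r_sys, r_dia) {
  stopifnot(all(dim(r_sys) == dim(r_dia)))
  if (any(r_dia <= 0)) stop("diastolic radius must be positive")
  D <- (r_sys - r_dia) / r_dia
  if (any(D < -1e-9))
    stop("simulation-consistency error: negative distensibility")
  D
}

#' Bilinear resampling onto the uniform grid
#'
#' Interpolates nodal values given on a (theta, z) product grid onto the
#' target \linkS4class{GridSpec}, with circumferential wrap-around. Exact
#' (bitwise) identity when the source already equals the target grid, and
#' exact on fields linear in z.
#'
#' @param values Source value matrix (length(theta) x length(z)).
#' @param theta Source circumferential node coordinates in ``[0, 2pi)``,
#'   increasing.
#' @param z Source axial node coordinates, increasing; must cover the target
#'   z range.
#' @param grid Target \linkS4class{GridSpec}.
#' @return Matrix (n_theta x n_z) on the target grid.
#' @export
resampleToGrid <- function(values, theta, z, grid) {
  stopifnot(nrow(values) == length(theta), ncol(values) == length(z))
  tc <- gridCoords(grid)
  if (min(z) > min(tc$z) + 1e-9 || max(z) < max(tc$z) - 1e-9)
    stop("data error: source axial coverage insufficient for the target grid")
  nt <- length(theta)
  ## theta: periodic lookup
  it_lo <- findInterval(tc$theta, theta)
  it_lo[it_lo == 0L] <- nt            # target below first node wraps to last
  it_hi <- it_lo %% nt + 1L
  th_lo <- theta[it_lo]
  span <- (theta[it_hi] - th_lo) %% (2 * pi)
  span[span == 0] <- 2 * pi
  wt <- ((tc$theta - th_lo) %% (2 * pi)) / span
  ## z: clamped linear lookup
  iz_lo <- pmin(pmax(findInterval(tc$z, z), 1L), length(z) - 1L)
  iz_hi <- iz_lo + 1L
  wz <- (tc$z - z[iz_lo]) / (z[iz_hi] - z[iz_lo])
  out <- matrix(0, grid@n_theta, grid@n_z)
  for (j in seq_len(grid@n_z)) {
    lo <- values[, iz_lo[j]] * (1 - wz[j]) + values[, iz_hi[j]] * wz[j]
    out[, j] <- lo[it_lo] * (1 - wt) + lo[it_hi] * wt
  }
  out
}

#' Encode a physical map as an 8-bit grayscale map
#'
#' Values are clipped to ``[lo, hi]`` and quantized with round-half-away-from-
#' zero to integers in ``[0, 255]``. One fixed global range is used per map
#' type across a whole dataset (defaults `c(0.9, 1.8)` for dilatation,
#' `c(0, 0.08)` for distensibility) so intensities are comparable between
#' records.
#'
#' @param field Numeric matrix.
#' @param lo,hi Range; `hi > lo`.
#' @return Integer matrix in ``[0, 255]`` with attribute `"n_clipped"`.
#' @examples
#' encodeGrayscale(matrix(c(0.9, 1.35, 1.8), 1), 0.9, 1.8)  # 0 128 255
#' @export
encodeGrayscale <- function(field, lo, hi) {
  if (hi <= lo) stop("parameter error: need hi > lo")
  n_clipped <- sum(field < lo | field > hi)
  x <- pmin(pmax(field, lo), hi)
  u <- (x - lo) / (hi - lo) * 255
  g <- floor(u + 0.5)    # round half away from zero (u >= 0)
  storage.mode(g) <- "integer"
  structure(g, n_clipped = n_clipped)
}

#' Decode an 8-bit grayscale map back to physical values
#'
#' @param g Integer matrix in ``[0, 255]``.
#' @param lo,hi The range used at encoding time.
#' @return Numeric matrix; within half a quantization step of the clipped
#'   original.
#' @export
decodeGrayscale <- function(g, lo, hi) {
  if (hi <= lo) stop("parameter error: need hi > lo")
  lo + (unclass(g) / 255) * (hi - lo)
}

#' Default dataset-wide grayscale ranges
#' @return Named list with `d` and `D` ranges.
#' @export
defaultGrayRanges <- function() list(d = c(0.9, 1.8), D = c(0, 0.08))

#' Random train/test split of record ids
#'
#' @param record_ids Character or integer vector of ids.
#' @param n_train Training-set size (default 450).
#' @param seed Integer seed.
#' @return List with `train` and `test` id vectors (disjoint, exhaustive).
#' @export
splitDataset <- function(record_ids, n_train = 450L, seed = 1L) {
  n <- length(record_ids)
  if (n_train >= n) stop("n_train must be below the number of records")
  perm <- withSeed(seed, sample(record_ids))
  list(train = sort(perm[seq_len(n_train)]),
       test = sort(perm[(n_train + 1L):n]), seed = as.integer(seed))
}
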