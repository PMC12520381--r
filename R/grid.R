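#' Construct a cylindrical sampling grid
#'
#' @param n_theta,n_z Node counts (default 41 x 41).
#' @param L Nondimensional axial length (default 1).
#' @return A \linkS4class{GridSpec}.
#' @examples
#' g <- gridSpec()
#' head(gridCoords(g)$theta)
#' @export
gridSpec <- function(n_theta = 41L, n_z = 41L, L = 1) {
  new("GridSpec", n_theta = as.integer(n_theta), n_z = as.integer(n_z), L = L)
}

#' Node coordinates of a grid
#'
#' theta nodes are uniform on the periodic circle, so the last node is one
#' spacing short of 2*pi; z nodes span `[0, L]` inclusively. Normalized
#' coordinates map both axes to `[0, 1]` (theta by theta/2pi, z by z/L).
#'
#' @param grid A \linkS4class{GridSpec}.
#' @return List with vectors `theta`, `z`, `theta_hat`, `z_hat` and the
#'   full-grid matrices `theta_grid`, `z_grid` (n_theta x n_z).
#' @export
gridCoords <- function(grid) {
  stopifnot(is(grid, "GridSpec"))
  theta <- 2 * pi * (seq_len(grid@n_theta) - 1L) / grid@n_theta
  z <- grid@L * (seq_len(grid@n_z) - 1L) / (grid@n_z - 1L)
  list(theta = theta, z = z,
       theta_hat = theta / (2 * pi), z_hat = z / grid@L,
       theta_grid = matrix(theta, grid@n_theta, grid@n_z),
       z_grid = matrix(z, grid@n_theta, grid@n_z, byrow = TRUE))
}

## run expr under a temporary RNG state seeded with `seed`; restores
## the caller's stream afterwards
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive reproducible child seeds from a base seed
#'
#' @param base_seed Integer base seed.
#' @param n Number of child seeds.
#' @return Integer vector of `n` seeds in ``[1, 2^31 - 2]``.
#' @export
deriveSeeds <- function(base_seed, n) {
  withSeed(base_seed, sample.int(2147483646L, n))
}
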