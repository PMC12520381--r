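## Reduced mechanobiologically-equilibrated growth-and-remodeling (G&R)
## membrane model. Each grid node is an independent thin-walled Laplace
## membrane made of elastin (deposited once, prestretched) plus a turnover
## pool (collagen + smooth muscle) deposited at stress s_h. Long-term G&R
## equilibrium at pressure P_gr determines the grown stretch lambda and the
## areal mass; an elastic (cardiac-cycle) solve about that state gives the
## loaded radii at diastole and systole.

## vectorized bisection; f must change sign on `[lo, hi]` elementwise
vbisect <- function(f, lo, hi, iters = 60L, context = "root solve") {
  flo <- f(lo)
  fhi <- f(hi)
  bad <- which(sign(flo) == sign(fhi) & flo != 0)
  if (length(bad))
    stop("simulation error: no sign change in bracket during ", context,
         " at node(s) ", paste(utils::head(bad, 5L), collapse = ", "))
  for (i in seq_len(iters)) {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    takelo <- sign(fm) == sign(flo)
    lo <- ifelse(takelo, mid, lo)
    flo <- ifelse(takelo, fm, flo)
    hi <- ifelse(takelo, hi, mid)
  }
  (lo + hi) / 2
}

#' Sensed intramural stress deviation under a mechanosensing defect
#'
#' Cells regulate wall turnover against the deviation
#' \eqn{\Delta\sigma = ((1-\delta)\,\sigma/\sigma_o) - 1}; a defect
#' \eqn{\delta > 0} scales down the sensed stress so elevated stress is
#' (erroneously) read as homeostatic.
#'
#' @param sigma Scalar stress measure (any consistent units).
#' @param sigma0 Homeostatic set-point (> 0).
#' @param delta Mechanosensing defect in ``[0, 1)``.
#' @return Dimensionless deviation (vectorized).
#' @examples
#' sensedStressDeviation(1.2, 1, 0)     # 0.2
#' sensedStressDeviation(1, 1, 0.28)    # -0.28
#' @export
sensedStressDeviation <- function(sigma, sigma0, delta) {
  if (any(sigma0 <= 0)) stop("sigma0 must be positive")
  if (any(delta < 0 | delta >= 1))
    stop("parameter error: delta must be in [0, 1) (total loss of sensing is unsolvable)")
  (1 - delta) * sigma / sigma0 - 1
}

#' Stress at which a defective sensor is satisfied
#'
#' Setting the sensed deviation to zero gives the erroneous equilibrium
#' target \eqn{\sigma^* = \sigma_o/(1-\delta)}.
#'
#' @inheritParams sensedStressDeviation
#' @return Target stress (vectorized).
#' @export
equilibriumTargetStress <- function(sigma0, delta) {
  if (any(delta < 0 | delta >= 1))
    stop("parameter error: delta must be in [0, 1)")
  sigma0 / (1 - delta)
}

#' Elastin fiber stress
#'
#' Neo-Hookean-type membrane fiber stress
#' \eqn{c_e((G_e\lambda)^2 - (G_e\lambda)^{-2})}: zero at the unloaded
#' natural configuration \eqn{G_e\lambda = 1} and strictly increasing.
#'
#' @param lam_total Total elastin-referential stretch \eqn{\lambda} (> 0);
#'   the deposition prestretch `G_e` multiplies it internally.
#' @param params A \linkS4class{WallParams}.
#' @return Fiber stress (vectorized).
#' @export
elastinStress <- function(lam_total, params) {
  if (any(lam_total <= 0)) stop("stretch must be positive")
  g <- params@G_e * lam_total
  params@c_e * (g^2 - g^-2)
}

#' Collagen/turnover-pool elastic stress about the deposition state
#'
#' Exponentially stiffening fiber stress
#' \eqn{s_h\,\lambda_{rel}^2\exp(k(\lambda_{rel}^2-1))} in terms of the
#' stretch relative to deposition; equals the deposition stress `s_h` at
#' \eqn{\lambda_{rel}=1} and is strictly increasing.
#'
#' @param lam_rel Stretch relative to the deposition configuration (> 0).
#' @param params A \linkS4class{WallParams}.
#' @param k Stiffening exponent; defaults to `params@k_c`. Pass the
#'   turnover-stiffened local exponent for lesion tissue.
#' @return Fiber stress (vectorized).
#' @export
collagenElasticStress <- function(lam_rel, params, k = params@k_c) {
  if (any(lam_rel <= 0)) stop("stretch must be positive")
  params@s_h * lam_rel^2 * exp(k * (lam_rel^2 - 1))
}

#' Solve the equilibrated growth-and-remodeling state at one node
#'
#' Finds the grown circumferential stretch \eqn{\lambda} at which the mixture
#' carries the (defect-shifted) target stress \eqn{\sigma^* = \sigma_o/(1-\vartheta_\delta)}
#' under thin-wall Laplace equilibrium at `P_gr`. With
#' \eqn{M(\lambda) = P_{gr}\lambda r_0\rho/\sigma^*} (total areal mass),
#' \eqn{\phi_e = m_e/M} and \eqn{\eta = 1-\vartheta_{ce}}, the residual is
#' \deqn{R(\lambda) = \phi_e\,\eta\,\sigma_e(\lambda) + (1-\phi_e)\,s_h - \sigma^*,}
#' solved by bisection on \eqn{\lambda \in `[0.5, 4]`}. At zero insult the
#' baseline \eqn{\lambda = 1} is recovered by construction of the
#' homeostatic identity.
#'
#' @param theta_ce Elastic-fiber integrity defect(s) in ``[0, 1)``.
#' @param theta_delta Mechanosensing defect(s) in ``[0, 1)``.
#' @param params A \linkS4class{WallParams}.
#' @return List with vectors `lam` (grown stretch), `m_plus` (turnover areal
#'   mass), `h` (thickness), plus internals `M`, `phi_e`, `eta`,
#'   `sigma_star`, `zeta` (turnover mass ratio used for cardiac-cycle
#'   stiffening).
#' @export
solveEquilibratedNode <- function(theta_ce, theta_delta, params) {
  if (any(theta_ce < 0 | theta_ce >= 1) || any(theta_delta < 0 | theta_delta >= 1))
    stop("parameter error: insult defects must be in [0, 1)")
  n <- max(length(theta_ce), length(theta_delta))
  theta_ce <- rep_len(theta_ce, n)
  theta_delta <- rep_len(theta_delta, n)
  eta <- 1 - theta_ce
  sigma_star <- equilibriumTargetStress(params@sigma0, theta_delta)
  Mof <- function(lam) params@P_gr * lam * params@r0 * params@rho / sigma_star
  R <- function(lam) {
    M <- Mof(lam)
    phi_e <- params@m_e / M
    phi_e * eta * elastinStress(lam, params) + (1 - phi_e) * params@s_h - sigma_star
  }
  lam <- vbisect(R, rep(0.5, n), rep(4, n), context = "equilibrated G&R solve")
  M <- Mof(lam)
  phi_e <- params@m_e / M
  if (any(phi_e <= 0 | phi_e >= 1))
    stop("model-consistency error: elastin mass fraction outside (0, 1) at the root")
  m_plus0 <- params@h0 * params@rho - params@m_e
  list(lam = lam, m_plus = M - params@m_e, h = M / params@rho,
       M = M, phi_e = phi_e, eta = eta, sigma_star = sigma_star,
       zeta = (M - params@m_e) / m_plus0)
}

#' Elastic (cardiac-cycle) pressurization about the grown state
#'
#' Solves for the elastic stretch \eqn{\lambda'} about the equilibrated state
#' from the membrane balance
#' \deqn{P\,(\lambda\lambda' r_0)/(h/\lambda') =
#'   \phi_e\,\eta\,\sigma_e(\lambda\lambda') + (1-\phi_e)\,\sigma_c(\lambda'),}
#' where incompressibility thins the membrane by \eqn{1/\lambda'} and the
#' turnover pool responds with the locally stiffened exponent
#' `k_c * zeta^q_turn` (remodeled lesion collagen is stiffer). At
#' `P = P_gr` the grown state (\eqn{\lambda' = 1}) is recovered.
#'
#' @param state Node state list from [solveEquilibratedNode()].
#' @param P Transmural pressure (> 0).
#' @param params A \linkS4class{WallParams}.
#' @return Vector of loaded inner radii \eqn{r = \lambda\lambda' r_0}, with
#'   attribute `"lam_el"` holding \eqn{\lambda'}.
#' @export
pressurizeVessel <- function(state, P, params) {
  if (P <= 0) stop("pressure must be positive")
  n <- length(state$lam)
  k_loc <- params@k_c * pmax(state$zeta, 1e-8)^params@q_turn
  g <- function(lp) {
    state$phi_e * state$eta * elastinStress(state$lam * lp, params) +
      (1 - state$phi_e) * collagenElasticStress(lp, params, k = k_loc) -
      P * state$lam * lp^2 * params@r0 * params@rho / state$M
  }
  lp <- vbisect(g, rep(0.25, n), rep(2.5, n), context = "elastic pressurization")
  structure(state$lam * lp * params@r0, lam_el = lp)
}

## circular moving average along theta (rows), width must be odd
smoothTheta <- function(x, width) {
  if (width <= 1) return(x)
  stopifnot(width %% 2 == 1)
  half <- (width - 1) / 2
  n <- nrow(x)
  out <- x
  for (k in seq_len(half)) {
    out <- out + x[c((k + 1):n, 1:k), , drop = FALSE] +
      x[c((n - k + 1):n, 1:(n - k)), , drop = FALSE]
  }
  out / width
}

#' @describeIn simulateTAA Per-node equilibrated solve at `P_gr`, elastic
#'   pressurization at `P_dia` and `P_sys`, optional circumferential
#'   smoothing of the radius fields (membrane continuity), and systolic
#'   stress diagnostics
#'   \eqn{\sigma_{\theta\theta} = P_{sys} r_{sys}/h'},
#'   \eqn{\sigma_{zz} = P_{sys} r_{sys}/(2h') + \sigma_{ax}^0 M/M_0}, and
#'   the intramural shear analog \eqn{(\sigma_{\theta\theta}-\sigma_{zz})/2}.
setMethod("simulateTAA", signature(pair = "InsultPair", params = "WallParams",
                                   grid = "GridSpec"),
  function(pair, params, grid) {
    dm <- c(grid@n_theta, grid@n_z)
    if (!all(dim(pair@theta_ce) == dm))
      stop("insult pair does not live on the supplied grid")
    st <- solveEquilibratedNode(as.vector(pair@theta_ce),
                                as.vector(pair@theta_delta), params)
    r_dia <- pressurizeVessel(st, params@P_dia, params)
    r_sys <- pressurizeVessel(st, params@P_sys, params)
    lp_sys <- attr(r_sys, "lam_el")
    h_sys <- (st$M / params@rho) / lp_sys
    sigma_tt <- params@P_sys * as.vector(r_sys) / h_sys
    M0 <- params@h0 * params@rho
    sigma_zz <- params@P_sys * as.vector(r_sys) / (2 * h_sys) +
      params@sigma_ax0 * st$M / M0
    mat <- function(v) matrix(v, dm[1], dm[2])
    r_dia_m <- smoothTheta(mat(r_dia), params@smooth_width)
    r_sys_m <- smoothTheta(mat(r_sys), params@smooth_width)
    new("VesselFields",
        lam = mat(st$lam), m_plus = mat(st$m_plus), h = mat(st$h),
        r_dia = r_dia_m, r_sys = r_sys_m,
        sigma_tt = mat(sigma_tt), sigma_zz = mat(sigma_zz),
        shear_analog = mat((sigma_tt - sigma_zz) / 2))
  })

## Template wall parameters before homeostatic calibration. ce_t fixes the
## baseline elastin load share (default 0.15: large enough that damaging
## elastic fibers stiffens the cardiac-cycle response, small enough that a
## pure mechanosensing insult can still reach aneurysmal dilatation at its
## cap); kc_t is the collagen stiffening exponent the calibration scales.
wallTemplate <- function(phi_e0 = 0.45, h0 = 0.1, G_e = 1.4,
                         P_sys = 120, P_dia = 80, elastin_share = 0.15,
                         kc_t = 4.7, q_turn = 2.5, sigma_ax_frac = 0.2,
                         smooth_width = 3) {
  sigma0 <- P_sys * 1 / h0
  c1 <- G_e^2 - G_e^-2
  list(phi_e0 = phi_e0, h0 = h0, G_e = G_e, P_sys = P_sys, P_dia = P_dia,
       ce_t = elastin_share * sigma0 / (phi_e0 * c1), kc_t = kc_t,
       q_turn = q_turn, sigma_ax_frac = sigma_ax_frac,
       smooth_width = smooth_width)
}

## Build a WallParams from a template and a stiffness scaling kappa,
## re-deriving sigma0 (Laplace at baseline) and s_h (homeostatic identity).
buildWallParams <- function(kappa, tpl) {
  sigma0 <- tpl$P_sys * 1 / tpl$h0
  c_e <- kappa * tpl$ce_t
  k_c <- kappa * tpl$kc_t
  se1 <- c_e * (tpl$G_e^2 - tpl$G_e^-2)
  s_h <- (sigma0 - tpl$phi_e0 * se1) / (1 - tpl$phi_e0)
  new("WallParams", r0 = 1, rho = 1, h0 = tpl$h0, phi_e0 = tpl$phi_e0,
      m_e = tpl$phi_e0 * tpl$h0, G_e = tpl$G_e, c_e = c_e, k_c = k_c,
      s_h = s_h, sigma0 = sigma0, sigma_ax0 = tpl$sigma_ax_frac * sigma0,
      q_turn = tpl$q_turn, P_dia = tpl$P_dia, P_sys = tpl$P_sys,
      P_gr = tpl$P_sys, smooth_width = tpl$smooth_width)
}

## Baseline distensibility of the zero-insult vessel (uniform, so one node)
baselineDistensibility <- function(params) {
  st <- solveEquilibratedNode(0, 0, params)
  r_d <- pressurizeVessel(st, params@P_dia, params)
  r_s <- pressurizeVessel(st, params@P_sys, params)
  as.numeric((r_s - r_d) / r_d)
}

#' Calibrate wall parameters to the baseline distensibility
#'
#' One-dimensional root-find on a global stiffness scaling `kappa` (applied
#' jointly to the elastin coefficient `c_e` and collagen exponent `k_c` of
#' the template) so that the zero-insult vessel's distensibility
#' \eqn{(r_S - r_D)/r_D} between `P_dia` and `P_sys` equals `target_D`
#' (default 0.05442). The set-point `sigma0` and deposition stress `s_h`
#' are re-derived at each trial so the homeostatic identity holds exactly at
#' \eqn{\lambda = 1}. Deterministic and idempotent.
#'
#' @param target_D Baseline distensibility target, in (0, 0.2).
#' @param template Template list from the internal defaults; override
#'   entries via `...`.
#' @param tol Tolerance on the achieved distensibility (default 1e-5).
#' @param ... Passed to the template constructor (e.g. `P_sys`, `phi_e0`).
#' @return A calibrated \linkS4class{WallParams} with attribute
#'   `"kappa"`.
#' @examples
#' wp <- homeostaticCalibration()
#' wp
#' @export
homeostaticCalibration <- function(target_D = 0.05442, template = NULL,
                                   tol = 1e-5, ...) {
  if (target_D <= 0 || target_D >= 0.2)
    stop("target baseline distensibility must be in (0, 0.2)")
  tpl <- if (is.null(template)) wallTemplate(...) else template
  f <- function(k) baselineDistensibility(buildWallParams(k, tpl)) - target_D
  ## kappa upper bound: s_h must stay above sigma0
  k_hi <- 0.98 * (1 - (1 - tpl$phi_e0)) /
    (tpl$phi_e0 * tpl$ce_t * (tpl$G_e^2 - tpl$G_e^-2) / (tpl$P_sys / tpl$h0))
  k_lo <- 0.05
  if (f(k_lo) * f(k_hi) > 0)
    stop("calibration error: distensibility target unreachable in the ",
         "stiffness-scaling bracket")
  kappa <- stats::uniroot(f, c(k_lo, k_hi), tol = 1e-12)$root
  params <- buildWallParams(kappa, tpl)
  achieved <- baselineDistensibility(params)
  if (abs(achieved - target_D) > tol)
    stop("calibration error: achieved baseline distensibility ", achieved,
         " misses the target by more than ", tol)
  structure(params, kappa = kappa)
}
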