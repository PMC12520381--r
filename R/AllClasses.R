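#' @import methods
#' @importFrom stats rnorm runif
NULL

#' Cylindrical sampling grid for the aortic domain
#'
#' The aortic segment is modeled as a thin-walled cylinder, unrolled to a
#' rectangular \eqn{(\theta, z)} domain sampled on a uniform grid. The
#' circumferential coordinate \eqn{\theta \in [0, 2\pi)} is periodic; the
#' axial coordinate \eqn{z \in `[0, L]`} is not. Normalized coordinates
#' \eqn{\{\hat\theta, \hat z\} \in `[0,1]`^2} are used by the operator trunks.
#'
#' @slot n_theta Integer, number of circumferential nodes (default 41).
#' @slot n_z Integer, number of axial nodes (default 41).
#' @slot L Numeric, nondimensional axial length (default 1).
#' @export
setClass("GridSpec",
  representation(n_theta = "integer", n_z = "integer", L = "numeric"),
  prototype(n_theta = 41L, n_z = 41L, L = 1)
)

setValidity("GridSpec", function(object) {
  if (object@n_theta < 4L || object@n_z < 2L)
    return("grid must have at least 4 circumferential and 2 axial nodes")
  if (object@L <= 0) return("axial length L must be positive")
  TRUE
})

#' Gaussian-random-field kernel on the cylindrical domain
#'
#' Squared-exponential covariance with chordal distance in the periodic
#' circumferential direction, so that cov(theta, theta + 2*pi) equals
#' cov(theta, theta) exactly.
#'
#' @slot variance Non-negative marginal variance.
#' @slot length_theta Circumferential correlation length (radians).
#' @slot length_z Axial correlation length (units of z).
#' @slot family Kernel family tag; only "squared_exponential" is implemented.
#' @export
setClass("GRFKernel",
  representation(variance = "numeric", length_theta = "numeric",
                 length_z = "numeric", family = "character"),
  prototype(variance = 1, length_theta = 1.0, length_z = 0.25,
            family = "squared_exponential")
)

setValidity("GRFKernel", function(object) {
  if (object@variance < 0) return("variance must be >= 0")
  if (object@length_theta <= 0 || object@length_z <= 0)
    return("correlation lengths must be positive")
  if (!identical(object@family, "squared_exponential"))
    return("unknown kernel family")
  TRUE
})

#' Normalized insult severity profile
#'
#' The spatial template \eqn{\vartheta^*(\theta,z) \in `[0,1]`} of local
#' mechanobiological compromise: 1 at the lesion apex, 0 in the unaffected
#' far field.
#'
#' @slot field Numeric matrix (n_theta x n_z) with values in `[0, 1]`; the
#'   maximum is exactly 1 unless the profile is identically zero.
#' @slot profile_id Character identifier.
#' @slot seed Integer seed that produced the profile.
#' @export
setClass("InsultProfile",
  representation(field = "matrix", profile_id = "character", seed = "integer")
)

setValidity("InsultProfile", function(object) {
  f <- object@field
  if (!all(is.finite(f))) return("profile field must be finite")
  if (min(f) < 0) return("profile field must be >= 0")
  mx <- max(f)
  if (mx > 1 + 1e-12) return("profile field must be <= 1")
  if (mx > 0 && abs(mx - 1) > 1e-9)
    return("nonzero profile must attain max exactly 1")
  TRUE
})

#' Combined two-contributor insult fields
#'
#' Pointwise scaling of a normalized profile into the two contributor fields:
#' compromised elastic fiber integrity
#' \eqn{\vartheta_{ce} = s\,w\,0.48\,\vartheta^*} and dysfunctional
#' mechanosensing \eqn{\vartheta_\delta = s\,(1-w)\,0.28\,\vartheta^*}, with
#' mixture weight \eqn{w \in `[0,1]`} (1 = pure elastic-fiber insult) and a
#' scale \eqn{s > 0} calibrated so the lesion reaches aneurysmal dilatation.
#'
#' @slot theta_ce Elastic-fiber integrity defect field, values in `[0, 0.48]`.
#' @slot theta_delta Mechanosensing defect field, values in `[0, 0.28]`.
#' @slot w Mixture weight in `[0, 1]`.
#' @slot s Positive scale.
#' @slot profile_id Parent profile identifier.
#' @slot combo_id Combination identifier.
#' @export
setClass("InsultPair",
  representation(theta_ce = "matrix", theta_delta = "matrix",
                 w = "numeric", s = "numeric",
                 profile_id = "character", combo_id = "character")
)

.CAP_CE <- 0.48
.CAP_DELTA <- 0.28

setValidity("InsultPair", function(object) {
  if (max(object@theta_ce) > .CAP_CE + 1e-9)
    return("theta_ce exceeds its cap 0.48")
  if (max(object@theta_delta) > .CAP_DELTA + 1e-9)
    return("theta_delta exceeds its cap 0.28")
  if (min(object@theta_ce) < -1e-12 || min(object@theta_delta) < -1e-12)
    return("insult fields must be non-negative")
  if (object@w < 0 || object@w > 1) return("mixture weight w must be in `[0,1]`")
  if (object@s <= 0) return("scale s must be positive")
  TRUE
})

#' Wall parameters of the reduced equilibrated growth-and-remodeling model
#'
#' Nondimensional parameters of a thin-walled, constrained-mixture-inspired
#' membrane: elastin (deposited once, prestretched by `G_e`, load scaled by
#' `c_e`) plus a turnover pool (collagen and smooth muscle, deposited at
#' stress `s_h` with exponential stiffening exponent `k_c`). The homeostatic
#' set-point `sigma0` satisfies thin-wall Laplace equilibrium at the
#' growth-and-remodeling pressure `P_gr` and the mixture identity at
#' \eqn{\lambda = 1}.
#'
#' @slot r0 Baseline inner radius (1 by convention).
#' @slot rho Mass density linking areal mass and thickness (1 by convention).
#' @slot h0 Baseline wall thickness.
#' @slot phi_e0 Baseline elastin areal mass fraction.
#' @slot m_e Elastin areal reference mass (`phi_e0 * h0 * rho`).
#' @slot G_e Elastin prestretch.
#' @slot c_e Elastin stiffness coefficient.
#' @slot k_c Collagen exponential stiffening exponent.
#' @slot s_h Deposition (prestress) stress of the turnover pool; exceeds
#'   `sigma0` so that the mixture equation is solvable.
#' @slot sigma0 Homeostatic scalar stress set-point.
#' @slot sigma_ax0 Axial prestress term for the axial-stress closure.
#' @slot q_turn Turnover-stiffening exponent: the local stiffening exponent
#'   during the cardiac cycle is `k_c * zeta^q_turn` where `zeta` is the
#'   turnover mass ratio, so remodeled (lesion) wall is stiffer.
#' @slot P_dia,P_sys,P_gr Diastolic, systolic and equilibrium pressures.
#' @slot smooth_width Odd circumferential smoothing width for simulated
#'   radius fields (nodes; 0 or 1 disables).
#' @export
setClass("WallParams",
  representation(r0 = "numeric", rho = "numeric", h0 = "numeric",
                 phi_e0 = "numeric", m_e = "numeric", G_e = "numeric",
                 c_e = "numeric", k_c = "numeric", s_h = "numeric",
                 sigma0 = "numeric", sigma_ax0 = "numeric", q_turn = "numeric",
                 P_dia = "numeric", P_sys = "numeric", P_gr = "numeric",
                 smooth_width = "numeric")
)

setValidity("WallParams", function(object) {
  pos <- c(r0 = object@r0, rho = object@rho, h0 = object@h0,
           phi_e0 = object@phi_e0, m_e = object@m_e, G_e = object@G_e,
           c_e = object@c_e, k_c = object@k_c, s_h = object@s_h,
           sigma0 = object@sigma0, P_dia = object@P_dia,
           P_sys = object@P_sys, P_gr = object@P_gr)
  if (any(pos <= 0))
    return(paste("non-positive parameter:",
                 paste(names(pos)[pos <= 0], collapse = ", ")))
  if (object@phi_e0 >= 1) return("phi_e0 must be < 1")
  if (object@s_h <= object@sigma0)
    return("deposition stress s_h must exceed the set-point sigma0")
  if (object@P_dia >= object@P_sys) return("P_dia must be below P_sys")
  ## homeostatic identity at lambda = 1
  se1 <- object@c_e * (object@G_e^2 - object@G_e^-2)
  res <- object@phi_e0 * se1 + (1 - object@phi_e0) * object@s_h - object@sigma0
  if (abs(res) > 1e-6 * object@sigma0)
    return("homeostatic identity violated: phi_e0*sigma_e(1) + (1-phi_e0)*s_h != sigma0")
  ## Laplace consistency at the baseline state
  if (abs(object@P_gr * object@r0 / object@h0 - object@sigma0) > 1e-6 * object@sigma0)
    return("sigma0 must equal P_gr*r0/h0 (thin-wall Laplace at baseline)")
  TRUE
})

#' Simulated vessel fields at the equilibrated, loaded state
#'
#' Per-node output of the reduced growth-and-remodeling simulator: grown
#' circumferential stretch, turnover mass, thickness, loaded inner radii at
#' diastole and systole, and systolic stress diagnostics.
#'
#' @slot lam Grown circumferential stretch \eqn{\lambda = r_{gr}/r_0}.
#' @slot m_plus Turnover (collagen + smooth muscle) areal mass field.
#' @slot h Thickness field at the grown state.
#' @slot r_dia,r_sys Loaded inner-radius fields at diastole / systole.
#' @slot sigma_tt,sigma_zz Circumferential / axial Cauchy stress at systole.
#' @slot shear_analog Intramural shear analog \eqn{(\sigma_{\theta\theta}-\sigma_{zz})/2}.
#' @export
setClass("VesselFields",
  representation(lam = "matrix", m_plus = "matrix", h = "matrix",
                 r_dia = "matrix", r_sys = "matrix",
                 sigma_tt = "matrix", sigma_zz = "matrix",
                 shear_analog = "matrix")
)

setValidity("VesselFields", function(object) {
  if (any(object@r_sys < object@r_dia - 1e-9))
    return("r_sys must be >= r_dia pointwise (positive distensibility)")
  if (any(object@h <= 0)) return("thickness must be positive")
  if (any(object@lam <= 0)) return("grown stretch must be positive")
  TRUE
})

#' Dilatation / distensibility map pair
#'
#' A 41 x 41 (or grid-sized) dilatation map d and distensibility map D for one
#' record, in one of two encodings: "heat" carries the physical values,
#' "grayscale" carries 8-bit integers in `[0, 255]` quantized under
#' dataset-wide fixed ranges (stored alongside so decoding is self-describing).
#'
#' @slot d Dilatation grid.
#' @slot D Distensibility grid.
#' @slot encoding "heat" or "grayscale".
#' @slot d_range,D_range Length-2 numeric (lo, hi) grayscale ranges.
#' @export
setClass("MapPair",
  representation(d = "matrix", D = "matrix", encoding = "character",
                 d_range = "numeric", D_range = "numeric")
)

setValidity("MapPair", function(object) {
  if (!object@encoding %in% c("heat", "grayscale"))
    return("encoding must be 'heat' or 'grayscale'")
  if (!all(dim(object@d) == dim(object@D)))
    return("d and D must share a grid")
  if (object@encoding == "grayscale") {
    v <- c(object@d, object@D)
    if (any(v != round(v)) || min(v) < 0 || max(v) > 255)
      return("grayscale maps must be integers in `[0, 255]`")
  }
  TRUE
})

#' TAA map dataset container
#'
#' A \linkS4class{SummarizedExperiment} whose rows are the grid nodes
#' (rowData: theta, z and normalized coordinates) and whose columns are the
#' simulated records. Assays hold, per record, the flattened ground-truth
#' insult fields, simulator fields, and dilatation / distensibility maps in
#' both encodings. `colData` carries profile/combo identifiers, the mixture
#' weight and calibrated scale, per-record maximum dilatation, seeds, and the
#' train/test split; `metadata` carries the generating configuration, wall
#' parameters and grayscale ranges.
#'
#' @export
setClass("TAAMapExperiment", contains = "SummarizedExperiment")

.REQUIRED_ASSAYS <- c("insult_profile", "theta_ce", "theta_delta",
                      "r_dia", "r_sys", "d_heat", "D_heat", "d_gray", "D_gray")
.REQUIRED_COLDATA <- c("profile_id", "combo_id", "w", "s", "dmax", "split")

setValidity("TAAMapExperiment", function(object) {
  missing_a <- setdiff(.REQUIRED_ASSAYS, SummarizedExperiment::assayNames(object))
  if (length(missing_a))
    return(paste("missing assays:", paste(missing_a, collapse = ", ")))
  missing_c <- setdiff(.REQUIRED_COLDATA,
                       colnames(SummarizedExperiment::colData(object)))
  if (length(missing_c))
    return(paste("missing colData columns:", paste(missing_c, collapse = ", ")))
  if (!all(c("grid", "gray_ranges") %in% names(S4Vectors::metadata(object))))
    return("metadata must contain 'grid' and 'gray_ranges'")
  for (a in c("d_gray", "D_gray")) {
    v <- SummarizedExperiment::assay(object, a)
    if (any(v != round(v)) || min(v) < 0 || max(v) > 255)
      return(paste0("assay '", a, "' must hold 8-bit integers in `[0, 255]`"))
  }
  spl <- SummarizedExperiment::colData(object)$split
  if (!all(spl %in% c("train", "test")))
    return("split must be 'train' or 'test' for every record")
  TRUE
})

#' Neural-operator model objects
#'
#' Virtual parent of the four architecture classes. A model maps a batch of
#' `41 x 41 x channels` input maps to a batch of `41 x 41 x 2` predicted
#' insult fields (elastic-fiber integrity, mechanosensing). Parameters are
#' stored as a named list of numeric arrays; `norm` holds the input/output
#' min-max normalization fitted on the training set.
#'
#' @slot arch Architecture tag.
#' @slot channels 1 (dilatation only) or 2 (dilatation + distensibility).
#' @slot encoding Input encoding the model expects ("grayscale" or "heat").
#' @slot spec Architecture hyperparameters (list).
#' @slot params Named list of numeric parameter arrays.
#' @slot norm Normalization constants (list; empty until trained).
#' @slot trained Logical.
#' @slot history Data frame of logged training loss.
#' @export
setClass("NeuralOperator",
  representation("VIRTUAL",
                 arch = "character", channels = "integer",
                 encoding = "character", spec = "list", params = "list",
                 norm = "list", trained = "logical", history = "data.frame"),
  prototype(trained = FALSE, norm = list(), history = data.frame())
)

#' @rdname NeuralOperator-class
#' @export
setClass("UNetOperator", contains = "NeuralOperator")

#' @rdname NeuralOperator-class
#' @export
setClass("DeepONetOperator", contains = "NeuralOperator",
  representation(branch = "character"))

#' @rdname NeuralOperator-class
#' @export
setClass("LNOOperator", contains = "NeuralOperator")

#' Training configuration
#'
#' @slot optimizer Only "adam" is implemented.
#' @slot lr Initial learning rate.
#' @slot schedule "constant", "cosine" or "exponential".
#' @slot batch_size Records per weight update.
#' @slot n_updates Weight-update budget.
#' @slot loss "mse" or "relative_l2".
#' @slot normalization "minmax" or "none".
#' @slot seed Integer seed for initialization and batching.
#' @slot tier "full" or "reduced".
#' @slot val_fraction Fraction of the training records carved out for
#'   best-model selection (used by the LNO), 0 to disable.
#' @slot log_every Loss-logging cadence in updates.
#' @export
setClass("TrainConfig",
  representation(optimizer = "character", lr = "numeric", schedule = "character",
                 batch_size = "integer", n_updates = "integer", loss = "character",
                 normalization = "character", seed = "integer", tier = "character",
                 val_fraction = "numeric", log_every = "integer")
)

setValidity("TrainConfig", function(object) {
  if (!object@optimizer %in% "adam") return("optimizer must be 'adam'")
  if (!object@schedule %in% c("constant", "cosine", "exponential"))
    return("unknown learning-rate schedule")
  if (!object@loss %in% c("mse", "relative_l2")) return("unknown loss")
  if (!object@normalization %in% c("minmax", "none"))
    return("normalization must be 'minmax' or 'none'")
  if (object@lr <= 0 || object@n_updates < 1L || object@batch_size < 1L)
    return("lr, n_updates and batch_size must be positive")
  if (object@val_fraction < 0 || object@val_fraction >= 1)
    return("val_fraction must be in `[0, 1)`")
  TRUE
})
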