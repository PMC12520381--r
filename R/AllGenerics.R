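#' Simulate the equilibrated aneurysmal vessel for one insult pair
#'
#' @param pair An \linkS4class{InsultPair}.
#' @param params A calibrated \linkS4class{WallParams}.
#' @param grid The \linkS4class{GridSpec} the pair lives on.
#' @return A \linkS4class{VesselFields}.
#' @export
setGeneric("simulateTAA", function(pair, params, grid) standardGeneric("simulateTAA"))

#' Train a neural operator
#'
#' @param model A \linkS4class{NeuralOperator}.
#' @param data Training data as returned by [operatorData()].
#' @param config A \linkS4class{TrainConfig}.
#' @return The trained model, with `history` filled in.
#' @export
setGeneric("trainOperator", function(model, data, config) standardGeneric("trainOperator"))

#' Predict insult fields from dilatation / distensibility maps
#'
#' @param model A trained \linkS4class{NeuralOperator}.
#' @param x Input maps: array `(41, 41, channels, n)` (or a single
#'   `(41, 41, channels)` record) on the scale the model was trained on
#'   (grayscale inputs are rescaled to ``[0, 1]`` internally).
#' @return Array `(41, 41, 2, n)` of predicted fields in physical units:
#'   channel 1 elastic-fiber integrity, channel 2 mechanosensing. Raw
#'   regression output; no clamping.
#' @export
setGeneric("predictInsults", function(model, x) standardGeneric("predictInsults"))

#' Number of trainable parameters of a model
#' @param model A \linkS4class{NeuralOperator}.
#' @return Integer count of trainable scalars.
#' @export
setGeneric("nParameters", function(model) standardGeneric("nParameters"))

#' @rdname nParameters
setMethod("nParameters", "NeuralOperator", function(model) {
  sum(vapply(model@params, length, integer(1)))
})

setMethod("show", "NeuralOperator", function(object) {
  cat(class(object), sprintf("(%s)", object@arch),
      sprintf("| channels=%d encoding=%s | %s params | %s\n",
              object@channels, object@encoding,
              format(nParameters(object), big.mark = ","),
              if (object@trained) "trained" else "untrained"))
})

setMethod("show", "GridSpec", function(object) {
  cat(sprintf("GridSpec: %d x %d nodes, theta periodic in `[0, 2pi)`, z in [0, %g]\n",
              object@n_theta, object@n_z, object@L))
})

setMethod("show", "WallParams", function(object) {
  cat("WallParams (nondimensional, reduced equilibrated G&R membrane)\n")
  cat(sprintf("  r0=%g h0=%g phi_e0=%g G_e=%g c_e=%.4g k_c=%.4g\n",
              object@r0, object@h0, object@phi_e0, object@G_e, object@c_e,
              object@k_c))
  cat(sprintf("  sigma0=%.4g s_h=%.4g (s_h/sigma0=%.3f) q_turn=%g\n",
              object@sigma0, object@s_h, object@s_h / object@sigma0,
              object@q_turn))
  cat(sprintf("  P_dia=%g P_sys=%g P_gr=%g smooth_width=%g\n",
              object@P_dia, object@P_sys, object@P_gr, object@smooth_width))
})

setMethod("show", "InsultProfile", function(object) {
  cat(sprintf("InsultProfile '%s' (%d x %d), support %.1f%% of nodes, seed %d\n",
              object@profile_id, nrow(object@field), ncol(object@field),
              100 * mean(object@field > 0), object@seed))
})

setMethod("show", "InsultPair", function(object) {
  cat(sprintf(
    "InsultPair '%s/%s': w=%.3g s=%.4g max(theta_ce)=%.3f max(theta_delta)=%.3f\n",
    object@profile_id, object@combo_id, object@w, object@s,
    max(object@theta_ce), max(object@theta_delta)))
})
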