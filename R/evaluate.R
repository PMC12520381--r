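#' Relative L2 error between a predicted and a true field
#'
#' \eqn{\lVert \hat\vartheta - \vartheta \rVert_2 / \lVert \vartheta \rVert_2}
#' over all grid nodes of one record.
#'
#' @param pred,truth Numeric arrays of identical shape.
#' @return Scalar error (>= 0).
#' @examples
#' relativeL2(matrix(1, 2, 2), matrix(1, 2, 2))  # 0
#' @export
relativeL2 <- function(pred, truth) {
  if (!identical(dim(pred), dim(truth)) && length(pred) != length(truth))
    stop("shape mismatch between prediction and truth")
  den <- sqrt(sum(truth^2))
  if (den == 0)
    stop("metric error: truth field has zero norm (record excluded)")
  sqrt(sum((pred - truth)^2)) / den
}

#' Signed pointwise error map
#'
#' \eqn{\hat\vartheta - \vartheta}; take `abs()` for unsigned magnitudes.
#'
#' @inheritParams relativeL2
#' @return Array of the same shape.
#' @export
absoluteErrorMap <- function(pred, truth) {
  stopifnot(length(pred) == length(truth))
  pred - truth
}

#' Insult-region-filtered relative L2 error
#'
#' The relative L2 error restricted to the nodes where the normalized insult
#' profile is at least `threshold` (default 0.50), concentrating the metric
#' on the most affected region.
#'
#' @inheritParams relativeL2
#' @param profile Normalized insult profile matrix (values in `[0, 1]`) or an
#'   \linkS4class{InsultProfile}.
#' @param threshold Mask threshold on the profile.
#' @return Scalar error.
#' @export
filteredError <- function(pred, truth, profile, threshold = 0.50) {
  if (is(profile, "InsultProfile")) profile <- profile@field
  mask <- profile >= threshold
  if (!any(mask)) stop("metric error: empty insult mask at threshold ", threshold)
  relativeL2(pred[mask], truth[mask])
}

#' Evaluate a trained operator on a test set
#'
#' Computes per-record relative L2 errors for each insult contributor, both
#' over the whole domain and restricted to the insult region
#' (profile >= `threshold`). Records whose true contributor field is
#' identically zero (pure single-contributor combinations) are excluded from
#' that contributor's aggregate, as the relative error is undefined there.
#' Both the mean-of-records aggregate (headline) and the pooled-norm
#' aggregate are reported.
#'
#' @param model A trained \linkS4class{NeuralOperator}.
#' @param data Test data from [operatorData()] (matching the model's
#'   channels/encoding).
#' @param threshold Insult-region filter threshold.
#' @return A list with the condition tags, aggregate errors `e_ce`,
#'   `e_delta`, pooled variants, filtered variants, and a per-record
#'   `S4Vectors::DataFrame`.
#' @export
evaluateOperator <- function(model, data, threshold = 0.50) {
  pred <- predictInsults(model, data$x)
  n <- dim(pred)[4]
  per <- matrix(NA_real_, n, 4,
                dimnames = list(NULL, c("e_ce", "e_delta",
                                        "e_ce_filt", "e_delta_filt")))
  num2 <- den2 <- c(ce = 0, delta = 0)
  for (r in seq_len(n)) {
    prof <- data$profile[, , r]
    for (h in 1:2) {
      tr <- data$y[, , h, r]
      pr <- pred[, , h, r]
      key <- c("ce", "delta")[h]
      if (sum(tr^2) > 0) {
        per[r, h] <- relativeL2(pr, tr)
        per[r, h + 2] <- filteredError(pr, tr, prof, threshold)
        num2[key] <- num2[key] + sum((pr - tr)^2)
        den2[key] <- den2[key] + sum(tr^2)
      }
    }
  }
  list(arch = model@arch, channels = model@channels,
       encoding = model@encoding,
       e_ce = mean(per[, "e_ce"], na.rm = TRUE),
       e_delta = mean(per[, "e_delta"], na.rm = TRUE),
       e_ce_pooled = sqrt(num2[["ce"]] / den2[["ce"]]),
       e_delta_pooled = sqrt(num2[["delta"]] / den2[["delta"]]),
       e_ce_filt = mean(per[, "e_ce_filt"], na.rm = TRUE),
       e_delta_filt = mean(per[, "e_delta_filt"], na.rm = TRUE),
       n_excluded_ce = sum(is.na(per[, "e_ce"])),
       n_excluded_delta = sum(is.na(per[, "e_delta"])),
       per_record = S4Vectors::DataFrame(id = data$ids, w = data$w, per))
}

#' Compare evaluation reports across channel conditions
#'
#' Builds the condition table (architecture x channels x encoding), the
#' per-architecture error ratio (dilatation-only error over
#' dilatation-plus-distensibility error, averaged over the two contributor
#' heads), and a ranking by 2-channel error. A console message (not a
#' failure) notes whether the UNet ranks first.
#'
#' @param reports List of reports from [evaluateOperator()].
#' @return A list with `table` (data.frame of all conditions), `ratios`
#'   (data.frame per architecture x encoding), and `ranking` (architectures
#'   ordered by mean 2-channel error).
#' @export
compareConditions <- function(reports) {
  tab <- do.call(rbind, lapply(reports, function(r)
    data.frame(arch = r$arch, channels = r$channels, encoding = r$encoding,
               e_ce = r$e_ce, e_delta = r$e_delta,
               e_ce_filt = r$e_ce_filt, e_delta_filt = r$e_delta_filt)))
  combos <- unique(tab[, c("arch", "encoding")])
  ratios <- do.call(rbind, lapply(seq_len(nrow(combos)), function(i) {
    a <- combos$arch[i]; e <- combos$encoding[i]
    one <- tab[tab$arch == a & tab$encoding == e & tab$channels == 1L, ]
    two <- tab[tab$arch == a & tab$encoding == e & tab$channels == 2L, ]
    if (nrow(one) != 1L || nrow(two) != 1L)
      stop("report error: missing channel condition for ", a, " / ", e)
    data.frame(arch = a, encoding = e,
               ratio = mean(c(one$e_ce, one$e_delta)) /
                 mean(c(two$e_ce, two$e_delta)))
  }))
  two_ch <- tab[tab$channels == 2L, ]
  rk <- stats::aggregate((e_ce + e_delta) / 2 ~ arch, data = two_ch, FUN = mean)
  names(rk)[2] <- "mean_error"
  rk <- rk[order(rk$mean_error), ]
  if (nrow(rk) && rk$arch[1] == "unet")
    message("ranking check: UNet is the best-performing architecture on 2-channel inputs")
  else if (nrow(rk))
    message("ranking note: best 2-channel architecture is ", rk$arch[1],
            " (not UNet) in this run")
  list(table = tab, ratios = ratios, ranking = rk)
}
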