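#' Label normal components as differential by the IQR outlier rule
#'
#' A normal component is labelled differential when one of its tails
#' reaches into the outlier region of the whole dataset:
#' `|mu_k| + tail_sd * sigma_k > iqr_mult * IQR(y)` (strict), with defaults
#' `tail_sd = 2` and `iqr_mult = 1.5`. The IQR uses the unweighted
#' empirical quartiles (linear-interpolation, type-7 convention). The
#' overdispersion family `f1` (uniform or exponential pair) is always
#' differential and is not part of the labels.
#'
#' @param model A fitted [mix_model()].
#' @param data Data frame with `y` (at least 4 observations for a
#'   meaningful IQR).
#' @param tail_sd,iqr_mult Rule constants; exposed for sensitivity
#'   analysis, defaults as above.
#' @return List of class `mix_labels`: `differential_normals` (integer
#'   indices into `model$normals`) and `iqr`.
#' @export
label_components <- function(model, data, tail_sd = 2, iqr_mult = 1.5) {
  validate_mix_model(model)
  data <- as_fit_data(data)
  if (nrow(data) < 4) abort("at least 4 observations are needed for the IQR rule.")
  iqr <- IQR(data$y, type = 7)
  if (iqr == 0) abort("IQR of `y` is zero; the outlier rule is undefined.")
  lab <- which(abs(model$normals$mu) + tail_sd * sqrt(model$normals$sigma2) >
                 iqr_mult * iqr)
  structure(list(differential_normals = as.integer(lab), iqr = iqr),
            class = "mix_labels")
}

#' Per-observation local false discovery rate
#'
#' The local fdr of a score is the share of the fitted mixture density at
#' that score attributable to the nondifferential normal components:
#' `fdr(y) = (1 - pi) * sum_{k nondifferential} gamma_k N(y; mu_k,
#' sigma_k^2) / f(y)`. It always lies in `[0, 1]`; if every component is
#' differential the fdr is identically 0.
#'
#' @param model A fitted [mix_model()].
#' @param labels A `mix_labels` from [label_components()].
#' @param y Numeric vector of scores.
#' @return Numeric vector of local fdr values in `[0, 1]`.
#' @export
local_fdr <- function(model, labels, y) {
  validate_mix_model(model)
  stopifnot(inherits(labels, "mix_labels"))
  check_scores(y)
  f <- mixture_density(model, y)
  if (any(f < 1e-300)) {
    abort("fitted density is zero at some observations; cannot form fdr.")
  }
  nd <- setdiff(seq_len(model$K), labels$differential_normals)
  if (length(nd) == 0) return(rep(0, length(y)))
  nm <- model$normals
  num <- rep(0, length(y))
  for (k in nd) {
    num <- num + nm$gamma[k] * dnorm(y, nm$mu[k], sqrt(nm$sigma2[k]))
  }
  pmin((1 - model$pi) * num / f, 1)
}

#' Call differential units by the weighted fdr rule
#'
#' Unit `i` is called differential when `fdr_i / w_i <= z0`. Downweighted
#' units must clear a proportionally stricter bar, and zero-weight units
#' are never called.
#'
#' @param fdr Numeric vector of local fdr values in `[0, 1]`.
#' @param w Numeric vector of robustness weights in `[0, 1]`.
#' @param z0 Threshold in (0, 1]; default 0.1.
#' @return Logical vector of calls.
#' @export
call_differential <- function(fdr, w, z0 = 0.1) {
  stopifnot(length(fdr) == length(w))
  if (any(fdr < 0 | fdr > 1)) abort("`fdr` values must lie in [0, 1].")
  if (any(w < 0 | w > 1)) abort("`w` values must lie in [0, 1].")
  if (!is.numeric(z0) || length(z0) != 1 || z0 <= 0 || z0 > 1) {
    abort("`z0` must lie in (0, 1].")
  }
  w > 0 & fdr <= z0 * w
}

#' True and false positive rates of differential calls
#'
#' @param calls Logical vector of calls.
#' @param truth Logical vector of ground-truth differential status, with
#'   at least one positive and one negative.
#' @return One-row tibble with `tpr = TP / (TP + FN)` and
#'   `fpr = FP / (FP + TN)`.
#' @examples
#' evaluate_calls(c(TRUE, FALSE, FALSE), c(TRUE, FALSE, TRUE))
#' @export
evaluate_calls <- function(calls, truth) {
  stopifnot(is.logical(calls), is.logical(truth),
            length(calls) == length(truth))
  if (!any(truth) || all(truth)) {
    abort("`truth` must contain at least one positive and one negative.")
  }
  tibble::tibble(
    tpr = sum(calls & truth) / sum(truth),
    fpr = sum(calls & !truth) / sum(!truth)
  )
}
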