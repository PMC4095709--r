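#' BIC and AIC on the maximize-is-better scale
#'
#' Both criteria use the weighted log-likelihood and the free-parameter
#' count of the fit: `BIC = 2 loglik - p log(n)` and
#' `AIC = 2 loglik - 2 p`. Larger is better. The BIC penalty uses the
#' number of observations `n`, treating the robustness weights as fixed
#' and known.
#'
#' @param fit A `mix_fit` from [fit_mixture()].
#' @param n Number of observations; defaults to the fitting sample size.
#' @return A single number.
#' @export
mix_bic <- function(fit, n = fit$n) {
  stopifnot(inherits(fit, "mix_fit"), is.finite(fit$loglik))
  if (n < 2) abort("`n` must be at least 2.")
  2 * fit$loglik - fit$n_params * log(n)
}

#' @rdname mix_bic
#' @export
mix_aic <- function(fit) {
  stopifnot(inherits(fit, "mix_fit"), is.finite(fit$loglik))
  2 * fit$loglik - 2 * fit$n_params
}

#' Scan mixture orders within one model class
#'
#' Fits `K = 1, ..., K_max` normal components (only `K = 1` for NUDGE) and
#' picks the order maximizing BIC, breaking ties toward the smaller K.
#' BIC is deliberately the within-class criterion: its stronger parameter
#' penalty guards against overfitting the order.
#'
#' @inheritParams fit_mixture
#' @param K_max Largest order to consider; default 6.
#' @return List with `fits` (all `mix_fit` objects, indexed by K) and
#'   `best` (the BIC-optimal fit).
#' @export
scan_orders <- function(model_class, data, control = em_control(), K_max = 6) {
  stopifnot(K_max >= 1)
  data <- as_fit_data(data)
  Ks <- if (model_class == "NUDGE") 1L else seq_len(K_max)
  fits <- vector("list", length(Ks))
  errs <- character()
  for (i in seq_along(Ks)) {
    fits[[i]] <- tryCatch(
      fit_mixture(model_class, K = Ks[i], data, control),
      error = function(e) {
        errs <<- c(errs, sprintf("K = %d: %s", Ks[i], conditionMessage(e)))
        NULL
      }
    )
  }
  ok <- !vapply(fits, is.null, logical(1))
  if (!any(ok)) {
    abort(paste0("all ", model_class, " fits failed:\n",
                 paste(errs, collapse = "\n")))
  }
  fits <- fits[ok]
  bics <- vapply(fits, function(f) f$bic, numeric(1))
  best <- fits[[which.max(bics >= max(bics))]]  # first (smallest K) maximizer
  list(fits = fits, best = best)
}

#' Pick the overall best class by AIC
#'
#' Given the BIC-best fit of each class, returns the one maximizing AIC.
#' Exact ties go to the class with the richer differential family:
#' GNG, then iNUDGE, then NUDGE.
#'
#' @param best_within Named list of `mix_fit` objects (any subset of
#'   `NUDGE`, `iNUDGE`, `GNG`; classes that could not be fitted may be
#'   absent).
#' @return The winning `mix_fit`.
#' @export
select_overall <- function(best_within) {
  best_within <- purrr::compact(best_within)
  if (length(best_within) == 0) abort("no fitted models to select from.")
  pref <- c(GNG = 3, iNUDGE = 2, NUDGE = 1)
  aics <- vapply(best_within, function(f) f$aic, numeric(1))
  classes <- vapply(best_within, function(f) f$model$model_class, character(1))
  ord <- order(aics, pref[classes], decreasing = TRUE)
  best_within[[ord[1]]]
}

#' Fit the full mixture ensemble to a table of difference scores
#'
#' The workhorse of the package: fits NUDGE, iNUDGE, and GNG to the scores,
#' chooses the number of normal components within iNUDGE and GNG by BIC,
#' picks the overall winner by AIC, labels differential normal components
#' by the IQR outlier rule, and computes per-unit weighted local false
#' discovery rates and differential calls at threshold `z0`. GNG is skipped
#' (with a message in `skipped`) when the scores are one-sided, since its
#' exponential offsets are then undefined.
#'
#' @param data Data frame with a numeric `y` column, optionally `id`, `u`,
#'   and `w`. If `u` is present and `w` absent, robustness weights are
#'   computed via [compute_weights()] with the given `weight_fun`/`tail`.
#' @param weight_fun,tail,c,taper Passed to [compute_weights()] when
#'   weights need deriving; defaults are lower-half Huber with c = 1.345.
#' @param K_max Largest normal-mixture order scanned; default 6.
#' @param z0 Local-fdr call threshold in (0, 1]; default 0.1.
#' @param classes Model classes to include in the ensemble.
#' @param control An [em_control()].
#' @return An object of class `mix_ensemble` with elements `scans`
#'   (per-class order scans), `best_within`, `best` (the overall winner),
#'   `labels` (differential component labels for the winner),
#'   `classification` (per-unit tibble: id, y, w, fdr, fdr_over_w, call),
#'   `data`, `z0`, and `skipped`.
#' @examples
#' d <- simulate_scores(n = 800, seed = 7)
#' fit <- fit_mixture_ensemble(d, K_max = 2,
#'                             control = em_control(n_restarts = 1, seed = 1))
#' glance(fit)
#' @export
fit_mixture_ensemble <- function(data, weight_fun = c("huber", "tukey", "none"),
                                 tail = c("lower", "upper", "two_tailed"),
                                 c = 1.345, taper = 4.685, K_max = 6,
                                 z0 = 0.1,
                                 classes = c("GNG", "iNUDGE", "NUDGE"),
                                 control = em_control()) {
  classes <- match.arg(classes, several.ok = TRUE)
  data <- tibble::as_tibble(data)
  if (!"w" %in% names(data)) {
    data <- compute_weights(data, weight_fun = match.arg(weight_fun),
                            tail = match.arg(tail), c = c, taper = taper)
  }
  data <- as_fit_data(data)

  scans <- list()
  skipped <- character()
  for (cl in classes) {
    scans[[cl]] <- tryCatch(
      scan_orders(cl, data, control = control, K_max = K_max),
      error = function(e) {
        skipped <<- c(skipped, sprintf("%s: %s", cl, conditionMessage(e)))
        NULL
      }
    )
  }
  scans <- purrr::compact(scans)
  if (length(scans) == 0) {
    abort(paste0("no model class could be fitted:\n",
                 paste(skipped, collapse = "\n")))
  }
  best_within <- purrr::map(scans, "best")
  best <- select_overall(best_within)

  labels <- label_components(best$model, data)
  fdr <- local_fdr(best$model, labels, data$y)
  calls <- call_differential(fdr, data$w, z0 = z0)
  ids <- if ("id" %in% names(data)) data$id else seq_len(nrow(data))
  classification <- tibble::tibble(
    id = ids, y = data$y, w = data$w, fdr = fdr,
    fdr_over_w = ifelse(data$w > 0, fdr / data$w, Inf), call = calls
  )

  structure(
    list(scans = scans, best_within = best_within, best = best,
         labels = labels, classification = classification, data = data,
         z0 = z0, skipped = skipped),
    class = "mix_ensemble"
  )
}

#' @export
print.mix_ensemble <- function(x, ...) {
  cat("<mix_ensemble>\n")
  print(tidy(x, all_classes = TRUE), ...)
  cat(sprintf("best overall: %s (K = %d) by AIC\n",
              x$best$model$model_class, x$best$model$K))
  cat(sprintf("differential calls at z0 = %g: %d of %d\n",
              x$z0, sum(x$classification$call), nrow(x$classification)))
  for (s in x$skipped) cat("  skipped", s, "\n")
  invisible(x)
}

#' Summaries of an ensemble fit
#'
#' `tidy()` returns the component table of the winning model (or, with
#' `all_classes = TRUE`, the per-class selection table of loglik, BIC,
#' AIC). `glance()` returns a one-row summary; `augment()` returns the
#' per-unit classification table.
#'
#' @param x A `mix_ensemble` from [fit_mixture_ensemble()].
#' @param all_classes Return the per-class model-selection table instead
#'   of the winner's components.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy mix_ensemble
#' @export
tidy.mix_ensemble <- function(x, all_classes = FALSE, ...) {
  if (!all_classes) return(tidy(x$best))
  purrr::map_dfr(x$best_within, function(f) {
    dplyr::mutate(glance(f),
                  chosen = identical(f$model$model_class,
                                     x$best$model$model_class))
  })
}

#' @rdname tidy.mix_ensemble
#' @method glance mix_ensemble
#' @export
glance.mix_ensemble <- function(x, ...) {
  dplyr::mutate(glance(x$best),
                n_differential_components = length(x$labels$differential_normals),
                n_calls = sum(x$classification$call), z0 = x$z0)
}

#' @rdname tidy.mix_ensemble
#' @method augment mix_ensemble
#' @export
augment.mix_ensemble <- function(x, ...) {
  x$classification
}

#' Serialize an ensemble selection report
#'
#' @param x A `mix_ensemble`.
#' @return A list (JSON-ready) with one entry per fitted model: class, K,
#'   loglik, n_params, bic, aic, and flags for within-class and overall
#'   winners.
#' @export
selection_report <- function(x) {
  stopifnot(inherits(x, "mix_ensemble"))
  fits <- unname(purrr::flatten(purrr::map(x$scans, "fits")))
  purrr::map(fits, function(f) {
    list(model_class = f$model$model_class, K = f$model$K,
         loglik = f$loglik, n_params = f$n_params, bic = f$bic, aic = f$aic,
         converged = f$converged,
         best_within = identical(f, x$best_within[[f$model$model_class]]),
         best_overall = identical(f, x$best))
  })
}
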