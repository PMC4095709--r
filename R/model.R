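#' Construct a mixture model of one of the three ensemble classes
#'
#' The ensemble considers three classes of two-level mixtures
#' `f(y) = (1 - pi) f0(y) + pi f1(y)`, where `f0` is a normal component
#' (NUDGE) or a K-component normal mixture (iNUDGE, GNG) describing the
#' centrally located, nondifferential-leaning scores, and `f1` captures
#' overdispersed (differential) scores: a uniform on `[a, b]` for
#' NUDGE/iNUDGE, or a pair of shifted exponentials on the two tails for GNG.
#'
#' @param model_class `"NUDGE"`, `"iNUDGE"`, or `"GNG"`.
#' @param pi First-level mixing weight of the differential family `f1`,
#'   in `[0, 1]`.
#' @param normals Data frame with columns `mu`, `sigma2` (> 0), `gamma`
#'   (mixing proportions summing to 1). NUDGE requires exactly one row.
#' @param a,b Uniform bounds, `a < b` (NUDGE / iNUDGE only).
#' @param rho Mixing proportion of the negative-side exponential within
#'   `f1` (GNG only).
#' @param beta1,beta2 Positive scale (mean) parameters of the negative- and
#'   positive-side shifted exponentials (GNG only).
#' @param xi1,xi2 Positive offsets: the negative-side density lives on
#'   `y < -xi1`, the positive side on `y > xi2` (GNG only).
#' @return An object of class `mix_model`.
#' @examples
#' m <- mix_model("NUDGE", pi = 0.1,
#'                normals = data.frame(mu = 0, sigma2 = 1, gamma = 1),
#'                a = -5, b = 5)
#' mixture_density(m, c(-1, 0, 1))
#' @export
mix_model <- function(model_class = c("NUDGE", "iNUDGE", "GNG"), pi, normals,
                      a = NULL, b = NULL, rho = NULL, beta1 = NULL,
                      beta2 = NULL, xi1 = NULL, xi2 = NULL) {
  model_class <- match.arg(model_class)
  normals <- tibble::as_tibble(normals)
  stopifnot(all(c("mu", "sigma2", "gamma") %in% names(normals)))
  f1 <- if (model_class == "GNG") {
    list(rho = rho, beta1 = beta1, beta2 = beta2, xi1 = xi1, xi2 = xi2)
  } else {
    list(a = a, b = b)
  }
  out <- structure(
    list(model_class = model_class, pi = pi, K = nrow(normals),
         normals = normals, f1 = f1),
    class = "mix_model"
  )
  validate_mix_model(out)
  out
}

validate_mix_model <- function(model) {
  stopifnot(inherits(model, "mix_model"))
  if (!is.numeric(model$pi) || model$pi < 0 || model$pi > 1) {
    abort("`pi` must lie in [0, 1].")
  }
  nm <- model$normals
  if (nrow(nm) < 1) abort("at least one normal component is required.")
  if (model$model_class == "NUDGE" && nrow(nm) != 1) {
    abort("NUDGE has exactly one normal component.")
  }
  if (any(nm$sigma2 <= 0)) abort("normal variances must be positive.")
  if (any(nm$gamma < 0) || abs(sum(nm$gamma) - 1) > 1e-8) {
    abort("normal mixing proportions `gamma` must be nonnegative and sum to 1.")
  }
  f1 <- model$f1
  if (model$model_class == "GNG") {
    if (is.null(f1$rho) || f1$rho < 0 || f1$rho > 1) {
      abort("`rho` must lie in [0, 1].")
    }
    if (is.null(f1$beta1) || f1$beta1 <= 0 || is.null(f1$beta2) || f1$beta2 <= 0) {
      abort("exponential scales `beta1`, `beta2` must be positive.")
    }
    if (is.null(f1$xi1) || f1$xi1 <= 0 || is.null(f1$xi2) || f1$xi2 <= 0) {
      abort("offsets `xi1`, `xi2` must be positive.")
    }
  } else {
    if (is.null(f1$a) || is.null(f1$b) || !(f1$a < f1$b)) {
      abort("uniform bounds must satisfy a < b.")
    }
  }
  invisible(model)
}

#' @export
print.mix_model <- function(x, ...) {
  cat(sprintf("<mix_model> %s: pi = %.4g, K = %d\n",
              x$model_class, x$pi, x$K))
  print(x$normals, ...)
  if (x$model_class == "GNG") {
    cat(sprintf("f1: rho = %.4g, beta = (%.4g, %.4g), xi = (%.4g, %.4g)\n",
                x$f1$rho, x$f1$beta1, x$f1$beta2, x$f1$xi1, x$f1$xi2))
  } else {
    cat(sprintf("f1: uniform on [%.4g, %.4g]\n", x$f1$a, x$f1$b))
  }
  invisible(x)
}

check_scores <- function(y) {
  if (!is.numeric(y) || length(y) < 1) abort("`y` must be a numeric vector.")
  if (anyNA(y) || any(!is.finite(y))) abort("`y` contains non-finite values.")
  y
}

# Unweighted per-part densities of f1; one column (uniform) or two (E1, E2).
f1_part_densities <- function(model, y) {
  if (model$model_class == "GNG") {
    xi1 <- model$f1$xi1; xi2 <- model$f1$xi2
    e1 <- ifelse(y < -xi1, exp(-(-y - xi1) / model$f1$beta1) / model$f1$beta1, 0)
    e2 <- ifelse(y > xi2, exp(-(y - xi2) / model$f1$beta2) / model$f1$beta2, 0)
    cbind(E1 = e1, E2 = e2)
  } else {
    cbind(U = dunif(y, model$f1$a, model$f1$b))
  }
}

f1_part_weights <- function(model) {
  if (model$model_class == "GNG") {
    model$pi * c(model$f1$rho, 1 - model$f1$rho)
  } else {
    model$pi
  }
}

#' Evaluate mixture density and per-component densities
#'
#' `mixture_density()` returns `f(y) = (1 - pi) f0(y) + pi f1(y)`.
#' `component_densities()` returns the unweighted density of every
#' component (the K normals followed by the `f1` part(s): one uniform
#' column, or the two shifted-exponential columns for GNG); weighting the
#' columns by `(1 - pi) * gamma_k` and `pi * (rho, 1 - rho)` (or `pi` for
#' the uniform) and summing each row reproduces `mixture_density()`.
#'
#' @param model A [mix_model()].
#' @param y Numeric vector of difference scores; must be finite.
#' @return For `mixture_density()`, a numeric vector of densities; for
#'   `component_densities()`, an `n x (K + parts)` matrix.
#' @export
mixture_density <- function(model, y) {
  validate_mix_model(model)
  check_scores(y)
  dens <- component_densities(model, y)
  as.numeric(dens %*% component_weights(model))
}

#' @rdname mixture_density
#' @export
component_densities <- function(model, y) {
  validate_mix_model(model)
  check_scores(y)
  nm <- model$normals
  norm_cols <- vapply(seq_len(nrow(nm)), function(k) {
    dnorm(y, nm$mu[k], sqrt(nm$sigma2[k]))
  }, numeric(length(y)))
  norm_cols <- matrix(norm_cols, nrow = length(y),
                      dimnames = list(NULL, paste0("N", seq_len(nrow(nm)))))
  cbind(norm_cols, f1_part_densities(model, y))
}

# Mixing weights aligned with component_densities() columns.
component_weights <- function(model) {
  c((1 - model$pi) * model$normals$gamma, f1_part_weights(model))
}

#' Estimate the shifted-exponential offsets from the data
#'
#' The GNG tails live strictly outside `(-xi1, xi2)`. The offsets are
#' treated as known and estimated once from the data as
#' `xi1 = |largest negative score|` and `xi2 = smallest positive score`;
#' they are not updated during EM.
#'
#' @param y Numeric vector containing at least one negative and one
#'   positive value.
#' @return Named list with positive elements `xi1` and `xi2`.
#' @examples
#' estimate_xi(c(-2, -0.5, 0.3, 1))
#' @export
estimate_xi <- function(y) {
  check_scores(y)
  neg <- y[y < 0]
  pos <- y[y > 0]
  if (length(neg) == 0 || length(pos) == 0) {
    abort(paste("`y` must contain both negative and positive values;",
                "the GNG class is inapplicable to one-sided data."))
  }
  list(xi1 = abs(max(neg)), xi2 = min(pos))
}

#' Number of free parameters of a mixture model
#'
#' Counts the parameters estimated by EM: `pi`, the `K - 1` free normal
#' proportions, `K` means and `K` variances, and for GNG additionally
#' `rho`, `beta1`, `beta2`. The uniform bounds and exponential offsets are
#' fixed at fit time and not counted. NUDGE: 3; iNUDGE: 3K; GNG: 3K + 3.
#'
#' @param model A [mix_model()].
#' @return Integer parameter count.
#' @export
count_params <- function(model) {
  validate_mix_model(model)
  K <- model$K
  p <- 1L + (K - 1L) + 2L * K
  if (model$model_class == "GNG") p <- p + 3L
  as.integer(p)
}
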