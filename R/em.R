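#' EM fitting control parameters
#'
#' @param tol Convergence threshold on the maximum absolute change of any
#'   free parameter between successive iterations; default `1e-5`.
#' @param max_iter Maximum EM iterations per run; default 2000.
#' @param n_restarts Number of EM runs per fit. The first run starts from
#'   `init_method`; subsequent runs use random initialization. The run with
#'   the highest weighted log-likelihood wins (ties to the earliest run).
#' @param seed Integer seed making the whole fit reproducible.
#' @param init_method `"kmeans"` (default), `"quantile"`, or `"random"`.
#' @return A list of class `em_control`.
#' @export
em_control <- function(tol = 1e-5, max_iter = 2000, n_restarts = 5,
                       seed = 1L, init_method = c("kmeans", "quantile", "random")) {
  stopifnot(is.numeric(tol), tol > 0, max_iter >= 1, n_restarts >= 1)
  structure(list(tol = tol, max_iter = as.integer(max_iter),
                 n_restarts = as.integer(n_restarts), seed = as.integer(seed),
                 init_method = match.arg(init_method)),
            class = "em_control")
}

# Coerce user tables to the internal (y, w) form.
as_fit_data <- function(data) {
  data <- tibble::as_tibble(data)
  if (!"y" %in% names(data)) abort("`data` must contain a `y` column.")
  check_scores(data$y)
  if (!"w" %in% names(data)) data$w <- rep(1, nrow(data))
  if (any(data$w < 0 | data$w > 1)) abort("weights `w` must lie in [0, 1].")
  if (nrow(data) < 2) abort("at least 2 observations are required.")
  data
}

#' Initialize a mixture model for EM
#'
#' Builds starting parameters for one EM run. `"kmeans"` clusters the
#' scores into K groups and uses the cluster means, variances, and
#' proportions; `"quantile"` places means at the `k/(K+1)` empirical
#' quantiles (type-7 convention) with common variance `var(y)/K`;
#' `"random"` draws means uniformly on the data range. In all cases
#' `pi` starts at 0.1 and, for GNG, `rho` at 0.5 with unit exponential
#' scales. The uniform bounds are the data range; the exponential offsets
#' come from [estimate_xi()] and stay fixed throughout EM.
#'
#' @param model_class `"NUDGE"`, `"iNUDGE"`, or `"GNG"`.
#' @param K Number of normal components (1 for NUDGE).
#' @param data Data frame with `y` (and optionally `w`).
#' @param method Initialization method (see above).
#' @param seed Integer seed (controls k-means and random draws).
#' @param xi Optional fixed GNG offsets (positive `xi1`, `xi2`); estimated
#'   from the data when `NULL`.
#' @return A [mix_model()].
#' @export
initialize_model <- function(model_class, K, data,
                             method = c("kmeans", "quantile", "random"),
                             seed = 1L, xi = NULL) {
  method <- match.arg(method)
  data <- as_fit_data(data)
  y <- data$y
  K <- as.integer(K)
  if (model_class == "NUDGE" && K != 1L) abort("NUDGE requires K = 1.")
  if (K > length(unique(y))) {
    abort("K exceeds the number of distinct score values.")
  }
  vy <- var(y)

  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)

  if (K == 1L) {
    mu <- mean(y); s2 <- vy; gam <- 1
  } else if (method == "kmeans") {
    # init quality is non-critical; silence Quick-TRANSfer convergence noise
    km <- suppressWarnings(kmeans(y, centers = K, nstart = 5))
    ord <- order(km$centers)
    mu <- as.numeric(km$centers)[ord]
    s2 <- vapply(seq_len(K), function(k) {
      yk <- y[km$cluster == k]
      if (length(yk) > 1) var(yk) else vy / K
    }, numeric(1))[ord]
    s2 <- pmax(s2, 1e-6 * vy)
    gam <- (km$size / length(y))[ord]
  } else if (method == "quantile") {
    mu <- as.numeric(quantile(y, probs = seq_len(K) / (K + 1), type = 7))
    s2 <- rep(vy / K, K)
    gam <- rep(1 / K, K)
  } else {
    mu <- sort(runif(K, min(y), max(y)))
    s2 <- rep(vy, K)
    gam <- rep(1 / K, K)
  }

  normals <- tibble::tibble(mu = mu, sigma2 = s2, gamma = gam / sum(gam))
  if (model_class == "GNG") {
    xi <- if (is.null(xi)) estimate_xi(y) else as.list(xi)
    mix_model("GNG", pi = 0.1, normals = normals, rho = 0.5,
              beta1 = 1, beta2 = 1, xi1 = xi$xi1, xi2 = xi$xi2)
  } else {
    mix_model(model_class, pi = 0.1, normals = normals,
              a = min(y), b = max(y))
  }
}

#' One E-step: posterior component responsibilities
#'
#' Returns the `n x (K + parts)` matrix of posterior probabilities that
#' each observation arose from each component, given the current model.
#' Rows sum to 1. Exposed mainly for inspection and testing; [fit_mixture()]
#' runs the full iteration in compiled code.
#'
#' @param model A [mix_model()].
#' @param data Data frame with `y` (and optionally `w`; weights do not
#'   enter the responsibilities).
#' @return Responsibility matrix with rows summing to 1.
#' @export
e_step <- function(model, data) {
  data <- as_fit_data(data)
  dens <- component_densities(model, data$y)
  wd <- sweep(dens, 2, component_weights(model), `*`)
  tot <- rowSums(wd)
  bad <- which(tot < 1e-300)
  if (length(bad) > 0) {
    abort(sprintf("all components have zero density at observation %d (y = %g).",
                  bad[1], data$y[bad[1]]))
  }
  wd / tot
}

#' One M-step: weighted-likelihood parameter updates
#'
#' Given responsibilities, maximizes the weighted log-likelihood
#' `sum_i w_i log f(y_i)` in closed form: every sum is taken with weights
#' `w_i * r_ik`, so `pi`, the normal proportions, means and variances, and
#' the exponential mixing/scale parameters are weighted moments. The
#' uniform bounds and exponential offsets are fixed and left untouched. A
#' component whose total weighted responsibility falls below `1e-10` keeps
#' its previous parameters and a warning attribute is set.
#'
#' @param resp Responsibility matrix from [e_step()].
#' @param data Data frame with `y` and `w`.
#' @param model The current [mix_model()].
#' @return The updated [mix_model()]; attribute `"warnings"` lists any
#'   variance-floor or frozen-component events.
#' @export
m_step <- function(resp, data, model) {
  data <- as_fit_data(data)
  y <- data$y; w <- data$w
  K <- model$K
  P <- if (model$model_class == "GNG") 2L else 1L
  stopifnot(ncol(resp) == K + P, nrow(resp) == length(y))
  sw <- sum(w)
  warns <- character()
  var_floor <- 1e-6 * var(y)

  pi_new <- sum(w * rowSums(resp[, K + seq_len(P), drop = FALSE])) / sw

  mass <- vapply(seq_len(K), function(k) sum(w * resp[, k]), numeric(1))
  normals <- model$normals
  if (sum(mass) > 1e-10) normals$gamma <- mass / sum(mass)
  for (k in seq_len(K)) {
    if (mass[k] < 1e-10) {
      warns <- c(warns, sprintf("normal component %d collapsed; parameters frozen", k))
      next
    }
    wr <- w * resp[, k]
    normals$mu[k] <- sum(wr * y) / mass[k]
    s2 <- sum(wr * (y - normals$mu[k])^2) / mass[k]
    if (s2 < var_floor) {
      s2 <- var_floor
      warns <- c(warns, sprintf("variance of normal component %d hit the floor (possible singularity)", k))
    }
    normals$sigma2[k] <- s2
  }

  f1 <- model$f1
  if (model$model_class == "GNG") {
    m1 <- sum(w * resp[, K + 1]); m2 <- sum(w * resp[, K + 2])
    if (m1 + m2 > 1e-10) f1$rho <- m1 / (m1 + m2)
    if (m1 > 1e-10) {
      f1$beta1 <- max(sum(w * resp[, K + 1] * (-y - f1$xi1)) / m1, 1e-10)
    }
    if (m2 > 1e-10) {
      f1$beta2 <- max(sum(w * resp[, K + 2] * (y - f1$xi2)) / m2, 1e-10)
    }
  }

  out <- if (model$model_class == "GNG") {
    mix_model("GNG", pi = pi_new, normals = normals, rho = f1$rho,
              beta1 = f1$beta1, beta2 = f1$beta2, xi1 = f1$xi1, xi2 = f1$xi2)
  } else {
    mix_model(model$model_class, pi = pi_new, normals = normals,
              a = f1$a, b = f1$b)
  }
  attr(out, "warnings") <- warns
  out
}

#' Weighted log-likelihood of a model on a dataset
#'
#' @param model A [mix_model()].
#' @param data Data frame with `y` and optionally `w`.
#' @return `sum_i w_i log f(y_i)`.
#' @export
weighted_loglik <- function(model, data) {
  data <- as_fit_data(data)
  f <- mixture_density(model, data$y)
  keep <- data$w > 0
  sum(data$w[keep] * log(f[keep]))
}

free_params <- function(model) {
  p <- c(pi = model$pi, model$normals$gamma, model$normals$mu,
         model$normals$sigma2)
  if (model$model_class == "GNG") {
    p <- c(p, model$f1$rho, model$f1$beta1, model$f1$beta2)
  }
  unname(p)
}

#' Fit one mixture model class by weighted-likelihood EM
#'
#' Runs `n_restarts` EM runs (first from `init_method`, the rest from
#' random starts) and keeps the run with the highest weighted
#' log-likelihood. Within every run the weighted log-likelihood is
#' nondecreasing; a run stops when the largest absolute parameter change
#' drops below `tol` or after `max_iter` iterations. Component variances
#' are clamped at `1e-6 * var(y)`; hitting that floor, or a component
#' losing essentially all responsibility, is recorded in `warnings`.
#'
#' @param model_class `"NUDGE"`, `"iNUDGE"`, or `"GNG"`.
#' @param K Number of normal components (forced to 1 for NUDGE).
#' @param data Data frame with `y` and optionally `w` (see
#'   [compute_weights()]); missing `w` means unit weights.
#' @param control An [em_control()].
#' @param xi Optional list or named vector with positive `xi1`, `xi2`
#'   fixing the GNG exponential offsets; by default they are estimated
#'   from the data via [estimate_xi()]. They are treated as known and are
#'   never updated by EM.
#' @return An object of class `mix_fit`: a list with elements `model`,
#'   `loglik`, `n_params`, `bic`, `aic`, `n_iter`, `converged`,
#'   `warnings`, `loglik_trace`, `restart`, and `n`.
#' @examples
#' d <- simulate_scores(n = 500, seed = 4)
#' fit_mixture("iNUDGE", K = 2, d, em_control(n_restarts = 1, seed = 1))
#' @export
fit_mixture <- function(model_class = c("NUDGE", "iNUDGE", "GNG"), K = 1,
                        data, control = em_control(), xi = NULL) {
  model_class <- match.arg(model_class)
  data <- as_fit_data(data)
  if (model_class == "NUDGE") K <- 1L
  K <- as.integer(K)
  n <- nrow(data)
  if (model_class == "GNG" && is.null(xi)) {
    estimate_xi(data$y)  # fail early if inapplicable
  }

  p_free <- 3L * K + if (model_class == "GNG") 3L else 0L
  if (n < p_free) abort("fewer observations than free parameters.")
  var_floor <- 1e-6 * var(data$y)

  best <- NULL
  for (r in seq_len(control$n_restarts)) {
    seed_r <- (control$seed + 104729L * (r - 1L)) %% .Machine$integer.max
    method_r <- if (r == 1L) control$init_method else "random"
    init <- initialize_model(model_class, K, data, method = method_r,
                             seed = seed_r, xi = xi)
    family <- if (model_class == "GNG") 1L else 0L
    res <- em_run_cpp(
      data$y, data$w, family,
      init$pi, init$normals$gamma, init$normals$mu, init$normals$sigma2,
      rho = init$f1$rho %||% 0.5, beta1 = init$f1$beta1 %||% 1,
      beta2 = init$f1$beta2 %||% 1, a = init$f1$a %||% 0,
      b = init$f1$b %||% 1, xi1 = init$f1$xi1 %||% 1,
      xi2 = init$f1$xi2 %||% 1,
      tol = control$tol, max_iter = control$max_iter, var_floor = var_floor
    )
    if (is.null(best) || res$loglik > best$loglik + 1e-12) {
      best <- res
      best$restart <- r
      best$init <- init
    }
  }

  normals <- tibble::tibble(mu = as.numeric(best$mu),
                            sigma2 = as.numeric(best$sigma2),
                            gamma = as.numeric(best$gamma) /
                              sum(as.numeric(best$gamma)))
  model <- if (model_class == "GNG") {
    mix_model("GNG", pi = best$pi, normals = normals, rho = best$rho,
              beta1 = best$beta1, beta2 = best$beta2,
              xi1 = best$init$f1$xi1, xi2 = best$init$f1$xi2)
  } else {
    mix_model(model_class, pi = best$pi, normals = normals,
              a = best$init$f1$a, b = best$init$f1$b)
  }

  warns <- character()
  if (best$floor_hit) {
    warns <- c(warns, "a component variance hit the floor (possible singularity)")
  }
  if (best$frozen) {
    warns <- c(warns, "a component lost all responsibility and was frozen")
  }
  p <- count_params(model)
  structure(
    list(model = model, loglik = best$loglik, n_params = p,
         bic = 2 * best$loglik - p * log(n), aic = 2 * best$loglik - 2 * p,
         n_iter = best$n_iter, converged = best$converged, warnings = warns,
         loglik_trace = as.numeric(best$loglik_trace),
         restart = best$restart, n = n),
    class = "mix_fit"
  )
}

#' @export
print.mix_fit <- function(x, ...) {
  cat(sprintf("<mix_fit> %s (K = %d): loglik = %.3f, BIC = %.3f, AIC = %.3f\n",
              x$model$model_class, x$model$K, x$loglik, x$bic, x$aic))
  cat(sprintf("  %s after %d iterations (restart %d)\n",
              if (x$converged) "converged" else "NOT converged",
              x$n_iter, x$restart))
  for (wn in x$warnings) cat("  warning:", wn, "\n")
  invisible(x)
}

#' @method tidy mix_fit
#' @export
tidy.mix_fit <- function(x, ...) {
  m <- x$model
  out <- tibble::tibble(
    component = paste0("normal", seq_len(m$K)),
    type = "normal",
    weight = (1 - m$pi) * m$normals$gamma,
    mu = m$normals$mu, sigma2 = m$normals$sigma2
  )
  if (m$model_class == "GNG") {
    out <- dplyr::bind_rows(out, tibble::tibble(
      component = c("exp_negative", "exp_positive"), type = "exponential",
      weight = m$pi * c(m$f1$rho, 1 - m$f1$rho),
      mu = c(-m$f1$xi1 - m$f1$beta1, m$f1$xi2 + m$f1$beta2),
      sigma2 = c(m$f1$beta1^2, m$f1$beta2^2)
    ))
  } else {
    out <- dplyr::bind_rows(out, tibble::tibble(
      component = "uniform", type = "uniform", weight = m$pi,
      mu = (m$f1$a + m$f1$b) / 2, sigma2 = (m$f1$b - m$f1$a)^2 / 12
    ))
  }
  out
}

#' @method glance mix_fit
#' @export
glance.mix_fit <- function(x, ...) {
  tibble::tibble(model_class = x$model$model_class, K = x$model$K,
                 loglik = x$loglik, n_params = x$n_params, bic = x$bic,
                 aic = x$aic, n_iter = x$n_iter, converged = x$converged,
                 n_warnings = length(x$warnings), n = x$n)
}
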