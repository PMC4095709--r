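#' Simulate two-condition log-expression for differential units
#'
#' Control-sample log-expression is uniform on (15, 30); the treatment
#' sample adds intensity-dependent noise and a signed effect:
#' `x2 = x1 + Z + (2B - 1) G` with `Z ~ N(0, 0.7 - 0.02 x1)` (the second
#' argument read as a variance, so lower-expressed units are noisier),
#' `B ~ Bernoulli(0.5)` choosing over- or under-expression, and the effect
#' size `G` drawn from one of three laws emulating different data types:
#' `exponential` (scale 1.4286, shifted by +1), `uniform` on (1, 4), or
#' `normal` with mean 2.5 and sd 0.75.
#'
#' @param m Number of differential units.
#' @param g_law `"exponential"`, `"uniform"`, or `"normal"`.
#' @param g_params Law-specific parameters; defaults
#'   `list(scale = 1.4286, offset = 1)`, `list(min = 1, max = 4)`, or
#'   `list(mean = 2.5, sd = 0.75)`.
#' @param seed Integer seed.
#' @param z_dispersion Whether `0.7 - 0.02 * x1` is the variance (default)
#'   or the sd of the intensity-dependent noise.
#' @return Tibble with columns `x1`, `x2`.
#' @export
simulate_differential <- function(m, g_law = c("exponential", "uniform", "normal"),
                                  g_params = NULL, seed = 1L,
                                  z_dispersion = c("variance", "sd")) {
  g_law <- match.arg(g_law)
  z_dispersion <- match.arg(z_dispersion)
  stopifnot(m >= 1)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)

  x1 <- runif(m, 15, 30)
  disp <- 0.7 - 0.02 * x1
  z_sd <- if (z_dispersion == "variance") sqrt(disp) else disp
  z <- rnorm(m, 0, z_sd)
  b <- rbinom(m, 1, 0.5)
  g <- switch(g_law,
    exponential = {
      p <- g_params %||% list(scale = 1.4286, offset = 1)
      rexp(m, rate = 1 / p$scale) + p$offset
    },
    uniform = {
      p <- g_params %||% list(min = 1, max = 4)
      runif(m, p$min, p$max)
    },
    normal = {
      p <- g_params %||% list(mean = 2.5, sd = 0.75)
      rnorm(m, p$mean, p$sd)
    }
  )
  tibble::tibble(x1 = x1, x2 = x1 + z + (2 * b - 1) * g)
}

#' Simulate two-condition log-expression for nondifferential units
#'
#' Null differences emulate the empirical null of a spotted-array
#' comparison, where nondifferential log-ratios stay within one unit of
#' zero. By default `x2 - x1` is drawn from a synthetic parametric
#' stand-in, N(0, 0.25^2) truncated to `[-1, 1]`; alternatively a pool of
#' real null differences (single-column text file or numeric vector, all
#' within `[-1, 1]`) is resampled with replacement.
#'
#' @param m Number of null units.
#' @param null_source `"parametric"` or `"pool"`.
#' @param pool Numeric vector of null differences, or a path to a
#'   single-column text file of them (required when
#'   `null_source = "pool"`).
#' @param seed Integer seed.
#' @return Tibble with columns `x1`, `x2`; all `|x2 - x1| <= 1`.
#' @export
simulate_null <- function(m, null_source = c("parametric", "pool"),
                          pool = NULL, seed = 1L) {
  null_source <- match.arg(null_source)
  stopifnot(m >= 1)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)

  x1 <- runif(m, 15, 30)
  if (null_source == "pool") {
    if (is.character(pool)) pool <- scan(pool, quiet = TRUE)
    if (is.null(pool) || length(pool) == 0) {
      abort("`pool` must supply at least one null difference.")
    }
    if (any(abs(pool) > 1)) {
      abort("pool values must have absolute value at most 1.")
    }
    d <- sample(pool, m, replace = TRUE)
  } else {
    # rejection sampling from N(0, 0.25^2) truncated to [-1, 1] (|z| <= 4 sd,
    # so acceptance is essentially 1)
    d <- rnorm(m, 0, 0.25)
    while (any(abs(d) > 1)) {
      bad <- abs(d) > 1
      d[bad] <- rnorm(sum(bad), 0, 0.25)
    }
  }
  tibble::tibble(x1 = x1, x2 = x1 + d)
}

#' Simulate a complete two-condition dataset with known truth
#'
#' Combines `round(n * p_diff)` differential and `n - round(n * p_diff)`
#' null units, shuffles their order, and returns per-unit difference
#' scores `y = x2 - x1`, average log-intensities `u = (x1 + x2) / 2`, and
#' the ground-truth differential labels. Identical seeds give identical
#' output.
#'
#' @param n Total number of units; default 10000.
#' @param p_diff Differential fraction in (0, 1); default 0.10.
#' @inheritParams simulate_differential
#' @inheritParams simulate_null
#' @return Tibble with columns `id`, `x1`, `x2`, `y`, `u`, `truth`.
#' @examples
#' d <- simulate_scores(n = 100, seed = 1)
#' sum(d$truth)
#' @export
simulate_scores <- function(n = 10000, p_diff = 0.10,
                            g_law = c("exponential", "uniform", "normal"),
                            g_params = NULL,
                            null_source = c("parametric", "pool"),
                            pool = NULL, seed = 1L,
                            z_dispersion = c("variance", "sd")) {
  stopifnot(n >= 2, p_diff > 0, p_diff < 1)
  m_diff <- round(n * p_diff)
  if (m_diff < 1) abort("`n * p_diff` rounds to zero differential units.")
  seed <- as.integer(seed)
  diff <- simulate_differential(m_diff, g_law = g_law, g_params = g_params,
                                seed = seed, z_dispersion = z_dispersion)
  null <- simulate_null(n - m_diff, null_source = null_source, pool = pool,
                        seed = (seed + 1L) %% .Machine$integer.max)

  out <- dplyr::bind_rows(
    dplyr::mutate(diff, truth = TRUE),
    dplyr::mutate(null, truth = FALSE)
  )
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed((seed + 2L) %% .Machine$integer.max)
  out <- out[sample.int(n), ]
  dplyr::mutate(out,
                id = paste0("unit", seq_len(n)),
                y = .data$x2 - .data$x1,
                u = (.data$x1 + .data$x2) / 2,
                .before = 1)
}

#' Run a replicated simulation study of the full pipeline
#'
#' For each replicate: simulate a dataset, derive lower-half Huber weights
#' from the average intensities, fit the ensemble, classify at `z0`, and
#' score every class (and the AIC-chosen ensemble pick) against the
#' ground truth. Deterministic given the master seed.
#'
#' @inheritParams simulate_scores
#' @param n_reps Number of replicate datasets.
#' @param z0 Call threshold; default 0.1.
#' @param K_max Largest order scanned; default 6.
#' @param weight_fun,tail Robustness weighting for the pipeline; defaults
#'   lower-half Huber.
#' @param control An [em_control()]; its seed is overridden per replicate.
#'   The study default uses two starts per fit (k-means plus one random
#'   start): at this sample size the k-means start already reaches the
#'   same optimum as larger restart counts.
#' @return Tibble with one row per replicate and model class (plus an
#'   `ensemble` row duplicating the chosen class): `rep`, `class`, `K`,
#'   `tpr`, `fpr`, `chosen`.
#' @export
run_simulation_study <- function(n_reps = 10, n = 10000, p_diff = 0.10,
                                 g_law = c("exponential", "uniform", "normal"),
                                 g_params = NULL,
                                 null_source = c("parametric", "pool"),
                                 pool = NULL, seed = 1L, z0 = 0.1, K_max = 6,
                                 weight_fun = "huber", tail = "lower",
                                 control = em_control(n_restarts = 2)) {
  stopifnot(n_reps >= 1)
  g_law <- match.arg(g_law)
  seed <- as.integer(seed)
  purrr::map_dfr(seq_len(n_reps), function(r) {
    seed_r <- (seed + 7907L * r) %% .Machine$integer.max
    d <- simulate_scores(n = n, p_diff = p_diff, g_law = g_law,
                         g_params = g_params, null_source = null_source,
                         pool = pool, seed = seed_r)
    ctrl <- control
    ctrl$seed <- seed_r
    ens <- tryCatch(
      fit_mixture_ensemble(d, weight_fun = weight_fun, tail = tail,
                           K_max = K_max, z0 = z0, control = ctrl),
      error = function(e) {
        abort(sprintf("replicate %d failed: %s", r, conditionMessage(e)))
      }
    )
    rows <- purrr::map_dfr(ens$best_within, function(f) {
      labs <- label_components(f$model, ens$data)
      fdr <- local_fdr(f$model, labs, ens$data$y)
      calls <- call_differential(fdr, ens$data$w, z0 = z0)
      dplyr::mutate(evaluate_calls(calls, d$truth),
                    class = f$model$model_class, K = f$model$K,
                    chosen = identical(f$model$model_class,
                                       ens$best$model$model_class),
                    .before = 1)
    })
    chosen_row <- dplyr::filter(rows, .data$chosen)
    rows <- dplyr::bind_rows(rows, dplyr::mutate(chosen_row, class = "ensemble"))
    dplyr::mutate(rows, rep = r, .before = 1)
  })
}
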