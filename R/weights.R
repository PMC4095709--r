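#' Standardize average log-intensities
#'
#' Centres and scales a numeric vector to sample mean 0 and sample standard
#' deviation 1. Robustness weights are defined on this standardized scale, so
#' average log-intensities must pass through here before any weight function.
#'
#' @param u Numeric vector, length at least 2, non-constant.
#' @return Numeric vector with mean 0 and sd 1.
#' @examples
#' z <- standardize_intensity(c(1, 2, 3))
#' c(mean(z), sd(z))
#' @export
standardize_intensity <- function(u) {
  if (!is.numeric(u) || length(u) < 2) {
    abort("`u` must be a numeric vector of length >= 2.")
  }
  if (anyNA(u) || any(!is.finite(u))) {
    abort("`u` contains non-finite values.")
  }
  s <- sd(u)
  if (s == 0) {
    abort("`u` is constant (sd 0); intensities cannot be standardized.")
  }
  (u - mean(u)) / s
}

#' Huber robustness weights on standardized intensities
#'
#' Lower-half Huber weights downgrade units whose average log-intensity is
#' unusually small: the weight is 1 for `u > -c` and `c / |u|` below. The
#' upper-half variant mirrors this, and the two-tailed variant downweights
#' both tails (`min` of the two halves, i.e. 1 for `|u| < c`, else `c/|u|`).
#'
#' @param u Numeric vector of standardized intensities (mean 0, sd 1; see
#'   [standardize_intensity()]).
#' @param c Positive tuning constant; the default 1.345 is the classical
#'   Huber choice giving 95% efficiency at the normal.
#' @return Numeric vector of weights in `[0, 1]`.
#' @examples
#' huber_lower_weight(c(0, -1.345, -2.69))
#' @export
huber_lower_weight <- function(u, c = 1.345) {
  check_weight_const(c)
  stopifnot(is.numeric(u))
  ifelse(u > -c, 1, c / abs(u))
}

#' @rdname huber_lower_weight
#' @export
huber_upper_weight <- function(u, c = 1.345) {
  huber_lower_weight(-u, c = c)
}

#' @rdname huber_lower_weight
#' @export
huber_two_tailed_weight <- function(u, c = 1.345) {
  pmin(huber_lower_weight(u, c = c), huber_upper_weight(u, c = c))
}

#' Tukey bisquare-style robustness weights
#'
#' A smooth lower-half taper: weight 1 for `u > -c`, the bisquare factor
#' `(1 - ((u + c) / taper)^2)^2` on `[-c - taper, -c]`, and 0 below. Unlike
#' the Huber weight this redescends to exactly zero, removing the most
#' extreme low-intensity units entirely. Upper and two-tailed variants
#' mirror/combine the lower half.
#'
#' @inheritParams huber_lower_weight
#' @param taper Positive width of the descent region; default 4.685, the
#'   classical bisquare constant.
#' @return Numeric vector of weights in `[0, 1]`.
#' @export
tukey_lower_weight <- function(u, c = 1.345, taper = 4.685) {
  check_weight_const(c)
  if (!is.numeric(taper) || length(taper) != 1 || !is.finite(taper) || taper <= 0) {
    abort("`taper` must be a single positive number.")
  }
  stopifnot(is.numeric(u))
  w <- rep(1, length(u))
  mid <- u <= -c & u >= -c - taper
  w[mid] <- (1 - ((u[mid] + c) / taper)^2)^2
  w[u < -c - taper] <- 0
  w
}

#' @rdname tukey_lower_weight
#' @export
tukey_upper_weight <- function(u, c = 1.345, taper = 4.685) {
  tukey_lower_weight(-u, c = c, taper = taper)
}

#' @rdname tukey_lower_weight
#' @export
tukey_two_tailed_weight <- function(u, c = 1.345, taper = 4.685) {
  pmin(tukey_lower_weight(u, c, taper), tukey_upper_weight(u, c, taper))
}

check_weight_const <- function(c) {
  if (!is.numeric(c) || length(c) != 1 || !is.finite(c) || c <= 0) {
    abort("`c` must be a single positive number.")
  }
  invisible(c)
}

#' Attach robustness weights to a score table
#'
#' Given a table of difference scores with an optional average log-intensity
#' column `u`, standardizes `u` and adds a weight column `w`. Without `u`
#' (or with `weight_fun = "none"`) all weights are 1.
#'
#' @param data Data frame with a numeric `y` column and optionally `u`.
#' @param weight_fun One of `"huber"`, `"tukey"`, `"none"`.
#' @param tail One of `"lower"`, `"upper"`, `"two_tailed"`; which intensity
#'   tail to downweight.
#' @param c,taper Tuning constants passed to the weight function.
#' @return The input as a tibble with a `w` column in `[0, 1]`.
#' @examples
#' d <- tibble::tibble(y = rnorm(5), u = c(10, 11, 9, 2, 12))
#' compute_weights(d)
#' @export
compute_weights <- function(data, weight_fun = c("huber", "tukey", "none"),
                            tail = c("lower", "upper", "two_tailed"),
                            c = 1.345, taper = 4.685) {
  weight_fun <- match.arg(weight_fun)
  tail <- match.arg(tail)
  data <- tibble::as_tibble(data)
  if (!"y" %in% names(data)) abort("`data` must contain a `y` column.")
  if (weight_fun == "none" || !"u" %in% names(data)) {
    data$w <- rep(1, nrow(data))
    return(data)
  }
  z <- standardize_intensity(data$u)
  data$w <- switch(
    paste(weight_fun, tail, sep = "_"),
    huber_lower      = huber_lower_weight(z, c),
    huber_upper      = huber_upper_weight(z, c),
    huber_two_tailed = huber_two_tailed_weight(z, c),
    tukey_lower      = tukey_lower_weight(z, c, taper),
    tukey_upper      = tukey_upper_weight(z, c, taper),
    tukey_two_tailed = tukey_two_tailed_weight(z, c, taper)
  )
  data
}
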