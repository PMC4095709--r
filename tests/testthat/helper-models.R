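# Fixture builders shared across the suite. Everything is generated in
# code under fixed seeds; no stored data.

random_model <- function(model_class, K = sample(1:3, 1)) {
  if (model_class == "NUDGE") K <- 1L
  gam <- runif(K, 0.2, 1)
  normals <- tibble::tibble(
    mu = sort(runif(K, -3, 3)),
    sigma2 = runif(K, 0.05, 2),
    gamma = gam / sum(gam)
  )
  pi <- runif(1, 0, 0.5)
  if (model_class == "GNG") {
    mix_model("GNG", pi = pi, normals = normals, rho = runif(1),
              beta1 = runif(1, 0.3, 3), beta2 = runif(1, 0.3, 3),
              xi1 = runif(1, 0.1, 1.5), xi2 = runif(1, 0.1, 1.5))
  } else {
    mix_model(model_class, pi = pi, normals = normals, a = -8, b = 8)
  }
}

# Draws from known truths for parameter-recovery checks.
draw_nudge <- function(n, seed, pi = 0.1) {
  set.seed(seed)
  k <- runif(n) < pi
  tibble::tibble(y = ifelse(k, runif(n, -5, 5), rnorm(n)))
}

draw_gng <- function(n, seed) {
  # pi = 0.2, rho = 0.5, beta = (1.5, 2), xi = (1, 1), f0 = N(0, 0.3^2)
  set.seed(seed)
  u <- runif(n)
  y <- rnorm(n, 0, 0.3)
  e1 <- u < 0.1
  e2 <- u >= 0.1 & u < 0.2
  y[e1] <- -(1 + rexp(sum(e1), 1 / 1.5))
  y[e2] <- 1 + rexp(sum(e2), 1 / 2)
  tibble::tibble(y = y)
}

draw_inudge2 <- function(n, seed) {
  # pi = 0.1 uniform(-6, 6); normals N(-1, 0.5^2), N(1, 0.8^2) equal weight
  set.seed(seed)
  u <- runif(n)
  y <- ifelse(u < 0.1, runif(n, -6, 6),
              ifelse(u < 0.55, rnorm(n, -1, 0.5), rnorm(n, 1, 0.8)))
  tibble::tibble(y = y)
}

# Numerical total-mass check: adaptive quadrature piecewise between the
# model's natural knots (component centres, support edges), so sharp
# components cannot be stepped over.
model_mass <- function(model) {
  knots <- model$normals$mu
  if (model$model_class == "GNG") {
    knots <- c(knots, -model$f1$xi1, model$f1$xi2)
  } else {
    knots <- c(knots, model$f1$a, model$f1$b)
  }
  knots <- sort(unique(knots))
  ends <- c(-Inf, knots, Inf)
  sum(vapply(seq_len(length(ends) - 1), function(i) {
    stats::integrate(function(y) mixture_density(model, y),
                     ends[i], ends[i + 1], rel.tol = 1e-10,
                     subdivisions = 1000L)$value
  }, numeric(1)))
}
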