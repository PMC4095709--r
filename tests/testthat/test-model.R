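test_that("mixture density reduces to known closed forms", {
  nudge <- mix_model("NUDGE", pi = 0,
                     normals = data.frame(mu = 0, sigma2 = 1, gamma = 1),
                     a = -5, b = 5)
  expect_equal(mixture_density(nudge, 0), 1 / sqrt(2 * pi))

  inudge <- mix_model("iNUDGE", pi = 1,
                      normals = data.frame(mu = 1, sigma2 = 1, gamma = 1),
                      a = 0, b = 2)
  expect_equal(mixture_density(inudge, 1), 0.5)

  gng <- mix_model("GNG", pi = 1,
                   normals = data.frame(mu = 0, sigma2 = 1, gamma = 1),
                   rho = 1, beta1 = 1, beta2 = 1, xi1 = 0.5, xi2 = 0.5)
  expect_equal(mixture_density(gng, -1.5), exp(-1))
  expect_equal(mixture_density(gng, 0), 0)  # inside the offset gap
})

test_that("density rejects invalid models and scores", {
  bad <- mix_model("NUDGE", pi = 0.1,
                   normals = data.frame(mu = 0, sigma2 = 1, gamma = 1),
                   a = -1, b = 1)
  bad$normals$gamma <- 0.7
  expect_error(mixture_density(bad, 0), "sum to 1")
  ok <- random_model("iNUDGE")
  expect_error(mixture_density(ok, c(0, NA)), "non-finite")
  expect_error(mixture_density(ok, Inf), "non-finite")
})

test_that("component densities reassemble the mixture and respect support", {
  set.seed(71)
  y <- seq(-6, 6, length.out = 101)
  for (cl in c("NUDGE", "iNUDGE", "GNG")) {
    for (rep in 1:5) {
      m <- random_model(cl)
      dens <- component_densities(m, y)
      w <- mixdiff:::component_weights(m)
      expect_equal(as.numeric(dens %*% w), mixture_density(m, y),
                   tolerance = 1e-12)
    }
  }
  gng <- mix_model("GNG", pi = 0.5,
                   normals = data.frame(mu = 0, sigma2 = 1, gamma = 1),
                   rho = 0.5, beta1 = 1, beta2 = 1, xi1 = 0.4, xi2 = 0.6)
  dens <- component_densities(gng, 0)
  expect_equal(unname(dens[1, c("E1", "E2")]), c(0, 0))
  inudge <- mix_model("iNUDGE", pi = 0.3,
                      normals = data.frame(mu = c(-1, 1), sigma2 = c(1, 1),
                                           gamma = c(0.5, 0.5)),
                      a = -2, b = 2)
  expect_equal(unname(component_densities(inudge, c(-1, 0, 1))[, "U"]),
               rep(0.25, 3))
})

test_that("every model class integrates to unit mass", {
  set.seed(99)
  for (cl in c("NUDGE", "iNUDGE", "GNG")) {
    for (rep in 1:10) {
      expect_equal(model_mass(random_model(cl)), 1, tolerance = 1e-6)
    }
  }
})

test_that("iNUDGE with K = 1 and NUDGE give identical densities", {
  normals <- data.frame(mu = 0.3, sigma2 = 0.8, gamma = 1)
  a <- -4; b <- 4
  m1 <- mix_model("NUDGE", pi = 0.15, normals = normals, a = a, b = b)
  m2 <- mix_model("iNUDGE", pi = 0.15, normals = normals, a = a, b = b)
  y <- seq(-5, 5, length.out = 201)
  expect_equal(mixture_density(m1, y), mixture_density(m2, y))
})

test_that("exponential offsets are estimated from the data boundary", {
  expect_equal(estimate_xi(c(-2, -0.5, 0.3, 1)), list(xi1 = 0.5, xi2 = 0.3))
  expect_equal(estimate_xi(c(-1, 1)), list(xi1 = 1, xi2 = 1))
  expect_error(estimate_xi(c(0.1, 0.2)), "GNG")
  expect_error(estimate_xi(c(-0.1, -0.2)), "GNG")
})

test_that("free-parameter counts follow the fixed-bounds convention", {
  nudge <- mix_model("NUDGE", pi = 0.1,
                     normals = data.frame(mu = 0, sigma2 = 1, gamma = 1),
                     a = -1, b = 1)
  expect_identical(count_params(nudge), 3L)
  g2 <- runif(2); g2 <- g2 / sum(g2)
  inudge <- mix_model("iNUDGE", pi = 0.1,
                      normals = data.frame(mu = c(0, 1), sigma2 = c(1, 1),
                                           gamma = g2),
                      a = -1, b = 1)
  expect_identical(count_params(inudge), 6L)
  g3 <- rep(1 / 3, 3)
  gng <- mix_model("GNG", pi = 0.1,
                   normals = data.frame(mu = c(-1, 0, 1),
                                        sigma2 = c(1, 1, 1), gamma = g3),
                   rho = 0.5, beta1 = 1, beta2 = 1, xi1 = 1, xi2 = 1)
  expect_identical(count_params(gng), 12L)
})
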