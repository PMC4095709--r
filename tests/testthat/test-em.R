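test_that("E-step responsibilities are proper posteriors", {
  set.seed(13)
  d <- tibble::tibble(y = rnorm(200))
  for (cl in c("NUDGE", "iNUDGE", "GNG")) {
    m <- random_model(cl)
    r <- e_step(m, d)
    expect_true(all(r >= 0))
    expect_equal(rowSums(r), rep(1, nrow(d)), tolerance = 1e-12)
  }
  # pi = 0: the differential family never claims responsibility
  m0 <- mix_model("iNUDGE", pi = 0,
                  normals = data.frame(mu = 0, sigma2 = 1, gamma = 1),
                  a = -5, b = 5)
  r0 <- e_step(m0, d)
  expect_equal(unname(r0[, "U"]), rep(0, nrow(d)))
  expect_equal(unname(r0[, "N1"]), rep(1, nrow(d)))
})

test_that("M-step reproduces closed-form weighted estimates", {
  # two symmetric points, all mass on the single normal
  d <- tibble::tibble(y = c(-1, 1), w = c(1, 1))
  m <- mix_model("NUDGE", pi = 0,
                 normals = data.frame(mu = 0.5, sigma2 = 2, gamma = 1),
                 a = -1, b = 1)
  resp <- matrix(c(1, 1, 0, 0), nrow = 2)
  out <- m_step(resp, d, m)
  expect_equal(out$normals$mu, 0)
  expect_equal(out$normals$sigma2, 1)
  expect_equal(out$pi, 0)

  # with unit weights and all responsibility on the normal, the update is
  # the ordinary MLE (1/n variance)
  set.seed(5)
  y <- rnorm(500, 2, 1.5)
  d2 <- tibble::tibble(y = y, w = rep(1, 500))
  resp2 <- cbind(rep(1, 500), rep(0, 500))
  out2 <- m_step(resp2, d2, m)
  expect_equal(out2$normals$mu, mean(y))
  expect_equal(out2$normals$sigma2, mean((y - mean(y))^2))
})

test_that("M-step is invariant to rescaling all weights", {
  set.seed(8)
  d <- tibble::tibble(y = rnorm(300), w = runif(300, 0.2, 1))
  m <- random_model("GNG")
  r <- e_step(m, d)
  a <- m_step(r, d, m)
  d_half <- dplyr::mutate(d, w = w / 2)  # halving = doubling up to clamp
  b <- m_step(r, d_half, m)
  expect_equal(a$pi, b$pi)
  expect_equal(a$normals, b$normals)
  expect_equal(a$f1, b$f1)
})

test_that("compiled EM iteration equals one R-stepped E+M iteration", {
  set.seed(21)
  d <- tibble::tibble(y = c(rnorm(400), runif(100, -4, 4)),
                      w = runif(500, 0.5, 1))
  for (cl in c("iNUDGE", "GNG")) {
    m0 <- initialize_model(cl, 2, d, "quantile", seed = 3)
    m1 <- m_step(e_step(m0, d), d, m0)
    fam <- if (cl == "GNG") 1L else 0L
    cpp <- mixdiff:::em_run_cpp(
      d$y, d$w, fam, m0$pi, m0$normals$gamma, m0$normals$mu,
      m0$normals$sigma2, m0$f1$rho %||% 0.5, m0$f1$beta1 %||% 1,
      m0$f1$beta2 %||% 1, m0$f1$a %||% 0, m0$f1$b %||% 1,
      m0$f1$xi1 %||% 1, m0$f1$xi2 %||% 1,
      tol = 1e300, max_iter = 1, var_floor = 1e-12)
    expect_equal(cpp$pi, m1$pi, tolerance = 1e-10)
    expect_equal(as.numeric(cpp$mu), m1$normals$mu, tolerance = 1e-10)
    expect_equal(as.numeric(cpp$sigma2), m1$normals$sigma2, tolerance = 1e-10)
    expect_equal(as.numeric(cpp$gamma), m1$normals$gamma, tolerance = 1e-10)
    if (cl == "GNG") {
      expect_equal(cpp$rho, m1$f1$rho, tolerance = 1e-10)
      expect_equal(cpp$beta1, m1$f1$beta1, tolerance = 1e-10)
      expect_equal(cpp$beta2, m1$f1$beta2, tolerance = 1e-10)
    }
  }
})

test_that("initialization is reproducible and matches stated conventions", {
  d <- tibble::tibble(y = c(-3, -1, 1, 3))
  q <- initialize_model("iNUDGE", 2, d, "quantile", seed = 1)
  expect_equal(q$normals$mu,
               as.numeric(quantile(d$y, c(1 / 3, 2 / 3), type = 7)))
  expect_equal(q$normals$sigma2, rep(var(d$y) / 2, 2))
  set.seed(2)
  d2 <- tibble::tibble(y = rnorm(100))
  one <- initialize_model("GNG", 1, d2, "kmeans", seed = 1)
  expect_equal(one$normals$mu, mean(d2$y))
  expect_equal(one$normals$sigma2, var(d2$y))
  expect_equal(one$pi, 0.1)
  expect_equal(one$f1$rho, 0.5)
  a <- initialize_model("iNUDGE", 3, d2, "random", seed = 42)
  b <- initialize_model("iNUDGE", 3, d2, "random", seed = 42)
  expect_identical(a, b)
  expect_error(initialize_model("iNUDGE", 5, tibble::tibble(y = c(1, 2, 1, 2)),
                                "kmeans", seed = 1),
               "distinct")
})

test_that("fitting recovers NUDGE truth and the loglik ascends", {
  d <- draw_nudge(20000, seed = 31)
  f <- fit_mixture("NUDGE", 1, d, em_control(seed = 1, n_restarts = 2))
  expect_lt(abs(f$model$pi - 0.1), 0.03)
  expect_lt(abs(f$model$normals$mu), 0.05)
  expect_lt(abs(f$model$normals$sigma2 - 1), 0.05)
  expect_true(f$converged)
  expect_false(is.unsorted(f$loglik_trace + 1e-8 * abs(f$loglik_trace)))
  # reported loglik is the weighted log-likelihood of the returned model
  expect_equal(f$loglik, weighted_loglik(f$model, d), tolerance = 1e-8)
})

test_that("fitting recovers GNG truth when offsets are known", {
  d <- draw_gng(20000, seed = 17)
  f <- fit_mixture("GNG", 1, d, em_control(seed = 1, n_restarts = 2),
                   xi = list(xi1 = 1, xi2 = 1))
  expect_lt(abs(f$model$pi - 0.2), 0.03)
  expect_lt(abs(f$model$f1$rho - 0.5), 0.05)
  expect_lt(abs(f$model$f1$beta1 - 1.5), 0.2)
  expect_lt(abs(f$model$f1$beta2 - 2), 0.2)
  expect_false(is.unsorted(f$loglik_trace + 1e-8 * abs(f$loglik)))
})

test_that("fitting recovers a two-component iNUDGE truth", {
  d <- draw_inudge2(20000, seed = 23)
  f <- fit_mixture("iNUDGE", 2, d, em_control(seed = 1, n_restarts = 2))
  o <- order(f$model$normals$mu)
  expect_lt(abs(f$model$normals$mu[o[1]] + 1), 0.1)
  expect_lt(abs(f$model$normals$mu[o[2]] - 1), 0.1)
  expect_lt(abs(f$model$normals$sigma2[o[1]] - 0.25), 0.1)
  expect_lt(abs(f$model$normals$sigma2[o[2]] - 0.64), 0.1)
})

test_that("recovery error shrinks as the sample grows", {
  err <- sapply(c(20000, 80000), function(n) {
    mean(sapply(1:3, function(s) {
      f <- fit_mixture("NUDGE", 1, draw_nudge(n, seed = 300 + s),
                       em_control(seed = s, n_restarts = 1))
      abs(f$model$pi - 0.1) + abs(f$model$normals$mu) +
        abs(f$model$normals$sigma2 - 1)
    }))
  })
  expect_lt(err[2], err[1])
})

test_that("iNUDGE with K = 1 and NUDGE reach the same fit", {
  d <- draw_nudge(3000, seed = 77)
  ctrl <- em_control(seed = 9, n_restarts = 1)
  a <- fit_mixture("NUDGE", 1, d, ctrl)
  b <- fit_mixture("iNUDGE", 1, d, ctrl)
  expect_equal(a$loglik, b$loglik, tolerance = 1e-6)
})

test_that("fits are bit-identical under a fixed seed", {
  d <- draw_nudge(2000, seed = 55)
  ctrl <- em_control(seed = 123, n_restarts = 3)
  a <- fit_mixture("iNUDGE", 2, d, ctrl)
  b <- fit_mixture("iNUDGE", 2, d, ctrl)
  expect_identical(a, b)
})

test_that("zero-weight observations carry no likelihood or M-step mass", {
  d <- draw_nudge(1000, seed = 61)
  d$w <- rep(1, nrow(d))
  spiked <- dplyr::bind_rows(d, tibble::tibble(y = rep(7, 25), w = 0))
  set.seed(91)
  m <- random_model("GNG")
  expect_equal(weighted_loglik(m, spiked), weighted_loglik(m, d))
  r_full <- e_step(m, spiked)
  expect_equal(nrow(r_full), nrow(spiked))  # responsibilities still defined
  upd_spiked <- m_step(r_full, spiked, m)
  upd_plain <- m_step(e_step(m, d), d, m)
  expect_equal(upd_spiked$pi, upd_plain$pi)
  expect_equal(upd_spiked$normals, upd_plain$normals)
  expect_equal(upd_spiked$f1, upd_plain$f1)
})

test_that("degenerate requests fail loudly", {
  expect_error(fit_mixture("GNG", 1, tibble::tibble(y = c(0.5, 1, 2)),
                           em_control(seed = 1)),
               "GNG")
  expect_error(fit_mixture("iNUDGE", 2, tibble::tibble(y = c(-1, 1)),
                           em_control(seed = 1)),
               "fewer observations|distinct")
})
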