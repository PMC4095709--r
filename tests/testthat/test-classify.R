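flat_model <- function(mus, sigma2s, gammas, pi = 0.1, a = -10, b = 10) {
  mix_model("iNUDGE", pi = pi,
            normals = data.frame(mu = mus, sigma2 = sigma2s, gamma = gammas),
            a = a, b = b)
}

test_that("IQR rule labels components by the stated strict inequality", {
  d <- tibble::tibble(y = rep(c(-1, 1), 500))  # IQR exactly 2, threshold 3
  m <- flat_model(mus = c(0, 4), sigma2s = c(0.01, 1), gammas = c(0.5, 0.5))
  lab <- label_components(m, d)
  expect_equal(lab$iqr, 2)
  expect_identical(lab$differential_normals, 2L)  # 0.2 < 3 < 6
  # |mu| + 2 sigma = 1.5 + 2 * 0.75 = 3 exactly: NOT differential
  m2 <- flat_model(mus = 1.5, sigma2s = 0.5625, gammas = 1)
  expect_length(label_components(m2, d)$differential_normals, 0)
  # just past the boundary flips the label
  m3 <- flat_model(mus = 1.5 + 1e-9, sigma2s = 0.5625, gammas = 1)
  expect_identical(label_components(m3, d)$differential_normals, 1L)
  expect_error(label_components(m, tibble::tibble(y = c(rep(0, 19), 1))),
               "zero")
})

test_that("local fdr is the nondifferential density share", {
  y <- seq(-6, 6, length.out = 121)
  d <- tibble::tibble(y = runif(500, -1, 1))
  # pi = 0 and nothing labeled differential: fdr identically 1
  m <- flat_model(mus = 0, sigma2s = 0.04, gammas = 1, pi = 0)
  lab <- structure(list(differential_normals = integer(), iqr = 1),
                   class = "mix_labels")
  expect_equal(local_fdr(m, lab, y), rep(1, length(y)))
  # everything differential: fdr identically 0
  lab_all <- structure(list(differential_normals = 1L, iqr = 1),
                       class = "mix_labels")
  expect_equal(local_fdr(m, lab_all, y), rep(0, length(y)))
  # heavy differential tail drives fdr to 0 far out
  m2 <- flat_model(mus = c(0, 0), sigma2s = c(0.04, 4), gammas = c(0.8, 0.2),
                   pi = 0.2, a = -50, b = 50)
  lab2 <- structure(list(differential_normals = 2L, iqr = 1),
                    class = "mix_labels")
  fdr2 <- local_fdr(m2, lab2, c(0, 3, 8, 20))
  expect_true(all(diff(fdr2) <= 0))
  expect_lt(fdr2[2], fdr2[1])
  expect_lt(fdr2[4], 1e-6)
  expect_true(all(fdr2 >= 0 & fdr2 <= 1))
})

test_that("fdr stays in [0,1] for random models and label sets", {
  set.seed(29)
  y <- seq(-8, 8, length.out = 200)
  for (rep in 1:20) {
    m <- random_model(sample(c("iNUDGE", "GNG"), 1))
    labs <- structure(
      list(differential_normals = which(runif(m$K) < 0.5), iqr = 1),
      class = "mix_labels")
    fdr <- local_fdr(m, labs, y)
    expect_true(all(fdr >= 0 & fdr <= 1))
  }
})

test_that("the weighted call rule behaves as specified", {
  expect_true(call_differential(0.05, 1, z0 = 0.1))
  expect_false(call_differential(0.05, 0.4, z0 = 0.1))  # 0.125 > 0.1
  expect_false(call_differential(0, 0, z0 = 0.1))       # zero weight never calls
  expect_error(call_differential(0.5, 1, z0 = 0), "z0")
  expect_error(call_differential(0.5, 1, z0 = 1.5), "z0")
  expect_error(call_differential(1.2, 1), "fdr")
})

test_that("calls are monotone in threshold and weight", {
  set.seed(77)
  fdr <- runif(300)
  w <- runif(300)
  c1 <- call_differential(fdr, w, z0 = 0.05)
  c2 <- call_differential(fdr, w, z0 = 0.2)
  expect_true(all(c2[c1]))  # lowering z0 never adds calls
  w_up <- pmin(w + 0.3, 1)
  c3 <- call_differential(fdr, w_up, z0 = 0.05)
  expect_true(all(c3[c1]))  # raising weights never removes calls
})

test_that("TPR/FPR arithmetic and degenerate truth handling", {
  perfect <- evaluate_calls(c(TRUE, TRUE, FALSE), c(TRUE, TRUE, FALSE))
  expect_equal(perfect$tpr, 1)
  expect_equal(perfect$fpr, 0)
  all_called <- evaluate_calls(rep(TRUE, 4), c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(all_called$tpr, 1)
  expect_equal(all_called$fpr, 1)
  truth <- rep(c(TRUE, FALSE), c(1000, 9000))
  calls <- rep(c(TRUE, FALSE, FALSE), c(900, 100, 9000))
  ev <- evaluate_calls(calls, truth)
  expect_equal(ev$tpr, 0.9)
  expect_equal(ev$fpr, 0)
  expect_error(evaluate_calls(c(TRUE, FALSE), c(TRUE, TRUE)), "negative")
})
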