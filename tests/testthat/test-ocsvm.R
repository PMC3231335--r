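test_that("the RBF kernel has its closed-form values and symmetry", {
  expect_identical(rbf_kernel(c(1, 2), c(1, 2), gamma = 3), 1)
  expect_equal(rbf_kernel(c(0, 0), c(1, 0), gamma = 1), exp(-1),
               tolerance = 1e-12)
  withr::with_seed(5, {
    for (i in 1:20) {
      x <- rnorm(4); y <- rnorm(4); g <- runif(1, 0.1, 10)
      expect_equal(rbf_kernel(x, y, g), rbf_kernel(y, x, g),
                   tolerance = 1e-15)
      expect_true(rbf_kernel(x, y, g) > 0 && rbf_kernel(x, y, g) <= 1)
    }
  })
  expect_error(rbf_kernel(c(1, 2), c(1, 2, 3), gamma = 1), "equal length")
})

test_that("dual feasibility holds for every fit", {
  withr::with_seed(31, {
    for (i in 1:10) {
      X <- matrix(rnorm(40 * 3, mean = 0.5, sd = 0.1), ncol = 3)
      nu <- runif(1, 0.05, 0.5)
      m <- fit_ocsvm(X, nu = nu, gamma = runif(1, 1, 30))
      a <- m$alpha_full
      expect_equal(sum(a), 1, tolerance = 1e-6)
      expect_true(all(a >= -1e-6))
      expect_true(all(a <= 1 / (nu * nrow(X)) + 1e-6))
    }
  })
})

test_that("a degenerate identical-point cluster is an inlier", {
  X <- matrix(rep(c(0.3, 0.5, 0.2), each = 10), nrow = 10)
  m <- fit_ocsvm(X, nu = 0.1, gamma = 1)
  expect_gte(decision_values(m, X[1, , drop = FALSE]), 0)
})

test_that("infeasible nu fails loudly", {
  X <- matrix(rnorm(8), ncol = 2)
  expect_error(fit_ocsvm(X, nu = 0.1, gamma = 1), "Infeasible nu")
})

test_that("the nu-property bounds outliers and support vectors empirically", {
  withr::with_seed(17, {
    for (rep in 1:20) {
      n <- 60
      X <- matrix(rnorm(n * 4, mean = 0.5, sd = 0.08), ncol = 4)
      nu <- sample(c(0.1, 0.2, 0.3), 1)
      m <- fit_ocsvm(X, nu = nu, gamma = 20)
      f <- decision_values(m, X)
      outlier_frac <- mean(f < -1e-8)
      sv_frac <- length(m$alpha) / n
      expect_lte(outlier_frac, nu + 0.05)
      expect_gte(sv_frac, nu - 0.05)
    }
  })
})

test_that("alphas and decision values match a dense QP oracle on small sets", {
  skip_if_not_installed("kernlab")
  withr::with_seed(63, {
    for (rep in 1:5) {
      n <- c(20, 25, 30, 18, 24)[rep]
      X <- matrix(rnorm(n * 2, mean = 0, sd = 1), ncol = 2)
      nu <- c(0.25, 0.2, 0.3, 0.5, 0.25)[rep]
      gamma <- c(0.5, 1, 0.3, 0.5, 2)[rep]
      m <- fit_ocsvm(X, nu = nu, gamma = gamma)
      a_oracle <- ipop_ocsvm_oracle(X, nu, gamma)
      expect_lt(max(abs(m$alpha_full - a_oracle)), 1e-4)
      # decision values from the oracle's alpha (same bias convention)
      K <- exp(-gamma * as.matrix(stats::dist(X))^2)
      g <- as.vector(K %*% a_oracle)
      C <- 1 / (nu * n)
      unb <- a_oracle > 1e-6 & a_oracle < C - 1e-6
      b_oracle <- mean(g[unb])
      f_oracle <- g - b_oracle
      expect_lt(max(abs(decision_values(m, X) - f_oracle)), 1e-4)
    }
  })
})

test_that("decision values agree with LIBSVM's one-class solver", {
  skip_if_not_installed("e1071")
  withr::with_seed(29, {
    X <- matrix(rnorm(50 * 3, mean = 0.4, sd = 0.1), ncol = 3)
    nu <- 0.2; gamma <- 5
    m <- fit_ocsvm(X, nu = nu, gamma = gamma)
    ref <- e1071::svm(X, type = "one-classification", kernel = "radial",
                      nu = nu, gamma = gamma, scale = FALSE)
    f_ref <- attr(stats::predict(ref, X, decision.values = TRUE),
                  "decision.values")[, 1]
    # LIBSVM scales the one-class dual so alphas sum to nu*l; rescale ours
    expect_gt(stats::cor(decision_values(m, X), f_ref), 0.9999)
    expect_gt(mean((decision_values(m, X) >= 0) ==
                     (stats::predict(ref, X))), 0.95)
  })
})

test_that("the decision function is invariant to training order", {
  withr::with_seed(41, {
    X <- matrix(rnorm(30 * 3, mean = 0.5, sd = 0.1), ncol = 3)
    probe <- matrix(rnorm(10 * 3, mean = 0.5, sd = 0.2), ncol = 3)
    m1 <- fit_ocsvm(X, nu = 0.2, gamma = 5)
    m2 <- fit_ocsvm(X[sample(nrow(X)), ], nu = 0.2, gamma = 5)
    expect_equal(decision_values(m1, probe), decision_values(m2, probe),
                 tolerance = 1e-5)
  })
})

test_that("far-away pixels are classified as anomalies", {
  withr::with_seed(19, {
    X <- matrix(rnorm(40 * 4, mean = 0.5, sd = 0.05), ncol = 4)
    m <- fit_ocsvm(X, nu = 0.1, gamma = 10)
    far <- matrix(5, nrow = 1, ncol = 4)  # many kernel widths away
    expect_lt(decision_values(m, far), 0)
  })
})

test_that("derive_endmember averages masked spectra", {
  vals <- array(0, dim = c(1, 2, 2))
  vals[1, 1, ] <- c(0.2, 0.4)
  vals[1, 2, ] <- c(0.4, 0.6)
  img <- spectral_image(vals, band_names = c("b1", "b2"))
  mask <- matrix(c(TRUE, TRUE), nrow = 1)
  expect_equal(unname(derive_endmember(img, mask)), c(0.3, 0.5))
  mask1 <- matrix(c(TRUE, FALSE), nrow = 1)
  expect_equal(unname(derive_endmember(img, mask1)), c(0.2, 0.4))
  expect_error(derive_endmember(img, matrix(FALSE, 1, 2)), "empty mask")
})

test_that("a noiseless scene recovers the library flower endmember exactly", {
  p <- scene_params(width = 64, height = 64, n_crowns = 5, noise_sd = 0,
                    flower_fraction_range = c(1, 1), seed = 6L)
  sc <- generate_scene(p)
  mask <- sc$fractions == 1   # truth pure pixels
  expect_gt(sum(mask), 0)
  em <- derive_endmember(sc$image, mask)
  flower <- endmember_spectrum(default_endmembers(), "flower")
  expect_lt(max(abs(em - flower)), 1e-9)
})

test_that("model serialization round-trips decision values", {
  withr::with_seed(53, {
    X <- matrix(rnorm(30 * 4, mean = 0.5, sd = 0.1), ncol = 4)
    m <- fit_ocsvm(X, nu = 0.2, gamma = 8, feature_scale = 100)
    path <- withr::local_tempfile(fileext = ".json")
    write_ocsvm(m, path)
    m2 <- read_ocsvm(path)
    probe <- matrix(rnorm(8 * 4, mean = 0.5, sd = 0.2), ncol = 4)
    expect_equal(decision_values(m2, probe), decision_values(m, probe),
                 tolerance = 1e-10)
  })
})
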