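test_that("quadratic background removal recovers the exact exponential", {
  x <- seq(35, 92, by = 1)
  q <- c(15, -0.08, 0.002)
  raw <- data.frame(x = x, intensity = 180 * exp(-0.05 * x) +
                      q[1] + q[2] * x + q[3] * x^2)
  corr <- remove_quadratic_background(raw, q)
  expect_equal(corr$intensity, 180 * exp(-0.05 * x), tolerance = 1e-12)
  # zero background is the identity
  corr0 <- remove_quadratic_background(raw, c(0, 0, 0))
  expect_equal(corr0$intensity, raw$intensity)
  expect_warning(
    remove_quadratic_background(data.frame(x = x, intensity = rep(1, 58)),
                                c(100, 0, 0)),
    class = "gapcanal_degenerate_profile")
})

test_that("background-corrected noisy profiles have unbiased residuals", {
  x <- seq(35, 92, by = 1)
  q <- c(15, -0.08, 0.002)
  qx <- q[1] + q[2] * x + q[3] * x^2
  true <- 180 * exp(-0.05 * x)
  mean_resid <- withr::with_seed(21, {
    mean(replicate(200, {
      raw <- data.frame(x = x,
                        intensity = true + qx + stats::rnorm(58, 0, 2))
      mean(remove_quadratic_background(raw, q)$intensity - true)
    }))
  })
  expect_lt(abs(mean_resid), 0.5)
})

test_that("exponential fit is exact on noiseless data and flags flats", {
  x <- seq(35, 92, by = 1)
  prof <- data.frame(x = x, intensity = 200 * exp(-0.04 * x))
  fit <- fit_exponential(prof)
  expect_equal(fit$A, 200, tolerance = 1e-10)
  expect_equal(fit$l, 0.04, tolerance = 1e-10)
  expect_false(attr(fit, "nonexponential"))
  flat <- fit_exponential(data.frame(x = x, intensity = rep(50, 58)))
  expect_true(attr(flat, "nonexponential"))
  expect_error(fit_exponential(data.frame(x = 1:5,
                                          intensity = c(1, 2, 0, 0, 0))),
               class = "gapcanal_unfittable")
})

test_that("exponential fit is unbiased under measurement noise", {
  x <- seq(5, 92, by = 1)
  true <- 200 * exp(-0.04 * x)
  fits <- withr::with_seed(31, {
    replicate(300, {
      f <- fit_exponential(data.frame(
        x = x, intensity = pmax(true + stats::rnorm(length(x), 0, 3), 0)),
        x_range = c(5, 70))  # region where the signal clears the noise
      c(f$A, f$l)
    })
  })
  se_A <- stats::sd(fits[1, ]) / sqrt(ncol(fits))
  se_l <- stats::sd(fits[2, ]) / sqrt(ncol(fits))
  expect_lt(abs(mean(fits[1, ]) - 200), 3 * se_A)
  expect_lt(abs(mean(fits[2, ]) - 0.04), 3 * se_l)
})

test_that("variance minimization collapses rescaled copies of one profile", {
  x <- seq(35, 80, by = 1)
  base <- 150 * exp(-0.05 * x)
  raws <- lapply(1:6, function(j) {
    data.frame(x = x, intensity = j * base + 10 * j)
  })
  res <- minimize_ensemble_variance(raws)
  pre <- sum(apply(vapply(raws, `[[`, numeric(length(x)), "intensity"),
                   1, stats::var))
  expect_lt(res$objective, 1e-10 * pre)
  expect_identical(attr(res$ensemble, "normalization_tag"),
                   "variance_minimizing")
  expect_true(all(res$scale > 0))
})

test_that("variance minimization beats random feasible normalizations", {
  x <- seq(35, 80, by = 1)
  raws <- withr::with_seed(41, {
    lapply(1:20, function(j) {
      A <- stats::rlnorm(1, log(150), 0.25)
      l <- stats::rlnorm(1, log(0.05), 0.05)
      s <- stats::runif(1, 0.5, 2)
      b <- stats::runif(1, 0, 30)
      data.frame(x = x, intensity = s * (A * exp(-l * x)) + b +
                   stats::rnorm(length(x), 0, 1))
    })
  })
  res <- minimize_ensemble_variance(raws)
  Y <- vapply(raws, `[[`, numeric(length(x)), "intensity")
  mu0 <- mean(Y)
  rand_obj <- withr::with_seed(42, {
    replicate(1000, {
      s <- stats::runif(20, 0.2, 3)
      b <- stats::runif(20, 0, 30)
      Z <- sweep(Y, 2, b, "-") %*% diag(s)
      gm <- mean(Z)
      if (abs(gm) > 1e-12) Z <- Z * mu0 / gm  # same gauge
      sum(apply(Z, 1, stats::var))
    })
  })
  expect_lte(res$objective, min(rand_obj))
  # the identity normalization is feasible, so never do worse than it
  expect_lte(res$objective, sum(apply(Y, 1, stats::var)))
})

test_that("median-profile selection equals the exhaustive argmin", {
  ens <- gen_bcd_ensemble(10, "wide", seed = 5)
  med <- select_median_profile(ens)
  zA <- scale(ens$A); zl <- scale(ens$l)
  d <- sqrt(zA^2 + zl^2)
  expect_identical(med$embryo_id, ens$embryo_id[which.min(d)])
  one <- bcd_ensemble(A = 100, l = 0.05, embryo_id = 7L)
  expect_identical(select_median_profile(one)$embryo_id, 7L)
})

test_that("threshold positions follow the exponential closed form", {
  prof <- bcd_exponential(200, 0.04)
  expect_equal(threshold_position(prof, 200 / exp(1)), 25)
  expect_equal(threshold_position(prof, 200), 0)
  expect_error(threshold_position(prof, 300),
               class = "gapcanal_no_crossing")
  # agreement with bisection root-finding on v(x) - c
  for (cc in c(5, 20, 80)) {
    xb <- stats::uniroot(function(x) eval_bcd(prof, x) - cc, c(0, 200),
                         tol = 1e-10)$root
    expect_equal(threshold_position(prof, cc), xb, tolerance = 1e-8)
  }
  # strictly decreasing in c, increasing in A
  cs <- seq(5, 150, by = 5)
  expect_true(all(diff(sapply(cs, threshold_position,
                              profile = prof)) < 0))
  As <- seq(120, 250, by = 10)
  expect_true(all(diff(sapply(As, function(A) {
    threshold_position(bcd_exponential(A, 0.04), 50)
  })) > 0))
})
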