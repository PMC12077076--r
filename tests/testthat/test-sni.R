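test_that("pair count follows the closed form", {
  expect_identical(count_pairs(2), 1L)
  expect_identical(count_pairs(16), 120L)
  expect_identical(count_pairs(248), 30628L)
  expect_error(count_pairs(1), ">= 2")
})

test_that("order (0,1,0) prewhitening returns the increments exactly", {
  set.seed(1)
  x <- cumsum(rnorm(500))
  ts <- sensor_ts(rbind(x, cumsum(rnorm(500))), sampling_rate_hz = 100)
  innov <- prewhiten(ts, prewhiten_config(order = c(0, 1, 0)))
  expect_equal(unname(innov$values[1, ]), diff(x), tolerance = 1e-12)
  expect_true(all(innov$diagnostics$converged))
})

test_that("AR(1) coefficient is recovered consistently across methods", {
  set.seed(2)
  x <- as.numeric(stats::filter(rnorm(10000), 0.9, method = "recursive"))
  # least-squares oracle: regression of x_t on x_{t-1}
  ols <- unname(coef(lm(x[-1] ~ x[-length(x)]))[2])
  expect_lt(abs(ols - 0.9), 0.05)
  ts <- sensor_ts(rbind(x, rnorm(10000)), sampling_rate_hz = 100)
  for (method in c("hr", "css")) {
    innov <- prewhiten(ts, prewhiten_config(order = c(1, 0, 0),
                                            estimation_method = method))
    # innovations should be white where the raw series was strongly autocorrelated
    r1 <- abs(acf(innov$values[1, ], lag.max = 1, plot = FALSE)$acf[2])
    expect_lt(r1, 5 / sqrt(ncol(innov$values)))
  }
})

test_that("prewhitening rejects constant and too-short series", {
  ts_const <- sensor_ts(rbind(rep(1, 400), rnorm(400)))
  expect_error(prewhiten(ts_const, fast_pw()), "S001")
  ts_short <- sensor_ts(matrix(rnorm(20), 2, 10))
  expect_error(prewhiten(ts_short, fast_pw()), "too short")
})

test_that("prewhitened innovations pass a whiteness bound on ARMA data", {
  set.seed(3)
  n <- 3000
  x <- t(replicate(3, as.numeric(stats::filter(rnorm(n), c(0.7, 0.2),
                                               method = "recursive"))))
  innov <- prewhiten(sensor_ts(x), prewhiten_config(order = c(5, 0, 1)))
  m <- ncol(innov$values)
  r <- apply(innov$values, 1, function(e) {
    max(abs(acf(e, lag.max = 5, plot = FALSE)$acf[2:6]))
  })
  expect_true(all(r < 5 / sqrt(m)))
})

test_that("cross-correlation matrix matches the direct Pearson formula", {
  m <- matrix(c(1, 2, 3, 4, 5,
                2, 4, 5, 4, 1,
                5, 3, 1, 3, 5), 3, 5, byrow = TRUE)
  cc <- crosscorr_matrix(m)
  pearson <- function(a, b) {
    sum((a - mean(a)) * (b - mean(b))) /
      sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  }
  for (i in 1:2) for (j in (i + 1):3) {
    expect_equal(cc[i, j], pearson(m[i, ], m[j, ]), tolerance = 1e-12)
  }
  expect_equal(diag(cc), rep(1, 3), ignore_attr = TRUE)
  expect_equal(crosscorr_matrix(rbind(m[1, ], m[1, ]))[1, 2], 1)
  expect_equal(crosscorr_matrix(rbind(m[1, ], -m[1, ]))[1, 2], -1)
  expect_error(crosscorr_matrix(rbind(m[1, ], rep(2, 5))), "zero-variance")
})

test_that("partial correlations match known closed forms", {
  expect_true(all(abs(partial_corr_matrix(diag(4), ridge = 0)) < 1e-12,
                  na.rm = TRUE))
  # 3x3 exchangeable 0.5: first-order recursion gives (0.5 - 0.25)/(1 - 0.25)
  r <- matrix(0.5, 3, 3); diag(r) <- 1
  p <- partial_corr_matrix(r, ridge = 0)
  expect_equal(p[upper.tri(p)], rep(1 / 3, 3), tolerance = 1e-12)
})

test_that("precision-matrix partials equal the regress-out brute force", {
  set.seed(4)
  for (rep in 1:10) {
    n_var <- sample(3:6, 1)
    x <- matrix(rnorm(60 * n_var), 60)
    x[, 1] <- x[, 1] + 0.5 * x[, 2]
    p <- partial_corr_matrix(cor(x), ridge = 0)
    expect_equal(p, pcor_brute(x), tolerance = 1e-8, ignore_attr = TRUE)
  }
})

test_that("singular correlation matrices are rejected with advice", {
  r <- matrix(1, 3, 3)
  expect_error(partial_corr_matrix(r, ridge = 0), "ridge")
  expect_silent(partial_corr_matrix(r, ridge = 1e-3))
})

test_that("Fisher z transform is the analytic atanh with clipping", {
  expect_equal(fisher_z_matrix(matrix(0, 2, 2) + diag(NA, 2))[1, 2], 0)
  # oracle: atanh(x) = log((1+x)/(1-x))/2
  expect_equal(fisher_z_matrix(matrix(0.5, 2, 2))[1, 2],
               log(1.5 / 0.5) / 2, tolerance = 1e-12)
  expect_equal(fisher_z_matrix(matrix(0.5, 2, 2))[1, 2], 0.5493061,
               tolerance = 1e-7)
  z1 <- fisher_z_matrix(matrix(1, 2, 2))
  expect_true(all(is.finite(z1)))
  expect_equal(z1[1, 2], atanh(1 - 1e-12))
})

test_that("compute_sni equals stage-by-stage composition and is symmetric", {
  set.seed(5)
  ts <- generate_subject_timeseries(6, 600, diag(6), seed = 11)
  cfg <- fast_pw()
  z <- compute_sni(ts, cfg)
  staged <- fisher_z_matrix(partial_corr_matrix(crosscorr_matrix(prewhiten(ts, cfg))))
  expect_equal(z, staged, ignore_attr = TRUE)
  expect_equal(z, t(z))
  expect_true(all(is.finite(z[upper.tri(z)])))
  expect_true(all(is.na(diag(z))))
  # tanh recovers the partial correlation
  pc <- partial_corr_matrix(crosscorr_matrix(prewhiten(ts, cfg)))
  expect_equal(tanh(z[upper.tri(z)]), pc[upper.tri(pc)], tolerance = 1e-9)
})

test_that("SNI is invariant to positive rescaling of any sensor", {
  set.seed(6)
  ts <- generate_subject_timeseries(5, 500, diag(5), seed = 12)
  z1 <- compute_sni(ts, fast_pw())
  scaled <- ts
  scaled$values[2, ] <- scaled$values[2, ] * 1000
  scaled$values[5, ] <- scaled$values[5, ] * 0.001
  z2 <- compute_sni(scaled, fast_pw())
  expect_equal(z1, z2, tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("prewhitening shrinks lag-1 autocorrelation at least five-fold", {
  set.seed(7)
  ts <- generate_subject_timeseries(8, 1200, diag(8), seed = 13)
  innov <- prewhiten(ts, fast_pw())
  lag1 <- function(m) mean(abs(apply(m, 1, function(v) {
    acf(v, lag.max = 1, plot = FALSE)$acf[2]
  })))
  expect_gt(lag1(ts$values) / lag1(innov$values), 5)
})

test_that("errors propagate with stage labels", {
  ts <- sensor_ts(rbind(rep(3, 400), rnorm(400)))
  expect_error(compute_sni(ts, fast_pw()), "\\[prewhiten\\]")
})
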