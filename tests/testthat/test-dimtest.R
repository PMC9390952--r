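# FOBI, Gaussian random field nulls, and the resampling dimension test.

test_that("FOBI separates a uniform from a Gaussian row", {
  set.seed(51)
  V <- 50000
  S <- rbind(runif(V, -sqrt(3), sqrt(3)), rnorm(V))
  R <- qr.Q(qr(matrix(rnorm(4), 2, 2)))
  d <- center_whiten(R %*% S)
  fb <- fobi(d)
  m <- match_components(fb$components, S)
  expect_true(all(m$correlations > 0.99))
})

test_that("FOBI is a fixed point on independent rows with distinct kurtoses", {
  set.seed(52)
  V <- 20000
  S <- rbind(rexp(V), runif(V), rnorm(V)^3)
  d <- center_whiten(S)
  fb <- fobi(d)
  m <- match_components(fb$components, S)
  expect_true(all(m$correlations > 0.98))
})

test_that("FOBI of Gaussian rows gives kurtosis scores near 0", {
  set.seed(53)
  d <- center_whiten(matrix(rnorm(5 * 20000), 5, 20000))
  fb <- suppressWarnings(fobi(d))
  expect_lt(max(fb$scores), 0.05)
})

test_that("iid noise rows are spatially white; GRF rows are smooth", {
  nm_iid <- noise_model("iid")
  Z <- sample_grf_rows(40, nm_iid, seed = 1, V = 1089)
  lag1 <- mean(sapply(1:40, function(i)
    cor(Z[i, -1], Z[i, -1089])))
  expect_lt(abs(lag1), 0.05)
  nm <- grid33()
  G <- sample_grf_rows(60, nm, seed = 2)
  arr <- array(t(G), c(33, 33, 60))
  acf_d <- sapply(c(1, 3, 6), function(d)
    cor(as.vector(arr[1:(33 - d), , ]), as.vector(arr[(1 + d):33, , ])))
  expect_gt(acf_d[1], 0.9)           # strong neighbour correlation
  expect_true(all(diff(acf_d) < 0))  # decaying with distance
  expect_gt(acf_d[3], 0.2)
})

test_that("GRF voxel marginals are standard normal", {
  nm <- grid33()
  G <- sample_grf_rows(500, nm, seed = 3, standardize = "none")
  for (vox in c(1, 17 * 33 + 17, 1089)) {  # corner, centre, corner
    ks <- ks.test(G[, vox], "pnorm")
    expect_gt(ks$p.value, 0.01)
  }
})

test_that("fwhm and grid validation errors", {
  expect_error(noise_model("grf", fwhm = -1, grid_shape = c(4, 4)), "fwhm")
  expect_error(noise_model("grf", fwhm = 3), "grid_shape")
})

test_that("test_k p-values use the add-one rule and never reach 0", {
  nm <- grid33()
  set.seed(54)
  X <- sample_grf_rows(8, nm)
  d <- center_whiten(X)
  r <- test_k(d, 0, B = 19, noise = nm, seed = 5, stats_out = TRUE)
  expect_gte(r$p_value, 1 / 20)
  expect_lte(r$p_value, 1)
  expect_equal(r$p_value, (1 + sum(r$null >= r$statistic)) / 20)
  # deep k on pure noise: statistic at the bottom of the spectrum, below
  # every null max, so the add-one count gives exactly 1
  r3 <- test_k(d, 7, B = 19, noise = nm, seed = 7, stats_out = TRUE)
  expect_true(all(r3$null >= r3$statistic))
  expect_equal(r3$p_value, 1)
})

test_that("binary search tests at most ceiling(log2(T)) hypotheses", {
  nm <- grid33()
  set.seed(55)
  X <- sample_grf_rows(16, nm)
  res <- estimate_dimension(center_whiten(X), B = 19, noise = nm, seed = 6)
  expect_lte(length(res$tested_k), ceiling(log2(16)))
  expect_true(all(res$p_values > 0 & res$p_values <= 1))
  expect_gte(res$q_hat, 0)
  expect_lte(res$q_hat, 15)
})

test_that("pure GRF input is estimated as dimension 0 most of the time", {
  nm <- grid33()
  qs <- sapply(1:8, function(r) {
    X <- sample_grf_rows(10, nm, seed = 100 + r)
    estimate_dimension(center_whiten(X), B = 39, noise = nm,
                       seed = 200 + r)$q_hat
  })
  expect_gte(mean(qs == 0), 0.7)  # ~ 1 - alpha, small-sample slack
})

test_that("planted spiky sources are detected and dimension recovered", {
  nm <- grid33()
  set.seed(57)
  # 3 strong super-Gaussian rows + 9 GRF rows
  V <- 1089
  spikes <- t(sapply(1:3, function(j) {
    x <- rnorm(V, 0, 0.05)
    x[sample(V, 12)] <- runif(12, 3, 8)
    x
  }))
  X <- rbind(spikes, sample_grf_rows(9, nm, seed = 58))
  M <- matrix(rnorm(144), 12, 12)
  d <- center_whiten(M %*% X)
  p2 <- test_k(d, 2, B = 99, noise = nm, seed = 59)
  expect_lt(p2, 0.05)
  res <- estimate_dimension(d, B = 99, noise = nm, seed = 60)
  expect_equal(res$q_hat, 3)
})

test_that("iid null overestimates the dimension of smoothed Gaussian data", {
  nm <- grid33()
  set.seed(61)
  X <- sample_grf_rows(12, nm)
  d <- center_whiten(X)
  q_grf <- estimate_dimension(d, B = 49, noise = nm, seed = 62)$q_hat
  q_iid <- estimate_dimension(d, B = 49, noise = noise_model("iid"),
                              seed = 63)$q_hat
  expect_gt(q_iid, q_grf)
})

test_that("true simulation dimension is recovered when fields are rough", {
  # at kernel FWHM 3 every source's kurtosis clears the null ceiling, so
  # the binary-search estimate hits the true dimension exactly
  des <- simulation_design(n_subjects = 2, svar_setting = "medium",
                           seed = 71, fwhm = 3)
  sim <- simulate_study(des)
  nm <- noise_model("grf", fwhm = 3, grid_shape = c(33, 33))
  qs <- sapply(1:2, function(i)
    estimate_dimension(center_whiten(sim$data[[i]]), B = 99, noise = nm,
                       seed = 80 + i)$q_hat)
  expect_equal(qs, c(25L, 25L))
})
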