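# Subject-level LNGCA: recovery, equivalences, invariants.

test_that("planted super-Gaussian source is recovered at q = 1", {
  pd <- planted_data(T_ = 8, V = 5000, n_ng = 1, seed = 21)
  f <- fit_lngca(center_whiten(pd$X), q = 1, restarts = 6, seed = 1)
  expect_gt(abs(cor(f$components[1, ], pd$S[1, ])), 0.95)
})

test_that("q = T fit equals noise-free ICA of the whole matrix", {
  # all rows non-Gaussian: the square rotation problem is well-posed and
  # both routes reach the same optimum from independent starts
  pd <- planted_data(T_ = 6, V = 3000, n_ng = 6, seed = 22)
  d <- center_whiten(pd$X)
  f_full <- fit_lngca(d, q = d$T, restarts = 8, seed = 2)
  # noise-free ICA route: rotate an orthonormal basis of the same row space
  basis <- d$X / sqrt((d$V - 1))
  g <- group_ica(basis, restarts = 8, seed = 3)
  expect_equal(f_full$objective, g$objective, tolerance = 1e-4)
  m <- match_components(g$components, f_full$components)
  expect_true(all(m$correlations > 0.999))
})

test_that("pure Gaussian data give objective near the Gaussian reference", {
  set.seed(31)
  d <- center_whiten(matrix(rnorm(6 * 8000), 6, 8000))
  f <- fit_lngca(d, q = 1, restarts = 4, seed = 4, swap_rounds = 5L)
  # maximum over rotations sits slightly above -1.43 at finite V
  expect_equal(f$objective, -1.43, tolerance = 0.03)
})

test_that("unmixing is semiorthogonal and components standardized, skew-positive, sorted", {
  pd <- planted_data(T_ = 7, V = 3000, n_ng = 3, seed = 23)
  d <- center_whiten(pd$X)
  f <- fit_lngca(d, q = 3, restarts = 6, seed = 5)
  expect_lt(max(abs(f$unmixing %*% t(f$unmixing) - diag(3))), 1e-6)
  expect_equal(unname(rowMeans(f$components)), rep(0, 3), tolerance = 1e-8)
  expect_equal(unname(rowSums(f$components^2) / (d$V - 1)), rep(1, 3),
               tolerance = 1e-8)
  expect_true(all(rowMeans(f$components^3) >= -1e-8))
  expect_true(all(diff(f$scores) <= 1e-12))
})

test_that("mixing reproduces the projection of centered data on the components", {
  pd <- planted_data(T_ = 6, V = 2500, n_ng = 2, seed = 24)
  d <- center_whiten(pd$X)
  f <- fit_lngca(d, q = 2, restarts = 6, seed = 6)
  xc <- pd$X - rowMeans(pd$X)
  recon <- f$mixing %*% f$components
  resid <- xc - recon
  # residual orthogonal to the component span
  expect_lt(max(abs(resid %*% t(f$components))), 1e-6 * d$V)
})

test_that("estimates are invariant (up to sign) to column permutation of the input", {
  pd <- planted_data(T_ = 6, V = 3000, n_ng = 1, seed = 25)
  perm <- sample(ncol(pd$X))
  f1 <- fit_lngca(center_whiten(pd$X), q = 1, restarts = 5, seed = 7)
  f2 <- fit_lngca(center_whiten(pd$X[, perm]), q = 1, restarts = 5, seed = 7)
  expect_gt(abs(cor(f1$components[1, perm], f2$components[1, ])), 0.999)
})

test_that("invalid q and unwhitened input are rejected", {
  pd <- planted_data(T_ = 5, V = 1000, seed = 26)
  d <- center_whiten(pd$X)
  expect_error(fit_lngca(d, q = 0), "q must")
  expect_error(fit_lngca(d, q = 6), "q must")
  expect_error(fit_lngca(pd$X, q = 1), "lngca_data")
})
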