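# Synthetic study generator: maps, mixing, variance bookkeeping.

test_that("digit-shaped group maps hit their designed non-Gaussianity", {
  sc <- rowMeans(replicate(20, apply(make_group_maps(seed = NULL), 1,
                                     logistic_score)))
  expect_equal(sc[1], -1.09, tolerance = 0.05)
  expect_equal(sc[2], -1.08, tolerance = 0.05)
  expect_equal(sc[3], -1.11, tolerance = 0.05)
})

test_that("group map active regions are disjoint so maps are uncorrelated", {
  S <- make_group_maps(seed = 5)
  cc <- cor(t(S))
  expect_lt(max(abs(cc[upper.tri(cc)])), 0.05)
  # zero-variance background still yields valid standardized maps
  S0 <- make_group_maps(seed = 5, bg_var = 0)
  expect_true(all(is.finite(apply(S0, 1, logistic_score))))
})

test_that("gamma random fields cover the designed score band", {
  g <- make_gamma_rf(100, seed = 6)
  sc <- apply(g, 1, logistic_score)
  band <- range(sc)
  expect_lt(band[1], -1.17)
  expect_gt(band[2], -0.88)
  # independent draws: typical pairwise correlation is negligible.  (The
  # maximum is not: at this smoothness a map is dominated by spikes at the
  # latent field's few maxima, and occasionally two maps spike at the same
  # location.)
  cc <- abs(cor(t(g[1:30, ])))
  expect_lt(median(cc[upper.tri(cc)]), 0.05)
})

test_that("gamma fields approach Gaussian as shape grows", {
  g <- make_gamma_rf(20, shape = 500, rate = 1, seed = 7)
  sc <- mean(apply(g, 1, logistic_score))
  expect_equal(sc, -1.43, tolerance = 0.03)
})

test_that("mixing matrix imposes the SVAR allocation exactly", {
  for (set in c("high", "medium", "low")) {
    des <- simulation_design(svar_setting = set, seed = 1)
    mx <- make_mixing(des, seed = 2)
    expect_equal(unname(mx$svar), unname(des$svar), tolerance = 1e-6)
    # group-block internal split
    gshare <- colSums(mx$M[, 1:3]^2) / sum(mx$M[, 1:3]^2)
    expect_equal(unname(gshare), c(0.154, 0.298, 0.548) / sum(c(0.154, 0.298, 0.548)),
                 tolerance = 1e-6)
    expect_equal(qr(mx$M)$rank, des$T)
  }
})

test_that("AR(1) columns have the designed autocorrelation; phi = 0 is white", {
  des <- simulation_design(seed = 3)
  mx <- make_mixing(des, seed = 4)
  # sample lag-1 ACF of a length-50 AR(1) is biased down by ~(1+4*phi)/T
  ac <- mean(apply(mx$M, 2, function(x) cor(x[-1], x[-length(x)])))
  expect_lt(abs(ac - (0.37 - (1 + 4 * 0.37) / 50)), 0.07)
  des0 <- simulation_design(phi = 0, seed = 3)
  mx0 <- make_mixing(des0, seed = 4)
  ac0 <- mean(apply(mx0$M, 2, function(x) cor(x[-1], x[-length(x)])))
  expect_lt(abs(ac0), 0.1)
})

test_that("simulate_study satisfies the generative model exactly", {
  des <- simulation_design(n_subjects = 3, seed = 8)
  sim <- simulate_study(des)
  expect_equal(dim(sim$data[[1]]), c(50L, 1089L))
  for (i in 1:3) {
    recon <- sim$mixing[[i]] %*% rbind(sim$group_maps,
                                       sim$individual_maps[[i]],
                                       sim$gauss_maps[[i]])
    expect_equal(sim$data[[i]], recon, tolerance = 1e-12)
  }
  # group maps shared, individual maps differ
  expect_lt(max(abs(cor(t(sim$individual_maps[[1]]), t(sim$individual_maps[[2]])))),
            0.9)
})

test_that("generation is reproducible under a fixed seed", {
  s1 <- simulate_study(simulation_design(n_subjects = 2, seed = 99))
  s2 <- simulate_study(simulation_design(n_subjects = 2, seed = 99))
  expect_identical(s1$data, s2$data)
  s3 <- simulate_study(simulation_design(n_subjects = 2, seed = 100))
  expect_false(isTRUE(all.equal(s1$data[[1]], s3$data[[1]])))
})
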