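# Group stage: concatenation, SVD subspace, rotation, individual components,
# back-reconstruction, and the PCA+ICA baseline.

test_that("concat_normalize stacks, centers and unit-norms rows", {
  set.seed(41)
  a <- matrix(rnorm(2 * 100), 2, 100)
  b <- matrix(rnorm(3 * 100), 3, 100)
  st <- concat_normalize(list(a, b))
  expect_equal(dim(st), c(5L, 100L))
  expect_equal(unname(rowSums(st^2)), rep(1, 5), tolerance = 1e-12)
  expect_lt(max(abs(rowMeans(st))), 1e-12)
  # scale invariance
  st3 <- concat_normalize(list(3 * a, b))
  expect_equal(st3, st, tolerance = 1e-12)
  expect_error(concat_normalize(list(a, matrix(0, 1, 100))), "zero row")
  expect_error(concat_normalize(list(a, matrix(1, 2, 50))), "voxels")
})

test_that("component duplicated across k subjects gives singular value sqrt(k)", {
  set.seed(42)
  v <- rnorm(500)
  v <- (v - mean(v)) / sqrt(sum((v - mean(v))^2))
  for (k in 2:10) {
    st <- do.call(rbind, replicate(k, list(v)))
    sub <- group_subspace(st, 1)
    expect_equal(sub$singular_values[1], sqrt(k), tolerance = 1e-8)
  }
})

test_that("two-subject principal angle: sigma^2 - 1 equals the correlation", {
  set.seed(43)
  for (rho in c(0.2, 0.5, 0.9)) {
    x <- rnorm(2000)
    y <- rho * x + sqrt(1 - rho^2) * rnorm(2000)
    st <- concat_normalize(list(rbind(x), rbind(y)))
    r <- cor(st[1, ], st[2, ])
    sub <- group_subspace(st, 2)
    expect_equal(sub$singular_values[1]^2 - 1, r, tolerance = 1e-6)
    # principal angle relation, second singular value mirrors it
    expect_equal(sub$singular_values[2]^2 - 1, -r, tolerance = 1e-6)
  }
})

test_that("orthonormal stack has all singular values 1", {
  q <- qr.Q(qr(matrix(rnorm(300 * 2), 300, 2)))
  sub <- group_subspace(t(q), 2)
  expect_equal(sub$singular_values, c(1, 1), tolerance = 1e-10)
})

test_that("iterative SVD path agrees with the dense path", {
  set.seed(44)
  st <- concat_normalize(list(matrix(rnorm(8 * 400), 8, 400),
                              matrix(rnorm(8 * 400), 8, 400)))
  dense <- group_subspace(st, 3)
  iter <- group_subspace(st, 3, iterative_above = 0)
  expect_equal(iter$singular_values, dense$singular_values,
               tolerance = 1e-6)
  # same subspace (power iteration converges more slowly in the basis
  # than in the singular values)
  P <- t(dense$basis) %*% dense$basis
  expect_lt(max(abs(iter$basis %*% P - iter$basis)), 1e-3)
})

test_that("group_ica with one component returns the basis up to sign", {
  set.seed(45)
  v <- rnorm(800)
  v <- v - mean(v)
  v <- v / sqrt(sum(v^2))
  g <- group_ica(rbind(v), seed = 1)
  vstd <- v / sqrt(sum(v^2) / 799)
  expect_equal(abs(cor(g$components[1, ], vstd)), 1, tolerance = 1e-10)
})

test_that("group_ica separates two disjoint-support sparse maps", {
  set.seed(46)
  V <- 2000
  s1 <- numeric(V); s1[1:40] <- runif(40, 2, 4)
  s2 <- numeric(V); s2[101:140] <- runif(40, 2, 4)
  S <- rbind(s1, s2)
  S <- S - rowMeans(S)
  R <- qr.Q(qr(matrix(rnorm(4), 2, 2)))  # random rotation
  mixed <- R %*% S
  basis <- t(qr.Q(qr(t(mixed))))  # orthonormal basis of the span
  g <- group_ica(basis, restarts = 20, seed = 2)
  m <- match_components(g$components, S)
  expect_true(all(m$correlations > 0.95))
})

test_that("subject_group_mixing: exact recovery, orthogonality, scaling", {
  set.seed(47)
  V <- 600; Tt <- 10
  Sg <- matrix(rnorm(3 * V), 3, V)
  Sg <- Sg - rowMeans(Sg)
  M <- matrix(rnorm(Tt * 3), Tt, 3)
  raw <- M %*% Sg
  bm <- subject_group_mixing(raw, Sg)
  expect_equal(bm$mixing, M, tolerance = 1e-8)
  expect_equal(subject_group_mixing(2 * raw, Sg)$variances,
               4 * bm$variances, tolerance = 1e-10)
  # data orthogonal to the group components -> all variances 0
  comp <- qr.Q(qr(t(rbind(Sg, matrix(rnorm(2 * V), 2, V)))))[, 4:5]
  raw_orth <- matrix(rnorm(Tt * 2), Tt, 2) %*% t(comp)
  expect_equal(unname(subject_group_mixing(raw_orth, Sg)$variances),
               rep(0, 3), tolerance = 1e-10)
})

test_that("individual_components: empty inside group span, recovers extra map", {
  set.seed(48)
  V <- 1500
  Sg <- matrix(rnorm(2 * V), 2, V)
  Sg <- Sg - rowMeans(Sg)
  # subject components entirely inside the group span
  inside <- matrix(rnorm(4), 2, 2) %*% Sg
  ind0 <- individual_components(inside, Sg, seed = 1)
  expect_equal(nrow(ind0$components), 0L)
  # group components plus one orthogonal sparse map
  extra <- numeric(V); extra[50:90] <- runif(41, 2, 4)
  extra <- extra - mean(extra)
  P <- t(Sg) %*% solve(Sg %*% t(Sg)) %*% Sg
  extra <- extra - as.vector(P %*% extra)  # orthogonal to the group span
  S_i <- rbind(Sg, extra)
  ind <- individual_components(S_i, Sg, restarts = 8, seed = 2)
  expect_equal(nrow(ind$components), 1L)
  expect_gt(abs(cor(ind$components[1, ], extra)), 0.95)
  # orthogonality to every group component
  expect_lt(max(abs(ind$components %*% t(Sg))), 1e-6 * V)
})

test_that("gica_baseline with no reduction matches the LNGCA group subspace", {
  set.seed(49)
  V <- 1500; Tt <- 5; k <- 6
  shared <- numeric(V); shared[1:50] <- runif(50, 2, 4)
  shared <- (shared - mean(shared)) / sd(shared)  # same energy as the noise
  raw <- lapply(seq_len(k), function(i) {
    S <- rbind(shared, matrix(rnorm((Tt - 1) * V), Tt - 1, V))
    M <- matrix(rnorm(Tt * Tt), Tt, Tt)
    M[, 1] <- 2 * M[, 1]  # shared source carries clearly more variance
    M %*% S
  })
  base <- gica_baseline(raw, q_subject = Tt, q_g = 1, restarts = 10, seed = 3)
  fit <- glngca(raw, q_g = 1, q_i = Tt, restarts = 6, group_restarts = 10,
                maxit = 3000, seed = 4)
  # equivalence of the two pipelines' group subspaces (finite-sample
  # estimates differ slightly: the group SVD weights subject rows by
  # unit norm in one and by variance in the other)
  r <- abs(cor(base$components[1, ], fit$group_components[1, ]))
  expect_gt(r, 0.9)
  expect_gt(abs(cor(base$components[1, ], shared)), 0.95)
})
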