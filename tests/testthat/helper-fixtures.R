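# Shared helpers: small planted-source datasets and brute-force oracles.

# T x V data with `n_ng` spiky super-Gaussian rows mixed among Gaussians.
planted_data <- function(T_ = 8, V = 2000, n_ng = 1, spike_frac = 0.02,
                         seed = 1) {
  set.seed(seed)
  S <- matrix(rnorm(T_ * V), T_, V)
  for (j in seq_len(n_ng)) {
    x <- rnorm(V, 0, 0.1)
    idx <- sample(V, ceiling(spike_frac * V))
    x[idx] <- runif(length(idx), 3, 6)
    S[j, ] <- x
  }
  M <- matrix(rnorm(T_ * T_), T_, T_)
  list(X = M %*% S, S = S[seq_len(n_ng), , drop = FALSE])
}

# Exhaustive assignment oracle: minimize total cost over all permutations.
brute_force_assignment <- function(cost) {
  n <- nrow(cost)
  perms <- gtools_permutations(n)
  best <- NULL
  best_cost <- Inf
  for (i in seq_len(nrow(perms))) {
    p <- perms[i, ]
    tc <- sum(cost[cbind(seq_len(n), p)])
    if (tc < best_cost) {
      best_cost <- tc
      best <- p
    }
  }
  list(perm = best, cost = best_cost)
}

# all permutations of 1..n (n <= 7), no external dependency
gtools_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  out <- NULL
  for (i in seq_len(n)) {
    rest <- gtools_permutations(n - 1L)
    vals <- setdiff(seq_len(n), i)
    out <- rbind(out, cbind(i, matrix(vals[rest], nrow(rest))))
  }
  out
}

grid33 <- function() noise_model("grf", fwhm = 9, grid_shape = c(33, 33))
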