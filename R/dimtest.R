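# Dimension of the non-Gaussian subspace: closed-form FOBI unmixing and a
# resampling test whose null draws spatially correlated Gaussian noise.

#' Fourth-order blind identification (FOBI)
#'
#' Closed-form ICA of a whitened matrix: the unmixing rotation is the
#' eigenbasis of the fourth-order scatter matrix
#' \eqn{\hat E[\|z\|^2 z z']}, computed over voxels.  Components are
#' returned standardized and sorted by decreasing [kurtosis_score()].
#' Because the solution is an eigen-decomposition, no restarts are needed,
#' which makes it fast enough to drive the resampling dimension test.
#'
#' @param whitened `m x V` matrix with uncorrelated unit-variance rows
#'   (an [center_whiten()] object or a bare matrix satisfying the
#'   whitening identities).
#' @return A `"component_set"` (see [sort_components()]) with an extra
#'   element `eigenvalues` (fourth-order scatter eigenvalues, decreasing)
#'   and `tied` (TRUE when near-tied eigenvalues made the rotation
#'   ill-determined; ties are broken deterministically by the eigen
#'   routine's fixed ordering).
#' @export
fobi <- function(whitened) {
  d <- .as_whitened(whitened)
  Z <- d$X
  m <- nrow(Z)
  V <- ncol(Z)
  nrm2 <- colSums(Z^2)
  C <- (Z * rep(nrm2, each = m)) %*% t(Z) / V
  e <- eigen(C, symmetric = TRUE)
  gaps <- abs(diff(e$values))
  tied <- m > 1L && any(gaps < 1e-8 * max(abs(e$values)))
  if (tied)
    warning("near-tied fourth-order eigenvalues; rotation is ill-determined")
  S <- t(e$vectors) %*% Z
  out <- sort_components(S, "kurtosis")
  out$eigenvalues <- e$values
  out$tied <- tied
  out
}

#' Resampling test for at most k non-Gaussian components
#'
#' Tests H0: the data contain at most `k` non-Gaussian components, against
#' at least `k + 1`.  The statistic is the `(k+1)`-th largest
#' [kurtosis_score()] among the FOBI components of the whitened data.  Its
#' null distribution is estimated by drawing `B` sets of `T - k` rows from
#' the Gaussian noise model, whitening them, applying FOBI, and recording
#' the maximum kurtosis score; the p-value uses the add-one convention
#' `(1 + #{null >= statistic}) / (B + 1)` and therefore is never 0.  Using
#' a spatially correlated (random field) null is what keeps smoothed
#' Gaussian noise from masquerading as signal.
#'
#' @param data An [center_whiten()] object (or whitened matrix).
#' @param k Hypothesized maximum number of non-Gaussian components,
#'   `0 <= k <= T - 1`.
#' @param B Number of null resamples.
#' @param noise A [noise_model()] matching the data's spatial layout.
#' @param seed Optional integer seed for the null draws.
#' @param stats_out When TRUE, also return the observed statistic and the
#'   null draws.
#' @return The p-value (or a list when `stats_out = TRUE`).
#' @export
test_k <- function(data, k, B = 200L, noise, seed = NULL,
                   stats_out = FALSE) {
  d <- .as_whitened(data)
  T_ <- d$T
  V <- d$V
  k <- as.integer(k)
  if (k < 0L || k > T_ - 1L) stop("k must be in [0, T-1]", call. = FALSE)
  if (B < 1L) stop("B must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  obs <- fobi(d)$scores[k + 1L]
  m <- T_ - k
  null_max <- numeric(B)
  for (b in seq_len(B)) {
    G <- sample_grf_rows(m, noise, V = V)
    Gw <- if (m > 1L) center_whiten(G) else .as_whitened(G)
    null_max[b] <- fobi(Gw)$scores[1L]
  }
  p <- (1 + sum(null_max >= obs)) / (B + 1)
  if (stats_out) list(p_value = p, statistic = obs, null = null_max) else p
}

#' Estimate the non-Gaussian subspace dimension
#'
#' Binary search over the nested hypotheses H0k ("at most k non-Gaussian
#' components") using [test_k()], assuming rejection is monotone in `k`.
#' The estimate is the smallest `k` whose test is *not* rejected at level
#' `alpha`; at most `ceiling(log2(T))` tests are run, and raw
#' (unadjusted) p-values are used throughout — the hypotheses are nested,
#' so a multiplicity correction would only cost power.
#'
#' @inheritParams test_k
#' @param alpha Significance level in (0, 1).
#' @return An object of class `"dim_test"`: `q_hat`, `tested_k`,
#'   `p_values`, `alpha`, `B`, `noise`.
#' @examples
#' \donttest{
#' nm <- noise_model("grf", fwhm = 9, grid_shape = c(33, 33))
#' X <- sample_grf_rows(12, nm, seed = 1)
#' estimate_dimension(center_whiten(X), B = 99, noise = nm, seed = 2)
#' }
#' @export
estimate_dimension <- function(data, alpha = 0.05, B = 200L, noise,
                               seed = NULL) {
  d <- .as_whitened(data)
  T_ <- d$T
  if (!is.null(seed)) set.seed(seed)
  tested_k <- integer(0)
  p_values <- numeric(0)
  run_test <- function(k) {
    p <- test_k(d, k, B = B, noise = noise, seed = NULL)
    tested_k <<- c(tested_k, k)
    p_values <<- c(p_values, p)
    p
  }
  lo <- 0L
  hi <- T_ - 1L
  # invariant: every k < lo is rejected, monotone rejection assumed above;
  # halves [lo, hi] each step, so at most ceiling(log2(T)) tests
  while (lo < hi) {
    mid <- (lo + hi) %/% 2L
    if (run_test(mid) > alpha) hi <- mid else lo <- mid + 1L
  }
  structure(
    list(q_hat = lo, tested_k = tested_k, p_values = p_values,
         alpha = alpha, B = B, noise = noise),
    class = "dim_test"
  )
}

#' @export
print.dim_test <- function(x, ...) {
  cat(sprintf(
    "Non-Gaussian dimension estimate: q_hat = %d (alpha = %g, B = %d)\n",
    x$q_hat, x$alpha, x$B))
  tab <- data.frame(k = x$tested_k, p = signif(x$p_values, 3))
  print(tab[order(tab$k), ], row.names = FALSE)
  invisible(x)
}
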