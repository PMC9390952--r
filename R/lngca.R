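# Subject-level LNGCA: fixed-point maximization of the logistic contrast
# over semiorthogonal unmixing matrices (a fastICA-style symmetric update).

# One restart of the symmetric fixed-point algorithm on a whitened T x V
# matrix.  U0 is q x T with orthonormal rows.  The contrast is
# G(y) = log f(y) with f the unit-variance logistic density, so
# g(y) = -tanh(y / 2s) / s and g'(y) = -(1 - tanh^2(y / 2s)) / (2 s^2).
.fp_once <- function(X, U, maxit, tol) {
  s <- .logis_scale
  V <- ncol(X)
  iters <- maxit
  converged <- FALSE
  U_best <- U
  obj_best <- NULL
  stall <- 0L
  for (it in seq_len(maxit)) {
    Y <- U %*% X
    th <- tanh(Y / (2 * s))
    G1 <- -th / s
    G2 <- -(1 - th^2) / (2 * s^2)
    Unew <- (G1 %*% t(X)) / V - rowMeans(G2) * U
    # symmetric orthogonalization: (Unew Unew')^{-1/2} Unew
    e <- eigen(Unew %*% t(Unew), symmetric = TRUE)
    if (min(e$values) < 1e-12 * max(e$values))
      stop("fixed-point update collapsed to a rank-deficient matrix",
           call. = FALSE)
    Unew <- e$vectors %*% (t(e$vectors) / sqrt(e$values)) %*% Unew
    delta <- max(abs(1 - abs(rowSums(Unew * U))))
    U <- Unew
    if (delta < tol) {
      iters <- it
      converged <- TRUE
      break
    }
    # directions in a purely Gaussian subspace have near-zero fixed-point
    # updates dominated by sampling noise and never settle in direction,
    # though the objective no longer improves; stop (keeping the best
    # iterate) once the objective has not improved for several checks
    if (it %% 10L == 0L) {
      obj <- .objective(U, X)
      if (is.null(obj_best) || obj > obj_best + 1e-8) {
        obj_best <- obj
        U_best <- U
        stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= 5L) {
          iters <- it
          converged <- TRUE
          U <- U_best
          break
        }
      }
    }
  }
  list(U = U, iters = iters, converged = converged)
}

.objective <- function(U, X) {
  Y <- U %*% X
  sum(apply(Y, 1L, logistic_score))
}

.random_semiorth <- function(q, T_) {
  t(qr.Q(qr(matrix(stats::rnorm(T_ * q), T_, q)))[, seq_len(q), drop = FALSE])
}

# Multi-restart driver shared by fit_lngca() and group_ica().  A restart
# whose update collapses (rank deficiency) is discarded; with
# require_converged = FALSE the best non-converged solution is accepted
# (used for coarse initializations where only the span matters).
.fastica_logistic <- function(X, q, restarts, maxit, tol, seed,
                              require_converged = TRUE) {
  if (!is.null(seed)) set.seed(seed)
  T_ <- nrow(X)
  best <- NULL
  iter_log <- integer(restarts)
  n_conv <- 0L
  for (r in seq_len(restarts)) {
    fit <- tryCatch(.fp_once(X, .random_semiorth(q, T_), maxit, tol),
                    error = function(e) NULL)
    if (is.null(fit)) next
    iter_log[r] <- fit$iters
    n_conv <- n_conv + fit$converged
    obj <- .objective(fit$U, X)
    if (is.null(best) || obj > best$objective)
      best <- list(U = fit$U, objective = obj, iters = fit$iters,
                   converged = fit$converged)
  }
  if (is.null(best))
    stop("every restart collapsed to a rank-deficient update",
         call. = FALSE)
  if (require_converged && n_conv == 0L)
    stop(sprintf(
      "no restart converged in %d iterations (best objective %.6f)",
      maxit, best$objective), call. = FALSE)
  best$iter_log <- iter_log
  best
}

# Greedy subspace improvement for dimension-reducing fits (q < T).  The
# symmetric fixed point can converge with a weak non-Gaussian direction
# left in the discarded orthogonal complement.  Each round extracts
# candidate directions from the complement of the current span (a small
# symmetric fastICA plus the closed-form FOBI rotation, which finds
# spike-like directions immediately), and if the best candidate scores
# higher than the currently weakest component, swaps it in and re-polishes;
# the swap is kept only when the full objective improves.
.swap_refine <- function(U, X, maxit, tol, rounds = 30L,
                         cand_restarts = 3L, fails_allowed = 3L) {
  q <- nrow(U)
  T_ <- nrow(X)
  if (q >= T_) return(U)
  fails <- 0L
  for (sw in seq_len(rounds)) {
    scores <- apply(U %*% X, 1L, logistic_score)
    Q <- qr.Q(qr(t(U)), complete = TRUE)[, (q + 1L):T_, drop = FALSE]
    Xc <- t(Q) %*% X
    qc <- min(5L, T_ - q)
    cands <- list()
    if (T_ - q > 1L) {
      fb <- fobi(Xc)
      Rrot <- fb$components %*% t(Xc) %*% solve(Xc %*% t(Xc))
      sc_f <- apply(fb$components, 1L, logistic_score)
      cands[[1L]] <- Rrot[which.max(sc_f), , drop = FALSE]
    }
    for (r in seq_len(cand_restarts)) {
      fr <- tryCatch(.fp_once(Xc, .random_semiorth(qc, T_ - q), 150L, tol),
                     error = function(e) NULL)
      if (is.null(fr)) next
      sc <- apply(fr$U %*% Xc, 1L, logistic_score)
      cands[[length(cands) + 1L]] <- fr$U[which.max(sc), , drop = FALSE]
    }
    if (length(cands) == 0L) break
    csc <- vapply(cands, function(u) logistic_score(as.vector(u %*% Xc)),
                  numeric(1))
    bestu <- cands[[which.max(csc)]]
    bestu <- bestu / sqrt(sum(bestu^2))
    jmin <- which.min(scores)
    improved <- FALSE
    if (max(csc) > scores[jmin] + 1e-6) {
      Ucand <- U
      Ucand[jmin, ] <- as.vector(t(Q %*% t(bestu)))
      fr <- tryCatch(.fp_once(X, Ucand, maxit, tol),
                     error = function(e) NULL)
      if (!is.null(fr) && .objective(fr$U, X) > .objective(U, X) + 1e-8) {
        U <- fr$U
        improved <- TRUE
      }
    }
    if (improved) fails <- 0L
    else {
      fails <- fails + 1L
      if (fails >= fails_allowed) break
    }
  }
  U
}

# Square-ICA initialization: fit the full T x T rotation (no dimension
# reduction, a better-behaved landscape), keep the q most non-Gaussian
# rows, and polish them as a q-dimensional fit.
.square_init <- function(X, q, maxit, tol) {
  T_ <- nrow(X)
  out <- tryCatch({
    # the Gaussian block of the square rotation never settles, so accept
    # the best non-converged solution at a loose tolerance; only its most
    # non-Gaussian rows are kept and re-polished
    fsq <- .fastica_logistic(X, T_, restarts = 2L, maxit = 200L,
                             tol = 1e-4, seed = NULL,
                             require_converged = FALSE)
    sc <- apply(fsq$U %*% X, 1L, logistic_score)
    U0 <- fsq$U[order(sc, decreasing = TRUE)[seq_len(q)], , drop = FALSE]
    e <- eigen(U0 %*% t(U0), symmetric = TRUE)
    U0 <- e$vectors %*% (t(e$vectors) / sqrt(e$values)) %*% U0
    .fp_once(X, U0, maxit, tol)$U
  }, error = function(e) NULL)
  out
}

# Standardize rows, flip signs so skewness >= 0, sort by logistic score.
# Returns the adjusted components together with the matching unmixing rows.
.finalize_components <- function(U, X) {
  S <- U %*% X
  mu <- rowMeans(S)
  sdv <- sqrt(rowSums((S - mu)^2) / (ncol(S) - 1))
  S <- (S - mu) / sdv
  U <- U / sdv
  flip <- ifelse(rowMeans(S^3) < 0, -1, 1)
  S <- S * flip
  U <- U * flip
  srt <- sort_components(S, "logistic")
  list(S = srt$components, U = U[srt$order, , drop = FALSE],
       scores = srt$scores)
}

#' Fit subject-level LNGCA
#'
#' Extracts the `q` most non-Gaussian spatial components of a whitened
#' subject data matrix by maximizing the summed logistic contrast over
#' semiorthogonal `q x T` unmixing matrices, using a symmetric fixed-point
#' update with symmetric orthogonalization and multiple random restarts.
#' Unlike PCA-based reduction, components are ranked by non-Gaussianity,
#' so low-variance non-Gaussian signals are retained.
#'
#' @param data An `"lngca_data"` object from [center_whiten()].
#' @param q Number of non-Gaussian components, `1 <= q <= T`.
#' @param restarts Number of random initializations; the restart with the
#'   best objective is kept.
#' @param maxit,tol Fixed-point iteration cap and convergence tolerance on
#'   `max |1 - |diag(U_new U_old')||`.
#' @param seed Optional integer seed for the restart initializations.
#' @param square_init Also try an initialization from the full square
#'   (`q = T`) ICA, keeping its `q` most non-Gaussian rows (only relevant
#'   when `q < T`).  The square landscape cannot "drop" a direction, so
#'   this start protects weak components.
#' @param swap_rounds Rounds of greedy subspace refinement: candidate
#'   directions are extracted from the orthogonal complement of the
#'   current span and swapped in for the weakest component whenever that
#'   improves the objective.  Set to 0 to disable.
#' @return An object of class `"lngca_fit"`: `components` (`q x V`, rows
#'   standardized, skew-positive, sorted by decreasing logistic score),
#'   `scores`, `unmixing` (`q x T`, semiorthogonal up to the row
#'   standardization), `mixing` (`T x q` least-squares map from components
#'   back to the centered data), `objective` (sum of logistic scores),
#'   `q`, `iters`, and `restart_iters`.
#' @examples
#' X <- matrix(rnorm(5 * 400), 5, 400)
#' X[1, ] <- rexp(400)  # one super-Gaussian source among Gaussians
#' f <- fit_lngca(center_whiten(X), q = 1, restarts = 4, seed = 1)
#' f$objective
#' @export
fit_lngca <- function(data, q, restarts = 40L, maxit = 500L, tol = 1e-6,
                      seed = NULL, square_init = TRUE, swap_rounds = 30L) {
  stopifnot(inherits(data, "lngca_data"), isTRUE(data$whitened))
  q <- as.integer(q)
  if (q < 1L || q > data$T)
    stop("q must satisfy 1 <= q <= T", call. = FALSE)
  best <- .fastica_logistic(data$X, q, restarts, maxit, tol, seed)
  if (square_init && q < data$T) {
    Us <- .square_init(data$X, q, maxit, tol)
    if (!is.null(Us) && .objective(Us, data$X) > best$objective) {
      best$U <- Us
      best$objective <- .objective(Us, data$X)
    }
  }
  if (swap_rounds > 0L && q < data$T) {
    Ur <- .swap_refine(best$U, data$X, maxit, tol, rounds = swap_rounds)
    obj_r <- .objective(Ur, data$X)
    if (obj_r > best$objective) {
      best$U <- Ur
      best$objective <- obj_r
    }
  }
  fin <- .finalize_components(best$U, data$X)
  S <- fin$S
  # mixing in centered-data units via least squares (S rows orthonormal up
  # to scaling, but solve generally for robustness)
  mixing <- NULL
  if (!is.null(data$transform)) {
    xc <- data$transform$centered * data$transform$row_scale
    mixing <- t(solve(S %*% t(S), S %*% t(xc)))
  }
  structure(
    list(components = S, scores = fin$scores, unmixing = fin$U,
         mixing = mixing, objective = best$objective, q = q,
         iters = best$iters, restart_iters = best$iter_log),
    class = "lngca_fit"
  )
}

#' @export
print.lngca_fit <- function(x, ...) {
  cat(sprintf(
    "Subject LNGCA fit: %d components, objective %.4f (%d iterations)\n",
    x$q, x$objective, x$iters))
  cat("logistic scores:", format(x$scores, digits = 4), "\n")
  invisible(x)
}
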