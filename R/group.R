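# Stage 2: group subspace via SVD of concatenated unit-norm subject
# components, group components via noise-free ICA, individual components in
# the orthogonal complement, and a temporal-concatenation PCA+ICA baseline.

#' Concatenate subject components with unit-norm rows
#'
#' Stacks the subjects' component matrices, mean-centering each row and
#' scaling it to Euclidean norm 1.  Centering first makes the squared
#' singular values of the stack interpretable through correlations
#' (for two subjects with one component each, `sigma_1^2 - 1` is the
#' components' correlation).
#'
#' @param subject_components List of `q_i x V` matrices sharing `V`.
#' @return A `(sum q_i) x V` matrix with unit-norm, mean-zero rows.
#' @export
concat_normalize <- function(subject_components) {
  stopifnot(is.list(subject_components), length(subject_components) >= 1L)
  Vs <- vapply(subject_components, ncol, integer(1))
  if (length(unique(Vs)) != 1L)
    stop("subjects disagree on the number of voxels V", call. = FALSE)
  stacked <- do.call(rbind, lapply(subject_components, as.matrix))
  stacked <- stacked - rowMeans(stacked)
  nrm <- sqrt(rowSums(stacked^2))
  if (any(nrm <= 0))
    stop("zero row(s) after centering: ",
         paste(which(nrm <= 0), collapse = ", "), call. = FALSE)
  stacked / nrm
}

#' Group non-Gaussian subspace by SVD
#'
#' Top right singular vectors of the concatenated unit-norm subject
#' components.  A component shared (duplicated) by `k` subjects produces a
#' singular value of `sqrt(k)`, so leading singular vectors average the
#' directions present across subjects.  For stacks larger than
#' `iterative_above` entries, a block power iteration on the `V x V`
#' implicit cross-product is used instead of a dense SVD.
#'
#' @param stacked Output of [concat_normalize()].
#' @param q_g Number of group components to retain.
#' @param iterative_above Entry-count threshold above which the iterative
#'   path is used (default keeps typical problem sizes on the dense path).
#' @param itmax,tol Power-iteration controls (iterative path only).
#' @return List with `basis` (`q_g x V`, orthonormal rows) and
#'   `singular_values` (length `q_g`).
#' @export
group_subspace <- function(stacked, q_g, iterative_above = 5e7,
                           itmax = 1000L, tol = 1e-10) {
  stacked <- as.matrix(stacked)
  q_g <- as.integer(q_g)
  rk <- min(dim(stacked))
  if (q_g < 1L || q_g > rk)
    stop("q_g must be between 1 and the rank bound of the stack",
         call. = FALSE)
  if (length(stacked) <= iterative_above) {
    sv <- svd(stacked, nu = 0, nv = q_g)
    d <- sv$d[seq_len(q_g)]
    basis <- t(sv$v)
  } else {
    # block power iteration on A'A without forming it
    V <- ncol(stacked)
    set.seed(0L)  # deterministic start; result is seed-independent at tol
    Q <- qr.Q(qr(matrix(stats::rnorm(V * q_g), V, q_g)))
    d_old <- rep(Inf, q_g)
    for (it in seq_len(itmax)) {
      Z <- crossprod(stacked, stacked %*% Q)
      Q <- qr.Q(qr(Z))
      d <- sqrt(abs(colSums(Q * Z)))
      if (max(abs(d - d_old)) < tol * max(d)) break
      d_old <- d
    }
    ord <- order(d, decreasing = TRUE)
    basis <- t(Q[, ord, drop = FALSE])
    d <- d[ord]
  }
  tolr <- max(dim(stacked)) * .Machine$double.eps * max(d, 1)
  if (any(d <= tolr))
    stop("q_g exceeds the numerical rank of the stacked components",
         call. = FALSE)
  list(basis = basis, singular_values = d)
}

#' Noise-free ICA rotation of an orthogonal basis
#'
#' Searches over orthogonal rotations of the group subspace basis for the
#' rotation maximizing the summed logistic contrast.  Output rows are
#' standardized, skew-positive and sorted by decreasing logistic score.
#'
#' @param basis `q_g x V` matrix with orthogonal rows (as from
#'   [group_subspace()]).
#' @param restarts,maxit,tol,seed As in [fit_lngca()].
#' @return List with `components` (`q_g x V`), `scores`, `rotation`
#'   (`q_g x q_g`), and `objective`.
#' @export
group_ica <- function(basis, restarts = 100L, maxit = 500L, tol = 1e-6,
                      seed = NULL) {
  basis <- as.matrix(basis)
  q <- nrow(basis)
  V <- ncol(basis)
  # orthonormalize rows defensively, then scale to whitened convention
  nrm <- sqrt(rowSums(basis^2))
  G <- (basis / nrm) %*% t(basis / nrm)
  if (max(abs(G - diag(q))) > 1e-6)
    stop("basis rows are not orthogonal", call. = FALSE)
  B <- sqrt(V - 1) * basis / nrm
  if (q == 1L) {
    fin <- .finalize_components(matrix(1, 1, 1), B)
    return(list(components = fin$S, scores = fin$scores,
                rotation = fin$U, objective = sum(fin$scores)))
  }
  best <- .fastica_logistic(B, q, restarts, maxit, tol, seed)
  fin <- .finalize_components(best$U, B)
  list(components = fin$S, scores = fin$scores, rotation = fin$U,
       objective = best$objective)
}

#' Subject mixing and time-course variances for group components
#'
#' Least-squares regression of a subject's (row-centered) data on the group
#' components gives the subject's time courses (`T x q_g` mixing matrix);
#' the variance of component `j`'s time course, `sum(M[, j]^2) / (T - 1)`,
#' summarizes how engaged the component is in that subject.  A component
#' orthogonal to the subject's data gets variance 0.
#'
#' @param raw_i `T x V` subject data matrix (rows are centered internally).
#' @param group_components `q_g x V` matrix of group spatial components.
#' @return List with `mixing` (`T x q_g`) and `variances` (length `q_g`).
#' @export
subject_group_mixing <- function(raw_i, group_components) {
  X <- as.matrix(raw_i)
  X <- X - rowMeans(X)
  S <- as.matrix(group_components)
  M <- t(solve(S %*% t(S), S %*% t(X)))
  list(mixing = M, variances = colSums(M^2) / (nrow(X) - 1))
}

#' Subject-specific components in the orthogonal complement
#'
#' Projects the group-component span out of a subject's estimated
#' non-Gaussian components, reduces the residual to rank `q_i - q_g` by
#' SVD, and rotates by noise-free ICA.  Every output row is orthogonal to
#' every group component by construction.
#'
#' @param S_i_hat `q_i x V` estimated subject components.
#' @param group_components `q_g x V` group components.
#' @param n_individual Number of individual components to extract; defaults
#'   to `q_i - q_g`.  Reduced (with a warning) if the residual has lower
#'   numerical rank.
#' @param restarts,maxit,tol,seed As in [fit_lngca()].
#' @return List with `components` (`n_individual x V`, possibly 0 rows),
#'   `scores`, and `n_dropped` (components lost to rank deficiency).
#' @export
individual_components <- function(S_i_hat, group_components,
                                  n_individual = NULL, restarts = 40L,
                                  maxit = 500L, tol = 1e-6, seed = NULL) {
  S_i <- as.matrix(S_i_hat)
  Sg <- as.matrix(group_components)
  V <- ncol(S_i)
  q_i <- nrow(S_i)
  q_g <- nrow(Sg)
  if (is.null(n_individual)) n_individual <- q_i - q_g
  if (n_individual <= 0L)
    return(list(components = matrix(0, 0, V), scores = numeric(0),
                n_dropped = 0L))
  # residual after projecting out the group span
  R <- S_i - t(solve(Sg %*% t(Sg), Sg %*% t(S_i))) %*% Sg
  sv <- svd(R, nu = 0, nv = min(q_i, n_individual))
  keep <- sum(sv$d > max(dim(R)) * .Machine$double.eps * sv$d[1L] &
                sv$d > 1e-8 * sqrt(V))
  keep <- min(keep, n_individual)
  n_dropped <- n_individual - keep
  if (n_dropped > 0L)
    warning(sprintf("residual subspace has rank %d; returning %d individual components",
                    keep, keep))
  if (keep == 0L)
    return(list(components = matrix(0, 0, V), scores = numeric(0),
                n_dropped = n_dropped))
  basis <- t(sv$v[, seq_len(keep), drop = FALSE])
  ica <- group_ica(basis, restarts = restarts, maxit = maxit, tol = tol,
                   seed = seed)
  list(components = ica$components, scores = ica$scores,
       n_dropped = n_dropped)
}

#' Temporal-concatenation group ICA baseline (PCA+ICA)
#'
#' The standard group ICA pipeline used for comparison: per-subject PCA
#' retaining `q_subject` components (or the smallest number explaining
#' `var_frac` of the variance), temporal concatenation, a second PCA to
#' `q_g` dimensions, then noise-free ICA.  Because subject reduction ranks
#' by variance, low-variance non-Gaussian signals may be discarded here
#' while group LNGCA retains them.
#'
#' @param raw List of `T x V` subject matrices.
#' @param q_subject Per-subject PCA dimension; ignored when `var_frac` is
#'   given.
#' @param q_g Number of group components.
#' @param var_frac Optional fraction in (0, 1]; per subject, the smallest
#'   dimension whose leading eigenvalues explain at least this fraction of
#'   variance is used.
#' @param restarts,maxit,tol,seed As in [fit_lngca()].
#' @return List with `components` (`q_g x V`), `scores`, `objective`, and
#'   `q_subject_used` (per-subject PCA dimensions).
#' @export
gica_baseline <- function(raw, q_subject = NULL, q_g, var_frac = NULL,
                          restarts = 100L, maxit = 500L, tol = 1e-6,
                          seed = NULL) {
  stopifnot(is.list(raw), length(raw) >= 1L)
  reduced <- vector("list", length(raw))
  q_used <- integer(length(raw))
  for (i in seq_along(raw)) {
    X <- as.matrix(raw[[i]])
    X <- X - rowMeans(X)
    sv <- svd(X, nu = 0)
    if (!is.null(var_frac)) {
      q_i <- which(cumsum(sv$d^2) / sum(sv$d^2) >= var_frac)[1L]
    } else {
      if (is.null(q_subject))
        stop("supply q_subject or var_frac", call. = FALSE)
      q_i <- min(q_subject, nrow(X))
    }
    q_used[i] <- q_i
    # principal-component time-reduced data: D V' restricted to top q_i
    reduced[[i]] <- sv$d[seq_len(q_i)] * t(sv$v[, seq_len(q_i), drop = FALSE])
  }
  stacked <- do.call(rbind, reduced)
  sub <- group_subspace(stacked, q_g)
  ica <- group_ica(sub$basis, restarts = restarts, maxit = maxit, tol = tol,
                   seed = seed)
  list(components = ica$components, scores = ica$scores,
       objective = ica$objective, q_subject_used = q_used,
       singular_values = sub$singular_values)
}
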