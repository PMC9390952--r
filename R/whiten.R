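# Pre-whitening of subject data matrices.

#' Center and whiten a subject data matrix
#'
#' Centers and scales the rows of a `T x V` data matrix (time courses of
#' unit variance), then maps to the scaled right-singular-vector basis:
#' the result `X` satisfies `X %*% rep(1, V) = 0` and
#' `X %*% t(X) / (V - 1) = diag(T)`.  The centering vector, row scales and
#' the de-whitening map are recorded so mixing matrices can be expressed in
#' the original (centered) data units.
#'
#' @param raw Numeric `T x V` matrix with `V > T`; must have full row rank
#'   after centering.
#' @return An object of class `"lngca_data"`: a list with `X` (whitened
#'   `T x V` matrix), `T`, `V`, `whitened = TRUE`, and `transform`, a list
#'   holding `center` (row means), `row_scale` (row standard deviations),
#'   `dewhiten` (`T x T`, maps whitened rows back to centered+scaled data)
#'   and `centered` (the centered, row-scaled data used for mixing-matrix
#'   least squares).
#' @examples
#' d <- center_whiten(matrix(rnorm(3 * 10), 3, 10))
#' max(abs(d$X %*% t(d$X) / 9 - diag(3)))  # ~ 0
#' @export
center_whiten <- function(raw) {
  raw <- as.matrix(raw)
  T_ <- nrow(raw)
  V <- ncol(raw)
  if (T_ < 2L) stop("need at least 2 rows (time points)", call. = FALSE)
  if (V <= T_) stop("need more columns (voxels) than rows", call. = FALSE)
  ctr <- rowMeans(raw)
  xc <- raw - ctr
  row_scale <- sqrt(rowSums(xc^2) / (V - 1))
  if (any(row_scale <= 0))
    stop("degenerate input: constant row(s) ",
         paste(which(row_scale <= 0), collapse = ", "), call. = FALSE)
  xc <- xc / row_scale
  sv <- svd(xc, nu = T_, nv = T_)
  tol <- max(dim(xc)) * .Machine$double.eps * sv$d[1L]
  rk <- sum(sv$d > tol)
  if (rk < T_)
    stop(sprintf("rank-deficient input: rank %d < %d rows", rk, T_),
         call. = FALSE)
  X <- sqrt(V - 1) * t(sv$v)                 # T x V, XX'/(V-1) = I
  dewhiten <- sv$u %*% (diag(sv$d, T_) / sqrt(V - 1))  # xc = dewhiten %*% X
  structure(
    list(X = X, T = T_, V = V, whitened = TRUE,
         transform = list(center = ctr, row_scale = row_scale,
                          dewhiten = dewhiten, centered = xc)),
    class = "lngca_data"
  )
}

#' @export
print.lngca_data <- function(x, ...) {
  cat(sprintf("Whitened data matrix: T = %d time points, V = %d voxels\n",
              x$T, x$V))
  invisible(x)
}

# Accept either an lngca_data object or a bare matrix that is already
# whitened (rows centered, Gram = (V-1) I).  Used by the dimension test.
.as_whitened <- function(data) {
  if (inherits(data, "lngca_data")) return(data)
  X <- as.matrix(data)
  g <- X %*% t(X) / (ncol(X) - 1)
  if (max(abs(g - diag(nrow(X)))) > 1e-6 || max(abs(rowMeans(X))) > 1e-6)
    stop("matrix is not whitened; call center_whiten() first", call. = FALSE)
  structure(list(X = X, T = nrow(X), V = ncol(X), whitened = TRUE,
                 transform = NULL),
            class = "lngca_data")
}
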