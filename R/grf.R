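# Spatially correlated Gaussian noise: Gaussian random fields generated by
# smoothing iid Gaussian grids with a Gaussian kernel of given FWHM.

#' Specify a noise model for the dimension test
#'
#' @param kind `"grf"` for a Gaussian random field (iid Gaussian grid
#'   smoothed with a Gaussian kernel, then standardized) or `"iid"` for
#'   white Gaussian rows.
#' @param fwhm Full width at half maximum of the smoothing kernel, in
#'   voxels (`grf` only); the kernel standard deviation is
#'   `fwhm / (2 sqrt(2 log 2))`.
#' @param grid_shape Integer dimensions of the voxel grid (1, 2 or 3
#'   dimensions); their product is the row length `V` (`grf` only).
#' @return An object of class `"noise_model"`.
#' @examples
#' noise_model("grf", fwhm = 9, grid_shape = c(33, 33))
#' @export
noise_model <- function(kind = c("grf", "iid"), fwhm = NULL,
                        grid_shape = NULL) {
  kind <- match.arg(kind)
  if (kind == "grf") {
    if (is.null(fwhm) || fwhm <= 0) stop("fwhm must be > 0", call. = FALSE)
    if (is.null(grid_shape) || any(grid_shape < 1))
      stop("grid_shape required for grf noise", call. = FALSE)
    grid_shape <- as.integer(grid_shape)
  }
  structure(list(kind = kind, fwhm = fwhm, grid_shape = grid_shape),
            class = "noise_model")
}

#' @export
print.noise_model <- function(x, ...) {
  if (x$kind == "iid") cat("Noise model: iid Gaussian\n")
  else cat(sprintf("Noise model: Gaussian random field, FWHM %.3g on grid %s\n",
                   x$fwhm, paste(x$grid_shape, collapse = " x ")))
  invisible(x)
}

# 1-D smoothing operator (n x n) for a Gaussian kernel with given FWHM,
# truncated at 4 sigma, reflecting boundaries, rows normalized to sum 1.
.smooth_operator <- function(n, fwhm) {
  sig <- fwhm / (2 * sqrt(2 * log(2)))
  r <- ceiling(4 * sig)
  w <- stats::dnorm(seq(-r, r), sd = sig)
  K <- matrix(0, n, n)
  for (d in seq(-r, r)) {
    j <- seq_len(n) + d
    j[j < 1L] <- 1L - j[j < 1L]          # reflect (edge repeated)
    j[j > n] <- 2L * n + 1L - j[j > n]
    K[cbind(seq_len(n), j)] <- K[cbind(seq_len(n), j)] + w[d + r + 1L]
  }
  K / rowSums(K)
}

# cache of per-(n, fwhm) smoothing operators
.grf_cache <- new.env(parent = emptyenv())

.get_smoother <- function(n, fwhm) {
  key <- sprintf("n%d_f%.8g", n, fwhm)
  if (is.null(.grf_cache[[key]]))
    .grf_cache[[key]] <- .smooth_operator(n, fwhm)
  .grf_cache[[key]]
}

# per-voxel standard deviation of the smoothed iid field: separable, so the
# voxelwise variance is the outer product of the 1-D operators' squared row
# norms.  Dividing by it keeps every voxel's marginal exactly N(0, 1) --
# without this, reflecting boundaries inflate edge-voxel variance and field
# extremes pile up along the edges.
.smooth_sd_grid <- function(grid_shape, fwhm) {
  norms <- lapply(grid_shape, function(n)
    sqrt(rowSums(.get_smoother(n, fwhm)^2)))
  arr <- norms[[1L]]
  if (length(norms) > 1L)
    for (d in 2L:length(norms)) arr <- outer(arr, norms[[d]])
  as.vector(arr)
}

#' Sample standardized Gaussian noise rows
#'
#' Draws `n_rows` independent rows from the noise model.  For `"grf"`,
#' each row is an iid standard-Gaussian grid smoothed along every grid
#' dimension with the Gaussian kernel (separable convolution, reflecting
#' boundaries), divided voxelwise by the theoretical smoothed standard
#' deviation (so every voxel's marginal is standard normal despite the
#' boundary treatment), and finally standardized to sample mean 0 and
#' variance 1.  Smoothing is linear, so marginals stay Gaussian; only the
#' spatial autocorrelation changes.
#'
#' @param n_rows Number of independent field realizations.
#' @param noise A [noise_model()]; for `"iid"` supply `V`.
#' @param seed Optional integer seed.
#' @param V Row length, required for `"iid"` noise (for `"grf"` it is
#'   `prod(grid_shape)`).
#' @param standardize `"row"` (default) additionally centers and scales
#'   each realized row; `"none"` returns the field with its exact N(0, 1)
#'   voxel marginals untouched (used by the copula construction of gamma
#'   fields, where the marginal must be exactly standard normal).
#' @return `n_rows x V` matrix.
#' @export
sample_grf_rows <- function(n_rows, noise, seed = NULL, V = NULL,
                            standardize = c("row", "none")) {
  standardize <- match.arg(standardize)
  stopifnot(inherits(noise, "noise_model"))
  if (!is.null(seed)) set.seed(seed)
  if (noise$kind == "iid") {
    if (is.null(V)) stop("V required for iid noise", call. = FALSE)
    Z <- matrix(stats::rnorm(n_rows * V), n_rows, V)
  } else {
    g <- noise$grid_shape
    V <- prod(g)
    A <- array(stats::rnorm(n_rows * V), dim = c(g, n_rows))
    nd <- length(g)
    # smooth along each grid dimension in turn (separable kernel)
    for (d in seq_len(nd)) {
      K <- .get_smoother(g[d], noise$fwhm)
      perm <- c(d, setdiff(seq_len(nd + 1L), d))
      A <- aperm(A, perm)
      dm <- dim(A)
      A <- array(K %*% matrix(A, dm[1L]), dm)
      A <- aperm(A, order(perm))
    }
    Z <- t(matrix(A, V, n_rows) / .smooth_sd_grid(g, noise$fwhm))
  }
  if (standardize == "none") return(Z)
  Z <- Z - rowMeans(Z)
  sdv <- sqrt(rowSums(Z^2) / (V - 1))
  Z / sdv
}
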