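# NIfTI input/output: 4D volumes + 3D binary mask <-> time x voxel matrix.

#' Extract a time-by-voxel matrix from a 4D NIfTI image
#'
#' Reads a 4D image and a 3D binary mask on the same grid and returns the
#' `T x V` matrix of in-mask voxel time series, with the voxel index map
#' needed to write results back as images.  Optional per-voxel
#' mean-centering and variance normalization mirror common resting-state
#' preprocessing; voxels with zero variance inside the mask are excluded
#' (with a warning) when normalization is requested.
#'
#' @param image Path to a 4D NIfTI file, or an `RNifti` image object.
#' @param mask Path to a 3D NIfTI mask (nonzero = in mask), or an image
#'   object.
#' @param center,scale Per-voxel centering / unit-variance scaling.
#' @return List with `data` (`T x V`), `index` (linear voxel indices into
#'   the 3D grid), `dim` (3D grid dimensions), and `mask` (logical 3D
#'   array).
#' @export
nifti_to_matrix <- function(image, mask, center = FALSE, scale = FALSE) {
  img <- if (is.character(image)) RNifti::readNifti(image) else image
  msk <- if (is.character(mask)) RNifti::readNifti(mask) else mask
  idim <- dim(img)
  mdim <- dim(msk)
  if (length(idim) != 4L)
    stop("image must be 4D (x, y, z, t)", call. = FALSE)
  if (!identical(as.integer(idim[1:3]), as.integer(mdim)))
    stop("image and mask grids differ", call. = FALSE)
  mlog <- array(as.array(msk) != 0, dim = mdim)
  index <- which(mlog)
  if (length(index) == 0L) stop("mask is empty", call. = FALSE)
  T_ <- idim[4L]
  vox <- matrix(as.array(img), prod(idim[1:3]), T_)[index, , drop = FALSE]
  X <- t(vox)                                    # T x V
  if (center || scale) {
    mu <- colMeans(X)
    if (center) X <- sweep(X, 2L, mu)
    if (scale) {
      sdv <- sqrt(colSums(sweep(X, 2L, if (center) 0 else mu)^2) /
                    (T_ - 1))
      keep <- sdv > 0
      if (!all(keep)) {
        warning(sprintf("excluding %d zero-variance voxel(s) inside mask",
                        sum(!keep)))
        X <- X[, keep, drop = FALSE]
        index <- index[keep]
        sdv <- sdv[keep]
      }
      X <- sweep(X, 2L, sdv, `/`)
    }
  }
  list(data = X, index = index, dim = as.integer(idim[1:3]), mask = mlog)
}

#' Write component maps (or data rows) back into NIfTI volumes
#'
#' Inverse of [nifti_to_matrix()]: places each row of `mat` at the mask's
#' voxel indices of a 3D volume (out-of-mask voxels are 0) and stacks rows
#' as the 4th dimension.
#'
#' @param mat `n x V` matrix whose columns correspond to `index`.
#' @param index,dim As returned by [nifti_to_matrix()].
#' @param file Optional path; when given, the image is written there.
#' @return The 4D array (invisibly when written to file).
#' @export
matrix_to_nifti <- function(mat, index, dim, file = NULL) {
  mat <- as.matrix(mat)
  vol <- array(0, c(dim, nrow(mat)))
  stride <- prod(dim)
  for (j in seq_len(nrow(mat)))
    vol[index + (j - 1L) * stride] <- mat[j, ]
  if (!is.null(file)) {
    RNifti::writeNifti(RNifti::asNifti(vol), file)
    return(invisible(vol))
  }
  vol
}
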