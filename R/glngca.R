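# Main model-fitting interface: the two-stage group LNGCA decomposition.

#' Fit the group LNGCA decomposition
#'
#' Two-stage decomposition of multi-subject data `X_i (T x V)` into group
#' spatial components shared by all subjects, subject-specific (individual)
#' components orthogonal to the group components, and residual Gaussian
#' noise:
#' \deqn{x_i(v) = M_i^g s_g(v) + M_i^I s_{I,i}(v) + M_i^n n_i(v).}
#' Stage 1 pre-whitens each subject and extracts its `q_i` most
#' non-Gaussian components with [fit_lngca()].  Stage 2 concatenates the
#' unit-norm subject components, takes the top `q_g` right singular vectors
#' as the group subspace, rotates them to independence by noise-free ICA,
#' and estimates each subject's individual components in the orthogonal
#' complement of the group span within that subject's estimated
#' non-Gaussian subspace.
#'
#' @param x List of subject data matrices (`T x V`, time by voxel).
#'   Subjects may have different `T` but must share `V`.
#' @param q_g Number of group components (a required modelling choice;
#'   `1 <= q_g <= min(q_i)`).
#' @param q_i Integer vector (recycled) of per-subject non-Gaussian
#'   dimensions, or `NULL` to estimate each by [estimate_dimension()]
#'   using `noise`, `alpha` and `B`.
#' @param n_individual Individual components per subject; default
#'   `q_i - q_g`.
#' @param restarts Restarts for the subject-level fits.
#' @param group_restarts Restarts for the group-level and individual-level
#'   noise-free ICA.
#' @param maxit,tol Fixed-point controls, see [fit_lngca()].
#' @param noise,alpha,B Dimension-test settings, used only when
#'   `q_i = NULL`; see [estimate_dimension()].
#' @param seed Optional integer seed; per-subject streams are derived from
#'   it.
#' @return An object of class `"glngca"` with elements
#'   `group_components` (`q_g x V`), `group_scores`, `singular_values`,
#'   `subject_mixing` (list of `T x q_g` matrices), `group_variances`
#'   (subjects x `q_g` matrix of time-course variances),
#'   `individual` (per subject: `components`, `mixing`, `scores`),
#'   `subject_fits` (stage-1 [fit_lngca()] objects), `q_g`, `q_i`,
#'   `dim_tests` (when dimensions were estimated) and `call`.
#' @examples
#' \donttest{
#' sim <- simulate_study(simulation_design(n_subjects = 4, seed = 7))
#' fit <- glngca(sim$data, q_g = 3, q_i = 25, restarts = 4, seed = 1)
#' fit
#' }
#' @seealso [gica_baseline()] for the PCA+ICA comparison pipeline,
#'   [match_components()] for scoring against references.
#' @export
glngca <- function(x, q_g, q_i = NULL, n_individual = NULL,
                   restarts = 40L, group_restarts = 100L,
                   maxit = 500L, tol = 1e-6,
                   noise = noise_model("grf", fwhm = 9,
                                       grid_shape = c(33, 33)),
                   alpha = 0.05, B = 200L, seed = NULL) {
  cl <- match.call()
  stopifnot(is.list(x), length(x) >= 2L)
  k <- length(x)
  Vs <- vapply(x, ncol, integer(1))
  if (length(unique(Vs)) != 1L)
    stop("all subjects must share the same number of voxels V",
         call. = FALSE)
  if (is.null(seed)) seed <- sample.int(2^31 - 1, 1L)
  data <- lapply(x, center_whiten)

  dim_tests <- NULL
  if (is.null(q_i)) {
    dim_tests <- vector("list", k)
    q_i <- integer(k)
    for (i in seq_len(k)) {
      dim_tests[[i]] <- estimate_dimension(data[[i]], alpha = alpha, B = B,
                                           noise = noise,
                                           seed = (seed + 7901L * i) %% 2147483647L)
      q_i[i] <- max(dim_tests[[i]]$q_hat, q_g)  # need q_i >= q_g to proceed
    }
  } else {
    q_i <- as.integer(rep_len(q_i, k))
  }
  if (q_g < 1L || q_g > min(q_i))
    stop("q_g must satisfy 1 <= q_g <= min(q_i)", call. = FALSE)

  subject_fits <- vector("list", k)
  for (i in seq_len(k)) {
    subject_fits[[i]] <- fit_lngca(data[[i]], q = q_i[i],
                                   restarts = restarts, maxit = maxit,
                                   tol = tol,
                                   seed = (seed + 1237L * i) %% 2147483647L)
  }

  stacked <- concat_normalize(lapply(subject_fits, `[[`, "components"))
  sub <- group_subspace(stacked, q_g)
  gica <- group_ica(sub$basis, restarts = group_restarts, maxit = maxit,
                    tol = tol, seed = (seed + 31L) %% 2147483647L)
  Sg <- gica$components

  subject_mixing <- vector("list", k)
  group_variances <- matrix(NA_real_, k, q_g)
  individual <- vector("list", k)
  for (i in seq_len(k)) {
    bm <- subject_group_mixing(x[[i]], Sg)
    subject_mixing[[i]] <- bm$mixing
    group_variances[i, ] <- bm$variances
    ind <- individual_components(subject_fits[[i]]$components, Sg,
                                 n_individual = if (is.null(n_individual))
                                   NULL else n_individual,
                                 restarts = group_restarts, maxit = maxit,
                                 tol = tol,
                                 seed = (seed + 571L * i) %% 2147483647L)
    imix <- if (nrow(ind$components) > 0) {
      Xc <- as.matrix(x[[i]])
      Xc <- Xc - rowMeans(Xc)
      Si <- ind$components
      t(solve(Si %*% t(Si), Si %*% t(Xc)))
    } else matrix(0, nrow(x[[i]]), 0)
    individual[[i]] <- list(components = ind$components, mixing = imix,
                            scores = ind$scores, n_dropped = ind$n_dropped)
  }

  structure(
    list(group_components = Sg, group_scores = gica$scores,
         singular_values = sub$singular_values,
         subject_mixing = subject_mixing,
         group_variances = group_variances,
         individual = individual, subject_fits = subject_fits,
         q_g = q_g, q_i = q_i, dim_tests = dim_tests, seed = seed,
         call = cl),
    class = "glngca"
  )
}

#' @export
print.glngca <- function(x, ...) {
  cat("Group LNGCA decomposition\n")
  cat(sprintf("  subjects: %d, voxels: %d\n",
              length(x$subject_mixing), ncol(x$group_components)))
  cat(sprintf("  group components: %d (logistic scores %s)\n", x$q_g,
              paste(format(x$group_scores, digits = 3), collapse = ", ")))
  cat(sprintf("  subject NG dimensions: %s\n",
              paste(x$q_i, collapse = ", ")))
  invisible(x)
}

#' @export
summary.glngca <- function(object, ...) {
  ind_n <- vapply(object$individual, function(z) nrow(z$components),
                  integer(1))
  out <- list(
    n_subjects = length(object$subject_mixing),
    V = ncol(object$group_components),
    q_g = object$q_g, q_i = object$q_i,
    group_scores = object$group_scores,
    singular_values = object$singular_values,
    n_individual = ind_n,
    group_variances = object$group_variances,
    subject_objectives = vapply(object$subject_fits, `[[`, numeric(1),
                                "objective")
  )
  class(out) <- "summary.glngca"
  out
}

#' @export
print.summary.glngca <- function(x, ...) {
  cat("Group LNGCA decomposition\n")
  cat(sprintf("  %d subjects, V = %d voxels\n", x$n_subjects, x$V))
  cat(sprintf("  q_g = %d group components; singular values: %s\n",
              x$q_g, paste(format(x$singular_values, digits = 4),
                           collapse = ", ")))
  cat("  group logistic scores:",
      format(x$group_scores, digits = 4), "\n")
  cat("  individual components per subject:",
      paste(x$n_individual, collapse = ", "), "\n")
  cat("  group time-course variances (per subject):\n")
  print(signif(x$group_variances, 4))
  invisible(x)
}

#' Subject mixing matrices of a group LNGCA fit
#'
#' @param object A `"glngca"` fit.
#' @param which `"group"` for the `T x q_g` group mixing matrices,
#'   `"individual"` for the individual-component mixing matrices.
#' @param ... Unused.
#' @return A list over subjects of mixing matrices.
#' @export
coef.glngca <- function(object, which = c("group", "individual"), ...) {
  which <- match.arg(which)
  if (which == "group") object$subject_mixing
  else lapply(object$individual, `[[`, "mixing")
}

#' Display group component maps
#'
#' Renders each group spatial component as an image when the voxel count
#' matches a `grid` (rows x columns), or as a line profile otherwise.
#'
#' @param x A `"glngca"` fit.
#' @param grid Integer length-2 grid to reshape each component into;
#'   guessed as a square when `NULL` and `V` is a perfect square.
#' @param ... Passed to [graphics::image()].
#' @export
plot.glngca <- function(x, grid = NULL, ...) {
  S <- x$group_components
  V <- ncol(S)
  if (is.null(grid) && isTRUE(all.equal(sqrt(V), round(sqrt(V)))))
    grid <- c(sqrt(V), sqrt(V))
  op <- graphics::par(mfrow = c(1, nrow(S)), mar = c(1, 1, 2, 1))
  on.exit(graphics::par(op))
  for (j in seq_len(nrow(S))) {
    if (!is.null(grid)) {
      graphics::image(matrix(S[j, ], grid[1], grid[2]), axes = FALSE,
                      main = sprintf("group %d", j), ...)
    } else {
      graphics::plot(S[j, ], type = "l", main = sprintf("group %d", j),
                     xlab = "voxel", ylab = "")
    }
  }
  invisible(x)
}
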