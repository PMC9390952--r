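# Synthetic multi-subject study generator: digit-shaped group maps, gamma
# random field individual maps, Gaussian random field noise, AR(1) mixing
# columns rescaled to a controlled subspace variance allocation (SVAR).

# variance allocation across (group, individual, Gaussian) subspaces and
# within the group subspace, estimated quantiles from a large rsfMRI study
.svar_table <- list(
  high   = c(group = 0.335, individual = 0.299, gauss = 0.366),
  medium = c(group = 0.176, individual = 0.386, gauss = 0.438),
  low    = c(group = 0.017, individual = 0.460, gauss = 0.523)
)
.group_split <- c(0.154, 0.298, 0.548)  # low/medium/high-variance group map

#' Describe a synthetic group study
#'
#' Collects all knobs of the simulation: 20 subjects on a 33 x 33 grid
#' (`V = 1089`) with 3 digit-shaped group maps, 22 gamma-random-field
#' individual maps and 25 Gaussian-random-field noise components per
#' subject (`T = 50`), AR(1) mixing columns with `phi = 0.37`, kernel FWHM
#' 9, gamma marginals with shape 0.02 and rate 1e-4, and one of three
#' subspace variance (SVAR) settings: `"high"` (33.5 : 29.9 : 36.6),
#' `"medium"` (17.6 : 38.6 : 43.8) or `"low"` (1.7 : 46 : 52.3) percent
#' across the group, individual and Gaussian subspaces.  Within the group
#' subspace the variance is split 15.4 : 29.8 : 54.8 across the three
#' maps; individual and Gaussian components share their subspace equally.
#'
#' @param n_subjects Number of subjects.
#' @param grid Grid dimensions; the packaged digit masks need `c(33, 33)`.
#' @param q_g,q_I,n_gauss Component counts (group, individual, Gaussian);
#'   `T = q_g + q_I + n_gauss`.
#' @param svar_setting `"high"`, `"medium"` or `"low"`.
#' @param phi AR(1) coefficient of the mixing columns.
#' @param fwhm Smoothing kernel FWHM for both random field types.
#' @param gamma_shape,gamma_rate Marginal parameters of the individual
#'   maps.
#' @param group_split Variance proportions of the three group columns.
#' @param seed Integer seed; all draws derive from it.
#' @return An object of class `"simulation_design"`.
#' @export
simulation_design <- function(n_subjects = 20L, grid = c(33L, 33L),
                              q_g = 3L, q_I = 22L, n_gauss = 25L,
                              svar_setting = c("medium", "high", "low"),
                              phi = 0.37, fwhm = 9,
                              gamma_shape = 0.02, gamma_rate = 1e-4,
                              group_split = NULL, seed = 1L) {
  svar_setting <- match.arg(svar_setting)
  if (is.null(group_split)) group_split <- .group_split[seq_len(q_g)]
  group_split <- group_split / sum(group_split)
  structure(
    list(n_subjects = as.integer(n_subjects), grid = as.integer(grid),
         q_g = as.integer(q_g), q_I = as.integer(q_I),
         n_gauss = as.integer(n_gauss),
         T = as.integer(q_g + q_I + n_gauss),
         V = as.integer(prod(grid)),
         svar_setting = svar_setting,
         svar = .svar_table[[svar_setting]],
         group_split = group_split,
         phi = phi, fwhm = fwhm,
         gamma_shape = gamma_shape, gamma_rate = gamma_rate,
         seed = as.integer(seed)),
    class = "simulation_design"
  )
}

#' @export
print.simulation_design <- function(x, ...) {
  cat(sprintf(
    "Simulation design: %d subjects, T = %d (%d group + %d individual + %d Gaussian), V = %d\n",
    x$n_subjects, x$T, x$q_g, x$q_I, x$n_gauss, x$V))
  cat(sprintf("  SVAR %s: %s\n", x$svar_setting,
              paste(sprintf("%.1f%%", 100 * x$svar), collapse = " : ")))
  invisible(x)
}

.read_digit_mask <- function(which) {
  f <- system.file("extdata", sprintf("digit_mask_%d.txt", which),
                   package = "glngca", mustWork = TRUE)
  lines <- readLines(f)
  m <- do.call(rbind, lapply(strsplit(lines, ""),
                             function(r) as.integer(r == "1")))
  m == 1L
}

#' Digit-shaped group spatial maps
#'
#' Builds the three group maps on the grid: active pixels in the shape of
#' a "1", a "2 2" pair, and a "3 3 3" triple (packaged binary masks with
#' pairwise disjoint active regions), with active values drawn
#' Uniform(0.5, 1) and background iid N(0, 0.001).  The mask sizes were
#' calibrated once so the maps' mean logistic scores land near -1.09,
#' -1.08 and -1.11.  Rows are standardized on output.
#'
#' @param grid Must be `c(33, 33)` for the packaged masks.
#' @param seed Optional integer seed.
#' @param bg_var Background variance (0 allowed: inactive pixels exactly
#'   zero before standardization).
#' @return `3 x V` matrix with standardized rows.
#' @export
make_group_maps <- function(grid = c(33L, 33L), seed = NULL,
                            bg_var = 0.001) {
  if (!identical(as.integer(grid), c(33L, 33L)))
    stop("packaged digit masks are 33 x 33", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  V <- prod(grid)
  S <- matrix(0, 3L, V)
  for (j in 1:3) {
    msk <- as.vector(.read_digit_mask(j))
    x <- if (bg_var > 0) stats::rnorm(V, 0, sqrt(bg_var)) else numeric(V)
    x[msk] <- stats::runif(sum(msk), 0.5, 1)
    S[j, ] <- x
  }
  S <- S - rowMeans(S)
  S / sqrt(rowSums(S^2) / (V - 1))
}

#' Gamma random field maps
#'
#' Spatially correlated fields with gamma marginals: an iid Gaussian grid
#' is smoothed at the given FWHM (its voxel marginals are exactly standard
#' normal), pushed through the standard normal CDF and then the gamma
#' quantile function (a Gaussian copula construction), and finally each
#' row is standardized.  With the default shape 0.02 the marginals are
#' extremely spiky, giving strongly super-Gaussian maps.
#'
#' @param n Number of independent maps.
#' @param grid Grid dimensions.
#' @param fwhm Smoothing kernel FWHM in voxels.
#' @param shape,rate Gamma marginal parameters.
#' @param seed Optional integer seed.
#' @return `n x V` matrix with standardized rows.
#' @export
make_gamma_rf <- function(n, grid = c(33L, 33L), fwhm = 9,
                          shape = 0.02, rate = 1e-4, seed = NULL) {
  stopifnot(shape > 0, rate > 0)
  nm <- noise_model("grf", fwhm = fwhm, grid_shape = grid)
  Z <- sample_grf_rows(n, nm, seed = seed, standardize = "none")
  U <- stats::pnorm(Z)
  # clamp away from 1 so qgamma stays finite for spiky shapes
  U <- pmin(pmax(U, 1e-12), 1 - 1e-12)
  G <- matrix(stats::qgamma(U, shape = shape, rate = rate),
              nrow = n, ncol = prod(grid))
  G <- G - rowMeans(G)
  G / sqrt(rowSums(G^2) / (prod(grid) - 1))
}

#' AR(1) mixing matrix with controlled variance allocation
#'
#' Simulates `T` independent AR(1) time series of length `T` (standard
#' Gaussian innovations, so marginal variance `1 / (1 - phi^2)`) as mixing
#' columns, then rescales each column so the sums of squared column norms
#' by block match the design's subspace variance allocation exactly: the
#' group block gets the setting's group share split
#' `design$group_split` across its columns, and the individual and
#' Gaussian blocks share their totals equally.  The variance of a
#' component is the sum of squares of its mixing column, so the realized
#' SVAR is imposed, not sampled.
#'
#' @param design A [simulation_design()].
#' @param seed Optional integer seed.
#' @return List with `M` (`T x T`, full rank), `block` (factor labelling
#'   columns group/individual/gauss) and `svar` (realized block
#'   proportions).
#' @export
make_mixing <- function(design, seed = NULL) {
  stopifnot(inherits(design, "simulation_design"))
  if (!is.null(seed)) set.seed(seed)
  T_ <- design$T
  phi <- design$phi
  for (attempt in 1:10) {
    M <- matrix(0, T_, T_)
    for (j in seq_len(T_)) {
      e <- stats::rnorm(T_)
      x <- numeric(T_)
      x[1] <- e[1] / sqrt(1 - phi^2)   # stationary start
      for (t in 2:T_) x[t] <- phi * x[t - 1] + e[t]
      M[, j] <- x
    }
    if (qr(M)$rank == T_) break
    warning("rank-deficient mixing draw; resampling")
  }
  blocks <- rep(c("group", "individual", "gauss"),
                c(design$q_g, design$q_I, design$n_gauss))
  # per-column target variance shares (sum to 1)
  share <- c(design$svar[["group"]] * design$group_split,
             rep(design$svar[["individual"]] / design$q_I, design$q_I),
             rep(design$svar[["gauss"]] / design$n_gauss, design$n_gauss))
  total <- T_  # arbitrary overall scale
  target <- share * total
  M <- sweep(M, 2L, sqrt(target / colSums(M^2)), `*`)
  realized <- vapply(c(group = "group", individual = "individual",
                       gauss = "gauss"),
                     function(b) sum(colSums(M^2)[blocks == b]),
                     numeric(1)) / total
  list(M = M, block = factor(blocks, levels = c("group", "individual",
                                                "gauss")),
       svar = realized)
}

#' Simulate a full multi-subject study
#'
#' Draws the shared group maps once, then per subject fresh individual
#' gamma-field maps, Gaussian-field noise rows and an AR(1) mixing matrix,
#' and forms `X_i = M_i %*% rbind(S_g, S_{I,i}, N_i)` (all source rows
#' standardized).  Every piece of ground truth is retained for evaluation.
#'
#' @param design A [simulation_design()].
#' @return An object of class `"simulation_truth"`: `design`,
#'   `group_maps` (`q_g x V`), and per-subject lists `individual_maps`,
#'   `gauss_maps`, `mixing` (with block labels), `svar` (realized), and
#'   `data` (`T x V` matrices).
#' @examples
#' sim <- simulate_study(simulation_design(n_subjects = 2, seed = 5))
#' dim(sim$data[[1]])
#' @export
simulate_study <- function(design = simulation_design()) {
  stopifnot(inherits(design, "simulation_design"))
  if (design$q_g > 3L)
    stop("at most 3 group maps are packaged", call. = FALSE)
  base_seed <- design$seed %% 2147483647L
  Sg <- make_group_maps(design$grid, seed = base_seed)[seq_len(design$q_g), ,
                                                       drop = FALSE]
  k <- design$n_subjects
  out <- list(design = design, group_maps = Sg,
              individual_maps = vector("list", k),
              gauss_maps = vector("list", k),
              mixing = vector("list", k),
              block = NULL, svar = vector("list", k),
              data = vector("list", k))
  for (i in seq_len(k)) {
    si <- (base_seed + 104729L * i) %% 2147483647L
    SI <- make_gamma_rf(design$q_I, design$grid, design$fwhm,
                        design$gamma_shape, design$gamma_rate, seed = si)
    N <- sample_grf_rows(design$n_gauss,
                         noise_model("grf", fwhm = design$fwhm,
                                     grid_shape = design$grid),
                         seed = (si + 1L) %% 2147483647L)
    mx <- make_mixing(design, seed = (si + 2L) %% 2147483647L)
    out$individual_maps[[i]] <- SI
    out$gauss_maps[[i]] <- N
    out$mixing[[i]] <- mx$M
    out$block <- mx$block
    out$svar[[i]] <- mx$svar
    out$data[[i]] <- mx$M %*% rbind(Sg, SI, N)
  }
  class(out) <- "simulation_truth"
  out
}

#' @export
print.simulation_truth <- function(x, ...) {
  print(x$design)
  cat(sprintf("  realized SVAR (subject 1): %s\n",
              paste(sprintf("%.1f%%", 100 * x$svar[[1]]), collapse = " : ")))
  invisible(x)
}
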