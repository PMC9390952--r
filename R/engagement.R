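# Group-difference test on component engagement (log time-course variance).

#' Test group differences in component engagement
#'
#' For each component, fits a linear model of the log time-course variance
#' on the group label plus optional covariates and reports the t-test of
#' the group coefficient; p-values are Benjamini-Hochberg adjusted across
#' the declared family.  Subjects whose variance is zero or missing (a
#' component orthogonal to their data has no defined log variance) are
#' excluded per component, with the exclusion count recorded.
#'
#' @param tab Data frame with one row per (component, subject).
#' @param value Name of the log-variance column.
#' @param component Name of the component-id column.
#' @param group Name of the two-level group column.
#' @param covariates Character vector of covariate column names (numeric
#'   or binary), possibly empty.
#' @param family_size Number of tests to adjust over; defaults to the
#'   number of components actually tested.
#' @return A data frame of class `"engagement_table"` with columns
#'   `component`, `estimate` (group coefficient, second level minus
#'   first), `t`, `p`, `p_adjusted`, `n_excluded`.
#' @examples
#' tab <- data.frame(component = rep(1:2, each = 10),
#'                   logvar = rnorm(20), group = rep(c("a", "b"), 10))
#' engagement_test(tab, value = "logvar")
#' @export
engagement_test <- function(tab, value = "log_variance",
                            component = "component", group = "group",
                            covariates = character(0),
                            family_size = NULL) {
  tab <- as.data.frame(tab)
  for (col in c(value, component, group, covariates))
    if (!col %in% names(tab))
      stop(sprintf("column '%s' not found", col), call. = FALSE)
  tab[[group]] <- factor(tab[[group]])
  if (nlevels(tab[[group]]) != 2L)
    stop("group column must have exactly two levels", call. = FALSE)
  comps <- unique(tab[[component]])
  res <- data.frame(component = comps, estimate = NA_real_, t = NA_real_,
                    p = NA_real_, n_excluded = 0L)
  rhs <- paste(c(group, covariates), collapse = " + ")
  fml <- stats::as.formula(paste0("`", value, "` ~ ", rhs))
  for (ii in seq_along(comps)) {
    d <- tab[tab[[component]] == comps[ii], , drop = FALSE]
    bad <- !is.finite(d[[value]])
    res$n_excluded[ii] <- sum(bad)
    d <- d[!bad, , drop = FALSE]
    fit <- stats::lm(fml, data = d)
    cf <- summary(fit)$coefficients
    grow <- grep(paste0("^", group), rownames(cf))[1L]
    res$estimate[ii] <- cf[grow, 1L]
    res$t[ii] <- cf[grow, 3L]
    res$p[ii] <- cf[grow, 4L]
  }
  if (is.null(family_size)) family_size <- nrow(res)
  res$p_adjusted <- stats::p.adjust(res$p, method = "BH", n = family_size)
  res <- res[c("component", "estimate", "t", "p", "p_adjusted",
               "n_excluded")]
  class(res) <- c("engagement_table", "data.frame")
  res
}
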