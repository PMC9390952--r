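# Matching estimated components to reference components.

#' Match components to references by absolute correlation
#'
#' Solves the assignment problem minimizing `sum(1 - |r|)` over pairs of
#' estimated and reference (true) component rows with the Hungarian
#' algorithm, matching the `min(q, p)` best pairs.  Components are defined
#' up to sign and permutation, so matching uses `|r|` and reports the sign
#' that makes each matched correlation positive.
#'
#' @param estimated `q x V` matrix of estimated components.
#' @param truth `p x V` matrix of reference components.
#' @return An object of class `"match_result"`: `permutation` (length `q`;
#'   `permutation[j]` is the reference row matched to estimated row `j`,
#'   `NA` if unmatched), `signs` (+/-1 per estimated row, `NA` if
#'   unmatched), `correlations` (`|r|` of each matched pair, `NA` if
#'   unmatched), and `unmatched` (indices of unmatched estimated rows).
#' @examples
#' S <- matrix(rnorm(3 * 50), 3, 50)
#' m <- match_components(-S[c(2, 3, 1), ], S)
#' m$permutation   # 2 3 1
#' @export
match_components <- function(estimated, truth) {
  E <- as.matrix(estimated)
  S <- as.matrix(truth)
  stopifnot(ncol(E) == ncol(S), nrow(E) >= 1L, nrow(S) >= 1L)
  q <- nrow(E)
  p <- nrow(S)
  r <- stats::cor(t(E), t(S))      # q x p
  cost <- 1 - abs(r)
  if (q <= p) {
    sol <- as.integer(clue::solve_LSAP(cost))
    perm <- sol
  } else {
    sol <- as.integer(clue::solve_LSAP(t(cost)))  # assign references
    perm <- rep(NA_integer_, q)
    perm[sol] <- seq_len(p)
  }
  corr <- rep(NA_real_, q)
  sgn <- rep(NA_real_, q)
  ok <- !is.na(perm)
  corr[ok] <- abs(r[cbind(which(ok), perm[ok])])
  sgn[ok] <- sign(r[cbind(which(ok), perm[ok])])
  sgn[ok][sgn[ok] == 0] <- 1
  structure(
    list(permutation = perm, signs = sgn, correlations = corr,
         unmatched = which(!ok)),
    class = "match_result"
  )
}

#' @export
print.match_result <- function(x, ...) {
  ok <- !is.na(x$permutation)
  cat(sprintf("Component matching: %d matched pairs", sum(ok)))
  if (length(x$unmatched))
    cat(sprintf(", unmatched estimated rows: %s",
                paste(x$unmatched, collapse = ", ")))
  cat("\n|r|:", format(x$correlations[ok], digits = 3), "\n")
  invisible(x)
}
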