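# Non-negativity-constrained least squares with many right-hand sides: the
# numerical kernel for both alternating updates. The active-set iteration runs
# in C++ on the normal equations (Gram matrix computed once per call).

#' Non-negative least squares for one or many right-hand sides
#'
#' Solves `min ||b_j - A x_j||^2` subject to `x_j >= 0` independently for each
#' column `b_j` of `B`, by the Lawson-Hanson active-set method on the normal
#' equations. At the solution the KKT conditions hold to tolerance: the
#' gradient `A'(Ax - b)` is >= -tol on the zero set and |gradient| <= tol on
#' the positive set. Rank-deficient active-set systems are resolved with the
#' least-norm solution rather than an error.
#'
#' An all-zero design column yields zero rows in the solution (a warning is
#' emitted); this occurs transiently during factorization when a cluster
#' empties.
#'
#' @param A design matrix, q x r, finite.
#' @param B target matrix q x s, or a vector of length q.
#' @param tol relative KKT tolerance; scaled internally by `max(abs(A'B))` so
#'   the stopping rule is dimensionless.
#' @return non-negative r x s matrix (or length-r vector if `B` was a vector).
#' @export
nnls_solve <- function(A, B, tol = 1e-10) {
  A <- as.matrix(A)
  vec_in <- is.null(dim(B))
  B <- as.matrix(B)
  check_finite(A, "design matrix")
  check_finite(B, "target matrix")
  if (nrow(A) != nrow(B))
    stop("design has ", nrow(A), " rows but targets have ", nrow(B))
  zero_cols <- which(colSums(abs(A)) == 0)
  if (length(zero_cols) > 0)
    warning("all-zero design column(s) ",
            paste(zero_cols, collapse = ", "),
            ": corresponding solution rows set to 0")
  X <- .nnls_multi_cpp(A, B, tol)
  if (vec_in) drop(X) else X
}
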