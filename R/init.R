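# Starting values for the basis matrix W: deterministic NNDSVD and seeded
# uniform-random draws. Only W needs initialising under alternating least
# squares; the first H update is an exact solve given W.

#' Uniform random initialization of the basis matrix
#'
#' @param n number of samples (rows).
#' @param k number of clusters (columns), `2 <= k < n`.
#' @param seed integer seed; the draw is reproducible given it.
#' @return n x k matrix of i.i.d. U\[0, 1\] entries.
#' @export
random_init <- function(n, k, seed) {
  if (k < 2 || k >= n) stop("need 2 <= k < n")
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_rng(old))
  set.seed(as.integer(seed))
  matrix(runif(n * k), nrow = n, ncol = k)
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' NNDSVD initialization of the basis matrix
#'
#' Non-negative double singular value decomposition: a deterministic,
#' SVD-based start. The k leading singular triplets of the column-wise
#' concatenation of the weight-scaled layers `[sqrt(theta_1) X^1 | ... |
#' sqrt(theta_m) X^m]` are computed; the leading column of W is
#' `sqrt(sigma_1) * u_1` (sign-flipped to be non-negative), and each later
#' column j takes the positive or negative part of `u_j` — whichever
#' (u-part, v-part) pairing has the larger product of norms — rescaled by
#' `sqrt(sigma_j * m_j)` where `m_j` is that product. Exact zeros are replaced
#' by `epsilon` so no basis column starts degenerate.
#'
#' @param collection a [multi_omics()] collection with non-negative layers.
#' @param k number of clusters; must not exceed the rank of the concatenated
#'   matrix.
#' @param epsilon small positive value replacing exact zeros.
#' @return n x k non-negative matrix, entrywise >= epsilon.
#' @export
nndsvd_init <- function(collection, k, epsilon = 1e-6) {
  stopifnot(inherits(collection, "multi_omics"))
  if (epsilon <= 0) stop("epsilon must be positive")
  theta <- layer_weights(collection)
  X <- do.call(cbind, Map(function(l, th) sqrt(th) * l$values,
                          collection$layers, theta))
  n <- nrow(X)
  if (k < 1 || k > min(dim(X))) stop("k out of range for NNDSVD")
  sv <- svd(X, nu = k, nv = k)
  if (sv$d[k] <= max(dim(X)) * .Machine$double.eps * sv$d[1])
    stop("concatenated data has rank < ", k, "; try a smaller k")
  W <- matrix(0, n, k)
  u1 <- sv$u[, 1]
  if (sum(u1) < 0) u1 <- -u1           # Perron vector up to sign
  W[, 1] <- sqrt(sv$d[1]) * abs(u1)
  if (k >= 2) {
    for (j in 2:k) {
      u <- sv$u[, j]; v <- sv$v[, j]
      up <- pmax(u, 0); un <- pmax(-u, 0)
      vp <- pmax(v, 0); vn <- pmax(-v, 0)
      mp <- sqrt(sum(up^2)) * sqrt(sum(vp^2))
      mn <- sqrt(sum(un^2)) * sqrt(sum(vn^2))
      if (mp >= mn) {
        nu <- sqrt(sum(up^2))
        dir <- if (nu > 0) up / nu else up
        W[, j] <- sqrt(sv$d[j] * mp) * dir
      } else {
        nu <- sqrt(sum(un^2))
        dir <- if (nu > 0) un / nu else un
        W[, j] <- sqrt(sv$d[j] * mn) * dir
      }
    }
  }
  W[W == 0] <- epsilon
  W
}
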