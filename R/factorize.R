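# Joint alternating NNLS factorization: a common basis W across layers,
# layer-specific coefficient matrices H^i, exact block-coordinate descent on
# the weighted squared-Frobenius objective.

#' Weighted Frobenius objective of a joint factorization
#'
#' `Q = sum_i theta_i ||X^i - W H^i||_F^2`.
#'
#' @param collection a [multi_omics()] collection.
#' @param W n x k basis matrix.
#' @param H list of m k x p_i coefficient matrices.
#' @param theta optional weight vector; defaults to the layer weights stored
#'   in the collection.
#' @return non-negative scalar.
#' @export
nmf_objective <- function(collection, W, H, theta = NULL) {
  Xs <- layer_matrices(collection)
  if (is.null(theta)) theta <- layer_weights(collection)
  if (length(H) != length(Xs)) stop("H must have one matrix per layer")
  total <- 0
  for (i in seq_along(Xs)) {
    if (nrow(Xs[[i]]) != nrow(W) || ncol(W) != nrow(H[[i]]) ||
        ncol(H[[i]]) != ncol(Xs[[i]]))
      stop("dimension mismatch between X^", i, ", W and H^", i)
    R <- Xs[[i]] - W %*% H[[i]]
    total <- total + theta[i] * sum(R * R)
  }
  total
}

#' Residual sum of squares of a fit
#'
#' Unweighted `sum_i ||X^i - W H^i||_F^2`; identical to [nmf_objective()]
#' with all weights 1. Used for the RSS-elbow rule of cluster-number
#' selection.
#'
#' @inheritParams nmf_objective
#' @return non-negative scalar.
#' @export
nmf_rss <- function(collection, W, H) {
  nmf_objective(collection, W, H, theta = rep(1, collection$m))
}

#' Coefficient update: solve for one layer's H given W
#'
#' Exact solve of `min_{H >= 0} ||X - W H||_F^2`; each feature column of X is
#' an independent NNLS problem with design W.
#'
#' @param X n x p non-negative layer matrix (or an [omics_layer()]).
#' @param W fixed n x k basis.
#' @return k x p non-negative coefficient matrix.
#' @export
update_H <- function(X, W) {
  if (inherits(X, "omics_layer")) X <- X$values
  nnls_solve(W, X)
}

#' Basis update: solve for W given all coefficient matrices
#'
#' Exact solve of `min_{W >= 0} sum_i theta_i ||X^i - W H^i||_F^2`. Each
#' sample row of W is an independent NNLS problem against the vertical stack
#' of `sqrt(theta_i) t(H^i)` with target the stacked, scaled sample rows.
#'
#' @param collection a [multi_omics()] collection.
#' @param H list of m k x p_i coefficient matrices.
#' @param theta optional weights (default: stored layer weights).
#' @return n x k non-negative basis matrix.
#' @export
update_W <- function(collection, H, theta = NULL) {
  Xs <- layer_matrices(collection)
  if (is.null(theta)) theta <- layer_weights(collection)
  D <- do.call(rbind, Map(function(Hi, th) sqrt(th) * t(Hi), H, theta))
  Tg <- do.call(rbind, Map(function(Xi, th) sqrt(th) * t(Xi), Xs, theta))
  t(nnls_solve(D, Tg))
}

#' Assign samples to clusters by row argmax of the basis matrix
#'
#' Ties break to the lowest column index. An all-zero row is assigned to
#' cluster 1 with a warning.
#'
#' @param W n x k basis matrix (column-normalized by convention; see
#'   [factorize()]).
#' @return integer labels of length n in `1..k`.
#' @export
assign_clusters <- function(W) {
  W <- as.matrix(W)
  if (ncol(W) < 2) stop("need k >= 2 columns to assign clusters")
  if (any(rowSums(W) == 0))
    warning("all-zero basis row(s): assigned to cluster 1")
  max.col(W, ties.method = "first")
}

#' Connectivity matrix of a cluster assignment
#'
#' `C[i, j] = 1` iff samples i and j carry the same label; symmetric with a
#' unit diagonal.
#'
#' @param labels integer labels.
#' @return n x n binary matrix.
#' @export
connectivity_matrix <- function(labels) {
  outer(labels, labels, `==`) * 1
}

normalize_columns <- function(W, H) {
  # unit Euclidean column norms on W, inverse scale on H rows; Q-invariant
  s <- sqrt(colSums(W^2))
  s[s == 0] <- 1
  W <- sweep(W, 2, s, "/")
  H <- lapply(H, function(Hi) Hi * s)
  list(W = W, H = H)
}

#' Fit the joint factorization at fixed k from a given start
#'
#' Alternates exact NNLS solves for all coefficient matrices H^i and then the
#' common basis W. After each outer iteration the columns of W are rescaled
#' to unit Euclidean norm (with the inverse scale on the rows of every H^i,
#' leaving the objective unchanged) and the objective Q, the absolute
#' reconstruction error `sum_i sum(|X^i - W H^i|)`, and the connectivity
#' matrix of the current assignment are recorded.
#'
#' Stopping: the connectivity matrix unchanged for `stability_count`
#' consecutive iterations, OR relative change of the reconstruction error
#' below `tol`, OR `max_iter` reached (flagged as not converged, no error).
#'
#' @param collection a [multi_omics()] collection of non-negative layers.
#' @param k number of clusters, `2 <= k < n`.
#' @param W_init non-negative n x k starting basis.
#' @param tol relative reconstruction-error change threshold (default 1e-4).
#' @param stability_count consecutive stable-connectivity iterations required
#'   (default 50).
#' @param max_iter iteration cap (default 200).
#' @param keep_history keep the full per-iteration connectivity history
#'   (needed for consensus matrices; default TRUE).
#' @param seed optional integer recorded in the result for bookkeeping.
#' @return an object of class `nmf_fit`: `W`, `H`, `k`, `labels`,
#'   `objective_trace`, `reconstruction_error_trace`, `connectivity_history`,
#'   `converged`, `convergence_reason`, `n_iter`, `seed`.
#' @export
factorize <- function(collection, k, W_init, tol = 1e-4,
                      stability_count = 50L, max_iter = 200L,
                      keep_history = TRUE, seed = NA_integer_) {
  stopifnot(inherits(collection, "multi_omics"))
  n <- collection$n
  if (k < 2 || k >= n) stop("need 2 <= k < n")
  W_init <- as.matrix(W_init)
  if (nrow(W_init) != n || ncol(W_init) != k)
    stop("W_init must be ", n, " x ", k)
  if (min(W_init) < 0) stop("W_init must be non-negative")
  theta <- layer_weights(collection)
  Xs <- layer_matrices(collection)

  W <- W_init
  obj_trace <- numeric(0)
  err_trace <- numeric(0)
  history <- if (keep_history) vector("list", max_iter) else NULL
  prev_C <- NULL
  stable <- 0L
  reason <- "max_iter"
  converged <- FALSE
  iter <- 0L

  while (iter < max_iter) {
    iter <- iter + 1L
    H <- lapply(Xs, update_H, W = W)
    W <- update_W(collection, H, theta)
    nm <- normalize_columns(W, H)
    W <- nm$W; H <- nm$H

    q <- 0; e <- 0
    for (i in seq_along(Xs)) {
      R <- Xs[[i]] - W %*% H[[i]]
      q <- q + theta[i] * sum(R * R)
      e <- e + sum(abs(R))
    }
    obj_trace[iter] <- q
    err_trace[iter] <- e

    labels <- suppressWarnings(assign_clusters(W))
    C <- connectivity_matrix(labels)
    if (keep_history) history[[iter]] <- C

    if (!is.null(prev_C) && identical(C, prev_C)) {
      stable <- stable + 1L
    } else {
      stable <- 0L
    }
    prev_C <- C
    if (stable >= stability_count) {
      reason <- "connectivity_stable"
      converged <- TRUE
      break
    }
    if (iter >= 2) {
      denom <- err_trace[iter - 1]
      rel <- if (denom > 0) abs(e - denom) / denom else 0
      if (rel < tol) {
        reason <- "reconstruction_error"
        converged <- TRUE
        break
      }
    }
  }

  labels <- suppressWarnings(assign_clusters(W))
  structure(
    list(W = W, H = H, k = k, theta = theta, labels = labels,
         sample_ids = collection$sample_ids,
         objective_trace = obj_trace[seq_len(iter)],
         reconstruction_error_trace = err_trace[seq_len(iter)],
         connectivity_history =
           if (keep_history) history[seq_len(iter)] else NULL,
         converged = converged, convergence_reason = reason,
         n_iter = iter, seed = seed),
    class = "nmf_fit"
  )
}

#' @export
print.nmf_fit <- function(x, ...) {
  cat(sprintf(
    "nmf_fit: k = %d, %d samples, %d layers; %d iterations (%s)\n",
    x$k, length(x$labels), length(x$H), x$n_iter, x$convergence_reason))
  cat(sprintf("  final objective Q = %.6g\n", tail_value(x$objective_trace)))
  cat("  cluster sizes:", paste(tabulate(x$labels, x$k), collapse = " "), "\n")
  invisible(x)
}

tail_value <- function(x) if (length(x)) x[length(x)] else NA_real_

#' Multi-start fit: one NNDSVD start plus uniform-random restarts
#'
#' Runs [factorize()] from one deterministic NNDSVD start and
#' `n_init - 1` seeded uniform-random starts (run r uses seed
#' `base_seed + r`), returning the run with the smallest final objective Q
#' together with per-run summaries (final Q, labels, iteration-averaged
#' consensus matrix).
#'
#' @param collection a [multi_omics()] collection.
#' @param k number of clusters.
#' @param n_init number of starts (default 30, the reference setting).
#' @param base_seed integer seed offsetting the random starts.
#' @param burn_in connectivity-history iterations discarded before averaging
#'   each run's consensus matrix (default 0: the consensus averages every
#'   iterative step up to convergence — the early, still-moving assignments
#'   are exactly what distinguishes an unstable k from a stable one).
#' @param ... passed to [factorize()] (`tol`, `stability_count`, `max_iter`).
#' @return an `nmf_fit` (the best run) with extra elements `runs` (data.frame
#'   of per-run final Q, iterations, convergence reason), `run_labels`
#'   (matrix n x n_init), `run_consensus` (list of per-run consensus
#'   matrices), `consensus` (the best run's consensus), `best_run`.
#' @export
run_multistart <- function(collection, k, n_init = 30L, base_seed = 0L,
                           burn_in = 0L, ...) {
  stopifnot(inherits(collection, "multi_omics"))
  if (n_init < 1) stop("n_init must be >= 1")
  n <- collection$n
  fits_meta <- vector("list", n_init)
  best <- NULL
  best_q <- Inf
  best_run <- NA_integer_
  run_labels <- matrix(NA_integer_, n, n_init)
  run_consensus <- vector("list", n_init)
  run_rss <- numeric(n_init)

  for (r in seq_len(n_init)) {
    W0 <- if (r == 1L) {
      tryCatch(nndsvd_init(collection, k),
               error = function(e) random_init(n, k, base_seed + 1L))
    } else {
      random_init(n, k, base_seed + r)
    }
    fit <- factorize(collection, k, W0, seed = base_seed + r, ...)
    q <- tail_value(fit$objective_trace)
    fits_meta[[r]] <- data.frame(
      run = r, init = if (r == 1L) "nndsvd" else "uniform",
      final_Q = q, n_iter = fit$n_iter, reason = fit$convergence_reason,
      stringsAsFactors = FALSE)
    run_labels[, r] <- fit$labels
    run_consensus[[r]] <- consensus_matrix(fit$connectivity_history,
                                           burn_in = burn_in)$values
    run_rss[r] <- nmf_rss(collection, fit$W, fit$H)
    if (q < best_q) {
      best_q <- q
      best <- fit
      best_run <- r
    }
  }
  best$runs <- do.call(rbind, fits_meta)
  best$runs$rss <- run_rss
  best$run_labels <- run_labels
  best$run_consensus <- run_consensus
  best$consensus <- run_consensus[[best_run]]
  best$best_run <- best_run
  best$base_seed <- base_seed
  best
}
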