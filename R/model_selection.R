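# Choosing the number of clusters: consensus matrices and the five selection
# measures (silhouette on 1 - consensus, cophenetic correlation, dispersion,
# RSS elbow, cross-validated cluster prediction index).

#' Average connectivity matrices into a consensus matrix
#'
#' The entrywise mean of binary connectivity matrices; entry (i, j) is the
#' empirical probability that samples i and j co-cluster over the averaged
#' iterations (or runs).
#'
#' @param connectivity_history non-empty list of n x n binary matrices.
#' @param burn_in number of leading matrices discarded before averaging
#'   (default 0); truncated so that at least one matrix remains.
#' @return an object of class `consensus_matrix` with elements `values`
#'   (n x n, symmetric, unit diagonal, entries in `[0, 1]`) and `count`.
#' @export
consensus_matrix <- function(connectivity_history, burn_in = 0L) {
  if (length(connectivity_history) == 0) stop("empty connectivity history")
  burn_in <- min(as.integer(burn_in), length(connectivity_history) - 1L)
  if (burn_in > 0)
    connectivity_history <- connectivity_history[-seq_len(burn_in)]
  values <- Reduce(`+`, connectivity_history) / length(connectivity_history)
  structure(list(values = values, count = length(connectivity_history)),
            class = "consensus_matrix")
}

as_consensus_values <- function(cbar) {
  if (inherits(cbar, "consensus_matrix")) cbar$values else as.matrix(cbar)
}

#' Average silhouette width using 1 - consensus as distance
#'
#' The consensus entries act as similarities, so `d = 1 - consensus` (diagonal
#' forced to 0) replaces a geometric distance. For each sample, `a` is its
#' mean distance to its own cluster (excluding itself), `b` the smallest mean
#' distance to another cluster, and the silhouette is `(b - a) / max(a, b)`.
#' Singleton clusters contribute 0.
#'
#' @param cbar a [consensus_matrix()] or plain n x n matrix.
#' @param labels integer cluster labels of length n with at least two
#'   non-empty clusters.
#' @return mean silhouette width in `[-1, 1]`.
#' @export
silhouette_consensus <- function(cbar, labels) {
  d <- 1 - as_consensus_values(cbar)
  diag(d) <- 0
  n <- length(labels)
  if (nrow(d) != n) stop("labels do not match consensus dimension")
  cl <- sort(unique(labels))
  if (length(cl) < 2) stop("silhouette undefined with a single cluster")
  sizes <- table(factor(labels, levels = cl))
  # mean distance from each sample to each cluster
  member <- outer(labels, cl, `==`) * 1          # n x kc
  sums <- d %*% member                            # n x kc total distances
  s <- numeric(n)
  for (j in seq_len(n)) {
    own <- match(labels[j], cl)
    n_own <- sizes[own]
    if (n_own == 1) { s[j] <- 0; next }
    a <- sums[j, own] / (n_own - 1)
    b <- min(sums[j, -own] / sizes[-own])
    m <- max(a, b)
    s[j] <- if (m > 0) (b - a) / m else 0
  }
  mean(s)
}

#' Cophenetic correlation of a consensus matrix
#'
#' Pearson correlation between the off-diagonal entries of `d = 1 - consensus`
#' and the cophenetic (dendrogram merge-height) distances from average-linkage
#' hierarchical clustering of `d`. Values near 1 indicate the consensus is
#' nearly ultrametric, i.e. the clustering is stable.
#'
#' @param cbar a [consensus_matrix()] or plain matrix, n >= 3.
#' @return correlation in `[-1, 1]`.
#' @export
cophenetic_coefficient <- function(cbar) {
  dmat <- 1 - as_consensus_values(cbar)
  diag(dmat) <- 0
  if (nrow(dmat) < 3) stop("need n >= 3 samples")
  d <- as.dist(dmat)
  if (max(d) - min(d) == 0)
    stop("constant distance matrix: cophenetic correlation undefined")
  hc <- hclust(d, method = "average")
  cor(d, cophenetic(hc))
}

#' Dispersion coefficient of a consensus matrix
#'
#' `rho = (1 / n^2) * sum_ij 4 (cbar_ij - 1/2)^2`: equal to 1 exactly when
#' every consensus entry is 0 or 1 (perfectly reproducible co-clustering) and
#' minimized at 0 when every entry is 1/2.
#'
#' @param cbar a [consensus_matrix()] or plain matrix.
#' @return value in `[0, 1]`.
#' @export
dispersion_coefficient <- function(cbar) {
  v <- as_consensus_values(cbar)
  mean(4 * (v - 0.5)^2)
}

#' Configuration for the cross-validated cluster prediction index
#'
#' @param k_range candidate numbers of clusters (default 2:8).
#' @param n_repeats train/test repetitions (default 20).
#' @param train_fraction fraction of samples in the training split
#'   (default 2/3).
#' @param n_init_train,n_init_test multi-start counts for the training and
#'   test fits (default 10 each).
#' @param base_seed integer seed controlling splits and all fits.
#' @param ... additional arguments passed on to [factorize()].
#' @return a `cpi_config` list.
#' @export
cpi_config <- function(k_range = 2:8, n_repeats = 20L, train_fraction = 2 / 3,
                       n_init_train = 10L, n_init_test = 10L,
                       base_seed = 0L, ...) {
  if (n_repeats < 1) stop("n_repeats must be >= 1")
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("train_fraction must be in (0, 1)")
  structure(list(k_range = as.integer(k_range),
                 n_repeats = as.integer(n_repeats),
                 train_fraction = train_fraction,
                 n_init_train = as.integer(n_init_train),
                 n_init_test = as.integer(n_init_test),
                 base_seed = as.integer(base_seed),
                 fit_args = list(...)),
            class = "cpi_config")
}

subset_collection <- function(collection, idx) {
  multi_omics(lapply(collection$layers, function(l) {
    omics_layer(l$values[idx, , drop = FALSE], l$sample_ids[idx],
                l$feature_ids, l$weight, l$name)
  }), align = FALSE)
}

#' Cross-validated cluster prediction index (CPI)
#'
#' For each repetition the samples are split into train and test sets. The
#' model is fitted on the training samples; the trained coefficient matrices
#' H^i then define, for the test samples, the non-negative least-squares
#' problem `min_{W >= 0} sum_i theta_i ||X^i_test - W H^i_train||^2` whose
#' row argmax gives "predicted" test labels. Independently, the model is
#' fitted on the test samples alone, giving "observed" labels. The repetition
#' score is the adjusted Rand index between the two partitions, and CPI(k) is
#' the mean over repetitions. Under a well-specified k the trained factors
#' transfer, so CPI peaks at the true number of clusters.
#'
#' @param collection a [multi_omics()] collection.
#' @param config a [cpi_config()].
#' @return list with `k_range`, `values` (n_repeats x k matrix of per-repeat
#'   ARIs) and `mean` (per-k means).
#' @export
cluster_prediction_index <- function(collection, config = cpi_config()) {
  stopifnot(inherits(collection, "multi_omics"))
  n <- collection$n
  ks <- config$k_range
  vals <- matrix(NA_real_, config$n_repeats, length(ks),
                 dimnames = list(NULL, paste0("k", ks)))
  n_train <- max(1L, round(config$train_fraction * n))
  if (n_train >= n) n_train <- n - 1L
  theta <- layer_weights(collection)

  for (rep_i in seq_len(config$n_repeats)) {
    split_seed <- config$base_seed + 1000L * rep_i
    old <- get0(".Random.seed", envir = globalenv())
    set.seed(split_seed)
    train_idx <- sort(sample.int(n, n_train))
    restore_rng(old)
    test_idx <- setdiff(seq_len(n), train_idx)
    train <- subset_collection(collection, train_idx)
    test <- subset_collection(collection, test_idx)
    Xs_test <- layer_matrices(test)
    for (ki in seq_along(ks)) {
      k <- ks[ki]
      if (k >= length(train_idx) || k >= length(test_idx)) next
      fit_tr <- do.call(run_multistart, c(list(
        train, k, n_init = config$n_init_train,
        base_seed = split_seed + 7L * k), config$fit_args))
      W_test <- update_W(test, fit_tr$H, theta)
      predicted <- suppressWarnings(assign_clusters(W_test))
      fit_te <- do.call(run_multistart, c(list(
        test, k, n_init = config$n_init_test,
        base_seed = split_seed + 7L * k + 3L), config$fit_args))
      observed <- fit_te$labels
      if (length(unique(observed)) < 2)
        warning("degenerate single-cluster observed partition (k = ", k,
                ", repetition ", rep_i, ")")
      vals[rep_i, ki] <- adjusted_rand_index(predicted, observed)
    }
  }
  list(k_range = ks, values = vals, mean = colMeans(vals, na.rm = TRUE))
}

#' Scan candidate cluster numbers and compute all selection measures
#'
#' For every k in `k_range` the model is fitted `n_init` times
#' ([run_multistart()]); silhouette, cophenetic correlation and dispersion are
#' computed per run from that run's iteration-averaged consensus matrix and
#' final labels, and RSS per run from its final factors. CPI, if requested,
#' runs its own cross-validation loop.
#'
#' @param collection a [multi_omics()] collection.
#' @param k_range candidate numbers of clusters.
#' @param n_init multi-start count per k (default 30).
#' @param measures character subset of
#'   `c("silhouette", "cophenetic", "dispersion", "rss", "cpi")`.
#' @param base_seed integer seed.
#' @param cpi a [cpi_config()] or NULL for defaults (its `k_range` and
#'   `base_seed` are overridden by this function's arguments).
#' @param consensus_across_runs if TRUE, also compute the across-run consensus
#'   measures (one value per k instead of per run).
#' @param ... passed to [factorize()].
#' @return an object of class `k_profile`: per-measure matrices of values
#'   (rows = runs or repetitions, columns = k), their per-k means, and the
#'   chosen k per measure via [select_k()].
#' @export
scan_k <- function(collection, k_range = 2:8, n_init = 30L,
                   measures = c("silhouette", "cophenetic", "dispersion",
                                "rss", "cpi"),
                   base_seed = 0L, cpi = NULL,
                   consensus_across_runs = FALSE, ...) {
  stopifnot(inherits(collection, "multi_omics"))
  measures <- match.arg(measures, several.ok = TRUE)
  k_range <- as.integer(k_range)
  consensus_measures <- intersect(measures,
                                  c("silhouette", "cophenetic", "dispersion"))
  out <- list(k_range = k_range, n_init = n_init, measures = measures,
              values = list(), mean = list())
  need_fits <- length(consensus_measures) > 0 || "rss" %in% measures
  if (need_fits) {
    per_run <- c(consensus_measures, if ("rss" %in% measures) "rss")
    for (msr in per_run)
      out$values[[msr]] <- matrix(NA_real_, n_init, length(k_range),
                                  dimnames = list(NULL, paste0("k", k_range)))
    if (consensus_across_runs)
      across <- matrix(NA_real_, 3, length(k_range),
                       dimnames = list(c("silhouette", "cophenetic",
                                         "dispersion"),
                                       paste0("k", k_range)))
    for (ki in seq_along(k_range)) {
      k <- k_range[ki]
      fit <- run_multistart(collection, k, n_init = n_init,
                            base_seed = base_seed + 100L * k, ...)
      for (r in seq_len(n_init)) {
        cb <- fit$run_consensus[[r]]
        lb <- fit$run_labels[, r]
        if ("silhouette" %in% per_run)
          out$values[["silhouette"]][r, ki] <- tryCatch(
            silhouette_consensus(cb, lb), error = function(e) NA_real_)
        if ("cophenetic" %in% per_run)
          out$values[["cophenetic"]][r, ki] <- tryCatch(
            cophenetic_coefficient(cb), error = function(e) NA_real_)
        if ("dispersion" %in% per_run)
          out$values[["dispersion"]][r, ki] <- dispersion_coefficient(cb)
      }
      if ("rss" %in% per_run)
        out$values[["rss"]][, ki] <- fit$runs$rss
      if (consensus_across_runs) {
        run_conn <- lapply(seq_len(n_init),
                           function(r) connectivity_matrix(fit$run_labels[, r]))
        cb <- consensus_matrix(run_conn)
        across["silhouette", ki] <- tryCatch(
          silhouette_consensus(cb, fit$labels), error = function(e) NA_real_)
        across["cophenetic", ki] <- tryCatch(
          cophenetic_coefficient(cb), error = function(e) NA_real_)
        across["dispersion", ki] <- dispersion_coefficient(cb)
      }
    }
    if (consensus_across_runs) out$across_runs <- across
  }
  if ("cpi" %in% measures) {
    if (is.null(cpi)) cpi <- cpi_config()
    cpi$k_range <- k_range
    cpi$base_seed <- as.integer(base_seed)
    cpi_res <- cluster_prediction_index(collection, cpi)
    out$values[["cpi"]] <- cpi_res$values
  }
  for (msr in names(out$values))
    out$mean[[msr]] <- colMeans(out$values[[msr]], na.rm = TRUE)
  out$selected <- vapply(names(out$mean), function(msr) {
    tryCatch(select_k(out, msr), error = function(e) NA_integer_)
  }, integer(1))
  class(out) <- "k_profile"
  out
}

#' @export
print.k_profile <- function(x, ...) {
  cat("k_profile over k =", paste(x$k_range, collapse = ", "), "\n")
  for (msr in names(x$mean)) {
    cat(sprintf("  %-11s mean: %s -> k = %s\n", msr,
                paste(sprintf("%.3f", x$mean[[msr]]), collapse = " "),
                x$selected[[msr]]))
  }
  invisible(x)
}

#' Choose the number of clusters from a selection profile
#'
#' Silhouette, cophenetic, dispersion and CPI choose the k with maximum mean
#' value (ties break to the smallest k). RSS uses the elbow heuristic: the
#' interior k maximizing the discrete second difference of the mean RSS curve
#' (which needs at least three candidate ks).
#'
#' @param profile a `k_profile` from [scan_k()], or any list with `k_range`
#'   and `mean[[measure]]`.
#' @param measure one of `"silhouette"`, `"cophenetic"`, `"dispersion"`,
#'   `"rss"`, `"cpi"`.
#' @return the chosen k (integer).
#' @export
select_k <- function(profile, measure) {
  if (is.null(profile$mean[[measure]]))
    stop("measure '", measure, "' not present in profile")
  m <- profile$mean[[measure]]
  ks <- profile$k_range
  if (measure == "rss") {
    if (length(ks) < 3)
      stop("RSS elbow needs at least 3 candidate k values")
    d2 <- m[seq_len(length(m) - 2)] - 2 * m[seq(2, length(m) - 1)] +
      m[seq(3, length(m))]
    return(as.integer(ks[which.max(d2) + 1L]))
  }
  as.integer(ks[which.max(m)])   # which.max takes the first (smallest k) tie
}
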