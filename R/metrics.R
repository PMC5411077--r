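# External validation metrics for comparing two partitions of the same
# samples: adjusted Rand index, purity, normalized entropy.

partition_contingency <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b))
    stop("partitions must have equal length")
  table(labels_a, labels_b)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected pair-counting agreement: 1 for identical partitions (up
#' to relabeling), expected value 0 for independent random partitions, and
#' possibly negative for worse-than-chance agreement. Symmetric and invariant
#' to label permutation.
#'
#' @param labels_a,labels_b vectors of equal length (n >= 2) coercible to
#'   factors.
#' @return ARI value <= 1.
#' @export
adjusted_rand_index <- function(labels_a, labels_b) {
  tab <- partition_contingency(labels_a, labels_b)
  n <- sum(tab)
  if (n < 2) stop("need at least 2 samples")
  choose2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(choose2(tab))
  sum_a <- sum(choose2(rowSums(tab)))
  sum_b <- sum(choose2(colSums(tab)))
  expected <- sum_a * sum_b / choose2(n)
  denom <- (sum_a + sum_b) / 2 - expected
  if (denom == 0) {
    identical_part <- sum_ij == sum_a && sum_ij == sum_b
    warning("degenerate ARI denominator; returning ",
            if (identical_part) 1 else 0)
    return(if (identical_part) 1 else 0)
  }
  (sum_ij - expected) / denom
}

#' Cluster purity of a predicted partition against the truth
#'
#' The proportion of samples that belong to the majority true class of their
#' predicted cluster: `(1/n) * sum_c max_t n_ct`. Equal to 1 iff every
#' predicted cluster is composed of a single true class.
#'
#' @param predicted,truth label vectors of equal length.
#' @return purity in `(0, 1]`.
#' @export
cluster_purity <- function(predicted, truth) {
  tab <- partition_contingency(predicted, truth)
  sum(apply(tab, 1, max)) / sum(tab)
}

#' Normalized cluster entropy of a predicted partition against the truth
#'
#' Size-weighted mean over predicted clusters of the Shannon entropy (base 2)
#' of the true-class composition, normalized by `log2(number of true classes)`
#' so the value lies in `[0, 1]`: 0 for pure clusters, 1 for maximal
#' confusion. `0 * log 0` is taken as 0.
#'
#' @param predicted,truth label vectors of equal length; at least two true
#'   classes.
#' @return normalized entropy in `[0, 1]`.
#' @export
cluster_entropy <- function(predicted, truth) {
  tab <- partition_contingency(predicted, truth)
  n_true <- ncol(tab)
  if (n_true < 2) stop("entropy needs at least 2 true classes")
  n <- sum(tab)
  cluster_sizes <- rowSums(tab)
  h <- vapply(seq_len(nrow(tab)), function(c) {
    p <- tab[c, ] / cluster_sizes[c]
    p <- p[p > 0]
    -sum(p * log2(p))
  }, numeric(1))
  sum(cluster_sizes / n * h) / log2(n_true)
}
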