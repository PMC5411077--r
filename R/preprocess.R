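# Preprocessing: non-negative shift, unit-max rescale, layer weights,
# feature filters. These are the transforms applied to each platform before
# the joint factorization.

#' Shift a matrix so all entries are non-negative
#'
#' If the minimum entry is negative, its absolute value is added to every
#' entry (the resulting minimum is exactly zero); otherwise the matrix is
#' returned unchanged.
#'
#' @param X numeric matrix with finite entries.
#' @return matrix of the same shape with min(X) >= 0.
#' @export
shift_nonnegative <- function(X) {
  X <- as.matrix(X)
  check_finite(X, "matrix")
  mn <- min(X)
  if (mn < 0) X <- X + abs(mn)
  X
}

#' Rescale a non-negative matrix to unit maximum
#'
#' Divides every entry by the matrix maximum so entries lie in `[0, 1]` with
#' max exactly 1. Applied per layer, this makes layers on different
#' measurement scales comparable before factorization.
#'
#' @param X non-negative numeric matrix with max(X) > 0.
#' @return matrix with entries in `[0, 1]`.
#' @export
rescale_unit_max <- function(X) {
  X <- as.matrix(X)
  check_finite(X, "matrix")
  mx <- max(X)
  if (mx <= 0) stop("cannot rescale: matrix maximum is not positive")
  X / mx
}

#' Shift and rescale every layer of a collection
#'
#' Convenience wrapper applying [shift_nonnegative()] then
#' [rescale_unit_max()] to each layer independently.
#'
#' @param collection a [multi_omics()] collection.
#' @return the collection with transformed layers.
#' @export
prepare_collection <- function(collection) {
  stopifnot(inherits(collection, "multi_omics"))
  collection$layers <- lapply(collection$layers, function(l) {
    l$values <- rescale_unit_max(shift_nonnegative(l$values))
    l
  })
  collection
}

#' Compute layer weights from mean sums of squares
#'
#' The weight of layer i is `theta_i = max_j(meanSS_j) / meanSS_i`, where
#' `meanSS_i` is the mean of the squared entries of layer i over all
#' `n * p_i` cells. The layer with the largest mean sum of squares gets
#' weight 1 and all weights are >= 1, so less energetic layers are
#' up-weighted to a comparable contribution in the joint objective.
#'
#' @param collection a [multi_omics()] collection with non-negative layers.
#' @return numeric vector of length m, all >= 1.
#' @export
compute_weights <- function(collection) {
  stopifnot(inherits(collection, "multi_omics"))
  mss <- vapply(layer_matrices(collection),
                function(X) mean(X^2), numeric(1))
  if (any(mss == 0)) {
    stop("layer ", which(mss == 0)[1],
         " has zero mean sum of squares; cannot weight an all-zero layer")
  }
  max(mss) / mss
}

#' Apply computed or user weights to a collection
#'
#' @param collection a [multi_omics()] collection.
#' @param weights `"auto"` to use [compute_weights()], or a numeric vector of
#'   length m of positive weights.
#' @return the collection with layer weights set.
#' @export
set_weights <- function(collection, weights = "auto") {
  stopifnot(inherits(collection, "multi_omics"))
  if (identical(weights, "auto")) {
    weights <- compute_weights(collection)
  }
  weights <- as.numeric(weights)
  if (length(weights) != collection$m || any(!is.finite(weights)) ||
      any(weights <= 0))
    stop("weights must be ", collection$m, " positive numbers or \"auto\"")
  for (i in seq_len(collection$m)) collection$layers[[i]]$weight <- weights[i]
  collection
}

#' Filter features by variability and zero proportion
#'
#' Keeps features whose sample standard deviation (n - 1 denominator) is at
#' least `sd_min` and whose proportion of exactly-zero entries is strictly
#' below `max_zero_prop` (the "less than 50% zeros" style of rule). Either
#' threshold may be `NULL` to skip that filter. Feature order is preserved.
#'
#' @param layer an [omics_layer()].
#' @param sd_min minimum sample standard deviation, or `NULL`.
#' @param max_zero_prop strict upper bound on the zero proportion in
#'   `[0, 1]`, or `NULL`.
#' @return the filtered [omics_layer()].
#' @export
filter_features <- function(layer, sd_min = NULL, max_zero_prop = NULL) {
  stopifnot(inherits(layer, "omics_layer"))
  keep <- rep(TRUE, ncol(layer$values))
  if (!is.null(sd_min)) {
    if (!is.finite(sd_min)) stop("sd_min must be finite")
    keep <- keep & (apply(layer$values, 2, sd) >= sd_min)
  }
  if (!is.null(max_zero_prop)) {
    if (!is.finite(max_zero_prop) || max_zero_prop < 0 || max_zero_prop > 1)
      stop("max_zero_prop must be in [0, 1]")
    zero_prop <- colMeans(layer$values == 0)
    keep <- keep & (zero_prop < max_zero_prop)
  }
  if (!any(keep)) stop("feature filter removed every feature")
  omics_layer(layer$values[, keep, drop = FALSE], layer$sample_ids,
              layer$feature_ids[keep], layer$weight, layer$name)
}
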