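#' omicsnmf: integrative multi-omics clustering by joint NMF
#'
#' Fits a shared non-negative basis matrix W across several omics layers
#' measured on the same samples, assigns each sample to the cluster with the
#' largest basis loading, and selects the number of clusters with
#' consensus-matrix statistics and a cross-validated cluster prediction
#' index.
#'
#' @useDynLib omicsnmf, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats cor hclust cophenetic as.dist rnorm runif sd
#' @importFrom utils head
#' @keywords internal
"_PACKAGE"

#' Construct a single omics layer
#'
#' An omics layer is one samples-by-features numeric matrix (samples in rows,
#' the orientation used throughout this package) together with sample and
#' feature identifiers and a positive layer weight theta.
#'
#' @param values numeric matrix, n samples x p features.
#' @param sample_ids character vector of unique sample identifiers (defaults
#'   to the matrix rownames, or `S1..Sn`).
#' @param feature_ids character vector of unique feature identifiers
#'   (defaults to the matrix colnames, or `F1..Fp`).
#' @param weight positive layer weight theta; layers with larger weight
#'   contribute more to the joint objective.
#' @param name optional layer name used in printing and file output.
#' @return an object of class `omics_layer`.
#' @export
omics_layer <- function(values, sample_ids = NULL, feature_ids = NULL,
                        weight = 1, name = NULL) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("layer values must be numeric")
  check_finite(values, "layer values")
  if (is.null(sample_ids)) {
    sample_ids <- rownames(values)
    if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(values)))
  }
  if (is.null(feature_ids)) {
    feature_ids <- colnames(values)
    if (is.null(feature_ids)) feature_ids <- paste0("F", seq_len(ncol(values)))
  }
  sample_ids <- as.character(sample_ids)
  feature_ids <- as.character(feature_ids)
  if (length(sample_ids) != nrow(values))
    stop("sample_ids length (", length(sample_ids),
         ") does not match row count (", nrow(values), ")")
  if (length(feature_ids) != ncol(values))
    stop("feature_ids length (", length(feature_ids),
         ") does not match column count (", ncol(values), ")")
  if (anyDuplicated(sample_ids))
    stop("duplicate sample id: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  if (anyDuplicated(feature_ids))
    stop("duplicate feature id: ",
         paste(unique(feature_ids[duplicated(feature_ids)]), collapse = ", "))
  if (!is.numeric(weight) || length(weight) != 1 || !is.finite(weight) ||
      weight <= 0)
    stop("weight must be a single positive number")
  dimnames(values) <- list(sample_ids, feature_ids)
  structure(
    list(values = values, sample_ids = sample_ids, feature_ids = feature_ids,
         weight = as.numeric(weight), name = name),
    class = "omics_layer"
  )
}

#' @export
print.omics_layer <- function(x, ...) {
  cat(sprintf("omics_layer%s: %d samples x %d features, weight = %.4g\n",
              if (is.null(x$name)) "" else paste0(" '", x$name, "'"),
              nrow(x$values), ncol(x$values), x$weight))
  invisible(x)
}

#' Bundle omics layers measured on the same samples
#'
#' Layers are aligned on their sample identifiers: the intersection of IDs is
#' taken in the order of the first layer, and every layer is subset to that
#' set. An error is raised if the intersection is empty, or if a layer cannot
#' be brought into the common order.
#'
#' @param layers a list of [omics_layer()] objects (bare matrices are
#'   promoted with weight 1).
#' @param align if `TRUE` (default) align layers by sample ID as described;
#'   if `FALSE`, require identical sample_ids in identical order.
#' @return an object of class `multi_omics` with elements `layers`, `n`, `m`,
#'   `sample_ids`.
#' @export
multi_omics <- function(layers, align = TRUE) {
  if (inherits(layers, "omics_layer")) layers <- list(layers)
  if (!is.list(layers) || length(layers) < 1)
    stop("need at least one layer (m >= 1)")
  layers <- lapply(layers, function(l) {
    if (inherits(l, "omics_layer")) l else omics_layer(l)
  })
  ids1 <- layers[[1]]$sample_ids
  if (align) {
    common <- ids1
    for (l in layers) common <- common[common %in% l$sample_ids]
    if (length(common) == 0) stop("no samples shared by all layers")
    layers <- lapply(layers, function(l) {
      idx <- match(common, l$sample_ids)
      omics_layer(l$values[idx, , drop = FALSE], common, l$feature_ids,
                  l$weight, l$name)
    })
  } else {
    for (i in seq_along(layers)) {
      if (!identical(layers[[i]]$sample_ids, ids1))
        stop("layer ", i, " sample_ids differ from layer 1 ",
             "(set align = TRUE to align by ID)")
    }
  }
  structure(
    list(layers = layers, n = length(layers[[1]]$sample_ids),
         m = length(layers), sample_ids = layers[[1]]$sample_ids),
    class = "multi_omics"
  )
}

#' @export
print.multi_omics <- function(x, ...) {
  cat(sprintf("multi_omics: %d layers on %d shared samples\n", x$m, x$n))
  for (i in seq_len(x$m)) {
    l <- x$layers[[i]]
    cat(sprintf("  [%d]%s %d features, weight = %.4g\n", i,
                if (is.null(l$name)) "" else paste0(" '", l$name, "'"),
                ncol(l$values), l$weight))
  }
  invisible(x)
}

# shared small validators ----------------------------------------------------

check_finite <- function(x, what = "matrix") {
  if (!all(is.finite(x))) {
    bad <- which(!is.finite(x), arr.ind = TRUE)[1, , drop = TRUE]
    stop("non-finite entry in ", what, " at [", bad[1], ", ", bad[2], "]")
  }
  invisible(TRUE)
}

layer_matrices <- function(collection) {
  lapply(collection$layers, `[[`, "values")
}

layer_weights <- function(collection) {
  vapply(collection$layers, `[[`, numeric(1), "weight")
}
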