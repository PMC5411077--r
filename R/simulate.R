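# Synthetic multi-omics generator: several layers sharing one sample-cluster
# structure, a stated proportion of features carrying cluster-specific mean
# shifts of a given effect size (in noise-SD units), Gaussian noise, optional
# cross-layer latent coupling, then the standard non-negative shift and
# unit-max rescale per layer.

#' Specify a synthetic multi-omics simulation
#'
#' @param k_true true number of clusters (>= 1).
#' @param n number of samples (>= 5 * k_true for k_true >= 2).
#' @param layers list of per-layer specs, each a list with `p` (feature
#'   count), `noise_sd` (Gaussian noise SD, default 1) and `diff_prop`
#'   (proportion of differential features, default 0.25).
#' @param effect_size cluster mean shift in noise-SD units (>= 0).
#' @param cluster_proportions simplex vector of length `k_true` (default
#'   equal).
#' @param cross_layer_coupling in `[0, 1]`: strength of a per-sample latent
#'   factor shared by all layers, mimicking inter-layer correlation
#'   (default 0.2).
#' @param seed integer seed.
#' @return a `simulation_spec` list.
#' @export
simulation_spec <- function(k_true = 3L, n = 90L,
                            layers = list(list(p = 60L), list(p = 60L),
                                          list(p = 60L)),
                            effect_size = 3.5,
                            cluster_proportions = NULL,
                            cross_layer_coupling = 0.2,
                            seed = 1L) {
  k_true <- as.integer(k_true)
  n <- as.integer(n)
  if (k_true < 1) stop("k_true must be >= 1")
  if (k_true >= 2 && n < 5L * k_true) stop("need n >= 5 * k_true")
  if (effect_size < 0) stop("effect_size must be >= 0")
  if (cross_layer_coupling < 0 || cross_layer_coupling > 1)
    stop("cross_layer_coupling must be in [0, 1]")
  if (is.null(cluster_proportions))
    cluster_proportions <- rep(1 / k_true, k_true)
  if (length(cluster_proportions) != k_true ||
      abs(sum(cluster_proportions) - 1) > 1e-8 ||
      any(cluster_proportions <= 0))
    stop("cluster_proportions must be a positive simplex vector of length ",
         k_true)
  layers <- lapply(layers, function(l) {
    list(p = as.integer(l$p),
         noise_sd = if (is.null(l$noise_sd)) 1 else l$noise_sd,
         diff_prop = if (is.null(l$diff_prop)) 0.25 else l$diff_prop)
  })
  for (l in layers) {
    if (l$p < 1 || l$noise_sd <= 0 || l$diff_prop < 0 || l$diff_prop > 1)
      stop("each layer needs p >= 1, noise_sd > 0, diff_prop in [0, 1]")
  }
  structure(list(k_true = k_true, n = n, layers = layers,
                 effect_size = effect_size,
                 cluster_proportions = cluster_proportions,
                 cross_layer_coupling = cross_layer_coupling,
                 seed = as.integer(seed)),
            class = "simulation_spec")
}

# largest-remainder apportionment: exact cluster sizes matching proportions
apportion <- function(n, proportions) {
  raw <- n * proportions
  sizes <- floor(raw)
  left <- n - sum(sizes)
  if (left > 0) {
    order_rem <- order(raw - sizes, decreasing = TRUE)
    sizes[order_rem[seq_len(left)]] <- sizes[order_rem[seq_len(left)]] + 1
  }
  as.integer(sizes)
}

# mutually distinct +-1 sign patterns for the k clusters over d features
cluster_sign_patterns <- function(k, d) {
  if (k == 1) return(matrix(1, 1, d))
  repeat {
    S <- matrix(sample(c(-1, 1), k * d, replace = TRUE), k, d)
    distinct <- TRUE
    for (a in seq_len(k - 1)) {
      for (b in seq(a + 1, k)) {
        if (all(S[a, ] == S[b, ])) distinct <- FALSE
      }
    }
    if (distinct) return(S)
  }
}

#' Generate a synthetic multi-omics collection with known clusters
#'
#' Truth labels are apportioned to the stated proportions. Within each layer,
#' `round(diff_prop * p)` differential features are chosen; every cluster
#' carries a mean shift of `+-(effect_size * noise_sd)` on those features with
#' a cluster-specific sign pattern (patterns are mutually distinct, so every
#' cluster pair differs on the differential set). Baseline feature means are
#' standard normal draws shared by all clusters; an optional per-sample latent
#' factor, scaled by `cross_layer_coupling`, is added to all layers through
#' per-feature loadings to mimic inter-layer correlation. Gaussian noise is
#' added and each layer is then shifted non-negative and rescaled to unit
#' maximum.
#'
#' @param spec a [simulation_spec()].
#' @return list of class `simulated_collection` with `collection` (a prepared
#'   [multi_omics()]), `truth` (integer labels), `differential_features`
#'   (per-layer index vectors), and `spec`.
#' @export
simulate_multiomics <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_rng(old))
  set.seed(spec$seed)

  sizes <- apportion(spec$n, spec$cluster_proportions)
  truth <- rep(seq_len(spec$k_true), times = sizes)
  z <- rnorm(spec$n)            # shared latent factor across layers

  layers <- vector("list", length(spec$layers))
  diff_sets <- vector("list", length(spec$layers))
  for (i in seq_along(spec$layers)) {
    ls <- spec$layers[[i]]
    p <- ls$p
    d <- round(ls$diff_prop * p)
    diff_idx <- if (d > 0) sort(sample.int(p, d)) else integer(0)
    mu <- rnorm(p)                               # baseline feature means
    shift <- matrix(0, spec$k_true, p)
    if (d > 0 && spec$effect_size > 0) {
      S <- cluster_sign_patterns(spec$k_true, d)
      shift[, diff_idx] <- S * spec$effect_size * ls$noise_sd
    }
    loadings <- rnorm(p)
    X <- matrix(mu, spec$n, p, byrow = TRUE) +
      shift[truth, , drop = FALSE] +
      spec$cross_layer_coupling * tcrossprod(z, loadings) +
      matrix(rnorm(spec$n * p, sd = ls$noise_sd), spec$n, p)
    X <- rescale_unit_max(shift_nonnegative(X))
    layers[[i]] <- omics_layer(
      X, sample_ids = paste0("S", seq_len(spec$n)),
      feature_ids = paste0("L", i, "F", seq_len(p)),
      weight = 1, name = paste0("layer", i))
    diff_sets[[i]] <- diff_idx
  }
  structure(list(collection = multi_omics(layers, align = FALSE),
                 truth = truth, differential_features = diff_sets,
                 spec = spec),
            class = "simulated_collection")
}

#' The factorial simulation grid: true k by effect size
#'
#' Enumerates the 5 x 9 design — true cluster counts 2..6 crossed with effect
#' sizes 0 to 4 in steps of 0.5 — at 25% differential features, on the
#' (configurable) scaled-down sizes used throughout this package.
#'
#' @param n samples per dataset (default 90).
#' @param p feature counts per layer (default `c(60, 60, 60)`).
#' @param k_true_values true cluster counts (default 2:6).
#' @param effect_sizes default `seq(0, 4, by = 0.5)`.
#' @param base_seed each spec gets a distinct seed derived from this.
#' @return list of [simulation_spec()] objects (length 45 by default).
#' @export
simulation_grid <- function(n = 90L, p = c(60L, 60L, 60L),
                            k_true_values = 2:6,
                            effect_sizes = seq(0, 4, by = 0.5),
                            base_seed = 1L) {
  specs <- list()
  idx <- 0L
  for (k in k_true_values) {
    for (es in effect_sizes) {
      idx <- idx + 1L
      specs[[idx]] <- simulation_spec(
        k_true = k, n = n,
        layers = lapply(p, function(pi) list(p = pi, diff_prop = 0.25)),
        effect_size = es, seed = base_seed + idx)
    }
  }
  specs
}
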