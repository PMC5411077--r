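test_that("consensus_matrix averages connectivity histories", {
  C1 <- connectivity_matrix(c(1, 1, 2))
  expect_equal(consensus_matrix(list(C1, C1, C1))$values, C1)

  C2 <- connectivity_matrix(c(1, 2, 2))
  cb <- consensus_matrix(list(C1, C2))
  expect_equal(cb$values[1, 2], 0.5)
  expect_equal(cb$values[2, 3], 0.5)
  expect_equal(diag(cb$values), rep(1, 3))
  expect_equal(cb$count, 2)

  # burn-in discards leading matrices but always keeps at least one
  cb2 <- consensus_matrix(list(C1, C2), burn_in = 1)
  expect_equal(cb2$values, C2)
  expect_equal(consensus_matrix(list(C1, C2), burn_in = 10)$values, C2)
  expect_error(consensus_matrix(list()), "empty")
})

test_that("consensus invariants hold for random label histories (property)", {
  set.seed(14)
  for (rep in 1:10) {
    hist <- lapply(1:8, function(i) connectivity_matrix(sample(1:3, 12,
                                                               TRUE)))
    v <- consensus_matrix(hist)$values
    expect_true(all(v >= 0 & v <= 1))
    expect_equal(v, t(v))
    expect_equal(diag(v), rep(1, 12))
  }
})

test_that("silhouette on consensus: perfect, uninformative, hand-computed", {
  labels <- c(1, 1, 2, 2, 3, 3)
  expect_equal(silhouette_consensus(block_consensus(labels), labels), 1)

  flat <- matrix(0.5, 4, 4); diag(flat) <- 1
  expect_equal(silhouette_consensus(flat, c(1, 1, 2, 2)), 0)

  # 4-sample hand oracle: s = (13/17 + 11/15 + 3/5 + 11/17) / 4 = 35/51
  cb <- rbind(c(1, .8, .2, .1), c(.8, 1, .3, .2),
              c(.2, .3, 1, .7), c(.1, .2, .7, 1))
  expect_equal(silhouette_consensus(cb, c(1, 1, 2, 2)), 35 / 51)

  # singleton cluster contributes 0
  expect_equal(silhouette_consensus(block_consensus(c(1, 2, 2, 2)),
                                    c(1, 2, 2, 2)),
               naive_silhouette(1 - block_consensus(c(1, 2, 2, 2)),
                                c(1, 2, 2, 2)))

  expect_error(silhouette_consensus(flat, rep(1, 4)), "single cluster")
})

test_that("silhouette agrees with a naive double-loop implementation", {
  set.seed(15)
  for (rep in 1:10) {
    n <- 10
    hist <- lapply(1:6, function(i) connectivity_matrix(sample(1:3, n, TRUE)))
    cb <- consensus_matrix(hist)$values
    labels <- sample(1:3, n, TRUE)
    if (length(unique(labels)) < 2) next
    d <- 1 - cb; diag(d) <- 0
    expect_equal(silhouette_consensus(cb, labels),
                 naive_silhouette(d, labels), tolerance = 1e-12)
  }
})

test_that("cophenetic coefficient: exact on ultrametric, oracle-checked", {
  labels <- rep(1:3, each = 4)
  expect_equal(cophenetic_coefficient(block_consensus(labels)), 1)

  # epsilon-perturbed block consensus stays close to 1 and matches the
  # brute-force pairwise merge-height computation
  set.seed(16)
  cb <- block_consensus(labels)
  noise <- matrix(runif(144, 0, 0.1), 12); noise <- (noise + t(noise)) / 2
  cbn <- pmin(pmax(cb - noise * (cb == 1) + noise * (cb == 0), 0), 1)
  diag(cbn) <- 1
  val <- cophenetic_coefficient(cbn)
  expect_gt(val, 0.9)
  expect_lt(val, 1.0)
  d <- 1 - cbn; diag(d) <- 0
  hc <- hclust(as.dist(d), method = "average")
  expect_equal(val, cor(as.dist(d), as.dist(brute_cophenetic(hc))),
               tolerance = 1e-12)

  expect_error(cophenetic_coefficient(matrix(1, 4, 4)), "constant")
})

test_that("dispersion coefficient formula and extremes", {
  expect_equal(dispersion_coefficient(block_consensus(rep(1:2, 3))), 1)
  two <- rbind(c(1, 0.5), c(0.5, 1))
  expect_equal(dispersion_coefficient(two), 0.5)
  expect_equal(dispersion_coefficient(matrix(0.5, 3, 3)), 0)
})

test_that("selection measures are invariant to sample permutation", {
  set.seed(17)
  n <- 12
  hist <- lapply(1:10, function(i) connectivity_matrix(sample(1:3, n, TRUE)))
  cb <- consensus_matrix(hist)$values
  # break ties with a tiny symmetric jitter: average-linkage trees (hence
  # cophenetic distances) are only order-invariant for tie-free distances
  jit <- matrix(runif(n * n, 0, 1e-6), n)
  cb <- pmax(pmin(cb - (jit + t(jit)) / 2, 1), 0)
  diag(cb) <- 1
  labels <- sample(1:3, n, TRUE)
  perm <- sample(n)
  cbp <- cb[perm, perm]
  expect_equal(silhouette_consensus(cbp, labels[perm]),
               silhouette_consensus(cb, labels))
  expect_equal(cophenetic_coefficient(cbp), cophenetic_coefficient(cb))
  expect_equal(dispersion_coefficient(cbp), dispersion_coefficient(cb))
})

test_that("nmf_rss equals the unweighted objective", {
  prob <- make_block_problem(n = 10, k = 2, m = 2, p = c(6, 5), seed = 18)
  coll <- prob$collection
  coll$layers[[1]]$weight <- 3
  W <- random_init(10, 2, seed = 1)
  H <- lapply(layer_mats(coll), function(X) update_H(X, W))
  expect_equal(nmf_rss(coll, W, H),
               nmf_objective(coll, W, H, theta = c(1, 1)))
  H0 <- lapply(layer_mats(prob), function(X) update_H(X, prob$W0))
  expect_lt(nmf_rss(prob$collection, prob$W0, H0), 1e-18)
})

test_that("CPI is 1 on strongly separated data and reproducible", {
  sim <- simulate_multiomics(simulation_spec(
    k_true = 2, n = 40, layers = list(list(p = 20), list(p = 20)),
    effect_size = 4, seed = 19))
  cfg <- cpi_config(k_range = 2, n_repeats = 3, n_init_train = 2,
                    n_init_test = 2, base_seed = 42)
  res <- cluster_prediction_index(sim$collection, cfg)
  expect_equal(unname(res$mean), 1)
  res2 <- cluster_prediction_index(sim$collection, cfg)
  expect_identical(res$values, res2$values)
})

test_that("CPI shows no near-perfect k under pure noise", {
  sim <- simulate_multiomics(simulation_spec(
    k_true = 3, n = 45, layers = list(list(p = 20), list(p = 20)),
    effect_size = 0, seed = 20))
  cfg <- cpi_config(k_range = 2:4, n_repeats = 3, n_init_train = 2,
                    n_init_test = 2, base_seed = 7)
  res <- cluster_prediction_index(sim$collection, cfg)
  expect_lt(max(res$mean), 0.9)
})

test_that("select_k rules: argmax, ties to smallest k, RSS elbow", {
  prof <- list(k_range = 2:5,
               mean = list(cpi = c(0.4, 0.9, 0.6, 0.5),
                           silhouette = c(0.2, 0.7, 0.7, 0.1),
                           rss = c(100, 40, 35, 33)))
  expect_equal(select_k(prof, "cpi"), 3L)
  expect_equal(select_k(prof, "silhouette"), 3L)   # tie -> smallest k
  expect_equal(select_k(prof, "rss"), 3L)          # max second difference
  expect_error(select_k(prof, "dispersion"), "not present")
  expect_error(select_k(list(k_range = 2:3, mean = list(rss = c(1, 2))),
                        "rss"), "at least 3")
})

test_that("scan_k produces a coherent profile on separable data", {
  sim <- simulate_multiomics(simulation_spec(
    k_true = 2, n = 40, layers = list(list(p = 20), list(p = 20)),
    effect_size = 4, seed = 21))
  prof <- scan_k(sim$collection, k_range = 2:4, n_init = 3, base_seed = 1,
                 measures = c("silhouette", "cophenetic", "dispersion",
                              "rss"),
                 consensus_across_runs = TRUE)
  expect_equal(dim(prof$values$silhouette), c(3L, 3L))
  expect_true(all(prof$values$rss >= 0, na.rm = TRUE))
  # RSS decreases with k on the mean curve
  expect_true(all(diff(prof$mean$rss) < 0))
  expect_equal(unname(prof$selected[["silhouette"]]), 2L)
  expect_equal(dim(prof$across_runs), c(3L, 3L))
  expect_true(all(prof$across_runs >= -1 & prof$across_runs <= 1,
                  na.rm = TRUE))
})
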