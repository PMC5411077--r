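sample_ids <- function(n) paste0("S", seq_len(n))

test_that("nmf_objective matches hand evaluation and edge cases", {
  prob <- make_block_problem(n = 12, k = 2, m = 2, p = c(5, 4), seed = 3)
  H0 <- lapply(layer_mats(prob), function(X) update_H(X, prob$W0))
  expect_lt(nmf_objective(prob$collection, prob$W0, H0), 1e-18)

  Xs <- layer_mats(prob)
  W0zero <- matrix(0, 12, 2)
  Hzero <- lapply(Xs, function(X) matrix(0, 2, ncol(X)))
  expect_equal(nmf_objective(prob$collection, W0zero, Hzero),
               sum(vapply(Xs, function(X) sum(X^2), numeric(1))))

  # one layer, X = I2, W = (1,1)', H = (0.5, 0.5): residuals all +-0.5
  coll <- multi_omics(omics_layer(diag(2)))
  expect_equal(nmf_objective(coll, matrix(1, 2, 1), list(matrix(0.5, 1, 2))),
               1.0)
  expect_error(nmf_objective(coll, matrix(1, 3, 1), list(matrix(0.5, 1, 2))),
               "dimension mismatch")
})

test_that("update_H: identity design returns the data; oracle agreement", {
  X <- matrix(runif(12), 4, 3)
  expect_equal(update_H(X, diag(4)), X)

  set.seed(31)
  W <- matrix(runif(5 * 3), 5, 3)
  Xl <- matrix(runif(5 * 4), 5, 4)
  H <- update_H(Xl, W)
  for (j in seq_len(4)) {
    oracle <- oracle_nnls(W, Xl[, j])
    expect_equal(nnls_objective(W, Xl[, j], H[, j]), oracle$objective,
                 tolerance = 1e-8)
  }
})

test_that("update_W solves the stacked joint problem exactly", {
  set.seed(32)
  # m = 1, theta = 1: symmetric to update_H on the transposed problem
  X <- matrix(runif(6 * 5), 6, 5)
  H <- list(matrix(runif(2 * 5), 2, 5))
  coll <- multi_omics(omics_layer(X))
  expect_equal(update_W(coll, H), t(update_H(t(X), t(H[[1]]))),
               tolerance = 1e-12)

  # m = 2 with unequal weights vs brute-force oracle on the stacked design
  ids <- sample_ids(5)
  Xs <- list(matrix(runif(5 * 3), 5, 3), matrix(runif(5 * 4), 5, 4))
  theta <- c(2.5, 1)
  coll2 <- multi_omics(list(omics_layer(Xs[[1]], ids, weight = theta[1]),
                            omics_layer(Xs[[2]], ids, weight = theta[2])),
                       align = FALSE)
  H2 <- list(matrix(runif(2 * 3), 2, 3), matrix(runif(2 * 4), 2, 4))
  W <- update_W(coll2, H2)
  D <- rbind(sqrt(theta[1]) * t(H2[[1]]), sqrt(theta[2]) * t(H2[[2]]))
  for (j in seq_len(5)) {
    cj <- c(sqrt(theta[1]) * Xs[[1]][j, ], sqrt(theta[2]) * Xs[[2]][j, ])
    oracle <- oracle_nnls(D, cj)
    expect_equal(nnls_objective(D, cj, W[j, ]), oracle$objective,
                 tolerance = 1e-8)
  }

  # exact solution feasible => objective 0
  prob <- make_block_problem(n = 10, k = 2, m = 2, p = c(6, 6), seed = 5)
  H0 <- lapply(layer_mats(prob), function(X) update_H(X, prob$W0))
  W0hat <- update_W(prob$collection, H0)
  expect_lt(nmf_objective(prob$collection, W0hat, H0), 1e-16)
})

test_that("assign_clusters is row argmax with first-index ties", {
  expect_equal(assign_clusters(rbind(c(0.9, 0.1), c(0.2, 0.8))), c(1L, 2L))
  expect_equal(assign_clusters(rbind(c(0.5, 0.5), c(0.1, 0.3))), c(1L, 2L))
  expect_warning(lab <- assign_clusters(rbind(c(0, 0), c(0, 1))),
                 "all-zero")
  expect_equal(lab, c(1L, 2L))
})

test_that("connectivity_matrix definition", {
  expect_equal(connectivity_matrix(c(1, 1, 2)),
               rbind(c(1, 1, 0), c(1, 1, 0), c(0, 0, 1)))
  expect_equal(connectivity_matrix(rep(2, 4)), matrix(1, 4, 4))
  expect_equal(connectivity_matrix(1:4), diag(4))
})

test_that("factorize recovers noiseless block structure exactly", {
  prob <- make_block_problem(n = 30, k = 3, m = 2, p = c(15, 15), seed = 8)
  fit <- factorize(prob$collection, k = 3,
                   W_init = random_init(30, 3, seed = 1))
  total <- sum(vapply(layer_mats(prob), function(X) sum(X^2), numeric(1)))
  expect_lt(tail(fit$objective_trace, 1), 1e-6 * total)
  expect_equal(adjusted_rand_index(fit$labels, prob$truth), 1)
  expect_true(all(fit$W >= 0))
  expect_true(all(vapply(fit$H, min, numeric(1)) >= 0))
})

test_that("objective trace is non-increasing (descent property)", {
  for (s in 1:5) {
    sim <- simulate_multiomics(simulation_spec(
      k_true = 3, n = 30, layers = list(list(p = 15), list(p = 15)),
      effect_size = 1.5, seed = s))
    fit <- factorize(sim$collection, 3, random_init(30, 3, seed = s),
                     max_iter = 60)
    q <- fit$objective_trace
    expect_true(all(diff(q) <= 1e-8 * q[1]))
  }
})

test_that("stopping rules: stability semantics and max_iter flag", {
  sim <- simulate_multiomics(simulation_spec(
    k_true = 2, n = 20, layers = list(list(p = 12)), effect_size = 3,
    seed = 2))
  W0 <- random_init(20, 2, seed = 3)
  # tol = 0 disables the error stop; find first t with C_t == C_{t+1}
  ref <- factorize(sim$collection, 2, W0, tol = 0,
                   stability_count = 10^6, max_iter = 40)
  expect_false(ref$converged)
  expect_equal(ref$convergence_reason, "max_iter")
  same <- vapply(seq_len(ref$n_iter - 1), function(t) {
    identical(ref$connectivity_history[[t]],
              ref$connectivity_history[[t + 1]])
  }, logical(1))
  t_stable <- which(same)[1]
  fit1 <- factorize(sim$collection, 2, W0, tol = 0, stability_count = 1,
                    max_iter = 40)
  expect_equal(fit1$convergence_reason, "connectivity_stable")
  expect_equal(fit1$n_iter, t_stable + 1L)
})

test_that("permutation equivariance and scale consistency", {
  sim <- simulate_multiomics(simulation_spec(
    k_true = 2, n = 24, layers = list(list(p = 10), list(p = 10)),
    effect_size = 2, seed = 6))
  W0 <- random_init(24, 2, seed = 7)
  fit <- factorize(sim$collection, 2, W0, max_iter = 30)

  perm <- sample(24)
  coll_p <- multi_omics(lapply(sim$collection$layers, function(l) {
    omics_layer(l$values[perm, ], l$sample_ids[perm], l$feature_ids,
                l$weight)
  }), align = FALSE)
  fit_p <- factorize(coll_p, 2, W0[perm, , drop = FALSE], max_iter = 30)
  expect_equal(fit_p$W, fit$W[perm, ], tolerance = 1e-10)
  expect_equal(fit_p$labels, fit$labels[perm])

  # multiply layer 1 by c, divide its weight by c^2: same assignments and Q.
  # (The absolute reconstruction-error stop is not scale-invariant, so pin
  # the iteration count to compare the traces.)
  c_ <- 5
  coll_s <- sim$collection
  coll_s$layers[[1]]$values <- c_ * coll_s$layers[[1]]$values
  coll_s$layers[[1]]$weight <- coll_s$layers[[1]]$weight / c_^2
  ref <- factorize(sim$collection, 2, W0, tol = 0, stability_count = 10^6,
                   max_iter = 25)
  fit_s <- factorize(coll_s, 2, W0, tol = 0, stability_count = 10^6,
                     max_iter = 25)
  expect_equal(fit_s$labels, ref$labels)
  expect_equal(fit_s$objective_trace, ref$objective_trace, tolerance = 1e-8)
})

test_that("two half-weight copies of a layer equal the single-layer fit", {
  sim <- simulate_multiomics(simulation_spec(
    k_true = 2, n = 20, layers = list(list(p = 12)), effect_size = 2,
    seed = 9))
  single <- sim$collection
  l <- single$layers[[1]]
  dup <- multi_omics(list(omics_layer(l$values, l$sample_ids, weight = 0.5),
                          omics_layer(l$values, l$sample_ids, weight = 0.5)),
                     align = FALSE)
  W0 <- random_init(20, 2, seed = 4)
  f1 <- factorize(single, 2, W0, max_iter = 25)
  f2 <- factorize(dup, 2, W0, max_iter = 25)
  expect_equal(f2$labels, f1$labels)
  expect_equal(f2$W, f1$W, tolerance = 1e-9)
  expect_equal(f2$objective_trace, f1$objective_trace, tolerance = 1e-8)
})

test_that("run_multistart selects the best run reproducibly", {
  sim <- simulate_multiomics(simulation_spec(
    k_true = 2, n = 24, layers = list(list(p = 12)), effect_size = 2.5,
    seed = 12))
  one <- run_multistart(sim$collection, 2, n_init = 1, base_seed = 5)
  expect_identical(one$runs$init, "nndsvd")
  expect_identical(one, run_multistart(sim$collection, 2, n_init = 1,
                                       base_seed = 5))

  ms <- run_multistart(sim$collection, 2, n_init = 5, base_seed = 5)
  expect_lte(tail(ms$objective_trace, 1), min(ms$runs$final_Q) + 1e-12)
  expect_equal(nrow(ms$runs), 5)
  ms2 <- run_multistart(sim$collection, 2, n_init = 5, base_seed = 5)
  expect_identical(ms$labels, ms2$labels)
  expect_identical(ms$runs, ms2$runs)
})
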