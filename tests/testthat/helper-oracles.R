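# Independent oracles used by the unit and acceptance tests. These are kept
# deliberately naive (enumeration, double loops) and must never call the
# package's own solver paths.

# Moore-Penrose pseudoinverse via SVD (avoids relying on MASS)
pinv_svd <- function(A, tol = 1e-12) {
  sv <- svd(A)
  pos <- sv$d > tol * max(sv$d, 1)
  if (!any(pos)) return(matrix(0, ncol(A), nrow(A)))
  sv$v[, pos, drop = FALSE] %*%
    (t(sv$u[, pos, drop = FALSE]) / sv$d[pos])
}

# Exhaustive active-set oracle for min ||b - A x||^2 s.t. x >= 0 (r <= ~12):
# try every subset of passive variables, solve unconstrained LS on it, keep
# the best feasible candidate.
oracle_nnls <- function(A, b) {
  r <- ncol(A)
  best_x <- rep(0, r)
  best_obj <- sum(b^2)
  for (mask in seq_len(2^r) - 1L) {
    P <- which(bitwAnd(mask, 2^(seq_len(r) - 1L)) > 0)
    if (length(P) == 0) next
    xP <- pinv_svd(A[, P, drop = FALSE]) %*% b
    if (any(xP < -1e-12)) next
    x <- rep(0, r)
    x[P] <- pmax(xP, 0)
    obj <- sum((b - A %*% x)^2)
    if (obj < best_obj) {
      best_obj <- obj
      best_x <- x
    }
  }
  list(x = best_x, objective = best_obj)
}

nnls_objective <- function(A, b, x) sum((b - A %*% x)^2)

# Brute-force cophenetic distances from an hclust tree: walk the merge list,
# record the merge height for every cross pair.
brute_cophenetic <- function(hc) {
  n <- length(hc$order)
  members <- as.list(seq_len(n))
  coph <- matrix(0, n, n)
  for (s in seq_len(nrow(hc$merge))) {
    left <- hc$merge[s, 1]
    right <- hc$merge[s, 2]
    li <- if (left < 0) -left else members[[n + left]]
    ri <- if (right < 0) -right else members[[n + right]]
    for (i in li) for (j in ri) {
      coph[i, j] <- hc$height[s]
      coph[j, i] <- hc$height[s]
    }
    members[[n + s]] <- c(li, ri)
  }
  coph
}

# Naive double-loop silhouette on a distance matrix (diag 0), singleton = 0.
naive_silhouette <- function(d, labels) {
  n <- length(labels)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    if (sum(own) == 1) { s[i] <- 0; next }
    a <- mean(d[i, own & seq_len(n) != i])
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(cl) mean(d[i, labels == cl]), numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

# Block-structured exact factorization problem: X^i = W0 H0^i with
# non-overlapping block support in W0 and strictly positive random H0^i.
make_block_problem <- function(n = 60, k = 3, m = 2, p = rep(20, m),
                               seed = 1) {
  set.seed(seed)
  truth <- rep(seq_len(k), length.out = n)
  truth <- sort(truth)
  W0 <- matrix(0, n, k)
  W0[cbind(seq_len(n), truth)] <- runif(n, 0.5, 1.5)
  layers <- lapply(seq_len(m), function(i) {
    H0 <- matrix(runif(k * p[i], 0.1, 1), k, p[i])
    omics_layer(W0 %*% H0, weight = 1, name = paste0("layer", i))
  })
  list(collection = multi_omics(layers, align = FALSE), truth = truth,
       W0 = W0)
}

layer_mats <- function(prob_or_coll) {
  coll <- if (inherits(prob_or_coll, "multi_omics")) prob_or_coll
          else prob_or_coll$collection
  lapply(coll$layers, `[[`, "values")
}

# A consensus matrix with perfect binary block structure for given labels.
block_consensus <- function(labels) {
  outer(labels, labels, `==`) * 1
}
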