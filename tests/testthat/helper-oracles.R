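# Independent oracles used across the test suite. These deliberately avoid
# the code paths they check: the covariance oracle enumerates MRCA path
# lengths with ape's node utilities, the GLS oracle inverts matrices
# explicitly, and the conditioning oracle assembles the joint normal by
# brute-force double loops.

# Brute-force Brownian covariance: shared root-to-MRCA path length per pair.
bf_vcv <- function(tree) {
  n <- length(tree$tip.label)
  depth <- ape::node.depth.edgelength(tree)   # distance from root
  M <- ape::mrca(tree)
  C <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      C[i, j] <- depth[M[i, j]]
    }
  }
  C
}

# Dense-matrix GLS oracle: explicit inverse, normal equations, SEs on
# n - k residual degrees of freedom.
bf_gls <- function(X, y, C) {
  n <- length(y)
  p <- ncol(X)
  Ci <- solve(C)
  XtCiX <- t(X) %*% Ci %*% X
  beta <- solve(XtCiX, t(X) %*% Ci %*% y)
  r <- y - X %*% beta
  rss <- drop(t(r) %*% Ci %*% r)
  sigma2_res <- rss / (n - p)
  se <- sqrt(diag(solve(XtCiX)) * sigma2_res)
  tval <- drop(beta) / se
  list(beta = drop(beta), se = se, t = tval,
       p = 2 * stats::pt(-abs(tval), df = n - p))
}

# Brute-force conditional moments of the missing cells of a species x trait
# matrix under the joint (tree x trait) normal, built cell by cell.
bf_condition <- function(Y, tree, mu, R, lambda) {
  n <- nrow(Y); k <- ncol(Y)
  Cb <- bf_vcv(tree)[rownames(Y), rownames(Y)]
  cells <- expand.grid(tip = seq_len(n), trait = seq_len(k))
  nc <- nrow(cells)
  S <- matrix(0, nc, nc)
  for (a in seq_len(nc)) {
    for (b in seq_len(nc)) {
      ct <- Cb[cells$tip[a], cells$tip[b]]
      if (cells$tip[a] != cells$tip[b]) ct <- ct * lambda
      S[a, b] <- R[cells$trait[a], cells$trait[b]] * ct
    }
  }
  muv <- mu[cells$trait]
  yv <- Y[cbind(cells$tip, cells$trait)]
  miss <- which(is.na(yv))
  obs <- which(!is.na(yv))
  Soo <- S[obs, obs, drop = FALSE]
  Smo <- S[miss, obs, drop = FALSE]
  cm <- muv[miss] + drop(Smo %*% solve(Soo, yv[obs] - muv[obs]))
  cv <- S[miss, miss, drop = FALSE] - Smo %*% solve(Soo, t(Smo))
  list(species = rownames(Y)[cells$tip[miss]],
       trait = colnames(Y)[cells$trait[miss]],
       mean = cm, var = diag(as.matrix(cv)))
}

# A star phylogeny of given depth (no shared history among tips).
star_tree <- function(n, depth = 1) {
  read_newick(paste0("(", paste0("t", seq_len(n), ":", depth, collapse = ","), ");"))
}

# Random small test instance for regression oracles.
rand_instance <- function(seed, n_min = 5, n_max = 15) {
  set.seed(seed)
  n <- sample(n_min:n_max, 1)
  tree <- simulate_tree(n, seed = seed + 1)
  lam <- runif(1)
  C <- lambda_transform(phylo_vcv(tree), lam)
  X <- cbind("(Intercept)" = 1, x = rnorm(n))
  y <- drop(rmvn_test(rep(0, n), C)) + X %*% c(1, 0.5)
  list(tree = tree, lambda = lam, C = C, X = X, y = drop(y), n = n)
}

# Test-side MVN sampler (chol-based, independent of the package internals).
rmvn_test <- function(mu, S) {
  mu + drop(crossprod(chol(S), rnorm(length(mu))))
}
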