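# Multivariate Brownian+lambda model fitting, conditional-moment
# imputation, multiple draws, pooling and the LOO reliability check.

test_that("two-tip complete-data ML matches the closed form", {
  # tree (A:1,B:1): C = I, ML mean = (y1+y2)/2, sigma2 = (y1-y2)^2/4
  tr <- read_newick("(A:1,B:1);")
  y <- c(A = 3, B = 7)
  tab <- data.frame(species = c("A", "B"), x = unname(y))
  fit <- fit_phylo_mvn(tab, tr, lambda = 1)
  expect_equal(unname(fit$root_means), 5)
  expect_equal(unname(fit$trait_cov[1, 1]), (3 - 7)^2 / 4)
})

test_that("parameters are recovered on complete simulated data", {
  Rtrue <- matrix(c(1, 0.6, 0.6, 1.5), 2,
                  dimnames = list(c("a", "b"), c("a", "b")))
  lam_true <- 0.7
  rel <- vapply(1:12, function(i) {
    tr <- simulate_tree(200, seed = 12000 + i)
    d <- simulate_traits(tr, Rtrue, lambda = lam_true,
                         root_means = c(1, -1), seed = 13000 + i)
    d$species <- rownames(d)
    f <- fit_phylo_mvn(d, tr)
    c(abs(f$trait_cov[1, 1] - 1) / 1,
      abs(f$trait_cov[2, 2] - 1.5) / 1.5,
      abs(f$trait_cov[1, 2] - 0.6) / 0.6,
      abs(f$lambda - lam_true) / lam_true)
  }, numeric(4))
  expect_lt(mean(rel), 0.15)
})

test_that("a duplicated trait is estimated as perfectly correlated", {
  tr <- simulate_tree(20, seed = 31)
  d <- simulate_traits(tr, matrix(1), lambda = 1, root_means = 0, seed = 32)
  tab <- data.frame(species = rownames(d), x = d[[1]], x2 = d[[1]])
  fit <- fit_phylo_mvn(tab, tr, lambda = 1)
  r <- fit$trait_cov[1, 2] / sqrt(fit$trait_cov[1, 1] * fit$trait_cov[2, 2])
  expect_equal(r, 1, tolerance = 1e-8)
})

test_that("all-missing traits are rejected as unidentifiable", {
  tr <- simulate_tree(6, seed = 33)
  tab <- data.frame(species = tr$tip.label, x = rnorm(6), z = NA_real_)
  expect_error(fit_phylo_mvn(tab, tr), "unidentifiable")
})

test_that("star-tree conditioning matches the closed form", {
  tr <- star_tree(4, depth = 2)
  tab <- data.frame(species = paste0("t", 1:4), x = c(1, 2, 3, NA))
  fit <- fit_phylo_mvn(tab, tr, lambda = 1)
  # ML root mean is the observed average (star tree: equal weights)
  expect_equal(unname(fit$root_means), 2, tolerance = 1e-6)
  mom <- impute_moments(tab, tr, fit)
  # no shared paths: conditional mean = root mean, variance = sigma2 * depth
  expect_equal(mom$cond_mean, 2, tolerance = 1e-6)
  expect_equal(mom$cond_var, unname(fit$trait_cov[1, 1]) * 2, tolerance = 1e-8)
})

test_that("a zero-distance sister pins the conditional distribution", {
  tr <- read_newick("((A:0,B:0):1,C:1);")
  tab <- data.frame(species = c("A", "B", "C"), x = c(0.7, NA, -0.2))
  pars <- structure(list(root_means = c(x = 0),
                         trait_cov = matrix(1, dimnames = list("x", "x")),
                         lambda = 1, loglik = NA, n_iter = 0L, traits = "x"),
                    class = "phylo_mvn")
  mom <- impute_moments(tab, tr, pars)
  expect_equal(mom$cond_mean, 0.7, tolerance = 1e-4)
  expect_equal(mom$cond_var, 0, tolerance = 1e-4)
})

test_that("impute_moments equals brute-force joint-normal conditioning", {
  for (s in 1:12) {
    set.seed(600 + s)
    n <- sample(3:6, 1)
    k <- sample(1:2, 1)
    tr <- simulate_tree(n, seed = 700 + s)
    R <- crossprod(matrix(rnorm(k * k), k)) + diag(0.3, k)
    dimnames(R) <- list(paste0("v", 1:k), paste0("v", 1:k))
    lam <- runif(1)
    d <- simulate_traits(tr, R, lambda = lam, root_means = rnorm(k),
                         seed = 800 + s)
    Y <- as.matrix(d)
    # random non-empty mask that keeps every trait partially observed
    nm <- sample(1:(n * k - k), 1)
    Y[sample(n * k, nm)] <- NA
    if (any(colSums(!is.na(Y)) == 0)) next
    mu <- rnorm(k)
    pars <- structure(list(root_means = stats::setNames(mu, colnames(Y)),
                           trait_cov = R, lambda = lam, loglik = NA,
                           n_iter = 0L, traits = colnames(Y)),
                      class = "phylo_mvn")
    tab <- data.frame(species = rownames(Y), Y)
    mom <- impute_moments(tab, tr, pars)
    oracle <- bf_condition(Y, tr, mu, R, lam)
    key_m <- paste(mom$species, mom$trait)
    key_o <- paste(oracle$species, oracle$trait)
    ord <- match(key_m, key_o)
    expect_lt(max(abs(mom$cond_mean - oracle$mean[ord])), 1e-8)
    expect_lt(max(abs(mom$cond_var - oracle$var[ord])), 1e-8)
    # variance shrinkage: conditional <= marginal
    expect_true(all(mom$cond_var <= mom$marginal_var + 1e-10))
  }
})

test_that("draws respect moments, seeds and observed cells", {
  tr <- simulate_tree(12, seed = 41)
  d <- simulate_traits(tr, matrix(c(1, 0.8, 0.8, 1), 2), lambda = 0.9,
                       root_means = c(0, 0), seed = 42)
  names(d) <- c("x", "y")
  tab <- data.frame(species = rownames(d), d)
  tab$x[c(2, 5, 9)] <- NA
  fit <- fit_phylo_mvn(tab, tr, lambda = 0.9)
  mom <- impute_moments(tab, tr, fit)
  imp <- draw_imputations(mom, tab, m = 5, seed = 77)
  expect_length(imp$tables, 5)
  # observed cells identical across all completed tables, bitwise
  obs_idx <- !is.na(tab$x)
  for (tb in imp$tables) {
    expect_identical(tb$x[obs_idx], tab$x[obs_idx])
    expect_identical(tb$y, tab$y)
    expect_false(anyNA(tb$x))
  }
  # determinism
  imp2 <- draw_imputations(mom, tab, m = 5, seed = 77)
  expect_identical(imp$tables, imp2$tables)
  # a cell's empirical mean over many draws matches its conditional mean
  cell_draws <- vapply(1:2000, function(i) {
    with_seed_val <- draw_imputations(mom, tab, m = 2, seed = i)
    with_seed_val$tables[[1]]$x[2]
  }, numeric(1))
  se <- sqrt(mom$cond_var[mom$species == tab$species[2]][1] / 2000)
  expect_lt(abs(mean(cell_draws) - mom$cond_mean[mom$species == tab$species[2]][1]),
            3 * se)
  expect_error(draw_imputations(mom, tab, m = 1), ">= 2")
})

test_that("zero conditional variance makes all draws identical", {
  tr <- read_newick("((A:0,B:0):1,C:1);")
  tab <- data.frame(species = c("A", "B", "C"), x = c(0.7, NA, -0.2))
  pars <- structure(list(root_means = c(x = 0),
                         trait_cov = matrix(1, dimnames = list("x", "x")),
                         lambda = 1, loglik = NA, n_iter = 0L, traits = "x"),
                    class = "phylo_mvn")
  mom <- impute_moments(tab, tr, pars)
  mom$cond_var <- pmax(mom$cond_var, 0)   # clamp numerical dust
  mom$cond_var[] <- 0
  imp <- draw_imputations(mom, tab, m = 4, seed = 9)
  vals <- vapply(imp$tables, function(tb) tb$x[2], numeric(1))
  expect_true(all(vals == vals[1]))
})

test_that("pooling reports mean and sample SD per parameter", {
  tr <- simulate_tree(10, seed = 51)
  d <- simulate_traits(tr, diag(2), lambda = 1, root_means = c(0, 0), seed = 52)
  names(d) <- c("x", "y")
  d$species <- rownames(d)
  f1 <- pgls(y ~ x, d, tr)
  # identical fits pool to SD zero everywhere
  pooled <- pool_fits(list(f1, f1, f1))
  expect_true(all(pooled$coefficients$estimate_sd == 0))
  expect_equal(pooled$lambda_sd, 0)
  # two fits with slopes 1 and 3 -> mean 2, SD sqrt(2)
  fa <- f1; fb <- f1
  fa$coefficients["x"] <- 1
  fb$coefficients["x"] <- 3
  p2 <- pool_fits(list(fa, fb))
  expect_equal(p2$coefficients$estimate_mean[p2$coefficients$term == "x"], 2)
  expect_equal(p2$coefficients$estimate_sd[p2$coefficients$term == "x"], sqrt(2))
  # permutation invariance
  p3 <- pool_fits(list(fb, fa))
  expect_equal(p2$coefficients, p3$coefficients)
  # incompatible specifications are rejected
  d$z <- rnorm(10)
  f2 <- pgls(y ~ z, d, tr)
  expect_error(pool_fits(list(f1, f2)), "incompatible")
})

test_that("LOO reliability is ~1 for deterministic dependence, ~0 for noise", {
  tr <- simulate_tree(30, seed = 61)
  d <- simulate_traits(tr, matrix(1), lambda = 1, root_means = 0, seed = 62)
  tab <- data.frame(species = rownames(d), x = d[[1]], y = 2 * d[[1]])
  fit <- fit_phylo_mvn(tab, tr, lambda = 1)
  r <- loo_reliability(tab, tr, fit)
  expect_gt(r[["y"]], 1 - 1e-6)
  # a trait with no signal and no cross-trait correlation imputes at ~0
  rs <- vapply(1:10, function(i) {
    tr2 <- simulate_tree(64, seed = 6000 + i)
    a <- simulate_traits(tr2, matrix(1), lambda = 1, root_means = 0,
                         seed = 6100 + i)[[1]]
    noise <- { set.seed(6200 + i); rnorm(64) }
    tab2 <- data.frame(species = tr2$tip.label, a = a, noise = noise)
    f2 <- fit_phylo_mvn(tab2, tr2)
    loo_reliability(tab2, tr2, f2)[["noise"]]
  }, numeric(1))
  expect_lt(abs(mean(rs)), 0.15)
})

test_that("refit mode agrees with fast mode under strong signal", {
  tr <- simulate_tree(16, seed = 71)
  d <- simulate_traits(tr, matrix(c(1, 0.95, 0.95, 1), 2), lambda = 1,
                       root_means = c(0, 0), seed = 73)
  names(d) <- c("x", "y")
  tab <- data.frame(species = rownames(d), d)
  fit <- fit_phylo_mvn(tab, tr, lambda = 1)
  fast <- loo_reliability(tab, tr, fit)
  slow <- loo_reliability(tab, tr, fit, refit = TRUE)
  expect_true(all(fast > 0.7))
  expect_lt(max(abs(fast - slow)), 0.3)
})

test_that("imputation error shrinks as cross-trait correlation grows", {
  rmse_at <- function(rho, nrep = 8) {
    mean(vapply(seq_len(nrep), function(i) {
      tr <- simulate_tree(40, seed = 8000 + 100 * round(rho * 10) + i)
      R <- matrix(c(1, rho, rho, 1), 2, dimnames = list(c("a", "b"), c("a", "b")))
      d <- simulate_traits(tr, R, lambda = 0.9, root_means = c(0, 0),
                           seed = 8500 + 100 * round(rho * 10) + i)
      tab <- data.frame(species = rownames(d), d)
      truth <- tab$a
      hide <- seq(1, 40, by = 4)
      tab$a[hide] <- NA
      f <- fit_phylo_mvn(tab, tr, lambda = 0.9)
      mom <- impute_moments(tab, tr, f)
      pred <- mom$cond_mean[match(tr$tip.label[hide], mom$species)]
      sqrt(mean((pred - truth[hide])^2))
    }, numeric(1)))
  }
  e0 <- rmse_at(0); e5 <- rmse_at(0.5); e9 <- rmse_at(0.9)
  expect_gt(e0, e5)
  expect_gt(e5, e9)
})

test_that("constant observed traits are rejected for correlation", {
  tr <- simulate_tree(8, seed = 81)
  tab <- data.frame(species = tr$tip.label, x = rnorm(8), y = rep(2, 8))
  fit <- structure(list(root_means = c(x = 0, y = 2),
                        trait_cov = diag(2, 2),
                        lambda = 1, loglik = NA, n_iter = 0L,
                        traits = c("x", "y")),
                   class = "phylo_mvn")
  dimnames(fit$trait_cov) <- list(c("x", "y"), c("x", "y"))
  expect_error(loo_reliability(tab, tr, fit, traits = "y"), "constant")
})
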