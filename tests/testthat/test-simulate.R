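# The synthetic-data generator: tree shape, Brownian+lambda trait scaling,
# the care-selection link in the sex-group summaries, and MCAR masking.

test_that("simulated trees are binary, ultrametric and deterministic", {
  tr <- simulate_tree(3, seed = 1)
  expect_equal(length(tr$tip.label), 3L)
  expect_equal(nrow(tr$edge), 4L)  # binary rooted: 2n - 2 edges
  big <- simulate_tree(64, seed = 7)
  depths <- ape::node.depth.edgelength(big)[seq_len(64)]
  expect_lt(diff(range(depths)), 1e-9)
  expect_true(all(big$edge.length > 0))
  expect_identical(write_newick(simulate_tree(64, seed = 7)),
                   write_newick(big))
  # a different seed gives a different tree
  expect_false(identical(write_newick(simulate_tree(64, seed = 8)),
                         write_newick(big)))
  expect_error(simulate_tree(2, seed = 1), ">= 3")
  coal <- simulate_tree(10, tree_model = "coalescent", seed = 3)
  expect_equal(length(coal$tip.label), 10L)
})

test_that("zero trait covariance returns the root means exactly", {
  tr <- simulate_tree(8, seed = 2)
  d <- simulate_traits(tr, matrix(0, 2, 2), lambda = 1,
                       root_means = c(3, -1), seed = 5)
  expect_true(all(d[[1]] == 3))
  expect_true(all(d[[2]] == -1))
})

test_that("Brownian tip variance equals rate times depth", {
  # two-tip tree of depth T: across replicates var(tip) ~ sigma2 * T
  tr <- read_newick("(A:2,B:2);")
  sigma2 <- 1.5
  vals <- vapply(1:500, function(i) {
    simulate_traits(tr, matrix(sigma2), lambda = 1, root_means = 0,
                    seed = 1000 + i)[[1]][1]
  }, numeric(1))
  expect_equal(var(vals), sigma2 * 2, tolerance = 0.2 * sigma2 * 2)
})

test_that("tip variance grows linearly in depth (Brownian scaling)", {
  sigma2 <- 0.8
  depths <- c(0.5, 1, 1.5, 2)
  vars <- vapply(depths, function(d) {
    tr <- star_tree(20, depth = d)
    vals <- vapply(1:150, function(i) {
      unlist(simulate_traits(tr, matrix(sigma2), lambda = 1, root_means = 0,
                             seed = round(7000 * d) + i))
    }, numeric(20))
    mean(vals^2)  # root mean 0: E[x^2] = sigma2 * d
  }, numeric(1))
  slope <- coef(lm(vars ~ depths))[2]
  expect_equal(unname(slope), sigma2, tolerance = 0.1 * sigma2)
})

test_that("lambda interpolates the sister-tip covariance", {
  # balanced tree with deep splits: sister pairs share half their depth
  tr <- read_newick("((A:1,B:1):1,(C:1,D:1):1);")
  cov_at <- function(lam, nrep = 800) {
    m <- vapply(1:800, function(i) {
      unlist(simulate_traits(tr, matrix(1), lambda = lam, root_means = 0,
                             seed = round(lam * 10000) + i))
    }, numeric(4))
    (cov(m[1, ], m[2, ]) + cov(m[3, ], m[4, ])) / 2
  }
  c1 <- cov_at(1)       # expectation 1 (shared path)
  ch <- cov_at(0.5)     # expectation 0.5
  expect_gt(ch / c1, 0.35)
  expect_lt(ch / c1, 0.65)
  # lambda 0: sister tips uncorrelated, |mean correlation| small
  m0 <- vapply(1:500, function(i) {
    unlist(simulate_traits(tr, matrix(1), lambda = 0, root_means = 0,
                           seed = 90000 + i))
  }, numeric(4))
  r0 <- (cor(m0[1, ], m0[2, ]) + cor(m0[3, ], m0[4, ])) / 2
  expect_lt(abs(r0), 0.05)
})

test_that("trait simulation is deterministic and validates input", {
  tr <- simulate_tree(6, seed = 4)
  a <- simulate_traits(tr, diag(2), lambda = 0.5, root_means = c(0, 0), seed = 9)
  b <- simulate_traits(tr, diag(2), lambda = 0.5, root_means = c(0, 0), seed = 9)
  expect_identical(a, b)
  bad <- matrix(c(1, 2, 2, 1), 2)  # indefinite
  expect_error(simulate_traits(tr, bad, lambda = 1, root_means = c(0, 0), seed = 1),
               "PSD")
  expect_error(simulate_traits(tr, diag(2), lambda = 1, root_means = 0, seed = 1),
               "length")
})

test_that("symmetric sex groups imply exactly zero effect sizes", {
  tr <- simulate_tree(20, seed = 5)
  g <- simulate_sex_groups(tr, effect_care_on_selection = 0, seed = 6,
                           noise_sd = 0)
  dI <- mapply(ln_cvr, g$rs_mean_m, g$rs_sd_m, g$rs_n_m,
               g$rs_mean_f, g$rs_sd_f, g$rs_n_f)
  dB <- mapply(hedges_d, g$bg_mean_m, g$bg_sd_m, g$bg_n_m,
               g$bg_mean_f, g$bg_sd_f, g$bg_n_f)
  expect_lt(max(abs(dI)), 1e-12)
  expect_lt(max(abs(dB)), 1e-12)
})

test_that("a null care effect yields no care-selection correlation", {
  tr <- simulate_tree(64, seed = 8)
  rbar <- mean(vapply(1:200, function(i) {
    g <- simulate_sex_groups(tr, effect_care_on_selection = 0, seed = 3000 + i)
    dI <- mapply(ln_cvr, g$rs_mean_m, g$rs_sd_m, g$rs_n_m,
                 g$rs_mean_f, g$rs_sd_f, g$rs_n_f)
    cor(g$care_frac, dI)
  }, numeric(1)))
  expect_lt(abs(rbar), 0.05)
})

test_that("a negative care effect is recovered by PGLS with high power", {
  signs <- vapply(1:30, function(i) {
    cfg <- sim_config(n_species = 64, effect_care_on_selection = -3,
                      seed = 4000 + i)
    ds <- simulate_dataset(cfg)
    der <- derive_indices(ds$raw)
    fit <- pgls(care_score ~ delta_I, der, ds$tree)
    unname(fit$coefficients["delta_I"])
  }, numeric(1))
  expect_gt(mean(signs < 0), 0.9)
})

test_that("masking is exact, reversible and deterministic", {
  tr <- simulate_tree(100, seed = 10)
  tab <- simulate_traits(tr, diag(3), lambda = 1, root_means = c(0, 0, 0),
                         seed = 11)
  names(tab) <- c("testis_mass_g", "male_mass_g", "female_mass_g")
  m <- apply_missingness(tab, c(testis_mass_g = 0.48), seed = 12)
  expect_equal(sum(is.na(m$data$testis_mass_g)), 48L)
  expect_equal(sum(unlist(m$mask)), 48L)
  expect_identical(m$truth, tab)
  # unmasked cells untouched
  expect_identical(m$data$male_mass_g, tab$male_mass_g)
  # rate 0 leaves the table unchanged
  m0 <- apply_missingness(tab, c(testis_mass_g = 0), seed = 12)
  expect_identical(m0$data, tab)
  # determinism
  m2 <- apply_missingness(tab, c(testis_mass_g = 0.48), seed = 12)
  expect_identical(m$mask, m2$mask)
  expect_error(apply_missingness(tab, c(testis_mass_g = 1)), "\\[0, 1\\)")
  expect_error(apply_missingness(tab, c(care_score = 0.2)), "never masked")
  expect_error(apply_missingness(tab, c(nope = 0.2)), "not in table")
})

test_that("default masking fractions follow the rounding rule at n = 64", {
  rates <- default_missing_rates()
  cfg <- sim_config(seed = 13)
  ds <- simulate_dataset(cfg, mask = TRUE)
  applied <- rates[names(rates) %in% names(ds$raw)]
  for (colname in names(applied)) {
    expect_equal(sum(ds$masked$mask[[colname]]),
                 round(applied[[colname]] * 64),
                 info = colname)
  }
})

test_that("auxiliary species are observed only for their columns", {
  cfg <- sim_config(n_species = 20, seed = 14)
  ds <- simulate_dataset(cfg, n_aux = 5)
  expect_equal(nrow(ds$raw), 25L)
  aux <- ds$raw[21:25, ]
  expect_true(all(!is.na(aux$male_mass_g)))
  expect_true(all(is.na(aux$rs_mean_m)))
  expect_true(all(is.na(aux$percent_male_care)))
})

test_that("sim_config validates and round-trips through YAML", {
  expect_error(sim_config(trait_covariance = matrix(c(1, 2, 2, 1), 2),
                          root_means = c(0, 0)), "positive semi-definite")
  expect_error(sim_config(missing_rates = c(x = 1.2)), "\\[0, 1\\)")
  cfg <- sim_config(n_species = 12, lambda_true = 0.7, seed = 99)
  path <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(n_species = 12, lambda_true = 0.7, seed = 99,
                        trait_covariance = list(c(1, 0.5), c(0.5, 1)),
                        root_means = c(0, 0)), path)
  cfg2 <- read_sim_config(path)
  expect_equal(cfg2$n_species, 12L)
  expect_equal(cfg2$lambda_true, 0.7)
  expect_equal(cfg2$trait_covariance, rbind(c(1, 0.5), c(0.5, 1)))
})

test_that("write_dataset emits the expected plain-text files", {
  cfg <- sim_config(n_species = 8, seed = 15)
  ds <- simulate_dataset(cfg, mask = TRUE)
  dir <- tempfile()
  write_dataset(ds, dir)
  expect_true(all(file.exists(file.path(dir, c("tree.nwk", "traits.csv",
                                               "traits_masked.csv", "mask.csv",
                                               "truth.csv")))))
  rt <- read_newick(file.path(dir, "tree.nwk"))
  expect_equal(sort(rt$tip.label), sort(ds$tree$tip.label))
})
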