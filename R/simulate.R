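# Synthetic phylogenies and trait data with known ground truth. The
# generator defines the study conditions every downstream test runs under:
# a 64-tip ultrametric tree, Brownian+lambda traits, per-sex success
# summaries whose implied selection effect sizes carry a tunable
# care-selection association, and MCAR missingness at fixed per-column
# fractions.

#' Simulation configuration
#'
#' Validates and bundles every knob of the synthetic-data generator. The
#' defaults emulate the study conditions of a 64-species comparative
#' dataset: a pure-birth timetree-like phylogeny, Brownian traits with a
#' common Pagel's lambda, 27/64 species without any parental care, and
#' missing-completely-at-random masking at the per-column fractions
#' 31% (female body mass), 20% (male body mass), 48% (testis mass),
#' 36% (male gamete size), 31% (female gamete mass), 27% (clutch size),
#' 14% / 7% / 23% (the three selection effect sizes).
#'
#' @param n_species Number of tips (>= 3).
#' @param tree_model `"pure_birth"` (ultrametric, default) or
#'   `"coalescent"`.
#' @param birth_rate Per-lineage speciation rate (arbitrary time units).
#' @param trait_covariance Symmetric PSD matrix over the simulated latent
#'   traits (Brownian rate units).
#' @param lambda_true Phylogenetic signal in \[0, 1\]; a scalar common
#'   lambda (default) or one value per trait.
#' @param root_means Trait means at the root.
#' @param effect_care_on_selection Slope linking the latent male-care
#'   fraction (centred) to the selection effect sizes; negative values mean
#'   more male care goes with weaker selection on males.
#' @param missing_rates Named fractions in \[0, 1) per maskable column.
#' @param prop_no_care Expected fraction of species with no care at all.
#' @param seed Master integer seed.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_species = 64,
                       tree_model = c("pure_birth", "coalescent"),
                       birth_rate = 1,
                       trait_covariance = diag(2),
                       lambda_true = 1,
                       root_means = numeric(nrow(as.matrix(trait_covariance))),
                       effect_care_on_selection = 0,
                       missing_rates = default_missing_rates(),
                       prop_no_care = 27 / 64,
                       seed = 1L) {
  tree_model <- match.arg(tree_model)
  trait_covariance <- as.matrix(trait_covariance)
  stopifnot(n_species >= 3, birth_rate >= 0,
            length(root_means) == nrow(trait_covariance),
            all(lambda_true >= 0), all(lambda_true <= 1),
            is.finite(effect_care_on_selection),
            prop_no_care >= 0, prop_no_care < 1)
  if (!is_psd(trait_covariance)) {
    stop("trait_covariance must be symmetric positive semi-definite",
         call. = FALSE)
  }
  if (any(missing_rates < 0) || any(missing_rates >= 1)) {
    stop("missing_rates must lie in [0, 1)", call. = FALSE)
  }
  structure(list(n_species = as.integer(n_species), tree_model = tree_model,
                 birth_rate = birth_rate, trait_covariance = trait_covariance,
                 lambda_true = lambda_true, root_means = root_means,
                 effect_care_on_selection = effect_care_on_selection,
                 missing_rates = missing_rates, prop_no_care = prop_no_care,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Default per-column missing-data fractions
#'
#' The marginal missingness pattern of the emulated 64-species dataset.
#' @return Named numeric vector of fractions.
#' @export
default_missing_rates <- function() {
  c(female_mass_g = 0.31, male_mass_g = 0.20, testis_mass_g = 0.48,
    male_gamete_size = 0.36, female_gamete_size = 0.31, clutch_size = 0.27,
    delta_I = 0.14, delta_I_s = 0.07, delta_beta_ss = 0.23)
}

#' Read a simulation configuration from a YAML file
#'
#' Flat key-value YAML with the same names as [sim_config()] arguments;
#' `trait_covariance` may be given as a matrix (list of rows).
#'
#' @param path YAML file path.
#' @return A `sim_config`.
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$trait_covariance)) {
    raw$trait_covariance <- do.call(rbind, raw$trait_covariance)
  }
  if (!is.null(raw$missing_rates)) raw$missing_rates <- unlist(raw$missing_rates)
  do.call(sim_config, raw)
}

#' Simulate a rooted binary phylogeny
#'
#' Pure-birth trees (default) are ultrametric with equal root-to-tip depths,
#' emulating a timetree; the coalescent model gives an alternative
#' ultrametric shape with long internal branches near the root. Identical
#' seeds give byte-identical trees.
#'
#' @param n_species Number of tips (>= 3).
#' @param tree_model `"pure_birth"` or `"coalescent"`.
#' @param birth_rate Speciation rate for the pure-birth model.
#' @param seed Integer seed.
#' @return A `phylo` object with tips `s1..sn`.
#' @export
simulate_tree <- function(n_species, tree_model = c("pure_birth", "coalescent"),
                          birth_rate = 1, seed = 1L) {
  tree_model <- match.arg(tree_model)
  if (n_species < 3) stop("n_species must be >= 3", call. = FALSE)
  tr <- with_seed(seed, {
    if (tree_model == "pure_birth") {
      ape::rphylo(n_species, birth = birth_rate, death = 0)
    } else {
      ape::rcoal(n_species)
    }
  })
  tr$tip.label <- paste0("s", seq_len(n_species))
  # guard against numerically zero branches from the simulator
  tr$edge.length[tr$edge.length <= 0] <- 1e-8
  validate_phylogeny(tr)
}

# Joint covariance over vec(tips x traits), column-stacked by trait:
# per-trait blocks R[i, j] * C with off-diagonal (between-tip) entries
# scaled by sqrt(lambda_i * lambda_j). With a scalar common lambda this is
# kron(R, lambda_transform(C, lambda)), which is always PSD.
joint_trait_cov <- function(C, R, lambda) {
  k <- nrow(R)
  lam <- rep_len(lambda, k)
  D <- diag(C)
  Coff <- C; diag(Coff) <- 0
  sl <- sqrt(lam)
  J <- kronecker(outer(sl, sl) * R, Coff) + kronecker(R, diag(D, nrow = length(D)))
  if (length(unique(lam)) > 1L && !is_psd(J, tol = 1e-7)) {
    stop("per-trait lambda combination yields a non-PSD joint covariance",
         call. = FALSE)
  }
  J
}

#' Simulate correlated traits under Brownian motion with Pagel's lambda
#'
#' Tip values are drawn from a multivariate normal whose among-species
#' covariance is the lambda-transformed phylogenetic covariance of the tree,
#' combined with the cross-trait covariance by a Kronecker product. With
#' `lambda = 0` tips are independent; with `lambda = 1` the full Brownian
#' expectation applies, so the variance of a tip grows linearly with its
#' depth at rate given by the trait covariance diagonal.
#'
#' @param tree A `phylo` object.
#' @param trait_covariance Symmetric PSD k x k matrix (Brownian rates and
#'   cross-trait covariances). An all-zero matrix returns the root means
#'   exactly.
#' @param lambda Phylogenetic signal, scalar or per-trait, in \[0, 1\].
#' @param root_means Length-k vector of root states.
#' @param seed Integer seed.
#' @return Data frame, species x traits, row names = tip labels. Column
#'   names are taken from `trait_covariance` dimnames or `trait1..k`.
#' @export
simulate_traits <- function(tree, trait_covariance, lambda = 1, root_means,
                            seed = 1L) {
  R <- as.matrix(trait_covariance)
  k <- nrow(R)
  if (length(root_means) != k) {
    stop("root_means length must match the trait covariance dimension",
         call. = FALSE)
  }
  if (!is_psd(R)) stop("trait_covariance is not PSD", call. = FALSE)
  if (any(lambda < 0 | lambda > 1)) stop("lambda must be in [0, 1]", call. = FALSE)
  C <- phylo_vcv(tree)
  n <- nrow(C)
  mu <- rep(root_means, each = n)
  vals <- if (all(R == 0)) mu else {
    J <- joint_trait_cov(C, R, lambda)
    with_seed(seed, rmvn1(mu, J))
  }
  out <- as.data.frame(matrix(vals, nrow = n, ncol = k))
  names(out) <- if (!is.null(colnames(R))) colnames(R) else paste0("trait", seq_len(k))
  rownames(out) <- rownames(C)
  out
}

#' Simulate per-sex success summaries with a tunable care-selection link
#'
#' For every tip the generator draws a latent male-care fraction
#' `u ~ Uniform(0, 1)` and a no-care flag, then builds per-sex summary
#' statistics (mean, SD, n) of reproductive success, mating success and the
#' Bateman gradient such that the *implied* sex-bias effect sizes are
#' `effect_care_on_selection * (u - 1/2)` plus independent Gaussian noise:
#' male and female CVs are set to `cv_female * exp(delta)` and `cv_female`,
#' so [ln_cvr()] on the summaries recovers delta exactly, and the male
#' Bateman mean is offset from the female mean by `delta * s_pool / J` so
#' [hedges_d()] recovers it too. With `effect = 0` and `noise_sd = 0` the
#' two sexes have identical CVs and gradient means, and every implied effect
#' size is exactly zero.
#'
#' @param tree A `phylo` object (supplies species names and count).
#' @param effect_care_on_selection Slope of the care-selection association.
#' @param seed Integer seed.
#' @param n_per_sex Sample size recorded in each summary.
#' @param cv_female Female coefficient of variation of both success measures.
#' @param noise_sd SD of the residual noise on each implied effect size.
#' @param prop_no_care Probability a species has no care at all.
#' @return Data frame with one row per species: latent `care_frac`,
#'   `percent_male_care` (NA for no-care species), `has_care`, and
#'   `rs_*`/`ms_*`/`bg_*` per-sex summary columns (see [trait_columns()]).
#' @export
simulate_sex_groups <- function(tree, effect_care_on_selection = 0, seed = 1L,
                                n_per_sex = 20L, cv_female = 0.5,
                                noise_sd = 0.1, prop_no_care = 27 / 64) {
  if (!is.finite(effect_care_on_selection)) {
    stop("effect_care_on_selection must be finite", call. = FALSE)
  }
  sp <- tree$tip.label
  n <- length(sp)
  with_seed(seed, {
    u <- stats::runif(n)
    has_care <- stats::runif(n) >= prop_no_care
    # extremes snap to strict uniparental care, keeping pct monotone in u
    pct <- 100 * u
    pct[u < 0.15] <- 0
    pct[u > 0.85] <- 100
    pct[!has_care] <- NA
    # effect size targets; care fraction u drives all three indices
    centred <- u - 0.5
    d_I <- effect_care_on_selection * centred + stats::rnorm(n, 0, noise_sd)
    d_Is <- effect_care_on_selection * centred + stats::rnorm(n, 0, noise_sd)
    d_B <- effect_care_on_selection * centred + stats::rnorm(n, 0, noise_sd)
    rs_mean_f <- stats::rlnorm(n, log(5), 0.3)
    rs_mean_m <- stats::rlnorm(n, log(5), 0.3)
    ms_mean_f <- stats::rlnorm(n, log(3), 0.2)
    ms_mean_m <- stats::rlnorm(n, log(3), 0.2)
    j <- 1 - 3 / (4 * (2 * n_per_sex - 2) - 1)
    bg_sd <- 0.8
    bg_mean_f <- rep(1.5, n)
    data.frame(
      species = sp,
      care_frac = u,
      percent_male_care = pct,
      has_care = has_care,
      rs_mean_m = rs_mean_m, rs_sd_m = cv_female * exp(d_I) * rs_mean_m,
      rs_n_m = n_per_sex,
      rs_mean_f = rs_mean_f, rs_sd_f = cv_female * rs_mean_f,
      rs_n_f = n_per_sex,
      ms_mean_m = ms_mean_m, ms_sd_m = cv_female * exp(d_Is) * ms_mean_m,
      ms_n_m = n_per_sex,
      ms_mean_f = ms_mean_f, ms_sd_f = cv_female * ms_mean_f,
      ms_n_f = n_per_sex,
      bg_mean_m = bg_mean_f + d_B * bg_sd / j, bg_sd_m = bg_sd,
      bg_n_m = n_per_sex,
      bg_mean_f = bg_mean_f, bg_sd_f = bg_sd, bg_n_f = n_per_sex,
      stringsAsFactors = FALSE
    )
  })
}

#' Mask trait cells completely at random at fixed per-column fractions
#'
#' For each named column, exactly `round(rate * n)` cells are set to `NA`,
#' chosen uniformly at random, so masking fractions are deterministic given
#' the rate. The original values are kept in a ground-truth store for
#' recovery tests. Parental-care columns (`care_score`,
#' `percent_male_care`, `has_care`) are never masked; supplying a rate for
#' one of them is an error.
#'
#' @param table Data frame of traits (rows = species).
#' @param missing_rates Named numeric vector of fractions in \[0, 1).
#' @param seed Integer seed.
#' @return A list of class `masked_traits`: `data` (with NAs), `mask`
#'   (logical data frame, TRUE = masked), `truth` (the input table).
#' @export
apply_missingness <- function(table, missing_rates, seed = 1L) {
  protected <- c("care_score", "percent_male_care", "has_care")
  bad <- intersect(names(missing_rates), protected)
  if (length(bad)) {
    stop("parental-care columns are never masked: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (any(missing_rates < 0) || any(missing_rates >= 1)) {
    stop("missing rates must lie in [0, 1)", call. = FALSE)
  }
  unknown <- setdiff(names(missing_rates), names(table))
  if (length(unknown)) {
    stop("column(s) not in table: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  n <- nrow(table)
  mask <- as.data.frame(matrix(FALSE, n, ncol(table)),
                        row.names = rownames(table))
  names(mask) <- names(table)
  out <- table
  with_seed(seed, {
    for (col in names(missing_rates)) {
      k <- round(missing_rates[[col]] * n)
      if (k > 0) {
        idx <- sample.int(n, k)
        mask[idx, col] <- TRUE
        out[idx, col] <- NA
      }
    }
  })
  structure(list(data = out, mask = mask, truth = table),
            class = "masked_traits")
}

#' @export
print.masked_traits <- function(x, ...) {
  cat(sprintf("masked trait table: %d species x %d columns, %d masked cells\n",
              nrow(x$data), ncol(x$data), sum(unlist(x$mask))))
  invisible(x)
}

#' Simulate a complete comparative dataset
#'
#' End-to-end generator: a tree, log-scale morphological traits evolved on
#' it (body masses, gamete sizes, testis mass, clutch size — correlated,
#' Brownian with lambda), per-sex success summaries with the configured
#' care-selection effect, and optional MCAR masking. The raw table follows
#' the [trait_columns()] dictionary and feeds straight into
#' [derive_indices()].
#'
#' @param config A [sim_config()].
#' @param mask Apply `config$missing_rates` to the raw table? The rates
#'   named for the derived effect-size columns (`delta_*`) are applied after
#'   index derivation by the caller and ignored here.
#' @param n_aux Number of auxiliary species (extra tips grafted into the
#'   simulation and observed for `aux_columns` only) to emulate augmenting
#'   the imputation with partially observed outside species.
#' @param aux_columns Raw columns observed for auxiliary species.
#' @return List of class `sim_dataset`: `tree`, `raw` (data frame),
#'   `latent` (ground-truth care fractions and morphological traits),
#'   `masked` (a `masked_traits`, when `mask = TRUE`), `config`.
#' @export
simulate_dataset <- function(config = sim_config(), mask = FALSE,
                             n_aux = 0L,
                             aux_columns = c("male_mass_g", "female_mass_g",
                                             "testis_mass_g", "clutch_size")) {
  stopifnot(inherits(config, "sim_config"))
  n_total <- config$n_species + n_aux
  tree <- simulate_tree(n_total, config$tree_model, config$birth_rate,
                        seed = derive_seed(config$seed, 1))
  # log-scale morphology: male mass, female mass, sperm size, egg mass,
  # testis mass, clutch size (correlated through a shared size axis)
  morph_names <- c("log_male_mass", "log_female_mass", "log_sperm",
                   "log_egg", "log_testis", "log_clutch")
  R <- matrix(0.6, 6, 6)
  diag(R) <- 1
  R <- R * 0.5  # Brownian rate 0.5 per unit depth
  dimnames(R) <- list(morph_names, morph_names)
  mu <- c(2, 2, -6, -2, -1, 1.5)
  lam <- if (length(config$lambda_true) == 1L) config$lambda_true else config$lambda_true[1]
  morph <- simulate_traits(tree, R, lambda = lam, root_means = mu,
                           seed = derive_seed(config$seed, 2))
  sexes <- simulate_sex_groups(tree, config$effect_care_on_selection,
                               seed = derive_seed(config$seed, 3),
                               prop_no_care = config$prop_no_care)
  raw <- data.frame(
    species = tree$tip.label,
    male_mass_g = exp(morph$log_male_mass),
    female_mass_g = exp(morph$log_female_mass),
    male_gamete_size = exp(morph$log_sperm),
    female_gamete_size = exp(morph$log_egg),
    testis_mass_g = exp(morph$log_testis),
    clutch_size = exp(morph$log_clutch),
    stringsAsFactors = FALSE
  )
  raw <- cbind(raw, sexes[, setdiff(names(sexes), c("species", "care_frac"))])
  if (n_aux > 0) {
    aux <- seq(config$n_species + 1L, n_total)
    keep_cols <- c("species", aux_columns)
    drop_cols <- setdiff(names(raw), keep_cols)
    raw[aux, drop_cols] <- NA
  }
  out <- list(tree = tree, raw = raw,
              latent = data.frame(species = tree$tip.label,
                                  care_frac = sexes$care_frac, morph),
              config = config)
  if (mask) {
    rates <- config$missing_rates[names(config$missing_rates) %in% names(raw)]
    out$masked <- apply_missingness(raw, rates,
                                    seed = derive_seed(config$seed, 4))
  }
  class(out) <- "sim_dataset"
  out
}

#' Write a simulated dataset to plain-text files
#'
#' @param dataset A `sim_dataset`.
#' @param dir Output directory (created if needed). Writes `tree.nwk`,
#'   `traits.csv`, and when masking was applied `traits_masked.csv`,
#'   `mask.csv` and `truth.csv`.
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "sim_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_newick(dataset$tree, file.path(dir, "tree.nwk"))
  utils::write.csv(dataset$raw, file.path(dir, "traits.csv"), row.names = FALSE)
  if (!is.null(dataset$masked)) {
    utils::write.csv(dataset$masked$data, file.path(dir, "traits_masked.csv"),
                     row.names = FALSE)
    utils::write.csv(dataset$masked$mask, file.path(dir, "mask.csv"),
                     row.names = FALSE)
    utils::write.csv(dataset$masked$truth, file.path(dir, "truth.csv"),
                     row.names = FALSE)
  }
  invisible(dir)
}
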