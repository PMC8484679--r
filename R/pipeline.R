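# Orchestration: derive per-species indices from the raw table, optionally
# impute missing values, run the planned PGLS models on the original and/or
# completed datasets, and emit a tidy report.

#' Derive the per-species analysis table from a raw trait table
#'
#' Computes every analysis variable from the raw columns (see
#' [trait_columns()]): the three selection effect sizes (lnCVR of
#' reproductive success, lnCVR of mating success, Hedges' d of Bateman
#' gradients), sexual size dimorphism, the two gametic bias indices, and the
#' parental-care score. A derived cell is `NA` whenever any raw input it
#' depends on is missing; no species is dropped here. When the raw table
#' already carries pre-computed `delta_I`, `delta_I_s` or `delta_beta_ss`
#' columns (effect sizes taken from an upstream meta-analytic source), they
#' are passed through unchanged by default.
#'
#' @param raw Raw data frame, one row per species.
#' @param use_precomputed Prefer pre-computed `delta_*` columns when present?
#' @param small_sample_correction Passed to [ln_cvr()].
#' @return Data frame with columns `species`, `delta_I`, `delta_I_s`,
#'   `delta_beta_ss`, `ssd`, `gamete_size_bias`, `gametic_investment_bias`,
#'   `care_score`, `has_care`.
#' @export
derive_indices <- function(raw, use_precomputed = TRUE,
                           small_sample_correction = TRUE) {
  raw <- as.data.frame(raw)
  if (!"species" %in% names(raw)) stop("raw table needs a `species` column", call. = FALSE)
  n <- nrow(raw)
  col <- function(name) if (name %in% names(raw)) raw[[name]] else rep(NA_real_, n)
  safe <- function(f, ...) {
    args <- list(...)
    vapply(seq_len(n), function(i) {
      a <- lapply(args, `[`, i)
      if (any(vapply(a, function(v) is.na(v) || (is.numeric(v) && !is.finite(v)),
                     logical(1)))) return(NA_real_)
      tryCatch(do.call(f, a), error = function(e) NA_real_)
    }, numeric(1))
  }
  d_I <- if (use_precomputed && "delta_I" %in% names(raw)) raw$delta_I else {
    safe(function(mm, sm, nm, mf, sf, nf)
      ln_cvr(mm, sm, nm, mf, sf, nf, small_sample_correction),
      col("rs_mean_m"), col("rs_sd_m"), col("rs_n_m"),
      col("rs_mean_f"), col("rs_sd_f"), col("rs_n_f"))
  }
  d_Is <- if (use_precomputed && "delta_I_s" %in% names(raw)) raw$delta_I_s else {
    safe(function(mm, sm, nm, mf, sf, nf)
      ln_cvr(mm, sm, nm, mf, sf, nf, small_sample_correction),
      col("ms_mean_m"), col("ms_sd_m"), col("ms_n_m"),
      col("ms_mean_f"), col("ms_sd_f"), col("ms_n_f"))
  }
  d_B <- if (use_precomputed && "delta_beta_ss" %in% names(raw)) raw$delta_beta_ss else {
    safe(hedges_d,
      col("bg_mean_m"), col("bg_sd_m"), col("bg_n_m"),
      col("bg_mean_f"), col("bg_sd_f"), col("bg_n_f"))
  }
  ssd_v <- safe(function(m, f) ssd(m, f, "weight"),
                col("male_mass_g"), col("female_mass_g"))
  gsb <- safe(gamete_size_bias,
              col("male_gamete_size"), col("male_mass_g"),
              col("female_gamete_size"), col("female_mass_g"))
  gib <- safe(gametic_investment_bias,
              col("testis_mass_g"), col("male_mass_g"),
              col("female_gamete_size"), col("clutch_size"),
              col("female_mass_g"))
  has_care <- if ("has_care" %in% names(raw)) as.logical(raw$has_care) else
    !is.na(col("percent_male_care"))
  cs <- care_score(col("percent_male_care"), has_care = has_care)
  data.frame(species = as.character(raw$species),
             delta_I = d_I, delta_I_s = d_Is, delta_beta_ss = d_B,
             ssd = ssd_v, gamete_size_bias = gsb,
             gametic_investment_bias = gib,
             care_score = as.numeric(cs), has_care = has_care,
             stringsAsFactors = FALSE)
}

#' The standard analysis plan
#'
#' Bivariate models pairing each selection effect size with each gametic
#' bias index, the care score with each effect size, and size dimorphism
#' with each effect size, plus the six multi-predictor models (one effect
#' size as response; one gametic bias index, SSD and the care score as
#' predictors). Models involving the care score are restricted to species
#' with some level of care automatically, because the score is `NA`
#' elsewhere and PGLS uses casewise deletion.
#'
#' @return Data frame of class `analysis_plan` with columns `model`,
#'   `formula` (character).
#' @export
default_plan <- function() {
  idx <- c("delta_I", "delta_I_s", "delta_beta_ss")
  gam <- c("gamete_size_bias", "gametic_investment_bias")
  biv <- c(
    unlist(lapply(idx, function(i) paste(i, "~", gam))),
    paste("care_score ~", idx),
    paste("ssd ~", idx)
  )
  multi <- unlist(lapply(idx, function(i)
    paste(i, "~", gam, "+ ssd + care_score")))
  plan <- data.frame(
    model = c(sprintf("bivariate_%02d", seq_along(biv)),
              sprintf("multi_%02d", seq_along(multi))),
    formula = c(biv, multi),
    stringsAsFactors = FALSE
  )
  class(plan) <- c("analysis_plan", "data.frame")
  plan
}

# Imputable numeric columns of a derived table (the care score is never
# imputed; it is categorical and excluded from the Gaussian model).
imputable_columns <- function(derived) {
  setdiff(names(derived)[vapply(derived, is.numeric, logical(1))],
          c("care_score"))
}

#' Run the planned PGLS models on a derived table
#'
#' `mode = "original"` fits every planned model on the table as-is
#' (casewise deletion of species with missing values). `mode = "complete"`
#' first imputes the missing numeric index cells by phylogenetic multiple
#' imputation (`m` completed datasets; the care score is never imputed),
#' fits every model in each completed dataset, and pools per-parameter mean
#' and SD across the `m` fits. Models with fewer than 4 usable species are
#' reported as skipped with a reason, never as a crash. The whole run is
#' deterministic in (`plan`, `seed`).
#'
#' @param derived Derived table from [derive_indices()].
#' @param tree A `phylo` covering the table's species. Species absent from
#'   the tree are an error unless `graft` places them.
#' @param plan An [default_plan()]-shaped data frame.
#' @param mode `"original"` or `"complete"`.
#' @param m Number of imputation draws in complete mode.
#' @param seed Master seed for the imputation draws.
#' @param graft Optional named character vector `new_tip = sister_taxon`;
#'   each named species is grafted onto its sister's terminal branch at
#'   half depth before fitting.
#' @return Object of class `analysis_report`: `results` (tidy data frame),
#'   `skipped` (model + reason), `manifest` (mode, seed, m, per-model
#'   lambda).
#' @export
run_plan <- function(derived, tree, plan = default_plan(),
                     mode = c("original", "complete"), m = 10L, seed = 1L,
                     graft = NULL) {
  mode <- match.arg(mode)
  derived <- as.data.frame(derived)
  if (!is.null(graft)) {
    for (sp in names(graft)) tree <- graft_species(tree, sp, graft[[sp]])
  }
  absent <- setdiff(derived$species, tree$tip.label)
  if (length(absent)) {
    stop("species not in tree (use `graft` to place them): ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  tables <- list(derived)
  if (mode == "complete") {
    cols <- imputable_columns(derived)
    sub <- derived[, c("species", cols)]
    if (anyNA(sub[, cols])) {
      pars <- fit_phylo_mvn(sub, tree)
      mom <- impute_moments(sub, tree, pars)
      imp <- draw_imputations(mom, sub, m = m, seed = seed)
      tables <- lapply(imp$tables, function(tb) {
        out <- derived
        out[, cols] <- tb[, cols]
        out
      })
    } else {
      tables <- rep(list(derived), m)
    }
  }
  results <- list()
  skipped <- data.frame(model = character(0), reason = character(0),
                        stringsAsFactors = FALSE)
  lambdas <- list()
  for (r in seq_len(nrow(plan))) {
    fml <- stats::as.formula(plan$formula[r])
    fits <- tryCatch(lapply(tables, function(tb) pgls(fml, tb, tree)),
                     error = function(e) e)
    if (inherits(fits, "error")) {
      skipped <- rbind(skipped, data.frame(model = plan$model[r],
                                           reason = conditionMessage(fits),
                                           stringsAsFactors = FALSE))
      next
    }
    if (mode == "original") {
      f <- fits[[1]]
      results[[length(results) + 1L]] <- data.frame(
        model = plan$model[r], dataset_mode = mode,
        term = names(f$coefficients),
        estimate = unname(f$coefficients), se = unname(f$se),
        t = unname(f$t), p = unname(f$p),
        lambda_hat = f$lambda, adj_r2 = f$adj_r2, n = f$n,
        stringsAsFactors = FALSE)
      lambdas[[plan$model[r]]] <- f$lambda
    } else {
      pooled <- pool_fits(fits)
      cf <- pooled$coefficients
      results[[length(results) + 1L]] <- data.frame(
        model = plan$model[r], dataset_mode = mode,
        term = cf$term,
        estimate_mean = cf$estimate_mean, estimate_sd = cf$estimate_sd,
        se_mean = cf$se_mean, se_sd = cf$se_sd,
        t_mean = cf$t_mean, t_sd = cf$t_sd,
        p_mean = cf$p_mean, p_sd = cf$p_sd,
        lambda_hat_mean = pooled$lambda_mean, lambda_hat_sd = pooled$lambda_sd,
        adj_r2_mean = pooled$adj_r2_mean, adj_r2_sd = pooled$adj_r2_sd,
        n = pooled$n, stringsAsFactors = FALSE)
      lambdas[[plan$model[r]]] <- pooled$lambda_mean
    }
  }
  structure(list(results = do.call(rbind, results), skipped = skipped,
                 manifest = list(mode = mode, m = if (mode == "complete") m else NA,
                                 seed = seed, lambda_hat = lambdas,
                                 n_models = nrow(plan),
                                 n_fitted = length(results),
                                 n_skipped = nrow(skipped))),
            class = "analysis_report")
}

#' @export
print.analysis_report <- function(x, ...) {
  cat(sprintf("analysis report (%s mode): %d models fitted, %d skipped\n",
              x$manifest$mode, x$manifest$n_fitted, x$manifest$n_skipped))
  invisible(x)
}

#' Write an analysis report to CSV + JSON
#'
#' @param report An `analysis_report`.
#' @param dir Output directory; writes `results.csv`, `skipped.csv` and
#'   `manifest.json`.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "analysis_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$results, file.path(dir, "results.csv"),
                   row.names = FALSE)
  utils::write.csv(report$skipped, file.path(dir, "skipped.csv"),
                   row.names = FALSE)
  jsonlite::write_json(report$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
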