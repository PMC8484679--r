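# Phylogenetic multiple imputation under a multivariate Brownian-motion
# model with a single common Pagel's lambda. The joint distribution of the
# species x trait matrix Y is vec(Y) ~ N(1 (x) mu, R (x) C_lambda), where C
# is the tree's Brownian covariance and R the cross-trait covariance.
# Missing cells are imputed from their exact conditional normal
# distribution given every observed cell.

# Coerce a trait table to a numeric matrix with species row names.
table_matrix <- function(table) {
  tab <- as.data.frame(table)
  sp <- if ("species" %in% names(tab)) as.character(tab$species) else rownames(tab)
  num <- vapply(tab, is.numeric, logical(1))
  num["species"] <- FALSE
  Y <- as.matrix(tab[, num, drop = FALSE])
  rownames(Y) <- sp
  Y
}

# Joint covariance over vec(Y) (column-stacked: cell (tip a, trait j) has
# index (j-1)*n + a) under the common-lambda model.
joint_cov <- function(C, R, lambda) {
  kronecker(R, lambda_transform(C, lambda))
}

# Complete-data ML for (mu, R) at fixed lambda; closed form via whitening.
complete_ml <- function(Y, C, lambda) {
  n <- nrow(Y); k <- ncol(Y)
  Cl <- lambda_transform(C, lambda)
  U <- chol(Cl)
  logdetC <- 2 * sum(log(diag(U)))
  Yw <- backsolve(U, Y, transpose = TRUE)
  onew <- backsolve(U, rep(1, n), transpose = TRUE)
  mu <- drop(crossprod(onew, Yw)) / sum(onew^2)
  Z <- Yw - outer(onew, mu)
  R <- crossprod(Z) / n
  ldR <- determinant(R, logarithm = TRUE)
  ldR <- if (ldR$sign <= 0) -Inf else as.numeric(ldR$modulus)
  loglik <- -0.5 * (n * k * log(2 * pi) + k * logdetC + n * ldR + n * k)
  list(root_means = mu, trait_cov = R, loglik = loglik, n_iter = 0L)
}

# One EM run for (mu, R) at fixed lambda with missing cells.
em_ml <- function(Y, C, lambda, init = NULL, max_iter = 200L, tol = 1e-6) {
  n <- nrow(Y); k <- ncol(Y)
  miss <- which(is.na(Y))            # linear indices into vec(Y)
  obs <- which(!is.na(Y))
  yobs <- Y[obs]
  miss_tip <- (miss - 1L) %% n + 1L
  miss_trait <- (miss - 1L) %/% n + 1L
  Cl <- lambda_transform(C, lambda)
  W <- chol2inv(chol(Cl))
  sW1 <- sum(W)
  W1 <- rowSums(W)
  depth_mean <- mean(diag(Cl))
  if (is.null(init)) {
    mu <- colMeans(Y, na.rm = TRUE)
    R <- diag(apply(Y, 2, stats::var, na.rm = TRUE) / depth_mean, k)
  } else {
    mu <- init$root_means
    R <- init$trait_cov
  }
  loglik <- -Inf
  for (it in seq_len(max_iter)) {
    Sigma <- joint_cov(C, R, lambda)
    muvec <- rep(mu, each = n)
    Soo <- Sigma[obs, obs, drop = FALSE]
    Uo <- tryCatch(chol(Soo), error = function(e) NULL)
    if (is.null(Uo)) {
      # regularize a degenerate trait covariance and retry next iteration
      R <- R + diag(1e-8 * max(diag(R)), k)
      next
    }
    dev <- yobs - muvec[obs]
    alpha <- backsolve(Uo, backsolve(Uo, dev, transpose = TRUE))
    ll_new <- -0.5 * (length(obs) * log(2 * pi) + 2 * sum(log(diag(Uo))) +
                        sum(dev * alpha))
    Smo <- Sigma[miss, obs, drop = FALSE]
    cond_mean <- muvec[miss] + drop(Smo %*% alpha)
    K <- backsolve(Uo, backsolve(Uo, t(Smo), transpose = TRUE))
    cond_cov <- Sigma[miss, miss, drop = FALSE] - Smo %*% K
    Yhat <- Y
    Yhat[miss] <- cond_mean
    # M step
    mu <- drop(crossprod(W1, Yhat)) / sW1
    Z <- Yhat - matrix(mu, n, k, byrow = TRUE)
    S <- t(Z) %*% W %*% Z
    # second-moment correction from the conditional covariance of the
    # missing cells: Delta[i, j] = sum_ab W[a, b] Cov(Y[a, i], Y[b, j])
    Delta <- matrix(0, k, k)
    Wmm <- W[miss_tip, miss_tip, drop = FALSE]
    for (i in seq_len(k)) {
      ri <- which(miss_trait == i)
      if (!length(ri)) next
      for (j in seq_len(i)) {
        rj <- which(miss_trait == j)
        if (!length(rj)) next
        v <- sum(Wmm[ri, rj, drop = FALSE] * cond_cov[ri, rj, drop = FALSE])
        Delta[i, j] <- Delta[i, j] + v
        if (i != j) Delta[j, i] <- Delta[j, i] + v
      }
    }
    R <- (S + Delta) / n
    R <- (R + t(R)) / 2
    if (is.finite(loglik) && abs(ll_new - loglik) < tol * (abs(loglik) + 1)) {
      loglik <- ll_new
      return(list(root_means = mu, trait_cov = R, loglik = loglik, n_iter = it))
    }
    loglik <- ll_new
  }
  list(root_means = mu, trait_cov = R, loglik = loglik, n_iter = max_iter)
}

#' Fit the multivariate Brownian+lambda model to a trait table with missing cells
#'
#' Maximum-likelihood estimation of the per-trait root means, the
#' cross-trait (Brownian rate) covariance matrix and a single common
#' Pagel's lambda, maximizing the observed-data likelihood. With complete
#' data the ML solution is closed-form at each lambda; with missing cells an
#' EM algorithm is used (exact conditional moments in the E step), and
#' lambda is profiled by a bounded one-dimensional search.
#'
#' @param table Species x trait table (data frame with a `species` column or
#'   species row names; only numeric columns are modelled).
#' @param tree A `phylo` object covering the table's species.
#' @param lambda `NULL` (default) to estimate lambda by ML, or a fixed value
#'   in \[0, 1\].
#' @param max_iter,tol EM iteration cap and relative log-likelihood
#'   convergence tolerance.
#' @param lambda_tol Tolerance of the outer lambda search.
#' @return An object of class `phylo_mvn`: `root_means`, `trait_cov`,
#'   `lambda`, `loglik`, `n_iter`, `traits`.
#' @export
fit_phylo_mvn <- function(table, tree, lambda = NULL, max_iter = 200L,
                          tol = 1e-6, lambda_tol = 1e-3) {
  Y <- table_matrix(table)
  n_obs_per_trait <- colSums(!is.na(Y))
  if (any(n_obs_per_trait == 0)) {
    stop("trait(s) with no observed values are unidentifiable: ",
         paste(colnames(Y)[n_obs_per_trait == 0], collapse = ", "),
         call. = FALSE)
  }
  C <- phylo_vcv(tree, tip_order = rownames(Y))
  complete <- !anyNA(Y)
  state <- new.env(parent = emptyenv())
  state$init <- NULL
  fit_at <- function(lam) {
    res <- if (complete) complete_ml(Y, C, lam)
           else em_ml(Y, C, lam, init = state$init, max_iter = max_iter, tol = tol)
    state$init <- res[c("root_means", "trait_cov")]
    res
  }
  if (is.null(lambda)) {
    opt <- stats::optimize(function(l) fit_at(l)$loglik, c(0, 1),
                           maximum = TRUE, tol = lambda_tol)
    cand <- c(0, opt$maximum, 1)
    ll <- c(fit_at(0)$loglik, opt$objective, fit_at(1)$loglik)
    lambda <- cand[which(ll >= max(ll) - 1e-9)[1]]
  } else {
    if (lambda < 0 || lambda > 1) stop("lambda must be in [0, 1]", call. = FALSE)
  }
  res <- fit_at(lambda)
  names(res$root_means) <- colnames(Y)
  dimnames(res$trait_cov) <- list(colnames(Y), colnames(Y))
  structure(list(root_means = res$root_means, trait_cov = res$trait_cov,
                 lambda = lambda, loglik = res$loglik, n_iter = res$n_iter,
                 traits = colnames(Y)),
            class = "phylo_mvn")
}

#' @export
print.phylo_mvn <- function(x, ...) {
  cat(sprintf("multivariate Brownian+lambda model: %d traits, lambda = %.3f, logLik = %.3f\n",
              length(x$traits), x$lambda, x$loglik))
  invisible(x)
}

#' Conditional moments of every missing trait cell
#'
#' For each missing cell, the exact conditional normal mean and variance
#' given all observed cells under the fitted joint (tree x trait)
#' covariance. These moments drive the random imputation draws; conditional
#' variances never exceed the cell's marginal variance under the model.
#'
#' @param table Species x trait table with missing cells.
#' @param tree A `phylo` object.
#' @param params A `phylo_mvn` fit (see [fit_phylo_mvn()]).
#' @return An object of class `imputation_moments`: data frame with columns
#'   `species`, `trait`, `cond_mean`, `cond_var`, `marginal_var`; the full
#'   conditional covariance of the missing cells is attached as attribute
#'   `"cond_cov"`.
#' @export
impute_moments <- function(table, tree, params) {
  stopifnot(inherits(params, "phylo_mvn"))
  Y <- table_matrix(table)
  Y <- Y[, params$traits, drop = FALSE]
  n <- nrow(Y); k <- ncol(Y)
  miss <- which(is.na(Y))
  if (!length(miss)) stop("no missing cells to impute", call. = FALSE)
  obs <- which(!is.na(Y))
  C <- phylo_vcv(tree, tip_order = rownames(Y))
  Sigma <- joint_cov(C, params$trait_cov, params$lambda)
  muvec <- rep(params$root_means, each = n)
  Soo <- Sigma[obs, obs, drop = FALSE]
  Uo <- chol_safe(Soo)
  dev <- Y[obs] - muvec[obs]
  alpha <- backsolve(Uo, backsolve(Uo, dev, transpose = TRUE))
  Smo <- Sigma[miss, obs, drop = FALSE]
  cond_mean <- muvec[miss] + drop(Smo %*% alpha)
  K <- backsolve(Uo, backsolve(Uo, t(Smo), transpose = TRUE))
  cond_cov <- Sigma[miss, miss, drop = FALSE] - Smo %*% K
  cond_cov <- (cond_cov + t(cond_cov)) / 2
  out <- data.frame(
    species = rownames(Y)[(miss - 1L) %% n + 1L],
    trait = colnames(Y)[(miss - 1L) %/% n + 1L],
    cond_mean = cond_mean,
    cond_var = pmax(diag(cond_cov), 0),
    marginal_var = diag(Sigma)[miss],
    stringsAsFactors = FALSE
  )
  structure(out, cond_cov = cond_cov, miss_index = miss,
            dims = c(n, k), traits = colnames(Y),
            species_order = rownames(Y), class = c("imputation_moments", "data.frame"))
}

#' Draw multiply imputed complete tables
#'
#' Produces `m` completed copies of the table (default 10): each missing
#' cell is filled with an independent normal draw at its conditional mean
#' and variance; observed cells are never touched. Each completed dataset
#' gets its own seed derived deterministically from the master seed, so the
#' whole set reproduces exactly.
#'
#' @param moments An `imputation_moments` object.
#' @param table The original table the moments were computed from.
#' @param m Number of completed datasets (>= 2).
#' @param seed Master integer seed.
#' @return Object of class `imputation_set`: `tables` (list of m completed
#'   data frames), `seeds`, `m`, `moments`.
#' @export
draw_imputations <- function(moments, table, m = 10L, seed = 1L) {
  stopifnot(inherits(moments, "imputation_moments"))
  if (m < 2) stop("m must be >= 2", call. = FALSE)
  tab <- as.data.frame(table)
  traits <- attr(moments, "traits")
  sp <- attr(moments, "species_order")
  row_of <- match(moments$species, sp)
  seeds <- vapply(seq_len(m), function(i) derive_seed(seed, i), integer(1))
  tables <- lapply(seq_len(m), function(i) {
    vals <- with_seed(seeds[i],
                      stats::rnorm(nrow(moments), moments$cond_mean,
                                   sqrt(moments$cond_var)))
    out <- tab
    tab_rows <- if ("species" %in% names(tab)) {
      match(moments$species, as.character(tab$species))
    } else match(moments$species, rownames(tab))
    for (r in seq_len(nrow(moments))) {
      out[tab_rows[r], moments$trait[r]] <- vals[r]
    }
    out
  })
  structure(list(tables = tables, seeds = seeds, m = as.integer(m),
                 moments = moments),
            class = "imputation_set")
}

#' @export
print.imputation_set <- function(x, ...) {
  cat(sprintf("imputation set: %d completed tables, %d imputed cells each\n",
              x$m, nrow(x$moments)))
  invisible(x)
}

#' Pool PGLS fits across multiply imputed datasets
#'
#' Summarizes the `m` per-dataset fits of one model as the sample mean and
#' sample SD (n-1 denominator) of every reported parameter: coefficient
#' estimates, standard errors, t, p, lambda and adjusted R-squared. This is
#' the mean +/- SD presentation used for completed-dataset analyses (not
#' Rubin's rules).
#'
#' @param fits List of `pgls_fit` objects sharing one model specification.
#' @return Object of class `pooled_pgls`: `coefficients` data frame with
#'   `*_mean` / `*_sd` columns per term, plus `lambda_mean`, `lambda_sd`,
#'   `adj_r2_mean`, `adj_r2_sd`, `n`, `m`.
#' @export
pool_fits <- function(fits) {
  if (length(fits) < 2) stop("need >= 2 fits to pool", call. = FALSE)
  if (!all(vapply(fits, inherits, logical(1), "pgls_fit"))) {
    stop("all elements must be pgls_fit objects", call. = FALSE)
  }
  terms0 <- names(fits[[1]]$coefficients)
  same <- vapply(fits, function(f) identical(names(f$coefficients), terms0),
                 logical(1))
  forms <- vapply(fits, function(f)
    if (is.null(f$formula)) "" else paste(deparse(f$formula), collapse = ""),
    character(1))
  if (!all(same) || length(unique(forms)) != 1L) {
    stop("fits have incompatible model specifications", call. = FALSE)
  }
  stat <- function(get) {
    M <- do.call(rbind, lapply(fits, get))
    list(mean = colMeans(M), sd = apply(M, 2, stats::sd))
  }
  est <- stat(function(f) f$coefficients)
  se <- stat(function(f) f$se)
  tv <- stat(function(f) f$t)
  pv <- stat(function(f) f$p)
  coefs <- data.frame(term = terms0,
                      estimate_mean = est$mean, estimate_sd = est$sd,
                      se_mean = se$mean, se_sd = se$sd,
                      t_mean = tv$mean, t_sd = tv$sd,
                      p_mean = pv$mean, p_sd = pv$sd,
                      row.names = NULL, stringsAsFactors = FALSE)
  lam <- vapply(fits, function(f) f$lambda, numeric(1))
  ar2 <- vapply(fits, function(f) f$adj_r2, numeric(1))
  structure(list(coefficients = coefs,
                 lambda_mean = mean(lam), lambda_sd = stats::sd(lam),
                 adj_r2_mean = mean(ar2), adj_r2_sd = stats::sd(ar2),
                 n = fits[[1]]$n, m = length(fits)),
            class = "pooled_pgls")
}

#' @export
print.pooled_pgls <- function(x, ...) {
  cat(sprintf("pooled PGLS over %d imputed datasets (N = %d)\n", x$m, x$n))
  print(within(x$coefficients, {
    estimate <- sprintf("%.3f ± %.3f", estimate_mean, estimate_sd)
  })[, c("term", "estimate", "p_mean", "p_sd")])
  cat(sprintf("lambda = %.3f ± %.3f, adj R2 = %.3f ± %.3f\n",
              x$lambda_mean, x$lambda_sd, x$adj_r2_mean, x$adj_r2_sd))
  invisible(x)
}

#' Leave-one-out reliability of the imputation
#'
#' Masks each *observed* cell in turn, recomputes its conditional mean given
#' every other observed cell under the fitted model, and reports the Pearson
#' correlation per trait between the original and the re-imputed values. A
#' correlation of 0.8 or above is the conventional bar for calling the
#' imputation reliable.
#'
#' The default fast mode conditions each held-out cell on all other cells
#' using model parameters fitted once (an exact single-inversion identity:
#' for a joint Gaussian, the held-out conditional mean is
#' `y_i - (Omega (y - mu))_i / Omega_ii` with `Omega` the observed-block
#' precision). `refit = TRUE` re-estimates the model parameters after each
#' deletion (lambda held at the fitted value), which is exact but quadratic
#' in the number of observed cells.
#'
#' @param table Species x trait table (with its missing cells).
#' @param tree A `phylo` object.
#' @param params A `phylo_mvn` fit.
#' @param traits Traits to assess (default: all modelled traits with >= 5
#'   observed cells and non-zero variance).
#' @param refit Refit model parameters for every deletion?
#' @return Named numeric vector of per-trait Pearson correlations.
#' @export
loo_reliability <- function(table, tree, params, traits = NULL, refit = FALSE) {
  stopifnot(inherits(params, "phylo_mvn"))
  Y <- table_matrix(table)
  Y <- Y[, params$traits, drop = FALSE]
  n <- nrow(Y)
  if (is.null(traits)) {
    ok <- colSums(!is.na(Y)) >= 5 &
      apply(Y, 2, function(v) stats::var(v, na.rm = TRUE) > 0)
    traits <- colnames(Y)[ok]
  } else {
    nobs <- colSums(!is.na(Y[, traits, drop = FALSE]))
    if (any(nobs < 5)) stop("need >= 5 observed cells per assessed trait", call. = FALSE)
    cv <- apply(Y[, traits, drop = FALSE], 2, stats::var, na.rm = TRUE)
    if (any(cv == 0)) stop("constant observed trait: correlation undefined", call. = FALSE)
  }
  obs <- which(!is.na(Y))
  obs_trait <- colnames(Y)[(obs - 1L) %/% n + 1L]
  if (!refit) {
    C <- phylo_vcv(tree, tip_order = rownames(Y))
    Sigma <- joint_cov(C, params$trait_cov, params$lambda)
    muvec <- rep(params$root_means, each = n)
    Soo <- Sigma[obs, obs, drop = FALSE]
    Omega <- chol2inv(chol_safe(Soo))
    res <- drop(Omega %*% (Y[obs] - muvec[obs]))
    pred <- Y[obs] - res / diag(Omega)
  } else {
    pred <- numeric(length(obs))
    for (i in seq_along(obs)) {
      Yi <- Y
      Yi[obs[i]] <- NA
      pi <- fit_phylo_mvn(as.data.frame(Yi), tree, lambda = params$lambda)
      mom <- impute_moments(as.data.frame(Yi), tree, pi)
      cell_sp <- rownames(Y)[(obs[i] - 1L) %% n + 1L]
      cell_tr <- colnames(Y)[(obs[i] - 1L) %/% n + 1L]
      pred[i] <- mom$cond_mean[mom$species == cell_sp & mom$trait == cell_tr]
    }
  }
  out <- vapply(traits, function(tr) {
    sel <- obs_trait == tr
    stats::cor(Y[obs][sel], pred[sel])
  }, numeric(1))
  names(out) <- traits
  out
}
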