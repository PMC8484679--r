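# Phylogenetic generalized least squares with maximum-likelihood Pagel's
# lambda. The estimator is authored here from the GLS normal equations;
# trees only enter through the covariance produced by phylo_vcv().

# Core GLS computation at a fixed covariance C (lambda already applied).
# Whitens through the Cholesky factor and runs OLS on the whitened system.
gls_core <- function(X, y, C, method = c("ML", "REML")) {
  method <- match.arg(method)
  X <- as.matrix(X)
  n <- length(y)
  p <- ncol(X)
  if (nrow(X) != n || nrow(C) != n || ncol(C) != n) {
    stop("dimension mismatch between X, y and C", call. = FALSE)
  }
  U <- tryCatch(chol(C), error = function(e) {
    stop("covariance matrix is singular or not positive definite", call. = FALSE)
  })
  logdetC <- 2 * sum(log(diag(U)))
  # C = U'U so the whitening operator is U^{-T}
  yw <- backsolve(U, y, transpose = TRUE)
  Xw <- backsolve(U, X, transpose = TRUE)
  qrX <- qr(Xw)
  if (qrX$rank < p) stop("design matrix is rank deficient", call. = FALSE)
  beta <- qr.coef(qrX, yw)
  resw <- yw - Xw %*% beta
  rss <- sum(resw^2)
  sigma2_ml <- rss / n
  sigma2_res <- rss / (n - p)
  XtX_inv <- chol2inv(qr.R(qrX))
  se <- sqrt(diag(XtX_inv) * sigma2_res)
  tval <- beta / se
  pval <- 2 * stats::pt(-abs(tval), df = n - p)
  loglik <- if (method == "ML") {
    -0.5 * (n * log(2 * pi) + n * log(sigma2_ml) + logdetC + n)
  } else {
    ldXX <- determinant(crossprod(Xw), logarithm = TRUE)$modulus
    -0.5 * ((n - p) * log(2 * pi) + (n - p) * log(sigma2_res) + logdetC +
              as.numeric(ldXX) + (n - p))
  }
  # R^2 against the intercept-only GLS fit in the same metric
  has_int <- any(apply(X, 2, function(col) all(col == col[1]) && col[1] != 0))
  if (has_int && p > 1) {
    onew <- backsolve(U, rep(1, n), transpose = TRUE)
    mu0 <- sum(onew * yw) / sum(onew^2)
    rss0 <- sum((yw - onew * mu0)^2)
  } else if (has_int) {
    rss0 <- rss  # intercept-only model: no explained variance
  } else {
    rss0 <- sum(yw^2)
  }
  r2 <- if (rss0 > 0) 1 - rss / rss0 else 0
  adj_r2 <- 1 - (1 - r2) * (n - 1) / (n - p)
  fitted_w <- drop(Xw %*% beta)
  list(coefficients = drop(beta), se = drop(se), t = drop(tval), p = drop(pval),
       sigma2 = sigma2_ml, sigma2_resid = sigma2_res, loglik = loglik,
       r2 = r2, adj_r2 = adj_r2, n = n, df_resid = n - p,
       residuals_whitened = drop(resw), fitted_whitened = fitted_w,
       residuals = drop(y - X %*% beta), fitted = drop(X %*% beta),
       logdetC = logdetC)
}

#' Generalized least squares fit at a fixed phylogenetic covariance
#'
#' Fits the linear model `y = X beta + e`, `e ~ N(0, sigma^2 C_lambda)`, for
#' a covariance supplied by the caller (typically
#' `lambda_transform(phylo_vcv(tree), lambda)`). Coefficients solve the GLS
#' normal equations; standard errors come from the inverse Fisher
#' information with the residual variance estimated on `n - k` degrees of
#' freedom, so on a star phylogeny (or at `lambda = 0` on an ultrametric
#' tree) the fit coincides with ordinary least squares, including t and p.
#' The Brownian rate `sigma2` is the ML estimate (divisor `n`) and enters
#' the reported log-likelihood.
#'
#' @param X Design matrix (include an intercept column explicitly).
#' @param y Response vector.
#' @param C Phylogenetic covariance over the same species, in row order.
#' @param lambda Optional lambda value to record in the fit object (the
#'   transform itself must already be applied to `C`).
#' @param method `"ML"` (default) or `"REML"` likelihood.
#' @return An object of class `pgls_fit`; see [pgls()] for the fields.
#' @export
gls_fit <- function(X, y, C, lambda = NA_real_, method = c("ML", "REML")) {
  method <- match.arg(method)
  fit <- gls_core(X, y, C, method)
  new_pgls_fit(fit, lambda = lambda, method = method,
               term_names = colnames(X), species = rownames(as.matrix(X)))
}

new_pgls_fit <- function(core, lambda, method, term_names = NULL,
                         species = NULL, formula = NULL) {
  if (is.null(term_names)) term_names <- paste0("b", seq_along(core$coefficients) - 1L)
  names(core$coefficients) <- names(core$se) <- names(core$t) <- names(core$p) <- term_names
  structure(c(core, list(lambda = lambda, method = method,
                         species = species, formula = formula)),
            class = "pgls_fit")
}

#' @export
print.pgls_fit <- function(x, ...) {
  cat("Phylogenetic GLS fit", if (!is.null(x$formula))
    paste0("(", deparse(x$formula), ")"), "\n")
  tab <- data.frame(Estimate = x$coefficients, `Std. Error` = x$se,
                    `t value` = x$t, `p value` = x$p, check.names = FALSE)
  print(round(tab, 4))
  cat(sprintf("lambda = %.4f, sigma2 = %.4g, adj R2 = %.3f, logLik = %.3f, N = %d\n",
              x$lambda, x$sigma2, x$adj_r2, x$loglik, x$n))
  invisible(x)
}

#' @export
coef.pgls_fit <- function(object, ...) object$coefficients

#' @export
logLik.pgls_fit <- function(object, ...) {
  structure(object$loglik, df = length(object$coefficients) + 2,
            class = "logLik")
}

# Profile log-likelihood in lambda: coefficients and sigma2 are profiled out
# analytically inside gls_core at each lambda.
profile_lambda <- function(X, y, C, method = "ML") {
  function(lambda) {
    gls_core(X, y, lambda_transform(C, lambda), method)$loglik
  }
}

#' PGLS with Pagel's lambda estimated by maximum likelihood
#'
#' Maximizes the profile log-likelihood over `lambda` in \[0, 1\] (bounded
#' one-dimensional search, tolerance 1e-6, coefficients and the Brownian
#' rate profiled out analytically at each lambda), compares the interior
#' optimum against both endpoints, and refits at the winner. Ties are broken
#' toward the smaller lambda.
#'
#' @param X Design matrix (intercept column included by the caller).
#' @param y Response vector.
#' @param tree A `phylo` object, or a pre-computed phylogenetic covariance
#'   matrix at `lambda = 1` whose rows match `y`.
#' @param method `"ML"` (default, matching how lambda is typically estimated
#'   in comparative analyses) or `"REML"`.
#' @return A `pgls_fit` with `lambda` set to the ML estimate.
#' @export
fit_lambda_ml <- function(X, y, tree, method = c("ML", "REML")) {
  method <- match.arg(method)
  C <- if (inherits(tree, "phylo")) phylo_vcv(tree) else as.matrix(tree)
  if (length(y) < 4L) stop("need >= 4 usable species", call. = FALSE)
  if (stats::var(y) == 0) stop("response is constant (degenerate response)", call. = FALSE)
  prof <- profile_lambda(X, y, C, method)
  opt <- stats::optimize(prof, interval = c(0, 1), maximum = TRUE, tol = 1e-6)
  cand <- c(0, opt$maximum, 1)
  ll <- c(prof(0), opt$objective, prof(1))
  best <- which(ll >= max(ll) - 1e-9)[1]  # ties toward smaller lambda
  lam <- cand[best]
  fit <- gls_core(X, y, lambda_transform(C, lam), method)
  new_pgls_fit(fit, lambda = lam, method = method, term_names = colnames(X))
}

#' Phylogenetic regression on a species trait table
#'
#' High-level interface: takes a model formula and a species-by-trait data
#' frame, drops every species with a missing value in any model variable
#' (casewise deletion, the rule that makes sample sizes vary across models),
#' prunes the covariance to the remaining species, and fits the regression
#' with ML Pagel's lambda (or at a fixed lambda).
#'
#' @param formula Model formula, e.g. `delta_I ~ gamete_size_bias`.
#' @param data Data frame with a `species` column (or species row names)
#'   matching the tree's tip labels.
#' @param tree A `phylo` object covering the table's species.
#' @param lambda `"ML"` (default) to estimate lambda, or a fixed value in
#'   \[0, 1\].
#' @param method `"ML"` or `"REML"`.
#' @return An object of class `pgls_fit`: list with `coefficients`, `se`,
#'   `t`, `p`, `lambda`, `sigma2`, `loglik`, `r2`, `adj_r2`, `n`,
#'   `df_resid`, raw and whitened `residuals`, `species` used, and the
#'   `formula`.
#' @examples
#' tr <- simulate_tree(16, seed = 1)
#' d <- simulate_traits(tr, diag(2), lambda = 1, root_means = c(0, 0), seed = 2)
#' d$species <- rownames(d)
#' names(d)[1:2] <- c("x", "y")
#' pgls(y ~ x, d, tr)
#' @export
pgls <- function(formula, data, tree, lambda = "ML", method = c("ML", "REML")) {
  method <- match.arg(method)
  data <- as.data.frame(data)
  species <- if ("species" %in% names(data)) as.character(data$species) else rownames(data)
  vars <- all.vars(formula)
  missing_vars <- setdiff(vars, names(data))
  if (length(missing_vars)) {
    stop("variable(s) not in table: ", paste(missing_vars, collapse = ", "),
         call. = FALSE)
  }
  keep <- stats::complete.cases(data[, vars, drop = FALSE])
  if (sum(keep) < 4L) {
    stop("insufficient data: fewer than 4 species with complete cases",
         call. = FALSE)
  }
  dat <- data[keep, , drop = FALSE]
  sp <- species[keep]
  mf <- stats::model.frame(formula, dat)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(formula, mf)
  C <- phylo_vcv(tree, tip_order = sp)
  fit <- if (identical(lambda, "ML")) {
    fit_lambda_ml(X, y, C, method = method)
  } else {
    gls_fit(X, y, lambda_transform(C, lambda), lambda = lambda, method = method)
  }
  fit$species <- sp
  fit$formula <- formula
  fit
}

#' Residual diagnostics for a PGLS fit
#'
#' Works on the phylogenetically whitened residuals (the quantities that are
#' i.i.d. normal when the model is correct): a Shapiro-Wilk normality test
#' and a fitted-vs-residual trend test (Pearson correlation between whitened
#' fitted values and whitened residuals). Optionally writes the two standard
#' diagnostic panels to a PNG file.
#'
#' @param fit A `pgls_fit`.
#' @param plot_file Optional path of a PNG to write.
#' @return List with `shapiro_W`, `shapiro_p`, `trend_cor`, `trend_p`, and
#'   the whitened residuals.
#' @export
diagnostics <- function(fit, plot_file = NULL) {
  stopifnot(inherits(fit, "pgls_fit"))
  r <- fit$residuals_whitened
  f <- fit$fitted_whitened
  if (all(abs(r) < 1e-12)) {
    sh <- list(statistic = c(W = 1), p.value = 1)
    tr <- list(estimate = 0, p.value = 1)
  } else {
    sh <- stats::shapiro.test(r)
    tr <- if (stats::var(f) > 0) {
      ct <- stats::cor.test(f, r)
      list(estimate = unname(ct$estimate), p.value = ct$p.value)
    } else list(estimate = 0, p.value = 1)
  }
  if (!is.null(plot_file)) {
    grDevices::png(plot_file, width = 900, height = 450)
    op <- graphics::par(mfrow = c(1, 2))
    graphics::plot(f, r, xlab = "fitted (whitened)",
                   ylab = "residual (whitened)", main = "Residuals vs fitted")
    graphics::abline(h = 0, lty = 2)
    stats::qqnorm(r); stats::qqline(r)
    graphics::par(op)
    grDevices::dev.off()
  }
  list(shapiro_W = unname(sh$statistic), shapiro_p = sh$p.value,
       trend_cor = unname(tr$estimate), trend_p = tr$p.value,
       residuals_whitened = r)
}
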