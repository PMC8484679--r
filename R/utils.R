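# internal helpers shared across modules

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards so simulation functions are pure in their seed.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic child seeds, kept inside 32-bit integer range.
derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 1009 + i * 9973) %% .Machine$integer.max)
}

check_positive <- function(x, name) {
  if (any(!is.finite(x)) || any(x <= 0)) {
    stop(sprintf("`%s` must be finite and strictly positive", name), call. = FALSE)
  }
  invisible(x)
}

# Draw one multivariate normal vector from N(mu, Sigma); Sigma may be
# singular (PSD), in which case an eigendecomposition square root is used.
rmvn1 <- function(mu, Sigma) {
  p <- length(mu)
  if (p == 0L) return(numeric(0))
  if (all(Sigma == 0)) return(mu)
  ch <- tryCatch(chol(Sigma), error = function(e) NULL)
  z <- stats::rnorm(p)
  if (!is.null(ch)) return(drop(mu + crossprod(ch, z)))
  ei <- eigen(Sigma, symmetric = TRUE)
  ev <- pmax(ei$values, 0)
  if (min(ei$values) < -1e-8 * max(abs(ei$values), 1)) {
    stop("covariance matrix is not positive semi-definite", call. = FALSE)
  }
  drop(mu + ei$vectors %*% (sqrt(ev) * z))
}

# Cholesky with a tiny-ridge fallback for numerically singular PSD blocks
# (e.g. perfectly collinear traits); errors if the matrix is genuinely
# indefinite.
chol_safe <- function(S) {
  out <- tryCatch(chol(S), error = function(e) NULL)
  if (!is.null(out)) return(out)
  ridge <- 1e-10 * mean(diag(S))
  out <- tryCatch(chol(S + diag(ridge, nrow(S))), error = function(e) NULL)
  if (is.null(out)) {
    stop("covariance block is singular: cannot condition", call. = FALSE)
  }
  out
}

# Symmetric PSD check used by input validators.
is_psd <- function(M, tol = 1e-8) {
  if (!isSymmetric(unname(M), tol = 1e-8)) return(FALSE)
  ev <- eigen((M + t(M)) / 2, symmetric = TRUE, only.values = TRUE)$values
  min(ev) >= -tol * max(abs(ev), 1)
}
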