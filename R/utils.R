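# Internal helpers: seeded evaluation, PSD checks, small linear algebra.

# Evaluate expr under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards so library code never perturbs user randomness.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  force(expr)
}

# One master seed -> k reproducible substream seeds (< 2^31), so that e.g.
# toggling measurement error does not perturb the latent draws.
derive_seeds <- function(seed, k) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, k))
}

is_psd <- function(m, tol = 1e-10) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) return(FALSE)
  if (max(abs(m - t(m))) > 1e-8 * max(1, max(abs(m)))) return(FALSE)
  ev <- eigen((m + t(m)) / 2, symmetric = TRUE, only.values = TRUE)$values
  all(ev >= -tol * max(1, abs(ev[1])))
}

stop_if_not_psd <- function(m, name) {
  if (!is_psd(m))
    stop(sprintf("'%s' must be a symmetric positive semi-definite matrix",
                 name), call. = FALSE)
  invisible(m)
}

symmetrize <- function(m) (m + t(m)) / 2

as_square_matrix <- function(x, name) {
  if (is.null(dim(x))) {
    d <- as.integer(sqrt(length(x)))
    if (length(x) == 1L) x <- matrix(x, 1L, 1L)
    else if (d * d == length(x)) x <- matrix(x, d, d)
    else stop(sprintf("'%s' cannot be interpreted as a square matrix", name),
              call. = FALSE)
  }
  if (nrow(x) != ncol(x))
    stop(sprintf("'%s' must be square", name), call. = FALSE)
  unname(as.matrix(x))
}

# Central finite-difference gradient; step scaled per coordinate.
num_gradient <- function(fn, x, h = 1e-6) {
  g <- numeric(length(x))
  for (j in seq_along(x)) {
    hj <- h * max(1, abs(x[j]))
    xp <- x; xp[j] <- xp[j] + hj
    xm <- x; xm[j] <- xm[j] - hj
    g[j] <- (fn(xp) - fn(xm)) / (2 * hj)
  }
  g
}

# Numeric Jacobian of a vector-valued function (rows = outputs).
num_jacobian <- function(fn, x, h = 1e-6) {
  f0 <- fn(x)
  J <- matrix(0, length(f0), length(x))
  for (j in seq_along(x)) {
    hj <- h * max(1, abs(x[j]))
    xp <- x; xp[j] <- xp[j] + hj
    xm <- x; xm[j] <- xm[j] - hj
    J[, j] <- (fn(xp) - fn(xm)) / (2 * hj)
  }
  J
}

# Cholesky with a tiny logged jitter fallback, for nearly singular PSD
# covariance blocks.
safe_chol <- function(S, jitter = 1e-10) {
  out <- tryCatch(chol(S), error = function(e) NULL)
  if (is.null(out)) {
    warning("covariance factorization needed a ", format(jitter),
            " diagonal jitter", call. = FALSE)
    out <- chol(S + diag(jitter * max(1, max(abs(diag(S)))), nrow(S)))
  }
  out
}
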