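# Exact generalized least squares under a fixed error covariance.

#' Generalized least squares under a known covariance
#'
#' Solves beta = (X' V^-1 X)^-1 X' V^-1 y by Cholesky whitening, with the
#' Gaussian log-likelihood profiled over the residual scale sigma^2. Standard
#' errors use the unbiased scale estimate RSS/(n - p). With `V = I` the fit
#' is ordinary least squares.
#'
#' @param X Design matrix (n x p, full rank).
#' @param y Response vector (length n).
#' @param V Positive-definite error covariance (n x n).
#' @return List with `coefficients`, `se`, `sigma2` (unbiased), `sigma2_ml`,
#'   `loglik` (ML, sigma^2 profiled), `rss` (whitened residual sum of
#'   squares), `logdet_V`, `fitted`, `residuals`, `n`, `p`, `cov_unscaled`.
#' @export
gls_fit <- function(X, y, V) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X)
  p <- ncol(X)
  if (length(y) != n) stop("X and y dimensions disagree")
  if (!all(dim(V) == c(n, n))) stop("V must be n x n")
  R <- tryCatch(chol(V),
                error = function(e) stop("V is not positive definite"))
  Xw <- backsolve(R, X, transpose = TRUE)
  yw <- backsolve(R, y, transpose = TRUE)
  if (qr(Xw)$rank < p) stop("design matrix is rank deficient")
  XtX <- crossprod(Xw)
  beta <- drop(solve(XtX, crossprod(Xw, yw)))
  names(beta) <- colnames(X)
  rw <- yw - Xw %*% beta
  rss <- sum(rw^2)
  logdet_V <- 2 * sum(log(diag(R)))
  sigma2_ml <- rss / n
  loglik <- -0.5 * (n * log(2 * pi * sigma2_ml) + logdet_V + n)
  cov_unscaled <- solve(XtX)
  sigma2 <- rss / (n - p)
  fitted <- drop(X %*% beta)
  list(
    coefficients = beta,
    se = sqrt(diag(cov_unscaled) * sigma2),
    sigma2 = sigma2,
    sigma2_ml = sigma2_ml,
    loglik = loglik,
    rss = rss,
    logdet_V = logdet_V,
    fitted = fitted,
    residuals = y - fitted,
    n = n, p = p,
    cov_unscaled = cov_unscaled
  )
}
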