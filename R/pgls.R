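# Phylogenetic generalized least squares with Pagel's lambda profiled by
# maximum likelihood. One observation per species; the error covariance is
# lambda_transform(C, lambda) scaled by sigma^2.

resolve_species <- function(data, species) {
  if (!is.null(species)) return(as.character(species))
  if (!is.null(data$species)) return(as.character(data$species))
  rn <- rownames(data)
  if (!is.null(rn) && !identical(rn, as.character(seq_len(nrow(data))))) {
    return(rn)
  }
  stop("supply species via a 'species' column, rownames, or the species arg")
}

#' Fit a phylogenetic regression with Pagel's lambda
#'
#' Generalized least squares with error covariance
#' `sigma^2 * lambda_transform(C, lambda)`. `lambda` is estimated by profiled
#' maximum likelihood over a grid on `[0, 1]` followed by local refinement
#' (ties broken toward smaller lambda), or held fixed if supplied. Confidence
#' intervals for coefficients use t quantiles on n - p degrees of freedom;
#' the lambda interval and per-term p values are likelihood-ratio based.
#'
#' @param formula Model formula evaluated in `data`.
#' @param data Data frame, one row per species.
#' @param tree Rooted `phylo` tree covering the species (alternative to `C`).
#' @param C A `phylo_covariance` or covariance matrix (alternative to `tree`).
#' @param species Character vector of species per row; defaults to a
#'   `species` column or informative rownames of `data`.
#' @param lambda `"ML"` (default) or a fixed value in `[0, 1]`.
#' @param grid_points Number of grid points for the lambda profile.
#' @return An object of class `pgls_fit`.
#' @export
fit_pgls <- function(formula, data, tree = NULL, C = NULL, species = NULL,
                     lambda = "ML", grid_points = 101) {
  if (is.null(C) && is.null(tree)) stop("supply a tree or a covariance")
  if (is.null(C)) C <- phylo_covariance(tree)
  sp <- resolve_species(data, species)
  if (anyDuplicated(sp)) stop("one observation per species is required")

  mf <- stats::model.frame(formula, data, na.action = stats::na.omit)
  dropped <- attr(mf, "na.action")
  if (!is.null(dropped)) sp <- sp[-dropped]
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  y <- stats::model.response(mf)
  n <- nrow(X)
  p <- ncol(X)
  if (n < p + 2) stop("non-identifiable: need at least p + 2 species")
  if (qr(X)$rank < p) stop("design matrix is rank deficient")

  Cm <- prune_covariance(C, sp)
  eg <- pgls_eigen(Cm, X, y)

  prof <- function(lam) pgls_profile_ll(eg, lam)$loglik
  if (identical(lambda, "ML")) {
    grid <- seq(0, 1, length.out = grid_points)
    ll <- vapply(grid, prof, numeric(1))
    i <- which.max(ll)            # first maximum: ties toward smaller lambda
    lo <- grid[max(1, i - 1)]
    hi <- grid[min(length(grid), i + 1)]
    lam_hat <- grid[i]
    if (hi > lo) {
      opt <- stats::optimize(prof, c(lo, hi), maximum = TRUE, tol = 1e-8)
      if (opt$objective > ll[i] + 1e-10) lam_hat <- opt$maximum
    }
  } else {
    if (!is.numeric(lambda) || lambda < 0 || lambda > 1) {
      stop("lambda must be 'ML' or a value in [0, 1]")
    }
    lam_hat <- lambda
  }

  at <- pgls_profile_ll(eg, lam_hat)
  lambda_ci <- if (identical(lambda, "ML")) {
    profile_interval(prof, lam_hat, at$loglik, 0, 1)
  } else c(NA_real_, NA_real_)

  se <- sqrt(diag(at$cov_unscaled) * at$sigma2)
  tq <- stats::qt(0.975, df = n - p)
  ci95 <- cbind(lower = at$beta - tq * se, upper = at$beta + tq * se)
  rownames(ci95) <- colnames(X)

  # likelihood-ratio p values: refit without each column, re-profiling lambda
  p_values <- rep(NA_real_, p)
  names(p_values) <- colnames(X)
  if (p > 1) {
    for (j in seq_len(p)) {
      eg_red <- pgls_eigen(Cm, X[, -j, drop = FALSE], y)
      prof_red <- function(lam) pgls_profile_ll(eg_red, lam)$loglik
      ll_red <- if (identical(lambda, "ML")) {
        stats::optimize(prof_red, c(0, 1), maximum = TRUE,
                        tol = 1e-8)$objective
      } else {
        prof_red(lam_hat)
      }
      lr <- max(0, 2 * (at$loglik - ll_red))
      p_values[j] <- stats::pchisq(lr, df = 1, lower.tail = FALSE)
    }
  }

  beta <- at$beta
  names(beta) <- colnames(X)
  fitted <- drop(X %*% beta)
  structure(list(
    call = match.call(),
    formula = formula,
    terms = attr(mf, "terms"),
    coefficients = beta,
    se = se,
    ci95 = ci95,
    lambda = lam_hat,
    lambda_ci = lambda_ci,
    lambda_fixed = !identical(lambda, "ML"),
    sigma2 = at$sigma2,
    loglik = at$loglik,
    p_values = p_values,
    n_obs = n,
    n_species = n,
    species = sp,
    fitted = fitted,
    residuals = y - fitted,
    transform_applied = FALSE,
    variance_components = c(total = at$sigma2),
    model = list(X = X, y = y, C = Cm)
  ), class = "pgls_fit")
}

# Eigen pre-decomposition: C is diag-scaled to a correlation-like matrix A so
# that lambda_transform(C, L) = Dg^(1/2) (L (A - I) + I) Dg^(1/2); a single
# eigendecomposition of A then gives every lambda's GLS in O(n p).
pgls_eigen <- function(Cm, X, y) {
  Dg <- diag(Cm)
  ds <- 1 / sqrt(Dg)
  A <- Cm * tcrossprod(ds)
  eg <- eigen(A, symmetric = TRUE)
  list(
    e = eg$values,
    Xs = crossprod(eg$vectors, X * ds),
    ys = drop(crossprod(eg$vectors, y * ds)),
    log_dg = sum(log(Dg)),
    n = nrow(X), p = ncol(X), colnames = colnames(X)
  )
}

pgls_profile_ll <- function(eg, lam) {
  w <- lam * (eg$e - 1) + 1
  if (any(w < 1e-12)) {
    return(list(loglik = -Inf, beta = rep(NA_real_, eg$p)))
  }
  iw <- 1 / w
  XtX <- crossprod(eg$Xs * iw, eg$Xs)
  Xty <- crossprod(eg$Xs * iw, eg$ys)
  beta <- drop(solve(XtX, Xty))
  r <- eg$ys - drop(eg$Xs %*% beta)
  rss <- sum(r^2 * iw)
  n <- eg$n
  logdet <- sum(log(w)) + eg$log_dg
  # a perfect fit has rss = 0; keep the profiled likelihood finite
  sigma2_ml <- max(rss / n, .Machine$double.xmin)
  list(
    loglik = -0.5 * (n * log(2 * pi * sigma2_ml) + logdet + n),
    beta = beta,
    sigma2 = rss / (n - eg$p),
    cov_unscaled = solve(XtX),
    rss = rss
  )
}

# Profile-likelihood interval at the chi-square(1) 95% cutoff, respecting the
# parameter's box constraints.
profile_interval <- function(prof, x_hat, ll_max, lower, upper,
                             drop = stats::qchisq(0.95, 1) / 2) {
  thr <- ll_max - drop
  f <- function(x) prof(x) - thr
  lo <- if (f(lower) >= 0) lower else {
    stats::uniroot(f, c(lower, x_hat), tol = 1e-6)$root
  }
  hi <- if (f(upper) >= 0) upper else {
    stats::uniroot(f, c(x_hat, upper), tol = 1e-6)$root
  }
  c(lo, hi)
}
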