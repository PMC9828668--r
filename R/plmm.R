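# Phylogenetic linear mixed model: y = X beta + a[species] + e, with the
# species effects a ~ N(0, sigma2_a * C) structured by the phylogeny and
# e ~ N(0, sigma2_e * I). The variance ratio gamma = sigma2_a / sigma2_e is
# profiled (REML by default); everything reduces to a single q x q
# eigendecomposition via the Woodbury identity, so repeated observations per
# species cost O(n) not O(n^3).

lmm_structure <- function(X, y, sp, Cq) {
  sp <- factor(sp)
  sp <- droplevels(sp)
  q <- nlevels(sp)
  Cq <- Cq[levels(sp), levels(sp), drop = FALSE]
  m <- as.numeric(table(sp))
  G <- Cq * tcrossprod(sqrt(m))
  eg <- eigen(G, symmetric = TRUE)
  e <- pmax(eg$values, 0)
  ZtX <- rowsum(X, sp)               # q x p, ordered by levels(sp)
  Zty <- drop(rowsum(matrix(y), sp))
  sm <- 1 / sqrt(m)
  S <- crossprod(eg$vectors, ZtX * sm)
  s_y <- drop(crossprod(eg$vectors, Zty * sm))
  list(
    XtX = crossprod(X), Xty = drop(crossprod(X, y)), yty = sum(y^2),
    S = S, s_y = s_y, e = e,
    n = nrow(X), p = ncol(X), q = q,
    colnames = colnames(X), levels = levels(sp), sp = sp,
    hbar = mean(diag(Cq))
  )
}

lmm_eval <- function(st, gamma, reml = TRUE) {
  k <- if (gamma == 0) rep(0, st$q) else gamma * st$e / (1 + gamma * st$e)
  XWX <- st$XtX - crossprod(st$S * k, st$S)
  XWy <- st$Xty - drop(crossprod(st$S, k * st$s_y))
  yWy <- st$yty - sum(k * st$s_y^2)
  beta <- tryCatch(drop(solve(XWX, XWy)), error = function(e) NULL)
  if (is.null(beta)) return(list(loglik = -Inf))
  rss <- max(yWy - sum(beta * XWy), 0)
  logdet_W <- sum(log1p(gamma * st$e))
  n <- st$n; p <- st$p
  rss <- max(rss, .Machine$double.xmin)   # keep a perfect fit finite
  if (reml) {
    sigma2 <- rss / (n - p)
    ld_XWX <- determinant(XWX, logarithm = TRUE)$modulus
    ll <- -0.5 * ((n - p) * log(2 * pi * sigma2) + logdet_W +
                    as.numeric(ld_XWX) + (n - p))
  } else {
    sigma2 <- rss / n
    ll <- -0.5 * (n * log(2 * pi * sigma2) + logdet_W + n)
  }
  list(loglik = ll, beta = beta, sigma2 = sigma2, rss = rss,
       XWX = XWX, logdet_W = logdet_W)
}

lmm_optimize <- function(st, reml = TRUE) {
  obj <- function(theta) lmm_eval(st, exp(theta), reml)$loglik
  grid <- seq(-14, 14, length.out = 29)
  ll <- vapply(grid, obj, numeric(1))
  ll0 <- lmm_eval(st, 0, reml)$loglik
  if (all(!is.finite(c(ll, ll0)))) {
    stop("mixed model fit failed: likelihood not finite")
  }
  i <- which.max(ll)
  lo <- grid[max(1, i - 1)]
  hi <- grid[min(length(grid), i + 1)]
  opt <- stats::optimize(obj, c(lo, hi), maximum = TRUE, tol = 1e-7)
  gamma <- exp(opt$maximum)
  best <- opt$objective
  if (ll0 >= best) {
    gamma <- 0
    best <- ll0
  }
  list(gamma = gamma, loglik = best)
}

#' Fit a phylogenetic linear mixed model
#'
#' Repeated observations per species are modelled with a species-level random
#' intercept whose covariance follows the phylogeny (`sigma2_a * C`) on top of
#' independent residuals (`sigma2_e * I`). The variance ratio is profiled by
#' REML (default); fixed-effect p values come from ML likelihood-ratio tests.
#' The phylogenetic signal is reported as the variance proportion
#' `lambda = sigma2_a * hbar / (sigma2_a * hbar + sigma2_e)`, where `hbar` is
#' the mean diagonal of `C` (1 for a unit-height ultrametric tree), with a
#' profile-likelihood interval.
#'
#' @param formula Model formula evaluated in `data`.
#' @param data Data frame of observations (several rows per species allowed).
#' @param species Character/factor of species per observation; defaults to a
#'   `species` column of `data`.
#' @param tree,C Phylogeny or species covariance (as in [fit_pgls()]).
#' @param reml Use REML (default) or ML for the variance profile.
#' @return An object of class `phylo_lmm`.
#' @export
fit_phylo_lmm <- function(formula, data, species = NULL, tree = NULL,
                          C = NULL, reml = TRUE) {
  if (is.null(C) && is.null(tree)) stop("supply a tree or a covariance")
  if (is.null(C)) C <- phylo_covariance(tree)
  sp <- if (is.null(species)) {
    if (is.null(data$species)) stop("supply species per observation")
    as.character(data$species)
  } else as.character(species)

  mf <- stats::model.frame(formula, data, na.action = stats::na.omit)
  dropped <- attr(mf, "na.action")
  if (!is.null(dropped)) sp <- sp[-dropped]
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  y <- stats::model.response(mf)
  if (length(unique(sp)) < 3) stop("need at least 3 species")
  Cq <- prune_covariance(C, sort(unique(sp)))

  st <- lmm_structure(X, y, sp, Cq)
  opt <- lmm_optimize(st, reml = reml)
  at <- lmm_eval(st, opt$gamma, reml = reml)
  ml_ll <- if (reml) lmm_optimize(st, reml = FALSE)$loglik else opt$loglik

  sigma2_e <- at$sigma2
  sigma2_a <- opt$gamma * sigma2_e
  hbar <- st$hbar
  lam_of <- function(g) g * hbar / (g * hbar + 1)
  lambda <- lam_of(opt$gamma)

  prof <- function(lam) {
    g <- lam / (hbar * (1 - lam))
    lmm_eval(st, g, reml = reml)$loglik
  }
  lam_hi_cap <- lam_of(exp(16))
  lambda_ci <- profile_interval(prof, min(lambda, lam_hi_cap), opt$loglik,
                                0, lam_hi_cap)
  lambda_ci[2] <- min(lambda_ci[2], 1)

  beta <- at$beta
  names(beta) <- st$colnames
  cov_b <- solve(at$XWX) * sigma2_e
  se <- sqrt(diag(cov_b))
  df <- max(st$q - st$p, 3)
  tq <- stats::qt(0.975, df = df)
  ci95 <- cbind(lower = beta - tq * se, upper = beta + tq * se)

  p_values <- rep(NA_real_, st$p)
  names(p_values) <- st$colnames
  if (st$p > 1) {
    for (j in seq_len(st$p)) {
      st_red <- lmm_structure(X[, -j, drop = FALSE], y, sp, Cq)
      ll_red <- lmm_optimize(st_red, reml = FALSE)$loglik
      lr <- max(0, 2 * (ml_ll - ll_red))
      p_values[j] <- stats::pchisq(lr, df = 1, lower.tail = FALSE)
    }
  }

  fitted <- drop(X %*% beta)
  structure(list(
    call = match.call(),
    formula = formula,
    terms = attr(mf, "terms"),
    coefficients = beta,
    se = se,
    ci95 = ci95,
    lambda = lambda,
    lambda_ci = lambda_ci,
    gamma = opt$gamma,
    variance_components = c(phylogenetic = sigma2_a, residual = sigma2_e),
    sigma2 = sigma2_e,
    loglik = opt$loglik,
    loglik_ml = ml_ll,
    reml = reml,
    p_values = p_values,
    n_obs = st$n,
    n_species = st$q,
    df = df,
    species = sp,
    fitted = fitted,
    residuals = y - fitted,
    transform_applied = FALSE,
    model = list(X = X, y = y, Cq = Cq)
  ), class = "phylo_lmm")
}

#' Keep or drop an interaction by likelihood ratio
#'
#' Compares a full model containing an interaction with its nested reduction
#' using an ML likelihood-ratio test and returns the full model if the
#' interaction is significant at `alpha`, otherwise the reduced model. The
#' test result is attached as attribute `"interaction_test"`.
#'
#' @param fit_full,fit_reduced Fitted `phylo_lmm` or `pgls_fit` objects; the
#'   reduced model must be nested in the full one.
#' @param alpha Two-sided significance threshold (default 0.05).
#' @return The chosen fit.
#' @export
drop_nonsignificant_interaction <- function(fit_full, fit_reduced,
                                            alpha = 0.05) {
  tf <- colnames(fit_full$model$X)
  tr <- colnames(fit_reduced$model$X)
  if (!all(tr %in% tf) || length(tr) >= length(tf)) {
    stop("models are not nested")
  }
  llf <- if (!is.null(fit_full$loglik_ml)) fit_full$loglik_ml
         else fit_full$loglik
  llr <- if (!is.null(fit_reduced$loglik_ml)) fit_reduced$loglik_ml
         else fit_reduced$loglik
  df <- length(tf) - length(tr)
  lr <- max(0, 2 * (llf - llr))
  p <- stats::pchisq(lr, df = df, lower.tail = FALSE)
  keep_full <- p < alpha
  chosen <- if (keep_full) fit_full else fit_reduced
  attr(chosen, "interaction_test") <- list(
    lr = lr, df = df, p_value = p, interaction_kept = keep_full
  )
  chosen
}
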