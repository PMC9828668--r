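# Repeatability (intraclass correlation) of repeated width measurements,
# estimated with a linear mixed model: measurement point as a random effect,
# measurement kind as a fixed effect.

#' Repeatability of repeated measurements
#'
#' Fits `value = kind + (1 | point) + e` by REML (through the same profiled
#' mixed-model machinery as [fit_phylo_lmm()], with an identity covariance
#' over points) and reports the intraclass correlation
#' `R = sigma2_point / (sigma2_point + sigma2_resid)` with a parametric
#' bootstrap confidence interval.
#'
#' @param values Numeric measurements.
#' @param point_id Identifier of the measured point for each value.
#' @param kind Optional measurement-kind label, entered as a fixed effect.
#' @param nboot Parametric bootstrap draws for the CI (default 1000).
#' @param conf Confidence level (default 0.95).
#' @param seed Optional integer seed for the bootstrap.
#' @return An object of class `repeatability_fit` with `R`, `ci`,
#'   `variance_components`, `n_points`, `n_obs`.
#' @export
repeatability <- function(values, point_id, kind = NULL, nboot = 1000,
                          conf = 0.95, seed = NULL) {
  y <- as.numeric(values)
  pt <- factor(point_id)
  if (nlevels(pt) < 2) stop("degenerate grouping: need >= 2 points")
  if (any(table(pt) < 2)) stop("every point needs >= 2 repeats")
  if (length(y) != length(pt)) stop("values and point_id lengths differ")

  X <- if (!is.null(kind) && length(unique(kind)) > 1) {
    stats::model.matrix(~ factor(kind))
  } else {
    matrix(1, length(y), 1, dimnames = list(NULL, "(Intercept)"))
  }

  q <- nlevels(pt)
  Cq <- diag(q)
  dimnames(Cq) <- list(levels(pt), levels(pt))

  fit1 <- repeatability_core(X, y, pt, Cq)
  if (!is.null(seed)) set.seed(seed)
  boot <- rep(NA_real_, nboot)
  if (nboot > 0 && fit1$R < 1) {
    sa <- sqrt(fit1$variance_components[["point"]])
    se_ <- sqrt(fit1$variance_components[["residual"]])
    mu <- drop(X %*% fit1$beta)
    idx <- as.integer(pt)
    for (b in seq_len(nboot)) {
      a <- stats::rnorm(q, 0, sa)
      ystar <- mu + a[idx] + stats::rnorm(length(y), 0, se_)
      boot[b] <- repeatability_core(X, ystar, pt, Cq)$R
    }
  } else if (nboot > 0) {
    boot[] <- 1
  }
  alpha <- (1 - conf) / 2
  ci <- if (nboot > 0) {
    unname(stats::quantile(boot, c(alpha, 1 - alpha), na.rm = TRUE))
  } else c(NA_real_, NA_real_)

  structure(list(
    R = fit1$R,
    ci = ci,
    conf = conf,
    variance_components = fit1$variance_components,
    coefficients = fit1$beta,
    n_points = q,
    n_obs = length(y),
    nboot = nboot
  ), class = "repeatability_fit")
}

repeatability_core <- function(X, y, pt, Cq) {
  # exact-repeat degenerate case: residuals vanish, R = 1 by definition
  gm <- stats::lm.fit(cbind(X, stats::model.matrix(~ 0 + pt)), y)
  scale_y <- max(stats::sd(y), .Machine$double.eps)
  if (sqrt(sum(gm$residuals^2) / length(y)) < 1e-10 * scale_y) {
    p_eff <- ncol(X)
    beta <- gm$coefficients[seq_len(p_eff)]
    return(list(R = 1,
                variance_components = c(point = stats::var(y), residual = 0),
                beta = beta))
  }
  st <- lmm_structure(X, y, pt, Cq)
  opt <- lmm_optimize(st, reml = TRUE)
  at <- lmm_eval(st, opt$gamma, reml = TRUE)
  s2e <- at$sigma2
  s2a <- opt$gamma * s2e
  list(R = s2a / (s2a + s2e),
       variance_components = c(point = s2a, residual = s2e),
       beta = at$beta)
}

#' @export
print.repeatability_fit <- function(x, ...) {
  cat("<repeatability_fit>\n")
  cat(sprintf("  R = %.4f  (%d%% parametric-bootstrap CI %.4f-%.4f)\n",
              x$R, round(100 * x$conf), x$ci[1], x$ci[2]))
  cat(sprintf("  variance: point %.4g, residual %.4g;  %d points, %d obs\n",
              x$variance_components[["point"]],
              x$variance_components[["residual"]], x$n_points, x$n_obs))
  invisible(x)
}
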