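# S3 methods shared by the fitted-model classes.

fit_kind <- function(x) {
  if (inherits(x, "pgls_fit")) "Phylogenetic GLS (Pagel's lambda)"
  else "Phylogenetic linear mixed model"
}

#' @export
print.pgls_fit <- function(x, ...) {
  cat("<", class(x)[1], "> ", fit_kind(x), "\n", sep = "")
  cat("  ", deparse(x$formula), "\n", sep = "")
  print(round(x$coefficients, 4))
  cat(sprintf("  lambda = %.3f [%.3f, %.3f], logLik = %.2f, n = %d\n",
              x$lambda, x$lambda_ci[1], x$lambda_ci[2], x$loglik, x$n_obs))
  invisible(x)
}

#' @export
print.phylo_lmm <- function(x, ...) {
  print.pgls_fit(x, ...)
}

summary_table <- function(x) {
  data.frame(
    term = names(x$coefficients),
    estimate = unname(x$coefficients),
    se = unname(x$se),
    ci_lower = unname(x$ci95[, 1]),
    ci_upper = unname(x$ci95[, 2]),
    p_value = unname(x$p_values),
    row.names = NULL
  )
}

#' @export
summary.pgls_fit <- function(object, ...) {
  out <- list(
    kind = fit_kind(object),
    formula = object$formula,
    table = summary_table(object),
    lambda = object$lambda,
    lambda_ci = object$lambda_ci,
    variance_components = object$variance_components,
    loglik = object$loglik,
    n_obs = object$n_obs,
    n_species = object$n_species,
    transform_applied = object$transform_applied
  )
  class(out) <- "summary.pgls_fit"
  out
}

#' @export
summary.phylo_lmm <- summary.pgls_fit

#' @export
print.summary.pgls_fit <- function(x, ...) {
  cat(x$kind, "\n")
  cat("  ", deparse(x$formula), "\n", sep = "")
  print(x$table, digits = 4)
  cat(sprintf("lambda = %.3f [%.3f, %.3f]\n",
              x$lambda, x$lambda_ci[1], x$lambda_ci[2]))
  cat("variance components:",
      paste(names(x$variance_components),
            signif(x$variance_components, 4), sep = " = ", collapse = ", "),
      "\n")
  cat(sprintf("logLik = %.3f, n_obs = %d, n_species = %d%s\n",
              x$loglik, x$n_obs, x$n_species,
              if (isTRUE(x$transform_applied)) ", response log-transformed"
              else ""))
  invisible(x)
}

#' @export
coef.pgls_fit <- function(object, ...) object$coefficients
#' @export
coef.phylo_lmm <- function(object, ...) object$coefficients

#' @export
confint.pgls_fit <- function(object, parm, level = 0.95, ...) {
  ci <- object$ci95
  if (level != 0.95) {
    tq <- stats::qt(1 - (1 - level) / 2,
                    df = if (!is.null(object$df)) object$df
                         else object$n_obs - length(object$coefficients))
    ci <- cbind(object$coefficients - tq * object$se,
                object$coefficients + tq * object$se)
    dimnames(ci) <- dimnames(object$ci95)
  }
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}
#' @export
confint.phylo_lmm <- confint.pgls_fit

#' @export
logLik.pgls_fit <- function(object, ...) {
  structure(object$loglik, df = length(object$coefficients) + 2,
            nobs = object$n_obs, class = "logLik")
}
#' @export
logLik.phylo_lmm <- function(object, ...) {
  structure(object$loglik, df = length(object$coefficients) + 3,
            nobs = object$n_obs, class = "logLik")
}

#' @export
residuals.pgls_fit <- function(object, ...) object$residuals
#' @export
residuals.phylo_lmm <- function(object, ...) object$residuals

#' @export
fitted.pgls_fit <- function(object, ...) object$fitted
#' @export
fitted.phylo_lmm <- function(object, ...) object$fitted

#' @export
predict.pgls_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  tt <- stats::delete.response(object$terms)
  mf <- stats::model.frame(tt, newdata)
  X <- stats::model.matrix(tt, mf)
  drop(X %*% object$coefficients)
}
#' @export
predict.phylo_lmm <- predict.pgls_fit

#' @export
plot.pgls_fit <- function(x, ...) {
  graphics::plot(x$fitted, x$residuals,
                 xlab = "Fitted values", ylab = "Residuals",
                 main = fit_kind(x), ...)
  graphics::abline(h = 0, lty = 2)
  invisible(x)
}
#' @export
plot.phylo_lmm <- plot.pgls_fit
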