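# S3 methods for the fitted-effect objects.

#' @export
print.vt_effect_fit <- function(x, ...) {
  cat(sprintf("<vt_effect_fit> beta_%s = %.4g (se %.3g, p = %.3g, %g%% CI [%.4g, %.4g]), n = %d%s\n",
              x$term, x$beta, x$se, x$p, 100 * (1 - x$alpha),
              x$ci[1], x$ci[2], x$n,
              if (isTRUE(x$collinear)) " [collinear]" else ""))
  invisible(x)
}

#' @export
coef.vt_effect_fit <- function(object, ...) {
  c(`(Intercept)` = object$beta0, object$coefficients)
}

#' @export
confint.vt_effect_fit <- function(object, parm, level = 0.95, ...) {
  if (!missing(level) && abs(level - (1 - object$alpha)) > 1e-12)
    stop("CI stored at level ", 1 - object$alpha, "; refit to change it")
  m <- matrix(object$ci, nrow = 1,
              dimnames = list(object$term,
                              paste0(100 * c(object$alpha / 2,
                                             1 - object$alpha / 2), " %")))
  m
}

#' @export
summary.vt_effect_fit <- function(object, ...) {
  out <- data.frame(term = object$term, estimate = object$beta,
                    std_error = object$se, p_value = object$p,
                    ci_lo = object$ci[1], ci_hi = object$ci[2],
                    n = object$n)
  class(out) <- c("summary.vt_effect_fit", "data.frame")
  out
}

#' @export
residuals.vt_effect_fit <- function(object, ...) object$residuals

#' @export
coef.vt_interannual_fit <- function(object, ...) {
  c(ndvi = object$beta_ndvi, p = object$beta_p, rs = object$beta_rs)
}
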