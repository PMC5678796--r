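## GLM fit + large-sample Wald z test of no genetic association.

fit_result <- function(beta_hat, se, z, p_value, converged) {
  structure(list(beta_hat = beta_hat, se = se, z = z, p_value = p_value,
                 converged = converged), class = "fit_result")
}

fit_nonconverged <- function() {
  fit_result(NA_real_, NA_real_, NA_real_, NA_real_, FALSE)
}

#' Fit the single-SNP generalized linear model
#'
#' Intercept-plus-genotype maximum-likelihood fit: logistic regression for a
#' binary outcome, ordinary least squares for a continuous one. The standard
#' error comes from the observed information at the MLE (the usual
#' `summary.glm` covariance). Convergence policy: at most 25 IRLS iterations;
#' a fit is flagged non-converged when the design is rank-deficient (e.g. a
#' monomorphic genotype or constant outcome), estimates are non-finite, or
#' the slope SE exceeds 100 on the link scale (the signature of complete
#' separation). Non-converged fits carry NA estimates and are never treated
#' as detections by [wald_test()].
#'
#' @param g_coded genotype covariate vector (analysis-model coding).
#' @param outcome outcome vector; must be 0/1 for the logistic family.
#' @param family `"logistic"` or `"gaussian"`.
#' @return a `fit_result`: `beta_hat` (log-OR for logistic, mean shift for
#'   gaussian), `se`, `z = beta_hat / se`, two-sided normal `p_value`, and a
#'   `converged` flag.
#' @examples
#' g <- rep(c(0, 1), each = 100)
#' y <- rep(c(0, 1, 0, 1), c(90, 10, 70, 30))
#' fit_glm(g, y, "logistic")$beta_hat # log((30/70)/(10/90))
#' @export
fit_glm <- function(g_coded, outcome, family = c("logistic", "gaussian")) {
  family <- match.arg(family)
  n <- length(g_coded)
  if (length(outcome) != n) {
    stop("`g_coded` and `outcome` must have equal length", call. = FALSE)
  }
  if (n < 2L) stop("need at least 2 observations", call. = FALSE)
  if (family == "logistic" && !all(outcome %in% c(0, 1))) {
    stop("logistic family requires a 0/1 outcome", call. = FALSE)
  }
  # unidentifiable slope or degenerate outcome: report non-convergence
  if (!all(is.finite(g_coded)) || var(g_coded) == 0 || var(outcome) == 0) {
    return(fit_nonconverged())
  }
  x <- cbind(1, g_coded)

  if (family == "logistic") {
    fit <- suppressWarnings(glm.fit(
      x, outcome, family = binomial(),
      control = glm.control(epsilon = 1e-10, maxit = 25L)
    ))
    if (fit$rank < 2L) return(fit_nonconverged())
    p1 <- seq_len(fit$rank)
    cov_unscaled <- chol2inv(fit$qr$qr[p1, p1, drop = FALSE])
    beta_hat <- unname(fit$coefficients[2L])
    se <- sqrt(cov_unscaled[2L, 2L])
    converged <- isTRUE(fit$converged) && is.finite(beta_hat) &&
      is.finite(se) && se < 100
  } else {
    fit <- lm.fit(x, outcome)
    if (fit$rank < 2L || any(fit$qr$pivot != seq_len(2L))) {
      return(fit_nonconverged())
    }
    sigma2 <- sum(fit$residuals^2) / (n - 2L)
    xtx_inv <- chol2inv(fit$qr$qr[1:2, 1:2, drop = FALSE])
    beta_hat <- unname(fit$coefficients[2L])
    se <- sqrt(sigma2 * xtx_inv[2L, 2L])
    converged <- is.finite(beta_hat) && is.finite(se)
  }

  if (!converged) {
    return(fit_result(beta_hat, se, NA_real_, NA_real_, FALSE))
  }
  z <- if (se == 0) {
    if (beta_hat == 0) 0 else sign(beta_hat) * Inf
  } else {
    beta_hat / se
  }
  fit_result(beta_hat, se, z, 2 * pnorm(-abs(z)), TRUE)
}

#' Wald z test of no genetic association
#'
#' Two-sided large-sample z test on the genotype coefficient: the effect is
#' detected when the fit converged and `p_value < alpha` (strict). A
#' non-converged fit is never a detection.
#'
#' @param fit a `fit_result` from [fit_glm()].
#' @param alpha significance level in (0, 1).
#' @return `TRUE` if the association is detected.
#' @export
wald_test <- function(fit, alpha = 0.05) {
  stopifnot(inherits(fit, "fit_result"),
            length(alpha) == 1L, alpha > 0, alpha < 1)
  isTRUE(fit$converged) && is.finite(fit$p_value) && fit$p_value < alpha
}

#' @export
print.fit_result <- function(x, ...) {
  if (!isTRUE(x$converged)) {
    cat("<fit_result> non-converged\n")
  } else {
    cat(sprintf("<fit_result> beta = %.5f (SE %.5f), z = %.3f, p = %.4g\n",
                x$beta_hat, x$se, x$z, x$p_value))
  }
  invisible(x)
}
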