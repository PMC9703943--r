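#' Multivariable MR: direct effects of several exposures
#'
#' Regresses variant-outcome effects on the matrix of variant-exposure
#' effects by weighted least squares without intercept, weights
#' \eqn{1/se_{out}^2} (fixed-effect two-sample MVMR). Standard errors come
#' from the weighted normal equations \eqn{(X'WX)^{-1}}, so with a single
#' exposure the fit reduces exactly to the fixed-effect IVW estimate.
#'
#' Instrument strength is summarized per exposure by the unconditional F
#' (mean squared z of the variant-exposure effects) and by a conditional F
#' computed with [conditional_f()], which measures the instrument signal
#' in one exposure not explained by its associations with the others. A
#' conditional F below ~5 marks an exposure whose direct effect is weakly
#' identified.
#'
#' @param exposure_betas L x K matrix of variant effects on the K
#'   exposures (column names name the exposures).
#' @param exposure_ses L x K matrix of their standard errors.
#' @param outcome_beta,outcome_se Length-L vectors of variant-outcome
#'   effects and SEs.
#' @param exposures Optional exposure names (default: column names).
#' @param outcome Outcome label.
#' @param condition_tol Reciprocal-condition-number threshold below which
#'   the exposure matrix is declared collinear (default 1e-10).
#' @return Object of class `mvmr_result`: `beta`, `se`, `pval` (per
#'   exposure), `conditional_f`, `unconditional_f`, `n_snps`.
#' @export
mvmr_fit <- function(exposure_betas, exposure_ses, outcome_beta,
                     outcome_se, exposures = colnames(exposure_betas),
                     outcome = "outcome", condition_tol = 1e-10) {
  X <- as.matrix(exposure_betas)
  S <- as.matrix(exposure_ses)
  L <- nrow(X); K <- ncol(X)
  if (is.null(exposures)) exposures <- paste0("exposure", seq_len(K))
  if (L <= K)
    stop_ratiomr("need more variants than exposures", "ratiomr_config_error")
  if (length(outcome_beta) != L || length(outcome_se) != L ||
        any(outcome_se <= 0))
    stop_ratiomr("outcome beta/se mismatch", "ratiomr_config_error")
  w <- 1 / outcome_se^2
  Xw <- X * sqrt(w)
  sv <- svd(Xw, nu = 0, nv = 0)$d
  if (sv[length(sv)] / sv[1L] < sqrt(condition_tol))
    stop_ratiomr("exposure effect matrix is (near-)rank-deficient",
                 "ratiomr_rank_error")
  XtWX <- crossprod(Xw)
  XtWy <- crossprod(X * w, outcome_beta)
  V <- solve(XtWX)
  beta <- drop(V %*% XtWy)
  se <- sqrt(diag(V))
  names(beta) <- names(se) <- exposures
  cf <- vapply(seq_len(K), function(k)
    conditional_f(X, S, k), numeric(1))
  uf <- colMeans((X / S)^2)
  names(cf) <- names(uf) <- exposures
  structure(list(beta = beta, se = se,
                 pval = 2 * stats::pnorm(-abs(beta / se)),
                 conditional_f = cf, unconditional_f = uf,
                 n_snps = L, exposures = exposures, outcome = outcome),
            class = "mvmr_result")
}

#' Conditional F statistic for one exposure in MVMR
#'
#' Regresses exposure `k`'s variant effects on the other exposures'
#' variant effects (weights \eqn{1/se_{x_k}^2}, no intercept) and forms
#' \eqn{F_{cond} = Q/(L-1)} with
#' \eqn{Q = \sum_i w_i (\beta_{x_k,i} - \hat\beta_{x_k,i})^2}, the
#' weighted residual sum of squares, and L the variant count. With
#' orthogonal (e.g. all-zero) co-exposure effects no signal is removed and
#' the statistic matches the unconditional scale; with proportional
#' effects it collapses to ~0. Cross-exposure sampling covariance is
#' assumed zero (separate samples).
#'
#' @inheritParams mvmr_fit
#' @param k Index of the exposure of interest.
#' @return Conditional F value.
#' @export
conditional_f <- function(exposure_betas, exposure_ses, k) {
  X <- as.matrix(exposure_betas)
  S <- as.matrix(exposure_ses)
  L <- nrow(X)
  if (L < 2L) stop_ratiomr("need >= 2 variants", "ratiomr_config_error")
  bk <- X[, k]
  wk <- 1 / S[, k]^2
  Xo <- X[, -k, drop = FALSE]
  sw <- sqrt(wk)
  qr_o <- qr(Xo * sw)
  fitted <- if (qr_o$rank == 0L) {
    rep(0, L)
  } else {
    drop(qr.fitted(qr_o, bk * sw)) / sw
  }
  Q <- sum(wk * (bk - fitted)^2)
  Q / (L - 1)
}

#' @export
print.mvmr_result <- function(x, ...) {
  cat(sprintf("Multivariable MR: %d exposures, %d variants -> %s\n",
              length(x$beta), x$n_snps, x$outcome))
  print(summary(x), row.names = FALSE)
  invisible(x)
}

#' @export
summary.mvmr_result <- function(object, ...) {
  data.frame(exposure = object$exposures, beta = object$beta,
             se = object$se, pval = object$pval,
             conditional_f = object$conditional_f,
             unconditional_f = object$unconditional_f,
             weak = object$conditional_f < 5,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' @export
coef.mvmr_result <- function(object, ...) object$beta

#' @export
confint.mvmr_result <- function(object, parm, level = 0.95, ...) {
  q <- stats::qnorm(1 - (1 - level) / 2)
  m <- cbind(object$beta - q * object$se, object$beta + q * object$se)
  colnames(m) <- sprintf("%g %%", c((1 - level) / 2,
                                    1 - (1 - level) / 2) * 100)
  m
}
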