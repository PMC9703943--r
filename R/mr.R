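#' Construct an MR result object
#'
#' @keywords internal
new_mr_result <- function(exposure, outcome, beta, se, method, n_snps,
                          binary_outcome) {
  z <- if (se > 0) beta / se else if (beta == 0) 0 else Inf
  pval <- 2 * stats::pnorm(-abs(z))
  res <- list(exposure = exposure, outcome = outcome,
              beta = beta, se = se, pval = pval, method = method,
              n_snps = n_snps, binary_outcome = isTRUE(binary_outcome))
  if (res$binary_outcome) {
    res$or <- exp(beta)
    res$or_low <- exp(beta - 1.96 * se)
    res$or_high <- exp(beta + 1.96 * se)
  }
  class(res) <- "mr_result"
  res
}

#' Wald-ratio causal estimate from a single instrument
#'
#' For a harmonized exposure/outcome pair sharing one instrument variant,
#' the causal effect per SD-unit increase in the exposure is
#' \eqn{\beta_{MR} = \beta_y / \beta_x} with standard error
#' \eqn{SE_{MR} = SE_y / |\beta_x|} (the absolute value keeps the SE
#' positive when the exposure effect is negative). For binary outcomes the
#' estimate is a log odds ratio and 95% CI bounds on the OR scale are
#' reported.
#'
#' @param exposure,outcome One-row summary-statistics `data.frame`s for
#'   the same variant, harmonized with [harmonize_pair()].
#' @param binary_outcome Is the outcome binary (log-odds betas)? Default:
#'   inferred from a non-missing `n_cases` in the outcome record.
#' @return Object of class `mr_result` with [coef()], [confint()],
#'   [print()] and [summary()] methods.
#' @export
wald_ratio <- function(exposure, outcome,
                       binary_outcome = !is.na(outcome$n_cases)) {
  stopifnot(nrow(exposure) == 1L, nrow(outcome) == 1L)
  if (exposure$variant_id != outcome$variant_id)
    stop_ratiomr("exposure and outcome records are for different variants",
                 "ratiomr_harmonization_error")
  if (exposure$beta == 0)
    stop_ratiomr("Wald ratio undefined: exposure beta is zero",
                 "ratiomr_undefined_ratio")
  beta <- outcome$beta / exposure$beta
  se <- outcome$se / abs(exposure$beta)
  new_mr_result(exposure$trait_id, outcome$trait_id, beta, se,
                method = "wald", n_snps = 1L,
                binary_outcome = binary_outcome)
}

#' Fixed-effect inverse-variance-weighted meta-analysis
#'
#' Pools estimates with weights \eqn{w_i = 1/se_i^2}:
#' \eqn{\beta = \sum w_i \beta_i / \sum w_i},
#' \eqn{se = (\sum w_i)^{-1/2}}. Used both for cross-cohort pooling of
#' SNP-outcome associations and for combining per-variant Wald ratios.
#'
#' @param beta,se Numeric vectors of estimates and positive SEs.
#' @return List with `beta`, `se`, `pval`.
#' @export
ivw_meta <- function(beta, se) {
  if (length(beta) == 0L)
    stop_ratiomr("no estimates to pool", "ratiomr_config_error")
  if (length(beta) != length(se) || any(se <= 0))
    stop_ratiomr("each estimate needs a positive SE",
                 "ratiomr_config_error")
  w <- 1 / se^2
  b <- sum(w * beta) / sum(w)
  s <- 1 / sqrt(sum(w))
  list(beta = b, se = s, pval = 2 * stats::pnorm(-abs(b / s)))
}

#' Multi-SNP inverse-variance-weighted MR
#'
#' Per-variant Wald ratios pooled by fixed-effect IVW (weights
#' \eqn{(\beta_{x,i}/SE_{y,i})^2}), for exposures instrumented by several
#' independent variants (e.g. positive-control risk factors).
#'
#' @param exposure,outcome Summary-statistics `data.frame`s over the same
#'   independent instrument variants, harmonized.
#' @inheritParams wald_ratio
#' @return Object of class `mr_result` (`method = "ivw_multi"`).
#' @export
ivw_multi_snp <- function(exposure, outcome,
                          binary_outcome = !all(is.na(outcome$n_cases))) {
  if (nrow(exposure) < 2L)
    stop_ratiomr("fewer than 2 variants: use wald_ratio()",
                 "ratiomr_config_error")
  m <- match(exposure$variant_id, outcome$variant_id)
  if (anyNA(m))
    stop_ratiomr("outcome records missing for some instrument variants",
                 "ratiomr_harmonization_error")
  outcome <- outcome[m, , drop = FALSE]
  if (any(exposure$beta == 0))
    stop_ratiomr("Wald ratio undefined: exposure beta is zero",
                 "ratiomr_undefined_ratio")
  b_i <- outcome$beta / exposure$beta
  s_i <- outcome$se / abs(exposure$beta)
  pooled <- ivw_meta(b_i, s_i)
  new_mr_result(exposure$trait_id[1L], outcome$trait_id[1L],
                pooled$beta, pooled$se, method = "ivw_multi",
                n_snps = nrow(exposure), binary_outcome = binary_outcome)
}

#' @export
print.mr_result <- function(x, ...) {
  cat(sprintf("MR (%s): %s -> %s [%d SNP%s]\n", x$method, x$exposure,
              x$outcome, x$n_snps, ifelse(x$n_snps > 1, "s", "")))
  if (x$binary_outcome)
    cat(sprintf("  OR %.3f (95%% CI %.3f-%.3f) per SD, p = %.3g\n",
                x$or, x$or_low, x$or_high, x$pval))
  else
    cat(sprintf("  beta %.4f (SE %.4f) per SD, p = %.3g\n",
                x$beta, x$se, x$pval))
  invisible(x)
}

#' @export
coef.mr_result <- function(object, ...) {
  stats::setNames(object$beta, paste0(object$exposure, "->", object$outcome))
}

#' @export
confint.mr_result <- function(object, parm, level = 0.95, ...) {
  q <- stats::qnorm(1 - (1 - level) / 2)
  m <- matrix(c(object$beta - q * object$se, object$beta + q * object$se),
              nrow = 1,
              dimnames = list(paste0(object$exposure, "->", object$outcome),
                              sprintf("%g %%", c((1 - level) / 2,
                                                 1 - (1 - level) / 2) * 100)))
  m
}

#' @export
summary.mr_result <- function(object, ...) {
  out <- data.frame(exposure = object$exposure, outcome = object$outcome,
                    method = object$method, n_snps = object$n_snps,
                    beta = object$beta, se = object$se, pval = object$pval,
                    stringsAsFactors = FALSE)
  if (object$binary_outcome) {
    out$or <- object$or; out$or_low <- object$or_low
    out$or_high <- object$or_high
  }
  out
}

#' Bonferroni-corrected p-value threshold
#'
#' `alpha / m`; the value rounded to 3 significant figures is attached as
#' attribute `"signif3"` (the form in which such thresholds are usually
#' quoted, e.g. 0.05/9 = 0.00556).
#'
#' @param alpha Family-wise error level.
#' @param m Number of tests (>= 1).
#' @return The threshold.
#' @export
bonferroni_threshold <- function(alpha = 0.05, m) {
  if (m < 1) stop_ratiomr("m must be >= 1", "ratiomr_config_error")
  thr <- alpha / m
  attr(thr, "signif3") <- signif(thr, 3)
  thr
}

#' Greedy LD clumping to independent variants
#'
#' Orders variants by ascending p (module tie-break rule) and keeps a
#' variant iff its p-value passes `p_threshold` and its squared LD
#' correlation with every previously kept variant is below
#' `r2_threshold`. Used to pick independent eQTL instruments
#' (p < 5e-5, r2 < 0.05 in the expression analyses).
#'
#' @param assocs Summary statistics; all variants must appear in `ld`.
#' @param ld An [ld_matrix()].
#' @param p_threshold Significance cutoff (default 5e-5).
#' @param r2_threshold Maximum pairwise r-squared (default 0.05).
#' @return The retained rows (possibly zero rows).
#' @export
clump_independent <- function(assocs, ld, p_threshold = 5e-5,
                              r2_threshold = 0.05) {
  if (!all(assocs$variant_id %in% ld$variant_ids))
    stop_ratiomr("variants missing from LD matrix", "ratiomr_config_error")
  cand <- assocs[assocs$pval < p_threshold, , drop = FALSE]
  cand <- cand[tie_order(cand$pval, cand$beta, cand$variant_id), ,
               drop = FALSE]
  kept <- character(0)
  keep_row <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    vid <- cand$variant_id[i]
    if (length(kept) == 0L) {
      keep_row[i] <- TRUE
      kept <- vid
      next
    }
    r2 <- ld$r[match(vid, ld$variant_ids), match(kept, ld$variant_ids)]^2
    if (all(r2 < r2_threshold)) {
      keep_row[i] <- TRUE
      kept <- c(kept, vid)
    }
  }
  out <- cand[keep_row, , drop = FALSE]
  rownames(out) <- NULL
  out
}
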