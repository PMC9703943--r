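#' Phenome-wide scan of a single variant across many traits
#'
#' For one instrument variant harmonized to the activity-increasing
#' allele across a set of traits, flags trait associations below the
#' Bonferroni threshold `alpha / (number of traits)` and reports signed
#' z-statistics.
#'
#' @param assocs Summary statistics: one row per trait, all for the same
#'   variant.
#' @param alpha Family-wise level (default 0.05).
#' @return `data.frame` of class `phenome_scan` with `trait_id`, `z`,
#'   `pval`, `flagged`, sorted by decreasing absolute z; the threshold is
#'   attached as attribute `"threshold"`.
#' @export
phenome_scan <- function(assocs, alpha = 0.05) {
  if (anyDuplicated(assocs$trait_id))
    stop_ratiomr("duplicated trait_id in phenome scan input",
                 "ratiomr_config_error")
  if (length(unique(assocs$variant_id)) > 1L)
    stop_ratiomr("phenome scan expects a single scanned variant",
                 "ratiomr_config_error")
  threshold <- alpha / nrow(assocs)
  out <- data.frame(trait_id = assocs$trait_id,
                    z = assocs$beta / assocs$se,
                    pval = assocs$pval,
                    flagged = assocs$pval < threshold,
                    stringsAsFactors = FALSE)
  out <- out[order(-abs(out$z), out$trait_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "threshold") <- threshold
  class(out) <- c("phenome_scan", "data.frame")
  out
}

#' Negative-control outcome check
#'
#' Reports the instrument's per-allele association with a control outcome
#' that cannot plausibly be affected by the exposure (e.g. skin color);
#' an association with p < 0.05 flags possible residual population
#' stratification.
#'
#' @param instrument,control_outcome Harmonized one-row records for the
#'   same variant.
#' @param warn_p Warning threshold on the raw p-value (default 0.05).
#' @return List: `estimate` (per-allele), `se`, `pval`, `warning` flag,
#'   `control` trait id.
#' @export
negative_control <- function(instrument, control_outcome, warn_p = 0.05) {
  stopifnot(nrow(control_outcome) == 1L)
  if (instrument$variant_id != control_outcome$variant_id)
    stop_ratiomr("records are for different variants",
                 "ratiomr_harmonization_error")
  list(estimate = control_outcome$beta, se = control_outcome$se,
       pval = control_outcome$pval,
       warning = control_outcome$pval < warn_p,
       control = control_outcome$trait_id)
}

#' Compare within-sibship and unrelated-sample estimates
#'
#' Within-sibship genetic associations are immune to population
#' stratification, assortative mating and indirect parental effects;
#' agreement with the standard unrelated-sample estimate supports the MR
#' assumptions. The two estimates are compared with
#' \eqn{z = (b_w - b_u)/\sqrt{se_w^2 + se_u^2}} (independent sampling
#' errors assumed; conservative when samples overlap).
#'
#' @param beta_within,se_within Within-sibship estimate and SE.
#' @param beta_unrelated,se_unrelated Unrelated-sample estimate and SE.
#' @return List: `difference`, `z`, `pval`.
#' @export
sibship_compare <- function(beta_within, se_within, beta_unrelated,
                            se_unrelated) {
  if (se_within <= 0 || se_unrelated <= 0)
    stop_ratiomr("standard errors must be positive", "ratiomr_config_error")
  difference <- beta_within - beta_unrelated
  z <- difference / sqrt(se_within^2 + se_unrelated^2)
  list(difference = difference, z = z,
       pval = 2 * stats::pnorm(-abs(z)))
}

#' Convert a 95% confidence interval to a standard error
#'
#' `(upper - lower) / (2 * 1.96)`, for published estimates reported only
#' with a CI.
#'
#' @param lower,upper CI bounds.
#' @return Standard error.
#' @export
ci_to_se <- function(lower, upper) (upper - lower) / (2 * 1.96)

#' Benjamini-Hochberg FDR gating
#'
#' Step-up adjusted p-values (via [stats::p.adjust()]) with pass flags at
#' q below `fdr` (default 5%), used to gate SNP-expression associations
#' per tissue.
#'
#' @param pvals P-values in `[0, 1]`.
#' @param fdr FDR level.
#' @return `data.frame` with `pval`, `qval`, `pass` (input order kept).
#' @export
bh_fdr <- function(pvals, fdr = 0.05) {
  if (any(pvals < 0 | pvals > 1 | is.na(pvals)))
    stop_ratiomr("p-values must be in [0,1]", "ratiomr_config_error")
  q <- stats::p.adjust(pvals, method = "BH")
  data.frame(pval = pvals, qval = q, pass = q < fdr)
}
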