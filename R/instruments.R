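#' Select the top cis variant as genetic instrument
#'
#' Returns the in-region variant most strongly associated with the
#' exposure (smallest p-value) among those below the genome-wide threshold.
#' Ties are broken by larger absolute effect, then variant id.
#'
#' @param assocs Exposure summary statistics.
#' @param region A [region_spec()].
#' @param p_threshold Association threshold (default 5e-8).
#' @return The selected variant (one-row `data.frame`).
#' @export
select_top_variant <- function(assocs, region, p_threshold = 5e-8) {
  if (nrow(assocs) == 0L)
    stop_ratiomr("no associations supplied", "ratiomr_no_instrument")
  cand <- assocs[in_region(assocs, region) & assocs$pval < p_threshold, ,
                 drop = FALSE]
  if (nrow(cand) == 0L)
    stop_ratiomr(sprintf("no variant in region %s passes p < %g",
                         region$gene, p_threshold),
                 "ratiomr_no_instrument")
  out <- cand[tie_order(cand$pval, cand$beta, cand$variant_id)[1L], ,
              drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Variance in the exposure explained by a variant
#'
#' \eqn{R^2 = 2 \beta^2 \mathrm{MAF} (1 - \mathrm{MAF})} with
#' \eqn{\mathrm{MAF} = \min(\mathrm{eaf}, 1 - \mathrm{eaf})} and beta in SD
#' units of the exposure.
#'
#' @param beta SD-unit per-allele effect.
#' @param eaf Effect-allele frequency in (0, 1).
#' @return R-squared value (vectorized).
#' @export
variance_explained <- function(beta, eaf) {
  if (any(eaf <= 0 | eaf >= 1))
    stop_ratiomr("eaf must be in (0,1)", "ratiomr_config_error")
  maf <- pmin(eaf, 1 - eaf)
  2 * beta^2 * maf * (1 - maf)
}

#' Instrument-strength F statistic
#'
#' \eqn{F = ((n - k - 1)/k) \cdot R^2/(1 - R^2)} for an instrument of `k`
#' variants jointly explaining `r2` of the exposure variance in a sample
#' of size `n`.
#'
#' @param r2 Variance explained, in `[0, 1)`.
#' @param n Sample size (must exceed `k + 1`).
#' @param k Number of variants in the instrument (default 1).
#' @return F statistic (vectorized).
#' @export
f_statistic <- function(r2, n, k = 1) {
  if (any(r2 < 0 | r2 >= 1))
    stop_ratiomr("r2 must be in [0,1)", "ratiomr_domain_error")
  if (any(n <= k + 1))
    stop_ratiomr("n must exceed k + 1", "ratiomr_domain_error")
  if (any(k < 1)) stop_ratiomr("k must be >= 1", "ratiomr_domain_error")
  ((n - k - 1) / k) * (r2 / (1 - r2))
}

#' Select and characterize the per-locus instrument
#'
#' Picks the top in-region variant; if it is palindromic and an LD matrix
#' is available, replaces it by the strongest non-palindromic LD proxy.
#' Reports variance explained and the F statistic.
#'
#' @param assocs Exposure summary statistics (SD-unit betas).
#' @param region A [region_spec()].
#' @param ld Optional [ld_matrix()] for proxy replacement.
#' @param p_threshold Association threshold (default 5e-8).
#' @param proxy_min_r2 Minimum r-squared for a proxy (default 0.8).
#' @return One-row `data.frame` of class `instrument_report`: gene, the
#'   instrument variant's fields, `r2`, `f_stat`, `k` and
#'   `replaced_palindromic` (original variant id, or NA).
#' @export
instrument_report <- function(assocs, region, ld = NULL,
                              p_threshold = 5e-8, proxy_min_r2 = 0.8) {
  top <- select_top_variant(assocs, region, p_threshold)
  replaced <- NA_character_
  if (is_palindromic(top)) {
    if (is.null(ld))
      stop_ratiomr(sprintf("top variant %s is palindromic and no LD matrix was supplied for proxy search",
                           top$variant_id), "ratiomr_proxy_error")
    cand <- assocs[in_region(assocs, region) &
                     assocs$pval < p_threshold, , drop = FALSE]
    proxy <- select_ld_proxy(top$variant_id, cand, ld,
                             min_r2 = proxy_min_r2)
    replaced <- top$variant_id
    top <- proxy
  }
  r2 <- variance_explained(top$beta, top$eaf)
  f <- f_statistic(r2, top$n, k = 1)
  out <- cbind(data.frame(gene = region$gene, stringsAsFactors = FALSE),
               top[, SUMSTAT_COLS, drop = FALSE],
               data.frame(r2 = r2, f_stat = f, k = 1L,
                          replaced_palindromic = replaced,
                          stringsAsFactors = FALSE))
  rownames(out) <- NULL
  class(out) <- c("instrument_report", "data.frame")
  out
}

#' @export
print.instrument_report <- function(x, ...) {
  cat(sprintf("Instrument for %s: %s (p=%.3g), R2=%.3f, F=%.1f%s\n",
              x$gene, x$variant_id, x$pval, x$r2, x$f_stat,
              ifelse(is.na(x$replaced_palindromic), "",
                     sprintf(" [proxy for palindromic %s]",
                             x$replaced_palindromic))))
  invisible(x)
}
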