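#' Specification of an enzyme-activity ratio trait
#'
#' An enzyme's activity is proxied by the ratio of its product to its
#' substrate metabolite (e.g. AA:DGLA for delta-5 desaturase). The spec
#' carries the phenotypic correlation of the two measured traits and the
#' fraction of samples shared between their GWAS, both needed for the
#' covariance of the two effect estimates.
#'
#' @param numerator Product trait id.
#' @param denominator Substrate trait id.
#' @param pheno_corr Phenotypic correlation of product and substrate,
#'   strictly in (-1, 1).
#' @param overlap_fraction Fraction of samples shared by the two component
#'   GWAS, in `[0, 1]` (1 when both traits were measured in one cohort).
#' @return Object of class `ratio_spec`.
#' @export
ratio_spec <- function(numerator, denominator, pheno_corr = 0,
                       overlap_fraction = 1) {
  if (identical(numerator, denominator))
    stop_ratiomr("numerator and denominator must differ",
                 "ratiomr_config_error")
  if (abs(pheno_corr) >= 1)
    stop_ratiomr("|pheno_corr| must be < 1", "ratiomr_config_error")
  if (overlap_fraction < 0 || overlap_fraction > 1)
    stop_ratiomr("overlap_fraction must be in [0,1]", "ratiomr_config_error")
  structure(list(numerator = numerator, denominator = denominator,
                 pheno_corr = pheno_corr,
                 overlap_fraction = overlap_fraction),
            class = "ratio_spec")
}

#' Derive ratio-trait GWAS summary statistics by the delta method
#'
#' Approximates per-variant associations with the ratio trait R = P/S
#' from the component traits' summary statistics, using the first-order
#' expansion about the population means (mu_P, mu_S):
#'
#' \deqn{\beta_R = \beta_P/\mu_S - (\mu_P/\mu_S^2)\,\beta_S}
#' \deqn{Var(\hat\beta_R) = Var(\hat\beta_P)/\mu_S^2 +
#'   \mu_P^2 Var(\hat\beta_S)/\mu_S^4 -
#'   2(\mu_P/\mu_S^3)\,Cov(\hat\beta_P,\hat\beta_S)}
#'
#' with \eqn{Cov(\hat\beta_P,\hat\beta_S)} approximated as
#' `overlap_fraction * pheno_corr * SE_P * SE_S`. The result is
#' standardized to SD units of the ratio using the SD implied by the same
#' first-order expansion of Var(P/S),
#' \deqn{Var(R) \approx \sigma_P^2/\mu_S^2 + \mu_P^2\sigma_S^2/\mu_S^4 -
#'   2\mu_P\,\rho\,\sigma_P\sigma_S/\mu_S^3.}
#'
#' @param product,substrate Summary statistics of the two component traits
#'   covering the same variants with harmonized allele orientation, with
#'   betas on the raw measurement scale (or SD units with `scale = "sd"`,
#'   converted through the metadata SDs).
#' @param meta_p,meta_s [trait_meta()] for product and substrate; raw-scale
#'   means and SDs are required and `meta_s$mean` must be nonzero.
#' @param spec A [ratio_spec()].
#' @param scale Scale of the component betas: `"raw"` or `"sd"`. Mixing
#'   scales between the two inputs is a configuration error, so a single
#'   setting applies to both.
#' @return Summary statistics for the ratio trait in SD units, with the
#'   implied ratio-trait [trait_meta()] attached as attribute `"meta"`.
#'   Variants present in only one input are dropped (attribute
#'   `"dropped"`).
#' @export
derive_ratio_gwas <- function(product, substrate, meta_p, meta_s, spec,
                              scale = c("raw", "sd")) {
  scale <- match.arg(scale)
  if (is.na(meta_s$mean) || meta_s$mean == 0)
    stop_ratiomr("substrate mean must be nonzero for ratio derivation",
                 "ratiomr_config_error")
  if (is.na(meta_p$mean))
    stop_ratiomr("product mean required", "ratiomr_config_error")
  common <- intersect(product$variant_id, substrate$variant_id)
  dropped <- setdiff(union(product$variant_id, substrate$variant_id), common)
  if (length(dropped))
    message(sprintf("derive_ratio_gwas: dropped %d variant(s) present in only one input",
                    length(dropped)))
  p <- product[match(common, product$variant_id), , drop = FALSE]
  s <- substrate[match(common, substrate$variant_id), , drop = FALSE]
  if (!all(p$effect_allele == s$effect_allele &
             p$other_allele == s$other_allele))
    stop_ratiomr("component inputs are not allele-harmonized",
                 "ratiomr_harmonization_error")

  bp <- p$beta; sp <- p$se
  bs <- s$beta; ss <- s$se
  if (scale == "sd") {
    if (is.na(meta_p$sd) || is.na(meta_s$sd))
      stop_ratiomr("raw-scale SDs required to rescale SD-unit inputs",
                   "ratiomr_config_error")
    bp <- bp * meta_p$sd; sp <- sp * meta_p$sd
    bs <- bs * meta_s$sd; ss <- ss * meta_s$sd
  }
  mu_p <- meta_p$mean; mu_s <- meta_s$mean

  beta_raw <- bp / mu_s - (mu_p / mu_s^2) * bs
  cov_hat <- spec$overlap_fraction * spec$pheno_corr * sp * ss
  var_raw <- sp^2 / mu_s^2 + mu_p^2 * ss^2 / mu_s^4 -
    2 * (mu_p / mu_s^3) * cov_hat

  # SD of the ratio from the same first-order expansion of Var(P/S)
  var_ratio <- meta_p$sd^2 / mu_s^2 + mu_p^2 * meta_s$sd^2 / mu_s^4 -
    2 * mu_p * spec$pheno_corr * meta_p$sd * meta_s$sd / mu_s^3
  if (is.na(var_ratio) || var_ratio <= 0)
    stop_ratiomr("implied ratio variance not positive; check means/SDs",
                 "ratiomr_config_error")
  sd_ratio <- sqrt(var_ratio)

  beta_sd <- beta_raw / sd_ratio
  se_sd <- sqrt(var_raw) / sd_ratio
  trait_id <- paste0(spec$numerator, ":", spec$denominator)
  out <- data.frame(variant_id = p$variant_id, chrom = p$chrom, pos = p$pos,
                    effect_allele = p$effect_allele,
                    other_allele = p$other_allele, eaf = p$eaf,
                    beta = beta_sd, se = se_sd,
                    pval = 2 * stats::pnorm(-abs(beta_sd / se_sd)),
                    n = pmin(p$n, s$n), n_cases = NA_real_,
                    trait_id = trait_id, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "dropped") <- dropped
  n_meta <- suppressWarnings(min(meta_p$n, meta_s$n, na.rm = TRUE))
  attr(out, "meta") <- trait_meta(trait_id, "quantitative",
                                  mean = mu_p / mu_s, sd = sd_ratio,
                                  n = if (is.finite(n_meta)) n_meta
                                  else NA_real_,
                                  ancestry = meta_p$ancestry)
  out
}
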