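#' Colocalization priors and approximate-Bayes-factor settings
#'
#' Per-variant prior probabilities that a variant is causal for trait 1
#' only (`p1`), trait 2 only (`p2`) or both (`p12`), plus the prior
#' effect-size variances used in the approximate Bayes factor: `w_quant`
#' for SD-unit quantitative traits (default 0.15^2) and `w_binary` for
#' log-odds binary traits (default 0.2^2).
#'
#' @param p1,p2,p12 Per-variant priors in (0, 1) with `p1+p2+p12 < 1`.
#' @param w_quant,w_binary Prior effect variances (> 0).
#' @return Object of class `coloc_config`.
#' @export
coloc_config <- function(p1 = 1e-4, p2 = 1e-4, p12 = 1e-6,
                         w_quant = 0.15^2, w_binary = 0.2^2) {
  if (any(c(p1, p2, p12) <= 0) || any(c(p1, p2, p12) >= 1) ||
        p1 + p2 + p12 >= 1)
    stop_ratiomr("priors must be in (0,1) with p1+p2+p12 < 1",
                 "ratiomr_config_error")
  if (w_quant <= 0 || w_binary <= 0)
    stop_ratiomr("prior variances must be positive", "ratiomr_config_error")
  structure(list(p1 = p1, p2 = p2, p12 = p12, w_quant = w_quant,
                 w_binary = w_binary), class = "coloc_config")
}

#' Log approximate Bayes factor for one variant
#'
#' Wakefield-style asymptotic Bayes factor comparing a causal model with
#' prior effect variance `w` against the null: with \eqn{z = \beta/se}
#' and shrinkage \eqn{r = w/(w + se^2)},
#' \deqn{\log ABF = \tfrac{1}{2}\log(1 - r) + z^2 r / 2.}
#'
#' @param beta Effect estimate.
#' @param se Positive standard error.
#' @param w Prior effect variance (>= 0; `w = 0` gives log ABF = 0).
#' @return Log Bayes factor (vectorized).
#' @export
log_abf <- function(beta, se, w) {
  if (any(se <= 0)) stop_ratiomr("se must be positive",
                                 "ratiomr_config_error")
  if (any(w < 0)) stop_ratiomr("w must be >= 0", "ratiomr_config_error")
  z <- beta / se
  r <- w / (w + se^2)
  0.5 * log1p(-r) + z^2 * r / 2
}

prior_w <- function(config, type) {
  switch(match.arg(type, c("quantitative", "binary")),
         quantitative = config$w_quant, binary = config$w_binary)
}

#' Bayesian colocalization posteriors for two traits over a region
#'
#' Enumerates, under a single-causal-variant-per-trait assumption, all
#' configurations of causal variants for two traits measured over the
#' same regional variant set, and returns posterior probabilities for the
#' five hypotheses: H1 association with trait 1 (exposure) only, H2 with
#' trait 2 (outcome) only, H3 with both via distinct variants, H4 with
#' both via one shared variant, H5 no association. (In the conventional
#' coloc numbering these are H1, H2, H3, H4 and H0.) All sums are done in
#' the log domain with log-sum-exp.
#'
#' @param trait1,trait2 Summary statistics over the same variants,
#'   harmonized to a common allele orientation.
#' @param config A [coloc_config()].
#' @param type1,type2 Trait types selecting the ABF prior variance.
#' @return Object of class `coloc_result`: posterior vector `pp`
#'   (`pp_h1` ... `pp_h5`), `n_variants`, the config, and per-variant log
#'   ABFs.
#' @export
coloc_posteriors <- function(trait1, trait2, config = coloc_config(),
                             type1 = "quantitative",
                             type2 = "quantitative") {
  if (nrow(trait1) == 0L)
    stop_ratiomr("empty region", "ratiomr_config_error")
  if (nrow(trait1) != nrow(trait2) ||
        !setequal(trait1$variant_id, trait2$variant_id))
    stop_ratiomr("trait1 and trait2 must cover the same variant set",
                 "ratiomr_config_error")
  trait2 <- trait2[match(trait1$variant_id, trait2$variant_id), ,
                   drop = FALSE]
  l1 <- log_abf(trait1$beta, trait1$se, prior_w(config, type1))
  l2 <- log_abf(trait2$beta, trait2$se, prior_w(config, type2))
  s1 <- logsumexp(l1)
  s2 <- logsumexp(l2)
  s4 <- logsumexp(l1 + l2)
  s3 <- logdiff(s1 + s2, s4) # sum over i != j pairs
  lw <- c(h1 = log(config$p1) + s1,
          h2 = log(config$p2) + s2,
          h3 = log(config$p1) + log(config$p2) + s3,
          h4 = log(config$p12) + s4,
          h5 = 0)
  pp <- exp(lw - logsumexp(lw))
  names(pp) <- paste0("pp_", names(lw))
  structure(list(pp = pp, n_variants = nrow(trait1), config = config,
                 variant_id = trait1$variant_id, labf1 = l1, labf2 = l2),
            class = "coloc_result")
}

#' @export
print.coloc_result <- function(x, ...) {
  cat(sprintf("Colocalization over %d variants (p1=%g, p2=%g, p12=%g)\n",
              x$n_variants, x$config$p1, x$config$p2, x$config$p12))
  lbl <- c("H1 exposure only", "H2 outcome only", "H3 distinct variants",
           "H4 shared variant", "H5 none")
  for (i in 1:5) cat(sprintf("  %-22s %6.1f%%\n", lbl[i], 100 * x$pp[i]))
  invisible(x)
}

#' Decision rule for strong shared-variant evidence
#'
#' TRUE when the posterior for a single shared causal variant (`pp_h4`)
#' is at least `threshold` (default 0.70).
#'
#' @param result A [coloc_posteriors()] result.
#' @param threshold Posterior probability cutoff.
#' @return Logical flag.
#' @export
strong_shared <- function(result, threshold = 0.70) {
  unname(result$pp["pp_h4"] >= threshold)
}

#' Single-variant approximate conditioning of regional associations
#'
#' Adjusts each variant's z-statistic for the signal carried through LD
#' with a chosen top variant:
#' \deqn{z_j' = (z_j - r_{jt} z_t) / \sqrt{1 - r_{jt}^2},}
#' keeping SEs fixed and recomputing betas (`beta' = z' se`) and normal
#' p-values; the top variant's adjusted z is 0. This is a lightweight
#' regional surrogate for full conditional analysis from individual-level
#' data and is used as a coloc sensitivity analysis when a region shows
#' evidence of distinct signals.
#'
#' @param assocs Regional summary statistics.
#' @param top Variant id conditioned on (must be present).
#' @param ld [ld_matrix()] covering all variants, allele-aligned with
#'   `assocs`.
#' @return Adjusted summary statistics (same layout).
#' @export
condition_region <- function(assocs, top, ld) {
  if (!top %in% assocs$variant_id)
    stop_ratiomr("top variant not in region", "ratiomr_config_error")
  idx <- match(assocs$variant_id, ld$variant_ids)
  if (anyNA(idx))
    stop_ratiomr("variants missing from LD matrix", "ratiomr_config_error")
  t_idx <- match(top, ld$variant_ids)
  r <- ld$r[idx, t_idx]
  is_top <- assocs$variant_id == top
  if (any(abs(r) >= 1 - 1e-12 & !is_top))
    stop_ratiomr("degenerate LD: |r| = 1 with the conditioning variant",
                 "ratiomr_degenerate_ld")
  z <- assocs$beta / assocs$se
  zt <- z[is_top]
  z_adj <- (z - r * zt) / sqrt(1 - r^2)
  z_adj[is_top] <- 0
  out <- assocs
  out$beta <- z_adj * out$se
  out$pval <- 2 * stats::pnorm(-abs(z_adj))
  out
}

#' Colocalization with conditional sensitivity analysis
#'
#' Runs [coloc_posteriors()]; if the posterior for distinct causal
#' variants exceeds `distinct_trigger` (default 0.30), conditions the
#' outcome trait on its own top variant (smallest p, module tie-break)
#' with [condition_region()] and re-runs colocalization on the adjusted
#' outcome statistics.
#'
#' @inheritParams coloc_posteriors
#' @param ld [ld_matrix()] for the region.
#' @param distinct_trigger `pp_h3` level that triggers the conditional
#'   re-analysis.
#' @return List of class `coloc_conditioned`: `primary` (coloc_result),
#'   `conditioned` (coloc_result or NULL), `conditioned_on` (variant id or
#'   NA).
#' @export
coloc_with_conditioning <- function(trait1, trait2, ld,
                                    config = coloc_config(),
                                    type1 = "quantitative",
                                    type2 = "quantitative",
                                    distinct_trigger = 0.30) {
  primary <- coloc_posteriors(trait1, trait2, config, type1, type2)
  conditioned <- NULL
  top <- NA_character_
  if (primary$pp["pp_h3"] > distinct_trigger) {
    o <- tie_order(trait2$pval, trait2$beta, trait2$variant_id)
    top <- trait2$variant_id[o[1L]]
    t2_adj <- condition_region(trait2, top, ld)
    conditioned <- coloc_posteriors(trait1, t2_adj, config, type1, type2)
  }
  structure(list(primary = primary, conditioned = conditioned,
                 conditioned_on = top), class = "coloc_conditioned")
}

#' @export
print.coloc_conditioned <- function(x, ...) {
  cat("Primary analysis:\n")
  print(x$primary)
  if (!is.null(x$conditioned)) {
    cat(sprintf("Sensitivity analysis (outcome conditioned on %s):\n",
                x$conditioned_on))
    print(x$conditioned)
  } else {
    cat("No conditional re-analysis triggered.\n")
  }
  invisible(x)
}

#' Regional association plot for two traits
#'
#' Position against -log10(p) for exposure and outcome, the usual visual
#' companion to a colocalization result.
#'
#' @param trait1,trait2 Regional summary statistics.
#' @param labels Trait labels for the legend.
#' @param ... Passed to [plot()].
#' @export
plot_region <- function(trait1, trait2,
                        labels = c(trait1$trait_id[1], trait2$trait_id[1]),
                        ...) {
  lp1 <- -log10(pmax(trait1$pval, 1e-300))
  lp2 <- -log10(pmax(trait2$pval, 1e-300))
  graphics::plot(trait1$pos / 1e6, lp1, pch = 16, col = "#1b61a8",
                 xlab = sprintf("chr%s position (Mb)", trait1$chrom[1]),
                 ylab = expression(-log[10](p)),
                 ylim = c(0, max(lp1, lp2) * 1.05), ...)
  graphics::points(trait2$pos / 1e6, lp2, pch = 17, col = "#c23b22")
  graphics::legend("topright", legend = labels, pch = c(16, 17),
                   col = c("#1b61a8", "#c23b22"), bty = "n")
  invisible(NULL)
}
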