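#' Scenario configuration for the synthetic-data generator
#'
#' Defines the study conditions every simulated dataset is drawn under:
#' a cis region of correlated variants, product and substrate fatty-acid
#' phenotypes (percent of total fatty acids) sharing a causal cis variant,
#' the enzyme-activity ratio trait, and a liability-scale binary outcome
#' downstream of the ratio. Defaults emulate a strong desaturase-like
#' locus: the causal allele speeds conversion, raising the product and
#' lowering the substrate.
#'
#' @param n_variants Number of regional variants (default 100).
#' @param n_exposure Exposure-cohort sample size (default 10000).
#' @param n_outcome Outcome-cohort sample sizes, one per cohort
#'   (default two cohorts of 10000).
#' @param ld_decay Latent autocorrelation between neighboring variants in
#'   `[0, 1)` (default 0.9).
#' @param maf_range Allele-frequency band variants are drawn from.
#' @param causal_variant Index of the shared causal variant (default:
#'   the middle of the region).
#' @param effect_product,effect_substrate Raw-scale per-allele effects on
#'   product and substrate (defaults +0.6 and -0.3 percentage points).
#' @param mu_product,mu_substrate Raw-scale phenotype means (8 and 3).
#' @param sd_product,sd_substrate Residual SDs (1.5 and 0.4; the
#'   substrate's coefficient of variation is kept moderate so the ratio
#'   P/S is well-behaved and its first-order expansion meaningful).
#' @param rho_ps Residual correlation of product and substrate (0.3).
#' @param outcome_logodds Log-odds of disease per SD of the ratio (0.5).
#' @param prevalence Baseline outcome prevalence (0.2).
#' @param case_fraction Optional case-control ascertainment fraction;
#'   NULL samples from the population.
#' @param outcome_direct_logodds Per-allele log-odds of a direct (non
#'   ratio-mediated) outcome variant, used by the distinct-causal
#'   scenario (0.25).
#' @return Object of class `scenario_config`.
#' @export
scenario_config <- function(n_variants = 100L, n_exposure = 10000L,
                            n_outcome = c(10000L, 10000L),
                            ld_decay = 0.9, maf_range = c(0.05, 0.5),
                            causal_variant = ceiling(n_variants / 2),
                            effect_product = 0.6,
                            effect_substrate = -0.3,
                            mu_product = 8, mu_substrate = 3,
                            sd_product = 1.5, sd_substrate = 0.4,
                            rho_ps = 0.3, outcome_logodds = 0.5,
                            prevalence = 0.2, case_fraction = NULL,
                            outcome_direct_logodds = 0.25) {
  if (ld_decay < 0 || ld_decay >= 1)
    stop_ratiomr("ld_decay must be in [0,1)", "ratiomr_config_error")
  if (causal_variant > n_variants)
    stop_ratiomr("causal index exceeds n_variants", "ratiomr_config_error")
  if (abs(rho_ps) >= 1)
    stop_ratiomr("|rho_ps| must be < 1", "ratiomr_config_error")
  if (any(maf_range <= 0) || any(maf_range >= 1))
    stop_ratiomr("maf_range must be inside (0,1)", "ratiomr_config_error")
  structure(as.list(environment()), class = "scenario_config")
}

# deterministic non-palindromic allele assignment per variant
assign_alleles <- function(m) {
  ea <- rep(c("A", "C", "G", "T"), length.out = m)
  oa <- rep(c("G", "T", "A", "C"), length.out = m)
  list(effect = ea, other = oa)
}

#' Simulate regional genotypes with linkage disequilibrium
#'
#' Allele frequencies are drawn uniformly in `maf_range`; haplotype
#' alleles come from thresholding a latent Gaussian first-order
#' autoregressive chain with neighbor autocorrelation `ld_decay` at each
#' variant's frequency quantile, so nearby variants are correlated and
#' correlation decays with distance. Genotypes are the sum of two
#' independent haplotypes. Fully reproducible from `seed`.
#'
#' @param n Number of individuals.
#' @param config A [scenario_config()].
#' @param seed Integer seed.
#' @param freq Optional fixed allele-frequency vector (shared across
#'   cohorts of one scenario); drawn from `maf_range` when NULL.
#' @return List: `genotypes` (n x m integer matrix of effect-allele
#'   counts), `variant_ids`, `chrom`, `pos`, `effect_allele`,
#'   `other_allele`, `freq`, and `ld` (empirical [ld_matrix()]).
#' @export
simulate_genotypes <- function(n, config = scenario_config(), seed,
                               freq = NULL) {
  m <- config$n_variants
  with_seed(seed, {
    if (is.null(freq))
      freq <- stats::runif(m, config$maf_range[1], config$maf_range[2])
    thresh <- stats::qnorm(freq)
    a <- config$ld_decay
    hap <- function() {
      z <- matrix(stats::rnorm(n * m), n, m)
      if (a > 0 && m > 1) {
        for (j in 2:m) z[, j] <- a * z[, j - 1] + sqrt(1 - a^2) * z[, j]
      }
      sweep(z, 2, thresh, "<") + 0L
    }
    G <- hap() + hap()
    ids <- sprintf("rs%04d", seq_len(m))
    al <- assign_alleles(m)
    sds <- apply(G, 2, stats::sd)
    if (any(sds == 0)) {
      # monomorphic draws cannot enter a correlation matrix; keep the LD
      # matrix defined by adding an epsilon-free fallback of r = 0
      cm <- diag(m)
      poly <- sds > 0
      cm[poly, poly] <- stats::cor(G[, poly, drop = FALSE])
    } else {
      cm <- stats::cor(G)
    }
    dimnames(cm) <- list(ids, ids)
    list(genotypes = G, variant_ids = ids, chrom = "11",
         pos = as.integer(61050000 + (seq_len(m) - 1L) * 9000L),
         effect_allele = al$effect, other_allele = al$other,
         freq = freq, ld = ld_matrix(cm, ids))
  })
}

#' Simulate product, substrate and ratio phenotypes
#'
#' `P = mu_P + G b_P + e_P`, `S = mu_S + G b_S + e_S` with residual
#' correlation `rho_ps`; the enzyme-activity trait is the ratio `P/S`.
#' Individuals with nonpositive substrate values are re-drawn (count
#' logged); a configuration expecting more than 1% nonpositive substrate
#' is rejected.
#'
#' @param geno A [simulate_genotypes()] bundle.
#' @param config A [scenario_config()].
#' @param seed Integer seed.
#' @param beta_product,beta_substrate Optional full per-variant raw
#'   effect vectors; default: the single shared causal variant from
#'   `config`.
#' @return `data.frame` with `product`, `substrate`, `ratio`.
#' @export
simulate_phenotypes <- function(geno, config = scenario_config(), seed,
                                beta_product = NULL,
                                beta_substrate = NULL) {
  G <- geno$genotypes
  n <- nrow(G); m <- ncol(G)
  if (is.null(beta_product)) {
    beta_product <- numeric(m)
    beta_product[config$causal_variant] <- config$effect_product
  }
  if (is.null(beta_substrate)) {
    beta_substrate <- numeric(m)
    beta_substrate[config$causal_variant] <- config$effect_substrate
  }
  gp <- drop(G %*% beta_product)
  gs <- drop(G %*% beta_substrate)
  rho <- config$rho_ps
  with_seed(seed, {
    draw <- function(k) {
      u1 <- stats::rnorm(k)
      u2 <- rho * u1 + sqrt(1 - rho^2) * stats::rnorm(k)
      cbind(u1, u2)
    }
    u <- draw(n)
    P <- config$mu_product + gp + config$sd_product * u[, 1]
    S <- config$mu_substrate + gs + config$sd_substrate * u[, 2]
    bad <- which(S <= 0)
    if (length(bad) > 0.01 * n)
      stop_ratiomr(sprintf("substrate mean too low: %.1f%% of values nonpositive",
                           100 * length(bad) / n), "ratiomr_config_error")
    tries <- 0L
    while (length(bad) && tries < 50L) {
      u <- draw(length(bad))
      P[bad] <- config$mu_product + gp[bad] + config$sd_product * u[, 1]
      S[bad] <- config$mu_substrate + gs[bad] + config$sd_substrate * u[, 2]
      bad <- bad[S[bad] <= 0]
      tries <- tries + 1L
    }
    data.frame(product = P, substrate = S, ratio = P / S)
  })
}

#' Simulate a liability-scale binary outcome downstream of the ratio
#'
#' Disease probability is logistic in the standardized ratio:
#' `logit P(Y=1) = qlogis(prevalence) + b z_ratio` with `b` the
#' configured log-odds per SD. Optional case-control ascertainment keeps
#' all cases and subsamples controls to a stated case fraction (the
#' per-SD log-odds is invariant to this by the logistic model).
#'
#' @param ratio Ratio-trait values.
#' @param config A [scenario_config()].
#' @param seed Integer seed.
#' @param logodds_per_sd Causal log-odds per SD (default from config).
#' @param eta_extra Optional additional linear-predictor term (e.g. a
#'   direct variant effect), length of `ratio`.
#' @return List: `y` (0/1 vector over the retained individuals) and
#'   `idx` (their row indices; all rows for population sampling).
#' @export
simulate_outcome <- function(ratio, config = scenario_config(), seed,
                             logodds_per_sd = config$outcome_logodds,
                             eta_extra = 0) {
  zr <- (ratio - mean(ratio)) / stats::sd(ratio)
  eta <- stats::qlogis(config$prevalence) + logodds_per_sd * zr + eta_extra
  with_seed(seed, {
    y <- stats::rbinom(length(ratio), 1L, stats::plogis(eta))
    idx <- seq_along(y)
    cf <- config$case_fraction
    if (!is.null(cf)) {
      cases <- which(y == 1L)
      controls <- which(y == 0L)
      n_ctrl <- min(length(controls),
                    round(length(cases) * (1 - cf) / cf))
      idx <- sort(c(cases, sample(controls, n_ctrl)))
      y <- y[idx]
    }
    list(y = y, idx = idx)
  })
}

#' Per-variant GWAS summary statistics from individual-level data
#'
#' Quantitative traits: closed-form simple linear regression per variant
#' (`beta = cov(G, y)/var(G)`). Binary traits: per-variant univariable
#' logistic maximum likelihood. P-values use the two-sided normal
#' approximation throughout, matching the summary-statistics data model.
#' Monomorphic variants are dropped with a log message.
#'
#' @param geno A [simulate_genotypes()] bundle.
#' @param y Trait values (numeric) or 0/1 outcome.
#' @param trait_id Trait label for the output.
#' @param binary Is `y` a binary outcome?
#' @param variants Optional variant indices to restrict to.
#' @param rows Optional individual (row) indices (e.g. an ascertained
#'   case-control subset).
#' @return Summary-statistics `data.frame`.
#' @export
compute_sumstats <- function(geno, y, trait_id, binary = FALSE,
                             variants = NULL, rows = NULL) {
  G <- geno$genotypes
  if (!is.null(rows)) G <- G[rows, , drop = FALSE]
  if (is.null(variants)) variants <- seq_len(ncol(G))
  G <- G[, variants, drop = FALSE]
  n <- nrow(G)
  if (length(y) != n)
    stop_ratiomr("genotype/trait dimension mismatch",
                 "ratiomr_config_error")
  gm <- colMeans(G)
  sxx <- colSums(G^2) - n * gm^2
  mono <- sxx <= 1e-12
  if (any(mono)) {
    message(sprintf("compute_sumstats: dropped %d monomorphic variant(s)",
                    sum(mono)))
    variants <- variants[!mono]
    G <- G[, !mono, drop = FALSE]
    gm <- gm[!mono]; sxx <- sxx[!mono]
  }
  if (binary) {
    fit1 <- function(g) {
      X <- cbind(1, g)
      f <- stats::glm.fit(X, y, family = stats::binomial())
      V <- solve(crossprod(X * sqrt(f$weights)))
      c(f$coefficients[2], sqrt(V[2, 2]))
    }
    est <- apply(G, 2, fit1)
    beta <- est[1, ]; se <- est[2, ]
  } else {
    my <- mean(y)
    sxy <- colSums(G * y) - n * gm * my
    syy <- sum(y^2) - n * my^2
    beta <- sxy / sxx
    sse <- pmax(syy - beta * sxy, 0)
    se <- sqrt(sse / (n - 2) / sxx)
  }
  data.frame(variant_id = geno$variant_ids[variants],
             chrom = geno$chrom,
             pos = geno$pos[variants],
             effect_allele = geno$effect_allele[variants],
             other_allele = geno$other_allele[variants],
             eaf = gm / 2, beta = beta, se = se,
             pval = 2 * stats::pnorm(-abs(beta / se)),
             n = n,
             n_cases = if (binary) sum(y) else NA_real_,
             trait_id = trait_id, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Build a complete synthetic scenario bundle with known ground truth
#'
#' Deterministic given `seed`. Regional scenarios share one set of allele
#' frequencies across the exposure cohort and every outcome cohort:
#' \describe{
#'   \item{shared_causal}{one cis variant drives the ratio, and disease
#'     liability depends on the ratio (log-odds per SD from the config).}
#'   \item{distinct_causal}{the ratio is driven by one variant while the
#'     outcome is driven directly by a different variant in LD r ~ 0.3
#'     with it (chosen as the variant whose empirical LD to the causal is
#'     nearest 0.3).}
#'   \item{null}{the ratio has its cis variant but no effect on the
#'     outcome.}
#'   \item{mediation}{a non-regional 40-variant polygenic design with two
#'     correlated quantitative exposures whose true direct effects on the
#'     outcome are 0.3 and 0.0, for multivariable-MR testing.}
#' }
#'
#' @param name Scenario name.
#' @param seed Integer seed.
#' @param config A [scenario_config()].
#' @return Object of class `scenario_bundle`: `sumstats` (per trait;
#'   outcome as a list with one element per cohort), `ld`, `meta`,
#'   `region`, `truth` and the echoed config.
#' @export
make_scenario <- function(name = c("shared_causal", "distinct_causal",
                                   "null", "mediation"),
                          seed, config = scenario_config()) {
  name <- match.arg(name)
  if (name == "mediation") return(make_mediation_scenario(seed, config))
  geno_x <- simulate_genotypes(config$n_exposure, config,
                               seed = derive_seed(seed, 1))
  phen_x <- simulate_phenotypes(geno_x, config, seed = derive_seed(seed, 2))
  ratio_z <- (phen_x$ratio - mean(phen_x$ratio)) / stats::sd(phen_x$ratio)

  ss_product <- compute_sumstats(geno_x, phen_x$product, "product")
  ss_substrate <- compute_sumstats(geno_x, phen_x$substrate, "substrate")
  ss_ratio <- compute_sumstats(geno_x, ratio_z, "activity_ratio")

  c1 <- config$causal_variant
  causal_outcome <- NA_character_
  c2 <- NA_integer_
  if (name == "distinct_causal") {
    r_to_c1 <- geno_x$ld$r[, c1]
    cand <- setdiff(seq_len(config$n_variants), c1)
    c2 <- cand[which.min(abs(abs(r_to_c1[cand]) - 0.3))]
    causal_outcome <- geno_x$variant_ids[c2]
  } else if (name == "shared_causal") {
    causal_outcome <- geno_x$variant_ids[c1]
  }
  b_out <- switch(name, shared_causal = config$outcome_logodds,
                  distinct_causal = 0, null = 0)

  ss_outcome <- vector("list", length(config$n_outcome))
  names(ss_outcome) <- paste0("cohort", seq_along(config$n_outcome))
  for (i in seq_along(config$n_outcome)) {
    g <- simulate_genotypes(config$n_outcome[i], config,
                            seed = derive_seed(seed, 10 + i),
                            freq = geno_x$freq)
    ph <- simulate_phenotypes(g, config, seed = derive_seed(seed, 20 + i))
    extra <- 0
    if (name == "distinct_causal") {
      gc2 <- g$genotypes[, c2]
      extra <- config$outcome_direct_logodds * (gc2 - mean(gc2))
    }
    out <- simulate_outcome(ph$ratio, config,
                            seed = derive_seed(seed, 30 + i),
                            logodds_per_sd = b_out, eta_extra = extra)
    ss_outcome[[i]] <- compute_sumstats(g, out$y, "cvd_outcome",
                                        binary = TRUE, rows = out$idx)
  }

  # true per-allele effect on the SD-unit ratio via the delta method
  mu_p <- config$mu_product; mu_s <- config$mu_substrate
  raw_eff <- config$effect_product / mu_s -
    (mu_p / mu_s^2) * config$effect_substrate
  truth <- list(causal_exposure = geno_x$variant_ids[c1],
                causal_outcome = causal_outcome,
                ratio_effect_per_allele = raw_eff / stats::sd(phen_x$ratio),
                logodds_per_sd = b_out)

  meta <- list(
    product = trait_meta("product", "quantitative",
                         mean = mean(phen_x$product),
                         sd = stats::sd(phen_x$product),
                         n = config$n_exposure, ancestry = "synthetic"),
    substrate = trait_meta("substrate", "quantitative",
                           mean = mean(phen_x$substrate),
                           sd = stats::sd(phen_x$substrate),
                           n = config$n_exposure, ancestry = "synthetic"),
    ratio = trait_meta("activity_ratio", "quantitative",
                       mean = mean(phen_x$ratio),
                       sd = stats::sd(phen_x$ratio),
                       n = config$n_exposure, ancestry = "synthetic"))

  structure(list(name = name, seed = seed, config = config,
                 region = region_spec("GENE1", "11", 61500000L),
                 sumstats = list(product = ss_product,
                                 substrate = ss_substrate,
                                 ratio = ss_ratio, outcome = ss_outcome),
                 ld = geno_x$ld, meta = meta, truth = truth),
            class = "scenario_bundle")
}

# polygenic two-exposure design for multivariable MR validation
make_mediation_scenario <- function(seed, config) {
  m <- 40L
  n <- config$n_exposure
  cfg <- config
  cfg$n_variants <- m
  cfg$ld_decay <- 0
  geno <- simulate_genotypes(n, cfg, seed = derive_seed(seed, 1))
  G <- geno$genotypes
  with_seed(derive_seed(seed, 2), {
    a1 <- stats::rnorm(m, 0, 0.12)
    a2 <- stats::rnorm(m, 0, 0.12)
    x1 <- drop(G %*% a1) + stats::rnorm(n)
    x2 <- 0.5 * x1 + drop(G %*% a2) + stats::rnorm(n)
    y <- 0.3 * x1 + 0 * x2 + stats::rnorm(n)
  })
  ss <- list(x1 = compute_sumstats(geno, x1, "target_expression"),
             x2 = compute_sumstats(geno, x2, "coexpressed_gene"),
             outcome = list(cohort1 = compute_sumstats(geno, y,
                                                       "cvd_outcome")))
  truth <- list(direct_effects = c(target_expression = 0.3,
                                   coexpressed_gene = 0),
                causal_exposure = NA_character_,
                causal_outcome = NA_character_)
  structure(list(name = "mediation", seed = seed, config = cfg,
                 region = NULL, sumstats = ss, ld = geno$ld,
                 meta = list(), truth = truth),
            class = "scenario_bundle")
}

#' @export
print.scenario_bundle <- function(x, ...) {
  cat(sprintf("Synthetic scenario '%s' (seed %d): %d variants\n",
              x$name, x$seed, x$config$n_variants))
  cat(sprintf("  traits: %s; outcome cohorts: %d\n",
              paste(setdiff(names(x$sumstats), "outcome"),
                    collapse = ", "),
              length(x$sumstats$outcome)))
  invisible(x)
}

#' Write a scenario bundle to a directory of plain-text files
#'
#' Summary statistics in the tab-delimited dialect, the LD matrix, a
#' truth table, and the echoed configuration as tab-separated key/value
#' pairs.
#'
#' @param bundle A [make_scenario()] bundle.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  flat <- bundle$sumstats
  out_list <- flat$outcome
  flat$outcome <- NULL
  for (nm in names(flat))
    write_sumstats(flat[[nm]], file.path(dir, paste0(nm, ".tsv")))
  for (nm in names(out_list))
    write_sumstats(out_list[[nm]],
                   file.path(dir, paste0("outcome_", nm, ".tsv")))
  write_ld_matrix(bundle$ld, file.path(dir, "ld.tsv"))
  tr <- bundle$truth
  truth_df <- data.frame(key = names(tr),
                         value = vapply(tr, function(v)
                           paste(format(v, digits = 15), collapse = ","),
                           character(1)))
  utils::write.table(truth_df, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  cfg <- bundle$config
  cfg_df <- data.frame(key = names(cfg),
                       value = vapply(cfg, function(v)
                         paste(format(v, digits = 15), collapse = ","),
                         character(1)))
  cfg_df <- rbind(cfg_df, data.frame(key = c("scenario", "seed"),
                                     value = c(bundle$name,
                                               as.character(bundle$seed))))
  utils::write.table(cfg_df, file.path(dir, "config.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
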