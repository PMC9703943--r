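test_that("generation is fully reproducible from the seed", {
  cfg <- scenario_config(n_variants = 20, n_exposure = 500)
  g1 <- simulate_genotypes(500, cfg, seed = 5)
  g2 <- simulate_genotypes(500, cfg, seed = 5)
  expect_identical(g1, g2)
  g3 <- simulate_genotypes(500, cfg, seed = 6)
  expect_false(identical(g1$genotypes, g3$genotypes))

  b1 <- make_scenario("shared_causal", seed = 11,
                      config = scenario_config(n_variants = 15,
                                               n_exposure = 400,
                                               n_outcome = 400,
                                               causal_variant = 8))
  b2 <- make_scenario("shared_causal", seed = 11,
                      config = scenario_config(n_variants = 15,
                                               n_exposure = 400,
                                               n_outcome = 400,
                                               causal_variant = 8))
  expect_identical(b1, b2)
})

test_that("simulation leaves no footprint on the caller's RNG stream", {
  set.seed(123)
  before <- .Random.seed
  invisible(simulate_genotypes(100, scenario_config(n_variants = 5),
                               seed = 1))
  expect_identical(.Random.seed, before)
})

test_that("ld_decay = 0 gives uncorrelated variants, > 0 gives neighbor LD", {
  cfg0 <- scenario_config(n_variants = 20, ld_decay = 0)
  g0 <- simulate_genotypes(10000, cfg0, seed = 51)
  off <- abs(g0$ld$r[upper.tri(g0$ld$r)])
  expect_lt(mean(off), 0.05)

  cfg9 <- scenario_config(n_variants = 20, ld_decay = 0.9)
  g9 <- simulate_genotypes(10000, cfg9, seed = 51)
  neighbor <- diag(g9$ld$r[-1, -nrow(g9$ld$r)])
  expect_gt(mean(abs(neighbor)), 0.5)
})

test_that("empirical allele frequencies stay within binomial bounds", {
  n <- 10000
  cfg <- scenario_config(n_variants = 30)
  g <- simulate_genotypes(n, cfg, seed = 52)
  emp <- colMeans(g$genotypes) / 2
  bound <- 3 * sqrt(g$freq * (1 - g$freq) / (2 * n))
  expect_true(all(abs(emp - g$freq) <= pmax(bound, 0.015)))
})

test_that("phenotypes follow the configured genetic architecture", {
  cfg <- scenario_config(n_variants = 10, causal_variant = 4,
                         effect_substrate = 0, ld_decay = 0)
  g <- simulate_genotypes(20000, cfg, seed = 61)
  ph <- simulate_phenotypes(g, cfg, seed = 62)
  # effect on the product only: per-allele ratio slope ~ effect / mu_S
  slope <- coef(lm(ph$ratio ~ g$genotypes[, 4]))[2]
  expect_equal(unname(slope), cfg$effect_product / cfg$mu_substrate,
               tolerance = 0.05)
  # product-substrate correlation matches the variance algebra
  f <- g$freq[cfg$causal_variant]
  vg <- 2 * f * (1 - f)
  cov_ps <- cfg$rho_ps * cfg$sd_product * cfg$sd_substrate +
    vg * cfg$effect_product * cfg$effect_substrate
  var_p <- cfg$sd_product^2 + vg * cfg$effect_product^2
  var_s <- cfg$sd_substrate^2 + vg * cfg$effect_substrate^2
  expect_equal(cor(ph$product, ph$substrate),
               cov_ps / sqrt(var_p * var_s), tolerance = 0.03)

  # null architecture: slopes consistent with zero
  cfg0 <- scenario_config(n_variants = 10, effect_product = 0,
                          effect_substrate = 0, ld_decay = 0)
  ph0 <- simulate_phenotypes(g, cfg0, seed = 63)
  z <- compute_sumstats(g, ph0$ratio, "r")
  expect_true(all(abs(z$beta / z$se) < 4.5))
})

test_that("an untenably low substrate mean is rejected", {
  cfg <- scenario_config(n_variants = 5, mu_substrate = 0.5,
                         sd_substrate = 0.4)
  g <- simulate_genotypes(2000, cfg, seed = 64)
  expect_error(simulate_phenotypes(g, cfg, seed = 65),
               class = "ratiomr_config_error")
})

test_that("closed-form OLS oracle on a hand-sized dataset", {
  geno <- list(genotypes = matrix(c(0, 1, 2, 0, 1, 1), ncol = 1),
               variant_ids = "rs1", chrom = "1", pos = 100L,
               effect_allele = "A", other_allele = "G")
  y <- c(1.0, 1.4, 2.1, 0.9, 1.6, 1.3)
  ss <- compute_sumstats(geno, y, "t")
  g <- geno$genotypes[, 1]
  expect_equal(ss$beta, cov(g, y) / var(g), tolerance = 1e-12)
  expect_equal(ss$eaf, mean(g) / 2)
  # recoding the effect allele flips the sign
  geno2 <- geno
  geno2$genotypes <- 2L - geno$genotypes
  ss2 <- compute_sumstats(geno2, y, "t")
  expect_equal(ss2$beta, -ss$beta, tolerance = 1e-12)
  expect_equal(ss2$se, ss$se, tolerance = 1e-12)
})

test_that("permutation null p-values are uniform", {
  cfg <- scenario_config(n_variants = 1, ld_decay = 0)
  g <- simulate_genotypes(300, cfg, seed = 71)
  y <- rnorm(300) # arbitrary trait, then permuted fresh per replicate
  set.seed(72)
  p <- replicate(400, compute_sumstats(g, sample(y), "t")$pval)
  expect_gt(ks.test(p, "punif")$p.value, 0.01)
})

test_that("binary sumstats agree with glm and logistic effects are recovered", {
  cfg <- scenario_config(n_variants = 3, causal_variant = 2, ld_decay = 0)
  g <- simulate_genotypes(8000, cfg, seed = 81)
  ph <- simulate_phenotypes(g, cfg, seed = 82)
  out <- simulate_outcome(ph$ratio, cfg, seed = 83, logodds_per_sd = 0.4)
  ss <- compute_sumstats(g, out$y, "d", binary = TRUE)
  ref <- glm(out$y ~ g$genotypes[, 2], family = binomial())
  expect_equal(ss$beta[2], unname(coef(ref)[2]), tolerance = 1e-6)
  expect_equal(ss$se[2], unname(sqrt(vcov(ref)[2, 2])), tolerance = 1e-4)
  expect_equal(ss$n_cases[1], sum(out$y))

  # per-SD log-odds recovered from individual-level logistic fit
  zr <- scale(ph$ratio)
  fit <- glm(out$y ~ zr, family = binomial())
  expect_lt(abs(coef(fit)[2] - 0.4), 1.96 * sqrt(vcov(fit)[2, 2]))
})

test_that("null outcome is independent of the ratio", {
  cfg <- scenario_config(n_variants = 2, ld_decay = 0)
  g <- simulate_genotypes(5000, cfg, seed = 91)
  ph <- simulate_phenotypes(g, cfg, seed = 92)
  pvals <- vapply(1:50, function(i) {
    out <- simulate_outcome(ph$ratio, cfg, seed = 1000 + i,
                            logodds_per_sd = 0)
    summary(glm(out$y ~ scale(ph$ratio),
                family = binomial()))$coefficients[2, 4]
  }, numeric(1))
  expect_gt(ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("case-control ascertainment preserves the per-SD log-odds", {
  cfg <- scenario_config(n_variants = 2, ld_decay = 0,
                         case_fraction = 0.5)
  g <- simulate_genotypes(30000, cfg, seed = 95)
  ph <- simulate_phenotypes(g, cfg, seed = 96)
  out <- simulate_outcome(ph$ratio, cfg, seed = 97, logodds_per_sd = 0.3)
  expect_equal(mean(out$y), 0.5, tolerance = 0.02)
  zr_all <- scale(ph$ratio)
  fit <- glm(out$y ~ zr_all[out$idx], family = binomial())
  expect_lt(abs(coef(fit)[2] - 0.3), 1.96 * sqrt(vcov(fit)[2, 2]) + 0.01)
})

test_that("scenario bundles expose coherent truth and file round trip", {
  cfg <- scenario_config(n_variants = 12, n_exposure = 1500,
                         n_outcome = 1500, causal_variant = 6)
  b <- make_scenario("distinct_causal", seed = 13, config = cfg)
  expect_false(b$truth$causal_exposure == b$truth$causal_outcome)
  r <- b$ld$r[b$truth$causal_exposure, b$truth$causal_outcome]
  expect_lt(abs(abs(r) - 0.3), 0.25)
  expect_equal(b$truth$logodds_per_sd, 0)

  d <- withr::local_tempdir()
  write_bundle(b, d)
  expect_true(all(file.exists(file.path(d, c("ratio.tsv", "product.tsv",
                                             "substrate.tsv",
                                             "outcome_cohort1.tsv",
                                             "ld.tsv", "truth.tsv",
                                             "config.tsv")))))
  back <- read_sumstats(file.path(d, "ratio.tsv"))
  expect_equal(back$beta, b$sumstats$ratio$beta, tolerance = 0)
  ld_back <- read_ld_matrix(file.path(d, "ld.tsv"))
  expect_equal(ld_back$r, b$ld$r, tolerance = 1e-12)
})
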