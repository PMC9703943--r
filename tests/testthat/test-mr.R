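pair_for <- function(bx, by, se_y = 0.01, binary = TRUE) {
  ex <- sumstats("rs1", "11", 61e6, "A", "G", eaf = 0.3, beta = bx,
                 se = 0.05, n = 1e4, trait_id = "x")
  ou <- sumstats("rs1", "11", 61e6, "A", "G", eaf = 0.3, beta = by,
                 se = se_y, n = 1e4,
                 n_cases = if (binary) 2000 else NA, trait_id = "y")
  list(ex = ex, ou = ou)
}

test_that("Wald ratio matches its closed form and handles the null", {
  p <- pair_for(0.5, 0.035, 0.01)
  res <- wald_ratio(p$ex, p$ou)
  expect_equal(res$beta, 0.07)
  expect_equal(res$se, 0.02)
  expect_equal(res$or, exp(0.07))
  expect_equal(res$or_low, exp(0.07 - 1.96 * 0.02))
  expect_equal(res$or_high, exp(0.07 + 1.96 * 0.02))
  expect_true(res$or_low < res$or && res$or < res$or_high)

  p0 <- pair_for(0.5, 0)
  res0 <- wald_ratio(p0$ex, p0$ou)
  expect_equal(res0$beta, 0)
  expect_equal(res0$pval, 1)

  pz <- pair_for(0, 0.02)
  expect_error(wald_ratio(pz$ex, pz$ou),
               class = "ratiomr_undefined_ratio")
})

test_that("SE stays positive and sign equivariance holds for negative exposure effects", {
  p <- pair_for(-0.5, 0.035, 0.01)
  res <- wald_ratio(p$ex, p$ou)
  expect_equal(res$beta, -0.07)
  expect_equal(res$se, 0.02)
  pos <- wald_ratio(pair_for(0.5, 0.035, 0.01)$ex,
                    pair_for(0.5, 0.035, 0.01)$ou)
  expect_equal(res$pval, pos$pval)
})

test_that("fixed-effect IVW pooling matches closed-form weights", {
  one <- ivw_meta(0.02, 0.01)
  expect_equal(one$beta, 0.02)
  expect_equal(one$se, 0.01)

  two <- ivw_meta(c(0.02, 0.02), c(0.01, 0.01))
  expect_equal(two$beta, 0.02)
  expect_equal(two$se, 0.01 / sqrt(2), tolerance = 1e-7)

  mix <- ivw_meta(c(0, 0.03), c(0.01, 0.02))
  expect_equal(mix$beta, 0.006)
  expect_equal(mix$se, 0.0089443, tolerance = 1e-5)

  expect_error(ivw_meta(numeric(0), numeric(0)),
               class = "ratiomr_config_error")
  # pooled variance cannot exceed the best single estimate's variance
  set.seed(1)
  for (i in 1:10) {
    b <- rnorm(5); s <- runif(5, 0.01, 0.2)
    expect_lte(ivw_meta(b, s)$se, min(s))
  }
})

test_that("multi-SNP IVW pools per-variant Wald ratios", {
  ids <- sprintf("rs%d", 1:3)
  ex <- sumstats(ids, "11", 61e6 + 1:3, "A", "G", eaf = 0.3,
                 beta = c(0.2, 0.4, 0.5), se = 0.02, n = 1e4,
                 trait_id = "x")
  ou <- sumstats(ids, "11", 61e6 + 1:3, "A", "G", eaf = 0.3,
                 beta = c(0.2, 0.4, 0.5) * 0.15, se = 0.02, n = 1e4,
                 n_cases = 2000, trait_id = "y")
  res <- ivw_multi_snp(ex, ou)
  expect_equal(res$beta, 0.15, tolerance = 1e-12)
  expect_equal(res$n_snps, 3L)

  # duplicating a variant k times shrinks the pooled SE by sqrt(k)
  k <- 4
  exk <- ex[rep(1, k), ]; exk$variant_id <- sprintf("rs%d", 1:k)
  ouk <- ou[rep(1, k), ]; ouk$variant_id <- sprintf("rs%d", 1:k)
  one <- wald_ratio(ex[1, ], ou[1, ])
  many <- ivw_multi_snp(exk, ouk)
  expect_equal(many$se, one$se / sqrt(k), tolerance = 1e-12)

  expect_error(ivw_multi_snp(ex[1, ], ou[1, ]),
               class = "ratiomr_config_error")
})

test_that("Bonferroni thresholds reproduce the standard quoted values", {
  t9 <- bonferroni_threshold(0.05, 9)
  expect_equal(attr(t9, "signif3"), 0.00556)
  t8 <- bonferroni_threshold(0.05, 8)
  expect_equal(attr(t8, "signif3"), 0.00625)
  expect_equal(as.numeric(bonferroni_threshold(0.05, 1)), 0.05)
  expect_error(bonferroni_threshold(0.05, 0),
               class = "ratiomr_config_error")
})

test_that("greedy clumping keeps the best of correlated variants", {
  ids <- c("a", "b", "c")
  ss <- sumstats(ids, "11", 61e6 + 1:3, "A", "G", eaf = 0.3,
                 beta = c(0.65, 0.55, 0.5), se = 0.1, n = 1e4,
                 trait_id = "x")
  ld <- simple_ld(ids, list(list(i = "a", j = "b", r = sqrt(0.9))))
  kept <- clump_independent(ss, ld, p_threshold = 1e-5,
                            r2_threshold = 0.05)
  expect_setequal(kept$variant_id, c("a", "c"))

  # mutually independent trio all kept
  kept2 <- clump_independent(ss, simple_ld(ids), p_threshold = 1e-5,
                             r2_threshold = 0.05)
  expect_equal(nrow(kept2), 3L)
})

test_that("greedy clumping equals exhaustive p-lexicographic selection on small sets", {
  # oracle: enumerate every independent subset passing p, take the one
  # whose sorted p-sequence is lexicographically smallest and maximal
  oracle <- function(ss, ld, p_thr, r2_thr) {
    ok <- which(ss$pval < p_thr)
    best <- NULL
    for (mask in seq_len(2^length(ok)) - 1L) {
      sel <- ok[bitwAnd(mask, 2^(seq_along(ok) - 1)) > 0]
      if (length(sel) < 2) {
        indep <- TRUE
      } else {
        rr <- ld$r[match(ss$variant_id[sel], ld$variant_ids),
                   match(ss$variant_id[sel], ld$variant_ids)]^2
        indep <- max(rr[upper.tri(rr)]) < r2_thr
      }
      if (!indep) next
      # maximality: no further eligible variant can be added
      can_add <- any(vapply(setdiff(ok, sel), function(j) {
        if (length(sel) == 0) return(TRUE)
        all(ld$r[match(ss$variant_id[j], ld$variant_ids),
                 match(ss$variant_id[sel], ld$variant_ids)]^2 < r2_thr)
      }, logical(1)))
      if (can_add) next
      key <- sort(ss$pval[sel])
      if (is.null(best)) {
        best <- sel
      } else {
        bk <- sort(ss$pval[best])
        L <- min(length(key), length(bk))
        cmp <- which(key[seq_len(L)] != bk[seq_len(L)])[1]
        better <- if (!is.na(cmp)) key[cmp] < bk[cmp]
        else length(key) > length(bk)
        if (better) best <- sel
      }
    }
    sort(ss$variant_id[best])
  }
  set.seed(11)
  for (rep in 1:10) {
    k <- sample(4:7, 1)
    ids <- sprintf("v%d", seq_len(k))
    z <- abs(rnorm(k, 4, 2)) + 1
    ss <- sumstats(ids, "1", seq_len(k), "A", "G", eaf = 0.3,
                   beta = z * 0.05, se = 0.05, n = 1e4, trait_id = "x")
    m <- diag(k)
    for (i in seq_len(k - 1)) for (j in (i + 1):k)
      m[i, j] <- m[j, i] <- runif(1, -0.6, 0.6)
    # make it a valid correlation matrix by shrinking toward identity
    ev <- min(eigen(m, symmetric = TRUE, only.values = TRUE)$values)
    if (ev < 0.05) m <- (m + diag(k) * (0.1 - ev)) / (1 + 0.1 - ev)
    ld <- ld_matrix(m, ids)
    got <- clump_independent(ss, ld, p_threshold = 1e-3,
                             r2_threshold = 0.1)
    expect_equal(sort(got$variant_id), oracle(ss, ld, 1e-3, 0.1))
  }
})
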