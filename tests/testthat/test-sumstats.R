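test_that("write/read round trip preserves records exactly", {
  ss <- tiny_sumstats()
  f <- withr::local_tempfile(fileext = ".tsv")
  write_sumstats(ss, f)
  back <- read_sumstats(f)
  expect_equal(back$variant_id, ss$variant_id)
  expect_equal(back$beta, ss$beta, tolerance = 0)
  expect_equal(back$se, ss$se, tolerance = 0)
  expect_equal(back$eaf, ss$eaf, tolerance = 0)
  expect_identical(attr(back, "rejections")$line, integer(0))
  # negative beta survives with its sign
  expect_equal(back$beta[2], -0.05)

  # empty table -> header-only file, re-readable
  write_sumstats(ss[0, ], f)
  expect_equal(length(readLines(f)), 1L)
  expect_equal(nrow(read_sumstats(f)), 0L)
})

test_that("invalid rows are rejected with per-row reasons, order kept", {
  ss <- tiny_sumstats()
  f <- withr::local_tempfile(fileext = ".tsv")
  write_sumstats(ss, f)
  lines <- readLines(f)
  # corrupt row 2: eaf = 1.2
  fields <- strsplit(lines[3], "\t")[[1]]
  fields[6] <- "1.2"
  lines[3] <- paste(fields, collapse = "\t")
  writeLines(lines, f)
  expect_message(back <- read_sumstats(f), "rejected 1 row")
  expect_equal(nrow(back), 2L)
  expect_equal(back$variant_id, c("rs1", "rs3"))
  rej <- attr(back, "rejections")
  expect_equal(rej$line, 3L)
  expect_match(rej$reason, "eaf")
})

test_that("missing mandatory columns and bad numerics are flagged", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("SNP\tCHR\tPOS", "rs1\t1\t100"), f)
  expect_error(read_sumstats(f), class = "ratiomr_config_error")

  ss <- tiny_sumstats()
  write_sumstats(ss, f)
  lines <- readLines(f)
  fields <- strsplit(lines[2], "\t")[[1]]
  fields[7] <- "not_a_number"
  lines[2] <- paste(fields, collapse = "\t")
  writeLines(lines, f)
  back <- read_sumstats(f, quiet = TRUE)
  expect_equal(attr(back, "rejections")$reason, "unparsable numeric in BETA")
})

test_that("pval/beta consistency invariant is enforced", {
  expect_error(
    sumstats("rs1", "1", 100, "A", "G", eaf = 0.3, beta = 0.5, se = 0.05,
             pval = 0.9, n = 1000, trait_id = "t"),
    class = "ratiomr_invalid_row")
})

test_that("palindromic detection follows allele complementarity", {
  ss <- sumstats(c("a", "b", "c", "d"), "1", 1:4,
                 effect_allele = c("A", "A", "C", "G"),
                 other_allele = c("T", "G", "G", "C"),
                 eaf = 0.2, beta = 0.1, se = 0.05, n = 100, trait_id = "t")
  expect_identical(is_palindromic(ss), c(TRUE, FALSE, TRUE, TRUE))
})

test_that("harmonization re-orients swapped outcome alleles", {
  ex <- sumstats("rs1", "1", 100, "A", "G", eaf = 0.3, beta = 0.5,
                 se = 0.05, n = 1e4, trait_id = "x")
  ou <- sumstats("rs1", "1", 100, "G", "A", eaf = 0.3, beta = 0.02,
                 se = 0.01, n = 1e4, trait_id = "y")
  h <- harmonize_pair(ex, ou)
  expect_equal(h$outcome$beta, -0.02)
  expect_equal(h$outcome$eaf, 0.7)
  expect_equal(h$outcome$effect_allele, "A")
  # magnitudes and p untouched by orientation flips
  expect_equal(abs(h$outcome$beta), 0.02)
  expect_equal(h$outcome$se, ou$se)
  expect_equal(h$outcome$pval, ou$pval)
})

test_that("activity-increasing convention flips both records together", {
  ex <- sumstats("rs1", "1", 100, "A", "G", eaf = 0.3, beta = -0.5,
                 se = 0.05, n = 1e4, trait_id = "x")
  ou <- sumstats("rs1", "1", 100, "A", "G", eaf = 0.3, beta = 0.02,
                 se = 0.01, n = 1e4, trait_id = "y")
  h <- harmonize_pair(ex, ou)
  expect_equal(h$exposure$beta, 0.5)
  expect_equal(h$exposure$effect_allele, "G")
  expect_equal(h$exposure$eaf, 0.7)
  expect_equal(h$outcome$beta, -0.02)
  expect_equal(h$outcome$eaf, 0.7)
})

test_that("ambiguous palindromes are excluded, clear ones kept", {
  ex <- sumstats(c("rs1", "rs2"), "1", c(100, 200), c("A", "A"),
                 c("T", "T"), eaf = c(0.49, 0.10), beta = c(0.2, 0.2),
                 se = 0.05, n = 1e4, trait_id = "x")
  ou <- sumstats(c("rs1", "rs2"), "1", c(100, 200), c("A", "A"),
                 c("T", "T"), eaf = c(0.48, 0.12), beta = c(0.1, 0.1),
                 se = 0.05, n = 1e4, trait_id = "y")
  h <- harmonize_pair(ex, ou)
  expect_equal(h$excluded$variant_id, "rs1")
  expect_equal(h$excluded$reason, "ambiguous_palindrome")
  expect_equal(h$exposure$variant_id, "rs2")
})

test_that("strand flips resolve for non-palindromic variants only", {
  ex <- sumstats("rs1", "1", 100, "A", "G", eaf = 0.3, beta = 0.5,
                 se = 0.05, n = 1e4, trait_id = "x")
  # reported on the other strand: T/C complements A/G
  ou <- sumstats("rs1", "1", 100, "T", "C", eaf = 0.3, beta = 0.02,
                 se = 0.01, n = 1e4, trait_id = "y")
  h <- harmonize_pair(ex, ou)
  expect_equal(h$outcome$beta, 0.02)
  expect_equal(h$outcome$effect_allele, "A")
  # truly irreconcilable alleles are a hard error
  ou2 <- sumstats("rs1", "1", 100, "A", "C", eaf = 0.3, beta = 0.02,
                  se = 0.01, n = 1e4, trait_id = "y")
  expect_error(harmonize_pair(ex, ou2),
               class = "ratiomr_harmonization_error")
})

test_that("harmonization is idempotent over random cases", {
  set.seed(7)
  pairs <- list(c("A", "G"), c("C", "T"), c("G", "A"), c("A", "T"),
                c("C", "G"))
  for (i in 1:25) {
    al <- pairs[[sample(5, 1)]]
    swap <- sample(c(TRUE, FALSE), 1)
    ex <- sumstats("rs1", "1", 100, al[1], al[2],
                   eaf = runif(1, 0.05, 0.95),
                   beta = rnorm(1, 0, 0.3), se = runif(1, 0.02, 0.1),
                   n = 1e4, trait_id = "x")
    ou <- sumstats("rs1", "1", 100,
                   if (swap) al[2] else al[1],
                   if (swap) al[1] else al[2],
                   eaf = if (swap) 1 - ex$eaf else ex$eaf,
                   beta = rnorm(1, 0, 0.1), se = runif(1, 0.02, 0.1),
                   n = 1e4, trait_id = "y")
    h1 <- harmonize_pair(ex, ou)
    if (nrow(h1$exposure) == 0L) next
    h2 <- harmonize_pair(h1$exposure, h1$outcome)
    expect_equal(h2$exposure, h1$exposure)
    expect_equal(h2$outcome, h1$outcome)
  }
})

test_that("LD proxy selection picks the strongest eligible variant", {
  cand <- sumstats(c("rs174546", "rsB", "rsP"), "11",
                   c(61100, 61200, 61300), c("C", "A", "A"),
                   c("T", "G", "T"), eaf = c(0.3, 0.3, 0.3),
                   beta = c(0.5, 0.4, 0.6), se = 0.05, n = 1e4,
                   trait_id = "x")
  ld <- simple_ld(c("rs174576", "rs174546", "rsB", "rsP"),
                  pairs = list(list(i = "rs174576", j = "rs174546",
                                    r = sqrt(0.93)),
                               list(i = "rs174576", j = "rsB",
                                    r = sqrt(0.85)),
                               list(i = "rs174576", j = "rsP",
                                    r = 0.99)))
  got <- select_ld_proxy("rs174576", cand, ld, min_r2 = 0.8)
  expect_equal(got$variant_id, "rs174546")
  expect_equal(attr(got, "proxy_r2"), 0.93, tolerance = 1e-12)

  # all candidates palindromic -> error
  pal_only <- cand[cand$variant_id == "rsP", ]
  expect_error(select_ld_proxy("rs174576", pal_only, ld),
               class = "ratiomr_proxy_error")
  # r2 floor respected
  expect_error(select_ld_proxy("rs174576", cand, ld, min_r2 = 0.95),
               class = "ratiomr_proxy_error")
})

test_that("LD matrix and region plumbing validate and round trip", {
  expect_error(ld_matrix(matrix(c(1, 0.5, 0.2, 1), 2, 2), c("a", "b")),
               class = "ratiomr_config_error")
  ld <- simple_ld(c("a", "b"), list(list(i = "a", j = "b", r = -0.4)))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_ld_matrix(ld, f)
  back <- read_ld_matrix(f)
  expect_equal(back$r, ld$r, tolerance = 1e-12)

  reg <- region_spec("FADS1", "11", 61567097L)
  expect_equal(reg$start, 61067097L)
  expect_equal(reg$end, 62067097L)
  ss <- tiny_sumstats()
  expect_identical(in_region(ss, reg), c(TRUE, TRUE, TRUE))
  expect_false(any(in_region(ss, region_spec("X", "2", 61200000L))))
})
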