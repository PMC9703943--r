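# Shared fixtures and independent oracles for the test suite.

# small well-formed association table built in code
tiny_sumstats <- function(trait = "exposure") {
  sumstats(variant_id = c("rs1", "rs2", "rs3"),
           chrom = "11", pos = c(61100000L, 61200000L, 61300000L),
           effect_allele = c("A", "C", "G"),
           other_allele = c("G", "T", "A"),
           eaf = c(0.30, 0.45, 0.12),
           beta = c(0.50, -0.05, 0.02),
           se = c(0.05, 0.04, 0.03),
           n = 10000, trait_id = trait)
}

# independent naive Benjamini-Hochberg step-up, O(m^2)
naive_bh <- function(p) {
  m <- length(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    # step-up: min over all j with p_j >= p_i of m * p_j / rank_j
    cand <- vapply(seq_len(m), function(j) {
      if (p[j] >= p[i]) m * p[j] / sum(p <= p[j]) else Inf
    }, numeric(1))
    q[i] <- min(1, min(cand))
  }
  q
}

# exhaustive-configuration colocalization oracle for small regions:
# enumerates every (variant-or-none) x (variant-or-none) causal
# configuration explicitly, in plain arithmetic
brute_coloc <- function(beta1, se1, beta2, se2, p1, p2, p12, w1, w2) {
  abf <- function(b, s, w) {
    z <- b / s
    r <- w / (w + s^2)
    exp(0.5 * log(1 - r) + z^2 * r / 2)
  }
  n <- length(beta1)
  bf1 <- vapply(seq_len(n), function(i) abf(beta1[i], se1[i], w1),
                numeric(1))
  bf2 <- vapply(seq_len(n), function(i) abf(beta2[i], se2[i], w2),
                numeric(1))
  s <- c(h1 = 0, h2 = 0, h3 = 0, h4 = 0, h5 = 0)
  for (i in c(0, seq_len(n))) {     # causal variant for trait 1 (0 = none)
    for (j in c(0, seq_len(n))) {   # causal variant for trait 2
      w <- 1
      if (i > 0) w <- w * p1 * bf1[i]
      if (j > 0) w <- w * p2 * bf2[j]
      if (i > 0 && j > 0 && i == j) w <- p12 * bf1[i] * bf2[j]
      h <- if (i == 0 && j == 0) "h5"
      else if (j == 0) "h1"
      else if (i == 0) "h2"
      else if (i == j) "h4"
      else "h3"
      s[h] <- s[h] + w
    }
  }
  s / sum(s)
}

# random small coloc instance (optionally with a shared signal)
random_region <- function(n, seed, shared = FALSE) {
  set.seed(seed)
  b1 <- rnorm(n, 0, 0.05)
  b2 <- rnorm(n, 0, 0.05)
  if (shared) {
    k <- sample(n, 1)
    b1[k] <- b1[k] + 0.4
    b2[k] <- b2[k] + 0.3
  }
  ids <- sprintf("rs%03d", seq_len(n))
  t1 <- sumstats(ids, "11", 61000000 + seq_len(n) * 1000, "A", "G",
                 eaf = runif(n, 0.1, 0.5), beta = b1,
                 se = runif(n, 0.04, 0.08), n = 10000, trait_id = "t1")
  t2 <- sumstats(ids, "11", 61000000 + seq_len(n) * 1000, "A", "G",
                 eaf = t1$eaf, beta = b2, se = runif(n, 0.04, 0.08),
                 n = 10000, trait_id = "t2")
  list(t1 = t1, t2 = t2)
}

# identity LD matrix over given ids with optional off-diagonal entries
simple_ld <- function(ids, pairs = NULL) {
  m <- diag(length(ids))
  dimnames(m) <- list(ids, ids)
  if (!is.null(pairs)) {
    for (p in pairs) {
      m[p$i, p$j] <- m[p$j, p$i] <- p$r
    }
  }
  ld_matrix(m, ids)
}
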