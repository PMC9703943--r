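#' GWAS summary statistics: data model, file I/O and allele harmonization
#'
#' A set of variant-trait associations is represented as a plain
#' `data.frame` with one row per variant and the columns
#' `variant_id`, `chrom`, `pos`, `effect_allele`, `other_allele`, `eaf`,
#' `beta`, `se`, `pval`, `n`, `n_cases` (NA for quantitative traits) and
#' `trait_id`. `beta` is the per-effect-allele association: SD units for
#' quantitative traits, log-odds for binary traits.
#'
#' @name sumstats-format
NULL

SUMSTAT_COLS <- c("variant_id", "chrom", "pos", "effect_allele",
                  "other_allele", "eaf", "beta", "se", "pval", "n",
                  "n_cases", "trait_id")

#' Construct a validated summary-statistics table
#'
#' Vectorized constructor; every argument is recycled to a common length.
#' Stops on the first invariant violation (use [read_sumstats()] for
#' tolerant row-wise rejection when ingesting files).
#'
#' @param variant_id rsID-style variant identifiers.
#' @param chrom Chromosome labels.
#' @param pos 1-based base-pair positions.
#' @param effect_allele,other_allele Single-base alleles (A/C/G/T).
#' @param eaf Effect-allele frequency, strictly in (0, 1).
#' @param beta Per-effect-allele effect estimate.
#' @param se Positive standard error of `beta`.
#' @param pval Two-sided p-value; defaults to the normal approximation
#'   `2 * pnorm(-|beta/se|)`.
#' @param n Sample size.
#' @param n_cases Case count for binary traits (NA otherwise).
#' @param trait_id Trait identifier.
#' @return A `data.frame` in the summary-statistics layout.
#' @export
sumstats <- function(variant_id, chrom, pos, effect_allele, other_allele,
                     eaf, beta, se, pval = NULL, n, n_cases = NA_integer_,
                     trait_id) {
  if (is.null(pval)) pval <- 2 * stats::pnorm(-abs(beta / se))
  df <- data.frame(variant_id = as.character(variant_id),
                   chrom = as.character(chrom),
                   pos = as.integer(pos),
                   effect_allele = toupper(as.character(effect_allele)),
                   other_allele = toupper(as.character(other_allele)),
                   eaf = as.numeric(eaf), beta = as.numeric(beta),
                   se = as.numeric(se), pval = as.numeric(pval),
                   n = as.numeric(n), n_cases = as.numeric(n_cases),
                   trait_id = as.character(trait_id),
                   stringsAsFactors = FALSE)
  bad <- check_sumstat_rows(df)
  if (any(!is.na(bad))) {
    i <- which(!is.na(bad))[1L]
    stop_ratiomr(sprintf("invalid association row %d (%s): %s",
                         i, df$variant_id[i], bad[i]), "ratiomr_invalid_row")
  }
  df
}

# Per-row invariant check; returns NA for valid rows, else a reason string.
check_sumstat_rows <- function(df) {
  reason <- rep(NA_character_, nrow(df))
  flag <- function(cond, msg) {
    cond[is.na(cond)] <- TRUE
    reason[is.na(reason) & cond] <<- msg
  }
  ok_allele <- function(a) a %in% c("A", "C", "G", "T")
  flag(!ok_allele(df$effect_allele), "effect_allele not one of A/C/G/T")
  flag(!ok_allele(df$other_allele), "other_allele not one of A/C/G/T")
  flag(df$effect_allele == df$other_allele, "effect_allele == other_allele")
  flag(!(df$eaf > 0 & df$eaf < 1), "eaf outside (0,1)")
  flag(!(df$se > 0), "se not positive")
  flag(!(df$pval >= 0 & df$pval <= 1), "pval outside [0,1]")
  flag(!(df$n > 0), "n not positive")
  # p must agree with the two-sided normal p for beta/se to a factor of 10
  # (skipped where both underflow double precision)
  p_exp <- 2 * stats::pnorm(-abs(df$beta / df$se))
  comparable <- is.na(reason) & p_exp > 1e-300 & df$pval > 1e-300
  off <- abs(log10(df$pval) - log10(p_exp)) > 1
  flag(comparable & off, "pval inconsistent with beta/se (factor > 10)")
  flag(is.na(reason) & (p_exp <= 1e-300) != (df$pval <= 1e-300),
       "pval inconsistent with beta/se (factor > 10)")
  reason
}

#' Default column-name mapping for summary-statistics files
#'
#' @param ... Name-value overrides, e.g. `SNP = "rsid"`.
#' @return Named character vector mapping internal fields to file columns.
#' @export
sumstats_dialect <- function(...) {
  d <- c(variant_id = "SNP", chrom = "CHR", pos = "POS",
         effect_allele = "EA", other_allele = "OA", eaf = "EAF",
         beta = "BETA", se = "SE", pval = "P", n = "N",
         n_cases = "N_CASES", trait_id = "TRAIT")
  ov <- list(...)
  if (length(ov)) {
    bad <- setdiff(names(ov), names(d))
    if (length(bad))
      stop_ratiomr(paste("unknown dialect field(s):",
                         paste(bad, collapse = ", ")),
                   "ratiomr_config_error")
    d[names(ov)] <- unlist(ov)
  }
  d
}

#' Read GWAS summary statistics from a tab-delimited file
#'
#' Rows violating the data-model invariants are dropped, with one logged
#' reason per row; the retained rows keep their file order. The rejection
#' log is attached as attribute `"rejections"` (a `data.frame` with `line`
#' and `reason`).
#'
#' @param path Path to a tab-delimited file with a header row.
#' @param dialect Column mapping from [sumstats_dialect()].
#' @param trait_id Trait id to assign when the file has no trait column.
#' @param quiet Suppress the rejection messages.
#' @return Summary-statistics `data.frame`.
#' @export
read_sumstats <- function(path, dialect = sumstats_dialect(),
                          trait_id = NULL, quiet = FALSE) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character",
                           check.names = FALSE, stringsAsFactors = FALSE)
  optional <- c("n_cases", "trait_id")
  need <- dialect[setdiff(names(dialect), optional)]
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop_ratiomr(paste("missing mandatory column(s):",
                       paste(miss, collapse = ", ")),
                 "ratiomr_config_error")
  get_col <- function(field, default = NA_character_) {
    col <- dialect[[field]]
    if (col %in% names(raw)) raw[[col]] else rep(default, nrow(raw))
  }
  num <- function(x) suppressWarnings(as.numeric(x))
  df <- data.frame(variant_id = get_col("variant_id"),
                   chrom = get_col("chrom"),
                   pos = as.integer(num(get_col("pos"))),
                   effect_allele = toupper(get_col("effect_allele")),
                   other_allele = toupper(get_col("other_allele")),
                   eaf = num(get_col("eaf")), beta = num(get_col("beta")),
                   se = num(get_col("se")), pval = num(get_col("pval")),
                   n = num(get_col("n")), n_cases = num(get_col("n_cases")),
                   trait_id = get_col("trait_id"),
                   stringsAsFactors = FALSE)
  if (!is.null(trait_id)) df$trait_id[is.na(df$trait_id)] <- trait_id
  numeric_src <- c(pos = "pos", eaf = "eaf", beta = "beta", se = "se",
                   pval = "pval", n = "n")
  reason <- rep(NA_character_, nrow(df))
  for (f in names(numeric_src)) {
    bad <- is.na(df[[f]]) & !is.na(raw[[dialect[[f]]]]) &
      nzchar(raw[[dialect[[f]]]])
    reason[is.na(reason) & bad] <- sprintf("unparsable numeric in %s",
                                           dialect[[f]])
  }
  inv <- check_sumstat_rows(df)
  reason[is.na(reason)] <- inv[is.na(reason)]
  keep <- is.na(reason)
  rejections <- data.frame(line = which(!keep) + 1L,
                           reason = reason[!keep],
                           stringsAsFactors = FALSE)
  if (nrow(rejections) && !quiet)
    message(sprintf("read_sumstats: rejected %d row(s): %s",
                    nrow(rejections),
                    paste(sprintf("line %d (%s)", rejections$line,
                                  rejections$reason), collapse = "; ")))
  out <- df[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rejections") <- rejections
  out
}

#' Write summary statistics to a tab-delimited file
#'
#' Numeric fields are written with 17 significant digits so that a
#' write/read round trip reproduces the records exactly.
#'
#' @param records Summary-statistics `data.frame`.
#' @param path Output path.
#' @param dialect Column mapping from [sumstats_dialect()].
#' @export
write_sumstats <- function(records, path, dialect = sumstats_dialect()) {
  out <- records[, SUMSTAT_COLS, drop = FALSE]
  for (f in c("eaf", "beta", "se", "pval", "n", "n_cases"))
    out[[f]] <- formatC(out[[f]], digits = 17, format = "g")
  out$n_cases[is.na(records$n_cases)] <- "NA"
  names(out) <- dialect[SUMSTAT_COLS]
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Test whether variants are palindromic
#'
#' A palindromic (strand-ambiguous) variant has complementary alleles:
#' A/T or C/G.
#'
#' @param assoc Summary-statistics `data.frame` (any number of rows).
#' @return Logical vector, one per row.
#' @export
is_palindromic <- function(assoc) {
  pair <- paste(pmin(assoc$effect_allele, assoc$other_allele),
                pmax(assoc$effect_allele, assoc$other_allele))
  pair %in% c("A T", "C G")
}

complement_alleles <- function(a) {
  c(A = "T", T = "A", C = "G", G = "C")[a]
}

#' Harmonize an exposure/outcome pair of association records
#'
#' Re-orients the outcome records to the exposure's effect allele (flipping
#' the outcome beta sign and `eaf -> 1 - eaf` when the alleles are listed
#' swapped), resolves strand flips for non-palindromic variants by allele
#' complementation, and then flips both records together wherever needed so
#' the effect allele is the exposure-increasing allele (exposure beta >= 0).
#'
#' Palindromic variants are never strand-resolved; they are retained only
#' when the minor-allele frequency is below `palindrome_maf_limit` in both
#' records and the allele frequencies agree on which allele is minor;
#' otherwise they are excluded with a reason code.
#'
#' @param exposure,outcome Summary-statistics `data.frame`s sharing variant
#'   ids (matched on `variant_id`; one or many rows).
#' @param palindrome_maf_limit Frequency above which a palindromic variant
#'   is considered ambiguous (default 0.42, i.e. ambiguity window
#'   0.42-0.5).
#' @param make_exposure_positive Apply the activity-increasing-allele sign
#'   convention (default TRUE); set FALSE for pure allele alignment, e.g.
#'   when pooling one trait's records across cohorts.
#' @return List with elements `exposure` and `outcome` (aligned, same row
#'   order) and `excluded` (a `data.frame` of `variant_id`, `reason`).
#' @export
harmonize_pair <- function(exposure, outcome, palindrome_maf_limit = 0.42,
                           make_exposure_positive = TRUE) {
  m <- match(exposure$variant_id, outcome$variant_id)
  if (anyNA(m))
    stop_ratiomr("exposure variants missing from outcome records",
                 "ratiomr_harmonization_error")
  outcome <- outcome[m, , drop = FALSE]
  ex <- exposure
  ou <- outcome
  n <- nrow(ex)
  drop_reason <- rep(NA_character_, n)
  pal <- is_palindromic(ex)

  same <- ou$effect_allele == ex$effect_allele &
    ou$other_allele == ex$other_allele
  swapped <- ou$effect_allele == ex$other_allele &
    ou$other_allele == ex$effect_allele
  # palindromes match under both strand readings; orient by frequency below
  unresolved <- !same & !swapped
  if (any(unresolved & !pal)) {
    idx <- which(unresolved & !pal)
    cea <- complement_alleles(ou$effect_allele[idx])
    coa <- complement_alleles(ou$other_allele[idx])
    s2 <- cea == ex$effect_allele[idx] & coa == ex$other_allele[idx]
    w2 <- cea == ex$other_allele[idx] & coa == ex$effect_allele[idx]
    ou$effect_allele[idx] <- cea
    ou$other_allele[idx] <- coa
    same[idx] <- s2
    swapped[idx] <- w2
    if (any(!s2 & !w2))
      stop_ratiomr(sprintf("irreconcilable alleles for variant(s): %s",
                           paste(ex$variant_id[idx][!s2 & !w2],
                                 collapse = ", ")),
                   "ratiomr_harmonization_error")
  }
  if (any(unresolved & pal))
    stop_ratiomr(sprintf("irreconcilable alleles for variant(s): %s",
                         paste(ex$variant_id[unresolved & pal],
                               collapse = ", ")),
                 "ratiomr_harmonization_error")

  flip <- swapped
  ou$beta[flip] <- -ou$beta[flip]
  ou$eaf[flip] <- 1 - ou$eaf[flip]
  ou$effect_allele[flip] <- ex$effect_allele[flip]
  ou$other_allele[flip] <- ex$other_allele[flip]

  if (any(pal)) {
    maf_ok <- pmin(ex$eaf, 1 - ex$eaf) < palindrome_maf_limit &
      pmin(ou$eaf, 1 - ou$eaf) < palindrome_maf_limit
    concordant <- (ex$eaf - 0.5) * (ou$eaf - 0.5) > 0
    amb <- pal & !(maf_ok & concordant)
    drop_reason[amb] <- "ambiguous_palindrome"
  }

  # activity-increasing allele convention: exposure beta made positive by
  # flipping BOTH records together
  neg <- ex$beta < 0 & is.na(drop_reason) & make_exposure_positive
  flip_both <- function(df, idx) {
    ea <- df$effect_allele[idx]
    df$effect_allele[idx] <- df$other_allele[idx]
    df$other_allele[idx] <- ea
    df$beta[idx] <- -df$beta[idx]
    df$eaf[idx] <- 1 - df$eaf[idx]
    df
  }
  ex <- flip_both(ex, which(neg))
  ou <- flip_both(ou, which(neg))

  keep <- is.na(drop_reason)
  excluded <- data.frame(variant_id = ex$variant_id[!keep],
                         reason = drop_reason[!keep],
                         stringsAsFactors = FALSE)
  ex <- ex[keep, , drop = FALSE]
  ou <- ou[keep, , drop = FALSE]
  rownames(ex) <- rownames(ou) <- NULL
  list(exposure = ex, outcome = ou, excluded = excluded)
}

#' Select a non-palindromic LD proxy for a target variant
#'
#' Used when the top instrument variant is palindromic and must be replaced
#' by a strand-unambiguous variant in strong LD.
#'
#' @param target Variant id to be proxied.
#' @param candidates Summary-statistics `data.frame` of candidate variants.
#' @param ld [ld_matrix()] covering the target and candidates.
#' @param min_r2 Minimum squared correlation with the target (default 0.8).
#' @return The selected candidate row (maximal r-squared; ties broken by
#'   smaller p, larger absolute beta, then variant id).
#' @export
select_ld_proxy <- function(target, candidates, ld, min_r2 = 0.8) {
  if (!target %in% ld$variant_ids)
    stop_ratiomr("target variant not in LD matrix", "ratiomr_proxy_error")
  cand <- candidates[candidates$variant_id != target &
                       !is_palindromic(candidates) &
                       candidates$variant_id %in% ld$variant_ids, ,
                     drop = FALSE]
  if (nrow(cand) == 0L)
    stop_ratiomr("no non-palindromic proxy candidate available",
                 "ratiomr_proxy_error")
  r2 <- ld$r[match(cand$variant_id, ld$variant_ids),
             match(target, ld$variant_ids)]^2
  cand <- cand[r2 >= min_r2, , drop = FALSE]
  r2 <- r2[r2 >= min_r2]
  if (nrow(cand) == 0L)
    stop_ratiomr(sprintf("no proxy with r2 >= %g for %s", min_r2, target),
                 "ratiomr_proxy_error")
  o <- order(-r2, cand$pval, -abs(cand$beta), cand$variant_id)
  out <- cand[o[1L], , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "proxy_r2") <- unname(r2[o[1L]])
  out
}

#' LD matrix of signed genotype correlations
#'
#' @param r Square numeric matrix of signed correlations, oriented to the
#'   same alleles as the associated summary statistics.
#' @param variant_ids Variant ids in matrix order.
#' @return An object of class `ld_matrix` (list with `variant_ids`, `r`).
#' @export
ld_matrix <- function(r, variant_ids = rownames(r)) {
  r <- as.matrix(r)
  if (is.null(variant_ids))
    stop_ratiomr("variant_ids required", "ratiomr_config_error")
  if (nrow(r) != ncol(r) || nrow(r) != length(variant_ids))
    stop_ratiomr("LD matrix dimension mismatch", "ratiomr_config_error")
  if (max(abs(r - t(r))) > 1e-8)
    stop_ratiomr("LD matrix not symmetric", "ratiomr_config_error")
  if (max(abs(diag(r) - 1)) > 1e-8)
    stop_ratiomr("LD matrix diagonal not 1", "ratiomr_config_error")
  if (max(abs(r)) > 1 + 1e-8)
    stop_ratiomr("LD correlations outside [-1,1]", "ratiomr_config_error")
  r <- (r + t(r)) / 2
  diag(r) <- 1
  r[r > 1] <- 1
  r[r < -1] <- -1
  dimnames(r) <- list(variant_ids, variant_ids)
  structure(list(variant_ids = as.character(variant_ids), r = r),
            class = "ld_matrix")
}

#' @export
print.ld_matrix <- function(x, ...) {
  cat(sprintf("LD matrix: %d variants (%s ... %s)\n",
              length(x$variant_ids), x$variant_ids[1L],
              x$variant_ids[length(x$variant_ids)]))
  invisible(x)
}

#' Read / write an LD matrix as tab-delimited text
#'
#' The file is a square matrix whose first row and first column hold the
#' variant ids.
#'
#' @param path File path.
#' @return For `read_ld_matrix`, an [ld_matrix()].
#' @export
read_ld_matrix <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t", row.names = 1L,
                           check.names = FALSE)
  ld_matrix(as.matrix(tab), variant_ids = rownames(tab))
}

#' @rdname read_ld_matrix
#' @param ld An [ld_matrix()].
#' @export
write_ld_matrix <- function(ld, path) {
  m <- format(ld$r, digits = 17, trim = TRUE)
  utils::write.table(cbind(ID = ld$variant_ids, m), path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Cis region around a target gene
#'
#' Bounds are 1-based and inclusive: `[gene_start - flank,
#' gene_end + flank]`, floored at 1.
#'
#' @param gene Gene symbol.
#' @param chrom Chromosome.
#' @param gene_start,gene_end Gene coordinates (default: point position).
#' @param flank Flank size in bp (default 500 kb).
#' @return Object of class `region_spec`.
#' @export
region_spec <- function(gene, chrom, gene_start, gene_end = gene_start,
                        flank = 500000L) {
  if (flank < 0) stop_ratiomr("flank must be >= 0", "ratiomr_config_error")
  if (gene_start > gene_end)
    stop_ratiomr("gene_start > gene_end", "ratiomr_config_error")
  structure(list(gene = gene, chrom = as.character(chrom),
                 start = max(1L, as.integer(gene_start - flank)),
                 end = as.integer(gene_end + flank),
                 flank = as.integer(flank)),
            class = "region_spec")
}

#' @export
print.region_spec <- function(x, ...) {
  cat(sprintf("region %s: chr%s:%d-%d (flank %d bp)\n", x$gene, x$chrom,
              x$start, x$end, x$flank))
  invisible(x)
}

#' Subset associations to a cis region
#' @param assocs Summary-statistics `data.frame`.
#' @param region A [region_spec()].
#' @return Logical vector marking in-region rows.
#' @export
in_region <- function(assocs, region) {
  assocs$chrom == region$chrom & assocs$pos >= region$start &
    assocs$pos <= region$end
}

#' Trait-level metadata
#'
#' Raw-scale mean and SD are needed to derive ratio-trait summary
#' statistics and to move between raw and SD-unit effects.
#'
#' @param trait_id Trait identifier.
#' @param trait_type `"quantitative"` or `"binary"`.
#' @param mean,sd Raw-scale mean and SD (quantitative traits).
#' @param n Sample size.
#' @param ancestry Ancestry label.
#' @return Object of class `trait_meta`.
#' @export
trait_meta <- function(trait_id, trait_type = c("quantitative", "binary"),
                       mean = NA_real_, sd = NA_real_, n = NA_real_,
                       ancestry = "unspecified") {
  trait_type <- match.arg(trait_type)
  if (trait_type == "quantitative" && (!is.na(sd) && sd <= 0))
    stop_ratiomr("sd must be positive for quantitative traits",
                 "ratiomr_config_error")
  structure(list(trait_id = trait_id, trait_type = trait_type,
                 mean = mean, sd = sd, n = n, ancestry = ancestry),
            class = "trait_meta")
}
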