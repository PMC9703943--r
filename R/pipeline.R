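#' Pipeline configuration
#'
#' Declares a full cis-MR analysis: the exposure (either ready-made
#' ratio-trait summary statistics or product/substrate components to be
#' combined by [derive_ratio_gwas()]), the cis region, per-cohort outcome
#' summary statistics, the LD matrix, and all thresholds. Summary
#' statistics may be given as in-memory `data.frame`s or as file paths in
#' the tab-delimited dialect; paths are resolved at validation time.
#'
#' @param region A [region_spec()].
#' @param exposure Either `list(sumstats = <df|path>)` for a ready
#'   SD-unit exposure, or `list(product =, substrate =, meta_p =,
#'   meta_s =, spec = ratio_spec(...))` for delta-method derivation.
#' @param outcomes Named list; each element
#'   `list(cohorts = list(<df|path>, ...), binary = TRUE)`.
#' @param ld An [ld_matrix()] or path.
#' @param thresholds Overrides for `instrument_p` (5e-8), `alpha` (0.05),
#'   `proxy_min_r2` (0.8), `distinct_trigger` (0.3), `ppa` (0.7),
#'   `fdr` (0.05), `clump_p` (5e-5), `clump_r2` (0.05).
#' @param coloc A [coloc_config()].
#' @param negative_controls Optional named list of one-row control-outcome
#'   records (df or path).
#' @param output_dir Optional directory for the result tables.
#' @param seed Integer seed recorded with the run.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(region, exposure, outcomes, ld = NULL,
                            thresholds = list(), coloc = coloc_config(),
                            negative_controls = NULL, output_dir = NULL,
                            seed = 1L) {
  thr <- list(instrument_p = 5e-8, alpha = 0.05, proxy_min_r2 = 0.8,
              distinct_trigger = 0.3, ppa = 0.7, fdr = 0.05,
              clump_p = 5e-5, clump_r2 = 0.05)
  bad <- setdiff(names(thresholds), names(thr))
  if (length(bad))
    stop_ratiomr(paste("unknown threshold(s):", paste(bad, collapse = ", ")),
                 "ratiomr_config_error")
  thr[names(thresholds)] <- thresholds
  if (thr$instrument_p <= 0 || thr$instrument_p > 1 ||
        thr$alpha <= 0 || thr$alpha > 1 || thr$ppa < 0 || thr$ppa > 1 ||
        thr$distinct_trigger < 0 || thr$distinct_trigger > 1)
    stop_ratiomr("threshold out of range", "ratiomr_config_error")
  resolve <- function(x, what) {
    if (is.character(x) && length(x) == 1L) {
      if (!file.exists(x))
        stop_ratiomr(sprintf("%s path not found: %s", what, x),
                     "ratiomr_config_error")
    }
    x
  }
  if (!is.null(exposure$sumstats)) resolve(exposure$sumstats, "exposure")
  for (nm in names(outcomes))
    for (co in outcomes[[nm]]$cohorts) resolve(co, nm)
  structure(list(region = region, exposure = exposure,
                 outcomes = outcomes, ld = ld, thresholds = thr,
                 coloc = coloc, negative_controls = negative_controls,
                 output_dir = output_dir, seed = as.integer(seed)),
            class = "pipeline_config")
}

load_sumstats <- function(x, trait_id = NULL) {
  if (is.character(x)) read_sumstats(x, trait_id = trait_id, quiet = TRUE)
  else x
}

#' Run the full cis-MR analysis pipeline
#'
#' Stages, in order: (optional) ratio-trait GWAS derivation; instrument
#' selection with palindromic-proxy replacement and strength metrics;
#' per-outcome harmonization, fixed-effect pooling of SNP-outcome
#' associations across cohorts, and Wald-ratio estimation with a
#' Bonferroni threshold over the outcome family; regional colocalization
#' with conditional sensitivity analysis; negative-control checks; report
#' rendering. Record counts into and out of every filter are logged. The
#' pipeline is a pure function of its configuration and inputs.
#'
#' @param config A [pipeline_config()].
#' @return Object of class `mr_pipeline`: `instruments`, `mr`, `coloc`
#'   tables, `negative_controls`, `report` (character lines), `log`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  log_lines <- character(0)
  logf <- function(...) log_lines <<- c(log_lines, sprintf(...))
  thr <- config$thresholds

  ld <- config$ld
  if (is.character(ld)) ld <- read_ld_matrix(ld)

  # --- exposure stage -----------------------------------------------
  ex <- config$exposure
  if (!is.null(ex$sumstats)) {
    exposure <- load_sumstats(ex$sumstats)
    logf("exposure: %d variants loaded", nrow(exposure))
  } else {
    product <- load_sumstats(ex$product, "product")
    substrate <- load_sumstats(ex$substrate, "substrate")
    exposure <- derive_ratio_gwas(product, substrate, ex$meta_p,
                                  ex$meta_s, ex$spec)
    logf("exposure: ratio GWAS derived for %d variants (dropped %d)",
         nrow(exposure), length(attr(exposure, "dropped")))
  }

  # --- instrument stage ---------------------------------------------
  instrument_tab <- NULL
  instrument <- NULL
  inst_err <- tryCatch({
    instrument_tab <- instrument_report(exposure, config$region, ld = ld,
                                        p_threshold = thr$instrument_p,
                                        proxy_min_r2 = thr$proxy_min_r2)
    instrument <- instrument_tab[1, SUMSTAT_COLS, drop = FALSE]
    logf("instrument: %s selected (r2=%.3f, F=%.1f)",
         instrument$variant_id, instrument_tab$r2, instrument_tab$f_stat)
    NULL
  }, ratiomr_no_instrument = function(e) conditionMessage(e))
  if (!is.null(inst_err)) logf("instrument: none (%s)", inst_err)

  # --- MR stage: pool cohorts, then Wald ratio ----------------------
  n_out <- length(config$outcomes)
  mr_threshold <- if (n_out) bonferroni_threshold(thr$alpha, n_out) else NA
  mr_rows <- list()
  coloc_rows <- list()
  for (nm in names(config$outcomes)) {
    spec_o <- config$outcomes[[nm]]
    cohorts <- lapply(spec_o$cohorts, load_sumstats, trait_id = nm)
    binary <- isTRUE(spec_o$binary)
    if (is.null(instrument)) next
    harmonized <- lapply(cohorts, function(co) {
      hit <- co[co$variant_id == instrument$variant_id, , drop = FALSE]
      if (nrow(hit) == 0L) return(NULL)
      harmonize_pair(instrument, hit)
    })
    harmonized <- Filter(function(h) !is.null(h) && nrow(h$outcome) == 1L,
                         harmonized)
    logf("outcome %s: instrument found in %d/%d cohort(s)", nm,
         length(harmonized), length(cohorts))
    if (length(harmonized) == 0L) next
    hx <- harmonized[[1]]$exposure
    pooled <- ivw_meta(vapply(harmonized, function(h) h$outcome$beta,
                              numeric(1)),
                       vapply(harmonized, function(h) h$outcome$se,
                              numeric(1)))
    pooled_rec <- harmonized[[1]]$outcome
    pooled_rec$beta <- pooled$beta
    pooled_rec$se <- pooled$se
    pooled_rec$pval <- pooled$pval
    res <- wald_ratio(hx, pooled_rec, binary_outcome = binary)
    row <- summary(res)
    row$n_cohorts <- length(harmonized)
    row$bonferroni_threshold <- attr(mr_threshold, "signif3")
    row$passes_bonferroni <- row$pval < mr_threshold
    mr_rows[[nm]] <- row

    # --- coloc stage: full-region pooled outcome stats --------------
    if (!is.null(ld)) {
      pooled_region <- pool_region(cohorts, exposure$variant_id)
      common <- intersect(exposure$variant_id, pooled_region$variant_id)
      if (length(common) >= 2L) {
        t1 <- exposure[match(common, exposure$variant_id), , drop = FALSE]
        t2 <- pooled_region[match(common, pooled_region$variant_id), ,
                            drop = FALSE]
        h <- harmonize_pair(t1, t2)
        cc <- coloc_with_conditioning(
          h$exposure, h$outcome, ld, config = config$coloc,
          type1 = "quantitative",
          type2 = if (binary) "binary" else "quantitative",
          distinct_trigger = thr$distinct_trigger)
        pp <- cc$primary$pp
        crow <- data.frame(exposure = exposure$trait_id[1], outcome = nm,
                           n_variants = cc$primary$n_variants,
                           t(pp), strong_shared =
                             unname(strong_shared(cc$primary, thr$ppa)),
                           conditioned = !is.null(cc$conditioned),
                           conditioned_on = cc$conditioned_on,
                           stringsAsFactors = FALSE)
        if (!is.null(cc$conditioned)) {
          cpp <- cc$conditioned$pp
          names(cpp) <- paste0("cond_", names(cpp))
          crow <- cbind(crow, t(cpp))
        }
        coloc_rows[[nm]] <- crow
        logf("coloc %s: %d variants, pp_h4=%.3f%s", nm,
             cc$primary$n_variants, pp["pp_h4"],
             if (!is.null(cc$conditioned)) " (conditioned rerun done)"
             else "")
      }
    }
  }
  mr_tab <- if (length(mr_rows)) do.call(rbind_fill, mr_rows) else NULL
  coloc_tab <- if (length(coloc_rows)) do.call(rbind_fill, coloc_rows)
  else NULL

  # --- negative controls --------------------------------------------
  nc <- NULL
  if (!is.null(config$negative_controls) && !is.null(instrument)) {
    nc <- do.call(rbind, lapply(names(config$negative_controls),
                                function(nm) {
      rec <- load_sumstats(config$negative_controls[[nm]], trait_id = nm)
      rec <- rec[rec$variant_id == instrument$variant_id, , drop = FALSE]
      if (nrow(rec) == 0L) return(NULL)
      h <- harmonize_pair(instrument, rec)
      r <- negative_control(h$exposure, h$outcome)
      data.frame(control = nm, estimate = r$estimate, se = r$se,
                 pval = r$pval, warning = r$warning,
                 stringsAsFactors = FALSE)
    }))
    if (!is.null(nc) && any(nc$warning))
      logf("negative controls: %d warning(s)", sum(nc$warning))
  }

  bundle <- structure(list(instruments = instrument_tab, mr = mr_tab,
                           coloc = coloc_tab, negative_controls = nc,
                           log = log_lines, seed = config$seed,
                           region = config$region),
                      class = "mr_pipeline")
  bundle$report <- render_report(bundle)

  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    wtab <- function(df, f) if (!is.null(df))
      utils::write.table(format(df, digits = 10),
                         file.path(config$output_dir, f), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    wtab(instrument_tab, "instruments.tsv")
    wtab(mr_tab, "mr_results.tsv")
    wtab(coloc_tab, "coloc_results.tsv")
    wtab(nc, "negative_controls.tsv")
    writeLines(bundle$report, file.path(config$output_dir, "report.txt"))
    writeLines(log_lines, file.path(config$output_dir, "pipeline.log"))
  }
  bundle
}

# fixed-effect pooling of per-variant outcome associations across cohorts
pool_region <- function(cohorts, variant_ids) {
  base <- cohorts[[1]]
  base <- base[base$variant_id %in% variant_ids, , drop = FALSE]
  if (length(cohorts) == 1L) return(base)
  for (i in seq_len(nrow(base))) {
    vid <- base$variant_id[i]
    recs <- lapply(cohorts, function(co)
      co[co$variant_id == vid, , drop = FALSE])
    recs <- Filter(function(r) nrow(r) == 1L, recs)
    al <- lapply(recs, function(r)
      harmonize_pair(base[i, , drop = FALSE], r,
                     make_exposure_positive = FALSE)$outcome)
    al <- Filter(function(r) nrow(r) == 1L, al)
    pooled <- ivw_meta(vapply(al, `[[`, numeric(1), "beta"),
                       vapply(al, `[[`, numeric(1), "se"))
    base$beta[i] <- pooled$beta
    base$se[i] <- pooled$se
    base$pval[i] <- pooled$pval
    base$n[i] <- sum(vapply(al, `[[`, numeric(1), "n"))
  }
  base
}

# rbind data.frames with unequal columns (missing filled with NA)
rbind_fill <- function(...) {
  dfs <- list(...)
  cols <- unique(unlist(lapply(dfs, names)))
  do.call(rbind, lapply(dfs, function(d) {
    for (c in setdiff(cols, names(d))) d[[c]] <- NA
    d[, cols, drop = FALSE]
  }))
}

#' Render a human-readable pipeline summary
#'
#' One block per exposure-outcome pair: OR (95% CI), p, multiplicity
#' flag, colocalization posteriors with the shared-variant decision, and
#' any triangulation warnings. Missing stages render as explicit gaps.
#'
#' @param bundle An `mr_pipeline` result.
#' @return Character vector of report lines.
#' @export
render_report <- function(bundle) {
  ln <- character(0)
  add <- function(...) ln <<- c(ln, sprintf(...))
  add("== cis-MR pipeline report ==")
  if (!is.null(bundle$region))
    add("Region: %s (chr%s:%d-%d)", bundle$region$gene,
        bundle$region$chrom, bundle$region$start, bundle$region$end)
  if (is.null(bundle$instruments)) {
    add("No instruments: no variant passed the selection threshold.")
  } else {
    it <- bundle$instruments
    add("Instrument: %s (R2=%.3f, F=%.1f)%s", it$variant_id, it$r2,
        it$f_stat,
        ifelse(is.na(it$replaced_palindromic), "",
               sprintf(" [proxy for palindromic %s]",
                       it$replaced_palindromic)))
  }
  if (is.null(bundle$mr)) {
    add("MR: no estimates (no instruments or no outcome overlap).")
  } else {
    for (i in seq_len(nrow(bundle$mr))) {
      r <- bundle$mr[i, ]
      eff <- if (!is.null(r$or) && !is.na(r$or))
        sprintf("OR %.3f (95%% CI %.3f-%.3f)", r$or, r$or_low, r$or_high)
      else sprintf("beta %.4f (SE %.4f)", r$beta, r$se)
      add("MR %s -> %s: %s, p=%.3g%s", r$exposure, r$outcome, eff,
          r$pval,
          ifelse(isTRUE(r$passes_bonferroni),
                 sprintf(" [passes Bonferroni %.3g]",
                         r$bonferroni_threshold), ""))
    }
  }
  if (!is.null(bundle$coloc)) {
    for (i in seq_len(nrow(bundle$coloc))) {
      r <- bundle$coloc[i, ]
      add("Coloc %s vs %s: H1=%.2f H2=%.2f H3=%.2f H4=%.2f H5=%.2f%s%s",
          r$exposure, r$outcome, r$pp_h1, r$pp_h2, r$pp_h3, r$pp_h4,
          r$pp_h5,
          ifelse(isTRUE(r$strong_shared), " [strong shared variant]", ""),
          ifelse(isTRUE(r$conditioned),
                 sprintf(" (conditioned on %s: H4=%.2f)",
                         r$conditioned_on, r$cond_pp_h4), ""))
    }
  }
  if (!is.null(bundle$negative_controls)) {
    for (i in seq_len(nrow(bundle$negative_controls))) {
      r <- bundle$negative_controls[i, ]
      if (isTRUE(r$warning))
        add("WARNING negative control %s: per-allele %.4g, p=%.3g (possible residual stratification)",
            r$control, r$estimate, r$pval)
    }
  }
  ln
}

#' @export
print.mr_pipeline <- function(x, ...) {
  writeLines(x$report)
  invisible(x)
}
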