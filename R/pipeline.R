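pipeline_stage <- function(name, code) {
  tryCatch(code, error = function(e) {
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
  })
}

write_tsv <- function(d, path) {
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Run the full two-sample MR pipeline from a configuration
#'
#' Orchestrates the analysis flow: instrument selection, harmonization,
#' Steiger and F filtering, univariable MR with all applicable methods,
#' sensitivity diagnostics (Cochran's Q, Egger intercept, MR-PRESSO with
#' outlier-corrected refit, leave-one-out), meta-analysis across outcome
#' datasets under the I-squared model rule, BH-FDR over the configured
#' family, optional multivariable MR with mediation per mediator, an
#' optional drug-target arm, and optional colocalization.  Every stage
#' writes TSV/JSON outputs under `out_dir`, and a machine-readable run
#' manifest records the seed, stage list, and SNP counts in and out of
#' each filter.
#'
#' Configuration is a named list (or the path of a YAML file) with
#' entries: `out_dir`; `seed`; `stages` (subset of `instruments`, `uvmr`,
#' `sensitivity`, `meta`, `fdr`, `mvmr`, `drugtarget`, `coloc`);
#' `exposure` (list with `path` and optional `label`, `binary`); one or
#' more outcome datasets under `outcomes` (list of such lists); optional
#' `ld` (path), `mediators` (list), `gene_targets` (path), and the
#' thresholds `clump_p`, `clump_r2`, `clump_kb`, `f_min`, `fdr_family`.
#'
#' @param config named list or YAML file path.
#' @return The run manifest, invisibly (also written as
#'   `manifest.json`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stages <- config$stages %||% c("instruments", "uvmr", "sensitivity",
                                 "meta", "fdr")
  out_dir <- config$out_dir %||% "."
  seed <- config$seed %||% 1L
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  manifest <- list(package = "mrpipe",
                   version = as.character(utils::packageVersion("mrpipe")),
                   seed = seed, stages = stages, counts = list(),
                   filter_order = c("significance", "clump", "harmonize",
                                    "steiger", "f_stat"))

  for (f in c(config$exposure$path,
              vapply(config$outcomes, function(o) o$path, ""))) {
    if (!file.exists(f)) stop("stage 'harmonize' failed: input file not found: ", f,
                              call. = FALSE)
  }

  exposure <- pipeline_stage("read_exposure", read_summary_stats(
    config$exposure$path, trait_label = config$exposure$label %||% "exposure",
    binary_trait = isTRUE(config$exposure$binary)))
  outcomes <- lapply(config$outcomes, function(o) {
    pipeline_stage("read_outcome", read_summary_stats(
      o$path, trait_label = o$label %||% "outcome",
      binary_trait = isTRUE(o$binary %||% TRUE)))
  })
  names(outcomes) <- vapply(config$outcomes,
                            function(o) o$label %||% "outcome", "")
  ld <- if (!is.null(config$ld)) read_ld_matrix(config$ld) else NULL

  snps <- exposure$snps$variant_id
  if ("instruments" %in% stages) {
    snps <- pipeline_stage("instruments", {
      cfg <- clump_config(config$clump_p %||% 5e-8,
                          config$clump_r2 %||% 0.001,
                          config$clump_kb %||% 10000)
      select_instruments(exposure, ld, cfg)
    })
    manifest$counts$candidates <- nrow(exposure$snps)
    manifest$counts$clumped <- length(snps)
    writeLines(snps, file.path(out_dir, "instruments.txt"))
  }

  results <- list()
  records_by_outcome <- list()
  if ("uvmr" %in% stages) {
    for (nm in names(outcomes)) {
      rec <- pipeline_stage("harmonize",
                            harmonize(exposure, outcomes[[nm]], snps,
                                      ld = ld))
      n_harm <- nrow(rec)
      st <- pipeline_stage("steiger", steiger_filter(rec))
      ff <- pipeline_stage("f_filter", f_filter(st$kept,
                                                config$f_min %||% 10))
      rec <- ff$kept
      manifest$counts[[nm]] <- list(
        harmonized = n_harm, steiger_dropped = nrow(st$dropped),
        weak_dropped = nrow(ff$dropped), final = nrow(rec))
      records_by_outcome[[nm]] <- rec
      res <- pipeline_stage("uvmr", run_uvmr(rec, seed = seed))
      results[[nm]] <- res
      write_tsv(mr_results_table(res, exposure$trait_label, nm),
                file.path(out_dir, paste0("uvmr_", nm, ".tsv")))
      write_instruments(rec, file.path(out_dir,
                                       paste0("instruments_", nm, ".tsv")))
    }
  }

  if ("sensitivity" %in% stages) {
    for (nm in names(records_by_outcome)) {
      rep <- pipeline_stage("sensitivity",
                            sensitivity_report(records_by_outcome[[nm]],
                                               seed = seed))
      if (!is.null(rep$loo)) {
        write_tsv(rep$loo, file.path(out_dir, paste0("loo_", nm, ".tsv")))
      }
      write_funnel_data(records_by_outcome[[nm]],
                        file.path(out_dir, paste0("funnel_", nm, ".tsv")))
      jsonlite::write_json(
        list(q = rep$q, q_df = rep$q_df, q_p = rep$q_p, i2 = rep$i2,
             egger_intercept = rep$egger_intercept,
             egger_intercept_p = rep$egger_intercept_p,
             presso_global_p = rep$presso_global_p,
             presso_outliers = as.list(rep$presso_outliers)),
        file.path(out_dir, paste0("sensitivity_", nm, ".json")),
        auto_unbox = TRUE, digits = NA)
    }
  }

  if ("meta" %in% stages && length(results) >= 2L) {
    meta <- pipeline_stage("meta", {
      b <- vapply(results, function(r) r$ivw_mre$beta, numeric(1))
      s <- vapply(results, function(r) r$ivw_mre$se, numeric(1))
      meta_analyze(b, s)
    })
    jsonlite::write_json(unclass(meta), file.path(out_dir, "meta.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  if ("fdr" %in% stages && length(results) > 0L) {
    fdr_tab <- pipeline_stage("fdr", {
      p <- vapply(results, function(r) r$ivw_mre$p, numeric(1))
      fam <- config$fdr_family %||% length(p)
      adj <- bh_fdr(p, family_size = fam)
      label <- ifelse(p < 0.05 & adj < 0.05, "significant",
                      ifelse(p < 0.05, "suggestive", "ns"))
      data.frame(outcome = names(results), p = unname(p),
                 p_fdr = unname(adj), interpretation = label,
                 stringsAsFactors = FALSE)
    })
    write_tsv(fdr_tab, file.path(out_dir, "fdr.tsv"))
  }

  if ("mvmr" %in% stages && length(config$mediators) > 0L) {
    outcome1 <- outcomes[[1]]
    rec1 <- records_by_outcome[[1]]
    total <- mr_ivw(rec1)
    med_rows <- list()
    for (m in config$mediators) {
      nm <- m$label %||% "mediator"
      med_rows[[nm]] <- pipeline_stage("mvmr", {
        mset <- read_summary_stats(m$path, trait_label = nm)
        msnps <- union(snps, select_instruments(mset, ld, clump_config(
          config$clump_p %||% 5e-8, config$clump_r2 %||% 0.001,
          config$clump_kb %||% 10000)))
        hm <- harmonize_mvmr(stats::setNames(list(exposure, mset),
                                             c(exposure$trait_label, nm)),
                             outcome1, msnps)
        mv <- mvmr_ivw(hm)
        med <- mediation(total, direct = list(beta = mv$beta[1],
                                              se = mv$se[1]))
        data.frame(mediator = nm, n_snp = attr(mv, "n_snp"),
                   total = med$total$beta, direct = med$direct$beta,
                   indirect = med$indirect$beta,
                   indirect_se = med$indirect$se,
                   proportion = med$proportion, p = med$p,
                   label = mediator_label(med), stringsAsFactors = FALSE)
      })
    }
    write_tsv(do.call(rbind, med_rows), file.path(out_dir, "mediation.tsv"))
  }

  if ("drugtarget" %in% stages && !is.null(config$gene_targets)) {
    dt <- pipeline_stage("drugtarget", {
      targets <- read_gene_targets(config$gene_targets)
      run_drug_target(exposure, outcomes[[1]], targets, ld = ld,
                      ld_aware = isTRUE(config$ld_aware))
    })
    write_tsv(dt, file.path(out_dir, "drug_target.tsv"))
  }

  if ("coloc" %in% stages) {
    cl <- pipeline_stage("coloc", {
      region_ids <- define_region(exposure,
                                  window_kb = config$coloc_kb %||% 100)
      r1 <- exposure
      r1$snps <- r1$snps[r1$snps$variant_id %in% region_ids, , drop = FALSE]
      r2 <- outcomes[[1]]
      r2$snps <- r2$snps[r2$snps$variant_id %in% region_ids, , drop = FALSE]
      coloc_abf(r1, r2)
    })
    jsonlite::write_json(list(pp = as.list(cl$pp),
                              n_variants = cl$n_variants,
                              priors = as.list(cl$priors)),
                         file.path(out_dir, "coloc.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
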