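#' Define a gene target for cis-instrument MR
#'
#' @param name gene symbol (e.g. "ANGPTL3").
#' @param chromosome chromosome label.
#' @param start,end 1-based inclusive gene coordinates.
#' @param flank_kb flanking window on each side in kb (default 100).
#' @return List of class `gene_target`.
#' @export
gene_target <- function(name, chromosome, start, end, flank_kb = 100) {
  stopifnot(start <= end, flank_kb >= 0)
  structure(list(name = name, chromosome = as.character(chromosome),
                 start = start, end = end, flank_kb = flank_kb),
            class = "gene_target")
}

#' Read gene targets from a BED-like TSV
#'
#' Expects columns `name`, `chromosome`, `start`, `end` (1-based inclusive
#' coordinates) and optionally `flank_kb`.
#'
#' @param path file path.
#' @param flank_kb default flank applied where the file has none.
#' @return List of `gene_target` objects, named by gene.
#' @export
read_gene_targets <- function(path, flank_kb = 100) {
  d <- utils::read.delim(path, sep = "\t", header = TRUE, comment.char = "#",
                         stringsAsFactors = FALSE)
  targets <- lapply(seq_len(nrow(d)), function(i) {
    fk <- if (!is.null(d$flank_kb)) d$flank_kb[i] else flank_kb
    gene_target(d$name[i], d$chromosome[i], d$start[i], d$end[i], fk)
  })
  stats::setNames(targets, d$name)
}

#' Extract cis instruments from a gene window
#'
#' Candidates are variants inside the closed window
#' \[start - flank, end + flank\] on the target's chromosome with
#' `p < p_threshold`.  They are then greedily pruned by ascending p-value
#' so that every kept pair has LD r^2 below `r2_prune` (default 0.30, the
#' permissive cis threshold that trades some correlation for instrument
#' strength).
#'
#' @param stats a `summary_stat_set` with positional fields.
#' @param target a [gene_target()].
#' @param ld an `ld_matrix` or `NULL` (variants absent from `ld` are
#'   treated as independent).
#' @param p_threshold significance threshold (default 5e-8).
#' @param r2_prune pairwise LD ceiling among kept instruments.
#' @return Character vector of kept variant ids (possibly empty, with a
#'   warning when the window holds no significant variants).
#' @export
extract_cis_instruments <- function(stats, target, ld = NULL,
                                    p_threshold = 5e-8, r2_prune = 0.30) {
  stopifnot(inherits(stats, "summary_stat_set"),
            inherits(target, "gene_target"))
  d <- stats$snps
  lo <- target$start - target$flank_kb * 1000
  hi <- target$end + target$flank_kb * 1000
  cand <- d[d$chromosome == target$chromosome &
              d$position >= lo & d$position <= hi &
              d$p < p_threshold, , drop = FALSE]
  if (nrow(cand) == 0L) {
    warning("no genome-wide significant variants in the ", target$name,
            " window; target unusable")
    return(character(0))
  }
  cand <- cand[order(cand$p, cand$position), , drop = FALSE]
  kept <- character(0)
  for (i in seq_len(nrow(cand))) {
    id <- cand$variant_id[i]
    ok <- TRUE
    if (!is.null(ld) && id %in% rownames(ld)) {
      prev <- intersect(kept, rownames(ld))
      if (length(prev) > 0 && any(ld[id, prev]^2 >= r2_prune)) ok <- FALSE
    }
    if (ok) kept <- c(kept, id)
  }
  kept
}

#' Drug-target (cis-instrument) MR
#'
#' Causal estimate for the exposure component attributable to one gene
#' target, expressed per 1-unit increase of the exposure.  The default is
#' multiplicative random-effects IVW treating the cis instruments as
#' independent; with `ld_aware = TRUE` a generalized IVW is fitted that
#' weights by the full LD-derived covariance of the outcome betas
#' (Sigma_ij = r_ij * se_i * se_j), appropriate because cis instruments
#' pruned only to r^2 < 0.30 remain correlated.
#'
#' @param cis an `mr_instruments` table of harmonized cis instruments.
#' @param ld an `ld_matrix` covering the instruments (required when
#'   `ld_aware = TRUE`).
#' @param ld_aware logical; account for instrument correlation.
#' @return An `mr_estimate` (method `"ivw_mre"`, `"wald"` for a single
#'   instrument, or `"ivw_gls"` when LD-aware).
#' @export
drug_target_mr <- function(cis, ld = NULL, ld_aware = FALSE) {
  stopifnot(is.data.frame(cis))
  j <- nrow(cis)
  if (j == 0L) stop("empty cis instrument set")
  if (j == 1L) return(wald_ratio(cis[1, ]))
  if (!ld_aware) return(mr_ivw(cis))
  if (is.null(ld)) stop("ld_aware = TRUE requires an LD matrix")
  ids <- cis$variant_id
  if (!all(ids %in% rownames(ld))) stop("LD matrix does not cover all cis instruments")
  r <- unclass(ld)[ids, ids, drop = FALSE]
  sy <- cis$outcome_se
  sigma <- r * tcrossprod(sy)
  si <- solve(sigma)
  bx <- cis$exposure_beta
  by <- cis$outcome_beta
  denom <- drop(t(bx) %*% si %*% bx)
  beta <- drop(t(bx) %*% si %*% by) / denom
  se <- sqrt(1 / denom)
  mr_estimate("ivw_gls", beta, se, j)
}

#' Run the drug-target MR arm over several gene targets
#'
#' For each target: extract cis instruments, harmonize them to the
#' outcome, estimate the causal effect, and apply BH-FDR across the
#' targets tested in this run (the FDR family is the run's target set).
#'
#' @param exposure,outcome `summary_stat_set` objects.
#' @param targets list of `gene_target` objects.
#' @param ld an `ld_matrix` or `NULL`.
#' @param ld_aware passed to [drug_target_mr()].
#' @param p_threshold,r2_prune passed to [extract_cis_instruments()].
#' @return data.frame with one row per usable target: estimate columns
#'   plus `p_fdr`.
#' @export
run_drug_target <- function(exposure, outcome, targets, ld = NULL,
                            ld_aware = FALSE, p_threshold = 5e-8,
                            r2_prune = 0.30) {
  rows <- list()
  for (tg in targets) {
    snps <- extract_cis_instruments(exposure, tg, ld,
                                    p_threshold = p_threshold,
                                    r2_prune = r2_prune)
    if (length(snps) == 0L) next
    rec <- harmonize(exposure, outcome, snps)
    est <- drug_target_mr(rec, ld = ld, ld_aware = ld_aware)
    rows[[tg$name]] <- data.frame(
      target = tg$name, n_snp = est$n_snp, method = est$method,
      beta = est$beta, se = est$se, or_ = est$or_, ci_low = est$ci_low,
      ci_high = est$ci_high, p = est$p, stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) stop("no usable drug targets")
  out <- do.call(rbind, rows)
  out$p_fdr <- bh_fdr(out$p)
  rownames(out) <- NULL
  out
}
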