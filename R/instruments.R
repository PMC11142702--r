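#' Clumping configuration
#'
#' Parameters for greedy LD clumping of genome-wide significant variants.
#' Defaults follow the conventional two-sample MR settings: genome-wide
#' significance 5e-8, independence at r^2 < 0.001 within a 10,000 kb window.
#'
#' @param p_threshold significance threshold for candidate instruments.
#' @param r2_threshold maximum pairwise LD r^2 among kept instruments.
#' @param window_kb clumping distance in kilobases.
#' @return A list of class `clump_config`.
#' @export
clump_config <- function(p_threshold = 5e-8, r2_threshold = 0.001,
                         window_kb = 10000) {
  stopifnot(p_threshold > 0, p_threshold < 1,
            r2_threshold >= 0, r2_threshold <= 1, window_kb > 0)
  structure(list(p_threshold = p_threshold, r2_threshold = r2_threshold,
                 window_kb = window_kb), class = "clump_config")
}

#' Select independent instruments by greedy LD clumping
#'
#' Candidates are variants with `p < p_threshold`, ranked by ascending
#' p-value (ties broken by chromosome then position, for determinism).  The
#' best candidate is kept and all remaining candidates on the same
#' chromosome within `window_kb` whose LD r^2 with it reaches
#' `r2_threshold` are removed; this repeats until no candidates remain.
#' Candidates absent from `ld` are treated as independent, with a warning.
#'
#' @param stats a [summary_stat_set()].
#' @param ld an `ld_matrix` of signed correlations (r, not r^2), or `NULL`.
#' @param cfg a [clump_config()].
#' @return Character vector of kept variant ids, in kept order (possibly
#'   empty).
#' @export
select_instruments <- function(stats, ld = NULL, cfg = clump_config()) {
  stopifnot(inherits(stats, "summary_stat_set"))
  d <- stats$snps
  cand <- d[d$p < cfg$p_threshold, , drop = FALSE]
  if (nrow(cand) == 0L) return(character(0))
  ord <- order(cand$p, cand$chromosome, cand$position)
  cand <- cand[ord, , drop = FALSE]
  if (!is.null(ld)) {
    missing_ld <- setdiff(cand$variant_id, rownames(ld))
    if (length(missing_ld) > 0) {
      warning(length(missing_ld),
              " candidate(s) absent from LD matrix; treated as independent")
    }
  }
  kept <- character(0)
  while (nrow(cand) > 0L) {
    top <- cand[1L, ]
    kept <- c(kept, top$variant_id)
    cand <- cand[-1L, , drop = FALSE]
    if (nrow(cand) == 0L) break
    near <- cand$chromosome == top$chromosome &
      abs(cand$position - top$position) <= cfg$window_kb * 1000
    in_ld <- rep(FALSE, nrow(cand))
    if (!is.null(ld) && top$variant_id %in% rownames(ld)) {
      present <- cand$variant_id %in% rownames(ld)
      in_ld[present] <-
        ld[top$variant_id, cand$variant_id[present]]^2 >= cfg$r2_threshold
    }
    cand <- cand[!(near & in_ld), , drop = FALSE]
  }
  kept
}

#' Variance in a trait explained by one SNP
#'
#' R^2 = 2 * MAF * (1 - MAF) * beta^2, where MAF = min(eaf, 1 - eaf) is the
#' minor-allele frequency.  Summing over an instrument set gives the set's
#' explained variance (assuming a standardized trait).
#'
#' @param eaf effect-allele frequency in (0, 1).
#' @param beta per-allele effect estimate.
#' @return Variance explained (vectorised).
#' @export
snp_r2 <- function(eaf, beta) {
  if (any(is.na(eaf)) || any(eaf <= 0) || any(eaf >= 1)) {
    stop("eaf must lie in (0, 1)")
  }
  maf <- pmin(eaf, 1 - eaf)
  2 * maf * (1 - maf) * beta^2
}

#' Instrument-strength F-statistic
#'
#' F = ((n - k - 1) / k) * (R^2 / (1 - R^2)).  An F below 10 is the
#' conventional weak-instrument flag.
#'
#' @param r2 variance explained, in \[0, 1).
#' @param n sample size (must exceed k + 1).
#' @param k number of instruments (1 for per-SNP strength).
#' @return The F-statistic (vectorised).
#' @export
f_statistic <- function(r2, n, k = 1) {
  if (any(is.na(r2)) || any(r2 < 0) || any(r2 >= 1)) stop("r2 must be in [0, 1)")
  if (any(is.na(n)) || any(n <= k + 1)) stop("n must exceed k + 1")
  ((n - k - 1) / k) * (r2 / (1 - r2))
}

# Per-SNP variance explained from the association z-score:
# F = (beta/se)^2, r2 = F / (F + n - 2).  Robust to missing eaf.
r2_from_z <- function(beta, se, n) {
  f <- (beta / se)^2
  f / (f + n - 2)
}

#' Steiger directionality filter
#'
#' Drops instruments whose estimated correlation with the outcome exceeds
#' their correlation with the exposure, guarding against reverse causation.
#' Per-SNP variance explained is computed from the association z-score by
#' default (`r2 = F / (F + n - 2)` with `F = (beta/se)^2`), which is
#' symmetric between traits and needs no allele frequencies; the
#' `2*MAF*(1-MAF)*beta^2` form can be requested when both sides carry eaf.
#' A Steiger z-test p-value (Fisher-z comparison of the two correlations)
#' is attached for reporting but does not drive the filter.
#'
#' @param records an `mr_instruments` table (see [harmonize()]).
#' @param method `"z"` (default) or `"eaf"`.
#' @return List with elements `kept` and `dropped`, each an
#'   `mr_instruments` table carrying `r2_exposure`, `r2_outcome` and
#'   `steiger_p` columns; together they partition the input.
#' @export
steiger_filter <- function(records, method = c("z", "eaf")) {
  method <- match.arg(method)
  stopifnot(is.data.frame(records))
  r <- records
  assessable <- !is.na(r$exposure_n) & !is.na(r$outcome_n)
  if (any(!assessable)) {
    warning(sum(!assessable),
            " record(s) without sample sizes dropped (Steiger unassessable)")
  }
  if (method == "eaf") {
    if (any(is.na(r$exposure_eaf)) || any(is.na(r$outcome_eaf))) {
      stop("method='eaf' requires eaf on both sides for every record")
    }
    r$r2_exposure <- snp_r2(r$exposure_eaf, r$exposure_beta)
    r$r2_outcome <- snp_r2(r$outcome_eaf, r$outcome_beta)
  } else {
    r$r2_exposure <- r2_from_z(r$exposure_beta, r$exposure_se, r$exposure_n)
    r$r2_outcome <- r2_from_z(r$outcome_beta, r$outcome_se, r$outcome_n)
  }
  rx <- sqrt(pmax(r$r2_exposure, 0))
  ry <- sqrt(pmax(r$r2_outcome, 0))
  zstat <- (atanh(pmin(rx, 0.999999)) - atanh(pmin(ry, 0.999999))) /
    sqrt(1 / pmax(r$exposure_n - 3, 1) + 1 / pmax(r$outcome_n - 3, 1))
  r$steiger_p <- 2 * stats::pnorm(-abs(zstat))
  keep <- assessable & !(r$r2_outcome > r$r2_exposure)  # ties retained
  list(kept = r[keep, , drop = FALSE], dropped = r[!keep, , drop = FALSE])
}

#' Find an LD proxy for a variant missing from the outcome data
#'
#' Among variants present in `outcome_stats`, returns the one with maximal
#' LD r^2 to `target`, provided that r^2 exceeds `r2_min`; otherwise `NA`.
#'
#' @param target variant id absent from the outcome set.
#' @param outcome_stats a `summary_stat_set`.
#' @param ld an `ld_matrix` containing `target`.
#' @param r2_min minimum acceptable proxy r^2 (default 0.8).
#' @return The proxy variant id, or `NA_character_`.
#' @export
find_proxy <- function(target, outcome_stats, ld, r2_min = 0.8) {
  stopifnot(inherits(outcome_stats, "summary_stat_set"))
  if (target %in% outcome_stats$snps$variant_id) {
    stop("target is present in the outcome set; no proxy needed")
  }
  if (is.null(ld) || !(target %in% rownames(ld))) {
    warning("target ", target, " not in LD matrix; no proxy available")
    return(NA_character_)
  }
  pool <- intersect(rownames(ld), outcome_stats$snps$variant_id)
  pool <- setdiff(pool, target)
  if (length(pool) == 0L) return(NA_character_)
  r2 <- ld[target, pool]^2
  best <- which.max(r2)
  if (r2[best] > r2_min) pool[best] else NA_character_
}

complement_allele <- function(a) {
  c(A = "T", T = "A", C = "G", G = "C")[a]
}

is_palindromic <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

#' Harmonize exposure and outcome summary statistics
#'
#' Builds the per-SNP instrument table for two-sample MR: for each selected
#' variant present in both sets, the outcome record is aligned to the
#' exposure's effect allele.  Swapped allele codings negate the outcome
#' beta and reflect its eaf; strand flips are resolved through allele
#' complements.  Palindromic (A/T, C/G) variants are resolved by allele
#' frequency when both eafs are available and both lie outside the
#' ambiguity zone `|eaf - 0.5| <= eaf_ambiguity`; otherwise they are
#' dropped.  Variants missing from the outcome set are dropped, or (with
#' `use_proxies = TRUE`) replaced by their best LD proxy at r^2 >
#' `proxy_r2_min`, the proxy's effect signed by the LD correlation.
#'
#' @param exposure,outcome `summary_stat_set` objects.
#' @param snps variant ids to harmonize (typically from
#'   [select_instruments()]); defaults to all exposure variants.
#' @param ld optional `ld_matrix`, needed only for proxy search.
#' @param use_proxies logical; default `FALSE` (fully offline run).
#' @param proxy_r2_min minimum proxy r^2.
#' @param eaf_ambiguity half-width of the palindromic ambiguity zone.
#' @return An `mr_instruments` data.frame with exposure_* and outcome_*
#'   columns, instrument-strength columns `r2_exposure` and `f_stat`, and a
#'   `drops` attribute recording excluded variants and reasons.
#' @export
harmonize <- function(exposure, outcome, snps = NULL, ld = NULL,
                      use_proxies = FALSE, proxy_r2_min = 0.8,
                      eaf_ambiguity = 0.08) {
  stopifnot(inherits(exposure, "summary_stat_set"),
            inherits(outcome, "summary_stat_set"))
  ex <- exposure$snps
  if (is.null(snps)) snps <- ex$variant_id
  ex <- ex[match(snps, ex$variant_id), , drop = FALSE]
  if (any(is.na(ex$variant_id))) stop("snps not all present in exposure set")
  oy <- outcome$snps
  n <- nrow(ex)

  j <- match(ex$variant_id, oy$variant_id)
  proxy_of <- rep(NA_character_, n)
  if (use_proxies && anyNA(j)) {
    for (i in which(is.na(j))) {
      proxy <- find_proxy(ex$variant_id[i], outcome, ld, proxy_r2_min)
      if (!is.na(proxy)) {
        j[i] <- match(proxy, oy$variant_id)
        proxy_of[i] <- ex$variant_id[i]
      }
    }
  }
  reason <- rep(NA_character_, n)
  reason[is.na(j)] <- "absent_from_outcome"
  jj <- ifelse(is.na(j), 1L, j)  # placeholder index; masked by `reason`
  o_ea <- oy$effect_allele[jj]
  o_oa <- oy$other_allele[jj]
  ob <- oy$beta[jj]
  oe <- oy$eaf[jj]

  pal <- is_palindromic(ex$effect_allele, ex$other_allele)
  same <- o_ea == ex$effect_allele & o_oa == ex$other_allele
  swapped <- o_ea == ex$other_allele & o_oa == ex$effect_allele
  comp_same <- complement_allele(o_ea) == ex$effect_allele &
    complement_allele(o_oa) == ex$other_allele
  comp_swapped <- complement_allele(o_ea) == ex$other_allele &
    complement_allele(o_oa) == ex$effect_allele
  is_proxy <- !is.na(proxy_of)

  # proxies: effect signed by the LD correlation with the target
  if (any(is_proxy)) {
    for (i in which(is_proxy)) {
      r <- ld[proxy_of[i], oy$variant_id[j[i]]]
      ob[i] <- sign(r) * ob[i]
      if (!is.na(oe[i]) && r < 0) oe[i] <- 1 - oe[i]
    }
  }

  plain <- is.na(reason) & !pal & !is_proxy
  reason[plain & !(same | swapped | comp_same | comp_swapped)] <-
    "allele_mismatch"
  flip <- plain & (swapped | comp_swapped) & is.na(reason)
  ob[flip] <- -ob[flip]
  oe[flip] <- 1 - oe[flip]

  # palindromic variants: letters cannot resolve strand; use eaf or drop
  pp <- is.na(reason) & pal & !is_proxy
  reason[pp & !(same | swapped)] <- "allele_mismatch"
  pp <- pp & is.na(reason)
  ambiguous <- pp & (is.na(ex$eaf) | is.na(oe) |
                       abs(ex$eaf - 0.5) <= eaf_ambiguity |
                       abs(oe - 0.5) <= eaf_ambiguity)
  reason[ambiguous] <- "palindromic_ambiguous"
  pp <- pp & is.na(reason)
  psw <- pp & swapped
  ob[psw] <- -ob[psw]
  oe[psw] <- 1 - oe[psw]
  # residual frequency mismatch after letter alignment = strand flip
  pflip <- pp & ((ex$eaf < 0.5) != (oe < 0.5))
  ob[pflip] <- -ob[pflip]
  oe[pflip] <- 1 - oe[pflip]

  keep <- is.na(reason)
  if (!any(keep)) {
    stop("no variants could be harmonized between exposure and outcome")
  }
  out <- data.frame(
    variant_id = ex$variant_id, chromosome = ex$chromosome,
    position = ex$position, effect_allele = ex$effect_allele,
    other_allele = ex$other_allele,
    exposure_beta = ex$beta, exposure_se = ex$se, exposure_eaf = ex$eaf,
    exposure_p = ex$p, exposure_n = ex$n,
    outcome_beta = ob, outcome_se = oy$se[jj], outcome_eaf = oe,
    outcome_p = oy$p[jj], outcome_n = oy$n[jj],
    proxy_of = proxy_of, stringsAsFactors = FALSE
  )[keep, , drop = FALSE]
  drops <- data.frame(variant_id = ex$variant_id[!keep],
                      reason = reason[!keep], stringsAsFactors = FALSE)
  rownames(out) <- NULL
  # per-SNP instrument strength: eaf-based R^2 where available, else z-based
  out$r2_exposure <- ifelse(
    !is.na(out$exposure_eaf),
    2 * pmin(out$exposure_eaf, 1 - out$exposure_eaf) *
      (1 - pmin(out$exposure_eaf, 1 - out$exposure_eaf)) * out$exposure_beta^2,
    r2_from_z(out$exposure_beta, out$exposure_se, out$exposure_n)
  )
  out$f_stat <- f_statistic(out$r2_exposure, out$exposure_n, 1)
  attr(out, "drops") <- drops
  class(out) <- c("mr_instruments", class(out))
  out
}

#' Exclude weak instruments by F-statistic
#'
#' @param records an `mr_instruments` table with an `f_stat` column.
#' @param f_min minimum F to retain (default 10).
#' @return List with `kept` and `dropped` tables partitioning the input.
#' @export
f_filter <- function(records, f_min = 10) {
  keep <- records$f_stat >= f_min
  list(kept = records[keep, , drop = FALSE],
       dropped = records[!keep, , drop = FALSE])
}

#' Export an instrument table (with drop reasons) as TSV
#' @param records an `mr_instruments` table from [harmonize()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_instruments <- function(records, path) {
  kept <- as.data.frame(records)
  kept$drop_reason <- ""
  drops <- attr(records, "drops")
  if (!is.null(drops) && nrow(drops) > 0) {
    pad <- kept[0, , drop = FALSE][seq_len(nrow(drops)), , drop = FALSE]
    pad$variant_id <- drops$variant_id
    pad$drop_reason <- drops$reason
    kept <- rbind(kept, pad)
  }
  utils::write.table(kept, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}
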