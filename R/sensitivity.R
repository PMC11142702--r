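# Leave-one-out IVW point estimates in O(J) via sufficient statistics:
# theta_{-j} = (S_wr - w_j r_j) / (S_w - w_j) with ratio-form weights.
loo_ivw_points <- function(bx, by, sy) {
  w <- bx^2 / sy^2
  r <- by / bx
  (sum(w * r) - w * r) / (sum(w) - w)
}

#' Cochran's Q heterogeneity test for an instrument set
#'
#' Q = sum_j w_j (rho_j - beta_ivw)^2 over per-SNP Wald ratios rho_j with
#' IVW weights w_j = exposure_beta^2 / outcome_se^2; df = J - 1; p from the
#' upper chi-square tail.  I^2 = max(0, (Q - df)/Q) (0 when Q = 0).
#'
#' @param records an `mr_instruments` table with at least 2 rows.
#' @return List with `q`, `q_df`, `q_p`, `i2`.
#' @export
cochran_q <- function(records) {
  v <- iv_vectors(records)
  j <- length(v$bx)
  if (j < 2L) stop("Cochran's Q needs >= 2 instruments")
  w <- v$bx^2 / v$sy^2
  rho <- v$by / v$bx
  beta <- sum(w * rho) / sum(w)
  q <- sum(w * (rho - beta)^2)
  df <- j - 1L
  list(q = q, q_df = df, q_p = stats::pchisq(q, df, lower.tail = FALSE),
       i2 = if (q > 0) max(0, (q - df) / q) else 0)
}

#' MR-Egger intercept test for directional pleiotropy
#'
#' Reports the Egger regression intercept, its standard error, and the
#' two-sided p-value; p < 0.05 conventionally flags directional
#' pleiotropy.
#'
#' @param records an `mr_instruments` table with at least 3 rows.
#' @return List with `intercept`, `se`, `p`.
#' @export
egger_intercept_test <- function(records) {
  e <- mr_egger(records)
  list(intercept = e$extra$egger_intercept,
       se = e$extra$egger_intercept_se,
       p = e$extra$egger_intercept_p)
}

# The PRESSO residual statistics for one dataset: per-SNP standardized
# leave-one-out residuals and their sum.
presso_stats <- function(bx, by, sy) {
  t_loo <- loo_ivw_points(bx, by, sy)
  d <- (by - t_loo * bx)^2 / sy^2
  list(d = d, rss = sum(d))
}

#' MR-PRESSO: global pleiotropy test, outlier search, distortion test
#'
#' The global test compares the observed residual sum of squares of the
#' leave-one-out IVW fits against its null distribution obtained by
#' redrawing exposure and outcome betas from their sampling distributions
#' under the fitted (leave-one-out) model, `n_sim` times.  Each SNP's
#' observed residual is compared with its own simulated distribution and
#' Bonferroni-adjusted; flagged outliers are removed and the global test
#' repeated while it stays below 0.05 and outliers remain.  The distortion
#' test compares the outlier-corrected IVW estimate with estimates after
#' removing random subsets of the same size.
#'
#' @param records an `mr_instruments` table with at least 4 rows.
#' @param n_sim simulated null datasets (default 1000).
#' @param outlier_alpha significance level for Bonferroni-adjusted
#'   per-SNP outlier calls (default 0.05).
#' @param seed RNG seed; with it fixed the result is reproducible.
#' @return List with `global_p` (of the initial set), `outliers` (variant
#'   ids), `distortion_p` (NA when no outliers), and `corrected` (IVW
#'   `mr_estimate` on the retained set).
#' @export
mr_presso <- function(records, n_sim = 1000, outlier_alpha = 0.05,
                      seed = 1L) {
  v <- iv_vectors(records)
  if (length(v$bx) < 4L) stop("MR-PRESSO needs >= 4 instruments")
  res <- with_seed(seed, {
    active <- seq_along(v$bx)
    outliers <- integer(0)
    global_p_first <- NA_real_
    repeat {
      bx <- v$bx[active]; sx <- v$sx[active]
      by <- v$by[active]; sy <- v$sy[active]
      j <- length(bx)
      obs <- presso_stats(bx, by, sy)
      t_loo <- loo_ivw_points(bx, by, sy)
      # simulate null betas under the per-SNP leave-one-out fitted model
      bx_sim <- matrix(stats::rnorm(j * n_sim, bx, sx), nrow = j)
      by_sim <- matrix(stats::rnorm(j * n_sim, t_loo * bx, sy), nrow = j)
      wsim <- bx_sim * by_sim / sy^2        # w_j * rho_j per column
      w2sim <- bx_sim^2 / sy^2
      t_loo_sim <- (rep(colSums(wsim), each = j) - wsim) /
        (rep(colSums(w2sim), each = j) - w2sim)
      d_sim <- (by_sim - t_loo_sim * bx_sim)^2 / sy^2
      rss_sim <- colSums(d_sim)
      global_p <- (1 + sum(rss_sim >= obs$rss)) / (n_sim + 1)
      if (is.na(global_p_first)) global_p_first <- global_p
      if (global_p >= 0.05) break
      p_snp <- (1 + rowSums(d_sim >= obs$d)) / (n_sim + 1)
      flagged <- which(pmin(p_snp * j, 1) < outlier_alpha)
      if (length(flagged) == 0L) break
      outliers <- c(outliers, active[flagged])
      active <- setdiff(active, active[flagged])
      if (length(active) < 2L) stop("no instruments survive outlier removal")
    }
    distortion_p <- NA_real_
    if (length(outliers) > 0L) {
      keep <- setdiff(seq_along(v$bx), outliers)
      theta_corr <- mr_ivw_point(v$bx[keep], v$by[keep], v$sy[keep])
      theta_all <- mr_ivw_point(v$bx, v$by, v$sy)
      d_obs <- (theta_corr - theta_all)
      d_sim <- vapply(seq_len(n_sim), function(s) {
        drop_s <- sample(seq_along(v$bx), length(outliers))
        keep_s <- setdiff(seq_along(v$bx), drop_s)
        mr_ivw_point(v$bx[keep_s], v$by[keep_s], v$sy[keep_s]) - theta_all
      }, numeric(1))
      distortion_p <- (1 + sum(abs(d_sim) >= abs(d_obs))) / (n_sim + 1)
    }
    list(global_p = global_p_first, outliers = outliers,
         distortion_p = distortion_p)
  })
  keep <- setdiff(seq_along(v$bx), res$outliers)
  corrected <- if (length(keep) >= 2L)
    mr_ivw(records[keep, , drop = FALSE]) else wald_ratio(records[keep, ])
  list(global_p = res$global_p, outliers = v$id[res$outliers],
       distortion_p = res$distortion_p, corrected = corrected)
}

# IVW point estimate from raw vectors (ratio form).
mr_ivw_point <- function(bx, by, sy) {
  w <- bx^2 / sy^2
  sum(w * (by / bx)) / sum(w)
}

#' Leave-one-out IVW analysis
#'
#' Refits IVW J times, omitting each instrument in turn; the result is a
#' plot-ready influence table.
#'
#' @param records an `mr_instruments` table with at least 3 rows.
#' @return data.frame with one row per omitted variant: `omitted`, `beta`,
#'   `se`, `or_`, `ci_low`, `ci_high`, `p`.
#' @export
leave_one_out <- function(records) {
  j <- nrow(records)
  if (j < 3L) stop("leave-one-out needs >= 3 instruments")
  rows <- lapply(seq_len(j), function(i) {
    e <- mr_ivw(records[-i, , drop = FALSE])
    data.frame(omitted = records$variant_id[i], beta = e$beta, se = e$se,
               or_ = e$or_, ci_low = e$ci_low, ci_high = e$ci_high, p = e$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Full sensitivity report for one instrument set
#'
#' Bundles Cochran's Q, the Egger intercept test, MR-PRESSO, and the
#' leave-one-out table.
#'
#' @param records an `mr_instruments` table (>= 4 rows for PRESSO; PRESSO
#'   and Egger are skipped with NA fields when too few instruments).
#' @param n_sim,seed passed to [mr_presso()].
#' @return List of class `sensitivity_report`.
#' @export
sensitivity_report <- function(records, n_sim = 1000, seed = 1L) {
  q <- cochran_q(records)
  j <- nrow(records)
  egger <- if (j >= 3L) egger_intercept_test(records) else
    list(intercept = NA_real_, se = NA_real_, p = NA_real_)
  presso <- if (j >= 4L) mr_presso(records, n_sim = n_sim, seed = seed) else
    list(global_p = NA_real_, outliers = character(0),
         distortion_p = NA_real_, corrected = NULL)
  loo <- if (j >= 3L) leave_one_out(records) else NULL
  structure(
    list(q = q$q, q_df = q$q_df, q_p = q$q_p, i2 = q$i2,
         egger_intercept = egger$intercept,
         egger_intercept_p = egger$p,
         presso_global_p = presso$global_p,
         presso_outliers = presso$outliers,
         presso_distortion_p = presso$distortion_p,
         presso_corrected = presso$corrected,
         loo = loo),
    class = "sensitivity_report"
  )
}

#' Funnel-plot data export
#'
#' Writes per-SNP Wald ratios against their precisions (1/se of the ratio)
#' as TSV, the layout a funnel plot is drawn from.
#'
#' @param records an `mr_instruments` table.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_funnel_data <- function(records, path) {
  v <- iv_vectors(records)
  d <- data.frame(variant_id = v$id, wald_ratio = v$by / v$bx,
                  precision = abs(v$bx) / v$sy)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
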