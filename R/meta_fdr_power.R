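#' Recover a log-scale estimate from a printed OR and 95% CI
#'
#' beta = ln(OR); se = (ln(ci_high) - ln(ci_low)) / (2 * 1.959964).  This
#' is how published odds ratios re-enter a meta-analysis.
#'
#' @param or_ odds ratio.
#' @param ci_low,ci_high 95% confidence limits (0 < ci_low <= or_ <=
#'   ci_high, ci_low < ci_high).
#' @return List with `beta` and `se`.
#' @export
estimate_from_or_ci <- function(or_, ci_low, ci_high) {
  if (any(ci_low <= 0) || any(ci_low > or_) || any(or_ > ci_high)) {
    stop("need 0 < ci_low <= or_ <= ci_high")
  }
  if (any(ci_high <= ci_low)) stop("degenerate CI (zero width)")
  list(beta = log(or_), se = (log(ci_high) - log(ci_low)) / (2 * Z95))
}

#' Inverse-variance meta-analysis with an I-squared model rule
#'
#' Pools k study estimates on the log scale.  The fixed-effect pooled
#' estimate, Cochran's Q, and I^2 are computed first; when I^2 < 0.5 the
#' fixed-effect model is reported, otherwise DerSimonian-Laird random
#' effects (tau^2 = max(0, (Q - (k-1)) / (sum(w) - sum(w^2)/sum(w))), with
#' re-weighting by 1/(se^2 + tau^2)).
#'
#' @param beta study estimates (log ORs), length >= 2.
#' @param se their standard errors (> 0).
#' @return Object of class `meta_result`: list with `model`
#'   ("fixed"/"random"), `beta`, `se`, `or_`, `ci_low`, `ci_high`, `p`,
#'   `q`, `i2`, `tau2`, `k`.
#' @export
meta_analyze <- function(beta, se) {
  k <- length(beta)
  if (k < 2L) stop("meta-analysis needs >= 2 studies")
  if (any(se <= 0)) stop("all standard errors must be positive")
  w <- 1 / se^2
  bf <- sum(w * beta) / sum(w)
  q <- sum(w * (beta - bf)^2)
  i2 <- if (q > 0) max(0, (q - (k - 1)) / q) else 0
  if (i2 < 0.5) {
    model <- "fixed"
    b <- bf
    s <- sqrt(1 / sum(w))
    tau2 <- 0
  } else {
    model <- "random"
    tau2 <- max(0, (q - (k - 1)) / (sum(w) - sum(w^2) / sum(w)))
    wr <- 1 / (se^2 + tau2)
    b <- sum(wr * beta) / sum(wr)
    s <- sqrt(1 / sum(wr))
  }
  structure(
    list(model = model, beta = b, se = s, or_ = exp(b),
         ci_low = exp(b - Z95 * s), ci_high = exp(b + Z95 * s),
         p = 2 * stats::pnorm(-abs(b / s)), q = q, i2 = i2, tau2 = tau2,
         k = k),
    class = "meta_result"
  )
}

#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf("%s-effect meta-analysis of %d studies: OR = %.3f (95%% CI %.3f-%.3f), p = %.3g, I2 = %.1f%%\n",
              x$model, x$k, x$or_, x$ci_low, x$ci_high, x$p, 100 * x$i2))
  invisible(x)
}

#' Benjamini-Hochberg FDR adjustment with an explicit family size
#'
#' Step-up BH adjusted p-values.  `family_size` lets the listed p-values
#' be adjusted as members of a larger testing family whose remaining
#' members are assumed non-significant: the multiplier uses
#' `family_size` while ranks stay those among the listed values (a
#' documented approximation).  Defaults to the number supplied.
#'
#' @param pvals p-values in (0, 1].
#' @param family_size total family size, >= length(pvals).
#' @return Adjusted p-values in input order, capped at 1.
#' @export
bh_fdr <- function(pvals, family_size = length(pvals)) {
  if (any(is.na(pvals)) || any(pvals <= 0) || any(pvals > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  if (family_size < length(pvals)) {
    stop("family_size must be at least the number of p-values")
  }
  stats::p.adjust(pvals, method = "BH", n = family_size)
}

#' Power of two-sample MR with a binary outcome
#'
#' The analytic approximation behind the standard MR power calculators:
#' with b = ln(OR) per unit exposure and an instrument explaining `r2_xz`
#' of the exposure variance,
#' power = Phi( sqrt(n * r2_xz * K * (1-K)) * |b| - z_{1-alpha/2} ),
#' where n is the outcome sample size and K its case fraction.
#'
#' @param n outcome GWAS sample size.
#' @param r2_xz variance of the exposure explained by the instruments,
#'   in \[0, 1).
#' @param case_fraction case fraction K in (0, 1).
#' @param or_ hypothesized causal odds ratio per unit exposure.
#' @param alpha two-sided significance level (default 0.05).
#' @return Power in \[0, 1\].
#' @export
mr_power_binary <- function(n, r2_xz, case_fraction, or_, alpha = 0.05) {
  if (n <= 0 || r2_xz < 0 || r2_xz >= 1 ||
      case_fraction <= 0 || case_fraction >= 1 ||
      or_ <= 0 || alpha <= 0 || alpha >= 1) {
    stop("parameter out of range")
  }
  b <- log(or_)
  ncp <- sqrt(n * r2_xz * case_fraction * (1 - case_fraction)) * abs(b)
  stats::pnorm(ncp - stats::qnorm(1 - alpha / 2))
}

#' Meta-analyze a forest-plot style study table
#'
#' Accepts either `(study, or_, ci_low, ci_high)` or `(study, beta, se)`
#' columns, converts printed ORs to the log scale, pools them with
#' [meta_analyze()], and returns both the per-study rows and the pooled
#' summary.
#'
#' @param studies data.frame as above.
#' @return List with `studies` (log-scale per-study table) and `pooled`
#'   (a `meta_result`).
#' @export
meta_analyze_table <- function(studies) {
  stopifnot(is.data.frame(studies))
  if (!is.null(studies$beta) && !is.null(studies$se)) {
    b <- studies$beta
    s <- studies$se
  } else if (!is.null(studies$or_)) {
    est <- estimate_from_or_ci(studies$or_, studies$ci_low, studies$ci_high)
    b <- est$beta
    s <- est$se
  } else {
    stop("need (beta, se) or (or_, ci_low, ci_high) columns")
  }
  list(
    studies = data.frame(study = studies$study, beta = b, se = s,
                         stringsAsFactors = FALSE),
    pooled = meta_analyze(b, s)
  )
}
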