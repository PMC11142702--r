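#' Define a colocalization region around the top association
#'
#' The reference variant is the one with the smallest p-value (ties broken
#' by lower position, for determinism); the region is every variant on the
#' reference's chromosome within `window_kb` of it (closed interval).
#'
#' @param stats a `summary_stat_set`, nonempty.
#' @param window_kb half-width of the region in kb (default 100).
#' @return Character vector of variant ids in the region.
#' @export
define_region <- function(stats, window_kb = 100) {
  stopifnot(inherits(stats, "summary_stat_set"))
  d <- stats$snps
  if (nrow(d) == 0L) stop("empty summary-stat set")
  ref <- d[order(d$p, d$position), ][1, ]
  inwin <- d$chromosome == ref$chromosome &
    abs(d$position - ref$position) <= window_kb * 1000
  d$variant_id[inwin]
}

#' Log approximate Bayes factor for one association
#'
#' Wakefield's approximation: with z = beta/se, V = se^2 and prior effect
#' variance W = prior_sd^2,
#' lABF = 0.5 * (log(V/(V+W)) + z^2 * W/(V+W)).
#'
#' @param beta effect estimate.
#' @param se its standard error (> 0).
#' @param prior_sd prior standard deviation of the true effect.
#' @return The log ABF (vectorised).
#' @export
compute_labf <- function(beta, se, prior_sd) {
  if (any(is.na(se)) || any(se <= 0)) stop("se must be positive")
  v <- se^2
  w <- prior_sd^2
  z2 <- (beta / se)^2
  0.5 * (log(v / (v + w)) + z2 * w / (v + w))
}

logsumexp <- function(x) {
  if (length(x) == 0L) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# log(exp(a) - exp(b)) for a >= b, guarding cancellation.
logdiffexp <- function(a, b) {
  if (b >= a) return(-Inf)
  a + log1p(-exp(b - a))
}

#' Approximate-Bayes-factor colocalization over a region pair
#'
#' Single-causal-variant enumeration over the variants shared by the two
#' regions: per-variant log ABFs for each trait are combined with the
#' prior probabilities `p1` (causal for trait 1 only), `p2` (trait 2
#' only), and `p12` (shared causal variant) into posterior probabilities
#' of the five hypotheses H0 (no association) through H4 (shared causal
#' variant).  All sums are computed in log space.
#'
#' @param region1,region2 `summary_stat_set` objects sharing >= 1 variant
#'   id; the analysis is restricted to the shared ids (logged).
#' @param p1,p2,p12 prior probabilities (defaults 1e-4, 1e-4, 1e-5).
#' @param prior_sd1,prior_sd2 prior effect standard deviations; default
#'   0.15 for a quantitative trait and 0.2 for a binary one, chosen per
#'   region's `binary_trait` flag.
#' @return Object of class `coloc_posterior`: list with `pp` (named
#'   PP.H0..PP.H4, summing to 1), `n_variants`, `priors`.
#' @export
coloc_abf <- function(region1, region2, p1 = 1e-4, p2 = 1e-4, p12 = 1e-5,
                      prior_sd1 = NULL, prior_sd2 = NULL) {
  stopifnot(inherits(region1, "summary_stat_set"),
            inherits(region2, "summary_stat_set"))
  if (is.null(prior_sd1)) prior_sd1 <- if (region1$binary_trait) 0.2 else 0.15
  if (is.null(prior_sd2)) prior_sd2 <- if (region2$binary_trait) 0.2 else 0.15
  shared <- intersect(region1$snps$variant_id, region2$snps$variant_id)
  if (length(shared) == 0L) stop("regions share no variant ids")
  n_all <- c(nrow(region1$snps), nrow(region2$snps))
  if (any(n_all > length(shared))) {
    message("restricting colocalization to ", length(shared),
            " shared variant(s)")
  }
  d1 <- region1$snps[match(shared, region1$snps$variant_id), ]
  d2 <- region2$snps[match(shared, region2$snps$variant_id), ]
  l1 <- compute_labf(d1$beta, d1$se, prior_sd1)
  l2 <- compute_labf(d2$beta, d2$se, prior_sd2)

  s1 <- logsumexp(l1)            # log sum_i BF1_i
  s2 <- logsumexp(l2)
  s12 <- logsumexp(l1 + l2)      # log sum_i BF1_i BF2_i
  # log sum_{i != j} BF1_i BF2_j = log( sum_i BF1_i * sum_j BF2_j - sum_i BF1_i BF2_i )
  s3 <- logdiffexp(s1 + s2, s12)

  lh <- c(
    H0 = 0,
    H1 = log(p1) + s1,
    H2 = log(p2) + s2,
    H3 = log(p1) + log(p2) + s3,
    H4 = log(p12) + s12
  )
  pp <- exp(lh - logsumexp(lh))
  names(pp) <- paste0("PP.", names(lh))
  structure(list(pp = pp, n_variants = length(shared),
                 priors = c(p1 = p1, p2 = p2, p12 = p12)),
            class = "coloc_posterior")
}

#' @export
print.coloc_posterior <- function(x, ...) {
  cat("coloc posterior over", x$n_variants, "shared variants:\n")
  print(round(x$pp, 4))
  invisible(x)
}
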