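# Normal 95% multiplier used for every confidence interval in the package.
Z95 <- stats::qnorm(0.975)

# Run code under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Construct an MR estimate object
#'
#' @param method estimator label.
#' @param beta causal log-effect (log odds ratio for binary outcomes).
#' @param se standard error of `beta`.
#' @param n_snp number of instruments used.
#' @param extra named list of method-specific fields.
#' @return An object of class `mr_estimate` with the estimate on both the
#'   log and odds-ratio scales, a normal-theory 95% CI, and a two-sided
#'   normal p-value.
#' @export
mr_estimate <- function(method, beta, se, n_snp, extra = list()) {
  stopifnot(se > 0, n_snp >= 1)
  p <- 2 * stats::pnorm(-abs(beta / se))
  structure(
    list(method = method, beta = beta, se = se, or_ = exp(beta),
         ci_low = exp(beta - Z95 * se), ci_high = exp(beta + Z95 * se),
         p = max(p, .Machine$double.xmin), n_snp = n_snp, extra = extra),
    class = "mr_estimate"
  )
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("%s: OR = %.3f (95%% CI %.3f-%.3f), beta = %.4f (se %.4f), p = %.3g, nSNP = %d\n",
              x$method, x$or_, x$ci_low, x$ci_high, x$beta, x$se, x$p,
              x$n_snp))
  invisible(x)
}

#' Wald ratio causal estimate from a single instrument
#'
#' beta = outcome_beta / exposure_beta with the first-order standard error
#' outcome_se / |exposure_beta| (exposure beta treated as fixed).
#'
#' @param rec a single-row `mr_instruments` table (or list) with
#'   `exposure_beta`, `outcome_beta`, `outcome_se`.
#' @return An `mr_estimate` with method `"wald"`.
#' @export
wald_ratio <- function(rec) {
  if (is.data.frame(rec)) {
    stopifnot(nrow(rec) == 1L)
    rec <- as.list(rec)
  }
  if (rec$exposure_beta == 0) stop("exposure_beta is 0; Wald ratio undefined")
  mr_estimate("wald", rec$outcome_beta / rec$exposure_beta,
              rec$outcome_se / abs(rec$exposure_beta), 1L)
}

# Shared plumbing: pull aligned vectors out of an instrument table.
iv_vectors <- function(records) {
  stopifnot(is.data.frame(records))
  list(bx = records$exposure_beta, sx = records$exposure_se,
       by = records$outcome_beta, sy = records$outcome_se,
       id = records$variant_id)
}

#' Inverse-variance-weighted MR (multiplicative random effects)
#'
#' Weighted regression of outcome betas on exposure betas through the
#' origin with weights 1/outcome_se^2 (equivalently the 1/variance-weighted
#' mean of per-SNP Wald ratios).  The fixed-effect standard error is
#' inflated by max(1, sqrt(Q/(J-1))): multiplicative random effects that
#' never shrink below the fixed-effect precision.
#'
#' @param records an `mr_instruments` table with at least 2 rows.
#' @return An `mr_estimate` with method `"ivw_mre"`; `extra` carries the
#'   heterogeneity scale factor.
#' @export
mr_ivw <- function(records) {
  v <- iv_vectors(records)
  j <- length(v$bx)
  if (j < 2L) stop("IVW needs >= 2 instruments; use wald_ratio for J = 1")
  w <- 1 / v$sy^2
  fit <- stats::lm(v$by ~ 0 + v$bx, weights = w)
  beta <- unname(stats::coef(fit)[1])
  se_fixed <- sqrt(1 / sum(w * v$bx^2))
  q <- sum(w * (v$by - beta * v$bx)^2)
  scale <- max(1, sqrt(q / (j - 1)))
  mr_estimate("ivw_mre", beta, se_fixed * scale, j,
              extra = list(q = q, overdispersion = scale))
}

#' MR-Egger regression
#'
#' Weighted linear regression of outcome betas on exposure betas with an
#' intercept (weights 1/outcome_se^2).  Exposure betas are first oriented
#' non-negative (outcome betas co-flipped) so the intercept is an
#' interpretable average directional-pleiotropy effect.  The slope is the
#' causal estimate; intercept, its se and p are reported in `extra`.
#' Standard errors carry the multiplicative overdispersion floor with
#' df = J - 2.
#'
#' @param records an `mr_instruments` table with at least 3 rows.
#' @return An `mr_estimate` with method `"egger"`.
#' @export
mr_egger <- function(records) {
  v <- iv_vectors(records)
  j <- length(v$bx)
  if (j < 3L) stop("MR-Egger needs >= 3 instruments")
  s <- ifelse(v$bx < 0, -1, 1)
  bx <- s * v$bx
  by <- s * v$by
  if (stats::sd(bx) < .Machine$double.eps^0.5 * max(abs(bx), 1)) {
    stop("degenerate design: exposure betas collinear with the intercept")
  }
  w <- 1 / v$sy^2
  fit <- stats::lm(by ~ bx, weights = w)
  sm <- summary(fit)
  sigma <- sm$sigma
  cf <- sm$coefficients
  scale <- max(1, sigma)
  slope_se <- cf["bx", "Std. Error"] / sigma * scale
  int_se <- cf["(Intercept)", "Std. Error"] / sigma * scale
  int <- cf["(Intercept)", "Estimate"]
  mr_estimate("egger", cf["bx", "Estimate"], slope_se, j,
              extra = list(
                egger_intercept = int, egger_intercept_se = int_se,
                egger_intercept_p = 2 * stats::pnorm(-abs(int / int_se)),
                overdispersion = scale))
}

# Weighted median by linear interpolation of the weighted empirical CDF
# evaluated at 0.5 (cumulative weight s_j = cumsum(w)_j - w_j / 2).
weighted_median_point <- function(ratios, weights) {
  o <- order(ratios)
  r <- ratios[o]
  w <- weights[o] / sum(weights)
  s <- cumsum(w) - w / 2
  stats::approx(s, r, xout = 0.5, rule = 2, ties = "ordered")$y
}

#' Weighted-median MR
#'
#' The weighted median of per-SNP Wald ratios, consistent when instruments
#' carrying at least half the total weight are valid.  Weights are
#' exposure_beta^2 / outcome_se^2 (inverse variance of the ratio).  The
#' standard error comes from a seeded parametric bootstrap that redraws
#' exposure and outcome betas from their normal sampling distributions.
#'
#' @param records an `mr_instruments` table with at least 3 rows.
#' @param n_boot bootstrap draws (default 1000).
#' @param seed RNG seed for the bootstrap.
#' @return An `mr_estimate` with method `"weighted_median"`.
#' @export
mr_weighted_median <- function(records, n_boot = 1000, seed = 1L) {
  v <- iv_vectors(records)
  j <- length(v$bx)
  if (j < 3L) stop("weighted median needs >= 3 instruments")
  w <- v$bx^2 / v$sy^2
  est <- weighted_median_point(v$by / v$bx, w)
  boots <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      bx <- stats::rnorm(j, v$bx, v$sx)
      by <- stats::rnorm(j, v$by, v$sy)
      weighted_median_point(by / bx, bx^2 / v$sy^2)
    }, numeric(1))
  })
  mr_estimate("weighted_median", est, stats::sd(boots), j,
              extra = list(n_boot = n_boot))
}

# Profile negative log-likelihood of theta for the valid set: each valid
# SNP contributes (by - theta*bx)^2 / (2*(sy^2 + theta^2*sx^2)) after
# maximizing over its latent true exposure effect.
cml_profile_nll <- function(theta, bx, sx, by, sy, valid) {
  sum((by[valid] - theta * bx[valid])^2 /
        (2 * (sy[valid]^2 + theta^2 * sx[valid]^2)))
}

# One cML fit at a fixed number K of invalid instruments: coordinate
# ascent between theta, the latent exposure effects, and the invalid set.
cml_fit_k <- function(bx, sx, by, sy, k, theta0, tol = 1e-8, max_iter = 200) {
  j <- length(bx)
  theta <- theta0
  invalid <- integer(0)
  conv <- FALSE
  for (it in seq_len(max_iter)) {
    # standardized residuals under the current theta determine invalidity
    resid2 <- (by - theta * bx)^2 / (sy^2 + theta^2 * sx^2)
    invalid_new <- if (k > 0) order(resid2, decreasing = TRUE)[seq_len(k)]
      else integer(0)
    valid <- setdiff(seq_len(j), invalid_new)
    if (length(valid) == 0L) return(NULL)
    # latent exposure effects for valid SNPs, then theta given them
    mu <- (bx[valid] / sx[valid]^2 + theta * by[valid] / sy[valid]^2) /
      (1 / sx[valid]^2 + theta^2 / sy[valid]^2)
    denom <- sum(mu^2 / sy[valid]^2)
    if (denom <= 0) return(NULL)
    theta_new <- sum(mu * by[valid] / sy[valid]^2) / denom
    conv <- abs(theta_new - theta) < tol && setequal(invalid_new, invalid)
    theta <- theta_new
    invalid <- invalid_new
    if (conv) break
  }
  valid <- setdiff(seq_len(j), invalid)
  nll <- cml_profile_nll(theta, bx, sx, by, sy, valid)
  # observed information of the profile likelihood by central difference
  h <- 1e-4 * (abs(theta) + 1e-3)
  d2 <- (cml_profile_nll(theta + h, bx, sx, by, sy, valid) -
           2 * nll +
           cml_profile_nll(theta - h, bx, sx, by, sy, valid)) / h^2
  se <- if (is.finite(d2) && d2 > 0) 1 / sqrt(d2) else NA_real_
  list(theta = theta, se = se, nll = nll, invalid = sort(invalid),
       converged = conv)
}

#' Constrained-maximum-likelihood MR (cML with BIC model selection)
#'
#' Maximizes the bivariate normal likelihood of the observed exposure and
#' outcome betas while allowing exactly K instruments to carry free
#' direct (pleiotropic) effects, for K = 0..`max_k`; K is selected by BIC
#' with effective sample size min(n_exposure, n_outcome).  For each K the
#' fit alternates between the causal effect, the latent exposure effects,
#' and the invalid set (the K largest standardized residuals) until the
#' causal effect changes by less than `tol`.
#'
#' @param records an `mr_instruments` table with at least 3 rows.
#' @param n_exposure,n_outcome GWAS sample sizes (default: max of the
#'   per-record values).
#' @param max_k maximum number of invalid instruments considered
#'   (default floor(J/2)).
#' @param seed seed for the random restarts.
#' @param n_start random restarts per K in addition to the IVW start.
#' @param tol,max_iter convergence controls.
#' @return An `mr_estimate` with method `"cml"`; `extra` carries the
#'   selected number of invalid instruments (`cml_k_invalid`), their
#'   variant ids, and the per-K BIC table.
#' @export
mr_cml <- function(records, n_exposure = NULL, n_outcome = NULL,
                   max_k = NULL, seed = 1L, n_start = 3,
                   tol = 1e-8, max_iter = 200) {
  v <- iv_vectors(records)
  j <- length(v$bx)
  if (j < 3L) stop("cML needs >= 3 instruments")
  if (is.null(n_exposure)) n_exposure <- max(records$exposure_n, na.rm = TRUE)
  if (is.null(n_outcome)) n_outcome <- max(records$outcome_n, na.rm = TRUE)
  if (is.null(max_k)) max_k <- floor(j / 2)
  max_k <- min(max_k, j - 2L)
  n_eff <- min(n_exposure, n_outcome)
  theta_ivw <- mr_ivw(records)$beta

  starts <- with_seed(seed, c(theta_ivw, stats::rnorm(n_start, theta_ivw,
                                                      abs(theta_ivw) + 0.1)))
  fits <- vector("list", max_k + 1L)
  for (k in 0:max_k) {
    best <- NULL
    for (s in starts) {
      f <- cml_fit_k(v$bx, v$sx, v$by, v$sy, k, s, tol, max_iter)
      if (!is.null(f) && f$converged &&
          (is.null(best) || f$nll < best$nll)) best <- f
    }
    fits[[k + 1L]] <- best
  }
  ok <- !vapply(fits, is.null, logical(1))
  if (!any(ok)) stop("cML failed to converge for every candidate K")
  bic <- vapply(seq_along(fits), function(i) {
    if (!ok[i]) return(Inf)
    2 * fits[[i]]$nll + (i - 1) * log(n_eff)
  }, numeric(1))
  sel <- which.min(bic)
  f <- fits[[sel]]
  if (is.na(f$se)) stop("cML information matrix not positive at optimum")
  mr_estimate("cml", f$theta, f$se, j,
              extra = list(cml_k_invalid = sel - 1L,
                           invalid_ids = v$id[f$invalid],
                           bic = stats::setNames(bic[ok],
                                                 paste0("K", which(ok) - 1))))
}

#' Run all applicable univariable MR estimators
#'
#' Dispatch by instrument count J: J = 1 gives the Wald ratio only; J = 2
#' adds IVW to the per-SNP Wald table; J >= 3 runs IVW, MR-Egger, weighted
#' median, and cML.
#'
#' @param records an `mr_instruments` table.
#' @param seed seed for the stochastic estimators.
#' @return Named list of `mr_estimate` objects (per-SNP Wald estimates
#'   under `$wald` as a list when J > 1).
#' @export
run_uvmr <- function(records, seed = 1L) {
  stopifnot(is.data.frame(records))
  j <- nrow(records)
  if (j == 0L) stop("no instruments supplied")
  if (j == 1L) return(list(wald = wald_ratio(records[1, ])))
  wald <- lapply(seq_len(j), function(i) wald_ratio(records[i, ]))
  names(wald) <- records$variant_id
  out <- list(wald = wald, ivw_mre = mr_ivw(records))
  if (j >= 3L) {
    out$egger <- mr_egger(records)
    out$weighted_median <- mr_weighted_median(records, seed = seed)
    out$cml <- mr_cml(records, seed = seed)
  }
  out
}

#' Flatten MR results into a table mirroring a forest-plot layout
#'
#' @param results named list of `mr_estimate` objects (per-SNP Wald lists
#'   are skipped).
#' @param exposure,outcome labels for the table.
#' @return data.frame with one row per method.
#' @export
mr_results_table <- function(results, exposure = "", outcome = "") {
  rows <- lapply(results, function(e) {
    if (!inherits(e, "mr_estimate")) return(NULL)
    data.frame(exposure = exposure, outcome = outcome, method = e$method,
               n_snp = e$n_snp, beta = e$beta, se = e$se, or_ = e$or_,
               ci_low = e$ci_low, ci_high = e$ci_high, p = e$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  rownames(out) <- NULL
  out
}
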