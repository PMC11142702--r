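#' Harmonize several exposures and one outcome to a shared allele coding
#'
#' Builds the multi-exposure instrument table for multivariable MR.  The
#' first exposure's effect alleles are the reference; every other exposure
#' and the outcome are aligned to them with the same rules as
#' [harmonize()].  Only variants present (and unambiguously alignable) in
#' all sets are retained.
#'
#' @param exposures named list of `summary_stat_set` objects (>= 1).
#' @param outcome a `summary_stat_set`.
#' @param snps variant ids to use (typically the union of each exposure's
#'   genome-wide hits after clumping).
#' @param ... passed to [harmonize()].
#' @return List with `exposure_beta` (J x E matrix), `exposure_se`
#'   (J x E), `outcome_beta`, `outcome_se`, `variant_id`, and `records`
#'   (the first exposure's harmonized table, for bookkeeping).
#' @export
harmonize_mvmr <- function(exposures, outcome, snps, ...) {
  stopifnot(is.list(exposures), length(exposures) >= 1)
  if (is.null(names(exposures))) {
    names(exposures) <- vapply(exposures, function(e) e$trait_label, "")
  }
  ref <- exposures[[1]]
  snps <- intersect(snps, ref$snps$variant_id)
  base <- harmonize(ref, outcome, snps, ...)
  ids <- base$variant_id
  aligned <- list()
  for (k in seq_along(exposures)) {
    if (k == 1L) next
    h <- harmonize(ref, exposures[[k]], intersect(ids, snps), ...)
    ids <- intersect(ids, h$variant_id)
    aligned[[names(exposures)[k]]] <- h
  }
  base <- base[match(ids, base$variant_id), , drop = FALSE]
  bx <- matrix(base$exposure_beta, ncol = 1)
  sx <- matrix(base$exposure_se, ncol = 1)
  for (nm in names(aligned)) {
    h <- aligned[[nm]]
    h <- h[match(ids, h$variant_id), , drop = FALSE]
    bx <- cbind(bx, h$outcome_beta)
    sx <- cbind(sx, h$outcome_se)
  }
  colnames(bx) <- colnames(sx) <- names(exposures)
  list(exposure_beta = bx, exposure_se = sx,
       outcome_beta = base$outcome_beta, outcome_se = base$outcome_se,
       variant_id = ids, records = base)
}

#' Multivariable IVW MR
#'
#' Weighted multivariable regression (no intercept) of outcome betas on
#' the matrix of exposure betas with weights 1/outcome_se^2, giving each
#' exposure's direct effect conditional on the others.  Standard errors
#' carry the multiplicative overdispersion floor (df = J - #exposures,
#' scale never below 1).
#'
#' @param exposure_beta J x E numeric matrix with exposure labels as
#'   column names (or the list returned by [harmonize_mvmr()], in which
#'   case the remaining arguments are taken from it).
#' @param outcome_beta,outcome_se outcome association vectors (length J).
#' @return Object of class `mvmr_result`: a data.frame with one row per
#'   exposure (`beta`, `se`, `or_`, `ci_low`, `ci_high`, `p`) plus
#'   attributes `n_snp` and `overdispersion`.
#' @export
mvmr_ivw <- function(exposure_beta, outcome_beta = NULL, outcome_se = NULL) {
  if (is.list(exposure_beta) && !is.null(exposure_beta$exposure_beta)) {
    outcome_beta <- exposure_beta$outcome_beta
    outcome_se <- exposure_beta$outcome_se
    exposure_beta <- exposure_beta$exposure_beta
  }
  x <- as.matrix(exposure_beta)
  if (is.null(colnames(x))) colnames(x) <- paste0("exposure", seq_len(ncol(x)))
  j <- nrow(x)
  e <- ncol(x)
  if (j < e + 2L) stop("MVMR needs at least #exposures + 2 instruments")
  qrx <- qr(sqrt(1 / outcome_se^2) * x)
  if (qrx$rank < e) {
    bad <- colnames(x)[setdiff(seq_len(e), qrx$pivot[seq_len(qrx$rank)])]
    stop("rank-deficient exposure matrix; collinear exposure(s): ",
         paste(bad, collapse = ", "))
  }
  w <- 1 / outcome_se^2
  fit <- stats::lm(outcome_beta ~ 0 + x, weights = w)
  sm <- summary(fit)
  sigma <- sm$sigma
  scale <- max(1, sigma)
  cf <- sm$coefficients
  beta <- cf[, "Estimate"]
  se <- cf[, "Std. Error"] / sigma * scale
  out <- data.frame(
    exposure = colnames(x), beta = unname(beta), se = unname(se),
    or_ = exp(unname(beta)),
    ci_low = exp(unname(beta) - Z95 * unname(se)),
    ci_high = exp(unname(beta) + Z95 * unname(se)),
    p = 2 * stats::pnorm(-abs(unname(beta) / unname(se))),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "n_snp") <- j
  attr(out, "overdispersion") <- scale
  class(out) <- c("mvmr_result", class(out))
  out
}

as_effect <- function(x) {
  if (inherits(x, "mr_estimate")) list(beta = x$beta, se = x$se)
  else list(beta = x$beta, se = x$se)
}

#' Two-step MR mediation analysis
#'
#' Decomposes the total effect of an exposure on an outcome into the
#' direct effect (from multivariable MR adjusting for the mediator) and
#' the indirect effect through the mediator.  The difference method takes
#' indirect = total - direct with se = sqrt(se_total^2 + se_direct^2)
#' (independence of the two estimates is assumed, a documented
#' approximation with summary data).  The product method multiplies the
#' exposure-to-mediator effect by the mediator-to-outcome effect
#' conditional on the exposure, with a first-order delta-method se.  The
#' proportion mediated is indirect/total with a delta-method CI; it may
#' legitimately fall outside \[0, 1\] (inconsistent mediation).
#'
#' @param total total-effect estimate (an `mr_estimate` or a
#'   `list(beta=, se=)`).
#' @param direct direct-effect estimate (same forms accepted); required
#'   for the difference method.
#' @param x_to_m,m_to_y_given_x exposure-to-mediator and conditional
#'   mediator-to-outcome estimates; required for the product method.
#' @param method `"difference"` (default) or `"product"`.
#' @return Object of class `mediation_result`: list with `total`,
#'   `direct`, `indirect` (each `beta` + `se` + `ci`), `proportion`,
#'   `proportion_ci`, and `p` (normal test of the indirect effect).
#' @export
mediation <- function(total, direct = NULL, x_to_m = NULL,
                      m_to_y_given_x = NULL,
                      method = c("difference", "product")) {
  method <- match.arg(method)
  tt <- as_effect(total)
  if (method == "difference") {
    if (is.null(direct)) stop("difference method needs the direct effect")
    dd <- as_effect(direct)
    ind <- tt$beta - dd$beta
    ind_se <- sqrt(tt$se^2 + dd$se^2)
  } else {
    if (is.null(x_to_m) || is.null(m_to_y_given_x)) {
      stop("product method needs x_to_m and m_to_y_given_x")
    }
    a <- as_effect(x_to_m)
    b <- as_effect(m_to_y_given_x)
    ind <- a$beta * b$beta
    ind_se <- sqrt(a$beta^2 * b$se^2 + b$beta^2 * a$se^2)
    dd <- if (!is.null(direct)) as_effect(direct) else
      list(beta = tt$beta - ind, se = NA_real_)
  }
  p_ind <- 2 * stats::pnorm(-abs(ind / ind_se))
  if (tt$beta == 0) {
    warning("total effect is 0; proportion mediated undefined")
    prop <- NA_real_
    prop_ci <- c(NA_real_, NA_real_)
  } else {
    prop <- ind / tt$beta
    prop_se <- sqrt(ind_se^2 / tt$beta^2 + ind^2 * tt$se^2 / tt$beta^4)
    prop_ci <- prop + c(-1, 1) * Z95 * prop_se
  }
  structure(
    list(total = tt,
         direct = dd,
         indirect = list(beta = ind, se = ind_se,
                         ci = ind + c(-1, 1) * Z95 * ind_se),
         proportion = prop, proportion_ci = prop_ci, p = p_ind,
         method = method),
    class = "mediation_result"
  )
}

#' @export
print.mediation_result <- function(x, ...) {
  cat(sprintf("mediation (%s method):\n", x$method))
  cat(sprintf("  total    %8.4f (se %.4f)\n", x$total$beta, x$total$se))
  cat(sprintf("  direct   %8.4f (se %.4f)\n", x$direct$beta, x$direct$se))
  cat(sprintf("  indirect %8.4f (se %.4f), p = %.3g\n",
              x$indirect$beta, x$indirect$se, x$p))
  if (!is.na(x$proportion)) {
    cat(sprintf("  proportion mediated %.4f (95%% CI %.4f, %.4f)\n",
                x$proportion, x$proportion_ci[1], x$proportion_ci[2]))
  }
  invisible(x)
}

#' Label a candidate mediator by its indirect-effect evidence
#'
#' "mediator" when the indirect-effect p-value is below `alpha`,
#' otherwise "attenuator/confounder-like".  A reporting aid only; the
#' substantive call is the analyst's.
#'
#' @param med a `mediation_result`.
#' @param alpha significance threshold (default 0.05).
#' @return Character label.
#' @export
mediator_label <- function(med, alpha = 0.05) {
  if (med$p < alpha) "mediator" else "attenuator/confounder-like"
}
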