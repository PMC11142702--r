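# Allele pairs used for simulated variants: non-palindromic, so harmonized
# sets never lose SNPs to strand ambiguity unless a test plants them.
SIM_ALLELE_PAIRS <- matrix(c("A", "G", "A", "C", "T", "G", "T", "C",
                             "G", "A", "C", "A", "G", "T", "C", "T"),
                           ncol = 2, byrow = TRUE)

#' Simulation configuration for synthetic GWAS summary statistics
#'
#' Defines the generating model for a two-sample MR experiment with known
#' truth.  Instrument effects on the exposure are scaled so their total
#' explained variance is `exposure_h2`; per-SNP sampling standard errors
#' follow the analytic 1/sqrt(2*MAF*(1-MAF)*n) form; outcome effects are
#' theta times the true exposure effect plus optional direct (horizontal)
#' pleiotropy and confounder-mediated (correlated) pleiotropy, on the
#' log-OR scale for a binary outcome.
#'
#' @param n_snp number of instruments.
#' @param maf_range minor-allele-frequency range, within (0, 0.5\].
#' @param exposure_h2 total variance in the exposure explained by the
#'   instruments, in (0, 1).
#' @param n_exposure,n_outcome,n_mediator GWAS sample sizes.  Defaults are
#'   desk-scale stand-ins for large consortium studies.
#' @param theta true causal effect of exposure on outcome (log-OR).
#' @param pleiotropy_frac fraction of SNPs with direct outcome effects.
#' @param pleiotropy_mean,pleiotropy_sd mean and sd of those direct
#'   effects (nonzero mean = directional pleiotropy).
#' @param correlated_frac fraction of SNPs acting through a shared
#'   confounder (correlated pleiotropy).
#' @param confounder_ratio outcome-to-exposure loading ratio of the
#'   confounder path.
#' @param mediator_chain optional list(beta_x_to_m, beta_m_to_y,
#'   beta_x_direct) switching on the mediation generator.
#' @param ld_blocks optional list(size, r): consecutive blocks of `size`
#'   SNPs with constant pairwise correlation `r`.
#' @param seed integer seed; a fixed seed makes the output bit-reproducible.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_snp = 100, maf_range = c(0.05, 0.5),
                       exposure_h2 = 0.1, n_exposure = 3e5,
                       n_outcome = 2e5, n_mediator = 2e5, theta = 0.2,
                       pleiotropy_frac = 0, pleiotropy_mean = 0,
                       pleiotropy_sd = 0.1, correlated_frac = 0,
                       confounder_ratio = 0.5, mediator_chain = NULL,
                       ld_blocks = NULL, seed = 1L) {
  stopifnot(n_snp >= 1, maf_range[1] > 0, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2],
            exposure_h2 > 0, exposure_h2 < 1,
            pleiotropy_frac >= 0, pleiotropy_frac <= 1,
            correlated_frac >= 0, correlated_frac <= 1)
  structure(as.list(environment()), class = "sim_config")
}

# Draw per-SNP scaffolding shared by the generators.
sim_variants <- function(n_snp, maf_range, prefix = "rs") {
  maf <- stats::runif(n_snp, maf_range[1], maf_range[2])
  pair <- SIM_ALLELE_PAIRS[sample.int(nrow(SIM_ALLELE_PAIRS), n_snp,
                                      replace = TRUE), , drop = FALSE]
  data.frame(
    variant_id = paste0(prefix, seq_len(n_snp)),
    chromosome = "1",
    position = seq_len(n_snp) * 2e7,   # 20 Mb apart: clumping-independent
    effect_allele = pair[, 1], other_allele = pair[, 2],
    eaf = maf, stringsAsFactors = FALSE
  )
}

# Scale raw effects so sum(2*maf*(1-maf)*b^2) = h2.
scale_to_h2 <- function(raw, maf, h2) {
  raw * sqrt(h2 / sum(2 * maf * (1 - maf) * raw^2))
}

# Observed summary statistics for one trait given true per-SNP effects.
observe_trait <- function(vars, b_true, n, trait_label, ancestry = "EUR",
                          binary = FALSE) {
  se <- 1 / sqrt(2 * vars$eaf * (1 - vars$eaf) * n)
  beta <- stats::rnorm(length(b_true), b_true, se)
  d <- vars
  d$beta <- beta
  d$se <- se
  d$p <- pmax(2 * stats::pnorm(-abs(beta / se)), .Machine$double.xmin)
  d$n <- n
  summary_stat_set(d, trait_label = trait_label, ancestry_label = ancestry,
                   binary_trait = binary)
}

# Exchangeable-block LD matrix for consecutive blocks.
block_ld_matrix <- function(ids, block_size, r) {
  n <- length(ids)
  m <- diag(n)
  starts <- seq(1, n, by = block_size)
  for (s in starts) {
    idx <- s:min(s + block_size - 1, n)
    m[idx, idx] <- r
    diag(m)[idx] <- 1
  }
  dimnames(m) <- list(ids, ids)
  as_ld_matrix(m)
}

#' Simulate a two-sample MR dataset with known truth
#'
#' Generates paired exposure and outcome summary-statistic sets under the
#' configured causal model.  With `ld_blocks` set, true marginal exposure
#' effects are the LD-propagated joint effects and the block LD matrix is
#' returned in the truth record.
#'
#' @param cfg a [sim_config()].
#' @return List with `exposure` and `outcome` (`summary_stat_set`s) and
#'   `truth`: every generating quantity (true effects, pleiotropy
#'   assignments, MAFs, analytic ses, the LD matrix if any, and the
#'   config itself), sufficient to replay the draw.
#' @export
simulate_two_sample <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed, {
    vars <- sim_variants(cfg$n_snp, cfg$maf_range)
    raw <- stats::rnorm(cfg$n_snp)
    ld <- NULL
    if (!is.null(cfg$ld_blocks)) {
      ld <- block_ld_matrix(vars$variant_id, cfg$ld_blocks$size,
                            cfg$ld_blocks$r)
      raw <- drop(unclass(ld) %*% raw)   # marginal = R %*% joint
    }
    b_exp <- scale_to_h2(raw, vars$eaf, cfg$exposure_h2)

    n_dir <- round(cfg$pleiotropy_frac * cfg$n_snp)
    dir_idx <- if (n_dir > 0) sample.int(cfg$n_snp, n_dir) else integer(0)
    alpha <- numeric(cfg$n_snp)
    alpha[dir_idx] <- stats::rnorm(n_dir, cfg$pleiotropy_mean,
                                   cfg$pleiotropy_sd)

    n_cor <- round(cfg$correlated_frac * cfg$n_snp)
    cor_idx <- if (n_cor > 0) sample.int(cfg$n_snp, n_cor) else integer(0)
    gamma <- numeric(cfg$n_snp)
    gamma[cor_idx] <- stats::rnorm(n_cor, 0, cfg$pleiotropy_sd)
    b_exp <- b_exp + gamma                       # confounder hits exposure
    b_out <- cfg$theta * b_exp + alpha +
      cfg$confounder_ratio * gamma               # ... and outcome directly

    exposure <- observe_trait(vars, b_exp, cfg$n_exposure, "exposure")
    outcome <- observe_trait(vars, b_out, cfg$n_outcome, "outcome",
                             binary = TRUE)
    list(exposure = exposure, outcome = outcome,
         truth = list(config = cfg, maf = vars$eaf,
                      beta_exposure = b_exp, beta_outcome = b_out,
                      pleiotropy_idx = dir_idx, pleiotropy = alpha,
                      confounder_idx = cor_idx, confounder = gamma,
                      theta = cfg$theta, ld = ld))
  })
}

#' Simulate an exposure-mediator-outcome chain
#'
#' The variant panel is doubled: the first `n_snp` variants instrument the
#' exposure (and reach the mediator and outcome only through it), the
#' second `n_snp` instrument the mediator directly.  The true total effect
#' of exposure on outcome is beta_x_direct + beta_x_to_m * beta_m_to_y and
#' the true proportion mediated follows.
#'
#' @param cfg a [sim_config()] with `mediator_chain` set.
#' @return List with `exposure`, `mediator`, `outcome`
#'   (`summary_stat_set`s over the shared panel) and `truth` including
#'   `total`, `direct`, `indirect` and `proportion`.
#' @export
simulate_mediation <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  chain <- cfg$mediator_chain
  if (is.null(chain)) stop("cfg$mediator_chain must be set")
  with_seed(cfg$seed, {
    n <- cfg$n_snp
    vars <- sim_variants(2 * n, cfg$maf_range)
    bx <- c(scale_to_h2(stats::rnorm(n), vars$eaf[1:n], cfg$exposure_h2),
            numeric(n))
    gm <- c(numeric(n),
            scale_to_h2(stats::rnorm(n), vars$eaf[(n + 1):(2 * n)],
                        cfg$exposure_h2))
    b_m <- chain$beta_x_to_m * bx + gm
    b_y <- chain$beta_x_direct * bx + chain$beta_m_to_y * b_m
    exposure <- observe_trait(vars, bx, cfg$n_exposure, "exposure")
    mediator <- observe_trait(vars, b_m, cfg$n_mediator, "mediator")
    outcome <- observe_trait(vars, b_y, cfg$n_outcome, "outcome",
                             binary = TRUE)
    indirect <- chain$beta_x_to_m * chain$beta_m_to_y
    total <- chain$beta_x_direct + indirect
    list(exposure = exposure, mediator = mediator, outcome = outcome,
         truth = list(config = cfg, beta_exposure = bx,
                      beta_mediator_own = gm, beta_mediator = b_m,
                      beta_outcome = b_y, total = total,
                      direct = chain$beta_x_direct, indirect = indirect,
                      proportion = indirect / total))
  })
}

#' Simulate a region pair for colocalization
#'
#' Variants sit 1 kb apart with exchangeable LD correlation `ld_block_r`.
#' Scenario `"H4"` plants one shared causal variant with expected |z| =
#' `z_causal` in both traits (LD-propagated); `"H3"` plants distinct
#' causal variants; `"H0"` is pure noise.
#'
#' @param n_variants number of variants (>= 2).
#' @param ld_block_r pairwise correlation among variants (0 = LD-free).
#' @param scenario one of "H0", "H3", "H4".
#' @param z_causal expected causal z-score magnitude (default 8).
#' @param seed RNG seed.
#' @param n1,n2 GWAS sample sizes of the two traits.
#' @return List with `region1`, `region2` (`summary_stat_set`s sharing
#'   variant ids) and `truth` (causal indices and the scenario).
#' @export
simulate_coloc_region <- function(n_variants, ld_block_r = 0,
                                  scenario = c("H0", "H3", "H4"),
                                  z_causal = 8, seed = 1L,
                                  n1 = 5e4, n2 = 5e4) {
  scenario <- match.arg(scenario)
  if (n_variants < 2L) stop("need at least 2 variants")
  with_seed(seed, {
    vars <- sim_variants(n_variants, c(0.1, 0.5), prefix = "cv")
    vars$position <- 1e6 + seq_len(n_variants) * 1000
    r <- matrix(ld_block_r, n_variants, n_variants)
    diag(r) <- 1
    cl <- chol(r)
    causal1 <- causal2 <- NA_integer_
    mu1 <- mu2 <- numeric(n_variants)
    if (scenario == "H4") {
      causal1 <- causal2 <- sample.int(n_variants, 1)
      mu1 <- r[, causal1] * z_causal
      mu2 <- r[, causal2] * z_causal
    } else if (scenario == "H3") {
      pick <- sample.int(n_variants, 2)
      causal1 <- pick[1]
      causal2 <- pick[2]
      mu1 <- r[, causal1] * z_causal
      mu2 <- r[, causal2] * z_causal
    }
    z1 <- mu1 + drop(crossprod(cl, stats::rnorm(n_variants)))
    z2 <- mu2 + drop(crossprod(cl, stats::rnorm(n_variants)))
    mk <- function(z, n, label) {
      d <- vars
      d$se <- 1 / sqrt(2 * d$eaf * (1 - d$eaf) * n)
      d$beta <- z * d$se
      d$p <- pmax(2 * stats::pnorm(-abs(z)), .Machine$double.xmin)
      d$n <- n
      summary_stat_set(d, trait_label = label)
    }
    list(region1 = mk(z1, n1, "trait1"), region2 = mk(z2, n2, "trait2"),
         truth = list(scenario = scenario, causal1 = causal1,
                      causal2 = causal2, ld_r = ld_block_r, seed = seed))
  })
}
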