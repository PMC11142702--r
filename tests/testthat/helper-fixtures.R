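# In-code fixtures shared across the suite.

# A data.frame of association records with sensible defaults.
toy_snps <- function(n = 3, variant_id = paste0("rs", seq_len(n)),
                     chromosome = "1", position = seq_len(n) * 1e5,
                     effect_allele = rep_len(c("A", "T", "G"), n),
                     other_allele = rep_len(c("G", "C", "A"), n),
                     eaf = rep_len(0.3, n), beta = rep_len(0.1, n),
                     se = rep_len(0.01, n), p = rep_len(1e-10, n),
                     n_sample = rep_len(1e5, n)) {
  data.frame(variant_id = variant_id, chromosome = chromosome,
             position = position, effect_allele = effect_allele,
             other_allele = other_allele, eaf = eaf, beta = beta, se = se,
             p = p, n = n_sample, stringsAsFactors = FALSE)
}

toy_set <- function(..., trait = "trait", ancestry = "EUR",
                    binary = FALSE) {
  summary_stat_set(toy_snps(...), trait_label = trait,
                   ancestry_label = ancestry, binary_trait = binary)
}

# A minimal harmonized instrument table straight from effect vectors.
toy_instruments <- function(bx, by, sy, sx = rep_len(0.01, length(bx)),
                            n_exp = 1e5, n_out = 1e5, eaf = 0.3) {
  j <- length(bx)
  d <- data.frame(
    variant_id = paste0("rs", seq_len(j)), chromosome = "1",
    position = seq_len(j) * 1e5,
    effect_allele = "A", other_allele = "G",
    exposure_beta = bx, exposure_se = sx, exposure_eaf = eaf,
    exposure_p = 2 * pnorm(-abs(bx / sx)), exposure_n = n_exp,
    outcome_beta = by, outcome_se = sy, outcome_eaf = eaf,
    outcome_p = 2 * pnorm(-abs(by / sy)), outcome_n = n_out,
    proxy_of = NA_character_, stringsAsFactors = FALSE
  )
  d$r2_exposure <- 2 * eaf * (1 - eaf) * bx^2
  d$f_stat <- ((n_exp - 2) / 1) * (d$r2_exposure / (1 - d$r2_exposure))
  d
}

# Symmetric LD matrix from variant ids and a function/constant of r.
toy_ld <- function(ids, r = 0) {
  n <- length(ids)
  m <- matrix(r, n, n)
  diag(m) <- 1
  dimnames(m) <- list(ids, ids)
  as_ld_matrix(m)
}

# The three published EUR TG->EMS study results (OR with 95% CI), used as
# the worked meta-analysis fixture throughout.
tg_ems_studies <- function() {
  data.frame(
    study = c("discovery", "replication_a", "replication_b"),
    or_ = c(1.112, 1.135, 1.149),
    ci_low = c(1.033, 1.016, 1.064),
    ci_high = c(1.198, 1.267, 1.240)
  )
}
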