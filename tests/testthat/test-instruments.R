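test_that("snp_r2 folds eaf to the minor allele and squares beta", {
  expect_equal(snp_r2(0.5, 0), 0)
  expect_equal(snp_r2(0.5, 0.1), 0.005)
  expect_equal(snp_r2(0.9, 0.2), 0.0072)  # MAF = 0.1
  expect_equal(snp_r2(0.1, 0.2), snp_r2(0.9, 0.2))
  expect_error(snp_r2(1.2, 0.1), "eaf")
  expect_error(snp_r2(0, 0.1), "eaf")
})

test_that("f_statistic matches the closed form and flags weak instruments", {
  expect_equal(f_statistic(0, 1000), 0)
  expect_equal(f_statistic(0.01, 1002, 1), 1000 * 0.01 / 0.99)
  expect_gt(f_statistic(0.01, 1002, 1), 10)   # retained at n = 1002
  expect_equal(f_statistic(0.01, 500, 1), 498 * 0.01 / 0.99)
  expect_lt(f_statistic(0.01, 500, 1), 10)    # weak at n = 500
  expect_error(f_statistic(1, 100), "r2")
  expect_error(f_statistic(0.1, 2, 1), "n")
})

test_that("f_statistic is strictly increasing in r2 and in n", {
  r2 <- seq(0.001, 0.5, length.out = 20)
  expect_true(all(diff(f_statistic(r2, 1000)) > 0))
  n <- seq(100, 10000, length.out = 20)
  expect_true(all(diff(f_statistic(0.01, n)) > 0))
})

test_that("greedy clumping keeps independent hits and prunes LD partners", {
  # three mutually independent genome-wide hits survive intact
  set <- toy_set(n = 3, position = c(1e6, 2e8, 5e8), p = rep(1e-9, 3))
  ld <- toy_ld(set$snps$variant_id, r = 0)
  expect_setequal(select_instruments(set, ld), c("rs1", "rs2", "rs3"))

  # two SNPs 5 kb apart at r^2 = 0.5: only the smaller p survives
  set <- toy_set(n = 2, position = c(1e6, 1e6 + 5e3), p = c(1e-9, 1e-8))
  ld <- toy_ld(set$snps$variant_id, r = sqrt(0.5))
  expect_equal(select_instruments(set, ld), "rs1")

  # nothing significant is an empty result, not an error
  set <- toy_set(n = 2, p = c(1e-4, 1e-3))
  expect_length(select_instruments(set, NULL), 0)
})

test_that("a tight LD block collapses to its smallest-p member", {
  set.seed(7)
  p <- sort(runif(10, 1e-12, 1e-8))[order(sample(10))]
  set <- toy_set(n = 10, position = 1e6 + seq_len(10) * 1000, p = p)
  ld <- toy_ld(set$snps$variant_id, r = sqrt(0.9))
  kept <- select_instruments(set, ld)
  # brute force: with pairwise r^2 = 0.9 >= 0.001 everywhere, every valid
  # subset within the window is a singleton; the best is argmin p
  expect_equal(kept, set$snps$variant_id[which.min(p)])
})

test_that("clumped output is pairwise valid under the config", {
  set.seed(11)
  n <- 40
  pos <- sort(sample(1e6:5e7, n))
  set <- toy_set(n = n, position = pos, p = 10^runif(n, -12, -8))
  m <- matrix(0, n, n)
  block <- (pos %/% 1e7) + 1
  for (b in unique(block)) {
    idx <- which(block == b)
    m[idx, idx] <- 0.6
  }
  diag(m) <- 1
  dimnames(m) <- list(set$snps$variant_id, set$snps$variant_id)
  ld <- as_ld_matrix(m)
  cfg <- clump_config()
  kept <- select_instruments(set, ld, cfg)
  kp <- set$snps[match(kept, set$snps$variant_id), ]
  for (i in seq_along(kept)) {
    for (k in seq_along(kept)) {
      if (i == k) next
      near <- abs(kp$position[i] - kp$position[k]) <= cfg$window_kb * 1000
      r2 <- ld[kept[i], kept[k]]^2
      expect_false(near && r2 >= cfg$r2_threshold)
    }
  }
})

test_that("candidates missing from the LD matrix clump as independent", {
  set <- toy_set(n = 3, position = c(1e6, 1.1e6, 1.2e6), p = rep(1e-9, 3))
  ld <- toy_ld(c("rs1", "rs2"), r = sqrt(0.9))
  expect_warning(kept <- select_instruments(set, ld), "independent")
  expect_true("rs3" %in% kept)
})

test_that("Steiger filtering partitions by directionality, ties retained", {
  # strong exposure association, weak outcome: kept
  rec <- toy_instruments(bx = c(0.1, 0.001, 0.05),
                         by = c(0.001, 0.1, 0.05 * 1),
                         sy = rep(0.01, 3))
  out <- steiger_filter(rec)
  expect_equal(out$kept$variant_id, c("rs1", "rs3"))   # rs3 is an exact tie
  expect_equal(out$dropped$variant_id, "rs2")
  expect_equal(nrow(out$kept) + nrow(out$dropped), nrow(rec))
  expect_length(intersect(out$kept$variant_id, out$dropped$variant_id), 0)
  expect_true(all(c("r2_exposure", "r2_outcome", "steiger_p") %in%
                    names(out$kept)))
})

test_that("Steiger drops unassessable records with a warning", {
  rec <- toy_instruments(bx = c(0.1, 0.1), by = c(0.01, 0.01),
                         sy = c(0.01, 0.01))
  rec$outcome_n[2] <- NA
  expect_warning(out <- steiger_filter(rec), "sample sizes")
  expect_equal(out$kept$variant_id, "rs1")
})

test_that("proxy search returns the argmax r2 above threshold only", {
  outcome <- toy_set(n = 3, variant_id = c("rsP1", "rsP2", "rsX"))
  ids <- c("rsT", "rsP1", "rsP2", "rsX")
  m <- diag(4)
  m[1, 2] <- m[2, 1] <- sqrt(0.95)
  m[1, 3] <- m[3, 1] <- sqrt(0.85)
  m[1, 4] <- m[4, 1] <- sqrt(0.5)
  dimnames(m) <- list(ids, ids)
  ld <- as_ld_matrix(m)
  expect_equal(find_proxy("rsT", outcome, ld), "rsP1")
  expect_equal(find_proxy("rsT", outcome, ld, r2_min = 0.96), NA_character_)
  expect_error(find_proxy("rsP1", outcome, ld), "no proxy needed")
  expect_warning(res <- find_proxy("rsZ", outcome, ld), "not in LD")
  expect_equal(res, NA_character_)
})

test_that("harmonization aligns swapped alleles by negating the outcome", {
  exposure <- toy_set(n = 1, effect_allele = "A", other_allele = "G",
                      beta = 0.1, eaf = 0.3)
  oy <- toy_snps(n = 1, effect_allele = "G", other_allele = "A",
                 beta = -0.05, eaf = 0.7)
  outcome <- summary_stat_set(oy)
  rec <- harmonize(exposure, outcome)
  expect_equal(rec$outcome_beta, 0.05)
  expect_equal(rec$outcome_eaf, 0.3)

  # identical coding is untouched
  outcome2 <- summary_stat_set(toy_snps(n = 1, effect_allele = "A",
                                        other_allele = "G", beta = -0.05,
                                        eaf = 0.3))
  rec2 <- harmonize(exposure, outcome2)
  expect_equal(rec2$outcome_beta, -0.05)
  expect_equal(rec2$outcome_eaf, 0.3)
})

test_that("palindromic variants resolve by frequency or drop", {
  exposure <- summary_stat_set(toy_snps(n = 2, effect_allele = "A",
                                        other_allele = "T",
                                        eaf = c(0.49, 0.2)))
  outcome <- summary_stat_set(toy_snps(n = 2, effect_allele = "A",
                                       other_allele = "T", beta = 0.05,
                                       eaf = c(0.49, 0.2)))
  rec <- harmonize(exposure, outcome)
  expect_equal(rec$variant_id, "rs2")    # rs1 ambiguous at eaf 0.49
  expect_equal(attr(rec, "drops")$reason, "palindromic_ambiguous")
  expect_equal(rec$outcome_beta, 0.05)

  # opposite-strand report: frequencies disagree, so the effect flips
  outcome_flip <- summary_stat_set(toy_snps(n = 2, effect_allele = "A",
                                            other_allele = "T",
                                            beta = 0.05,
                                            eaf = c(0.49, 0.8)))
  rec2 <- harmonize(exposure, outcome_flip, snps = "rs2")
  expect_equal(rec2$outcome_beta, -0.05)
  expect_equal(rec2$outcome_eaf, 0.2)
})

test_that("allele flipping is an involution", {
  exposure <- toy_set(n = 5, beta = rnorm(5, 0, 0.1), eaf = 0.3)
  oy <- toy_snps(n = 5, beta = rnorm(5, 0, 0.05), eaf = 0.3)
  outcome <- summary_stat_set(oy)
  direct <- harmonize(exposure, outcome)
  # swap the outcome coding, then harmonize: same result as direct
  oy2 <- oy
  oy2$effect_allele <- oy$other_allele
  oy2$other_allele <- oy$effect_allele
  oy2$beta <- -oy$beta
  oy2$eaf <- 1 - oy$eaf
  swapped <- harmonize(exposure, summary_stat_set(oy2))
  expect_equal(swapped$outcome_beta, direct$outcome_beta)
  expect_equal(swapped$outcome_eaf, direct$outcome_eaf)
})

test_that("harmonize uses proxies only when asked, signed by LD r", {
  exposure <- toy_set(n = 2, beta = c(0.1, 0.2), eaf = 0.3)
  oy <- toy_snps(n = 2, variant_id = c("rs1", "rsProxy"),
                 beta = c(0.05, 0.04), eaf = 0.3)
  outcome <- summary_stat_set(oy)
  ids <- c("rs1", "rs2", "rsProxy")
  m <- diag(3)
  m[2, 3] <- m[3, 2] <- -sqrt(0.9)
  dimnames(m) <- list(ids, ids)
  ld <- as_ld_matrix(m)

  no_proxy <- harmonize(exposure, outcome, ld = ld)
  expect_equal(no_proxy$variant_id, "rs1")
  expect_equal(attr(no_proxy, "drops")$reason, "absent_from_outcome")

  with_proxy <- harmonize(exposure, outcome, ld = ld, use_proxies = TRUE)
  expect_equal(nrow(with_proxy), 2)
  expect_equal(with_proxy$proxy_of[2], "rs2")
  expect_equal(with_proxy$outcome_beta[2], -0.04)  # negative LD r flips
})

test_that("weak instruments are excluded by the F filter", {
  rec <- toy_instruments(bx = c(0.2, 0.001), by = c(0.05, 0.01),
                         sy = c(0.01, 0.01))
  out <- f_filter(rec)
  expect_equal(out$kept$variant_id, "rs1")
  expect_equal(out$dropped$variant_id, "rs2")
})
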