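---
title: "Methods: two-sample Mendelian randomization in mrpipe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-sample Mendelian randomization in mrpipe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrpipe)
```

# The model

Two-sample MR treats genetic variants as instrumental variables. For
variant $j$ we observe the estimated per-allele effect on the exposure,
$\hat\beta_{Xj}$ with standard error $\sigma_{Xj}$, from one GWAS, and on
the outcome, $\hat\beta_{Yj}$ with $\sigma_{Yj}$, from another. If variant
$j$ is a valid instrument — associated with the exposure (relevance), not
associated with confounders (exchangeability), and affecting the outcome
only through the exposure (exclusion) — then under a linear structural
model $\beta_{Yj} = \theta\,\beta_{Xj}$, and each Wald ratio
$\rho_j = \hat\beta_{Yj}/\hat\beta_{Xj}$ estimates the causal effect
$\theta$. For a binary outcome all effects live on the log-odds scale and
$e^\theta$ is the causal odds ratio per unit of exposure.

Everything in the package is a way of (a) choosing variants for which the
three assumptions are defensible, (b) combining their ratios efficiently,
or (c) detecting and absorbing violations of exclusion (horizontal
pleiotropy).

# Instrument selection and quality control

The default screening chain, in order: genome-wide significance
($p < 5\times10^{-8}$) → greedy LD clumping → allele harmonization (with
optional proxy substitution) → Steiger directionality filter → weak
instrument exclusion ($F \ge 10$). The order is recorded in the run
manifest; significance and clumping must precede harmonization (they
define the candidate set), while applying Steiger and the F filter after
harmonization lets them see the final aligned records. Nothing in the
underlying theory fixes the relative order of the last two filters; both
are deterministic record-wise, so their order does not change the result.

**Clumping** (`select_instruments`) is the standard greedy procedure:
candidates sorted by ascending p-value; the best is kept and all
candidates on the same chromosome within the window (default 10,000 kb)
with $r^2$ at or above the threshold (default 0.001) are removed. Ties at
equal p are broken by chromosome then position, so the output is
deterministic. Candidates absent from the supplied LD matrix are treated
as independent with a warning — the package never computes LD itself, it
consumes a panel-derived matrix (`read_ld_matrix`).

**Instrument strength.** Per-SNP variance explained is
$R^2 = 2\,\mathrm{MAF}(1-\mathrm{MAF})\beta^2$ when the allele frequency
is available, and the z-score form $R^2 = F/(F+n-2)$ with
$F = (\beta/\sigma)^2$ otherwise. The F-statistic
$F = \frac{n-k-1}{k}\,\frac{R^2}{1-R^2}$ with $k=1$ is computed per SNP
and instruments with $F < 10$ are dropped — the conventional
weak-instrument rule of thumb.

**Steiger filtering** (`steiger_filter`) drops a variant when its
estimated correlation with the outcome exceeds that with the exposure,
since such a variant more plausibly acts on the outcome first. The
default per-trait $R^2$ recipe is the z-based form: it is symmetric
between traits and works when outcome files lack allele frequencies
(common in practice); the frequency-based form is available by argument.
The filter is a deterministic rule, as usually applied; a Steiger z-test
p-value (Fisher-z comparison of the two correlations) is attached for
reporting but does not drive the decision. Exact ties are retained —
there is no evidence of reversed direction.

**Harmonization** (`harmonize`) aligns each outcome record to the
exposure's effect allele: swapped codings negate the outcome beta and
reflect its frequency; strand flips resolve through allele complements.
Palindromic variants (A/T, C/G) carry no strand information in their
letters, so they are resolved by allele frequency when both sides have
one and both lie outside the ambiguity zone $|\mathrm{eaf}-0.5| \le
0.08$ — a common community default wide enough to absorb
frequency-estimation noise — and dropped otherwise. Proxy substitution
(off by default, matching a fully offline run) replaces a variant missing
from the outcome set by its best LD partner at $r^2 > 0.8$, the proxy's
effect signed by the LD correlation. Indels and multi-allelic records are
rejected at parse time; all the analyses here are SNP-based.

# Estimators

**IVW (multiplicative random effects)** is the workhorse: the weighted
mean of Wald ratios with weights $w_j = \hat\beta_{Xj}^2/\sigma_{Yj}^2$,
identically the weighted regression of outcome betas on exposure betas
through the origin with weights $1/\sigma_{Yj}^2$ (the regression form is
used; ratio- and regression-form point estimates coincide). Heterogeneity
among ratios (Cochran's $Q$) inflates the fixed-effect standard error by
$\max\!\left(1, \sqrt{Q/(J-1)}\right)$ — multiplicative random effects
with a floor at the fixed-effect precision, so homogeneous data are never
rewarded with an artificially small error.

**MR-Egger** adds an intercept to the weighted regression. Exposure betas
are first oriented non-negative (outcome betas co-flipped) so the
intercept estimates the average directional pleiotropic effect; the slope
is the causal estimate, with the same multiplicative overdispersion floor
at $J-2$ degrees of freedom. A design in which all exposure betas are
equal is collinear with the intercept and is refused.

**Weighted median**: ratios are ordered, weights normalized, and the
estimate is the linear interpolation of the weighted empirical CDF at
0.5 (cumulative weight $s_j = \sum_{i\le j} w_i - w_j/2$). It is
consistent when instruments carrying at least half the weight are valid.
The standard error comes from a parametric bootstrap (default 1000
draws, seeded) redrawing both exposure and outcome betas from their
sampling distributions.

**cML** (constrained maximum likelihood): for each candidate count $K$ of
invalid instruments, the bivariate-normal likelihood of the observed
betas is maximized with exactly $K$ variants allowed free direct effects.
The fit alternates between the causal effect, the latent true exposure
effects, and the invalid set (the $K$ largest standardized residuals),
to a tolerance of $10^{-8}$ within 200 iterations, from the IVW start
plus a few seeded random restarts. $K$ is selected by BIC with effective
sample size $\min(n_X, n_Y)$; the standard error comes from the curvature
(central-difference Hessian) of the profile likelihood at the optimum.
Model selection rather than model averaging is the default — it yields a
discrete, reportable invalid set.

`run_uvmr` dispatches on the instrument count: one instrument gives the
Wald ratio only; two give per-SNP Wald ratios plus IVW; three or more run
all estimators.

# Sensitivity analysis

**Cochran's Q / I²** quantify ratio heterogeneity;
$I^2 = \max(0, (Q - \mathrm{df})/Q)$.

**MR-PRESSO**: the observed statistic is the weighted residual sum of
squares of each variant against the leave-one-out IVW fit. Its null
distribution is simulated (default 1000 draws) by redrawing exposure and
outcome betas from their sampling distributions under the fitted
leave-one-out model. Per-SNP outlier p-values compare each observed
residual with its own simulated distribution and are Bonferroni-adjusted
across the $J$ instruments; flagged outliers are removed and the global
test repeated while it remains below 0.05. One numerical constraint
matters in practice: the smallest attainable per-SNP p-value is
$1/(n_\mathrm{sim}+1)$, so the Bonferroni-adjusted call can only fall
below $\alpha$ when $n_\mathrm{sim} > J/\alpha$ — with 50 instruments at
$\alpha = 0.05$, at least 1000 (the package's tests use 2000) simulations
are needed for the outlier search to have any resolution. The distortion
test (corrected-versus-uncorrected shift against random same-size
removals) is reported but never alters estimates automatically. With the
seed fixed the whole procedure is bit-reproducible.

**Leave-one-out** refits IVW omitting each variant in turn, exported as a
plot-ready influence table, alongside funnel-plot data (ratio versus
precision).

When the global test keeps rejecting after outlier removal, the package
surfaces the warning and the corrected-IVW path; genome-wide Bayesian
mixture modelling of correlated pleiotropy is outside its scope and users
are pointed to dedicated tools.

# Multivariable MR and mediation

`mvmr_ivw` regresses outcome betas on the matrix of exposure betas
(no intercept, weights $1/\sigma_{Yj}^2$), giving each exposure's direct
effect conditional on the others, with the same overdispersion floor at
$J - E$ degrees of freedom. Rank-deficient designs are refused with the
collinear exposure named.

Two-step mediation decomposes the total effect of exposure on outcome
(univariable IVW) into the direct effect (MVMR adjusting for the
mediator) and the indirect effect. The difference method sets
$\mathrm{indirect} = \mathrm{total} - \mathrm{direct}$ with
$\mathrm{se} = \sqrt{\mathrm{se}^2_\mathrm{total} +
\mathrm{se}^2_\mathrm{direct}}$; treating the two estimates as
independent is a documented approximation — with summary data their
covariance is not identified, and the shared instruments make the true
covariance positive, so the reported se errs on the wide side for the
difference. The product method multiplies the exposure→mediator effect by
the conditional mediator→outcome effect, with a first-order delta-method
se. The proportion mediated is indirect/total with a delta-method CI; it
may legitimately fall outside $[0,1]$ (inconsistent mediation), and is
reported as missing when the total effect is zero. Whether a covariate is
"a mediator" or "a confounder" is a structural claim the data alone
cannot settle; `mediator_label` applies the usual reporting rule
(indirect-effect $p < 0.05$) and leaves the substantive call to the
analyst.

# Drug-target MR

Cis instruments for a gene target are the genome-wide-significant
variants in the closed window [start − flank, end + flank] (default
flank 100 kb), greedily pruned by ascending p-value to pairwise
$r^2 < 0.30$. That permissive threshold trades residual correlation for
instrument strength in a short region; since plain IVW assumes
independent instruments, a generalized IVW weighting by the full
LD-derived covariance of the outcome betas
($\Sigma_{ij} = r_{ij}\sigma_{Yi}\sigma_{Yj}$) is available behind a
flag, and the run report records which was used. Positive equicorrelation
reduces effective information, so the LD-aware standard error is the
larger, honest one. Estimates are always expressed per unit *increase* of
the exposure; interpreting a target pharmacologically as exposure
*lowering* flips the sign of the reported log-OR, not the analysis. Gene
coordinates are user-supplied input (1-based inclusive, BED-like TSV) —
the package hard-codes no annotation. The FDR family for a drug-target
run is the set of targets tested in that run.

# Colocalization

For a region pair sharing variant ids, per-variant Wakefield log
approximate Bayes factors
$\mathrm{lABF} = \tfrac12\left[\log\frac{V}{V+W} +
z^2\frac{W}{V+W}\right]$ (with $V$ the squared se, $W$ the prior effect
variance, $z$ the association z-score) are combined by single-causal-
variant enumeration into posteriors over the five hypotheses: no
association (H0), trait-specific association (H1, H2), distinct causal
variants (H3), one shared causal variant (H4). Priors default to
$(p_1, p_2, p_{12}) = (10^{-4}, 10^{-4}, 10^{-5})$ and the prior effect
sd to 0.15 for quantitative and 0.2 for binary traits — the cited
package-ecosystem defaults, used in the absence of study-specific
information. All sums run in log space (log-sum-exp; H3 through a guarded
log-difference), so hundreds of variants with $|z| \approx 8$ do not
overflow. The region is defined around the smallest-p variant (ties to
the lower position) with a closed ±100 kb window. Only the intersection
of variant ids enters, and the restriction is logged. A posterior
$\mathrm{PP.H4} > 0.8$ is the conventional evidence threshold for a
shared causal variant.

# Meta-analysis, FDR, and power

Published odds ratios re-enter analysis as $\beta = \ln \mathrm{OR}$,
$\mathrm{se} = (\ln \mathrm{CI}_u - \ln \mathrm{CI}_l)/(2 \times
1.959964)$. Meta-analysis pools on the log scale: fixed-effect
inverse-variance when $I^2 < 0.5$ (strict comparison), otherwise
DerSimonian–Laird random effects. BH-FDR takes an explicit family size:
when a table lists only some members of a declared testing family, the
step-up multiplier uses the full family size with ranks among the listed
values — a documented approximation equivalent to assuming the unlisted
members rank below none of the listed ones. Binary-outcome power uses the
standard analytic approximation
$\Phi\!\left(\sqrt{n R^2 K(1-K)}\,|\ln \mathrm{OR}| - z_{1-\alpha/2}\right)$
with $K$ the outcome case fraction.

# The synthetic generator

`simulate_two_sample` emulates the statistical structure two-sample MR
assumes, and its controlled violations. MAFs are uniform on a range
(default 0.05–0.5); true per-SNP exposure effects are Gaussian, scaled so
the instruments jointly explain `exposure_h2` (default 0.1) of the
exposure; sampling standard errors follow the analytic
$1/\sqrt{2\,\mathrm{MAF}(1-\mathrm{MAF})\,n}$ form exactly; outcome
effects are $\theta$ times the true exposure effect plus optional direct
pleiotropy (a designated fraction of SNPs, Gaussian effects whose nonzero
mean makes the pleiotropy directional) and correlated pleiotropy (a
confounder loading entering both traits). Default sample sizes
($3\times10^5$ exposure, $2\times10^5$ outcome) are desk-scale stand-ins
for consortium GWAS: large enough that instruments are strong
($F \gg 10$) and weak-instrument bias is negligible, small enough that
replicated calibration suites run in seconds. Binary-outcome effects are
generated directly on the log-OR scale with Gaussian noise — adequate for
summary-statistic methods, with no individual-level simulation.
`simulate_mediation` doubles the panel (exposure instruments plus the
mediator's own instruments) so multivariable designs are full rank by
construction, and records the true total, direct, indirect, and
proportion mediated. `simulate_coloc_region` plants a shared causal
variant (H4), distinct variants (H3), or pure noise (H0) with
exchangeable LD.

What the generator does **not** emulate: realistic genome-wide LD maps
(LD is block-exchangeable at most), allele-frequency spectra, sample
overlap between the two GWAS, population stratification, or
winner's-curse selection of instruments. Passing calibration suites
therefore demonstrates the estimators' correctness under their stated
assumptions, not robustness to every failure mode of real consortium
data.

# Numerical and design choices

- All confidence intervals use the normal multiplier 1.959964; p-values
  are two-sided normal (chi-square for Q).
- p-values of exactly 0 in input files are clamped to the smallest
  positive double with a warning — consortium files commonly underflow,
  and rejecting such rows would silently discard the strongest signals.
- Positions are 1-based; gene and coloc windows are closed intervals.
- LD matrices are validated (symmetry within $10^{-8}$, unit diagonal,
  entries in $[-1,1]$) and then exactly symmetrized.
- Overdispersion scaling never shrinks below 1 in any weighted fit.
- The bootstrap, PRESSO, cML restarts, and every generator take explicit
  seeds and restore the caller's RNG state; with seeds fixed, outputs are
  bit-reproducible, and pipeline reruns produce byte-identical files.
- Replicated test suites use 200 replicates (100 for the outlier-
  detection design) with 100 SNPs for calibration and 50 for detection
  and mediation chains — sizes at which binomial noise on a coverage or
  size estimate is a few percent.
- In the planted-outlier design the pleiotropic effect is planted on the
  highest-weight instrument, at twice that instrument's exposure beta:
  an outlier on a near-null instrument carries essentially no IVW weight,
  so only a weight-bearing outlier both distorts the estimate and lets
  its removal demonstrably restore it.

# Limitations

- Sample overlap between exposure and outcome GWAS is not modelled.
- The difference-method mediation se assumes independent total and direct
  estimates (see above).
- The FDR family-size device approximates ranks when the family is larger
  than the listed p-values.
- Colocalization assumes a single causal variant per trait per region; no
  fine-mapping-aware extension is provided.
- No genotype-level computation: LD always arrives as a user-supplied
  matrix, and proxies are only as good as that matrix.
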