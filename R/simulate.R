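#' Ground-truth parameters for the three-cohort simulator
#'
#' Bundles and validates the generative parameters of
#' [simulate_cohorts()]: a structural model in which a set of independent
#' variants affects a quantitative exposure X, the exposure affects a
#' mediator M, and both affect a quantitative outcome Y, with optional
#' horizontally pleiotropic instrument effects on Y and a shared
#' confounder U loading on all three traits. A disjoint set of variants
#' carries direct effects on the mediator, mirroring the fact that in a
#' two-step design the mediator has its own genome-wide association study
#' and its own instruments; without them the mediator-to-outcome leg has no
#' valid instruments (the exposure's variants reach Y through the direct
#' exposure path and so violate the exclusion restriction for M).
#'
#' Derived truths are attached: `true_total = tau_direct + alpha * theta`
#' and `true_proportion = alpha * theta / true_total` (when the total is
#' nonzero).
#'
#' @param n_snps Total simulated variants.
#' @param n_instruments Variants with nonzero effect on the exposure.
#' @param n_mediator_instruments Variants with direct effects on the
#'   mediator (disjoint from the exposure instruments).
#' @param maf_range Minor-allele-frequency range, a sub-interval of (0, 0.5).
#' @param gamma_scale,delta_scale Typical per-allele effect magnitude of the
#'   exposure / mediator instruments on a variance-1 trait; individual
#'   effects are drawn uniformly in ±\[0.4, 1.8\] times the scale, echoing
#'   the wide spread of effect sizes among real genome-wide hits.
#' @param alpha Exposure-to-mediator structural effect.
#' @param theta Mediator-to-outcome structural effect.
#' @param tau_direct Direct exposure-to-outcome effect.
#' @param pleio_fraction Fraction of exposure instruments with direct
#'   outcome effects (horizontal pleiotropy).
#' @param pleio_mean,pleio_sd Normal distribution of those direct effects;
#'   directional when the mean is nonzero, balanced when zero.
#' @param confounder_loading Loading of the shared standard-normal
#'   confounder on all three traits.
#' @param n_exp,n_med,n_out Cohort sizes; the three cohorts are
#'   non-overlapping by construction (each is drawn independently and
#'   observes only its own trait), matching the two-sample assumption.
#' @param seed Integer seed; the emitted tables are bit-identical across
#'   runs with the same seed.
#' @return A validated list of class `mr_truth`.
#' @export
truth_params <- function(n_snps = 100, n_instruments = 30,
                         n_mediator_instruments = 30,
                         maf_range = c(0.1, 0.4),
                         gamma_scale = 0.12, delta_scale = 0.12,
                         alpha = 0.25, theta = 0.20, tau_direct = 0.15,
                         pleio_fraction = 0, pleio_mean = 0, pleio_sd = 0.05,
                         confounder_loading = 0,
                         n_exp = 20000, n_med = 20000, n_out = 20000,
                         seed = 1) {
  if (!(n_instruments >= 1 && n_instruments + n_mediator_instruments <= n_snps)) {
    abort("need n_instruments >= 1 and n_instruments + n_mediator_instruments <= n_snps")
  }
  if (!(length(maf_range) == 2 && maf_range[1] > 0 && maf_range[2] < 0.5 &&
        maf_range[1] < maf_range[2])) {
    abort("maf_range must be an increasing interval inside (0, 0.5)")
  }
  if (!(pleio_fraction >= 0 && pleio_fraction <= 1)) {
    abort("pleio_fraction must lie in [0, 1]")
  }
  if (min(n_exp, n_med, n_out) < 100) abort("cohort sizes must be at least 100")
  true_total <- tau_direct + alpha * theta
  structure(
    list(
      n_snps = n_snps, n_instruments = n_instruments,
      n_mediator_instruments = n_mediator_instruments,
      maf_range = maf_range,
      gamma_scale = gamma_scale, delta_scale = delta_scale,
      alpha = alpha, theta = theta, tau_direct = tau_direct,
      pleio_fraction = pleio_fraction, pleio_mean = pleio_mean,
      pleio_sd = pleio_sd, confounder_loading = confounder_loading,
      n_exp = n_exp, n_med = n_med, n_out = n_out,
      seed = as.integer(seed),
      true_total = true_total,
      true_proportion = if (true_total != 0) alpha * theta / true_total else NA_real_
    ),
    class = "mr_truth"
  )
}

#' Per-variant marginal association
#'
#' Simple-regression slope of a trait on one genotype column, its standard
#' error and two-sided p-value (t reference with n - 2 degrees of freedom):
#' the summary statistic a GWAS reports per variant.
#'
#' @param g Genotype dosage vector (0/1/2 copies of the effect allele).
#' @param y Trait vector of the same length.
#' @return A one-row tibble with `beta`, `se`, `pval`.
#' @export
marginal_stats <- function(g, y) {
  if (length(g) != length(y)) abort("g and y must have equal length")
  n <- length(g)
  if (n < 3) abort("marginal_stats() needs at least 3 observations")
  sxx <- sum((g - mean(g))^2)
  if (sxx == 0) abort("marginal_stats(): genotype column is constant")
  sxy <- sum((g - mean(g)) * (y - mean(y)))
  syy <- sum((y - mean(y))^2)
  beta <- sxy / sxx
  rss <- max(syy - beta * sxy, 0)
  se <- sqrt(rss / (n - 2) / sxx)
  tval <- if (se > 0) beta / se else sign(beta) * Inf
  tibble(beta = beta, se = se, pval = 2 * pt(-abs(tval), df = n - 2))
}

# Matrix version: one trait against every genotype column at once.
.marginal_stats_mat <- function(G, y) {
  n <- nrow(G)
  gc <- sweep(G, 2, colMeans(G))
  yc <- y - mean(y)
  sxx <- colSums(gc^2)
  if (any(sxx == 0)) abort("simulated genotype column is constant; widen maf_range or n")
  sxy <- drop(crossprod(gc, yc))
  syy <- sum(yc^2)
  beta <- sxy / sxx
  rss <- pmax(syy - beta * sxy, 0)
  se <- sqrt(rss / (n - 2) / sxx)
  tval <- beta / se
  list(beta = beta, se = se, pval = 2 * pt(-abs(tval), df = n - 2),
       eaf = colMeans(G) / 2)
}

#' Simulate three non-overlapping GWAS cohorts with known causal structure
#'
#' Draws, for each cohort, genotypes `G_ij ~ Binomial(2, maf_j)` at
#' independent variants, a standard-normal confounder U, and the structural
#' traits
#' \deqn{X = \sum_j \gamma_j G_j + c U + \epsilon_X}
#' \deqn{M = \alpha X + \sum_j \delta_j G_j + c U + \epsilon_M}
#' \deqn{Y = \tau X + \theta M + \sum_j \eta_j G_j + c U + \epsilon_Y}
#' with residual variances set so each trait has variance near 1. The
#' exposure cohort observes only X, the mediator cohort only M, the outcome
#' cohort only Y; each trait is summarized by per-variant marginal
#' regressions ([marginal_stats()]), yielding three summary-statistics
#' tables with estimated effect-allele frequencies and the cohort sample
#' size. Variants are simulated without linkage, so the returned LD object
#' is empty (all pairs independent). Allele pairs are drawn among
#' non-palindromic combinations so harmonization is exercised by swaps, not
#' drops.
#'
#' @param truth A [truth_params()] object.
#' @return A list with `exposure`, `mediator`, `outcome` (each an
#'   `mr_sumstats` tibble), `ld` (an [ld_info()]), and `truth`.
#' @examples
#' sim <- simulate_cohorts(truth_params(n_snps = 20, n_instruments = 5,
#'                                      n_mediator_instruments = 5,
#'                                      n_exp = 500, n_med = 500, n_out = 500))
#' sim$exposure
#' @export
simulate_cohorts <- function(truth) {
  stopifnot(inherits(truth, "mr_truth"))
  p <- truth$n_snps
  withr::local_seed(truth$seed)

  maf <- runif(p, truth$maf_range[1], truth$maf_range[2])
  # Non-palindromic allele pairs only.
  pair_pool <- rbind(
    c("A", "G"), c("A", "C"), c("G", "A"), c("C", "A"),
    c("T", "G"), c("T", "C"), c("G", "T"), c("C", "T")
  )
  pick <- sample.int(nrow(pair_pool), p, replace = TRUE)
  annot <- tibble(
    snp_id = sprintf("rs%05d", seq_len(p)),
    chrom = as.character(((seq_len(p) - 1) %% 22) + 1),
    pos = 1e6 * (((seq_len(p) - 1) %/% 22) + 1) + seq_len(p),
    effect_allele = pair_pool[pick, 1],
    other_allele = pair_pool[pick, 2]
  )

  idx_exp <- seq_len(truth$n_instruments)
  idx_med <- truth$n_instruments + seq_len(truth$n_mediator_instruments)
  gamma <- numeric(p)
  # Effect magnitudes spread over a ~5-fold range, echoing the spread of
  # per-variant effects in real scans (and giving Egger's intercept the
  # instrument-strength variation it needs for identification).
  gamma[idx_exp] <- truth$gamma_scale * runif(truth$n_instruments, 0.4, 1.8) *
    sample(c(-1, 1), truth$n_instruments, replace = TRUE)
  delta <- numeric(p)
  if (truth$n_mediator_instruments > 0) {
    delta[idx_med] <- truth$delta_scale *
      runif(truth$n_mediator_instruments, 0.4, 1.8) *
      sample(c(-1, 1), truth$n_mediator_instruments, replace = TRUE)
  }
  eta <- numeric(p)
  n_pleio <- round(truth$pleio_fraction * truth$n_instruments)
  if (n_pleio > 0) {
    pleio_idx <- sample(idx_exp, n_pleio)
    # Directional pleiotropy is defined relative to the exposure-increasing
    # allele, so a nonzero mean shifts every ratio estimate the same way.
    eta[pleio_idx] <- sign(gamma[pleio_idx]) *
      rnorm(n_pleio, truth$pleio_mean, truth$pleio_sd)
  }

  cc <- truth$confounder_loading
  var_g <- 2 * maf * (1 - maf)
  sd_x <- sqrt(max(0.1, 1 - sum(var_g * gamma^2) - cc^2))
  sd_m <- sqrt(max(0.1, 1 - truth$alpha^2 - sum(var_g * delta^2) - cc^2))
  sd_y <- sqrt(max(0.1, 1 - truth$tau_direct^2 - truth$theta^2 -
                     sum(var_g * eta^2) - cc^2))

  gen_cohort <- function(n, trait) {
    G <- matrix(rbinom(n * p, 2L, rep(maf, each = n)), n, p)
    U <- rnorm(n)
    X <- drop(G %*% gamma) + cc * U + rnorm(n, sd = sd_x)
    y <- if (trait == "X") {
      X
    } else {
      M <- truth$alpha * X + drop(G %*% delta) + cc * U + rnorm(n, sd = sd_m)
      if (trait == "M") {
        M
      } else {
        truth$tau_direct * X + truth$theta * M + drop(G %*% eta) +
          cc * U + rnorm(n, sd = sd_y)
      }
    }
    st <- .marginal_stats_mat(G, y)
    dplyr::bind_cols(annot, tibble(
      eaf = st$eaf, beta = st$beta, se = st$se, pval = st$pval, n = n
    ))
  }

  # Cohorts drawn sequentially from one stream; non-overlap holds because
  # every draw is independent and each cohort sees only its own trait.
  exposure <- as_sumstats(gen_cohort(truth$n_exp, "X"),
                          trait_label = "exposure", quiet = TRUE)
  mediator <- as_sumstats(gen_cohort(truth$n_med, "M"),
                          trait_label = "mediator", quiet = TRUE)
  outcome <- as_sumstats(gen_cohort(truth$n_out, "Y"),
                         trait_label = "outcome", quiet = TRUE)
  list(
    exposure = exposure, mediator = mediator, outcome = outcome,
    ld = ld_info(), truth = truth
  )
}
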