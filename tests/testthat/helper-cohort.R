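# Small-problem generator configs used across tests: 30 regions (435 links)
# and 60 SNPs keep leave-one-out loops fast while preserving the full group
# structure (212 subjects, 139 train / 73 test).

small_planted_links <- function(effect = 0.3) {
  data.frame(edge = c(10, 60, 110, 160, 210, 260, 310, 360),
             direction = rep(c("increased", "decreased"), c(6, 2)),
             effect = effect)
}

small_sim_config <- function(seed = 1, effect = 0.3, ...) {
  sim_config(
    n_regions = 30, n_snps = 60,
    planted_links = small_planted_links(effect),
    planted_snps = data.frame(snp = c(5, 15, 25, 35, 45, 55),
                              role = rep(c("risk", "protective"), each = 3),
                              log_odds = 1.5),
    cannabis_links = data.frame(edge = c(410, 420), effect = 0.15),
    seed = seed, ...)
}

# No group-dependent structure at all: zero planted effects, no drinker
# personality shift or post-onset attenuation, homogeneous sex proportions.
null_sim_config <- function(seed = 1, n_regions = 30, n_snps = 60) {
  sim_config(
    n_regions = n_regions, n_snps = n_snps,
    planted_links = data.frame(edge = 1, direction = "increased", effect = 0),
    planted_snps = data.frame(snp = 1, role = "risk", log_odds = 0),
    cannabis_links = data.frame(edge = 2, effect = 0),
    impulsivity_params = list(mean_14 = 12, subject_sd = 1.7,
                              occasion_sd = 0.6, decline = 1.0,
                              attenuation = 0, drinker_shift = 0),
    sensation_params = list(mean_14 = 13.6, subject_sd = 2.0,
                            occasion_sd = 0.7, decline = 0.15,
                            attenuation = 0, drinker_shift = 0),
    female_prop = c(long_term = 0.5, medium_term = 0.5, short_term = 0.5,
                    control_I = 0.5, control_II = 0.5),
    seed = seed)
}

cohort_covariates <- function(cohort) {
  data.frame(sex = factor(cohort$phenotypes$sex),
             site = factor(cohort$phenotypes$site))
}

# Brute-force Jonckheere-Terpstra statistic for a list of group value vectors
jt_stat_oracle <- function(vals) {
  jt <- 0
  k <- length(vals)
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      for (a in vals[[i]]) {
        jt <- jt + sum(a < vals[[j]]) + 0.5 * sum(a == vals[[j]])
      }
    }
  }
  jt
}

# Exact one-sided JT p-value by enumerating every distinct assignment of the
# pooled values to groups of the given sizes (independent of the package's
# convolution code path).
jt_exact_oracle <- function(values, sizes, jt_obs) {
  n <- length(values)
  stats <- c()
  splits <- function(idx, sizes) {
    if (length(sizes) == 1) return(list(list(idx)))
    out <- list()
    for (p in utils::combn(idx, sizes[1], simplify = FALSE)) {
      for (rest in splits(setdiff(idx, p), sizes[-1])) {
        out[[length(out) + 1]] <- c(list(p), rest)
      }
    }
    out
  }
  for (a in splits(seq_len(n), sizes)) {
    stats <- c(stats, jt_stat_oracle(lapply(a, function(ix) values[ix])))
  }
  mean(stats >= jt_obs - 1e-9)
}
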