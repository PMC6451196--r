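#' Configuration for the synthetic three-wave cohort generator
#'
#' Defines the statistical structure the analysis pipeline assumes: five
#' onset-stratified groups with the study's sample sizes, a 200-region
#' connectivity vector per subject, binary SNP indicators, ESPAD-banded
#' substance use at ages 14/16/19, and SURPS personality trajectories whose
#' impulsivity decline attenuates after binge-drinking onset. Planted
#' connectivity links and SNPs carry effects scaled by a non-increasing
#' onset-group gradient (long >= medium >= short > controls = 0), encoding the
#' working hypothesis that earlier and heavier exposure leaves larger
#' signatures.
#'
#' @param group_sizes named counts for `long_term`, `medium_term`,
#'   `short_term`, `control_I`, `control_II` (defaults 54/52/41/44/21).
#' @param n_regions number of atlas regions (default 200, i.e. 19,900 links).
#' @param n_snps number of binary SNP indicators (default 600).
#' @param n_sites number of acquisition sites (default 8).
#' @param planted_links data.frame(edge, direction, effect): connectivity-unit
#'   shifts added for drinkers (direction `increased`/`decreased`), scaled by
#'   `trend_gradient`. NULL = defaults (16 increased, 8 decreased, effect 0.2).
#' @param planted_snps data.frame(snp, role, log_odds): carrier-probability
#'   log-odds shifts for drinkers (role `risk`/`protective`), gradient-scaled.
#'   NULL = defaults (12 risk, 12 protective, log-odds 1.5).
#' @param cannabis_links data.frame(edge, effect): links shifted in cannabis
#'   users only, disjoint from `planted_links`; supports specificity probes.
#' @param trend_gradient non-increasing multipliers for
#'   long/medium/short-term drinkers (default 1, 0.6, 0.3).
#' @param impulsivity_params,sensation_params lists with `mean_14`,
#'   `subject_sd`, `occasion_sd`, `decline` (per two-year period, scale
#'   units), `attenuation` (fractional post-onset reduction of the decline),
#'   `drinker_shift` (baseline elevation, gradient-scaled).
#' @param noise_sd list: `fc` (per-link SD), `site_fc` (per-site, per-link
#'   offset SD), `site_measure` (site offsets on behavioral measures, as a
#'   fraction of each measure's SD).
#' @param fc_mean baseline Fisher-z-like connectivity mean.
#' @param snp_maf baseline carrier probability per SNP.
#' @param snp_trend if TRUE, planted SNP effects are scaled by
#'   `trend_gradient` like the connectivity effects. Default FALSE: a genetic
#'   predisposition is constant over time, so planted SNP effects apply at
#'   full strength to every drinker group.
#' @param cannabis_user_prob probability of the latent cannabis-user flag
#'   (assigned independently of drinking group).
#' @param onset_threshold banded binge score defining a drinker at a wave.
#' @param female_prop named per-group proportion of female subjects.
#' @param seed integer seed; identical seeds give byte-identical cohorts.
#' @return a validated `bt_sim_config` list.
#' @export
sim_config <- function(group_sizes = c(long_term = 54, medium_term = 52,
                                       short_term = 41, control_I = 44,
                                       control_II = 21),
                       n_regions = 200, n_snps = 600, n_sites = 8,
                       planted_links = NULL, planted_snps = NULL,
                       cannabis_links = NULL,
                       trend_gradient = c(long_term = 1, medium_term = 0.6,
                                          short_term = 0.3),
                       impulsivity_params = list(mean_14 = 12, subject_sd = 1.7,
                                                 occasion_sd = 0.6,
                                                 decline = 1.0,
                                                 attenuation = 0.85,
                                                 drinker_shift = 0.8),
                       sensation_params = list(mean_14 = 13.6, subject_sd = 2.0,
                                               occasion_sd = 0.7,
                                               decline = 0.15, attenuation = 0,
                                               drinker_shift = 0.7),
                       noise_sd = list(fc = 0.15, site_fc = 0.03,
                                       site_measure = 0.2),
                       fc_mean = 0.2, snp_maf = 0.25,
                       cannabis_user_prob = 0.35,
                       snp_trend = FALSE,
                       onset_threshold = 2,
                       female_prop = c(long_term = 0.574, medium_term = 0.385,
                                       short_term = 0.390, control_I = 0.568,
                                       control_II = 0.810),
                       seed = 1) {
  n_edges <- n_regions * (n_regions - 1) / 2
  if (is.null(planted_links) || is.null(planted_snps) ||
      is.null(cannabis_links)) {
    def <- default_planted(n_edges, n_snps)
    planted_links <- planted_links %||% def$links
    planted_snps <- planted_snps %||% def$snps
    cannabis_links <- cannabis_links %||% def$cannabis
  }
  cfg <- structure(list(
    group_sizes = group_sizes, n_regions = n_regions, n_snps = n_snps,
    n_sites = n_sites, planted_links = planted_links,
    planted_snps = planted_snps, cannabis_links = cannabis_links,
    trend_gradient = trend_gradient, impulsivity_params = impulsivity_params,
    sensation_params = sensation_params, noise_sd = noise_sd,
    fc_mean = fc_mean, snp_maf = snp_maf, snp_trend = snp_trend,
    cannabis_user_prob = cannabis_user_prob,
    onset_threshold = onset_threshold, female_prop = female_prop,
    seed = seed), class = "bt_sim_config")
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  errs <- character()
  req_groups <- c("long_term", "medium_term", "short_term", "control_I",
                  "control_II")
  if (!all(req_groups %in% names(cfg$group_sizes))) {
    errs <- c(errs, "group_sizes must name all five groups")
  } else if (any(cfg$group_sizes < 0)) {
    errs <- c(errs, "group sizes must be non-negative")
  }
  g <- cfg$trend_gradient
  if (length(g) != 3 || any(diff(unname(g)) > 1e-12) || any(g < 0)) {
    errs <- c(errs, paste0("trend_gradient must be non-increasing over ",
                           "long -> medium -> short and non-negative"))
  }
  n_edges <- cfg$n_regions * (cfg$n_regions - 1) / 2
  if (any(cfg$planted_links$edge < 1 | cfg$planted_links$edge > n_edges)) {
    errs <- c(errs, "planted link indices out of range")
  }
  if (nrow(cfg$planted_snps) &&
      any(cfg$planted_snps$snp < 1 | cfg$planted_snps$snp > cfg$n_snps)) {
    errs <- c(errs, "planted SNP indices out of range")
  }
  sds <- c(cfg$impulsivity_params$subject_sd, cfg$impulsivity_params$occasion_sd,
           cfg$sensation_params$subject_sd, cfg$sensation_params$occasion_sd,
           cfg$noise_sd$fc)
  if (any(sds <= 0)) errs <- c(errs, "all SDs must be > 0")
  if (cfg$onset_threshold < 1 || cfg$onset_threshold > 6) {
    errs <- c(errs, "onset_threshold must be in 1..6")
  }
  if (length(errs)) stop_collected(errs, "invalid simulation config")
  invisible(cfg)
}

# Deterministic default planted-feature positions, spread over the index
# ranges so they touch unrelated region pairs / loci.
default_planted <- function(n_edges, n_snps) {
  if (n_edges < 40 || n_snps < 48) {
    stop("default planted features need >= 40 edges and >= 48 SNPs; ",
         "supply planted_links/planted_snps explicitly for smaller problems",
         call. = FALSE)
  }
  edge_pos <- unique(round(seq(3, n_edges - 2, length.out = 20)))
  links <- data.frame(
    edge = edge_pos[1:12],
    direction = rep(c("increased", "decreased"), c(8, 4)),
    effect = 0.3)
  cannabis <- data.frame(edge = edge_pos[13:20], effect = 0.15)
  snp_pos <- unique(round(seq(2, n_snps - 1, length.out = 24)))
  snps <- data.frame(snp = snp_pos,
                     role = rep(c("risk", "protective"), each = 12),
                     log_odds = 1.5)
  list(links = links, snps = snps, cannabis = cannabis)
}

#' Generate a seeded synthetic cohort
#'
#' Produces a cohort object whose components mirror the measurement battery
#' of a three-wave adolescent study: a phenotype table (ESPAD bands, SURPS /
#' NEO / Kirby / Cantab scores, sex, site), a subjects x links connectivity
#' matrix, a binary genotype matrix, and a `truth` record of everything that
#' was planted (for recovery tests only; the analysis never reads it).
#'
#' Drinker ESPAD binge trajectories are consistent with each group's onset
#' wave; planted connectivity/SNP effects are scaled by the onset gradient;
#' impulsivity declines at the control rate until onset and at the attenuated
#' rate afterwards (a period counts as post-onset when it ends at or after
#' the onset wave).
#'
#' @param config a [sim_config()] object.
#' @return object of class `bt_cohort`: list with `phenotypes`, `connectivity`,
#'   `edges`, `genotypes`, `truth`, `config`.
#' @export
generate_cohort <- function(config = sim_config()) {
  validate_sim_config(config)
  with_seed(config$seed, generate_cohort_impl(config))
}

generate_cohort_impl <- function(cfg) {
  sizes <- cfg$group_sizes[c("long_term", "medium_term", "short_term",
                             "control_I", "control_II")]
  n <- sum(sizes)
  group <- rep(names(sizes), sizes)
  subject_id <- sprintf("S%04d", seq_len(max(n, 1))[seq_len(n)])
  grad <- c(cfg$trend_gradient[c("long_term", "medium_term", "short_term")],
            control_I = 0, control_II = 0)[group]
  grad[is.na(grad)] <- 0
  is_drinker <- group %in% c("long_term", "medium_term", "short_term")

  sex <- ifelse(runif(n) < cfg$female_prop[group], "F", "M")
  site <- sample.int(cfg$n_sites, n, replace = TRUE)

  espad <- simulate_espad(group, n)
  cannabis_user <- runif(n) < cfg$cannabis_user_prob
  cann <- simulate_cannabis(n, cannabis_user)
  smoke <- simulate_smoking(n)

  n_edges <- cfg$n_regions * (cfg$n_regions - 1) / 2
  conn <- matrix(rnorm(n * n_edges, cfg$fc_mean, cfg$noise_sd$fc), n, n_edges)
  site_fc <- matrix(rnorm(cfg$n_sites * n_edges, 0, cfg$noise_sd$site_fc),
                    cfg$n_sites, n_edges)
  conn <- conn + site_fc[site, , drop = FALSE]
  for (k in seq_len(nrow(cfg$planted_links))) {
    e <- cfg$planted_links$edge[k]
    s <- if (cfg$planted_links$direction[k] == "increased") 1 else -1
    conn[, e] <- conn[, e] + s * cfg$planted_links$effect[k] * grad
  }
  for (k in seq_len(nrow(cfg$cannabis_links))) {
    e <- cfg$cannabis_links$edge[k]
    conn[cannabis_user, e] <- conn[cannabis_user, e] + cfg$cannabis_links$effect[k]
  }
  colnames(conn) <- paste0("edge_", seq_len(n_edges))
  rownames(conn) <- subject_id

  snp_grad <- if (isTRUE(cfg$snp_trend)) grad else as.numeric(is_drinker)
  geno <- simulate_genotypes(cfg, n, snp_grad)
  rownames(geno) <- subject_id

  onset_wave <- c(long_term = 14, medium_term = 16, short_term = 19,
                  control_I = Inf, control_II = Inf)[group]
  site_scale <- cfg$noise_sd$site_measure
  imp <- simulate_trajectory(cfg$impulsivity_params, n, grad, onset_wave,
                             site, cfg$n_sites, site_scale,
                             sex_effect = c(F = 0, M = 0.2)[sex])
  sen <- simulate_trajectory(cfg$sensation_params, n, grad, onset_wave,
                             site, cfg$n_sites, site_scale,
                             sex_effect = c(F = 0, M = 0.5)[sex])
  anx <- simulate_trajectory(list(mean_14 = 11.5, subject_sd = 2.0,
                                  occasion_sd = 0.8, decline = -0.1,
                                  attenuation = 0, drinker_shift = 0),
                             n, grad, onset_wave, site, cfg$n_sites,
                             site_scale, sex_effect = c(F = 0.4, M = 0)[sex])
  neg <- simulate_trajectory(list(mean_14 = 12.5, subject_sd = 2.6,
                                  occasion_sd = 1.0, decline = 0.05,
                                  attenuation = 0, drinker_shift = 0),
                             n, grad, onset_wave, site, cfg$n_sites,
                             site_scale, sex_effect = 0)

  pheno <- data.frame(subject_id = subject_id, group = group, sex = sex,
                      site = site, stringsAsFactors = FALSE)
  pheno[paste0("binge_", c(14, 16, 19))] <- espad$binge
  pheno[paste0("occasion_", c(14, 16, 19))] <- espad$occasion
  pheno[paste0("cannabis_", c(14, 16, 19))] <- cann
  pheno[paste0("smoking_", c(14, 16, 19))] <- smoke
  for (w in c(14, 16, 19)) {
    pheno[[paste0("surps_impulsivity_", w)]] <- imp[[as.character(w)]]
    pheno[[paste0("surps_sensation_seeking_", w)]] <- sen[[as.character(w)]]
    pheno[[paste0("surps_anxiety_", w)]] <- anx[[as.character(w)]]
    pheno[[paste0("surps_negative_thinking_", w)]] <- neg[[as.character(w)]]
  }
  pheno <- cbind(pheno, simulate_flat_measures(n, site, cfg$n_sites,
                                               site_scale, sex))

  truth <- list(planted_links = cfg$planted_links,
                planted_snps = cfg$planted_snps,
                cannabis_links = cfg$cannabis_links,
                cannabis_user = cannabis_user,
                trend_gradient = cfg$trend_gradient,
                impulsivity_params = cfg$impulsivity_params,
                sensation_params = cfg$sensation_params,
                onset_threshold = cfg$onset_threshold,
                group_sizes = as.list(sizes))

  structure(list(phenotypes = pheno, connectivity = conn,
                 edges = edge_index(cfg$n_regions), genotypes = geno,
                 truth = truth, config = cfg),
            class = "bt_cohort")
}

# Banded (0-6) lifetime-drunkenness trajectories consistent with each group's
# onset wave; lifetime counts are non-decreasing so bands are too.
simulate_espad <- function(group, n) {
  b14 <- b16 <- b19 <- integer(n)
  i <- group == "long_term"
  b14[i] <- 2L + rbinom(sum(i), 4, 0.22)
  b16[i] <- pmin(6L, b14[i] + rbinom(sum(i), 3, 0.33))
  b19[i] <- pmin(6L, b16[i] + rbinom(sum(i), 3, 0.38))
  i <- group == "medium_term"
  b14[i] <- rbinom(sum(i), 1, 0.06)
  b16[i] <- 2L + rbinom(sum(i), 4, 0.24)
  b19[i] <- pmin(6L, b16[i] + rbinom(sum(i), 3, 0.64))
  i <- group == "short_term"
  b14[i] <- rbinom(sum(i), 1, 0.02)
  b16[i] <- pmax(b14[i], rbinom(sum(i), 1, 0.17))
  b19[i] <- 2L + rbinom(sum(i), 4, 0.39)
  o14 <- pmin(6L, b14 + rbinom(n, 2, 0.3))
  o16 <- pmin(6L, pmax(o14, b16) + rbinom(n, 2, 0.35))
  o19 <- pmin(6L, pmax(o16, b19) + rbinom(n, 2, 0.4))
  is_ctrl <- group %in% c("control_I", "control_II")
  o14[is_ctrl] <- rbinom(sum(is_ctrl), 2, 0.2)
  o16[is_ctrl] <- pmin(6L, o14[is_ctrl] + rbinom(sum(is_ctrl), 2, 0.3))
  o19[is_ctrl] <- pmin(6L, o16[is_ctrl] + rbinom(sum(is_ctrl), 2, 0.4))
  list(binge = data.frame(b14, b16, b19),
       occasion = data.frame(o14, o16, o19))
}

simulate_cannabis <- function(n, user) {
  c14 <- c16 <- c19 <- integer(n)
  k <- sum(user)
  c14[user] <- rbinom(k, 1, 0.2)
  c16[user] <- pmin(6L, c14[user] + 1L + rbinom(k, 2, 0.5))
  c19[user] <- pmin(6L, c16[user] + rbinom(k, 2, 0.6))
  nk <- sum(!user)
  c19[!user] <- rbinom(nk, 1, 0.08)
  data.frame(c14, c16, c19)
}

simulate_smoking <- function(n) {
  s14 <- rbinom(n, 2, 0.1)
  s16 <- pmin(6L, s14 + rbinom(n, 2, 0.2))
  s19 <- pmin(6L, s16 + rbinom(n, 2, 0.25))
  data.frame(s14, s16, s19)
}

simulate_genotypes <- function(cfg, n, grad) {
  p <- matrix(cfg$snp_maf, n, cfg$n_snps)
  base_logit <- qlogis(cfg$snp_maf)
  for (k in seq_len(nrow(cfg$planted_snps))) {
    j <- cfg$planted_snps$snp[k]
    s <- if (cfg$planted_snps$role[k] == "risk") 1 else -1
    p[, j] <- plogis(base_logit + s * cfg$planted_snps$log_odds[k] * grad)
  }
  g <- matrix(rbinom(n * cfg$n_snps, 1, p), n, cfg$n_snps)
  colnames(g) <- paste0("snp_", seq_len(cfg$n_snps))
  g
}

# Three-wave personality trajectory: subject-level intercept, per-period
# decline attenuated after binge-drinking onset, site and sex offsets,
# occasion-level noise.
simulate_trajectory <- function(par, n, grad, onset_wave, site, n_sites,
                                site_scale, sex_effect) {
  u <- rnorm(n, 0, par$subject_sd)
  base <- par$mean_14 + par$drinker_shift * grad + u
  att1 <- ifelse(16 >= onset_wave, par$attenuation, 0)
  att2 <- ifelse(19 >= onset_wave, par$attenuation, 0)
  m14 <- base
  m16 <- m14 - par$decline * (1 - att1)
  m19 <- m16 - par$decline * (1 - att2)
  site_off <- rnorm(n_sites, 0, site_scale * par$subject_sd)[site]
  mk <- function(m) m + site_off + sex_effect + rnorm(n, 0, par$occasion_sd)
  list(`14` = mk(m14), `16` = mk(m16), `19` = mk(m19))
}

# Age-19 cross-sectional measures with no planted group effect: five NEO
# factors, five Kirby discounting rates, fourteen Cantab measures.
simulate_flat_measures <- function(n, site, n_sites, site_scale, sex) {
  specs <- list(
    neo_neuroticism = c(20, 8.5), neo_extraversion = c(29, 6.2),
    neo_openness = c(28.5, 5.8), neo_conscientiousness = c(31, 5.5),
    neo_agreeableness = c(30.5, 6.5),
    kirby_overall = c(0.02, 0.03), kirby_small = c(0.03, 0.04),
    kirby_medium = c(0.02, 0.03), kirby_large = c(0.02, 0.03),
    kirby_mean = c(0.02, 0.03),
    cantab_1 = c(515, 95), cantab_2 = c(500, 85), cantab_3 = c(6.1, 4.7),
    cantab_4 = c(8, 5), cantab_5 = c(0.18, 0.12), cantab_6 = c(1600, 460),
    cantab_7 = c(0.48, 0.11), cantab_8 = c(0.96, 0.06),
    cantab_9 = c(2.0, 0.95), cantab_10 = c(0.53, 0.12),
    cantab_11 = c(96, 7.3), cantab_12 = c(0.93, 0.045),
    cantab_13 = c(11, 11), cantab_14 = c(27.7, 5.9))
  sex_num <- as.numeric(sex == "F")
  out <- lapply(names(specs), function(nm) {
    ms <- specs[[nm]]
    site_off <- rnorm(n_sites, 0, site_scale * ms[2])[site]
    sex_off <- if (nm == "neo_agreeableness") 0.3 * ms[2] * sex_num else 0
    rnorm(n, ms[1], ms[2]) + site_off + sex_off
  })
  names(out) <- names(specs)
  as.data.frame(out)
}
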