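#' Default end-to-end run configuration
#'
#' All pipeline parameters with their defaults: the synthetic-cohort
#' generator settings, stratification threshold, selection rules, trend-test
#' level, classifier settings and longitudinal-test settings. Every default
#' is echoed into the run report for provenance.
#'
#' @return nested list of class `bt_run_config`.
#' @export
default_run_config <- function() {
  structure(list(
    seed = 1,
    cohort_dir = NULL,                 # read a written cohort instead of simulating
    sim = sim_config(),
    stratify = list(onset_threshold = 2,
                    control_sizes = c(control_I = 44, control_II = 21)),
    select = list(chi2_alpha = 0.001, retention_threshold = 0.9,
                  lambda_rule = "1se", nri = TRUE),
    trend = list(alpha = 0.05,
                 ordering = c("control_I", "control_II", "short_term",
                              "medium_term", "long_term"),
                 personality = c("surps_impulsivity_19",
                                 "surps_sensation_seeking_19",
                                 "surps_anxiety_19",
                                 "surps_negative_thinking_19")),
    classify = list(cost = 1,
                    svm2_candidates = c("iFC", "rSNP", "pSNP"),
                    n_boot = 5000,
                    drinker_strata = list("<=4" = 0:4, "5" = 5, "6" = 6),
                    control_strata = list("<=2" = 0:2, ">=3" = 3:6)),
    longitudinal = list(n_perm = 1000,
                        scales = c("impulsivity", "sensation_seeking")),
    out_dir = NULL), class = "bt_run_config")
}

#' Validate and complete a run configuration
#'
#' Fills unspecified fields from [default_run_config()], rejects unknown
#' keys, and checks parameter bounds; all problems are collected and
#' reported together. A missing seed is defaulted with a warning.
#'
#' @param raw_config a (possibly partial) configuration list.
#' @return a completed `bt_run_config`; errors abort with the full list of
#'   problems.
#' @export
validate_config <- function(raw_config = list()) {
  def <- default_run_config()
  errs <- character()
  if (inherits(raw_config, "bt_sim_config")) {
    raw_config <- list(sim = raw_config)
  }
  unknown <- setdiff(names(raw_config), names(def))
  if (length(unknown)) {
    errs <- c(errs, paste0("unknown key(s): ", paste(unknown, collapse = ", ")))
  }
  cfg <- def
  for (k in intersect(names(raw_config), names(def))) {
    if (k %in% c("stratify", "select", "trend", "classify", "longitudinal")) {
      sub_unknown <- setdiff(names(raw_config[[k]]), names(def[[k]]))
      if (length(sub_unknown)) {
        errs <- c(errs, paste0("unknown key(s) in ", k, ": ",
                               paste(sub_unknown, collapse = ", ")))
      }
      for (kk in intersect(names(raw_config[[k]]), names(def[[k]]))) {
        cfg[[k]][[kk]] <- raw_config[[k]][[kk]]
      }
    } else if (!is.null(raw_config[[k]])) {
      cfg[[k]] <- raw_config[[k]]
    }
  }
  if (!("seed" %in% names(raw_config))) {
    warning("no seed supplied; defaulting to seed = 1", call. = FALSE)
  }
  check <- function(ok, msg) if (!isTRUE(ok)) errs <<- c(errs, msg)
  check(is.numeric(cfg$seed) && length(cfg$seed) == 1 && is.finite(cfg$seed),
        "seed must be a single finite number")
  rt <- cfg$select$retention_threshold
  check(is.numeric(rt) && length(rt) == 1 && rt > 0 && rt <= 1,
        "retention_threshold must be in (0,1]")
  check(cfg$select$chi2_alpha > 0 && cfg$select$chi2_alpha < 1,
        "chi2_alpha must be in (0,1)")
  check(cfg$select$lambda_rule %in% c("1se", "min"),
        "lambda_rule must be '1se' or 'min'")
  check(cfg$trend$alpha > 0 && cfg$trend$alpha < 1,
        "trend alpha must be in (0,1)")
  check(cfg$classify$cost > 0, "cost must be > 0")
  check(cfg$classify$n_boot >= 0, "n_boot must be >= 0")
  check(cfg$longitudinal$n_perm >= 0, "n_perm must be >= 0")
  check(cfg$stratify$onset_threshold >= 1 && cfg$stratify$onset_threshold <= 6,
        "onset_threshold must be in 1..6")
  if (!is.null(cfg$sim)) {
    tryCatch(validate_sim_config(cfg$sim),
             error = function(e) errs <<- c(errs, conditionMessage(e)))
  }
  if (length(errs)) stop_collected(errs)
  class(cfg) <- "bt_run_config"
  cfg
}

#' Run the full analysis pipeline
#'
#' Executes every stage in order on a synthetic (or previously written)
#' cohort: stratification and train/test split; per-stratum stability
#' selection with LOO classification and NRI domain contributions (long-term
#' and short-term strata vs Control I); summary scores from the final
#' retained sets (links from the long-term stratum, SNPs retained in both
#' strata); the Jonckheere-Terpstra trend filter over summary and
#' personality scores; the two-layer hierarchical classifier trained on the
#' training sample and evaluated on the held-out medium-term + Control II
#' sample; and the longitudinal trajectory analyses. Identical configuration
#' and seed give an identical report.
#'
#' @param config a (partial) run configuration; see [default_run_config()].
#' @return list of class `bt_run_report` with per-stage results; if
#'   `config$out_dir` is set, intermediate tables and `report.json` are
#'   written there.
#' @export
run_full <- function(config = list()) {
  cfg <- validate_config(config)
  seeds <- vapply(1:6, function(k) child_seed(cfg$seed, k), integer(1))
  stage <- function(name, expr) {
    t0 <- Sys.time()
    out <- tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
    message(sprintf("[bingetrace] %-12s %6.1fs", name,
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    out
  }

  cohort <- stage("cohort", {
    if (!is.null(cfg$cohort_dir)) read_cohort(cfg$cohort_dir) else {
      sim <- cfg$sim
      sim$seed <- seeds[1]
      generate_cohort(sim)
    }
  })
  pheno <- cohort$phenotypes

  groups <- stage("stratify", {
    g <- assign_groups(pheno, onset_threshold = cfg$stratify$onset_threshold,
                       control_sizes = cfg$stratify$control_sizes)
    split_train_test(g)
  })
  group_sizes <- table(groups$group)
  train_ix <- which(groups$sample == "train")
  test_ix <- which(groups$sample == "test")
  covs <- pheno[, c("sex", "site")]
  covs$site <- factor(covs$site)
  covs$sex <- factor(covs$sex)
  y_all <- as.integer(groups$group %in% c("long_term", "medium_term",
                                          "short_term"))

  stratum <- function(drinker_group, k) {
    ix <- which(groups$group %in% c(drinker_group, "control_I"))
    svm_stratum_analysis(cohort$connectivity[ix, , drop = FALSE],
                         cohort$genotypes[ix, , drop = FALSE],
                         covs[ix, , drop = FALSE], y_all[ix],
                         chi2_alpha = cfg$select$chi2_alpha,
                         retention_threshold = cfg$select$retention_threshold,
                         lambda_rule = cfg$select$lambda_rule,
                         cost = cfg$classify$cost, seed = seeds[k],
                         compute_nri = isTRUE(cfg$select$nri))
  }
  svm_long <- stage("svm_long", stratum("long_term", 2))
  svm_short <- stage("svm_short", stratum("short_term", 3))

  scores_all <- stage("scores", {
    # links from the long-term stratum; SNPs retained in both strata with a
    # consistent role
    retained_links <- svm_long$fc_stability$retained
    sl <- svm_long$snp_stability$retained
    ss <- svm_short$snp_stability$retained
    common <- merge(sl, ss, by = c("feature", "role"))
    retained_snps <- common[, c("feature", "role")]
    rfit <- residualize(cohort$connectivity[train_ix, , drop = FALSE],
                        covs[train_ix, , drop = FALSE])
    res_conn <- apply_residualization(rfit, cohort$connectivity, covs)
    sc <- summary_scores(res_conn, cohort$genotypes, retained_links,
                         retained_snps)
    list(scores = sc, retained_links = retained_links,
         retained_snps = retained_snps,
         empty = attr(sc, "empty_scores"))
  })

  trend <- stage("trend", {
    cand <- cbind(scores_all$scores,
                  pheno[, cfg$trend$personality, drop = FALSE])
    trend_select(cand, groups$group, ordering = cfg$trend$ordering,
                 directions = list(iFC = "increased", dFC = "decreased",
                                   rSNP = "increased", pSNP = "decreased"),
                 alpha = cfg$trend$alpha, covariates = covs)
  })

  hier <- stage("train", {
    retained_feats <- trend$feature[trend$retained]
    svm2_feats <- intersect(cfg$classify$svm2_candidates, retained_feats)
    svm2_fallback <- length(svm2_feats) == 0
    if (svm2_fallback) svm2_feats <- cfg$classify$svm2_candidates
    svm3_feats <- intersect(cfg$trend$personality, retained_feats)
    svm3_fallback <- length(svm3_feats) == 0
    if (svm3_fallback) svm3_feats <- cfg$trend$personality
    model <- fit_hierarchical(
      covs[train_ix, , drop = FALSE],
      scores_all$scores[train_ix, svm2_feats, drop = FALSE],
      pheno[train_ix, svm3_feats, drop = FALSE],
      y_all[train_ix], cost = cfg$classify$cost)
    list(model = model, svm2_features = svm2_feats,
         svm3_features = svm3_feats,
         svm2_fallback = svm2_fallback, svm3_fallback = svm3_fallback)
  })

  heldout <- stage("evaluate", {
    evaluate_heldout(hier$model,
                     covs[test_ix, , drop = FALSE],
                     scores_all$scores[test_ix, , drop = FALSE],
                     pheno[test_ix, , drop = FALSE],
                     y_all[test_ix],
                     binge_band = pheno$binge_19[test_ix],
                     occasion_band = pheno$occasion_19[test_ix],
                     drinker_strata = cfg$classify$drinker_strata,
                     control_strata = cfg$classify$control_strata,
                     n_boot = cfg$classify$n_boot, seed = seeds[4])
  })

  longitudinal <- stage("longitudinal", {
    if (cfg$longitudinal$n_perm == 0) {
      list(skipped = TRUE)
    } else {
      out <- lapply(cfg$longitudinal$scales, function(s) {
        longitudinal_analysis(pheno, groups, scale = s,
                              n_perm = cfg$longitudinal$n_perm,
                              seed = seeds[5])
      })
      names(out) <- cfg$longitudinal$scales
      out
    }
  })

  report <- structure(list(
    config = cfg,
    group_sizes = as.list(group_sizes),
    n_total = sum(group_sizes[names(group_sizes) != "excluded"]),
    n_train = length(train_ix), n_test = length(test_ix),
    n_excluded = sum(groups$group == "excluded"),
    svm_long = list(loo = svm_long$loo[c("accuracy", "auc")],
                    nri = svm_long$nri,
                    n_retained_links = nrow(svm_long$fc_stability$retained),
                    n_retained_snps = nrow(svm_long$snp_stability$retained)),
    svm_short = list(loo = svm_short$loo[c("accuracy", "auc")],
                     nri = svm_short$nri,
                     n_retained_links = nrow(svm_short$fc_stability$retained),
                     n_retained_snps = nrow(svm_short$snp_stability$retained)),
    retained_links = scores_all$retained_links,
    retained_snps = scores_all$retained_snps,
    trend = trend,
    hierarchical = list(loo = hier$model$loo,
                        svm2_features = hier$svm2_features,
                        svm3_features = hier$svm3_features,
                        svm2_fallback = hier$svm2_fallback,
                        svm3_fallback = hier$svm3_fallback),
    heldout = heldout,
    longitudinal = longitudinal), class = "bt_run_report")
  report$.internal <- list(cohort = cohort, groups = groups,
                           scores = scores_all$scores,
                           model = hier$model)

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_cohort(cohort, file.path(cfg$out_dir, "cohort"))
    data.table::fwrite(groups, file.path(cfg$out_dir, "groups.tsv"),
                       sep = "\t")
    data.table::fwrite(cbind(subject_id = pheno$subject_id,
                             scores_all$scores),
                       file.path(cfg$out_dir, "scores.tsv"), sep = "\t")
    data.table::fwrite(trend, file.path(cfg$out_dir, "trend.tsv"), sep = "\t")
    save_model(hier$model, file.path(cfg$out_dir, "model.json"))
    rep_out <- report
    rep_out$.internal <- NULL
    jsonlite::write_json(strip_classes(rep_out),
                         file.path(cfg$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = I(17), null = "null",
                         force = TRUE)
  }
  report
}

strip_classes <- function(x) {
  if (is.list(x)) {
    x <- lapply(x, strip_classes)
    attributes(x) <- list(names = names(x))
  }
  x
}
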