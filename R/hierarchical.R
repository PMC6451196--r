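#' Stratum classifier with leave-one-out stability selection and NRI
#'
#' Builds the single-stratum drinkers-vs-controls classifier (the
#' "SVM-long" / "SVM-short" construction). Connectivity is first
#' residualized on the stratum covariates (a low-dimensional nuisance fit
#' whose dependence on any single subject is O(1/n)); then, within every
#' leave-one-out fold, discriminative links are selected by lasso-logistic
#' regression at a fixed penalty (chosen once by cross-validated deviance on
#' the full stratum), SNPs are screened by chi-squared tests, the four
#' summary scores are computed from the fold's selections, and a margin
#' classifier on covariates + scores is trained to score the held-out
#' subject. Selection frequencies across folds give the stability result;
#' reduced models refit per fold without each domain give its
#' net-reclassification contribution.
#'
#' @param connectivity subjects x links matrix for the stratum.
#' @param genotypes subjects x SNPs binary matrix.
#' @param covariates data.frame (sex, site) for the stratum.
#' @param labels binary labels (1 = drinker).
#' @param chi2_alpha SNP screening level.
#' @param retention_threshold stability retention cut (strict; default 0.9).
#' @param lambda_rule `"1se"` or `"min"` penalty rule.
#' @param cost margin-classifier cost.
#' @param seed seed for the penalty cross-validation folds.
#' @param compute_nri also fit the domain-reduced models per fold and report
#'   net-reclassification contributions (default TRUE).
#' @return list of class `bt_stratum`: `fc_stability`, `snp_stability`
#'   (`bt_stability` objects), `loo` (accuracy, auc, decision values),
#'   `nri` (list fc/snp/covariates of `bt_nri`), `lambda`.
#' @export
svm_stratum_analysis <- function(connectivity, genotypes, covariates, labels,
                                 chi2_alpha = 0.001,
                                 retention_threshold = 0.9,
                                 lambda_rule = c("1se", "min"), cost = 1,
                                 seed = NULL, compute_nri = TRUE) {
  lambda_rule <- match.arg(lambda_rule)
  conn <- as.matrix(connectivity)
  geno <- as.matrix(genotypes)
  y <- as.integer(as.numeric(labels) > 0)
  n <- nrow(conn)
  stopifnot(nrow(geno) == n, nrow(covariates) == n, length(y) == n)
  cov_mm <- residual_design(covariates, n)
  cov_feats <- cov_mm[, -1, drop = FALSE]  # indicators without intercept

  # penalty chosen once on the full stratum (residualized), then frozen
  res_full <- residualize(conn, covariates)$residuals
  sel0 <- lasso_select_links(res_full, y, rule = lambda_rule, seed = seed)
  lambda <- attr(sel0, "lambda")

  fc_counts <- fc_signs <- numeric(ncol(conn))
  snp_counts <- snp_signs <- numeric(ncol(geno))
  dv <- matrix(NA_real_, n, 4,
               dimnames = list(NULL, c("full", "no_fc", "no_snp", "no_cov")))
  res_all <- res_full
  for (i in seq_len(n)) {
    tr <- setdiff(seq_len(n), i)
    sel_fc <- lasso_select_links(res_all[tr, , drop = FALSE], y[tr],
                                 lambda = lambda)
    sel_snp <- chi2_select_snps(geno[tr, , drop = FALSE], y[tr],
                                alpha = chi2_alpha)
    fc_counts[sel_fc$feature] <- fc_counts[sel_fc$feature] + 1
    fc_signs[sel_fc$feature] <- fc_signs[sel_fc$feature] + sel_fc$sign
    snp_counts[sel_snp$feature] <- snp_counts[sel_snp$feature] + 1
    snp_signs[sel_snp$feature] <- snp_signs[sel_snp$feature] +
      ifelse(sel_snp$role == "risk", 1, -1)
    sc <- summary_scores(
      res_all, geno,
      retained_links = data.frame(
        feature = sel_fc$feature,
        direction = ifelse(sel_fc$sign > 0, "increased", "decreased")),
      retained_snps = sel_snp[, c("feature", "role")])
    feats <- cbind(cov_feats, as.matrix(sc))
    variants <- list(
      full = seq_len(ncol(feats)),
      no_fc = which(!colnames(feats) %in% c("iFC", "dFC")),
      no_snp = which(!colnames(feats) %in% c("rSNP", "pSNP")),
      no_cov = which(colnames(feats) %in% c("iFC", "dFC", "rSNP", "pSNP")))
    if (!compute_nri) variants <- variants["full"]
    for (v in names(variants)) {
      fx <- feats[, variants[[v]], drop = FALSE]
      fit <- train_margin_classifier(fx[tr, , drop = FALSE], y[tr],
                                     cost = cost)
      dv[i, v] <- predict(fit, fx[i, , drop = FALSE])[1]
    }
  }
  loo <- list(accuracy = mean((dv[, "full"] > 0) == (y == 1)),
              auc = rank_auc(dv[, "full"], y),
              decision_values = dv[, "full"])
  # margins from different feature sets are not on a common scale, so the
  # movement comparison uses standardized decision values
  zsc <- function(v) {
    s <- sd(v)
    (v - mean(v)) / (if (is.finite(s) && s > 0) s else 1)
  }
  nri <- if (compute_nri) list(
    fc = nri_domain_contribution(zsc(dv[, "full"]), zsc(dv[, "no_fc"]), y),
    snp = nri_domain_contribution(zsc(dv[, "full"]), zsc(dv[, "no_snp"]), y),
    covariates = nri_domain_contribution(zsc(dv[, "full"]),
                                         zsc(dv[, "no_cov"]), y)
  ) else NULL
  fc_stab <- stability_from_tallies(fc_counts, fc_signs, n,
                                    retention_threshold)
  snp_stab <- stability_from_tallies(snp_counts, snp_signs, n,
                                     retention_threshold)
  snp_stab$table$direction <- ifelse(snp_stab$table$direction == "increased",
                                     "risk", "protective")
  if (nrow(snp_stab$retained)) {
    snp_stab$retained$direction <- ifelse(
      snp_stab$retained$direction == "increased", "risk", "protective")
  }
  names(snp_stab$retained)[names(snp_stab$retained) == "direction"] <- "role"
  names(snp_stab$table)[names(snp_stab$table) == "direction"] <- "role"
  structure(list(fc_stability = fc_stab, snp_stability = snp_stab,
                 loo = loo, nri = nri, lambda = lambda),
            class = "bt_stratum")
}

#' Fit the two-layer hierarchical classifier
#'
#' In-layer: three margin classifiers on disjoint domains — SVM1 on the
#' covariates (sex, site indicators), SVM2 on the trend-surviving brain/gene
#' summary scores, SVM3 on the trend-surviving personality scores. Each is
#' evaluated by leave-one-out on the training sample, and the out-layer SVM4
#' is trained on the three LOO decision values, so no subject's out-layer
#' input was produced by a model that saw that subject. At prediction time
#' the in-layer models refit on the full training sample feed SVM4.
#'
#' @param covariates training covariate data.frame (sex, site).
#' @param scores training summary-score data.frame (columns = SVM2 inputs).
#' @param personality training personality data.frame (columns = SVM3
#'   inputs).
#' @param labels binary labels (1 = drinker).
#' @param cost margin-classifier cost.
#' @return object of class `bt_hierarchical`: in-layer fits, `svm4`,
#'   `loo` (out-layer LOO accuracy/AUC on the training sample),
#'   `feature_names`.
#' @export
fit_hierarchical <- function(covariates, scores, personality, labels,
                             cost = 1) {
  domains <- list(covariates = covariates, scores = scores,
                  personality = personality)
  for (d in names(domains)) {
    if (is.null(domains[[d]]) || ncol(as.data.frame(domains[[d]])) == 0) {
      stop("missing in-layer domain: ", d, call. = FALSE)
    }
  }
  y <- as.integer(as.numeric(labels) > 0)
  cov_mm <- residual_design(covariates, length(y))[, -1, drop = FALSE]
  feats <- list(covariates = cov_mm,
                scores = as.matrix(as.data.frame(scores)),
                personality = as.matrix(as.data.frame(personality)))
  trainer <- function(x, y) train_margin_classifier(x, y, cost = cost)
  in_loo <- lapply(feats, function(fx) loo_evaluate(fx, y, trainer)$decision_values)
  d_mat <- do.call(cbind, in_loo)
  colnames(d_mat) <- c("svm1", "svm2", "svm3")
  svm4 <- train_margin_classifier(d_mat, y, cost = cost)
  dv4 <- loo_evaluate(d_mat, y, trainer)
  in_final <- lapply(feats, function(fx) trainer(fx, y))
  structure(list(svm1 = in_final$covariates, svm2 = in_final$scores,
                 svm3 = in_final$personality, svm4 = svm4,
                 loo = list(accuracy = dv4$accuracy, auc = dv4$auc),
                 feature_names = list(
                   covariates = colnames(cov_mm),
                   scores = colnames(feats$scores),
                   personality = colnames(feats$personality)),
                 cost = cost),
            class = "bt_hierarchical")
}

#' Predict from a hierarchical classifier
#'
#' @param object a `bt_hierarchical` model.
#' @param covariates,scores,personality new-subject domain inputs with the
#'   training columns.
#' @param ... unused.
#' @return list: `decision` (SVM4 decision values), `class` (0/1),
#'   `in_layer` (matrix of the three in-layer decision values).
#' @export
predict.bt_hierarchical <- function(object, covariates, scores, personality,
                                    ...) {
  cov_mm <- residual_design(covariates, nrow(as.data.frame(covariates)))
  cov_mm <- cov_mm[, colnames(cov_mm) != "(Intercept)", drop = FALSE]
  miss <- setdiff(object$feature_names$covariates, colnames(cov_mm))
  if (length(miss)) {  # unseen level pattern: absent indicator = all zero
    add <- matrix(0, nrow(cov_mm), length(miss),
                  dimnames = list(NULL, miss))
    cov_mm <- cbind(cov_mm, add)
  }
  cov_mm <- cov_mm[, object$feature_names$covariates, drop = FALSE]
  sc <- as.matrix(as.data.frame(scores)[, object$feature_names$scores,
                                        drop = FALSE])
  pe <- as.matrix(as.data.frame(personality)[,
                                             object$feature_names$personality,
                                             drop = FALSE])
  d_mat <- cbind(svm1 = predict(object$svm1, cov_mm),
                 svm2 = predict(object$svm2, sc),
                 svm3 = predict(object$svm3, pe))
  dec <- predict(object$svm4, d_mat)
  list(decision = dec, class = as.integer(dec > 0), in_layer = d_mat)
}

#' Evaluate a hierarchical model on the held-out sample
#'
#' Overall accuracy; accuracy stratified by lifetime-occasion band within
#' controls and by lifetime-binge band within drinkers; contribution of each
#' model input as the absolute Pearson correlation of the input with the
#' SVM4 output, with seeded bootstrap percentile confidence intervals for
#' the difference between each score contribution and the covariate-layer
#' contribution.
#'
#' @param model `bt_hierarchical` fit (frozen; nothing here refits it).
#' @param covariates,scores,personality test-sample domain inputs.
#' @param labels binary test labels (1 = drinker).
#' @param binge_band,occasion_band test-sample ESPAD bands at age 19 used
#'   for stratification.
#' @param drinker_strata,control_strata named lists of band values defining
#'   the accuracy strata.
#' @param n_boot bootstrap resamples (default 5000).
#' @param seed bootstrap seed.
#' @return list: `accuracy`, `drinker_strata`, `control_strata`,
#'   `contributions`, `contrast_ci`, `n`.
#' @export
evaluate_heldout <- function(model, covariates, scores, personality, labels,
                             binge_band, occasion_band,
                             drinker_strata = list("<=4" = 0:4, "5" = 5,
                                                   "6" = 6),
                             control_strata = list("<=2" = 0:2, ">=3" = 3:6),
                             n_boot = 5000, seed = NULL) {
  y <- as.integer(as.numeric(labels) > 0)
  stopifnot(length(binge_band) == length(y),
            length(occasion_band) == length(y))
  pr <- predict(model, covariates, scores, personality)
  correct <- pr$class == y
  strat_acc <- function(strata, band, mask) {
    vapply(strata, function(vals) {
      ix <- mask & band %in% vals
      if (!any(ix)) NA_real_ else mean(correct[ix])
    }, numeric(1))
  }
  inputs <- cbind(as.matrix(as.data.frame(scores)[,
                                                  model$feature_names$scores,
                                                  drop = FALSE]),
                  as.matrix(as.data.frame(personality)[,
                                                       model$feature_names$personality,
                                                       drop = FALSE]),
                  covariate_layer = pr$in_layer[, "svm1"])
  contrib <- apply(inputs, 2, function(v) {
    if (sd(v) == 0 || sd(pr$decision) == 0) return(NA_real_)
    abs(cor(v, pr$decision))
  })
  score_cols <- setdiff(colnames(inputs), "covariate_layer")
  contrast_ci <- NULL
  if (n_boot > 0 && length(score_cols)) {
    n <- length(y)
    boot <- with_seed(seed, {
      vapply(seq_len(n_boot), function(b) {
        ix <- sample.int(n, n, replace = TRUE)
        dec <- pr$decision[ix]
        if (sd(dec) == 0) return(rep(NA_real_, length(score_cols)))
        cov_c <- if (sd(inputs[ix, "covariate_layer"]) == 0) NA_real_ else
          abs(cor(inputs[ix, "covariate_layer"], dec))
        vapply(score_cols, function(sc) {
          if (sd(inputs[ix, sc]) == 0) return(NA_real_)
          abs(cor(inputs[ix, sc], dec)) - cov_c
        }, numeric(1))
      }, numeric(length(score_cols)))
    })
    boot <- matrix(boot, nrow = length(score_cols))
    contrast_ci <- t(apply(boot, 1, quantile, probs = c(0.025, 0.975),
                           na.rm = TRUE))
    rownames(contrast_ci) <- paste0(score_cols, "_minus_covariates")
  }
  list(accuracy = mean(correct),
       drinker_strata = strat_acc(drinker_strata, binge_band, y == 1),
       control_strata = strat_acc(control_strata, occasion_band, y == 0),
       contributions = contrib,
       contrast_ci = contrast_ci,
       n = length(y))
}

#' Serialize a fitted hierarchical model to versioned JSON
#'
#' Weights, intercepts and standardization constants are written at full
#' precision, so a reloaded model reproduces predictions bit-identically.
#'
#' @param model `bt_hierarchical` or `bt_margin` object.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
save_model <- function(model, path) {
  payload <- list(format = "bingetrace-model", version = 1L,
                  type = class(model)[1], model = serialize_model(model))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17),
                       null = "null")
  invisible(path)
}

serialize_model <- function(m) {
  if (inherits(m, "bt_margin")) {
    out <- unclass(m)
    if (!is.null(out$SV)) out$SV <- as.data.frame(out$SV)
    out$.class <- "bt_margin"
    return(out)
  }
  if (inherits(m, "bt_hierarchical")) {
    out <- unclass(m)
    for (f in c("svm1", "svm2", "svm3", "svm4")) {
      out[[f]] <- serialize_model(out[[f]])
    }
    out$.class <- "bt_hierarchical"
    return(out)
  }
  m
}

#' Load a model written by [save_model()]
#'
#' @param path JSON model file.
#' @return the reconstructed model object.
#' @export
load_model <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(payload$format, "bingetrace-model")) {
    stop("not a bingetrace model file: ", path, call. = FALSE)
  }
  deserialize_model(payload$model)
}

deserialize_model <- function(x) {
  cls <- x$.class
  x$.class <- NULL
  if (identical(cls, "bt_margin")) {
    for (f in c("center", "scale", "w")) {
      if (!is.null(x[[f]])) x[[f]] <- unlist_named(x[[f]])
    }
    if (!is.null(x$SV)) x$SV <- as.matrix(x$SV)
    class(x) <- "bt_margin"
    return(x)
  }
  if (identical(cls, "bt_hierarchical")) {
    for (f in c("svm1", "svm2", "svm3", "svm4")) {
      x[[f]] <- deserialize_model(x[[f]])
    }
    x$feature_names <- lapply(x$feature_names, unlist)
    class(x) <- "bt_hierarchical"
    return(x)
  }
  x
}

unlist_named <- function(v) {
  out <- unlist(v)
  if (is.null(names(out)) && !is.null(names(v))) names(out) <- names(v)
  out
}
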