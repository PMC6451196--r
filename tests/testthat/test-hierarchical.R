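make_training_features <- function(seed, n = 120, informative = TRUE) {
  n <- 2 * (n %/% 2)
  withr::with_seed(seed, {
    y <- rep(c(0, 1), each = n / 2)
    shift <- if (informative) 1.5 else 0
    covariates <- data.frame(sex = factor(sample(c("F", "M"), n, TRUE)),
                             site = factor(sample(1:4, n, TRUE)))
    scores <- data.frame(iFC = rnorm(n) + shift * y,
                         rSNP = rnorm(n) + 0.8 * shift * y,
                         pSNP = rnorm(n) - 0.8 * shift * y)
    personality <- data.frame(impulsivity = rnorm(n) + 0.7 * shift * y)
    list(covariates = covariates, scores = scores,
         personality = personality, y = y)
  })
}

test_that("the stacked model learns informative domains and stays leakage-safe", {
  d <- make_training_features(31)
  model <- fit_hierarchical(d$covariates, d$scores, d$personality, d$y)
  expect_gt(model$loo$accuracy, 0.75)
  # out-layer consumes exactly three in-layer decision values
  expect_identical(length(model$svm4$w), 3L)
  # prediction for one subject is independent of other rows in the batch
  one <- predict(model, d$covariates[1, , drop = FALSE],
                 d$scores[1, , drop = FALSE],
                 d$personality[1, , drop = FALSE])
  all_ <- predict(model, d$covariates, d$scores, d$personality)
  expect_equal(one$decision, all_$decision[1], tolerance = 1e-12)
  # frozen state untouched by prediction (checksum equality)
  f1 <- withr::local_tempfile(fileext = ".json")
  f2 <- withr::local_tempfile(fileext = ".json")
  save_model(model, f1)
  invisible(predict(model, d$covariates, d$scores, d$personality))
  save_model(model, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("null features give chance-level out-layer LOO accuracy", {
  d <- make_training_features(32, n = 138, informative = FALSE)
  model <- fit_hierarchical(d$covariates, d$scores, d$personality, d$y)
  expect_gte(model$loo$accuracy, 0.4)
  expect_lte(model$loo$accuracy, 0.6)
})

test_that("a missing in-layer domain is an error naming the domain", {
  d <- make_training_features(33)
  expect_error(fit_hierarchical(d$covariates, d$scores[, 0], d$personality,
                                d$y),
               "scores")
  expect_error(fit_hierarchical(d$covariates, d$scores, NULL, d$y),
               "personality")
})

test_that("hierarchical models reload bit-identically", {
  d <- make_training_features(34)
  model <- fit_hierarchical(d$covariates, d$scores, d$personality, d$y)
  f <- withr::local_tempfile(fileext = ".json")
  save_model(model, f)
  model2 <- load_model(f)
  newd <- make_training_features(35, n = 100)
  p1 <- predict(model, newd$covariates, newd$scores, newd$personality)
  p2 <- predict(model2, newd$covariates, newd$scores, newd$personality)
  expect_identical(p1$decision, p2$decision)
})

test_that("held-out evaluation stratifies accuracy and bounds null contributions", {
  d <- make_training_features(36, n = 100)
  model <- fit_hierarchical(d$covariates, d$scores, d$personality, d$y)
  te <- make_training_features(37, n = 74)
  withr::with_seed(38, {
    binge <- ifelse(te$y == 1, sample(c(3, 5, 6), 74, TRUE), 0)
    occ <- ifelse(te$y == 0, sample(0:4, 74, TRUE), 5)
  })
  ev <- evaluate_heldout(model, te$covariates, te$scores, te$personality,
                         te$y, binge_band = binge, occasion_band = occ,
                         n_boot = 200, seed = 1)
  expect_gt(ev$accuracy, 0.65)
  expect_named(ev$drinker_strata, c("<=4", "5", "6"))
  expect_named(ev$contributions,
               c("iFC", "rSNP", "pSNP", "impulsivity", "covariate_layer"))
  # informative score inputs out-contribute the covariate layer
  expect_gt(ev$contributions[["iFC"]], ev$contributions[["covariate_layer"]])
  expect_identical(nrow(ev$contrast_ci), 4L)
  # an empty stratum reports NA, not zero
  ev2 <- evaluate_heldout(model, te$covariates, te$scores, te$personality,
                          te$y, binge_band = rep(6, 74),
                          occasion_band = occ,
                          n_boot = 0)
  expect_true(is.na(ev2$drinker_strata[["5"]]))
})

test_that("stability-selected stratum analysis finds planted structure", {
  co <- generate_cohort(small_sim_config(seed = 41))
  g <- assign_groups(co$phenotypes)
  ix <- which(g$group %in% c("long_term", "control_I"))
  covs <- cohort_covariates(co)[ix, ]
  y <- as.integer(g$group[ix] == "long_term")
  sa <- svm_stratum_analysis(co$connectivity[ix, ], co$genotypes[ix, ],
                             covs, y, seed = 1)
  truth_links <- co$truth$planted_links$edge
  rec <- mean(truth_links %in% sa$fc_stability$retained$feature)
  expect_gte(rec, 0.5)
  expect_gt(sa$loo$accuracy, 0.8)
  expect_gt(sa$loo$auc, 0.85)
  # retained directions match the planted ones
  merged <- merge(sa$fc_stability$retained,
                  co$truth$planted_links,
                  by.x = "feature", by.y = "edge")
  expect_true(all(merged$direction.x == merged$direction.y))
  # informative domains move reclassification in the right direction
  expect_gt(sa$nri$snp$z, 0)
})

test_that("the stacked model beats the covariates-only layer on held-out data", {
  wins <- 0L
  for (s in 1:5) {
    co <- generate_cohort(small_sim_config(seed = 600 + s))
    g <- split_train_test(assign_groups(co$phenotypes))
    covs <- cohort_covariates(co)
    tr <- which(g$sample == "train"); te <- which(g$sample == "test")
    y <- as.integer(g$group %in% c("long_term", "medium_term", "short_term"))
    rfit <- residualize(co$connectivity[tr, ], covs[tr, ])
    res <- apply_residualization(rfit, co$connectivity, covs)
    sc <- summary_scores(res, co$genotypes,
                         data.frame(feature = co$truth$planted_links$edge,
                                    direction = co$truth$planted_links$direction),
                         data.frame(feature = co$truth$planted_snps$snp,
                                    role = co$truth$planted_snps$role))
    pers <- co$phenotypes[, "surps_impulsivity_19", drop = FALSE]
    model <- fit_hierarchical(covs[tr, ], sc[tr, c("iFC", "rSNP", "pSNP")],
                              pers[tr, , drop = FALSE], y[tr])
    pr <- predict(model, covs[te, ], sc[te, ], pers[te, , drop = FALSE])
    acc_full <- mean(pr$class == y[te])
    cov_mm <- stats::model.matrix(~ ., covs)[, -1]
    svm1 <- train_margin_classifier(cov_mm[tr, ], y[tr])
    acc_cov <- mean(as.integer(predict(svm1, cov_mm[te, ]) > 0) == y[te])
    if (acc_full > acc_cov) wins <- wins + 1L
  }
  expect_gte(wins, 4L)
})
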