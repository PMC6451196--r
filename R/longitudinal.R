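#' Per-subject developmental difference scores
#'
#' Changes in a personality scale between assessment waves:
#' `d_16_14 = value(16) - value(14)` and `d_19_16 = value(19) - value(16)`.
#' Subjects with a missing wave are dropped with a log message.
#'
#' @param values n x 3 matrix or data.frame with columns for ages 14, 16, 19
#'   (in that order).
#' @return data.frame `d_16_14`, `d_19_16`; indices of dropped rows in
#'   attribute `"dropped"`.
#' @export
difference_scores <- function(values) {
  v <- as.matrix(values)
  if (ncol(v) != 3) stop("expected three wave columns (14, 16, 19)",
                         call. = FALSE)
  keep <- complete.cases(v)
  if (any(!keep)) {
    message("dropping ", sum(!keep), " subject(s) with missing waves")
  }
  out <- data.frame(d_16_14 = v[keep, 2] - v[keep, 1],
                    d_19_16 = v[keep, 3] - v[keep, 2])
  attr(out, "dropped") <- which(!keep)
  out
}

#' Sign-flip permutation test for paired period differences
#'
#' Tests whether the within-subject change differs between two periods. The
#' observed statistic is the median (default; configurable to the mean) of
#' `d2 - d1`; the null is built by independently flipping the sign of each
#' pair's difference (equivalent to swapping the two period values within a
#' pair). Small samples are handled by exhaustive enumeration of all 2^n
#' sign patterns; otherwise Monte-Carlo sampling with the add-one convention
#' `p = (1 + #{|stat_perm| >= |stat_obs|}) / (1 + n_perm)`.
#'
#' @param d1,d2 paired difference scores (equal length n >= 5 for the
#'   Monte-Carlo mode; n < 5 forces exact mode).
#' @param n_perm Monte-Carlo permutations (default 1000).
#' @param seed seed for the Monte-Carlo draw.
#' @param statistic `"median"` (default) or `"mean"`.
#' @param exact force (TRUE) or forbid (FALSE) exhaustive enumeration;
#'   default NULL enumerates when n <= 12.
#' @return list: `p` (two-sided), `statistic` (observed), `method`,
#'   `n_perm`.
#' @export
paired_median_permutation_test <- function(d1, d2, n_perm = 1000, seed = NULL,
                                           statistic = c("median", "mean"),
                                           exact = NULL) {
  statistic <- match.arg(statistic)
  stopifnot(length(d1) == length(d2))
  d <- d2 - d1
  n <- length(d)
  stat_fun <- if (statistic == "median") median else mean
  obs <- stat_fun(d)
  if (n < 5) exact <- TRUE
  if (is.null(exact)) exact <- n <= 12
  if (exact) {
    if (n > 16) stop("exact mode limited to n <= 16", call. = FALSE)
    signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
    perm <- apply(signs * rep(d, each = nrow(signs)), 1, stat_fun)
    p <- mean(abs(perm) >= abs(obs) - 1e-12)
    return(list(p = p, statistic = obs, method = "exact", n_perm = 2^n))
  }
  d <- sort(d)  # sign flips are exchangeable; sorting makes the Monte-Carlo
                # p-value invariant to pair ordering
  perm <- with_seed(seed, {
    s <- matrix(sample(c(-1, 1), n_perm * n, replace = TRUE), n_perm, n)
    apply(s * rep(d, each = n_perm), 1, stat_fun)
  })
  p <- (1 + sum(abs(perm) >= abs(obs) - 1e-12)) / (1 + n_perm)
  list(p = p, statistic = obs, method = "monte-carlo", n_perm = n_perm)
}

#' Repeated-measures ANOVA time-by-group interaction
#'
#' Two-way mixed-design ANOVA with time as the within-subject factor and
#' group as the between-subject factor, using the conventional
#' subject-within-group error term for the interaction. Reports the
#' uncorrected p alongside a Greenhouse-Geisser corrected p computed from
#' the pooled within-group covariance of the repeated measures.
#'
#' @param values n x T matrix of repeated measures (one column per time
#'   level, complete cases).
#' @param group length-n factor with two levels.
#' @return list: `F`, `df1`, `df2`, `p`, `p_gg`, `epsilon`.
#' @export
rm_anova_interaction <- function(values, group) {
  y <- as.matrix(values)
  group <- factor(group)
  if (nlevels(group) != 2) stop("exactly two groups required", call. = FALSE)
  if (any(table(group) < 2)) {
    stop("each group needs at least two subjects", call. = FALSE)
  }
  if (anyNA(y)) stop("complete cases required", call. = FALSE)
  n <- nrow(y); Tn <- ncol(y)
  long <- data.frame(
    value = as.vector(y),
    time = factor(rep(seq_len(Tn), each = n)),
    group = rep(group, Tn),
    subject = factor(rep(seq_len(n), Tn)))
  fit <- aov(value ~ group * time + Error(subject), data = long)
  within <- summary(fit)[["Error: Within"]][[1]]
  row_int <- grep("group:time", rownames(within))
  row_res <- grep("Residuals", rownames(within))
  Fv <- within[row_int, "F value"]
  df1 <- within[row_int, "Df"]
  df2 <- within[row_res, "Df"]
  p <- within[row_int, "Pr(>F)"]
  # Greenhouse-Geisser epsilon from the pooled within-group covariance
  resid_wide <- y - rowsum(y, group)[group, ] / as.vector(table(group))[group]
  S <- crossprod(resid_wide) / (n - nlevels(group))
  Cc <- diag(Tn) - 1 / Tn
  Sc <- Cc %*% S %*% Cc
  eps <- sum(diag(Sc))^2 / ((Tn - 1) * sum(Sc * Sc))
  list(F = Fv, df1 = df1, df2 = df2, p = p,
       p_gg = pf(Fv, eps * df1, eps * df2, lower.tail = FALSE),
       epsilon = eps)
}

#' Longitudinal trajectory analysis of a personality scale
#'
#' Runs the full developmental-change analysis for one scale: residualizes
#' the three wave scores on sex and site, computes per-period difference
#' scores, tests the pre- vs post-onset change in short-term drinkers with
#' the sign-flip permutation test, and tests the time-by-group interaction
#' (short-term drinkers vs pooled controls) with mixed-design repeated
#' measures ANOVA, both on the three wave scores and on the two difference
#' scores.
#'
#' Only short-term drinkers have a clean pre-onset period (14-16) and
#' post-onset period (16-19), so they are the default drinker group here;
#' other drinker groups have confounded periods.
#'
#' @param phenotypes cohort phenotype table.
#' @param groups data.frame from [assign_groups()].
#' @param scale scale name, e.g. `"impulsivity"` or `"sensation_seeking"`
#'   (column prefix `surps_<scale>_<wave>`).
#' @param n_perm permutations for the paired test; 0 skips it.
#' @param seed seed for the permutation draw.
#' @return list: `scale`, `n_drinkers`, `n_controls`, `difference_medians`,
#'   `permutation` (or NULL if skipped), `anova_scores`,
#'   `anova_differences`.
#' @export
longitudinal_analysis <- function(phenotypes, groups, scale = "impulsivity",
                                  n_perm = 1000, seed = NULL) {
  cols <- paste0("surps_", scale, "_", c(14, 16, 19))
  if (!all(cols %in% names(phenotypes))) {
    stop("phenotypes lack columns: ",
         paste(setdiff(cols, names(phenotypes)), collapse = ", "),
         call. = FALSE)
  }
  grp <- groups$group[match(phenotypes$subject_id, groups$subject_id)]
  keep <- grp %in% c("short_term", "control_I", "control_II")
  ph <- phenotypes[keep, , drop = FALSE]
  grp2 <- factor(ifelse(grp[keep] == "short_term", "short_term", "control"),
                 levels = c("control", "short_term"))
  raw <- as.matrix(ph[, cols])
  covs <- data.frame(sex = factor(ph$sex), site = factor(ph$site))
  # covariate and wave adjustments are estimated on controls only, so the
  # drinkers' post-onset dynamics are not absorbed into the adjustment
  rfit <- residualize(raw[grp2 == "control", , drop = FALSE],
                      covs[grp2 == "control", , drop = FALSE])
  vals <- apply_residualization(rfit, raw, covs)
  diffs <- difference_scores(vals)
  is_short <- grp2 == "short_term"
  # the sign-flip test uses raw within-subject differences: subject-constant
  # covariate effects cancel exactly in them, whereas estimated adjustments
  # would add a shared offset that breaks sign-flip exchangeability
  diffs_raw <- difference_scores(raw)
  perm <- if (n_perm > 0) {
    paired_median_permutation_test(diffs_raw$d_16_14[is_short],
                                   diffs_raw$d_19_16[is_short],
                                   n_perm = n_perm, seed = seed)
  } else NULL
  list(scale = scale,
       n_drinkers = sum(is_short), n_controls = sum(!is_short),
       difference_medians = c(
         drinkers_d_16_14 = median(diffs$d_16_14[is_short]),
         drinkers_d_19_16 = median(diffs$d_19_16[is_short]),
         controls_d_16_14 = median(diffs$d_16_14[!is_short]),
         controls_d_19_16 = median(diffs$d_19_16[!is_short])),
       permutation = perm,
       anova_scores = rm_anova_interaction(vals, grp2),
       anova_differences = rm_anova_interaction(as.matrix(diffs), grp2))
}
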