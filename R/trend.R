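#' Covariate-adjusted two-sample t-test
#'
#' The group effect is the coefficient of the binary group indicator in a
#' linear model that also contains the covariate design (indicator-coded sex
#' and site plus intercept). With no covariates this reduces exactly to the
#' classic pooled two-sample t-test.
#'
#' @param values numeric response vector.
#' @param group binary group indicator (1 = drinker).
#' @param covariates optional data.frame of covariates.
#' @return list: `t`, `df`, `p` (two-sided), `estimate`.
#' @export
adjusted_t_test <- function(values, group, covariates = NULL) {
  g <- as.numeric(as.numeric(group) > 0)
  if (!is.null(covariates)) {
    d <- residual_design(covariates, length(values))
    if (max(abs(suppressWarnings(qr.resid(qr(d), g)))) < 1e-10) {
      stop("group indicator is collinear with the covariates", call. = FALSE)
    }
  }
  dat <- data.frame(.y = values, .group = g)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    covariates[] <- lapply(covariates, function(col) {
      if (is.character(col)) factor(col) else col
    })
    dat <- cbind(dat, covariates)
  }
  fit <- stats::lm(.y ~ ., data = dat)
  cf <- coef(fit)
  if (is.na(cf[".group"])) {
    stop("group indicator is collinear with the covariates", call. = FALSE)
  }
  sm <- summary(fit)$coefficients
  list(t = unname(sm[".group", "t value"]),
       df = fit$df.residual,
       p = unname(sm[".group", "Pr(>|t|)"]),
       estimate = unname(cf[".group"]))
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjusted p-values, monotone in rank order and capped at 1.
#'
#' @param p_values numeric vector of p-values, each between 0 and 1.
#' @return adjusted p-values in the input order.
#' @export
fdr_adjust <- function(p_values) {
  if (any(!is.finite(p_values)) || any(p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  p.adjust(p_values, method = "BH")
}

#' Jonckheere-Terpstra test for an ordered group trend
#'
#' Tests for a monotone increase of a feature across ordered groups. The
#' statistic is the sum of pairwise Mann-Whitney counts over ordered group
#' pairs, with half credit for ties. Three p-value modes: exact null
#' distribution via convolution of Mann-Whitney distributions (tie-free
#' data), exact enumeration of group assignments (small tied samples), and
#' the tie-corrected normal approximation. `"auto"` picks the exact modes for
#' small samples and the asymptotic mode otherwise; fully tied data return
#' z = 0, p = 0.5 by convention.
#'
#' @param values numeric feature values.
#' @param groups group labels aligned with `values`.
#' @param ordering character vector of group labels from lowest to highest
#'   expected value (e.g. controls first, long-term drinkers last).
#' @param method `"auto"`, `"exact"` or `"asymptotic"`.
#' @return list of class `bt_jt`: `jt`, `jt_max`, `z`, `p` (one-sided, for
#'   increase along `ordering`), `method`, `ordering`, `n_groups`.
#' @export
jt_test <- function(values, groups, ordering = sort(unique(as.character(groups))),
                    method = c("auto", "exact", "asymptotic")) {
  method <- match.arg(method)
  g <- factor(as.character(groups), levels = ordering)
  if (anyNA(g)) stop("groups contain labels not in `ordering`", call. = FALSE)
  ng <- table(g)
  if (any(ng == 0)) {
    stop("empty group(s): ", paste(names(ng)[ng == 0], collapse = ", "),
         call. = FALSE)
  }
  k <- nlevels(g)
  vals <- split(values, g)
  jt <- 0
  for (a in seq_len(k - 1)) {
    for (b in (a + 1):k) {
      jt <- jt + sum(outer(vals[[a]], vals[[b]], "<")) +
        0.5 * sum(outer(vals[[a]], vals[[b]], "=="))
    }
  }
  n <- length(values)
  jt_max <- (n^2 - sum(ng^2)) / 2
  mean_jt <- jt_max / 2
  ties <- table(values)
  has_ties <- any(ties > 1)
  # tie-corrected variance (Kendall-type decomposition)
  t_j <- as.numeric(ties); n_g <- as.numeric(ng)
  A <- n * (n - 1) * (2 * n + 5) -
    sum(n_g * (n_g - 1) * (2 * n_g + 5)) -
    sum(t_j * (t_j - 1) * (2 * t_j + 5))
  B <- sum(n_g * (n_g - 1) * (n_g - 2)) * sum(t_j * (t_j - 1) * (t_j - 2))
  C <- sum(n_g * (n_g - 1)) * sum(t_j * (t_j - 1))
  v <- A / 72 +
    (if (n > 2) B / (36 * n * (n - 1) * (n - 2)) else 0) +
    C / (8 * n * (n - 1))
  z <- if (v > 0) (jt - mean_jt) / sqrt(v) else 0

  use <- method
  if (method == "auto") {
    use <- if (!has_ties && n <= 40) "exact"
    else if (has_ties && n <= 12) "exact"
    else "asymptotic"
  }
  if (use == "exact") {
    p <- if (!has_ties) {
      if (n > 60) stop("exact convolution limited to n <= 60", call. = FALSE)
      jt_exact_convolution_p(jt, n_g)
    } else {
      if (n > 14) {
        stop("exact enumeration with ties limited to n <= 14", call. = FALSE)
      }
      jt_exact_enumeration_p(values, n_g, jt)
    }
  } else {
    p <- if (v > 0) pnorm(z, lower.tail = FALSE) else 0.5
  }
  structure(list(jt = jt, jt_max = jt_max, z = z, p = p, method = use,
                 ordering = ordering, n_groups = n_g),
            class = "bt_jt")
}

# Exact upper-tail p for tie-free data. Under H0 the statistic decomposes
# into independent Mann-Whitney statistics of each group against the pool of
# earlier groups, so the null pmf is the convolution of dwilcox pmfs.
jt_exact_convolution_p <- function(jt_obs, n_g) {
  dist <- 1
  cum <- n_g[1]
  for (k in 2:length(n_g)) {
    dk <- dwilcox(0:(cum * n_g[k]), cum, n_g[k])
    new <- numeric(length(dist) + length(dk) - 1)
    for (i in seq_along(dk)) {
      idx <- i:(i + length(dist) - 1)
      new[idx] <- new[idx] + dist * dk[i]
    }
    dist <- new
    cum <- cum + n_g[k]
  }
  support <- seq_along(dist) - 1
  sum(dist[support >= jt_obs - 1e-9])
}

# Exact p by enumerating all distinct assignments of the observed values to
# the ordered groups (handles ties); feasible for small total n.
jt_exact_enumeration_p <- function(values, n_g, jt_obs) {
  stats <- jt_all_assignment_stats(values, n_g)
  mean(stats >= jt_obs - 1e-9)
}

jt_all_assignment_stats <- function(values, n_g) {
  n <- length(values)
  recurse <- function(remaining_idx, sizes) {
    if (length(sizes) == 1) {
      return(list(list(split = list(remaining_idx))))
    }
    out <- list()
    picks <- utils::combn(remaining_idx, sizes[1], simplify = FALSE)
    for (p in picks) {
      rest <- recurse(setdiff(remaining_idx, p), sizes[-1])
      for (r in rest) out[[length(out) + 1]] <- list(split = c(list(p), r$split))
    }
    out
  }
  assignments <- recurse(seq_len(n), n_g)
  vapply(assignments, function(a) {
    vals <- lapply(a$split, function(ix) values[ix])
    jt <- 0
    k <- length(vals)
    for (i in seq_len(k - 1)) {
      for (j in (i + 1):k) {
        jt <- jt + sum(outer(vals[[i]], vals[[j]], "<")) +
          0.5 * sum(outer(vals[[i]], vals[[j]], "=="))
      }
    }
    jt
  }, numeric(1))
}

#' Trend filter: retain features consistent with the onset-ordered hypothesis
#'
#' Applies the Jonckheere-Terpstra test to each candidate feature across the
#' ordered groups, in the direction in which the feature deviates from
#' controls (features expected to decrease in drinkers are negated so one
#' code path serves both directions). Features with one-sided trend p below
#' `alpha` are retained.
#'
#' @param scores data.frame of candidate features (summary scores,
#'   personality scores), one row per subject.
#' @param groups group labels.
#' @param ordering group labels from lowest to highest expected deviation,
#'   default `control_I`, `control_II`, `short_term`, `medium_term`,
#'   `long_term`.
#' @param directions optional named vector (`"increased"`/`"decreased"`) per
#'   feature; by default inferred from the sign of the pooled
#'   drinkers-minus-controls mean difference.
#' @param alpha one-sided significance cut (default 0.05).
#' @param covariates optional covariate data.frame; features are residualized
#'   before testing.
#' @return data.frame: `feature`, `direction`, `jt`, `z`, `p`, `retained`.
#' @export
trend_select <- function(scores, groups,
                         ordering = c("control_I", "control_II", "short_term",
                                      "medium_term", "long_term"),
                         directions = NULL, alpha = 0.05,
                         covariates = NULL) {
  scores <- as.data.frame(scores)
  if (!is.null(covariates)) {
    scores <- as.data.frame(residualize(scores, covariates)$residuals)
  }
  is_drinker <- groups %in% c("long_term", "medium_term", "short_term")
  out <- lapply(names(scores), function(f) {
    v <- scores[[f]]
    dir_f <- directions[[f]] %||%
      (if (mean(v[is_drinker]) >= mean(v[!is_drinker])) "increased"
       else "decreased")
    vv <- if (dir_f == "decreased") -v else v
    res <- jt_test(vv, groups, ordering = ordering, method = "asymptotic")
    data.frame(feature = f, direction = dir_f, jt = res$jt, z = res$z,
               p = res$p, retained = res$p < alpha)
  })
  do.call(rbind, out)
}
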