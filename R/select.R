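#' Lasso-logistic selection of discriminative connectivity links
#'
#' Fits an L1-penalized logistic regression of drinker status (coded 1)
#' on the link matrix and returns the links with non-zero coefficients at
#' the chosen penalty, with the coefficient sign (positive = increased in
#' drinkers). Columns are standardized internally on the data supplied, so
#' calling this on a training fold never uses held-out subjects.
#'
#' @param x subjects x links numeric matrix.
#' @param y binary labels (1 = drinker).
#' @param lambda optional fixed penalty. If NULL the penalty is chosen by
#'   cross-validated deviance on `x` (see `rule`).
#' @param rule `"1se"` (default; sparsest penalty within one standard error
#'   of the deviance minimum) or `"min"`.
#' @param nfolds folds for the internal cross-validation.
#' @param seed seed for the internal fold assignment.
#' @return data.frame with columns `feature` (column index) and `sign`
#'   (+1/-1); the penalty used is attached as attribute `"lambda"`.
#' @export
lasso_select_links <- function(x, y, lambda = NULL, rule = c("1se", "min"),
                               nfolds = 10, seed = NULL) {
  rule <- match.arg(rule)
  y <- as.numeric(y)
  if (length(unique(y)) < 2) {
    stop("labels must contain both classes", call. = FALSE)
  }
  x <- as.matrix(x)
  if (is.null(lambda)) {
    foldid <- with_seed(seed, sample(rep_len(seq_len(nfolds), nrow(x))))
    cv <- glmnet::cv.glmnet(x, y, family = "binomial", foldid = foldid,
                            standardize = TRUE, nlambda = 60,
                            lambda.min.ratio = 0.02)
    lambda <- if (rule == "1se") cv$lambda.1se else cv$lambda.min
    fit <- cv$glmnet.fit
    cf <- coef(fit, s = lambda, exact = FALSE)
  } else {
    # short warm-start path down to the requested penalty
    path <- lambda * c(4, 2, 1)
    fit <- glmnet::glmnet(x, y, family = "binomial", lambda = path,
                          standardize = TRUE)
    cf <- coef(fit, s = lambda, exact = FALSE)
  }
  cf <- as.numeric(cf)[-1]
  nz <- which(cf != 0)
  out <- data.frame(feature = nz, sign = sign(cf[nz]))
  attr(out, "lambda") <- lambda
  out
}

#' Chi-squared selection of SNPs with group-dependent carrier frequency
#'
#' Screens binary mutation indicators with a 2x2 chi-squared test (no
#' continuity correction) of carrier frequency in drinkers vs controls.
#' Zero-variance SNPs are skipped with a log message.
#'
#' @param genotypes subjects x SNPs binary matrix.
#' @param y binary labels (1 = drinker).
#' @param alpha significance level for selection (default 0.001).
#' @param verbose emit a message when zero-variance SNPs are skipped.
#' @return data.frame of selected SNPs: `feature`, `chi2`, `p`, `role`
#'   (`risk` if carrier frequency is higher in drinkers, else `protective`);
#'   skipped column indices in attribute `"skipped"`.
#' @export
chi2_select_snps <- function(genotypes, y, alpha = 0.001, verbose = FALSE) {
  g <- as.matrix(genotypes)
  y <- as.numeric(y)
  if (length(unique(y)) < 2) {
    stop("labels must contain both classes", call. = FALSE)
  }
  n1 <- sum(y == 1); n0 <- sum(y == 0); n <- n1 + n0
  a <- colSums(g[y == 1, , drop = FALSE])   # carriers among drinkers
  c0 <- colSums(g[y == 0, , drop = FALSE])  # carriers among controls
  tot <- a + c0
  skipped <- which(tot == 0 | tot == n)
  b <- n1 - a; d <- n0 - c0
  chi2 <- n * (a * d - b * c0)^2 /
    (pmax(tot, 1) * pmax(n - tot, 1) * n1 * n0)
  p <- pchisq(chi2, df = 1, lower.tail = FALSE)
  keep <- setdiff(which(p < alpha), skipped)
  if (verbose && length(skipped)) {
    message("skipping ", length(skipped), " zero-variance SNP(s)")
  }
  out <- data.frame(feature = keep, chi2 = chi2[keep], p = p[keep],
                    role = ifelse(a[keep] / n1 > c0[keep] / n0, "risk",
                                  "protective"),
                    row.names = NULL)
  attr(out, "skipped") <- skipped
  out
}

#' Leave-one-out stability selection
#'
#' Runs a deterministic feature selector on every leave-one-out subsample and
#' retains the features selected in strictly more than `retention_threshold`
#' of the n iterations. The per-feature direction is the majority sign across
#' iterations; features whose sign is exactly tied are dropped from the
#' retained set, since an inconsistent direction contradicts the signed
#' summary-score semantics downstream.
#'
#' @param selector function(data, labels) returning a data.frame with columns
#'   `feature` (column index) and `sign` (+1/-1).
#' @param data subjects x features matrix.
#' @param labels binary labels aligned with `data` rows.
#' @param retention_threshold retention cut on the selection frequency
#'   (strict inequality; default 0.9).
#' @return list of class `bt_stability`: `table` (data.frame feature,
#'   frequency, direction, retained), `retained` (data.frame feature,
#'   direction), `n_iterations`.
#' @export
loo_stability <- function(selector, data, labels, retention_threshold = 0.9) {
  data <- as.matrix(data)
  n <- nrow(data)
  counts <- numeric(ncol(data))
  sign_sum <- numeric(ncol(data))
  for (i in seq_len(n)) {
    sel <- tryCatch(selector(data[-i, , drop = FALSE], labels[-i]),
                    error = function(e) {
                      stop("selector failed in fold ", i, ": ",
                           conditionMessage(e), call. = FALSE)
                    })
    counts[sel$feature] <- counts[sel$feature] + 1
    sign_sum[sel$feature] <- sign_sum[sel$feature] + sel$sign
  }
  stability_from_tallies(counts, sign_sum, n, retention_threshold)
}

stability_from_tallies <- function(counts, sign_sum, n, retention_threshold) {
  freq <- counts / n
  direction <- ifelse(sign_sum > 0, "increased",
                      ifelse(sign_sum < 0, "decreased", NA))
  seen <- which(counts > 0)
  tab <- data.frame(feature = seen, frequency = freq[seen],
                    direction = direction[seen],
                    retained = freq[seen] > retention_threshold &
                      !is.na(direction[seen]),
                    row.names = NULL)
  structure(list(table = tab,
                 retained = tab[tab$retained, c("feature", "direction")],
                 n_iterations = n),
            class = "bt_stability")
}

#' Collapse retained features into per-subject summary scores
#'
#' iFC / dFC are the sums of a subject's connectivity values over the
#' retained increased / decreased links; rSNP / pSNP count the mutations the
#' subject carries over the retained risk / protective SNPs. An empty
#' retained set yields a zero score, flagged in attribute `"empty_scores"`.
#'
#' @param connectivity subjects x links matrix (typically covariate-adjusted).
#' @param genotypes subjects x SNPs binary matrix.
#' @param retained_links data.frame(feature, direction in
#'   increased/decreased).
#' @param retained_snps data.frame(feature, role in risk/protective).
#' @return data.frame with columns `iFC`, `dFC`, `rSNP`, `pSNP`.
#' @export
summary_scores <- function(connectivity, genotypes, retained_links,
                           retained_snps) {
  connectivity <- as.matrix(connectivity)
  genotypes <- as.matrix(genotypes)
  check_feats <- function(idx, p, what) {
    bad <- idx[idx < 1 | idx > p]
    if (length(bad)) {
      stop("retained ", what, " absent from data: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  inc <- retained_links$feature[retained_links$direction == "increased"]
  dec <- retained_links$feature[retained_links$direction == "decreased"]
  rsk <- retained_snps$feature[retained_snps$role %in% c("risk", "increased")]
  prt <- retained_snps$feature[retained_snps$role %in%
                                 c("protective", "decreased")]
  check_feats(c(inc, dec), ncol(connectivity), "link(s)")
  check_feats(c(rsk, prt), ncol(genotypes), "SNP(s)")
  sum_over <- function(m, idx) {
    if (length(idx) == 0) numeric(nrow(m)) else
      rowSums(m[, idx, drop = FALSE])
  }
  out <- data.frame(iFC = sum_over(connectivity, inc),
                    dFC = sum_over(connectivity, dec),
                    rSNP = sum_over(genotypes, rsk),
                    pSNP = sum_over(genotypes, prt))
  attr(out, "empty_scores") <- c(iFC = length(inc) == 0,
                                 dFC = length(dec) == 0,
                                 rSNP = length(rsk) == 0,
                                 pSNP = length(prt) == 0)
  out
}
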