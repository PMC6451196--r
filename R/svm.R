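#' Train a margin classifier (support-vector machine)
#'
#' Thin wrapper around a libsvm C-classification fit that (i) standardizes
#' features with training-estimated constants, (ii) applies class weights
#' proportional to inverse class prevalence so unbalanced drinker/control
#' samples do not degenerate to majority prediction, and (iii) normalizes the
#' decision-function sign so a greater value always means more likely to be
#' a case (label 1). Linear fits are stored in primal form (weights +
#' intercept), which makes them exactly serializable.
#'
#' @param x subjects x features numeric matrix (finite).
#' @param y binary labels, 1 = case/drinker.
#' @param kernel `"linear"` (default) or `"radial"`.
#' @param cost soft-margin cost parameter C.
#' @param class_weights `"inverse"` (default) or `"none"`.
#' @param gamma RBF kernel width (default 1/ncol(x)).
#' @return object of class `bt_margin`, with a [predict.bt_margin()] method.
#' @export
train_margin_classifier <- function(x, y, kernel = c("linear", "radial"),
                                    cost = 1,
                                    class_weights = c("inverse", "none"),
                                    gamma = NULL) {
  kernel <- match.arg(kernel)
  class_weights <- match.arg(class_weights)
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (any(!is.finite(x))) stop("features must be finite", call. = FALSE)
  y <- as.integer(as.numeric(y) > 0)
  if (length(unique(y)) < 2) {
    stop("both classes must be present", call. = FALSE)
  }
  center <- colMeans(x)
  scale_ <- apply(x, 2, sd)
  scale_[scale_ == 0 | !is.finite(scale_)] <- 1
  xs <- sweep(sweep(x, 2, center), 2, scale_, "/")
  yf <- factor(y, levels = c(0, 1))
  wts <- if (class_weights == "inverse") {
    tb <- table(yf)
    setNames(as.numeric(length(y) / (2 * tb)), names(tb))
  } else NULL
  fit <- e1071::svm(xs, yf, kernel = kernel, cost = cost, scale = FALSE,
                    gamma = gamma %||% (1 / max(1, ncol(xs))),
                    class.weights = wts)
  dv <- attr(predict(fit, xs, decision.values = TRUE), "decision.values")[, 1]
  flip <- if (mean(dv[y == 1]) < mean(dv[y == 0])) -1 else 1
  obj <- list(kernel = kernel, center = center, scale = scale_, cost = cost,
              flip = flip)
  if (kernel == "linear") {
    obj$w <- flip * drop(crossprod(fit$coefs, fit$SV))
    obj$b <- flip * (-fit$rho)
  } else {
    obj$SV <- fit$SV
    obj$coefs <- flip * drop(fit$coefs)
    obj$b <- flip * (-fit$rho)
    obj$gamma <- fit$gamma
  }
  class(obj) <- "bt_margin"
  obj
}

#' Decision values or class predictions from a margin classifier
#'
#' @param object a `bt_margin` fit.
#' @param newdata subjects x features matrix on the original scale.
#' @param type `"decision"` (signed score; positive = case) or `"class"`
#'   (0/1).
#' @param ... unused.
#' @return numeric vector of decision values or 0/1 predictions.
#' @export
predict.bt_margin <- function(object, newdata, type = c("decision", "class"),
                              ...) {
  type <- match.arg(type)
  x <- as.matrix(newdata)
  storage.mode(x) <- "double"
  xs <- sweep(sweep(x, 2, object$center), 2, object$scale, "/")
  dec <- if (object$kernel == "linear") {
    drop(xs %*% object$w) + object$b
  } else {
    k <- exp(-object$gamma *
               (outer(rowSums(xs^2), rowSums(object$SV^2), "+") -
                  2 * tcrossprod(xs, object$SV)))
    drop(k %*% object$coefs) + object$b
  }
  if (type == "decision") dec else as.integer(dec > 0)
}

#' Rank-based AUC of decision values (midrank tie convention)
#'
#' Equals the Mann-Whitney U statistic divided by n1*n0; constant decision
#' values give 0.5.
#'
#' @param decision_values numeric scores, larger = more case-like.
#' @param labels binary labels (1 = case).
#' @return AUC between 0 and 1.
#' @export
rank_auc <- function(decision_values, labels) {
  y <- as.numeric(labels) > 0
  n1 <- sum(y); n0 <- sum(!y)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(decision_values)
  (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Leave-one-out evaluation of a classifier specification
#'
#' Retrains the supplied trainer on every leave-one-out fold (so any
#' standardization or selection inside the trainer is re-estimated per fold)
#' and scores the held-out subject. Folds whose training set collapses to a
#' single class are skipped with a warning and reported.
#'
#' @param x subjects x features matrix.
#' @param y binary labels (1 = case).
#' @param trainer function(x, y) returning an object whose `predict` yields
#'   decision values; default trains a linear margin classifier.
#' @return list: `accuracy`, `auc`, `decision_values`, `skipped` (fold ids).
#' @export
loo_evaluate <- function(x, y,
                         trainer = function(x, y)
                           train_margin_classifier(x, y)) {
  x <- as.matrix(x)
  y <- as.integer(as.numeric(y) > 0)
  n <- nrow(x)
  if (n < 4) stop("need at least 4 subjects", call. = FALSE)
  dv <- rep(NA_real_, n)
  skipped <- integer(0)
  for (i in seq_len(n)) {
    if (length(unique(y[-i])) < 2) {
      skipped <- c(skipped, i)
      next
    }
    fit <- trainer(x[-i, , drop = FALSE], y[-i])
    dv[i] <- predict(fit, x[i, , drop = FALSE])[1]
  }
  if (length(skipped)) {
    warning("skipped single-class fold(s): ",
            paste(skipped, collapse = ", "), call. = FALSE)
  }
  ok <- !is.na(dv)
  list(accuracy = mean((dv[ok] > 0) == (y[ok] == 1)),
       auc = rank_auc(dv[ok], y[ok]),
       decision_values = dv, skipped = skipped)
}

#' Continuous (category-free) net reclassification improvement
#'
#' Quantifies how adding a feature domain moves per-subject scores relative
#' to a reduced model: NRI = (P(up|case) - P(down|case)) +
#' (P(down|control) - P(up|control)), where "up" means the full-model score
#' exceeds the reduced-model score. The z statistic uses the standard
#' asymptotic variance 4/n_case + 4/n_control; ties (no movement) count
#' neither up nor down, and a fully tied comparison returns NRI = 0, p = 1.
#'
#' @param full per-subject scores from the model including the domain.
#' @param reduced scores from the model without it.
#' @param labels binary labels (1 = case).
#' @return list of class `bt_nri`: `nri`, `z`, `p`, `n`, `n_case`,
#'   `n_control`.
#' @export
nri_domain_contribution <- function(full, reduced, labels) {
  y <- as.numeric(labels) > 0
  stopifnot(length(full) == length(reduced), length(full) == length(y))
  up <- full > reduced
  down <- full < reduced
  n1 <- sum(y); n0 <- sum(!y)
  nri <- (mean(up[y]) - mean(down[y])) + (mean(down[!y]) - mean(up[!y]))
  if (!any(up | down)) {
    return(structure(list(nri = 0, z = 0, p = 1, n = n1 + n0,
                          n_case = n1, n_control = n0), class = "bt_nri"))
  }
  z <- nri / sqrt(4 / n1 + 4 / n0)
  structure(list(nri = nri, z = z, p = 2 * pnorm(-abs(z)), n = n1 + n0,
                 n_case = n1, n_control = n0), class = "bt_nri")
}
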