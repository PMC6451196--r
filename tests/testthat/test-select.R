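test_that("lasso picks a single strongly planted link, with the right sign", {
  withr::with_seed(8, {
    n <- 60
    x <- matrix(rnorm(n * 100, 0.2, 0.15), n, 100)
    y <- rep(c(0, 1), each = n / 2)
    x[y == 1, 37] <- x[y == 1, 37] + 0.5  # very large effect
  })
  sel <- lasso_select_links(x, y, rule = "1se", seed = 1)
  expect_true(37 %in% sel$feature)
  expect_identical(sel$sign[sel$feature == 37], 1)
  # at a strong penalty the selected set collapses to the planted edge alone
  strong <- lasso_select_links(x, y, lambda = 0.15)
  expect_identical(strong$feature, 37L)
  expect_identical(strong$sign, 1)
  # oracle: exhaustive single-edge logistic fits rank edge 37 first
  dev <- vapply(seq_len(ncol(x)), function(j)
    stats::glm(y ~ x[, j], family = stats::binomial)$deviance, numeric(1))
  expect_identical(which.min(dev), 37L)
})

test_that("labels independent of all edges at maximal penalty select nothing", {
  withr::with_seed(9, {
    x <- matrix(rnorm(50 * 40), 50, 40)
    y <- rep(c(0, 1), 25)
  })
  sel <- lasso_select_links(x, y, lambda = 10)
  expect_identical(nrow(sel), 0L)
  expect_error(lasso_select_links(x, rep(1, 50)), "both classes")
})

test_that("chi-squared screen matches the hand-computed 2x2 example", {
  # drinkers 30 carriers / 10 non, controls 10 / 30 -> chi2 = 20 exactly
  g <- cbind(c(rep(1, 30), rep(0, 10), rep(1, 10), rep(0, 30)))
  y <- rep(c(1, 0), each = 40)
  sel <- chi2_select_snps(g, y, alpha = 0.001)
  expect_equal(sel$chi2, 20, tolerance = 1e-12)
  expect_identical(sel$role, "risk")
  # same frequencies in both groups -> not selected
  g0 <- cbind(rep(c(1, 0), 40))
  expect_identical(nrow(chi2_select_snps(g0, y, alpha = 0.5)), 0L)
  # mutation concentrated in controls -> protective
  g2 <- cbind(c(rep(0, 35), rep(1, 5), rep(1, 30), rep(0, 10)))
  sel2 <- chi2_select_snps(g2, y, alpha = 0.001)
  expect_identical(sel2$role, "protective")
})

test_that("zero-variance SNPs are skipped and logged", {
  g <- cbind(all_zero = rep(0L, 20), informative = rep(c(1L, 0L), each = 10))
  y <- rep(c(1, 0), each = 10)
  expect_message(sel <- chi2_select_snps(g, y, alpha = 0.01, verbose = TRUE),
                 "zero-variance")
  expect_identical(unname(attr(sel, "skipped")), 1L)
  expect_identical(sel$feature, 2L)
})

test_that("stability selection retains only near-unanimous features, strictly", {
  # data column 2: five +1 then five -1 -> a selector keyed on its fold mean
  # picks feature 2 in exactly 5 of 10 folds; feature 3 is keyed on subject 1
  # and appears in 9 of 10 folds (frequency 0.9, NOT retained: strict rule)
  dat <- cbind(rnorm(10), rep(c(1, -1), each = 5), c(9, 1:8, 0))
  selector <- function(d, l) {
    feats <- 1L
    if (mean(d[, 2]) > 0) feats <- c(feats, 2L)
    if (any(d[, 3] == 9)) feats <- c(feats, 3L)
    data.frame(feature = feats, sign = 1)
  }
  st <- loo_stability(selector, dat, rep(c(0, 1), 5))
  tab <- st$table
  expect_equal(tab$frequency[tab$feature == 1], 1.0)
  expect_equal(tab$frequency[tab$feature == 2], 0.5)
  expect_equal(tab$frequency[tab$feature == 3], 0.9)
  expect_identical(st$retained$feature, 1L)
})

test_that("stability frequencies are invariant to subject order", {
  withr::with_seed(3, {
    dat <- matrix(rnorm(20 * 6), 20, 6)
    y <- rep(c(0, 1), 10)
    perm <- sample(20)
  })
  selector <- function(d, l) {
    cors <- abs(apply(d, 2, function(col) stats::cor(col, l)))
    data.frame(feature = which(cors > 0.3),
               sign = sign(apply(d, 2, function(col)
                 stats::cor(col, l)))[cors > 0.3])
  }
  a <- loo_stability(selector, dat, y)$table
  b <- loo_stability(selector, dat[perm, ], y[perm])$table
  expect_equal(a[order(a$feature), ], b[order(b$feature), ],
               ignore_attr = TRUE)
})

test_that("features with tied direction are dropped from the retained set", {
  dat <- matrix(rnorm(10 * 2), 10, 2)
  selector <- local({
    k <- 0
    function(d, l) {
      k <<- k + 1
      data.frame(feature = 1L, sign = if (k %% 2) 1 else -1)
    }
  })
  st <- loo_stability(selector, dat, rep(c(0, 1), 5))
  expect_identical(nrow(st$retained), 0L)
  expect_equal(st$table$frequency[st$table$feature == 1], 1.0)
})

test_that("selector failures abort naming the fold", {
  selector <- function(d, l) if (nrow(d) == 9) stop("boom") else
    data.frame(feature = 1L, sign = 1)
  expect_error(loo_stability(selector, matrix(0, 10, 1), rep(0:1, 5)),
               "fold 1")
})

test_that("summary scores add connectivity and count mutations", {
  conn <- rbind(c(0.5, 0.5, 0.5, -0.2), c(0.1, 0.2, 0.3, 0.4))
  geno <- rbind(c(1L, 0L, 1L, 0L, 0L, 1L), c(1L, 1L, 1L, 1L, 1L, 0L))
  links <- data.frame(feature = c(1, 2, 3, 4),
                      direction = c("increased", "increased", "increased",
                                    "decreased"))
  snps <- data.frame(feature = 1:6,
                     role = rep(c("risk", "protective"), each = 3))
  sc <- summary_scores(conn, geno, links, snps)
  expect_equal(sc$iFC, c(1.5, 0.6))
  expect_equal(sc$dFC, c(-0.2, 0.4))
  expect_identical(sc$rSNP, c(2, 3))
  expect_identical(sc$pSNP, c(1, 2))
})

test_that("summary scores are linear in connectivity and flag empty sets", {
  withr::with_seed(5, {
    a <- matrix(rnorm(8), 2, 4)
    b <- matrix(rnorm(8), 2, 4)
  })
  links <- data.frame(feature = c(1, 3), direction = "increased")
  snps <- data.frame(feature = integer(0), role = character(0))
  geno <- matrix(0L, 2, 2)
  s_ab <- summary_scores(a + b, geno, links, snps)
  s_a <- summary_scores(a, geno, links, snps)
  s_b <- summary_scores(b, geno, links, snps)
  expect_equal(s_ab$iFC, s_a$iFC + s_b$iFC, tolerance = 1e-12)
  expect_true(attr(s_a, "empty_scores")[["rSNP"]])
  expect_identical(s_a$rSNP, c(0, 0))
  expect_error(summary_scores(a, geno,
                              data.frame(feature = 99,
                                         direction = "increased"), snps),
               "99")
})
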