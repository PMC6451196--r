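test_that("default configuration reproduces the study's group bookkeeping", {
  co <- generate_cohort(small_sim_config(seed = 1))
  ph <- co$phenotypes
  expect_identical(nrow(ph), 212L)
  expect_identical(as.integer(table(ph$group)[c("long_term", "medium_term",
                                                "short_term", "control_I",
                                                "control_II")]),
                   c(54L, 52L, 41L, 44L, 21L))
  expect_identical(nrow(co$connectivity), 212L)
  expect_identical(nrow(co$genotypes), 212L)
  expect_true(all(is.finite(co$connectivity)))
  expect_true(all(co$genotypes %in% 0:1))
  # every subject has banded ESPAD records at all three waves
  espad_cols <- c(outer(c("binge_", "occasion_", "cannabis_", "smoking_"),
                        c(14, 16, 19), paste0))
  expect_false(anyNA(ph[, espad_cols]))
  expect_true(all(as.matrix(ph[, espad_cols]) %in% 0:6))
})

test_that("binge trajectories are consistent with each group's onset wave", {
  co <- generate_cohort(small_sim_config(seed = 3))
  ph <- co$phenotypes
  thr <- co$truth$onset_threshold
  expect_true(all(ph$binge_14[ph$group == "long_term"] >= thr))
  expect_true(all(ph$binge_14[ph$group == "medium_term"] < thr))
  expect_true(all(ph$binge_16[ph$group == "medium_term"] >= thr))
  expect_true(all(ph$binge_16[ph$group == "short_term"] < thr))
  expect_true(all(ph$binge_19[ph$group == "short_term"] >= thr))
  ctrl <- ph$group %in% c("control_I", "control_II")
  expect_true(all(ph[ctrl, c("binge_14", "binge_16", "binge_19")] == 0))
})

test_that("identical seeds give identical cohorts; different seeds differ", {
  a <- generate_cohort(small_sim_config(seed = 11))
  b <- generate_cohort(small_sim_config(seed = 11))
  expect_identical(a, b)
  c <- generate_cohort(small_sim_config(seed = 12))
  expect_false(identical(a$connectivity, c$connectivity))
})

test_that("invalid configurations are rejected with all problems reported", {
  expect_error(small_sim_config(group_sizes = c(long_term = -1,
                                                medium_term = 52,
                                                short_term = 41,
                                                control_I = 44,
                                                control_II = 21)),
               "non-negative")
  expect_error(small_sim_config(trend_gradient = c(long_term = 0.3,
                                                   medium_term = 0.6,
                                                   short_term = 1)),
               "non-increasing")
  expect_error(sim_config(n_regions = 30, n_snps = 60,
                          planted_links = data.frame(edge = 9999,
                                                     direction = "increased",
                                                     effect = 0.1)),
               "out of range")
})

test_that("null configuration leaves no detectable group differences", {
  n_sig <- 0L
  for (s in 1:40) {
    co <- generate_cohort(null_sim_config(seed = s, n_regions = 10,
                                          n_snps = 20))
    ph <- co$phenotypes
    drinker <- ph$group == "long_term"
    ctrl <- ph$group == "control_I"
    for (v in list(co$connectivity[, 1], ph$surps_impulsivity_19,
                   ph$neo_neuroticism)) {
      p <- stats::t.test(v[drinker], v[ctrl])$p.value
      if (p < 0.001) n_sig <- n_sig + 1L
    }
  }
  expect_lte(n_sig, 2L)  # 120 null tests at alpha = 0.001
})

test_that("planted increased links have onset-graded group means", {
  ok <- 0L
  n_rep <- 60L
  for (s in seq_len(n_rep)) {
    co <- generate_cohort(small_sim_config(seed = 1000 + s))
    edge <- co$truth$planted_links$edge[1]
    m <- tapply(co$connectivity[, edge], co$phenotypes$group, mean)
    ctrl <- mean(co$connectivity[co$phenotypes$group %in%
                                   c("control_I", "control_II"), edge])
    if (m["long_term"] >= m["medium_term"] &&
        m["medium_term"] >= m["short_term"] && m["short_term"] >= ctrl) {
      ok <- ok + 1L
    }
  }
  expect_gte(ok / n_rep, 0.95)
})

test_that("impulsivity declines at the control rate pre-onset and slower after", {
  co <- generate_cohort(small_sim_config(seed = 21))
  ph <- co$phenotypes
  d1 <- ph$surps_impulsivity_16 - ph$surps_impulsivity_14
  d2 <- ph$surps_impulsivity_19 - ph$surps_impulsivity_16
  ctrl <- ph$group %in% c("control_I", "control_II")
  # controls: the two period changes share the same mean
  expect_gt(stats::t.test(d1[ctrl], d2[ctrl], paired = TRUE)$p.value, 0.01)
  # short-term drinkers: smaller improvement (less negative change) post-onset
  short <- ph$group == "short_term"
  expect_gt(mean(d2[short]), mean(d1[short]))
  expect_lt(stats::t.test(d2[short], d1[short], paired = TRUE)$p.value, 0.01)
})

test_that("cohorts round-trip losslessly through write/read", {
  co <- generate_cohort(small_sim_config(seed = 7))
  d <- withr::local_tempdir()
  write_cohort(co, d, genotype_format = "vcf")
  co2 <- read_cohort(d)
  expect_identical(unname(co$connectivity), unname(co2$connectivity))
  expect_identical(matrix(as.integer(co$genotypes), nrow(co$genotypes)),
                   matrix(as.integer(co2$genotypes), nrow(co2$genotypes)))
  ph <- co$phenotypes
  expect_equal(ph, co2$phenotypes, tolerance = 0, ignore_attr = TRUE)
  expect_identical(co$edges, co2$edges)
  # minimal VCF: header + one row per SNP
  vcf <- readLines(file.path(d, "genotypes.vcf"))
  expect_identical(length(vcf), 3L + ncol(co$genotypes))
  expect_match(vcf[1], "VCFv4.2")
})

test_that("empty cohorts write valid headers with zero data rows", {
  cfg <- small_sim_config(seed = 1)
  cfg$group_sizes[] <- 0
  co <- generate_cohort(cfg)
  expect_identical(nrow(co$phenotypes), 0L)
  d <- withr::local_tempdir()
  write_cohort(co, d)
  co2 <- read_cohort(d)
  expect_identical(nrow(co2$phenotypes), 0L)
  expect_identical(names(co2$phenotypes), names(co$phenotypes))
})
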