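test_that("signed-rank statistic and exact p match hand values and symmetry", {
  # all-positive differences 1..5: W = 0 (min-rank-sum), p = 2/32
  res <- wilcoxon_signed_rank(c(2, 4, 6, 8, 10), c(1, 2, 3, 4, 5))
  expect_equal(res$W, 0)
  expect_equal(res$p, 2 / 32)
  expect_equal(res$method, "exact enumeration")

  # swapping the samples leaves p (and W) unchanged
  a <- c(3.2, 1.1, 5.6, 2.2, 9.1, 4.4, 0.5)
  b <- c(2.0, 1.9, 5.0, 2.9, 3.3, 4.8, 1.0)
  r1 <- wilcoxon_signed_rank(a, b)
  r2 <- wilcoxon_signed_rank(b, a)
  expect_equal(r1$p, r2$p)
  expect_equal(r1$W, r2$W)

  expect_error(wilcoxon_signed_rank(1:6, 1:6), "zero")
  expect_error(wilcoxon_signed_rank(c(1, 2, 3, 4, 5), c(1, 2, 3, 4, 6)),
               "at least 5")
  expect_error(wilcoxon_signed_rank(1:3, 1:4), "equal length")
})

test_that("exact p equals the enumeration oracle for n <= 10, ties included", {
  set.seed(37)
  for (i in 1:20) {
    n <- sample(5:10, 1)
    a <- round(rnorm(n, 1, 2), 1)
    b <- round(rnorm(n, 0, 2), 1)
    if (sum(a - b != 0) < 5) next
    expect_equal(wilcoxon_signed_rank(a, b)$p, oracle_wilcoxon_exact(a, b),
                 info = paste("draw", i))
  }
  # approximate branch stays close to the exact one just above threshold
  set.seed(38)
  a <- rnorm(14, 0.8); b <- rnorm(14)
  p_exact <- wilcoxon_signed_rank(a, b, exact_threshold = 20)$p
  p_norm <- wilcoxon_signed_rank(a, b, exact_threshold = 5)$p
  expect_lt(abs(p_exact - p_norm), 0.05)
})

test_that("univariate MANOVA equals one-way ANOVA via Wilks' lambda", {
  set.seed(41)
  tab <- data.frame(g = rep(c("u", "v"), each = 8),
                    y = c(rnorm(8, 0), rnorm(8, 1)))
  res <- manova_groups(tab, "g", "y")
  an <- anova(stats::lm(y ~ g, tab))
  lambda <- res$wilks$statistic
  n <- nrow(tab); k <- 2
  f_from_lambda <- (1 - lambda) / lambda * (n - k) / (k - 1)
  expect_equal(f_from_lambda, an$`F value`[1], tolerance = 1e-10)
  expect_equal(res$wilks$p, an$`Pr(>F)`[1], tolerance = 1e-10)

  # identical groups: p ~ 1, nothing flagged
  tab2 <- data.frame(g = rep(c("u", "v"), each = 6), y = rep(1:6, 2))
  res2 <- manova_groups(tab2, "g", "y")
  expect_gt(res2$wilks$p, 0.99)
  expect_false(any(res2$contrasts$significant))

  # guards
  expect_error(manova_groups(tab[1:8, ], "g", "y"), "at least 2 groups")
  tab3 <- rbind(tab, data.frame(g = "w", y = 5))
  expect_error(manova_groups(tab3, "g", "y"), "at least 2 observations")
  # singular within-group covariance (duplicated column)
  tab4 <- data.frame(g = rep(c("u", "v"), each = 4), y1 = rnorm(8))
  tab4$y2 <- tab4$y1
  expect_error(manova_groups(tab4, "g", c("y1", "y2")), "singular|residuals")
})

test_that("Bonferroni adjustment is correct and flags are monotone in alpha", {
  p <- c(0.001, 0.02, 0.2)
  expect_equal(bonferroni(p), pmin(1, 3 * p))
  expect_equal(bonferroni(0.5, m = 10), 1)
  co <- sample_cohort(seed = 6)
  res <- run_paper_contrasts(co$lesions, co$healthy)
  expect_true(all(res$contrasts$p_adj >= res$contrasts$p))
  res_loose <- run_paper_contrasts(co$lesions, co$healthy, alpha = 0.2)
  expect_true(all(res$contrasts$significant <= res_loose$contrasts$significant))
})

test_that("cortex vs cyst separation has power at published effect sizes", {
  # cohort drawn at the published means/SDs (n = 13 cortex, 5 cysts);
  # D_tri differs by ~15 SDs, so the contrast should flag nearly always
  hits <- 0L
  n_rep <- 50L
  for (r in seq_len(n_rep)) {
    co <- sample_cohort(n_solid = 13, n_cyst = 5, seed = 100 + r)
    cortex <- co$healthy[co$healthy$tissue == "healthy_cortex", ]
    tab <- rbind(data.frame(g = "cortex", D_tri = cortex$D_tri),
                 data.frame(g = "cyst",
                            D_tri = co$lesions$D_tri[co$lesions$type == "cyst"]))
    res <- manova_groups(tab, "g", "D_tri")
    if (all(res$contrasts$significant)) hits <- hits + 1L
  }
  expect_gte(hits / n_rep, 0.95)
})

test_that("the full published contrast grid runs and annotates", {
  co <- sample_cohort(n_solid = 13, n_cyst = 5, seed = 8)
  res <- run_paper_contrasts(co$lesions, co$healthy)
  expect_s3_class(res$contrasts, "comparison_result")
  # a-j MANOVA letters plus x, y, z Wilcoxon letters, 7 parameters each
  expect_setequal(unique(res$contrasts$letter), c(letters[1:10], "x", "y", "z"))
  expect_equal(sum(res$contrasts$letter == "a"), 7L)
  expect_named(res$significance, PARAM7)
  expect_type(res$significance, "character")
  # deterministic given the same input table
  res2 <- run_paper_contrasts(co$lesions, co$healthy)
  expect_identical(res$contrasts, res2$contrasts)
  # cyst separation on diffusivity should surface letter b (cortex vs cyst)
  expect_match(res$significance[["D_tri"]], "b")

  # cohort with only healthy tissue: only contrasts j and z/x-type survive
  empty_lesions <- co$lesions[0, ]
  w <- testthat::capture_warnings(
    res_h <- run_paper_contrasts(empty_lesions, co$healthy))
  expect_true(any(grepl("skipping", w)))
  expect_setequal(unique(res_h$contrasts$letter), c("j", "z"))
})
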