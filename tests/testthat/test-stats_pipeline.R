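test_that("fence screening removes exactly the records outside the fences", {
  # hand-computed fences for {1..9, 100}: Q1 = 3.25, Q3 = 7.75, IQR = 4.5,
  # so [-3.5, 14.5] — only 100 falls outside
  df <- data.frame(bird_id = as.character(1:10), line = "A",
                   x = c(1:9, 100))
  flt <- iqr_filter(df, traits = "x", k = 1.5)
  expect_equal(flt$removed$bird_id, "10")
  expect_equal(nrow(flt$retained), 9)
  # identical values: fences collapse onto the value, nothing removed
  same <- data.frame(bird_id = as.character(1:6), line = "A", x = 5)
  expect_equal(iqr_filter(same, "x")$n_removed, 0)
  # screening is per line
  two <- data.frame(bird_id = as.character(1:12),
                    line = rep(c("A", "B"), each = 6),
                    x = c(10, 11, 12, 13, 14, 15, 1010, 1011, 1012, 1013,
                          1014, 1015))
  expect_equal(iqr_filter(two, "x")$n_removed, 0)
  # degenerate inputs
  expect_error(iqr_filter(df[1:3, ], "x"), "at least 4")
  expect_error(iqr_filter(df, "nope"), "unknown")
  expect_error(iqr_filter(rbind(df, df), "x", k = -1e9), "every record")
})

test_that("missing trait values never flag a record", {
  df <- data.frame(bird_id = as.character(1:8), line = "A",
                   x = c(1, 2, 3, 4, 5, 6, 7, NA))
  expect_equal(iqr_filter(df, "x")$n_removed, 0)
})

test_that("the between-line test reports means, SEs and a symmetric p-value", {
  df <- data.frame(line = rep(c("A", "B"), each = 5),
                   x = c(1, 2, 3, 4, 5, 11, 12, 13, 14, 15))
  cmp <- line_ttest(df, "x")
  expect_equal(cmp$mean_1, 3)
  expect_equal(cmp$mean_2, 13)
  expect_equal(cmp$se_1, sd(1:5) / sqrt(5))
  # swapping group labels leaves the p-value unchanged
  df2 <- df; df2$line <- rep(c("B", "A"), each = 5)
  expect_equal(line_ttest(df2, "x")$p_value, cmp$p_value)
  # identical groups: t = 0, p = 1
  same <- data.frame(line = rep(c("A", "B"), each = 4), x = rep(1:4, 2))
  cmp2 <- line_ttest(same, "x")
  expect_equal(cmp2$t, 0)
  expect_equal(cmp2$p_value, 1)
  # constant, equal groups: p = 1 by convention
  const <- data.frame(line = rep(c("A", "B"), each = 4), x = 1)
  expect_equal(line_ttest(const, "x")$p_value, 1)
  # well-separated groups with tiny jitter
  sep <- data.frame(line = rep(c("A", "B"), each = 4),
                    x = c(0, 1e-9, -1e-9, 0, 1, 1 + 1e-9, 1 - 1e-9, 1))
  expect_lt(line_ttest(sep, "x")$p_value, 0.001)
})

test_that("type-I error of the Welch test sits at the nominal level", {
  set.seed(20)
  reps <- 2000
  p <- vapply(seq_len(reps), function(i) {
    df <- data.frame(line = rep(c("A", "B"), c(43, 44)), x = rnorm(87))
    line_ttest(df, "x")$p_value
  }, numeric(1))
  expect_gte(mean(p < 0.05), 0.035)
  expect_lte(mean(p < 0.05), 0.065)
})

test_that("correlation matrices are symmetric, unit-diagonal and masked", {
  set.seed(1)
  df <- data.frame(a = rnorm(20))
  df$b <- 2 * df$a                  # exact linear dependence
  df$c <- rnorm(20)
  cm <- correlation_matrix(df, alpha = 0.05)
  expect_equal(cm$r, t(cm$r))
  expect_equal(diag(cm$r), c(a = 1, b = 1, c = 1))
  expect_equal(cm$r["a", "b"], 1)
  expect_false(cm$mask["a", "b"])
  # constant trait: undefined correlation, masked with NA
  df$d <- 7
  cm2 <- suppressWarnings(correlation_matrix(df))
  expect_true(is.na(cm2$r["a", "d"]))
  expect_true(cm2$mask["a", "d"])
  # pairwise-complete handling of a missing value
  df3 <- data.frame(a = c(1, 2, 3, 4, NA), b = c(2, 4, 6, 8, 10),
                    c = c(5, 3, 1, 2, 4))
  cm3 <- correlation_matrix(df3)
  expect_equal(cm3$n["a", "b"], 4L)
  expect_equal(cm3$n["b", "c"], 5L)
  expect_equal(cm3$r["a", "b"], 1)
})

test_that("masking rejects at about the nominal rate under independence", {
  set.seed(33)
  hits <- vapply(seq_len(1000), function(i) {
    df <- data.frame(a = rnorm(44), b = rnorm(44))
    !correlation_matrix(df)$mask["a", "b"]
  }, logical(1))
  expect_gt(mean(hits), 0.029)   # 3 binomial SDs around 0.05
  expect_lt(mean(hits), 0.071)
})

test_that("the principal component summary matches a direct eigendecomposition", {
  set.seed(8)
  n <- 60
  f <- rnorm(n)
  df <- data.frame(t1 = f + rnorm(n, sd = 0.3), t2 = -f + rnorm(n, sd = 0.5),
                   t3 = rnorm(n), t4 = f + rnorm(n, sd = 1),
                   t5 = rnorm(n, sd = 2))
  pc <- pca_summary(df, standardize = TRUE)
  expect_equal(sum(pc$explained_variance), 100)
  ev <- eigen(cor(df), symmetric = TRUE)
  expect_equal(pc$explained_variance, ev$values / sum(ev$values) * 100)
  expect_equal(abs(pc$loadings), abs(ev$vectors), ignore_attr = TRUE,
               tolerance = 1e-8)
  expect_equal(crossprod(pc$loadings), diag(5), ignore_attr = TRUE)
  expect_true(all(colSums(pc$contributions) - 100 < 1e-8))
  # two perfectly correlated standardized traits: one dimension carries all
  df2 <- data.frame(a = f, b = 2 * f)
  pc2 <- suppressMessages(pca_summary(df2, standardize = TRUE))
  expect_equal(pc2$explained_variance[1], 100)
  expect_equal(pc2$rank, 1)
})

test_that("a dominant factor's variance share is recovered at scale", {
  set.seed(12)
  n <- 10000
  # five standardized traits, each = sqrt(h) * factor + sqrt(1-h) * noise:
  # dimension 1 should explain about h + (1-h)/5 of the variance
  h <- 0.6
  f <- rnorm(n)
  df <- as.data.frame(lapply(1:5, function(i) {
    sqrt(h) * f + sqrt(1 - h) * rnorm(n)
  }))
  pc <- pca_summary(df, standardize = TRUE)
  expect_lt(abs(pc$explained_variance[1] - (h + (1 - h) / 5) * 100), 1)
})

test_that("ordinary least squares fits report the right table and R-squared", {
  set.seed(5)
  n <- 44
  em <- rnorm(n, 50, 5); dbw <- rnorm(n, 1700, 100)
  y <- 5 - 0.06 * em + rnorm(n, sd = 1e-8)
  df <- data.frame(fcr = y, em = em, dbw = dbw)
  fit <- fit_performance_model(df, "fcr")
  expect_equal(fit$coefficients$estimate[fit$coefficients$term == "em"], -0.06,
               tolerance = 1e-5)
  expect_gt(fit$r_squared, 0.999999)
  expect_equal(fit$df_residual, n - 3)
  # null response: R-squared stays near its 2/(n-1) expectation
  r2 <- vapply(seq_len(200), function(i) {
    d <- data.frame(fcr = rnorm(n), em = rnorm(n), dbw = rnorm(n))
    fit_performance_model(d, "fcr")$r_squared
  }, numeric(1))
  expect_lt(abs(mean(r2) - 2 / (n - 1)), 0.02)
})

test_that("single-coefficient models obey the squared-correlation identity", {
  set.seed(6)
  n <- 44
  dc <- rnorm(n, 70, 3)
  y <- 50 * dc + rnorm(n, sd = 5)
  df <- data.frame(rfc = y, dc_dm = dc)
  fit <- fit_dc_model(df, "rfc", "dc_dm")
  expect_equal(fit$coefficients$estimate[2], 50, tolerance = 0.05)
  expect_equal(fit$r_squared, cor(y, dc)^2, tolerance = 1e-12)
  # affine rescaling of the predictor: R-squared and p invariant
  df2 <- data.frame(rfc = y, dc_dm = 10 * dc + 3)
  fit2 <- fit_dc_model(df2, "rfc", "dc_dm")
  expect_equal(fit2$r_squared, fit$r_squared, tolerance = 1e-12)
  expect_equal(fit2$coefficients$p_value[2], fit$coefficients$p_value[2],
               tolerance = 1e-9)
  expect_equal(fit2$coefficients$estimate[2], fit$coefficients$estimate[2] / 10,
               tolerance = 1e-9)
  # permutation null: the slope is significant about 5% of the time
  sig <- vapply(seq_len(200), function(i) {
    d <- data.frame(rfc = sample(y), dc_dm = dc)
    fit_dc_model(d, "rfc", "dc_dm")$coefficients$p_value[2] < 0.05
  }, logical(1))
  expect_lt(mean(sig), 0.12)
  expect_error(fit_dc_model(data.frame(rfc = y, dc_dm = 1), "rfc", "dc_dm"),
               "constant")
})
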