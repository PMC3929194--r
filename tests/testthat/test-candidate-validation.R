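test_that("group_stats reproduces the printed marbling summaries", {
  gs <- group_stats(table1_fixture())
  expect_equal(round(gs$mean[gs$group == "low"], 2), 9.54)
  expect_equal(round(gs$sem[gs$group == "low"], 2), 1.35)
  # printed per-animal values average 20.8467; the text's 20.84 was rounded
  # from unrounded measurements, so match at the printed precision
  expect_equal(gs$mean[gs$group == "high"], 20.84, tolerance = 0.01 / 20.84)
  expect_equal(round(gs$sem[gs$group == "high"], 2), 1.52)
  expect_equal(gs$n, c(6L, 6L))
})

test_that("group_stats contract: sem definition and small groups", {
  df <- data.frame(group = c("a", "a", "a", "b", "b"),
                   imf_percent = c(5, 5, 5, 1, 3))
  gs <- group_stats(df)
  expect_equal(gs$mean, c(5, 2))
  expect_equal(gs$sem, c(0, sd(c(1, 3)) / sqrt(2)))
  expect_error(group_stats(data.frame(group = c("a", "a", "b"),
                                      imf_percent = 1:3)),
               "fewer than 2.*b")
})

test_that("fold change is the ratio of group means", {
  fx <- data.frame(group = factor(rep(c("low", "high"), each = 3),
                                  levels = c("low", "high")),
                   DPYD = c(0.2, 0.26, 0.32, 0.8, 0.84, 0.88),
                   flat = rep(0.5, 6),
                   neg = c(-1, -1, -1, 1, 1, 1))
  expect_equal(fold_change(fx, "DPYD"), mean(c(0.8, 0.84, 0.88)) / 0.26)
  expect_equal(fold_change(fx, "flat"), 1)
  expect_error(fold_change(fx, "neg"), "positive")
})

test_that("trait regression recovers generating coefficients", {
  sim <- simulate_trait_regression(n = 200, b_expr = 2, noise_sd = 0.1,
                                   seed = 22)
  rep <- trait_regression(sim, "gene01")
  expect_gt(rep$expression_estimate, 1.9)
  expect_lt(rep$expression_estimate, 2.1)
  expect_equal(rep$df_residual, 200 - 4)
  # near-zero noise: near-exact recovery, p underflow survives printing
  sim0 <- simulate_trait_regression(n = 50, b_expr = 1.5, noise_sd = 1e-8,
                                    seed = 23)
  rep0 <- trait_regression(sim0, "gene01")
  truth <- attr(sim0, "truth")
  expect_equal(unname(rep0$coefficients["gene01", "Estimate"]),
               unname(truth["b_expr"]), tolerance = 1e-6)
  expect_lt(rep0$expression_p, 1e-15)
  expect_output(print(rep0), "< 1e-15")
})

test_that("rank-deficient designs are rejected with the offending column", {
  sim <- simulate_trait_regression(n = 30, seed = 24)
  sim$gene01 <- 1            # constant expression column
  expect_error(trait_regression(sim, "gene01"), "collinear.*gene01")
  sim2 <- simulate_trait_regression(n = 30, seed = 25)
  sim2$housekeeping <- 2 * sim2$age_months
  expect_error(trait_regression(sim2, "gene01"), "collinear")
})

test_that("OLS equals the normal-equations closed form", {
  set.seed(26)
  sim <- simulate_trait_regression(n = 80, seed = 26)
  rep <- trait_regression(sim, "gene01")
  X <- cbind(1, sim$gene01, sim$age_months, sim$housekeeping)
  beta <- solve(t(X) %*% X, t(X) %*% sim$imf_percent)
  expect_equal(unname(rep$coefficients[, "Estimate"]),
               as.numeric(beta), tolerance = 1e-10)
})

test_that("regression slope recovery has small mean bias", {
  slopes <- vapply(1:50, function(s)
    trait_regression(simulate_trait_regression(n = 100, b_expr = 2,
                                               noise_sd = 0.1,
                                               seed = 1000 + s),
                     "gene01")$expression_estimate, 0)
  expect_lt(abs(mean(slopes) - 2) / 2, 0.02)
})

test_that("expression-trait correlation and its t-transform p-value", {
  df <- data.frame(imf_percent = c(1, 2, 3, 4, 5),
                   same = c(1, 2, 3, 4, 5),
                   anti = c(5, 4, 3, 2, 1))
  expect_equal(expression_trait_correlation(df, "same")$r, 1)
  expect_equal(expression_trait_correlation(df, "anti")$r, -1)
  # closed-form check at n = 12, r = 0.85
  r <- 0.85; n <- 12
  t_ref <- r * sqrt((n - 2) / (1 - r^2))
  p_ref <- 2 * pt(t_ref, df = n - 2, lower.tail = FALSE)
  set.seed(27)
  repeat {      # draw a fixture whose sample r rounds to 0.85
    x <- rnorm(n); y <- 0.85 * scale(x) + sqrt(1 - 0.85^2) * rnorm(n)
    if (abs(cor(x, y) - 0.85) < 1e-3) break
  }
  res <- expression_trait_correlation(
    data.frame(imf_percent = as.numeric(y), g = x), "g")
  expect_equal(res$p_value, p_ref, tolerance = 0.05)
  expect_equal(p_ref, 0.00046, tolerance = 0.01)  # the t-transform scale
  expect_error(expression_trait_correlation(
    data.frame(imf_percent = 1:5, g = rep(1, 5)), "g"), "zero variance")
  expect_error(expression_trait_correlation(
    data.frame(imf_percent = 1:2, g = 1:2), "g"), "3 observations")
})

test_that("PCA matches an eigendecomposition oracle", {
  set.seed(28)
  fx <- as.data.frame(matrix(rnorm(4 * 3), 4, 3,
                             dimnames = list(NULL, c("a", "b", "c"))))
  pca <- candidate_pca(fx, c("a", "b", "c"), scale. = TRUE)
  ev <- eigen(cor(as.matrix(fx)))
  expect_equal(pca$sdev^2, ev$values, tolerance = 1e-10)
  for (j in 1:3)
    expect_equal(abs(pca$loadings[, j]), abs(ev$vectors[, j]),
                 tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(sum(pca$var_prop), 1, tolerance = 1e-12)
  expect_equal(colMeans(pca$scores), rep(0, 3), tolerance = 1e-10,
               ignore_attr = TRUE)
  # components orthogonal
  expect_equal(crossprod(pca$loadings), diag(1, 3), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("PCA degenerate and collinear behavior", {
  n <- 10
  base <- rnorm(n)
  fx <- data.frame(a = base, b = 2 * base + 3, const = rep(1, n))
  expect_error(candidate_pca(fx, c("a", "const")), "const")
  # perfectly collinear pair: PC1 explains everything
  pca <- candidate_pca(fx, c("a", "b"))
  expect_equal(pca$var_prop[1], 1, tolerance = 1e-12)
  # PC2 relationship signs reported per gene
  expect_setequal(names(pca$pc2_relationship), c("a", "b"))
  expect_true(all(pca$pc2_relationship %in% c("positive", "negative")))
})
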