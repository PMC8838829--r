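# Group statistics and cross-validated binary classification.

make_labeled <- function(n = 15, shift = c(0, 1, 2), sd = 1, seed = 1) {
  with_seed(seed, data.frame(
    value = stats::rnorm(3 * n, rep(shift, each = n), sd),
    label = rep(c("normal", "moderate", "severe"), each = n)))
}

test_that("binary metrics match hand-computed confusion matrices", {
  yt <- c(rep("wbc", 4), rep("normal", 4))
  expect_equal(binary_metrics(yt, yt),
               c(OACC = 1, BACC = 1, F1 = 1, MCC = 1))
  # all-positive prediction on a 2:1 positive:negative set
  yt2 <- c(rep("wbc", 6), rep("normal", 3))
  m <- binary_metrics(yt2, rep("wbc", 9))
  expect_equal(unname(m), c(2 / 3, 1 / 2, 12 / 15, 0))
  # inverted perfect prediction
  inv <- ifelse(yt == "wbc", "normal", "wbc")
  expect_equal(binary_metrics(yt, inv)[["MCC"]], -1)
  expect_equal(binary_metrics(yt, inv)[["OACC"]], 0)
  expect_error_class(binary_metrics(yt, yt[-1]), "fb_invalid_argument")
})

test_that("balanced accuracy equals overall accuracy under symmetric errors", {
  yt <- rep(c("wbc", "normal"), each = 10)
  yp <- yt
  yp[c(1, 11)] <- rev(yp[c(1, 11)])  # one error in each class
  m <- binary_metrics(yt, yp)
  expect_equal(m[["OACC"]], m[["BACC"]])
})

test_that("all five classifiers separate well-separated classes perfectly", {
  x <- c(1:10, 31:40)
  y <- rep(c("normal", "wbc"), each = 10)
  for (mod in c("LDA", "QDA", "DT", "SVM", "KNN")) {
    pred <- fit_predict_1d(mod, x, y, x)
    expect_identical(as.character(pred), y, info = mod)
  }
  expect_error_class(fit_predict_1d("MLP", x, y, x), "fb_invalid_argument")
  expect_error_class(fit_predict_1d("LDA", x, rep("wbc", 20), x),
                     "fb_degenerate_fit")
})

test_that("LDA places its boundary at the midpoint of equal-variance classes", {
  set.seed(7)
  x <- c(rnorm(200, 0), rnorm(200, 4))
  y <- rep(c("normal", "wbc"), each = 200)
  grid <- seq(-2, 6, by = 0.01)
  pred <- fit_predict_1d("LDA", x, y, grid)
  boundary <- grid[max(which(pred == "normal"))]
  midpoint <- (mean(x[1:200]) + mean(x[201:400])) / 2
  expect_lt(abs(boundary - midpoint), 0.05)
})

test_that("QDA agrees with a brute-force Gaussian density comparison", {
  set.seed(11)
  x <- c(rnorm(300, 0, 0.5), rnorm(300, 3, 2))
  y <- factor(rep(c("normal", "wbc"), each = 300))
  grid <- seq(-4, 8, by = 0.05)
  pred <- fit_predict_1d("QDA", x, y, grid)
  # oracle: per-class Gaussian densities with sample moments, equal priors
  mu <- tapply(x, y, mean); s <- tapply(x, y, stats::sd)
  post_wbc <- stats::dnorm(grid, mu[["wbc"]], s[["wbc"]]) >
              stats::dnorm(grid, mu[["normal"]], s[["normal"]])
  oracle <- ifelse(post_wbc, "wbc", "normal")
  expect_gt(mean(as.character(pred) == oracle), 0.98)
  # with unequal variances the narrow class is enclosed by two boundaries
  flips <- sum(diff(as.integer(pred)) != 0)
  expect_identical(flips, 2L)
})

test_that("repeated CV is unbiased under the null and deterministic", {
  set.seed(3)
  x <- rnorm(60)
  y <- rep(c("normal", "wbc"), 30)
  m1 <- repeated_cv(x, y, "LDA", seed = 5)
  m2 <- repeated_cv(x, y, "LDA", seed = 5)
  expect_identical(m1, m2)
  expect_lt(abs(m1[["MCC"]]), 0.15)
})

test_that("repeated CV scores rise with class separation", {
  res <- sapply(c(0.5, 1.5, 3), function(d) {
    with_seed(17, {
      x <- c(rnorm(20, 0), rnorm(25, d))
      y <- c(rep("normal", 20), rep("wbc", 25))
      repeated_cv(x, y, "SVM", seed = 9)
    })
  })
  for (i in 1:4) expect_true(all(diff(res[i, ]) > -0.02))
})

test_that("duplicating every sample leaves CV metrics nearly unchanged", {
  with_seed(23, {
    x <- c(rnorm(20, 0), rnorm(20, 2.5))
    y <- rep(c("normal", "wbc"), each = 20)
    m1 <- repeated_cv(x, y, "KNN", seed = 1)
    m2 <- repeated_cv(rep(x, 2), rep(y, 2), "KNN", seed = 1)
    expect_lt(max(abs(m1 - m2)), 0.15)  # fold-draw noise only
  })
})

test_that("CV refuses unusable inputs", {
  expect_error_class(repeated_cv(1:10, rep("a", 10), "LDA"),
                     "fb_invalid_argument")
  expect_error_class(
    repeated_cv(1:4, c("a", "a", "a", "b"), "LDA", folds = 4),
    "fb_degenerate_fit")
})

test_that("fold-level averaging is available and bounded", {
  with_seed(31, {
    x <- c(rnorm(20, 0), rnorm(20, 3))
    y <- rep(c("normal", "wbc"), each = 20)
    m <- repeated_cv(x, y, "LDA", seed = 2, average = "fold")
    expect_true(all(m[c("OACC", "BACC", "F1")] >= 0 &
                    m[c("OACC", "BACC", "F1")] <= 1))
    expect_true(m[["MCC"]] >= -1 && m[["MCC"]] <= 1)
  })
})

test_that("group statistics recover a perfect monotone feature", {
  tab <- make_labeled(n = 12, shift = c(0, 5, 10), sd = 0.5)
  # feature exactly equal to the ordinal score
  tab$copy <- severity_score(tab$label)
  gs <- group_statistics(tab)
  expect_equal(gs$summary$rho[gs$summary$feature == "copy"], 1)
  expect_lt(gs$summary$p[gs$summary$feature == "value"], 1e-6)
  lt <- gs$letters["value", ]
  expect_identical(unname(lt[c("severe", "moderate", "normal")]),
                   c("a", "b", "c"))
})

test_that("Spearman correlation matches the rank-formula oracle", {
  x <- c(3.1, 0.2, 5.5, 2.2, 4.0, 1.1)
  score <- c(2, 0, 2, 1, 1, 0)
  tab <- data.frame(value = x,
                    label = c("severe", "normal", "severe",
                              "moderate", "moderate", "normal"))
  gs <- group_statistics(rbind(tab, tab))  # >= 2 per group
  oracle <- stats::cor(rank(rep(x, 2)), rank(rep(score, 2)))
  expect_equal(gs$summary$rho[1], oracle, tolerance = 1e-12)
})

test_that("null groups rarely earn distinct Tukey letters", {
  separated <- vapply(1:100, function(s) {
    tab <- make_labeled(n = 8, shift = c(0, 0, 0), seed = s)
    gs <- group_statistics(tab)
    any(gs$letters["value", ] != "a")
  }, logical(1))
  expect_gte(mean(!separated), 0.9)
})

test_that("group statistics validate their input", {
  tab <- data.frame(value = rnorm(10), label = rep("normal", 10))
  expect_error_class(group_statistics(tab), "fb_invalid_argument")
  expect_error_class(group_statistics(data.frame(x = 1)),
                     "fb_invalid_argument")
})
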