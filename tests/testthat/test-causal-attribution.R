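test_that("training learns separable data and is seed-deterministic", {
  set.seed(61)
  n <- 200
  X <- cbind(a = c(rnorm(n / 2, -2), rnorm(n / 2, 2)), b = rnorm(n))
  y <- rep(c(0, 1), each = n / 2)
  for (arch in c("random_forest", "elastic_net_logistic")) {
    fit <- trainModel(modelConfig(arch, "sources", seed = 3), X, y)
    expect_equal(aucScore(fit$predict(X), y), 1, tolerance = 0.005)
    fit2 <- trainModel(modelConfig(arch, "sources", seed = 3), X, y)
    expect_identical(fit$predict(X), fit2$predict(X))
  }
  expect_error(trainModel(modelConfig("random_forest", "sources"),
                          X, rep(1, n)), "both classes")
})

test_that("label-permuted data scores at chance", {
  set.seed(62)
  n <- 400
  X <- matrix(rnorm(n * 4), n, 4)
  y <- sample(rep(0:1, each = n / 2))
  cfg <- modelConfig("elastic_net_logistic", "sources", seed = 4,
                     cvFolds = 4L)
  fold <- rep(1:4, length.out = n)
  aucs <- vapply(1:4, function(k) {
    fit <- trainModel(cfg, X[fold != k, ], y[fold != k])
    aucScore(fit$predict(X[fold == k, ]), y[fold == k])
  }, 0)
  expect_lt(abs(mean(aucs) - 0.5), 0.06)
})

test_that("gradient boosted trees fit a nonlinear boundary", {
  set.seed(63)
  n <- 500
  X <- matrix(rnorm(n * 2), n, 2, dimnames = list(NULL, c("u", "v")))
  y <- as.integer(X[, 1] * X[, 2] > 0)
  fit <- trainModel(modelConfig("gradient_boosted_trees", "sources",
                                seed = 5), X, y)
  expect_gt(aucScore(fit$predict(X), y), 0.95)
})

test_that("permutation Shapley matches the additive closed form", {
  set.seed(64)
  w <- c(2, -1, 0.5, 3)
  f <- function(M) drop(as.matrix(M) %*% w)
  bg <- matrix(rnorm(200 * 4, mean = 1), 200, 4)
  xs <- matrix(rnorm(30 * 4), 30, 4)
  expl <- shapleyValues(f, xs, bg, nPermutations = 10L, seed = 6)
  # for an additive model every permutation gives the same attribution:
  # phi_i = w_i (x_i - mean(background_i)) exactly
  closed <- sweep(sweep(xs, 2, colMeans(bg)), 2, w, `*`)
  expect_equal(expl@values, closed, tolerance = 1e-10, ignore_attr = TRUE)
  # efficiency identity on every sample
  expect_equal(expl@baseValue + rowSums(expl@values), f(xs),
               tolerance = 1e-10)
})

test_that("permutation Shapley converges to exact enumeration values", {
  set.seed(65)
  f <- function(M) {
    M <- as.matrix(M)
    M[, 1] * M[, 2] + 2 * M[, 3]       # interaction model, d = 3
  }
  bg <- matrix(rnorm(60 * 3), 60, 3)
  x <- c(1.2, -0.7, 0.4)
  expl <- shapleyValues(f, matrix(x, 1), bg, nPermutations = 300L,
                        seed = 7)
  exact <- exactShapley(f, x, bg)
  expect_equal(drop(expl@values), exact, tolerance = 0.02,
               ignore_attr = TRUE)
  # duplicate features under a symmetric model get equal attributions
  g <- function(M) as.matrix(M)[, 1] * as.matrix(M)[, 2]
  # exchangeable features need an exchangeable background
  b <- rnorm(100)
  bgd <- cbind(b, b, rnorm(100))
  xd <- c(1.5, 1.5, 0)
  exactd <- exactShapley(g, xd, bgd)
  expect_equal(exactd[1], exactd[2], tolerance = 1e-10)
})

test_that("effect aggregation splits polarities and preserves ranks under scaling", {
  v <- matrix(c(0.1, -0.2, 0.3,
                0.5, 0.1, -0.4), 3, 2,
              dimnames = list(NULL, c("S1", "S2")))
  preds <- rowSums(v) + 1
  expl <- new("ShapleyExplanation", values = v, baseValue = 1,
              predictions = preds, nPermutations = 1L, seed = 1L)
  eff <- aggregateEffects(expl)
  expect_equal(eff$mean_positive_effect, c(0.2, 0.3))
  expect_equal(eff$mean_negative_effect, c(-0.2, -0.4))
  expect_setequal(eff$rank_malignant, 1:2)
  # all-zero attributions: both effects 0
  z <- matrix(0, 2, 2)
  expl0 <- new("ShapleyExplanation", values = z, baseValue = 0.5,
               predictions = c(0.5, 0.5), nPermutations = 1L, seed = 1L)
  eff0 <- aggregateEffects(expl0)
  expect_equal(eff0$mean_positive_effect, c(0, 0))
  expect_equal(eff0$mean_negative_effect, c(0, 0))
  # positive scaling scales effects and preserves ranks
  expl3 <- new("ShapleyExplanation", values = 3 * v, baseValue = 1,
               predictions = 1 + rowSums(3 * v), nPermutations = 1L,
               seed = 1L)
  eff3 <- aggregateEffects(expl3)
  expect_equal(eff3$mean_positive_effect, 3 * eff$mean_positive_effect)
  expect_equal(eff3$rank_malignant, eff$rank_malignant)
  expect_equal(eff3$rank_benign, eff$rank_benign)
})

test_that("efficiency is enforced by the explanation class", {
  bad <- matrix(c(0.5, 0.5), 1, 2)
  expect_error(new("ShapleyExplanation", values = bad, baseValue = 0,
                   predictions = 3, nPermutations = 1L, seed = 1L),
               "efficiency")
})

test_that("model comparison pairs causal and associational configurations", {
  set.seed(66)
  n <- 300
  S <- matrix(rnorm(n * 3), n, 3)
  y <- rbinom(n, 1, plogis(2 * S[, 1] - 2 * S[, 2]))
  testIdx <- 1:60
  # identical features in both spaces: paired differences center on 0
  cmp <- compareModels(S, S, y, testIdx,
                       architectures = "elastic_net_logistic",
                       nSeeds = 3L, seed = 8)
  expect_equal(nrow(cmp$auc), 6L)
  expect_lt(abs(cmp$paired$mean_diff), 0.02)
  # degenerate single seed still yields a well-formed table
  cmp1 <- compareModels(S, S, y, testIdx,
                        architectures = "elastic_net_logistic",
                        nSeeds = 1L, seed = 9)
  expect_equal(nrow(cmp1$auc), 2L)
  expect_true(is.na(cmp1$paired$sd_diff))
})

test_that("sources beat entangled noisy copies of themselves", {
  set.seed(67)
  n <- 500
  S <- matrix(rLaplace(n * 4), n, 4)
  y <- rbinom(n, 1, plogis(2.5 * S[, 1] - 2.5 * S[, 2]))
  # associational space: entangled noisy linear copies of the sources
  Mx <- matrix(rnorm(4 * 12), 4, 12)
  X <- S %*% Mx + matrix(rnorm(n * 12, 0, 1), n, 12)
  cmp <- compareModels(S, X, y, testIdx = 1:100,
                       architectures = "elastic_net_logistic",
                       nSeeds = 2L, seed = 10)
  expect_gte(cmp$paired$mean_diff, -0.02)
})

test_that("expression-vs-attribution report bins outcomes with intervals", {
  set.seed(68)
  n <- 400
  expr <- rnorm(n)
  attr <- -0.5 * expr + rnorm(n, 0, 0.1)
  out <- rbinom(n, 1, plogis(-2 * expr))      # enriched at negative expr
  rep <- expressionVsAttributionReport(expr, attr, out, nBins = 8)
  expect_equal(sum(rep$bins$n), n)
  expect_true(all(rep$bins$lower <= rep$bins$p & rep$bins$p <=
                    rep$bins$upper))
  # monotone-decreasing trend over bins
  expect_lt(cor(rep$bins$bin_mid, rep$bins$p, method = "kendall"), -0.5)
  # constant outcome: flat curve at 1
  repc <- expressionVsAttributionReport(expr, attr, rep(1, n), nBins = 5)
  expect_true(all(repc$bins$p == 1))
})
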