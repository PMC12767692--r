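test_that("whitening produces identity covariance and honest rank errors", {
  set.seed(41)
  v <- matrix(rnorm(20 * 500), 20, 500) +
    outer(rnorm(20), rnorm(500))          # one strong shared direction
  pw <- fitPcaWhitening(v, 8)
  cz <- tcrossprod(pw$whitened) / (ncol(v) - 1)
  expect_lt(max(abs(cz - diag(8))), 1e-6)
  expect_lt(max(abs(crossprod(pw$basis) - diag(8))), 1e-9)
  # m = n on full-rank data: lossless reconstruction
  pwF <- fitPcaWhitening(v, 20)
  rec <- pwF$basis %*% (pwF$whitened * sqrt(pwF$var)) + pwF$mean
  expect_lt(max(abs(rec - v)) / max(abs(v)), 1e-9)
  # retained variance is the top of the full eigendecomposition
  ev <- eigen(stats::cov(t(v)), symmetric = TRUE, only.values = TRUE)$values
  expect_equal(pw$retainedVar, sum(ev[1:8]), tolerance = 1e-8)
  # rank-deficient input: error names the achievable rank
  vr <- outer(rnorm(20), rnorm(500)) + outer(rnorm(20), rnorm(500))
  expect_error(fitPcaWhitening(vr, 10), "rank 2")
})

test_that("fixed-point ICA separates two Laplace sources", {
  set.seed(42)
  s <- matrix(rLaplace(2 * 50000), 2, 50000)
  A <- matrix(c(2, 1, 1, -1.5), 2, 2)
  x <- A %*% s
  pw <- fitPcaWhitening(x, 2)
  ica <- fastIcaFit(pw$whitened, seed = 7)
  expect_true(ica$converged)
  expect_lt(max(abs(tcrossprod(ica$w) - diag(2))), 1e-6)
  est <- ica$w %*% pw$whitened
  rec <- recoveryScore(s, est)
  expect_true(all(rec$assignment$abs_r >= 0.99))
  # determinism under a fixed seed
  ica2 <- fastIcaFit(pw$whitened, seed = 7)
  expect_identical(ica$w, ica2$w)
})

test_that("Gaussian-only input still yields an orthonormal rotation", {
  set.seed(43)
  z <- matrix(rnorm(3 * 20000), 3, 20000)
  pw <- fitPcaWhitening(z, 3)
  ica <- suppressWarnings(fastIcaFit(pw$whitened, seed = 1,
                                     maxIter = 200L))
  expect_lt(max(abs(tcrossprod(ica$w) - diag(3))), 1e-6)
})

test_that("sign orientation makes dominant elements positive and preserves the reconstruction", {
  gt <- tinyGroundTruth()
  sim <- simulateCrossSections(gt, 5000, seed = 44)
  std <- fitStandardizer(sim$x)
  ds <- discoverSignatures(applyStandardizer(std, sim$x), 6, std, seed = 45)
  A <- mixing(ds$model)
  dom <- apply(abs(A), 2, which.max)
  expect_true(all(A[cbind(dom, seq_len(ncol(A)))] > 0))
  # flipping a column and re-orienting restores it, with identical A %*% S
  m2 <- ds$model
  m2@mixing[, 3] <- -m2@mixing[, 3]
  m2@unmixing[3, ] <- -m2@unmixing[3, ]
  e2 <- exprValues(ds$expressions)
  e2[3, ] <- -e2[3, ]
  or <- orientSigns(m2, e2)
  expect_equal(or$model@mixing, mixing(ds$model))
  expect_equal(or$model@mixing %*% or$expressions,
               mixing(ds$model) %*% exprValues(ds$expressions),
               tolerance = 1e-9)
})

test_that("expressions are pinned to mean 0, SD 0.5 exactly once", {
  gt <- tinyGroundTruth()
  sim <- simulateCrossSections(gt, 4000, seed = 46)
  std <- fitStandardizer(sim$x)
  ds <- discoverSignatures(applyStandardizer(std, sim$x), 6, std, seed = 47)
  e <- exprValues(ds$expressions)
  expect_lt(max(abs(rowMeans(e))), 1e-6)
  expect_equal(unname(apply(e, 1, sd)), rep(0.5, 6), tolerance = 1e-6)
  # guarded against double application
  expect_error(scaleExpressions(ds$model, e), "already")
  # for Gaussian-distributed expressions, ~95% lie in [-1, 1]
  set.seed(48)
  g <- matrix(rnorm(2 * 40000), 2)
  sc <- scaleExpressions(
    new("SignatureModel", m = 2L,
        catalog = S4Vectors::DataFrame(variable_id = c("a", "b"),
                                       mode = "lab"),
        standardizer = new("Standardizer",
                           center = c(a = 0, b = 0),
                           scale = c(a = 1, b = 1)),
        pcaMean = c(0, 0), pcaBasis = diag(2), pcaVar = c(1, 1),
        mixing = diag(2), unmixing = diag(2),
        sourceCenter = c(0, 0), sourceScale = c(1, 1), scaled = FALSE,
        convergence = list(), seed = 1L), g)
  frac <- mean(abs(sc$expressions) <= 1)
  expect_equal(frac, 0.9545, tolerance = 0.01)
})

test_that("expression inference round-trips and inverts the mixing", {
  gt <- tinyGroundTruth()
  sim <- simulateCrossSections(gt, 4000, seed = 49)
  std <- fitStandardizer(sim$x)
  xs <- applyStandardizer(std, sim$x)
  ds <- discoverSignatures(xs, 6, std, seed = 50)
  # discovery matrix in -> stored expressions out
  again <- inferExpressions(ds$model, xs)
  expect_equal(exprValues(again), exprValues(ds$expressions),
               tolerance = 1e-6)
  # input equal to A's column j (plus the mean) -> unit impulse on source j
  A <- mixing(ds$model)
  j <- 2L
  raw <- 1 / ds$model@sourceScale[j]   # one scaled unit of source j
  vj <- ds$model@pcaMean + A[, j] * raw
  catalog <- as.data.frame(rowData(xs))
  xj <- CrossSectionMatrix(cbind(vj, vj), catalog,
                           data.frame(record_id = c("p", "q"),
                                      sample_day = 0))
  sj <- exprValues(inferExpressions(ds$model, xj))[, 1]
  centerOff <- -ds$model@sourceCenter * ds$model@sourceScale
  impulse <- sj - centerOff             # remove the stored affine offset
  expect_equal(unname(impulse[j]), 1, tolerance = 1e-6)
  expect_lt(max(abs(impulse[-j])), 1e-6)
  # dimension mismatch is rejected
  small <- CrossSectionMatrix(matrix(0, 3, 1),
                              data.frame(variable_id = c("a", "b", "c"),
                                         mode = "lab"),
                              data.frame(record_id = "p", sample_day = 0))
  expect_error(inferExpressions(ds$model, small), "dimension mismatch")
})

test_that("partial signature match without dominant elements yields nonzero expression", {
  # characterization of the partial-match phenomenon: a profile matching a
  # signature except for its dominant elements still expresses the source,
  # possibly with negative polarity
  gt <- tinyGroundTruth()
  sim <- simulateCrossSections(gt, 6000, seed = 51)
  std <- fitStandardizer(sim$x)
  xs <- applyStandardizer(std, sim$x)
  ds <- discoverSignatures(xs, 6, std, seed = 52)
  A <- mixing(ds$model)
  j <- 1L
  pr <- pruneSignature(ds$model, colnames(A)[j], threshold = 0.5)
  dominant <- pr$view$variable_id[seq_len(pr$k)]
  vj <- A[, j] / ds$model@sourceScale[j]
  vj[dominant] <- 0                      # drop the dominant elements
  xj <- CrossSectionMatrix(cbind(ds$model@pcaMean + vj,
                                 ds$model@pcaMean + vj),
                           as.data.frame(rowData(xs)),
                           data.frame(record_id = c("p", "q"),
                                      sample_day = 0))
  sj <- exprValues(inferExpressions(ds$model, xj))[, 1]
  centerOff <- -ds$model@sourceCenter * ds$model@sourceScale
  expect_gt(abs(sj[j] - centerOff[j]), 1e-3)
})

test_that("signature pruning matches hand-computed L2 ratios", {
  pr <- pruneSignature(c(a = 3, b = 4, c = 0))
  expect_equal(pr$k, 2L)
  expect_equal(pr$view$cumulative_fraction[1], 0.8)   # 4/5
  expect_equal(pr$view$cumulative_fraction[3], 1)
  expect_equal(pruneSignature(c(0, 0, 5))$k, 1L)
  # n equal-magnitude elements: k = ceiling(0.975^2 * n)
  for (n in c(10, 40, 100))
    expect_equal(pruneSignature(rep(1, n))$k, as.integer(ceiling(0.975^2 *
                                                                   n)))
  expect_error(pruneSignature(c(0, 0, 0)), "all-zero")
  # cumulative fractions are nondecreasing and end at 1
  set.seed(53)
  pr2 <- pruneSignature(rnorm(25))
  expect_true(all(diff(pr2$view$cumulative_fraction) >= -1e-12))
  expect_equal(pr2$view$cumulative_fraction[25], 1)
})

test_that("effects back-transform additively for labs and multiplicatively for codes", {
  catalog <- data.frame(variable_id = c("lab1", "code1", "code2"),
                        mode = c("lab", "code", "code"))
  std <- new("Standardizer",
             center = c(lab1 = 0, code1 = 0, code2 = 0),
             scale = c(lab1 = 2.5, code1 = 1 / log(2) * log(2), code2 = 3))
  std@scale["code1"] <- 0.7
  view <- list(view = data.frame(
    variable_id = c("lab1", "code1", "code2"),
    weight = c(1.2, log(2) / 0.7, 0),
    cumulative_fraction = c(0.8, 0.95, 1)))
  bt <- backTransformEffects(view, std, catalog)
  expect_equal(bt$view$effect[1], 1.2 * 2.5)          # additive: w * sigma
  expect_equal(bt$view$operator[1], "+")
  expect_equal(bt$view$effect[2], 2)                  # factor 2.0
  expect_equal(bt$view$operator[2], "x")
  expect_equal(bt$view$effect[3], 1)                  # weight 0 -> factor 1
})

test_that("decomposition recovers sources from stacked cross-sections", {
  gt <- sampleGroundTruth(60, 8, seed = 54)
  sim <- simulateCrossSections(gt, 10000, noiseSd = 0.1, seed = 55)
  std <- fitStandardizer(sim$x)
  ds <- discoverSignatures(applyStandardizer(std, sim$x), 8, std, seed = 56)
  rec <- recoveryScore(sim$expressions, exprValues(ds$expressions))
  expect_gte(rec$meanAbsR, 0.9)
  expect_gte(rec$minAbsR, 0.8)
  # reconstruction error bounded by the PCA residual
  v <- xsValues(applyStandardizer(std, sim$x))
  vc <- v - rowMeans(v)
  sRaw <- ds$model@unmixing %*% vc
  resid <- norm(vc - ds$model@mixing %*% sRaw, "F") / norm(vc, "F")
  pcaResid <- sqrt(1 - sum(ds$model@pcaVar) /
                     (sum(apply(v, 1, var))))
  expect_lte(resid, pcaResid + 1e-6)
})
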