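bruteAssignment <- function(cost) {
  n <- nrow(cost)
  perms <- function(v) {
    if (length(v) == 1L) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    out
  }
  best <- Inf; bestP <- NULL
  for (p in perms(seq_len(ncol(cost)))) {
    tot <- sum(cost[cbind(seq_len(n), p[seq_len(n)])])
    if (tot < best) { best <- tot; bestP <- p[seq_len(n)] }
  }
  list(cost = best, p = bestP)
}

test_that("Hungarian assignment matches brute-force enumeration", {
  set.seed(71)
  for (rep in 1:20) {
    n <- sample(2:6, 1)
    cost <- matrix(runif(n * n, -5, 5), n, n)
    a <- solveAssignment(cost)
    expect_equal(sum(cost[cbind(seq_len(n), a)]),
                 bruteAssignment(cost)$cost, tolerance = 1e-10)
    expect_setequal(a, seq_len(n))
  }
  # rectangular: extra columns stay unassigned
  cost <- matrix(runif(12), 3, 4)
  a <- solveAssignment(cost)
  expect_length(a, 3L)
  expect_equal(anyDuplicated(a), 0L)
})

test_that("recovery score is invariant to ICA's indeterminacies", {
  set.seed(72)
  s <- matrix(rLaplace(5 * 2000), 5, 2000,
              dimnames = list(paste0("T", 1:5), NULL))
  perm <- c(3, 1, 5, 2, 4)
  flips <- c(1, -1, 1, -1, -1)
  scales <- c(2, 0.5, 7, 1, 0.1)
  est <- (s * flips * scales)[perm, ]
  rec <- recoveryScore(s, est)
  expect_equal(rec$meanAbsR, 1, tolerance = 1e-12)
  # row names travel with the permutation, so each true source matches the
  # estimated row carrying its own name
  expect_equal(rec$assignment$est_source, paste0("T", 1:5))
  # independent estimates carry no signal
  est0 <- matrix(rnorm(5 * 2000), 5, 2000)
  expect_lt(recoveryScore(s, est0)$meanAbsR, 0.1)
  # extra estimated sources stay unmatched
  est2 <- rbind(s, matrix(rnorm(2 * 2000), 2, 2000))
  rec2 <- recoveryScore(s, est2)
  expect_equal(nrow(rec2$assignment), 5L)
  expect_equal(rec2$meanAbsR, 1, tolerance = 1e-12)
})

test_that("reference-list metrics respond to matches as expected", {
  ref <- data.frame(
    category = c("malignant", "malignant", "malignant", "benign"),
    element = c("e1", "e2", "e3", "b1"),
    group_key = c("g1", "g1", "g2", "b1"),
    signature_ids = c("1;2", "1;2", "", "9"))
  ref$signatures <- lapply(strsplit(ref$signature_ids, ";"),
                           function(v) v[nzchar(v)])
  cm <- completeness(ref, "malignant", "element")
  expect_equal(cm$fraction, 2 / 3)
  cg <- completeness(ref, "malignant", "group")
  expect_equal(cg$fraction, 1 / 2)
  dm <- decomposition(ref, "malignant", "element")
  expect_equal(dm$mean, 2)
  # every matched element having exactly one signature gives 1.0
  db <- decomposition(ref, "benign", "element")
  expect_equal(db$mean, 1)
  # no matches at all: completeness 0, decomposition errors
  ref0 <- ref
  ref0$signatures <- rep(list(character()), 4)
  expect_equal(completeness(ref0, "malignant")$fraction, 0)
  expect_error(decomposition(ref0, "malignant"), "no matched")
  # a category absent from the list is an error, distinct from zero matches
  onlyMal <- ref[ref$category == "malignant", ]
  expect_error(completeness(onlyMal, "benign"), "empty category")
})

test_that("displayed decomposition truncates toward zero at one decimal", {
  ref <- data.frame(category = "malignant",
                    element = c("x", "y"), group_key = c("x", "y"),
                    signature_ids = c("1;2;3;4;5;6", "7;8;9;10;11"))
  ref$signatures <- strsplit(ref$signature_ids, ";")
  d <- decomposition(ref, "malignant", "element")
  expect_equal(d$mean, 5.5)
  expect_equal(d$displayed, 5.5)
  ref2 <- ref
  ref2$signatures <- list(as.character(1:9), as.character(10:19))
  expect_equal(decomposition(ref2, "malignant")$displayed, 9.5)
})

test_that("evidence tally counts Direct grades among the top k", {
  causes <- data.frame(mean_causal_effect = seq(0.9, 0.1, length.out = 9),
                       evidence = c("Direct", "Strong", "Direct/Moderate",
                                    "Weak", "Absent", "Direct", "Mixed",
                                    "Strong", "Direct"))
  t5 <- tallyEvidence(causes, topK = 5L)
  expect_equal(t5$nDirect, 2L)
  t9 <- tallyEvidence(causes, topK = 9L)
  expect_equal(t9$nDirect, 4L)
  t0 <- tallyEvidence(causes, topK = 0L)
  expect_true(all(t0$counts == 0L))
})

test_that("bundled reference fixtures load with expected shapes", {
  ref <- readReferenceList()
  expect_equal(sum(ref$category == "malignant"), 13L)
  expect_equal(sum(ref$category == "benign"), 23L)
  tm <- topInferredCauses("malignant")
  tb <- topInferredCauses("benign")
  expect_equal(nrow(tm), 20L)
  expect_equal(nrow(tb), 20L)
  sz <- evaluationSetSize()
  expect_equal(sz$total, sz$malignant + sz$benign)
})
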