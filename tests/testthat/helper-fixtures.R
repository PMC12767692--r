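# Small hand-built cohort used across the unit tests: three records with
# known events, spans, demographics and index days.
toyCohort <- function() {
  demo <- data.frame(
    record_id = c("A", "B", "C"),
    sex = c("female", "male", "male"),
    race = c("white", "black", "white"),
    birth_day_offset = c(-20000, -15000, -10000))
  labs <- data.frame(
    record_id = c("A", "A", "A", "B", "B", "B"),
    day = c(0, 10, 50, 5, 20, 90),
    test_id = "glucose",
    value = c(1, 3, 2, 5, 6, 4))
  codes <- data.frame(
    record_id = c("A", "A", "B", "C"),
    day = c(10, 200, 30, 100),
    code_id = c("cough", "nodule", "cough", "nodule"))
  meds <- data.frame(record_id = "A", day = 40, med_id = "statin")
  EHRCohort(demo, labs = labs, codes = codes, meds = meds,
            spans = setNames(c(400, 100, 150), c("A", "B", "C")),
            index = setNames(c(250, 90, 120), c("A", "B", "C")))
}

tinyGroundTruth <- function(seed = 5L, ...) {
  sampleGroundTruth(nVars = 30L, mSources = 6L, seed = seed, ...)
}

# exact Shapley values by enumeration over all feature subsets, using the
# same marginal (background-mean) value function as the estimator
exactShapley <- function(predictFun, x, background) {
  d <- length(x)
  vOf <- function(S) {
    M <- background
    if (length(S)) M[, S] <- matrix(x[S], nrow(background), length(S),
                                    byrow = TRUE)
    mean(predictFun(M))
  }
  phi <- numeric(d)
  subsets <- lapply(0:(2^d - 1), function(b) which(bitwAnd(b, 2^(0:(d - 1)))
                                                   > 0))
  vals <- vapply(subsets, vOf, 0)
  keyOf <- function(S) sum(2^(S - 1)) + 1
  for (i in seq_len(d)) {
    for (k in seq_along(subsets)) {
      S <- subsets[[k]]
      if (i %in% S) next
      w <- factorial(length(S)) * factorial(d - length(S) - 1) / factorial(d)
      phi[i] <- phi[i] + w * (vals[keyOf(c(S, i))] - vals[k])
    }
  }
  phi
}
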