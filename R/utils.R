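#' @importFrom stats rbinom rpois runif rnorm plogis qnorm median quantile
#'   sd var cor splinefun approx setNames predict
#' @importFrom methods new validObject is slot
#' @importFrom utils head read.csv write.csv
NULL

DAYS_PER_YEAR <- 365.25

#' Draw from a zero-mean Laplace (two-sided exponential) distribution
#'
#' Heavy-tailed, super-Gaussian law used for active latent-source
#' expressions; non-Gaussianity is what makes the linear decomposition
#' identifiable.
#'
#' @param n number of draws.
#' @param sd standard deviation of the distribution (scale is `sd/sqrt(2)`).
#' @return numeric vector of length `n`.
#' @export
rLaplace <- function(n, sd = 1) {
  u <- runif(n) - 0.5
  -(sd / sqrt(2)) * sign(u) * log(1 - 2 * abs(u))
}

#' Rank-based AUC
#'
#' Area under the ROC curve via the Wilcoxon rank statistic. Used for all
#' internal model scoring; cross-checked against pROC in the test suite.
#'
#' @param scores numeric predictions (higher = more positive).
#' @param labels 0/1 vector (or logical) of true classes.
#' @return AUC in \[0, 1\].
#' @export
aucScore <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% c(0L, 1L)))
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop("aucScore: both classes must be present")
  r <- rank(scores)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (as.numeric(n1) * n0)
}

#' Derive a stage seed from a global seed and a tag
#'
#' Deterministic and always below 2^31, so the result is a valid R integer
#' seed. Used to give every pipeline stage and repetition its own stream.
#'
#' @param seed integer master seed.
#' @param tag character label of the consumer.
#' @return integer seed.
#' @export
deriveSeed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 48271 + h * 7919) %% 2147483647)
}

# md5 of an arbitrary R object via serialization to a temp file
# (stable within a session; used for pipeline stage caching).
objectHash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  # version = 3, xdr: platform-independent serialization
  saveRDS(x, f, version = 3)
  unname(tools::md5sum(f))
}

# stratified k-fold assignment, deterministic given the RNG state
stratifiedFolds <- function(y, k) {
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

`%||%` <- function(a, b) if (is.null(a)) b else a
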