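#' @include AllClasses.R AllGenerics.R models.R
NULL

.shapleyCore <- function(predictFun, samples, background, nPermutations,
                         seed) {
  samples <- as.matrix(samples)
  background <- as.matrix(background)
  stopifnot(ncol(samples) == ncol(background), nrow(background) >= 1L,
            nPermutations >= 1L)
  n <- nrow(samples); d <- ncol(samples); B <- nrow(background)
  set.seed(seed)
  base <- mean(predictFun(background))
  phi <- matrix(0, n, d, dimnames = list(rownames(samples),
                                         colnames(samples)))
  sampleRow <- rep(seq_len(n), each = B)
  for (p in seq_len(nPermutations)) {
    perm <- sample.int(d)
    # M starts as the background replicated under every sample; features are
    # switched to the sample's values one at a time in permutation order.
    M <- background[rep(seq_len(B), times = n), , drop = FALSE]
    vPrev <- rep(base, n)
    for (j in perm) {
      M[, j] <- samples[sampleRow, j]
      v <- rowsum(predictFun(M), sampleRow) / B
      phi[, j] <- phi[, j] + (drop(v) - vPrev)
      vPrev <- drop(v)
    }
  }
  phi <- phi / nPermutations
  preds <- predictFun(samples)
  list(values = phi, baseValue = base, predictions = preds)
}

#' Monte-Carlo permutation Shapley values
#'
#' Estimates marginal-expectation (interventional) Shapley values by
#' averaging feature contributions over random permutations: for each
#' permutation the features are switched from background to sample values
#' in order, and each feature is credited with the change in the expected
#' prediction. Because the full background set is reused at every
#' coalition, the per-permutation contributions telescope and the
#' efficiency identity `base + sum(phi) = f(x)` holds exactly for every
#' explained sample.
#'
#' @param model an `ehrsigModel` (from [trainModel()]) or any function
#'   mapping a feature matrix to numeric predictions.
#' @param samples matrix of rows to explain.
#' @param background matrix of background rows (marginal reference
#'   distribution); a fixed random subsample of a few hundred training rows
#'   is typical.
#' @param nPermutations Monte-Carlo permutations.
#' @param seed RNG seed.
#' @param ... unused.
#' @return a [ShapleyExplanation-class]
#' @name shapleyValues
#' @aliases shapleyValues,function-method shapleyValues,ehrsigModel-method
NULL

#' @rdname shapleyValues
setMethod("shapleyValues", "function",
  function(model, samples, background, nPermutations = 16L, seed = 1L, ...) {
    res <- .shapleyCore(model, samples, background, nPermutations, seed)
    new("ShapleyExplanation", values = res$values,
        baseValue = res$baseValue, predictions = res$predictions,
        nPermutations = as.integer(nPermutations), seed = as.integer(seed))
  })

setOldClass("ehrsigModel")

#' @rdname shapleyValues
setMethod("shapleyValues", "ehrsigModel",
  function(model, samples, background, nPermutations = 16L, seed = 1L, ...) {
    shapleyValues(model$predict, samples, background, nPermutations, seed)
  })

#' Aggregate attributions into polarity-specific per-source causal effects
#'
#' For each feature (source), the malignant-polarity effect is the mean of
#' its strictly positive per-sample attributions (disease-generating
#' direction) and the benign-polarity effect is the mean of its strictly
#' negative attributions (protective direction); sources with no qualifying
#' attributions get effect 0. Ranks are by descending |effect| within each
#' polarity, ties broken by source order.
#'
#' @param explanation a [ShapleyExplanation-class]
#' @return data.frame(source_id, mean_positive_effect,
#'   mean_negative_effect, rank_malignant, rank_benign).
#' @export
aggregateEffects <- function(explanation) {
  v <- explanation@values
  pos <- apply(v, 2L, function(col) {
    p <- col[col > 0]; if (length(p)) mean(p) else 0 })
  neg <- apply(v, 2L, function(col) {
    p <- col[col < 0]; if (length(p)) mean(p) else 0 })
  ids <- colnames(v) %||% sprintf("f%d", seq_len(ncol(v)))
  ord <- function(e) {
    r <- integer(length(e))
    r[order(abs(e), decreasing = TRUE)] <- seq_along(e)
    r
  }
  data.frame(source_id = ids, mean_positive_effect = unname(pos),
             mean_negative_effect = unname(neg),
             rank_malignant = ord(pos), rank_benign = ord(neg))
}

#' Expression-vs-attribution report for one source
#'
#' Emits the per-record (expression, attribution, outcome) triples and an
#' expression-binned empirical outcome probability with binomial confidence
#' intervals — the view that reveals partial-signature expression (records
#' expressing a source negatively yet attributed positive risk).
#'
#' @param expressions per-record expression of the source.
#' @param attributions per-record Shapley attribution of the source.
#' @param outcomes 0/1 outcome per record.
#' @param nBins number of equal-count expression bins.
#' @param conf confidence level for the binomial intervals.
#' @return list(points = data.frame(expression, attribution, outcome),
#'   bins = data.frame(bin_mid, n, p, lower, upper)).
#' @export
expressionVsAttributionReport <- function(expressions, attributions,
                                          outcomes, nBins = 10L,
                                          conf = 0.95) {
  stopifnot(length(expressions) == length(attributions),
            length(expressions) == length(outcomes))
  outcomes <- as.integer(outcomes)
  points <- data.frame(expression = expressions,
                       attribution = attributions, outcome = outcomes)
  qs <- unique(quantile(expressions, probs = seq(0, 1, length.out =
                                                   nBins + 1L)))
  bin <- cut(expressions, qs, include.lowest = TRUE)
  bins <- do.call(rbind, lapply(levels(bin), function(b) {
    sel <- bin == b
    k <- sum(outcomes[sel]); n <- sum(sel)
    ci <- stats::binom.test(k, n, conf.level = conf)$conf.int
    data.frame(bin_mid = median(expressions[sel]), n = n, p = k / n,
               lower = ci[1], upper = ci[2])
  }))
  list(points = points, bins = bins)
}
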