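#' @include AllClasses.R AllGenerics.R cross-sections.R
NULL

#' PCA whitening
#'
#' Centers the standardized variables, computes the top-`m` eigenvectors of
#' their covariance, and rescales so the retained components have identity
#' covariance. Reduction to `m` components is the first step of the
#' independent-component decomposition.
#'
#' @param values n_vars x t matrix (standardized cross-sections).
#' @param m number of retained components (<= rank).
#' @return list(mean, basis (n x m, orthonormal), var (eigenvalues),
#'   whitened (m x t, identity covariance), totalVar, retainedVar).
#' @export
fitPcaWhitening <- function(values, m) {
  n <- nrow(values); t <- ncol(values)
  stopifnot(m >= 1L, m <= min(n, t))
  mu <- rowMeans(values)
  xc <- values - mu
  cv <- tcrossprod(xc) / (t - 1)
  eg <- eigen(cv, symmetric = TRUE)
  rank <- sum(eg$values > max(eg$values) * 1e-12)
  if (m > rank)
    stop(sprintf("m = %d exceeds achievable rank %d", m, rank))
  basis <- eg$vectors[, seq_len(m), drop = FALSE]
  d <- eg$values[seq_len(m)]
  z <- (t(basis) %*% xc) / sqrt(d)
  rownames(basis) <- rownames(values)
  list(mean = mu, basis = basis, var = d, whitened = z,
       totalVar = sum(eg$values), retainedVar = sum(d))
}

#' Fixed-point ICA on whitened data
#'
#' Symmetric (parallel) fixed-point iteration with the logcosh contrast
#' (`g = tanh(alpha * u)`), followed by symmetric decorrelation of the
#' rotation at every step. Converges when the maximum change of any
#' direction (1 minus |cosine| to its previous self) falls below `tol`;
#' otherwise returns the partial result with a warning.
#'
#' @param z m x t whitened matrix (identity covariance).
#' @param alpha logcosh steepness in \[1, 2\].
#' @param tol convergence tolerance.
#' @param maxIter iteration budget.
#' @param seed seed for the random orthonormal initialization.
#' @return list(w (m x m orthonormal rotation, sources = w %*% z),
#'   converged, iterations, change).
#' @export
fastIcaFit <- function(z, alpha = 1, tol = 1e-4, maxIter = 500L, seed = 1L) {
  m <- nrow(z); t <- ncol(z)
  set.seed(seed)
  w <- qr.Q(qr(matrix(rnorm(m * m), m, m)))
  symDecor <- function(w) {
    e <- eigen(tcrossprod(w), symmetric = TRUE)
    e$vectors %*% diag(1 / sqrt(e$values), m) %*% t(e$vectors) %*% w
  }
  w <- symDecor(w)
  change <- NA_real_
  for (it in seq_len(maxIter)) {
    u <- w %*% z
    gu <- tanh(alpha * u)
    gprime <- alpha * (1 - gu^2)
    w1 <- (gu %*% t(z)) / t - diag(rowMeans(gprime), m) %*% w
    w1 <- symDecor(w1)
    change <- max(abs(abs(rowSums(w1 * w)) - 1))
    w <- w1
    if (change < tol) break
  }
  converged <- change < tol
  if (!converged)
    warning(sprintf(
      "fastIcaFit did not converge in %d iterations (last change %.3g)",
      maxIter, change))
  list(w = w, converged = converged, iterations = it, change = change)
}

#' Discover latent clinical signatures
#'
#' Full decomposition of a standardized cross-section matrix `X` into
#' `X ~ A S`: PCA reduction/whitening to `m` components, fixed-point ICA,
#' sign orientation (the dominant element of every signature is a positive
#' change), and per-source affine scaling of expressions to mean 0, SD 0.5
#' on the discovery set.
#'
#' @param x a standardized [CrossSectionMatrix-class] (the discovery set).
#' @param m number of sources.
#' @param standardizer the [Standardizer-class] used to standardize `x`
#'   (kept for back-transforming effects to original units).
#' @param tol,maxIter,alpha ICA settings, see [fastIcaFit()].
#' @param seed ICA initialization seed (required for reproducibility).
#' @return list(model = [SignatureModel-class],
#'   expressions = [SourceExpressionMatrix-class] of scaled discovery-set
#'   expressions).
#' @export
discoverSignatures <- function(x, m, standardizer, tol = 1e-4,
                               maxIter = 500L, alpha = 1, seed = 1L) {
  v <- xsValues(x)
  pw <- fitPcaWhitening(v, m)
  ica <- fastIcaFit(pw$whitened, alpha = alpha, tol = tol,
                    maxIter = maxIter, seed = seed)
  # unmixing: s_raw = W D^{-1/2} E' (x - mean); mixing: pseudo-inverse
  unmix <- ica$w %*% (t(pw$basis) / sqrt(pw$var))
  mix <- pw$basis %*% (t(ica$w) * sqrt(pw$var))
  dimnames(mix) <- list(rownames(v), sprintf("S%04d", seq_len(m)))
  dimnames(unmix) <- list(colnames(mix), rownames(v))
  model <- new("SignatureModel", m = as.integer(m),
               catalog = rowData(x), standardizer = standardizer,
               pcaMean = pw$mean, pcaBasis = pw$basis, pcaVar = pw$var,
               mixing = mix, unmixing = unmix,
               sourceCenter = setNames(numeric(m), colnames(mix)),
               sourceScale = setNames(rep(1, m), colnames(mix)),
               scaled = FALSE,
               convergence = ica[c("converged", "iterations", "change")],
               seed = as.integer(seed))
  sRaw <- unmix %*% (v - pw$mean)
  or <- orientSigns(model, sRaw)
  sc <- scaleExpressions(or$model, or$expressions)
  expr <- SourceExpressionMatrix(sc$expressions, colData(x))
  list(model = sc$model, expressions = expr)
}

#' Construct a SourceExpressionMatrix
#'
#' @param values m x t expression matrix.
#' @param provenance DataFrame/data.frame of per-column provenance.
#' @return a [SourceExpressionMatrix-class]
#' @export
SourceExpressionMatrix <- function(values, provenance) {
  new("SourceExpressionMatrix", SummarizedExperiment(
    assays = list(expressions = values),
    colData = S4Vectors::DataFrame(provenance)))
}

#' @describeIn SourceExpressionMatrix the expression matrix.
#' @param x a [SourceExpressionMatrix-class]
#' @export
exprValues <- function(x) assay(x, "expressions")

#' Accessors for SignatureModel
#'
#' @param object a [SignatureModel-class]
#' @return `mixing`: the n x m signature matrix A; `unmixing`: the m x n
#'   inverse map; `nSources`: m; `sourceAffine`: data.frame of per-source
#'   center and scale.
#' @name SignatureModel-accessors
NULL

#' @rdname SignatureModel-accessors
setMethod("mixing", "SignatureModel", function(object) object@mixing)
#' @rdname SignatureModel-accessors
setMethod("unmixing", "SignatureModel", function(object) object@unmixing)
#' @rdname SignatureModel-accessors
setMethod("nSources", "SignatureModel", function(object) object@m)
#' @rdname SignatureModel-accessors
setMethod("sourceAffine", "SignatureModel", function(object)
  data.frame(source_id = colnames(object@mixing),
             center = unname(object@sourceCenter),
             scale = unname(object@sourceScale)))

setMethod("show", "SignatureModel", function(object) {
  cat("SignatureModel:", object@m, "sources over",
      nrow(object@mixing), "variables\n")
  cat("  ICA converged:", object@convergence$converged, "in",
      object@convergence$iterations, "iterations\n")
  cat("  expressions scaled to SD 0.5:", object@scaled, "\n")
})

#' Orient signature signs
#'
#' ICA leaves each source's sign arbitrary; the convention is that the
#' dominant (largest |weight|) element of every signature is a positive
#' change. Flipping a signature negates the matching expression row, so the
#' reconstruction `A S` is unchanged. Ties on the dominant element are
#' broken by lowest variable index.
#'
#' @param model a [SignatureModel-class]
#' @param expressions m x t raw expression matrix aligned with the model.
#' @return list(model, expressions) with signs applied.
#' @export
orientSigns <- function(model, expressions) {
  A <- model@mixing
  dom <- apply(abs(A), 2L, which.max)   # which.max takes the first on ties
  flip <- vapply(seq_len(ncol(A)),
                 function(j) sign(A[dom[j], j]) < 0, NA)
  if (any(flip)) {
    A[, flip] <- -A[, flip, drop = FALSE]
    model@mixing <- A
    model@unmixing[flip, ] <- -model@unmixing[flip, , drop = FALSE]
    expressions[flip, ] <- -expressions[flip, , drop = FALSE]
  }
  list(model = model, expressions = expressions)
}

#' Scale discovery-set expressions to mean 0, SD 0.5
#'
#' The scale of each source is non-identifiable, so expressions are pinned
#' by convention to zero mean and 0.5 standard deviation over the discovery
#' set. The per-source affine parameters are stored on the model and applied
#' to all future inferences. Guarded to run once.
#'
#' @param model an unscaled [SignatureModel-class]
#' @param expressions m x t raw discovery expressions.
#' @return list(model (scaled), expressions (scaled)).
#' @export
scaleExpressions <- function(model, expressions) {
  if (model@scaled) stop("scaleExpressions has already been applied")
  ctr <- rowMeans(expressions)
  sds <- apply(expressions, 1L, sd)
  if (any(sds <= .Machine$double.eps * 100))
    stop("degenerate source with zero expression variance")
  scl <- 0.5 / sds
  model@sourceCenter[] <- ctr
  model@sourceScale[] <- scl
  model@scaled <- TRUE
  list(model = model, expressions = (expressions - ctr) * scl)
}

#' Infer source expressions for new cross-sections
#'
#' Applies the discovery-set pipeline to new standardized cross-sections:
#' PCA projection, unmixing, then the stored per-source affine. On the
#' discovery matrix this reproduces the stored expressions.
#'
#' @param model a fitted, scaled [SignatureModel-class]
#' @param x a standardized [CrossSectionMatrix-class] over the same
#'   variables.
#' @param ... unused.
#' @return a [SourceExpressionMatrix-class]
#' @name inferExpressions
#' @aliases inferExpressions,SignatureModel,CrossSectionMatrix-method
setMethod("inferExpressions", c("SignatureModel", "CrossSectionMatrix"),
  function(model, x, ...) {
    v <- xsValues(x)
    if (nrow(v) != ncol(model@unmixing))
      stop("variable dimension mismatch: model has ",
           ncol(model@unmixing), " variables, input has ", nrow(v))
    sRaw <- model@unmixing %*% (v - model@pcaMean)
    s <- (sRaw - model@sourceCenter) * model@sourceScale
    SourceExpressionMatrix(s, colData(x))
  })

#' Prune a signature for display
#'
#' Orders a signature's variables by |weight| and keeps the smallest `k`
#' whose retained L2 norm is at least `threshold` (default 97.5%) of the
#' full vector's norm. Reports per-element cumulative-information fractions
#' (`||top-j||_2 / ||full||_2`).
#'
#' @param model a [SignatureModel-class] (or a plain numeric weight vector).
#' @param sourceId signature column name or index.
#' @param threshold retained-information threshold in (0, 1\].
#' @return list(source_id, k, view = data.frame(variable_id, weight,
#'   cumulative_fraction), threshold).
#' @export
pruneSignature <- function(model, sourceId = NULL, threshold = 0.975) {
  w <- if (is.numeric(model)) model else model@mixing[, sourceId]
  if (all(w == 0)) stop("all-zero signature column")
  ids <- names(w) %||% as.character(seq_along(w))
  o <- order(abs(w), decreasing = TRUE)
  cumfrac <- sqrt(cumsum(w[o]^2) / sum(w^2))
  k <- which(cumfrac >= threshold - 1e-12)[1]
  list(source_id = if (is.numeric(model)) NA_character_ else
         as.character(sourceId),
       k = as.integer(k),
       view = data.frame(variable_id = ids[o], weight = unname(w[o]),
                         cumulative_fraction = unname(cumfrac)),
       threshold = threshold)
}

#' Back-transform signature effects to original units
#'
#' Signature weights live in standardized space. Undoing the per-variable
#' standardization gives the effect of a one-unit expression increase in
#' each variable's native units: additive (`weight * scale`) for labs,
#' medications and demographics; multiplicative
#' (`exp(weight * scale)`, a rate factor) for billing-code intensities,
#' which are modeled on the log scale.
#'
#' @param view result of [pruneSignature()].
#' @param standardizer the discovery-set [Standardizer-class].
#' @param catalog variable catalog (for per-variable modes).
#' @return the view with columns `effect` and `operator` (`+`/`-` additive,
#'   `x`/`/` multiplicative) added.
#' @export
backTransformEffects <- function(view, standardizer, catalog) {
  df <- view$view
  mode <- setNames(catalog$mode, catalog$variable_id)[df$variable_id]
  scl <- standardizer@scale[df$variable_id]
  raw <- df$weight * unname(scl)
  mult <- mode == "code"
  df$effect <- ifelse(mult, exp(raw), raw)
  df$operator <- ifelse(mult, ifelse(raw >= 0, "x", "/"),
                        ifelse(raw >= 0, "+", "-"))
  # report multiplicative factors >= 1 with "/" giving the reciprocal
  df$effect[mult & raw < 0] <- exp(-raw[mult & raw < 0])
  view$view <- df
  view
}
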