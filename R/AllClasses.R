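#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

# ---------------------------------------------------------------------------
# EHRCohort: long-format multi-modal event store for a set of patient records
# ---------------------------------------------------------------------------

#' EHRCohort: multi-modal electronic-health-record cohort
#'
#' Container for a cohort of longitudinal patient records in long format:
#' laboratory observations, billing-code events, medication mentions and
#' per-record demographics. Time is fractional days from each record's start
#' (day 0). Optional per-record index day (the event anchoring prediction,
#' e.g. first pulmonary-nodule code) and binary outcome label.
#'
#' @slot labs data.frame(record_id, day, test_id, value)
#' @slot codes data.frame(record_id, day, code_id)
#' @slot meds data.frame(record_id, day, med_id)
#' @slot demo data.frame(record_id, sex, race, birth_day_offset)
#' @slot index named numeric, index day per record (NA if absent)
#' @slot spans named numeric, record length in days
#' @slot labels named character, "positive"/"negative" or NA
#'
#' @exportClass EHRCohort
setClass("EHRCohort",
  slots = c(
    labs = "data.frame", codes = "data.frame", meds = "data.frame",
    demo = "data.frame", index = "numeric", spans = "numeric",
    labels = "character"
  )
)

.checkEventFrame <- function(df, what, cols, spans) {
  if (!all(cols %in% names(df)))
    return(sprintf("%s: missing required column(s) %s", what,
                   paste(setdiff(cols, names(df)), collapse = ", ")))
  if (nrow(df) == 0L) return(TRUE)
  if (any(!is.finite(df$day)) || any(df$day < 0))
    return(sprintf("%s: event days must be finite and >= 0", what))
  if (!all(df$record_id %in% names(spans)))
    return(sprintf("%s: record_id not present in demographics", what))
  if (any(df$day > spans[df$record_id] + 1e-9))
    return(sprintf("%s: event day exceeds record span", what))
  TRUE
}

setValidity("EHRCohort", function(object) {
  msgs <- character()
  if (!all(c("record_id", "sex", "race", "birth_day_offset") %in%
           names(object@demo)))
    msgs <- c(msgs, "demo: requires record_id, sex, race, birth_day_offset")
  ids <- object@demo$record_id
  if (anyDuplicated(ids)) msgs <- c(msgs, "demo: duplicated record_id")
  if (!identical(sort(names(object@spans)), sort(as.character(ids))))
    msgs <- c(msgs, "spans must be named by every record_id")
  for (chk in list(
    .checkEventFrame(object@labs, "labs",
                     c("record_id", "day", "test_id", "value"), object@spans),
    .checkEventFrame(object@codes, "codes",
                     c("record_id", "day", "code_id"), object@spans),
    .checkEventFrame(object@meds, "meds",
                     c("record_id", "day", "med_id"), object@spans)))
    if (!isTRUE(chk)) msgs <- c(msgs, chk)
  if (nrow(object@labs) && any(!is.finite(object@labs$value)))
    msgs <- c(msgs, "labs: values must be finite")
  idx <- object@index
  if (!identical(sort(names(idx)), sort(as.character(ids))))
    msgs <- c(msgs, "index must be named by every record_id")
  bad <- !is.na(idx) & idx > object@spans[names(idx)] + 1e-9
  if (any(bad)) msgs <- c(msgs, "index day exceeds record span")
  lab <- object@labels
  if (!identical(sort(names(lab)), sort(as.character(ids))))
    msgs <- c(msgs, "labels must be named by every record_id")
  if (!all(lab[!is.na(lab)] %in% c("positive", "negative")))
    msgs <- c(msgs, "labels must be 'positive' or 'negative'")
  if (length(msgs)) msgs else TRUE
})

# ---------------------------------------------------------------------------
# Curves
# ---------------------------------------------------------------------------

#' ClinicalCurve: continuous-time representation of one variable in one record
#'
#' Every variable of every record is represented as a function defined (and
#' finite) at every day in `[0, span]`. Kinds:
#' \describe{
#'   \item{constant}{fixed value everywhere (missing labs at the population
#'     median; absent medications at 0; demographic indicators).}
#'   \item{interp}{shape-preserving monotone-cubic interpolation through
#'     laboratory observations, constant beyond the first/last observation.}
#'   \item{step}{piecewise-constant 0/1 medication presence intervals.}
#'   \item{kernelrate}{Gaussian-kernel billing-code intensity (events/year)
#'     with reflection boundary correction, stored on the log scale.}
#'   \item{linear}{affine in time (age).}
#' }
#'
#' @slot kind one of constant/interp/step/kernelrate/linear
#' @slot mode data mode: lab/code/med/demo
#' @slot transform "identity" or "log" (scale on which values live)
#' @slot x,y breakpoints / event days and values (kind-dependent)
#' @slot constant constant value (kind "constant")
#' @slot span record span in days
#' @slot params kind-specific parameters (bandwidth, floor rate, ...)
#' @exportClass ClinicalCurve
setClass("ClinicalCurve",
  slots = c(kind = "character", mode = "character", transform = "character",
            x = "numeric", y = "numeric", constant = "numeric",
            span = "numeric", params = "list"),
  prototype = prototype(kind = "constant", mode = "lab",
                        transform = "identity", x = numeric(), y = numeric(),
                        constant = 0, span = 0, params = list())
)

setValidity("ClinicalCurve", function(object) {
  if (!object@kind %in% c("constant", "interp", "step", "kernelrate", "linear"))
    return("unknown curve kind")
  if (length(object@x) && is.unsorted(object@x, strictly = TRUE) &&
      object@kind == "interp")
    return("interp breakpoints must be strictly increasing")
  TRUE
})

#' CurveSet: all variables' curves for one record
#'
#' Complete over a variable catalog: every catalog variable has an entry
#' (fallback curves stand in for unobserved variables, never an absence).
#'
#' @slot recordId record identifier
#' @slot span record span in days
#' @slot curves named list of [ClinicalCurve-class], one per catalog variable
#' @exportClass CurveSet
setClass("CurveSet",
  slots = c(recordId = "character", span = "numeric", curves = "list"))

# ---------------------------------------------------------------------------
# Matrices as SummarizedExperiments
# ---------------------------------------------------------------------------

#' CrossSectionMatrix: stacked standardizable cross-sections
#'
#' A [SummarizedExperiment-class] whose single assay `"values"` holds the
#' n_variables x t_samples matrix of curve values; `rowData` carries the
#' variable catalog (variable_id, mode, vocabulary) and `colData` the sampling
#' provenance (record_id, sample_day).
#'
#' @exportClass CrossSectionMatrix
setClass("CrossSectionMatrix", contains = "SummarizedExperiment")

setValidity("CrossSectionMatrix", function(object) {
  a <- SummarizedExperiment::assayNames(object)
  if (!"values" %in% a) return("assay 'values' required")
  v <- SummarizedExperiment::assay(object, "values")
  if (any(!is.finite(v))) return("cross-section values must be finite")
  cd <- SummarizedExperiment::colData(object)
  if (!all(c("record_id", "sample_day") %in% names(cd)))
    return("colData must carry record_id and sample_day provenance")
  rd <- SummarizedExperiment::rowData(object)
  if (!all(c("variable_id", "mode") %in% names(rd)))
    return("rowData must carry the variable catalog (variable_id, mode)")
  TRUE
})

#' SourceExpressionMatrix: inferred latent-source expressions
#'
#' A [SummarizedExperiment-class] with assay `"expressions"` (m_sources x
#' t_samples); `colData` shares the provenance of the cross-section matrix the
#' expressions were inferred from.
#'
#' @exportClass SourceExpressionMatrix
setClass("SourceExpressionMatrix", contains = "SummarizedExperiment")

# ---------------------------------------------------------------------------
# Standardizer
# ---------------------------------------------------------------------------

#' Standardizer: invertible per-variable affine scaling
#'
#' @slot center,scale named numeric, per-variable; `scale > 0` always
#'   (degenerate zero-variance variables get scale 1 and are listed in
#'   `degenerate`).
#' @slot degenerate ids of variables with zero variance on the fitting set
#' @exportClass Standardizer
setClass("Standardizer",
  slots = c(center = "numeric", scale = "numeric", degenerate = "character"))

setValidity("Standardizer", function(object) {
  if (length(object@center) != length(object@scale))
    return("center/scale length mismatch")
  if (any(object@scale <= 0)) return("scales must be > 0")
  TRUE
})

# ---------------------------------------------------------------------------
# SignatureModel
# ---------------------------------------------------------------------------

#' SignatureModel: PCA whitening + ICA decomposition with scaling conventions
#'
#' Holds everything needed to map a standardized cross-section x to scaled
#' source expressions and back: the PCA basis used for reduction, the ICA
#' mixing matrix A (columns are clinical signatures in standardized space),
#' the unmixing matrix U with `U %*% A = I` on the retained subspace, and the
#' per-source affine (center, scale) fixing expressions to mean 0, SD 0.5 on
#' the discovery set.
#'
#' @slot m number of latent sources
#' @slot catalog variable catalog (DataFrame: variable_id, mode, ...)
#' @slot standardizer the [Standardizer-class] fitted on the discovery set
#' @slot pcaMean per-variable mean removed before PCA
#' @slot pcaBasis n x m orthonormal basis
#' @slot pcaVar per-component variances (eigenvalues)
#' @slot mixing n x m matrix A
#' @slot unmixing m x n matrix U
#' @slot sourceCenter,sourceScale per-source affine: scaled = (raw - center) * scale
#' @slot scaled has [scaleExpressions()] been applied (guarded to run once)
#' @slot convergence list(converged, iterations, tol)
#' @slot seed ICA initialization seed
#' @exportClass SignatureModel
setClass("SignatureModel",
  slots = c(m = "integer", catalog = "DataFrame",
            standardizer = "Standardizer",
            pcaMean = "numeric", pcaBasis = "matrix", pcaVar = "numeric",
            mixing = "matrix", unmixing = "matrix",
            sourceCenter = "numeric", sourceScale = "numeric",
            scaled = "logical", convergence = "list", seed = "integer"))

setValidity("SignatureModel", function(object) {
  m <- object@m
  if (ncol(object@mixing) != m || nrow(object@unmixing) != m)
    return("mixing/unmixing dimensions disagree with m")
  if (nrow(object@mixing) != ncol(object@unmixing))
    return("mixing rows != unmixing columns")
  ua <- object@unmixing %*% object@mixing
  if (max(abs(ua - diag(m))) > 1e-6)
    return("unmixing %*% mixing must be the identity on the retained subspace")
  TRUE
})

# ---------------------------------------------------------------------------
# ShapleyExplanation
# ---------------------------------------------------------------------------

#' ShapleyExplanation: per-sample, per-feature attributions
#'
#' Monte-Carlo permutation estimate of marginal-expectation Shapley values.
#' Efficiency holds by construction: `baseValue + rowSums(values)` equals the
#' model prediction for every explained sample (exactly, because the full
#' background is reused at every coalition so the per-permutation sums
#' telescope).
#'
#' @slot values samples x features attribution matrix
#' @slot baseValue expected prediction over the background set
#' @slot predictions model predictions for the explained samples
#' @slot nPermutations,seed estimator metadata
#' @exportClass ShapleyExplanation
setClass("ShapleyExplanation",
  slots = c(values = "matrix", baseValue = "numeric",
            predictions = "numeric", nPermutations = "integer",
            seed = "integer"))

setValidity("ShapleyExplanation", function(object) {
  if (length(object@predictions) != nrow(object@values))
    return("predictions length must match explained samples")
  resid <- abs(object@baseValue + rowSums(object@values) - object@predictions)
  if (any(resid > 1e-6 + 1e-6 * abs(object@predictions)))
    return("efficiency violated: base + sum(attributions) != prediction")
  TRUE
})

# ---------------------------------------------------------------------------
# GroundTruth for the synthetic generator
# ---------------------------------------------------------------------------

#' GroundTruth: latent-source world underlying a synthetic cohort
#'
#' @slot nVars,mSources dimensions
#' @slot mixing n x m sparse true mixing matrix, unit-norm columns
#' @slot catalog data.frame(variable_id, mode) for the synthetic variables
#' @slot sourceSparsity probability a source is active in a record
#' @slot sourceScale SD of active-source expressions (Laplace law)
#' @slot amplitude per-variable effect scale of one expression unit (the
#'   latent profile is `amplitude * mixing %*% s`)
#' @slot causalSources indices of sources that drive the outcome
#' @slot outcomeWeights per-causal-source log-odds weights
#' @slot demoSources indices of the two sources that drive demographics
#' @slot labBaseline per-lab-variable baseline level
#' @exportClass GroundTruth
setClass("GroundTruth",
  slots = c(nVars = "integer", mSources = "integer", mixing = "matrix",
            catalog = "data.frame", sourceSparsity = "numeric",
            sourceScale = "numeric", amplitude = "numeric",
            causalSources = "integer",
            outcomeWeights = "numeric", demoSources = "integer",
            labBaseline = "numeric"))

setValidity("GroundTruth", function(object) {
  if (object@mSources < 2L) return("at least 2 sources required")
  if (!identical(dim(object@mixing),
                 c(object@nVars, object@mSources)))
    return("mixing must be nVars x mSources")
  nrm <- sqrt(colSums(object@mixing^2))
  if (any(abs(nrm - 1) > 1e-8)) return("mixing columns must be unit-norm")
  if (!all(object@causalSources %in% seq_len(object@mSources)))
    return("causalSources out of range")
  if (length(object@outcomeWeights) != length(object@causalSources))
    return("one outcome weight per causal source")
  TRUE
})
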