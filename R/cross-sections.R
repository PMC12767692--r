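#' @include AllClasses.R AllGenerics.R
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   rowData colData
#' @importFrom S4Vectors DataFrame
NULL

#' Sample cross-section times for one record
#'
#' The number of samples is Poisson with mean `span_years * densityPerYear`
#' (default one sample per three record-years) and the times are i.i.d.
#' uniform on `[0, span]`: a record may be sampled once, more than once, or
#' not at all, with longer records sampled more often on average.
#'
#' @param spanDays record span in days (>= 0).
#' @param densityPerYear mean sampling density (samples per record-year).
#' @return numeric vector of sampled days (possibly empty).
#' @export
sampleTimes <- function(spanDays, densityPerYear = 1 / 3) {
  stopifnot(spanDays >= 0, densityPerYear >= 0)
  n <- rpois(1L, spanDays / DAYS_PER_YEAR * densityPerYear)
  runif(n, 0, spanDays)
}

#' Sampling plan over a cohort's curve sets
#'
#' @param curvesets named list of [CurveSet-class]
#' @param densityPerYear samples per record-year.
#' @param seed RNG seed for reproducible plans.
#' @return data.frame(record_id, sample_day).
#' @export
samplingPlan <- function(curvesets, densityPerYear = 1 / 3, seed = 1L) {
  set.seed(seed)
  rows <- lapply(curvesets, function(cs) {
    d <- sampleTimes(cs@span, densityPerYear)
    if (length(d)) data.frame(record_id = cs@recordId, sample_day = d)
    else NULL
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(record_id = character(), sample_day = numeric())
  rownames(out) <- NULL
  out
}

#' Plan taking exactly one cross-section per record at its index day
#'
#' Used for the evaluation set, where prediction uses the state of the record
#' at the anchoring event.
#'
#' @param x an [EHRCohort-class] with index days present.
#' @return data.frame(record_id, sample_day).
#' @export
indexDayPlan <- function(x) {
  stopifnot(is(x, "EHRCohort"), all(!is.na(indexDays(x))))
  data.frame(record_id = recordIds(x),
             sample_day = unname(indexDays(x)[recordIds(x)]))
}

#' Assemble the cross-section data matrix
#'
#' Column j of the matrix holds every catalog variable's curve value for
#' record `plan$record_id[j]` at day `plan$sample_day[j]`; the variable
#' (row) order is the catalog order.
#'
#' @param curvesets named list of [CurveSet-class], complete over the
#'   catalog.
#' @param plan data.frame(record_id, sample_day) from [samplingPlan()] or
#'   [indexDayPlan()].
#' @param catalog variable catalog fixing row order.
#' @return a [CrossSectionMatrix-class] (n_vars x nrow(plan)).
#' @export
assembleMatrix <- function(curvesets, plan, catalog) {
  nv <- nrow(catalog)
  t <- nrow(plan)
  vals <- matrix(NA_real_, nv, t,
                 dimnames = list(catalog$variable_id, NULL))
  byRec <- split(seq_len(t), plan$record_id)
  for (rid in names(byRec)) {
    cs <- curvesets[[rid]]
    if (is.null(cs)) stop("no curve set for record ", rid)
    cols <- byRec[[rid]]
    days <- plan$sample_day[cols]
    for (i in seq_len(nv)) {
      cv <- cs@curves[[catalog$variable_id[i]]]
      if (is.null(cv)) stop("curve set incomplete for record ", rid)
      vals[i, cols] <- curveValue(cv, days)
    }
  }
  if (any(!is.finite(vals)))
    stop("internal error: curve undefined at a sampled day")
  CrossSectionMatrix(vals, catalog, plan)
}

#' Construct a CrossSectionMatrix
#'
#' @param values n_vars x t matrix.
#' @param catalog variable catalog (rows).
#' @param provenance data.frame(record_id, sample_day) (columns).
#' @return a [CrossSectionMatrix-class]
#' @export
CrossSectionMatrix <- function(values, catalog, provenance) {
  stopifnot(nrow(values) == nrow(catalog),
            ncol(values) == nrow(provenance))
  rownames(values) <- catalog$variable_id
  new("CrossSectionMatrix", SummarizedExperiment(
    assays = list(values = values),
    rowData = DataFrame(catalog),
    colData = DataFrame(provenance)))
}

#' @describeIn CrossSectionMatrix the values matrix.
#' @param x a [CrossSectionMatrix-class]
#' @export
xsValues <- function(x) assay(x, "values")

#' Fit a per-variable standardizer
#'
#' Centers and scales each variable (matrix row) to zero mean and unit
#' variance across samples, putting all variables onto roughly the same
#' scale. Zero-variance variables get scale 1 (with a warning) so the map
#' stays invertible.
#'
#' @param x a [CrossSectionMatrix-class] with at least 2 samples.
#' @return a [Standardizer-class]
#' @export
fitStandardizer <- function(x) {
  v <- xsValues(x)
  if (ncol(v) < 2L) stop("fitStandardizer: need at least 2 samples")
  ctr <- rowMeans(v)
  sc <- apply(v, 1L, sd)
  degen <- rownames(v)[sc <= .Machine$double.eps * 10]
  if (length(degen)) {
    warning("zero-variance variable(s): ", paste(degen, collapse = ", "),
            "; scale set to 1")
    sc[degen] <- 1
  }
  new("Standardizer", center = ctr, scale = sc, degenerate = degen)
}

#' Apply / invert a standardizer
#'
#' `applyStandardizer` maps values to standardized space; `invertStandardizer`
#' is its exact inverse (round trip to 1e-9).
#'
#' @param std a [Standardizer-class]
#' @param x a [CrossSectionMatrix-class] over the same variables.
#' @return a [CrossSectionMatrix-class] with transformed values.
#' @export
applyStandardizer <- function(std, x) {
  v <- xsValues(x)
  stopifnot(identical(rownames(v), names(std@center)))
  v <- (v - std@center) / std@scale
  out <- x
  SummarizedExperiment::assay(out, "values") <- v
  out
}

#' @rdname applyStandardizer
#' @export
invertStandardizer <- function(std, x) {
  v <- xsValues(x)
  stopifnot(identical(rownames(v), names(std@center)))
  v <- v * std@scale + std@center
  out <- x
  SummarizedExperiment::assay(out, "values") <- v
  out
}
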