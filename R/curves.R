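#' @include AllClasses.R AllGenerics.R
NULL

#' Evaluate a clinical curve
#'
#' @param curve a [ClinicalCurve-class]
#' @param day numeric vector of days (in `[0, span]`).
#' @return numeric vector of curve values; always finite.
#' @name curveValue
#' @aliases curveValue,ClinicalCurve-method
setMethod("curveValue", "ClinicalCurve", function(curve, day) {
  switch(curve@kind,
    constant = rep(curve@constant, length(day)),
    linear = curve@params$intercept + curve@params$slope * day,
    interp = {
      x <- curve@x; y <- curve@y
      if (length(x) == 1L) rep(y, length(day))
      else {
        m <- curve@params$slopes
        if (is.null(m)) m <- .fcSlopes(x, y)
        .hermiteEval(pmin(pmax(day, x[1]), x[length(x)]), x, y, m)
      }
    },
    step = {
      # value 1 on the union of persistence intervals
      b <- curve@params$bounds   # matrix: start, end (merged, disjoint)
      if (is.null(b) || nrow(b) == 0L) rep(0, length(day))
      else {
        out <- numeric(length(day))
        for (i in seq_len(nrow(b)))
          out[day >= b[i, 1] & day <= b[i, 2]] <- 1
        out
      }
    },
    kernelrate = {
      log(.kernelRate(day, curve@x, curve@span, curve@params$bandwidth) +
            curve@params$floorRate)
    },
    stop("unknown curve kind"))
})

# Fritsch-Carlson limited slopes for a shape-preserving cubic Hermite
# interpolant: zero slope wherever the secants change sign (local extrema
# sit exactly on observations) and |m| capped at 3x the adjacent secants,
# so every piece is monotone between its endpoints - no overshoot.
.fcSlopes <- function(x, y) {
  n <- length(x)
  s <- diff(y) / diff(x)
  m <- numeric(n)
  m[1] <- s[1]; m[n] <- s[n - 1L]
  if (n > 2L) {
    for (i in 2:(n - 1L)) {
      if (s[i - 1L] * s[i] <= 0) m[i] <- 0
      else m[i] <- (s[i - 1L] + s[i]) / 2
    }
  }
  for (i in seq_len(n - 1L)) {
    if (s[i] == 0) { m[i] <- 0; m[i + 1L] <- 0 }
    else {
      cap <- 3 * abs(s[i])
      if (abs(m[i]) > cap) m[i] <- sign(m[i]) * cap
      if (abs(m[i + 1L]) > cap) m[i + 1L] <- sign(m[i + 1L]) * cap
    }
  }
  m
}

.hermiteEval <- function(xq, x, y, m) {
  i <- findInterval(xq, x, rightmost.closed = TRUE)
  i[i < 1L] <- 1L
  i[i >= length(x)] <- length(x) - 1L
  h <- x[i + 1L] - x[i]
  t <- (xq - x[i]) / h
  h00 <- (1 + 2 * t) * (1 - t)^2
  h10 <- t * (1 - t)^2
  h01 <- t^2 * (3 - 2 * t)
  h11 <- t^2 * (t - 1)
  h00 * y[i] + h10 * h * m[i] + h01 * y[i + 1L] + h11 * h * m[i + 1L]
}

# Gaussian-kernel event-rate estimate in events/year with reflection
# boundary correction at 0 and span (keeps each event's unit mass inside
# the record, so the integrated rate conserves the event count).
.kernelRate <- function(day, events, span, bandwidth) {
  if (length(events) == 0L) return(rep(0, length(day)))
  dd <- outer(day, events, `-`)
  out <- rowSums(stats::dnorm(dd, 0, bandwidth)) +
    rowSums(stats::dnorm(outer(day, -events, `-`), 0, bandwidth)) +
    rowSums(stats::dnorm(outer(day, 2 * span - events, `-`), 0, bandwidth))
  out * DAYS_PER_YEAR    # events/day -> events/year
}

#' Laboratory-value curve
#'
#' Shape-preserving monotone-cubic interpolation through the observations
#' (exact at every observation day, no overshoot between points, constant
#' extrapolation beyond the first/last observation). With no observations the
#' curve is the constant population median. Same-day duplicate observations
#' are averaged before fitting.
#'
#' @param days,values observation days and values (sorted by day).
#' @param populationMedian fallback level when the record has no observations
#'   of this test.
#' @param span record span in days.
#' @return a [ClinicalCurve-class] (mode "lab", identity scale).
#' @export
labCurve <- function(days, values, populationMedian, span = max(days, 0)) {
  stopifnot(length(days) == length(values), is.finite(populationMedian))
  if (length(days) == 0L)
    return(new("ClinicalCurve", kind = "constant", mode = "lab",
               transform = "identity", constant = populationMedian,
               span = span))
  if (anyDuplicated(days)) {
    values <- as.numeric(tapply(values, days, mean))
    days <- sort(unique(days))
  }
  if (length(days) == 1L)
    return(new("ClinicalCurve", kind = "constant", mode = "lab",
               transform = "identity", constant = values[1], span = span))
  o <- order(days)
  new("ClinicalCurve", kind = "interp", mode = "lab",
      transform = "identity", x = days[o], y = values[o], span = span,
      params = list(slopes = .fcSlopes(days[o], values[o])))
}

#' Billing-code intensity curve
#'
#' Treats code occurrences as a probabilistic point process and estimates a
#' smooth occurrence rate (events/year) by Gaussian-kernel smoothing with
#' reflection boundary correction, stored on the log scale:
#' `value = log(rate + floorRate)`. With zero events the curve is the
#' constant `log(floorRate)`. The integral of `exp(value) - floorRate` over
#' the record recovers the event count (mass conservation).
#'
#' @param days event days.
#' @param span record span in days (> 0).
#' @param bandwidthDays Gaussian kernel SD in days.
#' @param floorRate additive rate floor (events/year) making the log finite.
#' @return a [ClinicalCurve-class] (mode "code", log scale).
#' @export
codeIntensityCurve <- function(days, span, bandwidthDays = 180,
                               floorRate = 0.01) {
  stopifnot(bandwidthDays > 0, floorRate > 0)
  if (span <= 0) stop("codeIntensityCurve: span must be > 0")
  if (length(days) == 0L)
    return(new("ClinicalCurve", kind = "constant", mode = "code",
               transform = "log", constant = log(floorRate), span = span))
  new("ClinicalCurve", kind = "kernelrate", mode = "code", transform = "log",
      x = as.numeric(days), span = span,
      params = list(bandwidth = bandwidthDays, floorRate = floorRate))
}

#' Medication presence curve
#'
#' Piecewise-constant 0/1 curve: 1 on the union of
#' `[mention_day, mention_day + persistenceDays]` intervals, 0 elsewhere;
#' overlapping mentions merge (values never exceed 1).
#'
#' @param days mention days.
#' @param persistenceDays assumed exposure persistence after a mention (> 0).
#' @param span record span in days.
#' @return a [ClinicalCurve-class] (mode "med").
#' @export
medicationCurve <- function(days, persistenceDays = 90, span = max(days, 0)) {
  stopifnot(persistenceDays > 0)
  if (length(days) == 0L)
    return(new("ClinicalCurve", kind = "constant", mode = "med",
               transform = "identity", constant = 0, span = span))
  days <- sort(as.numeric(days))
  starts <- days; ends <- days + persistenceDays
  # merge overlapping intervals
  ms <- starts[1]; me <- ends[1]; bounds <- NULL
  for (i in seq_along(starts)[-1]) {
    if (starts[i] <= me) me <- max(me, ends[i])
    else { bounds <- rbind(bounds, c(ms, me)); ms <- starts[i]; me <- ends[i] }
  }
  bounds <- rbind(bounds, c(ms, me))
  new("ClinicalCurve", kind = "step", mode = "med", transform = "identity",
      x = days, span = span, params = list(bounds = bounds))
}

#' Demographic indicator curves
#'
#' Constant 1 for the record's sex/race level and 0 for all others (unknown
#' levels give all-zero indicators); age is a linearly increasing curve,
#' `(day - birth_day_offset)/365.25` years.
#'
#' @param sex,race categorical values for the record.
#' @param birthDayOffset birth day relative to record start (usually
#'   negative).
#' @param catalog variable catalog (rows with mode "demo" are filled).
#' @param span record span in days.
#' @return named list of [ClinicalCurve-class], one per demo catalog variable.
#' @export
demographicCurves <- function(sex, race, birthDayOffset, catalog,
                              span = 0) {
  dc <- catalog[catalog$mode == "demo", , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(dc))) {
    vid <- dc$variable_id[i]
    if (dc$vocabulary_id[i] == "age") {
      out[[vid]] <- new("ClinicalCurve", kind = "linear", mode = "demo",
                        transform = "identity", span = span,
                        params = list(intercept = -birthDayOffset /
                                        DAYS_PER_YEAR,
                                      slope = 1 / DAYS_PER_YEAR))
    } else {
      level <- sub("^(sex|race)_", "", vid)
      val <- if (dc$vocabulary_id[i] == "sex") as.character(sex)
             else as.character(race)
      out[[vid]] <- new("ClinicalCurve", kind = "constant", mode = "demo",
                        transform = "identity",
                        constant = as.numeric(identical(level, val)),
                        span = span)
    }
  }
  out
}

#' Build the complete curve set for one record
#'
#' One curve per catalog variable: labs via [labCurve()] (population median
#' fallback), codes via [codeIntensityCurve()], medications via
#' [medicationCurve()], demographics via [demographicCurves()]. The returned
#' set is complete over the catalog by construction.
#'
#' @param record a record list as returned by [getRecord()].
#' @param catalog variable catalog from [buildCatalog()].
#' @param populationMedians named numeric of per-test fallback medians.
#' @param bandwidthDays,floorRate,persistenceDays mode parameters, see the
#'   per-mode constructors.
#' @return a [CurveSet-class]
#' @export
recordCurveSet <- function(record, catalog, populationMedians,
                           bandwidthDays = 180, floorRate = 0.01,
                           persistenceDays = 90) {
  span <- max(record$span_days, 1)
  curves <- vector("list", nrow(catalog))
  names(curves) <- catalog$variable_id
  labs <- record$labs; codes <- record$codes; meds <- record$meds
  labSplit <- if (nrow(labs)) split(labs, labs$test_id) else list()
  codeSplit <- if (nrow(codes)) split(codes$day, codes$code_id) else list()
  medSplit <- if (nrow(meds)) split(meds$day, meds$med_id) else list()
  for (i in seq_len(nrow(catalog))) {
    vid <- catalog$variable_id[i]
    curves[[vid]] <- switch(catalog$mode[i],
      lab = {
        obs <- labSplit[[vid]]
        if (is.null(obs))
          labCurve(numeric(), numeric(),
                   populationMedians[[vid]] %||% 0, span)
        else labCurve(obs$day, obs$value,
                      populationMedians[[vid]] %||% median(obs$value), span)
      },
      code = codeIntensityCurve(codeSplit[[vid]] %||% numeric(), span,
                                bandwidthDays, floorRate),
      med = medicationCurve(medSplit[[vid]] %||% numeric(),
                            persistenceDays, span),
      demo = NULL)
  }
  dc <- demographicCurves(record$demographics$sex[1],
                          record$demographics$race[1],
                          record$demographics$birth_day_offset[1],
                          catalog, span)
  curves[names(dc)] <- dc
  new("CurveSet", recordId = record$record_id, span = span, curves = curves)
}

#' Per-test population medians
#'
#' @param x an [EHRCohort-class]
#' @param catalog variable catalog.
#' @return named numeric, median observed value per laboratory test (0 for
#'   tests never observed in the cohort).
#' @export
populationMedians <- function(x, catalog) {
  labIds <- catalog$variable_id[catalog$mode == "lab"]
  out <- setNames(rep(0, length(labIds)), labIds)
  if (nrow(x@labs)) {
    med <- tapply(x@labs$value, x@labs$test_id, median)
    out[names(med)] <- med
  }
  out
}

#' Curve sets for a whole cohort
#'
#' @inheritParams recordCurveSet
#' @param x an [EHRCohort-class]
#' @param catalog variable catalog; defaults to [buildCatalog()] of `x`.
#' @param populationMedians per-test fallbacks; computed from `x` if NULL.
#' @return named list of [CurveSet-class], one per record.
#' @export
cohortCurves <- function(x, catalog = buildCatalog(x),
                         populationMedians = NULL, bandwidthDays = 180,
                         floorRate = 0.01, persistenceDays = 90) {
  stopifnot(is(x, "EHRCohort"))
  pm <- populationMedians %||% populationMedians(x, catalog)
  ids <- recordIds(x)
  labSplit <- split(x@labs, x@labs$record_id)
  codeSplit <- split(x@codes, x@codes$record_id)
  medSplit <- split(x@meds, x@meds$record_id)
  demoSplit <- split(x@demo, x@demo$record_id)
  empty <- list(labs = .emptyLabs(), codes = .emptyCodes(),
                meds = .emptyMeds())
  out <- lapply(ids, function(id) {
    rec <- list(record_id = id, span_days = unname(x@spans[id]),
                labs = labSplit[[id]] %||% empty$labs,
                codes = codeSplit[[id]] %||% empty$codes,
                meds = medSplit[[id]] %||% empty$meds,
                demographics = demoSplit[[id]])
    recordCurveSet(rec, catalog, pm, bandwidthDays, floorRate,
                   persistenceDays)
  })
  names(out) <- ids
  out
}
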