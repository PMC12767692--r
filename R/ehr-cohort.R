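#' @include AllClasses.R AllGenerics.R
NULL

.emptyLabs <- function() data.frame(record_id = character(), day = numeric(),
                                    test_id = character(), value = numeric(),
                                    stringsAsFactors = FALSE)
.emptyCodes <- function() data.frame(record_id = character(), day = numeric(),
                                     code_id = character(),
                                     stringsAsFactors = FALSE)
.emptyMeds <- function() data.frame(record_id = character(), day = numeric(),
                                    med_id = character(),
                                    stringsAsFactors = FALSE)

.sortEvents <- function(df) {
  if (nrow(df))
    df[order(df$record_id, df$day, method = "radix"), , drop = FALSE]
  else df
}

#' Construct an EHRCohort
#'
#' @param demo data.frame with columns record_id, sex, race, birth_day_offset;
#'   one row per record (defines the cohort membership).
#' @param labs,codes,meds long-format event tables (see [EHRCohort-class]);
#'   may be empty.
#' @param index optional data.frame(record_id, index_day) or named numeric.
#' @param spans optional data.frame(record_id, span_days) or named numeric;
#'   defaults to each record's last event day (0 if no events).
#' @param labels optional data.frame(record_id, label) or named character with
#'   values "positive"/"negative".
#' @return an [EHRCohort-class]
#' @export
EHRCohort <- function(demo, labs = .emptyLabs(), codes = .emptyCodes(),
                      meds = .emptyMeds(), index = NULL, spans = NULL,
                      labels = NULL) {
  demo <- as.data.frame(demo)
  ids <- as.character(demo$record_id)
  labs <- .sortEvents(as.data.frame(labs))
  codes <- .sortEvents(as.data.frame(codes))
  meds <- .sortEvents(as.data.frame(meds))
  asNamed <- function(x, col, default) {
    out <- setNames(rep(default, length(ids)), ids)
    if (is.null(x)) return(out)
    if (is.data.frame(x)) {
      out[as.character(x$record_id)] <- x[[col]]
    } else out[names(x)] <- x
    out
  }
  if (is.null(spans)) {
    spans <- setNames(numeric(length(ids)), ids)
    for (df in list(labs, codes, meds)) {
      if (nrow(df)) {
        mx <- tapply(df$day, df$record_id, max)
        spans[names(mx)] <- pmax(spans[names(mx)], mx)
      }
    }
  } else spans <- asNamed(spans, "span_days", 0)
  index <- asNamed(index, "index_day", NA_real_)
  labels <- asNamed(labels, "label", NA_character_)
  new("EHRCohort", labs = labs, codes = codes, meds = meds, demo = demo,
      index = index, spans = spans, labels = labels)
}

#' Accessors for EHRCohort
#'
#' @param x an [EHRCohort-class]
#' @param value replacement labels (named character)
#' @return the corresponding component.
#' @name EHRCohort-accessors
#' @aliases recordIds nRecords labEvents codeEvents medEvents demographics
#'   indexDays recordSpans recordLabels recordLabels<-
NULL

#' @rdname EHRCohort-accessors
setMethod("recordIds", "EHRCohort", function(x)
  as.character(x@demo$record_id))
#' @rdname EHRCohort-accessors
setMethod("nRecords", "EHRCohort", function(x) nrow(x@demo))
#' @rdname EHRCohort-accessors
setMethod("labEvents", "EHRCohort", function(x) x@labs)
#' @rdname EHRCohort-accessors
setMethod("codeEvents", "EHRCohort", function(x) x@codes)
#' @rdname EHRCohort-accessors
setMethod("medEvents", "EHRCohort", function(x) x@meds)
#' @rdname EHRCohort-accessors
setMethod("demographics", "EHRCohort", function(x) x@demo)
#' @rdname EHRCohort-accessors
setMethod("indexDays", "EHRCohort", function(x) x@index)
#' @rdname EHRCohort-accessors
setMethod("recordSpans", "EHRCohort", function(x) x@spans)
#' @rdname EHRCohort-accessors
setMethod("recordLabels", "EHRCohort", function(x) x@labels)
#' @rdname EHRCohort-accessors
setMethod("recordLabels<-", "EHRCohort", function(x, value) {
  x@labels[names(value)] <- value
  validObject(x)
  x
})

setMethod("show", "EHRCohort", function(object) {
  cat("EHRCohort with", nRecords(object), "records\n")
  cat("  labs:", nrow(object@labs), "observations of",
      length(unique(object@labs$test_id)), "tests\n")
  cat("  codes:", nrow(object@codes), "events of",
      length(unique(object@codes$code_id)), "codes\n")
  cat("  meds:", nrow(object@meds), "mentions of",
      length(unique(object@meds$med_id)), "medications\n")
  nlab <- sum(!is.na(object@labels))
  cat("  index day present:", sum(!is.na(object@index)),
      "| labeled:", nlab, "\n")
})

#' Extract one record as a list
#'
#' @param x an [EHRCohort-class]
#' @param id record identifier
#' @return list with elements record_id, span_days, labs, codes, meds,
#'   demographics, index_day, label.
#' @export
getRecord <- function(x, id) {
  stopifnot(is(x, "EHRCohort"), id %in% recordIds(x))
  pick <- function(df) df[df$record_id == id, , drop = FALSE]
  list(record_id = id,
       span_days = unname(x@spans[id]),
       labs = pick(x@labs), codes = pick(x@codes), meds = pick(x@meds),
       demographics = x@demo[x@demo$record_id == id, , drop = FALSE],
       index_day = unname(x@index[id]),
       label = unname(x@labels[id]))
}

# ---------------------------------------------------------------------------
# Readers / writers: one delimited table per mode, keyed by record_id
# ---------------------------------------------------------------------------

.cohortFiles <- c(labs = "labs.csv", codes = "codes.csv", meds = "meds.csv",
                  demo = "demo.csv", index = "index.csv", spans = "spans.csv",
                  labels = "labels.csv")

#' Read a cohort from its canonical delimited-table layout
#'
#' Expects `labs.csv` (record_id, day, test_id, value), `codes.csv`
#' (record_id, day, code_id), `meds.csv` (record_id, day, med_id),
#' `demo.csv` (record_id, sex, race, birth_day_offset) and optionally
#' `index.csv` (record_id, index_day), `spans.csv` (record_id, span_days),
#' `labels.csv` (record_id, label) under `dir`. Event files may be absent
#' (treated as empty). Events are sorted by day within record; counts are
#' preserved.
#'
#' @param dir directory containing the tables.
#' @return an [EHRCohort-class]
#' @export
readCohort <- function(dir) {
  stopifnot(dir.exists(dir))
  rd <- function(name, required = FALSE, cols = NULL) {
    f <- file.path(dir, .cohortFiles[[name]])
    if (!file.exists(f)) {
      if (required) stop("missing required file: ", f)
      return(NULL)
    }
    df <- as.data.frame(data.table::fread(f, colClasses = list(
      character = "record_id")))
    if (!is.null(cols) && !all(cols %in% names(df)))
      stop("schema error in ", f, ": expected columns ",
           paste(cols, collapse = ", "))
    df
  }
  demo <- rd("demo", required = TRUE,
             cols = c("record_id", "sex", "race", "birth_day_offset"))
  labs <- rd("labs", cols = c("record_id", "day", "test_id", "value"))
  codes <- rd("codes", cols = c("record_id", "day", "code_id"))
  meds <- rd("meds", cols = c("record_id", "day", "med_id"))
  for (df in list(labs, codes, meds))
    if (!is.null(df) && nrow(df) && any(df$day < 0))
      stop("validation error: negative event day")
  EHRCohort(demo,
            labs = labs %||% .emptyLabs(),
            codes = codes %||% .emptyCodes(),
            meds = meds %||% .emptyMeds(),
            index = rd("index"), spans = rd("spans"), labels = rd("labels"))
}

#' Write a cohort in the canonical delimited-table layout
#'
#' Inverse of [readCohort()]: a write/read round trip reproduces every field.
#'
#' @param x an [EHRCohort-class]
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeCohort <- function(x, dir) {
  stopifnot(is(x, "EHRCohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, name) data.table::fwrite(df, file.path(dir,
                                              .cohortFiles[[name]]))
  wr(x@labs, "labs"); wr(x@codes, "codes"); wr(x@meds, "meds")
  wr(x@demo, "demo")
  ids <- recordIds(x)
  wr(data.frame(record_id = ids, span_days = unname(x@spans[ids])), "spans")
  if (any(!is.na(x@index)))
    wr(data.frame(record_id = ids, index_day = unname(x@index[ids])), "index")
  if (any(!is.na(x@labels)))
    wr(data.frame(record_id = ids, label = unname(x@labels[ids])), "labels")
  invisible(dir)
}

# ---------------------------------------------------------------------------
# Cohort operations
# ---------------------------------------------------------------------------

#' Truncate every record at its index day
#'
#' Drops all events occurring after the index day and sets each record's span
#' to the index day, so that no post-index information (other than the label)
#' remains. Idempotent.
#'
#' @param x an [EHRCohort-class]; every record must have an index day.
#' @param ... unused.
#' @return a truncated [EHRCohort-class]
#' @name truncateAtIndex
#' @aliases truncateAtIndex,EHRCohort-method
setMethod("truncateAtIndex", "EHRCohort", function(x, ...) {
  if (any(is.na(x@index)))
    stop("truncateAtIndex: every record needs an index day")
  keep <- function(df) df[df$day <= x@index[df$record_id] + 1e-12, ,
                          drop = FALSE]
  new("EHRCohort", labs = keep(x@labs), codes = keep(x@codes),
      meds = keep(x@meds), demo = x@demo, index = x@index,
      spans = x@index, labels = x@labels)
})

#' Outcome labeling from post-index malignancy codes
#'
#' A record is \emph{positive} if any malignancy code occurs on relative day
#' `d - index_day` within the closed window `[lo, hi]` (default `[4, 1095]`);
#' \emph{excluded} if any malignancy code occurs before the window opens
#' (same-day/immediate diagnoses and prior cancer history); \emph{negative}
#' otherwise. The result is invariant to event order and to events after the
#' window closes.
#'
#' @param x an [EHRCohort-class] (not yet truncated: labeling needs the
#'   post-index events).
#' @param malignancyCodes nonempty character vector of malignancy code ids.
#' @param window inclusive `[lo, hi]` relative-day window.
#' @param ... unused.
#' @return factor per record with levels positive/negative/excluded, named by
#'   record id.
#' @name assignLabels
#' @aliases assignLabels,EHRCohort-method
setMethod("assignLabels", "EHRCohort",
  function(x, malignancyCodes, window = c(4, 1095), ...) {
  if (length(malignancyCodes) == 0L)
    stop("configuration error: empty malignancy code set")
  stopifnot(length(window) == 2L, window[1] <= window[2])
  if (any(is.na(x@index)))
    stop("assignLabels: every record needs an index day")
  ids <- recordIds(x)
  out <- setNames(rep("negative", length(ids)), ids)
  ev <- x@codes[x@codes$code_id %in% malignancyCodes, , drop = FALSE]
  if (nrow(ev)) {
    rel <- ev$day - x@index[ev$record_id]
    pos <- unique(ev$record_id[rel >= window[1] & rel <= window[2]])
    excl <- unique(ev$record_id[rel < window[1]])
    out[pos] <- "positive"
    out[excl] <- "excluded"   # exclusion overrides: prior/same-day cancer
  }
  factor(out, levels = c("positive", "negative", "excluded"))
})

#' Cohort summary statistics
#'
#' Per-stratum counts and percentages for sex and race, and per-record
#' medians with interquartile intervals (IQI, the central 50% range) for
#' record length, per-mode event counts, and unique-vocabulary counts.
#'
#' @param x a nonempty [EHRCohort-class]
#' @param ... unused.
#' @return list with elements `n`, `strata` (data.frame: field, level, count,
#'   percent) and `perRecord` (data.frame: statistic, median, q25, q75).
#' @name cohortSummary
#' @aliases cohortSummary,EHRCohort-method
setMethod("cohortSummary", "EHRCohort", function(x, ...) {
  n <- nRecords(x)
  if (n == 0L) stop("empty cohort")
  ids <- recordIds(x)
  strat <- do.call(rbind, lapply(c("sex", "race"), function(f) {
    tb <- table(x@demo[[f]])
    data.frame(field = f, level = names(tb), count = as.integer(tb),
               percent = 100 * as.integer(tb) / n)
  }))
  cnt <- function(df, idcol = NULL) {
    tot <- setNames(integer(length(ids)), ids)
    if (nrow(df)) {
      if (is.null(idcol)) tb <- table(df$record_id)
      else tb <- tapply(df[[idcol]], df$record_id,
                        function(v) length(unique(v)))
      tot[names(tb)] <- as.integer(tb)
    }
    tot
  }
  stats <- list(
    record_length_days = unname(x@spans[ids]),
    n_billing_codes = cnt(x@codes),
    n_lab_results = cnt(x@labs),
    n_med_mentions = cnt(x@meds),
    unique_billing_codes = cnt(x@codes, "code_id"),
    unique_lab_tests = cnt(x@labs, "test_id"),
    unique_medications = cnt(x@meds, "med_id"))
  perRecord <- data.frame(
    statistic = names(stats),
    median = vapply(stats, median, 0),
    q25 = vapply(stats, function(v) unname(quantile(v, 0.25)), 0),
    q75 = vapply(stats, function(v) unname(quantile(v, 0.75)), 0),
    row.names = NULL)
  list(n = n, strata = strat, perRecord = perRecord)
})

#' Build a variable catalog from a cohort
#'
#' Fixes the matrix row order for all downstream stages: laboratory tests,
#' then billing codes, then medications, then demographic indicator variables
#' (one 0/1 variable per declared sex/race level, plus age).
#'
#' @param x an [EHRCohort-class]
#' @param sexLevels,raceLevels declared vocabularies for the categorical
#'   fields; defaults to the levels observed in the cohort.
#' @return data.frame(variable_id, mode, vocabulary_id) with unique
#'   variable_ids in fixed order.
#' @export
buildCatalog <- function(x, sexLevels = NULL, raceLevels = NULL) {
  stopifnot(is(x, "EHRCohort"))
  sexLevels <- sexLevels %||% sort(unique(as.character(x@demo$sex)))
  raceLevels <- raceLevels %||% sort(unique(as.character(x@demo$race)))
  mk <- function(id, mode, vocab) if (length(id))
    data.frame(variable_id = id, mode = mode, vocabulary_id = vocab) else NULL
  cat <- rbind(
    mk(sort(unique(x@labs$test_id)), "lab", "lab"),
    mk(sort(unique(x@codes$code_id)), "code", "code"),
    mk(sort(unique(x@meds$med_id)), "med", "med"),
    mk(paste0("sex_", sexLevels), "demo", "sex"),
    mk(paste0("race_", raceLevels), "demo", "race"),
    mk("age_years", "demo", "age"))
  stopifnot(!anyDuplicated(cat$variable_id))
  rownames(cat) <- NULL
  cat
}
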