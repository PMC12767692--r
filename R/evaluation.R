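#' @include AllClasses.R AllGenerics.R
NULL

#' Minimum-cost bipartite assignment (Hungarian method)
#'
#' Jonker–Volgenant shortest-augmenting-path variant, O(n^3). Rectangular
#' matrices (rows <= cols) are handled by leaving extra columns unassigned.
#'
#' @param cost numeric cost matrix (nrow <= ncol).
#' @return integer vector: for each row, the assigned column.
#' @export
solveAssignment <- function(cost) {
  cost <- as.matrix(cost)
  nr <- nrow(cost); nc <- ncol(cost)
  stopifnot(nr >= 1L, nr <= nc, all(is.finite(cost)))
  # pad to square with zero-cost dummy rows
  if (nr < nc) cost <- rbind(cost, matrix(0, nc - nr, nc))
  n <- nc
  # potentials u, v; p[j]: row matched to column j (0 = none). 1-based with
  # a virtual column 0 stored at index 1.
  u <- numeric(n + 1L); v <- numeric(n + 1L)
  p <- integer(n + 1L); way <- integer(n + 1L)
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 1L
    minv <- rep(Inf, n + 1L)
    used <- rep(FALSE, n + 1L)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]; delta <- Inf; j1 <- 0L
      for (j in 2L:(n + 1L)) {
        if (!used[j]) {
          cur <- cost[i0, j - 1L] - u[i0 + 1L] - v[j]
          if (cur < minv[j]) { minv[j] <- cur; way[j] <- j0 }
          if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
        }
      }
      for (j in seq_len(n + 1L)) {
        if (used[j]) { u[p[j] + 1L] <- u[p[j] + 1L] + delta
                       v[j] <- v[j] - delta }
        else minv[j] <- minv[j] - delta
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == 1L) break
    }
  }
  assign <- integer(n)
  for (j in 2L:(n + 1L)) if (p[j] > 0L) assign[p[j]] <- j - 1L
  assign[seq_len(nr)]
}

#' Score recovery of latent sources against ground truth
#'
#' The decomposition is identifiable only up to permutation, sign and
#' positive rescaling of the sources, so recovery is scored by the optimal
#' one-to-one assignment (Hungarian method) maximizing the summed
#' |correlation| between true and estimated expression rows.
#'
#' @param trueS m_true x t matrix of true expressions.
#' @param estS m_est x t matrix of estimated expressions
#'   (`m_est >= m_true`; extra estimated sources stay unmatched).
#' @return list(assignment = data.frame(true_source, est_source, r, abs_r,
#'   sign_agreement), meanAbsR, minAbsR).
#' @export
recoveryScore <- function(trueS, estS) {
  trueS <- as.matrix(trueS); estS <- as.matrix(estS)
  stopifnot(ncol(trueS) == ncol(estS), nrow(trueS) <= nrow(estS))
  keep <- apply(trueS, 1L, sd) > 0
  if (!all(keep)) {
    warning("constant true expression row(s) excluded from matching")
    trueS <- trueS[keep, , drop = FALSE]
  }
  keepE <- apply(estS, 1L, sd) > 0
  estS <- estS[keepE, , drop = FALSE]
  r <- cor(t(trueS), t(estS))           # m_true x m_est
  assign <- solveAssignment(-abs(r))
  rs <- r[cbind(seq_len(nrow(r)), assign)]
  df <- data.frame(
    true_source = rownames(trueS) %||% seq_len(nrow(trueS)),
    est_source = (rownames(estS) %||% seq_len(nrow(estS)))[assign],
    r = rs, abs_r = abs(rs), sign_agreement = rs > 0)
  list(assignment = df, meanAbsR = mean(abs(rs)), minAbsR = min(abs(rs)))
}

# ---------------------------------------------------------------------------
# Reference etiology list metrics
# ---------------------------------------------------------------------------

#' Read a reference etiology list
#'
#' Delimited table with columns `category` (malignant/benign), `element`,
#' `group_key` (elements sharing a signature set, e.g. primary-lung-cancer
#' cell types), `signature_ids` (semicolon-separated, possibly empty) and
#' optional `evidence_grade`.
#'
#' @param path CSV path; defaults to the bundled nodule-etiology reference.
#' @return data.frame with a parsed `signatures` list-column.
#' @export
readReferenceList <- function(path = system.file("extdata",
                                "nodule_etiology_reference.csv",
                                package = "ehrsig")) {
  df <- as.data.frame(data.table::fread(path, colClasses = "character"))
  stopifnot(all(c("category", "element", "group_key", "signature_ids")
                %in% names(df)))
  df$signatures <- lapply(strsplit(df$signature_ids, ";", fixed = TRUE),
                          function(v) v[nzchar(trimws(v))])
  stopifnot(!anyDuplicated(paste(df$category, df$element)))
  df
}

.refSubset <- function(reference, category, granularity) {
  sel <- reference[reference$category == category, , drop = FALSE]
  if (nrow(sel) == 0L) stop("empty category: ", category)
  if (granularity == "element") {
    sel$key <- sel$element
    sigs <- sel$signatures
  } else {
    sel$key <- sel$group_key
    sigs <- lapply(split(sel$signatures, sel$group_key),
                   function(l) unique(unlist(l)))
    sel <- data.frame(key = names(sigs))
  }
  list(keys = unique(sel$key), sigs = sigs)
}

#' Completeness of the discovered signatures against a reference list
#'
#' Fraction of reference elements (or element groups) with at least one
#' matching discovered signature.
#'
#' @param reference data.frame from [readReferenceList()].
#' @param category "malignant" or "benign".
#' @param granularity count per `"element"` row or per `"group"` of rows
#'   sharing a `group_key`.
#' @return list(fraction, matched, total, percent).
#' @export
completeness <- function(reference, category = c("malignant", "benign"),
                         granularity = c("element", "group")) {
  category <- match.arg(category)
  granularity <- match.arg(granularity)
  rs <- .refSubset(reference, category, granularity)
  matched <- sum(vapply(rs$sigs, function(s) length(s) > 0L, NA))
  total <- length(rs$sigs)
  list(fraction = matched / total, matched = matched, total = total,
       percent = round(100 * matched / total))
}

#' Decomposition factor of matched reference elements
#'
#' Mean number of discovered signatures per matched reference element (or
#' group): how finely the model splits each listed cause. The displayed
#' value is truncated toward zero at one decimal; full precision is always
#' returned.
#'
#' @inheritParams completeness
#' @return list(mean, displayed, totalSignatures, matchedElements).
#' @export
decomposition <- function(reference, category = c("malignant", "benign"),
                          granularity = c("element", "group")) {
  category <- match.arg(category)
  granularity <- match.arg(granularity)
  rs <- .refSubset(reference, category, granularity)
  counts <- vapply(rs$sigs, length, 0L)
  counts <- counts[counts > 0L]
  if (length(counts) == 0L)
    stop("no matched elements in category ", category)
  m <- sum(counts) / length(counts)
  list(mean = m, displayed = trunc(m * 10) / 10,
       totalSignatures = sum(counts), matchedElements = length(counts))
}

#' Tally evidence grades among the top-ranked inferred causes
#'
#' @param causes data.frame with columns `evidence` (grade strings; a grade
#'   containing "Direct" counts as directly listed) ordered by causal-effect
#'   rank, or with a `mean_causal_effect` column to order by.
#' @param topK how many top causes to tally (<= nrow).
#' @return list(counts = table of grades, nDirect, topK).
#' @export
tallyEvidence <- function(causes, topK = 20L) {
  stopifnot("evidence" %in% names(causes), topK <= nrow(causes),
            topK >= 0L)
  if ("mean_causal_effect" %in% names(causes))
    causes <- causes[order(-abs(causes$mean_causal_effect)), , drop = FALSE]
  top <- utils::head(causes, topK)
  grades <- c("Direct", "Strong", "Moderate", "Weak", "Mixed", "Absent")
  counts <- vapply(grades, function(g) sum(grepl(g, top$evidence)), 0L)
  list(counts = counts, nDirect = unname(counts["Direct"]), topK = topK)
}

#' Bundled top inferred causes of malignant / benign nodules
#'
#' Transcription of the published top-20 inferred-cause tables (source id,
#' name, polarity-specific mean causal effect, literature evidence grade),
#' used as worked-example fixtures for the evidence tally.
#'
#' @param polarity "malignant" or "benign".
#' @return data.frame ordered by |mean causal effect|.
#' @export
topInferredCauses <- function(polarity = c("malignant", "benign")) {
  polarity <- match.arg(polarity)
  f <- system.file("extdata", sprintf("top_causes_%s.csv", polarity),
                   package = "ehrsig")
  as.data.frame(data.table::fread(f))
}

#' Bundled reference cohort summary counts
#'
#' Transcription of the published data-summary table: per-set record counts
#' and demographic strata for the discovery set and the labeled evaluation
#' set (malignant / benign).
#'
#' @return data.frame(set, field, level, count).
#' @export
referenceCohortCounts <- function() {
  f <- system.file("extdata", "reference_cohort_counts.csv",
                   package = "ehrsig")
  as.data.frame(data.table::fread(f))
}

#' Evaluation-set size from the bundled reference counts
#'
#' @return list(malignant, benign, total).
#' @export
evaluationSetSize <- function() {
  df <- referenceCohortCounts()
  rec <- df[df$field == "n_records" & df$set != "discovery", ]
  out <- setNames(as.list(rec$count), rec$level)
  out$total <- sum(rec$count)
  out
}
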