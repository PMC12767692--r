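#' @include AllClasses.R AllGenerics.R
NULL

#' Sample a latent-source ground truth
#'
#' Builds the hidden world a synthetic cohort is generated from: a sparse
#' n_vars x m_sources mixing matrix with unit-norm, pairwise well-separated
#' columns (|cosine| < 0.95, resampled otherwise), a variable catalog split
#' across the four data modes, a designated set of outcome-driving (causal)
#' sources, and two dedicated demographic sources so that demographic
#' signatures exist to recover.
#'
#' Defaults reflect the study conditions exercised throughout the package:
#' each source is active in a record with probability 0.5, active expressions
#' follow a unit-SD Laplace law (super-Gaussian, as the decomposition
#' requires), and three causal sources carry log-odds weights (4, 4, -4),
#' giving a Bayes-optimal AUC of about 0.92 for the binary outcome.
#'
#' @param nVars number of observed variables (>= mSources).
#' @param mSources number of latent sources (>= 2).
#' @param sparsity expected fraction of nonzero loadings per signature.
#' @param seed RNG seed.
#' @param modeFractions named fractions of variables per mode (lab, code,
#'   med); demographic variables (2 sex + 3 race + age) take the remainder.
#' @param causalSources indices of outcome-driving sources.
#' @param outcomeWeights log-odds weight per causal source.
#' @param sourceSparsity probability a source is active in a record.
#' @param sourceScale SD of active-source expressions.
#' @param amplitude per-variable effect scale of one expression unit:
#'   effects on observed variables are `amplitude * mixing %*% s`, so a
#'   strongly expressed source shifts its loaded labs by a couple of
#'   measurement-noise SDs and multiplies its loaded code rates severalfold
#'   (clinically meaningful effect sizes).
#' @param maxTries resampling budget for degenerate/collinear columns.
#' @return a [GroundTruth-class]
#' @export
sampleGroundTruth <- function(nVars, mSources, sparsity = 0.3, seed = 1L,
                              modeFractions = c(lab = 0.4, code = 0.4,
                                                med = 0.1),
                              causalSources = seq_len(min(3L, mSources - 2L)),
                              outcomeWeights = NULL,
                              sourceSparsity = 0.5, sourceScale = 1,
                              amplitude = 3, maxTries = 100L) {
  stopifnot(nVars >= mSources, mSources >= 2L, sparsity > 0, sparsity <= 1)
  set.seed(seed)
  nDemo <- 6L  # sex_female, sex_male, race_* x3, age_years
  stopifnot(nVars > nDemo + 2L)
  nLab <- max(1L, round((nVars - nDemo) * modeFractions[["lab"]] /
                          sum(modeFractions)))
  nCode <- max(1L, round((nVars - nDemo) * modeFractions[["code"]] /
                           sum(modeFractions)))
  nMed <- nVars - nDemo - nLab - nCode
  stopifnot(nMed >= 1L)
  catalog <- data.frame(
    variable_id = c(sprintf("lab%03d", seq_len(nLab)),
                    sprintf("code%03d", seq_len(nCode)),
                    sprintf("med%03d", seq_len(nMed)),
                    "sex_female", "sex_male",
                    "race_black", "race_other", "race_white", "age_years"),
    mode = c(rep("lab", nLab), rep("code", nCode), rep("med", nMed),
             rep("demo", nDemo)))
  nEvent <- nLab + nCode + nMed
  demoSources <- c(mSources - 1L, mSources)
  sampleCol <- function(j) {
    for (try in seq_len(maxTries)) {
      w <- numeric(nVars)
      if (j %in% demoSources) {
        # demographic sources load on the indicator variables (sex for the
        # first, race for the second) plus a light touch of event variables
        rows <- if (j == demoSources[1]) nEvent + 1:2 else nEvent + 3:5
        w[rows] <- rnorm(length(rows), 0, 1)
        extra <- sample(nEvent, max(1L, round(0.05 * nEvent)))
        w[extra] <- rnorm(length(extra), 0, 0.3)
      } else {
        nz <- which(rbinom(nEvent, 1L, sparsity) == 1L)
        if (length(nz) == 0L) next
        w[nz] <- rnorm(length(nz))
      }
      if (sum(w^2) > 0) return(w / sqrt(sum(w^2)))
    }
    stop("could not sample a nonzero signature column; sparsity too low")
  }
  A <- vapply(seq_len(mSources), sampleCol, numeric(nVars))
  for (try in seq_len(maxTries)) {
    cosMax <- max(abs(crossprod(A)[upper.tri(diag(mSources))]))
    if (cosMax < 0.95) break
    worst <- which(abs(crossprod(A)) * upper.tri(diag(mSources)) == cosMax,
                   arr.ind = TRUE)[1, 2]
    A[, worst] <- sampleCol(worst)
    if (try == maxTries) stop("could not decorrelate signature columns")
  }
  causalSources <- as.integer(causalSources)
  if (is.null(outcomeWeights))
    outcomeWeights <- c(4, 4, -4)[seq_along(causalSources)]
  new("GroundTruth", nVars = as.integer(nVars),
      mSources = as.integer(mSources), mixing = A, catalog = catalog,
      sourceSparsity = sourceSparsity, sourceScale = sourceScale,
      amplitude = amplitude,
      causalSources = causalSources, outcomeWeights = outcomeWeights,
      demoSources = as.integer(demoSources),
      labBaseline = setNames(rnorm(nLab, 50, 10),
                             catalog$variable_id[seq_len(nLab)]))
}

#' Simulation configuration
#'
#' @param nRecords cohort size.
#' @param meanSpanYears mean record length (spans are exponential, matching
#'   the long-tailed lengths of real cohorts).
#' @param labObsRate laboratory observations per variable-year.
#' @param codeBaseRate baseline billing-code events per year.
#' @param medBaseLogit baseline log-odds of medication presence.
#' @param noiseSd SD of Gaussian observation noise on laboratory values.
#' @param seed RNG seed.
#' @return list of class "SimConfig".
#' @export
simConfig <- function(nRecords, meanSpanYears = 10, labObsRate = 4,
                      codeBaseRate = 2, medBaseLogit = -2, noiseSd = 0.25,
                      seed = 1L) {
  stopifnot(nRecords >= 1, meanSpanYears > 0, labObsRate >= 0,
            codeBaseRate >= 0, noiseSd >= 0)
  structure(list(nRecords = as.integer(nRecords),
                 meanSpanYears = meanSpanYears, labObsRate = labObsRate,
                 codeBaseRate = codeBaseRate, medBaseLogit = medBaseLogit,
                 noiseSd = noiseSd, seed = as.integer(seed)),
            class = "SimConfig")
}

#' Draw per-record source expressions
#'
#' Each source is active with probability `sourceSparsity`; active values are
#' zero-mean Laplace with SD `sourceScale`. The two demographic sources are
#' always active (every record has a sex and race). Expressions are constant
#' within a record.
#'
#' @param gt a [GroundTruth-class]
#' @param n number of records.
#' @return m_sources x n matrix of expressions.
#' @export
simulateExpressions <- function(gt, n) {
  m <- gt@mSources
  s <- matrix(rLaplace(m * n, gt@sourceScale), m, n) *
    matrix(rbinom(m * n, 1L, gt@sourceSparsity), m, n)
  s[gt@demoSources, ] <- matrix(rLaplace(length(gt@demoSources) * n,
                                         gt@sourceScale),
                                length(gt@demoSources), n)
  rownames(s) <- sprintf("S%02d", seq_len(m))
  s
}

# demographics are a deterministic readout of the demographic sources'
# expressions: sex by sign, race by terciles
.demoFromSources <- function(gt, s) {
  sexSrc <- s[gt@demoSources[1], ]
  raceSrc <- s[gt@demoSources[2], ]
  qs <- stats::qnorm(c(1 / 3, 2 / 3))  # fixed population cutpoints
  race <- cut(raceSrc, c(-Inf, qs, Inf),
              labels = c("black", "other", "white"))
  data.frame(sex = ifelse(sexSrc > 0, "female", "male"),
             race = as.character(race))
}

#' Simulate one patient record from its latent expressions
#'
#' Given a record's source expressions `s`, the latent per-variable profile
#' is `xstar = mixing %*% s`. Observation processes per mode:
#' \itemize{
#'  \item labs: observed at Poisson-thinned random times at `labObsRate`
#'    per variable-year, value = baseline + xstar + Gaussian noise;
#'  \item codes: Poisson process with log-rate `log(codeBaseRate) + xstar`;
#'  \item meds: present with probability `plogis(medBaseLogit + xstar)`;
#'    if present, mention days are a sparse Poisson process;
#'  \item demographics: sex by the sign of the first demographic source,
#'    race by terciles of the second; age from a uniform birth offset.
#' }
#'
#' @param gt a [GroundTruth-class]
#' @param cfg a [simConfig()] (its `seed` is not consulted here; the caller
#'   owns the RNG state).
#' @param s expression vector (length m_sources); drawn if NULL.
#' @param recordId id for the generated record.
#' @param spanDays record span; drawn exponential if NULL.
#' @return list(record = getRecord()-style list, s = expressions).
#' @export
simulateRecord <- function(gt, cfg, s = NULL, recordId = "r1",
                           spanDays = NULL) {
  if (is.null(s)) s <- simulateExpressions(gt, 1L)[, 1L]
  if (is.null(spanDays)) {
    # exponential (long-tailed) spans, truncated to a plausible EHR era:
    # at least 60 days, at most 60 years of history
    spanDays <- stats::rexp(1, 1 / (cfg$meanSpanYears * DAYS_PER_YEAR))
    spanDays <- min(max(60, spanDays), 60 * DAYS_PER_YEAR)
  }
  xstar <- gt@amplitude * drop(gt@mixing %*% s)
  names(xstar) <- gt@catalog$variable_id
  spanYears <- spanDays / DAYS_PER_YEAR
  cat <- gt@catalog
  labIds <- cat$variable_id[cat$mode == "lab"]
  codeIds <- cat$variable_id[cat$mode == "code"]
  medIds <- cat$variable_id[cat$mode == "med"]
  # labs
  nObs <- rpois(length(labIds), cfg$labObsRate * spanYears)
  labs <- if (sum(nObs)) {
    tid <- rep(labIds, nObs)
    data.frame(record_id = recordId, day = runif(sum(nObs), 0, spanDays),
               test_id = tid,
               value = gt@labBaseline[tid] + xstar[tid] +
                 rnorm(sum(nObs), 0, cfg$noiseSd), row.names = NULL)
  } else .emptyLabs()
  # codes: Poisson with per-variable log-rate shift
  rate <- cfg$codeBaseRate * exp(xstar[codeIds])
  nEv <- rpois(length(codeIds), rate * spanYears)
  codes <- if (sum(nEv)) {
    data.frame(record_id = recordId, day = runif(sum(nEv), 0, spanDays),
               code_id = rep(codeIds, nEv), row.names = NULL)
  } else .emptyCodes()
  # meds: presence Bernoulli, then sparse mention process while present
  pres <- rbinom(length(medIds), 1L,
                 plogis(cfg$medBaseLogit + xstar[medIds])) == 1L
  # refill-like mention process while present (~2 mentions/year)
  nMen <- ifelse(pres, 1L + rpois(length(medIds), 2 * spanYears), 0L)
  meds <- if (sum(nMen)) {
    data.frame(record_id = recordId, day = runif(sum(nMen), 0, spanDays),
               med_id = rep(medIds, nMen), row.names = NULL)
  } else .emptyMeds()
  demo <- .demoFromSources(gt, matrix(s, ncol = 1))
  demo <- data.frame(record_id = recordId, sex = demo$sex, race = demo$race,
                     birth_day_offset = -runif(1, 30, 85) * DAYS_PER_YEAR)
  list(record = list(record_id = recordId, span_days = spanDays,
                     labs = labs, codes = codes, meds = meds,
                     demographics = demo, index_day = spanDays,
                     label = NA_character_),
       s = s)
}

#' Simulate a full cohort with known ground truth
#'
#' Draws per-record expressions, generates every record's multi-modal events
#' with [simulateRecord()], sets each record's index day at its span (the
#' anchoring event closes the observation window), and draws binary outcome
#' labels from `Bernoulli(plogis(sum(outcomeWeights * s[causalSources])))`.
#' Fully deterministic under the config seed.
#'
#' @param gt a [GroundTruth-class]
#' @param cfg a [simConfig()]
#' @return list(cohort = [EHRCohort-class] with labels and index days,
#'   expressions = m x n matrix of the hidden truth, labels = 0/1 vector) —
#'   the hidden components are for evaluation only.
#' @export
simulateCohort <- function(gt, cfg) {
  set.seed(cfg$seed)
  n <- cfg$nRecords
  ids <- sprintf("rec%06d", seq_len(n))
  s <- simulateExpressions(gt, n)
  colnames(s) <- ids
  eta <- drop(crossprod(s[gt@causalSources, , drop = FALSE],
                        gt@outcomeWeights))
  y <- rbinom(n, 1L, plogis(eta))
  names(y) <- ids
  recs <- vector("list", n)
  for (i in seq_len(n))
    recs[[i]] <- simulateRecord(gt, cfg, s = s[, i], recordId = ids[i])$record
  bindMode <- function(el, empty) {
    dfs <- lapply(recs, `[[`, el)
    out <- data.table::rbindlist(dfs)
    if (nrow(out)) as.data.frame(out) else empty
  }
  cohort <- EHRCohort(
    demo = as.data.frame(data.table::rbindlist(
      lapply(recs, `[[`, "demographics"))),
    labs = bindMode("labs", .emptyLabs()),
    codes = bindMode("codes", .emptyCodes()),
    meds = bindMode("meds", .emptyMeds()),
    index = setNames(vapply(recs, `[[`, 0, "span_days"), ids),
    spans = setNames(vapply(recs, `[[`, 0, "span_days"), ids),
    labels = setNames(ifelse(y == 1L, "positive", "negative"), ids))
  list(cohort = cohort, expressions = s, labels = y)
}

#' Directly simulate a cross-section matrix from the ground truth
#'
#' Bypasses the event-level observation processes: draws `tSamples`
#' expression vectors and emits `values = mixing %*% s + noise`. This is the
#' idealized regime for benchmarking the decomposition itself (curve
#' transformation adds its own distortions, exercised by the event-level
#' generator).
#'
#' @param gt a [GroundTruth-class]
#' @param tSamples number of cross-sections.
#' @param noiseSd additive Gaussian noise SD.
#' @param seed RNG seed.
#' @return list(x = [CrossSectionMatrix-class], expressions = m x t truth).
#' @export
simulateCrossSections <- function(gt, tSamples, noiseSd = 0.1, seed = 1L) {
  set.seed(seed)
  s <- simulateExpressions(gt, tSamples)
  v <- gt@amplitude * gt@mixing %*% s +
    matrix(rnorm(gt@nVars * tSamples, 0, noiseSd),
                                gt@nVars, tSamples)
  prov <- data.frame(record_id = sprintf("xs%06d", seq_len(tSamples)),
                     sample_day = 0)
  list(x = CrossSectionMatrix(v, gt@catalog, prov), expressions = s)
}

#' Simulate a labeled evaluation set of cross-sections
#'
#' One cross-section per record (its state at the anchoring event), plus a
#' binary outcome drawn from the logistic model on the causal sources:
#' `Bernoulli(plogis(sum(outcomeWeights * s[causalSources])))`.
#'
#' @param gt a [GroundTruth-class]
#' @param n number of records.
#' @param noiseSd additive Gaussian observation noise SD.
#' @param seed RNG seed.
#' @return list(x = [CrossSectionMatrix-class], expressions = m x n truth,
#'   labels = 0/1 vector).
#' @export
simulateEvaluationSet <- function(gt, n, noiseSd = 0.1, seed = 1L) {
  sim <- simulateCrossSections(gt, n, noiseSd = noiseSd, seed = seed)
  eta <- drop(crossprod(sim$expressions[gt@causalSources, , drop = FALSE],
                        gt@outcomeWeights))
  labels <- rbinom(n, 1L, plogis(eta))
  c(sim, list(labels = labels))
}

#' Write the hidden ground truth alongside a simulated cohort
#'
#' @param gt a [GroundTruth-class]
#' @param sim result of [simulateCohort()].
#' @param dir output directory; truth goes under `dir/truth/`.
#' @return `dir`, invisibly.
#' @export
writeGroundTruth <- function(gt, sim, dir) {
  td <- file.path(dir, "truth")
  dir.create(td, recursive = TRUE, showWarnings = FALSE)
  data.table::fwrite(data.frame(variable_id = gt@catalog$variable_id,
                                gt@mixing), file.path(td, "mixing.csv"))
  data.table::fwrite(data.frame(record_id = colnames(sim$expressions),
                                t(sim$expressions)),
                     file.path(td, "expressions.csv"))
  data.table::fwrite(data.frame(causal_source = gt@causalSources,
                                weight = gt@outcomeWeights),
                     file.path(td, "causal.csv"))
  invisible(dir)
}
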