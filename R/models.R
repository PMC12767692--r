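#' @include AllClasses.R AllGenerics.R
#' @importFrom randomForest randomForest
#' @importFrom glmnet cv.glmnet
#' @importFrom xgboost xgboost xgb.DMatrix
NULL

.architectures <- c("random_forest", "gradient_boosted_trees",
                    "elastic_net_logistic")

#' Supervised model configuration
#'
#' Six valid configurations: three architectures x two input spaces. Models
#' on source expressions are causal (inputs are mutually independent root
#' causes); models on raw variables are associational baselines.
#'
#' @param architecture one of `"random_forest"`, `"gradient_boosted_trees"`,
#'   `"elastic_net_logistic"`.
#' @param inputSpace `"sources"` or `"variables"` (bookkeeping tag).
#' @param grid optional named list of hyperparameter vectors overriding the
#'   built-in small grids.
#' @param cvFolds folds for hyperparameter cross-validation.
#' @param seed training seed.
#' @return list of class "ModelConfig".
#' @export
modelConfig <- function(architecture = .architectures,
                        inputSpace = c("sources", "variables"),
                        grid = NULL, cvFolds = 5L, seed = 1L) {
  architecture <- match.arg(architecture)
  inputSpace <- match.arg(inputSpace)
  structure(list(architecture = architecture, inputSpace = inputSpace,
                 grid = grid, cvFolds = as.integer(cvFolds),
                 seed = as.integer(seed)), class = "ModelConfig")
}

.defaultGrid <- function(architecture, d) {
  switch(architecture,
    random_forest = expand.grid(
      mtry = unique(pmax(1L, c(floor(sqrt(d)), floor(d / 3)))),
      nodesize = c(5L, 20L)),
    gradient_boosted_trees = expand.grid(
      max_depth = c(2L, 4L), nrounds = c(60L, 150L), eta = 0.1),
    elastic_net_logistic = expand.grid(alpha = c(0.1, 0.5, 0.9)))
}

.fitOne <- function(architecture, X, y, par, seed) {
  set.seed(seed)
  switch(architecture,
    random_forest = {
      fit <- randomForest(x = X, y = factor(y, levels = c(0, 1)),
                          ntree = 300L, mtry = par$mtry,
                          nodesize = par$nodesize)
      list(fit = fit,
           predict = function(newX)
             unname(predict(fit, newX, type = "prob")[, "1"]))
    },
    gradient_boosted_trees = {
      fit <- xgboost::xgb.train(
        params = list(objective = "binary:logistic",
                      max_depth = par$max_depth, eta = par$eta,
                      nthread = 1L),
        data = xgb.DMatrix(as.matrix(X), label = y),
        nrounds = par$nrounds, verbose = 0)
      list(fit = fit,
           predict = function(newX)
             predict(fit, xgb.DMatrix(as.matrix(newX))))
    },
    elastic_net_logistic = {
      fold <- stratifiedFolds(y, 5L)
      fit <- cv.glmnet(as.matrix(X), y, family = "binomial",
                       alpha = par$alpha, foldid = fold,
                       standardize = TRUE)
      list(fit = fit,
           predict = function(newX)
             drop(predict(fit, as.matrix(newX), s = "lambda.min",
                          type = "response")))
    })
}

#' Train a probabilistic classifier with cross-validated hyperparameters
#'
#' Selects hyperparameters from a small grid by stratified k-fold
#' cross-validated AUC, then refits on all rows. Deterministic under the
#' config seed.
#'
#' @param config a [modelConfig()].
#' @param X feature matrix (rows = samples).
#' @param y 0/1 labels aligned with the rows of `X`; both classes required.
#' @return object of class "ehrsigModel" with elements `predict(newX)`
#'   (probability scorer), `best` (chosen hyperparameters), `cvAuc`,
#'   `config`.
#' @export
trainModel <- function(config, X, y) {
  y <- as.integer(y)
  stopifnot(is(config, "ModelConfig") || inherits(config, "ModelConfig"))
  if (length(unique(y)) < 2L)
    stop("trainModel: both classes must be present")
  stopifnot(nrow(X) == length(y))
  X <- as.matrix(X)
  grid <- config$grid %||% .defaultGrid(config$architecture, ncol(X))
  grid <- as.data.frame(grid)
  cvAuc <- rep(NA_real_, nrow(grid))
  if (nrow(grid) > 1L) {
    set.seed(config$seed)
    fold <- stratifiedFolds(y, config$cvFolds)
    for (g in seq_len(nrow(grid))) {
      aucs <- vapply(seq_len(config$cvFolds), function(k) {
        tr <- fold != k
        fit <- .fitOne(config$architecture, X[tr, , drop = FALSE], y[tr],
                       grid[g, , drop = FALSE],
                       deriveSeed(config$seed, paste0("cv", g, k)))
        aucScore(fit$predict(X[!tr, , drop = FALSE]), y[!tr])
      }, 0)
      cvAuc[g] <- mean(aucs)
    }
    best <- grid[which.max(cvAuc), , drop = FALSE]
  } else best <- grid[1L, , drop = FALSE]
  fit <- .fitOne(config$architecture, X, y, best,
                 deriveSeed(config$seed, "final"))
  structure(list(predict = fit$predict, fit = fit$fit, best = best,
                 cvAuc = cvAuc, grid = grid, config = config,
                 featureNames = colnames(X)),
            class = "ehrsigModel")
}

#' @export
print.ehrsigModel <- function(x, ...) {
  cat("ehrsigModel:", x$config$architecture, "on", x$config$inputSpace,
      "\n  chosen hyperparameters:",
      paste(names(x$best), unlist(x$best), sep = "=", collapse = ", "),
      "\n")
  invisible(x)
}

#' Refit a trained model with fixed hyperparameters and a new seed
#'
#' Retrains the same architecture on (possibly new) data using the
#' hyperparameters already selected for `model`, as in seed-repetition
#' studies where selection happens once and training variability is measured
#' across seeds.
#'
#' @param model an `ehrsigModel` from [trainModel()].
#' @param X,y training data.
#' @param seed training seed.
#' @return an `ehrsigModel` (without re-running selection).
#' @export
refitModel <- function(model, X, y, seed) {
  fit <- .fitOne(model$config$architecture, as.matrix(X), as.integer(y),
                 model$best, as.integer(seed))
  structure(list(predict = fit$predict, fit = fit$fit, best = model$best,
                 cvAuc = model$cvAuc, grid = model$grid,
                 config = model$config, featureNames = colnames(X)),
            class = "ehrsigModel")
}

#' Compare causal and associational model configurations
#'
#' Trains each architecture on both input spaces (source expressions =
#' causal; raw variables = associational) on a common training split,
#' selects hyperparameters once per configuration by cross-validation, then
#' retrains each configuration with `nSeeds` different seeds and evaluates
#' every fit on the common held-out test set. Reports the per-seed AUC
#' distribution and the paired seed-wise causal-minus-associational
#' differences per architecture.
#'
#' @param sourceFeatures samples x m matrix of inferred source expressions.
#' @param variableFeatures samples x n matrix of raw variable values
#'   (cross-sections), row-aligned with `sourceFeatures`.
#' @param y 0/1 labels.
#' @param testIdx indices of the common held-out test rows.
#' @param architectures subset of architectures to run.
#' @param nSeeds number of training repetitions per configuration.
#' @param seed master seed.
#' @return list(auc = data.frame(architecture, input_space, seed, auc),
#'   summary = per-configuration mean/sd, paired = per-architecture paired
#'   difference summary).
#' @export
compareModels <- function(sourceFeatures, variableFeatures, y, testIdx,
                          architectures = .architectures, nSeeds = 10L,
                          seed = 1L) {
  stopifnot(nrow(sourceFeatures) == length(y),
            nrow(variableFeatures) == length(y))
  trIdx <- setdiff(seq_along(y), testIdx)
  spaces <- list(sources = sourceFeatures, variables = variableFeatures)
  rows <- list()
  for (arch in architectures) for (sp in names(spaces)) {
    X <- as.matrix(spaces[[sp]])
    cfg <- modelConfig(arch, sp, seed = deriveSeed(seed, paste0(arch, sp)))
    # hyperparameters fixed once, then nSeeds retrains
    base <- trainModel(cfg, X[trIdx, , drop = FALSE], y[trIdx])
    for (k in seq_len(nSeeds)) {
      fit <- .fitOne(arch, X[trIdx, , drop = FALSE], as.integer(y[trIdx]),
                     base$best, deriveSeed(seed, paste0(arch, sp, "rep", k)))
      rows[[length(rows) + 1L]] <- data.frame(
        architecture = arch, input_space = sp, seed = k,
        auc = aucScore(fit$predict(X[testIdx, , drop = FALSE]), y[testIdx]))
    }
  }
  auc <- do.call(rbind, rows)
  sm <- stats::aggregate(auc ~ architecture + input_space, auc, function(v)
    c(mean = mean(v), sd = if (length(v) > 1L) sd(v) else NA_real_))
  summary <- data.frame(sm[1:2], mean_auc = sm$auc[, "mean"],
                        sd_auc = sm$auc[, "sd"])
  paired <- do.call(rbind, lapply(intersect(architectures,
                                            unique(auc$architecture)),
    function(arch) {
      a <- auc[auc$architecture == arch, ]
      if (!all(c("sources", "variables") %in% a$input_space)) return(NULL)
      d <- a$auc[a$input_space == "sources"] -
           a$auc[a$input_space == "variables"]
      data.frame(architecture = arch, mean_diff = mean(d),
                 sd_diff = if (length(d) > 1L) sd(d) else NA_real_,
                 n_seeds = length(d))
    }))
  list(auc = auc, summary = summary, paired = paired)
}
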