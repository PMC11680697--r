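#' Mean Bernoulli deviance
#'
#' `-2 * mean(y*log(p) + (1-y)*log(1-p))`, the loss used both for boosting
#' and for cross-validated model selection. Probabilities are clipped to
#' `[1e-12, 1 - 1e-12]` for numeric safety.
#'
#' @param y binary outcome vector (0/1).
#' @param p predicted probability vector, same length.
#' @return mean deviance (non-negative scalar).
#' @examples
#' bernoulli_deviance(c(1, 0), c(0.5, 0.5))  # 2 * log(2)
#' @export
bernoulli_deviance <- function(y, p) {
  if (length(y) == 0L || length(y) != length(p))
    stop("y and p must be non-empty vectors of equal length", call. = FALSE)
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -2 * mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Area under the ROC curve
#'
#' Computed as the normalised Mann-Whitney U statistic (rank formulation):
#' the probability that a randomly chosen positive outscores a randomly
#' chosen negative, with ties counted one half.
#'
#' @param y binary outcome vector (0/1); both classes must be present.
#' @param p score/probability vector.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(y, p) {
  if (length(y) != length(p) || length(y) == 0L)
    stop("y and p must be non-empty vectors of equal length", call. = FALSE)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0L || n0 == 0L)
    stop("AUC undefined: both outcome classes must be present", call. = FALSE)
  r <- rank(p, ties.method = "average")
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Default hyperparameter grids for behaviour-model tuning
#'
#' Learning rates 0.01, 0.025, 0.005, 0.0025, 0.001 and tree complexities
#' (interaction depths) 1 through 9: 45 combinations in total.
#'
#' @name tuning_grids
#' @export
default_lr_grid <- c(0.01, 0.025, 0.005, 0.0025, 0.001)

#' @rdname tuning_grids
#' @export
default_depth_grid <- 1:9

predictor_names <- c("u", "v", "w", "tke")

# split a training table into the predictor matrix and outcome vector
split_table <- function(table) {
  ycol <- intersect(c("y_follow", "y_random"), names(table))
  if (length(ycol) != 1L)
    stop("training table must have exactly one of y_follow / y_random",
         call. = FALSE)
  if (!all(predictor_names %in% names(table)))
    stop("training table must have predictor columns u, v, w, tke",
         call. = FALSE)
  list(X = as.matrix(table[, predictor_names, drop = FALSE]),
       y = as.numeric(table[[ycol]]),
       kind = if (ycol == "y_follow") "follow_the_flow" else "swim_direction")
}

check_two_classes <- function(y) {
  if (length(y) == 0L)
    stop("training table is empty; nothing to fit", call. = FALSE)
  if (length(unique(y)) < 2L)
    stop("training table has a single outcome class; model cannot be fit",
         call. = FALSE)
}

#' Tune a boosted-tree behaviour model by cross-validation
#'
#' Runs stratified k-fold cross-validation for every combination of learning
#' rate (shrinkage) and tree complexity (interaction depth) in the grids.
#' For each combination, trees are added until the held-out deviance stops
#' improving (early stopping with the given patience), which fixes the
#' number of trees; the combination minimising cross-validated deviance is
#' selected, with ties broken by higher cross-validated AUC and then by
#' fewer trees.
#'
#' @param table training table from [build_datasets()] (columns
#'   `u,v,w,tke` plus `y_follow` or `y_random`).
#' @param lr_grid learning rates to evaluate (default [default_lr_grid]).
#' @param depth_grid tree complexities to evaluate
#'   (default [default_depth_grid]).
#' @param k number of folds (default 10).
#' @param seed integer RNG seed controlling fold assignment.
#' @param max_trees largest ensemble size considered (default 10000).
#' @param patience early-stopping patience in boosting iterations
#'   (default 50).
#' @return object of class `smolt_cv_result`: list with `records` (one row
#'   per combination: `learning_rate`, `tree_complexity`, `n_trees`,
#'   `cv_deviance`, `cv_auc`, `train_deviance`, `train_auc`) and `best`
#'   (list of `learning_rate`, `tree_complexity`, `n_trees`).
#' @export
tune_brt <- function(table, lr_grid = default_lr_grid,
                     depth_grid = default_depth_grid, k = 10, seed = 1,
                     max_trees = 10000, patience = 50) {
  st <- split_table(table)
  check_two_classes(st$y)
  if (nrow(st$X) < k)
    stop("need at least k = ", k, " observations for ", k, "-fold CV",
         call. = FALSE)
  grid <- expand.grid(learning_rate = lr_grid, tree_complexity = depth_grid,
                      KEEP.OUT.ATTRS = FALSE)
  dm <- xgboost::xgb.DMatrix(st$X, label = st$y, nthread = 1)
  rec <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    set.seed(seed)  # identical fold assignment for every combination
    params <- list(objective = "binary:logistic",
                   eta = grid$learning_rate[i],
                   max_depth = grid$tree_complexity[i],
                   nthread = 1, seed = seed,
                   eval_metric = "auc", eval_metric = "logloss")
    cv <- xgboost::xgb.cv(params = params, data = dm, nrounds = max_trees,
                          nfold = k, stratified = TRUE,
                          early_stopping_rounds = patience, verbose = 0)
    best_it <- cv$early_stop$best_iteration %||% cv$niter
    log <- as.data.frame(cv$evaluation_log)
    rec[[i]] <- data.frame(
      learning_rate = grid$learning_rate[i],
      tree_complexity = grid$tree_complexity[i],
      n_trees = as.integer(best_it),
      cv_deviance = 2 * log$test_logloss_mean[best_it],
      cv_auc = log$test_auc_mean[best_it],
      train_deviance = 2 * log$train_logloss_mean[best_it],
      train_auc = log$train_auc_mean[best_it]
    )
  }
  records <- do.call(rbind, rec)
  ord <- order(records$cv_deviance, -records$cv_auc, records$n_trees)
  best <- records[ord[1L], ]
  structure(list(
    records = records,
    best = list(learning_rate = best$learning_rate,
                tree_complexity = best$tree_complexity,
                n_trees = best$n_trees),
    model_kind = st$kind, k = k, seed = seed
  ), class = "smolt_cv_result")
}

#' @export
print.smolt_cv_result <- function(x, ...) {
  cat(sprintf("<smolt_cv_result> %s: %d combinations, %d-fold CV\n",
              x$model_kind, nrow(x$records), x$k))
  cat(sprintf("  best: lr = %g, depth = %d, %d trees\n",
              x$best$learning_rate, x$best$tree_complexity, x$best$n_trees))
  invisible(x)
}

#' Fit a boosted-tree behaviour model
#'
#' Fits the final gradient-boosted tree ensemble to all observations at the
#' supplied hyperparameters (typically the best combination from
#' [tune_brt()]). The relative influence of each predictor is the ensemble's
#' split-gain attribution normalised to percent.
#'
#' @param table training table (see [tune_brt()]).
#' @param hyperparams list with `learning_rate`, `tree_complexity`,
#'   `n_trees` (e.g. `cv$best`).
#' @param seed integer seed; identical seed, data and hyperparameters give
#'   bit-identical predictions.
#' @param model_kind `"follow_the_flow"` or `"swim_direction"`; inferred
#'   from the outcome column when omitted.
#' @return object of class `smolt_brt` with elements `model_kind`,
#'   `hyperparams`, `predictor_names`, `influence` (named percent vector
#'   summing to 100), `prevalence`, `n_obs` and the fitted booster.
#' @export
fit_brt <- function(table, hyperparams, seed = 1, model_kind = NULL) {
  st <- split_table(table)
  check_two_classes(st$y)
  hp <- hyperparams
  stopifnot(hp$learning_rate > 0, hp$tree_complexity >= 1, hp$n_trees >= 1)
  dm <- xgboost::xgb.DMatrix(st$X, label = st$y, nthread = 1)
  set.seed(seed)
  booster <- xgboost::xgb.train(
    params = list(objective = "binary:logistic", eta = hp$learning_rate,
                  max_depth = hp$tree_complexity, nthread = 1, seed = seed),
    data = dm, nrounds = hp$n_trees, verbose = 0)
  imp <- xgboost::xgb.importance(model = booster)
  influence <- stats::setNames(numeric(length(predictor_names)),
                               predictor_names)
  if (!is.null(imp) && nrow(imp) > 0L) {
    influence[imp$Feature] <- imp$Gain * 100
  } else {
    # degenerate ensemble with no splits (e.g. constant features):
    # attribution is undefined, reported as uniform
    influence[] <- 100 / length(predictor_names)
  }
  structure(list(
    model_kind = model_kind %||% st$kind,
    hyperparams = list(learning_rate = hp$learning_rate,
                       tree_complexity = as.integer(hp$tree_complexity),
                       n_trees = as.integer(hp$n_trees)),
    predictor_names = predictor_names,
    influence = influence,
    prevalence = mean(st$y),
    n_obs = length(st$y),
    seed = seed,
    booster = booster
  ), class = c("smolt_brt", "smolt_behavior_model"))
}

#' @export
print.smolt_brt <- function(x, ...) {
  cat(sprintf("<smolt_brt> %s: depth %d, shrinkage %g, %d trees, n = %d\n",
              x$model_kind, x$hyperparams$tree_complexity,
              x$hyperparams$learning_rate, x$hyperparams$n_trees, x$n_obs))
  inf <- sort(x$influence, decreasing = TRUE)
  cat("  influence:", paste(sprintf("%s %.1f%%", names(inf), inf),
                            collapse = ", "), "\n")
  invisible(x)
}

#' Predict a behaviour probability
#'
#' @param model a fitted behaviour model ([fit_brt()], [constant_model()] or
#'   [truth_model()]).
#' @param hydraulics named numeric vector or data.frame with `u`, `v`, `w`,
#'   `tke`; all four must be present and finite.
#' @return probability (or vector of probabilities), strictly in (0, 1).
#' @export
predict_prob <- function(model, hydraulics) {
  UseMethod("predict_prob")
}

as_predictor_matrix <- function(hydraulics) {
  if (is.data.frame(hydraulics)) {
    if (!all(predictor_names %in% names(hydraulics)))
      stop("hydraulics must provide u, v, w and tke", call. = FALSE)
    X <- as.matrix(hydraulics[, predictor_names, drop = FALSE])
  } else {
    h <- hydraulics
    if (is.null(names(h)) && length(h) == 4L) names(h) <- predictor_names
    if (!all(predictor_names %in% names(h)))
      stop("hydraulics must provide u, v, w and tke", call. = FALSE)
    X <- matrix(h[predictor_names], nrow = 1,
                dimnames = list(NULL, predictor_names))
  }
  if (anyNA(X) || any(!is.finite(X)))
    stop("hydraulics absent or non-finite: cell is not navigable water",
         call. = FALSE)
  X
}

#' @export
predict_prob.smolt_brt <- function(model, hydraulics) {
  X <- as_predictor_matrix(hydraulics)
  p <- stats::predict(model$booster,
                      xgboost::xgb.DMatrix(X, nthread = 1))
  pmin(pmax(p, 1e-12), 1 - 1e-12)
}

#' Constant-probability stub model
#'
#' A behaviour model that always returns the same probability. Used for the
#' drift-only baseline (p = 1 forces every step to follow the flow) and in
#' tests of the simulator's decision loop.
#'
#' @param p probability in `[0, 1]`.
#' @param model_kind label carried for bookkeeping.
#' @return object of class `smolt_constant`.
#' @export
constant_model <- function(p, model_kind = "constant") {
  stopifnot(is.numeric(p), length(p) == 1L, p >= 0, p <= 1)
  structure(list(p = p, model_kind = model_kind),
            class = c("smolt_constant", "smolt_behavior_model"))
}

#' @export
predict_prob.smolt_constant <- function(model, hydraulics) {
  n <- if (is.data.frame(hydraulics)) nrow(hydraulics) else 1L
  rep(model$p, n)
}

#' Relative influence of the hydraulic predictors
#'
#' @param model a fitted [fit_brt()] model.
#' @return data.frame of `predictor` and `influence` (percent, descending;
#'   sums to 100).
#' @export
relative_influence <- function(model) {
  stopifnot(inherits(model, "smolt_brt"))
  inf <- sort(model$influence, decreasing = TRUE)
  data.frame(predictor = names(inf), influence = unname(inf))
}

#' Training and cross-validated performance of a fitted model
#'
#' Recomputes training AUC and deviance from the fitted ensemble and pairs
#' them with the cross-validated statistics of the matching grid entry, in
#' the layout conventional for reporting boosted-tree behaviour models.
#'
#' @param model a [fit_brt()] model.
#' @param table the training table the model was fitted to.
#' @param cv optional `smolt_cv_result` for the CV columns.
#' @return one-row data.frame: `model`, `interaction_depth`, `shrinkage`,
#'   `n_trees`, `auc`, `cv_auc`, `deviance`, `cv_deviance` (CV columns `NA`
#'   when `cv` is not supplied).
#' @export
model_metrics <- function(model, table, cv = NULL) {
  st <- split_table(table)
  p <- predict_prob(model, as.data.frame(st$X))
  cv_auc <- cv_dev <- NA_real_
  if (!is.null(cv)) {
    r <- cv$records
    hit <- which(r$learning_rate == model$hyperparams$learning_rate &
                 r$tree_complexity == model$hyperparams$tree_complexity)
    if (length(hit)) {
      cv_auc <- r$cv_auc[hit[1L]]
      cv_dev <- r$cv_deviance[hit[1L]]
    }
  }
  data.frame(model = model$model_kind,
             interaction_depth = model$hyperparams$tree_complexity,
             shrinkage = model$hyperparams$learning_rate,
             n_trees = model$hyperparams$n_trees,
             auc = auc(st$y, p), cv_auc = cv_auc,
             deviance = bernoulli_deviance(st$y, p), cv_deviance = cv_dev)
}

#' Overfitting gap between cross-validated and training deviance
#'
#' The percentage by which cross-validated deviance exceeds training
#' deviance, `100 * (cv_deviance / deviance - 1)`; the standard diagnostic
#' for boosted-tree overfitting.
#'
#' @param deviance training deviance.
#' @param cv_deviance cross-validated deviance.
#' @return percent gap (positive when the model overfits).
#' @export
overfit_gap <- function(deviance, cv_deviance) {
  stopifnot(all(deviance > 0))
  100 * (cv_deviance / deviance - 1)
}

#' Reference parameterisation of the original field study
#'
#' Published performance table for the two behaviour models fitted to the
#' combined Mandal and Orkla telemetry data (140 smolts, 32,994 positions):
#' tuned interaction depth, shrinkage and ensemble size, with training and
#' cross-validated AUC and deviance. Those data are available on request
#' only, so this table serves as the reference configuration fixture for
#' refits and for overfitting diagnostics.
#'
#' @return data.frame with columns `model`, `interaction_depth`,
#'   `shrinkage`, `n_trees`, `auc`, `cv_auc`, `deviance`, `cv_deviance`.
#' @export
reference_brt_metrics <- function() {
  utils::read.csv(system.file("extdata", "reference_brt_metrics.csv",
                              package = "smoltsim"))
}

#' Save / load a fitted behaviour model
#'
#' The booster is serialised with its native JSON format; a sidecar JSON
#' carries the model kind, hyperparameters, influence and seed.
#'
#' @param model a [fit_brt()] model.
#' @param path base path; writes `<path>.ubj` (booster) and `<path>.json`
#'   (sidecar).
#' @return invisibly, the base path.
#' @rdname model_io
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "smolt_brt"))
  xgboost::xgb.save(model$booster, paste0(path, ".ubj"))
  side <- model[setdiff(names(model), "booster")]
  side$influence <- as.list(model$influence)  # keep predictor names in JSON
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @param path base path used in [save_model()].
#' @rdname model_io
#' @export
load_model <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  side$influence <- unlist(side$influence)
  booster <- xgboost::xgb.load(paste0(path, ".ubj"))
  structure(c(side, list(booster = booster)),
            class = c("smolt_brt", "smolt_behavior_model"))
}
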