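#' Stacking: cross-validated meta-learning over member probabilities
#'
#' The meta-features of an item are the concatenated class-probability
#' vectors of the member classifiers (`m * C` columns). A meta-learner is
#' fitted under stratified k-fold cross-validation: for each fold it is
#' trained on the other k-1 folds and predicts the held-out fold, so every
#' fused probability is out-of-fold and the reported stacking accuracy is
#' not inflated by refitting on the items it is scored on.
#'
#' @name stacking
NULL

#' Stacking configuration
#'
#' @param folds number of cross-validation folds (default 5).
#' @param meta_learner `"gbt"` — gradient-boosted trees (xgboost, multiclass
#'   softprob objective, multiclass log-loss evaluation) — or
#'   `"multinomial"` — multinomial logistic regression (`nnet::multinom`), a
#'   fast deterministic fallback.
#' @param nrounds boosting-round cap for `"gbt"` (default 1000).
#' @param early_stopping patience, in rounds without log-loss improvement on
#'   the inner validation split, before boosting stops (default 50).
#' @param tune_budget random-search trials for gbt hyperparameters, run
#'   within each training split only; 0 uses fixed defaults (default 50).
#' @return object of class `"stacking_config"`.
#' @export
stacking_config <- function(folds = 5L, meta_learner = c("gbt", "multinomial"),
                            nrounds = 1000L, early_stopping = 50L,
                            tune_budget = 50L) {
  meta_learner <- match.arg(meta_learner)
  if (folds < 2L) stop("folds must be >= 2", call. = FALSE)
  if (nrounds < 1L || early_stopping < 1L) {
    stop("nrounds and early_stopping must be positive", call. = FALSE)
  }
  structure(list(folds = as.integer(folds), meta_learner = meta_learner,
                 nrounds = as.integer(nrounds),
                 early_stopping = as.integer(early_stopping),
                 tune_budget = as.integer(tune_budget)),
            class = "stacking_config")
}

# Stratified fold assignment; errors when any fold would miss a class.
stratified_folds <- function(truth, folds, seed) {
  local_seed(seed, {
    assign_fold <- integer(length(truth))
    for (cls in unique(truth)) {
      idx <- sample(which(truth == cls))
      assign_fold[idx] <- rep_len(seq_len(folds), length(idx))
    }
    per <- table(factor(assign_fold, levels = seq_len(folds)), truth)
    if (any(per == 0L)) {
      stop(sprintf(
        "stratification failed: some fold has no items of some class; use fewer than %d folds",
        folds), call. = FALSE)
    }
    assign_fold
  })
}

#' Stacked fusion with an out-of-fold meta-learner
#'
#' @param ps a [prediction_set()]; all members must carry probabilities.
#' @param members classifier names (default all).
#' @param config a [stacking_config()].
#' @param seed integer seed governing fold assignment, hyperparameter search
#'   and boosting randomness.
#' @return a `"fusion_result"` with method `"ST"`; `fused_probs` are the
#'   out-of-fold meta-learner probabilities.
#' @examples
#' ps <- simulate_predictions(n_items = 100, n_classifiers = 3, seed = 3)
#' fr <- stack_fuse(ps, config = stacking_config(meta_learner = "multinomial"))
#' mean(fr$fused_labels == ps$truth)
#' @export
stack_fuse <- function(ps, members = ps$classifiers,
                       config = stacking_config(), seed = 1L) {
  members <- match_members(ps, members)
  if (any(ps$prob_free[members])) {
    stop("stacking requires probability-bearing members", call. = FALSE)
  }
  n <- length(ps$truth)
  if (n < config$folds) stop("need at least one item per fold", call. = FALSE)
  X <- do.call(cbind, lapply(members, function(m) ps$probs[[m]]))
  colnames(X) <- paste(rep(members, each = length(ps$classes)),
                       rep(as.character(ps$classes), length(members)),
                       sep = ".")
  y <- ps$truth
  fold <- stratified_folds(y, config$folds, derive_seed(seed, "folds"))

  fused <- matrix(NA_real_, n, length(ps$classes),
                  dimnames = list(ps$item_ids, as.character(ps$classes)))
  for (f in seq_len(config$folds)) {
    tr <- fold != f
    fit_seed <- derive_seed(seed, "fold", f)
    fused[!tr, ] <- if (config$meta_learner == "multinomial") {
      fit_predict_multinom(X[tr, , drop = FALSE], y[tr],
                           X[!tr, , drop = FALSE], length(ps$classes))
    } else {
      fit_predict_gbt(X[tr, , drop = FALSE], y[tr], X[!tr, , drop = FALSE],
                      length(ps$classes), config, fit_seed)
    }
  }
  fused <- fused / rowSums(fused)
  labels <- max.col(fused, ties.method = "first")
  fusion_result(fused, labels, "ST", members,
                weights = NULL, tie_items = character())
}

fit_predict_multinom <- function(Xtr, ytr, Xte, n_class) {
  df <- as.data.frame(Xtr)
  df$.y <- factor(ytr, levels = seq_len(n_class))
  fit <- nnet::multinom(.y ~ ., data = df, trace = FALSE, maxit = 200L,
                        MaxNWts = 100000L)
  p <- stats::predict(fit, newdata = as.data.frame(Xte), type = "probs")
  if (is.null(dim(p))) p <- matrix(p, nrow = nrow(Xte))  # 2-class case
  if (ncol(p) != n_class) {
    full <- matrix(0, nrow(Xte), n_class)
    full[, as.integer(colnames(p))] <- p
    p <- full
  }
  unname(p)
}

# Gradient-boosted meta-learner: optional seeded random-search tuning on an
# inner 80/20 split of the training fold, then refit with early stopping.
fit_predict_gbt <- function(Xtr, ytr, Xte, n_class, config, seed) {
  inner <- local_seed(derive_seed(seed, "inner"), {
    stratified_holdout(ytr, frac = 0.2)
  })
  dtrain <- xgboost::xgb.DMatrix(Xtr[!inner, , drop = FALSE],
                                 label = ytr[!inner] - 1L)
  dvalid <- xgboost::xgb.DMatrix(Xtr[inner, , drop = FALSE],
                                 label = ytr[inner] - 1L)
  base <- list(objective = "multi:softprob", num_class = n_class,
               eval_metric = "mlogloss", nthread = 1L,
               eta = 0.1, max_depth = 4L, min_child_weight = 1,
               subsample = 0.9, colsample_bytree = 0.9, lambda = 1)
  cands <- list(base)
  if (config$tune_budget > 0L) {
    cands <- c(cands, local_seed(derive_seed(seed, "tune"), {
      lapply(seq_len(config$tune_budget), function(i) {
        utils::modifyList(base, list(
          eta = stats::runif(1, 0.02, 0.3),
          max_depth = sample(2:8, 1L),
          min_child_weight = stats::runif(1, 0.5, 8),
          subsample = stats::runif(1, 0.5, 1),
          colsample_bytree = stats::runif(1, 0.5, 1),
          lambda = 10^stats::runif(1, -2, 1)))
      })
    }))
  }
  best <- NULL
  for (par in cands) {
    par$seed <- derive_seed(seed, "xgb")
    fit <- xgboost::xgb.train(
      params = par, data = dtrain, nrounds = config$nrounds,
      evals = list(valid = dvalid),
      early_stopping_rounds = config$early_stopping, verbose = 0)
    score <- as.numeric(xgboost::xgb.attributes(fit)$best_score)
    if (is.null(best) || score < best$score) {
      best <- list(fit = fit, score = score)
    }
  }
  # predict() uses the early-stopping best iteration by default
  unname(stats::predict(best$fit, xgboost::xgb.DMatrix(Xte)))
}

# logical vector marking a stratified holdout of roughly `frac` per class
stratified_holdout <- function(y, frac) {
  hold <- logical(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    take <- max(1L, floor(length(idx) * frac))
    hold[sample(idx, take)] <- TRUE
  }
  hold
}
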