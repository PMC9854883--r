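#' Ensemble pruning by accuracy ranking
#'
#' The ranking method orders member classifiers by standalone overall
#' accuracy and builds ensembles from the top-k prefix for every k. Sweeping
#' k over 2..m for each fusion method yields the full method-by-size grid
#' from which the best ensemble size per method is read off.
#'
#' @name pruning
NULL

#' Rank member classifiers by standalone accuracy
#'
#' Sorted by overall accuracy descending; ties are broken by macro F1, then
#' classifier id (ties are noted in the result so the arbitrary final
#' tie-break is auditable).
#'
#' @param x a [prediction_set()], or a count-table data.frame with columns
#'   `classifier, class, tp, fp, fn, tn` (the [load_fixture()] layout).
#' @param ... unused.
#' @return object of class `"member_ranking"`: data.frame with columns
#'   `rank`, `classifier`, `accuracy`, `macro_f1`, plus a `tie_note`
#'   attribute listing tied accuracy groups (empty when none).
#' @examples
#' rank_members(load_fixture("counts16"))
#' @export
rank_members <- function(x, ...) UseMethod("rank_members")

#' @export
rank_members.prediction_set <- function(x, ...) {
  acc <- member_accuracy(x)
  f1 <- vapply(x$classifiers, function(m) {
    rep <- evaluate_predictions(x$truth, predicted_labels(x, m)[, 1L],
                                x$classes, ci_method = NULL, na_rm = TRUE)
    rep$macro$f1
  }, 0)
  build_ranking(x$classifiers, acc, f1)
}

#' @export
rank_members.data.frame <- function(x, ...) {
  stopifnot(all(c("classifier", "class", "tp", "fp", "fn", "tn") %in% names(x)))
  per <- split(x, x$classifier)
  acc <- vapply(per, function(d) {
    sum(d$tp) / (d$tp[1L] + d$fp[1L] + d$fn[1L] + d$tn[1L])
  }, 0)
  f1 <- vapply(per, function(d) {
    rep <- metric_report(d, ci_method = NULL, na_rm = TRUE)
    rep$macro$f1
  }, 0)
  build_ranking(names(per), acc, f1)
}

build_ranking <- function(ids, acc, f1) {
  ord <- order(-acc, -f1, ids)
  out <- data.frame(rank = seq_along(ids), classifier = ids[ord],
                    accuracy = unname(acc[ord]), macro_f1 = unname(f1[ord]),
                    row.names = NULL)
  dup <- duplicated(out$accuracy) | duplicated(out$accuracy, fromLast = TRUE)
  note <- if (any(dup)) {
    paste("tied accuracy:", paste(out$classifier[dup], collapse = ", "))
  } else character()
  structure(out, tie_note = note, class = c("member_ranking", "data.frame"))
}

#' Pruning sweep over top-k ensembles
#'
#' For each fusion method and each ensemble size k in `k_range`, fuses the
#' top-k prefix of the accuracy ranking and evaluates it. WAV/WHV weights
#' are re-optimized from scratch at every k, and the stack is re-fitted at
#' every k, mirroring per-k optimized ensembles. The k = 1 row (the top
#' single classifier) is included as the pruning baseline.
#'
#' By default weights are optimized on a seeded stratified half of the
#' items and all ensembles are evaluated on the other half, so the reported
#' accuracies are not optimized on the items they are computed from. With
#' `paper_mode = TRUE` the optimization and evaluation sets are both the
#' full item set — the protocol of the benchmark study this package
#' reproduces.
#'
#' @param ps a [prediction_set()].
#' @param methods subset of `c("sv", "wav", "whv", "st")`.
#' @param k_range ensemble sizes to sweep (default `2:m`).
#' @param budget evaluation budget per weight optimization (default 200).
#' @param stack_config a [stacking_config()] for the `"st"` method.
#' @param seed master seed; per-(method, k) seeds are derived from it.
#' @param paper_mode optimize weights on the evaluation items themselves
#'   (see above).
#' @return object of class `"sweep_result"`: `grid` data.frame (`method`,
#'   `k`, `accuracy`, `precision`, `sensitivity`, `specificity`, `f1`,
#'   `auc`, `members`, `seed`), `best_k` data.frame per method (ties go to
#'   the smallest k), `ranking`, `baseline` (k = 1 row), `eval_items`,
#'   `opt_items`, `paper_mode`.
#' @examples
#' ps <- simulate_predictions(n_items = 80, n_classifiers = 4, seed = 4)
#' sw <- prune_sweep(ps, methods = c("sv", "wav"), budget = 20, seed = 4,
#'                   paper_mode = TRUE)
#' sw$best_k
#' @export
prune_sweep <- function(ps, methods = c("sv", "wav", "whv", "st"),
                        k_range = NULL, budget = 200L,
                        stack_config = stacking_config(), seed = 1L,
                        paper_mode = FALSE) {
  methods <- match.arg(methods, several.ok = TRUE)
  m <- n_classifiers(ps)
  if (m < 2L) stop("pruning needs at least two classifiers", call. = FALSE)
  if (is.null(k_range)) k_range <- 2:m
  if (any(k_range < 1L | k_range > m)) {
    stop("k_range must lie in 1..m", call. = FALSE)
  }
  ranking <- rank_members(ps)
  order_ids <- ranking$classifier

  if (paper_mode) {
    opt_items <- eval_items <- seq_along(ps$truth)
  } else {
    hold <- local_seed(derive_seed(seed, "split"), {
      stratified_holdout(ps$truth, frac = 0.5)
    })
    opt_items <- which(hold)
    eval_items <- which(!hold)
  }

  eval_fusion <- function(fr) {
    rep <- evaluate_predictions(ps$truth[eval_items],
                                fr$fused_labels[eval_items], ps$classes,
                                ci_method = NULL, na_rm = TRUE)
    auc <- if (!is.null(fr$fused_probs)) {
      macro_auc(fr$fused_probs[eval_items, , drop = FALSE],
                ps$truth[eval_items], ps$classes, na_rm = TRUE)$macro
    } else NA_real_
    c(accuracy = rep$overall_accuracy, precision = rep$macro$precision,
      sensitivity = rep$macro$sensitivity,
      specificity = rep$macro$specificity, f1 = rep$macro$f1, auc = auc)
  }

  rows <- list()
  for (method in methods) {
    for (k in sort(k_range)) {
      members <- order_ids[seq_len(k)]
      kseed <- derive_seed(seed, method, k)
      fr <- switch(
        method,
        sv  = soft_vote(ps, members),
        wav = {
          wv <- optimize_weights(ps, members, method = "sv",
                                 items = opt_items, budget = budget,
                                 seed = kseed)
          soft_vote(ps, members, wv)
        },
        whv = {
          wv <- optimize_weights(ps, members, method = "hv",
                                 items = opt_items, budget = budget,
                                 seed = kseed)
          hard_vote(ps, members, wv)
        },
        st  = stack_fuse(ps, members, config = stack_config, seed = kseed))
      stats_row <- eval_fusion(fr)
      rows[[length(rows) + 1L]] <- data.frame(
        method = method, k = k, t(stats_row),
        members = paste(members, collapse = "+"), seed = kseed,
        row.names = NULL)
    }
  }
  grid <- do.call(rbind, rows)

  top1 <- fusion_result(NULL,
                        predicted_labels(ps, order_ids[1L])[, 1L],
                        "TOP1", order_ids[1L], NULL)
  baseline <- data.frame(method = "top1", k = 1L, t(eval_fusion(top1)),
                         members = order_ids[1L], seed = NA_integer_,
                         row.names = NULL)

  best_k <- do.call(rbind, lapply(split(grid, grid$method), function(d) {
    d <- d[order(d$k), ]
    d[which.max(d$accuracy), c("method", "k", "accuracy", "members")]
  }))
  rownames(best_k) <- NULL

  structure(
    list(grid = grid, best_k = best_k, ranking = ranking,
         baseline = baseline, eval_items = eval_items,
         opt_items = opt_items, paper_mode = paper_mode, seed = seed),
    class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("<sweep_result> %d grid entries (%s; k in %d..%d)%s\n",
              nrow(x$grid), paste(unique(x$grid$method), collapse = ", "),
              min(x$grid$k), max(x$grid$k),
              if (x$paper_mode) ", paper mode" else ""))
  cat("best k per method:\n")
  print(x$best_k, row.names = FALSE)
  invisible(x)
}

#' Write a sweep grid as CSV
#' @param sw a `"sweep_result"`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sweep_grid <- function(sw, path) {
  utils::write.csv(sw$grid, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
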