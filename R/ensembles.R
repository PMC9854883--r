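#' Fusion methods: soft voting, weighted voting, and weight optimization
#'
#' Four fusion rules are supported. Soft voting (SV) averages member
#' probability vectors and takes the argmax; weighted average voting (WAV)
#' is the same rule with non-uniform member weights; weighted hard voting
#' (WHV, weighted majority voting) sums member weights over hard votes; and
#' stacking (see [stack_fuse()]) trains a meta-learner on member
#' probabilities. Weights for WAV/WHV are found by sequential model-based
#' (Bayesian) optimization of fusion accuracy on a labeled objective set.
#'
#' @name ensembles
NULL

#' Construct a voting weight vector
#'
#' Weights are non-negative with at least one positive entry and are stored
#' normalized to sum 1 — argmax fusion decisions are invariant to positive
#' rescaling, so the normalization is purely a canonical form.
#'
#' @param weights named (by classifier) or unnamed non-negative numerics.
#' @param provenance free-form list recording where the weights came from
#'   (`"uniform"`, `"user"`, or the optimizer's record).
#' @return object of class `"weight_vector"`.
#' @export
weight_vector <- function(weights, provenance = "user") {
  w <- as.numeric(weights)
  if (anyNA(w) || any(w < 0)) {
    stop("weights must be non-negative", call. = FALSE)
  }
  if (sum(w) <= 0) stop("at least one weight must be positive", call. = FALSE)
  structure(list(weights = stats::setNames(w / sum(w), names(weights)),
                 provenance = provenance),
            class = "weight_vector")
}

uniform_weights <- function(members) {
  weight_vector(stats::setNames(rep(1, length(members)), members),
                provenance = "uniform")
}

resolve_weights <- function(weights, members) {
  if (is.null(weights)) return(uniform_weights(members))
  if (!inherits(weights, "weight_vector")) weights <- weight_vector(weights)
  w <- weights$weights
  if (!is.null(names(w))) {
    miss <- setdiff(members, names(w))
    if (length(miss)) {
      stop(sprintf("no weight for member(s): %s", paste(miss, collapse = ", ")),
           call. = FALSE)
    }
    weights$weights <- w[members]
  } else if (length(w) != length(members)) {
    stop("weight vector length does not match member count", call. = FALSE)
  }
  weights
}

#' Soft voting / weighted average voting
#'
#' Fused probability of item i for class c is `sum_j w_j p_ij(c)` with
#' normalized weights; the fused label is the row argmax. Uniform weights
#' give plain soft voting (SV); non-uniform weights give weighted average
#' voting (WAV). Probability-free (hard-label-only) members are refused.
#'
#' @param ps a [prediction_set()].
#' @param members classifier names (default all).
#' @param weights a [weight_vector()], bare numeric, or `NULL` for uniform.
#' @return object of class `"fusion_result"`: `fused_probs` (`N x C`),
#'   `fused_labels` (1-based), `method` (`"SV"` or `"WAV"`), `members`,
#'   `weights`, `tie_events`.
#' @examples
#' ps <- simulate_predictions(n_items = 40, n_classifiers = 3, seed = 1)
#' fr <- soft_vote(ps)
#' mean(fr$fused_labels == ps$truth)
#' @export
soft_vote <- function(ps, members = ps$classifiers, weights = NULL) {
  members <- match_members(ps, members)
  if (any(ps$prob_free[members])) {
    stop(sprintf("probability-free member(s) cannot soft vote: %s",
                 paste(members[ps$prob_free[members]], collapse = ", ")),
         call. = FALSE)
  }
  wv <- resolve_weights(weights, members)
  w <- wv$weights
  fused <- matrix(0, length(ps$truth), length(ps$classes),
                  dimnames = list(ps$item_ids, as.character(ps$classes)))
  for (j in seq_along(members)) {
    fused <- fused + w[j] * ps$probs[[members[j]]]
  }
  labels <- max.col(fused, ties.method = "first")
  ties <- which(rowSums(abs(fused - fused[cbind(seq_len(nrow(fused)), labels)]) < 1e-12) > 1L)
  method <- if (identical(wv$provenance, "uniform")) "SV" else "WAV"
  fusion_result(fused, labels, method, members, wv,
                tie_items = ps$item_ids[ties])
}

#' Hard voting / weighted majority voting
#'
#' Each member casts its argmax label; the score of class c is the summed
#' weight of members voting c and the fused label is the top-scoring class.
#' Exact score ties are resolved by `tie_rule` and logged in `tie_events`:
#' `"first-member"` gives the tie to the class voted by the earliest-listed
#' (i.e. highest-ranked) member whose vote is among the tied classes,
#' falling back to the lowest class index; `"lowest-class"` always takes the
#' lowest tied class index.
#'
#' @inheritParams soft_vote
#' @param tie_rule `"first-member"` (default) or `"lowest-class"`.
#' @return a `"fusion_result"` with `fused_probs = NULL` and method `"HV"`
#'   (uniform weights) or `"WHV"`.
#' @export
hard_vote <- function(ps, members = ps$classifiers, weights = NULL,
                      tie_rule = c("first-member", "lowest-class")) {
  members <- match_members(ps, members)
  tie_rule <- match.arg(tie_rule)
  wv <- resolve_weights(weights, members)
  w <- wv$weights
  n <- length(ps$truth); k <- length(ps$classes)
  votes <- predicted_labels(ps, members)
  scores <- matrix(0, n, k)
  for (j in seq_along(members)) {
    scores[cbind(seq_len(n), votes[, j])] <-
      scores[cbind(seq_len(n), votes[, j])] + w[j]
  }
  top <- apply(scores, 1L, max)
  is_tied <- rowSums(abs(scores - top) < 1e-12) > 1L
  labels <- max.col(scores, ties.method = "first")
  if (any(is_tied)) {
    for (i in which(is_tied)) {
      tied <- which(abs(scores[i, ] - top[i]) < 1e-12)
      if (tie_rule == "first-member") {
        hit <- which(votes[i, ] %in% tied)
        labels[i] <- if (length(hit)) votes[i, hit[1L]] else tied[1L]
      } else {
        labels[i] <- tied[1L]
      }
    }
  }
  method <- if (identical(wv$provenance, "uniform")) "HV" else "WHV"
  fusion_result(NULL, labels, method, members, wv,
                tie_items = ps$item_ids[is_tied])
}

fusion_result <- function(fused_probs, fused_labels, method, members, weights,
                          tie_items = character()) {
  structure(
    list(fused_probs = fused_probs, fused_labels = as.integer(fused_labels),
         method = method, members = members, weights = weights,
         tie_events = list(count = length(tie_items), items = tie_items)),
    class = "fusion_result")
}

#' @export
print.fusion_result <- function(x, ...) {
  cat(sprintf("<fusion_result> %s over %d members, N=%d, ties broken: %d\n",
              x$method, length(x$members), length(x$fused_labels),
              x$tie_events$count))
  invisible(x)
}

#' Fusion accuracy against the truth of a prediction set
#' @param fr a `"fusion_result"`.
#' @param ps the [prediction_set()] it was computed from.
#' @param items optional item positions to score.
#' @return overall accuracy.
#' @export
fusion_accuracy <- function(fr, ps, items = seq_along(ps$truth)) {
  mean(fr$fused_labels[items] == ps$truth[items])
}

#' Turn a fusion result into a one-member prediction set
#'
#' Lets fused outputs feed back into the metrics, pruning and comparison
#' machinery (and be written with [write_prediction_set()]). Hard-vote
#' results, which carry no probabilities, become one-hot and are flagged
#' probability-free.
#'
#' @param fr a `"fusion_result"`.
#' @param ps the source [prediction_set()].
#' @param name classifier name for the fused model.
#' @return a [prediction_set()] with one classifier.
#' @export
fusion_as_prediction_set <- function(fr, ps, name = fr$method) {
  if (is.null(fr$fused_probs)) {
    p <- matrix(0, length(fr$fused_labels), length(ps$classes),
                dimnames = list(ps$item_ids, as.character(ps$classes)))
    p[cbind(seq_along(fr$fused_labels), fr$fused_labels)] <- 1
    pf <- stats::setNames(TRUE, name)
  } else {
    p <- fr$fused_probs
    pf <- stats::setNames(FALSE, name)
  }
  prediction_set(stats::setNames(list(p), name), ps$truth,
                 classes = ps$classes, item_ids = ps$item_ids, prob_free = pf)
}

#' Optimize voting weights by sequential model-based search
#'
#' Searches `[0, 1]^m` (weights are normalized before use) for the weight
#' vector maximizing fusion accuracy on a labeled objective subset, using a
#' Gaussian-process surrogate with expected improvement. The uniform vector
#' is always evaluated first, so the returned weights never score below
#' uniform on the objective set; the whole search is deterministic under
#' `seed`.
#'
#' @param ps a [prediction_set()].
#' @param members classifier names.
#' @param method `"sv"`: objective is weighted-average-voting accuracy;
#'   `"hv"`: weighted-hard-voting accuracy.
#' @param items item positions forming the labeled objective set (default
#'   all items — the benchmark's own protocol; pass a validation split to
#'   avoid optimizing on the set you report).
#' @param budget number of objective evaluations (default 200).
#' @param seed integer seed.
#' @return a [weight_vector()] whose `provenance` records the method,
#'   budget, seed, achieved objective and the uniform baseline.
#' @examples
#' ps <- simulate_predictions(n_items = 80, n_classifiers = 4, seed = 2)
#' wv <- optimize_weights(ps, budget = 30, seed = 2)
#' wv$provenance$objective_value >= wv$provenance$uniform_value
#' @export
optimize_weights <- function(ps, members = ps$classifiers,
                             method = c("sv", "hv"),
                             items = seq_along(ps$truth),
                             budget = 200L, seed = 1L) {
  members <- match_members(ps, members)
  method <- match.arg(method)
  if (length(items) == 0L) stop("objective subset is empty", call. = FALSE)
  if (budget < 1L) stop("budget must be >= 1", call. = FALSE)
  sub <- subset_prediction_set(ps, members, items)
  fuse <- if (method == "sv") soft_vote else hard_vote
  objective <- function(w) {
    if (sum(w) <= 1e-12) return(-1)  # degenerate all-zero proposal
    fr <- fuse(sub, members, weight_vector(stats::setNames(w, members)))
    mean(fr$fused_labels == sub$truth)
  }
  m <- length(members)
  res <- smbo_maximize(objective, dim = m, budget = budget, seed = seed,
                       first = rep(0.5, m))
  uniform_value <- res$y[1L]
  w_best <- res$x
  if (sum(w_best) <= 1e-12) w_best <- rep(0.5, m)
  weight_vector(
    stats::setNames(w_best, members),
    provenance = list(method = "smbo-gp-ei",
                      objective = method, budget = budget, seed = seed,
                      objective_value = res$value,
                      uniform_value = uniform_value,
                      n_objective_items = length(items)))
}
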