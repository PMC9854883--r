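#' Prediction sets: containers and delimited-text I/O
#'
#' A *prediction set* bundles the outputs of `m` trained classifiers on the
#' same `N` items: per classifier an `N x C` row-stochastic matrix of class
#' probabilities (or a one-hot matrix for classifiers that only emit hard
#' labels), plus the `N` ground-truth labels and a fixed, ordered class
#' registry. All downstream fusion, pruning and evaluation operates on this
#' container.
#'
#' @name prediction_data
NULL

# Row sums within 1 +/- RENORM_TOL are silently renormalized; beyond that the
# file is considered corrupt and rejected.
RENORM_TOL <- 1e-3

#' Construct a class registry
#'
#' An ordered set of unique class labels. The order is authoritative: every
#' matrix, report and serialized artifact in the package uses it, and the
#' integer encoding used by [diversity_matrix()] is the 1-based position in
#' this order.
#'
#' @param classes character vector of unique, non-empty class labels.
#' @return A character vector of class `"class_registry"`.
#' @examples
#' class_registry(c("BLT", "LCY", "MLC", "PLC"))
#' @export
class_registry <- function(classes) {
  classes <- as.character(classes)
  if (length(classes) < 2L) {
    stop("a class registry needs at least two classes", call. = FALSE)
  }
  if (anyDuplicated(classes) || any(!nzchar(classes)) || anyNA(classes)) {
    stop("class labels must be unique and non-empty", call. = FALSE)
  }
  structure(classes, class = "class_registry")
}

#' Construct a multi-classifier prediction set
#'
#' @param probs named list, one `N x C` numeric matrix per classifier, rows =
#'   items, columns = classes in registry order. Every row must sum to 1
#'   within `1e-3` (it is renormalized exactly to 1) and contain values in
#'   `[0, 1]`.
#' @param truth character (class labels) or integer (1-based class indices)
#'   vector of length `N` with the ground-truth class of every item.
#' @param classes a [class_registry()] or character vector of class labels in
#'   fixed order. Defaults to the column names of the first matrix.
#' @param item_ids optional character vector of item identifiers; defaults to
#'   the rownames of the first matrix or `item1..itemN`.
#' @param prob_free named logical flagging classifiers whose matrices are
#'   one-hot encodings of hard labels only; those members are refused by
#'   probability-dependent operations (soft voting, ROC/AUC, stacking).
#' @return An object of class `"prediction_set"` with elements `classes`,
#'   `classifiers`, `probs`, `truth` (integer, 1-based), `item_ids`,
#'   `prob_free`.
#' @seealso [read_prediction_set()], [predicted_labels()], [soft_vote()]
#' @export
prediction_set <- function(probs, truth, classes = NULL, item_ids = NULL,
                           prob_free = NULL) {
  if (!is.list(probs) || length(probs) == 0L) {
    stop("`probs` must be a non-empty named list of matrices", call. = FALSE)
  }
  if (is.null(names(probs)) || any(!nzchar(names(probs)))) {
    names(probs) <- paste0("clf", seq_along(probs))
  }
  classifiers <- names(probs)
  if (anyDuplicated(classifiers)) {
    stop("classifier names must be unique", call. = FALSE)
  }
  probs <- lapply(probs, function(p) {
    p <- as.matrix(p)
    storage.mode(p) <- "double"
    p
  })
  if (is.null(classes)) {
    classes <- colnames(probs[[1L]])
    if (is.null(classes)) {
      stop("`classes` not given and first matrix has no column names",
           call. = FALSE)
    }
  }
  if (!inherits(classes, "class_registry")) classes <- class_registry(classes)
  n_class <- length(classes)
  n <- nrow(probs[[1L]])

  if (is.null(item_ids)) item_ids <- rownames(probs[[1L]])
  if (is.null(item_ids)) item_ids <- paste0("item", seq_len(n))
  item_ids <- as.character(item_ids)
  if (length(item_ids) != n || anyDuplicated(item_ids)) {
    stop("item ids must be unique and one per row", call. = FALSE)
  }

  for (j in seq_along(probs)) {
    p <- probs[[j]]
    if (nrow(p) != n) {
      stop(sprintf("classifier '%s' has %d rows; expected %d",
                   classifiers[j], nrow(p), n), call. = FALSE)
    }
    if (ncol(p) != n_class) {
      stop(sprintf("classifier '%s' has %d columns; registry has %d classes",
                   classifiers[j], ncol(p), n_class), call. = FALSE)
    }
    if (!is.null(colnames(p))) {
      unknown <- setdiff(colnames(p), as.character(classes))
      if (length(unknown)) {
        stop(sprintf("classifier '%s': unknown class column(s) %s",
                     classifiers[j], paste(unknown, collapse = ", ")),
             call. = FALSE)
      }
      p <- p[, as.character(classes), drop = FALSE]
    }
    if (anyNA(p) || any(p < 0) || any(p > 1 + RENORM_TOL)) {
      stop(sprintf("classifier '%s': probabilities outside [0, 1]",
                   classifiers[j]), call. = FALSE)
    }
    rs <- rowSums(p)
    bad <- which(abs(rs - 1) > RENORM_TOL)
    if (length(bad)) {
      stop(sprintf(
        "classifier '%s': probability row(s) %s sum outside [%g, %g] (e.g. row '%s' sums to %.6g)",
        classifiers[j], paste(utils::head(item_ids[bad], 5L), collapse = ", "),
        1 - RENORM_TOL, 1 + RENORM_TOL, item_ids[bad[1L]], rs[bad[1L]]),
        call. = FALSE)
    }
    p <- p / rs
    dimnames(p) <- list(item_ids, as.character(classes))
    probs[[j]] <- p
  }

  truth_idx <- encode_labels(truth, classes)
  if (length(truth_idx) != n) {
    stop(sprintf("truth has length %d; expected %d", length(truth_idx), n),
         call. = FALSE)
  }

  if (is.null(prob_free)) {
    prob_free <- stats::setNames(rep(FALSE, length(classifiers)), classifiers)
  } else {
    pf <- stats::setNames(rep(FALSE, length(classifiers)), classifiers)
    pf[names(prob_free)] <- as.logical(prob_free)
    prob_free <- pf
  }

  structure(
    list(classes = classes, classifiers = classifiers, probs = probs,
         truth = truth_idx, item_ids = item_ids, prob_free = prob_free),
    class = "prediction_set")
}

# labels -> 1-based registry indices, validating membership
encode_labels <- function(labels, classes) {
  if (is.numeric(labels)) {
    idx <- as.integer(labels)
    if (any(idx < 1L) || any(idx > length(classes)) || anyNA(idx)) {
      stop("truth indices outside the class registry", call. = FALSE)
    }
    return(idx)
  }
  idx <- match(as.character(labels), as.character(classes))
  if (anyNA(idx)) {
    stop(sprintf("label(s) not in registry: %s",
                 paste(unique(labels[is.na(idx)]), collapse = ", ")),
         call. = FALSE)
  }
  idx
}

#' @export
print.prediction_set <- function(x, ...) {
  cat(sprintf("<prediction_set> %d classifiers x %d items x %d classes\n",
              length(x$classifiers), length(x$truth), length(x$classes)))
  cat("classes:    ", paste(x$classes, collapse = ", "), "\n")
  cat("classifiers:", paste(utils::head(x$classifiers, 8L), collapse = ", "),
      if (length(x$classifiers) > 8L) "..." else "", "\n")
  if (any(x$prob_free)) {
    cat("hard-label only:",
        paste(x$classifiers[x$prob_free], collapse = ", "), "\n")
  }
  invisible(x)
}

#' Number of items / classifiers in a prediction set
#' @param ps a [prediction_set()].
#' @return integer.
#' @export
n_items <- function(ps) length(ps$truth)

#' @rdname n_items
#' @export
n_classifiers <- function(ps) length(ps$classifiers)

#' Hard labels predicted by each classifier
#'
#' Row-wise argmax of each probability matrix (first maximum on exact ties,
#' which is deterministic; softmax-derived matrices essentially never tie).
#'
#' @param ps a [prediction_set()].
#' @param members classifier names (default all).
#' @return integer matrix, `N x length(members)`, of 1-based class indices.
#' @export
predicted_labels <- function(ps, members = ps$classifiers) {
  members <- match_members(ps, members)
  out <- vapply(members, function(m) max.col(ps$probs[[m]], ties.method = "first"),
                integer(length(ps$truth)))
  out <- matrix(as.integer(out), nrow = length(ps$truth),
                ncol = length(members))
  dimnames(out) <- list(ps$item_ids, members)
  out
}

#' Standalone overall accuracy of each member classifier
#' @param ps a [prediction_set()].
#' @param members classifier names (default all).
#' @param items optional integer vector of item positions to score.
#' @return named numeric vector of overall accuracies.
#' @export
member_accuracy <- function(ps, members = ps$classifiers,
                            items = seq_along(ps$truth)) {
  lab <- predicted_labels(ps, members)
  apply(lab[items, , drop = FALSE], 2L, function(l) mean(l == ps$truth[items]))
}

match_members <- function(ps, members) {
  members <- as.character(members)
  if (length(members) == 0L) stop("empty member list", call. = FALSE)
  miss <- setdiff(members, ps$classifiers)
  if (length(miss)) {
    stop(sprintf("unknown classifier(s): %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  }
  members
}

#' Subset a prediction set
#' @param ps a [prediction_set()].
#' @param members classifiers to keep (in the given order).
#' @param items integer item positions to keep.
#' @return a [prediction_set()].
#' @export
subset_prediction_set <- function(ps, members = ps$classifiers,
                                  items = seq_along(ps$truth)) {
  members <- match_members(ps, members)
  prediction_set(
    probs = lapply(stats::setNames(members, members),
                   function(m) ps$probs[[m]][items, , drop = FALSE]),
    truth = ps$truth[items], classes = ps$classes,
    item_ids = ps$item_ids[items], prob_free = ps$prob_free[members])
}

# ---- delimited-text I/O ----------------------------------------------------

#' Read a prediction set from delimited text
#'
#' The combined dialect has one row per (item, classifier) with columns
#' `item_id, classifier, <class1>, ..., <classC>`; alternatively one file per
#' classifier with columns `item_id, <class1>, ..., <classC>` (the classifier
#' name is then the file's base name). The truth file has columns
#' `item_id, label`. Items are aligned across classifiers by `item_id`, never
#' by file order; classifiers covering different item sets are an error.
#'
#' @param paths character vector: one combined file, or one file per
#'   classifier.
#' @param truth_path path of the truth file.
#' @param classes optional class order; defaults to the class columns of the
#'   first file, in file order.
#' @param sep field separator, `","` (default) or `"\t"`.
#' @param hard_classifiers classifier names whose rows are one-hot hard
#'   labels; flagged probability-free.
#' @return a [prediction_set()].
#' @export
read_prediction_set <- function(paths, truth_path, classes = NULL, sep = ",",
                                hard_classifiers = character()) {
  for (p in c(paths, truth_path)) {
    if (!file.exists(p)) stop(sprintf("file not found: %s", p), call. = FALSE)
  }
  tr <- utils::read.table(truth_path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("item_id", "label") %in% names(tr))) {
    stop("truth file must have columns item_id, label", call. = FALSE)
  }
  tr$item_id <- as.character(tr$item_id)

  tabs <- list()
  for (p in paths) {
    d <- utils::read.table(p, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
    if (!"item_id" %in% names(d)) {
      stop(sprintf("%s: missing item_id column", p), call. = FALSE)
    }
    d$item_id <- as.character(d$item_id)
    if ("classifier" %in% names(d)) {
      tabs <- c(tabs, split(d, d$classifier))
    } else {
      nm <- sub("\\.[^.]*$", "", basename(p))
      tabs[[nm]] <- d
    }
  }
  if (anyDuplicated(names(tabs))) {
    stop("duplicate classifier tables across files", call. = FALSE)
  }

  first <- tabs[[1L]]
  cls_cols <- setdiff(names(first), c("item_id", "classifier"))
  if (is.null(classes)) classes <- cls_cols
  registry <- if (inherits(classes, "class_registry")) classes else class_registry(classes)
  unknown <- setdiff(cls_cols, as.character(registry))
  if (length(unknown)) {
    stop(sprintf("unknown class column(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }

  ids <- tr$item_id  # truth-file order is authoritative
  probs <- lapply(tabs, function(d) {
    if (!setequal(d$item_id, ids)) {
      missing_ids <- setdiff(ids, d$item_id)
      extra_ids <- setdiff(d$item_id, ids)
      stop(sprintf(
        "item sets differ from truth: missing [%s]; unexpected [%s]",
        paste(utils::head(missing_ids, 5L), collapse = ", "),
        paste(utils::head(extra_ids, 5L), collapse = ", ")), call. = FALSE)
    }
    d <- d[match(ids, d$item_id), , drop = FALSE]
    m <- as.matrix(d[, as.character(registry), drop = FALSE])
    rownames(m) <- ids
    m
  })
  truth <- tr$label[match(ids, tr$item_id)]
  pf <- stats::setNames(names(tabs) %in% hard_classifiers, names(tabs))
  prediction_set(probs, truth, classes = registry, item_ids = ids,
                 prob_free = pf)
}

#' Write a prediction set as a combined delimited-text file
#'
#' Inverse of [read_prediction_set()]: emits the combined dialect plus a
#' truth file. Probabilities round-trip to better than `1e-9`.
#'
#' @param ps a [prediction_set()].
#' @param path output file for the combined prediction table.
#' @param truth_path output file for the truth table (skipped if `NULL`).
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
write_prediction_set <- function(ps, path, truth_path = NULL, sep = ",") {
  blocks <- lapply(ps$classifiers, function(m) {
    data.frame(item_id = ps$item_ids, classifier = m,
               as.data.frame(ps$probs[[m]], check.names = FALSE),
               check.names = FALSE, row.names = NULL)
  })
  out <- do.call(rbind, blocks)
  utils::write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
  if (!is.null(truth_path)) {
    utils::write.table(
      data.frame(item_id = ps$item_ids,
                 label = as.character(ps$classes)[ps$truth]),
      truth_path, sep = sep, row.names = FALSE, quote = FALSE,
      fileEncoding = "UTF-8")
  }
  invisible(path)
}

# ---- confusion matrices and one-vs-rest counts -----------------------------

#' Multiclass confusion matrix
#'
#' Rows are actual classes, columns predicted classes, in registry order.
#'
#' @param truth,pred equal-length vectors of class labels or 1-based indices.
#' @param classes a [class_registry()] or character vector of class labels.
#' @return A `C x C` integer matrix of class `"confusion_matrix"` with a
#'   `classes` attribute.
#' @examples
#' confusion(c(1, 2, 2), c(1, 2, 1), classes = c("a", "b"))
#' @export
confusion <- function(truth, pred, classes) {
  if (!inherits(classes, "class_registry")) classes <- class_registry(classes)
  t_idx <- encode_labels(truth, classes)
  p_idx <- encode_labels(pred, classes)
  if (length(t_idx) != length(p_idx)) {
    stop("truth and pred must have equal length", call. = FALSE)
  }
  k <- length(classes)
  cm <- matrix(0L, k, k, dimnames = list(actual = as.character(classes),
                                         predicted = as.character(classes)))
  tab <- table(factor(t_idx, levels = seq_len(k)),
               factor(p_idx, levels = seq_len(k)))
  cm[] <- as.integer(tab)
  structure(cm, classes = classes, class = c("confusion_matrix", "matrix"))
}

#' One-vs-rest counts for one class of a confusion matrix
#'
#' Collapses a multiclass confusion matrix to binary counts with the chosen
#' class as positive: TP is the diagonal cell, FN the rest of its row, FP the
#' rest of its column, TN everything else.
#'
#' @param cm a [confusion()] matrix.
#' @param class_index 1-based class position or class label.
#' @return a [class_counts()] object.
#' @export
ovr_counts <- function(cm, class_index) {
  k <- nrow(cm)
  if (is.character(class_index)) {
    class_index <- match(class_index, rownames(cm))
  }
  if (is.na(class_index) || class_index < 1L || class_index > k) {
    stop("invalid class index", call. = FALSE)
  }
  tp <- cm[class_index, class_index]
  fn <- sum(cm[class_index, ]) - tp
  fp <- sum(cm[, class_index]) - tp
  tn <- sum(cm) - tp - fn - fp
  class_counts(tp, fp, fn, tn)
}

#' One-vs-rest TP/FP/FN/TN counts
#'
#' @param tp,fp,fn,tn non-negative integer counts for one class treated as
#'   positive against the rest.
#' @return an object of class `"class_counts"`.
#' @export
class_counts <- function(tp, fp, fn, tn) {
  v <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (anyNA(v) || any(v < 0) || any(v != round(v))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  v <- stats::setNames(as.integer(round(v)), c("tp", "fp", "fn", "tn"))
  structure(as.list(v), class = "class_counts")
}

#' @export
print.class_counts <- function(x, ...) {
  cat(sprintf("<class_counts> tp=%d fp=%d fn=%d tn=%d (N=%d)\n",
              x$tp, x$fp, x$fn, x$tn, x$tp + x$fp + x$fn + x$tn))
  invisible(x)
}
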