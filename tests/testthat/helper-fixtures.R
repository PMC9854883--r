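# Shared builders and independent oracles for the test suite.

# Random row-stochastic prediction set: m classifiers, n items, C classes.
rand_ps <- function(n = 20L, n_class = 3L, m = 2L, seed = 1L,
                    classifiers = sprintf("m%02d", seq_len(m))) {
  set.seed(seed)
  probs <- lapply(seq_len(m), function(j) {
    p <- matrix(stats::runif(n * n_class), n, n_class)
    p <- p / rowSums(p)
    colnames(p) <- paste0("c", seq_len(n_class))
    p
  })
  names(probs) <- classifiers
  prediction_set(probs, truth = sample(seq_len(n_class), n, replace = TRUE),
                 classes = paste0("c", seq_len(n_class)))
}

# One-hot prediction set from a label matrix (n x m), for hard-vote tests.
labels_ps <- function(lab, truth, n_class = max(lab, truth),
                      classifiers = sprintf("m%02d", seq_len(ncol(lab)))) {
  probs <- lapply(seq_len(ncol(lab)), function(j) {
    p <- matrix(0, nrow(lab), n_class,
                dimnames = list(NULL, paste0("c", seq_len(n_class))))
    p[cbind(seq_len(nrow(lab)), lab[, j])] <- 1
    p
  })
  names(probs) <- classifiers
  prediction_set(probs, truth = truth, classes = paste0("c", seq_len(n_class)),
                 prob_free = stats::setNames(rep(TRUE, ncol(lab)), classifiers))
}

# Brute-force AUC oracle: count positive-negative score pairs, ties = 1/2.
auc_pairs <- function(scores, pos) {
  sp <- scores[pos]; sn <- scores[!pos]
  if (!length(sp) || !length(sn)) return(NA_real_)
  tot <- 0
  for (a in sp) tot <- tot + sum(a > sn) + 0.5 * sum(a == sn)
  tot / (length(sp) * length(sn))
}

# Assert agreement with a value printed at 3 decimal places: within one
# unit in the third decimal (covers round-vs-truncate at publication).
expect_printed3 <- function(actual, printed) {
  expect_lt(max(abs(actual - printed)), 1e-3 + 1e-12)
}

# Realize a C x C confusion matrix consistent with one-vs-rest counts:
# diagonal = tp, row sums = tp + fn, col sums = tp + fp. Greedy transport
# over the off-diagonal cells, then 2-cycle repairs when a row's remainder
# can only face its own (forbidden) diagonal column.
realize_confusion <- function(tp, fn, fp, classes) {
  k <- length(tp)
  cm <- diag(tp)
  rrem <- fn
  crem <- fp
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (i == j) next
      x <- min(rrem[i], crem[j])
      cm[i, j] <- cm[i, j] + x
      rrem[i] <- rrem[i] - x
      crem[j] <- crem[j] - x
    }
  }
  guard <- 0L
  while (any(rrem > 0)) {
    guard <- guard + 1L
    stopifnot(guard < 10000L)
    i <- which(rrem > 0)[1L]
    stopifnot(crem[i] > 0)  # only the forbidden column remains
    moved <- FALSE
    for (i2 in setdiff(seq_len(k), i)) {
      for (j2 in setdiff(seq_len(k), c(i, i2))) {
        if (cm[i2, j2] > 0) {
          d <- min(rrem[i], crem[i], cm[i2, j2])
          cm[i2, j2] <- cm[i2, j2] - d
          cm[i2, i] <- cm[i2, i] + d
          cm[i, j2] <- cm[i, j2] + d
          rrem[i] <- rrem[i] - d
          crem[i] <- crem[i] - d
          moved <- TRUE
          break
        }
      }
      if (moved) break
    }
    stopifnot(moved)
  }
  stopifnot(all(rrem == 0), all(crem == 0))
  dimnames(cm) <- list(actual = classes, predicted = classes)
  structure(cm, classes = class_registry(classes),
            class = c("confusion_matrix", "matrix"))
}

# Truth/prediction pair realizing a given McNemar contingency.
realize_mcnemar <- function(n00, n01, n10, n11) {
  n <- n00 + n01 + n10 + n11
  truth <- rep(1L, n)
  p1 <- c(rep(1L, n00), rep(1L, n01), rep(2L, n10), rep(2L, n11))
  p2 <- c(rep(1L, n00), rep(2L, n01), rep(1L, n10), rep(2L, n11))
  list(truth = truth, p1 = p1, p2 = p2)
}
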