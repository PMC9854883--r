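#' Paired-classifier comparison and diversity diagnostics
#'
#' McNemar's test compares two classifiers on the same items through their
#' discordant counts: n01 items classified correctly only by the first,
#' n10 only by the second. The statistic is the uncorrected
#' `chi^2 = (n01 - n10)^2 / (n01 + n10)` on 1 degree of freedom; an optional
#' continuity-corrected variant is available but off by default, matching
#' the printed formula this package reproduces.
#'
#' Ensemble diversity is summarized by the Pearson correlation matrix of the
#' members' integer-encoded predicted labels; pairs at or above the
#' redundancy threshold (default 0.95) are flagged as too similar for
#' fusion to help. The class-index encoding makes this diagnostic
#' encoding-sensitive (relabeling classes changes it); Cramér's V on the
#' same label pairs is offered as an encoding-free alternative.
#'
#' @name stats_module
NULL

#' McNemar's paired test from truth and two prediction vectors
#'
#' @param truth,pred1,pred2 equal-length label vectors (names or 1-based
#'   indices).
#' @param classes optional registry for label encoding; defaults to treating
#'   the vectors as comparable as-is.
#' @param correction apply the continuity correction
#'   `(|n01 - n10| - 1)^2 / (n01 + n10)` (default `FALSE`).
#' @return object of class `"mcnemar_result"`: `n00`, `n01`, `n10`, `n11`,
#'   `chi2`, `p`, `degenerate` (`TRUE` when `n01 + n10 == 0`, in which case
#'   `chi2 = 0`, `p = 1`), `correction`.
#' @examples
#' mcnemar_compare(c(1, 1, 2, 2), c(1, 1, 2, 1), c(1, 2, 2, 2))
#' @export
mcnemar_compare <- function(truth, pred1, pred2, classes = NULL,
                            correction = FALSE) {
  if (!is.null(classes)) {
    if (!inherits(classes, "class_registry")) classes <- class_registry(classes)
    truth <- encode_labels(truth, classes)
    pred1 <- encode_labels(pred1, classes)
    pred2 <- encode_labels(pred2, classes)
  }
  if (length(truth) != length(pred1) || length(truth) != length(pred2)) {
    stop("truth, pred1 and pred2 must have equal length", call. = FALSE)
  }
  c1 <- pred1 == truth
  c2 <- pred2 == truth
  n00 <- sum(c1 & c2); n01 <- sum(c1 & !c2)
  n10 <- sum(!c1 & c2); n11 <- sum(!c1 & !c2)
  disc <- n01 + n10
  if (disc == 0L) {
    chi2 <- 0; p <- 1; degenerate <- TRUE
  } else {
    num <- if (correction) (abs(n01 - n10) - 1)^2 else (n01 - n10)^2
    chi2 <- num / disc
    p <- stats::pchisq(chi2, df = 1L, lower.tail = FALSE)
    degenerate <- FALSE
  }
  structure(list(n00 = n00, n01 = n01, n10 = n10, n11 = n11,
                 chi2 = chi2, p = p, degenerate = degenerate,
                 correction = correction),
            class = "mcnemar_result")
}

#' @export
print.mcnemar_result <- function(x, ...) {
  cat(sprintf("<mcnemar_result> n00=%d n01=%d n10=%d n11=%d\n",
              x$n00, x$n01, x$n10, x$n11))
  cat(sprintf("chi2 = %.4f, p = %.4g%s%s\n", x$chi2, x$p,
              if (x$correction) " (continuity-corrected)" else "",
              if (x$degenerate) " [degenerate: no discordant items]" else ""))
  invisible(x)
}

#' Diversity matrix of predicted-label correlations
#'
#' Pearson correlation between every pair of members' predicted-label
#' vectors under the registry's fixed integer encoding. A member predicting
#' a single class constantly has undefined correlations; its row and column
#' are `NA` and it is listed in `constant_members`.
#'
#' @param ps a [prediction_set()] with at least two classifiers.
#' @param threshold redundancy threshold; pairs with correlation at or above
#'   it are flagged (default 0.95).
#' @return object of class `"diversity_matrix"`: `corr` (`m x m`, unit
#'   diagonal), `flagged` (data.frame of redundant pairs), `threshold`,
#'   `constant_members`.
#' @export
diversity_matrix <- function(ps, threshold = 0.95) {
  if (n_classifiers(ps) < 2L) {
    stop("diversity needs at least two classifiers", call. = FALSE)
  }
  lab <- predicted_labels(ps)
  const <- apply(lab, 2L, function(v) length(unique(v)) == 1L)
  cc <- suppressWarnings(stats::cor(lab))
  cc[const, ] <- NA_real_
  cc[, const] <- NA_real_
  diag(cc) <- 1
  pairs <- which(upper.tri(cc) & !is.na(cc) & cc >= threshold, arr.ind = TRUE)
  flagged <- data.frame(member1 = colnames(lab)[pairs[, 1L]],
                        member2 = colnames(lab)[pairs[, 2L]],
                        corr = cc[pairs], row.names = NULL)
  structure(list(corr = cc, flagged = flagged, threshold = threshold,
                 constant_members = colnames(lab)[const]),
            class = "diversity_matrix")
}

#' @export
print.diversity_matrix <- function(x, digits = 3L, ...) {
  cat(sprintf("<diversity_matrix> %d members, redundancy threshold %.2f\n",
              ncol(x$corr), x$threshold))
  off <- x$corr[upper.tri(x$corr)]
  cat(sprintf("off-diagonal range: %.3f .. %.3f\n",
              min(off, na.rm = TRUE), max(off, na.rm = TRUE)))
  if (nrow(x$flagged)) {
    cat("redundant pairs:\n"); print(x$flagged, row.names = FALSE)
  } else cat("no redundant pairs\n")
  if (length(x$constant_members)) {
    cat("constant members (undefined):",
        paste(x$constant_members, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Cramér's V between two members' predicted labels
#'
#' Encoding-free association alternative to the Pearson diagnostic of
#' [diversity_matrix()].
#'
#' @param ps a [prediction_set()].
#' @param member1,member2 classifier names.
#' @return Cramér's V in `[0, 1]`.
#' @export
cramers_v <- function(ps, member1, member2) {
  lab <- predicted_labels(ps, c(member1, member2))
  tab <- table(factor(lab[, 1L], levels = seq_along(ps$classes)),
               factor(lab[, 2L], levels = seq_along(ps$classes)))
  n <- sum(tab)
  chi2 <- suppressWarnings(stats::chisq.test(tab, correct = FALSE)$statistic)
  k <- min(dim(tab)) - 1L
  if (k == 0L || n == 0L) return(NA_real_)
  sqrt(as.numeric(chi2) / (n * k))
}

#' Write the lower triangle of a diversity matrix as CSV
#'
#' One row per member, columns up to the diagonal — the layout of published
#' classifier-correlation tables.
#'
#' @param dm a [diversity_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_diversity_matrix <- function(dm, path) {
  cc <- round(dm$corr, 3L)
  cc[upper.tri(cc)] <- NA
  df <- data.frame(member = rownames(cc), as.data.frame(cc),
                   check.names = FALSE, row.names = NULL)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
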