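#' Seeded generator of correlated multi-classifier prediction sets
#'
#' Emulates the statistical structure of a bank of CNN classifiers tested on
#' the same balanced multiclass image set: each classifier has a target
#' standalone accuracy ("skill") and the classifiers' errors are correlated
#' through a shared latent evidence signal. Per item a shared noise vector
#' is drawn; classifier j's logits mix that shared signal (weight `rho`)
#' with idiosyncratic noise (weight `1 - rho`) plus a bias on the true
#' class whose scale is calibrated by bisection so the classifier's realized
#' overall accuracy matches its skill target. Probabilities are a softmax of
#' the logits, so rows sum to 1 exactly and the argmax label is unchanged by
#' the temperature.
#'
#' @name synthetic
NULL

#' Default per-classifier skill targets
#'
#' Evenly spans 0.72 down to 0.62 — the accuracy band of the 16-CNN
#' liver-ultrasound benchmark the package ships fixtures for.
#'
#' @param m number of classifiers.
#' @return numeric vector of length `m`, decreasing.
#' @export
default_skills <- function(m) seq(0.72, 0.62, length.out = m)

#' Generate a correlated synthetic prediction set
#'
#' @param n_items number of items; must be divisible by `n_classes` (truth
#'   supports are exactly balanced). Default 1000.
#' @param n_classes number of classes (default 4).
#' @param n_classifiers number of member classifiers (default 16).
#' @param skill per-classifier target overall accuracy, each in
#'   `(1/n_classes, 1)`; default [default_skills()].
#' @param rho shared-signal mixing weight in `[0, 1)` controlling pairwise
#'   predicted-label correlation. The default 0.45 places the off-diagonal
#'   correlations of the 16-member default inside the 0.33–0.75 band
#'   reported for the benchmark's CNNs.
#' @param temperature softmax temperature (> 0) for probability sharpness;
#'   affects probabilities, not labels. Default 1.
#' @param seed integer seed; the generated set is fully deterministic given
#'   the configuration and seed.
#' @param classes,classifiers optional label vectors; defaults `class1..C` /
#'   `clf01..m`.
#' @return a [prediction_set()] with attribute `"calibration"`: data.frame
#'   of per-classifier target and realized accuracy and the fitted bias
#'   scale.
#' @examples
#' ps <- simulate_predictions(n_items = 200, n_classifiers = 4, seed = 7)
#' attr(ps, "calibration")
#' @export
simulate_predictions <- function(n_items = 1000L, n_classes = 4L,
                                 n_classifiers = 16L,
                                 skill = default_skills(n_classifiers),
                                 rho = 0.45, temperature = 1, seed = 7L,
                                 classes = NULL, classifiers = NULL) {
  if (n_items %% n_classes != 0L) {
    stop("n_items must be divisible by n_classes (balanced truth)",
         call. = FALSE)
  }
  if (length(skill) != n_classifiers) {
    stop("need one skill target per classifier", call. = FALSE)
  }
  if (any(skill <= 1 / n_classes) || any(skill >= 1)) {
    stop(sprintf("skill targets must lie in (1/%d, 1)", n_classes),
         call. = FALSE)
  }
  if (rho < 0 || rho >= 1) stop("rho must lie in [0, 1)", call. = FALSE)
  if (temperature <= 0) stop("temperature must be positive", call. = FALSE)
  if (is.null(classes)) classes <- paste0("class", seq_len(n_classes))
  if (is.null(classifiers)) {
    classifiers <- sprintf("clf%02d", seq_len(n_classifiers))
  }
  registry <- class_registry(classes)

  local_seed(derive_seed(seed, "generate"), {
    truth <- sample(rep(seq_len(n_classes), n_items / n_classes))
    shared <- matrix(stats::rnorm(n_items * n_classes), n_items, n_classes)
    probs <- vector("list", n_classifiers)
    calib <- data.frame(classifier = classifiers, target = skill,
                        realized = NA_real_, bias = NA_real_)
    for (j in seq_len(n_classifiers)) {
      noise <- matrix(stats::rnorm(n_items * n_classes), n_items, n_classes)
      mix <- rho * shared + (1 - rho) * noise
      b <- calibrate_bias(mix, truth, skill[j])
      logits <- mix
      logits[cbind(seq_len(n_items), truth)] <-
        logits[cbind(seq_len(n_items), truth)] + b
      z <- exp((logits - apply(logits, 1L, max)) / temperature)
      probs[[j]] <- z / rowSums(z)
      calib$realized[j] <-
        mean(max.col(logits, ties.method = "first") == truth)
      calib$bias[j] <- b
    }
    names(probs) <- classifiers
    ps <- prediction_set(probs, truth, classes = registry)
    attr(ps, "calibration") <- calib
    ps
  })
}

# Smallest bias scale whose realized argmax accuracy reaches `target`,
# found by doubling then 60 bisection steps on the realized draw itself.
# Accuracy is a non-decreasing step function of the bias, so this lands
# within one item flip (1/N) of the target.
calibrate_bias <- function(mix, truth, target) {
  n <- nrow(mix)
  acc <- function(b) {
    m <- mix
    m[cbind(seq_len(n), truth)] <- m[cbind(seq_len(n), truth)] + b
    mean(max.col(m, ties.method = "first") == truth)
  }
  lo <- 0; hi <- 1
  while (acc(hi) < target) {
    hi <- hi * 2
    if (hi > 64) stop("skill target unattainable", call. = FALSE)
  }
  for (i in seq_len(60L)) {
    mid <- (lo + hi) / 2
    if (acc(mid) >= target) hi <- mid else lo <- mid
  }
  hi
}

#' Load a shipped count-table fixture
#'
#' Two delimited-text fixtures mirror the published 4-class
#' liver-ultrasound benchmark: `"counts16"` — one-vs-rest TP/FP/FN/TN for
#' each of the 16 CNNs on the 1000-image test set — and
#' `"counts_ensembles"` — the same counts for the best pruned ensemble of
#' each fusion method (SV16, ST9, WAV7, WHV13). Every row satisfies
#' `tp + fp + fn + tn = 1000` and `tp + fn = 250` (250 test images per
#' class); [load_fixture()] re-validates both identities on load.
#'
#' @param table `"counts16"` or `"counts_ensembles"`.
#' @return data.frame with columns `classifier, class, tp, fp, fn, tn`;
#'   classes in registry order BLT, LCY, MLC, PLC within classifier.
#' @examples
#' head(load_fixture("counts16"))
#' @export
load_fixture <- function(table = c("counts16", "counts_ensembles")) {
  table <- match.arg(table)
  fname <- switch(table, counts16 = "fll_cnn16_counts.csv",
                  counts_ensembles = "fll_ensemble_counts.csv")
  path <- system.file("extdata", fname, package = "fusemble", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  tot <- df$tp + df$fp + df$fn + df$tn
  if (any(tot != tot[1L])) {
    stop("corrupt fixture: unequal totals", call. = FALSE)
  }
  sup <- df$tp + df$fn
  if (any(sup != sup[1L])) {
    stop("corrupt fixture: unequal class supports", call. = FALSE)
  }
  df
}
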