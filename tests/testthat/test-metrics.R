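test_that("per-class metrics reproduce published rows and flag 0/0 as undefined", {
  # single-CNN BLT row
  m <- class_metrics(class_counts(172, 59, 78, 691))
  expect_printed3(m$precision, 0.745)
  expect_printed3(m$sensitivity, 0.688)
  expect_printed3(m$specificity, 0.921)
  expect_printed3(m$f1, 0.715)

  # ensemble LCY row: no false positives at all
  m2 <- class_metrics(class_counts(230, 0, 20, 750))
  expect_printed3(m2$precision, 1.0)
  expect_equal(m2$specificity, 1.0)

  # empty positive-prediction set: precision undefined, sensitivity 0
  m3 <- class_metrics(class_counts(0, 0, 5, 5))
  expect_true(is.na(m3$precision))
  expect_equal(m3$sensitivity, 0)

  # undefined propagates to the macro unless na_rm
  counts <- list(a = class_counts(0, 0, 5, 5), b = class_counts(5, 5, 0, 0))
  rep_na <- metric_report(counts, ci_method = NULL)
  expect_true(is.na(rep_na$macro$precision))
  rep_rm <- metric_report(counts, ci_method = NULL, na_rm = TRUE)
  expect_false(is.na(rep_rm$macro$precision))
})

test_that("macro report reproduces the published per-model summaries", {
  tbl <- load_fixture("counts16")
  rx <- metric_report(tbl[tbl$classifier == "ResNeXt101", ], ci_method = NULL)
  expect_printed3(rx$macro$precision, 0.731)
  expect_printed3(rx$macro$sensitivity, 0.719)
  expect_printed3(rx$overall_accuracy, 0.719)
  expect_printed3(rx$macro$f1, 0.724)

  ens <- load_fixture("counts_ensembles")
  wav7 <- metric_report(ens[ens$classifier == "WAV7", ], ci_method = NULL)
  expect_printed3(wav7$macro$specificity, 0.928)
  expect_printed3(wav7$overall_accuracy, 0.783)

  # perfect predictor on balanced supports
  perfect <- lapply(1:4, function(i) class_counts(250, 0, 0, 750))
  names(perfect) <- paste0("c", 1:4)
  rp <- metric_report(perfect, ci_method = NULL)
  expect_printed3(rp$overall_accuracy, 1)
  expect_equal(unlist(rp$macro), c(precision = 1, sensitivity = 1,
                                   specificity = 1, f1 = 1,
                                   macro_class_accuracy = 1))
})

test_that("macro sensitivity equals overall accuracy under balanced supports", {
  set.seed(11)
  for (rep in 1:10) {
    k <- sample(2:5, 1L)
    per <- sample(5:40, 1L)
    truth <- rep(seq_len(k), each = per)
    pred <- sample(seq_len(k), k * per, replace = TRUE)
    r <- evaluate_predictions(truth, pred, paste0("c", seq_len(k)),
                              ci_method = NULL)
    expect_equal(r$macro$sensitivity, r$overall_accuracy, tolerance = 1e-12)
  }
})

test_that("Wilson and Wald intervals match published values and prop.test", {
  expect_printed3(proportion_ci(172, 250, "wilson"), c(0.628, 0.742))
  expect_printed3(proportion_ci(719, 1000, "wald"), c(0.691, 0.747))
  expect_printed3(proportion_ci(0, 10, "wilson")[1L], 0)

  # wilson == score interval of prop.test without continuity correction
  for (s in c(0, 1, 5, 17, 50)) {
    ci <- proportion_ci(s, 50, "wilson")
    ref <- stats::prop.test(s, 50, correct = FALSE)$conf.int
    expect_equal(ci, as.numeric(ref), tolerance = 1e-9)
  }

  # contains the point estimate, lies in [0,1], narrows with n
  set.seed(3)
  for (rep in 1:25) {
    n <- sample(5:500, 1L)
    s <- sample(0:n, 1L)
    ci <- proportion_ci(s, n, "wilson")
    expect_true(ci[1] <= s / n && s / n <= ci[2])
    expect_true(ci[1] >= 0 && ci[2] <= 1)
    ci4 <- proportion_ci(4L * s, 4L * n, "wilson")
    expect_lt(diff(ci4), diff(ci) + 1e-12)
  }

  expect_error(proportion_ci(1, 0), "positive")
  expect_error(proportion_ci(5, 3), "\\[0, n\\]")
})

test_that("macro CIs average per-class bounds and reproduce the published macro CI", {
  tbl <- load_fixture("counts16")
  rx <- metric_report(tbl[tbl$classifier == "ResNeXt101", ],
                      ci_method = "wald")
  expect_printed3(rx$macro_cis$sensitivity, c(0.666, 0.772))

  same <- replicate(4, c(0.2, 0.4), simplify = FALSE)
  expect_equal(macro_ci(same), c(0.2, 0.4))
  degen <- list(c(0.3, 0.3), c(0.5, 0.5))
  expect_equal(macro_ci(degen), c(0.4, 0.4))
})

test_that("one-vs-rest AUC equals the pair-counting oracle", {
  probs <- cbind(a = c(0.9, 0.8, 0.4, 0.3), b = c(0.1, 0.2, 0.6, 0.7))
  expect_equal(ovr_roc_auc(probs, c("a", "b", "a", "b"), "a"), 0.75)

  # perfectly separating and all-tied scores
  sep <- cbind(a = c(0.9, 0.8, 0.2, 0.1), b = c(0.1, 0.2, 0.8, 0.9))
  expect_equal(ovr_roc_auc(sep, c("a", "a", "b", "b"), "a"), 1)
  flat <- cbind(a = rep(0.5, 4), b = rep(0.5, 4))
  expect_equal(ovr_roc_auc(flat, c("a", "a", "b", "b"), "a"), 0.5)

  # single-class truth is undefined
  expect_true(is.na(ovr_roc_auc(probs, c("a", "a", "a", "a"), "b")))

  # 200 random draws with N <= 12, including tied scores
  set.seed(7)
  for (rep in 1:200) {
    n <- sample(2:12, 1L)
    scores <- sample(seq(0, 1, by = 0.25), n, replace = TRUE)
    pos <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (all(pos) || all(!pos)) pos[1L] <- !pos[1L]
    probs <- cbind(a = scores, b = 1 - scores)
    truth <- ifelse(pos, "a", "b")
    expect_equal(ovr_roc_auc(probs, truth, "a"), auc_pairs(scores, pos))
  }
})

test_that("AUC agrees with pROC and with trapezoidal ROC-curve area", {
  skip_if_not_installed("pROC")
  set.seed(5)
  for (rep in 1:5) {
    n <- 40L
    scores <- round(runif(n), 2)
    truth <- sample(c("a", "b"), n, replace = TRUE)
    probs <- cbind(a = scores, b = 1 - scores)
    ours <- ovr_roc_auc(probs, truth, "a")
    ref <- suppressMessages(
      as.numeric(pROC::auc(pROC::roc(truth == "a", scores,
                                     direction = "<", quiet = TRUE))))
    expect_equal(ours, ref, tolerance = 1e-12)
    crv <- ovr_roc_curve(probs, truth, "a")
    trap <- sum(diff(crv$fpr) * (head(crv$tpr, -1) + tail(crv$tpr, -1)) / 2)
    expect_equal(ours, trap, tolerance = 1e-12)
  }
})

test_that("macro AUC averages per-class AUCs over the registry", {
  ps <- rand_ps(n = 30L, n_class = 4L, m = 1L, seed = 13L)
  res <- macro_auc(ps$probs[[1L]], ps$truth, ps$classes)
  expect_length(res$per_class, 4L)
  expect_equal(res$macro, mean(res$per_class))
})

test_that("report writers emit readable CSV and JSON", {
  tbl <- load_fixture("counts16")
  rep <- metric_report(tbl[tbl$classifier == "Xception", ])
  csv <- withr::local_tempfile(fileext = ".csv")
  write_metric_report(rep, csv)
  back <- read.csv(csv)
  expect_equal(back$class, c("BLT", "LCY", "MLC", "PLC", "macro"))
  expect_equal(back$precision[back$class == "macro"],
               round(rep$macro$precision, 3))
  js <- withr::local_tempfile(fileext = ".json")
  write_metric_report(rep, js)
  parsed <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(parsed$overall_accuracy, rep$overall_accuracy)
})
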