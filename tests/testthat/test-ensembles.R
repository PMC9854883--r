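test_that("soft voting averages probabilities and argmaxes", {
  p1 <- matrix(c(0.6, 0.4), 1, 2, dimnames = list(NULL, c("a", "b")))
  p2 <- matrix(c(0.3, 0.7), 1, 2, dimnames = list(NULL, c("a", "b")))
  ps <- prediction_set(list(x = p1, y = p2), truth = "b")
  fr <- soft_vote(ps)
  expect_equal(unname(fr$fused_probs[1, ]), c(0.45, 0.55))
  expect_equal(fr$fused_labels, 2L)
  expect_equal(fr$method, "SV")

  # weights (2, 1): scores proportional to (1.4, 1.6)
  p2b <- matrix(c(0.2, 0.8), 1, 2, dimnames = list(NULL, c("a", "b")))
  ps2 <- prediction_set(list(x = p1, y = p2b), truth = "b")
  fr2 <- soft_vote(ps2, weights = weight_vector(c(x = 2, y = 1)))
  expect_equal(unname(fr2$fused_probs[1, ]), c(1.4, 1.6) / 3)
  expect_equal(fr2$fused_labels, 2L)
  expect_equal(fr2$method, "WAV")

  # single member with weight 1 is the member's own argmax
  ps3 <- rand_ps(n = 25L, n_class = 3L, m = 1L, seed = 2L)
  fr3 <- soft_vote(ps3)
  expect_equal(fr3$fused_labels, unname(predicted_labels(ps3)[, 1L]))
})

test_that("weighted hard voting sums vote weights and logs broken ties", {
  # votes (A, B, B) with weights (0.5, 0.3, 0.3): B wins 0.6 to 0.5
  lab <- cbind(1L, 2L, 2L)
  ps <- labels_ps(lab, truth = 1L, n_class = 2L)
  fr <- hard_vote(ps, weights = weight_vector(
    stats::setNames(c(0.5, 0.3, 0.3), ps$classifiers)))
  expect_equal(fr$fused_labels, 2L)
  expect_equal(fr$method, "WHV")
  expect_equal(fr$tie_events$count, 0L)

  # two-member tie goes to the first-listed (top-ranked) member's vote
  ps2 <- labels_ps(cbind(1L, 2L), truth = 1L, n_class = 2L)
  fr2 <- hard_vote(ps2)
  expect_equal(fr2$fused_labels, 1L)
  expect_equal(fr2$tie_events$count, 1L)
  fr2r <- hard_vote(ps2, members = rev(ps2$classifiers))
  expect_equal(fr2r$fused_labels, 2L)
  fr2l <- hard_vote(ps2, tie_rule = "lowest-class")
  expect_equal(fr2l$fused_labels, 1L)

  # unanimous votes win regardless of weights
  ps3 <- labels_ps(cbind(c(2L, 3L), c(2L, 3L), c(2L, 3L)),
                   truth = c(2L, 3L), n_class = 3L)
  fr3 <- hard_vote(ps3, weights = weight_vector(
    stats::setNames(c(0.01, 0.01, 0.98), ps3$classifiers)))
  expect_equal(fr3$fused_labels, c(2L, 3L))

  expect_error(hard_vote(ps3, members = character()), "empty member")
})

test_that("fused labels are invariant to positive weight rescaling", {
  set.seed(21)
  for (rep in 1:20) {
    ps <- rand_ps(n = 30L, n_class = 4L, m = 4L, seed = 100L + rep)
    w <- runif(4, 0.1, 1)
    scale <- runif(1, 0.01, 50)
    names(w) <- ps$classifiers
    a <- soft_vote(ps, weights = weight_vector(w))
    b <- soft_vote(ps, weights = weight_vector(w * scale))
    expect_identical(a$fused_labels, b$fused_labels)
    ah <- hard_vote(ps, weights = weight_vector(w))
    bh <- hard_vote(ps, weights = weight_vector(w * scale))
    expect_identical(ah$fused_labels, bh$fused_labels)
  }
})

test_that("uniform-weight WAV coincides with SV; degenerate weight vectors mimic members", {
  for (rep in 1:50) {
    ps <- rand_ps(n = 20L, n_class = 3L, m = 3L, seed = 300L + rep)
    sv <- soft_vote(ps)
    wav <- soft_vote(ps, weights = weight_vector(
      stats::setNames(rep(1 / 3, 3), ps$classifiers)))
    expect_identical(sv$fused_labels, wav$fused_labels)
    expect_equal(sv$fused_probs, wav$fused_probs, tolerance = 1e-12)
  }
  # weight (1, 0, 0) under hard voting reproduces member 1 exactly
  ps <- rand_ps(n = 40L, n_class = 4L, m = 3L, seed = 77L)
  w <- stats::setNames(c(1, 0, 0), ps$classifiers)
  frh <- hard_vote(ps, weights = weight_vector(w))
  expect_equal(frh$fused_labels, unname(predicted_labels(ps)[, 1L]))
})

test_that("an ensemble of identical members equals the single member", {
  base <- rand_ps(n = 30L, n_class = 3L, m = 1L, seed = 5L)
  p <- base$probs[[1L]]
  ps <- prediction_set(list(a = p, b = p, c = p), truth = base$truth,
                       classes = base$classes)
  single <- unname(predicted_labels(ps)[, 1L])
  expect_equal(soft_vote(ps)$fused_labels, single)
  expect_equal(hard_vote(ps)$fused_labels, single)
  wv <- optimize_weights(ps, budget = 10L, seed = 3L)
  expect_equal(soft_vote(ps, weights = wv)$fused_labels, single)
  st <- stack_fuse(ps, config = stacking_config(
    folds = 3L, meta_learner = "multinomial"), seed = 3L)
  expect_gte(mean(st$fused_labels == ps$truth),
             mean(single == ps$truth) - 0.15)
})

test_that("majority voting of many independent mediocre members beats them", {
  # 11 members at accuracy 0.7; majority vote should clear 0.7 in >= 95/100
  n <- 200L
  wins <- 0L
  for (rep in 1:100) {
    set.seed(4000L + rep)
    truth <- rep(1:4, each = n / 4L)
    lab <- vapply(1:11, function(j) {
      correct <- runif(n) < 0.7
      wrong <- vapply(truth, function(t) sample(setdiff(1:4, t), 1L), 0L)
      ifelse(correct, truth, wrong)
    }, integer(n))
    ps <- labels_ps(lab, truth, n_class = 4L)
    acc <- mean(hard_vote(ps)$fused_labels == truth)
    if (acc > 0.7) wins <- wins + 1L
  }
  expect_gte(wins, 95L)
})

test_that("weight optimization honours the uniform-first guarantee", {
  # perfect + adversarial member: optimum puts (almost) all weight on perfect
  set.seed(9)
  n <- 60L
  truth <- sample(1:3, n, replace = TRUE)
  perfect <- matrix(0.05, n, 3); perfect[cbind(1:n, truth)] <- 0.9
  wrong_cls <- (truth %% 3L) + 1L
  advers <- matrix(0.05, n, 3); advers[cbind(1:n, wrong_cls)] <- 0.9
  colnames(perfect) <- colnames(advers) <- paste0("c", 1:3)
  ps <- prediction_set(list(good = perfect, bad = advers), truth = truth,
                       classes = paste0("c", 1:3))
  wv <- optimize_weights(ps, budget = 60L, seed = 1L)
  expect_equal(wv$provenance$objective_value, 1)
  fr <- soft_vote(ps, weights = wv)
  expect_equal(mean(fr$fused_labels == ps$truth), 1)

  # identical members: constant objective equals the single-member accuracy
  base <- rand_ps(n = 40L, n_class = 3L, m = 1L, seed = 6L)
  twin <- prediction_set(list(a = base$probs[[1L]], b = base$probs[[1L]]),
                         truth = base$truth, classes = base$classes)
  wv2 <- optimize_weights(twin, budget = 10L, seed = 2L)
  expect_equal(wv2$provenance$objective_value,
               mean(predicted_labels(twin)[, 1L] == twin$truth))

  # never below the uniform baseline, across 20 seeds; re-run to verify
  for (s in 1:20) {
    ps <- simulate_predictions(n_items = 120L, n_classifiers = 4L,
                               seed = 500L + s)
    wv <- optimize_weights(ps, budget = 12L, seed = s)
    expect_gte(wv$provenance$objective_value, wv$provenance$uniform_value)
    refused <- soft_vote(ps, weights = wv)
    expect_equal(mean(refused$fused_labels == ps$truth),
                 wv$provenance$objective_value)
  }

  expect_error(optimize_weights(rand_ps(seed = 1L), budget = 0L), "budget")
})

test_that("weight optimization is deterministic under a fixed seed", {
  ps <- simulate_predictions(n_items = 120L, n_classifiers = 4L, seed = 8L)
  a <- optimize_weights(ps, budget = 15L, seed = 42L)
  b <- optimize_weights(ps, budget = 15L, seed = 42L)
  expect_identical(a$weights, b$weights)
  c <- optimize_weights(ps, budget = 15L, seed = 43L)
  expect_false(identical(a$weights, c$weights))
})

test_that("weight vectors validate and normalize", {
  expect_error(weight_vector(c(-1, 2)), "non-negative")
  expect_error(weight_vector(c(0, 0)), "positive")
  wv <- weight_vector(c(a = 2, b = 6))
  expect_equal(unname(wv$weights), c(0.25, 0.75))
  ps <- rand_ps(m = 2L, seed = 1L)
  expect_error(soft_vote(ps, weights = weight_vector(c(zz = 1, yy = 1))),
               "no weight for member")
})

test_that("fusion results feed back as prediction sets", {
  ps <- rand_ps(n = 25L, n_class = 3L, m = 3L, seed = 31L)
  fr <- soft_vote(ps)
  back <- fusion_as_prediction_set(fr, ps, name = "fused")
  expect_equal(unname(predicted_labels(back)[, 1L]), fr$fused_labels)
  expect_false(back$prob_free[["fused"]])
  frh <- hard_vote(ps)
  backh <- fusion_as_prediction_set(frh, ps, name = "hv")
  expect_true(backh$prob_free[["hv"]])
  expect_equal(unname(predicted_labels(backh)[, 1L]), frh$fused_labels)
})
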