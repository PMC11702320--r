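test_that("counts_from_labels tallies correctly and validates input", {
  x <- counts_from_labels(c(1, 1, 0), c(1, 0, 0))
  expect_equal(as.numeric(x), c(1, 0, 1, 1))
  expect_equal(as.numeric(counts_from_labels(rep(1, 5), rep(1, 5))),
               c(5, 0, 0, 0))
  set.seed(11)
  actual <- rbinom(200, 1, 0.4); pred <- rbinom(200, 1, 0.6)
  x <- counts_from_labels(actual, pred)
  # brute-force per-element tally
  tally <- table(factor(pred, 0:1), factor(actual, 0:1))
  expect_equal(as.numeric(x),
               c(tally["1", "1"], tally["1", "0"], tally["0", "1"], tally["0", "0"]))
  expect_equal(attr(x, "n"), 200)
  expect_error(counts_from_labels(c(1, 0), c(1, 0, 1)), "length")
  expect_error(counts_from_labels(c(1, 2, 0), c(1, 0, 0)), "index 2")
})

test_that("mcc matches hand-computed values and the NA contract", {
  expect_equal(round(mcc(confusion_counts(90, 9, 1, 0)), 3), -0.032)
  expect_equal(round(mcc(confusion_counts(88, 8, 3, 1)), 4), 0.1141)
  expect_identical(mcc(confusion_counts(7, 0, 0, 3)), 1)
  expect_identical(mcc(confusion_counts(0, 4, 6, 0)), -1)
  # zero numerator with positive margins
  expect_equal(mcc(confusion_counts(8, 4, 10, 5)), 0)
  # NA exactly when a margin is zero
  expect_true(is.na(mcc(confusion_counts(0, 0, 3, 5))))   # predicted-positive
  expect_true(is.na(mcc(confusion_counts(0, 3, 0, 5))))   # actual-positive
  expect_true(is.na(mcc(confusion_counts(5, 3, 0, 0))))   # actual-negative
  expect_true(is.na(mcc(confusion_counts(5, 0, 3, 0))))   # predicted-negative
})

test_that("mcc symmetries, Pearson equivalence and scale invariance", {
  set.seed(21)
  for (i in 1:20) {
    x <- c(rmultinom(1, 80, c(0.3, 0.2, 0.2, 0.3)))
    if (any(c(x[1] + x[2], x[1] + x[3], x[4] + x[2], x[4] + x[3]) == 0)) next
    r <- mcc(confusion_counts(x[1], x[2], x[3], x[4]))
    # class swap (tp<->tn, fp<->fn) invariant; prediction flip negates
    expect_equal(mcc(confusion_counts(x[4], x[3], x[2], x[1])), r)
    expect_equal(mcc(confusion_counts(x[2], x[1], x[4], x[3])), -r)
    # scale invariance
    expect_equal(mcc(confusion_counts(7 * x[1], 7 * x[2], 7 * x[3], 7 * x[4])), r)
    expect_equal(mcc(cell_probs(x[1] / 80, x[2] / 80, x[3] / 80, x[4] / 80)), r)
    # Pearson correlation of the underlying label vectors
    actual <- rep(c(1, 0, 1, 0), x)
    pred   <- rep(c(1, 1, 0, 0), x)
    if (sd(actual) > 0 && sd(pred) > 0)
      expect_equal(r, cor(pred, actual), tolerance = 1e-12)
  }
})

test_that("metric_set reproduces the worked example and per-metric NA", {
  m <- metric_set(confusion_counts(90, 9, 1, 0))
  expect_equal(round(m$accuracy, 3), 0.900)
  expect_equal(round(m$f1, 3), 0.947)
  expect_equal(round(m$mcc, 3), -0.032)
  perfect <- metric_set(confusion_counts(5, 0, 0, 5))
  expect_true(all(unlist(perfect) == 1))
  expect_equal(metric_set(confusion_counts(88, 8, 3, 1))$accuracy, 0.89)
  # tnr undefined when no actual negatives
  m2 <- metric_set(confusion_counts(4, 0, 2, 0))
  expect_true(is.na(m2$tnr))
  expect_false(is.na(m2$tpr))
})

test_that("fisher and modified transforms: values, round trips, relation", {
  expect_identical(fisher_z(0), 0)
  expect_equal(fisher_z(0.4), 0.423649, tolerance = 1e-6)
  expect_identical(mt_transform(0), 0)
  expect_equal(mt_transform(1), log(3) / 2, tolerance = 1e-12)
  for (x in c(-0.9, -0.5, 0, 0.5, 0.9))
    expect_equal(fisher_z_inv(fisher_z(x)), x, tolerance = 1e-12)
  for (x in c(-1.8, -1, 0, 1, 1.8))
    expect_equal(mt_transform_inv(mt_transform(x)), x, tolerance = 1e-12)
  # g(x) = f(x/2), both strictly increasing
  grid <- seq(-1.9, 1.9, by = 0.1)
  expect_equal(mt_transform(grid), fisher_z(grid / 2), tolerance = 1e-12)
  expect_true(all(diff(mt_transform(grid)) > 0))
  expect_error(fisher_z(1), "< 1")
  expect_error(mt_transform(-2), "< 2")
})

test_that("marginalize conserves mass and matches the direct cell sums", {
  u <- paired_cell_probs(rep(1 / 8, 8))
  expect_equal(as.numeric(marginalize(u, 1)), rep(0.25, 4))
  expect_equal(as.numeric(marginalize(u, 2)), rep(0.25, 4))
  agree <- paired_cell_probs(c(p111 = 0.5, p110 = 0, p101 = 0, p100 = 0,
                               p011 = 0, p010 = 0, p001 = 0, p000 = 0.5))
  for (l in 1:2) {
    expect_equal(as.numeric(marginalize(agree, l)), c(0.5, 0, 0, 0.5))
    expect_identical(mcc(marginalize(agree, l)), 1)
  }
  set.seed(31)
  for (i in 1:10) {
    p <- rand_paired_probs()
    v <- as.numeric(p)  # (111,110,101,100,011,010,001,000)
    m1 <- c(v[1] + v[3], v[2] + v[4], v[5] + v[7], v[6] + v[8])
    m2 <- c(v[1] + v[5], v[2] + v[6], v[3] + v[7], v[4] + v[8])
    expect_equal(as.numeric(marginalize(p, 1)), m1, tolerance = 1e-15)
    expect_equal(as.numeric(marginalize(p, 2)), m2, tolerance = 1e-15)
    expect_equal(mcc(marginalize(p, 1)),
                 mcc(cell_probs(m1[1], m1[2], m1[3], m1[4])))
    expect_equal(sum(as.numeric(marginalize(p, 2))), 1, tolerance = 1e-12)
  }
})
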