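test_that("dice evaluates the confusion-count formula", {
  cc <- function(tp, fp, fn, tn = 0) {
    structure(list(TP = tp, FP = fp, FN = fn, TN = tn),
              class = "confusion_counts")
  }
  expect_equal(dice(cc(5, 0, 0)), 1)
  expect_equal(dice(cc(2, 1, 1)), 4 / 6)
  expect_equal(dice(cc(0, 3, 2)), 0)
  expect_equal(dice(cc(0, 0, 0, 10)), 1)   # empty masks agree perfectly
})

test_that("confusion counts partition the pixels", {
  set.seed(1)
  p <- random_mask(13, 9)
  t <- random_mask(13, 9)
  cc <- confusion_counts(p, t)
  expect_equal(cc$TP + cc$FP + cc$FN + cc$TN, 13 * 9)
  expect_error(confusion_counts(p, random_mask(9, 13)), "different shapes")
  expect_error(confusion_counts(p * 2, t), "binary")
})

test_that("iou matches its definition and the both-empty convention", {
  m <- random_mask(8, 8)
  expect_equal(iou(m, m), 1)
  expect_equal(iou(matrix(0, 4, 4), matrix(0, 4, 4)), 1)
  a <- matrix(0, 2, 3); a[1, 1] <- 1
  b <- matrix(0, 2, 3); b[2, 2] <- 1
  expect_equal(iou(a, b), 0)
  # TP=2 FP=1 FN=1 configuration
  p <- matrix(c(1, 1, 1, 0), 2, 2)
  t <- matrix(c(1, 1, 0, 1), 2, 2)
  expect_equal(iou(p, t), 0.5)
  expect_equal(dice(p, t), 2 * 0.5 / (1 + 0.5))
})

test_that("Dice equals 2*IoU/(1+IoU) for random binary mask pairs", {
  set.seed(42)
  for (i in 1:200) {
    p <- random_mask(11, 7, p = stats::runif(1, 0.1, 0.9))
    t <- random_mask(11, 7, p = stats::runif(1, 0.1, 0.9))
    j <- iou(p, t)
    expect_equal(dice(p, t), 2 * j / (1 + j), tolerance = 1e-12)
  }
})

test_that("soft Dice loss behaves at its extremes and stays in [0, 1]", {
  set.seed(2)
  t <- random_mask(16, 16, 0.4)
  expect_equal(dice_loss(t, t), 0)              # eps cancels exactly
  expect_gt(dice_loss(1 - t, t), 0.98)          # disjoint, up to smoothing
  for (i in 1:20) {
    p <- matrix(stats::runif(64), 8, 8)
    l <- dice_loss(p, random_mask(8, 8))
    expect_gte(l, 0)
    expect_lte(l, 1)
  }
  expect_error(dice_loss(matrix(0.5, 2, 2), matrix(0L, 3, 3)),
               "different shapes")
  expect_error(dice_loss(matrix(2, 2, 2), matrix(0L, 2, 2)), "\\[0, 1\\]")
})

test_that("soft Dice loss decreases along the interpolation path to truth", {
  set.seed(3)
  t <- random_mask(12, 12, 0.5)
  p0 <- matrix(stats::runif(144), 12, 12)
  lambdas <- seq(0, 1, by = 0.1)
  losses <- vapply(lambdas, function(l) dice_loss((1 - l) * p0 + l * t, t), 0)
  expect_true(all(diff(losses) < 1e-12))
})

test_that("analytic Dice-loss gradient matches central differences", {
  set.seed(4)
  p <- matrix(stats::runif(64), 8, 8)
  t <- random_mask(8, 8, 0.5)
  g <- dice_loss_grad(p, t)
  h <- 1e-6
  for (idx in sample(64, 12)) {
    pp <- p; pp[idx] <- pp[idx] + h
    pm <- p; pm[idx] <- pm[idx] - h
    num <- (dice_loss(pp, t) - dice_loss(pm, t)) / (2 * h)
    expect_equal(g[idx], num, tolerance = 1e-4)
  }
})

test_that("soft Dice on binary input equals the count-based Dice", {
  set.seed(5)
  for (i in 1:20) {
    p <- random_mask(9, 9)
    t <- random_mask(9, 9)
    expect_equal(1 - dice_loss(p, t, eps = 0), dice(p, t), tolerance = 1e-12)
  }
})

test_that("aggregate_metrics takes unweighted per-image means", {
  r <- aggregate_metrics(data.frame(dice = c(1, 0.5), iou = c(1, 0.4)))
  expect_equal(r$accuracy_percent, 75)
  expect_equal(r$mean_iou, 0.7)
  one <- aggregate_metrics(data.frame(dice = 0.8, iou = 0.6))
  expect_equal(one$accuracy_percent, 80)
  dup <- aggregate_metrics(data.frame(dice = rep(0.8, 7), iou = rep(0.6, 7)))
  expect_equal(dup$accuracy_percent, 80)
  expect_equal(dup$mean_iou, 0.6)
  expect_error(aggregate_metrics(data.frame(dice = numeric(), iou = numeric())),
               "no per-image")
})

test_that("metrics_report validates ranges and writes the CSV schema", {
  rows <- data.frame(variant = c("vanilla", "dense"),
                     accuracy = c(93.68, 96.43), mean_iou = c(0.69, 0.68),
                     params_millions = c(2.93, 5.4))
  path <- withr::local_tempfile(fileext = ".csv")
  metrics_report(rows, path)
  back <- utils::read.csv(path)
  expect_equal(back$variant, rows$variant)
  expect_equal(back$accuracy, rows$accuracy)
  bad <- rows; bad$accuracy[1] <- 120
  expect_error(metrics_report(bad), "\\[0, 100\\]")
})
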