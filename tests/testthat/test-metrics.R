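# Confusion counting, the five overlap scores, aggregation conventions and
# overlay rendering, all checked against brute-force pixel counting.

test_that("confusion counts handle identity, complement and an explicit grid", {
  set.seed(1)
  t <- matrix(rbinom(25, 1, 0.4), 5, 5)
  cc <- confusion_counts(t, t)
  expect_equal(cc$fp, 0)
  expect_equal(cc$fn, 0)
  expect_equal(cc$tp, sum(t))
  cc2 <- confusion_counts(1 - t, t)
  expect_equal(cc2$tp, 0)
  expect_equal(cc2$tn, 0)
  # explicit 4x4 grids: truth has 4 foreground pixels, prediction hits 3 of
  # them and adds 2 strays
  truth <- matrix(0, 4, 4); truth[1, 1:4] <- 1
  pred <- matrix(0, 4, 4); pred[1, 1:3] <- 1; pred[2, 1:2] <- 1
  cc3 <- confusion_counts(pred, truth)
  expect_equal(cc3$tp, 3)
  expect_equal(cc3$fn, 1)
  expect_equal(cc3$fp, 2)
  expect_equal(cc3$tn, 10)
  expect_error(confusion_counts(matrix(0, 2, 2), matrix(0, 3, 3)),
               class = "cxrseg_validation_error")
  expect_error(confusion_counts(matrix(0.5, 2, 2), matrix(0, 2, 2)),
               class = "cxrseg_validation_error")
})

test_that("the five scores match hand arithmetic and edge conventions", {
  m <- compute_metrics(list(tp = 3, fp = 1, fn = 1, tn = 11))
  expect_equal(m[["jaccard"]], 0.6)
  expect_equal(m[["dice"]], 0.75)
  expect_equal(m[["accuracy"]], 0.875)
  expect_equal(m[["sensitivity"]], 0.75)
  expect_equal(m[["specificity"]], 11 / 12)
  perfect <- compute_metrics(list(tp = 5, fp = 0, fn = 0, tn = 11))
  expect_true(all(perfect == 1))
  zero <- compute_metrics(list(tp = 0, fp = 2, fn = 3, tn = 11))
  expect_equal(zero[["jaccard"]], 0)
  expect_equal(zero[["dice"]], 0)
  # vacuous agreement on blank masks
  blank <- compute_metrics(list(tp = 0, fp = 0, fn = 0, tn = 16))
  expect_equal(blank[["jaccard"]], 1)
  expect_equal(blank[["dice"]], 1)
  expect_equal(blank[["sensitivity"]], 1)
  expect_equal(blank[["accuracy"]], 1)
})

test_that("scores agree with brute-force counting on random mask pairs", {
  set.seed(42)
  for (rep in 1:25) {
    p <- matrix(rbinom(256, 1, runif(1, 0.1, 0.9)), 16, 16)
    t <- matrix(rbinom(256, 1, runif(1, 0.1, 0.9)), 16, 16)
    cc <- confusion_counts(p, t)
    rf <- ref_confusion(p, t)
    expect_equal(cc[c("tp", "tn", "fp", "fn")], rf)
    expect_equal(cc$tp + cc$tn + cc$fp + cc$fn, 256)
    m <- compute_metrics(cc)
    # per-image Dice/Jaccard identity
    expect_equal(m[["dice"]], 2 * m[["jaccard"]] / (1 + m[["jaccard"]]),
                 tolerance = 1e-14)
    # prediction/truth swap symmetry
    ms <- compute_metrics(confusion_counts(t, p))
    expect_equal(ms[["jaccard"]], m[["jaccard"]])
    expect_equal(ms[["dice"]], m[["dice"]])
    expect_equal(ms[["accuracy"]], m[["accuracy"]])
  }
})

test_that("aggregation modes behave on single, identical and mixed inputs", {
  t1 <- matrix(c(1, 1, 0, 0), 2, 2)
  p1 <- matrix(c(1, 0, 0, 0), 2, 2)
  rep1 <- evaluate_masks(list(p1), list(t1))
  for (mode in c("per-image-mean", "pooled")) {
    ag <- aggregate_metrics(rep1, mode)
    expect_equal(unname(ag[1:5]), unname(rep1[[1]]$metrics))
  }
  rep2 <- evaluate_masks(list(p1, p1), list(t1, t1))
  expect_equal(unname(aggregate_metrics(rep2, "pooled")[1:5]),
               unname(rep1[[1]]$metrics))
  # mixed counts: pooled equals the formulas on summed counts
  t2 <- matrix(c(1, 1, 1, 0), 2, 2)
  p2 <- matrix(c(1, 1, 0, 1), 2, 2)
  rep3 <- evaluate_masks(list(p1, p2), list(t1, t2))
  summed <- list(tp = 0, tn = 0, fp = 0, fn = 0)
  for (r in rep3) for (k in names(summed)) summed[[k]] <- summed[[k]] + r$counts[[k]]
  expect_equal(unname(aggregate_metrics(rep3, "pooled")[1:5]),
               unname(compute_metrics(summed)))
  expect_error(aggregate_metrics(list()), class = "cxrseg_validation_error")
})

test_that("overlay colours partition pixels exactly into the four classes", {
  set.seed(5)
  p <- matrix(rbinom(64, 1, 0.5), 8, 8)
  t <- matrix(rbinom(64, 1, 0.5), 8, 8)
  rgb <- render_overlay(p, t)
  cc <- confusion_counts(p, t)
  green <- sum(rgb[, , 2] == 1 & rgb[, , 1] == 0 & rgb[, , 3] == 0)
  red <- sum(rgb[, , 1] == 1 & rgb[, , 2] == 0 & rgb[, , 3] == 0)
  blue <- sum(rgb[, , 3] == 1 & rgb[, , 1] == 0 & rgb[, , 2] == 0)
  black <- sum(rgb[, , 1] == 0 & rgb[, , 2] == 0 & rgb[, , 3] == 0)
  expect_equal(green, cc$tp)
  expect_equal(red, cc$fp)
  expect_equal(blue, cc$fn)
  expect_equal(black, cc$tn)
  # perfect prediction: green and black only
  rgb2 <- render_overlay(t, t)
  expect_equal(sum(rgb2[, , 1]), 0)
  expect_equal(sum(rgb2[, , 2] == 1), sum(t))
  # empty prediction, nonempty truth: blue and black only
  rgb3 <- render_overlay(matrix(0, 8, 8), t)
  expect_equal(sum(rgb3[, , 1]) + sum(rgb3[, , 2]), 0)
  expect_equal(sum(rgb3[, , 3] == 1), sum(t))
  # round-trips through PNG
  f <- tempfile(fileext = ".png")
  render_overlay(p, t, f)
  expect_true(file.exists(f))
  back <- png::readPNG(f)
  expect_equal(back, rgb, tolerance = 1e-7)
})

test_that("the CSV report carries the J/D/Acc/Sn/Sp columns and aggregates", {
  t <- matrix(c(1, 1, 0, 0), 2, 2)
  p <- matrix(c(1, 0, 0, 0), 2, 2)
  f <- tempfile(fileext = ".csv")
  df <- write_metrics_csv(evaluate_masks(list(p, t), list(t, t)), f)
  got <- utils::read.csv(f)
  expect_true(all(c("J", "D", "Acc", "Sn", "Sp") %in% names(got)))
  expect_equal(nrow(got), 4)  # 2 images + 2 aggregate rows
  expect_equal(got$J[2], 100)
  # evaluating truth against itself scores 100.00 everywhere
  expect_true(all(got[2, c("J", "D", "Acc", "Sn", "Sp")] == 100))
})
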