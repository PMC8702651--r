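test_that("confusion counts enumerate the 2x2 cases", {
  pred <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2)
  gt <- matrix(c(TRUE, FALSE, TRUE, FALSE), 2, 2)
  cc <- confusion_counts(pred, gt)
  expect_equal(unlist(cc), c(tp = 1, fp = 1, tn = 1, fn = 1))

  same <- confusion_counts(gt, gt)
  expect_equal(same$fp + same$fn, 0)
  opp <- confusion_counts(!gt, gt)
  expect_equal(opp$tp + opp$tn, 0)
  expect_error(confusion_counts(pred, matrix(TRUE, 3, 3)), "shapes")
})

test_that("evaluation scores match hand-worked confusion tables", {
  r <- eval_metrics(80, 20, 880, 20)
  expect_equal(r$dsc, 0.8)
  expect_equal(r$sensitivity, 0.8)
  expect_equal(r$vvd, 0)

  r2 <- eval_metrics(40, 10, 40, 10)
  expect_equal(r2$mcc, (1600 - 100) / 2500)  # 0.6

  m <- matrix(runif(64) > 0.5, 8, 8)
  perfect <- eval_masks(m, m)
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$specificity, 1)
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$dsc, 1)
  expect_equal(perfect$mcc, 1)
  expect_equal(perfect$vvd, 0)

  # empty ground truth yields undefined sentinels, not zeros
  r0 <- eval_metrics(0, 5, 95, 0)
  expect_true(is.nan(r0$sensitivity) && is.nan(r0$dsc) && is.nan(r0$vvd))
})

test_that("evaluation agrees with the pixel-enumeration oracle", {
  set.seed(77)
  for (i in 1:5) {
    pred <- matrix(runif(64 * 64) > runif(1, 0.3, 0.7), 64, 64)
    gt <- matrix(runif(64 * 64) > runif(1, 0.3, 0.7), 64, 64)
    b <- brute_eval(pred, gt)
    r <- eval_masks(pred, gt)
    expect_identical(c(r$tp, r$fp, r$tn, r$fn),
                     as.numeric(c(b$tp, b$fp, b$tn, b$fn)))
    ref <- eval_metrics(b$tp, b$fp, b$tn, b$fn)
    expect_equal(r$dsc, ref$dsc)
    expect_equal(r$mcc, ref$mcc)
  }
})

test_that("DSC and MCC are symmetric under prediction/truth swap", {
  set.seed(5)
  pred <- matrix(runif(400) > 0.5, 20, 20)
  gt <- matrix(runif(400) > 0.4, 20, 20)
  a <- eval_masks(pred, gt)
  b <- eval_masks(gt, pred)
  expect_equal(a$dsc, b$dsc)
  expect_equal(a$mcc, b$mcc)
})

test_that("within-subject SD matches hand computations", {
  expect_equal(within_subject_sd(matrix(c(3, 3, 3, 5, 5, 5), 2, 3,
                                        byrow = TRUE)), 0)
  expect_equal(within_subject_sd(matrix(c(1, 3), 1, 2)), sqrt(2))
  expect_equal(within_subject_sd(matrix(c(1, 3, 2, 4), 2, 2, byrow = TRUE)),
               sqrt(2))
  expect_error(within_subject_sd(matrix(c(1, NA), 1, 2)), "2 repeats")
})

test_that("coefficient of variation is Sw as a percent of the mean", {
  expect_equal(coefficient_of_variation(sqrt(2), 2.5), 100 * sqrt(2) / 2.5)
  expect_equal(coefficient_of_variation(0, 10), 0)
  expect_equal(coefficient_of_variation(1, 100), 1)
  expect_true(is.nan(coefficient_of_variation(1, 0)))
})

test_that("one-way ICC matches hand-worked ANOVA tables", {
  perfect <- matrix(c(0, 0, 10, 10, 20, 20), 3, 2, byrow = TRUE)
  expect_equal(intraclass_correlation(perfect), 1)

  # no between-subject variance: MSB = 0, MSW = 0.5, k = 2 -> -1
  flat <- matrix(c(1, 2, 1, 2, 1, 2), 3, 2, byrow = TRUE)
  expect_equal(intraclass_correlation(flat), -1)

  expect_warning(deg <- intraclass_correlation(matrix(7, 3, 2)), "equal")
  expect_true(is.nan(deg))
})

test_that("ICC mean squares agree with the aov decomposition", {
  set.seed(19)
  tab <- matrix(rnorm(24 * 4, rep(rnorm(24, sd = 2), 4)), 24, 4)
  icc <- intraclass_correlation(tab)
  df <- data.frame(y = as.vector(tab),
                   subject = factor(rep(seq_len(24), 4)))
  ms <- summary(stats::aov(y ~ subject, df))[[1]][["Mean Sq"]]
  expect_equal(icc, (ms[1] - ms[2]) / (ms[1] + 3 * ms[2]), tolerance = 1e-10)
})

test_that("repeatability report covers every metric in both layouts", {
  arr <- array(rnorm(10 * 3 * 2), c(10, 3, 2),
               dimnames = list(NULL, NULL, c("vd", "fd")))
  rep1 <- repeatability_report(arr)
  expect_identical(rep1$metric, c("vd", "fd"))
  expect_identical(rep1$n_subjects, c(10L, 10L))
  expect_identical(rep1$n_repeats, c(3L, 3L))

  # duplicated repeats: Sw = 0, ICC = 1 wherever subjects differ
  base <- rnorm(8)
  arr2 <- array(rep(base, 2 * 2), c(8, 2, 2),
                dimnames = list(NULL, NULL, c("a", "b")))
  rep2 <- repeatability_report(arr2)
  expect_equal(rep2$sw, c(0, 0))
  expect_equal(rep2$icc, c(1, 1))

  # long data.frame layout
  df <- data.frame(subject = rep(1:6, each = 2), rep = rep(1:2, 6),
                   vd = rnorm(12))
  rep3 <- repeatability_report(df)
  expect_identical(rep3$metric, "vd")
  expect_identical(rep3$n_repeats, 2L)
})

test_that("repeated phantom acquisitions give highly reliable density", {
  vd <- sapply(1:10, function(sd) {
    reps <- phantom_repeat_series(phantom_spec(size_px = 192L, seed = sd), 4L)
    sapply(reps, function(b) {
      lg <- segment_large_vessels(b$image)
      mean(fuse_branches(lg, segment_capillaries(b$image, lg$final_mask)))
    })
  })
  icc <- intraclass_correlation(t(vd))
  expect_gte(icc, 0.8)
})
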