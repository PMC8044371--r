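test_that("confusion counts match a per-element tally", {
  cc <- confusion_counts(c(1, 1, 0, 0), c(1, 1, 0, 0))
  expect_equal(unclass(cc)[c("TP", "TN", "FP", "FN")],
               list(TP = 2L, TN = 2L, FP = 0L, FN = 0L))
  cc <- confusion_counts(c(1, 0), c(0, 1))
  expect_equal(cc$FP + cc$FN, 2L)
  expect_equal(cc$TP + cc$TN, 0L)
  set.seed(14)
  y <- stats::rbinom(200, 1, 0.4); k <- stats::rbinom(200, 1, 0.6)
  cc <- confusion_counts(y, k)
  tally <- table(factor(paste0(y, k), levels = c("11", "00", "01", "10")))
  expect_equal(c(cc$TP, cc$TN, cc$FP, cc$FN), unname(as.integer(tally)))
  expect_equal(cc$TP + cc$TN + cc$FP + cc$FN, 200L)
  expect_error(confusion_counts(1, c(1, 0)), "length")
  expect_error(confusion_counts(2, 1), "0/1")
})

test_that("threshold metrics follow the printed formulas", {
  m <- classification_metrics(list(TP = 5, TN = 5, FP = 0, FN = 0))
  expect_equal(c(m$SN, m$SP, m$ACC, m$MCC), c(1, 1, 1, 1))
  m <- classification_metrics(list(TP = 3, TN = 4, FP = 1, FN = 2))
  expect_equal(m$SN, 0.6)
  expect_equal(m$SP, 0.8)
  expect_equal(m$ACC, 0.7)
  expect_equal(m$MCC, 10 / sqrt(600))
  # all calls negative: zero-denominator conventions
  m <- classification_metrics(list(TP = 0, TN = 6, FP = 0, FN = 4))
  expect_equal(m$SN, 0)
  expect_equal(m$SP, 1)
  expect_equal(m$MCC, 0)
  expect_true("MCC" %in% m$degenerate)
})

test_that("MCC stays in [-1,1], is class-swap symmetric, and label-flip negates it", {
  set.seed(15)
  for (i in 1:300) {
    cts <- as.list(stats::setNames(sample(0:30, 4, replace = TRUE),
                                   c("TP", "TN", "FP", "FN")))
    if (sum(unlist(cts)) == 0) next
    m <- classification_metrics(cts)$MCC
    expect_gte(m, -1); expect_lte(m, 1)
    swapped <- classification_metrics(list(TP = cts$TN, TN = cts$TP,
                                           FP = cts$FN, FN = cts$FP))$MCC
    expect_equal(swapped, m, tolerance = 1e-12)
    flipped <- classification_metrics(list(TP = cts$FN, TN = cts$FP,
                                           FP = cts$TN, FN = cts$TP))$MCC
    expect_equal(flipped, -m, tolerance = 1e-12)
  }
})

test_that("AUC is the tie-aware pair statistic", {
  expect_equal(roc_auc(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1))$auc, 1.0)
  expect_equal(roc_auc(c(1, 0, 1, 0), rep(0.5, 4))$auc, 0.5)
  # enumerate the 4 positive-negative pairs: 3 concordant
  expect_equal(roc_auc(c(1, 0, 1, 0), c(0.9, 0.8, 0.7, 0.6))$auc, 0.75)
  expect_error(roc_auc(c(1, 1), c(0.2, 0.3)), "both classes")
})

test_that("AUC is monotone-invariant and complements under score negation", {
  set.seed(16)
  y <- stats::rbinom(80, 1, 0.5); y[1:2] <- c(0, 1)
  s <- stats::rnorm(80)
  a <- roc_auc(y, s)$auc
  expect_equal(roc_auc(y, exp(2 * s))$auc, a)         # strictly monotone map
  expect_equal(roc_auc(y, -s)$auc, 1 - a)
})

test_that("AUC agrees with an independent implementation on tie-free data", {
  skip_if_not_installed("pROC")
  set.seed(17)
  for (i in 1:10) {
    y <- c(0, 1, stats::rbinom(58, 1, 0.5))
    s <- stats::rnorm(60)
    ref <- as.numeric(suppressMessages(pROC::auc(y, s, direction = "<")))
    expect_equal(roc_auc(y, s)$auc, ref, tolerance = 1e-12)
  }
})

test_that("ROC points sweep thresholds from (0,0) to (1,1)", {
  set.seed(18)
  y <- c(0, 1, stats::rbinom(28, 1, 0.5))
  s <- stats::runif(30)
  roc <- roc_auc(y, s)$roc
  expect_equal(roc$FPR[1], 0); expect_equal(roc$TPR[1], 0)
  expect_equal(roc$FPR[nrow(roc)], 1); expect_equal(roc$TPR[nrow(roc)], 1)
  expect_true(all(diff(roc$FPR) >= 0) && all(diff(roc$TPR) >= 0))
})

test_that("balanced-class accuracy lies between SN and SP", {
  set.seed(19)
  for (i in 1:50) {
    n <- 40
    y <- rep(c(0, 1), each = n / 2)
    k <- stats::rbinom(n, 1, 0.5)
    m <- classification_metrics(confusion_counts(y, k))
    expect_gte(m$ACC, min(m$SN, m$SP) - 1e-12)
    expect_lte(m$ACC, max(m$SN, m$SP) + 1e-12)
  }
})

test_that("the ablation table flags winners and deltas subtract element-wise", {
  mk <- function(sn, sp, acc, mcc, auc) {
    data.frame(task = c("t1", "t2"), n = 10, TP = 1, TN = 1, FP = 1, FN = 1,
               SN = sn, SP = sp, ACC = acc, MCC = mcc, AUC = auc,
               stringsAsFactors = FALSE)
  }
  single <- mk(c(0.7, 0.8), c(0.6, 0.7), c(0.65, 0.75), c(0.3, 0.5), c(0.7, 0.8))
  same <- ablation_report(single, single)
  expect_true(all(same$table$best == ""))
  expect_true(all(as.matrix(same$delta[, -1]) == 0))
  multi <- mk(c(0.8, 0.9), c(0.7, 0.8), c(0.75, 0.85), c(0.5, 0.7), c(0.8, 0.9))
  rep2 <- ablation_report(multi, single)
  mrows <- rep2$table[rep2$table$model == "Multi", ]
  expect_true(all(mrows$best == "SN,SP,ACC,MCC,AUC"))
  expect_equal(rep2$delta$AUC, c(0.1, 0.1))
  expect_equal(as.matrix(rep2$delta[, -1]),
               as.matrix(multi[, c("SN", "SP", "ACC", "MCC", "AUC")]) -
                 as.matrix(single[, c("SN", "SP", "ACC", "MCC", "AUC")]),
               ignore_attr = TRUE)
  single_bad <- single; single_bad$task <- c("t1", "t3")
  expect_error(ablation_report(multi, single_bad), "different task sets")
  lines <- utils::capture.output(render_ablation(rep2))
  expect_true(any(grepl("80\\.00", lines)))  # percentages to 2 decimals
})

test_that("predictions TSV round-trips through write/read", {
  d <- data.frame(id = c("a", "b"), task = "t", label = c(1L, 0L),
                  score = c(0.9, 0.1), call = c(1L, 0L),
                  stringsAsFactors = FALSE)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_predictions(d, f)
  expect_equal(read_predictions(f), d)
})
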