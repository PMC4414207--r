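test_that("positivity thresholds are interpolated control percentiles", {
  m <- matrix(1:100, 1, dimnames = list("m1", NULL))
  expect_equal(fitThresholds(m, "m1"), c(m1 = 95.05))
  const <- matrix(7, 1, 10, dimnames = list("m1", NULL))
  expect_equal(fitThresholds(const, "m1"), c(m1 = 7))
  # raising the percentile never lowers a threshold
  set.seed(1)
  m2 <- matrix(2^rnorm(60), 3, 20, dimnames = list(paste0("m", 1:3), NULL))
  t90 <- fitThresholds(m2, paste0("m", 1:3), 90)
  t99 <- fitThresholds(m2, paste0("m", 1:3), 99)
  expect_true(all(t99 >= t90))
  expect_error(fitThresholds(m2, paste0("m", 1:3), 40),
               "configuration error")
  expect_error(fitThresholds(m2, "absent"), "absent")
  expect_error(fitThresholds(m2[, 1:3], "m1"), "5 control")
})

test_that("weight methods behave as specified", {
  thr <- c(m1 = 1)
  # unit weights
  m <- matrix(2^rnorm(20), 1, 20, dimnames = list("m1", NULL))
  lab <- rep(c(TRUE, FALSE), 10)
  expect_equal(as.numeric(fitWeights(m, lab, thr, "unit")), 1)
  # indicator distribution identical between classes -> logistic weight 0
  mEq <- matrix(rep(c(2, 0.5), 10), 1, dimnames = list("m1", NULL))
  labBlock <- rep(c(TRUE, FALSE), each = 10)
  expect_equal(unname(as.numeric(fitWeights(mEq, labBlock, thr,
                                            "logistic"))), 0)
  # constructed 2x2 with odds ratio 9 -> coefficient ln 9
  lev <- c(rep(2, 9), rep(0.5, 3), rep(2, 3), rep(0.5, 9))
  lab2 <- rep(c(TRUE, FALSE), c(12, 12))
  w <- fitWeights(matrix(lev, 1, dimnames = list("m1", NULL)), lab2, thr,
                  "logistic")
  expect_equal(unname(as.numeric(w)), log(9), tolerance = 1e-6)
  # complete separation falls back to the log2fc weight with a warning
  sep <- c(rep(2, 10), rep(0.5, 10))
  expect_warning(
    wSep <- fitWeights(matrix(sep, 1, dimnames = list("m1", NULL)),
                       rep(c(TRUE, FALSE), each = 10), thr, "logistic"),
    "complete separation")
  expect_equal(unname(as.numeric(wSep)), 2, tolerance = 1e-12)  # |log2 2/0.5|
  expect_identical(attr(wSep, "fallback"), "m1")
})

test_that("the risk score is the weighted positivity count", {
  model <- toyModel(c("a", "b", "c"), thresholds = c(1, 1, 1),
                    weights = c(5, 5, 4.89), cutoff = 7)
  # indicators (1, 0, 1) -> 5 + 4.89 = 9.89
  expect_equal(unname(riskScore(c(a = 2, b = 0.5, c = 2), model)), 9.89)
  expect_equal(unname(riskScore(c(a = 0.5, b = 0.5, c = 0.5), model)), 0)
  # a level exactly at threshold does not count as positive
  expect_equal(unname(riskScore(c(a = 1, b = 1, c = 1), model)), 0)
  expect_error(riskScore(c(a = 2, b = 2), model), "c")
  # with the published weight sum 14.89 the attainable range is [0, 14.89]
  m2 <- toyModel(c("a", "b", "c"), c(1, 1, 1), c(5, 5, 4.89), cutoff = 7.449)
  expect_equal(scoreMax(m2), 14.89)
  set.seed(3)
  lv <- matrix(2^rnorm(300), 3, dimnames = list(c("a", "b", "c"), NULL))
  sc <- riskScore(lv, m2)
  expect_true(all(sc >= 0 & sc <= 14.89))
  # monotone non-decreasing in any marker's level
  lv2 <- lv; lv2["a", ] <- lv2["a", ] * 10
  expect_true(all(riskScore(lv2, m2) >= sc))
})

test_that("unit-weight scores count positive markers", {
  model <- toyModel(c("a", "b", "c"), c(1, 1, 1), c(1, 1, 1), cutoff = 1.5)
  set.seed(5)
  lv <- matrix(2^rnorm(90), 3, dimnames = list(c("a", "b", "c"), NULL))
  sc <- riskScore(lv, model)
  expect_true(all(sc == floor(sc) & sc >= 0 & sc <= 3))
  expect_equal(sc, colSums(lv > 1))
})

test_that("cutoff selection: separable case, midpoint rule and the
           exhaustive Youden oracle", {
  # perfectly separated: the midpoint of the separating gap is returned
  expect_equal(chooseCutoff(c(8, 9, 1, 2), c(TRUE, TRUE, FALSE, FALSE)), 5)
  # midpoint method reproduces the half-range cutoff structure
  expect_equal(chooseCutoff(method = "midpoint", scoreMax = 6.428), 3.214)
  oracle <- function(scores, labels) {
    s <- sort(unique(scores))
    cand <- (s[-1] + s[-length(s)]) / 2
    j <- vapply(cand, function(cut) {
      mean(scores[labels] > cut) + mean(scores[!labels] <= cut)
    }, numeric(1))
    # smallest cutoff among the (numerically) tied maximisers
    list(cut = min(cand[j >= max(j) - 1e-9]), j = max(j))
  }
  set.seed(11)
  for (i in 1:200) {
    n <- sample(4:30, 1)
    scores <- sample(0:8, n, replace = TRUE) / 2
    labels <- c(TRUE, FALSE, sample(c(TRUE, FALSE), n - 2, TRUE))
    if (length(unique(scores)) < 2) next
    o <- oracle(scores, labels)
    got <- chooseCutoff(scores, labels)
    expect_equal(got, o$cut)
    hi <- scores > got
    expect_equal(mean(hi[labels]) + mean(!hi[!labels]), o$j)
  }
  expect_error(chooseCutoff(c(1, 2), c(TRUE, TRUE)), "both classes")
})

test_that("classification is strict at the cutoff boundary", {
  expect_identical(classifyScores(c(7.449, 7.5, 0), 7.449),
                   c("low", "high", "low"))
  expect_identical(classifyScores(rep(0, 3), 0), rep("low", 3))
})

test_that("confusion metrics reproduce worked contingency tables", {
  # 19 true / 0 false positives, 1 false / 20 true negatives
  ct <- new("ConfusionTable", tp = 19L, fp = 0L, fn = 1L, tn = 20L)
  expect_equal(ppv(ct), 1)
  expect_equal(npv(ct), 20 / 21)
  expect_equal(sensitivity(ct), 0.95)
  # 17/1/3/19
  ct2 <- new("ConfusionTable", tp = 17L, fp = 1L, fn = 3L, tn = 19L)
  expect_equal(ppv(ct2), 17 / 18)
  expect_equal(npv(ct2), 19 / 22)
  # degenerate: no positives at all
  ct3 <- confusionMetrics(rep("low", 10), rep(FALSE, 10))
  expect_equal(specificity(ct3), 1)
  expect_true(is.na(sensitivity(ct3)))
  expect_true(is.na(ppv(ct3)))
  expect_error(confusionMetrics(c("high"), c(TRUE, FALSE)), "equal length")
})

test_that("a fitted model round-trips through JSON", {
  pe <- generateCohort(smallConfig(seed = 8))
  model <- suppressWarnings(fitRiskModel(pe, paste0("lnc000", 1:3)))
  path <- withr::local_tempfile(fileext = ".json")
  writeRiskModel(model, path)
  back <- readRiskModel(path)
  expect_identical(panelMarkers(back), panelMarkers(model))
  expect_equal(positivityThresholds(back), positivityThresholds(model))
  expect_equal(riskWeights(back), riskWeights(model))
  expect_equal(cutoff(back), cutoff(model))
})

test_that("strong planted effects give near-perfect training diagnostics", {
  good <- 0L
  for (s in 1:20) {
    pe <- generateCohort(smallConfig(seed = 600 + s))
    model <- suppressWarnings(fitRiskModel(pe, paste0("lnc000", 1:3)))
    ev <- evaluateFrozen(model, pe,
                         truth = selectSamples(pe, group = "HCC",
                                               phase = "training",
                                               timepoint = "pre_op")[
                           selectSamples(pe, phase = "training",
                                         timepoint = c("pre_op", "none"))],
                         samples = selectSamples(pe, phase = "training",
                                                 timepoint = c("pre_op",
                                                               "none")))
    if (sensitivity(ev$confusion) > 0.9 && specificity(ev$confusion) > 0.9)
      good <- good + 1L
  }
  expect_gte(good, 19L)
})
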