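test_that("comparing a group against itself is a null comparison", {
  m <- matrix(2^rnorm(40, 6), 10, 4,
              dimnames = list(NULL, paste0("s", 1:4)))
  pe <- toyExperiment(m, group = rep("HCC", 4),
                      timepoint = rep("pre_op", 4))
  sel <- rep(TRUE, 4)
  res <- differentialTest(pe, sel, sel, paired = TRUE)
  expect_equal(res$log2_fold, rep(0, 10))
  expect_true(all(res$direction == "none"))
  expect_equal(res$p_value, rep(1, 10))
  expect_equal(res$fold, rep(1, 10))
})

test_that("the two-sample Student t matches the closed form on toy values", {
  # A = (8, 9, 10), B = (5, 6, 7): pooled sd = 1,
  # t = 3 / sqrt(2/3) = 3.6742, df = 4
  v <- matrix(2^c(8, 9, 10, 5, 6, 7), 1)
  pe <- toyExperiment(v, group = c(rep("HCC", 3), rep("control", 3)))
  res <- differentialTest(pe, c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
                          c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE))
  tHand <- 3 / sqrt(1 * (1 / 3 + 1 / 3))
  expect_equal(res$log2_fold, 3)
  expect_equal(res$fold, 8)
  expect_identical(res$direction, "up")
  expect_equal(res$p_value, 2 * pt(-tHand, df = 4), tolerance = 1e-12)
  # and agrees with stats::t.test on the same numbers
  expect_equal(res$p_value,
               t.test(c(8, 9, 10), c(5, 6, 7), var.equal = TRUE)$p.value,
               tolerance = 1e-12)
})

test_that("t p-values agree with an exact permutation oracle at small n", {
  permP <- function(a, b) {
    x <- c(a, b); n <- length(a)
    tstat <- function(i) {
      g1 <- x[i]; g2 <- x[-i]
      sp <- sqrt(((n - 1) * var(g1) + (n - 1) * var(g2)) / (2 * n - 2))
      (mean(g1) - mean(g2)) / (sp * sqrt(2 / n))
    }
    t0 <- tstat(seq_len(n))
    idx <- utils::combn(2 * n, n)
    perms <- apply(idx, 2, tstat)
    mean(abs(perms) >= abs(t0) - 1e-12)
  }
  set.seed(17)
  for (k in 1:3) {
    a <- rnorm(4, 1); b <- rnorm(4)
    pe <- toyExperiment(matrix(2^c(a, b), 1),
                        group = rep(c("HCC", "control"), each = 4))
    res <- differentialTest(pe, rep(c(TRUE, FALSE), each = 4),
                            rep(c(FALSE, TRUE), each = 4))
    expect_lt(abs(res$p_value - permP(a, b)), 0.12)
  }
})

test_that("planted markers come out up-regulated and significant", {
  cfg <- smallConfig(seed = 31, caseEffect = 2)
  pe <- generateCohort(cfg)
  res <- differentialTest(pe,
                          selectSamples(pe, group = "HCC",
                                        timepoint = "pre_op",
                                        phase = "training"),
                          selectSamples(pe, group = "control",
                                        phase = "training"))
  mk <- res$transcript_id %in% plantedMarkers(cfg)$markers
  expect_true(all(res$direction[mk] == "up"))
  expect_true(all(res$p_value[mk] < 0.05))
})

test_that("pairing errors and replication errors are reported", {
  m <- matrix(2^rnorm(8, 6), 2, 4, dimnames = list(NULL, paste0("s", 1:4)))
  pe <- toyExperiment(m, group = rep("HCC", 4),
                      timepoint = c("pre_op", "pre_op", "post_op", "none"),
                      patient = c("p1", "p2", "p1", "p3"))
  expect_error(differentialTest(pe, c(TRUE, TRUE, FALSE, FALSE),
                                c(FALSE, FALSE, TRUE, TRUE), paired = TRUE),
               "pairing error.*p2", ignore.case = TRUE)
  expect_error(differentialTest(pe, c(TRUE, FALSE, FALSE, FALSE),
                                c(FALSE, TRUE, TRUE, TRUE)),
               "insufficient replication")
})

test_that("deregulated sets split by direction and shrink with the
           threshold", {
  res <- data.frame(transcript_id = c("a", "b", "c"),
                    mean_a = 6, mean_b = 5,
                    log2_fold = c(1, -1, 1), fold = 2,
                    direction = c("up", "down", "up"),
                    p_value = c(0.01, 0.01, 0.2), paired = FALSE)
  sets <- selectDeregulated(res, filterSpec(pThreshold = 0.05))
  expect_identical(sets, list(up = "a", down = "b"))
  expect_identical(selectDeregulated(res, filterSpec(pThreshold = 1e-6)),
                   list(up = character(0), down = character(0)))
  allP1 <- transform(res, p_value = 1)
  s1 <- selectDeregulated(allP1, filterSpec())
  expect_length(c(s1$up, s1$down), 0)
  # monotonicity over random tables
  set.seed(4)
  for (i in 1:20) {
    r <- data.frame(transcript_id = paste0("t", 1:50), mean_a = 0,
                    mean_b = 0, log2_fold = rnorm(50), fold = 1,
                    direction = sample(c("up", "down"), 50, TRUE),
                    p_value = runif(50), paired = FALSE)
    loose <- selectDeregulated(r, filterSpec(pThreshold = 0.2))
    tight <- selectDeregulated(r, filterSpec(pThreshold = 0.05))
    expect_true(all(tight$up %in% loose$up))
    expect_true(all(tight$down %in% loose$down))
  }
})

test_that("candidate intersection is an exact, order-stable set operation", {
  expect_identical(intersectCandidates(c("A", "B", "C"), c("B", "C", "D")),
                   c("B", "C"))
  expect_identical(intersectCandidates(c("A"), c("B")), character(0))
  set.seed(9)
  for (i in 1:20) {
    u <- sample(letters, sample(0:15, 1))
    d <- sample(letters, sample(0:15, 1))
    r <- intersectCandidates(u, d)
    expect_true(all(r %in% u) && all(r %in% d))
    expect_identical(r, sort(r))
  }
})

test_that("the intensity/fold filter applies both thresholds in every
           comparison and is antitone in them", {
  mk <- function(signal, fold) {
    data.frame(transcript_id = paste0("c", seq_along(signal)),
               mean_a = signal, mean_b = signal - log2(fold),
               log2_fold = log2(fold), fold = fold,
               direction = "up", p_value = 0.01, paired = FALSE)
  }
  # (signal, fold) = (6,3),(4,3),(6,1.5),(5,2),(7,8) -> survivors 1, 4, 5
  tab <- mk(c(6, 4, 6, 5, 7), c(3, 3, 1.5, 2, 8))
  out <- filterCandidates(paste0("c", 1:5), list(tab), filterSpec())
  expect_identical(out, c("c1", "c4", "c5"))
  # vacuous thresholds keep everything
  expect_identical(
    filterCandidates(paste0("c", 1:5), list(tab),
                     filterSpec(minFold = 1, minSignal = 0)),
    sort(paste0("c", 1:5)))
  # a candidate failing in any one comparison is removed
  tab2 <- mk(c(6, 6, 6, 6, 6), c(8, 1.5, 8, 8, 8))
  expect_false("c2" %in% filterCandidates(paste0("c", 1:5),
                                          list(a = tab, b = tab2),
                                          filterSpec()))
  expect_error(filterCandidates(c("c1", "zz"), list(tab), filterSpec()),
               "zz")
  set.seed(2)
  for (i in 1:20) {
    t1 <- mk(runif(30, 2, 9), 2^runif(30, 0, 3))
    base <- filterCandidates(paste0("c", 1:30), list(t1), filterSpec())
    harder <- filterCandidates(paste0("c", 1:30), list(t1),
                               filterSpec(minFold = 3, minSignal = 6))
    expect_true(all(harder %in% base))
  }
})

test_that("volcano coordinates are (log2 fold, -log10 p) with a capped
           ceiling", {
  res <- data.frame(transcript_id = c("a", "b", "c"), mean_a = 0,
                    mean_b = 0, log2_fold = c(1, 2, 0), fold = 1,
                    direction = "up", p_value = c(0.01, 1, 0),
                    paired = FALSE)
  v <- volcanoTable(res)
  expect_equal(nrow(v), 3)
  expect_equal(v$neg_log10_p[1], 2)
  expect_equal(v$neg_log10_p[2], 0)
  expect_equal(v$neg_log10_p[3], 300)
})

test_that("hierarchical ordering is a permutation of the transcripts", {
  pe <- generateCohort(smallConfig(seed = 2, nTranscripts = 12))
  ord <- clusterOrder(pe)
  expect_setequal(ord, rownames(pe))
})
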