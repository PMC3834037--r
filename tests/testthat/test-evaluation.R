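test_that("confusion from scores matches a per-point counting oracle", {
  cm <- confusion_from_scores(c(0.9, 0.1), c(1, 0), 0.5)
  expect_equal(unclass(cm)[c("tp", "tn", "fp", "fn")], c(1, 1, 0, 0),
               ignore_attr = TRUE)

  cm2 <- confusion_from_scores(c(0.9, 0.1), c(1, 0), 2)
  expect_equal(cm2[["tp"]] + cm2[["fp"]], 0)

  set.seed(101)
  scores <- runif(100)
  labels <- rbinom(100, 1, 0.4)
  thr <- 0.37
  cm3 <- confusion_from_scores(scores, labels, thr)
  expect_equal(cm3[["tp"]], sum(scores >= thr & labels == 1))
  expect_equal(cm3[["tn"]], sum(scores < thr & labels == 0))
  expect_equal(sum(unclass(cm3)), 100)
  expect_error(confusion_from_scores(1:3, 0:1, 0.5), "same length")
})

test_that("classification metrics reproduce hand-computed values and edge
          cases", {
  m <- classification_metrics(confusion_matrix(tp = 4, tn = 10, fp = 0,
                                               fn = 2))
  expect_equal(m$sensitivity, 4 / 6)
  expect_equal(m$specificity, 1)
  expect_equal(m$q, (4 / 6 + 1) / 2)
  expect_equal(m$mcc, 40 / sqrt(4 * 6 * 10 * 12))
  expect_equal(m$f1, 0.8)

  perfect <- classification_metrics(confusion_matrix(10, 20, 0, 0))
  expect_equal(unlist(perfect), c(acc = 1, sensitivity = 1,
                                  specificity = 1, mcc = 1, q = 1, f1 = 1))

  # zero denominators are tagged undefined, not 0
  allneg <- classification_metrics(confusion_matrix(0, 5, 0, 0))
  expect_true(is.na(allneg$sensitivity))
  expect_true(is.na(allneg$mcc))
})

test_that("MCC is symmetric under class swap and bounded on random
          matrices", {
  set.seed(102)
  for (i in 1:50) {
    cm <- confusion_matrix(tp = rpois(1, 20) + 1, tn = rpois(1, 20) + 1,
                           fp = rpois(1, 10), fn = rpois(1, 10))
    m <- classification_metrics(cm)
    swapped <- classification_metrics(confusion_matrix(
      tp = cm[["tn"]], tn = cm[["tp"]], fp = cm[["fn"]], fn = cm[["fp"]]))
    expect_equal(m$mcc, swapped$mcc)
    expect_true(m$mcc >= -1 && m$mcc <= 1)
  }
})

test_that("ROC curve endpoints, tie grouping and the 4-point oracle", {
  rc <- roc_curve(c(0.9, 0.8, 0.3, 0.2), c(1, 0, 1, 0))
  expect_equal(rc$fpr[1], 0)
  expect_equal(rc$tpr[1], 0)
  expect_equal(rc$fpr[nrow(rc)], 1)
  expect_equal(rc$tpr[nrow(rc)], 1)
  # exhaustive threshold enumeration oracle
  for (i in seq_len(nrow(rc))) {
    t <- rc$threshold[i]
    expect_equal(rc$sensitivity[i], mean(c(0.9, 0.3) >= t))
    expect_equal(rc$specificity[i], mean(c(0.8, 0.2) < t))
  }

  sep <- roc_curve(c(3, 4, 1, 2), c(1, 1, 0, 0))
  expect_true(any(sep$fpr == 0 & sep$tpr == 1))

  const <- roc_curve(rep(1, 10), rep(0:1, 5))
  expect_equal(nrow(const), 2)
  expect_equal(auc(const), 0.5)

  expect_error(roc_curve(1:4, rep(1, 4)), "both classes")
})

test_that("trapezoidal AUC equals the rank concordance estimator", {
  expect_equal(auc(c(0.9, 0.8, 0.3, 0.2), c(1, 0, 1, 0)), 0.75)
  expect_equal(auc(c(3, 4, 1, 2), c(1, 1, 0, 0)), 1)

  set.seed(103)
  for (i in 1:100) {
    n <- sample(10:60, 1)
    scores <- sample(round(runif(n), 2))  # ties on purpose
    labels <- c(1, 0, rbinom(n - 2, 1, 0.5))
    expect_equal(auc(scores, labels), auc_concordance(scores, labels),
                 tolerance = 1e-12)
  }
})

test_that("AUC agrees with pROC on a shared instance", {
  skip_if_not_installed("pROC")
  set.seed(104)
  scores <- rnorm(80) + rep(c(1, 0), each = 40) * 1.2
  labels <- rep(c(1, 0), each = 40)
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE)))
  expect_equal(auc(scores, labels), ref, tolerance = 1e-12)
})

test_that("partial AUC: band identities, monotonicity and known values", {
  set.seed(105)
  scores <- rnorm(100) + rep(c(0.8, 0), each = 50)
  labels <- rep(c(1, 0), each = 50)
  expect_equal(partial_auc(scores, labels, 0, 1), auc(scores, labels),
               tolerance = 1e-12)

  # perfect classifier: the 0-0.2 band is a full-height rectangle
  expect_equal(partial_auc(c(3, 4, 1, 2), c(1, 1, 0, 0), 0, 0.2), 0.2)
  # uninformative scores: triangle under the diagonal, 0.2^2/2
  expect_equal(partial_auc(rep(1, 10), rep(0:1, 5), 0, 0.2), 0.02)

  p1 <- partial_auc(scores, labels, 0, 0.1)
  p2 <- partial_auc(scores, labels, 0, 0.2)
  expect_lte(p1, p2)
  expect_lte(p2, auc(scores, labels))
  expect_error(partial_auc(scores, labels, 0.5, 0.2), "fpr_lo < fpr_hi")
})

test_that("DeLong test: identity, symmetry, and agreement with pROC", {
  set.seed(106)
  labels <- rep(c(1, 0), each = 60)
  a <- rnorm(120) + labels
  b <- 0.5 * a + rnorm(120, sd = 0.8)

  same <- delong_test(a, a, labels)
  expect_equal(same$auc_diff, 0)
  expect_equal(same$p_value, 1)

  ab <- delong_test(a, b, labels)
  ba <- delong_test(b, a, labels)
  expect_equal(ab$p_value, ba$p_value)
  expect_equal(ab$auc_diff, -ba$auc_diff)

  skip_if_not_installed("pROC")
  ref <- pROC::roc.test(
    pROC::roc(labels, a, quiet = TRUE, direction = "<", levels = c(0, 1)),
    pROC::roc(labels, b, quiet = TRUE, direction = "<", levels = c(0, 1)),
    method = "delong")
  expect_equal(ab$p_value, as.numeric(ref$p.value), tolerance = 1e-8)
})

test_that("stratified bootstrap CI: determinism, degenerate statistic and
          sane AUC interval", {
  set.seed(107)
  labels <- rep(c(1, 0), each = 50)
  scores <- rnorm(100) + labels

  const <- bootstrap_ci(function(s, l) 0.5, scores, labels,
                        n_boot = 200, seed = 3)
  expect_equal(const$low, const$high)

  ci1 <- bootstrap_ci(auc_concordance, scores, labels, n_boot = 300,
                      seed = 7)
  ci2 <- bootstrap_ci(auc_concordance, scores, labels, n_boot = 300,
                      seed = 7)
  expect_equal(ci1[c("low", "high")], ci2[c("low", "high")])
  expect_lt(ci1$low, ci1$estimate)
  expect_gt(ci1$high, ci1$estimate)
  expect_error(bootstrap_ci(auc_concordance, scores, labels, n_boot = 50),
               "at least 100")
})

test_that("threshold selectors match exhaustive search over all cuts", {
  exhaustive <- function(scores, labels, objective) {
    cand <- sort(unique(scores))
    vals <- vapply(cand, function(t) {
      m <- classification_metrics(confusion_from_scores(scores, labels, t))
      objective(m)
    }, numeric(1))
    cand[vals == max(vals)]
  }
  set.seed(108)
  for (i in 1:20) {
    scores <- round(runif(40), 2)
    labels <- c(1, 0, rbinom(38, 1, 0.5))
    yj <- select_threshold(scores, labels, "youden")
    best <- exhaustive(scores, labels,
                       function(m) m$sensitivity + m$specificity - 1)
    expect_true(yj %in% best)
    ul <- select_threshold(scores, labels, "upper-left")
    best_ul <- exhaustive(scores, labels, function(m) {
      -sqrt((1 - m$sensitivity)^2 + (1 - m$specificity)^2)
    })
    expect_true(ul %in% best_ul)
  }

  # perfectly separated scores: both criteria separate the classes
  s <- c(5, 6, 7, 1, 2, 3)
  l <- c(1, 1, 1, 0, 0, 0)
  for (crit in c("youden", "upper-left")) {
    t <- select_threshold(s, l, crit)
    m <- classification_metrics(confusion_from_scores(s, l, t))
    expect_equal(m$sensitivity + m$specificity, 2)
  }
})

test_that("high-sensitivity / high-specificity targets are honoured", {
  set.seed(109)
  scores <- rnorm(200) + rep(c(1.5, 0), each = 100)
  labels <- rep(c(1, 0), each = 100)
  ths <- select_threshold(scores, labels, "high-sensitivity", target = 0.9)
  m <- classification_metrics(confusion_from_scores(scores, labels, ths))
  expect_gte(m$sensitivity, 0.9)
  # largest such threshold: nudging it up breaks the target
  above <- min(scores[scores > ths])
  m2 <- classification_metrics(confusion_from_scores(scores, labels, above))
  expect_lt(m2$sensitivity, 0.9)

  thp <- select_threshold(scores, labels, "high-specificity", target = 0.95)
  mp <- classification_metrics(confusion_from_scores(scores, labels, thp))
  expect_gte(mp$specificity, 0.95)
  expect_error(select_threshold(scores, labels, "high-sensitivity"),
               "target")
})

test_that("per-residue confusion counts regions correctly and is invariant
          to region splitting", {
  pred <- data.frame(start = 1, end = 10)
  truth <- data.frame(start = 6, end = 15)
  cm <- per_residue_confusion(pred, truth, 20)
  expect_equal(unclass(cm)[c("tp", "fp", "fn", "tn")], c(5, 5, 5, 5),
               ignore_attr = TRUE)

  none <- per_residue_confusion(pred[0, ], truth, 20)
  expect_equal(unclass(none)[c("tp", "fp", "fn", "tn")], c(0, 0, 10, 10),
               ignore_attr = TRUE)

  same <- per_residue_confusion(truth, truth, 20)
  expect_equal(same[["fp"]] + same[["fn"]], 0)

  # splitting a region into adjacent subregions changes nothing
  split <- data.frame(start = c(1, 4, 8), end = c(3, 7, 10))
  expect_equal(unclass(per_residue_confusion(split, truth, 20)),
               unclass(cm))

  expect_error(per_residue_confusion(data.frame(start = 1, end = 25),
                                     truth, 20), "out of bounds")

  # batched over two proteins, counts sum to total length
  pred2 <- data.frame(sequence_id = c("a", "b"), start = c(1, 3),
                      end = c(4, 8))
  truth2 <- data.frame(sequence_id = c("a", "b"), start = c(2, 1),
                       end = c(5, 2))
  cmb <- per_residue_confusion(pred2, truth2, c(a = 10, b = 12))
  expect_equal(sum(unclass(cmb)), 22)
})
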