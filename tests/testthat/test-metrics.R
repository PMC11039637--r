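test_that("confusion counts match hand-built cases and reject bad input", {
  truth <- exact_mask(100, 20, nrow = 10)
  expect_equal(unclass(confusion(truth, truth))[c("tp", "tn", "fp", "fn")],
               list(tp = 20L, tn = 80L, fp = 0L, fn = 0L))
  zero <- truth * 0L
  cc <- confusion(zero, truth)
  expect_equal(c(cc$tp, cc$tn, cc$fp, cc$fn), c(0, 80, 0, 20))
  expect_error(confusion(matrix(0, 2, 2), matrix(0, 3, 3)), "shape")
  expect_error(confusion(matrix(2, 2, 2), matrix(0, 2, 2)), "binary")
})

test_that("percentage metrics reproduce hand arithmetic", {
  c10 <- list(tp = 10, tn = 70, fp = 10, fn = 10)
  expect_equal(accuracy(c10), 80)
  expect_equal(sensitivity(c10), 50)
  expect_equal(specificity(c10), 87.5)
  expect_equal(precision(c10), 50)
  expect_equal(f1(c10), 50)
  expect_equal(mcc(c10), 100 * (10 * 70 - 10 * 10) / sqrt(20 * 20 * 80 * 80))
  perfect <- list(tp = 20, tn = 80, fp = 0, fn = 0)
  expect_equal(accuracy(perfect), 100)
  expect_equal(f1(perfect), 100)
  expect_equal(mcc(perfect), 100)
})

test_that("undefined metrics raise classed errors; MCC zero-marginal warns", {
  allneg <- list(tp = 0, tn = 80, fp = 0, fn = 20)
  expect_equal(sensitivity(allneg), 0)
  expect_equal(specificity(allneg), 100)
  expect_error(precision(allneg), class = "lesionforge_undefined_metric")
  expect_warning(expect_equal(mcc(allneg), 0), "undefined")
})

test_that("as-printed compatibility formulas reproduce the literal text", {
  c10 <- list(tp = 10, tn = 70, fp = 10, fn = 10)
  expect_equal(accuracy(c10, as_printed = TRUE), 100 * 80 / 90)  # FP omitted
  expect_equal(sensitivity(c10, as_printed = TRUE), specificity(c10))
  expect_equal(precision(c10, as_printed = TRUE), specificity(c10))
  expect_equal(mcc(c10, as_printed = TRUE),
               100 * (10 * 70 - 10 * 10) / sqrt(20 * 20 * 80 * 80))
})

test_that("all metrics match the brute-force oracle on random instances", {
  set.seed(101)
  for (i in 1:200) {
    n <- sample(20:200, 1)
    pred <- rbinom(n, 1, runif(1, 0.2, 0.8))
    truth <- rbinom(n, 1, runif(1, 0.2, 0.8))
    o <- oracle_confusion(pred, truth)
    cc <- confusion(pred, truth)
    expect_identical(unclass(cc)[c("tp", "tn", "fp", "fn")], o)
    eps <- sample(c(0, 1), 1)
    expect_equal(jaccard(pred, truth, eps), oracle_jaccard(pred, truth, eps))
  }
})

test_that("dice and jaccard obey the closed-form relation", {
  set.seed(77)
  for (i in 1:50) {
    pred <- rbinom(64, 1, 0.4); truth <- rbinom(64, 1, 0.4)
    if (sum(pred) + sum(truth) == 0) next
    j <- jaccard(pred, truth); d <- dice(pred, truth)
    expect_gte(d, j)
    expect_equal(d, 2 * j / (1 + j))
  }
  m <- exact_mask(100, 30, 10)
  expect_equal(jaccard(m, m), 1)
  expect_equal(dice(m, m), 1)
  disj <- exact_mask(100, 30, 10); disj2 <- 1L - disj
  expect_equal(jaccard(disj, disj2), 0)
  expect_equal(dice(disj, disj2), 0)
})

test_that("f1 never exceeds the larger of precision and sensitivity; ranges hold", {
  set.seed(55)
  for (i in 1:300) {
    cc <- list(tp = sample(1:50, 1), tn = sample(1:50, 1),
               fp = sample(1:50, 1), fn = sample(1:50, 1))
    expect_lte(f1(cc), max(precision(cc), sensitivity(cc)) + 1e-12)
    for (v in c(accuracy(cc), sensitivity(cc), specificity(cc), precision(cc))) {
      expect_gte(v, 0); expect_lte(v, 100)
    }
    expect_gte(mcc(cc), -100); expect_lte(mcc(cc), 100)
  }
  # label inversion swaps sensitivity and specificity
  cc <- list(tp = 12, tn = 30, fp = 7, fn = 9)
  inv <- list(tp = cc$tn, tn = cc$tp, fp = cc$fn, fn = cc$fp)
  expect_equal(sensitivity(inv), specificity(cc))
  expect_equal(specificity(inv), sensitivity(cc))
})

test_that("mcc is -100 for a perfectly inverted prediction", {
  truth <- exact_mask(100, 40, 10)
  expect_equal(mcc(confusion(1L - truth, truth)), -100)
})

test_that("rank AUC matches direct enumeration on a small case", {
  scores <- c(0.9, 0.8, 0.4, 0.3, 0.2)
  labels <- c(1, 1, 0, 1, 0)
  pairs <- expand.grid(p = which(labels == 1), n = which(labels == 0))
  direct <- mean(scores[pairs$p] > scores[pairs$n])
  expect_equal(auc_rank(scores, labels), direct)
})

test_that("metric_table aggregates per-image rows with mean and sd", {
  truths <- list(exact_mask(64, 16, 8), exact_mask(64, 16, 8))
  tab <- metric_table(truths, truths)
  expect_equal(nrow(tab), 4)
  expect_equal(tab$accuracy[tab$stat == "mean"], 100)
  expect_equal(tab$jaccard[tab$stat == "sd"], 0)
})
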