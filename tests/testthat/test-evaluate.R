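test_that("confusion matrices tally labels correctly", {
  y <- c("a", "b", "c", "a")
  cm <- confusion_matrix(y, y)
  expect_true(all(cm$counts[upper.tri(cm$counts)] == 0))
  expect_equal(unname(diag(cm$counts)), c(2L, 1L, 1L))

  cm0 <- confusion_matrix(character(), character(), labels = c("x", "y"))
  expect_true(all(cm0$counts == 0))

  set.seed(41)
  yt <- sample(c("a", "b", "c"), 12, replace = TRUE)
  yp <- sample(c("a", "b", "c"), 12, replace = TRUE)
  cm3 <- confusion_matrix(yt, yp, labels = c("a", "b", "c"))
  for (i in 1:3) for (j in 1:3) {
    expect_equal(cm3$counts[i, j],
                 sum(yt == c("a", "b", "c")[i] & yp == c("a", "b", "c")[j]))
  }
  expect_error(confusion_matrix("a", "z", labels = "a"), "z",
               class = "sdcl_validation_error")
})

test_that("metrics match direct counting on the worked binary example", {
  cm <- confusion_matrix(rep(c("neg", "pos"), c(10, 10)),
                         rep(c("neg", "pos"), c(10, 10)))
  perfect <- classification_metrics(cm, "binary")
  expect_equal(c(perfect$accuracy, perfect$precision, perfect$recall, perfect$f1),
               rep(1, 4))

  # counts [[8,2],[1,9]] with the second class positive
  yt <- rep(c("n", "p"), c(10, 10))
  yp <- c(rep("n", 8), rep("p", 2), "n", rep("p", 9))
  m <- classification_metrics(confusion_matrix(yt, yp), "binary")
  expect_equal(m$accuracy, 17 / 20)
  expect_equal(m$precision, 9 / 11, tolerance = 1e-12)
  expect_equal(m$recall, 9 / 10, tolerance = 1e-12)
  expect_equal(m$f1, 2 * (9 / 11) * (9 / 10) / (9 / 11 + 9 / 10), tolerance = 1e-12)
})

test_that("weighted aggregation equals the support-weighted mean of per-class values", {
  set.seed(42)
  yt <- sample(c("a", "b", "c"), 60, replace = TRUE, prob = c(0.5, 0.3, 0.2))
  yp <- ifelse(runif(60) < 0.6, yt, sample(c("a", "b", "c"), 60, replace = TRUE))
  cm <- confusion_matrix(yt, yp, c("a", "b", "c"))
  m <- classification_metrics(cm, "weighted")
  pc <- tidy(m)
  expect_equal(m$precision, sum(pc$support * pc$precision) / sum(pc$support))
  expect_equal(m$recall, sum(pc$support * pc$recall) / sum(pc$support))
  expect_equal(m$f1, sum(pc$support * pc$f1) / sum(pc$support))
  expect_equal(m$accuracy, sum(diag(cm$counts)) / sum(cm$counts))
})

test_that("binary formulas agree with the one-vs-rest reduction on 2x2 matrices", {
  set.seed(43)
  for (i in 1:20) {
    counts <- matrix(rpois(4, 8), 2)
    if (sum(counts) == 0 || any(rowSums(counts) == 0)) next
    yt <- rep(c("n", "p"), rowSums(counts))
    yp <- c(rep(c("n", "p"), counts[1, ]), rep(c("n", "p"), counts[2, ]))
    cm <- confusion_matrix(yt, yp, c("n", "p"))
    mb <- suppressWarnings(classification_metrics(cm, "binary"))
    pc <- suppressWarnings(tidy(classification_metrics(cm, "weighted")))
    expect_equal(mb$precision, pc$precision[2])
    expect_equal(mb$recall, pc$recall[2])
    expect_equal(mb$f1, pc$f1[2])
  }
})

test_that("F1 is bounded and zero exactly when precision * recall is zero", {
  set.seed(44)
  for (i in 1:50) {
    counts <- matrix(rpois(9, 3), 3)
    if (sum(counts) == 0) next
    yt <- rep(c("a", "b", "c"), rowSums(counts))
    yp <- unlist(lapply(1:3, function(r) rep(c("a", "b", "c"), counts[r, ])))
    m <- suppressWarnings(classification_metrics(confusion_matrix(yt, yp), "macro"))
    pc <- tidy(m)
    expect_true(all(pc$f1 >= 0 & pc$f1 <= 1))
    expect_equal(pc$f1 == 0, pc$precision * pc$recall == 0)
  }
})

test_that("accuracy is invariant under class-order permutation", {
  set.seed(45)
  yt <- sample(c("a", "b", "c"), 40, replace = TRUE)
  yp <- sample(c("a", "b", "c"), 40, replace = TRUE)
  m1 <- suppressWarnings(classification_metrics(confusion_matrix(yt, yp, c("a", "b", "c"))))
  m2 <- suppressWarnings(classification_metrics(confusion_matrix(yt, yp, c("c", "a", "b"))))
  expect_equal(m1$accuracy, m2$accuracy)
})

test_that("separable features evaluate to perfect accuracy, deterministically", {
  set.seed(46)
  x <- rbind(matrix(rnorm(100, 0), 50, 2), matrix(rnorm(100, 8), 50, 2))
  y <- rep(c("lo", "hi"), each = 50)
  r1 <- evaluate_features(x, y, classifier_svm("linear"), seed = 3)
  expect_equal(r1$accuracy, 1)
  r2 <- evaluate_features(x, y, classifier_svm("linear"), seed = 3)
  expect_identical(glance(r1), glance(r2))
  expect_identical(attr(r1, "test_index"), attr(r2, "test_index"))
})

test_that("shuffled labels score near chance level", {
  set.seed(47)
  x <- matrix(rnorm(300), 100, 3)
  accs <- vapply(1:15, function(s) {
    y <- sdcl:::with_seed(s, sample(rep(c("a", "b"), each = 50)))
    suppressWarnings(evaluate_features(x, y, classifier_svm("linear"), seed = s)$accuracy)
  }, 1)
  expect_lt(abs(mean(accs) - 0.5), 0.15)
})

test_that("splits that would empty a class are refused", {
  x <- matrix(rnorm(24), 12, 2)
  y <- c(rep("a", 11), "b")
  expect_error(evaluate_features(x, y, classifier_svm(), test_fraction = 0.5),
               class = "sdcl_validation_error")
  expect_error(evaluate_features(x[1:4, ], y[1:4], classifier_svm()),
               class = "sdcl_validation_error")
})

test_that("alternative classifier adapters run end to end", {
  set.seed(48)
  x <- rbind(matrix(rnorm(60, 0), 30, 2), matrix(rnorm(60, 6), 30, 2))
  y <- rep(c("lo", "hi"), each = 30)
  for (clf in list(classifier_knn(3), classifier_rf(50), classifier_lda(),
                   classifier_mlp(size = 4, maxit = 100))) {
    r <- evaluate_features(x, y, clf, seed = 5)
    expect_gt(r$accuracy, 0.8)
  }
})
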