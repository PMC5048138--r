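test_that("RBF SVM decision scores are oriented and class-swap symmetric", {
  X <- rbind(matrix(stats::rnorm(20, mean = 2, sd = 0.1), 10),
             matrix(stats::rnorm(20, mean = -2, sd = 0.1), 10))
  y <- rep(c("positive", "negative"), each = 10)
  m <- train(X, y, svm_config(C = 10, gamma = 0.5))
  s <- decision_scores(m, X)
  expect_true(all(s[1:10] > 0))
  expect_true(all(s[11:20] < 0))

  yswap <- rep(c("negative", "positive"), each = 10)
  s2 <- decision_scores(train(X, yswap, svm_config(C = 10, gamma = 0.5)), X)
  expect_true(all(sign(s2) == -sign(s)))

  expect_error(train(X, rep("positive", 20)), "both classes")
})

test_that("an RBF kernel separates the XOR pattern at suitable gamma", {
  X <- rbind(c(0, 0), c(1, 1), c(0, 1), c(1, 0))
  y <- c("positive", "positive", "negative", "negative")
  ok <- FALSE
  for (g in c(0.5, 1, 2, 4, 8)) {
    s <- decision_scores(train(X, y, svm_config(C = 2^10, gamma = g)), X)
    if (all(s[1:2] > 0) && all(s[3:4] < 0)) ok <- TRUE
  }
  expect_true(ok)
})

test_that("jackknife scores every sample once and separable data reaches auROC 1", {
  set.seed(53)
  X <- rbind(matrix(stats::rnorm(30, 3, 0.2), 15),
             matrix(stats::rnorm(30, -3, 0.2), 15))
  y <- rep(c("positive", "negative"), each = 15)
  res <- jackknife_eval(X, y, svm_config(C = 10, gamma = 0.5))
  expect_length(res$scores, 30L)
  expect_equal(res$auroc, 1.0)
  expect_error(jackknife_eval(X[1:2, ], y[1:2]), "at least 3")
})

test_that("labels assigned at random to uninformative rows give chance-level auROC", {
  aurocs <- vapply(1:3, function(seed) {
    set.seed(seed)
    X <- matrix(stats::rnorm(200 * 4), 200, 4)
    y <- sample(rep(c("positive", "negative"), each = 100))
    jackknife_eval(X, y, svm_config(gamma = 0.25))$auroc
  }, numeric(1))
  expect_true(all(abs(aurocs - 0.5) <= 0.1))
})

test_that("jackknife on identical rows shows the leave-one-out imbalance artifact", {
  # With all feature rows identical, each fold's constant score tracks the
  # majority of the remaining labels, which is always the class opposite
  # the held-out sample: a perfect anti-ranking, auROC = 0.
  set.seed(2)
  X <- matrix(1, 40, 4)
  y <- sample(rep(c("positive", "negative"), each = 20))
  expect_equal(jackknife_eval(X, y, svm_config())$auroc, 0)
})

test_that("ROC curves step through tie groups from (0,0) to (1,1)", {
  r <- roc_curve(c(0.9, 0.8, 0.3, 0.1),
                 c("positive", "positive", "negative", "negative"))
  expect_equal(auroc(r), 1.0)

  expect_equal(auroc_scores(rep(1, 10), rep(c("positive", "negative"), 5)),
               0.5)  # total tie

  # pairwise enumeration: (0.9, 0.4, 0.6, 0.1) with (+, -, +, -)
  expect_equal(auroc_scores(c(0.9, 0.4, 0.6, 0.1),
                            c("positive", "negative", "positive",
                              "negative")), 1.0)

  set.seed(59)
  s <- stats::rnorm(25)
  lab <- sample(c("positive", "negative"), 25, replace = TRUE,
                prob = c(0.4, 0.6))
  r2 <- roc_curve(s, lab)
  expect_equal(r2$fpr[1], 0)
  expect_equal(r2$tpr[1], 0)
  expect_equal(r2$fpr[nrow(r2)], 1)
  expect_equal(r2$tpr[nrow(r2)], 1)
  expect_true(all(diff(r2$fpr) >= 0) && all(diff(r2$tpr) >= 0))

  expect_error(roc_curve(1:3, rep("positive", 3)), "both")
})

test_that("trapezoidal auROC equals the pairwise rank statistic and is monotone-invariant", {
  set.seed(61)
  for (rep in 1:20) {
    n <- sample(5:30, 1)
    scores <- round(stats::rnorm(n), sample(0:2, 1))  # induce ties
    labels <- sample(c("positive", "negative"), n, replace = TRUE)
    if (length(unique(labels)) < 2) next
    a <- auroc_scores(scores, labels)
    expect_equal(a, brute_auroc(scores, labels))
    # strictly monotone transforms leave auROC unchanged
    expect_equal(auroc_scores(exp(scores), labels), a)
    expect_equal(auroc_scores(3 * scores - 7, labels), a)
  }
})

test_that("auROC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(67)
  scores <- stats::rnorm(40)
  labels <- sample(c("positive", "negative"), 40, replace = TRUE)
  ref <- as.numeric(pROC::auc(pROC::roc(
    response = labels, predictor = scores, levels = c("negative", "positive"),
    direction = "<", quiet = TRUE)))
  expect_equal(auroc_scores(scores, labels), ref)
})

test_that("grid search enumerates the full grid and breaks ties toward small C, gamma", {
  X <- matrix(stats::rnorm(40), 20, 2)
  y <- rep(c("positive", "negative"), 10)

  one <- grid_search(X, y, svm_config(C_grid = 4, gamma_grid = 0.25),
                     evaluator = function(X, y, cfg) 0.7)
  expect_equal(c(one$C, one$gamma), c(4, 0.25))

  n_calls <- 0L
  res <- grid_search(X, y, svm_config(),
                     evaluator = function(X, y, cfg) {
                       n_calls <<- n_calls + 1L
                       0.5
                     })
  expect_equal(n_calls, 231L)  # 21 C values x 11 gamma values
  expect_equal(res$C, 2^-5)    # all tie -> smallest C, then smallest gamma
  expect_equal(res$gamma, 2^-15)
  expect_equal(nrow(res$grid), 231L)
})

test_that("jackknife on duplicated two-point data scores the classes symmetrically", {
  X <- matrix(rep(c(1, -1), each = 12), ncol = 1)
  y <- rep(c("positive", "negative"), each = 12)
  res <- jackknife_eval(X, y, svm_config(C = 1, gamma = 1))
  expect_equal(res$scores[1:12], -res$scores[13:24], tolerance = 1e-6)
  expect_equal(res$auroc, 1.0)
})
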