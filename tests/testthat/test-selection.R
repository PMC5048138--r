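test_that("three-state discretization cuts at mean +/- population sigma", {
  expect_equal(discretize(rep(0, 5)), rep(2L, 5))
  # {-10, 0, 10}: sigma = sqrt(200/3) ~ 8.16 -> low, mid, high
  expect_equal(discretize(c(-10, 0, 10)), c(1L, 2L, 3L))
  set.seed(31)
  x <- stats::rnorm(50)
  expect_identical(discretize(x), discretize(3.7 * x - 12))  # affine invariant
  expect_error(discretize(1), "at least 2")
})

test_that("plug-in mutual information matches exhaustive cell enumeration", {
  x <- rep(c(0L, 1L), each = 10)
  expect_equal(mutual_information(x, x), 1)  # two equiprobable states

  # printed 2x2 joint table {(0,0):4, (0,1):1, (1,0):1, (1,1):4}
  cx <- rep(c(0L, 0L, 1L, 1L), c(4L, 1L, 1L, 4L))
  cy <- rep(c(0L, 1L, 0L, 1L), c(4L, 1L, 1L, 4L))
  brute <- 0
  for (a in 0:1) for (b in 0:1) {
    pab <- mean(cx == a & cy == b)
    brute <- brute + pab * log2(pab / (mean(cx == a) * mean(cy == b)))
  }
  expect_equal(mutual_information(cx, cy), brute)
  expect_equal(brute, 0.2780719, tolerance = 1e-6)

  expect_error(mutual_information(1:3, 1:4), "equal length")
})

test_that("mutual information is symmetric, non-negative, and self-MI is entropy", {
  set.seed(37)
  for (rep in 1:10) {
    cx <- sample(1:3, 40, replace = TRUE)
    cy <- sample(1:3, 40, replace = TRUE)
    expect_equal(mutual_information(cx, cy), mutual_information(cy, cx))
    expect_gte(mutual_information(cx, cy), -1e-12)
    p <- table(cx) / length(cx)
    expect_equal(mutual_information(cx, cx), -sum(p * log2(p)))
  }

  # independent uniform codes at large n: MI near zero
  set.seed(38)
  cx <- sample(1:3, 5000, replace = TRUE)
  cy <- sample(1:3, 5000, replace = TRUE)
  expect_lt(mutual_information(cx, cy), 0.01)
})

test_that("mRMR ranks a label-equal feature first and defers duplicates", {
  n <- 60
  y <- rep(c("positive", "negative"), each = n / 2)
  ybin <- as.numeric(y == "positive")

  # a feature equal to the label attains the maximal relevance (1 bit)
  set.seed(41)
  X0 <- cbind(f_label = ybin, f_noise1 = stats::rnorm(n),
              f_noise2 = stats::rnorm(n))
  rk0 <- mrmr_rank(X0, y)
  expect_equal(rk0$order[1], 1L)
  expect_equal(rk0$relevance[1], 1)

  # rank-1 = noisy label readout; its exact copy carries full redundancy
  # (MI = its entropy) and is deferred behind a weaker independent feature
  set.seed(42)
  flip <- function(z, rate) ifelse(stats::runif(n) < rate, 1 - z, z)
  X <- cbind(f_top = flip(ybin, 0.15) * 10,
             f_dup = flip(ybin, 0.15) * 10,  # same flips: exact copy
             f_indep = flip(ybin, 0.25) * 10,
             f_noise = stats::rnorm(n))
  X[, 2] <- X[, 1]
  rk <- mrmr_rank(X, y)
  expect_equal(rk$order[1], 1L)
  expect_lt(which(rk$order == 3L), which(rk$order == 2L))
  expect_setequal(rk$order, 1:4)
  expect_equal(rk$order, oracle_mrmr(X, y))
})

test_that("mRMR equals exhaustive greedy search on small instances", {
  set.seed(43)
  for (rep in 1:8) {
    n <- 30
    p <- sample(3:8, 1)
    y <- sample(c("positive", "negative"), n, replace = TRUE)
    X <- matrix(stats::rnorm(n * p), n, p,
                dimnames = list(NULL, paste0("f", 1:p)))
    X[, 1] <- X[, 1] + (y == "positive") * 2
    expect_equal(mrmr_rank(X, y)$order, oracle_mrmr(X, y))
  }
})

test_that("incremental feature selection evaluates every nested prefix", {
  set.seed(47)
  n <- 30
  y <- rep(c("positive", "negative"), each = n / 2)
  X <- matrix(stats::rnorm(n * 6), n, 6,
              dimnames = list(NULL, paste0("f", 1:6)))
  X[, 2] <- X[, 2] + (y == "positive") * 3
  calls <- list()
  ev <- function(Xs, ys) {
    calls[[length(calls) + 1L]] <<- colnames(Xs)
    auroc_scores(rowSums(Xs), ys)
  }
  curve <- ifs(X, y, mrmr_rank(X, y), ev)
  expect_length(curve$auroc, 6L)
  expect_equal(lengths(calls), 1:6)  # nested prefixes, one per k
  # prefix completeness: the last point is the evaluator on the full matrix
  expect_equal(curve$auroc[6],
               auroc_scores(rowSums(X[, mrmr_rank(X, y)$order]), y))
  expect_equal(curve$best_k, which.max(curve$auroc))

  one <- ifs(X[, 2, drop = FALSE], y, 1L,
             function(Xs, ys) auroc_scores(Xs[, 1], ys))
  expect_length(one$auroc, 1L)
  expect_equal(one$best_k, 1L)
})

test_that("IFS finds a small subset when few features are informative", {
  hits <- 0L
  for (seed in 1:5) {
    set.seed(seed)
    n <- 40
    y <- rep(c("positive", "negative"), each = n / 2)
    inform <- sapply(1:5, function(i)
      (y == "positive") * 2 + stats::rnorm(n))
    noise <- matrix(stats::rnorm(n * 50), n, 50)
    X <- cbind(inform, noise)
    colnames(X) <- paste0("f", 1:55)
    rk <- mrmr_rank(X, y)
    curve <- ifs(X, y, rk,
                 evaluator = function(Xs, ys)
                   jackknife_eval(Xs, ys, svm_config(gamma = 1 / 55))$auroc)
    if (curve$best_k <= 15 &&
        curve$auroc[curve$best_k] >= curve$auroc[length(curve$auroc)])
      hits <- hits + 1L
  }
  expect_gte(hits, 4L)
})
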