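#' SVM configuration
#'
#' Holds the RBF-kernel operating point and the hyperparameter grids for
#' [grid_search()]: C over 2^-5..2^15 and gamma over 2^-15..2^-5, both with
#' exponent step 1 (21 x 11 = 231 grid points).
#'
#' @param C Penalty constant.
#' @param gamma RBF kernel width.
#' @param C_grid,gamma_grid Strictly increasing candidate vectors.
#' @return Object of class `SvmConfig`.
#' @export
svm_config <- function(C = 2^5, gamma = 2^-8,
                       C_grid = 2^(-5:15), gamma_grid = 2^(-15:-5)) {
  stopifnot(C > 0, gamma > 0, length(C_grid) > 0, length(gamma_grid) > 0)
  if (any(diff(C_grid) <= 0) || any(diff(gamma_grid) <= 0))
    stop("grids must be strictly increasing")
  structure(list(C = C, gamma = gamma, C_grid = C_grid,
                 gamma_grid = gamma_grid),
            class = "SvmConfig")
}

#' Train an RBF-kernel SVM and expose oriented decision scores
#'
#' A maximum-margin classifier with radial basis function kernel at the
#' configured (C, gamma). Decision scores are oriented so that larger
#' values favor the positive class.
#'
#' @param X Numeric sample-by-feature matrix.
#' @param y Labels (`"positive"` / `"negative"`), both classes present.
#' @param config An [svm_config()].
#' @return Object of class `SvmModel`.
#' @export
train <- function(X, y, config = svm_config()) {
  y <- as.character(y)
  if (length(unique(y)) < 2L)
    stop("training data must contain both classes")
  fit <- e1071::svm(x = X, y = factor(y, levels = c("negative", "positive")),
                    scale = FALSE, kernel = "radial",
                    cost = config$C, gamma = config$gamma)
  structure(list(fit = fit, config = config), class = "SvmModel")
}

#' @rdname train
#' @param model A trained `SvmModel`.
#' @param newX Matrix of samples to score.
#' @return `decision_scores` returns a numeric vector, positive-class-high.
#' @export
decision_scores <- function(model, newX) {
  pred <- stats::predict(model$fit, newX, decision.values = TRUE)
  dv <- attr(pred, "decision.values")
  # libsvm reports the decision value for colname "A/B" as favoring A.
  sgn <- if (startsWith(colnames(dv)[1], "positive")) 1 else -1
  as.numeric(dv[, 1]) * sgn
}

#' ROC curve from decision scores
#'
#' Thresholds sweep the unique scores in descending order; tied scores are
#' grouped into a single step. The curve starts at (0, 0) and ends at
#' (1, 1) with both coordinates non-decreasing.
#'
#' @param scores Real-valued decision scores (higher = more positive).
#' @param labels Labels (`"positive"` / `"negative"`), both present.
#' @return Data frame with columns `fpr`, `tpr`.
#' @export
roc_curve <- function(scores, labels) {
  pos <- as.character(labels) == "positive"
  if (!any(pos) || all(pos))
    stop("ROC requires both positive and negative labels")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  p <- pos[ord]
  ends <- which(c(s[-1] != s[-length(s)], TRUE))  # last index per tie block
  tpr <- c(0, cumsum(p)[ends] / sum(pos))
  fpr <- c(0, cumsum(!p)[ends] / sum(!pos))
  data.frame(fpr = fpr, tpr = tpr)
}

#' Area under the ROC curve
#'
#' Trapezoidal area; with tie-grouped thresholds this equals the pairwise
#' (rank-sum) statistic, ties counted one half.
#'
#' @param roc A data frame from [roc_curve()].
#' @return Area in \[0, 1\].
#' @export
auroc <- function(roc) {
  sum(diff(roc$fpr) * (roc$tpr[-nrow(roc)] + roc$tpr[-1]) / 2)
}

#' @rdname auroc
#' @inheritParams roc_curve
#' @export
auroc_scores <- function(scores, labels) auroc(roc_curve(scores, labels))

#' Jackknife (leave-one-out) evaluation of a feature matrix
#'
#' Each of the n samples is scored by an SVM trained on the other n - 1;
#' ROC and auROC are computed from the n held-out decision scores.
#'
#' @param X Numeric sample-by-feature matrix (n >= 3).
#' @param y Labels, both classes present.
#' @param config An [svm_config()].
#' @return Object of class `EvalResult`: `scores`, `labels`, `roc`,
#'   `auroc`, `config`.
#' @export
jackknife_eval <- function(X, y, config = svm_config()) {
  n <- nrow(X)
  if (n < 3L) stop("jackknife needs at least 3 samples")
  scores <- numeric(n)
  for (i in seq_len(n)) {
    model <- train(X[-i, , drop = FALSE], y[-i], config)
    scores[i] <- decision_scores(model, X[i, , drop = FALSE])
  }
  eval_result(scores, y, config)
}

eval_result <- function(scores, labels, config) {
  roc <- roc_curve(scores, labels)
  structure(list(scores = scores, labels = as.character(labels), roc = roc,
                 auroc = auroc(roc), config = config),
            class = "EvalResult")
}

#' @export
print.EvalResult <- function(x, ...) {
  cat(sprintf("<EvalResult: n = %d, auROC = %.3f (C = %g, gamma = %g)>\n",
              length(x$scores), x$auroc, x$config$C, x$config$gamma))
  invisible(x)
}

#' Jackknife evaluation on windows with per-fold PWM rebuilding
#'
#' Like [jackknife_eval()] but operating on labeled windows: the F1
#' position-scoring features are rebuilt inside every leave-one-out fold
#' from a PWM pair that excludes the held-out window, so no label
#' information leaks into the held-out F1 features. Groups F2-F4 are
#' window-intrinsic and computed once.
#'
#' @param positives,negatives Labeled window lists (total n >= 3).
#' @param config A [window_config()].
#' @param groups Feature groups to use.
#' @param svm An [svm_config()].
#' @param table Property table.
#' @param p0,alpha PWM background and pseudocount.
#' @return An `EvalResult`.
#' @export
jackknife_windows <- function(positives, negatives, config = window_config(),
                              groups = c("F1", "F2", "F3", "F4"),
                              svm = svm_config(), table = aa_property_table(),
                              p0 = 0.05, alpha = 1) {
  windows <- c(positives, negatives)
  n <- length(windows)
  if (n < 3L) stop("jackknife needs at least 3 samples")
  y <- c(rep("positive", length(positives)), rep("negative", length(negatives)))
  fixed_groups <- setdiff(groups, "F1")
  fixed <- if (length(fixed_groups)) {
    assemble_features(windows, config, table = table,
                      groups = fixed_groups)$X
  } else NULL
  use_f1 <- "F1" %in% groups
  if (use_f1) {
    L <- nchar(windows[[1]]$residues)
    sel_offs <- flank_offsets(config$w1)
    sel_cols <- match(sel_offs, window_offsets(L))
    # residue index matrix (n x w1 columns), NA for X
    R <- windows_residue_matrix(windows)[, sel_cols, drop = FALSE]
    Ridx <- matrix(match(R, AA20), nrow = n)
    cpos <- residue_counts(positives)
    cneg <- residue_counts(negatives)
    per_window_counts <- function(w) residue_counts(list(w))
  }
  scores <- numeric(n)
  for (i in seq_len(n)) {
    if (use_f1) {
      cp <- cpos
      cn <- cneg
      dec <- per_window_counts(windows[[i]])
      if (y[i] == "positive") cp <- cp - dec else cn <- cn - dec
      D <- pwm_from_counts(cp, p0, alpha) - pwm_from_counts(cn, p0, alpha)
      Dsel <- D[, sel_cols, drop = FALSE]
      F1 <- matrix(0, n, length(sel_cols),
                   dimnames = list(NULL, paste0("F1:score:", sel_offs)))
      for (j in seq_along(sel_cols)) {
        idx <- Ridx[, j]
        ok <- !is.na(idx)
        F1[ok, j] <- Dsel[idx[ok], j]
      }
      Xfold <- if (is.null(fixed)) F1 else cbind(F1, fixed)
    } else {
      Xfold <- fixed
    }
    model <- train(Xfold[-i, , drop = FALSE], y[-i], svm)
    scores[i] <- decision_scores(model, Xfold[i, , drop = FALSE])
  }
  eval_result(scores, y, svm)
}

#' Exhaustive (C, gamma) grid search
#'
#' Evaluates every grid pair with the supplied evaluator (default:
#' jackknife auROC) and returns the best pair; ties break toward smaller C,
#' then smaller gamma.
#'
#' @param X Numeric sample-by-feature matrix.
#' @param y Labels.
#' @param config An [svm_config()] supplying the grids.
#' @param evaluator Function `(X, y, config) -> auROC`.
#' @return List with `C`, `gamma`, `auroc` and the full `grid` data frame.
#' @export
grid_search <- function(X, y, config = svm_config(), evaluator = NULL) {
  if (is.null(evaluator))
    evaluator <- function(X, y, cfg) jackknife_eval(X, y, cfg)$auroc
  grid <- expand.grid(C = config$C_grid, gamma = config$gamma_grid,
                      KEEP.OUT.ATTRS = FALSE)
  grid <- grid[order(grid$C, grid$gamma), ]
  grid$auroc <- NA_real_
  best <- list(C = NA_real_, gamma = NA_real_, auroc = -Inf)
  for (r in seq_len(nrow(grid))) {
    cfg <- svm_config(C = grid$C[r], gamma = grid$gamma[r],
                      C_grid = config$C_grid, gamma_grid = config$gamma_grid)
    a <- evaluator(X, y, cfg)
    grid$auroc[r] <- a
    if (a > best$auroc) best <- list(C = grid$C[r], gamma = grid$gamma[r],
                                     auroc = a)
  }
  rownames(grid) <- NULL
  c(best, list(grid = grid))
}
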