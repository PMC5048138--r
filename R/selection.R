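#' Three-state discretization of a feature
#'
#' Values are cut at mean +/- sigma (population standard deviation), with
#' inclusive boundaries: at or below `mean - sigma` is low (1), at or above
#' `mean + sigma` is high (3), otherwise mid (2). Inclusive cuts keep
#' two-valued features informative (a balanced binary feature splits into
#' low/high rather than collapsing to mid). Constant features discretize to
#' all-mid; the scheme is invariant under affine transforms of the feature.
#'
#' @param x Numeric vector, length >= 2.
#' @return Integer codes in `{1, 2, 3}`.
#' @export
discretize <- function(x) {
  if (length(x) < 2L) stop("need at least 2 samples")
  mu <- mean(x)
  sigma <- sqrt(mean((x - mu)^2))
  if (sigma == 0) return(rep(2L, length(x)))
  codes <- rep(2L, length(x))
  codes[x <= mu - sigma] <- 1L
  codes[x >= mu + sigma] <- 3L
  codes
}

#' Plug-in mutual information between two code vectors
#'
#' MI in bits from the joint contingency table, with `0 * log(0) := 0`.
#'
#' @param cx,cy Discrete code vectors of equal length.
#' @return Mutual information in bits (>= 0 up to floating error).
#' @export
mutual_information <- function(cx, cy) {
  if (length(cx) != length(cy)) stop("code vectors must have equal length")
  joint <- table(cx, cy) / length(cx)
  px <- rowSums(joint)
  py <- colSums(joint)
  outer_p <- outer(px, py)
  nz <- joint > 0
  sum(joint[nz] * log2(joint[nz] / outer_p[nz]))
}

#' mRMR feature ranking (MID criterion)
#'
#' Features are discretized (see [discretize()]) and ranked greedily: the
#' first feature maximizes relevance I(f; y); each subsequent feature
#' maximizes relevance minus the mean mutual information with the features
#' already selected (the "mutual information difference" criterion). Ties
#' break toward the lower feature index.
#'
#' @param X Numeric sample-by-feature matrix (>= 2 features).
#' @param y Class labels.
#' @return Object of class `MrmrRanking`: `order` (a permutation of feature
#'   indices), `relevance` (per-feature MI with the class, input order),
#'   `scheme = "MID"`, and feature `names`.
#' @export
mrmr_rank <- function(X, y) {
  p <- ncol(X)
  if (p < 2L) stop("need at least 2 features")
  codes <- apply(X, 2L, discretize)
  ycode <- as.integer(factor(y))
  relevance <- apply(codes, 2L, mutual_information, cy = ycode)
  selected <- integer(0)
  remaining <- seq_len(p)
  red_sum <- numeric(p)  # sum of MI with already-selected features
  for (step in seq_len(p)) {
    score <- if (length(selected) == 0L) relevance[remaining]
             else relevance[remaining] - red_sum[remaining] / length(selected)
    pick <- remaining[which.max(score)]  # which.max: first max = lowest index
    selected <- c(selected, pick)
    remaining <- setdiff(remaining, pick)
    if (length(remaining))
      red_sum[remaining] <- red_sum[remaining] +
        apply(codes[, remaining, drop = FALSE], 2L, mutual_information,
              cy = codes[, pick])
  }
  structure(list(order = selected, relevance = unname(relevance),
                 scheme = "MID", names = colnames(X)),
            class = "MrmrRanking")
}

#' @export
print.MrmrRanking <- function(x, ...) {
  cat(sprintf("<MrmrRanking (%s) of %d features; top: %s>\n", x$scheme,
              length(x$order),
              paste(utils::head(if (is.null(x$names)) x$order
                                else x$names[x$order], 3L), collapse = ", ")))
  invisible(x)
}

#' Incremental feature selection along a ranking
#'
#' Evaluates every nested prefix of the ranking (k = 1..n features) with
#' the supplied evaluator and reports the auROC curve and the best prefix
#' length (maximal auROC, ties toward smaller k).
#'
#' @param X Numeric sample-by-feature matrix.
#' @param y Class labels.
#' @param ranking An [mrmr_rank()] result or an integer permutation.
#' @param evaluator Function `(X_subset, y) -> auROC` (typically a
#'   jackknife SVM evaluation).
#' @return Object of class `IfsCurve`: `k`, `auroc`, `best_k`.
#' @export
ifs <- function(X, y, ranking, evaluator) {
  ord <- if (inherits(ranking, "MrmrRanking")) ranking$order else ranking
  stopifnot(length(ord) == ncol(X), !anyDuplicated(ord))
  auroc <- numeric(length(ord))
  for (k in seq_along(ord)) {
    auroc[k] <- tryCatch(evaluator(X[, ord[seq_len(k)], drop = FALSE], y),
                         error = function(e)
                           stop("evaluator failed at k = ", k, ": ",
                                conditionMessage(e)))
  }
  structure(list(k = seq_along(ord), auroc = auroc,
                 best_k = which.max(auroc)),  # first max = smallest k
            class = "IfsCurve")
}

#' @export
print.IfsCurve <- function(x, ...) {
  cat(sprintf("<IfsCurve over %d subsets; peak auROC %.3f at k = %d>\n",
              length(x$k), x$auroc[x$best_k], x$best_k))
  invisible(x)
}
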