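# Brute-force auROC: the pairwise (rank-sum) statistic with ties = 1/2.
brute_auroc <- function(scores, labels) {
  pos <- scores[labels == "positive"]
  neg <- scores[labels == "negative"]
  total <- 0
  for (p in pos) for (n in neg)
    total <- total + (p > n) + 0.5 * (p == n)
  total / (length(pos) * length(neg))
}

# Independent exhaustive greedy mRMR (MID) oracle. MI computed through the
# entropy identity I(X;Y) = H(X) + H(Y) - H(X,Y); redundancy re-derived
# from scratch at every step (no incremental bookkeeping).
oracle_entropy <- function(v) {
  p <- table(v) / length(v)
  -sum(p * log2(p))
}
oracle_mi <- function(x, y) {
  oracle_entropy(x) + oracle_entropy(y) -
    oracle_entropy(paste(x, y, sep = "|"))
}
oracle_mrmr <- function(X, y) {
  codes <- apply(X, 2L, discretize)
  ycode <- as.integer(factor(y))
  p <- ncol(X)
  selected <- integer(0)
  while (length(selected) < p) {
    remaining <- setdiff(seq_len(p), selected)
    best <- NA_integer_
    best_score <- -Inf
    for (j in remaining) {
      rel <- oracle_mi(codes[, j], ycode)
      red <- if (length(selected) == 0L) 0
             else mean(vapply(selected, function(s)
               oracle_mi(codes[, j], codes[, s]), numeric(1)))
      score <- rel - red
      if (score > best_score + 1e-12) {
        best_score <- score
        best <- j
      }
    }
    selected <- c(selected, best)
  }
  selected
}
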