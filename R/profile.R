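# Residue characters of a window list as an n x L character matrix.
windows_residue_matrix <- function(windows) {
  do.call(rbind, lapply(windows, function(w)
    strsplit(w$residues, "", fixed = TRUE)[[1]]))
}

# Column offsets for a window of length L (center = 0).
window_offsets <- function(L) seq_len(L) - (L + 1L) %/% 2L

#' Per-position residue frequencies and conservation
#'
#' For each position l of a window set, computes the residue frequency
#' vector f_i(l) over the 20 standard residues (padding/unknown `X` is
#' excluded from both numerator and denominator) and the conservation value
#'
#'   M(l) = sum_i f_i(l) * log2( f_i(l) / p0 ),   0*log(0) := 0,
#'
#' the relative entropy of the observed distribution against a uniform
#' background p0. M(l) = 0 exactly when all residues occur at the background
#' frequency; larger M(l) means stronger positional conservation.
#'
#' @param windows Non-empty list of equal-length [residue_window()]s.
#' @param p0 Background frequency per residue (default 0.05 = 1/20).
#' @return Object of class `PositionProfile`: `freqs` (20 x L), `M`
#'   (length L, `NA` for all-X columns), `empty` (logical flags), `p0`, `L`.
#' @export
position_conservation <- function(windows, p0 = 0.05) {
  if (length(windows) == 0L) stop("need at least one window")
  mat <- windows_residue_matrix(windows)
  L <- ncol(mat)
  freqs <- matrix(0, 20L, L, dimnames = list(AA20, window_offsets(L)))
  M <- numeric(L)
  empty <- logical(L)
  for (l in seq_len(L)) {
    col <- mat[, l]
    col <- col[col != "X"]
    if (length(col) == 0L) {
      empty[l] <- TRUE
      M[l] <- NA_real_
      next
    }
    f <- tabulate(factor(col, levels = AA20), nbins = 20L) / length(col)
    freqs[, l] <- f
    nz <- f > 0
    M[l] <- sum(f[nz] * log2(f[nz] / p0))
  }
  structure(list(freqs = freqs, M = M, empty = empty, p0 = p0, L = L),
            class = "PositionProfile")
}

# Raw residue counts (20 x L) over a window list, X excluded.
residue_counts <- function(windows) {
  mat <- windows_residue_matrix(windows)
  L <- ncol(mat)
  counts <- matrix(0L, 20L, L, dimnames = list(AA20, window_offsets(L)))
  for (l in seq_len(L)) {
    col <- mat[, l]
    counts[, l] <- tabulate(factor(col[col != "X"], levels = AA20),
                            nbins = 20L)
  }
  counts
}

# PWM weights from a count matrix: log2 of pseudocount-smoothed frequency
# over background. With counts n_xl, column totals N_l, pseudocount alpha:
#   w(x,l) = log2( (n_xl + alpha*p0*N_l) / ((N_l + alpha*N_l*sum(p0)) * p0) )
pwm_from_counts <- function(counts, p0 = 0.05, alpha = 1,
                            allow_infinite = FALSE) {
  N <- colSums(counts)
  sum_p0 <- 20 * p0
  W <- matrix(0, nrow(counts), ncol(counts), dimnames = dimnames(counts))
  nz <- N > 0
  if (any(nz)) {
    num <- sweep(counts[, nz, drop = FALSE], 2L, alpha * p0 * N[nz], `+`)
    den <- (N[nz] + alpha * N[nz] * sum_p0) * p0
    W[, nz] <- log2(sweep(num, 2L, den, `/`))
  }
  if (any(is.infinite(W))) {
    if (!allow_infinite)
      stop("zero counts with alpha = 0 produce -Inf weights; ",
           "set allow_infinite = TRUE or use alpha > 0")
  }
  W
}

#' Build a position weight matrix from a window set
#'
#' Weights are log2 ratios of pseudocount-smoothed residue frequency over a
#' uniform background: a column whose counts are exactly background-
#' distributed has all-zero weights (for `alpha = 0`), and `alpha > 0`
#' keeps every weight finite on sparse data. All-X (padding-only) columns
#' get zero weights.
#'
#' @param windows Non-empty list of equal-length windows.
#' @param p0 Background frequency (default 0.05).
#' @param alpha Pseudocount weight; the pseudocount added to residue x is
#'   `alpha * p0 * N_l`.
#' @param allow_infinite With `alpha = 0`, allow `-Inf` for zero counts
#'   instead of raising an error.
#' @return 20 x L numeric matrix (rows = residues, columns = offsets).
#' @export
build_pwm <- function(windows, p0 = 0.05, alpha = 1, allow_infinite = FALSE) {
  if (length(windows) == 0L) stop("need at least one window")
  pwm_from_counts(residue_counts(windows), p0, alpha, allow_infinite)
}

#' Positive/negative PWM pair
#'
#' @param positives,negatives Window lists for the two classes.
#' @inheritParams build_pwm
#' @return Object of class `PWMPair` with elements `pos`, `neg`, `p0`,
#'   `alpha`, `offsets`.
#' @export
pwm_pair <- function(positives, negatives, p0 = 0.05, alpha = 1) {
  pos <- build_pwm(positives, p0, alpha)
  neg <- build_pwm(negatives, p0, alpha)
  if (!identical(dim(pos), dim(neg)))
    stop("positive and negative windows have different lengths")
  structure(list(pos = pos, neg = neg, p0 = p0, alpha = alpha,
                 offsets = as.integer(colnames(pos))),
            class = "PWMPair")
}

#' Position scoring of a query window against a PWM pair
#'
#' For the residue x_l observed at offset l of the query (l = -flank..-1,
#' +1..+flank; the invariant central threonine is excluded), the score is
#'
#'   F(l) = pos_pwm[x_l, l] - neg_pwm[x_l, l].
#'
#' Positive values indicate that offset resembles phosphorylated contexts.
#' Padding/unknown (`X`) scores 0.
#'
#' @param window A [residue_window()].
#' @param pair A [pwm_pair()].
#' @param flank Offsets per side to score; must be covered by the PWMs.
#' @return Named numeric vector of length `2*flank` (offsets in increasing
#'   order, 0 omitted).
#' @export
score_peptide <- function(window, pair, flank) {
  stopifnot(inherits(pair, "PWMPair"))
  offs <- c(-(flank:1), 1:flank)
  if (!all(offs %in% pair$offsets))
    stop("flank ", flank, " exceeds the PWM width (",
         max(pair$offsets), ")")
  chars <- strsplit(window$residues, "", fixed = TRUE)[[1]]
  w_offs <- window_offsets(length(chars))
  if (!all(offs %in% w_offs)) stop("flank exceeds the window length")
  D <- pair$pos - pair$neg
  out <- numeric(length(offs))
  for (i in seq_along(offs)) {
    x <- chars[match(offs[i], w_offs)]
    out[i] <- if (x == "X") 0 else D[x, as.character(offs[i])]
  }
  names(out) <- as.character(offs)
  out
}

#' Per-offset descriptive statistics for both classes
#'
#' Tabulates, for every offset of the window and separately for positives
#' and negatives: the 3-state secondary-structure frequencies (over non-X
#' states), mean accessibility, the mean of each physicochemical property
#' (raw table values, X excluded), and the conservation M(l).
#'
#' @param positives,negatives Non-empty window lists.
#' @param property_table 20 x 9 property matrix (see [aa_property_table()]).
#' @param p0 Background frequency for M(l).
#' @return Data frame with one row per (offset, class).
#' @export
positional_stats <- function(positives, negatives,
                             property_table = aa_property_table(),
                             p0 = 0.05) {
  if (length(positives) == 0L || length(negatives) == 0L)
    stop("both classes must be non-empty")
  one_class <- function(windows, cls) {
    res <- windows_residue_matrix(windows)
    ssm <- do.call(rbind, lapply(windows, function(w)
      strsplit(w$ss, "", fixed = TRUE)[[1]]))
    accm <- do.call(rbind, lapply(windows, function(w) w$acc))
    L <- ncol(res)
    prof <- position_conservation(windows, p0)
    rows <- lapply(seq_len(L), function(l) {
      sscol <- ssm[, l]
      sscol <- sscol[sscol != "X"]
      ssf <- if (length(sscol)) {
        tabulate(factor(sscol, levels = c("H", "E", "C")), 3L) / length(sscol)
      } else rep(NA_real_, 3L)
      rescol <- res[, l]
      rescol <- rescol[rescol != "X"]
      pm <- if (length(rescol)) {
        colMeans(property_table[rescol, , drop = FALSE])
      } else stats::setNames(rep(NA_real_, ncol(property_table)),
                             colnames(property_table))
      c(list(offset = window_offsets(L)[l], class = cls,
             freq_H = ssf[1], freq_E = ssf[2], freq_C = ssf[3],
             mean_acc = mean(accm[, l]), M = prof$M[l]),
        as.list(stats::setNames(pm, paste0("mean_", names(pm)))))
    })
    do.call(rbind, lapply(rows, function(r) as.data.frame(r)))
  }
  out <- rbind(one_class(positives, "positive"),
               one_class(negatives, "negative"))
  rownames(out) <- NULL
  out
}
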