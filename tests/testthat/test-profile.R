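# 20 windows of length 3: left flank runs through all 20 residues (uniform
# column), right flank is always A (degenerate column).
uniform_degenerate_windows <- function() {
  lapply(AA20_test, function(a)
    mk_window(paste0(a, "TA"), center_pos = 2L))
}

test_that("position conservation is zero on uniform and log2(20) on degenerate columns", {
  prof <- position_conservation(uniform_degenerate_windows())
  expect_equal(prof$M[1], 0)                 # uniform at p0 = 0.05
  expect_equal(prof$M[2], log2(20))          # all-T center, single residue
  expect_equal(prof$M[3], log2(20))          # all-A column
  expect_equal(colnames(prof$freqs), c("-1", "0", "1"))

  # column {A: 0.5, C: 0.5} -> 2 * 0.5 * log2(0.5 / 0.05)
  half <- c(lapply(1:5, function(i) mk_window("ATA", center_pos = 2L)),
            lapply(1:5, function(i) mk_window("CTA", center_pos = 2L)))
  prof2 <- position_conservation(half)
  expect_equal(prof2$M[1], 2 * 0.5 * log2(0.5 / 0.05))

  expect_error(position_conservation(list()), "at least one")
})

test_that("conservation is non-negative over random profiles and flags all-X columns", {
  set.seed(5)
  for (rep in 1:10) {
    windows <- replicate(15, random_window(11), simplify = FALSE)
    prof <- position_conservation(windows)
    expect_true(all(prof$M >= -1e-12))
  }
  padded <- lapply(1:4, function(i)
    mk_window(paste0("XX", sample(AA20_test, 1), "T",
                     sample(AA20_test, 1), "XX"),
              center_pos = 4L))
  prof <- position_conservation(padded)
  expect_true(all(prof$empty[c(1, 2, 6, 7)]))
  expect_true(all(is.na(prof$M[c(1, 2, 6, 7)])))
})

test_that("PWM weights are zero at background, match hand-smoothed values, and ignore duplication", {
  # counts uniform at N_l * p0 (one window per residue), alpha = 0; the
  # degenerate T/A columns need allow_infinite for their zero counts
  pwm0 <- build_pwm(uniform_degenerate_windows(), alpha = 0,
                    allow_infinite = TRUE)
  expect_equal(unname(pwm0[, 1]), rep(0, 20))

  # single sequence with A at offset -1, alpha = 1:
  # log2((1 + 0.05) / (2 * 0.05))
  one <- list(mk_window("ATA", center_pos = 2L))
  pwm1 <- build_pwm(one, alpha = 1)
  expect_equal(pwm1["A", "-1"], log2(1.05 / 0.1))

  # duplicating every window leaves the PWM unchanged
  windows <- replicate(8, random_window(7), simplify = FALSE)
  expect_equal(build_pwm(windows), build_pwm(c(windows, windows)))

  # alpha = 0 with zero counts: error unless -Inf explicitly allowed
  expect_error(build_pwm(one, alpha = 0), "-Inf")
  inf_pwm <- build_pwm(one, alpha = 0, allow_infinite = TRUE)
  expect_equal(inf_pwm["C", "-1"], -Inf)
})

test_that("position scoring is the positive-minus-negative PWM lookup", {
  set.seed(8)
  pos <- replicate(10, random_window(7), simplify = FALSE)
  neg <- replicate(10, random_window(7), simplify = FALSE)

  # identical classes -> identically zero scores
  same <- pwm_pair(pos, pos)
  w <- random_window(7)
  expect_equal(unname(score_peptide(w, same, 3)), rep(0, 6))

  # all-X flanks -> zero scores (padding neutrality)
  pair <- pwm_pair(pos, neg)
  xw <- mk_window("XXXTXXX", center_pos = 4L)
  expect_equal(unname(score_peptide(xw, pair, 3)), rep(0, 6))

  # hand-filled toy PWM pair over offsets -1..+1: F = pos - neg at the
  # observed residue
  toy <- pair
  toy$pos[, ] <- 0
  toy$neg[, ] <- 0
  toy$pos["A", "-1"] <- 1
  toy$neg["A", "-1"] <- -1
  toy$neg["G", "1"] <- 2.5
  tw <- mk_window("ATG", center_pos = 2L)
  expect_equal(unname(score_peptide(tw, toy, 1)), c(1 - (-1), 0 - 2.5))

  # flank wider than the PWM
  expect_error(score_peptide(w, pair, 5), "exceeds")
})

test_that("label-swapped PWM training exactly negates the score vector", {
  set.seed(13)
  pos <- replicate(12, random_window(), simplify = FALSE)
  neg <- replicate(12, random_window(), simplify = FALSE)
  fwd <- pwm_pair(pos, neg)
  rev <- pwm_pair(neg, pos)
  for (i in 1:5) {
    w <- random_window()
    expect_equal(score_peptide(w, rev, 6), -score_peptide(w, fwd, 6))
  }
})

test_that("positional statistics tabulate both classes and swap symmetrically", {
  coil <- replicate(6, {
    w <- random_window(11)
    w$acc <- rep(1, 11)
    w
  }, simplify = FALSE)
  st <- positional_stats(coil, coil)
  expect_equal(st$freq_C, rep(1, nrow(st)))
  expect_equal(st$mean_acc, rep(1, nrow(st)))

  set.seed(21)
  pos <- replicate(8, random_window(11), simplify = FALSE)
  neg <- replicate(8, random_window(11), simplify = FALSE)
  a <- positional_stats(pos, neg)
  b <- positional_stats(neg, pos)
  swap <- function(df) {
    df$class <- ifelse(df$class == "positive", "negative", "positive")
    df
  }
  a2 <- swap(a)
  b2 <- b[order(b$class, b$offset), ]
  a2 <- a2[order(a2$class, a2$offset), ]
  rownames(a2) <- rownames(b2) <- NULL
  expect_equal(a2, b2)
})
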