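# Build a ResidueWindow from strings; defaults: all-coil ss, zero acc.
mk_window <- function(residues, ss = NULL, acc = NULL,
                      label = NA_character_, id = "p", center_pos = 16L) {
  L <- nchar(residues)
  if (is.null(ss)) ss <- strrep("C", L)
  if (is.null(acc)) acc <- rep(0, L)
  residue_window(id, center_pos, residues, ss, acc, label)
}

# Random threonine-centered window (uniform flanks over the 20 residues).
random_window <- function(L = 31L, label = NA_character_) {
  chars <- sample(AA20_test, L, replace = TRUE)
  chars[(L + 1L) %/% 2L] <- "T"
  mk_window(paste(chars, collapse = ""), label = label,
            acc = stats::runif(L))
}

AA20_test <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
               "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Generate a balanced synthetic dataset at the given seed/signal.
sim_dataset <- function(n_pos, n_neg, seed, signal = "strong", ...) {
  sim <- generate(generator_params(n_pos = n_pos, n_neg = n_neg,
                                   seed = seed, signal = signal, ...))
  suppressMessages(build_dataset(sim$proteins, sim$sites))
}
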