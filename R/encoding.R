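# Feature-group property sets (F3 = physical, F4 = chemical).
F3_PROPERTIES <- c("rigidity", "flexibility", "irreplaceability")
F4_PROPERTIES <- c("hydrophobicity", "hydrophilicity", "mass", "pk1", "pk2",
                   "pi")

# Secondary-structure scalar encoding; X (padding) sits at the midpoint.
SS_CODE <- c(H = 0.0, E = 0.5, C = 1.0, X = 0.5)

#' Load the amino-acid physicochemical property table
#'
#' Nine properties per residue: rigidity, flexibility, irreplaceability
#' (physical group) and hydrophobicity, hydrophilicity, mass, pk1, pk2, pi
#' (chemical group). The packaged TSV documents the provenance of each
#' column and can be replaced by the user.
#'
#' @param path Path to a property TSV (default: the packaged table).
#' @return 20 x 9 numeric matrix, rownames = residues.
#' @export
aa_property_table <- function(path = system.file("extdata",
                                                 "aa_properties.tsv",
                                                 package = "phosT")) {
  tab <- utils::read.delim(path, comment.char = "#",
                           stringsAsFactors = FALSE)
  props <- c(F3_PROPERTIES, F4_PROPERTIES)
  if (!all(c("aa", props) %in% names(tab)))
    stop("property table must have columns aa, ",
         paste(props, collapse = ", "))
  if (!setequal(tab$aa, AA20))
    stop("property table must cover exactly the 20 standard residues")
  m <- as.matrix(tab[props])
  rownames(m) <- tab$aa
  m[AA20, , drop = FALSE]
}

# Min-max scale each property column over the 20 residues.
scale_property_table <- function(table) {
  apply(table, 2L, function(v) (v - min(v)) / (max(v) - min(v)))
}

# Signed flanking offsets for a window size w (w/2 per side, center excluded).
flank_offsets <- function(w) {
  if (w %% 2L != 0L || w < 2L || w > 30L)
    stop("window size must be even and between 2 and 30, got ", w)
  c(-(w %/% 2L):-1L, 1L:(w %/% 2L))
}

# Characters of a window at the given signed offsets.
window_chars_at <- function(window, offsets, what = c("residues", "ss")) {
  what <- match.arg(what)
  chars <- strsplit(window[[what]], "", fixed = TRUE)[[1]]
  offs <- window_offsets(length(chars))
  if (!all(offsets %in% offs))
    stop("window size exceeds the available flank of the window")
  chars[match(offsets, offs)]
}

#' Encode secondary structure and accessibility (feature group F2)
#'
#' For each of the `w` flanking offsets (w/2 per side, center excluded) two
#' values are emitted: the secondary-structure scalar (H = 0, E = 0.5,
#' C = 1, X = 0.5) and the accessibility scaled to \[0, 1\] by a
#' dataset-wide maximum (X positions contribute 0).
#'
#' @param window A [residue_window()].
#' @param w Even window size (total flanking residues, 2..30).
#' @param acc_max Dataset-wide accessibility maximum used for scaling.
#' @return Named numeric vector of length `2*w`
#'   (`F2:ss:<offset>`, `F2:acc:<offset>` interleaved by offset).
#' @export
encode_structure <- function(window, w, acc_max = 1) {
  offs <- flank_offsets(w)
  sschr <- window_chars_at(window, offs, "ss")
  accv <- window$acc[match(offs, window_offsets(length(window$acc)))]
  accv <- if (acc_max > 0) pmin(accv / acc_max, 1) else rep(0, length(accv))
  out <- as.vector(rbind(SS_CODE[sschr], accv))
  names(out) <- as.vector(rbind(paste0("F2:ss:", offs),
                                paste0("F2:acc:", offs)))
  out
}

#' Encode physicochemical properties (feature groups F3/F4)
#'
#' For each flanking offset and each requested property, emits the
#' min-max-scaled table value of the residue observed there; X (padding or
#' unknown) encodes as 0.5, the scale midpoint.
#'
#' @param window A [residue_window()].
#' @param w Even window size (total flanking residues, 2..30).
#' @param properties Character vector of property names drawn from the
#'   table's nine columns.
#' @param table Property table (see [aa_property_table()]).
#' @return Named numeric vector of length `length(properties) * w`, ordered
#'   by offset then property (`F?:<property>:<offset>`).
#' @export
encode_physchem <- function(window, w, properties,
                            table = aa_property_table()) {
  unknown <- setdiff(properties, colnames(table))
  if (length(unknown))
    stop("unknown property name(s): ", paste(unknown, collapse = ", "))
  offs <- flank_offsets(w)
  chars <- window_chars_at(window, offs, "residues")
  scaled <- scale_property_table(table)
  group <- ifelse(properties %in% F3_PROPERTIES, "F3", "F4")
  vals <- matrix(0.5, length(properties), length(offs))
  known <- chars != "X"
  if (any(known))
    vals[, known] <- t(scaled[chars[known], properties, drop = FALSE])
  out <- as.vector(vals)  # offset-major: all properties at offset 1, then 2, ...
  names(out) <- as.vector(vapply(offs, function(o)
    paste0(group, ":", properties, ":", o), character(length(properties))))
  out
}

#' Window-size configuration for the four feature groups
#'
#' Each group has its own even window size (total flanking residues, the
#' central threonine excluded): `w1` for the PWM position-scoring group F1,
#' `w2` for structure/accessibility F2, `w3` for the physical properties F3,
#' `w4` for the chemical properties F4. The full feature dimension is
#' `w1 + 2*w2 + 3*w3 + 6*w4`; the defaults (12, 12, 24, 18) give 216.
#'
#' @param w1,w2,w3,w4 Even integers in 2..30.
#' @return Object of class `WindowConfig`.
#' @export
window_config <- function(w1 = 12L, w2 = 12L, w3 = 24L, w4 = 18L) {
  for (w in c(w1, w2, w3, w4)) flank_offsets(w)  # validates
  structure(list(w1 = as.integer(w1), w2 = as.integer(w2),
                 w3 = as.integer(w3), w4 = as.integer(w4)),
            class = "WindowConfig")
}

#' @export
print.WindowConfig <- function(x, ...) {
  cat(sprintf("<WindowConfig F1=%d F2=%d F3=%d F4=%d -> %d features>\n",
              x$w1, x$w2, x$w3, x$w4, feature_dimension(x)))
  invisible(x)
}

#' @rdname window_config
#' @param config A `WindowConfig`.
#' @param groups Feature groups included.
#' @return `feature_dimension` returns the total feature count.
#' @export
feature_dimension <- function(config, groups = c("F1", "F2", "F3", "F4")) {
  sum(c(F1 = config$w1, F2 = 2L * config$w2, F3 = 3L * config$w3,
        F4 = 6L * config$w4)[groups])
}

#' Assemble the full feature matrix for a window set
#'
#' Concatenates, per window, the four feature groups in order: F1 (PWM
#' position-score differences at flank `w1/2`), F2 (structure +
#' accessibility), F3 (physical properties), F4 (chemical properties).
#'
#' @param windows List of labeled [residue_window()]s.
#' @param config A [window_config()].
#' @param pair A [pwm_pair()] (required when F1 is included).
#' @param table Property table.
#' @param acc_max Accessibility scaling maximum; defaults to the maximum
#'   over the supplied windows.
#' @param groups Subset of `c("F1","F2","F3","F4")` to encode.
#' @return A `FeatureMatrix` (see [write_feature_matrix()]).
#' @export
assemble_features <- function(windows, config, pair = NULL,
                              table = aa_property_table(), acc_max = NULL,
                              groups = c("F1", "F2", "F3", "F4")) {
  stopifnot(inherits(config, "WindowConfig"), length(windows) > 0L)
  groups <- match.arg(groups, several.ok = TRUE)
  if ("F1" %in% groups) {
    if (is.null(pair)) stop("group F1 requires a PWM pair")
    if (!all(flank_offsets(config$w1) %in% pair$offsets))
      stop("F1 window size ", config$w1, " exceeds the PWM width")
  }
  if (is.null(acc_max))
    acc_max <- max(vapply(windows, function(w) max(w$acc), numeric(1)))
  encode_one <- function(w) {
    parts <- list()
    if ("F1" %in% groups) {
      f1 <- score_peptide(w, pair, config$w1 %/% 2L)
      names(f1) <- paste0("F1:score:", names(f1))
      parts$F1 <- f1
    }
    if ("F2" %in% groups) parts$F2 <- encode_structure(w, config$w2, acc_max)
    if ("F3" %in% groups)
      parts$F3 <- encode_physchem(w, config$w3, F3_PROPERTIES, table)
    if ("F4" %in% groups)
      parts$F4 <- encode_physchem(w, config$w4, F4_PROPERTIES, table)
    unlist(parts, use.names = TRUE)
  }
  rows <- lapply(windows, encode_one)
  X <- do.call(rbind, rows)
  colnames(X) <- sub("^F[1-4]\\.", "", colnames(X))  # drop unlist() prefixes
  y <- vapply(windows, function(w) w$label, character(1))
  fm <- feature_matrix(X, y, config)
  fm$acc_max <- acc_max
  fm
}

#' Sweep the window size of one feature group
#'
#' Encodes the chosen group alone at each candidate size, evaluates each
#' encoding with the supplied jackknife-auROC evaluator, and returns the
#' size attaining the maximal auROC (ties broken toward the smaller size)
#' together with the full size/auROC curve.
#'
#' @param positives,negatives Labeled window lists.
#' @param group One of `"F1".."F4"`.
#' @param sizes Candidate even sizes (default 10, 12, ..., 30).
#' @param evaluator Function `(positives, negatives, config, groups) ->
#'   auROC`; defaults to [jackknife_windows()] with the default SVM
#'   configuration (F1 PWMs rebuilt per fold).
#' @param ... Passed to the default evaluator (e.g. `svm_config`).
#' @return List with `best_size` and `curve` (data frame of size, auroc).
#' @export
optimize_window_size <- function(positives, negatives, group,
                                 sizes = seq(10L, 30L, 2L),
                                 evaluator = NULL, ...) {
  group <- match.arg(group, c("F1", "F2", "F3", "F4"))
  if (length(sizes) == 0L) stop("no candidate sizes supplied")
  if (is.null(evaluator))
    evaluator <- function(pos, neg, config, groups)
      jackknife_windows(pos, neg, config, groups = groups, ...)$auroc
  auroc <- numeric(length(sizes))
  for (i in seq_along(sizes)) {
    cfg_args <- list(w1 = 12L, w2 = 12L, w3 = 24L, w4 = 18L)
    cfg_args[[c(F1 = "w1", F2 = "w2", F3 = "w3", F4 = "w4")[group]]] <-
      sizes[i]
    cfg <- do.call(window_config, cfg_args)
    auroc[i] <- tryCatch(evaluator(positives, negatives, cfg, group),
                         error = function(e)
                           stop("evaluator failed at size ", sizes[i], ": ",
                                conditionMessage(e)))
  }
  ord <- order(-auroc, sizes)  # max auROC, ties -> smaller size
  list(best_size = sizes[ord[1]],
       curve = data.frame(size = sizes, auroc = auroc))
}
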