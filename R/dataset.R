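#' Construct a residue window
#'
#' A residue window is a fixed-length peptide centered on a threonine, with
#' per-residue secondary structure and accessibility and an optional class
#' label. Offsets are signed relative to the central threonine (center = 0);
#' positions outside the protein are padded with residue `X`, structure `X`
#' and accessibility 0.
#'
#' @param protein_id Source protein id.
#' @param center_pos 1-based position of the central threonine.
#' @param residues Character string of length `2*flank+1`.
#' @param ss Character string over `{H,E,C,X}`, same length.
#' @param acc Numeric vector of non-negative accessibilities, same length.
#' @param label `"positive"`, `"negative"` or `NA`.
#' @return An object of class `ResidueWindow`.
#' @export
residue_window <- function(protein_id, center_pos, residues, ss, acc,
                           label = NA_character_) {
  L <- nchar(residues)
  if (L %% 2L == 0L) stop("window length must be odd")
  center <- (L + 1L) %/% 2L
  if (substr(residues, center, center) != "T")
    stop("window center must be threonine, found '",
         substr(residues, center, center), "'")
  if (nchar(ss) != L || length(acc) != L)
    stop("residues, ss and acc must have equal length")
  if (any(acc < 0)) stop("accessibility must be non-negative")
  structure(list(protein_id = protein_id, center_pos = as.integer(center_pos),
                 residues = residues, ss = ss, acc = as.numeric(acc),
                 label = label),
            class = "ResidueWindow")
}

#' @export
print.ResidueWindow <- function(x, ...) {
  cat(sprintf("<ResidueWindow %s:%d [%s] %s>\n", x$protein_id, x$center_pos,
              x$label, x$residues))
  invisible(x)
}

#' Extract a threonine-centered window from a protein
#'
#' @param protein A [protein_record()]; if it carries no `ss`/`acc`
#'   annotations, in-protein positions default to coil / 0.
#' @param center_pos 1-based position of the central residue; must be `T`.
#' @param flank Residues per side (default 15, giving a 31-mer).
#' @param label Optional class label to attach.
#' @return A [residue_window()].
#' @export
extract_window <- function(protein, center_pos, flank = 15L,
                           label = NA_character_) {
  stopifnot(inherits(protein, "ProteinRecord"))
  n <- nchar(protein$sequence)
  if (center_pos < 1L || center_pos > n)
    stop("center position ", center_pos, " outside protein '", protein$id, "'")
  if (substr(protein$sequence, center_pos, center_pos) != "T")
    stop("protein '", protein$id, "' position ", center_pos,
         " is not a threonine")
  idx <- (center_pos - flank):(center_pos + flank)
  inside <- idx >= 1L & idx <= n
  res <- rep("X", length(idx))
  sschr <- rep("X", length(idx))
  accv <- rep(0, length(idx))
  seq_chars <- strsplit(protein$sequence, "", fixed = TRUE)[[1]]
  res[inside] <- seq_chars[idx[inside]]
  ss_src <- if (is.null(protein$ss)) strrep("C", n) else protein$ss
  ss_chars <- strsplit(ss_src, "", fixed = TRUE)[[1]]
  sschr[inside] <- ss_chars[idx[inside]]
  if (!is.null(protein$acc)) accv[inside] <- protein$acc[idx[inside]]
  residue_window(protein$id, center_pos, paste(res, collapse = ""),
                 paste(sschr, collapse = ""), accv, label)
}

#' Build positive and negative window sets from proteins and a site table
#'
#' One positive window is extracted per listed phosphothreonine. Negatives
#' are every other threonine in proteins that contain at least one positive,
#' i.e. center threonines not listed as positive.
#'
#' @param proteins Named list of [protein_record()]s.
#' @param sites Site data frame (see [read_site_table()]).
#' @param flank Residues per side (default 15).
#' @return List with elements `positives` and `negatives`, each a list of
#'   [residue_window()]s.
#' @export
build_dataset <- function(proteins, sites, flank = 15L) {
  sites <- validate_site_table(sites, proteins)
  pos_sites <- sites[sites$label == "positive", , drop = FALSE]
  positives <- vector("list", nrow(pos_sites))
  for (i in seq_len(nrow(pos_sites)))
    positives[[i]] <- extract_window(proteins[[pos_sites$protein_id[i]]],
                                     pos_sites$position[i], flank, "positive")
  negatives <- list()
  for (id in unique(pos_sites$protein_id)) {
    p <- proteins[[id]]
    t_pos <- which(strsplit(p$sequence, "", fixed = TRUE)[[1]] == "T")
    listed <- pos_sites$position[pos_sites$protein_id == id]
    for (pos in setdiff(t_pos, listed))
      negatives[[length(negatives) + 1L]] <-
        extract_window(p, pos, flank, "negative")
  }
  message("built ", length(positives), " positive and ", length(negatives),
          " negative windows")
  list(positives = positives, negatives = negatives)
}

#' Balance a window set by clustering-based undersampling
#'
#' Windows are encoded to numeric vectors, partitioned into `k` clusters by
#' k-means under a fixed seed, and the member of each cluster closest to its
#' centroid (Euclidean; ties broken toward the lowest input index) is kept.
#' Output order follows cluster index, so repeated runs with the same seed
#' are identical.
#'
#' @param windows List of [residue_window()]s.
#' @param k Number of representatives to retain.
#' @param seed Integer seed for the clustering.
#' @param encoder Function mapping a list of windows to a numeric matrix
#'   (rows = windows).
#' @return A list of `k` windows (a subset of the input), with a
#'   `provenance` attribute recording `k`, `seed` and the method.
#' @export
cluster_undersample <- function(windows, k, seed, encoder) {
  n <- length(windows)
  if (k > n) stop("k (", k, ") exceeds the number of windows (", n, ")")
  if (k == n) {
    attr(windows, "provenance") <- list(k = k, seed = seed, method = "identity")
    return(windows)
  }
  X <- encoder(windows)
  stopifnot(is.matrix(X), nrow(X) == n)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  km <- suppressWarnings(stats::kmeans(X, centers = k, iter.max = 100L,
                                       nstart = 5L))
  reps <- integer(k)
  for (j in seq_len(k)) {
    members <- which(km$cluster == j)
    d2 <- rowSums((X[members, , drop = FALSE] -
                   matrix(km$centers[j, ], length(members), ncol(X),
                          byrow = TRUE))^2)
    reps[j] <- members[which.min(d2)]  # which.min: first minimum = lowest index
  }
  out <- windows[reps]
  attr(out, "provenance") <- list(k = k, seed = seed, method = "kmeans")
  out
}

# Save/restore the global RNG state so seeded helpers do not perturb the
# caller's random stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}
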