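# Canonical 20-residue alphabet; X marks unknown/padding.
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
AA_ALPHABET <- c(AA20, "X")

#' Construct a protein record
#'
#' A protein record holds one amino-acid sequence plus optional per-residue
#' structural annotations: 3-state secondary structure (`H` helix, `E`
#' strand, `C` coil) and solvent accessibility (non-negative, in whatever
#' units the annotation source uses).
#'
#' @param id Unique protein identifier.
#' @param sequence Amino-acid string over `ACDEFGHIKLMNPQRSTVWY` plus `X`.
#' @param ss Optional secondary-structure string over `{H,E,C}`, same length
#'   as `sequence`.
#' @param acc Optional numeric vector of non-negative accessibilities, same
#'   length as `sequence`.
#' @return An object of class `ProteinRecord`.
#' @export
protein_record <- function(id, sequence, ss = NULL, acc = NULL) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (nchar(sequence) == 0L)
    stop("protein '", id, "': zero-length sequence")
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  bad <- setdiff(unique(chars), AA_ALPHABET)
  if (length(bad))
    stop("protein '", id, "': characters outside alphabet: ",
         paste(bad, collapse = ", "))
  if (!is.null(ss)) {
    stopifnot(is.character(ss), length(ss) == 1L)
    if (nchar(ss) != nchar(sequence))
      stop("protein '", id, "': ss length != sequence length")
    ss_bad <- setdiff(unique(strsplit(ss, "")[[1]]), c("H", "E", "C", "X"))
    if (length(ss_bad))
      stop("protein '", id, "': invalid secondary-structure states: ",
           paste(ss_bad, collapse = ", "))
  }
  if (!is.null(acc)) {
    acc <- as.numeric(acc)
    if (length(acc) != nchar(sequence))
      stop("protein '", id, "': acc length != sequence length")
    if (any(is.na(acc)) || any(acc < 0))
      stop("protein '", id, "': accessibilities must be non-negative")
  }
  structure(list(id = id, sequence = sequence, ss = ss, acc = acc),
            class = "ProteinRecord")
}

#' @export
print.ProteinRecord <- function(x, ...) {
  cat(sprintf("<ProteinRecord %s: %d aa%s%s>\n", x$id, nchar(x$sequence),
              if (!is.null(x$ss)) ", ss" else "",
              if (!is.null(x$acc)) ", acc" else ""))
  invisible(x)
}

#' Read protein sequences from a FASTA file
#'
#' Sequences are uppercased, internal whitespace is stripped, and characters
#' outside the 20-residue alphabet (+X) are mapped to `X` with a warning.
#' Record ids are the first whitespace-delimited token of each header.
#'
#' @param path Path to a FASTA file.
#' @return Named list of [protein_record()] objects (no annotations).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty FASTA file: ", path)
  hdr <- startsWith(lines, ">")
  if (!hdr[1]) stop("malformed FASTA (does not start with '>'): ", path)
  rec_idx <- cumsum(hdr)
  ids <- vapply(lines[hdr], function(h)
    strsplit(trimws(sub("^>", "", h)), "\\s+")[[1]][1], character(1),
    USE.NAMES = FALSE)
  if (anyNA(ids) || any(!nzchar(ids)))
    stop("FASTA header without an id in ", path)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate FASTA id(s): ", paste(dup, collapse = ", "))
  seqs <- vapply(seq_along(ids), function(i) {
    paste(lines[!hdr & rec_idx == i], collapse = "")
  }, character(1))
  seqs <- toupper(gsub("\\s+", "", seqs))
  n_mapped <- 0L
  out <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    if (nchar(seqs[i]) == 0L)
      stop("record '", ids[i], "': zero-length sequence")
    chars <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
    outside <- !(chars %in% AA_ALPHABET)
    if (any(outside)) {
      n_mapped <- n_mapped + sum(outside)
      chars[outside] <- "X"
    }
    out[[i]] <- protein_record(ids[i], paste(chars, collapse = ""))
  }
  if (n_mapped > 0L)
    warning(n_mapped, " character(s) outside the amino-acid alphabet mapped to X")
  names(out) <- ids
  out
}

#' Write protein records to FASTA
#'
#' @param proteins Named list of [protein_record()] objects.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(proteins, path, width = 60L) {
  con <- file(path, open = "wb")  # binary: byte-identical across platforms
  on.exit(close(con))
  for (p in proteins) {
    s <- p$sequence
    starts <- seq(1L, nchar(s), by = width)
    chunks <- substring(s, starts, pmin(starts + width - 1L, nchar(s)))
    writeLines(c(paste0(">", p$id), chunks), con, sep = "\n")
  }
  invisible(path)
}

#' Attach per-residue structural annotations from a TSV file
#'
#' The annotation dialect is a tab-separated table with columns
#' `protein_id`, `pos` (1-based), `aa`, `ss` (one of `H`, `E`, `C`) and
#' `acc` (>= 0). Every annotated residue must match the FASTA sequence;
#' residues without a row default to coil (`C`) with accessibility 0, and
#' the number of defaulted residues is reported.
#'
#' @param path Path to the annotation TSV.
#' @param proteins Named list of [protein_record()]s to annotate.
#' @return The protein list with `ss`/`acc` filled in for every record.
#' @export
read_annotations <- function(path, proteins) {
  if (!file.exists(path)) stop("file not found: ", path)
  ann <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("protein_id", "pos", "aa", "ss", "acc")
  if (!all(need %in% names(ann)))
    stop("annotation file must have columns: ", paste(need, collapse = ", "))
  if (any(!ann$ss %in% c("H", "E", "C")))
    stop("annotation ss values must be H, E or C")
  if (any(ann$acc < 0)) stop("annotation acc values must be >= 0")
  unknown <- setdiff(unique(ann$protein_id), names(proteins))
  if (length(unknown))
    stop("annotation references unknown protein(s): ",
         paste(unknown, collapse = ", "))
  n_default <- 0L
  by_prot <- split(ann, ann$protein_id)
  for (id in names(proteins)) {
    p <- proteins[[id]]
    n <- nchar(p$sequence)
    ss <- rep("C", n)
    acc <- rep(0, n)
    rows <- by_prot[[id]]
    if (!is.null(rows)) {
      if (any(rows$pos < 1L | rows$pos > n))
        stop("protein '", id, "': annotation position out of range")
      seq_chars <- strsplit(p$sequence, "", fixed = TRUE)[[1]]
      mism <- which(seq_chars[rows$pos] != rows$aa)
      if (length(mism))
        stop("protein '", id, "': annotation residue mismatch at position ",
             rows$pos[mism[1]], " (sequence has ", seq_chars[rows$pos[mism[1]]],
             ", annotation says ", rows$aa[mism[1]], ")")
      ss[rows$pos] <- rows$ss
      acc[rows$pos] <- rows$acc
      n_default <- n_default + (n - length(unique(rows$pos)))
    } else {
      n_default <- n_default + n
    }
    proteins[[id]] <- protein_record(id, p$sequence,
                                     ss = paste(ss, collapse = ""), acc = acc)
  }
  if (n_default > 0L)
    message(n_default, " residue(s) without annotation defaulted to ss=C, acc=0")
  proteins
}

#' Read a phosphosite table
#'
#' Tab-separated columns `protein_id`, `position` (1-based) and `label`
#' (`positive`, `negative` or `unlabeled`). Every referenced position must
#' be a threonine in the corresponding protein.
#'
#' @param path Path to the site TSV.
#' @param proteins Named list of [protein_record()]s the sites refer to.
#' @return Data frame with columns `protein_id`, `position`, `label`.
#' @export
read_site_table <- function(path, proteins) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("protein_id", "position", "label")
  if (!all(need %in% names(tab)))
    stop("site table must have columns: ", paste(need, collapse = ", "))
  validate_site_table(tab, proteins)
}

#' @rdname read_site_table
#' @param sites A site data frame to validate in place of a file.
#' @export
validate_site_table <- function(sites, proteins) {
  if (any(!sites$label %in% c("positive", "negative", "unlabeled")))
    stop("site labels must be positive, negative or unlabeled")
  unknown <- setdiff(unique(sites$protein_id), names(proteins))
  if (length(unknown))
    stop("site table references unknown protein(s): ",
         paste(unknown, collapse = ", "))
  for (i in seq_len(nrow(sites))) {
    p <- proteins[[sites$protein_id[i]]]
    pos <- sites$position[i]
    if (pos < 1L || pos > nchar(p$sequence))
      stop("site ", sites$protein_id[i], ":", pos, " out of range")
    res <- substr(p$sequence, pos, pos)
    if (res != "T")
      stop("site ", sites$protein_id[i], ":", pos,
           " is not a threonine (found ", res, ")")
  }
  sites[c("protein_id", "position", "label")]
}

#' Write / read a feature matrix as CSV
#'
#' The CSV has one header row of feature names plus a final `label` column;
#' numeric values round-trip at full precision. Feature names follow the
#' `group:property:offset` convention so group and offset tags survive the
#' round trip.
#'
#' @param fm A `FeatureMatrix` (see [assemble_features()]).
#' @param path Output/input CSV path.
#' @return `write_feature_matrix` returns `path` invisibly;
#'   `read_feature_matrix` returns a `FeatureMatrix`.
#' @export
write_feature_matrix <- function(fm, path) {
  stopifnot(inherits(fm, "FeatureMatrix"))
  df <- as.data.frame(fm$X, check.names = FALSE, optional = TRUE)
  # %.17g guarantees bit-exact double round trips (plain significand output
  # can drop the final ulp)
  df[] <- lapply(df, function(v) sprintf("%.17g", v))
  df$label <- fm$y
  readr::write_csv(df, path)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- readr::read_csv(path, progress = FALSE, name_repair = "minimal",
                        col_types = readr::cols(.default =
                                                  readr::col_character()))
  if (!"label" %in% names(df)) stop("feature CSV lacks a 'label' column")
  y <- df$label
  # parse through as.numeric: C strtod round-trips %.17g output bit-exactly
  X <- do.call(cbind, lapply(df[setdiff(names(df), "label")], as.numeric))
  feature_matrix(X, y)
}

# Internal constructor shared by encoding and I/O; parses group/offset tags
# from "group:property:offset" names.
feature_matrix <- function(X, y, config = NULL) {
  stopifnot(is.matrix(X), nrow(X) == length(y))
  if (is.null(colnames(X)) || anyDuplicated(colnames(X)))
    stop("feature matrix requires unique column names")
  parts <- strsplit(colnames(X), ":", fixed = TRUE)
  groups <- vapply(parts, `[`, character(1), 1L)
  offsets <- suppressWarnings(as.integer(vapply(parts, function(p)
    p[length(p)], character(1))))
  structure(list(X = X, y = as.character(y), groups = groups,
                 offsets = offsets, config = config),
            class = "FeatureMatrix")
}

#' @export
print.FeatureMatrix <- function(x, ...) {
  cat(sprintf("<FeatureMatrix: %d samples x %d features (%s)>\n",
              nrow(x$X), ncol(x$X),
              paste(sprintf("%s:%d", names(table(x$groups)), table(x$groups)),
                    collapse = ", ")))
  invisible(x)
}
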