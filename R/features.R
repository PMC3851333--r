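#' @title Feature encodings for pattern windows
#' @description Four families of fixed-length numeric encodings turn a
#'   pattern window into SVM input: k-mer composition (4/16/64 dims for
#'   k = 1/2/3), one-hot sequence profile (4 bits per arm-row token, 56 dims
#'   at w = 14), one-hot structure profile (arm row then complement row,
#'   112 dims at w = 14), and the extended structure profile with an
#'   explicit loop/bulge state (5 bits per token over both rows, 140 dims
#'   at w = 14).
#' @name features
NULL

RNA_BASES <- c("A", "C", "G", "U")

kmer_alphabet <- function(k) {
  # lexicographic over (A, C, G, U)
  grid <- expand.grid(rep(list(RNA_BASES), k), stringsAsFactors = FALSE)
  sort(do.call(paste0, rev(grid)))
}

#' k-mer composition of a pattern window
#'
#' Counts overlapping k-mers along the arm row (and, optionally, also the
#' complement row, pooling counts) and reports relative frequencies in
#' lexicographic k-mer order over (A, C, G, U). Any k-mer touching a gap is
#' excluded from both numerator and denominator.
#'
#' @param win a `pattern_window`.
#' @param k k-mer size, 1, 2 or 3 (4, 16 or 64 dimensions).
#' @param use_structure_rows also count k-mers on the complement row (the
#'   "structure-based" composition of the method).
#' @param counts return raw counts instead of relative frequencies.
#' @return Named numeric vector of length `4^k`, with attribute `scheme`;
#'   an all-gap window yields a zero vector with attribute
#'   `degenerate = TRUE`.
#' @export
kmer_composition <- function(win, k, use_structure_rows = FALSE,
                             counts = FALSE) {
  stopifnot(inherits(win, "pattern_window"), k %in% 1:3)
  alphabet <- kmer_alphabet(k)
  tally <- stats::setNames(numeric(length(alphabet)), alphabet)
  rows <- list(win$arm_tokens)
  if (use_structure_rows) rows <- c(rows, list(win$complement_tokens))
  for (row in rows) {
    n <- length(row)
    if (n < k) next
    for (s in seq_len(n - k + 1L)) {
      mer <- row[s:(s + k - 1L)]
      if (anyNA(mer)) next
      key <- paste(mer, collapse = "")
      tally[key] <- tally[key] + 1
    }
  }
  total <- sum(tally)
  out <- if (counts || total == 0) tally else tally / total
  attr(out, "scheme") <- paste0("comp", k)
  if (total == 0) attr(out, "degenerate") <- TRUE
  out
}

one_hot <- function(tokens, bits) {
  # bits = 4: gap -> all-zero block; bits = 5: gap is its own class
  blocks <- vapply(tokens, function(t) {
    v <- numeric(bits)
    if (is.na(t)) {
      if (bits == 5L) v[5L] <- 1
    } else {
      v[match(t, RNA_BASES)] <- 1
    }
    v
  }, numeric(bits))
  as.numeric(blocks)
}

#' One-hot sequence profile of a window
#'
#' Each arm-row token becomes a 4-bit block (A = 1000, C = 0100, G = 0010,
#' U = 0001); gaps become all-zero blocks. 56 dimensions at width 14.
#'
#' @param win a `pattern_window`.
#' @return Numeric 0/1 vector of length `4 * width`, attribute
#'   `scheme = "binary_seq"`.
#' @export
binary_sequence <- function(win) {
  stopifnot(inherits(win, "pattern_window"))
  out <- one_hot(win$arm_tokens, 4L)
  attr(out, "scheme") <- "binary_seq"
  out
}

#' One-hot structure profile of a window
#'
#' Arm-row blocks followed by complement-row blocks, 4 bits per token; an
#' unpaired (gap) position contributes a zero block on the complement row,
#' encoding the absence of base pairing. 112 dimensions at width 14.
#'
#' @param win a `pattern_window`.
#' @return Numeric 0/1 vector of length `8 * width`, attribute
#'   `scheme = "binary_struct"`.
#' @export
binary_structure <- function(win) {
  stopifnot(inherits(win, "pattern_window"))
  out <- c(one_hot(win$arm_tokens, 4L), one_hot(win$complement_tokens, 4L))
  attr(out, "scheme") <- "binary_struct"
  out
}

#' Extended one-hot structure profile with an explicit loop/bulge state
#'
#' Both rows, 5 bits per token: A = 10000 ... U = 00010 and loop/bulge
#' (gap) = 00001, so exactly one bit is set per token and the loop/bulge
#' feature is no longer conflated with "no information". 140 dimensions at
#' width 14.
#'
#' @param win a `pattern_window`.
#' @return Numeric 0/1 vector of length `10 * width`, attribute
#'   `scheme = "extbinary_struct"`.
#' @export
extended_binary_structure <- function(win) {
  stopifnot(inherits(win, "pattern_window"))
  out <- c(one_hot(win$arm_tokens, 5L), one_hot(win$complement_tokens, 5L))
  attr(out, "scheme") <- "extbinary_struct"
  out
}

#' Encode one window under a named scheme
#'
#' @param win a `pattern_window`.
#' @param scheme one of `"comp1"`, `"comp2"`, `"comp3"`, `"binary_seq"`,
#'   `"binary_struct"`, `"extbinary_struct"`.
#' @param use_structure_rows for the composition schemes only: pool counts
#'   over both rows.
#' @param counts for the composition schemes only: raw counts instead of
#'   frequencies.
#' @return Numeric feature vector.
#' @export
encode_window <- function(win, scheme = c("extbinary_struct", "binary_seq",
                                          "binary_struct", "comp1", "comp2",
                                          "comp3"),
                          use_structure_rows = FALSE, counts = FALSE) {
  scheme <- match.arg(scheme)
  switch(scheme,
         comp1 = kmer_composition(win, 1L, use_structure_rows, counts),
         comp2 = kmer_composition(win, 2L, use_structure_rows, counts),
         comp3 = kmer_composition(win, 3L, use_structure_rows, counts),
         binary_seq = binary_sequence(win),
         binary_struct = binary_structure(win),
         extbinary_struct = extended_binary_structure(win))
}

#' Encode a list of windows into a feature matrix
#'
#' @param windows list of `pattern_window`s (all the same width).
#' @inheritParams encode_window
#' @return Numeric matrix, one row per window, with attribute `scheme`.
#' @export
encode_windows <- function(windows, scheme = "extbinary_struct",
                           use_structure_rows = FALSE, counts = FALSE) {
  stopifnot(length(windows) > 0L)
  rows <- lapply(windows, encode_window, scheme = scheme,
                 use_structure_rows = use_structure_rows, counts = counts)
  x <- do.call(rbind, rows)
  rownames(x) <- vapply(windows, `[[`, "", "hairpin_id")
  attr(x, "scheme") <- scheme
  x
}

#' Write a labelled feature matrix
#'
#' `format = "tsv"` writes a dense table (`label` column first);
#' `format = "svmlight"` writes the sparse `label index:value` format used
#' by classic SVM tools (+1 for cleavage, -1 otherwise; 1-based feature
#' indices in the canonical encoding order).
#'
#' @param x feature matrix from [encode_windows()].
#' @param labels character/factor vector of window labels.
#' @param path output file.
#' @param format `"tsv"` or `"svmlight"`.
#' @param provenance optional named list of `# key: value` header comments
#'   (TSV only).
#' @export
write_feature_matrix <- function(x, labels, path,
                                 format = c("tsv", "svmlight"),
                                 provenance = NULL) {
  format <- match.arg(format)
  stopifnot(nrow(x) == length(labels))
  if (format == "tsv") {
    df <- data.frame(label = as.character(labels), x,
                     stringsAsFactors = FALSE, check.names = FALSE)
    write_tsv_with_header(df, path, provenance)
  } else {
    y <- ifelse(as.character(labels) == "cleavage", "+1", "-1")
    lines <- vapply(seq_len(nrow(x)), function(i) {
      nz <- which(x[i, ] != 0)
      paste(y[i], paste(sprintf("%d:%g", nz, x[i, nz]), collapse = " "))
    }, character(1))
    writeLines(lines, path)
  }
  invisible(path)
}
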