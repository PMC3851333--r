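#' Construct a pre-miRNA hairpin record
#'
#' A hairpin couples an RNA sequence with its secondary structure in
#' dot-bracket notation and, optionally, the minimum free energy (MFE) of
#' that structure. Positions are 1-based throughout the package.
#'
#' The sequence is normalised on construction: `T` is converted to `U` and
#' case is folded to upper. Residues outside `{A, C, G, U}` after
#' normalisation are rejected, as are structures whose brackets are
#' unbalanced or that use more than one bracket family (pseudoknots are not
#' supported; miRNA hairpins are nested).
#'
#' @param id character identifier.
#' @param sequence RNA (or DNA; `T` is converted) sequence string.
#' @param dotbracket structure string over `(`, `)`, `.`, same length as
#'   `sequence`.
#' @param mfe optional free energy in kcal/mol.
#' @return An object of class `"hairpin"`: a list with elements `id`,
#'   `sequence`, `dotbracket` and `mfe`.
#' @examples
#' h <- hairpin("h1", "GGGAAACCC", "(((...)))", mfe = -1.2)
#' h
#' @export
hairpin <- function(id, sequence, dotbracket, mfe = NULL) {
  stopifnot(is.character(id), length(id) == 1L,
            is.character(sequence), length(sequence) == 1L,
            is.character(dotbracket), length(dotbracket) == 1L)
  sequence <- normalize_rna(sequence, id = id)
  if (nchar(sequence) != nchar(dotbracket)) {
    stop(sprintf("hairpin '%s': sequence length (%d) != structure length (%d)",
                 id, nchar(sequence), nchar(dotbracket)), call. = FALSE)
  }
  check_dotbracket(dotbracket, id = id)
  if (!is.null(mfe)) {
    mfe <- as.numeric(mfe)
    stopifnot(length(mfe) == 1L, is.finite(mfe))
  }
  structure(list(id = id, sequence = sequence, dotbracket = dotbracket,
                 mfe = mfe),
            class = "hairpin")
}

#' @export
print.hairpin <- function(x, ...) {
  cat(sprintf("<hairpin> %s (%d nt%s)\n", x$id, nchar(x$sequence),
              if (is.null(x$mfe)) "" else sprintf(", MFE %.2f kcal/mol", x$mfe)))
  cat(" ", x$sequence, "\n ", x$dotbracket, "\n", sep = "")
  invisible(x)
}

# T->U, upper case; reject anything outside ACGU.
normalize_rna <- function(sequence, id = "?") {
  s <- chartr("tT", "uU", toupper(sequence))
  s <- toupper(s)
  bad <- gsub("[ACGU]", "", s)
  if (nchar(bad) > 0L) {
    stop(sprintf("hairpin '%s': non-ACGU residue(s) after normalization: %s",
                 id, paste(unique(strsplit(bad, "")[[1]]), collapse = ", ")),
         call. = FALSE)
  }
  s
}

check_dotbracket <- function(db, id = "?") {
  chars <- strsplit(db, "")[[1]]
  bad <- setdiff(unique(chars), c("(", ")", "."))
  if (length(bad) > 0L) {
    stop(sprintf("hairpin '%s': unsupported structure character(s): %s (only one bracket family; pseudoknots rejected)",
                 id, paste(bad, collapse = ", ")), call. = FALSE)
  }
  depth <- cumsum((chars == "(") - (chars == ")"))
  if (any(depth < 0L) || depth[length(depth)] != 0L) {
    stop(sprintf("hairpin '%s': unbalanced brackets in dot-bracket string", id),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Parse Vienna-style dot-bracket records
#'
#' Reads multi-record text in the layout emitted by RNAfold and similar
#' folding tools: an optional `>`-prefixed header line, a sequence line, and
#' a structure line optionally suffixed by the free energy in parentheses,
#' e.g. `"(((...))) (-1.20)"`.
#'
#' @param text character scalar (possibly multi-line) or character vector of
#'   lines.
#' @return A list of [hairpin()] objects. Records without a header are named
#'   `record_1`, `record_2`, ...
#' @examples
#' parse_vienna(">h1\nGGGAAACCC\n(((...))) (-1.20)")
#' @export
parse_vienna <- function(text) {
  lines <- if (length(text) == 1L) strsplit(text, "\n", fixed = TRUE)[[1]] else text
  lines <- sub("\r$", "", lines)
  lines <- lines[!grepl("^\\s*$", lines)]
  out <- list()
  i <- 1L
  rec <- 0L
  while (i <= length(lines)) {
    rec <- rec + 1L
    if (startsWith(lines[i], ">")) {
      id <- trimws(sub("^>", "", lines[i]))
      id <- strsplit(id, "\\s+")[[1]][1]
      i <- i + 1L
    } else {
      id <- sprintf("record_%d", rec)
    }
    if (i + 1L > length(lines)) {
      stop(sprintf("record '%s' (line %d): truncated record, expected sequence and structure lines",
                   id, i), call. = FALSE)
    }
    seq_line <- trimws(lines[i])
    struct_line <- trimws(lines[i + 1L])
    i <- i + 2L
    mfe <- NULL
    m <- regmatches(struct_line,
                    regexec("^(\\S+)(?:\\s+\\(\\s*(-?[0-9]+(?:\\.[0-9]+)?)\\s*\\))?$",
                            struct_line))[[1]]
    if (length(m) == 0L) {
      stop(sprintf("record '%s': cannot parse structure line '%s'",
                   id, struct_line), call. = FALSE)
    }
    db <- m[2]
    if (nzchar(m[3])) mfe <- as.numeric(m[3])
    out[[id]] <- hairpin(id, seq_line, db, mfe = mfe)
  }
  out
}

#' Read hairpin sequences from a FASTA file
#'
#' Sequence-only input; structures must be supplied separately (e.g. via
#' [parse_vienna()] or [fold_hairpins()]). Uses Biostrings when available,
#' with a plain-text fallback.
#'
#' @param path FASTA file path.
#' @return Named character vector of normalised RNA sequences.
#' @export
read_hairpin_fasta <- function(path) {
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    set <- Biostrings::readBStringSet(path)
    seqs <- as.character(set)
    names(seqs) <- vapply(strsplit(names(set), "\\s+"), `[`, "", 1)
  } else {
    lines <- readLines(path)
    idx <- grep("^>", lines)
    if (length(idx) == 0L) stop("no FASTA records in ", path, call. = FALSE)
    ends <- c(idx[-1] - 1L, length(lines))
    seqs <- mapply(function(a, b) paste(lines[(a + 1L):b], collapse = ""),
                   idx, ends)
    names(seqs) <- vapply(strsplit(sub("^>", "", lines[idx]), "\\s+"), `[`, "", 1)
  }
  vapply(seq_along(seqs),
         function(i) normalize_rna(seqs[[i]], id = names(seqs)[i]),
         character(1), USE.NAMES = FALSE) -> norm
  names(norm) <- names(seqs)
  norm
}

#' Fold sequences with an external RNAfold executable
#'
#' Optional convenience: shells out to an installed ViennaRNA `RNAfold`
#' binary and parses its dot-bracket output. Input structures remain
#' first-class; nothing in the package requires folding.
#'
#' @param sequences named character vector of RNA sequences.
#' @param rnafold path to the RNAfold executable.
#' @return List of [hairpin()] objects with MFE populated.
#' @export
fold_hairpins <- function(sequences, rnafold = Sys.which("RNAfold")) {
  if (!nzchar(rnafold)) stop("RNAfold executable not found", call. = FALSE)
  if (is.null(names(sequences))) {
    names(sequences) <- sprintf("seq_%d", seq_along(sequences))
  }
  fasta <- paste0(">", names(sequences), "\n", unname(sequences), collapse = "\n")
  out <- system2(rnafold, args = c("--noPS"), input = fasta, stdout = TRUE)
  parse_vienna(out)
}

#' Compute the base-pair partner map of a dot-bracket structure
#'
#' @param dotbracket dot-bracket string (balanced, one bracket family).
#' @return Integer vector: `pm[i]` is the 1-based partner of position `i`,
#'   or `NA` if unpaired. Symmetric: `pm[pm[i]] == i`.
#' @examples
#' pair_map("(((...)))")
#' @export
pair_map <- function(dotbracket) {
  check_dotbracket(dotbracket)
  chars <- strsplit(dotbracket, "")[[1]]
  n <- length(chars)
  pm <- rep(NA_integer_, n)
  stack <- integer(0)
  for (i in seq_len(n)) {
    if (chars[i] == "(") {
      stack <- c(stack, i)
    } else if (chars[i] == ")") {
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      pm[i] <- j
      pm[j] <- i
    }
  }
  pm
}

# Inverse of pair_map; used to assert the round-trip identity.
render_dotbracket <- function(pm) {
  out <- rep(".", length(pm))
  paired <- which(!is.na(pm))
  out[paired[pm[paired] > paired]] <- "("
  out[paired[pm[paired] < paired]] <- ")"
  paste(out, collapse = "")
}

#' Check that a structure is a single stem-loop
#'
#' A usable hairpin has exactly one terminal (hairpin) loop and no
#' multiloop branching. Structures with several loops are reported invalid;
#' callers decide whether to reject or skip them.
#'
#' @param pm pair map from [pair_map()], or a dot-bracket string.
#' @return List with `valid` (logical) and `n_loops` (number of hairpin
#'   loops, i.e. innermost base pairs).
#' @examples
#' validate_single_loop("(((...)))")        # valid
#' validate_single_loop("((...))((...))")   # 2 loops
#' @export
validate_single_loop <- function(pm) {
  if (is.character(pm)) pm <- pair_map(pm)
  opening <- which(!is.na(pm) & pm > seq_along(pm))
  # a hairpin loop sits inside each pair that encloses no other pair
  innermost <- vapply(opening, function(i) {
    j <- pm[i]
    j > i + 1L && all(is.na(pm[(i + 1L):(j - 1L)]))
  }, logical(1))
  n_loops <- sum(innermost)
  list(valid = n_loops == 1L, n_loops = n_loops)
}

# Stem extent of one arm: positions from the outermost pair to the loop,
# bulged (unpaired) nucleotides included, flanking tails excluded.
arm_positions <- function(pm, arm = c("5p", "3p")) {
  arm <- match.arg(arm)
  opening <- which(!is.na(pm) & pm > seq_along(pm))
  if (length(opening) == 0L) stop("empty stem: structure has no base pairs",
                                  call. = FALSE)
  if (arm == "5p") {
    seq.int(min(opening), max(opening))
  } else {
    closing <- pm[opening]
    seq.int(min(closing), max(closing))
  }
}
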