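# Shared plain-text I/O: TSV with `# key: value` provenance comments.

write_tsv_with_header <- function(df, path, provenance = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(provenance)) {
    for (k in names(provenance)) {
      writeLines(sprintf("# %s: %s", k, as.character(provenance[[k]])), con)
    }
  }
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv_skip_comments <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Read a cleavage-site annotation table
#'
#' TSV with columns `hairpin_id`, `arm` (5p/3p) and `cut_after` (1-based);
#' `#` comment lines are skipped.
#'
#' @param path TSV file.
#' @return Data frame with those three columns.
#' @export
read_annotations <- function(path) {
  df <- read_tsv_skip_comments(path)
  need <- c("hairpin_id", "arm", "cut_after")
  if (!all(need %in% names(df))) {
    stop("annotation file must have columns hairpin_id, arm, cut_after: ",
         path, call. = FALSE)
  }
  if (!all(df$arm %in% c("5p", "3p"))) {
    stop("annotation arm values must be 5p or 3p: ", path, call. = FALSE)
  }
  df$cut_after <- as.integer(df$cut_after)
  df[need]
}

#' Read a hairpin-to-family map
#'
#' TSV with columns `hairpin_id` and `family` (the semantics of miFam-style
#' family files: homologous hairpins share a family). Hairpins absent from
#' the map are later treated as singleton families.
#'
#' @param path TSV file.
#' @return Named character vector, `hairpin_id -> family`.
#' @export
read_family_map <- function(path) {
  df <- read_tsv_skip_comments(path)
  if (!all(c("hairpin_id", "family") %in% names(df))) {
    stop("family map must have columns hairpin_id, family: ", path,
         call. = FALSE)
  }
  if (anyDuplicated(df$hairpin_id)) {
    dup <- unique(df$hairpin_id[duplicated(df$hairpin_id)])
    stop("hairpin(s) mapped to more than one family: ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  stats::setNames(as.character(df$family), df$hairpin_id)
}

#' Write hairpins as FASTA plus Vienna dot-bracket records
#'
#' @param hairpins list of [hairpin()] objects.
#' @param fasta,structures output paths (either may be `NULL` to skip).
#' @export
write_hairpins <- function(hairpins, fasta = NULL, structures = NULL) {
  if (!is.null(fasta)) {
    writeLines(unlist(lapply(hairpins, function(h) {
      c(paste0(">", h$id), h$sequence)
    })), fasta)
  }
  if (!is.null(structures)) {
    writeLines(unlist(lapply(hairpins, function(h) {
      struct <- if (is.null(h$mfe)) h$dotbracket
                else sprintf("%s (%.2f)", h$dotbracket, h$mfe)
      c(paste0(">", h$id), h$sequence, struct)
    })), structures)
  }
  invisible(hairpins)
}
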