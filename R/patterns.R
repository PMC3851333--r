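#' @title Pattern windows around candidate cleavage sites
#' @description Fixed-width windows over the duplex alignment. A window of
#'   width `w` (8, 10, 12 or 14) spans `w` alignment columns with the
#'   represented cut bond between tokens `w/2` and `w/2 + 1`; it carries the
#'   anchoring-arm row and the complementary row, gaps (`NA`) included.
#' @name pattern_window
NULL

new_pattern_window <- function(hairpin_id, arm, width, arm_tokens,
                               complement_tokens, center_cut_after, label) {
  stopifnot(length(arm_tokens) == width, length(complement_tokens) == width)
  structure(list(hairpin_id = hairpin_id, arm = arm, width = width,
                 arm_tokens = arm_tokens,
                 complement_tokens = complement_tokens,
                 center_cut_after = center_cut_after, label = label),
            class = "pattern_window")
}

#' @export
print.pattern_window <- function(x, ..., dialect = c("dash", "zero")) {
  dialect <- match.arg(dialect)
  gap <- if (dialect == "dash") "-" else "0"
  tok <- function(v) paste(ifelse(is.na(v), gap, v), collapse = "")
  cat(sprintf("<pattern_window> %s %s w=%d center=%s label=%s\n",
              x$hairpin_id, x$arm, x$width,
              ifelse(is.na(x$center_cut_after), "?", x$center_cut_after),
              x$label))
  half <- x$width / 2
  cat(" arm: ", substr(tok(x$arm_tokens), 1, half), "|",
      substr(tok(x$arm_tokens), half + 1, x$width), "\n", sep = "")
  cat(" opp: ", substr(tok(x$complement_tokens), 1, half), "|",
      substr(tok(x$complement_tokens), half + 1, x$width), "\n", sep = "")
  invisible(x)
}

check_width <- function(width) {
  if (!(length(width) == 1L && width %in% c(8L, 10L, 12L, 14L))) {
    stop("width must be one of 8, 10, 12, 14", call. = FALSE)
  }
  as.integer(width)
}

# Column index of the token immediately 5'-of-bond (in column order) for a
# cut after hairpin position `cut_after` on the anchoring arm.
center_column <- function(da, cut_after) {
  anchor <- attr(da, "anchor_arm")
  target <- if (anchor == "5p") cut_after else cut_after + 1L
  cc <- match(target, da$anchor_pos)
  if (is.na(cc)) {
    stop(sprintf("cut position %d not on the %s stem of '%s'",
                 cut_after, anchor, attr(da, "hairpin_id")), call. = FALSE)
  }
  cc
}

# Extract the window whose cut bond lies between columns cc and cc + 1.
# Columns outside the stem are gap-padded on both rows.
window_at_column <- function(da, cc, width, label, center_cut_after) {
  idx <- seq.int(cc - width %/% 2L + 1L, cc + width %/% 2L)
  if (max(idx) < 1L || min(idx) > nrow(da)) {
    stop("window lies entirely outside the stem", call. = FALSE)
  }
  inside <- idx >= 1L & idx <= nrow(da)
  arm_tok <- rep(NA_character_, width)
  opp_tok <- rep(NA_character_, width)
  arm_tok[inside] <- da$anchor_tok[idx[inside]]
  opp_tok[inside] <- da$opp_tok[idx[inside]]
  new_pattern_window(attr(da, "hairpin_id"), attr(da, "anchor_arm"),
                     width, arm_tok, opp_tok, center_cut_after, label)
}

#' Extract the cleavage (positive) pattern window around a cut site
#'
#' The window spans arm positions `cut_after - w/2 + 1 .. cut_after + w/2`,
#' placing the cut bond at the centre; positions beyond the stem are
#' gap-padded so every annotated site yields exactly one window.
#'
#' @param da a [build_duplex_alignment()] result whose anchor arm matches
#'   the site's arm.
#' @param site a [cleavage_site()].
#' @param width window width, one of 8, 10, 12, 14.
#' @return A `pattern_window` labelled `"cleavage"`.
#' @export
extract_cleavage_pattern <- function(da, site, width = 14) {
  width <- check_width(width)
  stopifnot(inherits(site, "cleavage_site"))
  if (site$arm != attr(da, "anchor_arm")) {
    stop(sprintf("site is on %s arm but alignment anchors %s",
                 site$arm, attr(da, "anchor_arm")), call. = FALSE)
  }
  cc <- center_column(da, site$cut_after)
  window_at_column(da, cc, width, "cleavage", site$cut_after)
}

#' Extract a non-cleavage (negative) pattern window
#'
#' The negative window is shifted into the body of the mature miRNA (toward
#' the 5' end on the 5p arm, toward the 3' end on the 3p arm), omitting at
#' least the six nucleotides adjacent to the cut: Dicer rarely cuts in the
#' middle of a mature miRNA, so these centres are confident negatives.
#'
#' @inheritParams extract_cleavage_pattern
#' @param offset shift of the window centre in alignment columns; must be
#'   `>= 7` so the six nucleotides next to the cut are omitted.
#' @return A `pattern_window` labelled `"noncleavage"`.
#' @export
extract_noncleavage_pattern <- function(da, site, width = 14, offset = 7) {
  width <- check_width(width)
  stopifnot(inherits(site, "cleavage_site"))
  if (offset < 7) {
    stop("offset must be >= 7 (the six nucleotides adjacent to the cut are omitted)",
         call. = FALSE)
  }
  if (site$arm != attr(da, "anchor_arm")) {
    stop(sprintf("site is on %s arm but alignment anchors %s",
                 site$arm, attr(da, "anchor_arm")), call. = FALSE)
  }
  cc <- center_column(da, site$cut_after) - as.integer(offset)
  shifted_cut <- if (attr(da, "anchor_arm") == "5p") {
    site$cut_after - as.integer(offset)
  } else {
    site$cut_after + as.integer(offset)
  }
  if (attr(da, "mode") == "full-alignment") {
    # column shift need not equal position shift when gaps intervene
    shifted_cut <- if (cc >= 1L && cc <= nrow(da)) da$anchor_pos[cc] else NA_integer_
  }
  window_at_column(da, cc, width, "noncleavage", shifted_cut)
}

#' Enumerate all overlapping scan windows along a stem
#'
#' Slides a width-`w` window one column at a time along the duplex
#' alignment, emitting every position where a full (unpadded) window fits.
#' With a known true site, exactly the window whose centre bond is the true
#' cut is labelled `"cleavage"` and all others `"noncleavage"`; with
#' `true_site = NULL` all windows are `"unlabeled"`.
#'
#' @inheritParams extract_cleavage_pattern
#' @param true_site optional [cleavage_site()] on the anchoring arm.
#' @return List of `pattern_window`s (empty when the stem is shorter than
#'   `width`). A stem of `N` columns yields `N - width + 1` windows.
#' @export
enumerate_scan_windows <- function(da, width = 14, true_site = NULL) {
  width <- check_width(width)
  n <- nrow(da)
  if (n < width) return(list())
  anchor <- attr(da, "anchor_arm")
  true_cut <- NA_integer_
  if (!is.null(true_site)) {
    stopifnot(inherits(true_site, "cleavage_site"))
    if (true_site$arm != anchor) {
      stop("true_site arm does not match the alignment anchor arm", call. = FALSE)
    }
    true_cut <- true_site$cut_after
  }
  lapply(seq.int(width %/% 2L, n - width %/% 2L), function(cc) {
    cut_here <- if (anchor == "5p") da$anchor_pos[cc] else da$anchor_pos[cc + 1L]
    label <- if (is.null(true_site)) "unlabeled"
             else if (!is.na(cut_here) && cut_here == true_cut) "cleavage"
             else "noncleavage"
    window_at_column(da, cc, width, label, cut_here)
  })
}

#' Write pattern windows to a TSV file
#'
#' Columns: `hairpin_id, arm, width, center, label, arm_tokens,
#' complement_tokens`. Gaps are rendered as `-` (`dialect = "dash"`) or `0`
#' (`dialect = "zero"`); both glyphs denote the same absent-nucleotide
#' state.
#'
#' @param windows list of `pattern_window`s.
#' @param path output file.
#' @param dialect gap glyph dialect.
#' @param provenance optional named list written as `# key: value` header
#'   comments.
#' @export
write_patterns_tsv <- function(windows, path, dialect = c("dash", "zero"),
                               provenance = NULL) {
  dialect <- match.arg(dialect)
  gap <- if (dialect == "dash") "-" else "0"
  tok <- function(v) paste(ifelse(is.na(v), gap, v), collapse = "")
  df <- data.frame(
    hairpin_id = vapply(windows, `[[`, "", "hairpin_id"),
    arm = vapply(windows, `[[`, "", "arm"),
    width = vapply(windows, `[[`, 0L, "width"),
    center = vapply(windows, function(w) as.integer(w$center_cut_after), 0L),
    label = vapply(windows, `[[`, "", "label"),
    arm_tokens = vapply(windows, function(w) tok(w$arm_tokens), ""),
    complement_tokens = vapply(windows, function(w) tok(w$complement_tokens), ""),
    stringsAsFactors = FALSE
  )
  write_tsv_with_header(df, path, provenance)
  invisible(df)
}
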