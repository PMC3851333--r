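#' Construct a cleavage-site record
#'
#' A Dicer cleavage site is the scissile bond AFTER a 1-based hairpin
#' position: `cut_after = i` means the bond between nucleotides `i` and
#' `i + 1`.
#'
#' @param arm `"5p"` or `"3p"`.
#' @param cut_after 1-based position of the nucleotide immediately 5' of the
#'   cut bond.
#' @return Object of class `"cleavage_site"`.
#' @export
cleavage_site <- function(arm = c("5p", "3p"), cut_after) {
  arm <- match.arg(arm)
  cut_after <- as.integer(cut_after)
  stopifnot(length(cut_after) == 1L, !is.na(cut_after), cut_after >= 1L)
  structure(list(arm = arm, cut_after = cut_after), class = "cleavage_site")
}

#' @export
print.cleavage_site <- function(x, ...) {
  cat(sprintf("<cleavage_site> %s arm, cut after position %d\n",
              x$arm, x$cut_after))
  invisible(x)
}

#' Build the antiparallel duplex alignment of a hairpin stem
#'
#' Aligns one stem arm (the anchoring arm) against its partially
#' complementary opposite arm, column by column. Columns run from the stem
#' base toward the terminal loop; the 5p row reads 5'->3' and the 3p row
#' 3'->5', so the two bases of a paired column are Watson-Crick (or wobble)
#' partners. Loop nucleotides are excluded.
#'
#' In `"arm-anchored"` mode there is exactly one column per anchoring-arm
#' stem nucleotide; an unpaired anchor nucleotide gets a gap (`NA`) on the
#' opposite row. This fixed geometry underlies the 14+14 window encodings.
#' In `"full-alignment"` mode, extra columns (gap on the anchoring row) are
#' inserted for opposite-arm bulge nucleotides lying between the partners of
#' consecutive anchor positions, reproducing the information content of
#' aligned structure renderings that print `-` placeholders.
#'
#' @param h a [hairpin()].
#' @param pm pair map; computed from `h` if `NULL`.
#' @param anchor_arm `"5p"` (default) or `"3p"`.
#' @param mode `"arm-anchored"` (default) or `"full-alignment"`.
#' @return Object of class `"duplex_alignment"`: a data frame with columns
#'   `anchor_tok`, `opp_tok` (bases, `NA` = gap), `anchor_pos`, `opp_pos`
#'   (1-based hairpin positions, `NA` = gap), and attributes `anchor_arm`,
#'   `mode`, `hairpin_id`.
#' @export
build_duplex_alignment <- function(h, pm = NULL,
                                   anchor_arm = c("5p", "3p"),
                                   mode = c("arm-anchored", "full-alignment")) {
  anchor_arm <- match.arg(anchor_arm)
  mode <- match.arg(mode)
  if (is.null(pm)) pm <- pair_map(h$dotbracket)
  vl <- validate_single_loop(pm)
  if (!vl$valid) {
    stop(sprintf("hairpin '%s': not a single stem-loop (%d hairpin loops)",
                 h$id, vl$n_loops), call. = FALSE)
  }
  bases <- strsplit(h$sequence, "")[[1]]
  anchor_idx <- arm_positions(pm, anchor_arm)
  if (anchor_arm == "3p") anchor_idx <- rev(anchor_idx)  # stem base -> loop

  a_pos <- integer(0); o_pos <- integer(0)
  prev_partner <- NA_integer_
  for (j in anchor_idx) {
    q <- pm[j]
    if (mode == "full-alignment" && !is.na(q) && !is.na(prev_partner)) {
      # opposite-arm bulges between partners of consecutive paired anchors
      gap_run <- if (anchor_arm == "5p") {
        if (prev_partner - q > 1L) seq.int(prev_partner - 1L, q + 1L) else integer(0)
      } else {
        if (q - prev_partner > 1L) seq.int(prev_partner + 1L, q - 1L) else integer(0)
      }
      for (r in gap_run) {
        a_pos <- c(a_pos, NA_integer_); o_pos <- c(o_pos, r)
      }
    }
    a_pos <- c(a_pos, j); o_pos <- c(o_pos, q)
    if (!is.na(q)) prev_partner <- q
  }

  da <- data.frame(
    anchor_tok = ifelse(is.na(a_pos), NA_character_, bases[ifelse(is.na(a_pos), 1L, a_pos)]),
    opp_tok = ifelse(is.na(o_pos), NA_character_, bases[ifelse(is.na(o_pos), 1L, o_pos)]),
    anchor_pos = a_pos,
    opp_pos = o_pos,
    stringsAsFactors = FALSE
  )
  attr(da, "anchor_arm") <- anchor_arm
  attr(da, "mode") <- mode
  attr(da, "hairpin_id") <- h$id
  class(da) <- c("duplex_alignment", "data.frame")
  da
}

#' @export
print.duplex_alignment <- function(x, ..., dialect = c("dash", "zero")) {
  dialect <- match.arg(dialect)
  gap <- if (dialect == "dash") "-" else "0"
  tok <- function(v) paste(ifelse(is.na(v), gap, v), collapse = "")
  anchor <- attr(x, "anchor_arm")
  cat(sprintf("<duplex_alignment> %s, anchor %s, %s, %d columns\n",
              attr(x, "hairpin_id"), anchor, attr(x, "mode"), nrow(x)))
  if (anchor == "5p") {
    cat(" 5p 5'-", tok(x$anchor_tok), "-3'\n", sep = "")
    cat(" 3p 3'-", tok(x$opp_tok), "-5'\n", sep = "")
  } else {
    cat(" 5p 5'-", tok(x$opp_tok), "-3'\n", sep = "")
    cat(" 3p 3'-", tok(x$anchor_tok), "-5'\n", sep = "")
  }
  invisible(x)
}

#' Map a cleavage site between hairpin arms via the 2-nt 3' overhang
#'
#' Dicer leaves a 2-nt 3' overhang on each end of the miR:miR* duplex, so
#' the two cut positions determine each other. For a 5p cut after position
#' `i`, the 5' nucleotide of the 3p mature strand is `k = partner(i - 2)`
#' and the 3p cut falls after `k - 1`. The 3p -> 5p direction is the exact
#' inverse, so the mapping round-trips to identity.
#'
#' @param pm pair map (or dot-bracket string).
#' @param site a [cleavage_site()].
#' @param strict if `TRUE` (default), an unpaired position at the overhang
#'   offset is an error; if `FALSE`, the nearest paired neighbour is used
#'   (with the positional difference compensated) and the result carries a
#'   `warning` attribute.
#' @return The [cleavage_site()] on the opposite arm.
#' @examples
#' pm <- pair_map(paste0(strrep("(", 10), strrep(".", 6), strrep(")", 10)))
#' map_cleavage_between_arms(pm, cleavage_site("5p", 8))  # 3p cut after 20
#' @export
map_cleavage_between_arms <- function(pm, site, strict = TRUE) {
  if (is.character(pm)) pm <- pair_map(pm)
  stopifnot(inherits(site, "cleavage_site"))
  i <- site$cut_after
  anchor <- if (site$arm == "5p") i - 2L else i + 1L
  if (anchor < 1L || anchor > length(pm)) {
    stop("overhang offset position outside the hairpin", call. = FALSE)
  }
  warn <- FALSE
  partner_at <- function(p) pm[p]
  k <- partner_at(anchor)
  if (is.na(k)) {
    if (strict) {
      stop(sprintf("unpaired at overhang offset (position %d)", anchor),
           call. = FALSE)
    }
    paired <- which(!is.na(pm))
    d <- abs(paired - anchor)
    p <- paired[order(d, paired)][1]
    # compensate the shift: on a regular stem partner(x) ~ partner(p) + (p - x)
    k <- pm[p] + (p - anchor)
    warn <- TRUE
  }
  out <- if (site$arm == "5p") {
    cleavage_site("3p", k - 1L)
  } else {
    cleavage_site("5p", k + 2L)
  }
  if (warn) attr(out, "warning") <- "unpaired at overhang offset; nearest paired neighbour used"
  out
}
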