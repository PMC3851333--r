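#' Build a labelled training set from hairpins and annotations
#'
#' For every annotated cleavage site this extracts the positive window
#' centred on the cut and its paired negative window shifted into the
#' mature miRNA body, encodes both under the requested scheme, and stacks
#' them into a feature matrix. One positive and one negative row per
#' annotation.
#'
#' @param hairpins named list of [hairpin()] objects (names = ids).
#' @param annotations data frame with `hairpin_id`, `arm`, `cut_after`
#'   (e.g. from [read_annotations()] or [make_dataset()]).
#' @param width window width (8/10/12/14).
#' @param scheme feature scheme (see [encode_window()]).
#' @param use_structure_rows for composition schemes.
#' @param offset negative-window shift (>= 7).
#' @param mode duplex-alignment mode.
#' @return List with `x` (feature matrix), `y` (factor
#'   cleavage/noncleavage), `ids` (hairpin id per row), `windows`.
#' @export
build_training_set <- function(hairpins, annotations, width = 14,
                               scheme = "extbinary_struct",
                               use_structure_rows = FALSE, offset = 7,
                               mode = c("arm-anchored", "full-alignment")) {
  mode <- match.arg(mode)
  unknown <- setdiff(annotations$hairpin_id, names(hairpins))
  if (length(unknown) > 0L) {
    stop("annotation references unknown hairpin id(s): ",
         paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
  }
  windows <- list()
  for (r in seq_len(nrow(annotations))) {
    id <- annotations$hairpin_id[r]
    arm <- annotations$arm[r]
    site <- cleavage_site(arm, annotations$cut_after[r])
    h <- hairpins[[id]]
    da <- build_duplex_alignment(h, anchor_arm = arm, mode = mode)
    windows[[length(windows) + 1L]] <-
      extract_cleavage_pattern(da, site, width)
    windows[[length(windows) + 1L]] <-
      extract_noncleavage_pattern(da, site, width, offset = offset)
  }
  x <- encode_windows(windows, scheme, use_structure_rows = use_structure_rows)
  y <- factor(vapply(windows, `[[`, "", "label"),
              levels = c("cleavage", "noncleavage"))
  list(x = x, y = y, ids = vapply(windows, `[[`, "", "hairpin_id"),
       windows = windows)
}

#' Build the overlapping-window (whole-stem) training set
#'
#' Enumerates every full window along each annotated hairpin's stem; the
#' window centred on the true cut is the positive, all others negatives
#' (roughly a 1:30 class ratio on typical stems). Optionally balances the
#' classes by negative subsampling.
#'
#' @inheritParams build_training_set
#' @param balance if `TRUE`, subsample negatives to the number of positives
#'   via [balanced_subsample()].
#' @param seed seed for the balancing subsample.
#' @return As [build_training_set()].
#' @export
build_scan_training_set <- function(hairpins, annotations, width = 14,
                                    scheme = "extbinary_struct",
                                    use_structure_rows = FALSE,
                                    balance = FALSE, seed = 1,
                                    mode = c("arm-anchored", "full-alignment")) {
  mode <- match.arg(mode)
  unknown <- setdiff(annotations$hairpin_id, names(hairpins))
  if (length(unknown) > 0L) {
    stop("annotation references unknown hairpin id(s): ",
         paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
  }
  windows <- list()
  for (r in seq_len(nrow(annotations))) {
    id <- annotations$hairpin_id[r]
    site <- cleavage_site(annotations$arm[r], annotations$cut_after[r])
    da <- build_duplex_alignment(hairpins[[id]], anchor_arm = site$arm,
                                 mode = mode)
    windows <- c(windows, enumerate_scan_windows(da, width, true_site = site))
  }
  labels <- vapply(windows, `[[`, "", "label")
  if (balance) {
    idx <- balanced_subsample(which(labels == "cleavage"),
                              which(labels == "noncleavage"), seed = seed)
    windows <- windows[c(idx$pos, idx$neg)]
  }
  x <- encode_windows(windows, scheme, use_structure_rows = use_structure_rows)
  y <- factor(vapply(windows, `[[`, "", "label"),
              levels = c("cleavage", "noncleavage"))
  list(x = x, y = y, ids = vapply(windows, `[[`, "", "hairpin_id"),
       windows = windows)
}
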