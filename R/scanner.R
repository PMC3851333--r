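#' Score every candidate cleavage site along a hairpin stem
#'
#' Slides the model's window along the duplex alignment, scores each full
#' window, and returns up to `top_k` candidate cuts with scores above the
#' threshold, sorted by descending score (ties: smaller position first).
#' The highest-scoring site is the most probable cut, but the top three
#' should be considered: mature miRNA isoforms arise from small shifts in
#' the Dicer cut.
#'
#' @param model a [dicer_svm()] fit carrying `scheme` and `width` tags.
#' @param da duplex alignment of the hairpin (anchor arm = arm to scan).
#' @param width window width; must match the model's training width.
#' @param threshold decision-score cutoff (defaults to the model's).
#' @param top_k maximum number of sites returned (default 3).
#' @return Object of class `"scan_result"`: list with `hairpin_id`, `arm`,
#'   `sites` (data frame `rank`, `cut_after`, `score`), `threshold`,
#'   `top_k`.
#' @export
scan_hairpin <- function(model, da, width = model$width,
                         threshold = model$threshold, top_k = 3) {
  stopifnot(inherits(model, "dicer_svm"), inherits(da, "duplex_alignment"))
  if (is.null(model$scheme)) {
    stop("model carries no feature-scheme tag; cannot encode scan windows",
         call. = FALSE)
  }
  if (!is.null(model$width) && width != model$width) {
    stop(sprintf("scan width %d does not match the model's training width %d",
                 width, model$width), call. = FALSE)
  }
  windows <- enumerate_scan_windows(da, width)
  if (length(windows) == 0L) {
    stop(sprintf("stem of '%s' is shorter than the window width %d",
                 attr(da, "hairpin_id"), width), call. = FALSE)
  }
  scores <- predict(model, windows, type = "score")
  cuts <- vapply(windows, function(w) as.integer(w$center_cut_after), 0L)
  keep <- which(scores > threshold & !is.na(cuts))
  ord <- keep[order(-scores[keep], cuts[keep])]
  ord <- utils::head(ord, top_k)
  sites <- data.frame(rank = seq_along(ord), cut_after = cuts[ord],
                      score = scores[ord])
  structure(list(hairpin_id = attr(da, "hairpin_id"),
                 arm = attr(da, "anchor_arm"),
                 sites = sites, threshold = threshold, top_k = top_k),
            class = "scan_result")
}

#' @export
print.scan_result <- function(x, ...) {
  cat(sprintf("<scan_result> %s (%s arm), threshold %g, top %d\n",
              x$hairpin_id, x$arm, x$threshold, x$top_k))
  if (nrow(x$sites) == 0L) cat("  no site above threshold\n")
  else print(`rownames<-`(transform(x$sites, score = round(score, 3)), NULL))
  invisible(x)
}

#' Position shift error of a predicted cleavage site
#'
#' `predicted - actual`: 0 means the predicted site matches the annotation,
#' -1 one nucleotide upstream (5'-ward), +1 one nucleotide downstream.
#'
#' @param predicted,actual cut positions (integers) or [cleavage_site()]s
#'   on the same arm.
#' @return Signed integer shift.
#' @export
position_shift_error <- function(predicted, actual) {
  arm_of <- function(s) if (inherits(s, "cleavage_site")) s$arm else NA_character_
  a1 <- arm_of(predicted); a2 <- arm_of(actual)
  if (!is.na(a1) && !is.na(a2) && a1 != a2) {
    stop("predicted and actual sites are on different arms", call. = FALSE)
  }
  pos_of <- function(s) if (inherits(s, "cleavage_site")) s$cut_after else as.integer(s)
  pos_of(predicted) - pos_of(actual)
}

#' Average absolute position shift error
#'
#' The absolute values of the signed shifts (-1 counted as 1, -2 as 2)
#' summed and divided by the number of sequences.
#'
#' @param values nonempty vector of signed shifts.
#' @return Mean absolute shift.
#' @examples
#' average_pse(c(0, -1, 2))  # 1
#' @export
average_pse <- function(values) {
  if (length(values) == 0L) stop("empty PSE list", call. = FALSE)
  mean(abs(values))
}

site_positions <- function(x, k) {
  sites <- if (inherits(x, "scan_result")) x$sites else x
  utils::head(sites$cut_after, k)
}

#' Classify the effect of a variant on the Dicer cleavage site
#'
#' Compares the top-k ranked cleavage sites predicted for the reference and
#' the variant hairpin. The annotated site (by default the reference rank-1
#' position) drives the call:
#' \itemize{
#'   \item `loss_of_site` — the annotated site no longer appears among the
#'     variant's top-k positions;
#'   \item `remain_same` — the top-ranked position is unchanged and the
#'     annotated site keeps its rank;
#'   \item `altered` — otherwise (the site survives but the ranking moved).
#' }
#' This is a convention: the minimal rule consistent with published
#' variant analyses, exposed as the default of a pluggable policy.
#'
#' @param ref,var [scan_hairpin()] results (or data frames with columns
#'   `rank`, `cut_after`, `score`) from the same model and width.
#' @param annotated optional annotated cut position; defaults to the
#'   reference rank-1 position.
#' @param k how many top sites to compare (default 3).
#' @return Object of class `"snp_effect"`: list with `label`, `ref_sites`,
#'   `var_sites`, `annotated_site`.
#' @export
classify_snp_effect <- function(ref, var, annotated = NULL, k = 3) {
  ref_sites <- if (inherits(ref, "scan_result")) ref$sites else as.data.frame(ref)
  var_sites <- if (inherits(var, "scan_result")) var$sites else as.data.frame(var)
  if (nrow(ref_sites) == 0L || nrow(var_sites) == 0L) {
    stop("empty site list; both scans must report at least one site",
         call. = FALSE)
  }
  ref_pos <- utils::head(ref_sites$cut_after, k)
  var_pos <- utils::head(var_sites$cut_after, k)
  if (is.null(annotated)) annotated <- ref_pos[1]
  annotated <- as.integer(annotated)
  label <- if (!(annotated %in% var_pos)) {
    "loss_of_site"
  } else {
    rank_ref <- match(annotated, ref_pos)
    rank_var <- match(annotated, var_pos)
    same_rank <- (is.na(rank_ref) && is.na(rank_var)) ||
      (!is.na(rank_ref) && !is.na(rank_var) && rank_ref == rank_var)
    if (var_pos[1] == ref_pos[1] && same_rank) "remain_same" else "altered"
  }
  structure(list(label = label,
                 ref_sites = utils::head(ref_sites, k),
                 var_sites = utils::head(var_sites, k),
                 annotated_site = annotated),
            class = "snp_effect")
}

#' @export
print.snp_effect <- function(x, ...) {
  cat(sprintf("<snp_effect> %s (annotated site %d)\n", x$label,
              x$annotated_site))
  cat("  reference top sites:", paste(x$ref_sites$cut_after, collapse = ", "), "\n")
  cat("  variant top sites:  ", paste(x$var_sites$cut_after, collapse = ", "), "\n")
  invisible(x)
}

#' Substitute a single nucleotide in a hairpin
#'
#' Applies `ref > alt` at `position`, keeping the supplied secondary
#' structure. Refolding the variant is the caller's responsibility (e.g.
#' via [fold_hairpins()]); by default the reference structure is retained,
#' which isolates the sequence contribution of the variant.
#'
#' @param h a [hairpin()].
#' @param position 1-based position of the variant.
#' @param ref expected reference base at that position (checked).
#' @param alt substituted base.
#' @param dotbracket optional replacement structure for the variant.
#' @return A new [hairpin()] (id suffixed with the variant).
#' @export
apply_variant <- function(h, position, ref, alt, dotbracket = NULL) {
  stopifnot(inherits(h, "hairpin"))
  position <- as.integer(position)
  ref <- normalize_rna(ref); alt <- normalize_rna(alt)
  if (position < 1L || position > nchar(h$sequence)) {
    stop("variant position outside the hairpin", call. = FALSE)
  }
  have <- substr(h$sequence, position, position)
  if (have != ref) {
    stop(sprintf("hairpin '%s': reference base at %d is %s, not %s",
                 h$id, position, have, ref), call. = FALSE)
  }
  seq2 <- h$sequence
  substr(seq2, position, position) <- alt
  hairpin(sprintf("%s_%d%s>%s", h$id, position, ref, alt), seq2,
          if (is.null(dotbracket)) h$dotbracket else dotbracket,
          mfe = NULL)
}
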