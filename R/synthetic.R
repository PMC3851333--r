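#' Specification for the synthetic hairpin generator
#'
#' Describes a population of seeded synthetic pre-miRNA hairpins with
#' annotated Dicer cleavage sites, miRNA-family structure, and a tunable
#' planted signal. The signal is planted both in base identity (a
#' position-specific multinomial tilt at fixed offsets around the true cut)
#' and in pairing state (bulges planted at fixed offsets from the cut), so
#' that structure-aware encodings can demonstrably beat sequence-only ones.
#' At `signal_strength = 0` the cut context is statistically
#' indistinguishable from the rest of the stem.
#'
#' @param n_hairpins number of hairpins.
#' @param stem_length integer range (min, max) of the 5p-arm stem length in
#'   nucleotides.
#' @param loop_length integer range of the terminal loop length.
#' @param bulge_probability per-position background probability of an
#'   unpaired stem nucleotide, outside the window region around the cut.
#' @param signal_strength in `[0, 1]`: scales both the base tilt and the
#'   planted-bulge probability near the cut.
#' @param n_families number of miRNA families; members of a family are
#'   mutated copies of a common ancestral hairpin.
#' @param wobble_rate fraction of paired columns emitted as G:U wobble
#'   pairs (exercises non-canonical pairing).
#' @param seed integer master seed; every hairpin derives its own stream
#'   from `(seed, index)`.
#' @return Object of class `"synthetic_spec"`.
#' @export
synthetic_spec <- function(n_hairpins = 100, stem_length = c(26, 32),
                           loop_length = c(4, 8), bulge_probability = 0.05,
                           signal_strength = 1, n_families = NULL,
                           wobble_rate = 0.1, seed = 1) {
  if (is.null(n_families)) n_families <- max(1L, n_hairpins %/% 5L)
  stopifnot(n_hairpins >= 1, length(stem_length) == 2,
            stem_length[1] >= 21, stem_length[2] >= stem_length[1],
            length(loop_length) == 2, loop_length[1] >= 3,
            loop_length[2] >= loop_length[1],
            bulge_probability >= 0, bulge_probability <= 1,
            signal_strength >= 0, signal_strength <= 1,
            wobble_rate >= 0, wobble_rate <= 1,
            n_families >= 1, n_families <= n_hairpins)
  structure(list(n_hairpins = as.integer(n_hairpins),
                 stem_length = as.integer(stem_length),
                 loop_length = as.integer(loop_length),
                 bulge_probability = bulge_probability,
                 signal_strength = signal_strength,
                 n_families = as.integer(n_families),
                 wobble_rate = wobble_rate,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

# Deterministic per-item stream seeds below 2^31.
derive_seed <- function(seed, i) {
  as.integer((as.double(seed) * 48271 + as.double(i) * 69621 + 11) %% 2147483629)
}

SIGNAL_MOTIF <- c("U", "G", "C", "A")   # at offsets -1, 0, +1, +2 from the cut
MOTIF_OFFSETS <- c(-1L, 0L, 1L, 2L)
PLANT_OFFSETS <- c(-5L, 3L)             # planted-bulge offsets from the cut

base_probs <- function(offset, signal) {
  p <- rep(0.25, 4)
  names(p) <- RNA_BASES
  hit <- match(offset, MOTIF_OFFSETS)
  if (!is.na(hit)) {
    tilt <- 0.5 * signal
    pm <- 0.25 + 0.75 * tilt
    p[] <- (1 - pm) / 3
    p[SIGNAL_MOTIF[hit]] <- pm
  }
  p
}

partner_base <- function(base, wobble) {
  comp <- c(A = "U", C = "G", G = "C", U = "A")
  if (wobble && base == "G") return("U")
  if (wobble && base == "U") return("G")
  comp[[base]]
}

# Family skeleton: geometry, pairing states, wobble flags and ancestral
# bases. Shared (up to seeded mutation) by all members of the family.
build_skeleton <- function(spec) {
  n_anchor <- sample(spec$stem_length[1]:spec$stem_length[2], 1)
  loop_len <- sample(spec$loop_length[1]:spec$loop_length[2], 1)
  lo <- max(14L, n_anchor - 10L); hi <- n_anchor - 7L
  if (lo > hi) stop("stem too short for the window and overhang geometry",
                    call. = FALSE)
  t <- sample(lo:hi, 1)
  protected <- seq.int(t - 13L, t + 7L)  # positive + shifted-negative windows
  paired <- rep(TRUE, n_anchor)
  for (j in seq_len(n_anchor)) {
    off <- j - t
    if (off %in% PLANT_OFFSETS) {
      paired[j] <- stats::runif(1) >= 0.9 * spec$signal_strength
    } else if (!(j %in% protected)) {
      paired[j] <- stats::runif(1) >= spec$bulge_probability
    }
  }
  paired[c(1L, n_anchor, t - 2L)] <- TRUE  # stem ends; unbulged overhang offset
  bulge3_after <- ifelse(
    paired & seq_len(n_anchor) > 1L &
      !(seq_len(n_anchor) %in% seq.int(t - 8L, t + 9L)),
    stats::runif(n_anchor) < spec$bulge_probability / 2, FALSE)
  wobble <- stats::runif(n_anchor) < spec$wobble_rate
  bases5 <- vapply(seq_len(n_anchor), function(j) {
    sample(RNA_BASES, 1, prob = base_probs(j - t, spec$signal_strength))
  }, character(1))
  loop <- sample(RNA_BASES, loop_len, replace = TRUE)
  list(n_anchor = n_anchor, loop_len = loop_len, t = t, paired = paired,
       bulge3_after = bulge3_after, wobble = wobble, bases5 = bases5,
       loop = loop)
}

realize_member <- function(spec, skel, id) {
  bases5 <- skel$bases5
  mutate <- stats::runif(skel$n_anchor) < 0.2
  for (j in which(mutate)) {
    bases5[j] <- sample(RNA_BASES, 1,
                        prob = base_probs(j - skel$t, spec$signal_strength))
  }
  loop <- skel$loop
  remut <- stats::runif(skel$loop_len) < 0.3
  loop[remut] <- sample(RNA_BASES, sum(remut), replace = TRUE)

  walk_base <- character(0); walk_db <- character(0)
  for (j in seq.int(skel$n_anchor, 1L)) {
    if (skel$paired[j]) {
      walk_base <- c(walk_base, partner_base(bases5[j], skel$wobble[j]))
      walk_db <- c(walk_db, ")")
      if (skel$bulge3_after[j]) {
        walk_base <- c(walk_base, sample(RNA_BASES, 1))
        walk_db <- c(walk_db, ".")
      }
    }
  }
  seq <- paste(c(bases5, loop, walk_base), collapse = "")
  db <- paste(c(ifelse(skel$paired, "(", "."), rep(".", skel$loop_len),
                walk_db), collapse = "")
  hairpin(id, seq, db)
}

#' Generate one synthetic hairpin with annotated cleavage sites
#'
#' Byte-identical output for identical `(spec$seed, index)`. The generated
#' structure is always balanced, nested and single-loop; the 5p and 3p cut
#' sites satisfy the 2-nt overhang relation of
#' [map_cleavage_between_arms()] (the overhang-offset position is never
#' bulged by construction).
#'
#' @param spec a [synthetic_spec()].
#' @param index 1-based hairpin index within the population.
#' @return List with `hairpin`, `cd5p`, `cd3p` (both [cleavage_site()]s)
#'   and `family`.
#' @export
make_hairpin <- function(spec, index) {
  stopifnot(inherits(spec, "synthetic_spec"), index >= 1)
  fam <- ((as.integer(index) - 1L) %% spec$n_families) + 1L
  skel <- with_seed(derive_seed(spec$seed, 1000000 + fam), build_skeleton(spec))
  id <- sprintf("syn-%04d", as.integer(index))
  h <- with_seed(derive_seed(spec$seed, index), realize_member(spec, skel, id))
  pm <- pair_map(h$dotbracket)
  cd5p <- cleavage_site("5p", skel$t)
  cd3p <- cleavage_site("3p", pm[skel$t - 2L] - 1L)
  list(hairpin = h, cd5p = cd5p, cd3p = cd3p,
       family = sprintf("fam-%03d", fam))
}

#' Generate a full synthetic dataset
#'
#' Produces `n_hairpins` hairpins plus the annotation and family tables
#' consumed by the rest of the pipeline; optionally writes them in the
#' package's standard plain-text formats (FASTA, Vienna structure records,
#' annotation TSV, family-map TSV). Rendered through the patterns module,
#' each hairpin contributes one cleavage and one non-cleavage window.
#'
#' @param spec a [synthetic_spec()].
#' @param dir optional output directory; created if missing.
#' @param arm which arm's cut to annotate (default `"5p"`).
#' @return List with `hairpins` (named list of [hairpin()]s), `annotations`
#'   (data frame `hairpin_id`, `arm`, `cut_after`), `families` (named
#'   vector), `sites` (data frame with both arms' cuts), and `paths` when
#'   files were written.
#' @export
make_dataset <- function(spec, dir = NULL, arm = c("5p", "3p")) {
  arm <- match.arg(arm)
  items <- lapply(seq_len(spec$n_hairpins), function(i) make_hairpin(spec, i))
  hairpins <- lapply(items, `[[`, "hairpin")
  names(hairpins) <- vapply(hairpins, `[[`, "", "id")
  sites <- data.frame(
    hairpin_id = names(hairpins),
    cd5p = vapply(items, function(it) it$cd5p$cut_after, 0L),
    cd3p = vapply(items, function(it) it$cd3p$cut_after, 0L),
    family = vapply(items, `[[`, "", "family"),
    stringsAsFactors = FALSE
  )
  annotations <- data.frame(
    hairpin_id = sites$hairpin_id, arm = arm,
    cut_after = if (arm == "5p") sites$cd5p else sites$cd3p,
    stringsAsFactors = FALSE
  )
  families <- stats::setNames(sites$family, sites$hairpin_id)
  paths <- NULL
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- list(fasta = file.path(dir, "hairpins.fa"),
                  structures = file.path(dir, "hairpins.vienna"),
                  annotations = file.path(dir, "annotations.tsv"),
                  families = file.path(dir, "families.tsv"))
    write_hairpins(hairpins, fasta = paths$fasta, structures = paths$structures)
    prov <- list(tool = paste("dicerscan", utils::packageVersion("dicerscan")),
                 seed = spec$seed, n_hairpins = spec$n_hairpins,
                 signal_strength = spec$signal_strength)
    write_tsv_with_header(annotations, paths$annotations, prov)
    write_tsv_with_header(
      data.frame(hairpin_id = names(families), family = unname(families),
                 stringsAsFactors = FALSE),
      paths$families, prov)
  }
  list(hairpins = hairpins, annotations = annotations, families = families,
       sites = sites, paths = paths)
}
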