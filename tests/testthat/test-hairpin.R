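test_that("parse_vienna reads well-formed records, with and without energies", {
  hs <- parse_vienna(">h1\nGGGAAACCC\n(((...))) (-1.20)")
  expect_length(hs, 1)
  h <- hs[["h1"]]
  expect_equal(h$sequence, "GGGAAACCC")
  expect_equal(h$dotbracket, "(((...)))")
  expect_equal(h$mfe, -1.2)

  h2 <- parse_vienna("GGGAAACCC\n(((...)))")[[1]]
  expect_null(h2$mfe)

  multi <- parse_vienna(">a\nGGGAAACCC\n(((...))) (-2.0)\n>b\nggtaaatacc\n((......))")
  expect_named(multi, c("a", "b"))
  expect_equal(multi$b$sequence, "GGUAAAUACC")  # T->U, case folded
})

test_that("parse errors name the offending record", {
  expect_error(parse_vienna(">x\nGGGAAACCC\n((..)"), "hairpin 'x'")
  expect_error(parse_vienna(">x\nGGGAAACCC\n(((....))"), "unbalanced")
  expect_error(parse_vienna(">x\nGGGAAACCC\n((...)))("), "unbalanced")
  expect_error(parse_vienna(">x\nGGGAANCCC\n(((...)))"), "non-ACGU")
  expect_error(parse_vienna(">x\nGGGAACCC\n(((...)))"), "length")
  expect_error(parse_vienna(">x\nGGGAAACCC"), "truncated")
  # pseudoknot bracket families rejected
  expect_error(hairpin("x", "GGGAAACCC", "((<...>))"), "pseudoknot")
})

test_that("pair_map matches brackets by stack discipline", {
  expect_equal(pair_map("(((...)))"),
               c(9L, 8L, 7L, NA, NA, NA, 3L, 2L, 1L))
  expect_true(all(is.na(pair_map("........."))))
  expect_equal(pair_map("((..))"), c(6L, 5L, NA, NA, 2L, 1L))
})

test_that("pair_map round-trips through dot-bracket rendering", {
  specs <- synthetic_spec(n_hairpins = 20, seed = 9)
  for (i in 1:20) {
    db <- make_hairpin(specs, i)$hairpin$dotbracket
    pm <- pair_map(db)
    expect_identical(dicerscan:::render_dotbracket(pm), db)
    # symmetry and irreflexivity
    paired <- which(!is.na(pm))
    expect_identical(pm[pm[paired]], paired)
    expect_false(any(pm[paired] == paired))
  }
})

test_that("validate_single_loop counts hairpin loops", {
  expect_equal(validate_single_loop("(((...)))"),
               list(valid = TRUE, n_loops = 1L))
  expect_equal(validate_single_loop("((...))((...))"),
               list(valid = FALSE, n_loops = 2L))
  expect_false(validate_single_loop("((..((...))..((...))))")$valid)
  expect_equal(validate_single_loop(".........")$n_loops, 0L)
})

test_that("arm-anchored duplex alignment pairs each anchor nucleotide once", {
  h <- hairpin("h", "GGGAAACCC", "(((...)))")
  da <- build_duplex_alignment(h)
  expect_equal(nrow(da), 3)
  expect_equal(da$anchor_tok, c("G", "G", "G"))
  expect_equal(da$opp_tok, c("C", "C", "C"))
  expect_equal(da$anchor_pos, 1:3)
  expect_equal(da$opp_pos, 9:7)
})

test_that("bulged anchor positions get a gap on the complement row", {
  # pairs 1-12, 2-11, 4-10, 5-9; position 3 bulged on the 5p arm
  h <- hairpin("b", "GGAGGAAACCCC", "((.((...))))")
  da <- build_duplex_alignment(h)
  expect_equal(da$anchor_tok, c("G", "G", "A", "G", "G"))
  expect_equal(da$opp_tok, c("C", "C", NA, "C", "C"))
  expect_equal(da$anchor_pos, 1:5)
  expect_equal(da$opp_pos, c(12L, 11L, NA, 10L, 9L))
})

test_that("3p anchoring mirrors the alignment and covers each 3p stem nucleotide once", {
  h <- hairpin("b", "GGAGGAAACCCC", "((.((...))))")
  da <- build_duplex_alignment(h, anchor_arm = "3p")
  expect_equal(attr(da, "anchor_arm"), "3p")
  expect_equal(sort(da$anchor_pos), 9:12)           # every 3p stem nt exactly once
  expect_equal(da$anchor_pos, c(12L, 11L, 10L, 9L)) # read 3' -> 5'
  expect_equal(da$opp_pos, c(1L, 2L, 4L, 5L))
})

test_that("full-alignment mode inserts opposite-arm bulge columns", {
  # position 10 is a 3p bulge between partners of anchors 2 and 3
  h <- hairpin("b3", "GGGAAAAACACC", "(((.....).))")
  pm <- pair_map(h$dotbracket)
  expect_equal(pm[3], 9L)
  expect_equal(pm[2], 11L)
  da_arm <- build_duplex_alignment(h)
  expect_equal(nrow(da_arm), 3)
  da_full <- build_duplex_alignment(h, mode = "full-alignment")
  expect_equal(nrow(da_full), 4)
  gap_col <- which(is.na(da_full$anchor_pos))
  expect_equal(gap_col, 3L)
  expect_equal(da_full$opp_pos[gap_col], 10L)
  expect_equal(da_full$opp_tok[gap_col], "A")
})

test_that("paired columns agree with the pair map, wobble pairs included", {
  spec <- synthetic_spec(n_hairpins = 15, seed = 21)
  saw_wobble <- FALSE
  for (i in 1:15) {
    h <- make_hairpin(spec, i)$hairpin
    pm <- pair_map(h$dotbracket)
    da <- build_duplex_alignment(h)
    paired <- !is.na(da$opp_pos)
    expect_identical(da$opp_pos[paired], pm[da$anchor_pos[paired]])
    pairs <- paste0(da$anchor_tok[paired], da$opp_tok[paired])
    expect_true(all(pairs %in% c("AU", "UA", "GC", "CG", "GU", "UG")))
    if (any(pairs %in% c("GU", "UG"))) saw_wobble <- TRUE
  }
  expect_true(saw_wobble)
})

test_that("multiloop structures are rejected by alignment construction", {
  h <- hairpin("m", "GGAAAUUGGAAAUU", "((...))((...))")
  expect_error(build_duplex_alignment(h), "single stem-loop")
})

test_that("2-nt overhang maps the worked 26-nt stem example", {
  pm <- pair_map(paste0(strrep("(", 10), strrep(".", 6), strrep(")", 10)))
  out <- map_cleavage_between_arms(pm, cleavage_site("5p", 8))
  expect_equal(out$arm, "3p")
  expect_equal(out$cut_after, 20L)
  back <- map_cleavage_between_arms(pm, out)
  expect_equal(back$arm, "5p")
  expect_equal(back$cut_after, 8L)
})

test_that("arm mapping round-trips on all interior cuts of perfect stems", {
  for (n_pairs in c(10, 14, 18)) {
    h <- perfect_stem(n_pairs)
    pm <- pair_map(h$dotbracket)
    for (i in 3:(n_pairs - 1)) {
      s3 <- map_cleavage_between_arms(pm, cleavage_site("5p", i))
      back <- map_cleavage_between_arms(pm, s3)
      expect_equal(back$cut_after, i)
      expect_equal(back$arm, "5p")
    }
  }
})

test_that("bulge at the overhang offset errors in strict mode, falls back in lenient", {
  db <- "(((((.((((....)))))))))"   # position 6 unpaired
  pm <- pair_map(db)
  site <- cleavage_site("5p", 8)    # offset position 6 is bulged
  expect_error(map_cleavage_between_arms(pm, site), "unpaired at overhang offset")
  len <- map_cleavage_between_arms(pm, site, strict = FALSE)
  expect_equal(len$arm, "3p")
  # nearest paired neighbour (position 5) with shift compensation
  expect_equal(len$cut_after, pm[5] + (5 - 6) - 1L)
  expect_match(attr(len, "warning"), "nearest paired")
})

test_that("FASTA reading and RNAfold shell-out round-trip a sequence", {
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">s1", "GGGGGAAAAAACCCCC", ">s2 desc", "acguacgu"), fa)
  seqs <- read_hairpin_fasta(fa)
  expect_equal(seqs, c(s1 = "GGGGGAAAAAACCCCC", s2 = "ACGUACGU"))
  if (nzchar(Sys.which("RNAfold"))) {
    hs <- fold_hairpins(seqs["s1"])
    expect_equal(hs[["s1"]]$sequence, "GGGGGAAAAAACCCCC")
    expect_equal(nchar(hs[["s1"]]$dotbracket), 16)
    expect_true(is.numeric(hs[["s1"]]$mfe))
  }
})
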