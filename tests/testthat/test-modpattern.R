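test_that("energy classification maps A/U to X and G/C to Y", {
  expect_equal(classify_energy("AUGC"), "XXYY")
  expect_equal(classify_energy(ref_strands$s2_antisense),
               "XXXXXXYXYXYYXXYYXXYYY")
  expect_error(classify_energy(""), "non-empty")
})

test_that("the bundled pattern table matches the printed cells", {
  printed <- tibble::tribble(
    ~case, ~set1_even, ~set2_odd, ~sense,
    "XXX",  "mXmXfX", "mXfXmX", "fXmXmX",
    "YYY",  "mYmYfY", "mYfYmY", "fYmYmY",
    "XYX",  "mXfYmX", "fXmYfX", "fXfYmX",
    "YXY",  "fYmXfY", "mYfXmY", "mYmXfY",
    "5'XY", "mXfY",   "fXmY",   "fXfX",
    "5'YX", "mYfX",   "fYmX",   "fYfX",
    "5'XX", "mXmX",   "fXfX",   "mXfX",
    "3'XY", "mXfY",   "fXmY",   "mXfX",
    "3'YX", "fYmX",   "mYfX",   "mYmX",
    "3'XX", "fXfX",   "mXmX",   "fXmX",
    "3'YY", "mYmY",   "fYfY",   "fYmY")
  tab <- pattern_table(derived = FALSE)
  expect_equal(tab[c("case", "set1_even", "set2_odd", "sense")], printed)
  # every cell covers its case length with m/f sugar letters
  for (col in c("set1_even", "set2_odd", "sense")) {
    expect_equal(nchar(tab[[col]]), 2 * nchar(sub("^[35]'", "", tab$case)))
    sugars <- unlist(lapply(tab[[col]], function(x) {
      ch <- strsplit(x, "")[[1]]; ch[seq(1, length(ch), 2)]
    }))
    expect_true(all(sugars %in% c("m", "f")))
  }
})

test_that("segmentation partitions any strand with terminals claimed first", {
  withr::with_seed(71, {
    for (i in 1:40) {
      s <- random_rna(sample(5:30, 1))
      segs <- segment_classes(classify_energy(s))
      expect_equal(sum(segs$length), nchar(s))
      expect_equal(segs$start[1], 1)
      expect_equal(segs$end[nrow(segs)], nchar(s))
      # contiguous, non-overlapping coverage
      expect_equal(segs$start[-1], segs$end[-nrow(segs)] + 1)
      expect_true(startsWith(segs$case[1], "5'"))
      expect_true(startsWith(segs$case[nrow(segs)], "3'"))
    }
  })
  expect_error(segment_classes("XYXY"), "at least 5")
})

test_that("pattern application follows the table cells positionwise", {
  # toy strand GCAUA (classes YYXXX): 5'YY | X | 3'XX under set2_odd
  # -> mYfY prefix, mX singleton, mXmX terminal
  toy <- apply_patterns("GCAUA", column = "set2_odd")
  expect_equal(serialize_modified(toy), "mGfCmAmUmA")
  # sense-column XXX cell is fXmXmX: strand with one internal XXX triplet
  s7 <- apply_patterns("AAAAAAA", column = "sense")
  expect_equal(serialize_modified(s7), "mAfAfAmAmAfAmA")
  # full 2'-OMe control design
  ome <- apply_patterns(ref_strands$s2_antisense, full_ome = TRUE)
  expect_true(all(ome$sugar == "m"))
  expect_equal(oligo_bases(ome), ref_strands$s2_antisense)
})

test_that("modification never alters the base sequence or length", {
  withr::with_seed(72, {
    for (col in c("set1_even", "set2_odd", "sense")) {
      for (i in 1:10) {
        s <- random_rna(sample(8:25, 1))
        o <- apply_patterns(s, column = col)
        expect_equal(nrow(o), nchar(s))
        expect_equal(oligo_bases(o), s)
        expect_true(all(o$sugar %in% c("m", "f")))
        # serialization round-trips the design
        expect_identical(parse_modified(serialize_modified(o))$sugar, o$sugar)
      }
    }
  })
})

test_that("missing pattern rows are reported by case name", {
  tab <- pattern_table(derived = FALSE) # no derived rows: singletons missing
  expect_error(apply_patterns("GCAUA", table = tab), "case")
})

test_that("junction motifs of the lead modified guide are detected", {
  oligo <- parse_modified(ref_strands$s2_12_antisense)
  rep <- junction_pattern_check(oligo)
  expect_true(rep$five_prime_mxfx)      # 5' mAfU
  expect_true(rep$both_classes_10_11)   # U10 / G11
  expect_true(rep$three_prime_motif)    # 3' fGmG on a G/C tail
  allm <- uniform_oligo(ref_strands$s2_antisense, "m")
  repm <- junction_pattern_check(allm)
  expect_false(repm$has_junction_myfymxfx)
  expect_false(repm$five_prime_mxfx)
  expect_length(repm$junction_myfymxfx_at, 0)
})
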