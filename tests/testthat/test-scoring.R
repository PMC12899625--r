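test_that("the engineered duplex scores exactly as the hand evaluation", {
  # criterion-by-criterion hand evaluation of the engineered site:
  # GC 8/21 = 38.1% in range; antisense GC 0% at 2-7 and 6/11 = 54.5% at
  # 8-18; A/U valley at sense 9-14; no tandem repeats; UU overhang; A at
  # antisense 1 and 6; G at sense 1; A at sense 3/19; no G/C at sense 19;
  # no G at sense 13; U at sense 10 -> 13 points from evaluable criteria
  card <- score_duplex(engineered_site())
  expect_s3_class(card, "sirna_scorecard")
  passed <- card$criterion[card$passed]
  expect_setequal(passed,
                  c("gc_global", "gc_asymmetry", "energy_valley",
                    "low_repeats", "tt_overhang", "as5_au", "s5_gc",
                    "as6_a", "s3_s19_a", "s19_weak", "s13_no_g", "s10_u"))
  expect_equal(attr(card, "total"), 13)
  expect_true(attr(card, "selectable"))
  not_eval <- card$criterion[!card$evaluated]
  expect_setequal(not_eval, c("accessibility", "offtarget"))
  expect_true(all(card$points[!card$evaluated] == 0))
})

test_that("positional criteria read the stated positions directly", {
  # sense with U at 10 and A at 3 and 19, global GC at 40%
  s <- "GCAGGCCGAUUAAGUCAUAUU"
  card <- score_duplex(s)
  get <- function(id, col) card[[col]][card$criterion == id]
  expect_true(get("s10_u", "passed"))
  expect_true(get("s3_s19_a", "passed"))
  expect_equal(gc_fraction(s) * 100, 42.9, tolerance = 0.05)
  expect_true(get("gc_global", "passed"))
})

test_that("weights sum to 16 while the stated maximum is 15", {
  p <- score_params()
  expect_equal(sum(p$weights), 16)
  expect_equal(p$stated_max, 15)
  expect_equal(unname(p$weights[c("energy_valley", "offtarget")]), c(2L, 2L))
  card <- score_duplex(engineered_site())
  expect_equal(attr(card, "max_points"), 16)
  expect_equal(attr(card, "stated_max"), 15)
  expect_lte(attr(card, "total"), attr(card, "max_points"))
})

test_that("scoring is a pure function of duplex and context", {
  fx <- make_fixtures(seed = 61)
  c1 <- score_duplex(fx$site, target_start = fx$site_start,
                     transcript = fx$transcripts$seq,
                     background = fx$background, target_id = "target_tx")
  c2 <- score_duplex(fx$site, target_start = fx$site_start,
                     transcript = fx$transcripts$seq,
                     background = fx$background, target_id = "target_tx")
  expect_identical(tidy(c1), tidy(c2))
  expect_identical(attr(c1, "total"), attr(c2, "total"))
})

test_that("an off-target hit can only lower the total", {
  fx_clean <- make_fixtures(seed = 62)
  fx_hit <- make_fixtures(seed = 62, offtarget_mismatches = 2)
  base_args <- list(fx_clean$site, target_start = fx_clean$site_start,
                    transcript = fx_clean$transcripts$seq,
                    target_id = "target_tx")
  t_clean <- attr(do.call(score_duplex,
                          c(base_args, list(background = fx_clean$background))),
                  "total")
  t_hit <- attr(do.call(score_duplex,
                        c(base_args, list(background = fx_hit$background))),
                "total")
  expect_lte(t_hit, t_clean)
  expect_equal(t_clean - t_hit, 2) # the clearance weight
})

test_that("ranking is descending with documented tie-breaks", {
  scored <- tibble::tibble(
    name = c("a", "b", "c"), target_start = c(5, 1, 9),
    score_total = c(12, 8, 14), energy_valley = c(2, 0, 2),
    offtarget = c(2, 2, 2), selectable = c(TRUE, FALSE, TRUE))
  ranked <- rank_candidates(scored)
  expect_equal(ranked$score_total, c(14, 12, 8))
  expect_equal(ranked$rank, 1:3)
  # equal totals: valley, then off-target, then lower start
  tied <- tibble::tibble(
    name = c("p", "q", "r"), target_start = c(7, 3, 5),
    score_total = c(10, 10, 10), energy_valley = c(0, 0, 2),
    offtarget = c(2, 0, 2))
  expect_equal(rank_candidates(tied)$name, c("r", "p", "q"))
  expect_equal(rank_candidates(tied)$name,
               rank_candidates(tied[c(2, 3, 1), ])$name)
  expect_equal(nrow(rank_candidates(scored[0, ])), 0)
})

test_that("selection threshold is a strict inequality", {
  p <- score_params(selection_threshold = 12)
  card <- score_duplex(engineered_site(), params = p) # total 13
  expect_true(attr(card, "selectable"))
  p13 <- score_params(selection_threshold = 13)
  expect_false(attr(score_duplex(engineered_site(), params = p13),
                    "selectable"))
})

test_that("auxiliary composition checks segment and balance as documented", {
  alt <- "AUGCAUGCAUGCAUGCAUGCA"
  chk <- composition_checks(alt)
  expect_true(chk$islands_2_3)   # all islets of 2 nt
  expect_true(chk$balance)       # 10/21 = 47.6% GC
  expect_false(chk$run_4to6)
  homo <- strrep("A", 21)
  expect_false(composition_checks(homo)$balance)
  expect_false(composition_checks(homo)$islands_2_3)
  # A/U start with C/G at 3-4 satisfies the conditional rule
  cond <- paste0("AUCG", strrep("AUGC", 4), "A")
  expect_true(composition_checks(cond)$conditional_34)
  expect_false(composition_checks(homo)$conditional_34)
  # one 4-6-mer homo-energy run is detected and tolerated by the islet rule
  run4 <- "GCAUGCAAAAGCAUGCAUGCA"
  chk4 <- composition_checks(run4)
  expect_true(chk4$run_4to6)
  expect_true(chk4$islands_2_3)
})
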