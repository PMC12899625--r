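test_that("enumeration yields one duplex per window position", {
  tx <- withr::with_seed(3, random_rna(30))
  cands <- enumerate_candidates(tx)
  expect_equal(nrow(cands), 10) # 30 - 21 + 1
  expect_equal(cands$target_start, 1:10)
  expect_true(all(nchar(cands$sense) == 21))
  expect_true(all(nchar(cands$antisense) == 21))
  # windows lie within the transcript and sense equals the window
  expect_true(all(substr(rep(as_rna(tx), 10), cands$target_start,
                         cands$target_end) == cands$sense))
  # a 21-nt transcript yields exactly one candidate equal to itself
  tx21 <- withr::with_seed(4, random_rna(21))
  one <- enumerate_candidates(tx21)
  expect_equal(nrow(one), 1)
  expect_equal(one$sense, tx21)
})

test_that("enumeration count is L - 20 and short transcripts warn", {
  withr::with_seed(5, {
    for (L in c(21, 25, 60, 121)) {
      expect_equal(nrow(enumerate_candidates(random_rna(L))), L - 20)
    }
  })
  expect_warning(out <- enumerate_candidates(withr::with_seed(6, random_rna(15))),
                 "shorter")
  expect_equal(nrow(out), 0)
})

test_that("duplex geometry matches the printed reference duplex", {
  # embed the printed sense strand; the enumerated candidate's paired core
  # must reproduce the printed guide strand's 19-nt core
  flank5 <- withr::with_seed(8, random_rna(20))
  flank3 <- withr::with_seed(9, random_rna(20))
  tx <- paste0(flank5, ref_strands$s2_sense, flank3)
  cands <- enumerate_candidates(tx)
  hit <- dplyr::filter(cands, .data$sense == ref_strands$s2_sense)
  expect_equal(nrow(hit), 1)
  expect_equal(hit$target_start, 21)
  expect_equal(substr(hit$antisense, 3, 21),
               substr(ref_strands$s2_antisense, 1, 19))
  # duplex-core complementarity invariant
  expect_equal(reverse_complement(substr(hit$sense, 1, 19)),
               substr(hit$antisense, 3, 21))
})

test_that("first-pass rules evaluate hand-checkable strands", {
  site <- engineered_site()
  anti <- reverse_complement(site)
  # engineered site: A/U antisense 5' end, G/C sense 5' end, A/U-rich seed
  expect_true(rule_uitei(site, anti))
  expect_true(rule_reynolds(site))
  expect_true(rule_amarzguioui(site))
  # an all-G sense violates the GC-content bounds of every rule set
  allg <- strrep("G", 21)
  expect_false(rule_uitei(allg, reverse_complement(allg)))
  expect_false(rule_reynolds(allg))
  expect_false(rule_amarzguioui(allg))
})

test_that("first-pass filtering is monotone, idempotent and auditable", {
  tx <- withr::with_seed(10, random_rna(120))
  cands <- enumerate_candidates(tx)
  filtered <- first_pass_filter(cands)
  expect_true(all(filtered$name %in% cands$name))
  expect_true(all(c("uitei", "reynolds", "amarzguioui", "first_pass")
                  %in% names(filtered)))
  again <- first_pass_filter(filtered)
  expect_equal(again$name, filtered$name)
  # intersection is at least as strict as union
  inter <- first_pass_filter(cands, mode = "intersection")
  expect_true(all(inter$name %in% filtered$name))
  # flags are populated for kept and dropped rows alike
  flagged <- first_pass_filter(cands, keep_all = TRUE)
  expect_equal(nrow(flagged), nrow(cands))
  # no-op and error cases
  expect_equal(first_pass_filter(cands, rules = character())$name, cands$name)
  expect_error(first_pass_filter(cands, rules = "unknown_rule"), "unknown rule")
})

test_that("a planted all-rules site survives the intersection filter", {
  fx <- make_fixtures(seed = 21)
  cands <- enumerate_candidates(fx$transcripts)
  kept <- first_pass_filter(cands, mode = "intersection")
  expect_true(fx$site_start %in% kept$target_start)
  expect_true(engineered_site() %in% kept$sense)
})
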