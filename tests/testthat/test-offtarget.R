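test_that("planted matches are reported at the exact identity", {
  withr::with_seed(51, {
    q <- random_rna(21)
    host <- random_rna(200)
    substr(host, 90, 110) <- q
    bg <- tibble::tibble(name = "bg1", seq = host)
    hits <- scan_offtargets(sense = q, background = bg)
    exact <- dplyr::filter(hits, .data$identity_pct == 100)
    expect_gte(nrow(exact), 1)
    expect_equal(exact$subject_start[1], 90)
    # one substitution -> 20/21
    q1 <- q
    substr(q1, 11, 11) <- setdiff(c("A", "C", "G", "U"),
                                  substr(q, 11, 11))[1]
    hits1 <- scan_offtargets(sense = q1, background = bg)
    expect_true(any(abs(hits1$identity_pct - 100 * 20 / 21) < 1e-9))
  })
})

test_that("the 85% threshold separates 3 from 4 mismatches on 21-mers", {
  fx <- make_fixtures(seed = 52, offtarget_mismatches = c(3, 4), n_decoys = 0)
  q <- fx$site
  hits <- scan_offtargets(sense = q, antisense = reverse_complement(q),
                          background = fx$background)
  hits <- dplyr::filter(hits, .data$subject_id != "target_tx")
  expect_true(any(grepl("offtarget_m3", hits$subject_id)))
  expect_false(any(grepl("offtarget_m4", hits$subject_id)))
  m3 <- dplyr::filter(hits, grepl("offtarget_m3", .data$subject_id))
  expect_equal(unique(m3$identity_pct), 100 * 18 / 21)
})

test_that("seeded scan agrees with the brute-force all-window scan", {
  withr::with_seed(53, {
    for (i in 1:8) {
      q <- random_rna(21)
      subj <- random_rna(300)
      # plant related copies at several mutation loads
      for (m in 0:4) {
        at <- 40 + m * 50
        mut <- q
        if (m > 0) {
          ch <- strsplit(mut, "")[[1]]
          pos <- sample(21, m)
          swap <- c(A = "C", C = "A", G = "U", U = "G")
          ch[pos] <- swap[ch[pos]]
          mut <- paste(ch, collapse = "")
        }
        substr(subj, at, at + 20) <- mut
      }
      bg <- tibble::tibble(name = "s", seq = subj)
      seeded <- scan_offtargets(sense = q, background = bg, method = "seed")
      exhaust <- scan_offtargets(sense = q, background = bg,
                                 method = "exhaustive")
      oracle <- brute_offtarget_scan(q, subj, 85)
      key <- function(df) {
        df <- df[order(df$orientation, df$subject_start), , drop = FALSE]
        paste(df$orientation, df$subject_start, round(df$identity_pct, 6))
      }
      expect_identical(key(as.data.frame(seeded)), key(oracle))
      expect_identical(key(as.data.frame(exhaust)), key(oracle))
    }
  })
})

test_that("hit tables are independent of background record order", {
  fx <- make_fixtures(seed = 54, offtarget_mismatches = c(2, 3))
  q <- fx$site
  bg <- fx$background
  h1 <- scan_offtargets(sense = q, background = bg)
  h2 <- scan_offtargets(sense = q, background = bg[rev(seq_len(nrow(bg))), ])
  expect_equal(as.data.frame(h1), as.data.frame(h2))
})

test_that("clearance excludes the intended target by id only", {
  fx <- make_fixtures(seed = 55, n_decoys = 2)
  q <- fx$site
  hits <- scan_offtargets(sense = q, antisense = reverse_complement(q),
                          background = fx$background)
  # the only hits are self-matches on the target record
  expect_true(all(hits$subject_id == "target_tx"))
  expect_false(offtarget_clearance(hits))
  expect_true(offtarget_clearance(hits, target_id = "target_tx"))
  expect_true(offtarget_clearance(hits[0, ]))
})

test_that("degenerate inputs are rejected", {
  expect_error(scan_offtargets(sense = "ACGUACGUACGUACGUACGUA",
                               background = tibble::tibble()),
               "unevaluable")
  bg <- tibble::tibble(name = "x", seq = "ACGU")
  expect_error(scan_offtargets(background = bg), "at least one query")
  expect_error(scan_offtargets(sense = "ACGU", background = bg,
                               threshold_pct = 0), "threshold")
})
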