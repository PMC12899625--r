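test_that("single-residue and delta masses are exact", {
  expect_equal(oligo_mass("rU"), 244.20, tolerance = 0.005)
  expect_equal(oligo_mass("rA"), 267.25, tolerance = 0.005)
  # 2'-OMe adds one CH2 per residue
  expect_equal(oligo_mass("mUmU", digits = NULL) -
                 oligo_mass("rUrU", digits = NULL),
               2 * 14.027, tolerance = 1e-6)
  # 2'-F replaces the 2'-OH
  expect_equal(oligo_mass("fU", digits = NULL) -
                 oligo_mass("rU", digits = NULL),
               18.998 - 15.999 - 1.008, tolerance = 1e-6)
  # each PS linkage swaps one oxygen for sulfur
  expect_equal(oligo_mass("mAsmU", digits = NULL) -
                 oligo_mass("mAmU", digits = NULL),
               32.06 - 15.999, tolerance = 1e-6)
})

test_that("the modified guide strand reproduces the printed calculated Mw", {
  expect_equal(oligo_mass(ref_strands$s2_12_antisense), 6889.34, tolerance = 0.1)
})

test_that("mass is additive in residues", {
  base <- "mAfUmGdT"
  o1 <- parse_modified(base)
  o2 <- parse_modified(paste0(base, "rC"))
  tab <- mass_table()
  expect_equal(oligo_mass(o2, digits = NULL) - oligo_mass(o1, digits = NULL),
               unname(tab$nucleoside[["C"]] + tab$delta[["r"]] +
                        tab$delta[["bridge"]]),
               tolerance = 1e-9)
})

test_that("additive masses agree with one-shot elemental summation", {
  withr::with_seed(81, {
    for (i in 1:10) {
      o <- parse_modified(random_modified_notation(sample(5:25, 1)))
      expect_equal(oligo_mass(o, digits = NULL), brute_oligo_mass(o),
                   tolerance = 0.05)
    }
  })
  allribo <- uniform_oligo(withr::with_seed(82, random_rna(21)), "r")
  expect_equal(oligo_mass(allribo, digits = NULL), brute_oligo_mass(allribo),
               tolerance = 0.05)
})

test_that("conjugate adducts and input validation work", {
  m0 <- oligo_mass("mAmU", digits = NULL)
  expect_equal(oligo_mass("mAmU", adduct = 1500, digits = NULL), m0 + 1500)
  bad <- parse_modified("mAmU")
  bad$sugar[1] <- "z"
  expect_error(oligo_mass(bad), "unknown sugar")
})

test_that("chained stage efficiencies reproduce the reported totals", {
  inline3 <- chain_yield(c(synthesis = 0.49, chromatography = 0.55,
                           desalting = 0.95))
  expect_equal(attr(inline3, "total"), 0.256025)
  expect_equal(attr(inline3, "label"), "26%")
  inline5 <- chain_yield(c(0.37, 0.55, 0.95))
  expect_equal(attr(inline5, "label"), "19%")
  expect_equal(attr(chain_yield(1.0), "label"), "100%")
})

test_that("total yield is permutation-invariant and stage-bounded", {
  withr::with_seed(83, {
    for (i in 1:10) {
      eff <- runif(sample(2:6, 1), 0.2, 1)
      tot <- attr(chain_yield(eff), "total")
      expect_equal(tot, attr(chain_yield(rev(eff)), "total"))
      expect_lte(tot, min(eff))
    }
  })
  expect_error(chain_yield(c(0.5, 0)), "0, 1")
  expect_error(chain_yield(c(0.5, 1.2)), "0, 1")
  expect_error(chain_yield(numeric()), "no stages")
})

test_that("delta-delta-Cq follows the closed-form identities", {
  mk <- function(t, h) tibble::tibble(ct_target = t, ct_housekeeping = h)
  # per-record normalization
  expect_equal(delta_ct(25.38, 25.00), 0.38)
  # ddCt 0 -> fold change 1; ddCt 1 -> 0.5
  same <- fold_change(mk(25.38, 25.00), mk(25.38, 25.00))
  expect_equal(same$ddct, 0)
  expect_equal(same$fold_change, 1)
  one <- fold_change(mk(26.0, 25.0), mk(25.0, 25.0))
  expect_equal(one$ddct, 1)
  expect_equal(one$fold_change, 0.5)
  # group means are used
  grp <- fold_change(mk(c(26, 27), c(25, 25)), mk(c(25, 25), c(25, 25)))
  expect_equal(grp$ddct, 1.5)
  expect_equal(grp$fold_change, 2^-1.5)
  expect_error(fold_change(mk(25, 25), tibble::tibble()), "at least one row")
  expect_error(delta_ct(-1, 25), "positive")
})
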