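# Printed reference strands (unmodified siPCSK9_2 duplex and the
# 2'-OMe/2'-F-modified siPCSK9_2_12 strands) used as fixed fixtures.
ref_strands <- list(
  s2_sense = "CAAGCAAGCAGACAUUUAUCU",
  s2_antisense = "AUAAAUGUCUGCUUGCUUGGG",
  s2_12_antisense = "mAfUmAfAmAfUmGmUmCmUmGfCmUfUmGfCmUfUmGfGmG",
  s2_12_sense = "fCmAmAmGmCmAmAmGmCmAfGfAfCmAmUmUmUmAmUmCmU"
)

random_rna <- function(n, p = c(A = 0.3, C = 0.2, G = 0.2, U = 0.3)) {
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

random_modified_notation <- function(n) {
  sugars <- sample(c("r", "m", "f", "d"), n, replace = TRUE)
  bases <- sample(c("A", "C", "G", "U", "T"), n, replace = TRUE)
  ps <- c(sample(c("", "s"), n - 1, replace = TRUE, prob = c(0.8, 0.2)), "")
  paste0(sugars, bases, ps, collapse = "")
}
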