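#' Published first-pass siRNA selection rules
#'
#' Predicates for the three classic published rule sets used for first-pass
#' candidate filtering. The duplex geometry is the 21/21-mer produced by
#' [enumerate_candidates()]; positional indices are 1-based from the 5' end
#' of the named strand, and "core" means sense positions 1-19.
#'
#' * `rule_uitei()`: the class-Ia conditions — A/U at the antisense 5' end;
#'   G/C at the sense 5' end; at least 4 A/U residues among antisense
#'   positions 1-7; no G/C stretch of 10 nt or more.
#' * `rule_reynolds()`: the 8-criterion score — +1 for core GC content
#'   30-52%; +1 per A/U at sense positions 15-19; +1 for absence of internal
#'   repeats (approximated as no self-complementary stretch of 5 nt or more
#'   within the core); +1 each for A at sense 19, A at sense 3, U at sense
#'   10; -1 for G/C at sense 19; -1 for G at sense 13. Functional at
#'   score >= 6.
#' * `rule_amarzguioui()`: core GC content 31.6-57.9% plus at least two of
#'   the three asymmetry/composition features — strong sense 5' end (G/C at
#'   position 1), A at sense position 6, weak sense 3' end (A/U at
#'   position 19).
#'
#' @param sense,antisense Duplex strands, 5'->3' (21-mers by convention;
#'   any length >= 19 is accepted).
#' @return Logical scalar.
#' @name first_pass_rules
NULL

sense_core <- function(sense, core_len = 19L) {
  substr(as_rna(check_strand(sense)), 1L, core_len)
}

#' @rdname first_pass_rules
#' @export
rule_uitei <- function(sense, antisense) {
  s <- as_rna(check_strand(sense))
  a <- as_rna(check_strand(antisense))
  au <- c("A", "U")
  seed <- seq_chars(substr(a, 1, 7))
  cond1 <- seq_chars(a)[1] %in% au
  cond2 <- seq_chars(s)[1] %in% c("G", "C")
  cond3 <- sum(seed %in% au) >= 4
  runs <- rle(seq_chars(s) %in% c("G", "C"))
  cond4 <- !any(runs$values & runs$lengths >= 10)
  cond1 && cond2 && cond3 && cond4
}

# TRUE when no substring of length k has its reverse complement elsewhere in
# the strand (a proxy for hairpin-forming internal repeats)
no_internal_repeat <- function(seq, k = 5L) {
  n <- nchar(seq)
  if (n < 2 * k) return(TRUE)
  subs <- substring(seq, 1:(n - k + 1L), k:n)
  rcs <- reverse_complement(subs)
  !any(vapply(rcs, function(r) grepl(r, seq, fixed = TRUE), logical(1)))
}

#' @rdname first_pass_rules
#' @export
rule_reynolds <- function(sense, antisense = NULL) {
  core <- sense_core(sense)
  ch <- seq_chars(core)
  au <- c("A", "U")
  score <- 0L
  gc <- gc_fraction(core) * 100
  if (gc >= 30 && gc <= 52) score <- score + 1L
  score <- score + sum(ch[15:19] %in% au)
  if (no_internal_repeat(core)) score <- score + 1L
  if (ch[19] == "A") score <- score + 1L
  if (ch[3] == "A") score <- score + 1L
  if (ch[10] == "U") score <- score + 1L
  if (ch[19] %in% c("G", "C")) score <- score - 1L
  if (ch[13] == "G") score <- score - 1L
  score >= 6L
}

#' @rdname first_pass_rules
#' @export
rule_amarzguioui <- function(sense, antisense = NULL) {
  core <- sense_core(sense)
  ch <- seq_chars(core)
  gc <- gc_fraction(core) * 100
  if (gc < 31.6 || gc > 57.9) return(FALSE)
  features <- c(ch[1] %in% c("G", "C"),
                ch[6] == "A",
                ch[19] %in% c("A", "U"))
  sum(features) >= 2
}

first_pass_rule_set <- function() {
  list(uitei = rule_uitei, reynolds = rule_reynolds,
       amarzguioui = rule_amarzguioui)
}
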