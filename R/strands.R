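#' Validate an RNA/DNA strand sequence
#'
#' Strands are plain uppercase character strings over `A,C,G,U` (RNA) with `T`
#' tolerated for DNA-style 3' overhangs. All user-facing functions accept
#' strands in either case; internally everything is canonicalised to
#' uppercase.
#'
#' @param seq Character vector of sequences.
#' @param allow_t Allow `T` in addition to the RNA alphabet (default `TRUE`,
#'   since deoxy `TT` overhangs are common in synthetic duplexes).
#' @return The canonical uppercase sequence(s), invisibly validated.
#' @export
check_strand <- function(seq, allow_t = TRUE) {
  if (length(seq) == 0 || any(is.na(seq)) || any(nchar(seq) == 0)) {
    stop("strand sequence must be a non-empty string", call. = FALSE)
  }
  seq <- toupper(seq)
  alphabet <- if (allow_t) "ACGUT" else "ACGU"
  bad <- stringr::str_detect(seq, sprintf("[^%s]", alphabet))
  if (any(bad)) {
    ch <- stringr::str_remove_all(seq[bad][1], sprintf("[%s]", alphabet))
    stop(sprintf("invalid character '%s' in strand (alphabet %s)",
                 substr(ch, 1, 1), alphabet), call. = FALSE)
  }
  seq
}

#' Reverse complement of an RNA strand
#'
#' Watson-Crick complement, reversed, in the RNA alphabet. `T` is treated as
#' `U` for pairing, so the result is always pure RNA. The operation is an
#' involution on RNA sequences.
#'
#' @param seq Character vector of sequences (`A,C,G,U,T`).
#' @return Character vector of reverse complements, 5'->3'.
#' @examples
#' reverse_complement("AUGC")  # "GCAU"
#' @export
reverse_complement <- function(seq) {
  seq <- check_strand(seq)
  comp <- chartr("ACGUT", "UGCAA", seq)
  vapply(strsplit(comp, ""), function(x) paste(rev(x), collapse = ""), "")
}

#' Convert a sequence to the RNA alphabet
#'
#' @param seq Character vector; `T` becomes `U`.
#' @return RNA-alphabet sequences.
#' @export
as_rna <- function(seq) chartr("Tt", "Uu", toupper(seq))

#' GC fraction of a sequence
#'
#' @param seq Character vector.
#' @param from,to Optional 1-based inclusive positional window; defaults to
#'   the whole sequence.
#' @return Numeric fraction in \[0, 1\].
#' @export
gc_fraction <- function(seq, from = 1L, to = NULL) {
  seq <- check_strand(seq)
  vapply(seq, function(s) {
    end <- if (is.null(to)) nchar(s) else min(to, nchar(s))
    s <- substr(s, from, end)
    mean(strsplit(s, "")[[1]] %in% c("G", "C"))
  }, numeric(1), USE.NAMES = FALSE)
}

# split a sequence into single characters
seq_chars <- function(seq) strsplit(seq, "")[[1]]
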