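#' Read a FASTA file into a tibble of strands
#'
#' Thin wrapper over [Biostrings::readBStringSet()]. Sequences are
#' canonicalised to uppercase; with `as_rna = TRUE` (the default) `T` is
#' converted to `U` so downstream positional criteria always see the RNA
#' alphabet.
#'
#' @param path Path to a FASTA file.
#' @param as_rna Convert `T` to `U` on read (default `TRUE`).
#' @return A tibble with columns `name`, `seq`, `length`. An empty file
#'   yields a zero-row tibble.
#' @export
read_fasta <- function(path, as_rna = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (file.size(path) == 0) {
    return(tibble::tibble(name = character(), seq = character(),
                          length = integer()))
  }
  set <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(set))
  if (as_rna) seqs <- as_rna(seqs)
  # take the id up to the first whitespace, as BLAST-style tools do
  ids <- stringr::str_extract(names(set), "^\\S+")
  tibble::tibble(name = ids, seq = unname(seqs),
                 length = nchar(unname(seqs)))
}

#' Write strands to a FASTA file
#'
#' @param strands A data frame with columns `name` and `seq` (as returned by
#'   [read_fasta()]), or a named character vector.
#' @param path Output path.
#' @param width Line wrap width for sequence lines (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(strands, path, width = 60L) {
  if (is.character(strands)) {
    strands <- tibble::tibble(name = names(strands), seq = unname(strands))
  }
  stopifnot(all(c("name", "seq") %in% names(strands)))
  set <- Biostrings::BStringSet(rlang::set_names(strands$seq, strands$name))
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}
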