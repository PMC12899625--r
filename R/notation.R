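#' Parse a modified-oligonucleotide notation string
#'
#' The notation is a concatenation of two-character tokens
#' `<sugar><base>` where the sugar prefix is one of `r` (ribo), `m`
#' (2'-O-methyl), `f` (2'-fluoro) or `d` (deoxy) and the base is one of
#' `A,C,G,U,T` -- e.g. `"mAfUmA"`. An `s` immediately after a token marks a
#' phosphorothioate (PS) linkage on the 3' side of that residue (Inclisiran
#' style, e.g. `"mAsfUs mA"` without the spaces). The final residue carries no
#' internucleotide linkage, so a trailing `s` is an error. Parsing is
#' case-insensitive in the base letter; sugar prefixes are lowercase.
#'
#' @param notation A single notation string.
#' @param name Optional oligo name stored as an attribute.
#' @return A `modified_oligo`: a tibble with one row per residue and columns
#'   `pos`, `base`, `sugar` (`r/m/f/d`), `linkage3` (`po/ps`; the last residue
#'   is always `po`).
#' @examples
#' parse_modified("mAfUmA")
#' @export
parse_modified <- function(notation, name = NULL) {
  if (!is.character(notation) || length(notation) != 1 || is.na(notation) ||
      nchar(notation) == 0) {
    stop("notation must be a single non-empty string", call. = FALSE)
  }
  chars <- seq_chars(notation)
  n <- length(chars)
  base <- character()
  sugar <- character()
  link <- character()
  i <- 1L
  while (i <= n) {
    ch <- chars[i]
    if (ch == "s" || ch == "S") {
      if (length(base) == 0) {
        stop(sprintf("parse error at offset %d: linkage 's' before any residue", i),
             call. = FALSE)
      }
      if (i > n - 0 && i == n) {
        # trailing s handled below after loop via position bookkeeping
      }
      if (link[length(link)] == "ps") {
        stop(sprintf("parse error at offset %d: duplicated 's' linkage mark", i),
             call. = FALSE)
      }
      link[length(link)] <- "ps"
      i <- i + 1L
      next
    }
    sg <- tolower(ch)
    if (!sg %in% c("r", "m", "f", "d")) {
      stop(sprintf("parse error at offset %d: unknown sugar prefix '%s'", i, ch),
           call. = FALSE)
    }
    if (i + 1L > n) {
      stop(sprintf("parse error at offset %d: dangling sugar prefix '%s'", i, ch),
           call. = FALSE)
    }
    b <- toupper(chars[i + 1L])
    if (!b %in% c("A", "C", "G", "U", "T")) {
      stop(sprintf("parse error at offset %d: unknown base '%s'", i + 1L,
                   chars[i + 1L]), call. = FALSE)
    }
    base <- c(base, b)
    sugar <- c(sugar, sg)
    link <- c(link, "po")
    i <- i + 2L
  }
  if (length(base) == 0) stop("notation contains no residues", call. = FALSE)
  if (link[length(link)] == "ps") {
    stop(sprintf("parse error at offset %d: trailing 's' (the last residue has no 3' linkage)",
                 n), call. = FALSE)
  }
  out <- tibble::tibble(pos = seq_along(base), base = base, sugar = sugar,
                        linkage3 = link)
  class(out) <- c("modified_oligo", class(out))
  attr(out, "name") <- name
  out
}

#' Serialize a modified oligo back to notation
#'
#' Inverse of [parse_modified()]: `parse_modified(serialize_modified(x))`
#' reproduces `x` exactly. Serialization is canonical (uppercase bases,
#' lowercase sugar prefixes).
#'
#' @param oligo A `modified_oligo` (or any data frame with `base`, `sugar`,
#'   `linkage3` columns).
#' @return A single notation string.
#' @export
serialize_modified <- function(oligo) {
  stopifnot(all(c("base", "sugar", "linkage3") %in% names(oligo)))
  if (nrow(oligo) == 0) stop("cannot serialize an empty oligo", call. = FALSE)
  if (oligo$linkage3[nrow(oligo)] != "po") {
    stop("last residue must have a plain (po) 3' terminus", call. = FALSE)
  }
  tok <- paste0(tolower(oligo$sugar), toupper(oligo$base),
                ifelse(oligo$linkage3 == "ps", "s", ""))
  paste(tok, collapse = "")
}

#' Base sequence carried by a modified oligo
#'
#' @param oligo A `modified_oligo`.
#' @param as_rna Map `T` to `U` (default `FALSE`: bases are reported as
#'   annotated).
#' @return A single character string of bases, 5'->3'.
#' @export
oligo_bases <- function(oligo, as_rna = FALSE) {
  s <- paste(oligo$base, collapse = "")
  if (as_rna) as_rna(s) else s
}

#' Build a modified oligo from a plain strand
#'
#' Convenience constructor assigning one sugar chemistry to every residue,
#' e.g. a fully 2'-O-methyl control design (`sugar = "m"`).
#'
#' @param seq A strand sequence.
#' @param sugar Single sugar code (`r`, `m`, `f`, `d`) applied to all
#'   residues.
#' @param name Optional oligo name.
#' @return A `modified_oligo`.
#' @export
uniform_oligo <- function(seq, sugar = "r", name = NULL) {
  seq <- check_strand(seq)
  stopifnot(sugar %in% c("r", "m", "f", "d"))
  b <- seq_chars(seq)
  out <- tibble::tibble(pos = seq_along(b), base = b,
                        sugar = rep(sugar, length(b)),
                        linkage3 = rep("po", length(b)))
  class(out) <- c("modified_oligo", class(out))
  attr(out, "name") <- name
  out
}

#' @export
print.modified_oligo <- function(x, ...) {
  nm <- attr(x, "name", exact = TRUE)
  cat("<modified_oligo", if (!is.null(nm)) paste0("'", nm, "'") else "",
      sprintf("%d nt>", nrow(x)), "\n")
  cat(" ", serialize_modified(x), "\n")
  invisible(x)
}
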