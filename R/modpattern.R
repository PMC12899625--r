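#' Classify nucleotides into energy classes
#'
#' Maps each position to its pairing-energy class: `X` for the low-energy
#' monomers A/U (two hydrogen bonds) and `Y` for the high-energy monomers
#' G/C (three hydrogen bonds). `T` counts as low-energy.
#'
#' @param seq A strand sequence.
#' @return A string over `{X, Y}` of the same length.
#' @examples
#' classify_energy("AUGC")  # "XXYY"
#' @export
classify_energy <- function(seq) {
  seq <- check_strand(seq)
  chartr("AUTGC", "XXXYY", seq)
}

#' Modification pattern table
#'
#' Loads the bundled X/Y pattern table: for each segment case (uniform and
#' alternating triplets, 5'/3' terminal dinucleotides) the per-position sugar
#' assignment (`m` = 2'-O-methyl, `f` = 2'-fluoro) under the three pattern
#' columns (`set1_even`, `set2_odd` antisense variants, and `sense`). With
#' `derived = TRUE` (default) the table is extended with derived rows needed
#' to cover arbitrary strands: the 4-mer split forms `mXfXfXmX` / `fYmYmYfY`
#' for uniform runs longer than three, prefix-derived rows for internal
#' 1-2-mer leftovers, and a `5'YY` terminal case (absent from the printed
#' table) derived as the `YYY`-run prefix.
#'
#' @param path Optional path to a pattern TSV (columns `case`, `set1_even`,
#'   `set2_odd`, `sense`).
#' @param derived Append the derived rows (default `TRUE`).
#' @return Tibble with columns `case`, `set1_even`, `set2_odd`, `sense`,
#'   `derived`.
#' @export
pattern_table <- function(path = NULL, derived = TRUE) {
  if (is.null(path)) {
    path <- system.file("extdata", "mod_patterns.tsv", package = "sirnadesign")
  }
  tab <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  stopifnot(all(c("case", "set1_even", "set2_odd", "sense") %in% names(tab)))
  tab$derived <- FALSE
  if (!derived) return(tab)
  prefix_row <- function(from, k, label) {
    r <- tab[tab$case == from, ]
    stopifnot(nrow(r) == 1)
    tibble::tibble(case = label,
                   set1_even = substr(r$set1_even, 1, 2 * k),
                   set2_odd = substr(r$set2_odd, 1, 2 * k),
                   sense = substr(r$sense, 1, 2 * k),
                   derived = TRUE)
  }
  extra <- dplyr::bind_rows(
    tibble::tibble(case = "XXXX", set1_even = "mXfXfXmX",
                   set2_odd = "mXfXfXmX", sense = "mXfXfXmX", derived = TRUE),
    tibble::tibble(case = "YYYY", set1_even = "fYmYmYfY",
                   set2_odd = "fYmYmYfY", sense = "fYmYmYfY", derived = TRUE),
    # the printed table has no 5'YY case; derive it as the YYY-run prefix
    prefix_row("YYY", 2, "5'YY"),
    prefix_row("XXX", 2, "XX"), prefix_row("YYY", 2, "YY"),
    prefix_row("XYX", 2, "XY"), prefix_row("YXY", 2, "YX"),
    prefix_row("XXX", 1, "X"), prefix_row("YYY", 1, "Y"))
  dplyr::bind_rows(tab, extra)
}

#' Segment an energy-class string for pattern application
#'
#' Partitions a strand's class string into the segments the pattern table
#' addresses: the 5' terminal dinucleotide (positions 1-2), internal
#' segments, and the 3' terminal dinucleotide (last two positions). Internal
#' segmentation is run-aware and deterministic, 5'->3': strict alternation
#' (`XYX` / `YXY`) is emitted as alternating triplets; uniform runs are
#' chunked, taking 4-mers first for runs longer than four; leftover 1-2-nt
#' islands become short segments served by derived pattern rows. The
#' segments always form a partition of the strand.
#'
#' @param classes A class string over `{X, Y}` (from [classify_energy()]).
#' @return Tibble with columns `start`, `end`, `length`, `classes`, `case`
#'   (the pattern-table key, `5'`/`3'`-prefixed for the terminals).
#' @export
segment_classes <- function(classes) {
  cls <- seq_chars(classes)
  L <- length(cls)
  if (L < 5) {
    stop("segmentation needs at least 5 positions (two terminals plus an internal segment)",
         call. = FALSE)
  }
  segs <- list(tibble::tibble(start = 1L, end = 2L))
  p <- 3L
  last <- L - 2L
  while (p <= last) {
    run <- 1L
    while (p + run <= last && cls[p + run] == cls[p]) run <- run + 1L
    if (run == 1L && p + 2L <= last &&
        cls[p + 1L] != cls[p] && cls[p + 2L] == cls[p]) {
      segs <- c(segs, list(tibble::tibble(start = p, end = p + 2L)))
      p <- p + 3L
    } else if (run == 1L) {
      segs <- c(segs, list(tibble::tibble(start = p, end = p)))
      p <- p + 1L
    } else {
      while (run > 4L) {
        segs <- c(segs, list(tibble::tibble(start = p, end = p + 3L)))
        p <- p + 4L
        run <- run - 4L
      }
      segs <- c(segs, list(tibble::tibble(start = p, end = p + run - 1L)))
      p <- p + run
    }
  }
  segs <- c(segs, list(tibble::tibble(start = L - 1L, end = L)))
  out <- dplyr::bind_rows(segs)
  out$length <- out$end - out$start + 1L
  out$classes <- vapply(seq_len(nrow(out)), function(i) {
    paste(cls[out$start[i]:out$end[i]], collapse = "")
  }, "")
  out$case <- out$classes
  out$case[1] <- paste0("5'", out$classes[1])
  out$case[nrow(out)] <- paste0("3'", out$classes[nrow(out)])
  out
}

# sugar letters of a pattern cell like "mXfYmX" -> c("m","f","m")
cell_sugars <- function(cell) {
  ch <- seq_chars(cell)
  ch[seq(1, length(ch), by = 2)]
}

#' Apply a modification pattern to a strand
#'
#' Segments the strand by energy class and assigns each position the sugar
#' chemistry dictated by the matching pattern-table cell of the chosen
#' column. Class letters inside cells are nominal; assignment is positionwise
#' by sugar letter, with the strand's own bases unchanged. A fully
#' 2'-O-methyl control design is available via `full_ome = TRUE`.
#'
#' @param seq Strand sequence (>= 5 nt).
#' @param column Pattern column: `"set2_odd"` (default; the odd antisense
#'   variants, the better-performing family), `"set1_even"` or `"sense"`.
#' @param table Pattern table from [pattern_table()].
#' @param full_ome Ignore the table and assign 2'-O-methyl everywhere.
#' @param name Optional oligo name.
#' @return A `modified_oligo`.
#' @export
apply_patterns <- function(seq, column = c("set2_odd", "set1_even", "sense"),
                           table = pattern_table(), full_ome = FALSE,
                           name = NULL) {
  column <- match.arg(column)
  seq <- as_rna(check_strand(seq))
  if (full_ome) return(uniform_oligo(seq, "m", name = name))
  segs <- segment_classes(classify_energy(seq))
  sugars <- character(nchar(seq))
  for (i in seq_len(nrow(segs))) {
    row <- table[table$case == segs$case[i], ]
    if (nrow(row) == 0) {
      stop(sprintf("no pattern row for segment case '%s' (positions %d-%d)",
                   segs$case[i], segs$start[i], segs$end[i]), call. = FALSE)
    }
    sg <- cell_sugars(row[[column]][1])
    if (length(sg) != segs$length[i]) {
      stop(sprintf("pattern cell '%s' does not cover the %d-nt segment '%s'",
                   row[[column]][1], segs$length[i], segs$case[i]),
           call. = FALSE)
    }
    sugars[segs$start[i]:segs$end[i]] <- sg
  }
  b <- seq_chars(seq)
  out <- tibble::tibble(pos = seq_along(b), base = b, sugar = sugars,
                        linkage3 = rep("po", length(b)))
  class(out) <- c("modified_oligo", class(out))
  attr(out, "name") <- name
  attr(out, "column") <- column
  out
}

#' Report junction and terminal modification motifs
#'
#' Inspects a modified antisense oligo for the features shared by the most
#' active designs: `mYfYmXfX` patterns at high-to-low energy junctions, the
#' presence of both energy classes at positions 10-11, an `mXfX` 5'
#' dinucleotide, and an `mXmX` or `fYmY` 3' dinucleotide.
#'
#' @param oligo A `modified_oligo` (conventionally a 21-mer antisense
#'   strand).
#' @return Named list: `junction_myfymxfx_at` (integer positions of the
#'   motif start), `has_junction_myfymxfx`, `classes_10_11`,
#'   `both_classes_10_11`, `five_prime_mxfx`, `three_prime_motif`.
#' @export
junction_pattern_check <- function(oligo) {
  stopifnot(inherits(oligo, "modified_oligo") || is.data.frame(oligo))
  cls <- seq_chars(classify_energy(paste(oligo$base, collapse = "")))
  sg <- oligo$sugar
  L <- length(cls)
  motif_at <- integer()
  if (L >= 4) {
    for (p in 1:(L - 3L)) {
      if (identical(cls[p:(p + 3L)], c("Y", "Y", "X", "X")) &&
          identical(sg[p:(p + 3L)], c("m", "f", "m", "f"))) {
        motif_at <- c(motif_at, p)
      }
    }
  }
  tail2 <- (L - 1L):L
  list(
    junction_myfymxfx_at = motif_at,
    has_junction_myfymxfx = length(motif_at) > 0,
    classes_10_11 = if (L >= 11) paste(cls[10:11], collapse = "") else NA_character_,
    both_classes_10_11 = L >= 11 && cls[10] != cls[11],
    five_prime_mxfx = identical(sg[1:2], c("m", "f")) &&
      identical(cls[1:2], c("X", "X")),
    three_prime_motif =
      (identical(sg[tail2], c("m", "m")) && identical(cls[tail2], c("X", "X"))) ||
      (identical(sg[tail2], c("f", "m")) && identical(cls[tail2], c("Y", "Y")))
  )
}
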