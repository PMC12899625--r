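#' Loop-penalty parameters for the folder
#'
#' Loads the bundled loop-penalty table used by the simplified
#' minimum-free-energy folder (hairpin / bulge / internal loop penalties with
#' logarithmic size extrapolation, and the linear multiloop model).
#'
#' @param path Optional path to a TSV with columns `name`, `value`.
#' @return Named list of numeric parameters.
#' @export
fold_params <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "fold_loop_params.tsv", package = "sirnadesign")
  }
  tab <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  as.list(rlang::set_names(tab$value, tab$name))
}

encode_rna <- function(seq) {
  codes <- c(A = 0L, C = 1L, G = 2L, U = 3L)
  unname(codes[seq_chars(as_rna(check_strand(seq)))])
}

#' Fold an RNA window to its minimum-free-energy structure
#'
#' Dynamic-programming MFE folding under a simplified nested energy model:
#' Watson-Crick pairs, nearest-neighbor stack increments (shared with
#' [nn_params()]), logarithmic loop penalties and a linear multiloop term.
#' The empty structure scores 0, so the MFE is never positive. Folding is
#' deterministic, including tie-breaking in the traceback (leftmost pairing
#' first). For windows above `max_len` an external folding engine should be
#' plugged in instead (see `engine`).
#'
#' @param seq RNA sequence (a window of at most `max_len` nt).
#' @param min_hairpin Minimum unpaired hairpin loop size (default 3).
#' @param params Loop parameters from [fold_params()].
#' @param nn Stack parameters from [nn_params()].
#' @param max_len Length cap for the in-house folder (default 200).
#' @param engine Optional external engine: a `function(seq)` returning a list
#'   with elements `mfe` (kcal/mol) and `structure` (dot-bracket string),
#'   e.g. an adapter around an installed thermodynamic folding program. When
#'   supplied it replaces the built-in dynamic program.
#' @return A `fold_result`: list with `seq`, `structure` (dot-bracket),
#'   `mfe` (kcal/mol) and `paired` (logical vector per position).
#' @examples
#' fold_window("GGGGAAAACCCC")
#' @export
fold_window <- function(seq, min_hairpin = 3L, params = fold_params(),
                        nn = nn_params(), max_len = 200L, engine = NULL) {
  seq <- as_rna(check_strand(seq))
  n <- nchar(seq)
  if (n > max_len && is.null(engine)) {
    stop(sprintf(paste0("window of %d nt exceeds the in-house folder cap (%d); ",
                        "supply an external folding engine via `engine`"),
                 n, max_len), call. = FALSE)
  }
  if (!is.null(engine)) {
    res <- engine(seq)
  } else {
    stack16 <- as.numeric(nn$stack[paste0(rep(c("A", "C", "G", "U"), each = 4),
                                          rep(c("A", "C", "G", "U"), 4))])
    res <- fold_mfe_cpp(encode_rna(seq), stack16, params, as.integer(min_hairpin))
  }
  structure_ok <- nchar(res$structure) == n
  if (!structure_ok) stop("folding engine returned a malformed structure",
                          call. = FALSE)
  out <- list(seq = seq, structure = res$structure, mfe = res$mfe,
              paired = seq_chars(res$structure) != ".")
  class(out) <- "fold_result"
  out
}

#' @export
print.fold_result <- function(x, ...) {
  cat("<fold_result ", nchar(x$seq), " nt, MFE ", sprintf("%.2f", x$mfe),
      " kcal/mol>\n", sep = "")
  cat(" ", x$seq, "\n ", x$structure, "\n", sep = "")
  invisible(x)
}

#' Base pairs of a fold result
#'
#' @param fold A `fold_result`.
#' @return Tibble with columns `i`, `j` (1-based paired positions, `i < j`).
#' @export
fold_pairs <- function(fold) {
  db <- seq_chars(fold$structure)
  open <- integer()
  ii <- integer(); jj <- integer()
  for (p in seq_along(db)) {
    if (db[p] == "(") open <- c(open, p)
    else if (db[p] == ")") {
      ii <- c(ii, open[length(open)]); jj <- c(jj, p)
      open <- open[-length(open)]
    }
  }
  dplyr::arrange(tibble::tibble(i = ii, j = jj), .data$i)
}

#' Target-site accessibility criterion
#'
#' Folds the transcript window centered on a candidate target site (clamped
#' at the transcript ends) and asks whether the site is sufficiently
#' single-stranded in the MFE structure: the criterion passes when the
#' fraction of site bases that are paired does not exceed `threshold`. An
#' accessible (mostly unpaired) site favors RISC loading onto the target.
#'
#' @param transcript Transcript sequence.
#' @param target_start 1-based start of the target site on the transcript.
#' @param site_len Site length (default 21).
#' @param window Total window length folded around the site (default 80).
#' @param threshold Maximum tolerated paired fraction of the site
#'   (default 0.5). `threshold = 1` always passes.
#' @param ... Passed on to [fold_window()].
#' @return Logical, with attributes `site_paired_fraction` and `fold`
#'   (the underlying `fold_result`).
#' @export
accessibility_criterion <- function(transcript, target_start, site_len = 21L,
                                    window = 80L, threshold = 0.5, ...) {
  transcript <- as_rna(check_strand(transcript))
  n <- nchar(transcript)
  site_end <- target_start + site_len - 1L
  if (target_start < 1 || site_end > n) {
    stop("target site lies outside the transcript", call. = FALSE)
  }
  pad <- max(0L, window - site_len)
  w_start <- max(1L, target_start - pad %/% 2L)
  w_end <- min(n, w_start + max(window, site_len) - 1L)
  w_start <- max(1L, min(w_start, w_end - max(window, site_len) + 1L))
  fold <- fold_window(substr(transcript, w_start, w_end), ...)
  site_idx <- (target_start:site_end) - w_start + 1L
  frac <- mean(fold$paired[site_idx])
  out <- frac <= threshold
  attr(out, "site_paired_fraction") <- frac
  attr(out, "fold") <- fold
  out
}
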