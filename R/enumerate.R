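#' Enumerate candidate siRNA duplexes along a transcript
#'
#' Slides a window of `length` nt along each transcript and emits one duplex
#' per position: the sense (passenger) strand is the transcript window
#' itself, the antisense (guide) strand its full reverse complement. The
#' paired duplex core is sense positions 1..(length - overhang) opposite
#' antisense positions (overhang + 1)..length, leaving `overhang`-nt 3'
#' annotated overhangs. For a transcript of length L this yields exactly
#' L - length + 1 candidates.
#'
#' @param transcripts A tibble of transcripts (columns `name`, `seq`, e.g.
#'   from [read_fasta()]) or a single sequence string.
#' @param length Duplex strand length (default 21; 19-23 supported).
#' @param overhang Annotated 3'-overhang length (default 2).
#' @return Tibble of candidates: `transcript_id`, `name`, `target_start`,
#'   `target_end` (1-based inclusive window on the transcript), `sense`,
#'   `antisense`, `overhang`. Transcripts shorter than the window contribute
#'   no rows (with a warning).
#' @export
enumerate_candidates <- function(transcripts, length = 21L, overhang = 2L) {
  if (length < 19L || length > 23L) {
    stop("duplex length must be between 19 and 23", call. = FALSE)
  }
  if (is.character(transcripts)) {
    transcripts <- tibble::tibble(
      name = if (!is.null(names(transcripts))) names(transcripts)
             else paste0("transcript", seq_along(transcripts)),
      seq = transcripts)
  }
  stopifnot(all(c("name", "seq") %in% names(transcripts)))
  out <- purrr::pmap(list(transcripts$name, transcripts$seq), function(id, tx) {
    tx <- as_rna(check_strand(tx))
    L <- nchar(tx)
    if (L < length) {
      warning(sprintf("transcript '%s' (%d nt) is shorter than the %d-nt window; skipped",
                      id, L, length), call. = FALSE)
      return(NULL)
    }
    starts <- seq_len(L - length + 1L)
    sense <- substring(tx, starts, starts + length - 1L)
    tibble::tibble(transcript_id = id,
                   name = sprintf("%s_%d", id, starts),
                   target_start = starts,
                   target_end = starts + length - 1L,
                   sense = sense,
                   antisense = reverse_complement(sense),
                   overhang = as.integer(overhang))
  })
  dplyr::bind_rows(out)
}

#' Apply published first-pass rules to a candidate set
#'
#' Evaluates the selected published rule sets (see [first_pass_rules]) for
#' every candidate and keeps those passing their union (default) or
#' intersection. Flag columns are populated for all requested rules so the
#' filtering decision is auditable. With an empty `rules` vector the filter
#' is a no-op.
#'
#' @param candidates Candidate tibble from [enumerate_candidates()].
#' @param rules Character subset of `c("uitei", "reynolds", "amarzguioui")`.
#' @param mode `"union"` (a candidate passes if any selected rule passes;
#'   default) or `"intersection"` (all selected rules must pass).
#' @param keep_all Keep non-passing rows (with their flags) instead of
#'   filtering them out (default `FALSE`).
#' @return The candidate tibble with one logical column per selected rule
#'   plus `first_pass` (the combined decision), filtered unless `keep_all`.
#' @export
first_pass_filter <- function(candidates,
                              rules = c("uitei", "reynolds", "amarzguioui"),
                              mode = c("union", "intersection"),
                              keep_all = FALSE) {
  mode <- match.arg(mode)
  known <- first_pass_rule_set()
  if (length(rules) == 0) {
    candidates$first_pass <- rep(TRUE, nrow(candidates))
    return(candidates)
  }
  bad <- setdiff(rules, names(known))
  if (length(bad) > 0) {
    stop("unknown rule name(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  for (r in rules) {
    f <- known[[r]]
    candidates[[r]] <- purrr::map2_lgl(candidates$sense, candidates$antisense,
                                       function(s, a) f(s, a))
  }
  flags <- as.matrix(candidates[rules])
  candidates$first_pass <- if (mode == "union") apply(flags, 1, any)
                           else apply(flags, 1, all)
  if (keep_all) candidates else dplyr::filter(candidates, .data$first_pass)
}
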