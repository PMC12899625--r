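#' Screen a duplex against a background transcript set
#'
#' Homology screen of the duplex strands against background records, in the
#' style of a strand-level BLAST check: a hit is any ungapped alignment of
#' the full query against a subject window whose percent identity exceeds
#' `threshold_pct`. Identity is `100 * matches / query length`; both subject
#' orientations are searched. The scan is seed-anchored: only windows sharing
#' an exact k-mer with the query are evaluated, with `k` chosen by the
#' pigeonhole bound so that no window above the threshold can be missed
#' (any window with at most `m` mismatches contains an exact run of at least
#' `ceiling((L - m) / (m + 1)) >= floor(L / (m + 1))` bases). Set
#' `method = "exhaustive"` to force evaluation of every window instead.
#'
#' @param sense,antisense Duplex strands (each screened as a query;
#'   pass only one to screen a single strand).
#' @param background Tibble of background records (columns `name`, `seq`),
#'   e.g. from [read_fasta()].
#' @param threshold_pct Report hits with identity strictly above this
#'   percentage (default 85).
#' @param k Seed length; `NULL` (default) derives the largest
#'   pigeonhole-valid k from the query length and threshold.
#' @param method `"seed"` (default) or `"exhaustive"`.
#' @return Tibble of hits: `query_strand`, `subject_id`, `subject_start`,
#'   `subject_end` (1-based inclusive, on the forward subject), `orientation`
#'   (`+`/`-`), `identity_pct`, `query_aln`, `subject_aln`; sorted by
#'   descending identity, then subject id, then start.
#' @export
scan_offtargets <- function(sense = NULL, antisense = NULL, background,
                            threshold_pct = 85, k = NULL,
                            method = c("seed", "exhaustive")) {
  method <- match.arg(method)
  if (is.null(sense) && is.null(antisense)) {
    stop("supply at least one query strand", call. = FALSE)
  }
  if (!is.data.frame(background) || nrow(background) == 0) {
    stop("background is empty: the off-target criterion is unevaluable",
         call. = FALSE)
  }
  if (threshold_pct <= 0 || threshold_pct > 100) {
    stop("threshold_pct must be in (0, 100]", call. = FALSE)
  }
  queries <- list(antisense = antisense, sense = sense)
  queries <- queries[!vapply(queries, is.null, logical(1))]
  hits <- purrr::imap(queries, function(q, strand_name) {
    q <- as_rna(check_strand(q))
    L <- nchar(q)
    kq <- k
    if (is.null(kq)) {
      m_max <- floor(L * (100 - threshold_pct) / 100)
      kq <- max(1L, L %/% (m_max + 1L))
    }
    purrr::pmap(list(background$name, background$seq), function(id, subj) {
      subj <- as_rna(check_strand(subj))
      purrr::map(c("+", "-"), function(ori) {
        s <- if (ori == "+") subj else reverse_complement(subj)
        starts <- if (method == "seed") seed_window_starts(q, s, kq)
                  else seq_len(max(0L, nchar(s) - L + 1L))
        if (length(starts) == 0) return(NULL)
        qc <- seq_chars(q)
        sc <- seq_chars(s)
        res <- purrr::map(starts, function(st) {
          win <- sc[st:(st + L - 1L)]
          ident <- 100 * sum(win == qc) / L
          if (ident <= threshold_pct) return(NULL)
          # report coordinates on the forward subject strand
          if (ori == "+") {
            fs <- st; fe <- st + L - 1L
          } else {
            fe <- nchar(s) - st + 1L; fs <- fe - L + 1L
          }
          tibble::tibble(query_strand = strand_name, subject_id = id,
                         subject_start = fs, subject_end = fe,
                         orientation = ori, identity_pct = ident,
                         query_aln = q, subject_aln = paste(win, collapse = ""))
        })
        dplyr::bind_rows(res)
      }) |> dplyr::bind_rows()
    }) |> dplyr::bind_rows()
  })
  out <- dplyr::bind_rows(hits)
  if (nrow(out) == 0) return(empty_hits())
  dplyr::arrange(out, dplyr::desc(.data$identity_pct), .data$subject_id,
                 .data$subject_start)
}

empty_hits <- function() {
  tibble::tibble(query_strand = character(), subject_id = character(),
                 subject_start = integer(), subject_end = integer(),
                 orientation = character(), identity_pct = numeric(),
                 query_aln = character(), subject_aln = character())
}

# candidate window start positions in `s` sharing an exact k-mer with `q`
seed_window_starts <- function(q, s, k) {
  L <- nchar(q)
  ns <- nchar(s)
  if (ns < L) return(integer())
  q_kmers <- substring(q, 1:(L - k + 1L), k:L)
  s_kmers <- substring(s, 1:(ns - k + 1L), (k):ns)
  idx <- which(s_kmers %in% q_kmers)
  if (length(idx) == 0) return(integer())
  # a seed at subject position p matching query offset o implies a window
  # starting at p - o + 1; collect all such implied starts
  starts <- integer()
  kmer_offsets <- split(seq_along(q_kmers), q_kmers)
  for (p in idx) {
    offs <- kmer_offsets[[s_kmers[p]]]
    starts <- c(starts, p - offs + 1L)
  }
  starts <- unique(starts)
  sort(starts[starts >= 1L & starts <= ns - L + 1L])
}

#' Off-target clearance
#'
#' A duplex is cleared when, excluding the intended target record, no
#' background hit above the homology threshold remains. Exclusion is by
#' record id (not by sequence) so true paralog hits on other records are
#' never masked.
#'
#' @param hits Hit tibble from [scan_offtargets()].
#' @param target_id Record id(s) of the intended target transcript.
#' @return Logical.
#' @export
offtarget_clearance <- function(hits, target_id = NULL) {
  if (!is.null(target_id)) {
    hits <- dplyr::filter(hits, !.data$subject_id %in% target_id)
  }
  nrow(hits) == 0
}
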