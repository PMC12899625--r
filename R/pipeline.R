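#' A designed target site satisfying every sequence criterion
#'
#' A 21-mer constructed so that, as the sense strand of a candidate duplex,
#' it passes all three published first-pass rule sets and every sequence
#' criterion of the scoring engine, and carries an A/U-rich center flanked
#' by G/C-rich ends (the energy-valley profile). Used by [make_fixtures()]
#' to plant a known best candidate in synthetic transcripts.
#'
#' @return A 21-nt sequence string.
#' @export
engineered_site <- function() "GCACGGCCAUUAAGUUAUAUU"

rand_rna <- function(n, p = c(A = 0.3, C = 0.2, G = 0.2, U = 0.3)) {
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# substitute m bases at deterministic, evenly spaced positions; every
# substitution is a transversion so identity drops by exactly 1/L each
mutate_site <- function(seq, m) {
  if (m == 0) return(seq)
  ch <- seq_chars(seq)
  pos <- unique(round(seq(2, length(ch) - 1, length.out = m)))
  swap <- c(A = "C", C = "A", G = "U", U = "G")
  ch[pos] <- swap[ch[pos]]
  paste(ch, collapse = "")
}

#' Generate synthetic design fixtures
#'
#' Builds a random transcript with (optionally) the engineered
#' all-criteria target site planted at a known position, plus a background
#' transcript set for the off-target screen: the target transcript itself
#' (so self-matching is exercised), random decoy records, and optional
#' planted off-target copies of the site carrying a chosen number of
#' mismatches. A manifest records the ground truth. All randomness is
#' governed by `seed`, so fixture generation is reproducible.
#'
#' @param transcript_length Length of the target transcript (default 300).
#' @param site_start Planted-site start (default: centered).
#' @param plant_site Plant the engineered site (default `TRUE`).
#' @param n_decoys Number of random background records (default 3).
#' @param decoy_length Length of each background record (default 400).
#' @param offtarget_mismatches Integer vector: for each entry `m`, one
#'   additional background record carries the planted site's sequence with
#'   exactly `m` substitutions.
#' @param seed Integer seed fixing all randomness.
#' @param dir Optional directory; when given, `transcript.fasta`,
#'   `background.fasta` and `manifest.tsv` are written there.
#' @return List with `transcripts` (tibble `name`, `seq`, `length`),
#'   `background` (same shape), `manifest` (tibble of planted features) and
#'   `site` (the planted 21-mer or `NA`).
#' @export
make_fixtures <- function(transcript_length = 300L, site_start = NULL,
                          plant_site = TRUE, n_decoys = 3L,
                          decoy_length = 400L,
                          offtarget_mismatches = integer(0),
                          seed = 1L, dir = NULL) {
  site <- engineered_site()
  sl <- nchar(site)
  if (transcript_length < sl) stop("transcript too short for the planted site",
                                   call. = FALSE)
  if (is.null(site_start)) site_start <- (transcript_length - sl) %/% 2L + 1L
  if (site_start < 1L || site_start + sl - 1L > transcript_length) {
    stop("planted site does not fit within the transcript", call. = FALSE)
  }
  withr::with_seed(seed, {
    tx <- rand_rna(transcript_length)
    manifest <- tibble::tibble(feature = character(), record = character(),
                               start = integer(), end = integer(),
                               mismatches = integer())
    if (plant_site) {
      substr(tx, site_start, site_start + sl - 1L) <- site
      manifest <- dplyr::bind_rows(manifest, tibble::tibble(
        feature = "target_site", record = "target_tx",
        start = site_start, end = site_start + sl - 1L, mismatches = 0L))
    }
    bg <- tibble::tibble(name = "target_tx", seq = tx)
    if (n_decoys > 0) {
      bg <- dplyr::bind_rows(bg, tibble::tibble(
        name = paste0("decoy_", seq_len(n_decoys)),
        seq = vapply(seq_len(n_decoys), function(i) rand_rna(decoy_length), "")))
    }
    for (i in seq_along(offtarget_mismatches)) {
      m <- offtarget_mismatches[i]
      host <- rand_rna(decoy_length)
      planted <- mutate_site(site, m)
      at <- (decoy_length - sl) %/% 2L + 1L
      substr(host, at, at + sl - 1L) <- planted
      rec <- sprintf("offtarget_m%d_%d", m, i)
      bg <- dplyr::bind_rows(bg, tibble::tibble(name = rec, seq = host))
      manifest <- dplyr::bind_rows(manifest, tibble::tibble(
        feature = "planted_offtarget", record = rec,
        start = at, end = at + sl - 1L, mismatches = as.integer(m)))
    }
    out <- list(
      transcripts = tibble::tibble(name = "target_tx", seq = tx,
                                   length = nchar(tx)),
      background = dplyr::mutate(bg, length = nchar(.data$seq)),
      manifest = manifest,
      site = if (plant_site) site else NA_character_,
      site_start = if (plant_site) site_start else NA_integer_)
  })
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_fasta(out$transcripts, file.path(dir, "transcript.fasta"))
    write_fasta(out$background, file.path(dir, "background.fasta"))
    readr::write_tsv(out$manifest, file.path(dir, "manifest.tsv"))
  }
  out
}

#' Run the full design pipeline
#'
#' Enumerate candidate duplexes along the transcript(s), apply the selected
#' published first-pass rules, score the survivors with the full criterion
#' set (including accessibility and, when a background is supplied, the
#' off-target screen) and rank them. The result is one row per surviving
#' candidate with per-criterion points, total, selectability and rank.
#'
#' @param transcripts Transcript tibble (`name`, `seq`) or a single
#'   sequence string.
#' @param background Optional background tibble for the off-target screen.
#' @param rules First-pass rules to apply (default all three; empty vector
#'   skips first-pass filtering).
#' @param mode Rule combination mode, `"union"` or `"intersection"`.
#' @param params Scoring parameters from [score_params()].
#' @param length Duplex length (default 21).
#' @return Ranked tibble (see [rank_candidates()]); zero rows when no
#'   candidate survives the first pass.
#' @export
design_pipeline <- function(transcripts, background = NULL,
                            rules = c("uitei", "reynolds", "amarzguioui"),
                            mode = "union", params = score_params(),
                            length = 21L) {
  if (is.character(transcripts)) {
    transcripts <- tibble::tibble(name = "transcript1", seq = transcripts)
  }
  if (!is.data.frame(transcripts) || nrow(transcripts) == 0) {
    warning("empty transcript set: nothing to design", call. = FALSE)
    return(empty_report())
  }
  transcripts <- dplyr::mutate(transcripts, seq = as_rna(toupper(.data$seq)))
  cands <- enumerate_candidates(transcripts, length = length)
  if (nrow(cands) == 0) return(empty_report())
  cands <- first_pass_filter(cands, rules = rules, mode = mode)
  if (nrow(cands) == 0) return(empty_report())
  scored <- score_candidates(cands, transcripts = transcripts,
                             background = background, params = params)
  rank_candidates(scored)
}

empty_report <- function() {
  tibble::tibble(rank = integer(), transcript_id = character(),
                 name = character(), target_start = integer(),
                 target_end = integer(), sense = character(),
                 antisense = character(), score_total = integer(),
                 selectable = logical())
}
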