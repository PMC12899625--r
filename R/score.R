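#' Scoring parameters
#'
#' Tunable parameters of the multi-criterion efficacy/specificity score. The
#' criterion weights sum to 16 (13 sequence points + 1 accessibility +
#' 2 off-target); the method's stated maximum is 15 — the two-point
#' discrepancy is carried on every scorecard as `max_points` vs `stated_max`
#' rather than silently reconciled, and the weights are user-editable here.
#'
#' @param gc_range Global GC content bounds, percent (default `c(36, 52)`).
#' @param gc_seed_max Max GC percent at antisense positions 2-7 (default 19).
#' @param gc_central_min Min GC percent at antisense positions 8-18
#'   (default 52).
#' @param valley_window Sense positions of the energy-valley window
#'   (default `9:14`).
#' @param valley_margin Energy-valley margin, kcal/mol (default 0.5).
#' @param accept_uu_overhang Count a `UU` sense 3' overhang as satisfying
#'   the `TT` overhang criterion (default `TRUE`).
#' @param fold_window,fold_threshold Window length and max paired fraction
#'   for the target-site accessibility criterion (defaults 80 and 0.5).
#' @param offtarget_threshold Homology clearance threshold, percent
#'   identity (default 85).
#' @param selection_threshold Candidates are selectable when
#'   `total > selection_threshold` (strict; default 10).
#' @param weights Named integer vector of criterion weights.
#' @return A list of parameters for [score_duplex()].
#' @export
score_params <- function(gc_range = c(36, 52), gc_seed_max = 19,
                         gc_central_min = 52, valley_window = 9:14,
                         valley_margin = 0.5, accept_uu_overhang = TRUE,
                         fold_window = 80L, fold_threshold = 0.5,
                         offtarget_threshold = 85,
                         selection_threshold = 10,
                         weights = NULL) {
  default_w <- c(gc_global = 1L, gc_asymmetry = 1L, energy_valley = 2L,
                 low_repeats = 1L, tt_overhang = 1L, as5_au = 1L,
                 s5_gc = 1L, as6_a = 1L, s3_s19_a = 1L, s19_weak = 1L,
                 s13_no_g = 1L, s10_u = 1L, accessibility = 1L,
                 offtarget = 2L)
  if (is.null(weights)) weights <- default_w
  weights <- unlist(weights) # tolerate YAML-config lists
  stopifnot(setequal(names(weights), names(default_w)))
  list(gc_range = gc_range, gc_seed_max = gc_seed_max,
       gc_central_min = gc_central_min, valley_window = valley_window,
       valley_margin = valley_margin, accept_uu_overhang = accept_uu_overhang,
       fold_window = fold_window, fold_threshold = fold_threshold,
       offtarget_threshold = offtarget_threshold,
       selection_threshold = selection_threshold,
       weights = weights[names(default_w)],
       stated_max = 15L)
}

# tandem dinucleotide repeat count: largest n such that (unit)^n occurs
max_tandem <- function(seq, unit) {
  n <- 0L
  while (grepl(strrep(unit, n + 1L), seq, fixed = TRUE)) n <- n + 1L
  n
}

#' Score one siRNA duplex
#'
#' Evaluates the full criterion set for a 21/21 duplex and returns a
#' per-criterion scorecard. Sequence criteria are always evaluated; the
#' energy-valley criterion uses the nearest-neighbor profile of the sense
#' core; the accessibility criterion needs `transcript` + `target_start`;
#' the off-target criterion needs a `background` set. Criteria whose context
#' inputs are absent award 0 points and are marked not evaluated rather than
#' erroring, so partial scoring is explicit in the output.
#'
#' Criteria (weight): global GC 36-52% (1); antisense GC <= 19% at positions
#' 2-7 and >= 52% at 8-18 (1); energy valley at sense positions 9-14 (2);
#' GC tandem repeats < 3 and AU tandem repeats < 4 (1); TT/UU 3' overhang
#' (1); A/U at antisense position 1 (1); G/C at sense position 1 (1); A at
#' antisense position 6 (1); A at sense positions 3 and 19 (1); no G/C at
#' sense position 19 (1); no G at sense position 13 (1); U at sense position
#' 10 (1); target-site accessibility (1); off-target clearance at the 85%
#' homology threshold (2).
#'
#' @param sense,antisense Duplex strands, 5'->3'. `antisense` defaults to
#'   the reverse complement of `sense`.
#' @param target_start 1-based site start on `transcript` (for the
#'   accessibility criterion).
#' @param transcript Transcript sequence containing the target site.
#' @param background Background tibble for the off-target screen
#'   (columns `name`, `seq`).
#' @param target_id Background record id(s) of the intended target, excluded
#'   from off-target hits.
#' @param params Parameters from [score_params()].
#' @param nn Nearest-neighbor parameters from [nn_params()].
#' @return A `sirna_scorecard` tibble with columns `criterion`, `evaluated`,
#'   `passed`, `weight`, `points`, `detail`; attributes `total`,
#'   `selectable`, `max_points`, `stated_max`.
#' @export
score_duplex <- function(sense, antisense = NULL, target_start = NULL,
                         transcript = NULL, background = NULL,
                         target_id = NULL, params = score_params(),
                         nn = nn_params()) {
  sense <- as_rna(check_strand(sense))
  if (is.null(antisense)) antisense <- reverse_complement(sense)
  antisense <- as_rna(check_strand(antisense))
  L <- nchar(sense)
  if (L != nchar(antisense) || L < 19L) {
    stop("scoring requires equal-length duplex strands of at least 19 nt",
         call. = FALSE)
  }
  s <- seq_chars(sense)
  a <- seq_chars(antisense)
  au <- c("A", "U")
  gc <- c("G", "C")
  w <- params$weights

  crit <- list()
  add <- function(id, passed, evaluated = TRUE, detail = "") {
    crit[[id]] <<- tibble::tibble(
      criterion = id, evaluated = evaluated,
      passed = evaluated && isTRUE(passed),
      weight = unname(w[id]),
      points = if (evaluated && isTRUE(passed)) unname(w[id]) else 0L,
      detail = detail)
  }

  gpc <- gc_fraction(sense) * 100
  add("gc_global", gpc >= params$gc_range[1] && gpc <= params$gc_range[2],
      detail = sprintf("GC %.1f%%", gpc))

  seed_gc <- mean(a[2:7] %in% gc) * 100
  central_gc <- mean(a[8:18] %in% gc) * 100
  add("gc_asymmetry",
      seed_gc <= params$gc_seed_max && central_gc >= params$gc_central_min,
      detail = sprintf("antisense GC 2-7: %.1f%%, 8-18: %.1f%%",
                       seed_gc, central_gc))

  prof <- nn_profile(sense, antisense, strand = "sense", params = nn)
  valley <- energy_valley(prof, window = params$valley_window,
                          margin = params$valley_margin)
  add("energy_valley", valley,
      detail = sprintf("window %d-%d, margin %.2f kcal/mol",
                       min(params$valley_window), max(params$valley_window),
                       params$valley_margin))

  gc_rep <- max_tandem(sense, "GC")
  au_rep <- max_tandem(sense, "AU")
  add("low_repeats", gc_rep < 3 && au_rep < 4,
      detail = sprintf("(GC)n max %d, (AU)n max %d", gc_rep, au_rep))

  oh <- substr(sense, L - 1L, L)
  tt_ok <- oh == "TT" || (params$accept_uu_overhang && oh == "UU")
  add("tt_overhang", tt_ok, detail = sprintf("sense 3' end '%s'", oh))

  add("as5_au", a[1] %in% au, detail = sprintf("antisense pos 1 '%s'", a[1]))
  add("s5_gc", s[1] %in% gc, detail = sprintf("sense pos 1 '%s'", s[1]))
  add("as6_a", a[6] == "A", detail = sprintf("antisense pos 6 '%s'", a[6]))
  add("s3_s19_a", s[3] == "A" && s[19] == "A",
      detail = sprintf("sense pos 3 '%s', pos 19 '%s'", s[3], s[19]))
  add("s19_weak", !s[19] %in% gc, detail = sprintf("sense pos 19 '%s'", s[19]))
  add("s13_no_g", s[13] != "G", detail = sprintf("sense pos 13 '%s'", s[13]))
  add("s10_u", s[10] == "U", detail = sprintf("sense pos 10 '%s'", s[10]))

  if (!is.null(transcript) && !is.null(target_start)) {
    acc <- accessibility_criterion(transcript, target_start, site_len = L,
                                   window = params$fold_window,
                                   threshold = params$fold_threshold)
    add("accessibility", as.logical(acc),
        detail = sprintf("site paired fraction %.2f",
                         attr(acc, "site_paired_fraction")))
  } else {
    add("accessibility", FALSE, evaluated = FALSE, detail = "not evaluated")
  }

  if (!is.null(background)) {
    hits <- scan_offtargets(sense = sense, antisense = antisense,
                            background = background,
                            threshold_pct = params$offtarget_threshold)
    clear <- offtarget_clearance(hits, target_id = target_id)
    add("offtarget", clear,
        detail = sprintf("%d hit(s) > %g%% identity",
                         nrow(dplyr::filter(hits,
                                            !.data$subject_id %in% target_id)),
                         params$offtarget_threshold))
  } else {
    add("offtarget", FALSE, evaluated = FALSE, detail = "not evaluated")
  }

  card <- dplyr::bind_rows(crit[names(w)])
  total <- sum(card$points)
  stopifnot(total <= sum(w))
  class(card) <- c("sirna_scorecard", class(card))
  attr(card, "total") <- total
  attr(card, "selectable") <- total > params$selection_threshold
  attr(card, "max_points") <- sum(w)
  attr(card, "stated_max") <- params$stated_max
  attr(card, "selection_threshold") <- params$selection_threshold
  card
}

#' @export
print.sirna_scorecard <- function(x, ...) {
  cat(sprintf("<sirna_scorecard: %d / %d points (stated maximum %d), %s>\n",
              attr(x, "total"), attr(x, "max_points"), attr(x, "stated_max"),
              if (attr(x, "selectable")) "selectable" else "not selectable"))
  print(tibble::as_tibble(x), n = nrow(x))
  invisible(x)
}

#' Score a table of candidates
#'
#' Vectorized wrapper around [score_duplex()]: one wide row per candidate
#' with a points column per criterion plus `score_total` and `selectable`.
#'
#' @param candidates Candidate tibble from [enumerate_candidates()] /
#'   [first_pass_filter()] (columns `transcript_id`, `target_start`, `sense`,
#'   `antisense`).
#' @param transcripts Optional transcript tibble (`name`, `seq`) enabling
#'   the accessibility criterion.
#' @param background Optional background tibble enabling the off-target
#'   criterion; the candidate's own transcript id is excluded from hits.
#' @param params,nn See [score_duplex()].
#' @return `candidates` with appended criterion columns, `score_total` and
#'   `selectable`. Scoring metadata (`max_points`, `stated_max`,
#'   `selection_threshold`) is attached as attributes.
#' @export
score_candidates <- function(candidates, transcripts = NULL,
                             background = NULL, params = score_params(),
                             nn = nn_params()) {
  tx_seq <- function(id) {
    if (is.null(transcripts)) return(NULL)
    i <- match(id, transcripts$name)
    if (is.na(i)) NULL else transcripts$seq[i]
  }
  rows <- purrr::pmap(
    list(candidates$transcript_id, candidates$target_start,
         candidates$sense, candidates$antisense),
    function(id, start, sen, anti) {
      card <- score_duplex(sen, anti, target_start = start,
                           transcript = tx_seq(id), background = background,
                           target_id = id, params = params, nn = nn)
      pts <- rlang::set_names(as.list(card$points), card$criterion)
      tibble::as_tibble(c(pts, list(score_total = attr(card, "total"),
                                    selectable = attr(card, "selectable"))))
    })
  out <- dplyr::bind_cols(candidates, dplyr::bind_rows(rows))
  attr(out, "max_points") <- sum(params$weights)
  attr(out, "stated_max") <- params$stated_max
  attr(out, "selection_threshold") <- params$selection_threshold
  out
}

#' Rank scored candidates
#'
#' Descending by total score; ties broken by energy-valley points (desc),
#' off-target points (desc), then lower target start — a deterministic,
#' documented ordering.
#'
#' @param scored Tibble from [score_candidates()].
#' @return The tibble, ranked, with a `rank` column prepended.
#' @export
rank_candidates <- function(scored) {
  if (nrow(scored) == 0) return(scored)
  out <- dplyr::arrange(scored, dplyr::desc(.data$score_total),
                        dplyr::desc(.data$energy_valley),
                        dplyr::desc(.data$offtarget), .data$target_start)
  dplyr::bind_cols(tibble::tibble(rank = seq_len(nrow(out))), out)
}

#' Auxiliary sequence-composition checks
#'
#' The supplementary design heuristics applied to a strand: overall AU/GC
#' balance near 50%; the distribution of A/U and G/C "islets" of 2-3 nt
#' (at most one longer run of 4-6 nt tolerated); the presence of one 4-6-mer
#' homo-energy run; uniform terminal dinucleotides of opposite classes; and
#' the conditional rule that positions 3-4 carry the class opposite to a
#' uniform first dinucleotide.
#'
#' @param seq A strand sequence (conventionally the guide strand).
#' @param balance_tol Tolerance on the 50% GC balance, percentage points
#'   (default 10).
#' @return Named logical list: `balance`, `islands_2_3`, `run_4to6`,
#'   `terminal_classes`, `conditional_34`.
#' @export
composition_checks <- function(seq, balance_tol = 10) {
  seq <- as_rna(check_strand(seq))
  cls <- seq_chars(classify_energy(seq))
  runs <- rle(cls)$lengths
  gc <- gc_fraction(seq) * 100
  first2 <- cls[1:2]
  last2 <- cls[(length(cls) - 1):length(cls)]
  pos34 <- cls[3:4]
  list(
    balance = abs(gc - 50) <= balance_tol,
    islands_2_3 = all(runs <= 3) ||
      (sum(runs > 3) == 1 && all(runs[runs > 3] <= 6)),
    run_4to6 = any(runs >= 4 & runs <= 6),
    terminal_classes = first2[1] == first2[2] && last2[1] == last2[2] &&
      first2[1] != last2[1],
    conditional_34 = first2[1] == first2[2] && pos34[1] == pos34[2] &&
      pos34[1] != first2[1]
  )
}
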