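# IUPAC average atomic weights used throughout the mass calculator
atomic_weights <- function() {
  c(C = 12.011, H = 1.008, N = 14.007, O = 15.999, P = 30.974,
    F = 18.998, S = 32.06)
}

#' Mass table for modified oligonucleotides
#'
#' Loads the elemental-composition table and computes the average masses
#' used by [oligo_mass()]: full ribonucleoside masses per base, sugar deltas
#' (2'-O-methyl, 2'-fluoro, deoxy) and per-linkage deltas (the phosphodiester
#' bridge and the phosphorothioate substitution). Masses are derived from
#' IUPAC average atomic weights at load time, so the table file carries only
#' atom counts and stays auditable.
#'
#' @param path Optional path to a composition TSV.
#' @return A list with named numeric vectors `nucleoside` (A, C, G, U, T)
#'   and `delta` (r, m, f, d, bridge, ps), plus the `elements` matrix of
#'   atom counts.
#' @export
mass_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "mass_table.tsv", package = "sirnadesign")
  }
  tab <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  aw <- atomic_weights()
  el <- as.matrix(tab[names(aw)])
  rownames(el) <- tab$key
  masses <- drop(el %*% aw)
  list(nucleoside = masses[tab$key[tab$kind == "nucleoside"]],
       delta = masses[tab$key[tab$kind == "delta"]],
       elements = el, kind = rlang::set_names(tab$kind, tab$key))
}

#' Average molecular weight of a modified oligonucleotide
#'
#' Free-acid (H+) form: 5'-OH and 3'-OH termini, protonated phosphates.
#' The mass is the sum of the per-residue nucleoside masses and sugar
#' deltas, plus one phosphodiester bridge increment per internucleotide
#' linkage, a phosphorothioate delta per PS linkage, and an optional
#' conjugate adduct (e.g. a GalNAc ligand plus linker, supplied as a single
#' mass constant).
#'
#' @param oligo A `modified_oligo` from [parse_modified()], or a notation
#'   string.
#' @param table Mass table from [mass_table()].
#' @param adduct Additional conjugate mass in g/mol (default 0).
#' @param digits Decimal places for the reported mass (default 2;
#'   `NULL` for full precision).
#' @return Average molecular weight in g/mol.
#' @examples
#' oligo_mass("rU")      # 244.20
#' oligo_mass("mUmU")    # two 2'-OMe residues, one bridge
#' @export
oligo_mass <- function(oligo, table = mass_table(), adduct = 0,
                       digits = 2) {
  if (is.character(oligo)) oligo <- parse_modified(oligo)
  if (!all(oligo$base %in% names(table$nucleoside))) {
    stop("unknown base in oligo", call. = FALSE)
  }
  if (!all(oligo$sugar %in% c("r", "m", "f", "d"))) {
    stop("unknown sugar chemistry in oligo", call. = FALSE)
  }
  n <- nrow(oligo)
  m <- sum(table$nucleoside[oligo$base]) +
    sum(table$delta[oligo$sugar]) +
    (n - 1L) * table$delta[["bridge"]] +
    sum(oligo$linkage3 == "ps") * table$delta[["ps"]] +
    adduct
  if (is.null(digits)) unname(m) else round(unname(m), digits)
}

#' Total elemental formula of a modified oligonucleotide
#'
#' Sums the atom counts of all residues, sugar deltas and linkage deltas
#' into one molecular formula (free-acid form). Useful as an independent
#' check on the additive mass computation.
#'
#' @inheritParams oligo_mass
#' @return Named integer vector of atom counts (C, H, N, O, P, F, S).
#' @export
oligo_formula <- function(oligo, table = mass_table()) {
  if (is.character(oligo)) oligo <- parse_modified(oligo)
  el <- table$elements
  counts <- colSums(el[oligo$base, , drop = FALSE]) +
    colSums(el[oligo$sugar, , drop = FALSE]) +
    (nrow(oligo) - 1L) * el["bridge", ] +
    sum(oligo$linkage3 == "ps") * el["ps", ]
  counts
}

round_half_up <- function(x, digits = 0) {
  floor(x * 10^digits + 0.5) / 10^digits
}

#' Multi-stage synthesis yield plan
#'
#' Chains per-stage efficiencies into a total yield: the total is the
#' product of all stage efficiencies, so it can never exceed the weakest
#' stage and is invariant to stage order. Percent labels round half-up to
#' the integer, matching how total yields are conventionally reported.
#'
#' @param stages Numeric vector of stage efficiencies in (0, 1], optionally
#'   named, or a data frame with columns `name` and `efficiency`.
#' @return A `yield_plan` tibble with columns `stage`, `name`,
#'   `efficiency`, `cumulative`; attributes `total` (fraction) and `label`
#'   (e.g. `"26%"`).
#' @examples
#' chain_yield(c(synthesis = 0.49, chromatography = 0.55, desalting = 0.95))
#' @export
chain_yield <- function(stages) {
  if (is.data.frame(stages)) {
    stopifnot("efficiency" %in% names(stages))
    eff <- stages$efficiency
    nm <- if ("name" %in% names(stages)) stages$name else NULL
  } else {
    eff <- as.numeric(stages)
    nm <- names(stages)
  }
  if (length(eff) == 0) stop("no stages supplied", call. = FALSE)
  if (any(is.na(eff)) || any(eff <= 0) || any(eff > 1)) {
    stop("stage efficiencies must lie in (0, 1]", call. = FALSE)
  }
  if (is.null(nm)) nm <- paste0("stage", seq_along(eff))
  out <- tibble::tibble(stage = seq_along(eff), name = nm, efficiency = eff,
                        cumulative = cumprod(eff))
  class(out) <- c("yield_plan", class(out))
  total <- prod(eff)
  attr(out, "total") <- total
  attr(out, "label") <- paste0(round_half_up(100 * total), "%")
  out
}

#' @export
print.yield_plan <- function(x, ...) {
  cat(sprintf("<yield_plan: %d stages, total %.1f%% (%s)>\n",
              nrow(x), 100 * attr(x, "total"), attr(x, "label")))
  print(tibble::as_tibble(x), n = nrow(x))
  invisible(x)
}

#' Per-record normalized cycle difference
#'
#' @param ct_target,ct_housekeeping Positive qPCR quantification cycle
#'   numbers for the target and housekeeping gene.
#' @return `ct_target - ct_housekeeping`.
#' @export
delta_ct <- function(ct_target, ct_housekeeping) {
  if (any(ct_target <= 0) || any(ct_housekeeping <= 0)) {
    stop("Ct values must be positive", call. = FALSE)
  }
  ct_target - ct_housekeeping
}

#' Relative expression by the delta-delta-Cq method
#'
#' Normalizes each record's target Ct to its housekeeping Ct, averages
#' within group, subtracts the control-group mean from the
#' experimental-group mean, and converts the difference to a fold change:
#' `2^-(ddCt)`. A fold change below 1 indicates knockdown of the target in
#' the experimental group.
#'
#' @param experimental,control Data frames with columns `ct_target` and
#'   `ct_housekeeping` (one row per reaction/replicate).
#' @return One-row tibble: `n_experimental`, `n_control`,
#'   `delta_ct_experimental`, `delta_ct_control`, `ddct`, `fold_change`.
#' @export
fold_change <- function(experimental, control) {
  for (g in list(experimental, control)) {
    if (!is.data.frame(g) || nrow(g) == 0 ||
        !all(c("ct_target", "ct_housekeeping") %in% names(g))) {
      stop("both groups need at least one row with ct_target and ct_housekeeping",
           call. = FALSE)
    }
  }
  d_exp <- mean(delta_ct(experimental$ct_target, experimental$ct_housekeeping))
  d_ctl <- mean(delta_ct(control$ct_target, control$ct_housekeeping))
  ddct <- d_exp - d_ctl
  tibble::tibble(n_experimental = nrow(experimental),
                 n_control = nrow(control),
                 delta_ct_experimental = d_exp,
                 delta_ct_control = d_ctl,
                 ddct = ddct,
                 fold_change = 2^(-ddct))
}
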