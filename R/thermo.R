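#' Nearest-neighbor duplex parameters
#'
#' Loads the bundled Watson-Crick RNA/RNA nearest-neighbor free-energy table
#' (dinucleotide stack increments at 37 C plus initiation and terminal A-U
#' terms). A different parameter file with the same schema can be supplied to
#' swap the set.
#'
#' @param path Optional path to a parameter TSV (columns `key`, `dg`).
#' @return A list with `stack` (named numeric, 16 dinucleotide steps),
#'   `init` and `term_au` (kcal/mol).
#' @export
nn_params <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "nn_stack_dg37.tsv", package = "sirnadesign")
  }
  tab <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  stopifnot(all(c("key", "dg") %in% names(tab)))
  vals <- rlang::set_names(tab$dg, tab$key)
  steps <- vals[setdiff(names(vals), c("init", "term_au"))]
  if (length(steps) != 16) {
    stop("nearest-neighbor table must provide all 16 dinucleotide steps",
         call. = FALSE)
  }
  list(stack = steps, init = unname(vals["init"]),
       term_au = unname(vals["term_au"]))
}

# extract the paired 19-nt core of a 21/21 duplex strand.
# sense core: positions 1..L-overhang; antisense core: positions overhang+1..L
duplex_core <- function(seq, strand = c("sense", "antisense"),
                        overhang = 2L) {
  strand <- match.arg(strand)
  seq <- as_rna(check_strand(seq))
  n <- nchar(seq)
  if (strand == "sense") substr(seq, 1L, n - overhang)
  else substr(seq, overhang + 1L, n)
}

#' Per-step nearest-neighbor free-energy profile of a duplex
#'
#' Computes the stack free-energy increment of every dinucleotide step of the
#' paired duplex core, on the requested strand's coordinate system. Overhangs
#' are excluded (core-only thermodynamics). The total adds the helix
#' initiation term and terminal A-U penalties.
#'
#' @param sense,antisense The duplex strands, 5'->3'. `antisense` may be
#'   omitted, in which case it is taken as the full reverse complement of
#'   `sense`.
#' @param strand Which strand's 5'->3' orientation indexes the profile
#'   (default `"sense"`; the paper-style valley criterion reads sense
#'   positions, the end-asymmetry diagnostic reads antisense positions).
#' @param overhang 3'-overhang length excluded from the core (default 2).
#' @param params Parameter set from [nn_params()].
#' @return A `thermo_profile`: tibble with columns `step` (1-based step
#'   index; step i covers strand positions i and i+1 of the core),
#'   `dinucleotide`, `dg` (kcal/mol). Attributes: `total_dg`, `init`,
#'   `strand`, `core`.
#' @export
nn_profile <- function(sense, antisense = NULL, strand = c("sense", "antisense"),
                       overhang = 2L, params = nn_params()) {
  strand <- match.arg(strand)
  sense <- as_rna(check_strand(sense))
  if (is.null(antisense)) antisense <- reverse_complement(sense)
  antisense <- as_rna(check_strand(antisense))
  score_core <- duplex_core(sense, "sense", overhang)
  as_core <- duplex_core(antisense, "antisense", overhang)
  if (reverse_complement(score_core) != as_core) {
    stop("duplex core is not fully complementary; the nearest-neighbor profile ",
         "is defined for perfect duplexes only", call. = FALSE)
  }
  core <- if (strand == "sense") score_core else as_core
  ch <- seq_chars(core)
  n <- length(ch)
  if (n < 2) stop("core too short for a step profile", call. = FALSE)
  dinuc <- paste0(ch[-n], ch[-1])
  dg <- unname(params$stack[dinuc])
  ends_au <- sum(c(ch[1], ch[n]) %in% c("A", "U"))
  total <- sum(dg) + params$init + ends_au * params$term_au
  out <- tibble::tibble(step = seq_len(n - 1L), dinucleotide = dinuc, dg = dg)
  class(out) <- c("thermo_profile", class(out))
  attr(out, "total_dg") <- total
  attr(out, "init") <- params$init
  attr(out, "strand") <- strand
  attr(out, "core") <- core
  out
}

#' Total duplex free energy of a profile
#' @param profile A `thermo_profile`.
#' @return Total free energy (kcal/mol), including initiation and terminal
#'   terms.
#' @export
total_dg <- function(profile) attr(profile, "total_dg")

# map a positional window (on the profiled strand's core) to step indices:
# step i covers positions i and i+1, so positions p..q -> steps p..q-1
window_steps <- function(profile, window) {
  steps <- seq(min(window), max(window) - 1L)
  if (min(steps) < 1 || max(steps) > nrow(profile)) {
    stop("window lies outside the step profile", call. = FALSE)
  }
  steps
}

#' Energy-valley criterion
#'
#' A duplex carries an "energy valley" when the stretch of steps covering the
#' given positional window is, on average, less stable (less negative step
#' free energy) than the remainder of the core by at least `margin`. The
#' canonical use reads sense-strand positions 9-14, the region whose local
#' instability favors target cleavage.
#'
#' @param profile A `thermo_profile` (normally of the sense strand).
#' @param window Positional window on the profiled core (default `9:14`).
#' @param margin Required difference of means, kcal/mol (default 0.5).
#' @param statistic `"mean"` (default; mean-in-window vs mean-of-rest) or
#'   `"min_window"` (window mean must exceed the most stable same-length
#'   window mean elsewhere by `margin`).
#' @return Logical.
#' @export
energy_valley <- function(profile, window = 9:14, margin = 0.5,
                          statistic = c("mean", "min_window")) {
  statistic <- match.arg(statistic)
  steps <- window_steps(profile, window)
  inside <- profile$dg[steps]
  outside <- profile$dg[-steps]
  if (length(outside) == 0) stop("valley window covers the whole profile",
                                 call. = FALSE)
  if (statistic == "mean") {
    return(mean(inside) - mean(outside) >= margin)
  }
  w <- length(steps)
  other <- setdiff(seq_len(nrow(profile) - w + 1L), steps[1])
  mins <- min(vapply(other, function(i) mean(profile$dg[i:(i + w - 1L)]),
                     numeric(1)))
  mean(inside) - mins >= margin
}

#' 5' / 3' end free-energy differential
#'
#' Mean step free energy of the first `k` steps minus the mean of the last
#' `k` steps, on the profiled strand (conventionally the antisense strand).
#' Positive values indicate the favorable asymmetry: a less stable 5' end and
#' a more stable 3' end, which biases guide-strand selection by AGO2.
#'
#' @param profile A `thermo_profile` (use `strand = "antisense"` in
#'   [nn_profile()] for the guide-strand orientation).
#' @param k Number of terminal steps per end (default 4).
#' @return Differential in kcal/mol.
#' @export
end_differential <- function(profile, k = 4L) {
  n <- nrow(profile)
  if (2L * k >= n + 1L) {
    stop("k too large: terminal windows overlap", call. = FALSE)
  }
  mean(profile$dg[seq_len(k)]) - mean(profile$dg[seq(n - k + 1L, n)])
}

#' Local energy differential between two strand positions
#'
#' Assigns each position the mean free energy of its flanking steps and
#' returns the absolute difference between two positions. Used to report the
#' energy contrast between antisense positions 10 and 11, a feature shared by
#' the most active modified designs.
#'
#' @param profile A `thermo_profile`.
#' @param i,j Positions on the profiled core (defaults 10 and 11).
#' @return Absolute difference of positional energies, kcal/mol.
#' @export
position_differential <- function(profile, i = 10L, j = 11L) {
  pos_energy <- function(p) {
    steps <- intersect(c(p - 1L, p), seq_len(nrow(profile)))
    if (length(steps) == 0) stop("position outside profile", call. = FALSE)
    mean(profile$dg[steps])
  }
  abs(pos_energy(i) - pos_energy(j))
}
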