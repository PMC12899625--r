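#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a scorecard into a plain per-criterion tibble
#'
#' @param x A `sirna_scorecard`.
#' @param ... Ignored.
#' @return Tibble with one row per criterion.
#' @export
tidy.sirna_scorecard <- function(x, ...) {
  out <- tibble::as_tibble(x)
  class(out) <- class(tibble::tibble())
  out
}

#' One-row summary of a scorecard
#'
#' @param x A `sirna_scorecard`.
#' @param ... Ignored.
#' @return Tibble: `total`, `max_points`, `stated_max`, `selectable`,
#'   `n_evaluated`.
#' @export
glance.sirna_scorecard <- function(x, ...) {
  tibble::tibble(total = attr(x, "total"),
                 max_points = attr(x, "max_points"),
                 stated_max = attr(x, "stated_max"),
                 selectable = attr(x, "selectable"),
                 n_evaluated = sum(x$evaluated))
}

#' Tidy a thermodynamic step profile
#'
#' @param x A `thermo_profile`.
#' @param ... Ignored.
#' @return Plain tibble of steps.
#' @export
tidy.thermo_profile <- function(x, ...) {
  out <- tibble::as_tibble(x)
  class(out) <- class(tibble::tibble())
  out
}

#' One-row summary of a thermodynamic profile
#'
#' @param x A `thermo_profile`.
#' @param ... Ignored.
#' @return Tibble: `strand`, `n_steps`, `total_dg`, `end_differential`.
#' @export
glance.thermo_profile <- function(x, ...) {
  tibble::tibble(strand = attr(x, "strand"), n_steps = nrow(x),
                 total_dg = attr(x, "total_dg"),
                 end_differential = end_differential(x))
}

#' Tidy a fold result into its base pairs
#'
#' @param x A `fold_result`.
#' @param ... Ignored.
#' @return Tibble of base pairs (`i`, `j`).
#' @export
tidy.fold_result <- function(x, ...) fold_pairs(x)

#' One-row summary of a fold result
#'
#' @param x A `fold_result`.
#' @param ... Ignored.
#' @return Tibble: `length`, `mfe`, `n_pairs`, `paired_fraction`.
#' @export
glance.fold_result <- function(x, ...) {
  tibble::tibble(length = nchar(x$seq), mfe = x$mfe,
                 n_pairs = nrow(fold_pairs(x)),
                 paired_fraction = mean(x$paired))
}
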