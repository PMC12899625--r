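# Independent oracles, deliberately written as straightforward enumeration /
# sliding-window code so they share no logic with the package implementation.

# ---- folding: exhaustive enumeration of nested Watson-Crick structures ----

# all nested pairings of seq with hairpin loops of at least `h` unpaired
# bases; each structure is a list of c(i, j) pairs
enum_structures <- function(seq, h = 3L) {
  ch <- strsplit(seq, "")[[1]]
  n <- length(ch)
  wc <- function(a, b) {
    (a == "A" && b == "U") || (a == "U" && b == "A") ||
      (a == "G" && b == "C") || (a == "C" && b == "G")
  }
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j) {
    if (i > j) return(list(list()))
    key <- paste0(i, "_", j)
    got <- memo[[key]]
    if (!is.null(got)) return(got)
    res <- rec(i + 1L, j) # i unpaired
    if (i + h + 1L <= j) {
      for (k in (i + h + 1L):j) {
        if (!wc(ch[i], ch[k])) next
        inner <- rec(i + 1L, k - 1L)
        outer <- rec(k + 1L, j)
        for (a in inner) for (b in outer) {
          res[[length(res) + 1L]] <- c(list(c(i, k)), a, b)
        }
      }
    }
    memo[[key]] <- res
    res
  }
  rec(1L, n)
}

# energy of one structure under the same loop decomposition the folder uses
structure_energy <- function(seq, pairs, nn = sirnadesign::nn_params(),
                             loopp = sirnadesign::fold_params()) {
  ch <- strsplit(seq, "")[[1]]
  n <- length(ch)
  if (length(pairs) == 0) return(0)
  pmap <- integer(n)
  for (pr in pairs) { pmap[pr[1]] <- pr[2]; pmap[pr[2]] <- pr[1] }
  hairpinE <- function(u) loopp$hairpin_base +
    loopp$log_coef * log(u / loopp$hairpin_ref)
  bulgeE <- function(u) loopp$bulge_base +
    loopp$log_coef * log(u / loopp$bulge_ref)
  internalE <- function(u1, u2) loopp$internal_base +
    loopp$log_coef * log((u1 + u2) / loopp$internal_ref) +
    min(loopp$internal_asym_max, loopp$internal_asym * abs(u1 - u2))
  branches <- function(i, j) {
    res <- list(); k <- i
    while (k <= j) {
      if (pmap[k] > k) { res[[length(res) + 1L]] <- c(k, pmap[k]); k <- pmap[k] + 1L }
      else k <- k + 1L
    }
    res
  }
  score_pair <- function(i, j) {
    br <- branches(i + 1L, j - 1L)
    if (length(br) == 0) return(hairpinE(j - i - 1L))
    if (length(br) == 1) {
      k <- br[[1]][1]; l <- br[[1]][2]
      u1 <- k - i - 1L; u2 <- j - l - 1L
      if (u1 + u2 > loopp$max_loop) return(Inf)
      e <- if (u1 == 0 && u2 == 0) {
        unname(nn$stack[paste0(ch[i], ch[i + 1L])])
      } else if (u1 == 0 || u2 == 0) bulgeE(u1 + u2) else internalE(u1, u2)
      return(e + score_pair(k, l))
    }
    unp <- (j - i - 1L) - sum(vapply(br, function(x) x[2] - x[1] + 1L, 1L))
    loopp$ml_close + loopp$ml_branch * (length(br) + 1L) +
      loopp$ml_unpaired * unp +
      sum(vapply(br, function(x) score_pair(x[1], x[2]), 1))
  }
  sum(vapply(branches(1L, n), function(x) score_pair(x[1], x[2]), 1))
}

brute_mfe <- function(seq, h = 3L) {
  structs <- enum_structures(seq, h)
  min(c(0, vapply(structs, function(s) structure_energy(seq, s), 1)))
}

# fold_pairs() tibble -> list of c(i, j) as structure_energy() expects
split_pairs <- function(pairs) {
  lapply(seq_len(nrow(pairs)), function(r) c(pairs$i[r], pairs$j[r]))
}

# ---- off-target: all-windows sliding identity scan ----

brute_offtarget_scan <- function(query, subject, threshold) {
  L <- nchar(query)
  qc <- strsplit(query, "")[[1]]
  out <- list()
  for (ori in c("+", "-")) {
    s <- if (ori == "+") subject else sirnadesign::reverse_complement(subject)
    sc <- strsplit(s, "")[[1]]
    ns <- length(sc)
    if (ns < L) next
    for (st in 1:(ns - L + 1L)) {
      ident <- 100 * sum(sc[st:(st + L - 1L)] == qc) / L
      if (ident > threshold) {
        fs <- if (ori == "+") st else ns - (st + L - 1L) + 1L
        out[[length(out) + 1L]] <- data.frame(
          orientation = ori, subject_start = fs, identity_pct = ident)
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(orientation = character(), subject_start = integer(),
                      identity_pct = numeric()))
  }
  res <- do.call(rbind, out)
  res[order(res$orientation, res$subject_start), , drop = FALSE]
}

# ---- thermodynamics: direct dinucleotide sum ----

brute_duplex_dg <- function(core, nn = sirnadesign::nn_params()) {
  ch <- strsplit(core, "")[[1]]
  tot <- nn$init
  for (i in 1:(length(ch) - 1)) {
    tot <- tot + nn$stack[[paste0(ch[i], ch[i + 1])]]
  }
  tot + sum(ch[c(1, length(ch))] %in% c("A", "U")) * nn$term_au
}

# ---- mass: one-shot elemental-formula summation with local constants ----

brute_oligo_mass <- function(oligo) {
  aw <- c(C = 12.011, H = 1.008, N = 14.007, O = 15.999, P = 30.974,
          F = 18.998, S = 32.06)
  formulas <- list( # full ribonucleosides
    A = c(C = 10, H = 13, N = 5, O = 4), C = c(C = 9, H = 13, N = 3, O = 5),
    G = c(C = 10, H = 13, N = 5, O = 5), U = c(C = 9, H = 12, N = 2, O = 6),
    T = c(C = 10, H = 14, N = 2, O = 6))
  total <- c(C = 0, H = 0, N = 0, O = 0, P = 0, F = 0, S = 0)
  addf <- function(tot, f) { tot[names(f)] <- tot[names(f)] + f; tot }
  for (i in seq_len(nrow(oligo))) {
    total <- addf(total, formulas[[oligo$base[i]]])
    total <- switch(oligo$sugar[i],
                    r = total,
                    m = addf(total, c(C = 1, H = 2)),
                    f = addf(total, c(H = -1, O = -1, F = 1)),
                    d = addf(total, c(O = -1)))
  }
  total <- addf(total, (nrow(oligo) - 1) * c(H = -1, O = 2, P = 1))
  total <- addf(total, sum(oligo$linkage3 == "ps") * c(O = -1, S = 1))
  sum(total * aw[names(total)])
}
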