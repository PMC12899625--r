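---
title: "Rational siRNA design: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rational siRNA design: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sirnadesign)
```

This vignette is the package's account of the science it implements: the
candidate model, each criterion of the scoring engine, the thermodynamic and
structural sub-models, the chemical-modification pattern engine, and the
laboratory calculators — together with the parameters that matter, the
numerical choices made where the method leaves them open, and the limits of
what the synthetic test battery demonstrates.

## The duplex model

A small interfering RNA (siRNA) is a ~21-nt duplex whose antisense (guide)
strand is loaded into RISC and directs cleavage of a complementary mRNA.
`enumerate_candidates()` slides a 21-nt window along the transcript and
emits one candidate per position: the sense (passenger) strand *is* the
window, and the antisense strand is its full reverse complement. The paired
core is sense positions 1–19 opposite antisense positions 3–21, with 2-nt
3′ overhang annotations. This is a deliberate simplification: synthesized
duplexes carry true overhangs (the guide core occupies guide positions
1–19, and the guide's own 3′ overhang is complementary to transcript bases
upstream of the window). The 19-bp core — the only part entering the
thermodynamic and complementarity calculations — is identical in both
representations; positional criteria are indexed 1-based from the 5′ end of
the strand they name, on the strand representation the enumerator produces.

## First-pass rules

The first filtering stage applies the three classic published rule sets
(`rule_uitei()`, `rule_reynolds()`, `rule_amarzguioui()`); the method that
motivated this package runs them through an external design service, so the
predicates here are implemented from their published formulations:

* **Ui-Tei class Ia**: A/U at the guide 5′ end; G/C at the passenger 5′
  end; ≥ 4 A/U among guide positions 1–7; no G/C stretch of ≥ 10 nt.
* **Reynolds**: an eight-criterion score (functional at ≥ 6): +1 for core
  GC 30–52%; +1 per A/U at sense 15–19; +1 for absence of internal
  repeats; +1 each for A19, A3, U10 of the sense; −1 for G/C at 19; −1 for
  G at 13. The internal-repeat criterion is defined in the original work
  via a hairpin melting temperature; here it is approximated as the absence
  of any self-complementary stretch of ≥ 5 nt, which captures the same
  hairpin-forming propensity without a duplex-melting model.
* **Amarzguioui**: core GC 31.6–57.9% plus at least two of three
  asymmetry/composition features (strong sense 5′ end, A at sense 6, weak
  sense 3′ end). The original report weighs more features; this reduced
  form keeps the two load-bearing ideas — composition bounds and duplex-end
  asymmetry — and is documented so users can substitute their own predicate.

Whether the original design run combined the rules by union or intersection
is not recorded; `first_pass_filter()` defaults to the union ("one or a
combination") and exposes `mode = "intersection"`.

## The scoring engine

`score_duplex()` awards points over 14 criteria. Thirteen are pure sequence
tests (global GC 36–52%; guide-strand GC ≤ 19% at positions 2–7 *and*
≥ 52% at 8–18; tandem-repeat limits; TT/UU overhang; the positional
identities listed in its help page), one is the thermodynamic energy-valley
test (weight 2), one the folding accessibility test (weight 1), and one
off-target clearance (weight 2). The enumerated weights sum to **16**,
while the method's stated ceiling is **15 points**; which criterion the
original authors down-weighted cannot be recovered, so the engine keeps the
enumerated weights and carries both numbers on every scorecard
(`max_points` = 16, `stated_max` = 15). Weights are user-editable through
`score_params()`, which is also where the ambiguity can be resolved by
anyone who prefers a 15-point normalization.

Two readings of the repeat criterion ("GC repeats fewer than 3 times and AU
repeats fewer than 4 times") are possible: run lengths of single bases, or
tandem dinucleotide repeats. The run-length reading would fail published
high-scoring strands ending in `GGG`, so the tandem reading — no `(GC)₃`
and no `(AU)₄` anywhere in the sense strand — is implemented.

Candidates are *selectable* when `total > 10` (strict inequality).
`rank_candidates()` orders by total, then energy-valley points, then
off-target points, then lower target position — a fully deterministic
ordering. Criteria whose context is missing (no transcript for the folder,
no background for the off-target screen) score 0 and are flagged
`evaluated = FALSE` rather than erroring, so partial scoring is always
explicit in the output.

The auxiliary composition heuristics (`composition_checks()`) report the ~50%
AU/GC balance (±10 percentage points by default — the source states no
tolerance), the islet-size rule (all same-class runs ≤ 3 nt, with at most
one 4–6-nt run tolerated, since the companion heuristic *requires* one such
run), the presence of that 4–6-mer, and the terminal-dinucleotide rules.

## Duplex thermodynamics

`nn_profile()` computes the per-step free-energy profile of the 19-bp core
from the Watson–Crick nearest-neighbor ΔG°₃₇ set of Xia et al. (1998),
shipped as a versioned TSV (`nn_stack_dg37.tsv`) and swappable via
`nn_params(path)`. Step *i* covers strand positions *i* and *i+1*; the
profile total adds the helix initiation term and per-end terminal A–U
penalties. Because Watson–Crick stacks are rotationally symmetric, the
guide-strand profile is the passenger profile read backwards — both
orientations are available through the `strand` argument.

The **energy valley** is nowhere defined quantitatively in the source
method, only located (sense positions 9–14). The implemented statistic is:
the mean step ΔG over the steps covered by the window (positions 9–14 →
steps 9–13) must exceed the mean over all remaining steps by at least a
margin, default **0.5 kcal/mol** — roughly half a weak-stack/strong-stack
contrast, chosen once as a scale the parameter table itself suggests. A
`min_window` alternative (window mean vs the most stable same-length window
elsewhere) is exposed, and both margin and window are configurable; the
defaults are part of the package's study conditions and are not tuned.

`end_differential()` (mean of the first *k* = 4 steps minus the last *k*,
guide orientation) quantifies the 5′/3′ asymmetry that biases AGO2
guide-strand selection; `position_differential()` reports the local energy
contrast between guide positions 10 and 11, a feature shared by the most
active designs. Positions are assigned the mean of their flanking steps.

## Target-site accessibility

The original method scores "secondary structure formation probability" of
the target region with an external folding server, used as a black box; the
criterion needs only a decision about whether the site is occluded.
`fold_window()` is a self-contained Zuker-style dynamic program over nested
structures: Watson–Crick pairs only, the same stack table as the duplex
thermodynamics, logarithmic hairpin/bulge/internal-loop penalties with a
0.5 kcal/mol-per-nt asymmetry term (capped), a linear multiloop model, a
30-nt interior-loop cap, and a minimum hairpin loop of 3 nt
(`fold_loop_params.tsv`). Deliberate exclusions: G·U wobble pairs, dangling
ends, coaxial stacking and tabulated special loops — this is an
accessibility classifier, not a general-purpose folder, and every
simplification is shared with the exhaustive-enumeration oracle that
verifies the DP exactly for sequences ≤ 14 nt. Traceback ties are broken
deterministically (leftmost pairable position first, then smallest
partner), so identical inputs give identical dot-brackets.

`accessibility_criterion()` folds an 80-nt window centered on the site
(clamped at transcript ends) and passes when at most half the site's bases
are paired in the MFE structure. Neither the window nor the threshold is
stated by the method; both are exposed (`fold_window`, `fold_threshold` in
`score_params()`). An alternative reading — folding the siRNA strand itself
rather than the target window — cannot be excluded from the source text;
target-site accessibility is implemented because it is the reading the
criterion's own description ("structures within the mRNA target regions")
supports. Windows above 200 nt are refused with a pointer to the `engine`
adapter, through which an external thermodynamic folder can be plugged in
(`function(seq) -> list(mfe, structure)`).

## Off-target screening

`scan_offtargets()` implements the ≤ 85% homology clearance rule as a
strand-level ungapped identity scan: a hit is any full-length alignment of
the query (either strand, both subject orientations) with percent identity
strictly above the threshold, identity = 100 × matches / query length. The
original method delegates this to BLAST; the rule, not the engine, is the
contract, and "% homology" is implemented as plain identity (coverage ×
identity cannot be reconstructed from the source). Gapped alignments are
not searched: on 21-mers at 85%, a gap costs at least as much identity as
the substitutions it replaces under this denominator.

The scan is seed-anchored: only windows sharing an exact *k*-mer with the
query are evaluated. The pigeonhole principle guarantees exhaustiveness
when *k* ≤ ⌊L/(m+1)⌋ for the maximum tolerable mismatch count
*m* = ⌊L(100−t)/100⌋; at L = 21, t = 85 this gives m = 3 and k = 5. The
default therefore *derives* k from (L, t) instead of fixing it — a fixed
k = 8 would silently miss 3-mismatch hits. `method = "exhaustive"` forces
the all-windows scan. Clearance (`offtarget_clearance()`) excludes the
intended target by record id, never by sequence, so genuine paralog hits
are not masked.

## The modification-pattern engine

Nucleotides divide into low-energy (A/U → `X`) and high-energy (G/C → `Y`)
classes (`classify_energy()`). The pattern table (`mod_patterns.tsv`)
assigns per-position sugar chemistries (2′-O-methyl `m` / 2′-fluoro `f`)
to segment cases — uniform triplets, alternating triplets, and terminal
dinucleotides — under three columns: the even and odd antisense variant
sets and the sense set. The file mirrors the printed table cell for cell,
including the sense-column `5'XY` cell that reads `fXfX` (its class letters
disagree with the case label; reproduced verbatim and applied positionwise
by sugar letter, the strand's own classes taking precedence).

`segment_classes()` partitions the strand deterministically: the terminal
dinucleotides are claimed first; internally, strict alternation emits
`XYX`/`YXY` triplets; uniform runs are chunked 4-mer-first when longer than
four (the split forms `mXfXfXmX`/`fYmYmYfY` serve the 4-mers); leftover
1–2-nt islands use rows derived as prefixes of the uniform-triplet rows. An
alternative segmentation — merging 2-nt islands into mixed junction
triplets — was rejected because the resulting case labels (`XXY`, `YXX`,
…) have no rows in the printed table and would make the engine fail on
ordinary strands. Two further derived rows close gaps the printed table
leaves open: the 4-mer split forms above, and a `5'YY` terminal case
(absent from the table, needed by any strand starting with two G/C),
derived as the `YYY` prefix. Derived rows are flagged in the
`derived` column so a user auditing a design can see exactly which
assignments came from the printed table.

The mapping from published variant numbers (e.g. "_12") to specific
column/recipe choices lives in unpublished supplementary material, so the
engine is table + column driven; `junction_pattern_check()` reports the
motifs the most active designs share (a `mYfYmXfX` high-to-low junction,
mixed classes at guide positions 10–11, a 5′ `mXfX` dinucleotide, a 3′
`mXmX` or `fYmY` dinucleotide) without scoring them.

## Laboratory calculators

`oligo_mass()` computes average molecular weights in the free-acid (H⁺)
convention — 5′-OH/3′-OH termini, protonated phosphates: Σ ribonucleoside
masses + sugar deltas + 61.96 g/mol per internucleotide bridge
(+HPO₃ − H₂O) + 16.06 per phosphorothioate linkage (O → S), plus an
optional conjugate adduct supplied as a single constant (the GalNAc–linker
moiety is outside this package's structural scope). All masses are derived
at load time from elemental compositions (`mass_table.tsv`) and IUPAC
average atomic weights rather than shipped as pre-rounded numbers: rounding
nucleoside masses to two decimals before summation accumulates ~0.2 g/mol
of error over a 21-mer, enough to miss a printed reference value at ±0.1.

`chain_yield()` multiplies stage efficiencies into a total (order-invariant,
bounded by the weakest stage) and renders percentages with half-up integer
rounding, the convention under which 0.256 prints as 26%. `fold_change()`
implements the ΔΔCq chain: per-record ΔCt = Ct(target) − Ct(housekeeping),
group means, ΔΔCt = experimental − control, fold change = 2^(−ΔΔCt).
Printed downstream expression ratios cannot be reconstructed here because
the control group's ΔCt values are not published; the formula layer is what
is validated.

## The synthetic-fixture generator

`make_fixtures()` builds the offline test world: a random 300-nt transcript
(a scale at which the enumeration, filtering and scoring stages all engage,
while a full scored pipeline run stays in seconds), with the engineered
21-mer `GCACGGCCAUUAAGUUAUAUU` planted at a known position. That site was
constructed by hand to satisfy all three first-pass rule sets and all 13
sequence criteria simultaneously, including the A/U valley between G/C
flanks; its scorecard is hand-verified criterion by criterion in the tests.
The background set contains the transcript itself (so id-based
self-exclusion is exercised), random decoys, and optional copies of the
site carrying an exact number of transversion mismatches — at 21 nt, 3
mismatches (85.7%) must be reported at the 85% threshold and 4 (81.0%)
must not. All randomness is fixed by the `seed` argument.

What the generator does *not* emulate: real transcript base composition and
long-range secondary structure, transcriptome-scale background size and
paralogy, expression weighting of off-targets, and any relationship between
score and measured silencing. Passing tests therefore demonstrate the
internal correctness and determinism of the machinery — enumeration
geometry, rule predicates, exact thermodynamic sums, MFE optimality,
scan exhaustiveness, pattern-table fidelity — not biological predictive
power, which the method's authors established experimentally.

## Degenerate inputs and numerical conventions

Empty strands, unknown alphabet characters, dangling notation tokens and
trailing phosphorothioate marks are rejected with positioned parse errors.
Transcripts shorter than the window enumerate to zero candidates with a
warning; an empty background makes the off-target criterion *unevaluable*
(flagged, zero points) in scoring but is an error when the scan is called
directly. Floating-point energy comparisons in the folder use an absolute
1e-7 tie tolerance; masses are reported to two decimals; yield labels round
half-up. All tabulated parameters live in plain-text files under
`inst/extdata/` with schema comments, so every constant in the package is
inspectable and replaceable.

## Known limitations

* The folder's simplified energy model (no wobble pairs, no dangles) makes
  its MFE values incomparable to Turner-model folders; only the
  paired/unpaired decision feeds the score, and an external engine can be
  plugged in where fidelity matters.
* The first-pass predicates are faithful reductions, not re-validations, of
  their published rule sets.
* The 15-vs-16 point ceiling ambiguity is surfaced, not resolved.
* Off-target identity is ungapped and unweighted by expression.
* The pattern engine emits designs; it does not predict which pattern
  variant silences best.
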