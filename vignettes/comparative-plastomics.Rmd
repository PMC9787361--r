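---
title: "Comparative plastomics with plastcmp: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative plastomics with plastcmp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plastcmp)
```

plastcmp analyses the structural observables that carry most of the
family-level phylogenetic signal in plastid genomes: inverted-repeat (IR)
junction geometry, gene and intron losses, nucleotide-diversity hotspots,
intron indel events coded as binary characters, and plastid tRNA cloverleaf
variants. This vignette explains the procedures, their assumptions, the
tunable parameters, and the choices made where the design was genuinely open.
Every empirical statement here is also computed by the test suite or by
`scripts/acceptance.R`; the vignette adds the reasoning, not new numbers.

## Quadripartite regions and junction geometry

A typical plastome is a circle of 120–160 kb carrying two identical inverted
repeats (IRb, IRa) that separate a large and a small single-copy region (LSC,
SSC). `infer_regions()` finds the maximal-length pair of disjoint
reverse-complement repeats by an exact k-mer anti-diagonal scan (k = 25,
always at most the IR length floor `min_ir`, default 1000 bp) and labels the
copy whose downstream neighbour is the SSC as IRb. Ties in repeat length
break to the lexicographically smallest start pair; a genome with no repeat
of at least `min_ir` bp is reported as IR-lacking and excluded downstream.
Internally all coordinates are 0-based half-open, converted to and from the
1-based inclusive flat-file convention only at the parser boundary; features
and regions may wrap the circular origin, stored unrolled.
`canonicalize_record()` rotates a record so the LSC starts at position 0,
which makes the four junctions JLB (LSC/IRb), JSB (IRb/SSC), JSA (SSC/IRa)
and JLA (IRa/LSC, the origin) well defined.

Junction states are purely geometric: a focal gene whose body crosses a
junction is an *expansion* of the IR into that gene (`overlap_bp` bases on
the IR side); a gene entirely on the single-copy side is a *contraction*
(`distance_bp` to the junction); no ancestral IR length is assumed, because
the six-way family pattern table can be reproduced from observable geometry
alone. IR copying makes the IR-interior part of a junction-spanning gene
reappear, reverse-complemented, at the mirrored junction; such truncated
duplicates are annotated as pseudogenes and reported as `pseudo-fragment`
rows with the same overlap width — a useful internal consistency check.
Family aggregation declares a state *mixed* as soon as one record deviates
(no majority rule), mirroring how exceptions are reported taxon by taxon in
comparative tables. Overlaps are measured on genome coordinates regardless
of strand; strand matters only for locating the trnH-GUG 3' terminus in the
conserved-feature check (3 bp inside IRa).

GC percentages exclude N from the denominator so they reflect base
composition rather than assembly coverage, and the IR column of the summary
reports one IR copy, which matches the 25–26 kb magnitudes conventional in
per-region size tables.

## Sliding-window nucleotide diversity and HPR calling

`nucleotide_diversity()` computes the raw average pairwise difference
proportion, \(\pi = \sum_{i<j} d_{ij} / (\binom{n}{2} L_{\mathrm{eff}})\).
No Jukes–Cantor correction is applied: the plastome-scale values this
statistic is used for are small (order 0.001–0.1), where the correction is
negligible and the uncorrected proportion is what comparative studies print.
The default gap policy drops every column containing a gap or N (the
complete-deletion analogue); pairwise deletion is available. Windows default
to 600 columns at step 200 — common sliding-window practice for plastome
polymorphism scans — and both are exposed because the right scale depends on
alignment length.

Highly polymorphic regions (HPRs) are called by a scale-free rule:
windows with \(\pi_w > \bar{\pi} + 2\,\mathrm{sd}(\pi)\), computed per group,
merged into maximal intervals when they overlap or touch. Absolute-threshold
and top-n rules are provided for exploration. Two numerical caveats are
deliberate: a constant profile (sd = 0) yields no calls rather than
everything, and because the mean and standard deviation include the hotspot
windows themselves, the rule loses sensitivity once elevated windows exceed
roughly a fifth of the profile — the synthetic hotspot default (1.6 kb in a
10 kb alignment) sits safely below that contamination regime, and real
multi-hotspot plastome scans should prefer `top:n` or an absolute threshold
if hotspots are expected to cover much of the alignment. Region assignment
labels a call LSC/SSC/IR by majority base-pair overlap of its mapped genome
interval, with deterministic tie order LSC, SSC, IR.

## Intron indel events and simple indel coding

Alignment gaps are first normalized: within flanking-repeat ambiguity a gap
run can occupy several column ranges without changing any row's residues, so
runs are slid left, one column at a time, while the residue left of the run
equals every other row's residue in the column the run would vacate. This
left-justification makes equivalent gaps occupy identical columns, which is
what lets extraction group them into shared events. Events are the distinct
(start, end) maximal gap runs, with the taxa carrying the gap as bearers;
leading and trailing runs are missing data (alignment-trim artifacts), never
events. The single-position rule absorbs a 1-column run lying within one
column of a longer event with the identical bearer set into that event,
because an isolated single position flanking an indel is not credible as an
independent mutation event.

Polarity is read off a reference: in outgroup mode, residues in the outgroup
at the event columns mean the bearers lost sequence (deletion), outgroup
gaps mean the non-bearers gained it (insertion), and a mixed or missing
outgroup state is ambiguous; majority mode substitutes the majority state
with ties ambiguous. Both modes exist because published polarity splits are
often reported without stating the rule. For family specificity the marked
set is the *carrier* set of the derived state — the bearers for a deletion,
the residue-holders (minus outgroups) for an insertion — since an insertion
confined to one family leaves the gap in everyone else. Strict mode requires
the carriers to be exactly the family's sampled taxa (the reading under
which unique indels are family barcodes); relaxed mode accepts any non-empty
subset confined to the family. Ambiguous-polarity events are tallied
separately and excluded from ins/del totals so the printed-style
`ins/del/total` cells stay internally consistent.

Simple indel coding emits one presence/absence character per event; a taxon
whose own gap run strictly contains the event's columns is scored `?`
(inapplicable — its state at those columns is unobservable), which is the
standard treatment and is what the parsimony layer expects for nested gaps.

## tRNA cloverleaf typing

Input is predictor-agnostic (sequence plus dot-bracket). Hairpins are
assigned positionally — first is the D arm, second the anticodon arm, last
the T (Ψ) arm, identified purely by position with no modified-base
inference — and everything between the anticodon and T arms is the variable
region, which may carry its own hairpin (the paired V-arm of type II tRNAs).
Typing follows the Brennan–Sundaralingam convention: V region of 4–5 nt is
type I, 10 nt or more is type II; the 6–9 nt gap is reported explicitly as
`intermediate` rather than silently binned, so unusual structures surface
instead of disappearing into a dichotomy. Bulge loops interrupting the
anticodon or T stems, anticodon loops longer than 7 nt, and long V regions
are flagged as anomalies. When the anticodon loop is canonical (7 nt) its
central triplet is cross-checked against the label; a mismatch warns rather
than errors because expanded loops legitimately shift the triplet.

A motif catalog (shipped as `extdata/trna_type_catalog.tsv`, codes A1–H2 for
eight plastid isotypes) maps V-loop sequences, anticodon-loop lengths and
bulge motifs to short type codes; the catalog is an editable TSV so further
distinctions can be added without code changes.

`fold_trna()` exists so the typing layer can be exercised without an
external structure predictor: it maximizes canonical (AU, GC, GU) stem pairs
over all cloverleaf templates within configurable stem/loop bounds
(canonical defaults: acceptor 7±1 bp, D 3–4 bp, anticodon 5±1 bp, T 5±1 bp,
loops and spacers within textbook ranges), breaking ties towards the 5'-most
pairing. It is an enumerative, not thermodynamic, folder; the bounds are a
parameter so small test molecules can be folded and verified exhaustively.

## Character mapping

Characters (SIC columns, or binarized tRNA classes) map onto a supplied
rooted tree by Hartigan's generalization of Fitch parsimony, so
multifurcating inputs are handled exactly; `?` is a wildcard over the
observed alphabet. A deterministic top-down pass fixes one
most-parsimonious reconstruction, delaying changes (a child keeps its
parent's state whenever its set allows — DELTRAN-style), and counts
independent origins of the derived state; a second pass preferring the
derived state flags characters whose origin count depends on the tie-break
(ACCTRAN/DELTRAN disagreement). One origin spanning more than one leaf is
clade-specific — family-specific when the origin clade's leaves are exactly
one family's sampled taxa — two or more origins are homoplasy, and
single-leaf characters are reported as autapomorphies rather than dropped,
since the threshold separating "informative" from autapomorphic is a
reporting choice, not a modelling one.

## What the synthetic data emulate — and what they do not

The generators plant every structure the pipeline claims to detect, under
one seed that determines all output byte-for-byte:

* **Plastomes** use a 30 kb template (LSC 16 kb, IR 4 kb, SSC 6 kb) — a
  1:5 scale model of a 150 kb plastome that preserves every junction, loss
  and repeat feature while keeping a 40-genome simulation around a few
  seconds. Genomes realize four junction patterns across eight families of
  five taxa, including the published family-signature widths (a 110 bp
  rps19 expansion and a 1077 bp ycf1 expansion), and three loss events
  (two gene losses, one intron loss). IR boundary bases are pinned so the
  planted repeat is exactly maximal.
* **Intron alignments** (17 loci) descend from a random ancestor with
  independent per-site substitutions at 1% — a uniform noise model, not a
  phylogenetic simulator, which is adequate because no stage estimates
  substitution parameters. Sixty events are planted with exact coordinates,
  polarity and carrier sets: mostly strict family-unique, three
  cross-family (homoplastic on the tree), one nested pair exercising the
  `?` state. Gap flanks are pinned so planted gaps cannot slide.
* **The hotspot alignment** draws per-site differences independently at
  p0 = 0.01 outside and p1 = 0.05 inside a 1.6 kb interval of 10 kb
  (n = 20), a fivefold contrast at which the z-score rule recovers the
  interval with Jaccard overlap ≥ 0.8 in essentially every seed.
* **tRNA sets** render cloverleaf templates whose stems are complementary
  by construction, drawn from {C, G} with unpaired positions A (outside
  motifs), so the planted dot-bracket is the unique maximal-pairing
  cloverleaf; five family-unique classes and one intrafamilially variable
  isotype are planted per the default plan.

Passing these tests demonstrates that the *measurement* layer is exact:
planted geometry, losses, events and classes are recovered with their exact
coordinates and labels. It does not demonstrate robustness to the failure
modes of real data — mis-annotated flat files, alignment error, repeat-rich
regions that confound gap placement beyond simple left-justification,
structure-prediction uncertainty, or IRs interrupted by N runs. Those enter
upstream of this package's contracts.

## Numerical choices and degenerate inputs

* Region intervals must tile the circle exactly and the IR copies must be
  byte-exact reverse complements; violations are errors, not warnings.
* π is `NA` (not 0) when no effective sites remain; profiles report
  `n_effective_sites` per window so such windows are visible.
* `call_hprs()` returns an empty, typed frame for degenerate profiles.
* All-gap alignment columns are rejected (they indicate an untrimmed
  alignment upstream).
* Deterministic tie-breaks throughout: smallest-start repeat pair, 5'-most
  fold pairing, DELTRAN state assignment with lexicographic fallback,
  LSC > SSC > IR region-label ties.
* Seeds derive from a single integer; derived seeds stay below 2^31.

## Problem sizes used by the checks

The packaged checks run, by the package's own choice, at: 200 random
alignments (≤ 20 × 200) for extraction-oracle equality; all 1068 rooted
binary trees on 3–6 leaves times all binary characters for parsimony-oracle
equality; 50 random alignments for the sliding-π oracle; 20 toy sequences
(≤ 40 nt, reduced bounds) for exhaustive fold equality; one full
demonstration simulation (40 taxa, 17 loci, 60 events, 400 tRNAs) for
end-to-end recovery; and 100 seeds for the hotspot-recovery property.

## Known limitations

* `infer_regions()` assumes the IR pair is the genome's dominant inverted
  repeat; heavily degraded or absent IRs are reported as IR-lacking rather
  than reconstructed.
* Gap normalization is a per-run left-justification; it does not perform a
  full re-alignment and can leave genuinely ambiguous repeat regions in
  distinct columns if rows disagree beyond single-run slides.
* The folder enumerates cloverleaf templates only; it cannot represent
  non-cloverleaf foldbacks and is not a substitute for covariance-model
  prediction on real sequences.
* Junction profiling expects the canonical LSC-first rotation (it rotates
  internally); records whose region map cannot be canonicalized (no IR) are
  out of scope downstream, matching the analysis contract.
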