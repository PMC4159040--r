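---
title: "Designing LNA clamps that block organelle SSU rRNA amplification: methods and modeling choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing LNA clamps that block organelle SSU rRNA amplification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lnaclamp)
```

## The problem

Culture-independent surveys of plant-associated bacteria amplify
small-subunit (SSU, 16S) rRNA genes with "universal" bacterial primers.
Plant mitochondria and plastids carry SSU rRNA genes homologous enough to
be co-amplified, and because organelle DNA dominates extracts from seeds,
leaves and roots, the organelle amplicons can swamp the bacterial signal.

PCR clamping suppresses the unwanted templates: a short oligonucleotide is
designed that is complementary to the *organelle* version of a region
overlapping a primer-binding site, cannot be extended (its 3' end is
phosphorylated), and binds more stably than the primer. Substituting
selected DNA residues with locked nucleic acid (LNA) bases raises the
duplex melting temperature and sharpens single-mismatch discrimination, so
the clamp can saturate organelle templates at an annealing step above the
primer's working temperature while leaving divergent bacterial templates
free. `lnaclamp` implements the computational side of this workflow:
degenerate-primer coverage engineering, clamp-window discovery on an
alignment, LNA placement under structural constraints, Tm targeting,
structural validation, in-silico PCR, and specificity screening.

## Degenerate primers and coverage

A degenerate primer is an IUPAC string; its concrete variants are the
Cartesian product of the per-position base sets. The bundled
`modified_63f` (`YRKGCYTWAYACATGCAAGTC`) carries six two-fold positions,
hence 64 variants, and contains the original `63f` as one of them.
Matching is *set-wise* throughout the package: a template position matches
a primer position iff their IUPAC base sets intersect, which reproduces
the min-over-variants mismatch count for concrete templates (the
test-suite checks this against a brute-force expanded-variant scan).

`coverage()` reports the fraction of a sequence set containing at least
one binding site within a mismatch budget; the default budget is 0,
mirroring "fully matched" probe-match semantics. `degenerate_for_coverage()`
raises coverage greedily, one position/base broadening at a time, with a
deterministic tie-break (lowest position index, then alphabetical base).
Greedy rather than exhaustive search is deliberate: manual degeneration of
a primer is itself an incremental judgment call, not an optimality claim,
and greedy broadening is monotone by construction. Published database-wide
coverage percentages are snapshot-dependent and are not reproduced here.

No 3'-end-weighted mismatch model is used (the design procedure this
package systematizes used none). Exact-match semantics over the full
primer length is the default; this is stricter than some coverage tools,
whose mismatch tolerance and window conventions are generally
unpublished, and the divergence is intentional and documented rather than
emulated.

## The thermodynamic model

Melting temperatures use the unified DNA/DNA nearest-neighbor parameter
set of SantaLucia (1998, PNAS 95:1460): two-state ΔH/ΔS summation with
terminal A·T / G·C initiation terms, the entropic salt correction
ΔS + 0.368·(N−1)·ln[Na⁺], and Tm = 1000·ΔH / (ΔS + R·ln(CT/4)) − 273.15
for non-self-complementary duplexes. Default conditions are 50 mM
monovalent salt and 0.25 µM total oligo — ordinary PCR-scale conditions,
chosen once and overridable via `thermo_model()`.

LNA substitution is modeled as a constant Tm increment per substituted
residue, default **+3.5 °C**. Published duplex measurements put each
internal LNA at roughly +2 to +8 °C depending on sequence context
(Braasch & Corey 2001, Chem Biol 8:1); a mid-low constant is typical of
evenly spread substitutions in 17–19-mers, which is exactly the regime the
design algorithm produces (run-length ≤ 3, maximal spacing). The vendor
calculators used in practice implement proprietary position-dependent
models; a published, citable scalar with the model identity logged in
every report is preferred here, and the ±5 °C tolerance used in
validation absorbs the difference. Under this model the four bundled
clamps score 67.3–72.8 °C against their 70 °C design target. Two useful
consequences are exact by construction: a clamp with an empty LNA mask
scores identically to `tm_dna()`, and predicted Tm is monotone
non-decreasing in LNA count.

Degenerate primers are scored as the mean over their expanded variants
(≤ 64), with the min/max attached as attributes.

## Window discovery

`find_clamp_windows()` operates on block (suppress) and pass (preserve)
sets in shared alignment coordinates. Per column it computes:

* the **block consensus** (majority base; ties break toward the base that
  mismatches more pass members, since a clamp wants discriminating
  residues);
* **block conservation**, the fraction of block members matching that
  consensus;
* **pass divergence**, the fraction of pass members whose base set does
  not intersect the consensus (gaps always diverge).

Candidate windows extend from the primer's 3' flank: they either overlap
the primer footprint by 2–4 bases (the clamp then physically competes
with primer extension) or sit up to `max_offset` columns past it, since
whether a usable window abuts the footprint exactly is a property of the
alignment, not of the method. Windows are discarded when the block
consensus contains a gap, mean block conservation falls below 0.9, or no
column is discriminating. Ranking is lexicographic: block conservation,
then pass divergence, then proximity to the primer 3' end (offset, then
smaller overlap, then shorter window, then leftmost start). Two scoring
conventions matter and are deliberate:

* *Conservation* is averaged over the **full window** — every position of
  the clamp must anneal to every block member.
* *Divergence* is averaged over the **clamp-specific (non-footprint)
  columns only**. The overlap bases are shared with the primer by design
  and carry no discriminating signal; including them would penalize
  overlapping windows relative to shifted ones for a constant that says
  nothing about specificity.

A **discriminating column** is one where pass divergence reaches a
threshold, default 0.7 — a formalization of "most bacteria differ here".
The threshold is configurable because it must sit below the actual
divergence rate of the data at hand: in the synthetic planted-truth
experiments shipped with the package the generator plants a per-base pass
divergence of 0.6, so those runs set `pass_div_threshold = 0.5`; at the
0.7 default, a 0.6-divergence column passes only by sampling noise and
the design would (correctly) report that no usable window exists.

## LNA placement, Tm tuning, validation

`select_lna_positions()` formalizes "LNA bases equally distributed, only
at organelle-specific positions, never in the primer overlap": from the
discriminating, non-overlap positions it selects a subset of the requested
size with no run of more than 3 consecutive LNA bases (stretches of 4 or
more are avoided as a synthesis/structure rule), maximizing first the
minimum gap between chosen positions, then the spanned width, breaking
remaining ties toward the lexicographically smallest set. The search is
exhaustive over valid subsets (the pools are small), hence deterministic.

`tune_to_tm()` exploits Tm monotonicity in LNA count: the count within
4–6 whose predicted Tm lies closest to the 70 °C target is selected,
re-running position selection per count; if no option lands within
tolerance the best-|deviation| candidate is returned and flagged.
Window-length alternatives are explored one level up, in `design_clamp()`,
which walks the ranked window list (lengths 16–20 are distinct candidates)
until a clamp passes all structural rules.

`validate_clamp()` reports one row per rule — length 15–25, LNA count
4–6, max run ≤ 3, mandatory 3'-phosphorylation, no LNA in the overlap
bases (hard rules), and the ±5 °C Tm tolerance (soft). Validation never
throws on content. The design report also lists block members with any
in-window mismatch against the clamp; members exceeding 2 mismatches are
flagged beyond the tolerated "one or two mismatch" outlier level observed
in real organelle collections. An alternate, stricter rule set for PNA
oligomers (purine content, G-stretches) is out of scope.

## In-silico PCR and specificity conventions

* `predict_amplicon()` pairs plus-strand forward sites with reverse-primer
  footprints downstream; **product length includes both primer
  footprints** (reverse end − forward start + 1), the convention under
  which the registered organelle records give 1616/1416/1876 bp products
  with the bundled primer pair. The fewest-total-mismatches pair (ties:
  shortest product) is flagged primary; products above 5 kb are ignored.
* `classify_blocking()` labels a template *blocked* when a clamp matches
  it within the budget (default 0 — perfect-match clamping) at a site
  overlapping a primer footprint. This is a sequence criterion, not a
  kinetic model: clamp efficacy in the tube also depends on concentration
  and annealing schedule, which are outside computational scope.
* `probe_match()` is strand-agnostic and counts matching database
  members, mirroring how a designed clamp is screened against a bacterial
  reference set for unintended perfect matches.
* `percent_identity()` rounds half-up. Published identity tables are not
  always internally consistent under a single rounding convention
  (e.g. 447/449 = 99.55% printed as 99% but 434/453 = 95.81% printed as
  96%), likely because printed fractions and percentages came from
  different alignment summaries; one convention is fixed here and only
  rows on which floor and half-up rounding agree are used as checks.

## What the synthetic generator emulates — and what it does not

`generate_fixture()` plants the structure the design method assumes: a
shared random backbone; one concrete variant of a degenerate primer at a
fixed site in every member; a clamp window starting `overlap_len` bases
before the footprint end whose consensus block members retain with
probability `block_window_conservation` (default 1.0) and pass members
mutate per-base at `pass_window_divergence` (default 0.6, uniform over
the three alternatives); independent background substitutions elsewhere
(default 0.05, a realistic within-organelle-family scale given that real
block collections show at most one or two mismatches). Primer-site
retention is per-member: a non-retained member receives one
match-breaking substitution inside the footprint, so a planted 80%
retention yields ≈ 0.8 exact-match coverage. Generation is
Mersenne-Twister deterministic under the `fixture_spec()` seed.

Standard experiment sizes, chosen once: 20 block members, 200 pass
members, 120-nt sequences, 100 seeded replicates for the recovery
experiment. These sizes make every constraint active while keeping a full
planted-truth replicate set cheap to recompute.

The generator does **not** emulate phylogenetic correlation between pass
members, indels/alignment error, chimeras, GC skew, or position-dependent
conservation within the 16S gene. Passing the planted-truth experiments
therefore demonstrates that the algorithm recovers the structure it is
specified against and respects its constraints — not that any particular
field alignment contains a usable window; on real alignments the
diagnostic path (no-window message, validation table, exception list) is
as much a part of the interface as the clamp itself.

## Numerical and degenerate-input choices

Coordinates are 0-based half-open internally and 1-based inclusive in all
user-facing tables. Gaps are `-` (`.` is normalized on read); `U` is
normalized to `T` with a note kept in the record description. A singleton
block set designs with a warning (conservation evidence is trivial); an
empty pass set is an error; identical block and pass sets produce no
discriminating columns and hence no windows. Stage identity is preserved
in errors propagated out of `design_clamp()`.

## Known limitations

* The LNA Tm term ignores sequence context and position; predictions are
  design-grade (ranking, targeting), not measurement-grade.
* Clamp blocking is combinatorial; concentration titrations and annealing
  kinetics must still be established at the bench.
* Multi-group targets (e.g. plastid lineages with distinct window
  haplotypes) require one clamp per group; cocktail design is left to the
  user.
* Alignments are consumed, not computed; trimming/masking decisions stay
  upstream.
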