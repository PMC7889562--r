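---
title: "Methods: probe design, density, and cross-genus evaluability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: probe design, density, and cross-genus evaluability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(chromopaint)
```

# The problem

Chromosome painting by oligo-FISH hybridizes pools of tens of thousands of
short (43–47 nt) labeled oligonucleotides to a chromosome or region.  Within
a genus the method is reliable; across a genus border it routinely fails,
because sequence divergence removes most probes' targets and the surviving
probes are spread too thinly along the chromosome to form a visible signal.
`chromopaint` implements the computational side of this problem end to end:
designing probe pools from a reference assembly, quantifying their expected
density on diverged targets, identifying the repeat classes (microsatellites,
tandem satellites) that cause non-specific signal, and running a
synteny-based workflow that evaluates probes against shallow reads of an
unassembled target genus.  Everything is testable on synthetic genomes
produced by the package's own seeded generator.

# The design pipeline

`design_probes()` runs four stages.

1. **Tiling.**  Every window of every length in `[min_length, max_length]`
   (defaults 43 and 47 nt) at every offset of the target region becomes a
   candidate; windows containing N are rejected.  The tiling stride is
   configurable for speed; stride 1 is the default and matches a
   maximal-overlap reading of "overlapping candidates".
2. **Off-target Tm screen.**  Each candidate is searched against the whole
   design assembly.  Hits overlapping the candidate's own locus are ignored;
   every other hit is converted to an effective duplex melting temperature
   (below) and the candidate is rejected when the hottest off-target duplex
   comes within `offtarget_tm_margin` (default 20 °C) of the perfect-match
   Tm.  The margin default is a declared convention, not a reconstruction of
   the original (proprietary) tool: with the default 1 °C/% penalty it lets a
   75%-identity off-target site pass (−25 °C) while a 90% site fails
   (−10 °C).
3. **Homeolog single-hit filter.**  Candidates are searched against the
   homeologous chromosome of the sister species; a candidate survives only
   if it has exactly one hit with E-value below `1e-5` and that hit's
   identity is at least 75%.  This encodes the published rule that a single
   strong homeolog hit both guarantees cross-species hybridization and
   excludes ambiguous (duplicated) targets.
4. **Non-overlap selection.**  Among survivors, a maximum-cardinality set of
   pairwise non-overlapping intervals is chosen with the earliest-end-first
   greedy scan, which is provably optimal for interval scheduling.  Ties on
   end coordinate go to the lower start, then the lexicographically smaller
   sequence, making the pipeline fully deterministic.

The published description orders the stages "non-overlapping candidates …
were blasted", i.e. selection before the homeolog filter.  We filter first
and select last (`order = "filter_then_select"`, the default) because
filtering first can only increase the density of the final set; the other
order is available behind the same switch and is covered by tests.  Whether
the original design enforced a minimum gap between probes is unknown;
abutting probes are allowed here (half-open intervals that touch do not
overlap).

# Melting temperature model

Perfect-match Tm uses the unified nearest-neighbor thermodynamic table
(ΔH in kcal/mol, ΔS in cal/mol/K), terminal initiation terms, and an
entropy-based monovalent-salt correction:

$$T_m = \frac{1000\,\Delta H}{\Delta S + 0.368\,(L-1)\ln[\mathrm{Na^+}] + R \ln(C_T/4)} - 273.15$$

with `[Na+] = 0.33 M` (2× SSC, a standard post-hybridization wash condition) and an assumed
probe concentration `C_T = 0.25 µM`.  The strand concentration is an
arbitrary fixed convention — it shifts all Tm values equally, so the
relative screening decisions are unaffected.

For mismatched probe/target duplexes no nearest-neighbor mismatch tables are
used (out of scope by design); instead a linear rule of thumb applies:
each percentage point of identity lost lowers Tm by
`mismatch_penalty_per_percent` (default 1 °C).  At 10% divergence the
median probe-wide identity in our simulations is ≈ 89%, so the median
effective Tm drops by ≈ 10–11 °C — reproducing the published observation
that homeolog Tm distributions sit about 10 °C below the intra-species
ones.  Note the identity that feeds the penalty in that evaluation is
*probe-wide* (matches / probe length): unaligned probe ends do not pair and
must count against the duplex.

# Similarity search and E-values

The search is a classic seed-and-extend: exact 11-mer seeding over both
strands, ungapped X-drop extension (X = 15 raw score units), and merging of
overlapping extensions on the same diagonal.  Scores default to +1/−2; the
scheme is configurable but pinned so that results are reproducible.  Gapped
extension is not performed; at probe length (≤47 nt) indels in the target
split an alignment into sub-threshold pieces, which is the behavior we want
for a hybridization surrogate.

Karlin–Altschul statistics: λ is the unique positive root of
`Σ p_i p_j exp(λ s_ij) = 1` at uniform base frequencies, found by bracketed
root finding.  K uses the lattice formula `K = A (1 − e^{−λδ})` with
`A = Σ_s s p(s) e^{λ s}` and δ the score gcd; for the default +1/−2 scheme
this is exact and reproduces the published ungapped blastn constants
(λ = 1.3327, K = 0.621).  For other schemes it is an approximation, which is
acceptable because E-values are used only as a configurable cutoff and all
package-internal expectations are derived under the same K.  The E-value is
`E = m·n·2^(−bit)` with `n` the *total* subject length; no finite-size edge
correction is applied (second-order at these scales).

The published equivalence "E < 1e-5 ≙ ≥75% similarity over the probe
length" depends on the scoring scheme and the subject size, so the two
thresholds are kept as independent configuration values and the equivalence
is never asserted.

# The D100 density index

D100 is the probe density of a moving window of 100 contiguous probes,
in probes per kb of DNA covered by those probes.  "Covered" is read as
*first probe start to last probe end*, inter-probe gaps included: that is
the only reading under which the published per-chromosome medians
(≈ 4–5 probes/kb for ~45-nt probes) are attainable — summing probe lengths
alone would pin every window near 22 probes/kb.  Windows advance by one
probe; chromosomes with fewer probes than the window contribute no windows
and report a missing median, mirroring blank cross-genus table cells for
unassembled targets.  When one probe set is evaluated against several
target chromosomes, `median_d100()` pools all windows before taking the
median (both pooled and per-chromosome outputs are available, since the
published table is ambiguous on this point).

# Microsatellites and blocking

Motif classes merge cyclic rotations and reverse complements (GA ≡ AG ≡ TC
≡ CT), because probes hybridize double-strandedly.  A run is annotated when
it has ≥3 units, spans ≥10 nt, and is ≥90% pure; these thresholds are
declared conventions chosen so that the published example oligos (whose
highlighted runs are ≥12 nt pure) are caught with margin.
`propose_blocking()` emits one ~30-nt unlabeled blocker per motif class —
(GA)₁₅, (GAA)₁₀ — at a default 2.5× molar excess (50 pmol blocker per
20 pmol labeled probes), matching the published blocking protocol.  The
hybridization outcome of blocking is wet-lab territory and is not modeled.

# Satellite discovery from reads

A tandem monomer longer than `read_length − k` (here 151 − 17 = 134 nt)
never recurs within a single read, so its period cannot be found by
within-read autocorrelation; it must be assembled across reads.  The
detector counts canonical 17-mers, estimates the single-copy modal depth
from the spectrum (walking past the depth-1 error valley), keeps k-mers
deeper than 3× modal, and walks the (k−1)-overlap graph of those k-mers
from the deepest node, always taking the deepest successor, until a node
repeats.  The cycle length is the monomer length; the consensus is read off
the cycle and canonicalized as the lexicographically smallest rotation over
both strands (a cycle has no natural start and the walk no natural
orientation).  Edges are defined by successor membership in the high-depth
set rather than by explicit read adjacency — with error k-mers already
excluded by the depth threshold the two definitions coincide in practice,
and the set form is simpler.

Abundance is the depth-weighted share of cycle k-mers among all
*non-singleton* read k-mers.  Excluding singletons (dominated by sequencing
errors: at 0.5% error ≈ 8% of k-mer instances contain an error) removes the
systematic underestimate that error k-mers would otherwise introduce in the
denominator, since error-containing copies of the satellite are equally
missing from the numerator.  This choice was fixed from the error-model
arithmetic, not tuned to any target.  `kmer_repeat_fraction()` by contrast
reports the plain depth-weighted fraction above 4× modal over *all* k-mers,
as its contract states.

# Cross-genus workflow

`run_crossgenus_workflow()` chains: design on the reference chromosome →
repeat library from the target-genus reads (satellite consensus +
microsatellite motifs + high-depth k-mers) → probe screening against that
library (≥75% identity over ≥30 nt to a satellite, any flagged motif run,
or ≥20% shared high-depth k-mers rejects) → syntenic read selection →
validation.  "Mapping preferentially" is quantified as best-hit-on-target
with a 5-bit margin over the best off-chromosome hit; the source work gives
no numeric criterion, so this is a configurable convention.  Validation
requires a hit with identity above 85% covering ≥90% of the probe — the
"greater than 85% homology" rule read as near-full-length, consistent with
the probe-length-wide similarity rule used in the design stage.  Optional
contig assembly from overlapping reads is deliberately not implemented; the
supplementary-candidate hook (tiling syntenic reads and mapping candidates
back to the reference chromosome) marks the extension point.

# The synthetic world

The generator states one fixed world rather than tunable scenery:

* genomes are i.i.d. uniform A/C/G/T (no composition bias; hooks for a
  biased model are documented but off);
* divergence is uniform random substitution at the requested rate, applied
  independently on each descendant branch, with optional geometric indels
  (default rate 0); realized divergence is within ±0.5 points of the
  request on ≥100 kb;
* the fusion fixture joins two reference chromosomes into one sister
  chromosome at 5% per-branch divergence — a typical intra-genus distance
  consistent with the ~95% homeolog identities implied by the published
  intra-genus results;
* reads are 2 × 151 nt pairs, normal insert (350 ± 50), uniform fragment
  placement on both strands, uniform substitution errors, constant base
  quality (quality modeling is irrelevant to the N-based filters used
  downstream);
* the satellite fixture uses the published monomer length (138 bp) and
  genome fraction (0.21%) at 30× coverage.

What a green test does *not* establish: real genomes are not uniform i.i.d.
sequence — they carry compositional skew, transposon families, segmental
duplications and soft-masked repeats that make off-target screening much
harder than on this synthetic background.  The acceptance suite therefore
checks parameter recovery and qualitative reproductions (density collapse
across a divergence ladder, two-color fusion painting), not the published
genome-scale numbers, which would require the original chromosome-scale assemblies
and read archives.

# Numerical and degenerate-input choices

* λ root finding: `uniroot` on (1e-9, 20), tolerance 1e-12.
* Regions shorter than the minimum probe length tile to an empty candidate
  list (not an error); all-N regions likewise, with the rejection logged.
* `d100_profile` refuses unsorted or overlapping intervals; profiles with
  fewer probes than the window return `NA` medians and `median_d100()`
  errors only if *every* pooled profile is empty.
* Greedy selection tie-breaks (end, start, sequence) make probe tables
  byte-identical across runs; all generator randomness flows through
  explicit seeds with a fixed RNG kind.
* `detect_satellite` returns a "not detected" result object rather than
  throwing when no k-mer exceeds the depth threshold or the walk dead-ends.

# Known limitations

* Ungapped extension only; a probe whose target carries an internal indel
  is reported as two partial hits (usually sub-threshold) rather than one
  gapped hit.  This is conservative for design and matches the package's
  hybridization-surrogate role.
* The linear mismatch-Tm rule ignores mismatch identity and position;
  nearest-neighbor mismatch parameters are out of scope.
* One satellite family is reported per read set (the deepest cycle);
  secondary families would require iterative masking, which is left as an
  extension.
* The stringency percentages quoted for the wet-lab washes (84.6 / 89.6)
  come with no formula and are not reproduced.
* `K` for non-default scoring schemes uses the lattice approximation noted
  above.
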