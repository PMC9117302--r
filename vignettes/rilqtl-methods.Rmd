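---
title: "Methods and design choices in rilqtl"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design choices in rilqtl}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rilqtl)
```

This vignette explains the statistical machinery behind each stage of the
package, the assumptions it rests on, the tunable parameters and their
defaults, and the places where the design was genuinely open and a choice
had to be made. Nothing here reports a number that the test suite or
`scripts/acceptance.R` does not itself compute.

## The setting

A biparental RIL population is a panel of near-homozygous lines derived by
repeated selfing from a single F₁. At a phased marker, each line carries
the allele of parent A or parent B (coded `A`/`B`), a residual heterozygous
call (`H`), or a missing call. Sequencing-based genotyping delivers these
calls sparsely and with errors, which is what the curation stage targets.
All downstream arithmetic is anchored to physical coordinates: 1-based bp,
and 1-based megabase units defined as `ceiling(bp / 1e6)`. Intervals in Mbp
are inclusive on both endpoints, and an interval's width is
`end − start + 1` units, so that whole-Mbp coverage sums behave like counts
of covered units. Translocated segments can be promoted to
pseudo-chromosomes with `split_segment()`; their original bp coordinates
are preserved so that positions cited against the source assembly remain
valid.

## Marker curation

`filter_markers()` retains a marker when its missing fraction is ≤ 0.50,
its minor allele frequency is ≥ 0.30, and its heterozygous fraction is
≤ 0.10. Boundary values are retained, reflecting the max/min wording of the
thresholds. MAF is computed over non-missing calls with an `H` contributing
half to each allele — the standard allele-frequency accounting; the
heterozygous fraction is taken among non-missing calls, since missing cells
say nothing about the genotype state. A marker failing several rules is
counted against the first in the order missing → MAF → het, so the audit
report's removals always sum to the input count.

The error signature that drives correction is the *double crossover*: a
homozygous call that contradicts its nearest homozygous neighbours on both
sides when those agree. True double crossovers within a few Mbp are rare in
selfed populations; singletons are almost always miscalls, and a marker
whose calls contradict both neighbours in most lines is phased backwards.
`correct_phase_and_outliers()` flips a marker when flipping removes at
least `flip_threshold = 0.5` double crossovers per informative line, and
removes it when even its better phase leaves a double-crossover rate above
`outlier_rate = 0.2`. Flips and removals change the flanking context of
neighbours, so the procedure iterates to a fixed point with a 10-pass
bound; non-convergence is reported in the audit trail rather than raised.

`impute_gbsi()` fills missing runs per line and chromosome. Runs flanked by
the same homozygous call take that call. Runs flanked by *different* calls
are filled from each end toward the centre, leaving a central uncertainty
zone of `zone = 1` marker (one extra when parity requires symmetry)
missing — somewhere in that run a crossover happened and its position is
unknowable, so the cells nearest the ambiguity stay missing. Under this
rule a run of one or two cells between different flanks is left entirely
missing. Isolated single-marker contradictions are set to the flanking
call; heterozygous calls are never altered (they carry real signal about
residual heterozygosity); leading and trailing runs stay missing by default
because they have only one flank — each rule is individually switchable.
The rules are applied to an internal fixed point, which makes the operation
idempotent. These heuristics emulate what a careful human curator does with
a graphical genotype display; they are deliberately *not* a hidden Markov
model, which is a different trade-off (model-based smoothing versus
transparent, auditable edits).

## Recombination landscape

The observed recombination rate between two markers is
`r = discordant / doubly-homozygous` over lines non-missing and homozygous
at both. This is the *observed RIL discordance*, not the per-meiosis
recombination fraction; over repeated selfing the two are related by
R = 2r/(1+2r), and a map-function correction is deliberately left out of
the matrix (the heat-map scale runs to 0.5, the independence plateau).
Pairs with fewer than `min_informative = 10` doubly homozygous lines are
treated as missing rather than zero — a zero from two informative lines
would paint spurious pseudo-linkage. Values above 0.5, which arise from
sampling noise or residual phase error, are capped at 0.5 for the display
matrix and retained raw.

`recombination_matrix()` averages r over all pairs of distinct markers
between two physical windows (default 16 Mbp wide, centred on coordinates
every `step = 10` Mbp; 1 Mbp steps for fine maps). A window containing no
markers is represented by the nearest marker on each side, so uniformly
spaced coordinates always carry values where the chromosome has data; a
chromosome with fewer than two markers yields missing rows and a message.
The implementation forms the full marker-by-marker discordance matrix with
dense linear algebra, which is fast up to a few thousand markers but
quadratic in memory; genome-wide marker sets much beyond ~10⁴ markers
should be windowed per chromosome pair.

`detect_anomalies()` reports maximal 4-connected blocks of window pairs
with r ≤ 0.2 (the teal anchor of the display scale — the point at which
linkage is unambiguous at these sample sizes). Between chromosomes any
such block is a pseudo-linkage call. Within a chromosome, physical linkage
makes near-diagonal cells low by definition, so only pairs separated by at
least `min_intra_sep = 50` Mbp are considered, and pairs where both windows
fall in the central 50% of the chromosome are masked as expected
pericentromeric suppression. Both the separation and the mask are
configurable; on genomes where centromeric suppression is not expected the
mask can be disabled with `centromere_frac = 0`.

## QTL scan

At each marker the lines homozygous A or B are split into two classes and

TS = n · ln(RSS₀ / RSS₁)

compares the least-squares fit with and without the marker-class effect
(RSS₀ from the reduced model, RSS₁ from the full model, n the lines used).
This variance-ratio form approximates the likelihood-ratio statistic for
Gaussian errors, converts exactly to the LOD scale by LOD = TS/(2 ln 10),
and reproduces the conventional anchor LOD 5 ↔ TS 23.03. It is invariant
to affine rescaling of the phenotype. A covariate marker, when supplied,
contributes its class effect to both models, so a marker collinear with
the covariate scores zero; the covariate is excluded from being tested
against itself. Markers with an empty class, fewer than `min_lines = 20`
usable lines, or zero residual variance are not scored (the last raises an
error in the scalar interface and is logged as missing in scans). The
direction of the effect is reported through the high-value parent and the
class-mean difference (the homozygous substitution effect — a
half-difference convention is available via `effect_scale`), not by
halving p-values.

Genome-wide thresholds come from permutations that shuffle phenotype values
across lines while keeping genotypes fixed; one permutation of lines is
shared by every marker (max-T resampling), and the threshold at level α is
the empirical (1−α) order statistic of the permutation maxima. The default
`n_perm = 1000` gives thresholds reproducible to within ~2% of a
10,000-permutation run at α = 0.05; studies quoting α = 0.001 should use
10⁴ permutations. The acceptance experiments in this package use 1,000
permutations per trait and verify the α = 0.05 calibration over 200
simulated null traits against the exact binomial 99% interval — a problem
size chosen to exercise the machinery at full population scale while the
suite stays quick.

`call_peaks()` takes, per chromosome, the maximum-TS marker above the
threshold (ties break to the lowest coordinate), grows the support
interval as the contiguous run of scored markers with TS ≥ 0.8 × peak (a
20% fall-off), masks the interval plus 75 Mbp on each side, and repeats.
Interval ends are marker positions reported in Mbp; no interpolation is
done between markers, because single-marker profiles carry no information
between markers. Note that secondary peaks are judged against the same
genome-wide threshold, which is anti-conservative for them; the exclusion
rule exists to stop one broad QTL being reported repeatedly, not to give
secondary peaks valid genome-wide p-values.

## Candidate-gene co-location

For a trait with QTL support intervals covering a fraction p of the genome
(in whole-Mbp units, after optional symmetric widening, clipping to
chromosome ends, and merging of overlaps), the chance that K or more of M
independently placed candidate genes land inside the intervals is the
binomial tail P(K ≥ N) = Σₖ₌ₙᴹ C(M,k) pᵏ(1−p)ᴹ⁻ᵏ. A gene co-locates when
its Mbp unit lies inside any interval, endpoints inclusive, and counts at
most once.

The binomial assumes uniform gene density, placement with replacement, and
no spacing constraint. `bootstrap_colocation()` relaxes all three: genes
are placed on the 1 Mbp unit grid with probabilities from a gene-density
profile (uniform unless a per-Mbp count table is supplied — the loader
accepts what any GFF3 annotation reduces to), subject to a minimum
separation of `min_sep = 100` Mbp between genes *on the same chromosome*.
Whether the separation should also apply across chromosomes is genuinely
ambiguous — physical distance between different chromosomes is undefined —
so the within-chromosome reading was adopted; the constraint exists to
stop homeologous copies of one gene being counted as independent draws,
and homeologs sit on different chromosomes by definition. Placement is
sequential with per-gene rejection and a 1,000-attempt budget; replicates
exhausting the budget are redrawn whole and counted in the diagnostics.
Tails come with the Monte-Carlo standard error √(p̂(1−p̂)/n_boot), and with
a uniform density and `min_sep = 0` the bootstrap converges to the
binomial — the package's cross-validation of the two routes.

## The simulator

`simulate_ril()` advances each line independently from the F₁ by
single-seed descent: per meiosis and chromosome the crossover count is
Poisson with mean equal to the genetic length (`cm_per_mbp` × length; 1
cM/Mbp by default — a deliberately flat landscape), positions are uniform,
and there is no crossover interference (Haldane). Generations are simulated
explicitly, so F₄ versus F₆ genuinely changes residual heterozygosity
((1/2)^(k−1) per locus at F_k). The defaults — 200 lines, F₆, markers
every 2 Mbp — mirror a mid-sized RIL panel with GBS-density markers.

Rearrangements are modelled by their observable meiotic consequences, not
cytologically. A translocation heterozygote recombines only inside the
declared pairing regions; a gamete's copy number of the translocated
segment is read from its ancestry at the insertion point on the recipient
chromosome and at the segment's home on the donor, and gametes with zero
copies (deficiency) or two (duplication) survive with configured
probabilities, else the meiosis is redrawn. Small, equal survival values
couple the two chromosomes into the pseudo-linkage pattern. With
*symmetric* survival the surviving gametes are an even mix of the two
parental combinations, so allele frequencies stay 1:1; directional
segregation distortion requires asymmetry, and the defaults therefore
expose `survival_def` and `survival_dup` separately (a hexaploid tolerates
a small duplication far better than a deficiency, so `survival_dup` >
`survival_def` is the natural asymmetric setting, and it distorts allele
frequencies toward the carrier parent on the recipient chromosome).
Inversion heterozygotes simply lose crossovers drawn inside the inverted
interval, which suppresses observable recombination there. An
independent per-region viability mechanism (`distortion`) covers
distortion unrelated to rearrangements.

Phenotypes are additive: value = mean + Σ effect·score + environment +
residual, score ∈ {−1, 0, +1} for B/H/A. When a QTL declares a variance
share h², the residual SD is derived from the *realised* genetic variance
of the simulated population, so the planted share is exact in expectation
for that population rather than for a hypothetical one.

What the simulator does **not** emulate: crossover interference, real
recombination landscapes (hot/cold spots, telomeric hotspots), linked or
epistatic QTL architectures, genotype-by-environment interaction beyond an
additive environment shift, allele-specific missingness, and the
read-level error process behind GBS calls (missingness, heterozygous
miscalls, and allele flips are planted independently per cell). Passing
tests therefore demonstrate correctness of the algorithms under the stated
statistical model, not robustness to every pathology of real data — most
importantly, MCAR missingness is kinder to run-based imputation than the
depth-correlated missingness of real GBS.

## Numerical and degenerate-input conventions

* Megabase units are ceilings of bp/10⁶; all interval arithmetic is
  integer in those units.
* Permutation thresholds use the order-statistic (type-1) quantile of the
  maxima; ties at the profile maximum break to the lowest coordinate;
  deterministic pass order everywhere (markers by position, lines by input
  order).
* Seeds are mandatory for the simulator and threaded through every
  stochastic routine; RNG state is saved and restored so library calls do
  not perturb a caller's stream.
* `r` values above 0.5 are capped (raw values retained); window pairs with
  no informative marker pair are missing, never zero.
* Degenerate scans (empty class, too few lines) yield missing statistics
  and are logged; a pipeline trait that fails entirely is reported in the
  run log without aborting other traits.
* The curation fixed-point loops are capped at 10 passes and report
  non-convergence instead of failing.

## Validation problem sizes

The test suite validates the closed-form pieces against hand-computed and
printed anchors, and the pipeline stages against simulator truth at the
following scales, chosen to be large enough for stable statistics and
small enough for a quick default run: rearrangement detection on 2 × 200
Mbp genomes with 200 lines (20 replicates per scenario); permutation
calibration on 1,000 markers × 200 lines × 200 null traits × 1,000
permutations; QTL recovery on 100 replicates of a 20%-variance QTL in 200
lines; curation fidelity at 30% missingness and 1% miscalls. The
acceptance script reruns the same computations from scratch under a
command-line seed.
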