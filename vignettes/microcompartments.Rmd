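---
title: "Detecting and quantifying Hi-C microcompartment domains with mcdtools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and quantifying Hi-C microcompartment domains with mcdtools}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Microcompartment domains (MCDs) are small stretches of active chromatin —
a few tens of kilobases, typically 25–125 kb — that interact focally with
one another at essentially every genomic distance in cis and between
chromosomes, so that a Hi-C map carries a fine grid of enriched
pixels between all pairs of domains. They are distinct from the two
structures classical Hi-C analysis targets: conventional A/B compartments
(megabase-scale checkerboard) and cohesin-extruded loops/TADs (focal dots
and triangles confined to short range). `mcdtools` implements the full
analysis chain around these domains: matrix balancing, distance-decay
normalization, enrichment-based MCD detection, pairwise-grid
quantification, compartment eigenvector/saddle/insulation analysis,
genome-wide sparse spectral clustering, extrusion-domain derivation from
loop lists, regulatory-element annotation with mitotic bookmarking, and
gene-reactivation timing statistics — plus a synthetic contact-map
generator that plants all of these structures with known ground truth, so
every stage is testable without any external dataset.

## The data model

A contact matrix is a bin table (fixed resolution, 0-based half-open
coordinates) plus an upper-triangle sparse pixel table of non-negative
counts. All per-region computations are organised by a *genome view* — an
ordered non-overlapping partition, typically chromosome arms. Balancing
weights (`NA` = masked bin) live in the bin table.

### Balancing (`balance_ic`)

Iterative correction finds per-bin weights making row sums of the
weighted matrix uniform. The first `ignore_diags = 2` diagonals are
excluded from the marginals (short-range ligation artefacts). Bins whose
log10 marginal deviates from the median by more than
`madmax_threshold = 5` median absolute deviations are masked before
iterating; the filter is two-sided, so both coverage deserts and
pathological high-coverage bins are removed. Convergence is declared when
the maximum relative deviation of the marginals drops below `tol = 1e-6`
(at most 1000 iterations, with an informative error reporting the
residual otherwise); weights are scaled so the mean unmasked balanced
marginal is 1.

### Expected and observed/expected (`compute_expected`, `observed_over_expected`)

The cis expected is the per-region mean balanced value at each separation
— zero pixels included, over pairs of unmasked bins — with a log-space
smoothed companion (an `n`-weighted running mean over the constant-ratio
window `[d/1.05, d*1.05]`; a constant-relative-width window preserves a
pure power law up to a constant factor). Trans expected is a scalar mean
per region pair. Flattening divides each balanced pixel by its expected;
pixels on masked bins, below `ignore_diags`, between two regions of one
chromosome, or with undefined expected are dropped and counted in a
report. By construction the per-diagonal mean of O/E over valid pairs is
exactly 1, which the test suite asserts to 1e-9.

### Contact scaling (`contact_scaling`)

P(s) pools the per-region expected sums; the log-log slope uses
second-order central differences on the non-uniform grid, which is exact
for a pure power law (asserted to 1e-3 in the tests). On noisy maps the
per-separation curve is pooled into geometric distance bins (ratio 1.12)
before differentiation — adjacent integer separations are so closely
spaced in log-s at long range that an unbinned derivative is pure noise.
A prominent local maximum of the slope is reported as the extruded-loop
"shoulder" when present.

## The synthetic generator

`synthetic_genome_spec()` + `simulate_contact_map()` draw a Poisson (or
negative binomial, via `dispersion`) sample of the intensity field

  cis:   `ps_scale * s^-ps_exponent * C(i,j) * L(i,j) * M(i,j) * b_i b_j`
  trans: `trans_base * C(i,j) * M(i,j) * b_i b_j`

globally scaled to `depth` expected counts, where

* `C = contrast^(p_i p_j)` is the compartment factor over the per-bin
  profile `p` in [-1, 1]. With a hard ±1 profile this is exactly the
  "contrast if same label, 1/contrast if opposite" checkerboard; the
  continuous form additionally behaves sensibly at block edges. The
  default profile is an alternating ±1 block wave (blocks 0.8–1.7 Mb)
  Gaussian-smoothed with sd `profile_edge_bins = 5` bins: at 10 kb,
  compartment identity in real maps changes gradually over ~100 kb, never
  as a step, and a step profile would manufacture sharp checkerboard
  corners that the enrichment kernels (correctly) fire on — an artefact
  of the caricature, not a property of the data the method was built for.
* `M = affinity_i * affinity_j` for bins lying in two *distinct* planted
  MCDs, 1 otherwise. The planted feature is the off-diagonal pairwise
  grid; a within-domain factor would instead plant a strong
  self-interaction block whose short-range pixels dominate the bin
  marginals (~3.7x coverage) and get the domain masked by any reasonable
  coverage filter.
* `L` multiplies loop pixels by their strength with a 1-bin Gaussian
  halo.
* `b_i` is a lognormal per-bin coverage bias (`bias_sd = 0.2`,
  natural-log scale) standing in for mappability/GC/accessibility bias.
  It is exactly what iterative correction removes; without it the
  simulated marginals are so uniform that a 5-MAD filter masks genuinely
  structured bins.
* An optional P(s) shoulder multiplies the decay by
  `exp(b * sigma * sqrt(2*pi) * pnorm(log(s/s0)/sigma))`, whose log-log
  derivative is a Gaussian bump of height `shoulder_strength` centred
  exactly at `loop_shoulder_bp` — convenient for testing shoulder
  localization.

Defaults are the desk-scale study conditions: 3 chromosomes x 20 Mb at
10 kb (6,000 bins), decay exponent 1.0, contrast 1.8, 30 MCDs of width
uniform in 25–125 kb at affinity 4 (placed with guaranteed 200 kb margins
and gaps), no loops (the sample defining MCDs is cohesin-depleted),
`trans_base = 5e-4` (~12% trans contacts), depth 2e7. Identical spec and
seed give byte-identical pixel tables.

What the generator does **not** emulate: polymer physics (no
excluded-volume or contact-propagation correlations; pixels are
independent Poisson draws), realistic karyotypes or translocations,
fragment-level biases, TAD-scale insulation structure beyond what loops
imply, and distance-dependent compartment weakening. Passing recovery
tests therefore demonstrate correctness of the *algorithms* under the
stated statistical structure, not performance guarantees on any
particular real dataset.

`simulate_annotation_tracks()` adds the 1D side: gene density positively
correlated with the profile, PLS/pELS/dELS elements planted inside MCDs
(`ccre_per_mcd` controls valency) with background CTCF/open sites,
accessibility peaks for a G1 and a mitosis condition such that a
`bookmark_fraction` of MCDs carry peaks in both, and H3K27ac/H3K4me3
coverage at the planted elements. `simulate_ntr_table()` builds gene NTR
time courses whose first crossing of the 10% threshold lands in the
assigned cluster (prometaphase/early/late/none), with an odds-ratio
enrichment of chosen clusters at MCDs.

## MCD detection

Detection runs on the flattened 10 kb map within each view region, up to
`max_dist = 30 Mb`:

1. **Kernel scoring** (`score_pixels`). Three footprint means per pixel:
   a centred square M and two flanking blocks V (above/below) and H
   (left/right), computed with NA-aware integral images; pixels whose M
   footprint is more than half masked are skipped. The default geometry
   is M 7x7 bins (`half_width = 3`, 70 kb) with flanks extending 7 bins
   (offsets 4–10, i.e. out to 105 kb). Two considerations set these
   sizes: the flanks must *clear* the largest target domains (a 125 kb
   domain spans ±6 bins around its centre, so flanks starting 2–3 bins
   out would sit inside the very feature they are meant to contrast), and
   at realistic depth the per-pixel counts beyond a few Mb are of order
   0.5, so footprints must average enough cells for a ratio threshold to
   measure structure rather than shot noise — with 3x3/18-cell footprints
   a few percent of stored pixels pass the ratio test by chance, in
   spatially correlated patches that survive density clustering.
2. **Thresholding** (`select_and_cluster`). A pixel is enriched when
   M ≥ 2·V **and** M ≥ 2·H (inclusive; the conjunctive reading keeps
   horizontal/vertical stripes out; `both = FALSE` switches to the
   disjunctive reading).
3. **Density clustering.** Enriched pixels are clustered in 2D pixel
   coordinates (Chebyshev metric, reachability cut `max_eps = 33 kb`,
   `min_samples = 5`); at a fixed eps cut this OPTICS-style extraction is
   the classical density-connected-components construction. Singletons
   and clusters smaller than `min_samples` are discarded. Clustering
   never joins pixels across view regions.
4. **Anchor calling** (`call_mcd_anchors`). The valency track counts, per
   bin, the clustered enriched pixels incident on it (row and column of
   each upper-triangle pixel once each). Prominent local maxima become
   summits (`find_peaks_1d`, topographic prominence, minimum separation
   2 bins); each footprint is the contiguous run of bins with valency at
   least half the summit's, overlapping footprints are trimmed at the
   valency minimum between summits, and footprints outside 25–125 kb are
   dropped. The default prominence is 15 = 3x`min_samples`: a single
   noise cluster can contribute at most about `min_samples` counts to one
   bin's valency, whereas a genuine grid member draws support from many
   partner domains, so demanding the equivalent of three minimal clusters
   separates the two regimes with a wide margin (recovery on the default
   conditions is flat anywhere in prominence 10–20).

`compare_anchor_sets()` partitions two anchor sets into A-specific /
shared / B-specific by footprint overlap after a symmetric tolerance
extension.

## Pairwise grids, pileups, strengths, stackups

`make_pairwise_grid()` projects all unordered anchor pairs
(summit-to-summit): cis within one view region under separation bounds,
trans across chromosomes. `aggregate_pileup()` averages O/E snippets with
a fixed flank (100 kb default) centred on each pair, NaN-padding beyond
region edges, optionally by group; grouped means recombine exactly to the
global mean weighted by snippet counts. `feature_strength()` is the
centre-over-corner ratio with the three window schemes: 50 kb centre /
60 kb corners for the cis grid (10 kb maps), a single 25 kb centre pixel
/ 50 kb corners for the trans grid (25 kb maps), 30 kb centre / 70 kb
corners for loops. Corner windows are flush with the pileup corners; a
configuration where the corners would touch the centre window is refused
rather than silently computed. Trans pileups expect a native 25 kb map —
the generator simulates any resolution directly, and no 10-to-25 kb
rebinning (a non-integer factor) is attempted. `stackup_track()` bins a
coverage track into 100 windows across centre ±100 kb for each interval,
bp-weighted, with off-chromosome parts missing.

## Compartments, saddles, insulation, spectral clustering

`eigs_cis_phased()` eigendecomposes O/E − 1 per region (masked bins
zeroed; ARPACK on a dense-block matvec, largest algebraic eigenvalues),
unit-normalizes, and flips each vector to correlate positively with a
phasing track (gene density in practice) — the solver's sign is
arbitrary, the phased sign is not. `saddle_strength()` digitizes a track
into 38 quantiles after trimming 2.5% from each end (rank-based, equal
occupancy; categorical tracks pass through untouched), accumulates
class-pair sums and valid-pair counts region by region, and reports
A strength `AA/((AB+BA)/2)` with AA averaged over the 20% most A-like
quantiles (and B analogously). On a noiseless multiplicative checkerboard
of contrast c this equals c² exactly; with `trim_fraction = 0` the
occupancy-weighted saddle mean is 1 to rounding. `insulation_score()` is
the classic diamond: mean O/E over the w x w window crossing each bin
(100 kb default), log2-normalized to the region mean — invariant to
global rescaling, flat on uniform maps, minimized at boundaries.

`spectral_cluster_genome()` is the genome-wide variant: flatten
(per-region cis decay + per-pair trans levels), mask listed bad regions,
iteratively correct the flattened map itself (so bin coverage cannot
masquerade as structure; after correction the flat vector is an exact
eigenvector, which is why E1 is trivial), then eigendecompose through
`igraph::arpack` — the solver only ever receives a matrix-vector closure
over the sparse map, never a dense genome-wide matrix. Eigenvectors are
ordered by |eigenvalue|; E2 onward are unit-normalized, weighted by
sqrt(|eigenvalue|) (eigenvalues of the indefinite O/E operator can be
negative), and k-means clustered (`stats::kmeans`, fixed seed, 10
restarts, default k = 8). The correlation between E2 and the concatenated
per-region EV1 is reported as a diagnostic without a pass/fail gate — no
published threshold exists for it. `cluster_mcd_overlap()` reports, per
cluster, bidirectional coverage against MCD footprints (by nucleotides
and by interval counts) and flags clusters exceeding 60% both ways.

A note on recovery metrics: judging EV1 recovery by *rank* correlation
against a two-valued ±1 profile is bounded near 0.87 even for perfect
recovery (a binary variable's Spearman ceiling against any continuous
one), so the recovery tests plant a continuous sinusoidal profile
(period 1.5 Mb) for that check; block profiles are kept where the
checkerboard closed forms are wanted.

## Loops, domains, annotation, reactivation

`filter_convergent_loops()` keeps loops whose upstream anchor overlaps a
forward CTCF motif and downstream anchor a reverse motif.
`derive_extrusion_domains()` clusters loops by anchor-1 overlap (one
extrusion line), spans each cluster from its most upstream anchor-1 start
to its most downstream anchor-2 end, and merges candidates to a fixpoint
whenever nested or overlapping by more than 70% of the *shorter* interval
(the permissive reading of "either"; `rule = "both"` gives the
conjunctive one). Merging sweeps left-to-right and is idempotent and
input-order independent (property-tested). Because partial overlaps below
the threshold survive, a short loop can legitimately lie inside two
overlapping domains; intra-domain pair classification therefore asks
whether *some single* domain contains both summits.
`classify_pairs_by_extrusion()` also tags anchors as anchored vs
extrusion-free (footprint vs loop-anchor overlap on 10 kb-snapped
coordinates) and flags pairs sitting on the two anchors of one loop.

`assign_ccre_hierarchy()` gives each bin the highest-priority regulatory
class among its overlapping elements, in the order PLS > pELS > dELS >
H3K4me3 > CTCF > open > not_open (the full seven-group ENCODE-style
ordering; the H3K4me3-only class sits between the enhancer classes and
CTCF). `overlap_enrichment()` is the ChromHMM-style fold enrichment,
`pool_and_bookmark()` applies the reciprocal 50%-of-length rule for
replicate-supported pooled peaks and the ≥1 bp rule for mitotic
bookmarking (no fraction is defined for bookmarking), and
`mcd_valency()` counts elements per anchor.

`classify_reactivation()` buckets genes by the first time their NTR
reaches 10% (inclusive; `strict` switches to >): t = 0 prometaphase,
1–2 h early, 3–5 h late, never none. `enrichment_fisher_bh()` runs
one-sided (greater) Fisher tests per cluster against MCD membership with
BH correction across clusters; odds ratios are the sample cross-product
(reported as NA on zero margins rather than continuity-corrected — exact
test semantics), and "none" genes stay in the background by default
(`background = "classified"` drops them).

## Pipeline and problem sizes

`run_pipeline()` executes simulate → balance → expected → detect →
grid/pileup/strength → compartments → (optional) spectral → annotate →
reactivation from a single YAML-serializable config with explicit seeds
per stochastic stage, writing artifacts and a JSON summary; reruns with
the same config reproduce the summary. A thin CLI (`exec/mcdtools`)
wraps simulate / mcd-call / run-all.

Problem sizes used by the test-suite and the acceptance script, chosen as
the smallest scales at which each question is statistically meaningful:
the full study conditions (3 x 20 Mb at 10 kb, depth 2e7) for detection
recall/precision, null calibration, grid enrichment, spectral 3-state
recovery and EV1 recovery; 2 x 10 Mb at 20 kb, depth 8e6, for the
contrast series of saddle strengths; toys of tens of bins wherever a
closed form or brute-force oracle is exact.

## Known limitations

* Detection is tuned for the 25–125 kb domain scale at 10 kb resolution;
  the kernel geometry is expressed in bins, so other resolutions need
  explicit kernel parameters.
* The cis expected is per-region only; pixels between two arms of one
  chromosome carry no expected model and are excluded from O/E.
* The generator's independence assumptions understate the spatial
  correlation of real Hi-C noise; recovery margins on real data will be
  narrower than on synthetic maps.
* Insulation boundary calling (thresholding the score into discrete
  boundaries) is not implemented; the score itself is.
* `find_peaks_1d` handles plateaus by reporting the plateau midpoint,
  which differs from conventions that report plateau edges.
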