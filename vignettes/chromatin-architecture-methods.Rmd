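---
title: "Methods: multiscale chromatin architecture analysis with hic3d"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multiscale chromatin architecture analysis with hic3d}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hic3d)
```

`hic3d` analyzes two-condition binned chromatin contact maps across the three
scales at which the 3D genome is usually described — compartments, topological
domains, and focal promoter–enhancer contacts — together with an entropy
statistic for overall contact order, enhancer classification from H3K27ac
signal, and downstream joins to expression and cross-species ortholog tables.
This vignette explains each model, its assumptions, the tunable parameters,
and the design choices made where the underlying literature leaves the
procedure open. Everything is exercised end-to-end on synthetic maps with
planted truth; the last section describes what those simulations do and do
not establish.

## Contact matrices and normalization

All computations consume a `contact_matrix`: per-chromosome symmetric
matrices of non-negative intrachromosomal contact values on a fixed binning
(`binned_genome`). Bins are half-open base-pair intervals; the last bin of a
chromosome may be short. Rows with zero coverage are masked before
balancing and propagate as no-call through PC1, DI, and IS.

**Balancing.** `kr_balance()` implements the Knight–Ruiz inner–outer
conjugate-gradient scheme for symmetric matrix scaling, which equalizes all
non-masked row sums. KR can stall on extreme matrices, so a symmetric
iterative-proportional-fitting (Sinkhorn) fallback runs when the iteration
budget is exhausted, with a warning. The balanced matrix is rescaled to
preserve the chromosome's total contact count, so balanced values remain on
a count-like scale. Balancing is idempotent up to the convergence tolerance
(default `1e-6`).

**Quantile normalization.** `quantile_normalize()` maps each replicate's
per-chromosome value distribution onto the average-quantile reference,
computed on the upper triangle and mirrored. The mapping assigns tie runs to
consecutive reference values rather than averaging them: averaging ties (as
some microarray-era implementations do) would leave the cross-sample sorted
vectors unequal on integer count data, which defeats the purpose of the
transform. It is off by default in the pipeline driver because its proper
scope (per-sample vs. cross-sample, before vs. after balancing) is a
study-level choice.

**Expected decay and O/E.** `expected_by_distance()` averages contacts
within each diagonal stratum; `observed_over_expected()` divides by the
stratum mean (zero where the stratum is empty). After O/E, stratum means are
1 by construction, which the tests assert.

**Replicate reproducibility.** `stratum_adjusted_correlation()` follows the
stratum-adjusted correlation idea: smooth both maps with a square mean
filter (half-width 1 bin by default), correlate within each diagonal
stratum, and combine with weights `n_d * sd_x(d) * sd_y(d)`. Strata beyond
25% of the chromosome (default) are ignored — distal strata are sparse and
noise-dominated. The statistic is 1 for identical maps, symmetric, and
invariant to a global positive rescaling of either map.

## Von Neumann entropy of contact order

For each chromosome, `von_neumann_entropy()` computes the Pearson
correlation matrix `C` of the columns of `log2(A + pseudocount)` over
non-masked bins, clips negative eigenvalues of `C` at zero, normalizes the
spectrum to sum to one, and returns `-sum(lambda * ln lambda)` in nats. A
map whose columns are highly correlated (strong, consistent block
structure) concentrates spectral mass on few eigenvalues and scores low; a
disordered map approaches `ln(n)`. The pseudocount (default 1) handles the
zeros that are certain in count matrices; clipping handles the tiny
negative eigenvalues numerical correlation matrices can have, and the
normalization step makes the spectrum sum to 1 regardless of clipping. The
statistic is reported per chromosome and per sample; comparing groups is a
report-level rank-sum comparison, because the statistic itself carries no
inferential model.

## A/B compartments

`compute_pc1()` takes the leading eigenvector of the correlation matrix of
the O/E map — the classical compartment convention. The sign of an
eigenvector is arbitrary, so `orient_and_label()` orients each chromosome
against covariates: if Spearman's rho between PC1 and GC content is
negative, the vector is negated; when `|rho_GC| < 0.1` the gene-count
covariate decides instead (GC is the primary criterion because it is the
more universal correlate of the active compartment; gene count is the
tiebreak for chromosomes where GC is uninformative). Bins with oriented
PC1 > 0 are A, < 0 are B, exact zeros and masked bins are no-call.
Orientation is idempotent.

The A-B index of bin *i* is `(meanA - meanB) / (meanA + meanB)` over the
bin's mean O/E contact with all A- and B-labeled bins (self excluded) — a
bounded, label-consistent summary of compartment preference. It is
undefined (no-call) on chromosomes lacking either label.

`detect_switches()` compares per-bin labels between conditions, merges
contiguous switched runs into events with direction and span, reports the
switched fraction over jointly labeled bins and per-condition %A/%B, and
annotates genes to events by TSS bin. Gene assignment by TSS (rather than
overlap span) keeps the mapping single-valued. Swapping the conditions maps
every A-to-B event to B-to-A with identical spans.

## Topological domains

`directionality_index()` contrasts, for each bin, the summed contacts to
the `half_width` upstream bins (A) versus downstream (B):
`DI = sign(B - A) * ((A - E)^2/E + (B - E)^2/E)` with `E = (A + B)/2`, zero
when `A = B` or `E = 0`. The default half-width of 10 bins matches the
window the approach is usually run with at domain-calling resolution.

`di_hmm_domains()` standardizes DI per chromosome and decodes a 3-state
Gaussian HMM (upstream-biased / none / downstream-biased). Parameters are
fitted by Baum–Welch from a fixed initialization — emission means
(-1, 0, +1), unit variances, self-transition 0.9 — and the Viterbi path is
decoded; a domain spans from the start of each downstream-biased run to the
end of the next upstream-biased run, with a 3-bin minimum (smaller calls
are decoding noise). If Baum–Welch fails to converge the fixed canonical
parameters are used with a warning. One subtlety is worth knowing: a fitted
chain is directional — its learned initial distribution and transition
matrix need not be time-reversible — so exact equivariance of calls under
genome reversal only holds with `refit = FALSE` (fixed symmetric
parameters), which the test suite uses for the mirror-symmetry check.

Boundary positions are domain edges, with one adjustment: where two
consecutive domains abut (gap of at most 2 bins), the two facing edges
collapse into a single midpoint boundary — otherwise every junction would
be counted twice, once from each flanking domain. Chromosome-terminal edges
are excluded from dynamics comparisons.

`insulation_score()` averages contacts over the `window x window` square
crossing each bin and reports `log2(raw / chromosomal mean)`; bins within
one window of a chromosome end are no-call. `partition_subtads()` splits
each large TAD at local insulation minima with prominence at least
`min_depth` (default 0.5 log2 units in the standalone function; the
pipeline driver uses window 3 and `min_depth = 0.2`, chosen because
sub-domains span only a handful of bins, so a narrow window and permissive
prominence recover short splits that a 10-bin window blurs away). Minima
closer than 3 bins to a TAD edge are ignored and sub-TADs tile their parent
exactly.

`boundary_dynamics()` matches two boundary sets greedily nearest-first
(ties leftmost) within `slack_bins` (default 1: reported boundary stability
in the literature implies tolerance to small shifts, and an exact-match
criterion would be dominated by one-bin decoding jitter); unmatched
boundaries are gained or lost.

## Promoter-anchored interactions and regulatory potential

`call_peis()` tests, for each promoter bin, all candidate partner bins
inside a distance window (defaults 10 kb–1 Mb; the window is fully
configurable because published distance filters for this step are
inconsistent, and both printed variants are reachable by argument) against
a domain-aware expected model:

1. **Candidate scope.** When the promoter lies inside a called domain,
   candidates are restricted to that domain. The enrichment approach this
   follows is domain-hierarchical — a promoter's interactions are scored
   against its own domain context — and restricting the scope keeps the
   null model locally correct. Promoters outside any domain use the
   background decay over the full window.
2. **Expected model.** A power law `log(mean) ~ log(1 + d)` is fitted per
   domain (stratum means weighted by pair counts) and separately for
   background pairs. With a nested domain set, each pair is attributed to
   the innermost domain containing both ends, so sub-domain enrichment is
   absorbed by the sub-domain's own fit instead of inflating its parent's
   residuals. The `+1` offset keeps the model finite at adjacent bins.
3. **Local correction.** The fitted expected value of each candidate is
   rescaled by the median observed/expected ratio of its flanking
   candidates (±3 bins, center excluded), clamped at 1 so the correction
   can only be conservative. Focal loops are single pairs, so their
   neighbors' median is untouched by the loop itself; locally constant
   model misfit — an imperfect domain edge, a missed sub-domain split — is
   absorbed.
4. **Test and retention.** A one-sided Poisson upper-tail p-value per pair,
   Benjamini–Hochberg across all tested pairs, retention at `q < 0.05`
   (default) with positive normalized intensity `In = observed − expected`
   and a minimum fold enrichment `observed ≥ 2 × expected`. The fold floor
   exists because at deep coverage a diffuse ~1.3–1.5× block-level
   enrichment that the domain model places slightly wrong is highly
   significant by p-value yet is not a focal interaction; corner-peak loop
   callers impose the same kind of floor.

The test runs on raw pooled counts: the Poisson null is only specified for
counts, and balancing rescales entries in a way that invalidates it. `In`
is therefore also on the raw count scale.

Per-gene regulatory potential is `RPS = sum(log10(max(In, 1)))` over the
gene's retained records — zero for genes without interactions. The clamp at
1 is deliberate: the unclamped sum is negative or undefined for weak
records (`In ≤ 1`), which would contradict the convention that a gene
without interactions scores zero; clamping makes RPS non-negative and
monotone in added records. `differential_rps()` computes
`log2((rps2 + 1)/(rps1 + 1))` and `delta = rps2 − rps1` and calls a gene up
when both exceed their thresholds (defaults `fc_threshold = 3`,
`delta_threshold = 2`; the alternative published pairing of (2, 3) is
reachable by argument — the two variants appear in different places in the
literature this implements, and the package treats the choice as
configuration, not substance).

## Enhancer classification

`chip_signal()` scores 1-kb bins as `log2((IP + c)/(input + c))` on
FPKM-like densities (pseudocount `c = 0.5` by default). A simple
threshold caller turns synthetic signal tracks into peaks; real studies
supply externally called peak BEDs. `merge_rank_elements()` merges peaks
within 12.5 kb (transitively) into elements whose aggregate signal is the
length-weighted sum of constituent peak signals, then ranks by signal.
`rose_classify()` scales rank and signal to the unit square and cuts where
a slope-1 line is tangent to the signal-vs-rank curve — computed as the
minimum of (scaled signal − scaled rank), which is the tangent point of the
convex curve; elements strictly above the cutoff signal are SE, the rest
RE. All-equal signals yield no SE; the classification is invariant to input
order and to appending zero-signal elements. `classify_poised()` labels
distal interaction anchors lacking any H3K27ac element overlap as PE.

## Integration

`filter_degs()` applies the standard thresholds — FDR strictly below 0.05,
|log2FC| of at least 1.5 (inclusive) — to externally supplied statistics;
the package deliberately contains no count-model fitting (a plain two-group
helper, `naive_deg_stats()`, exists for synthetic data and is documented as
non-inferential). `fold_change_summary()` and `ortholog_partition()` round
half-up at 2 decimals, matching printed-style precision; `round_half_up()`
exists because base R rounds half-even. The ortholog partition enforces
exact conservation (A-only + B-only + shared = regulated-in-either) and
reports percentages over the regulated set; among shared genes with known
directions, the discordant subset is listed.

## The synthetic study and what it shows

`make_truth()` plants, per chromosome (default 4 chromosomes × 250 bins at
a 20-kb analog): large TADs of 20–30 bins containing 2–3 sub-TADs of at
least 6 bins; compartment labels assigned to geometric runs of consecutive
TADs (compartments are unions of domains — the nesting real maps show, and
the arrangement under which a domain-stratified expected model is well
specified); promoter–distal loops within TADs (distance 4–12 bins), a
subset of which are designated super-enhancer-driven with doubled contact
strength and a broad, order-of-magnitude-taller H3K27ac element at the
distal anchor; GC and gene-density covariates elevated in A bins; and gene
baselines. Condition 2 flips compartment labels over TAD-aligned runs
totalling exactly `round(switch_fraction × bins)` bins (default 2.42%, the
scale of switching the analyses of this kind report), removes
`n_boundary_changes = 2` interior TAD boundaries (near-total domain
stability), and rewires 30% of loops into condition-specific ones
(extensive focal rewiring). All randomness derives from one seed, and the
truth serializes to JSON round-trip identically.

`simulate_contact_map()` draws Poisson counts around
`lambda(i,j) ∝ (1+|i−j|)^(−1) × 1.6^[same compartment] × 2^[same TAD] ×
1.4^[same sub-TAD] × 5^[active loop]` (×2 again for SE loops), scaled to 2
million expected contacts per chromosome — minutes of compute on one CPU
while leaving every planted effect comfortably above noise.
`simulate_chip_tracks()` adds element heights to a flat noisy input;
`simulate_expression()` draws negative-binomial replicates around log-means
coupled to compartment state and planted regulatory potential.

The default problem sizes used by the test suite and the acceptance script
are: 10 seeds (tests) or 5 seeds (script) × 2 conditions for
planted-structure recovery; 50 decay-only seeds for null calibration; 200
replicate draws for the simulator moment check. These sizes keep the whole
suite in the minutes range on a single CPU while leaving the binomial and
Monte-Carlo tolerances meaningful.

**What passing these simulations does not show.** The generator is
deliberately idealized: Poisson counts (no overdispersion beyond an
optional NB stress parameter in the expression model), exact power-law
decay, boundaries aligned to bins, loops of uniform strength, covariates
cleanly coupled to the A state, and no masked or repetitive regions beyond
zero-coverage rows. Real maps have copy-number structure, distance-decay
curvature, fuzzy boundaries, and orders of magnitude more bins per
chromosome arm. Recovery metrics here validate the implementation's
correctness under its own model assumptions — they are not performance
claims for real tissue Hi-C, and the headline counts real studies print
(thousands of TADs, tens of thousands of interactions) depend on
sequencing depths this package's test harness intentionally does not
emulate.

## Numerical choices and degenerate inputs

- KR tolerance `1e-6` on the squared residual of row sums; IPF fallback
  with the same tolerance; chromosomes with fewer than 2 unmasked bins are
  left untouched.
- PC1 requires 10 usable bins per chromosome (configurable); constant O/E
  columns are dropped before the correlation.
- Entropy requires 3 non-masked bins and errors on all-constant columns
  naming the bin.
- DI is exactly 0 at `A = B` or `E = 0`; HMM emission variances are floored
  at `1e-3` to avoid state collapse; ties in Viterbi resolve to the
  lower-indexed state.
- Insulation at chromosome ends is no-call rather than edge-truncated: a
  truncated window changes the statistic's scale mid-track.
- Boundary matching ties resolve leftmost; matching is greedy
  nearest-first.
- BH correction runs across all tested promoter–candidate pairs jointly,
  not per promoter.
- Percent-style outputs round half-up at 2 decimals.

## Known limitations

- The PEI null is Poisson with a plug-in expected model; it does not
  propagate uncertainty in the decay fit (the local-median correction and
  fold floor are pragmatic guards, and the null-calibration test is
  accordingly conservative rather than exact).
- The HMM decoder assumes one DI regime per chromosome; chromosomes mixing
  very different contact depths (e.g., unbalanced input) should be balanced
  first.
- `quantile_normalize()` assigns tie runs in a fixed order, so it is not
  strictly rank-preserving within ties.
- Interchromosomal contacts are out of scope throughout.
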