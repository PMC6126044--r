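---
title: "Models and methods: solubilization kinetics and cross-metagenome bin tracking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermodigest)
```

This vignette is the package's own account of the science it implements:
the rate law and its assumptions, the bin-matching algorithm and the
decisions behind each threshold, what the synthetic-data generators do and
do not emulate, and the numerical choices a maintainer would want spelled
out. Nothing here states an empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## 1. The recalcitrant-fraction first-order rate law

Lignocellulose solubilization in a well-mixed digester is modelled as first
order in the *accessible* carbohydrate only:

$$ r = k\,(C - C_0 f_r) $$

where $C$ (g monomer-equivalent/L) is unutilized carbohydrate, $C_0$ is the
carbohydrate concentration entering with the feed, $k$ (1/day) is the rate
constant and $f_r$ the recalcitrant fraction — the share of entering
carbohydrate still unconverted at infinite residence time. The model's
assumptions: the recalcitrant pool is inert on the timescale of operation
(no slow second pool), accessibility is a property of the substrate rather
than of the community, and the reactor is at steady state when sampled.

Each steady state at residence time RT supplies one $(C, r)$ point through
the washout identities $C = C_0(1-\mathrm{FCS})$ and
$r = C_0\,\mathrm{FCS}/\mathrm{RT}$, and the parameters come from
**unweighted ordinary least squares** of $r$ on $C$: $k$ is the slope and
$f_r = -b/(k C_0)$ from the intercept $b$. Unweighted OLS is used because
per-point variances are rarely available for this assay and the points are
few; the standard error of $f_r$ is propagated from the coefficient
covariance by the first-order delta method. A fitted slope $\le 0$ is
rejected as non-physical rather than reported.

Everything is kept on a **monomer-equivalent basis** (glucose, xylose,
arabinose equivalents per g as-is solids); no anhydro-correction factors
(1.111/1.136) are applied anywhere, so feed composition, $C_0$, FCS and the
fitted parameters are mutually consistent.

Solving $k(C - C_0 f_r) = (C_0 - C)/\mathrm{RT}$ gives the steady state
under continuous washout,
$$ \mathrm{FCS}(\mathrm{RT}) = (1-f_r)\,\frac{k\,\mathrm{RT}}{1+k\,\mathrm{RT}}, $$
strictly increasing in RT and in $k$ and bounded by $1-f_r$
(`predict_steady_state_fcs()`).

One documentation note for users comparing rate constants across studies:
descriptive first-order constants for lignocellulose vary with whether the
recalcitrant pool is subtracted from the driving concentration. A constant
fitted to $r = kC$ on the same data is systematically smaller than the $k$
of this model (values near 0.5/day versus near 0.7/day on typical
switchgrass steady states); the two definitions should not be compared
directly. This package implements only the recalcitrant-corrected
definition.

## 2. The semi-continuous reactor simulator

`simulate_reactor()` tracks two pools per litre: accessible $A$ with
$\mathrm{d}A/\mathrm{d}t = -kA$ between feed events, and inert recalcitrant
$R$. The feeding protocol mirrors bench practice: `feeds_per_rt = 10`
events per residence time, each withdrawing `replaced_fraction = 0.10` of
the volume and adding the same volume of feed ($C_0(1-f_r)$ accessible,
$C_0 f_r$ recalcitrant per litre added). The config validator enforces
`feeds_per_rt × replaced_fraction = 1` so the nominal residence time
(volume over volume fed per day) is exactly `rt_days`. Between events the
decay is applied analytically, so feed-event mass conservation holds to
floating-point precision (a property test asserts $\le 10^{-9}$ relative).
Measured-FCS noise is multiplicative Gaussian with coefficient of variation
`noise_cv`, truncated to $[0,1]$; real assays report standard deviations
but no error model, and a CV-parameterised model is the simplest one
consistent with magnitude-proportional scatter.

**Discrete feeding has observable consequences**, and the simulator exposes
them rather than hiding them:

* `fcs` / `fcs_measured` — the instantaneous value when slurry is
  withdrawn (just before a feed event). This is what a bench assay of the
  withdrawn sample measures, and `generate_steady_state_dataset()` reports
  it. Fitting the rate law to these samples recovers $k$ to about 1% but
  *underestimates $f_r$ by about 0.03*: pre-feed concentrations sit below
  the cycle average by a nearly RT-independent offset ($\approx$ 0.45 g/L
  at the default parameters), which shifts the intercept but not the
  slope. A dedicated test pins this bias against a closed-form
  discrete-steady-state oracle, and the noise-robustness test (1%
  CV, 8 RT levels, 200 seeded replicates) therefore measures the median
  $f_r$ error against the protocol's noiseless estimand, not against the
  continuous-model truth.
* `fcs_interval_mean` — the time average over the inter-feed interval,
  summarised by `steady_state_summary()$fcs_cycle_mean`. This is the
  quantity comparable with the continuous closed form (they agree within
  0.01 at RT = 20 d after a 3-RT burn-in) and the one the acceptance
  script reports for the steady-state prediction.

The burn-in before "steady state" is 3 residence times, matching how the
bench protocol declares steady state. Simulations in the tests use 4–10
residence times (40–100 feed events); these sizes make every kinetics test
run in seconds while leaving the transient far behind.

## 3. Cross-sample bin matching

The matching rule: for bins $X$, $Y$ from different metagenome samples,
compute $p_{X \to Y}$ = fraction of $X$'s proteins whose best-hit identity
in $Y$ strictly exceeds 90%, and symmetrically $p_{Y \to X}$; call the
bins the same organism when $\max(p_{X \to Y}, p_{Y \to X}) \ge 0.70$.
Three decisions here were genuinely open:

* **Denominator.** Each directional proportion divides by the query bin's
  full protein count (proteins with no hit at all stay in the
  denominator), not by the number of aligned pairs.
* **Direction.** Either direction suffices. A bin recovered at low
  coverage is a subset of the same organism's high-coverage bin; the
  fragment-to-full direction is then near 1.0 even when the full-to-fragment
  direction is small, and requiring both directions would break exactly
  the coverage-tier matching the method exists for.
* **Same-sample pairs are never compared** — the algorithm identifies
  organisms *across* samples; within-sample deduplication is a different
  problem (and would need different thresholds).

**Identity engine.** Hits are scored by exact Smith–Waterman local
alignment (BLOSUM62, gap open 10, gap extension 1) via Biostrings.
Identity is *identical aligned residues divided by the shorter sequence
length*. Dividing by the local alignment length instead would let a
5-residue perfect segment between unrelated proteins count as 100%
identity; normalising by the shorter sequence makes 90% identity mean
"90% of the smaller protein is conserved", which is the quantity the
same-organism rule needs. Candidate pairs come from an exact 8-mer
prefilter: any pair whose best alignment exceeds 90% identity over
$L \ge 89$ residues must, by pigeonhole, share an exact run of at least
$\lceil (L-m)/(m+1) \rceil \ge 8$ residues (with $m < 0.1L$ non-identical
columns), so the filter is lossless above the threshold for the protein
lengths used here (≥ 100 aa), while unrelated random proteins collide with
probability $\sim L^2/20^8$. Identical sequences are recognised by string
equality and short-circuit to 100%.

**QC and network pruning.** Edges are dropped when either endpoint has
contamination > 20% or completeness < 40% (boundary values survive; the
thresholds are read as strict "greater/less than"). Strain heterogeneity
is carried through but not filtered on. Bins connected by fewer than three
surviving edges are removed *iteratively to a fixed point* — a single pass
would leave bins whose entire support was itself pruned — and the
remaining connected components are kept only if they span strictly more
than three samples. A brute-force oracle (explicit degree-pruning loop
plus boolean-matrix transitive closure) checks the igraph implementation
on 100 seeded random graphs in the suite.

**Taxonomy and abundance.** A track takes the species label of the
reference with the highest *effective* ANI — the minimum of the BLAST and
MUMmer estimates, so both methods must support the call — when that value
strictly exceeds 95%; otherwise the coarser rank label is kept. An exact
tie between references is flagged `ambiguous` rather than broken
arbitrarily. Relative abundance is the track's coverage mass (depth ×
length) as a share of the sample total, averaged over the samples where
the track is present.

## 4. Marker and CAZyme profiling

A track encodes a marker when **strictly more than half** of its member
bins carry it ("majority" read strictly: a 2-of-4 tie counts as absent,
which errs toward conservatism in incomplete bins). Pathway completeness
is the unweighted fraction of a marker set present by this consensus —
`complete` at 1, `partial_high` strictly above 0.70, otherwise
`incomplete` (exactly 70% is incomplete; copy-number weighting is not
used). CAZyme inventories count CAZy-category domains normalized by the
number of member bins, so organisms recovered in more samples do not look
artificially enzyme-rich; a protein is "modular" when it carries at least
two CAZy-category domains; dockerin and cohesin modules are recognised by
configurable marker ids (defaults PF00404 and PF00963, their standard Pfam
accessions). Domain architectures are printed in ascending start order
with longer-domain-first on start ties (a deterministic tie-break chosen
so nested or piggyback domains render stably).

The shipped `default_marker_sets()` contains only the explicitly
documented accessions (xylose catabolism: pfam01261, pfam00370, pfam02782;
single sentinels pfam01268 and pfam04216 for syntrophic acetate and
butyrate oxidation); real analyses should supply complete curated sets.
Annotation itself (HMM search, CAZy classification) is an input, not
reimplemented.

## 5. What the synthetic community emulates — and what it does not

`generate_community()` draws each genome's proteins independently and
uniformly at random (lengths uniform on 100–400 aa by default), so
inter-genome best-hit identity sits far below the 90% threshold — the
"well-separated genomes" regime. `sample_bins()` emulates multi-sample
binning: per sample each genome yields one bin retaining a uniform random
protein subset (completeness, drawn from 50–95% by default, with
half-up rounding so realized counts are exact), padded with other genomes'
proteins to the target contamination (≤ 10% by default, defined as
contaminant-protein share of the bin). Emitted QC equals realized truth
exactly, because the QC filter's semantics — not CheckM's marker-based
estimator — are what need testing. Markers are assigned to
`marker_copies = 6` carrier proteins per genome, emulating the multi-copy
gene families and operon redundancy that make pathway markers robust to
subsampling; with single-copy carriers a 60%-complete bin would miss its
markers 40% of the time and no majority rule could recover the profile.
Coverage masses are drawn per genome and sample and reported both as the
coverage table and as abundance truth, making the abundance computation a
round trip.

Passing these benchmarks therefore shows that the *algorithmic* layers —
matching rule, thresholds, pruning, consensus, accounting — are correct
with respect to their definitions. It does **not** show robustness to what
real metagenomes add: paralogs and horizontally transferred genes (which
blur the inter-genome separation), strain mixtures within one bin,
chimeric contigs, annotation error, or CheckM's estimation error on
completeness and contamination. The optional related-strain generator
(point mutation at 2%/residue, best-hit identities clustering near 98%)
probes the identity threshold's boundary but is not a population-genetic
model.

The default benchmark (10 genomes × 1000 proteins × 4 samples, ~31k
proteins in 40 bins) matches in under half a minute on one core thanks to
the prefilter; the test suite uses smaller communities (4–6 genomes,
60–80 proteins) everywhere correctness, not scale, is at issue.

## 6. Balance closure

Electron balance: COD recovery = $100 (4.0\,m_{\mathrm{CH_4}} +
\mathrm{COD}_{\mathrm{slurry}})/\mathrm{COD}_{\mathrm{feed}}$, with the
fixed oxidation stoichiometry 4.00 g COD per g CH₄. Mass balance: methane,
gaseous CO₂, dissolved CO₂ and freeze-dried slurry solids over dry feed.
Dissolved CO₂ uses a deliberately simple, fully documented carbonate
estimate: Henry's law at the headspace CO₂ partial pressure (default
constant 0.0164 mol L⁻¹ atm⁻¹ at 55 °C) plus bicarbonate from the first
dissociation at the measured pH (default pKa₁ 6.30; carbonate ion is
negligible below pH ≈ 9 and ignored). Both the Henry constant and pKa are
arguments, since thermophilic ionic strengths shift them.
`reactor_balance_streams()` converts a simulation into loss-free streams
under glucose-equivalent stoichiometry (C₆H₁₂O₆ → 3 CH₄ + 3 CO₂) so both
recoveries close at 100% exactly — the conservation oracle used in the
tests.

## 7. Degenerate inputs and error policy

Negative solubilization (residual exceeding feed) raises a
measurement-inconsistency error carrying both masses — never silently
clipped, because clipping hides assay problems. Fits require ≥ 3 points
with non-degenerate abscissae; all-equal $C$ is a fit error, not an
`NaN`. Zero feed masses, zero total coverage, empty marker sets,
same-sample bin comparisons and missing QC records are all typed errors
naming the offending quantity. Empty annotation sets yield all-zero
CAZyme profiles (a valid observation), and an empty track table is a valid
pipeline result. All thresholds are validated once, in
`run_thresholds()`, with the canonical defaults
(0.70, 90, 40, 20, 3, 3, 95, 0.70).
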