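---
title: "Open-search delta-mass analysis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Open-search delta-mass analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(openptm)
library(dplyr)
```

# The problem

A closed database search identifies only the modifications it was told to
look for. An open search widens the precursor tolerance to hundreds of
daltons, so every modification — anticipated or not — appears as a delta
mass (ΔM), the difference between the experimental precursor mass and the
theoretical mass of the unmodified peptide. The price is a downstream
analysis problem: a ΔM histogram with hundreds of overlapping peaks,
contaminated by decoys and incorrect matches, in which biological
modifications must be separated from preparation artefacts, localized to
protein sites, quantified, and related to the experimental design.

`openptm` implements that downstream pipeline for a label-free,
spectral-counting design with grouped replicates (the default emulates a
liver phosphoproteome over control vs two durations of high-fat diet,
three animals each). This vignette records the models, the tunable
parameters, and the design decisions taken where more than one reasonable
choice existed.

# Delta-mass recalibration and peak modelling

Instrument drift leaves each LC-MS run with a small systematic ΔM offset.
`recalibrate()` estimates it per sample as the median ΔM of the
unmodified population (|ΔM| < 0.05 Da, at least 50 PSMs) and subtracts
it. This is deliberately a constant per-sample correction: m/z- or
intensity-dependent recalibration models exist, but a constant captures
the dominant term and makes no assumptions the synthetic data could not
test. Samples with too few anchors are left uncorrected with a warning.

`detect_peaks()` smooths the recalibrated ΔM values with a Gaussian
kernel (default bandwidth 0.005 Da, matched to ~3 mDa measurement noise
on an Orbitrap-class instrument), takes local maxima of the density as
peak apexes and the flanking local minima as boundaries, and discards
peaks supported by fewer than `min_psm = 5` PSMs. Boundaries are shared
minima, so peaks never overlap, and the reported apex is the mean ΔM of
the member PSMs. The grid (2^20 points by default) keeps the grid
spacing well below the bandwidth across a ~600 Da range.

Isotope satellites (+1.003355·k Da of a parent peak, k ≤ 3) are kept as
separate peaks at this stage; `collapse_isotopes()` maps each satellite
to its more abundant parent afterwards, which keeps peak detection and
annotation independent.

# Three-level FDR

`fdr_filter()` computes target-decoy q-values in three strata: over all
PSMs, within 1-Da ΔM bins (`round(ΔM)`), and within each detected peak.
The estimator is `FDR(s) = #decoys(score ≥ s) / #targets(score ≥ s)`,
monotonized into q-values by a cumulative minimum from the score-sorted
tail; ties rank decoys above targets, which is conservative. A PSM
passes only if all three q-values are at or below the threshold (default
0.01). PSMs falling outside every peak form their own peak-level
stratum — in practice that stratum is dominated by incorrect matches and
decoys, so unassigned PSMs rarely pass, which is exactly the behaviour
the peak-level filter exists to provide.

# Annotation and composite decomposition

`annotate_peaks()` matches apexes against a modification catalog within
0.01 Da (ΔM values are conventionally reported to two decimals).
`decompose_composite()` explains an unannotated ΔM as a multiset of at
most `max_terms` catalog masses plus up to `max_isotopes` C13 spacings,
enumerated exhaustively and ranked by absolute error, then by fewer
components, then by name — so the ranking is deterministic under catalog
reordering. Losses (negative masses) participate like gains. A worked
set of identities from the built-in catalog:

```{r composites}
decompose_composite(80.95)[1, ]    # phosphorylation + deamidation
decompose_composite(95.96)[1, ]    # phosphorylation + oxidation
decompose_composite(-89.03)[1, ]   # Met loss + N-terminal acetylation
decompose_composite(-9.06, max_terms = 3)[1, ]  # ... + phosphorylation
```

One printed identity deserves a note: the −15.04 Da shift decomposes,
with precise masses, as deamidation + ammonia loss + one C13
(0.984016 − 17.026549 + 1.003355 = −15.039178). The alternative reading
"two deamidations + ammonia loss" sums to −15.0585 and falls outside any
sensible tolerance of −15.04; the implementation follows the precise
masses.

# Residue and quintile specificity; artefact calls

For each peak, `residue_profile()` reports the percentage of PSMs
modified on each residue type, minus a per-PSM background: the frequency
of that residue at offsets {−3…−1, +1…+3} from the modified position,
averaged over the offsets that fall inside the peptide (truncated flanks
are dropped, not padded — padding would bias short peptides). The
per-PSM-then-average convention is one of two defensible readings of
"average frequency of the three previous and three subsequent
positions"; it weights every PSM equally regardless of how many flank
positions survive truncation.

`quintile_profile()` assigns the modified position `pos` in a peptide of
length `L` to quintile `floor(5·(pos−1)/L) + 1` (clamped to 5).
`classify_origin()` calls a peak **artefactual** when more than 70% of
its PSMs fall in the first quintile, computed over PSMs whose peptide
does not start at protein position 1. Protein-N-terminal peptides are
excluded because genuine protein N-terminal chemistry (Met loss,
N-terminal acetylation) is first-quintile by construction yet
biological. Calls require at least 10 usable PSMs — and at least 10
internal ones for an artefact call — below which the estimate of a
percentage is too unstable; peaks below the floor are `unknown` (or
`biological` when the peak lives almost entirely on protein-N-terminal
peptides).

# Sites, the pgK filter, and quantitation

`map_to_sites()` integrates modified peptides into qdna elements:
protein `q`, ΔM peak `d`, residue type `a`, protein position
`n = peptide_start + mod_pos − 1`. Partial-digestion peptidoforms
covering the same position merge; the same position with a different ΔM
peak is a different element. Site identity uses the peak id rather than
the raw ΔM float, so floating-point jitter cannot split a site. PSMs
whose claimed residue disagrees with the protein sequence are rejected
and logged; decoy-protein PSMs are excluded.

Bulky charge-switching Lys modifications such as glycerophosphoryl-Lys
block tryptic cleavage at the modified residue, so every genuine PSM of
such a site must be a partial digestion. `partial_digestion_filter()`
implements the minimal reading of that constraint: the modified Lys must
not be the peptide's C-terminal residue. (A stricter variant would also
demand a missed cleavage elsewhere; the C-terminal criterion is the part
the chemistry actually forces.)

`quantify()` builds the layered quantitation table at either level:
`F = (X + 0.5) / T` (counts scaled by total sample PSMs, with a 0.5
pseudocount so zeros survive the log), `R = log2(F / median_s F)` against
the per-element median over all nine samples (a reference more robust to
outliers than a three-sample control mean), and `Z = (R − mean)/sd`
standardized per sample across elements — the reading under which the
standardized protein quantities have exactly zero mean and unit SD in
every sample, which the tests assert to 1e-6. `filter_quantifiable()`
keeps elements whose PSM sum across samples is strictly greater than 15
and (by default) observed in every sample; both halves of that
definition are exposed as arguments because "quantified in all the
samples" admits either reading.

`protein_normalize()` computes `Zq_qdna = Z_site − Z_protein` and
re-standardizes per sample, detecting site-level changes independent of
the parent protein's abundance. Subtraction of standardized values is a
design choice (no formula is forced by the data model); it is documented
here and trivially swappable.

# Correlation network and cohesiveness clustering

`correlation_network()` connects quantified sites whose `Zq_qdna`
profiles correlate with Pearson r > 0.5 across the nine samples;
negative correlations never create edges. `cluster_cohesive()` grows
clusters greedily from every node (processed by descending weighted
degree, ties by label), at each step taking the single addition or
removal that most increases the cohesiveness
`f(V) = W_in / (W_in + W_bound + penalty·|V|)` with `penalty = 2`.
Candidates are merged in a single pass when the overlap score
`|A∩B|²/(|A|·|B|)` reaches 0.8, and reported clusters must have at least
5 members, weighted density at least 0.3 (the numeric interpretation
chosen for an "automatic" density setting), and a one-sided Mann–Whitney
p ≤ 0.05 comparing each member's in-cluster weight against its boundary
weight — the per-vertex construction, which remains powered even for
well-separated clusters with very few boundary edges. An isolated
5-clique of unit weights scores exactly f = 10/(10 + 0 + 2·5) = 0.5.

`ks_two_sample()` wraps the two-sample Kolmogorov–Smirnov test (exact
when n·m ≤ 10⁴, asymptotic otherwise) for comparing the cumulative
distribution of a cluster's group-averaged values against a reference
set; `group_average()` produces the per-group means and
treatment-minus-control contrasts behind the heatmaps.

# What the synthetic data emulate — and what they do not

`simulate_psm_dataset()` generates the statistical structure every stage
consumes:

* an in-silico proteome (120 proteins, lengths ~N(380, 90), combined K/R
  density 0.12) digested by the combined trypsin/LysC rule with up to 5
  missed cleavages, emitting peptides of 7–30 residues;
* modified PSMs whose ΔM is the catalog mass plus N(0, 0.003 Da) noise
  (truncated at 4 SD) plus a per-sample calibration offset
  (SD 0.002 Da);
* background modified sites for each biological catalog entry (160
  sites, log-normal abundances around 12 PSMs/sample) placed on residues
  matching the entry's specificity — internal Lys only for
  glycerophosphoryl-Lys, protein position 1 for N-terminal entries;
* artefact events (ammonia loss, carbamylation) placed uniformly within
  the first sequence quintile of random peptides, and C13
  precursor-isotope events at ΔM ≈ +1.003;
* ground-truth-false target PSMs and decoy PSMs (reversed sequences,
  mirrored coordinates) in equal expected numbers, with scores from a
  Gaussian 3 SD below the correct-target distribution, so target-decoy
  FDR estimation has a calibrated, non-trivial operating point;
* planted effects: two modules of 20 phospho-sites each, ±1 log2 units
  in both treatment groups, multiplied by a per-animal severity factor
  ~N(1, 0.25). The severity factor emulates animal-to-animal variation
  in disease progression and is what gives co-responding sites their
  shared within-group co-variation — without it, module sites would
  co-vary only through the group means and their mutual correlations
  would be capped well below what coordinated biology shows. Planted
  sites sit on well-sampled proteins (~80 site PSMs and ~200 unmodified
  PSMs per sample) so that site effects survive protein normalization,
  as the well-quantified sites that drive network analysis do in real
  data.

Expected per-sample depth is ~15,000–18,000 PSMs (~160k PSMs across the
nine samples), sized so that every simulation-backed test completes in
seconds while all percentage estimates are stable. The generator is
deterministic under its seed.

What it does **not** emulate: fragment spectra and localization
ambiguity (the engine's best position is taken at face value, and no
Ascore-style rescoring exists downstream), retention time, chimeric
spectra, peptide-specific ionization efficiency, or correlated decoy
structure. Passing tests therefore demonstrate the correctness of the
downstream statistics under the stated generative model, not the
behaviour of any search engine on raw spectra.

A second, matrix-level generator (`simulate_response_matrix()`) emits
standardized site profiles directly — two anti-correlated 20-site
modules over a 10-site flat background, log2 noise SD 0.2 — and is used
to study the clustering stage in isolation. The separation matters: with
only nine samples, the chance probability that two unrelated profiles
correlate above 0.5 is ≈ 9%, so in a large network random
pattern-matching sites necessarily dilute recovered modules. That is a
property of the design size, not of the clustering implementation, and
the matrix-level scenario measures the algorithm at the operating point
where the signal is identifiable.

# Numerical choices and degenerate inputs

* Peak detection on an empty PSM set returns an empty peak table; a
  cluster smaller than `min_psm` yields no peak.
* `fdr_filter()` with zero decoys sets all q-values to 0 with a warning.
* `quantify()` refuses zero sample totals and zero cross-element
  variance; `correlation_network()` drops zero-variance sites with a
  message.
* Ties: score ties rank decoys first (FDR); annotation and decomposition
  ties break by component count, then name; clustering seed order breaks
  ties by node label. All three make reruns bit-identical.
* Positions are 1-based and inclusive throughout, in both peptide and
  protein coordinates.

# Known limitations

* The constant per-sample recalibration ignores any m/z-dependence of
  the mass error.
* Artefact classification is a single-threshold rule on one summary
  statistic; borderline peaks (e.g. 50–70% first-quintile) stay
  biological by construction.
* Cohesiveness clustering is greedy and, on dense noisy graphs, admits
  chance-correlated nodes into otherwise clean clusters; reported
  clusters should be read together with their density and p-value.
* Spectral counting saturates for very abundant sites; no
  intensity-based quantitation is attempted.
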