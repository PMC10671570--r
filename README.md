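# openptm

Downstream analysis of **open-search** shotgun proteomics in R.

In an open database search the precursor mass tolerance is set to tens or
hundreds of daltons, so every unanticipated peptide modification shows up
as a **delta mass** (ΔM): the experimental precursor mass minus the
theoretical mass of the unmodified peptide candidate. A single
phosphoproteome experiment then yields a ΔM distribution with hundreds of
peaks — phosphorylation at +79.966331 Da, its C13 isotope satellites at
+1.003355·k, metabolite-derived modifications such as
glycerophosphoryl-Lys (+167.98 Da), sample-preparation artefacts, and
composite shifts that are sums of simpler ones (79.97 + 0.98 = 80.95 Da).
`openptm` implements everything downstream of the search engine:

* **Delta-mass peak modelling** — per-sample recalibration against the
  unmodified PSM population, Gaussian-kernel density peak detection with
  local-minima boundaries, and PSM-to-peak assignment.
* **Target-decoy FDR at three levels** — q-values computed globally,
  within 1-Da ΔM bins, and within each ΔM peak
  (`FDR(s) = #decoys(score ≥ s) / #targets(score ≥ s)`, monotonized);
  a PSM is accepted only if all three q-values pass the 1% threshold.
* **Annotation** — catalog lookup, exhaustive composite decomposition
  (multisets of catalog masses plus C13 spacings), isotope-satellite
  collapsing.
* **Specificity profiling** — per-peak residue frequencies corrected by
  the average frequency at the ±3 flanking positions, sequence-quintile
  distributions, and artefact classification: a ΔM concentrated (>70%)
  in the first sequence quintile of internal (non-protein-N-terminal)
  peptides is a digestion/fragmentation artefact, not biology.
* **Site aggregation (qdna)** — modified peptides sharing protein `q`,
  ΔM peak `d`, residue type `a` and protein position `n` integrate into
  one quantifiable site; a stringent partial-digestion filter for
  cleavage-blocking Lys modifications (pgK) removes PSMs whose modified
  Lys sits at the peptide C-terminus.
* **Standardized spectral-count quantitation** — counts scaled by total
  sample PSMs, log2-transformed against the per-element median across
  samples, z-scored per sample (`Zq`, `Zqdna`), and protein-normalized
  site quantities (`Zq_qdna = Z_site − Z_protein`, re-standardized).
* **Response-module discovery** — Pearson correlation network over
  `Zq_qdna` profiles (edges at r > 0.5) clustered by greedy cohesiveness
  maximization, `f(V) = W_in / (W_in + W_bound + penalty·|V|)`, with
  single-pass overlap merging, Mann–Whitney significance and two-sample
  Kolmogorov–Smirnov comparisons of group-averaged distributions.
* **A synthetic-data generator** — `simulate_psm_dataset()` emits a full
  PSM table (with ground truth) over a 3-group × 3-replicate design:
  in-silico proteome, tryptic/LysC digestion with missed cleavages,
  catalog-mass ΔM draws, first-quintile artefact placement, decoys with
  overlapping score distributions, and planted per-site group effects in
  two anti-correlated response modules.

## Worked example

```r
library(openptm)

cfg  <- sim_config(seed = 7)            # the default study conditions
sim  <- simulate_psm_dataset(cfg)       # ~160k PSMs, 9 samples
psms <- recalibrate(sim$psms)
peaks <- detect_peaks(psms)
dplyr::arrange(peaks, dplyr::desc(psm_count))[1:6, ]
#>   peak_id         apex     left    right psm_count
#> 1 pk_0042   0.00000455  -0.0655   0.0305     82531
#> 2 pk_0076  80.0         79.9     80.0        41451
#> 3 pk_0052  16.0         16.0     16.0         2816
#> 4 pk_0044   0.984        0.922    0.997       1876
#> 5 pk_0107 168.         168.     168.          1689
#> 6 pk_0036 -17.0        -17.1    -17.0         1285
```

The unmodified population sits at 0 Da, phosphorylation at 79.97 Da,
Met oxidation at 15.99 Da, deamidation at 0.98 Da, glycerophosphoryl-Lys
at 167.98 Da and ammonia loss at −17.03 Da. Filtering and annotation:

```r
psms <- fdr_filter(assign_to_peaks(psms, peaks))
sum(psms$fdr_pass)
#> [1] 131559                     # of 161336, at three-level 1% FDR

annotate_peaks(peaks[which.min(abs(peaks$apex - 79.966)), ])
#>   peak_id  apex name         error
#> 1 pk_0076  80.0 phospho -0.0000238

decompose_composite(80.95)[1, ]      # the 80.95 Da composite
#>   components            n_terms n_isotopes  mass     error
#> 1 deamidation + phospho       2          0  81.0 -0.000347
```

Specificity profiles diagnose artefacts — note how the +42.01 Da peak
(protein N-terminal acetylation) is 100% first-quintile but *biological*,
because its peptides start at protein position 1, while −17.03 Da
(ammonia loss) and +43.01 Da (carbamylation) are peptide-N-terminal
artefacts:

```r
prof <- specificity_profiles(psms[psms$fdr_pass, ], peaks)
head(tidy(prof)[order(-tidy(prof)$quintile1_freq), ], 3)
#>   peak_id  apex n_psm origin      quintile1_freq
#> 1 pk_0064  42.0   897 biological           100
#> 2 pk_0065  43.0   653 artefactual          100
#> 3 pk_0036 -17.0  1222 artefactual           99.9
```

From there, `map_to_sites()` + `site_counts()` build the qdna count
table, `quantify()` / `protein_normalize()` produce the `Zq_qdna` layer,
and `correlation_network()` + `cluster_cohesive()` recover coordinated
site-response modules (see the vignette in `vignettes/` for the full
pipeline, including the group-response clustering and KS statistics).

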