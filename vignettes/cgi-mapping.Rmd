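---
title: "Mapping CpG islands and their methylation from CAP/MAP enrichment tracks"
author: "capmapr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping CpG islands and their methylation from CAP/MAP enrichment tracks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(capmapr)
```

## Scope and model

`capmapr` analyses per-base read-depth tracks from affinity purifications
that partition the genome by CpG methylation state. CAP-seq retains DNA
fragments carrying clusters of unmethylated CpGs, so its peaks delineate
the unmethylated CpG-island (CGI) complement; MAP-seq retains methylated
fragments (on the order of one methyl-CpG per 100 bp and above) and is the
reciprocal map. The package takes the tracks as given — read mapping,
duplicate handling and replicate pooling happen upstream — and implements
everything from normalization to biology-level summaries. All intervals
are `GRanges` (1-based, closed); WIG, BED and GTF conventions are
converted at the file boundary, so exactly one coordinate convention
exists inside the package.

The pipeline for a typical study is:

1. `normalize_tracks()` per assay;
2. `find_peaks()` per tissue and `union_peak_sets()` → the CGI set;
3. `cgi_cpg_annotate()` + `classify_cgi()` + `intersect_features()`;
4. `dm_matrix()` against the germline reference, then
   `consensus_tumour_calls()` / `conservation_table()` as the design
   requires;
5. `composite_profile()`, `density_bin_summary()`,
   `pairwise_correlation()`, `overlap_table()`,
   `category_percentage_table()` for figure-level tables.

## Normalization

Like-assay samples are made comparable by scaling each track to a common
total (`scale_like_samples()`), the constant approximating the average
read number of the group; an explicit constant is accepted for
reproducibility across runs. Scaling acts on per-base depth because depth
is the only granularity the tracks provide, and it therefore produces
fractional values — `DepthTrack` stores real numbers, and `write_wig()`
prints them with 17 significant digits so round trips are bit-exact.

MAP tracks carry diffuse signal from the partially methylated bulk genome
(~75% of bulk CpGs are methylated). Fluctuations of that background
between samples would skew the scaling constant, so `normalize_tracks()`
computes MAP scale factors from background-removed copies
(`remove_background()`, per-base depth floor, default 2) but applies them
to the intact tracks. The composition matters: flooring the tracks
themselves converts the smooth Poisson background under each CGI (window
totals around 20 reads, ratios pinned near 1) into sparse isolated spikes,
which measurably destabilizes the sliding-window methylation ratios. CAP
tracks show minimal intervening background and are not floored. What
constitutes "background" is not uniquely defined by the assay; the depth
floor is a declared, configurable rule.

## Peak calling: the H/L/G rule

`find_peaks()` has three constants (`peak_params()`): minimum per-base
read height **H**, minimum region length **L** (bp), and the gap **G**
(bp) permitted in the length parameter. Bases with depth ≥ H are marked;
consecutive marked runs separated by at most G unmarked bases merge into
one candidate (the gap counts toward the span, flanking unmarked bases
never do); candidates spanning ≥ L bp are reported. Two conventions are
fixed here and enforced by tests: the gap bound is *inclusive* (a gap of
exactly G bp merges — "permitted" read as an allowance), and gap bases
count toward the L test. The caller is monotone: lowering H or L, or
raising G, can only add covered bases — the formal counterpart of a
gentler wash recovering additional, CpG-poorer islands.

Peaks carry no scores; any statistic needed downstream is recomputed from
the track. Per-assay default profiles (`peak_params(assay = "CAP")`:
H = 2.5, L = 300, G = 50) are calibrated on the package's synthetic
fixtures at mean depth 5 reads/bp — real datasets need their own
constants, which are deliberately required configuration.

`union_peak_sets()` merges per-tissue (or per-stringency) peak sets into
one non-redundant CGI set; abutting intervals merge, and the operation is
idempotent, commutative and associative.

## CpG composition

`cpg_stats()` counts CG dinucleotides with an overlapping scan and uses
the classical Gardiner–Garden expectation, `oe = n_CpG·L/(n_C·n_G)` —
the convention behind the usual o/e ≥ 0.6 island-prediction threshold;
the bulk-genome reference value is ≈ 0.21. `N` bases reduce the effective
length and can form no CpG; sliding windows (`sliding_cpg_oe()`, default
400 bp/10 bp; 300 bp/10 bp is a common variant) with more than 20% N are
reported missing rather than computed from slivers. When a sequence has
no C or no G the ratio is undefined and returned as `NA`, never 0.

Density bins (`density_bin()`) follow the six labels `<5, 5-6, 6-7, 7-8,
8-9, >9` CpGs/100 bp. Whether boundaries are open or closed is not
determined by the labels; the package fixes left-closed/right-open
interior bins, with 9.0 falling in `>9` so that exactly six exhaustive
bins cover all densities — a declared convention, enforced by tests.

## Positional classification

`classify_cgi()` extends each CGI by `flank` bp (default 100) and calls
it **ATSS** when the extension reaches any gene's transcription start
site, otherwise **Intragenic** when it overlaps a gene body, otherwise
**Intergenic**. The classes are exclusive and exhaustive; ATSS takes
precedence because promoter status is the biologically privileged call,
and a CGI spanning two TSSs (bidirectional promoter) is simply ATSS.
"Overlapping the 5′ end ± 100 bp" admits two readings (a window around
the TSS point, or a 5′ region of unstated size); the TSS-point reading is
implemented. Classification expects one interval per gene — collapse
transcript-level annotation first with `collapse_gene_models()`.

## Differential methylation

For each CGI, `window_means()` computes mean depth in 100 bp windows with
a 20 bp slide, and `dm_score()` compares somatic versus germline-reference
series window by window (`dm_params()`):

* window read totals are reconstructed as mean × window length — the
  tracks do not preserve individual reads, so the 4-read floor applies to
  depth mass (configurable);
* if both totals are below the floor the ratio is set to 1, removing bias
  from small fluctuations at low depth;
* otherwise the ratio is `(T_test + 1)/(T_ref + 1)`: the floor rule
  covers only the both-low case, and without a pseudocount a zero
  reference window gives an infinite ratio; ε = 1 read is the smallest
  unit of evidence and is configurable;
* the CGI scores +1 when some frame of 10 consecutive windows contains at
  least 9 with log2 ratio > 2 ("9 out of 10 contiguous" is read as a
  frame containing 9 exceedances, not 9 consecutive exceedances), −1 with
  the mirrored threshold (the negative direction is defined symmetrically,
  with +1 meaning more methylated than the sperm reference, so the ratio
  is test/reference), else 0;
* CGIs with fewer than 10 windows (shorter than 280 bp) are non-evaluable
  and score 0 with a flag; a proportional rule (≥ ⌈0.9·n⌉ of n windows)
  is available behind `dm_params(proportional = TRUE)`.

`dm_matrix()` applies this per CGI × sample; `consensus_tumour_calls()`
partitions a matched cohort with the "methylated in at least 3 of 5
tumours, no normals" rule (thresholds configurable), and
`conservation_table()` summarizes cross-species agreement over a supplied
ortholog pairing, excluding intergenic CGIs by default. Orthology itself
is an input — the package performs no liftover.

## Summaries

`composite_profile()` anchors a 5 kb span at each interval's midpoint
(CGIs vary in length; midpoint anchoring is the declared convention) and
reports per-offset medians and quartiles of 500 bp/100 bp window means;
intervals truncated by chromosome ends contribute only their defined
windows. `density_bin_summary()` relates each density bin to the mean
signal over the central 2 kb. `pairwise_correlation()` bins both tracks
into contiguous 1 kb windows and retains windows where both tracks are
zero — the statistic is defined over *every* window, not covered windows
only; a trailing partial window is dropped everywhere (`bin_track()`), as
padding would bias window means. Correlation of a vector with itself is
returned as exactly 1, and zero-variance inputs give `NA` rather than an
error or a propagated NaN. `welch_t()` is the two-sided Welch test with
Welch–Satterthwaite degrees of freedom; two exactly constant samples
raise an error (no statistic is defined), a documented contract.

## The synthetic-data generator

The simulator exists so that every claim the pipeline makes can be scored
against known truth at desk scale. Its defaults are the package's study
conditions and are not tuned per test:

* **Background genome**: first-order Markov chain whose transition matrix
  is solved in closed form (`dinuc_transition()`) so the stationary
  composition hits the target G+C (0.40) exactly while the C→G transition
  is damped to realize CpG o/e = 0.21, the bulk-genome average.
* **Islands**: ~1 kb segments (800–1200 bp) regenerated at G+C 0.65 and
  o/e drawn uniformly from 0.4–1.1, i.e. roughly 4–12 CpGs per 100 bp —
  up to the canonical "one CpG every ten base pairs" and down to island
  densities that standard prediction thresholds miss. Placement respects
  a planted class mix of 48% ATSS / 26% intragenic / 26% intergenic and
  keeps ≥ 2 kb between islands and ≥ 300 bp clearance from gene
  boundaries, so planted classes are unambiguous under the ±100 bp
  classification flank.
* **Methylation**: independent Bernoulli per CGI and somatic tissue at
  class-specific rates (ATSS 0.03, intragenic 0.24, intergenic 0.14 —
  the observed somatic preference for orphans); the germline is always
  unmethylated, which is what makes sperm the reference. Bulk-genome
  CpGs count as 75% methylated (the 70–80% midpoint), as a deterministic
  weight rather than a per-CpG coin flip.
* **Assays** (`assay_params()`): the genome is tiled into 200 bp
  fragments; each tile's retention follows the assay model (logistic in
  unmethylated-CpG density for CAP; threshold at 1 methyl-CpG/100 bp for
  MAP, with a small diffuse bulk retention that motivates background
  removal; linear gain in density at unmethylated islands for H3K4me3;
  active-promoter indicator for RNAPII) and per-base depth is
  `Poisson(mean_depth × retention + background_depth)` with defaults
  5 and 0.2 reads/bp.
* **Wash stringency**: no quantitative retention-versus-salt curve is
  recoverable from the phenomenology (600 mM → 560 mM NaCl), so
  stringency is abstracted as the logistic midpoint: 5.0 CpGs/100 bp
  (high) versus 3.5 (low). `simulate_cap_stringency_pair()` draws the two
  tracks coupled by Poisson superposition — the low-stringency track is
  the high-stringency track plus extra retained signal — which is both
  the physically sensible picture of a gentler wash on the same library
  and the construction that makes peak-coverage nesting a theorem rather
  than a tendency.

Everything is deterministic per seed; `write_fixture_bundle()`
materializes a scenario as FASTA/GTF/TSV/WIG with an md5 manifest, and
identical configurations reproduce identical checksums.

What the simulator does **not** emulate: mappability and GC bias,
copy-number changes in tumours, fragment-length variation (fixed tiles,
for reproducibility), read-level artefacts, correlated methylation
between neighbouring CGIs or between tissues, partial (allelic or
cell-mixture) methylation, and realistic chromosome counts — each
scenario is one chromosome. Passing tests therefore demonstrate that the
algorithms implement their contracts and recover truth under the stated
noise model, not that the default constants are optimal for any real
dataset.

## Validation scenarios and problem sizes

The test suite and `scripts/acceptance.R` run four scenarios, sized so a
full validation completes in about a minute on one CPU while keeping
every per-class count in double digits: the **default** scenario (2 Mb,
80 genes, 100 islands, tissues sperm/blood/cerebellum, mean depth
5 reads/bp) for island recovery, stringency nesting, differential
methylation, replicate nulls, H3K4me3 density response and
classification; **X-inactivation** (0.8 Mb, 40 islands, 15 methylated in
the female sample only) as the calibration design for the
differential-methylation caller; **tumour cohort** (1 Mb, 60 islands,
5 normals + 5 tumours, a planted tumour-specific set methylated in 3–5
tumours and no normals, polycomb flags enriched on it); and
**two-species** (two 0.8 Mb genomes with shifted island-density
distributions and an ortholog pairing table) for the conservation
summary. Recovery is scored at 50% reciprocal overlap. Against these
truths the pipeline reaches precision/recall ≥ 0.95 for island recovery
and sensitivity/specificity ≥ 0.95 for methylation calls, with zero
calls on replicate-versus-replicate comparisons.

## Known limitations

* Peak-calling constants and the background floor are dataset properties;
  the shipped defaults are calibrated only for the simulator's depth
  regime.
* The differential-methylation floor operates on depth mass, not read
  count, and therefore inherits the normalization scale.
* `density_bin_summary()` and `composite_profile()` treat each CGI's
  midpoint as its anchor; asymmetric islands blur profiles slightly.
* Tumour consensus calling ignores copy number; amplified regions can
  inflate MAP ratios in real data.
* The o/e metric is the only sequence-based island criterion implemented;
  the package deliberately does not re-implement full sequence-prediction
  algorithms.

## A compact end-to-end run

```{r example, eval = FALSE}
sc  <- scenario_default(genome_length = 5e5, n_genes = 24, n_islands = 30)
sim <- simulate_scenario(sc, seed = 42)

cap   <- normalize_tracks(sim$tracks$CAP, "CAP")$tracks
cgis  <- union_peak_sets(lapply(cap, find_peaks,
                                params = peak_params(assay = "CAP")))
cgis  <- cgi_cpg_annotate(cgis, sim$genome)
cgis$class <- classify_cgi(cgis, sim$genes)

map    <- normalize_tracks(sim$tracks$MAP, "MAP")$tracks
scores <- dm_matrix(cgis, map$sperm, map[c("blood", "cerebellum")])
category_percentage_table(cgis$class,
                          list(meth_blood = scores[, "blood"] == 1))
```
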