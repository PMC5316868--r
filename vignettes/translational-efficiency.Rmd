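---
title: "Estimating translational efficiency from paired Ribo-Seq and RNA-Seq"
author: "riboTE"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating translational efficiency from paired Ribo-Seq and RNA-Seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riboTE)
```

## The measurement

Ribosome profiling sequences the ~30-nt mRNA fragments protected by
elongating ribosomes (RPFs); a matched RNA-Seq library measures mRNA
abundance. The ratio of the two on a gene's coding sequence is its
translational efficiency (TE): how many ribosomes the message carries per
mRNA copy. The package estimates TE per gene, asks which genes deviate from
the transcriptome-wide norm, and compares TE between tissues.

Three preprocessing conventions shape the counts:

* **A-site assignment.** An RPF is attributed to the codon in the
  ribosome's aminoacyl site, at a length-dependent offset from the
  fragment's 5' end: +14 nt for fragments ≤ 29 nt, +15 for 30–31, +16 for
  32–35, +17 for ≥ 36. `asite_offset()` is this rule; it is applied to
  both library types so Ribo and RNA reads pass through an identical
  counting window.
* **Codon masking.** Initiation-proximal pileup (a known artifact of
  cycloheximide pre-treatment) and termination make the first and last
  codons unrepresentative of elongation, so counting excludes the first 15
  and the last 5 codons of each CDS (`count_cds()`, 0-based codons, codon
  `k` occupying CDS nucleotides `[3k, 3k+3)`; "first 15" means codons
  0–14).
* **One transcript per gene.** All coordinates are transcript-space,
  0-based, half-open, on a single canonical isoform per gene
  (`select_canonical()`: explicit tag, else longest CDS, longest
  transcript, smallest id).

## The model

For gene $g$ and library $j$, the codon-masked CDS count is modelled as
negative binomial with $\mathrm{Var} = \mu + \alpha\mu^2$ (the DESeq
parameterization; $\alpha = 0$ is Poisson) and a log-linear mean:

$$\log \mu_{gj} = \log s_j + \beta_{0g} + \beta_{\mathrm{lib},g}\,x_j
  + \text{replicate effects}$$

where $x_j$ indicates a Ribo-Seq library and $s_j$ is the library's size
factor (median across usable genes of the count over the gene's geometric
mean, computed on the natural scale as in the original DESeq; genes with
any zero count are excluded from the median). The TE estimate is the
library-type coefficient, $\log_2 TE_g = \hat\beta_{\mathrm{lib},g}/\ln 2$.

Fitting is iteratively reweighted least squares with fixed per-gene
dispersion, vectorized across genes sharing the design matrix
(`nb_glm()` exposes the single-gene fit). Standard errors come from the
inverse expected information.

**Testing against the median.** Genes are compared to the transcriptome
median $m$ of $\log_2 TE$ by a Wald statistic
$z_g = (\log_2 TE_g - m)/\mathrm{se}_g$, two-sided normal p-values, and
Benjamini–Hochberg adjustment over all fitted genes. The median is treated
as fixed: with thousands of genes its sampling error is negligible next to
the per-gene standard errors. `classify_te()` labels genes **TE-low**
(**TE-high**) when FDR < 0.05 and the gene sits at least threefold below
(above) the median; both thresholds are arguments.

**Between-tissue differential TE.** With two tissues the design gains a
tissue main effect and a library-by-tissue interaction; the interaction
coefficient is $\Delta\log_2 TE$. Tissue levels are ordered
alphabetically, so the sign convention (recorded in the fit's
`$convention` field) is invariant to how the libraries happen to be
listed, and swapping tissue labels negates every estimate.
`classify_delta()` calls a gene at FDR < 0.2 and $|\Delta\log_2 TE| \ge 1$
(a twofold TE change).

**Exclusions.** A gene with zero counts in every library of either type
has undefined TE and is returned with `NA` results; genes whose IRLS does
not converge within 50 iterations are likewise flagged `NA`.

## Dispersion

With three biological replicates per condition, per-gene dispersion
estimates are extremely noisy, and plugging them into Wald tests makes the
tests anticonservative. The default (`dispersion = "trend"`) therefore:

1. computes a method-of-moments estimate per gene from normalized counts
   within replicate groups, subtracting the shot-noise term
   $\bar\mu\,\overline{1/s_j}$ so that pure counting noise maps to
   $\alpha \approx 0$;
2. fits a parametric mean–dispersion trend
   $\alpha(\mu) = a_0 + a_1/\mu$ across genes by gamma regression (with a
   flat-median fallback when the regression cannot be fitted);
3. assigns each gene the larger of its own estimate and the trend value
   ("maximum" sharing, the behaviour of the original DESeq), floored at
   $10^{-8}$.

`dispersion = "per-gene"` skips steps 2–3; `dispersion = "fixed"` uses a
supplied constant (required when there is a single replicate). Under a
simulated global null (2,000 genes, 3 replicates, mean count 200,
$\alpha = 0.05$) the resulting Wald test rejects at the nominal 5% level at
an observed rate of about 4%, slightly conservative, as the maximum-sharing
rule intends — the acceptance suite checks this calibration, and that no
TE-low/TE-high calls survive the FDR and threefold gates under the null.

## QC diagnostics

`qc_report()` bundles the four library diagnostics. Ribo fragments are
positioned by A-site; RNA fragments by their 5' end (an RNA read has no
ribosome geometry, and region fractions should reflect where the fragment
actually lies). Counting for the TE model, by contrast, shifts both
library types by the same offset rule — there the point is an identical
window, not a physical position.

* `length_histogram()` — RPF length distribution; a good library has a
  sharp mode near 30 nt.
* `region_distribution()` — fractions over 5'UTR / CDS / 3'UTR; RPFs
  should be predominantly (~80%) CDS.
* `frame_periodicity()` — A-site frame relative to the CDS start; strong
  enrichment of frame 0 reflects codon-stepping ribosomes.
* `metagene()` — mean normalized density over −30..+149 nt around the CDS
  start and −150..+29 around the CDS end. Genes enter only if 5'UTR and
  3'UTR are ≥ 50 nt, CDS ≥ 500 nt, and ≥ 300 reads map anywhere on the
  transcript (all boundaries inclusive — a 49-nt UTR fails, exactly 300
  reads pass; reads are counted per library set passed in, pooling
  whatever libraries the caller supplies). Each gene's per-nucleotide
  counts are divided by its total mapped reads before averaging, making
  the profile invariant to any single gene's depth.

## The synthetic-data generator

The generator provides ground truth for every downstream stage. Defaults
mirror the study conditions the pipeline targets: 3 biological replicates
× 2 library types × 1–2 tissues, NB counts with per-gene TE, and
positional fragments with

* a fragment-length distribution over 26–36 nt peaked at 30 nt,
* A-site frame proportions 0.7/0.15/0.15,
* 80% of Ribo A-sites in the CDS, the rest uniform over the UTRs,
* threefold A-site density over the first 15 codons (the start-proximal
  ramp), and
* RNA fragments uniform over the transcript.

The frame, CDS-fraction and ramp values are qualitative stand-ins chosen
to resemble a good ribosome-profiling library (the hallmarks are a ~30-nt
mode, clear periodicity, ~80% CDS); they are configurable through
`fragment_profile()` and are not calibrated to any particular deposited
dataset. Each fragment's CDS/UTR stratum is drawn once and kept through
boundary resampling, so the realized CDS fraction is an unbiased binomial
draw at the nominal rate. Fragment counts per gene and library equal the
count-table entry exactly.

`make_transcriptome()` plants a Poisson number of uAUGs at recorded
positions in otherwise AUG-free 5'UTRs (an accidental ATG is removed by
replacing its middle base, which cannot create a new one), and builds CDSs
with a start, a stop and no internal in-frame stop. The uORF scanner must
therefore recover exactly the planted canonical sites — a cross-module
consistency check the test suite enforces on every generated gene.

What the generator does **not** emulate: sequencing errors, alignment
ambiguity and multimapping, rRNA contamination reads (the layered filter
is exercised with labelled flags instead), positional biases beyond the
ramp (no codon-level pausing, no nucleotide composition bias), isoform
mixtures, and library-preparation batch effects. Passing tests on
synthetic data show the estimators are correct under the stated model, not
that real libraries satisfy the model.

## uORF annotation and in-silico mutagenesis

`find_start_sites()` reports every AUG in the 5'UTR regardless of context,
plus every near-cognate codon (the nine codons one substitution from AUG)
in a favourable Kozak context. The default favourability rule tests
the immediately flanking context: with the codon occupying positions 0–2,
G at −1 and A/G at +3 (the first nucleotide after the codon). This
numbering is unusual — classical Kozak notation puts A/G at −3 and G at
+4 — so both are implemented (`convention = "adjacent"` (default) or
`"classical"`) rather than silently preferring either.

Each site is classified by walking in-frame triplets to the first stop
(UAA/UAG/UGA), continuing into the CDS when the UTR has none: a stop
upstream of the CDS start makes a **uORF**; otherwise a nonzero frame
offset against the main ORF makes an **oORF** (overlap out of frame), and
frame offset 0 an **in-frame extension**. A stop codon that straddles the
UTR/CDS junction counts as upstream termination (its start lies in the
UTR).

`apply_mutation()` implements the three mutagenesis operations used to
dissect uORF function — start-codon point mutation (canonically to AAG or
CAG), stop disruption (e.g. ugUGA→ugAGA), and insertion of C/CC just
before the CDS (+1/+2 frameshift) — and re-annotates. Inserting a total of
3 nt restores all reading frames, and hence all site classes, with one
documented exception: a stop codon that straddled the UTR/CDS junction is
itself disrupted by an insertion at the junction, so sites terminating at
such a stop may legitimately change class.

## Reporter and polysome statistics

Reporter TE is (Fluc activity / Rluc activity) ÷ (Fluc RNA / Rluc RNA),
expressed relative to the same quantity for the HBB-5'UTR control of the
same transfection batch; per-construct values are averaged across batches
(biological replicates) with their SD. Heavy-polysome association corrects
each sucrose fraction's qPCR signal by its spike-in recovery and reports
the heavy share of the corrected total as a percentage; which fractions
count as "heavy" is an input label (`mark_heavy()`), since fractionation
geometry is apparatus-specific. Group comparisons use Student's two-sample
t-test (equal variances by default, matching the convention the assays
were analysed with; Welch by flag) with the usual star coding (`**` p <
0.01, `*` p < 0.05).

## Numerical choices and edge cases

* IRLS: initialization at $\mu = \max(y, 0.5)$, linear predictors clamped
  to ±30, convergence at $\max|\Delta\beta| < 10^{-8}$, 50 iterations.
* Dispersion floor $10^{-8}$; method-of-moments estimates may be negative
  (sub-Poisson sampling noise) and are floored or absorbed by the trend.
* A-sites falling beyond the transcript end are dropped, not clipped, and
  the number dropped is reported — clipping would fabricate positions.
* Adapter trimming repeats until a fixed point, so the operation is
  idempotent; matching is exact with a 3-nt minimum overlap. The
  published quality cutoff ("Phred > 33") is read as mean base quality,
  with a per-base minimum available via `mode = "min"`.
* Empty inputs return empty, typed results (empty histogram, zero-gene
  metagene with a message) rather than errors.

## Validation scales

The acceptance checks run at 2,000 genes, 3 replicates, NB dispersion
0.05, lognormal mean CDS counts centred at 200 (TE recovery and null
calibration; planted strata at log2 TE ∈ {−2, 0, +2}) or 500
(between-tissue ΔTE, ±2 planted in 10% of genes), and ~1e5 fragments for
the QC recoveries; scanner oracles use 1,000 random 300-nt UTRs. These
sizes give Monte-Carlo error comfortably inside the asserted tolerances
(e.g. binomial SE ≈ 0.0015 on the frame-0 fraction against a ±0.02 band).

## Known limitations

* The NB GLM is fit per gene with dispersion treated as known; no
  empirical-Bayes shrinkage of the TE estimates themselves.
* TE is gene-level on one canonical isoform; isoform-specific translation
  is out of scope.
* The uORF scanner reports sequence potential, not translational evidence;
  initiation-site profiling, conservation and RNA structure are not
  consulted.
* The median-reference test assumes most genes share a common TE baseline;
  in a transcriptome where translation is globally perturbed the median
  itself shifts.
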