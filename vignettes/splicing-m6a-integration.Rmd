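---
title: "Methods: joint analysis of alternative splicing and m6A methylation"
author: "spliceMeth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: joint analysis of alternative splicing and m6A methylation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spliceMeth)
```

# Scope and model overview

spliceMeth analyses how N6-methyladenosine (m6A) mRNA methylation relates
to pre-mRNA alternative splicing (AS) between two conditions — the
motivating setting is oxidative (soleus-like, "SOL") versus glycolytic
(extensor-digitorum-longus-like, "EDL") skeletal muscle, profiled with
paired RNA-seq and MeRIP-seq in a 2-condition x 3-replicate design. The
pipeline has six analysis stages, each exposed as plain functions and
driven end to end by `run_pipeline()`:

1. **Event cataloguing** — the five-type AS taxonomy (SE, A5SS, A3SS, MXE,
   RI) derived from annotated transcript structures by pairwise transcript
   comparison.
2. **Quantification** — FPKM for genes, percent-spliced-in (PSI) for
   events.
3. **Differential testing** — a negative-binomial Wald test for
   expression, a pooled binomial likelihood-ratio test for PSI,
   Benjamini–Hochberg control throughout.
4. **MeRIP-seq enrichment** — window-based m6A peak calling from binned
   IP/input coverage, MFPKM enrichment, differential methylation.
5. **Integration** — the four-quadrant SE-DMAS classification (skipped
   exons with both differential PSI and differential m6A), AS-fraction and
   AS-count-quartile analyses, RRACH motif scanning, knockdown
   intersection.
6. **Network** — a splicing-factor (SF) to event Spearman correlation
   network over the differential events.

A first-class synthetic-data generator (`simulate_dataset()`) produces
every input with known planted truth, so all stages are testable without
any external download.

# Event definitions

All internal coordinates are 0-based half-open; GTF (1-based closed) and
BED (0-based half-open) are converted at the I/O boundary and nowhere
else. Given two transcripts A and B of one gene:

* **SE** — an internal exon of A whose flanking junctions both appear in A,
  while B splices the flanking exons directly together (carries the
  junction from the upstream exon's end to the downstream exon's start).
* **RI** — B carries a single exon spanning exactly two consecutive exons
  of A plus the intervening intron.
* **A5SS / A3SS** — A and B share one boundary of an exon and the facing
  splice site of the adjacent exon, but differ at the other boundary. The
  5'/3' label is assigned relative to transcript orientation, so the same
  geometry labels differently on opposite strands (and reflecting a gene's
  coordinates while flipping strand preserves the label — a property the
  tests verify).
* **MXE** — two non-overlapping internal exons, each flanked by exons
  sharing both junctions, that never co-occur in any transcript of the
  gene.

Duplicate events (same type, strand, and junction-defining coordinates)
are emitted once; flanking-exon outer edges are annotation detail, not
identity. Detection is annotation-only: junctions not present in the gene
models are never discovered. Correctness is established against an
independent exhaustive enumeration over the exon universe on randomized
toy models.

# Quantification

FPKM is `count / (length/1000) / (library_size/1e6)` with library size
the total counted fragments (configurable). A gene is *expressed* when
FPKM >= 0.5 in at least one library (both thresholds configurable; the
boundary is inclusive).

PSI uses the length-normalised estimator
`psi = (I/l_I) / (I/l_I + S/l_S)` with `I`/`S` the inclusion/skipping
junction counts and `l_I`/`l_S` the effective lengths of the two forms.
Effective lengths are data (columns of the event table), not constants:
they depend on read length, which the package does not assume. PSI is
reported missing below a junction-coverage floor of `I + S >= 10` reads
(configurable); untested events are excluded from the BH family, since
family size changes the FDR.

# Differential testing

**Expression.** Median-of-ratios size factors; per-gene method-of-moments
dispersion pooled within conditions; a common dispersion–mean trend
`alpha(mu) = a0 + a1/mu` fitted across genes; a Wald test on the log2
fold-change of normalised condition means with a delta-method standard
error using the trend dispersion. A gene is differentially expressed when
`|log2FC| >= 1` (inclusive) and BH FDR < 0.05. This is a deliberately
compact substitute for a full GLM framework: with the strong planted
effects and the calibration regimes exercised here it is essentially
equivalent, and both its power and its null behaviour are measured by the
test suite rather than assumed.

**Splicing.** Junction counts are pooled across the replicates of each
condition and modelled binomially. The read-level inclusion proportion
`q` maps one-to-one onto PSI through the effective lengths
(`q = psi*l_I / (psi*l_I + (1-psi)*l_S)` — the same map `estimate_psi()`
inverts), so the likelihood-ratio test of "shared q" versus
"condition-specific q" is exactly the test of shared versus
condition-specific PSI, evaluated on the quantity that is actually
binomial. We test on the raw counts rather than on length-reweighted
pseudo-counts because reweighting distorts the effective sample size and
with it the chi-squared calibration. The LRT statistic is referred to
chi-squared with 1 df; BH across tested events; DAS at FDR < 0.05 with an
optional (default off) `|delta PSI|` reporting floor. Replicates are
pooled, so between-replicate biological variability in PSI is not
modelled — the design trades the hierarchical replicate model for
calibration that the suite can verify directly (planted-null flagged
fraction and planted-effect power are both measured over many seeds).

Direction conventions are fixed throughout: condition 2 (SOL-like) minus
condition 1 (EDL-like); `increased`/`decreased` for PSI, `hyper`/`hypo`
for methylation.

# MeRIP-seq enrichment

Bins (default 100 bp here; the caller accepts any grid) tile exonic
regions with paired IP/input counts per replicate. Peak calling is per
condition: pooled IP versus pooled input per bin with a one-sided Fisher
exact test against the library totals, BH across bins, and a fold floor
of 2. Fold enrichment is the bin's IP/input ratio divided by the
library's **median** bin ratio: the median is a background estimate that
the enriched bins themselves cannot inflate, which matters when a large
fraction of genes carries peaks. Adjacent significant bins merge into
peaks; per-condition peak sets are unioned into a single list so
differential testing has one family.

MFPKM is `FPKM_IP / FPKM_input` computed per replicate and then averaged
arithmetically over a condition's replicates (mean of ratios, not ratio
of means — the two differ and the mean-of-ratios reading matches the
per-replicate definition of the measure). Replicates with zero input
FPKM are excluded and counted; a condition with no usable replicate
yields a missing MFPKM and an untested peak.

Differential methylation per peak: `log2FC = log2(MFPKM_2 / MFPKM_1)`,
with the p-value from a two-sided Fisher exact test on the pooled 2x2
(IP, input) x (condition) table, BH across peaks, significant at
padj < 0.05. **Known limitation:** the Fisher test conditions on totals
and ignores between-replicate overdispersion, so with strong biological
noise it overstates significance for non-differential peaks. The
downstream quadrant analysis is protected by its joint requirements
(significant differential PSI *and* an overlapping significant peak, with
directions taken from signs), but peak-level differential calls on noisy
real data should be read as a screen, not as calibrated inference.

# Integration

A SE-DMAS record joins an SE-type DAS event (FDR < 0.05) to a significant
differential peak (padj < 0.05) overlapping its cassette exon
(bedtools-style half-open intersection; intervals touching only at a
boundary do not overlap). When several significant peaks overlap one
exon, the largest overlap wins, ties broken by leftmost peak start — a
deterministic single record per event. The quadrant label crosses the PSI
direction with the m6A direction; marginals and a gene-level roll-up are
reported. Peak-level (not exon-summed) m6A change is used.

An *m6A-modified gene* is a gene containing at least one called peak in
either condition. The AS-count quartile analysis groups modified genes by
type-7 (linear interpolation) quartiles of their AS-event counts — high:
count >= Q3; low: count <= Q1; medium between; if Q1 = Q3 the precedence
high-then-low keeps the partition total. The group comparison uses a
one-sided Mann–Whitney test on gene-level log2FC(MFPKM) (the comparison
statistic is not dictated by the quadrant definitions; Mann–Whitney is
the assumption-light choice and the test records it).

RRACH (R = A/G, H = A/C/U) scanning counts all, including overlapping,
matches of `[AG][AG]AC[ACU]`; `N` never matches; reverse-strand scanning
reports positions on input coordinates. The scan is a vectorised
set-membership pass over the sequence, oracle-checked against an
independent regex implementation; `scan_fasta_rrach()` applies it to
FASTA windows (e.g. 1 kb around skipped exons).

Knockdown intersection identifies events by (gene, cassette-exon
coordinates, strand). A guard detects the classic failure mode: zero
overlap that becomes perfect overlap after a 1-bp shift raises a loud
warning about mixed 0-based/1-based conventions.

# Correlation network

Every (SF, DAS event) pair is tested: Spearman rho on mid-ranks between
SF expression and event PSI across samples (pairs with missing PSI
dropped per pair, minimum 4 complete samples). P-values use the
t-approximation by default; an exact permutation p (full enumeration, n
<= 8) is available for the study's n = 6 regime — note that at n = 6 the
smallest two-sided exact p is 2/720, which BH at realistic family sizes
cannot push below 0.05, so the exact mode is for single-pair inference,
not network screening. The BH family is all pairs actually tested
(constant vectors are skipped and counted). Edges require |rho| >= 0.9
and padj < 0.05; "|rho|" because repressive and activating factors are
both of interest (a positive-only toggle exists). Per-SF degree ("hub")
tables are reported; exports are GraphML and SIF with role/type/DE node
attributes.

With n = 6 the rho grid is coarse and mid-rank tie handling materially
affects results; ties are averaged, and that convention is fixed and
stated rather than configurable.

# The synthetic-data generator

`simulate_dataset()` emulates the targeted study design: 2 conditions x 3
biological replicates, paired IP/input MeRIP libraries. Per gene it
plants exactly one known AS structure (or two cassettes, or none), so the
truth catalogue is a constructive by-product rather than a re-derivation:

* junction counts: total `n ~ Poisson(depth_per_event)` per event and
  sample, inclusion `I ~ Binomial(n, q(psi))` with the same PSI-to-read
  proportion map the estimator inverts — so `estimate_psi` is unbiased by
  construction;
* gene counts: negative binomial around
  `baseline x length x library factor x 2^(log2FC x condition)`, with the
  dispersion a knob whose zero limit is Poisson;
* MeRIP bins: NB input counts, IP counts at background (1x), constitutive
  peak (`2^merip_base_log2`, default 4x), or differential peak
  (`2^(base + condition x planted_m6a_log2fc)`) enrichment; differential
  peaks are preferentially planted on cassette exons of differential SE
  events, which is what makes the SE-DMAS quadrant truth exact;
* SF expression: `log2 expr = a + b x PSI_sample + N(0, noise)` with
  alternating slope signs, appended as continuous FPKM-scale rows —
  continuous so that the zero-noise Spearman rho is exactly +/-1 (integer
  rounding could create ties and break the invariant).

One global seed feeds per-stage sub-seeds, so adding a stage never
perturbs earlier streams and identical configurations are bit-identical
(including the GTF byte stream). Defaults (depth 100 junction
reads/event, 100/bin MeRIP input, dispersion 0.05, delta-PSI 0.3, m6A
log2FC 2, DE log2FC 2) are chosen once for desk-scale test power: they
represent a well-powered bulk experiment, not any particular public
dataset.

What the generator does **not** emulate — and therefore what green tests
do not establish about real data: read-level artefacts (mapping bias, GC,
duplicates), between-replicate biological PSI variability (per-sample
true PSI equals the condition value, which is exactly what makes the
pooled LRT's null calibration checkable), correlated genes, isoform-level
expression structure, realistic sequence content (beyond what the RRACH
scanner needs), and a full-scale tissue census (tens of thousands of
events from hundreds of millions of reads). Published headline counts
are used only as printed arithmetic inputs, never as simulation targets.

# Numerical choices and degenerate inputs

* Percentages in catalogue summaries: two decimals, round half to even
  (the convention matching the published "84.32%" precision);
  intersection shares: one decimal.
* `0 log 0 = 0` in the binomial log-likelihood; proportions clamped to
  `[1e-12, 1 - 1e-12]`; LR statistics floored at 0.
* Wald test: pseudocount 0.5 on condition means guards zero-mean genes;
  dispersion trend coefficients floored at (1e-8, 0).
* Zero-depth samples yield I = S = 0 and a missing PSI, flagged by the
  coverage floor, not an error; zero-input MeRIP bins give `Inf`/0 folds
  deterministically and are never divided blindly.
* Quantiles: type 7 exclusively; boundary genes at Q1 = Q3 go to `high`
  by stated precedence.
* All tabular outputs carry a header comment declaring their coordinate
  convention; the report JSON is validated against a bundled schema and
  is byte-identical across reruns of the same config (no timestamps).

# Problem sizes used by the test and acceptance suites

Simulated designs use 60–200 genes, the 2x3 design, and the default
depths above; power and calibration are measured over 10–50 seeds per
property (differential PSI power over 50 seeds; null calibration over
10–20 seeds x 1000–2000 genes; peak recovery over 10 seeds; quadrant
exactness at depth 1000 over 3–5 seeds). These sizes were chosen as the
smallest at which the binomial/NB standard errors make the stated
thresholds (power >= 0.90, null flagged fraction <= 0.075, recovery >=
0.90) comfortably decidable, and they keep the full suite in the
low minutes on one CPU.
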