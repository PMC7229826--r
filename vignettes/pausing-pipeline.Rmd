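---
title: "Spike-in normalized analysis of promoter-proximal pausing: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spike-in normalized analysis of promoter-proximal pausing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spikepause)
```

# The problem

In metazoans, RNA polymerase II frequently initiates and then pauses
20–60 bp downstream of the transcription start site; release of this
promoter-proximal paused polymerase into productive elongation is a major
regulated step.  Nascent-transcription assays such as PRO-seq map the 3'
end of each nascent RNA — the exact position of an engaged polymerase — at
base resolution, so a gene's regulatory state can be read from where its
signal sits: piled at the pause site, or spread through the gene body.

Two quantitative complications motivate this package.  First, a treatment
that perturbs chromatin globally (an HDAC inhibitor, for instance) can
shift *total* nascent transcription, and any normalization that divides by
library size silently removes exactly the effect under study.  The remedy
is a spike-in: a fixed amount of foreign-genome material added to every
sample, so that cross-sample scale can be recovered from reads mapping to
the foreign genome alone.  Second, the interesting signal is a *shift*
of reads between small windows (pause region versus gene body), which
requires strand-aware, single-base window arithmetic that is easy to get
wrong by one base.  The package fixes one convention and uses it
everywhere: genomic coordinates are 0-based half-open (BED semantics);
gene-relative coordinates are 1-based with no position 0 (TSS = +1, the
base upstream is -1), mirror-mapped on the minus strand, so the window
-50..+100 spans exactly 150 bases.

# Quantities computed

**Window counts and TPM.**  For a gene with canonical transcript of length
$L$ (canonical = longest CDS; ties broken by transcript length, then by
smallest transcript id), the pipeline counts 3' ends in the promoter window
$-50..+100$ and the body window $+500..L-100$.  Counts are converted to a
per-region density, reads per kb per million primary-genome mapped reads:
$$\mathrm{TPM} = \frac{C / (\ell/1000)}{N / 10^6},$$
with $C$ the window count, $\ell$ the window length and $N$ the sample's
primary (non-spike) read total.  This per-region density is both depth-
and length-invariant, which is what the ratio below requires.  Genes with
mean $\log_2(\mathrm{TPM}+1) > 3$ over samples are called expressed; the
+1 pseudocount keeps all-zero genes finite (and excluded).

**Pausing index.**  $\mathrm{PI} = \mathrm{TPM}_{-50..+100} /
\mathrm{TPM}_{+500..L-100}$.  Higher PI means proportionally more
polymerase held at the pause site.  When the body density is zero the PI
is flagged undefined rather than infinite.  A variant with the body window
running to the TES itself is available (`body_tes_offset = 0`) because both
window conventions circulate in the literature; the `+500..L-100` form is
the default.  Genes shorter than 700 bp are flagged and excluded from PI
and body statistics — 700 is the smallest length for which the body window
is at least 100 bp wide.

**Differential testing.**  Feature counts (gene bodies, ChIP peaks, ATAC
peaks — the same machinery serves all three) are modelled as
$$K_{ij} \sim \mathrm{NB}\!\left(\mu_{ij} = s_j\, m_{g(j)},\;
\mathrm{Var} = \mu + \alpha_i \mu^2\right),$$
with $s_j$ the per-sample size factor and $g(j)$ the condition.  Spike-in
size factors are each sample's spike total divided by the geometric mean
of spike totals, so their logs sum to zero.  The reported effect is
$\log_2(\hat m_T/\hat m_C)$ with a two-sided normal Wald p-value, BH FDR
across tested features, and the class labels *up*/*down* (FDR < 10%),
*unchanged* (FDR > 50%), *indeterminate* (between), *untested* (all-zero).

**Estimating equation, not offset-IRLS.**  Group means are estimated as
arithmetic means of normalized counts $K_{ij}/s_j$ — the solution of the
NB estimating equation with equal weights within a condition.  Two
properties motivated this choice over the weighted (offset-IRLS) maximum
likelihood fit.  First, invariance: multiplying any sample's counts and
its spike total by a constant rescales all normalized counts by a common
factor, so every fold change is *exactly* unchanged; the weighted MLE
shifts by order $\alpha$ times the replicate disagreement because the
rescaled sample's NB weight changes relative to its replicate.  A
normalization claim that holds exactly is easier to audit than one that
holds to within an uncontrolled approximation.  Second, transparency: the
estimator is closed-form, and whenever size factors are equal within each
group it coincides with the Poisson/NB GLM solution, so closed-form GLM
oracles validate it directly.  The price is a small efficiency loss when
size factors differ strongly within a group; at the factor spreads
spike-ins produce (typically within ±30% of 1) it is negligible.

**Dispersion.**  With two replicates per condition there are only two
residual degrees of freedom per feature, so the per-feature
method-of-moments estimate
$\hat\alpha_i = (v_i - \bar\mu_i \overline{1/s})/\bar\mu_i^2$ (within-
condition residual variance $v_i$ on normalized counts) is extremely
noisy and negative for a large fraction of features.  The estimate is
stabilized in two steps: a mean–dispersion trend $a/\bar\mu + b$ is fit
across features by least squares, and each feature's dispersion is the
log-scale blend $\exp(w \log \alpha_{\mathrm{trend}} + (1-w)\log
\hat\alpha_i)$ with $w = 0.5$, where $\hat\alpha_i$ is first floored at
the trend.  The floor makes shrinkage one-sided: a feature can be *more*
dispersed than the trend but never less.  This matters: flooring at a
tiny constant instead lets the blend drag dispersions toward zero for the
many features whose raw estimate is negative by chance, and the resulting
near-Poisson tests badly overstate significance at this design size.
With the one-sided floor, the null fraction of $p < 0.05$ sits in the
0.04–0.05 range and BH at 10% makes essentially no false calls on null
data (both properties are measured in the test suite).  A group whose
counts are all zero has its mean floored at half a read so that the fold
change is large but finite and the standard error honestly wide.

**Metagene profiles and window tests.**  Signal is averaged on a grid of
TSS-relative offsets, scaled by size factor, replicates averaged within
condition; offsets past a gene's end are masked and excluded from means.
The paired comparison between conditions sums each gene's signal over a
window (+1..+70 for the pause site, +70..+200 for the early body; the
shared boundary belongs to both, following the printed window notation)
and applies a two-sided paired t-test across genes.  Sums rather than
means are used as the per-gene statistic — equivalent up to a constant
for a fixed window — and replicates are averaged before pairing, making
the gene the pairing unit.  When all per-gene differences are equal the
statistic is undefined and flagged degenerate instead of fabricating a
p-value.

**Peak operations.**  Interval work uses half-open arithmetic with
overlap meaning at least one shared base: merging peak sets never joins
book-ended intervals; blacklist filtering drops any peak overlapping any
blacklist interval; promoter assignment attaches a peak to a gene when it
overlaps $[\mathrm{TSS}-1\,\mathrm{kb}, \mathrm{TSS}+1\,\mathrm{kb})$ and
keeps the peak with the largest $|\log_2 \mathrm{FC}|$ per gene.
Enhancers are peaks whose *summit* lies more than 100 bp from every TSS —
the summit is the sharper anchor; an edge-distance mode exists for
comparison.  Chromatin-feature matrices are standardized per feature
(z-scores, sample SD; constant features yield zeros and a flag) so that
assays of different affinity can be averaged over gene sets.

**qPCR arithmetic.**  Relative expression uses $\Delta\Delta C_t$ with
efficiency fixed at 2 and averaging done in $C_q$ space across
replicates.  ChIP-qPCR enrichment is divided by the arithmetic mean of
designated intergenic background loci, then (when provided) by the
identically-normalized histone H3 value at the same locus.  The
arithmetic mean of backgrounds is the plainest reading of background
correction; with a single background locus the two conventions coincide.

# The synthetic experiment

Downstream stages are exercised against a generator whose defaults *are*
the study conditions of the test suite.  Per gene, initiation rate $I_g$
is log-normal and pause-release probability $r_g$ is Beta-distributed;
steady state puts pause occupancy proportional to $I_g/r_g$ and body
occupancy proportional to $I_g L_g r_g/(r_g+t)$ with termination weight
$t$.  Treatment multiplies $r_g$ by $f$ (capped at 1) at target genes
only: signal leaves the pause window and enters the body, which is the
pause-release signature the pipeline is designed to detect.  Window
counts are NB with dispersion $\alpha$; pause reads land uniformly in
+20..+60 (inside the canonical pause region), elongation reads uniformly
from +61 to $L-100$ so the early gene body carries the released
polymerases while the differential window +500..$L-100$ sees a clean
body signal.  Spike reads are Poisson with mean $S\lambda_j$: spike
*abundance* is condition-independent, but each sample's depth distortion
$\lambda_j$ scales spike and primary reads alike — that is precisely why
spike totals recover cross-sample scale, and the simulated ChIP branch
shows the converse: under a global gain with compensating depth
distortion, library-size factors erase the gain while spike factors
recover it.

Default conditions, chosen as a desk-scale rendering of a typical
spike-in nascent-transcription study: 500 genes (50 targets), 2
replicates per condition, $f = 3$, $\alpha = 0.05$, 1.5 million primary
reads per sample (about 3,000 reads per gene, matching the per-gene depth
of a 20–40M-read library over ~6,000 expressed genes), spike base 50,000
reads, depth distortion log-normal with $\sigma = 0.15$, gene lengths
log-normal around 4 kb (minimum 700 bp, shorter draws redrawn and
logged).  Non-target release probabilities follow Beta(2, 3); targets
follow Beta(1, 15) — responders are the *most highly paused* genes, an
order of magnitude more paused than average.  The termination weight
$t = 1$ reflects that premature termination competes effectively with
release at stably paused genes, putting typical release efficiency
$r/(r+t)$ near 0.26 for non-targets and 0.06 for targets.  The null and
calibration suites use 2,000 genes with no targets; Monte-Carlo
properties run over 20 fixed seeds (10 in the acceptance script).  These
problem sizes are the package's chosen study scale.

What the generator does *not* emulate — and hence what passing tests do
not establish about real data: base-composition or mappability bias,
fragment-length effects, replicate batch structure, correlated genes,
peak-calling uncertainty, or annotation error.  Counts at two genes are
independent given the configuration, so the FDR behaviour measured here
is the independent-features case.

# Degenerate inputs and numerical conventions

All-zero features are reported `untested` rather than fitted; p-values of
untested features are excluded from the BH denominator.  Zero spike
totals are an error with advice (pseudo-count or exclusion) rather than a
silent factor of zero.  Ties in canonical-transcript selection and in
largest-change peak assignment are broken deterministically (documented
order), so runs are reproducible byte-for-byte from a seed, which the
test suite asserts by hashing written files.  bedGraph output merges runs
of equal scaled value, omits uncovered bases, and survives a write/read
round trip exactly at 9 significant digits.  The dispersion floor
constant is $10^{-8}$ and exists only to protect logarithms.

# Limitations

The Wald reference is normal; at two replicates per condition the test
leans on the one-sided dispersion floor for calibration, and designs with
a single replicate per condition are fit but their p-values should not be
trusted.  The differential module covers two-group contrasts only — no
multi-factor designs, continuous covariates, or outlier replacement.
Isoform-aware quantification is out of scope: one canonical transcript
represents each gene.  The spike-in convention is a chromosome-name
prefix, so mixed-genome alignment artifacts (reads mapping to both
genomes) are outside the model.
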