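---
title: "Detecting seasonally methylated cytosines: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting seasonally methylated cytosines: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(semseason)
library(dplyr)
```

## The problem

Plant DNA methylation occurs in three sequence contexts — CG, CHG and CHH
(H = A, C or T), read from the two bases downstream of the cytosine on its
own strand — and is, on the whole, a stable epigenetic mark. Whole-genome
bisulfite sequencing of the same clonal individual at several time points
across a year makes it possible to ask which individual cytosines
nevertheless change with the seasons. `semseason` implements the full
analysis around that question:

* per-cytosine detection of *seasonally methylated cytosines* (SeMCs)
  across T sampling dates, with genome-wide false-discovery control;
* genome-scale summaries: bulk levels per context and date, 100-kb windowed
  levels against repeat density, per-repeat seasonal series, and bisulfite
  conversion-rate estimation from an unmethylated spike-in;
* the association between gene-body CG methylation (gbM) and the seasonal
  *average* and *range* of RNA expression;
* a fully seeded synthetic methylome generator with planted ground truth,
  used for every calibration and recovery test in the package.

All user-facing functions take and return tibbles, so results chain with
the usual dplyr verbs.

## The SeMC statistic

At one cytosine with methylated/unmethylated counts $(m_t, u_t)$ at dates
$t = 1, \dots, T$, a SeMC is a site that is differentially methylated
between *at least two* dates. The site statistic is

$$p_{\min} = \min_{i < j} \; p_{\text{Fisher}}\!\left(
\begin{bmatrix} m_i & u_i \\ m_j & u_j \end{bmatrix}\right),$$

the minimum over all $\binom{T}{2}$ date pairs of the two-sided Fisher
exact p-value (tail defined, as in `stats::fisher.test`, as the sum of
hypergeometric probabilities no larger than the observed table's, with
relative tolerance $10^{-7}$ for ties). A date enters a pair only if its
total coverage reaches `min_cov` (default 5); a site with no testable pair
is excluded rather than assigned $p = 1$. The inner loop is compiled (Rcpp
with a cached log-factorial table) because a genome-scale run performs
millions of exact tests.

False discovery is controlled within each context separately by Storey
q-values computed on the per-site statistics: $\hat\pi_0$ is estimated on
the grid $\lambda = 0.05, 0.10, \dots, 0.95$ with a cubic smoothing spline
evaluated at $\lambda = 0.95$ and clipped to $(0, 1]$, and
$q_{(i)} = \hat\pi_0 \, m \, p_{(i)} / i$ with cumulative minima enforced
from the largest p downward. A site is called a SeMC when
$p_{\min} < \alpha$ (default 0.001) *and* $q < q_{\max}$ (default 0.2).

### Calibration of the minimum-p statistic

Under the null, $p_{\min}$ is the minimum of 28 dependent valid p-values
and is therefore stochastically *smaller* than uniform. This has a concrete
consequence we measured on pure-null simulations (coverage 20, $5 \times
10^4$ CG sites): the null $p_{\min}$ distribution has almost no mass above
$\lambda = 0.95$, so $\hat\pi_0$ collapses toward 0, q-values collapse with
it, and roughly 1% of null sites end up flagged. The estimate does not
absorb the multiplicity — it amplifies it.

The package therefore exposes two modes:

* `correction = "none"` (default): the literal minimum-p pipeline. Use it
  to mirror the reference analysis; its call counts should be read as
  anti-conservative.
* `correction = "sidak"`: $p' = 1 - (1 - p_{\min})^{\#\text{pairs}}$ per
  site before the q-value step. On the same null simulations this mode
  leaves the q < 0.2 call set empty in 19/20 replicates, and with 10%
  planted SeMCs (amplitude 0.4, coverage 20) its empirical FDR at
  q < 0.2 is about 8%, comfortably under the nominal 20%. Every assertion
  about error rates in the test suite runs in this mode. The $\alpha$ gate
  always applies to the raw $p_{\min}$, matching the statistic's
  definition.

An omnibus alternative (`method = "omnibus"`, a G-test on the full
$2 \times T$ table of coverage-passing dates) is available behind a switch;
the pairwise minimum remains the default because it is the closest literal
reading of "differently methylated between at least two time points".

Peak timing is the date of the maximum raw per-date ratio (no smoothing);
exact ties go to the earliest date and are flagged. Genomic location uses
the precedence exon > intron > intergenic. Seasonal profiles of the called
SeMCs can be ordered by average-linkage clustering under correlation
distance $d = 1 - r$ (zero-variance profiles get $d = 1$ to all others),
with the dendrogram exported as Newick text.

## Genome-scale summaries

Every methylation level in the package is the *pooled* ratio
$\sum m / \sum (m + u)$ over the chosen site–date observations, never a
mean of per-site ratios; a region with no calls is undefined (`NA`), never
zero. Windows tile each sequence at a fixed width (default 100 kb, last
window truncated); a site belongs to the window containing its 0-based
position, so window site counts add exactly to the genome total. Repeat
density merges overlapping repeats before counting covered bases. The
conversion rate is one minus the pooled level on the spike-in contig,
per date.

## gbM and expression stability

Gene-body methylation is the pooled CG level over the full annotated gene
span (introns included; `exon_only` switches to exons), computed per date
and then averaged across dates — gbM is seasonally stable, and the per-date
output (`per_date = TRUE`) lets that stability be inspected directly.

Expression enters as log2(RPM + 1) per gene and date. The seasonal
*average* is the arithmetic mean across dates; the seasonal *range* is
max − min of a centred moving average of the date-ordered series
(window 3 by default, truncated at the edges; window 1 disables smoothing
and reduces the range to the raw max − min). The exact smoothing recipe of
the upstream two-year weekly series is not restated in the source this
package follows, so the windowed max − min stands in as the obvious robust
choice; it is configurable and flagged as an approximation.

Expressed genes (average > 1.0) are split into five bins at the
20/40/60/80 gbM percentiles (boundary ties go to the lower bin). All ten
pairwise two-sided Mann–Whitney tests are Holm-adjusted (valid without
independence assumptions; Bonferroni/BH are available) at $\alpha = 0.01$,
and a compact letter display is built by insert-and-absorb so that bins
sharing a letter are not significantly different. The monotone trend is
summarised by the Spearman rank correlation between gbM and range across
genes.

## The synthetic-data generator

The generator emulates the statistical structure of the study, not its
sequences. Defaults encode the study conditions; they are fixed once and
are not tuning knobs.

* **Sampling design**: 8 dates at ~1.5-month intervals from mid-November
  to early September.
* **Genome**: random contigs (default 4 × 150 kb, GC 0.36) in alternating
  25-kb blocks — "heterochromatic" blocks with ~60% repeat bases, "genic"
  blocks with ~5% — plus genes (0.9–2.5 kb, 2–4 exons) placed in
  repeat-free parts of genic blocks, and a 20-kb unannotated spike-in
  contig.
* **Methylation**: per-context baselines CG 0.45, CHG 0.20, CHH 0.06;
  additive repeat boosts (0.40/0.40/0.15) create the methylation–repeat
  coupling; CG sites inside a gene take the gene's planted gbM level
  (Beta(2.25, 2.75), mean matched to the CG baseline so gene bodies do not
  shift the genome-wide CG level).
* **SeMCs**: a small fraction of sites (default 0.5%, matching "less than
  0.5% of cytosines") receive a raised-cosine seasonal bump
  $A \cos^2(\pi d / w)$ for circular day-distance $d < w/2$ from a planted
  peak date, with default amplitude 0.4 and width $w = 135$ days (one
  season). A full-year cosine was rejected at design time: with samples
  45 days apart its peak-versus-neighbour contrast is smaller than binomial
  noise at realistic coverage, so the peak month would be unidentifiable by
  construction, defeating the generator's purpose. The bump amplitude is
  shrunk into the $[0,1]$ headroom rather than clipped, so the planted peak
  stays the unique maximum. Peak dates are biased (default 50%) toward a
  context-specific modal month — July for CG, March for CHG, September for
  CHH — and CHH SeMCs are planted only in intergenic repeats by default,
  emulating their observed concentration there.
* **Counts**: depth ~ Poisson(`coverage_mean`, default 20), methylated
  calls ~ Binomial(depth, p). This is the simplest model under which the
  Fisher test is correctly calibrated, which is what makes the type-I-error
  tests meaningful. Incomplete bisulfite conversion flips unmethylated
  calls at rate 0.005 (spike-in conversion ~99.5%, matching the ">99%"
  regime); the spike-in's true level is exactly 0.
* **Expression**: per gene,
  $\log_2(\mathrm{RPM}+1) = \mu(g) + A(g)\cos(2\pi(\mathrm{doy}-\phi)/365)
  + \varepsilon$, with amplitude $A(g) = 1.5\,(1 - c\,g)$ decreasing in the
  gene's gbM $g$ (coupling $c$, default 0.7), mean increasing weakly in
  $g$, gene-specific uniform phase, Gaussian noise (sd 0.2), floored at 0.
  One gene carries a planted intronic repeat whose CHH methylation peaks in
  March while the gene's expression runs in anti-phase — the
  seasonally-expressed-locus motif used by `feature_association()`.

The planted gbM is drawn in the methylome stage (so planted gene-body
counts and expression coupling share one truth value) and the expression
stage consumes it, drawing fresh values only for genes without one.

What the generator does *not* emulate: per-site baseline heterogeneity
(real methylomes are bimodal per site, not uniform at the context
baseline), read-level errors and mapping bias, biological replicates,
linkage between neighbouring sites, and SNP variation. Passing the
recovery tests therefore shows the estimators and error control are
correct under the stated sampling model, not that the pipeline is robust
to artefacts absent from that model.

## Numerical and design choices

* Internal coordinates are 0-based half-open everywhere; GFF3, BED and
  cytosine reports are converted at the file boundary. CG sites are *not*
  merged across strands — each cytosine is an independent analysis unit.
  Sites whose trinucleotide runs off the sequence end or contains an
  ambiguity base get no context and are excluded from all analyses.
* Missing (site, date) coverage is encoded as (0, 0) and handled by the
  coverage filter, never imputed.
* The coverage filter (`min_cov = 5`) is a package choice: Fisher tests on
  near-zero counts are uninformative and inflate eligible-site counts. The
  reference analysis states no filter, which is one reason its absolute
  SeMC counts are not reproducible.
* Quintile boundary ties go to the lower bin; an all-equal gbM vector is an
  error (quintiles undefined), not an arbitrary split.
* Degenerate inputs are answered with errors or flags, not silent zeros:
  zero-variance window levels make the window correlation an error,
  constant methylation makes a feature association `NA` with a flag, a
  fully tied Mann–Whitney pair gets p = 1.
* `run_pipeline()` writes every inter-stage artifact to disk, so any stage
  can be deleted and rerun from the upstream files; a fixed-seed rerun is
  byte-identical, and the JSON manifest records package version, config
  hash, seed and per-stage row counts.

## Problem sizes used in the tests

The shipped test suite and acceptance checks run entirely on generated
data at desk scale, chosen as the smallest sizes at which the statistical
assertions are well-powered: null calibration on $5 \times 10^4$ CG sites
across 20 seeded replicates, FDR control on $2 \times 10^4$ sites with 10%
planted SeMCs across 10 seeds, peak recovery on ~2,000 detected SeMCs,
estimator recovery on ~200-kb genomes and 60 genes, and the gbM–stability
contrast on 130 genes across 20 replicates per coupling setting.

## Worked example

```{r example, eval = FALSE}
library(semseason)
library(dplyr)

cfg <- simulation_config(seed = 1)
sim <- simulate_dataset(cfg)

# genome-scale profile
bulk_levels(sim$series, exclude_seq = "spike_lambda")
conversion_rate(sim$series)

# SeMC detection (calibrated mode) and downstream views
res <- detect_semcs(sim$series, sim$annotation,
                    exclude_seq = "spike_lambda", correction = "sidak")
semc_counts(res)
location_breakdown(res)
autoplot(res)

# gbM vs expression stability
gbm  <- gene_body_methylation(sim$series, sim$annotation)
bins <- quintile_bins(gbm, seasonal_summary(sim$expression))
groupwise_tests(bins)
glance(association_analysis(bins))
```

## Known limitations

* The reference study's absolute SeMC counts depend on unreported coverage
  filters and the deposited sequencing reads; the package reproduces the
  method, and all quantitative validation is against planted synthetic
  truth.
* The literal minimum-p mode is anti-conservative by construction (see
  above); calibrated error rates require the Šidák mode.
* The smoothed max − min seasonal range is a stand-in for the upstream
  study's unpublished recipe.
* Clustering all SeMCs is quadratic in their number; the pipeline caps the
  dendrogram at a seeded subsample (default 2,000 profiles).
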