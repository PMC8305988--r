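---
title: "The genomic fabric model: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The genomic fabric model: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gfabric)
```

# The model

`gfabric` characterizes each gene of a replicated, multi-region
transcriptome by three coordinates computed from the same spot-level
expression values:

* **AVE**, the average expression level: the mean over a gene's redundant
  spots of the mean over the J biological replicates. Regions are
  typically put in *median-gene units* (`median_units = TRUE`), i.e. all
  values are divided by the median gene's AVE, which makes levels
  comparable across regions and makes AVE-derived quantities invariant to
  the overall fluorescence scale.
* **REV**, the relative expression variability: a pooled coefficient of
  variation across replicates, corrected by the mid-point of the
  chi-square confidence estimate of a CV,
  $$\mathrm{REV}_i \;=\; \underbrace{\tfrac12\!\left(
  \sqrt{\tfrac{r}{\chi^2_{0.975}(r)}} +
  \sqrt{\tfrac{r}{\chi^2_{0.025}(r)}}\right)}_{\text{correction, } \to 1
  \text{ as } r \to\infty}
  \;\sqrt{\tfrac{1}{R_i}\sum_k \left(\tfrac{s_{ik}}{\mu_{ik}}\right)^2}
  \times 100\%,$$
  with $r = J R_i - 1$ degrees of freedom, $\mu_{ik}, s_{ik}$ the mean
  and (J−1)-denominator SD of spot $k$ across replicates. The correction
  inflates small-replicate CVs (2.148 at $r=3$, 1.098 at $r=43$) so that
  redundantly probed genes are not unfairly advantaged — and it is what
  keeps the variability ranking stable (see *Why the estimator details
  matter* below).
* **COR**, the expression correlation of two genes: the Pearson
  correlation of their *spot-averaged* replicate profiles (length J).

The assumption behind COR and everything built on it is that biological
replicates are perturbed instances of the same system: genes that must
act in stoichiometric proportion fluctuate together (synergism), genes in
competing programs fluctuate oppositely (antagonism), and unrelated genes
fluctuate independently.

On top of these coordinates:

* the **gene commanding height**
  $\mathrm{GCH}_i = \frac{\langle REV\rangle}{REV_i}\,
  e^{4\,\overline{COR^2_{ij}}}$ ranks genes by how tightly they are
  controlled *and* how broadly they are coordinated; the rank-1 gene is
  the region's **gene master regulator** (GMR);
* the **composite regulation criterion** calls a gene regulated between a
  region and the reference when the signed expression ratio exceeds a
  variability-dependent cut-off
  $CUT = 1 + \sqrt{2(REV_{ref}^2 + REV_{reg}^2)}/100$ *and* a
  Bonferroni-corrected heteroscedastic (Welch) test gives p < 0.05;
* the **weighted individual regulation**
  $WIR = AVE_{ref}\,\mathrm{sign}(x)(|x|-1)(1-p)$ grades contributions
  continuously, and the pathway mean of $|WIR|$ is the **WPR**.

# Pairwise coordination and its significance

Significance of a correlation on J paired replicate values uses the
t-transform with J − 2 degrees of freedom. At J = 4 and α = 0.05 the
two-sided boundary is |COR| = 0.950 to three decimals, which is the
threshold quoted throughout the outputs. An *independence band*
(default |COR| ≤ 0.05) declares a pair independent; pairs that are
neither significant nor near zero stay *undecided*. The band is a
declared convention — nothing in the underlying test defines "significant
independence" — and is configurable everywhere it is used.

# Design choices in genuinely open places

**The pooled correlation form.** The literal pooled double-sum form of
COR (cross-spot deviation products over per-gene sums) is not bounded by
1 for redundantly probed genes and does not give COR(g, g) = 1, which
contradicts the self-correlation sanity check the method itself relies
on. The package therefore correlates spot-averaged profiles by default —
this reduces exactly to the pooled form when both genes have a single
spot — and retains the literal form behind `mode = "literal"` for
comparison.

**Normalization.** The stated target is classic: bring every replica
array to the median background-subtracted fluorescence of all spots.
The naive implementation — matching each array's *marginal* median —
injects a per-array scale error on the order of the sample-median noise
(about 1–2% at a few thousand spots). That error is shared by every gene
on the array and becomes a hard floor under REV, destroying exactly the
ultra-stable genes (REV « 1%) the hierarchy depends on. `gfabric`
therefore estimates the per-array factors from *paired spot-wise ratios*
to the per-spot geometric-mean reference (the median-of-ratios estimator
familiar from sequencing size factors), which is several-fold less noisy
at the same array size, and then re-anchors the grand median so the
stated normalization target still holds. Convergence is declared when
the factors change by less than `tol = 1e-6` (two rounds in practice;
`max_iter = 100`).

**Signal floor.** The background-subtracted signal is floored at
`epsilon = 1` fluorescence unit so logs and ratios stay finite; spots
with fg < 2·bg have already been removed by the quality filter at that
point, so the floor only touches pathological inputs.

**Bonferroni over redundant spots.** The gene-level p is
`min(1, R · min_k p_k)` over the per-spot Welch tests — the most
conservative reading of "Bonferroni over redundant spots". The same
corrected p feeds the WIR, keeping the two regulation measures
consistent.

**WPR.** The pathway-level aggregate averages |WIR| (magnitudes), the
reading consistent with reporting WPR as a positive size; signed
averaging is available via `signed = TRUE`.

**Ties in the hierarchy.** Equal GCH scores are ordered by lower REV,
then alphabetically, so reruns are bit-identical.

**Degenerate inputs.** Zero-variance profiles yield flagged `NA`
correlations (never silent zeros) and "undecided" coordination; REV = 0
genes are excluded from the GCH ranking with a warning (infinite
transcription control); genes absent from one region of a contrast are
flagged not-comparable and excluded from pathway percentages.

# What the synthetic generator emulates — and what it does not

`generate_study()` draws, per region, replicate gene levels from a
log-normal model: gene *i* in replica *j* has
$a_{ij} = m_i \exp(\sigma_i \zeta_{ij} - \sigma_i^2/2)$ with
$\sigma_i^2 = \log(1 + cv_i^2)$, so means and CVs are exact by
construction. Within-module coordination is induced by a shared
per-replica latent factor per module:
$\zeta = \sqrt{w}\, z_{\text{module},j} + \sqrt{1-w}\,\varepsilon$,
giving log-scale correlation $w$ (the level-scale correlation is slightly
lower for large CVs). This latent-factor construction is positive
semidefinite by construction and costs O(genes), which is what makes
10,000-gene studies routine.

Key default conditions:

* 4 regions × 4 replicates; ~10% of genes probed by 2–11 spots.
* Per-gene CVs: log-normal, median 15%, spread 0.8 on the log scale,
  truncated to [5%, 190%]. The thin low tail is deliberate: the
  ultra-stable extreme (≈ 0.3%) is carried by the planted master
  regulators, mirroring how the most stable gene of a real region sits
  far below the bulk. Median REVs of generated regions land in the
  10–35% range typical of replicated tissue regions.
* The planted GMR: CV 0.3%, membership in the largest correlated module
  (only in its own region; elsewhere it gets a median CV and no module),
  probed by 11 spots.
* Planted regulation: 40 genes per non-reference region at signed
  fold 4, CV 5% in both regions.
* Records: background uniform in [20, 60] a.u., foreground =
  background + signal, 1% of records flagged corrupted (planted genes
  kept clean so the ground truth stays defined), a handful of control
  spots with empty gene symbols.

**Spot redundancy.** Each spot carries a fixed multiplicative affinity
factor (CV 2%, constant across replicates — a probe property), and the
*idiosyncratic* part of the replicate noise is drawn independently per
spot. The second point matters: if redundant spots were exact noisy
copies of one shared gene draw, the pooled CV of an 11-spot gene would
still fluctuate with only 3 effective degrees of freedom while enjoying
the 11-spot correction coefficient — a combination that lets ordinary
genes collapse below the planted regulator by chi-square luck. Drawing
the idiosyncratic component per spot realizes the `r = 4R − 1`
degrees-of-freedom model that the REV estimator assumes. The module
component stays shared across a gene's spots, so spot-averaged profiles
keep the gene-level correlation structure.

What the generator does *not* emulate: scanner physics, dye bias,
spatial artifacts, intensity-dependent (curved) normalization bias,
probe cross-hybridization, and cell-type mixture effects. Passing the
recovery tests therefore shows the pipeline is correct and well-behaved
under its own model assumptions — not that those assumptions hold for
any particular real array.

# Problem sizes and numerical checks

The test suite exercises the pipeline at the sizes a single CPU handles
in seconds: ground-truth recovery uses 20 studies of 2,000 genes
(master-regulator rank-1 recovery), a 10,000-gene two-region null for
the composite criterion's type-I control (≤ 6% flagged), 10,000 genes
for the mutual independence of AVE/REV/COR (all pairwise |r| < 0.05),
and 200-gene instances for oracle equivalence, where the blocked
correlation accumulation must match naive per-pair loops to 1e-9
relative (1e-12 for individual correlations). Full-matrix statistics are
computed in row blocks (default 512 genes) so the gene-by-gene matrix is
never materialized; at 15,000 genes the mean-squared-correlation pass
costs a few seconds and O(block × genes) memory.

One reformulated check: for two genes in disjoint independent modules,
the similarity of their coordination profiles is, at J = 4, essentially
the two genes' own sample correlation — a quantity with a wide null
spread — so the suite tests the property as symmetry around zero across
independent studies together with a same-module positive control,
rather than as a small bound on a single pair.

# Known limitations

* Four replicates give very coarse correlation estimates; every
  pairwise classification (|COR| > 0.95) carries the full weight of that
  small n. The package reports n alongside every coordination record.
* The chi-square CV interval underlying the REV correction assumes
  approximate normality of replicate values; for CVs approaching 1 the
  log-normal reality departs from it, and sample CVs at J = 4 are
  noticeably biased downward there (the generator's moment-recovery test
  is therefore asserted on the well-conditioned CV range).
* Median-of-ratios factors still leave a shared residual scale noise of
  a few tenths of a percent at a few thousand spots per array; REVs
  below that level are only measurable for redundantly probed genes.
* The overexpression forecast is a sign prediction on the coordinated,
  regulated panel; it makes no claim about effect sizes or phenotype.
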