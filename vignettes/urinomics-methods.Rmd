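---
title: "Methods: urinary biomarker discovery, targeted validation and screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: urinary biomarker discovery, targeted validation and screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(urinomics)
```

## The problem

Preeclampsia alters the urinary proteome well before clinical onset, which
makes urine an attractive, non-invasive matrix for screening biomarkers. Two
features of this setting shape every statistical choice in this package:

* **Proteinuria is a global confounder.** Preeclamptic kidneys leak protein,
  so *every* protein's measured intensity tends to rise in case urine. A
  naive per-protein fold-change test would call most of the proteome
  "regulated". The analysis must separate *relative* regulation from the
  bulk shift.
* **Biomarker studies are staged.** An untargeted label-free (LFQ) discovery
  stage with ~1000 quantified proteins and a dozen subjects per arm feeds a
  targeted (parallel reaction monitoring, PRM) validation stage on ~20
  candidate proteins, which feeds a longitudinal screening evaluation with
  ROC curves. Each stage has its own data type and error model.

`urinomics` implements all three stages plus a synthetic-data generator that
emulates the statistical structure the analysis assumes, with planted ground
truth, so that the whole pipeline is testable without patient data.

## Discovery stage

### Fold changes and the centered z-score

For each protein the log2 fold change is the difference of observed group
means of log2 intensity (available-case; missing values are excluded):

$$FC_g = \overline{\log_2 I}_{g,\mathrm{case}} - \overline{\log_2 I}_{g,\mathrm{ctrl}}.$$

The proteinuria shift is (to first order) common to all proteins of a case
sample, so it moves every $FC_g$ by the same constant. Centering across
proteins removes it exactly:

$$z_g = \frac{FC_g - \overline{FC}}{\mathrm{sd}(FC)},$$

with the sd using the $n-1$ denominator. `center_fold_changes()` is
location-invariant by construction: multiplying all case samples by any
constant $k$ moves every fold change by $\log_2 k$ and leaves the z vector
untouched (this invariance is asserted to 1e-10 in the test suite). The z is
computed on *log2* fold changes, not raw ratios: up- and down-regulation are
only symmetric on the log scale, and the volcano representation of the
results uses the same axis. A zero fold-change sd (all proteins identical)
is a degenerate input and raises an error rather than returning NaN.

### Moderated t-test

Significance is assessed by an empirical-Bayes moderated two-sample t-test
computed on log2 intensities. Per protein, the pooled residual variance
$s_g^2$ on $d_g = n_{1g} + n_{2g} - 2$ df is shrunk toward a prior
$(d_0, s_0^2)$:

$$\tilde s_g^2 = \frac{d_0 s_0^2 + d_g s_g^2}{d_0 + d_g}, \qquad
  t_g = \frac{FC_g}{\tilde s_g \sqrt{1/n_{1g} + 1/n_{2g}}},$$

with a two-sided p-value from a t distribution on $d_0 + d_g$ df, capped at
the pooled residual df of the dataset (a prior cannot contribute more
information than the data it was fit to). The prior is estimated by the
method of moments on log residual variances (digamma/trigamma moments of the
scaled-F distribution, with a Newton inversion of the trigamma function);
when the observed log-variance dispersion does not exceed its sampling
noise, the prior df is infinite and $s_0^2$ is the mean variance. The two
limits anchor the implementation: $d_0 = 0$ reproduces the classical pooled
t-test exactly, and $d_0 \to \infty$ replaces every variance by $s_0^2$.
The estimator is cross-checked against the standard microarray/proteomics
implementation of the same scheme in the test suite; the in-package code is
the one the pipeline runs.

Raw p-values are BH-adjusted (`adjust_bh()`, step-up), and a protein is
called regulated when $|z| > 1.96$ **and** $q < 0.05$, both strict
inequalities (the rule is stated with ">" and "<"). The direction is the
sign of z. The moderated test is computed on intensities, not on z: the z
enters only through the selection rule, so the two filters act jointly.

### Filtering, candidate shortlisting, PCA and clustering

* `filter_quantified()` keeps proteins observed in at least half the
  samples of one group and at least twice per group, so that group means
  and variances exist.
* `shortlist_candidates()` mirrors how a targeted panel is designed from a
  discovery hit list: peptides carrying oxidized methionine or missed
  tryptic cleavages are disqualified as quantifiers (both are chemically or
  enzymatically unstable and quantify poorly), proteins with fewer than two
  surviving peptides are dropped (a PRM assay monitors two precursors per
  protein), and the survivors are ranked by fold change, ties by total
  signal intensity. The exact ranking weights behind a published panel are
  rarely recoverable; fold change followed by intensity is this package's
  documented choice.
* PCA and complete-linkage clustering need complete matrices, so missing
  values are imputed at half the per-sample observed minimum — the standard
  left-censoring-consistent choice for LFQ data. Imputation is used *only*
  here; fold changes and tests are available-case. Clustering uses
  Euclidean distance on row-centered log2 intensities; only the linkage is
  externally fixed, the distance is this package's choice.

## Targeted (PRM) stage

The chain is: best-transition selection, peak integration, two-stage
normalization, two-peptide roll-up, Welch comparison.

* **Best transition** (`pick_best_transition()`): the transition maximizing
  integrated area over a robust noise estimate (MAD of the off-peak
  signal). Exact ties break lexicographically by transition id so reruns
  are reproducible.
* **Peak integration** (`integrate_peak()`): apex = maximum within a
  scheduled window; boundaries extend from the apex to the first local
  minimum below 1% of the apex (or the window edge); a linear baseline
  between the boundary points is subtracted and the area is a trapezoidal
  integral floored at zero. The 1%-of-apex rule and linear baseline are
  configurable conventions — vendor software does not publish its boundary
  model. On a noiseless Gaussian of amplitude $A$ and width $\sigma$ the
  area is within 1% of $A\sigma\sqrt{2\pi}$ at grid steps of $\sigma/10$ or
  finer.
* **Dual normalization** (`compute_normalization()`,
  `apply_normalization()`): stage 1 divides by the sample's median iRT
  standard-peptide area (iRT peptides are spiked at a fixed amount after
  digestion, so their signal tracks instrument drift only); stage 2 divides
  by the summed, iRT-normalized areas of the biotinidase (BTD) reference
  peptides (an endogenous urine protein that is stable between groups, so
  its signal tracks how much material was loaded — the Bradford-assay
  error). The stage order is fixed: iRT first, then reference. Whether the
  reference "signal" is a sum, mean or single peptide is not externally
  specified; the sum of the two quantifier peptides is used, which makes
  the reference protein roll up to a sample-independent constant. Any
  technical factor common to all of a sample's traces cancels end to end —
  the test suite asserts exact cancellation of planted drift and loading
  factors when noise is off.
* **Roll-up** (`rollup_protein()`): protein value = sum of its two
  quantifier peptides. If one peptide is missing the other is used and the
  value is flagged `partial` (dropping the protein is the stricter
  alternative; the flag lets a caller enforce it).
* **Comparison** (`compare_groups()`): PE/CTL ratio of group means and a
  Welch t-test on the normalized linear intensities (a log-scale option is
  provided; the scale used by the original software is unknowable). Ratio
  of means rather than mean of ratios: it is stable when individual control
  values are small. Constant-and-equal groups return $t = 0, p = 1$ rather
  than erroring.

## Screening evaluation

* `auc()` is the Mann-Whitney estimator (ties count 0.5) and equals the
  trapezoidal integral of the `roc_points()` step curve, which uses the
  "score ≥ threshold" rule.
* `auc_inference()` uses the Hanley-McNeil SE under the exponential
  approximation with a normal 95% CI clipped to [0, 1] and a two-sided
  normal test against AUC = 0.5. This matches what standard statistics
  packages report by default; a DeLong variant is available via
  `roc_summary(..., ci_method = "delong")` for the variance-from-placements
  school.
* `sensitivity_at_fpr()` uses the empirical order-statistic threshold: the
  $\lceil (1-f)\,n_\mathrm{ctrl} \rceil$-th smallest control score, with
  strictly-greater positivity and no interpolation. With 20 controls and
  $f = 0.10$ this admits exactly 2 control positives, i.e. the achieved FPR
  equals the target exactly at this design size; in general the achieved
  FPR (reported alongside) never exceeds the target.
* `longitudinal_table()` flags a protein as significantly upregulated at a
  timepoint when the Welch p < 0.05 *and* the ratio exceeds 1 — screening
  markers are directional, and the both-timepoint marker set intersects
  these flags across timepoints.

## Synthetic-data generator

The generator is first-class, tested code; its defaults define the
simulated study conditions.

**Discovery cohorts** (`generate_discovery_cohort()`): additive on the log2
scale (log-normal intensities), $\log_2 I_{gs} = \mu_g + \beta_g
\mathrm{case}(s) + \pi_s + \epsilon_{gs}$. Defaults: 1108 proteins, 12 vs
12 samples; baselines $\mathcal N(23, 2^2)$ (log2 LFQ-intensity scale);
technical noise sd 0.5 (a typical between-replicate LFQ spread); 53 up / 9
down planted with $|\beta| \sim U(1.5, 3)$; proteinuria shift
$\pi_s \sim \mathcal N(1, 0.3^2)$ in cases (a ~2-fold global inflation).
Missingness is missing-not-at-random through a logistic detection curve,
$P(\mathrm{miss}) = \mathrm{logit}^{-1}((m_0 - \log_2 I)/k)$ with midpoint
$m_0 = 18.5$ and slope 1, giving a few percent overall missingness
concentrated in low-abundance proteins, as in real LFQ matrices. The
proteinuria confounder is a *single per-sample multiplicative factor on all
proteins* — the minimal mechanism that produces the global fold-change
shift the z-centering corrects; real proteinuria is partially
protein-selective (see Limitations).

**PRM chromatograms** (`generate_prm_dataset()`): scheduled acquisition
windows of ±1.5 min around each peptide's expected retention time, sampled
every 0.02 min; Gaussian peaks of sd 0.08 min (~11 s FWHM, a realistic
nano-LC peak); per-peptide response shares (0.6/0.4 between a protein's two
quantifier peptides) and per-transition responses (1/0.55/0.25); optional
truncated-normal baseline noise and a small per-sample retention-time
jitter. Endogenous peptides scale with per-sample loading × drift factors;
iRT peptides with drift only. The default panel is the 21-protein urinary
panel with two peptides each, plus BTD and the 11 standard iRT kit
peptides.

**Longitudinal cohorts** (`generate_longitudinal_cohort()`): 10 cases vs 20
controls at two timepoints by default (the composite case group includes
preeclampsia and/or fetal-growth-restriction outcomes); each subject
carries a $\mathcal N(0, 0.3^2)$ log2 random intercept shared across its
timepoints; planted effects are scheduled per protein and timepoint. The
default workflow plants 2 markers at both timepoints and 4 late-only
(log2 effect 1.5), mirroring the 2-of-21 / 6-of-21 screening structure, on
the post-normalization intensity scale (so the global proteinuria term is
off by default here).

**What the generator does not emulate** — and therefore what passing tests
do *not* establish about real data: correlated protein co-regulation
(effects are planted independently), protein-selective proteinuria
(molecular-weight-dependent leakage), interference and co-eluting peaks in
PRM traces, retention-time drift *within* a run, batch effects, and
clinical covariates (BMI, gestational age) that a matched design absorbs.
The pipeline's correctness claims are about its statistical machinery, not
about clinical performance.

## Numerical and design choices

* Strict inequalities in the selection rule; ties at the threshold are not
  selected.
* BH adjustment delegates to `stats::p.adjust(method = "BH")` behind the
  `adjust_bh()` validation surface and is property-tested against a
  literal step-up implementation.
* The Welch test is implemented explicitly (so the constant-group edge
  cases are defined) and verified against `stats::t.test` to 1e-10.
* Clustering tie-breaks follow `stats::hclust`; dendrograms export to
  Newick via `ape`.
* One global seed expands into fixed per-stage sub-seeds
  (`derive_seed()`), so stages can be rerun independently and the full
  pipeline is bit-reproducible: manifests contain config echo, package
  version and output checksums (timestamps go to a side log precisely so
  that manifests of identical runs are byte-identical).
* Test problem sizes: the acceptance-style properties run at the study's
  own scale (1108 × 24 discovery matrices, 20 replicates for calibration
  and recovery; the full 55-peptide PRM panel at 12 samples; 20
  longitudinal replicates at 30 subjects × 2 timepoints). Unit tests use
  micro designs (2-3 proteins, 4-8 samples) chosen to make hand-computed
  oracles feasible.

## Limitations

* The moderated test assumes exchangeable log-variances across proteins;
  strongly abundance-dependent variance would call for a trended prior,
  which is not implemented.
* The PRM integrator assumes one peak per scheduled window; co-eluting
  interferences would be integrated into the area.
* Sensitivity-at-FPR by empirical order statistics is step-valued in small
  cohorts; confidence intervals for the detection rate are not provided.
* The single-factor proteinuria model makes z-centering exactly correct by
  construction; on real data the correction is only as good as the
  commonality of the shift.
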