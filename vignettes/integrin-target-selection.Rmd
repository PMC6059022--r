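---
title: "Selecting integrin heterodimer drug targets from tumor expression data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selecting integrin heterodimer drug targets from tumor expression data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Integrins are heterodimeric transmembrane receptors, each assembled from one
of 18 alpha and one of 9 beta subunits. The 27 subunit genes combine under
fixed pairing rules into 24 known functional receptors; the receptor — not
the individual chain — is the druggable entity. Because many solid tumors
overexpress particular integrins to drive adhesion, migration, angiogenesis
and metastasis, an integrin that is abundant on tumor cells but not on the
matched normal tissue is an attractive target for antagonists and for
ligand-directed drug delivery.

`dimertarget` implements a transparent, rules-based selection pipeline for
such targets. Starting from a raw RNA-seq count matrix with tumor/normal
labels, it:

1. tests each subunit gene for differential expression with a
   negative-binomial (NB) Wald test (`nb_de()` / `nb_wald_test()`);
2. ranks significantly overexpressed genes with a fold-change/FDR metric
   (`compute_metric()`, `rank_targets()`);
3. filters candidates on absolute expression (average FPKM at a cutoff of
   10, the conventional moderate-expression threshold);
4. optionally corroborates candidates at the protein level from ordinal
   immunohistochemistry (IHC) staining tallies (`score_ihc()`);
5. pairs passing subunits into receptors under the catalog's pairing rules
   and labels each call with its supporting evidence
   (`call_heterodimers()`).

A seeded synthetic cohort generator (`sim_config()`, `simulate_counts()`,
`simulate_ihc()`, `make_demo_study()`) reproduces the statistical structure
each stage assumes, so the entire pipeline is testable offline.

## The differential expression model

For gene $g$ and sample $s$ with raw count $K_{gs}$ we assume

$$K_{gs} \sim \mathrm{NB}(\mu_{gs}, \alpha_g), \qquad
  \mathrm{Var}(K_{gs}) = \mu_{gs} + \alpha_g \mu_{gs}^2,$$

$$\log \mu_{gs} = \log f_{gs} + \beta_{0g} + \beta_{1g}\,
  \mathbb{1}[s \in \text{tumor}],$$

where $f_{gs}$ is a known normalization factor and $\alpha_g$ the gene's
dispersion. The reported effect is $\log_2\!\mathrm{FC}_g = \beta_{1g}/\ln 2$:
positive values mean higher expression in tumor.

**Normalization.** Sequencing depth is estimated with the median-of-ratios
estimator over genes counted in every sample (`size_factors()`). An
externally supplied gene-by-sample factor matrix (e.g. GC-content or length
bias factors produced upstream) can be layered on top: each gene's row is
first rescaled to geometric mean exactly 1 — so normalized counts stay on
the scale of the raw counts — and then multiplied by the size factors
(`normalization_factors()`). The package deliberately does not fit a bias
model of its own; it only enforces the row-geometric-mean-1 contract on
whatever factors are supplied.

**Dispersion.** $\alpha_g$ is estimated per gene by the method of moments on
normalized counts, $\hat\alpha = \max\!\big(0, (s^2 - \bar m)/\bar m^2\big)$
within each condition, averaged across the two conditions and floored at
$10^{-8}$. This is a plain per-gene estimator, not an empirical-Bayes
shrinkage scheme: it is simple, fully testable and adequate at the cohort
sizes the pipeline targets (tens of samples per arm). The cost is noisier
dispersion estimates than a shrinkage estimator would give; plugging them
into the Wald statistic makes the test mildly anti-conservative (empirical
type-I error around 0.05–0.07 at $n = 50$ per arm in the packaged
simulations), which the acceptance suite monitors.

**Testing.** With $\hat\alpha_g$ fixed, the two-parameter model is fit by
iteratively reweighted least squares with the log normalization factors as
offset. The Wald statistic $z = \hat\beta_1 / \mathrm{SE}(\hat\beta_1)$ is
referred to the standard normal, two-sided. P-values are adjusted across
tested genes by Benjamini–Hochberg (`bh_adjust()`; the FDR column). Genes
with all-zero counts are reported untested with missing statistics. A gene
expressed in only one condition has an unbounded maximum-likelihood
coefficient; the fitter caps coefficients at $|\beta| \le 20$ on the
natural-log scale and adds a $10^{-8}$ ridge to the normal equations, so
such genes still get finite (boundary) estimates rather than infinities.
The unshrunk coefficient is reported as the fold change — no fold-change
moderation is applied.

## The ranking metric

Significantly overexpressed genes (strictly $\mathrm{FDR} < 0.05$ and
$\log_2\mathrm{FC} > 0$) are scored as

$$\mathrm{Metric} = \log_2\mathrm{FC} - \frac{\mathrm{FDR}}{0.05},$$

clamped below at zero. Dividing the FDR by the significance threshold makes
an FDR at the boundary cost a full fold-change unit while a tiny FDR costs
essentially nothing, so the ranking is driven by effect size among clearly
significant genes. Two boundary choices were genuinely open and are resolved
as follows: genes whose raw score is negative (small fold change, FDR near
the threshold) are *clamped to zero and retained* rather than dropped,
matching a reported scale with a hard lower bound of zero; and only
overexpressed genes are ranked at all, since the score exists to prioritize
targets for inhibition.

## Absolute expression and the borderline band

Differential expression alone can nominate a gene that is barely expressed.
Candidates are therefore filtered on average FPKM with a default cutoff of
10. Genes within 10% below the cutoff (`fpkm_borderline`) are flagged but do
not count as passing: the band exists to surface "near miss" subunits for
manual review. The band width is a display/reporting device, configurable
via `borderline_frac`; it does not feed eligibility. When an FPKM table is
not available, `compute_fpkm()` derives one from counts and transcript
lengths, averaging over tumor samples (the filter asks whether the *tumor*
expresses the target at an actionable level).

## IHC quantification

Pathology atlases report per-sample staining as one of four ordinal levels.
These are mapped to fixed values (not detected = 0, low = 0.33,
medium = 0.66, high = 1) and tumor samples are summarized by the weighted
average of their level values. A subunit is called overexpressed at the
protein level when this weighted average strictly exceeds the numeric value
of the single assigned normal-tissue level; equality is not overexpression.
Records without stained samples are emitted with `reason = "no_data"` so
that downstream integration can distinguish "no evidence" from "negative
evidence" — in public atlases `ITGA4` and `ITGA10` have no IHC results at
all, and the demo fixture encodes them that way. Antibody validation is
assumed to have happened upstream; an `antibody_id` column, if present, is
carried through for provenance only.

## Receptor calls and evidence classes

Subunit-level passes become receptor-level calls under the pairing rules:

* **strict** — both chains of an allowed pair pass; the default, matching
  the requirement that the whole receptor be overexpressed;
* **relaxed** — one passing chain suffices, on the rationale that abundant
  message for one chain can drive surface expression of the heterodimer
  even when the partner sits at normal levels. `n_pass_subunits` records
  whether one or both chains passed; every two-chain relaxed call is also a
  strict call.

Two refinements are configurable because the underlying convention is
genuinely ambiguous: whether a borderline-FPKM gene may *anchor* a relaxed
call (default no; `allow_borderline_anchor`), and whether the silent partner
of a relaxed call must itself clear the FPKM cutoff (default no;
`relaxed_partner_fpkm`). RNA-derived and IHC-derived calls are finally
merged into evidence classes: `rna_only`, `ihc_only`, or `both`. IHC calls
use strict pairing by default, and an explicit organ-to-subtype map
(`ihc_map`) lets one organ-level IHC record apply to several cancer
subtypes (e.g. lung IHC to both lung adeno- and squamous carcinoma) instead
of relying on name matching.

## What the generator emulates — and what it does not

The synthetic cohort generator draws NB counts with gene-specific
dispersions, planted tumor/normal fold changes, log-normal library-size
factors (sd 0.15 on the log scale), optional log-normal gene-by-sample
factor structure, a configured average-FPKM table, and multinomial IHC
tallies with a planted staining shift. Its defaults define the study
conditions used throughout the tests: 50 tumor and 50 normal samples, NB
mean 100 in normal tissue, dispersion 0.1, planted $\log_2$ fold change 2,
planted-gene FPKM 50 against a background of 5. All randomness flows from a
single seed through an isolated RNG scope (`withr::with_seed`), so a fixed
seed reproduces a cohort byte-for-byte without touching the session RNG.

Two simulation-design points deserve emphasis. First, global size-factor
normalization assumes most genes are not differentially expressed; the
fold-change recovery experiments therefore plant effects on a small fraction
of genes (20 of 1000). Planting a one-directional effect on a large fraction
shifts the size factors and deflates every estimate — a property of
median-of-ratios normalization itself, which the test suite demonstrates
rather than hides. Second, the calibration experiment (1000 null genes, 50
vs 50) sizes the Monte-Carlo error of the empirical type-I rate at about
0.008, which is why the acceptance band is 0.03–0.07 rather than a point.

The generator does **not** emulate several features of real cohorts: GC- and
length-dependent bias (an external factor matrix is accepted but never
fitted), outlier samples and within-arm heterogeneity, correlated genes,
subtype structure, or realistic per-gene FPKM distributions. Passing tests
on synthetic cohorts show the machinery is correct under its stated model,
not that the model captures everything in clinical RNA-seq data.

## Numerical choices and degenerate inputs

* Dispersion floor $10^{-8}$; at or below it the NB likelihood is
  numerically Poisson and the generator draws Poisson counts outright.
* IRLS: at most 100 iterations, convergence at $10^{-8}$ maximum
  coefficient change; hitting the $|\beta| \le 20$ cap counts as
  convergence at the boundary. Non-converged genes are marked untested with
  a warning — never a pipeline abort.
* BH adjustment passes missing p-values through and counts only non-missing
  tests; ties in the metric ranking break lexicographically by gene symbol
  so output order is deterministic.
* `size_factors()` errors (with a suggestion) when no gene is counted in
  every sample, rather than silently switching to a pseudo-reference.
* An empty DE table ranks to an empty table; an empty pass set calls no
  receptors; `ITGBL1`, which has no identified alpha partner, can never
  appear in a call.

## Known limitations

The 18th alpha chain of the packaged catalog is `ITGA2B` ($\alpha$IIb),
required by the canonical 24-receptor table although subunit lists in the
literature sometimes enumerate only 17 alphas by name. The pipeline handles
single-factor tumor/normal designs only — no batch covariates or paired
samples — and works on the gene level (no isoforms, no activation states,
no non-obligate pairings). Metric values are not comparable across cancers
with different cohort sizes, and the plug-in dispersion makes the Wald test
slightly liberal at small $n$; both are reporting caveats rather than
correctness issues, and both are visible in the packaged simulations.
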