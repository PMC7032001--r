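---
title: "Models and methods behind lncoexp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind lncoexp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lncoexp)
```

`lncoexp` analyses a two-genotype, two-treatment RNA-seq design: a
drought-tolerant and a drought-sensitive genotype, sampled under drought
stress (DS) and after re-watering (RW), with three biological replicates
per cell. This vignette explains the statistical machinery, the choices
made where the methodology was genuinely open, and what the synthetic
data generator does and does not emulate.

## Expression and differential calling

Counts are fragment counts per gene. FPKM is computed from its
definition, `count · 10⁹ / (length · library size)`, with the library
size taken as the column total of mapped fragments. Condition summaries
are arithmetic means over the replicate FPKM values.

The RW-versus-DS contrast within one genotype is tested per feature with
a negative-binomial Wald test. Counts are normalized by relative library
size; writing $m_g$ for the group mean of the normalized counts, the
statistic is

$$ z = \frac{\log m_{RW} - \log m_{DS}}
           {\sqrt{\hat v_{DS}/(n\,m_{DS}^2) + \hat v_{RW}/(n\,m_{RW}^2)}} $$

where $\hat v_g$ is the group sample variance — the method-of-moments
estimate of the NB variance $\mu + \phi\mu^2$. Two numerical choices
matter here:

* **Reference distribution.** With three replicates per group the
  variance estimate is noisy; a standard-normal reference is
  anticonservative (we measured null type-I error of 0.08–0.13 at a
  nominal 0.05 in NB simulations). Referencing $z$ to Student t with
  $n_1 + n_2 - 2$ degrees of freedom restores calibration: measured
  type-I error 0.047–0.055 across dispersions 0.01–0.3 and means
  10–500. The acceptance suite re-verifies this on 10,000-feature null
  simulations at $\phi \in \{0.01, 0.3\}$.
* **Degenerate features.** All-zero features get $p = 1$ with a
  `degenerate` flag. When one group is all-zero a continuity shift of
  0.5 is applied so the log contrast exists; a zero group variance is
  floored at the Poisson variance ($\hat v_g = m_g$), the NB lower
  bound.

p-values are converted to q-values by Benjamini–Hochberg
($q_{(i)} = \min_{j \ge i} p_{(j)} m / j$), and a feature is called
`up`/`down` at $q \le 0.05$ and $|\log_2$ ratio$| \ge 1$. The fold
change uses a pseudo-expression $\varepsilon = 0.1$ FPKM on both means,
so ratios stay finite and sortable; $\varepsilon$ is configurable. The
tested universe is every feature expressed (mean FPKM > 0) in at least
one condition of the genotype — there is no single right
minimum-expression filter for this design, so the filter is exposed and
its default is the weakest defensible one.

## The co-expression network

All (DE lncRNA, DE mRNA) pairs are scored with the Pearson correlation
of their per-replicate FPKM profiles, and edges are kept at
$|r| \ge 0.95$ and $p < 0.05$ with the t-based correlation test on
$n - 2$ df. Three open points were resolved as follows:

* **Which samples enter the correlation.** We correlate across the six
  samples of one genotype (3 DS + 3 RW replicates). Using condition
  means instead would leave $n = 2$, where $p < 0.05$ is unattainable
  under any correlation test — so per-replicate profiles are the only
  reading under which these thresholds are coherent.
* **Multiplicity.** Edge p-values are deliberately *not* corrected; the
  threshold is a raw $p < 0.05$ alongside the much stronger $|r|$
  cutoff. This is configurable.
* **Both endpoints DE.** The network is restricted to differentially
  expressed features on both sides, which is what makes trend labels
  (`same` when both endpoints move in the same direction) well defined
  for every edge.

Constant profiles are excluded from pairing with a warning. The hub is
the maximum-degree node, ties broken lexicographically so reports are
deterministic. Subnetworks are extracted by the term annotation of the
mRNA endpoint; lncRNAs stay only while incident. Exports are SIF and
GraphML (typed nodes; `r`, `p`, `trend` edge attributes).

## Cis co-location

"Cis" is taken as interval gap ≤ 100 kb on the same chromosome,
strand-agnostic — a common cis-regulation heuristic; the window is a
parameter. Distance is 0 for overlapping loci and otherwise the
difference between the nearer start and the farther end. Coordinates are
1-based inclusive (the GFF3 convention) throughout.

## Enrichment and length-bias correction

Over-representation uses the hypergeometric upper tail
$P(X \ge k)$ with $N$ population genes, $K$ in the term, $n$ in the
study set and $k$ in both, BH-corrected within each namespace (GO and
KEGG separately). The reported rich factor is $k/K$. The population
defaults to the genotype's expressed mRNAs; whether a whole-genome or
expressed-gene universe is more faithful is unknowable from outside, so
it is an argument.

Length bias — longer genes collect more fragments and are easier to
call DE — is corrected in the opt-in Wallenius mode. $P(DE\,|\,length)$
is estimated by quantile-binned proportions made monotone with
pooled-adjacent-violators (`stats::isoreg`), normalized to mean 1; each
term's odds parameter is the mean weight inside over outside, and the
p-value is the upper tail of the Wallenius noncentral hypergeometric
distribution. The pmf is computed by exact dynamic programming over the
sequential biased-urn process ($O(nK)$ states), which *is* the
distribution's definition, so a single exact algorithm serves all urn
sizes; unit odds provably reduce to the central hypergeometric, and the
tests verify both the reduction (to 1e-10) and agreement with exhaustive
enumeration and Monte-Carlo urn sampling.

## TF profiling and qPCR concordance

Transcription factors (membership from a user- or simulator-provided
feature→family table) DE in at least one genotype are partitioned into
genotype-specific, shared-direction and converse classes; counts are
reported at gene level with a family rollup, since family-level tallies
alone conflate genes. qPCR concordance regresses RNA-seq log2 fold
changes (response) on qPCR log2 fold changes (predictor) — the
orientation of a standard platform-validation scatter — pooling the two
genotypes' probes into one fit, and reports slope and $R^2$.

## What the simulator emulates

`generate_study()` draws NB counts with $Var = \mu + \phi\mu^2$ and a
gene-wise mean assembled on the FPKM scale: base level
$10^{U(1,\,2.5)}$ FPKM, length (200–2000 bp lncRNA, 500–5000 bp mRNA),
and an intended library size of 15–25 M fragments. Defaults: 5000
mRNAs, 500 lncRNAs, dispersion $\phi = 0.01$ (tightly controlled
greenhouse replicates), 15% of features DE per genotype with
$|\log_2 FC| \sim U(1.5, 3)$ — the minimum is ≥ 1 so every planted
effect clears the call threshold by construction — and replicate noise
of 0.25 log2 units.

Three planted modules (5 lncRNAs + 20 mRNAs each) share, per genotype,
one latent per-sample profile added in log2 space. Two properties of
that latent are deliberate design, not convenience:

* It is **centred and standardized within each treatment group**
  (spread exactly `module_latent_sd` = 0.8 log2 units). A raw random
  draw would leave each module's realized strength — and hence the
  detectability of all its members at once — at the mercy of a
  three-replicate draw; standardizing makes "planted" mean planted.
* Profiles of different modules are **mutually orthogonal** (randomly
  rotated Helmert contrasts per treatment block). With only six
  samples, independent draws occasionally align, which would make
  between-module pairs spuriously co-correlate; orthogonality encodes
  the intent that distinct modules are distinct co-expression
  programmes. Up to $2(r-1)$ orthogonal programmes exist with $r$
  replicates; beyond that a fresh rotation starts.

Module members carry a strong shared treatment response
($|\log_2 FC| \sim U(4.5, 5.5)$, i.e. 22–45-fold — the range of strong
drought-marker induction). The size is not incidental: the latent
variance that creates the within-module correlation is, to the DE test,
biological noise, so module members need a larger effect than ordinary
DE features to be reliably called. With the default settings the
planted-pair recovery of the network stage is ≥ 95% across seeds while
between-module false edges are essentially absent.

Module lncRNAs are relocated to within 50 kb of a partner mRNA (planted
cis positives), all module mRNAs are annotated to one planted KEGG
"pathway" term, and a synthetic qPCR table perturbs the true effects
with $N(0, \sigma)$ log2 noise ($\sigma = 0.25$; 0 reproduces them
exactly).

The simulator does **not** emulate: read-level artefacts (no FASTQ,
mapping or assembly), isoforms and alternative splicing, batch or lane
effects, GC/mappability biases, count outliers, or annotation errors.
Passing tests therefore demonstrate the pipeline's statistical
correctness under a clean NB world, not robustness to those artefacts.

## Determinism and problem sizes

All randomness flows from one integer seed through a scoped RNG (the
caller's `.Random.seed` is never touched), and identical configs give
byte-identical outputs, including `report.json`. The test suite runs
the full default study once, calibration nulls at 10,000 features,
planted-effect recovery over 20 seeds of 1500 features, and 100-seed
qPCR noise sweeps — sizes chosen so the whole suite exercises every
claim in about a minute on one core.

## Known limitations

* The NB test is a two-group Wald test; it does not borrow dispersion
  strength across genes (no shrinkage) and supports no covariates.
* Dense networks are expected: with six samples and a dominant
  treatment contrast, strongly DE features co-vary, so thresholded
  correlation networks have many edges beyond planted structure. This
  mirrors real thresholded co-expression analyses and is why recovery
  is assessed against planted modules, not edge counts.
* GO term relationships (DAG ancestor propagation) are out of scope;
  term maps are taken as given.
* The length-bias weight fit assumes a monotone bias and equal-weight
  quantile bins.
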