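---
title: "Models and methods behind pepwire"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind pepwire}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`pepwire` asks how pharmacological kinase inhibition reshapes the
repertoire of HLA class I presented peptides, using four quantified
MS layers (immunopeptidome, phospho-immunopeptidome, proteome,
phosphoproteome) and a signed causal interaction network. This vignette
is the package's own account of its models, parameter choices, numerical
conventions and limitations.

## The quantitative model of a layer

Every layer is a features × samples matrix of log2 intensities inside an
`OmicsLayer` (a `SummarizedExperiment` subclass) with an explicit `NA`
missing marker — never a numeric sentinel, which could collide with real
intensities. The design is four conditions (one control, three kinase
inhibitor treatments) × three biological replicates.

Preprocessing follows the standard immunopeptidomics recipe:

* **log2 transform** of strictly positive raw intensities.
* **Detection filter**: a feature is kept iff it is observed in at least
  `detectionMin = 2` of the 3 replicates of *at least one* condition. A
  feature present 3/3 in control and 0/3 elsewhere is deliberately kept:
  complete treatment-induced loss is a signal, not a quality problem.
* **MinProb imputation** (q = 0.01): missing cells of sample $s$ are
  drawn from $N(\mu_s, \sigma_s)$ with $\mu_s$ the 0.01 quantile of the
  sample's observed values and $\sigma_s = 0.3\,\mathrm{sd}_s$. The
  quantile mean is given by the method's definition; the sd scale 0.3 is
  this package's explicit reconstruction (narrow enough that imputed
  values stay in the censored tail, wide enough to avoid ties). Observed
  cells are never altered, and the draws are deterministic under the
  stage seed. A sample with fewer than two observed values is an error:
  its quantile and sd are undefined.
* **Differential testing**: per feature and treatment, a two-sided
  equal-variance Student *t*-test against control (the classical choice
  for balanced triplicates; Welch is available via `varEqual = FALSE`).
  P-values are Benjamini–Hochberg adjusted **within one layer × one
  treatment comparison** — the natural family for per-treatment volcano
  plots; significance requires both adjusted $p < 0.05$ and
  $|\log_2 FC| > 0.5$. Imputation precedes testing, so fold-changes are
  computed on complete matrices. With zero pooled variance (noiseless
  synthetic fixtures) the p-value degenerates to 0 when the means differ
  and 1 otherwise, with a logged warning.

## Sign propagation and the three mechanisms

The causal network is a directed graph with edge signs
$\pm 1$ (activation/up-regulation vs inhibition/down-regulation), typed
edges (phosphorylation edges carry a residue-level site and must leave a
kinase; transcriptional edges must leave a TF), and node flags for
kinase, TF, druggability and target-pathway membership. A drug enters at
its inhibited kinase with sign $-1$ and propagates along a path as

$$\mathrm{sign}(\text{path}) = -\prod_{e \in \text{path}} \mathrm{sign}(e),$$

the empty path returning $-1$ (the inhibited kinase itself). Site-level
phosphorylation edges carry sign $+1$ — a kinase raises the occupancy of
its site — so "site phosphorylation follows upstream-kinase activity" is
a consequence of the algebra, not a special case.

* **Mechanism 1 — direct peptide phosphorylation.** For each significant
  phospho-HLA peptide, the annotated upstream kinases of its site are
  linked to the treatment's inhibited kinases by all shortest directed
  paths of ≤ 2 steps; the propagated kinase activity times the site edge
  sign predicts the peptide direction. The upstream kinase's activity is
  independently supported by the majority sign of its activation-site
  phosphosites in the phosphoproteome (ties are flagged).
* **Mechanism 2 — source-protein stability.** For significant HLA
  peptides whose source protein carries a stability-regulating
  phosphosite: site phosphorylation follows the upstream kinase (paths of
  ≤ 2 steps — the one cap that is an explicit part of the procedure),
  protein stability is site sign × (+1 stabilizing / −1 destabilizing),
  protein abundance follows stability, and peptide supply opposes it — a
  stabilized protein is degraded less and feeds fewer peptides into
  presentation.
* **Mechanism 3 — transcription-factor control.** TFs reachable in ≤ 3
  steps get an activity sign from their activity-site phosphorylation
  (activating site: same sign; inhibitory site: flipped; no annotated
  site: propagation alone, flagged), and each signed TF→target edge
  predicts the target protein and its peptides.

Design choices made where the procedure was genuinely open, and why:

* **Path direction** is from the inhibited kinase outward along causal
  edge direction — downstream propagation of the drug effect is the only
  causally meaningful reading of "paths linking" the two kinases.
* **Step caps**: mechanism 2's two-step cap is part of the procedure;
  mechanism 1 mirrors it (both describe short kinase-to-kinase relays),
  and mechanism 3 defaults to 3 because "directly or indirectly
  regulated" TFs sit one relay further. All caps are config-exposed, and
  raising a cap can only add assignments (verified as a property test).
* **Multiple shortest paths** are all evaluated; one row is emitted per
  (peptide, treatment, mechanism, path) and a triple counts as recovered
  when *any* path yields a consistent verdict.
* **Lenient vs strict consistency**: lenient (the default) requires the
  peptide sign to match and checks supporting layers only when they are
  measured *and* significant; strict additionally fails on any measured
  supporting observation that does not match, including
  measured-but-unchanged ("none") observations. Lenient is the default
  because intermediate measurements are frequently unavailable in real
  multi-omic designs.
* Mechanisms are **not mutually exclusive**: one peptide may receive M1,
  M2 and M3 assignments simultaneously.
* When a kinase has several annotated activation sites its observed
  activity is the majority sign, with ties flagged as 0.

## The proximity screen

Candidate kinases are screened by connectivity to the antigen processing
and presentation machinery node set: the exact number of **simple
directed paths** of length 1–4 that end at the *first* target member
reached (no pass-through counting), plus the shortest directed distance,
Z-scored across all nodes with finite distance. Selection requires
Z < 0 (closer than average) and druggability; ordering is by descending
path count with lexicographic ties. Two conventions to note: paths are
simple with a hard length cap of 4 (a cap is mandatory for tractability
on dense networks and is config-exposed), and the Z-score uses the
sample (n−1) standard deviation so that distances {1, 2, 3} standardize
to {−1, 0, +1}; with a single finite distance the Z-score is defined as
0. Edge signs are deliberately ignored here — the screen looks for
regulators in either direction; sign handling belongs to the mechanism
engine.

## Antigen set logic

TAAs are binder peptides (strong ∪ weak calls by default; a config flag
restricts to strong) present in ≥ 1 of the disease-cohort samples and in
0 benign samples. Putative TAAs are TAAs significantly *up* in ≥ 1
treatment. Peptide identity across datasets is the upper-cased amino-acid
string. All set outputs are order-invariant and reproducible by plain set
algebra, which the tests exploit as an independent oracle.

## What the synthetic generator emulates

The generator stands in for the deposited study data and plants a known
ground truth. Its defaults are the study conditions: 4 conditions × 3
replicates; log-normal baselines ($\log_2$ intensities
$\sim N(25, 2^2)$); homoscedastic replicate noise sd 0.5 so the Student
assumption is exact; planted effects of magnitude 2.0 $\log_2$ units
whose **signs are derived by propagating each motif**, so cross-layer
consistency holds by construction (e.g. a destabilizing site with
phospho down ⇒ protein up ⇒ peptides down); 10 motifs per mechanism per
treatment; left-censored missingness
$p(x) = 0.3\,\sigma((m - x)/1.0)$ with midpoint $m$ at the 5th intensity
percentile; a 21-sample disease cohort and 30 benign samples with 30
planted TAAs and 15 CTA source proteins.

Scales not fixed by the study design were chosen once for realism
against the reported dataset sizes: ~60 phospho-HLA peptides (30 planted
+ 30 background), 2000 background peptides, 10 target genes per planted
TF with one presented peptide each (mirroring the reported TF : protein :
peptide ratios), plus drug-reachable decoy TFs and background stability
sites wired to *unreachable* kinases so that precision is actually
exercised. Background peptides' missingness, binder classes (~95%
strong/weak) and presence structure are Bernoulli draws with planted
floors; patient data are binary presence calls, so no cohort intensities
are simulated.

What the generator does **not** emulate: peptide sequence realism beyond
random 9-mers, correlated replicate noise, batch effects, intensity-
dependent variance, multi-mapping peptides (one source protein per
peptide by default; multi-mapping is exercised by dedicated fixtures),
and any spectrum-level artifacts. Passing tests on synthetic data
therefore demonstrate the correctness of the inference machinery under
its stated assumptions, not performance on real spectra.

## Statistical power and a known limitation

A consequence worth stating explicitly, because it shapes what recovery
rates one should expect: with $n = 3$ vs 3 the *t*-statistic has 4
degrees of freedom and a planted $|\log_2 FC| = 2$ at noise sd 0.5 gives
noncentrality $\delta = 2/(0.5\sqrt{2/3}) \approx 4.9$ — about 0.95
power at a raw $\alpha = 0.05$. Benjamini–Hochberg changes this
dramatically depending on the *fraction* of truly changed features in
the family. Solving the BH fixed point
$\alpha_{\mathrm{eff}} = q \cdot (\text{expected discoveries})/m$ with
the noncentral-*t* power function shows: when most features carry
effects (the dense calibration experiment used in the acceptance tests),
power stays ≈ 0.94; when only a few percent of ~2000 features are
planted (the default synthetic study), the fixed point collapses and
per-feature sensitivity drops to a few percent. Direct simulation
reproduces both regimes. Mechanism recovery is gated on per-layer
significance, so at default noise its recall — and therefore F1 — is
small even though precision remains ≈ 1, while zero-noise runs recover
every planted mechanism exactly. This is a property of sparse BH testing
at very low degrees of freedom, not of the assignment engine; it is the
reason real studies in this regime either see much larger fold-changes
than 2 (up to 1000-fold in strong perturbations) or moderate variance
across features.

Problem sizes used by the test-suite and acceptance computations — 2000
null features × 20 seeds for calibration, 1000 dense planted features ×
5 seeds for power, 100 random ≤ 12-node graphs for the path oracle, 20
default-noise synthetic studies for recovery — were chosen as the
smallest sizes at which the binomial/oracle tolerances are meaningful.

## Numerical and formatting conventions

* All residue positions are 1-based; site feature ids are
  `PROTEIN_S39`-style strings.
* TSVs mark missing values as empty or literal `NA`; doubles are
  serialized with 17 significant digits so write → read is the identity.
* Every stochastic stage takes an explicit seed derived from the single
  run seed by `deriveSeed()` (stable, < 2^31), making full pipeline runs
  byte-deterministic; determinism is asserted on md5 digests.
* Parsers fail loudly with named locations (unknown sample column,
  duplicated feature id, sign outside ±1, unknown config key) rather
  than coercing.
* Kinase families are single nodes with `family_members`; the inhibitor
  map may target the family node or a member, and family expansion is
  applied when collecting a treatment's inhibited kinases. Complexes and
  families are member-expanded by default in path computations.
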