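---
title: "Predicting synthetic lethality from short peptide clusters: models and design choices"
author: "pepSL"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting synthetic lethality from short peptide clusters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A synthetic lethal genetic interaction (SLGI) is the extreme form of genetic
interaction: knocking out either of two nonessential genes leaves the cell
alive, knocking out both kills it. SLGIs reveal compensatory pathways and
complexes, but experimental screens are laborious, and most computational
predictors lean on other genome-wide data (expression, localization,
networks). pepSL implements a sequence-only predictor: the hypothesis is that
short conserved polypeptide stretches — typically shorter than classical
domains — carry the functional signal, and that protein-pair synthetic
lethality can be explained by pairwise interactions between *clusters* of
such peptides. Because short peptide clusters cover more of a proteome than
curated domain databases do, the approach trades curated annotation for
coverage.

The pipeline has four stages, each an exported module:

1. **Windows** — every protein is chopped into peptides of length $L = 25$
   by a sliding window of step $w = 5$.
2. **Significant pairs** — Smith-Waterman local alignment under BLOSUM62
   with a linear gap penalty of 14 scores every window against all windows
   of *other* proteins; per-window extreme-value statistics turn a p-value
   threshold ($10^{-6}$) into a per-window score threshold, and a pair is
   kept only if it is significant in *both* directions.
3. **Clusters** — each significant pair seeds a cluster that is grown to a
   fixpoint by an iterative align / build-profile / search loop, then
   clusters are deduplicated, merged (three overlap rules) and filtered
   (minimum 3 members; optional promiscuity cap of 20/50/100 proteins).
4. **EM** — cluster-pair interaction probabilities $\Pr(C_{ij}=1)$ are
   estimated from known SLGIs under a noisy-OR observation model, and
   protein-pair probabilities follow as
   $\Pr(L_{mn}=1) = 1 - \prod_{i \in C(m), j \in C(n)} (1 - \Pr(C_{ij}=1))$.

## Significance model

The scores of one 25-mer against a large population of unrelated 25-mers
are modeled as Gumbel: $F(x) = \exp(-e^{-(x-\mu)/\beta})$. The fit is by
the method of moments, $\beta = \sigma\sqrt{6}/\pi$ and
$\mu = \bar X - 0.5772\,\beta$, with $\sigma$ the $n-1$ sample standard
deviation; the constant is the conventional truncation of the
Euler–Mascheroni constant. Karlin-Altschul form: $\lambda = 1/\beta$,
$K = e^{\mu/\beta}/(mn)$, $E = Kmn\,e^{-\lambda S}$, and
$P = 1 - e^{-E}$. Because $K$ divides by $mn$ and $E$ multiplies by it,
the sequence lengths cancel and the score threshold for a target p-value
$p$ reduces to $S_{\min} = \mu - \beta\,\ln(-\ln(1-p))$; we keep the full
parameterization in the API because each operation is a meaningful unit.
The inversion uses the exact $E^\ast = -\ln(1-p)$ rather than the small-$p$
approximation $E \approx p$, and significance is $S \ge S_{\min}$ so that
analytically exact threshold cases pass.

Each window's threshold is fitted on its *complete* cross-protein score
population — thresholds genuinely differ between windows, which is the
point of the per-window calibration. Windows whose population cannot
support a fit (fewer than two subjects, zero variance) are skipped with a
warning. At bench scale this full-population fit needs enough background:
a planted family contributes of order 1% of all windows, and its true
matches fatten the sample standard deviation. Our fixtures use a few
hundred proteins so the inflation stays small; with toy proteomes of only
tens of proteins the fitted thresholds can exceed the maximum attainable
score, and the scan honestly returns nothing.

## Alignment scorer

"Penalty for gap and mismatch = 14" is read as a *linear gap penalty* of 14
per gap symbol, with mismatch costs taken from BLOSUM62 itself — an extra
flat mismatch penalty would contradict using BLOSUM62 to score similarity.
The scorer is implemented in C++ (integer DP, rolling row); ties for the
optimal score are broken toward the smallest (query end, subject end) and
the traceback prefers diagonal, then up, then left — only the score feeds
downstream stages. Residues outside the matrix alphabet fall back to the
matrix's `X` column when present, else to a `-1`-against-everything
fallback symbol, so degenerate inputs survive without inflating scores.
Proteins shorter than $L$ contribute one full-length window (the smallest
yeast protein has 16 residues; dropping short proteins would contradict the
near-total proteome coverage the method aims for), and no tail window is
emitted beyond the last full step.

## Profile model and its calibration

The original work grew clusters with ClustalW + HMMER. The contribution is
the iterate-to-fixpoint framework, not a particular HMM implementation, so
pepSL uses an internal profile model with the same operation contracts: a
progressive multiple alignment (average-linkage guide tree on best-offset
identity; profile-profile Needleman-Wunsch with free terminal gaps, since
members are fixed-phase windows of a common motif region), followed by
per-column natural-log odds with pseudocount 1 against a uniform $1/20$
background. Columns with more than 50% gaps are dropped so the profile
length tracks the conserved core. Members are canonically sorted before
alignment, making the profile invariant to input order.

Searching places the profile ungapped along each window, allowing
overhangs with at least 10 overlapping columns (windows of one motif sit
at different phases of the $w=5$ grid; requiring full containment would
orphan shifted windows). E-values come from a Gumbel null fitted to the profile's
own score population over the catalog — with one deliberate deviation from
plain moment fitting: the null is fitted by matching the 25th and 50th
percentiles to the Gumbel quantile function. At proteome scale (hundreds
of thousands of windows) a true family is a vanishing fraction of the
population and a moment fit is safe; at bench scale a family can be
several percent of all windows, and its members inflate a moment-fitted
scale enough to destroy the member/background separation (measured: scale
1.43 contaminated versus 0.57 clean on one fixture). Lower-quantile
matching ignores the upper tail — where every true match lives — entirely,
the same spirit in which profile calibrators fit their null to
random-sequence scores. A consequence worth stating plainly: our E-value
scale is internally consistent but not numerically comparable to HMMER's,
so the search thresholds ($10^{-10}$, $10^{-15}$, $10^{-20}$) are knobs of
*this* calibration. On the synthetic worlds below, $10^{-10}$ recovers
planted families completely, while stricter settings fragment them — hence
the pipeline default of `evalueThreshold = 1e-10`.

Cluster growth only ever adds members, so it terminates; a cap of 100
iterations guards a hypothetical non-monotone external search adapter.
`clusterAll` grows one cluster per seed pair and is order-independent; for
pipeline-scale runs `skipContained = TRUE` skips seeds already contained in
an earlier grown cluster (thousands of seeds per family otherwise), and a
test checks that the post-processed catalog is unchanged by the shortcut.
Merging applies the shared-member rule (any overlap, or 10% / 20% of the
smaller cluster) transitively to a fixpoint via union-find rounds, so the
result does not depend on processing order.

## EM estimation

With $M_{ij}$ (interacting protein pairs carrying cluster pair $\{i,j\}$),
$N_{ij}$ (expected non-interacting cluster pairs within interacting protein
pairs) and the fixed $K_{ij}$ (non-interacting protein pairs carrying
$\{i,j\}$, counted once over all protein pairs of the feature-bearing
universe minus the known positives), the model is the standard noisy-OR
feature-pair EM. Initialization sets $\Pr(C_{ij}=1) = M/(M+N+K)$ with
$N=0$; the E-step gives each cluster pair of an interacting protein pair
the posterior $r = p_{ij}/\Pr(L_{mn}=1)$; the M-step is
$(E[M]+a)/(E[M]+E[N]+K+a+b)$ with pseudocounts $a=b=1$, which keeps every
probability strictly inside $(0,1)$. Sums run over observed interacting
pairs only; non-interacting pairs enter through $K$ — the only reading
under which $K$ "remains unchanged".

One design choice deserves emphasis. The convergence monitor is the
observed-data log-posterior: the noisy-OR likelihood of the positives,
$(1-p_{ij})^{K_{ij}}$ for the non-interacting support, and the Beta
pseudocount terms. This is the quantity EM provably never decreases, and
it is what "the likelihood of observed protein genetic interactions"
denotes. The literal complete-data product (expected counts in the
exponents, pseudocounts included) is recorded alongside in
`completeLogLik`; it has no general ascent guarantee, though it ascends on
all our fixtures. Stopping is $|\Delta \log L| < 10^{-6}$ by default.

Prediction is the noisy-OR over a pair's cluster pairs; cluster pairs never
seen in training get the pure-pseudocount value $a/(a+b) = 1/2$ (the
M-step with empty counts), and pairs with no cluster pairs at all are
reported *unscorable* (`NA`) rather than probability 0 — absence of
features is absence of evidence, mirroring the coverage accounting of the
original evaluation. Evaluation uses the Mann-Whitney AUC with midrank
ties.

## The synthetic world

`generateProteome` emulates exactly what the downstream stages need to see:
i.i.d. background residues (uniform by default — yeast composition would
only complicate the extreme-value picture without changing any contract),
protein lengths from a truncated normal matching the yeast marginals
(mean 450, sd 380, clipped to [16, 4901]), and motif families of ~25-mers
planted at random offsets (deliberately off the window grid, to exercise
phase handling) with i.i.d. point substitutions. Interaction labels are
sampled *from the model itself*: planted family-pair probabilities
$p^\ast$ feed the same noisy-OR that the predictor assumes. A green
end-to-end test therefore establishes that the pipeline recovers planted
structure and probabilities under its own generative assumptions — it says
nothing about how well the noisy-OR describes real genetic networks, about
paralog structure, domain architectures, or composition bias, none of
which are simulated.

Test fixtures keep the planted structure at the stated scale (e.g. 500
proteins, 10 families of 30 noisy copies at 10% substitutions for the
clustering-recovery check) but set background lengths near 130 residues
instead of the yeast-like 450 default: the all-vs-all scan is quadratic in
window count, and the shorter background keeps the suite within a
single-CPU test budget while leaving every contract intact. The scan was
verified to behave identically, only slower, at longer lengths.

## Numerical and degenerate-input choices

* Moment fits error (rather than guess) on populations with fewer than two
  scores or zero variance; the pair scan skips such windows with a warning,
  and cluster growth freezes the cluster.
* The E-step handles an all-zero positive pair (possible only at
  initialization) by letting it contribute nothing for that iteration; with
  unit pseudocounts the state cannot persist.
* Probabilities are combined in log space (`log1p`, `expm1`) so products of
  many $(1-p)$ factors neither underflow nor lose precision.
* Deterministic tie-breaks throughout: canonical (lexicographic) pair and
  window ordering, sorted cluster members, seeded generators; re-running
  any stage on identical input is byte-identical.

## Known limitations

* The profile model is position-specific scoring without insert/delete
  states; gapped profile search and Plan7 HMMs are out of scope, as is
  annotation of clusters against domain databases.
* E-value thresholds are calibration-specific (see above); reproducing the
  original counts and AUCs would require the yeast proteome, the SGD SLGI
  set, the published benchmark, and the exact ClustalW/HMMER binaries.
* With a promiscuity cap active, *looser* merging can reduce protein
  coverage: big merged clusters get removed by the cap. Coverage therefore
  rises as the merge rule tightens (any overlap, 10%, 20% of the smaller
  cluster), and is merge-invariant when no cap is applied.
* The EM assumes cluster-pair independence; correlated features (nested or
  overlapping clusters) violate it mildly after merging.
* K-counting and prediction restrict to proteins carrying at least one
  cluster; pairs outside that universe are unscorable by construction.
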