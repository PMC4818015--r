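---
title: "Mapping immune cell-abundance QTLs by deconvolution: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping immune cell-abundance QTLs by deconvolution: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vocal)
```

## The problem

Genetic association studies of the immune system ask which DNA variants
change the abundance of particular immune cell types. Measuring those
abundances directly (by sorting or cytometry) across a large genotyped
population is laborious, so most studies cover only a few cell types. This
package instead *infers* cell-type abundances from bulk tissue expression
profiles and maps their genetic control, requiring only two ubiquitous data
types: tissue transcriptomes and genotypes.

The inputs are

* a reference matrix $X$ ($m$ genes $\times$ $n$ cell types) of expression
  signatures of isolated immune cell types (replicate columns per cell type
  are supported and collapsed by averaging),
* a tissue expression matrix $Y$ ($m$ genes $\times$ $l$ individuals,
  log scale), and
* a genotype matrix $D$ ($l$ individuals $\times$ $q$ loci) of a homozygous
  (e.g. recombinant inbred) population, with a genetic map.

The output is a set of *immune trait associations*: (cell type, locus)
pairs where allelic variation changes the inferred abundance of the cell
type — the locus is then an *iQTL* (immune quantitative trait locus).

## The five-step algorithm

**Step 1 — marker initialization.** Deconvolution is more stable on a small
set of informative marker genes than on the whole transcriptome. The
package builds $k$ *pairwise-disjoint* marker sets $F^{(1)},\dots,F^{(k)}$
of target size $\Psi$, each chosen from the genes left over by earlier
sets. Four methods are provided: `top_varying` (highest across-cell-type
variance), `cell_tagging` (per gene, rank cell types by mean expression and
t-test the top cell type's replicates against the pooled second- and
third-ranked replicates; pick, per cell type round-robin, the genes with
the best p-values), `cell_tagging_facs` (set 1 is a supplied list of
cell-isolation surface markers, the rest by tagging), and `random`.

The tagging test is implemented as a single pooled two-sample t-test of the
top cell type's replicates against the union of the second and third
(the alternative — two separate tests combined — fits the method's "best
t-test p-values" framing less directly). When the reference has no
replicates, a fallback scores genes by the top-vs-next expression gap
standardized by the gene's MAD across cell types. Ties are broken
lexicographically by gene id so marker construction is reproducible.

**Step 2 — deconvolution.** For each individual $s$ and marker set $u$,
the marker expression vector is modeled as a mixture of reference
signatures, $y^{(s,u)} = X^{(u)} \theta^{(s,u)}$, and $\theta$ is estimated
by elastic-net regression (via glmnet) with mixing $\alpha = 0.05$ and a
100-value geometric penalty path ending at
$\lambda_{\min} = 0.2\,\lambda_{\max}$; coefficients are reported at the
path terminus, on the original predictor scale, with the intercept
discarded. The nearly-ridge mixing handles the over-parameterized regime
($n$ cell types possibly exceeding $\Psi$ markers) while still zeroing
clearly absent cell types. The package constructs the penalty path
explicitly (probing glmnet for $\lambda_{\max}$ first), because glmnet's
internal early stopping would otherwise end the path above the documented
terminus. No non-negativity constraint is imposed: with baseline-subtracted
input, abundances are relative and signed. Row $c$ of the resulting matrix
— cell type $c$'s inferred abundance across individuals — is the *immune
trait* of $c$ under marker set $u$.

**Step 3 — genome scans.** Each immune trait is tested against each locus
with the two-group fixed-effect model
$\theta_c = d^{(v)}\beta_{v,c} + \varepsilon$,
$\varepsilon \sim N(0,\sigma^2)$, i.e. the equal-variance F(1, n-2) /
two-sample t-test. Heterozygous and unknown genotype calls are dropped per
locus rather than imputed (recombinant inbred strains are nominally
homozygous; such calls are noise). Degenerate tests — under 2 samples in
an allele group, or a constant trait — score $p = 1$, never `NaN`, which
keeps the downstream aggregation free of special cases and is
conservative. The $k$ maps of p-values $p_u(c,v)$ are the *association
maps*.

**Step 4 — aggregation.** True iQTLs should be recovered by *different*
marker sets; noise should not. Fisher's combined probability test turns
the $k$ maps into one:
$$a_{c,v} = \Pr\!\left(\chi^2_{2k} \ge -2\sum_{u=1}^{k}\ln p_u(c,v)\right),$$
with p-values floored at $10^{-300}$ before the logarithm. Thresholding
$-\log a_{c,v} \ge T_i$ yields the significant set $W_i$.

**Step 5 — filtration.** A marker whose own expression is under genetic
control (an eQTL target) at locus $v$ drags the inferred abundance of its
cell type with it, manufacturing a spurious iQTL at $v$. A gene-level eQTL
map $p(g_j, v)$ is computed once, up front, over the union of all marker
genes, and thresholded at $T_e$ into $W_e$. The confounded set is
$$F' = \{\, g_j \mid \exists (c,v) \in W_i \text{ s.t. } (g_j,v) \in W_e \,\},$$
i.e. genes with a significant eQTL at a locus that is simultaneously a
called iQTL. Every marker set is filtered, $F^{(u)} \leftarrow F^{(u)}
\setminus F'$, removed markers are never readmitted, and steps 2–4 are
repeated; the loop stops when an iteration removes nothing (a hard cap
guards against pathological oscillation, and a cap of 0 disables
filtration entirely). $W_i$ is recomputed each iteration from the current
marker sets; associations are always recomputed on the final sets before
reporting. Because the eQTL map is cached threshold-free, changing $T_e$
costs nothing.

`run_vocal()` orchestrates all five steps; `vocal_cli()` exposes
`simulate` / `run` / `evaluate` / `benchmark` subcommands for shell use.

### The base of the `-log` thresholds

The significance cutoffs are quoted as $T_i = 10$, $T_e = 40$ (benchmark
preset) and $T_i = 5$, $T_e = 10$ (tissue preset) on an unspecified
"$-\log$" scale. This package interprets them on the **natural-log** scale
(`log_base = exp(1)`, exposed as a parameter). The decisive argument is
internal consistency of the benchmark preset: under the benchmark's own
generative model ($\sigma^2 = 10^{-4}$, eQTL effect $\gamma_e = 0.05$,
$l = 60$ strains), the strongest attainable hotspot eQTL has
$p \sim 10^{-20}$, so on a base-10 scale $T_e = 40$ could never be reached
and the filtration step would be inert — contradicting the method's central
design goal. On the natural scale, $-\ln p \approx 40$–$60$ for exactly
those hotspots, so $T_e = 40$ selects strong eQTL targets and nothing else.

### Permutation FDR

Because traits are *predicted*, nominal p-values are assessed empirically:
the sample labels of the expression matrix are permuted (genotypes fixed),
the full analysis is rerun per permutation — permuting expression labels
permutes the deconvolved traits and the eQTL map coherently — and
FDR$(t)$ = mean permuted discovery count / real discovery count. A real
count of zero yields an *undefined* FDR (flagged), not zero. The FDR is
computed once on the final model rather than inside each filtration
iteration, treating it as an assessment of the output. Marker resampling
(step 1) and permutations address different problems: confounding and
reproducibility versus multiple testing.

## The synthetic benchmark

`simulate_dataset()` generates tissue datasets with known genetic control,
and `evaluate_result()` scores recovered associations, enabling controlled
experiments on every design choice above.

**Genotypes.** `generate_ri_genotypes()` fabricates a homozygous
recombinant inbred panel (default 102 strains, 500 loci on 20 chromosomes)
as a Markov chain along each chromosome with per-interval recombination
probability 0.08 — giving the long shared haplotype blocks real RI panels
have. Each simulated dataset uses `l = 60` strains drawn without
replacement (strains with heterozygous/unknown calls at a simulated causal
locus are excluded before the draw).

**Ground truth.** $n_i$ iQTL loci and $n_e$ eQTL-hotspot loci are drawn
without replacement; each locus gets a uniform activation/repression
direction; each iQTL a uniform target cell type; each hotspot 10 target
genes from a randomly chosen co-expressed gene group (groups may overlap
between hotspots). Gene groups are built by average-linkage hierarchical
clustering of the pooled marker genes on $1 - r$ (Pearson), cut at
$r > 0.7$, keeping sub-trees of more than 10 genes. Average linkage is a
deliberate (configurable) choice; the clustering method is otherwise a
free parameter of the protocol.

**Fractions and expression.** Every strain starts at the uniform
composition $1/n$; a strain carrying allele B at an iQTL shifts the target
cell type by $\pm(1/n)\gamma_i$ and the row is renormalized to sum to 1
(fractions stay positive for $\gamma_i < 1$). Expression is
$$y_{j,s} = \sum_c \theta_c^{(s)} r_{j,c} + \varphi_j^{(s)} + \varepsilon,
\qquad \varepsilon \sim N(0, \sigma^2),$$
where $\varphi_j^{(s)} = \pm\gamma_e$ for hotspot target genes in allele-B
strains and 0 otherwise. Reference values are mixed on the scale provided
(no exponentiation), and $\sigma^2 = 10^{-4}$ by default.

**Sibling partition.** Real analyses never deconvolve with the exact cell
types present in the tissue. The benchmark therefore splits cell types
into *sibling pairs* from the same isolation group: one sibling generates
the data ($R$), the other is handed to the algorithm ($X$). Ground-truth
scoring maps each data-generation cell type to its deconvolution sibling.

**The synthetic reference.** `generate_synthetic_reference()` fabricates a
sibling-structured reference so the whole suite runs without downloads:
8 sibling pairs by default, each owning a 20-gene signature block elevated
5 log-units over a baseline of $\sim$2, with 3 jittered replicate columns
per cell type. Two features were calibrated to reproduce the *difficulty*
of real references, then frozen: signatures are partially shared between
cell-type pairs (probability 0.5 per other pair, at 0.2–0.7 of the full
elevation), and siblings diverge by independent gene-level noise sized so
their profiles correlate at $\approx 0.85$. Without these, signatures are
orthogonal, deconvolution is essentially exact, and every benchmark
condition saturates near AUC 1 — a regime in which neither multi-set
aggregation nor filtration has anything left to contribute. With them,
abundance estimates bleed between related cell types exactly as they do
with real immune references, and the benchmark spans a realistic AUC
range. What the generator still does **not** emulate: heavy-tailed and
heteroscedastic expression noise, cis-eQTL structure (hotspot targets are
chosen by co-expression, not genomic position), environmental covariates,
epistasis, and lineage-shaped correlation between more than two related
cell types. Passing benchmarks therefore demonstrate correctness of the
machinery and the claimed orderings under this model, not performance on
any particular real tissue.

**Scoring.** The label universe is all (deconvolution cell type, locus)
pairs; a pair is positive iff the locus is a simulated iQTL whose target's
sibling is that cell type. The AUC is the rank statistic of
$-\log_{10} a_{c,v}$ over positives versus negatives, ties counting half.
Because RI panels contain runs of genotype-identical loci that no
association method can distinguish from the causal locus, an `ld_collapse`
option also counts genotype-identical loci as positive; benchmarks report
both variants (`auc` and `auc_exact`).

## Numerical choices and degenerate inputs

* p-values are clamped to $(10^{-300}, 1]$ everywhere; perfectly separated
  groups score $10^{-300}$, degenerate tests score 1.
* The cell-tagging t-test floors a zero pooled variance at $10^{-12}$
  (reported), so identical replicates give $t = \pm\infty \to p \approx 0$
  for a real gap and $t = 0, p = 1$ for no gap.
* All-zero expression vectors skip the elastic net and return exact zeros;
  all-zero traits score $p = 1$ at every locus.
* Duplicate gene rows collapse by arithmetic mean at load time (the
  standard microarray convention); matrices are dense throughout (the
  method's data scale does not justify sparse storage).
* The baseline sample used for normalization is dropped after subtraction
  (an all-zero column is degenerate for association testing).
* Marker sets reduced below 2 genes by filtration are skipped by
  deconvolution (with the emptied-set warning); the run errors only if
  *all* sets empty.
* All randomness (marker sampling, simulation, strain draws, permutations)
  flows from explicit seeds through an RNG-state-preserving wrapper, so
  identical configurations give identical results end to end.

## Problem sizes used by the shipped experiments

The packaged tests and the acceptance script run the benchmark at
$n = 8$ sibling pairs, $m = 2000$ genes, 500 loci, $l = 60$ of 102 panel
strains, $k \le 10$, $\Psi = 2n = 16$, with 20 paired replicate datasets
per compared condition (10 for the strong-signal condition). These sizes
keep a full ordering experiment to a few minutes while leaving every
mechanism (aggregation, filtration, LD) active; larger values only narrow
the confidence intervals.

## Known limitations

* The association model handles homozygous two-allele populations only; no
  covariates, kinship correction, or interval mapping.
* iQTL *intervals* are a reporting convention (maximal runs of contiguous
  significant loci), not an LD-based confidence region.
* The tagging t-test form (one pooled test vs two combined tests) and the
  clustering linkage are conventions where the protocol is underspecified;
  both are isolated behind single functions and easy to swap.
* In the benchmark's easiest conditions (few iQTLs, strong recovery) both
  a single pooled marker set and several disjoint sets sit near AUC 1, so
  the reproducibility advantage of disjoint sets is not measurable there;
  it shows in harder regimes (e.g. the k = 1 versus k = 10 contrast at six
  iQTLs).
* Permutation FDR reruns the pipeline per permutation and is therefore the
  most expensive component; use modest `n_perm` exploratively.
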