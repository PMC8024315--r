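---
title: "Consensus regulatory networks from paired expression and accessibility replicates"
author: "cregnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus regulatory networks from paired expression and accessibility replicates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cregnet)
library(GenomicRanges)
```

# The problem

Paired RNA-seq and ATAC-seq assays measure, in the same biological
sample, which genes are expressed and which regulatory elements (REs)
are accessible. From one such pair a context-specific gene regulatory
network can be inferred: directed transcription factor (TF) to target
gene (TG) regulations, each mediated by a cis-regulatory module (CRM) —
the set of accessible elements bound by that TF to regulate that TG.
Replicate samples, however, yield visibly different networks: both the
edge scores and the CRM boundaries fluctuate. `cregnet` addresses the
two halves of this problem: scoring one replicate's network, and
integrating several replicate networks into a single consensus that is
more reliable than any one of them. The motivating application is
developmental systems such as cranial neural crest cells, where the
resulting network is used to interpret GWAS variants and evolutionary
elements, but nothing in the package is specific to that system.

# Per-replicate network construction

The trans-regulation score of TF $i$ on TG $j$ in one sample is

$$ S_{ij} = \Big(\sum_k B_{ik}\,\mathrm{RE}_k\,I_{kj}\Big)\times
   2^{|R_{ij}|}\times\sqrt{\mathrm{TFA}_i\,\mathrm{TG}_j} $$

with the factors:

* $B_{ik}$ — motif binding strength of TF $i$ on element $k$: the sum of
  log-odds scores of all both-strand windows at or above the motif's hit
  threshold (`motifBindingMatrix()`). The default threshold is 60% of a
  motif's maximum achievable score; this is exposed because no single
  cutoff suits all motif sharpnesses.
* $\mathrm{RE}_k$ — the element's normalized accessibility.
* $I_{kj}$ — the element-to-gene interaction weight, learned once by
  regressing each gene's expression on its candidate elements'
  accessibility across a panel of paired samples
  (`fitInteractionModel()`; ordinary least squares, ridge on demand for
  underdetermined designs). Candidate elements default to a 200 kb
  window around the TSS (`candidateElements()`), a conventional
  cis-regulatory horizon; the window is configurable and an external
  candidate table can be supplied instead.
* $R_{ij}$ — TF-TG expression correlation across the same panel; the
  absolute value enters the exponent, so strong negative co-expression
  counts as strongly as positive (repressors are informative too).
* $\mathrm{TFA}_i$ — TF activity, the geometric mean of the TF's
  expression and its motif enrichment in open elements. Enrichment is
  hit density relative to dinucleotide-shuffled copies of the same
  sequences (Altschul–Erickson shuffling, 10 copies by default), floored
  at $10^{-3}$ so that an unexpressed TF — and only an unexpressed TF —
  has activity zero.

The inner sum can be negative because the panel regression is
unconstrained; we clamp it at zero, because the consensus model's
feasible set requires $S_{ij}\ge 0$ and a negative accessibility-weighted
sum is evidence of no activating regulation, not of negative strength.

A replicate network (`buildReplicateNetwork()`) keeps the triplets whose
score exceeds a quantile of the positive scores (default 0.5, exposed —
there is no canonical cutoff) and records each kept pair's CRM as the
merged candidate elements on which the TF has a motif hit. "Normalized
expression" means `log2(x+1)` followed by equalizing column sums
(`normalizeExpression()`); the convention is tagged on the matrix so
downstream steps can assert it.

# Consensus optimization

Given $R$ replicate networks $(S^r, C^r)$ — scores plus per-base binary
CRM vectors on a shared union frame (`alignCrmFrames()`) — the consensus
$(S, C)$ minimizes

$$ Q=\sum_{i,j,r}\omega_r\big\{(S_{ij}-S^r_{ij})^2+\alpha\|C_{ij}-C^r_{ij}\|_2^2\big\}
 -\beta\sum_{i,j}S_{ij}\|C_{ij}\|_1-\gamma\sum_{i,j,q}C_{ijq}C_{ij(q-1)}+\mu\|S\|_1 $$

subject to $S_{ij}\ge 0$ and binary $C$. The four terms trade replicate
fidelity (weighted by per-replicate $\omega_r$, default equal),
consistency between a pair's strength and the length of its CRM
($\beta$), continuity of CRM bases along the genome ($\gamma$), and
sparsity of the edge set ($\mu$). The binary program is NP-hard; we
relax $C\in[0,1]$ and iterate the stationarity conditions:

$$ S_{ij}\leftarrow\frac{1}{2\omega}\Big(2\sum_r\omega_rS^r_{ij}+\beta\|C_{ij}\|_1-\mu\Big),\qquad
   C_{ijq}\leftarrow\frac{1}{\omega}\sum_r\omega_rC^r_{ijq}
   +\frac{\beta}{2\omega\alpha}S_{ij}
   +\frac{\gamma}{2\omega\alpha}\big(C_{ij(q-1)}+C_{ij(q+1)}\big) $$

with $\omega=\sum_r\omega_r$ and zero boundary neighbours. Numerical
choices, all visible in `consensusOptimize()`:

* Jacobi-style updates (previous iterate on the right-hand side) with
  projection after every step: $S$ onto $[0,\infty)$, $C$ onto $[0,1]$,
  keeping iterates feasible throughout.
* Initialization at the $\beta=\gamma=\mu=0$ solution — the
  $\omega$-weighted replicate means — which the iteration reproduces
  exactly in that degenerate limit (asserted to $10^{-12}$ in the test
  suite).
* Convergence requires both $\max|\Delta S|<\varepsilon$ and the maximum
  per-base $|\Delta C|<\varepsilon$; on convergence the *pre-update*
  iterate is returned, so one application of the maps moves every
  coordinate of the reported solution by less than $\varepsilon$ — the
  fixed-point property the tests verify by independent re-evaluation.
* Pairs absent from a replicate contribute $S^r_{ij}=0$ and an all-zero
  $C^r$ vector: the objective sums over all replicates and absence is
  evidence of no support.
* $\alpha>0$ is required whenever $\beta$ or $\gamma$ is used (both
  updates divide by $2\omega\alpha$).

The relaxed $C$ must become binary CRMs at the end; the solver's source
does not pin this step down, so `finalizeNetwork()` makes the rule
explicit: bases at or above `cThreshold` (default 0.5, majority of the
relaxed evidence) become 1, maximal runs become intervals, and triplets
with strength at or below `keepSmin` or an empty CRM are dropped. During
iteration $\|C\|_1$ uses the relaxed values — the relaxation is only
useful if its interior values carry information.

Two naive baselines (`baselineIntegrate()`) frame the comparison: the
union network (pair kept if present anywhere; generous recall, noisy)
and the intersection network (pair kept only if present everywhere;
clean but small). `selectParameters()` runs a parameter grid and picks
the setting with the best F1 against a gold-standard edge list, breaking
ties toward larger recall and then smaller $\mu$ — recall is the scarce
commodity against sparse gold standards.

# Network architecture

`clusterTfModules()` groups TFs by hierarchical clustering of their
score rows (Euclidean distance, complete linkage — the defaults of the
heatmap tooling this analysis is usually paired with; both exposed),
cutting at $k=2$ by default, with module 1 the broadest regulators.
`denseSubnetwork()` extracts the dense TF backbone by maximizing
$\sum_{ij}S^0_{ij}u_iv_j$ over non-negative unit vectors: alternating
projected power iteration, which for a non-negative matrix attains the
leading singular value with non-negative vectors (Perron–Frobenius);
seeded random restarts guard against non-unique optima, and the tests
check the objective against an independent singular value decomposition.
The program runs on the raw score submatrix; a caller who wants
normalized input can scale beforehand — scaling changes only the
objective, not the vectors. Roles follow the importance cutoffs
$u_i\ge\mu_c=0.1$, $v_i\ge v_c=0.05$: upstream (out-going only), core
(both), downstream (in-coming only). `subnetworkDensityPvalue()` asks
whether a selected TF set is denser (mean off-diagonal weight) than
uniformly resampled same-size sets, reporting a one-tailed t-test
against the null sample and the raw exceedance fraction.

# Annotation

`extractSubnetwork()` pulls the triplets selected by a gene set (TG
membership), a SNP set (SNP position on a CRM base of the *binarized*
CRM — the natural reading of a binary membership condition), or a region
set (≥ 1 bp CRM overlap; we do not implement a base-weighted dot-product
reading). `filterByZscore()` then standardizes each target's CRM
strengths with the population standard deviation and removes CRMs below
$\lambda$ (1.5 isolates clearly dominant CRMs, 0 keeps above-average
ones); targets with fewer than two CRMs or zero spread are exempt —
a z-score is meaningless there.

`snpRegionFc()` computes SNP fold-change enrichment over a p-value
ladder ($1$ down to $10^{-9}$ by decades by default): each SNP's p is
its minimum over traits, and at each threshold
$\mathrm{FC}=(P_r/L_r)/(P/L)$ compares SNP density inside the (merged)
regions with the genome-wide density. `alleleMotifDiff()` rescans the
windows covering a variant under both alleles and reports gained/lost
motifs and score changes. `empiricalOverlapPvalue()` relocates an
element set uniformly at random — lengths preserved, same chromosome by
default (a genome-wide flag exists), overlaps among relocated elements
allowed — and reports the fraction of relocations whose overlap count
reaches the observed count. Because published empirical p-values are
sometimes computed with a strictly-greater rule, both variants and the
plus-one-corrected value are returned rather than guessing one intent.

# The synthetic generator

`generateTruth()` builds the study the tests run on: a random genome
(default 2 chromosomes × 100 kb), 300 non-overlapping elements, 20 TFs
with sharply peaked motifs, 100 TGs, truth edges at density 0.1 with
log-normal strengths, each edge's motif planted into 1–3 candidate
elements of its target, and a linear element-to-gene model that
generates expression from accessibility. Two identifiability choices are
deliberate: each element is used by at most one target gene (reuse
across targets would couple one element's regression weight to several
genes, making exact recovery impossible even without noise), and the
planted motifs' hit threshold defaults to 0.9 of the maximum score, so
essentially only exact plants are hits. Planted instances within one
element never overwrite each other.

`simulateReplicates()` adds zero-clamped Gaussian noise (default
standard deviation 0.2 × the mean truth strength) to every pair's score
— so noise also creates spurious edges, as it does in practice — and
jitters CRM endpoints by ±10 bp. `simulateSnpPanel()` places causal
SNPs uniformly over truth CRM bases with minimum-trait p-values
$10^{-U(5,9)}$ and background SNPs uniformly with $U(0,1)$ p-values.
Everything is deterministic given the seed, and the generator restores
the caller's RNG stream.

What the generator does *not* emulate: linkage disequilibrium among
SNPs, read-level noise, peak calling, motif families with shared
binding preferences, chromatin-state correlation along the genome, or
replicate-specific batch structure. Passing tests therefore demonstrate
correctness of the algorithms under the stated noise model, not
performance on real sequencing data.

Study sizes used by the test suite and the acceptance script, chosen to
keep each study in the minutes range on one CPU: the
consensus-versus-single-replicate comparison runs the full default
generator (6 replicates, 20 TFs × 100 TGs) over 20 independent
simulations with the $\mu\in\{0, 0.1, 1\}$ sparsity grid; the null
calibration of the overlap test uses 200 trials of 200 shuffles with
150 elements per trial (the overlap count must be fine-grained for its
empirical p-value to be approximately uniform — with a handful of
elements the p distribution is an unavoidably coarse staircase); motif
and solver oracles run on instances of a few dozen elements.

# Worked example

```{r example, eval = FALSE}
truth <- generateTruth(truthConfig(seed = 1))
sim <- simulateReplicates(truth, seed = 2)
cn <- finalizeNetwork(consensusOptimize(sim$networks, mu = 1))
cn
gold <- setNames(edges(truth$network), c("regulator", "target"))
univ <- c(paste0("TF", 1:20), paste0("TG", 1:100))
edgeMetrics(setNames(edges(cn), c("regulator", "target")), gold, univ)
```

# Known limitations

* The consensus iteration is a fixed-point scheme on the relaxed
  problem's stationarity conditions, not a certified global optimizer;
  for large $\beta$ or $\gamma$ relative to $\omega\alpha$ it can fail
  to contract (the solver then returns the last iterate with a
  warning).
* The per-replicate scoring assumes activating regulation through
  accessibility; repressive regulation enters only through the
  correlation factor.
* The nearest-TSS baseline uses enhancer midpoints and raw distance; it
  is a deliberately simple proximity rule, not a gene-regulatory domain
  model.
* Coordinates are converted between the 0-based half-open text formats
  and 1-based closed `GRanges` at the I/O boundary only; cited genomic
  positions in external text should be checked against their source's
  convention before comparison.
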