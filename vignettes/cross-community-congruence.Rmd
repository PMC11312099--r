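---
title: "Cross-community congruence: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-community congruence: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crosscomm)
```

# The question the package answers

Paired microbial communities — the endophytes of a holoparasitic plant and
the rhizosphere of its host, gut and skin microbiota of the same animals,
bacteria and fungi of the same soil cores — often appear to change in
concert across samples. `crosscomm` quantifies that impression and then
asks a sharper question: *which* taxonomic groups carry the concordance?

The core procedure is a four-stage chain:

1. **Weighted UniFrac** turns each community's count table and phylogeny
   into a sample-by-sample distance matrix. For samples with relative
   abundance vectors $p$ and $q$, each branch of length $b$ whose
   descendant leaves hold abundance totals $P$ and $Q$ contributes
   $b\,|P - Q|$; the normalized variant divides by $\sum b\,(P + Q)$ so
   distances live in $[0, 1]$.
2. **PCoA** (classical metric scaling) embeds each distance matrix:
   Gower-center $B = -\tfrac12 J D^{(2)} J$, eigendecompose, and scale
   eigenvectors by $\sqrt{\lambda}$. The congruence analysis uses the
   first two axes.
3. **Symmetric Procrustes** superimposes the two ordinations. After
   centering and unit-norm scaling of both score matrices, the SVD
   $X^\top Y = U \Sigma V^\top$ gives the congruence statistic
   $t_0 = \operatorname{tr}\Sigma = \sqrt{1 - m^2}$, with $t_0 = 1$ for
   perfectly superimposable configurations and $t_0 \approx$ the null
   level for unrelated ones. **PROTEST** permutes the sample order of one
   side to attach a p-value, using the add-one estimator
   $(1 + \#\{t_{\mathrm{perm}} \ge t_0\})/(B + 1)$.
4. **Leave-one-out $\Delta t$**: for every group at a chosen rank
   (phylum by default), remove the group's taxa from *both* tables,
   recompute UniFrac, PCoA and $t_0'$, and report
   $\Delta t = t_0' - t_0$. Groups that support the congruence yield
   negative $\Delta t$; groups that mask it yield positive values.

Around this chain the package provides alpha diversity (Chao1, Simpson,
Pielou), rarefaction, co-occurrence networks with Zi/Pi node roles, and a
microbe–metabolite Spearman + Z-test screen, because these are the
analyses a study of such a system runs on the same tables.

# The synthetic-data generator

Real paired-community data with a *known* answer do not exist, so the
package ships a generator whose ground truth is explicit. Per sample $j$,
shared factors $f_j \sim N(0, I_K)$ and community-specific factors
$g^A_j, g^B_j \sim N(0, I_K)$; per taxon $i$, a baseline
$b_i \sim N(0,1)$ and loadings $w_i \sim N(0, I_K / K)$. The
log-propensity in community $C$ is

$$\eta^C_{ij} = b_i + w_i^\top\!\left(\lambda f_j + (1-\lambda) g^C_j\right) + \varepsilon_{ij},
\qquad \varepsilon_{ij} \sim N(0, \sigma^2),$$

relative abundances are the softmax of $\eta$ over taxa, and counts are
multinomial at a fixed depth $N$. The coupling $\lambda \in [0,1]$ is the
dial: $\lambda = 0$ gives independent communities (a null for PROTEST),
$\lambda = 1$ fully shared structure. When a **carrier phylum** is set,
taxa outside it have their shared-factor term replaced by an independent
community-B-only factor, so the carrier alone links the two communities —
exactly the situation the leave-one-out statistic is supposed to detect.

Defaults describe the reference scenario used throughout validation:
30 taxa in 5 phyla on 20 paired samples, $K = 3$ factors,
$\lambda = 0.9$, carrier `Phylum_1`, $\sigma = 0.5$, 5,000 reads per
sample. These are desk-scale sizes chosen to resemble a small amplicon
study after abundance filtering; they keep a full 20-replicate recovery
experiment under a minute.

Trees are Yule (pure-birth) topologies with independent exponential(1)
branch lengths. Phyla are made monophyletic by cutting the tree at its
deepest internal edges (tip-ward, ties to the lowest node id), which
peels small terminal clades off a dominant residual group; groups are
labelled `Phylum_1`, `Phylum_2`, ... by decreasing size. Two properties
recommend this construction. First, removing a phylum then corresponds to
pruning whole clades, as with real phyla. Second, the dominant group is a
realistic carrier: in the motivating systems the congruence-supporting
phyla (e.g. Ascomycota among root fungi) are dominant community members,
and a carrier that holds a vanishing share of the community could not be
detected by *any* abundance-weighted method at these sample sizes.

Coupled metabolites track one taxon's log relative abundance with slope
$|\alpha_m| \sim U(1, 2)$ (random sign) plus Gaussian noise; uncoupled
metabolites are pure noise. Intensities are shifted non-negative, which
leaves every rank-based statistic untouched.

What the generator does **not** emulate: sequencing error and chimeras,
overdispersion beyond the multinomial, phylogenetic signal in the factor
loadings (loadings are i.i.d. across taxa, so related taxa do not
co-respond more than unrelated ones), metabolite–metabolite correlation,
and compositional effects stronger than the softmax induces. Passing
tests therefore show that the statistics recover the structure they
target in clean compositional count data — not that they are robust to
every artefact of a real sequencing run.

# Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `coupling` ($\lambda$) | 0.9 | weight of shared vs community-specific factors, in $[0,1]$ |
| `carrier_phylum` | `"Phylum_1"` | only its taxa carry the shared signal in community B (`NULL`: all taxa) |
| `noise_sd` ($\sigma$) | 0.5 | taxon-by-sample log-propensity noise |
| `reads_per_sample` ($N$) | 5000 | multinomial depth (reads) |
| `n_factors` ($K$) | 3 | latent dimensionality |
| `normalized` (UniFrac) | `TRUE` | bounded variant; raw sum available |
| `n_axes` (PCoA) | 2 | axes entering Procrustes |
| `n_permutations` | 999 | PROTEST permutations |
| `r_threshold`, `p_threshold` | 0.6, 0.05 | network edge filter, both strict |
| `zi_threshold`, `pi_threshold` | 2.5, 0.62 | node-role cutoffs |

The role thresholds follow the conventional module-hub/connector scheme;
they are exposed as arguments because the underlying studies rarely print
them. The edge filter is deliberately strict on both sides (`|r| > 0.6`
**and** `p < 0.05`): an edge at exactly the threshold is excluded.

# Numerical and design choices

**Normalized UniFrac by default.** Only "weighted UniFrac" is named in
the motivating analyses; the normalized form is bounded, is the common
default in ecology toolkits, and makes distances comparable across sample
pairs. The raw variant is a flag, and the leave-one-out loop inherits
whichever the caller picks.

**Negative PCoA eigenvalues are dropped, not corrected.** No Cailliez or
Lingoes adjustment: the congruence chain uses only the leading two axes,
which the correction leaves essentially unchanged, and
`proportion_explained` uses the sum of positive eigenvalues as its
denominator. Each axis is sign-fixed (largest-magnitude score positive)
so repeated runs write identical files.

**Symmetric Procrustes, reflections allowed.** Both configurations are
centered and scaled to unit Frobenius norm before the SVD, making
$t_0(X, Y) = t_0(Y, X)$ a correlation-like statistic in $[0, 1]$. The
optimal orthogonal map may include a reflection, the standard choice for
this protocol. $t_0$ is clamped at 1 against rounding overshoot so the
invariant $t_0 = \sqrt{1 - m^2}$ holds to $10^{-10}$.

**Leave-one-out removes the group from both communities.** Removing from
one side only would leave the other side's UniFrac unchanged; the
one-sided variant remains available (`side = "one"`). Baseline and
leave-one-out $t_0$ are always computed under identical settings, so
$\Delta t$ is a pure group effect. A group whose removal would empty any
sample is skipped, warned about, and flagged in the output rather than
silently dropped. A group with zero abundance everywhere yields
$\Delta t = 0$ exactly, a useful self-check.

**Greedy modularity is authored in-package.** The Clauset–Newman–Moore
agglomeration is implemented directly with a stated deterministic
tie-break (lowest community-id pair, communities identified by their
smallest node index) and an explicit best-Q cut along the merge path;
an exhaustive-search oracle on a two-clique fixture pins the behaviour
in the tests. Modularity is computed on the unweighted graph — edge
presence only — since module analysis in this setting does not use edge
signs or weights.

**Pseudo-p by per-taxon permutation.** Null datasets permute each taxon's
values independently across samples, destroying pairwise association
while preserving each taxon's margin; `p = (1 + \#\{|r_{null}| \ge |r|\})/(B+1)`.
The term "bootstrap" is used loosely in this literature; the permutation
null is the variant that is exact under independence, and the resampling
scheme is isolated in one function should a resampling-with-replacement
variant ever be needed.

**Spearman + Fisher-z screen.** Significance uses
$z = \operatorname{atanh}(r)\sqrt{n-3}$ against the standard normal,
two-sided, with $r$ clamped to $\pm(1 - 10^{-15})$ so perfect monotone
association gives $p = 0$ rather than an infinity. The classical 1.06
variance correction for Spearman correlations is *not* applied, which
makes the test mildly anticonservative at small $n$ (empirically a 5.2%
rejection rate at the nominal 5% with $n = 20$); flags are raw-p by
design to match the star-annotation convention, with Benjamini–Hochberg
available behind `p_adjust = "BH"`.

**SparCC-basic.** The log-ratio-variance estimator with the sparsity
approximation and up to 10 exclusion rounds of the most-correlated pair
is provided for compositional data (`method = "sparcc"`); Spearman on
relative abundances is the default because its null behaviour under
permutation is exact and fast.

**Boundary semantics are literal.** Differential-metabolite screening
keeps a row iff VIP > 1 (strict), p < 0.05 (strict) and |log2FC| ≥ 1
(inclusive) — the three boundary cases are pinned in the tests.

# Degenerate inputs

All-zero samples are errors naming the sample; taxa with positive counts
missing from the tree are errors listing the offenders; constant features
are skipped with a warning in correlation screens; a module whose
within-degree standard deviation is zero gets $Z_i = 0$ for all members;
isolated nodes get $P_i = 0$; Pielou evenness is `NA` for single-taxon
samples; trees without branch lengths load with lengths 0 and a warning.

# What the validation shows

The test suite establishes, among others: exact agreement of weighted
UniFrac with a brute-force branch-enumeration oracle on random
tree/table pairs ($10^{-10}$); $t_0 = 1$ to $10^{-10}$ under arbitrary
rigid transforms and agreement with a 2-D rotation-grid search to
$10^{-6}$; PROTEST type-I error inside the exact binomial 99% band at
$\alpha = 0.05$ over 500 null replicates; recovery of the carrier phylum
as the most negative $\Delta t$ in at least 18 of 20 replicate scenarios
under the reference conditions; and the null calibration plus
near-certain detection of planted couplings by the association screen.
Problem sizes in the suite (up to 10-leaf trees for oracle comparisons,
20-sample scenarios, 500-replicate calibrations) were chosen so the whole
suite runs in about a minute on one core while keeping every Monte-Carlo
bound comfortably powered.

# Known limitations

* $\Delta t$ attributes congruence to groups one at a time; two phyla
  that jointly carry a signal redundantly can each look dispensable.
* With 2 PCoA axes and 20 samples the Procrustes null mean is well above
  zero, so $t_0$ values need their PROTEST p-value for interpretation —
  a bare $t_0 \approx 0.4$ means little.
* The Fisher-z Spearman test is approximate at small $n$ (see above);
  for $n < 10$ an exact permutation test would be preferable.
* SparCC-basic implements the core estimator, not the full iterative
  procedure with multiple random pseudo-count draws.
* The generator's phyla are monophyletic by construction except the one
  residual group, which is the tree minus the peeled clades.
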