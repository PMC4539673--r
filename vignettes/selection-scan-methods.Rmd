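---
title: "Methods: selection scans on ortholog clusters"
author: "orthoselect"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: selection scans on ortholog clusters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orthoselect)
```

# Overview

`orthoselect` scans clusters of orthologous coding sequences from a small
set of closely related species (the motivating setting is four freshwater
snail species) for signatures of positive selection, using three
complementary tests, and asks which biological-process GO categories are
over-represented among the selected genes. The pipeline is:

1. **Codon-aware alignment** of each cluster: translate, align the
   proteins, back-translate so gaps respect codon boundaries.
2. **Divergence filter**: clusters whose mean pairwise nucleotide
   divergence is 10% or more are discarded, to limit misalignment and
   saturation artefacts.
3. **Three selection tests**: branch-model dN/dS with likelihood-ratio
   tests, a codon-level McDonald–Kreitman (MK) test driven by read-depth
   and allele-count data, and a physicochemical amino-acid property test.
4. **Consensus**: per-cluster union/intersection bookkeeping across
   methods, and a chi-squared homogeneity test of category frequencies
   across branches.
5. **Dual-set GO enrichment** with Benjamini–Hochberg FDR control.

A codon-sequence simulator generates data with the statistical structure
each stage assumes, so every stage is testable without external data.

# The codon substitution model

The branch test uses a GY94-style continuous-time Markov model over the
61 sense codons. The instantaneous rate from codon $i$ to $j$ is zero
unless they differ at exactly one nucleotide position and $j$ is a sense
codon; otherwise

$$ q_{ij} = \pi_j \,\kappa^{[\text{transition}]}\, \omega^{[\text{non-synonymous}]} $$

with $\kappa$ the transition/transversion rate ratio, $\omega = dN/dS$,
and $\pi$ the stationary codon frequencies. $\omega = 1$ corresponds to
neutral evolution, $\omega < 1$ to purifying and $\omega > 1$ to positive
selection. The generator is rescaled so branch lengths are expected
substitutions per codon.

Implementation choices:

* **Codon frequencies** are fixed at their F3x4 estimates (products of
  position-specific nucleotide frequencies, renormalized over sense
  codons) with a pseudocount of 0.5 per nucleotide and position so all
  frequencies stay positive on short alignments.
* **Likelihood** is computed by Felsenstein pruning over compressed codon
  site patterns; codon columns containing a gap, `N` or stop in any row
  are excluded. The reversible generator is diagonalized through its
  symmetrized form, and the decompositions are cached per $(\kappa,
  \omega)$ within a fit, since most optimizer moves only change branch
  lengths.
* **Fitting**: the rooted input tree is unrooted (root placement is not
  identifiable under a reversible model), and the likelihood is maximized
  by bounded quasi-Newton (L-BFGS-B) over $\kappa \in [0.1, 50]$,
  $\omega \in [10^{-4}, 20]$ and branch lengths in $[10^{-6}, 5]$, with a
  convergence tolerance of about $10^{-6}$ relative on the
  log-likelihood. Three deterministic starts (a data-driven
  initialization from the mean pairwise divergence, plus an up- and a
  down-jittered copy) guard against local optima; free-ratio fits can be
  warm-started from the one-ratio solution, which is also the natural
  nested starting point.
* **Test**: one-ratio (a single shared $\omega$) versus free-ratio (one
  $\omega$ per branch) fits are compared by a likelihood-ratio test with
  `branches − 1` degrees of freedom (five branches on an unrooted
  four-taxon tree, hence `df = 4`). P-values are corrected across
  clusters by Benjamini–Hochberg. A branch is called positively selected
  when its free-ratio $\hat\omega > 1$ **and** the cluster-level LRT
  passes the FDR threshold (0.05 by default) — the conjunction is the
  conservative reading when both criteria are reported side by side.

# The codon-level MK test

For a species pair with per-position read depths and allele counts, every
complete codon (no gap or `N` in either row) is classified position by
position:

* A position is **polymorphic** when read depth is at least 10 and the
  minor allele frequency is at least 0.2 (computed over allele counts,
  not raw depth, since depth may include ambiguous reads); below depth
  10 it is `no_data`; otherwise monomorphic. The inclusive reading of
  the MAF cutoff is deliberate — a strict inequality at a published
  cutoff value would be meaningless.
* Positions polymorphic in either species contribute to **P** (one event
  per polymorphic species and position, labelled synonymous or
  non-synonymous by applying the major-to-minor change on that species'
  codon background). A position that is both polymorphic and divergent
  counts as P only: the counting is exclusive, and polymorphism is the
  more conservative assignment.
* Positions whose letters differ between the species and are monomorphic
  in both (including `no_data`, which is treated as monomorphic for
  D-calling, with the cluster's no-data fraction reported) contribute to
  **D**. Multi-hit codons are resolved by Nei–Gojobori-style averaging
  over all minimal mutational pathways, excluding pathways through stop
  codons; this can make counts fractional.

Positive selection is called from the raw ratio comparison
$D_n/D_s > P_n/P_s$, evaluated in cross-product form
$D_n P_s > P_n D_s$ with two guards: at least one synonymous observation
($D_s > 0$ or $P_s > 0$) and $D_n > 0$, so degenerate tables are never
called. The classical 2×2 Fisher p-value is reported alongside for
auditability but plays no role in the verdict.

# The amino-acid property test

Ancestral codon states are reconstructed at the internal nodes by
marginal maximum likelihood under the fitted one-ratio model (MAP state
per node and site; ties broken towards the codon with the higher
stationary frequency; sites with maximum posterior below 0.5 are skipped
on that branch). For every branch and codon where the parent and child
amino acids differ, one event per property scale records the absolute
property change.

The package ships 31 published amino-acid property scales (bulkiness,
polarity, isoelectric point, hydropathy, volume, accessible surface
area, charge, flexibility, and related scales) taken from the AAindex
collection bundled with the seqinr package; any user-supplied table is
accepted. Changes are binned into 8 equal-width **impact classes**
spanning the range of property changes observed when every
single-nucleotide non-synonymous change among sense codons is enumerated
with equal weight; classes 6–8 are "radical".

A window of 20 codons slides along the alignment (step 1 by default);
within each window the observed class counts are compared to the neutral
expectation by a chi-squared goodness-of-fit test, pooling classes with
expected count below 1 and skipping windows with fewer than 2 events. A
branch is called positive when some property has a window with
$p < 0.001$ containing at least two distinct codons whose events reach
impact class ≥ 6 — the two-codon requirement guards against single
sequencing or assembly errors.

# Consensus and enrichment

Per-cluster verdicts from the three methods are merged into union and
intersection counts ("how many clusters are positive by at least one
method / exactly one / all three"). For a functional category, a
chi-squared test with uniform expected frequencies asks whether its
positive clusters are spread homogeneously across branch classes
(`df = branches − 1`); MK calls are tagged with a species pair rather
than a branch and are excluded from this per-branch test.

GO enrichment is a one-tailed hypergeometric over-representation test
per term, BH-corrected, with the reference annotation set as the
universe. It is run twice — once for the selected clusters, once for
their complement — and terms enriched in **both** sets are flagged as
possible ascertainment bias and excluded from interpretation
(the dual-set exclusion rule). GO terms are used as annotated; no
ancestor propagation through the ontology graph is performed, because the
annotation inputs are flat term lists and propagation would change counts
in ways the caller cannot audit.

# The synthetic-data generator

`simulateStudy()` emulates the inputs the pipeline consumes:

* Root codons are drawn from the stationary distribution (uniform over
  sense codons by default) and evolved along the fixed species tree under
  branch-specific $\omega$ via the model's transition matrices. The
  default tree is a four-species caterpillar — a sister pair plus two
  successively deeper outgroups — with branch lengths chosen so the mean
  nucleotide divergence stays below the 10% filter, as in the kind of
  closely related species group the pipeline targets.
* Defaults: $\kappa = 2$, background $\omega = 0.2$ (typical purifying
  load), $\omega = 4$ on one designated branch in a 10% fraction of
  clusters, 150 codons per cluster.
* **Polymorphism** is overlaid at the leaves independently of the
  phylogenetic process (an infinite-sites-style overlay, not a
  within-species coalescent — a documented simplification sufficient to
  exercise the MK test's statistical structure): each nucleotide position
  becomes polymorphic with probability $\theta/3$ per site
  ($\theta = 0.03$ heterozygous sites per codon by default, i.e. about
  one SNP per 100 nt, a realistic transcriptome-wide density), with minor
  allele frequency uniform on $[0.1, 0.5]$ and the minor allele drawn
  from the same $\kappa$-biased mutation process as divergence — without
  that bias the MK test's neutral expectation would not hold by
  construction. Read depths are negative-binomial (mean 30, dispersion
  5), emulating RNA-seq coverage heterogeneity so that the depth ≥ 10
  rule actually censors data.
* **GO annotations**: each cluster draws 3 background terms uniformly
  from a pool of 50; planted terms are added with probability 0.08 to
  unselected and `min(1, 0.08 × odds)` to selected clusters (odds 10 by
  default).

What passing tests on these simulations do **not** show: robustness to
misalignment, assembly chimeras, within-species population structure,
indel evolution, or annotation noise — none of which the generator
emulates.

# Calibration experiments and their problem sizes

The test suite validates the machinery in two ways. Exact oracles:
pruning equals exhaustive enumeration over internal-node codon states on
2-, 3- and 4-taxon trees to $10^{-10}$; MK pathway averaging equals
exhaustive minimal-pathway enumeration for all 61×61 codon pairs;
neutral impact-class distributions equal a brute-force enumeration of the
genetic code; enrichment p-values equal hypergeometric tail sums.

Statistical calibration, with sizes chosen to balance precision against
runtime: $\omega$ recovery over 50 clusters × 500 codons per setting;
elevated-branch detection (ω = 4) over 50 such clusters; the LRT type-I
rate over 200 neutral replicates of 120 codons; MK neutrality
(divergence ratio vs polymorphism ratio) over 200 two-species replicates;
property-test p-value uniformity over ≥200 windows drawn one per
simulated cluster so the Kolmogorov–Smirnov test sees independent values.
For that last experiment the generator is run with $\kappa = 1$ and the
model parameters are supplied from the simulation truth rather than
re-estimated: the neutral expectation weights every single-nucleotide
change equally, so a transition-biased mutation process would make the
goodness-of-fit test reject for reasons unrelated to the window scan
being validated. The calibration is restricted to windows with at least
4 events: the chi-squared reference distribution is asymptotic, and
below that the p-values are so discrete that no continuous-uniformity
check is meaningful (the package's own scan keeps its default of 2
events, where the call threshold of p < 0.001 is still conservative).
Even so the p-values remain mildly discrete, which is inherent to
small-count goodness-of-fit tests.

# Known limitations

* The progressive protein aligner is deterministic and exact for pairs,
  but like all progressive methods it can be suboptimal for more
  sequences; a pre-made protein alignment can be supplied instead.
* No site-model or branch-site tests; the branch test averages over
  sites and has limited power for selection confined to a few codons —
  that is what the property test's window scan compensates for.
* The MK verdict is the raw ratio comparison, faithfully reproducing the
  decision rule it implements — it is a classifier, not a significance
  test. Under neutral simulation roughly half the clusters fall on the
  positive side of the ratio comparison; interpret the verdict together
  with the reported Fisher p-value when error control matters.
* The MK implementation is unpolarized (no outgroup) and does not
  estimate the adaptive proportion α.
* Ancestral-state uncertainty is handled by thresholding the marginal
  posterior, not by integrating over reconstructions.
* Fractional MK counts are rounded for the auxiliary Fisher test.
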