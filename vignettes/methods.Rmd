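---
title: "Methods: connectivity screening of germinal-zone signatures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: connectivity screening of germinal-zone signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nichescreen)
```

This vignette documents the models, parameter choices, and numerical
conventions behind `nichescreen`. The package screens directional
transcriptional signatures of neural germinal-zone states — dorsal versus
lateral subventricular-zone (SVZ) identity, the oligodendrocyte lineage,
and the postnatal-versus-adult neural-stem-cell (NSC) state — against a
database of drug-perturbation expression profiles, ranks the drugs by how
many signature genes they perturb, and characterizes the hits.

## Signature construction

A *contrast* compares a positive condition range (the state the signature
should capture) against a negative range. Per probe we use the two-sample
Student *t* with pooled variance, two-sided, across all replicate samples
of each range; Benjamini–Hochberg adjustment runs over all tested probes.
A probe passes when its linear fold change satisfies
\(2^{|\Delta|} \ge \theta_{FC}\) (\(\Delta\) the log2 mean difference) and
its BH *q* is below the FDR level. The screening defaults are
\(\theta_{FC} = 1.8\) and FDR < 5%; a 1.65-fold variant of the same filter
is the convention for profiling secreted-morphogen expression, and both are
plain arguments to `contrast_spec()`.

Design notes, where the procedure was genuinely open:

* *"Student's t test"* is read as the pooled-variance test, not Welch —
  matching the test that name denotes; replicate groups here are small and
  of equal design.
* Fold-change thresholds are interpreted on the **linear** scale
  (1.8× means \(|\Delta| \ge \log_2 1.8 \approx 0.848\)).
* Probe → gene collapsing keeps the probe with the biggest **absolute**
  fold change (ties: smaller *p*, then lexicographic probe id). Directional
  signatures require the absolute reading; a signed maximum would
  systematically discard strong down-regulation.
* Zero-variance degenerate probes: equal group means give \(t = 0, p = 1\);
  unequal means with zero pooled variance give \(p = 0\).
* Negative-range *refinement* removes a passing gene when any refinement
  contrast shows it passing the same thresholds **in the same direction**
  (it is then not specific to the positive range). The any-direction
  variant is available via `exclude = "any"`; same-direction is the default
  because a gene moving the opposite way in the refinement range does not
  contradict specificity.

## Connectivity scoring

The default scorer is the classic two-sided Kolmogorov–Smirnov running-sum
statistic of connectivity mapping. For one tag set (the signature's up- or
down-genes) of size \(t\) at sorted positions \(V(j)\) in an instance's
ranking of \(n\) genes:

\[
a = \max_{j} \left( \tfrac{j}{t} - \tfrac{V(j)}{n} \right), \qquad
b = \max_{j} \left( \tfrac{V(j)}{n} - \tfrac{j-1}{t} \right),
\]

with \(ks = a\) if \(a > b\), else \(-b\). The combined instance score is
\(ks_{up} - ks_{down}\) when the two statistics have opposite signs and 0
otherwise; it lies in \([-2, 2]\). Signatures with an empty side are scored
one-sided (the populated side's statistic, negated for the down side) and
flagged. Signature genes absent from an instance's universe are dropped per
instance with a logged count.

The alternative `"corr"` scorer is the Pearson correlation between the
signature's ±1 direction vector and the instance's log2 fold changes over
the gene intersection (minimum overlap 3), with a two-sided *p* from the
*t* transform of *r*. Both scorers ship because the screening literature
uses both lineages of pattern matching; the KS statistic is the default.

Instance scores aggregate to drugs by the mean (median by flag), then all
drug aggregates are divided by the maximum absolute aggregate so scores lie
in \([-1, 1]\). Calls are made by sign above a configurable magnitude floor
(default 0: any nonzero score is called). Aggregation by mean is a package
choice; drug-level summarization is not dictated by the screening
literature this pipeline follows.

Permutation *p*-values rescore `n_perm` random signatures of identical
up/down sizes drawn from the gene universe, per drug, with
\(p = (1 + \#\{|null| \ge |obs|\}) / (n_{perm} + 1)\). Each drug consumes
its own RNG stream derived from the master seed and a hash of the drug
name, so *p*-values are independent of database order. One calibration
caveat is intrinsic to the KS statistic: the same-sign rule places a
probability atom at exactly 0 (roughly half of null scores), so its
permutation *p* is discrete and conservative rather than continuously
uniform. Null calibration is therefore assessed with the correlation
scorer, whose statistic is continuous; its *p*-values are uniform on the
null up to the \(1/(n_{perm}+1)\) grid.

## Target genes and drug ranking

A drug's *perturbed genes* pool its instance profiles: per gene, the mean
log2 fold change and a one-sample Student *t* against 0 across instances;
genes with \(p \le 0.05\) are kept, and probe-level databases collapse to
genes by the max-|FC| rule after filtering. Single-instance drugs cannot
support a *t*-test; an explicit fold-change fallback threshold must be
supplied and the result is flagged. *Target genes* are the intersection of
the perturbed set with the query signature, and their count is the ranking
statistic: drugs split by call sign, sorted by count descending, ties by
name ascending. The package reports the intersection count by default
(that is what the target-gene definition prescribes); the raw perturbed
count is available for comparison since published count tables can be read
either way.

Screen-to-screen similarity is summarized by the top-\(k\) ranking overlap
\(|A_k \cap B_k| / k\); for random rankings over \(d\) drugs its
expectation is \(k/d\), which the tests verify by simulation.

## Annotation

Ranked drugs are classified by the functional category of their
highest-priority protein target, priority being row order of the
drug-target table; a drug with several targets counts once, because the
category breakdown is a pie that must sum to 100%. Drugs without targets
fall into `uncharacterized`. Rows order by count descending with
alphabetical tie-break — the clockwise pie order.

Target-gene enrichment uses the one-sided hypergeometric tail
\(P(X \ge k)\) per category with BH adjustment across categories, run
separately on up- and down-regulated target genes. A proprietary
process-network statistic used in commercial platforms is not publicly
specified; the hypergeometric over-representation test is the standard open
substitute and is documented as such. Default reporting FDR is 2% (1% for
the stricter oligodendrocyte profiling convention); both are arguments.

## Expression profiling

Target-gene expression is row-standardized (mean 0, s.d. 1; constant rows
become zeros and are flagged) and clustered agglomeratively with
1 − Pearson distance and average (UPGMA) linkage — the usual defaults for
expression heatmaps; Euclidean distance and complete linkage are flags.
The agglomeration loop is written in the package rather than delegated,
because the output contract fixes behaviour `hclust` leaves unspecified:
ties in the minimum inter-cluster distance resolve toward the
smallest-label pair, and leaf order follows the tighter-cluster-first
recursion (the lower-height child leads; singletons have height 0). On
tie-free data the dendrogram agrees with `hclust` exactly (the test suite
compares cophenetic matrices), and `as_hclust()` converts the result for
plotting and `cutree`.

## Subnetworks

Shortest paths use Dijkstra's algorithm (via igraph) over non-negative
edge weights; unweighted graphs get unit weights. All tied predecessors
are retained so every shortest path is enumerable. The subnetwork
connecting a screen's target genes is the union of all shortest paths
between seed pairs, assembled by whole path-length strata in ascending
order: a stratum is added only if the running node count stays within the
cap (default window 70–80 nodes). Never truncating within a stratum makes
the result order-independent and monotone in the cap; a union that ends
below the lower cap is returned as-is and flagged. Disconnected seed pairs
are reported, never silently dropped. The signaling-to-transcription
option restricts pairs to paths from a ligand/receptor/kinase seed to a
transcription-factor/target-gene seed.

## The synthetic-data generators

The generators emulate the statistical structure of a germinal-zone
expression compendium and a rank-based drug-perturbation database; their
defaults are the package's study conditions and are not tuned per run.

* **Compendium** — seven conditions (dNSC, dTAP, lNSC, lTAP, OPC, mOL,
  aNSC) × 3 replicates; 1,000 genes with 1–3 probes each; per-probe
  baselines \(\mathcal{N}(7, 1.2^2)\) on the log2 scale, i.i.d. Gaussian
  noise with s.d. 0.5 — the simplest model consistent with RMA-normalized
  intensities, which is all the input contract assumes. Each screen plants
  a disjoint block of 150 differential genes with log2 effect 2.0 (4× the
  noise s.d., a strong but realistic microarray effect), half up and half
  down; probes of a planted gene share its direction with magnitudes
  jittered ±20% so max-|FC| collapsing is non-trivial.
* **Drug database** — 200 drugs × 3 instances over the same gene universe.
  Null drugs draw exchangeable uniform keys; a planted mimic of strength
  \(s\) and sign + sets the key of up-genes to \((1-s)u + s\) and of
  down-genes to \((1-s)u\), so displacement toward the rank extremes is
  proportional to \(s\), the expected KS score is monotone in \(s\), and at
  \(s = 1\) every up-gene ranks above every null gene, which ranks above
  every down-gene. Sign − swaps the two sets. Fold changes are the normal
  quantile of the rank midpoint, so ranks and fold changes are always
  consistent. Cell line and dose metadata are generic labels: the screening
  literature does not specify the instance structure it averages over, so
  the instance model is deliberately plain.
* **Annotations** — six categories named after the broad perturbagen
  classes (receptor antagonists, signaling, metabolism, gene regulation,
  epigenetics, cell cycle) partition both the protein-target universe and
  the gene universe; every drug receives 1–3 protein targets.
* **Graph** — a directed typed graph over a sample of the gene universe; a
  random-attachment backbone over 90% of nodes guarantees a weak giant
  component ≥ 80%, with no self-loops.

Every generator draws from its own RNG stream, derived from the master
seed by a fixed offset, so adding one generator never perturbs another's
output, and the whole pipeline is a pure function of (config, seed).

What the synthetic data does *not* emulate: probe-level cross-hybridization
and platform quirks, batch effects, correlated noise between genes,
cell-line-specific drug responses, and dose–response structure. Passing
tests therefore demonstrate correctness of the statistics and determinism
of the pipeline on data with the declared structure, not robustness to the
artefacts of real microarray compendia.

## Problem sizes and tolerances

The test suite and acceptance script use these sizes: spiked-drug recovery
at 200 drugs × 1,000 genes × 3 instances with 5 planted mimics of strength
0.9; KS-oracle equivalence on 1,000 random pairs with universes ≤ 20
(exact equality); DE oracles at tolerance 1e-10 on the packaged 12-probe
fixture; null calibration on 500 single-instance strength-0 drugs with 200
permutations, judged by a 10-bin chi-squared goodness-of-fit at
\(\alpha = 0.01\); network oracles on 200 random graphs ≤ 8 nodes
(exhaustive simple-path enumeration) and 40-node stratum-rule fixtures;
clustering oracles on 4–6-point fixtures. The four-screen end-to-end run
uses a reduced 250-gene, 30-drug configuration
(`inst/extdata/synthetic_config.yaml`) and checks byte-identical manifests
across repeated runs.

## Known limitations

* The KS permutation *p* is conservative by construction (atom at 0); use
  the correlation scorer when calibrated *p*-values matter.
* Moderated/empirical-Bayes *t* statistics, paired designs, and
  multi-factor models are out of scope for signature construction.
* Drug-level aggregation ignores cell-line stratification.
* The hypergeometric enrichment does not model ontology structure or
  gene-length bias; categories are treated as flat sets.
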