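---
title: "Methods: network entropy and the tITH score"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: network entropy and the tITH score}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tith)
```

## The model

`tith` treats a bulk RNA-seq sample as a state of a protein-interaction
network and measures intratumor heterogeneity as drift of that state
toward maximal ambiguity. Three ingredients:

**Mass-action neighbor distributions.** For gene $i$ with neighbor set
$J_i$ and expression values $e_j \ge 0$ (log2-normalized units), the
probability of interaction with neighbor $j$ is
$p_{ij} = e_j / \sum_{k \in J_i} e_k$. The assumption is that binding
events are proportional to partner abundance (law of mass action);
everything downstream depends only on expression *ratios* within each
neighborhood, so the measure is invariant to global rescaling of a
sample.

**Per-gene Jensen–Shannon divergence.** Two samples are compared at
gene $i$ by the JSD of its neighbor distributions,
$\mathrm{JSD}_i = \tfrac12\mathrm{KLD}(P\|M) + \tfrac12\mathrm{KLD}(Q\|M)$
with $M = \tfrac12(P+Q)$. The mixture guarantees finite divergences
whenever either side is positive; with base-2 logarithms
$\mathrm{JSD}_i \in [0,1]$. The network divergence nJSD is the plain
mean of $\mathrm{JSD}_i$ over usable genes.

**The tITH ratio.** With a normal reference $N$, a tumor $T$, and the
maximally ambiguous state $A$ (all genes equally expressed, every
neighbor distribution uniform),
$NT = \mathrm{nJSD}(N,T)$, $TA = \mathrm{nJSD}(T,A)$, and
$$\mathrm{tITH} = \frac{NT}{NT + TA} \in [0,1].$$
The ratio form was chosen as the unique simple combination that is 0
when the tumor matches the normal reference, 1 when the tumor reaches
state A, bounded in $[0,1]$, and invariant to the logarithm base (the
base rescales $NT$ and $TA$ equally). When $NT + TA = 0$ — the tumor
is simultaneously identical to both references — the score is returned
as 0 with a `degenerate` flag rather than NaN, since such a sample
shows no evidence of drift.

## Gene universes and degenerate inputs

All computations run on the *common universe*: network genes measured
in both profiles. Within a neighborhood, neighbors missing from either
profile are dropped from both sides, so $P$ and $Q$ are always aligned
on identical support. Genes whose neighbor-expression sum is zero in
either state have no defined distribution there; they are excluded
from the average and counted (`n_genes_skipped`), never imputed —
imputing uniform distributions would silently shrink divergences.
$0\log(0/x) := 0$ throughout.

For tITH, both $NT$ and $TA$ are averaged over the *same* gene set:
genes defined for the normal–tumor comparison (state A is defined for
every gene of degree ≥ 1, so this set is the binding constraint).
Averaging the two distances over different gene sets would make their
ratio compare incomparable scales. A consequence used by the tests:
for any partition of the usable genes into sets, the count-weighted
mean of per-set $NT$ (or $TA$) values reconstructs the global value
exactly.

## Pathway scores

`pathway_tith()` keeps each gene's neighborhood in the *full* network
and restricts only the averaging set to the pathway's genes. The
alternative reading — divergences on the pathway-induced subgraph — is
available via `neighborhoods = "subgraph"` but is off by default: the
restricted-average form is the one consistent with describing
pathway-level scores as "an average of per-gene divergences of the
genes in a pathway", and it preserves the partition-consistency
property above. Pathway genes absent from the usable network fall
outside the average and are reflected in `n_genes_used`.

`pathway_screen()` reports raw two-sided Pearson correlation p-values
between per-sample pathway scores and an external covariate (e.g. a
genome-derived subclone count); Benjamini–Hochberg q-values are
optional (`adjust = "BH"`) and off by default so that raw-threshold
screening (such as p < 0.001) is the primary interface.

## Tunable parameters

| parameter | default | units / meaning |
|---|---|---|
| `transform` (`load_expression`) | `none` | set `log2p1` to map raw counts/TPM through log2(x+1); negatives always rejected |
| `collapse` | `max` | duplicate gene rows collapse by per-sample maximum (the usual probe-to-symbol convention); `mean` available |
| `min_score`/`score_column` (`load_network`) | off | confidence filter applied at load time only; the divergence math never weights edges, because the mass-action probability has no edge-weight term |
| `base` | 2 | logarithm base; bounds per-gene JSD in [0,1]; tITH is base-invariant |
| `scale` (`aggregate_reference`, `mix_profiles`) | `log2` | averaging on the stored log2 scale; `linear` averages un-logged abundances |
| `value` (`ambiguous_reference`) | 1.0 | any positive constant is equivalent by scaling invariance |

The normal reference for a cohort is the per-gene arithmetic mean of
the normal samples on the log2 scale ("mean expression level" of the
pooled normals of a cancer type). Linear-scale averaging is offered
because physical RNA pools mix linearly; the log2-scale default matches
how the score is defined on log-normalized data.

## The synthetic cohort generator

`generate_synthetic_cohort()` emulates exactly the ingredients the
clone-mixing experiments need:

* a **random PPI**: Barabási–Albert by default (`m = 3`, mean degree
  ≈ 6, heavy-tailed like curated interactomes), Erdős–Rényi as an
  alternative; only the largest connected component is kept;
* a **baseline state**: per-gene log2 values drawn
  $N(\mu = 3, \sigma = 2)$ clipped at 0 — a realistic spread for
  log2-normalized RNA-seq;
* **clones**: baseline + independent $N(0, d)$ per gene, clipped at 0,
  with divergence $d$ = 1.0 by default, giving clone-to-clone spread
  comparable to unrelated cell lines.

It deliberately does **not** model read-count noise, dropout,
library-size effects, correlated (pathway-coherent) perturbations, or
gene-gene expression covariance. Passing simulation tests therefore
demonstrates the *mechanics* of the measure — averaging divergent
clones provably drives the bulk toward state A — not that any
particular real tissue will show a given score. `mix_profiles()`
averages k columns sampled without replacement (mixtures are "k
distinct clones"), on the log2 scale by default to match how the
mixing design is defined on log-normalized data; linear mixing is a
flag.

`bulk_vs_cells_zscore()` uses the sample (n−1) standard deviation of
the single-cell distances and a one-sided lower-tail normal p-value:
the question is specifically whether the bulk is *closer* to state A
than its cells.

## Numerical choices

* Neighbor lists are stored lexicographically sorted, so every
  summation order is deterministic and `njsd(X, Y)` equals
  `njsd(Y, X)` bit for bit.
* Per-gene JSDs are clamped to $[0, \log_b 2]$ to absorb rounding at
  the 1e-16 level; the vectorized path is verified against a literal
  per-gene loop transcription to 1e-12 in the test suite, exhaustively
  over all graphs on ≤ 5 nodes.
* All randomness flows through `set.seed` on user-supplied seeds;
  generator and experiment outputs are bit-reproducible.

## Problem sizes used by the test suite

The simulation checks run at desk scale, chosen once: 200 genes and
128 clones for the mixing curve (100 replicates per mixture size,
sizes 1–128 doubling), 50 clones for the bulk-vs-cells test with 100
seeded repetitions for its detection and null-rejection rates, and
graphs of 5–15 nodes for the metric fuzzing (1,000 instances in the
main fuzz). These sizes
keep the full suite comfortably fast while leaving each statistical
conclusion unambiguous (trend p-values far below their thresholds).

## Known limitations

* The score is relative to the chosen network: comparing tITH values
  across different PPIs requires the stability check the user must do
  (the measure itself is defined per network).
* Non-tumor cell content (stromal/immune infiltration) also pushes a
  bulk profile toward ambiguity; tITH measures mixture, not its cause.
* Genes outside the PPI, and neighborhoods wiped out by zeros, are
  invisible to the score; `n_genes_used` makes the effective universe
  auditable.
* The normal reference pools samples per cohort; per-patient matched
  normals can be supplied by calling `tith()` directly.
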