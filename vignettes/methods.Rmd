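---
title: "Methods: phase-contrast transcriptomics and signature matching"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phase-contrast transcriptomics and signature matching}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(estrocycle)
```

# Scope and model

`estrocycle` analyzes two-phase (estrus vs diestrus) RNA-seq designs across
many tissues. Its stages mirror the standard order of such analyses:
per-tissue differential expression, trend-based tissue comparison, gene-set
over-representation, network hubness, signed-regulon transcription-factor
(TF) activity, and transcriptomic-alteration-signature (TAS) matching that
aggregates outcome labels into phase-protection calls. Everything operates
on tibbles and composes with the pipe; `autoplot()`, `tidy()` and `glance()`
methods cover each result type.

## Differential expression on pooled counts

Replicate counts are summed per phase and compared as rates. For gene $g$
with pooled counts $K_A, K_B$ and pooled library sizes $N_A, N_B$:

$$\mathrm{log_2FC} = \log_2 \frac{(K_A + c)/N_A}{(K_B + c)/N_B}, \qquad
z = \frac{K_A/N_A - K_B/N_B}{\sqrt{\hat p (1-\hat p)(1/N_A + 1/N_B)}},$$

with $\hat p = (K_A+K_B)/(N_A+N_B)$ and pseudocount $c = 1$ applied to the
fold change only (the test sees raw pooled counts). Genes with zero pooled
counts in both phases are excluded before testing — their fold change is
undefined. p-values are BH-adjusted per tissue over all tested genes, and a
DEG requires $|\mathrm{log_2FC}| \ge 1$ and $q \le 0.05$, both inclusive.

Two modeling points deserve emphasis:

* **The pooled z-test is a deliberate, fully specified stand-in** for the
  MA-plot random-sampling family of pooled-count DE tests. It is exact under
  its own sampling model (independent Poisson counts), which is also the
  `nb_dispersion = 0` limit of the synthetic generator; all null-calibration
  properties in the test suite are stated and checked there.
* **Under biological overdispersion the test is anti-conservative**, as is
  the whole pooled-count family: with NB variance $\mu + \phi\mu^2$ the
  binomial standard error understates the truth by a factor growing with
  $\phi\mu$, so raw q-values on overdispersed nulls are badly inflated. The
  $|\mathrm{log_2FC}| \ge 1$ filter absorbs much of this in practice, and the
  acceptance report deliberately publishes the resulting false-discovery
  proportion at the generator's default $\phi = 0.1$ rather than hiding it.
  Users with enough replicates who need calibrated per-gene inference should
  use a dispersion-modeling GLM (e.g. edgeR/DESeq2) upstream and feed the
  resulting tables into the downstream stages; replicate-level dispersion
  modeling is intentionally out of scope here.

Degenerate inputs: a pooled rate of exactly 0 or 1 forces equal observed
rates, reported as $z = 0$, $p = 1$.

## Tissue trends, clustering, prioritization

Each tissue's DEGs are encoded ±1 (up/down in estrus). For a tissue pair the
similarity is the cosine of the two ±1 vectors restricted to the genes that
are DEGs in *both* tissues — equivalently mean agreement minus mean
disagreement; pairs sharing no DEGs are `NA` by design, never an error.
Tissues are prioritized by total DEG count, and the top `k_ectts = 6` are
the estrous-cycle target tissues (ECTTs); ties break lexicographically by
tissue id so the selection is deterministic.

## Over-representation

For each tissue, three DEG sets (up, down, union) are tested against each
gene set by the one-sided hypergeometric tail $P(X \ge \text{overlap})$. The
**universe is the set of genes tested for DE in that tissue**, not the whole
genome: the background must be the population from which the DEG set was
actually drawn, and the generators and data never guarantee genome-wide
coverage. BH runs within each tissue × collection × direction family —
the three directions answer different questions and are corrected
separately. Reporting rules: a term is *shared* when significant in ≥ 5
tissues; two terms are *linked* when their contributing DEG unions overlap
by ≥ 25 % of the **smaller** set (symmetric, and conservative for nested
sets).

## Network hubness

Centralities on the directed signaling network are total degree (the
hubness reading is directionless), betweenness normalized by
$(N-1)(N-2)$, and PageRank (damping 0.85, uniform personalization, dangling
mass redistributed uniformly; the vector sums to 1 within $10^{-9}$).
Multi-edges and self-loops are collapsed on load — curated signaling edge
lists carry no meaningful weights. The hubness test is a one-sided Wilcoxon
rank-sum of DEG-node centralities against the remaining network nodes (the
background is the network minus the DEGs: the question is positional, not
genome-wide), exact when $n + m \le 12$ with no ties and otherwise the
normal approximation with tie and continuity corrections. A constant pooled
sample is flagged degenerate with $p = 1$.

## TF activity

A regulon is a signed target set; sign 0 means regulation of unknown
direction. For direction $d \in \{+1, -1\}$ the consistency score over
targets in the trend domain is

$$S = \sum_{\text{signed } t} \big[ \mathbb{1}(\tau_t = d\,s_t) -
\mathbb{1}(\tau_t = -d\,s_t) \big] + \sum_{\text{sign-0 } t}
\mathbb{1}(t \text{ is a DEG}),$$

where $\tau_t$ is the target's trend and $s_t$ the edge sign. This
correct-minus-incorrect statistic is the package's own, fully specified
replacement for proprietary consistency tests whose exact formulas are not
published; it preserves the inferential contract (directional consistency,
one-sided $q \le 0.05$) while remaining testable. On fully signed regulons
it is antisymmetric in direction, which the suite checks.

The null permutes trend labels over the measured-gene universe $B$ times
(realized, equivalently and cheaply, by sampling target-sized subsets of the
universe-length trend vector) with the add-one estimate
$p = (1 + \#\{S^\ast \ge S\})/(B+1)$, so $p \in (0, 1]$ always. Both
directions are tested per TF, BH runs across all (TF, direction) pairs per
tissue, and one direction per TF is kept — smaller $q$, ties broken by
larger $|S|$ — because a TF cannot be coherently up- and down-active in one
tissue. The activity score is $\pm\min(-\log_{10} q,\ 16)$: the cap (a q
floor of $10^{-16}$) keeps scores finite and ranking-stable. Key TFs are
those significant in ≥ 4 ECTTs, keeping per-tissue directions (the same TF
may act oppositely in different tissues). Default $B = 1000$ resolves
$p$ to $10^{-3}$, the smallest value BH can usefully exploit at these
family sizes.

## TAS matching and PTSP

A TAS is the per-gene pooled-rate log2FC vector of one contrast. Matching
uses the Spearman correlation over the **gene-space intersection** of query
and member (zero-filling the union would manufacture rank ties), with
`min_overlap = 100` shared genes required for an SCC to be computed at all.
p-values use the t approximation $t = r\sqrt{(n-2)/(1-r^2)}$ — standard at
transcriptome-scale $n$. Library redundancy is removed by a greedy pass in
curation order, per tissue: a member is kept iff its SCC with every
already-kept same-tissue member is < 0.5. Input order is the tie-break;
determinism matters more than any optimality claim here. Both inclusive
thresholds (hit at $|SCC| \ge 0.1$, redundant at $SCC \ge 0.5$) are compared
with $10^{-12}$ slack because average-rank correlations of exact-boundary
configurations land one ulp below the rational value.

Each significant hit with a labeled outcome votes: the query phase is
protective iff the hit correlates positively with a beneficial state or
negatively with a deleterious one. The verdict is the majority, with a
two-sided exact binomial sign test against 0.5; ties and empty vote sets are
indeterminate, and negating all correlation signs provably flips the
verdict. **Ovary and uterus are excluded from verdicts by default**
(`include_reproductive = FALSE`): in reproductive tissues, correlations with
"deleterious" signatures often reflect ordinary cyclic physiology
(luteinization, decidualization) rather than harm, so a protection verdict
there is not interpretable the same way.

## The synthetic generator

`sim_config()` defaults are the emulated study conditions: 2 phases × 3
biological replicates, expected library size $10^6$ (a deliberately
scaled-down transcriptome; real libraries are ~20× deeper, but rate-based
statistics scale), NB dispersion 0.1 (a typical bulk RNA-seq value),
planted $|\mathrm{log_2FC}| = 2$ on 10 % of genes, 15 tissues. Baseline
gene rates are log-normal (sdlog 1.5) normalized to the library size.

* **Correlated TAS members** use a Gaussian copula: query values are mapped
  to normal scores $z$, and a member with target Spearman $\rho$ is
  $r z + \sqrt{1-r^2}\,\varepsilon$ with $r = 2\sin(\pi\rho/6)$ — the exact
  bivariate-normal relation between Pearson and Spearman correlation, so the
  population target is hit analytically rather than by numeric calibration.
  Outcome labels couple to correlation signs through the planted protective
  phase, and label paths follow a fixed 1–3-level hierarchy
  (outcome / {disease, chemical treatment, lifestyle} / subtype).
* **Networks** grow by directed preferential attachment; gene ids are
  assigned to nodes by random permutation so that, with planting disabled,
  DEGs are exchangeable with background. Planted hubs receive randomly
  oriented extra edges up to **twice the 95th degree percentile** — a hub is
  defined as a node decisively in the tail, not at its edge.
* **Regulons**: planted-active TFs draw all targets from the DEG set, a
  fraction `tf_consistency` with concordant edge sign and the rest
  discordant, so the planted consistency is exact by construction; with
  fewer DEGs than `targets_per_tf` the planted regulon shrinks (minimum 3
  targets, else the TF is not planted and not claimed in the truth).
  Inactive TFs draw targets from the whole universe with random signs.
* **The multi-tissue study** (`simulate_study()`) plants each tissue's DEGs
  as a shared core (60 % of the budget) plus tissue-specific extras, with
  two tissue modules of opposite core orientation and a per-tissue burden
  factor in [0.3, 1.7]. This reproduces the phenomena the pipeline is meant
  to detect: a two-block tissue clustering, a DEG-burden ranking, TFs
  recoverable across tissues with module-dependent direction, and — because
  planted TFs are themselves DEGs whose trend matches their direction — a
  positive expression–activity correlation. Protective phases alternate
  across tissues, so phase-protection verdicts have non-trivial truth.

What the generator does **not** emulate: read-level artifacts, GC and batch
effects, gene–gene correlation beyond the planted structures, ortholog
mapping noise, and the curation biases of a real signature library. Passing
tests therefore demonstrate correctness of the statistical machinery and
recoverability of planted structure, not performance on real tissue data.

## Numerical and reproducibility choices

Every generator is a pure function of (config, seed); a single master seed
derives per-stage substreams by hashing stage names, so stages are
independently reproducible and the pipeline is byte-deterministic under a
fixed seed (the run manifest records the config hash). Permutation p-values
are never 0 by construction. Undefined quantities are markers, not errors:
`NA` for correlations of constant rank vectors and for tissue pairs without
shared DEGs, `NULL`/skip for untestable regulons, warnings plus empty
results for empty backgrounds or empty per-tissue libraries.

Problem sizes in the shipped tests and acceptance script — 1,500–5,000
genes, 8 tissues, libraries of 20–60 members, $B$ = 200–1000, 10–100 seeds
per property — are the package's chosen desk-scale study; they are large
enough for the stated recovery and calibration properties while keeping a
full run in minutes.

## Known limitations

* No replicate-level dispersion modeling; see the calibration discussion
  above.
* SCC-threshold matching across libraries of differing gene dimensionality
  carries mild bias (the |SCC| ≥ 0.1 rule fixes the effect size, not the
  evidence level); `min_overlap` bounds but does not remove this.
* The consistency score is a stand-in, not a reimplementation, for
  proprietary quaternary consistency tests; its permutation null conditions
  on the observed DEG count.
* PTSP verdicts inherit the curation quality of the outcome labels; with few
  voting hits the binomial sign test is honest about that uncertainty.
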