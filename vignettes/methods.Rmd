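---
title: "Joint tri-factorization of heterogeneous cancer data: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint tri-factorization of heterogeneous cancer data: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`trifuse` embeds six entity families — cancer types, patients, genes,
pathways, protein complexes and drugs — in three shared latent spaces by
jointly factorizing every available relation between them. The three
spaces group families that are semantically interchangeable downstream:
space 1 holds patients and cancer types, space 2 holds genes, pathways and
complexes, space 3 holds drugs.

Each relation matrix $R_e$ contributes one sub-objective, and the form of
its decomposition follows the shape of the data:

* **NMF**, $R \approx G_a G_b^\top$, when both families live in the same
  latent space (patient × cancer diagnosis, gene × complex, gene ×
  pathway). The inner dimension is the shared space's $k$.
* **NMTF**, $R \approx G_a S_e G_b^\top$, when the families live in
  different spaces (patient × gene expression, patient × gene mutation,
  drug × gene targets). The central matrix $S_e$ ($k_{row} \times
  k_{col}$) is specific to the relation and translates between the spaces.
* **SNMTF**, $A \approx G S_e G^\top$ with symmetric $S_e$, for square
  symmetric within-family data (PPI network, drug chemical similarity).

The joint objective is the unweighted sum of squared Frobenius
reconstruction errors,

$$J = \sum_e \left\lVert R_e - \hat R_e \right\rVert_F^2 ,$$

and the factor $G_f$ of each family is shared by every sub-objective that
involves the family. That sharing is the entire integration mechanism: a
patient's embedding must simultaneously explain their diagnosis, their
expression profile and their mutations, so it ends up *context-aware* —
shaped by all the data at once. A per-relation weight hook exists in the
code but defaults to 1 for every relation; balancing heterogeneous
sub-objectives is a known open issue for this model class and we keep the
unweighted form.

### Update rules

All factors are non-negative and optimized by multiplicative updates. For
a shared factor the numerator and denominator gradient terms are summed
over every incident relation before the elementwise update

$$G_f \leftarrow G_f \circ
  \frac{\sum_e \mathrm{num}_e(f)}{\sum_e \mathrm{den}_e(f) + \varepsilon},$$

with, per relation kind (writing $B = G_b^\top G_b$):

| kind | role | numerator | denominator |
|------|------|-----------|-------------|
| NMF  | row  | $R G_b$   | $G_a B$     |
| NMTF | row  | $R G_b S^\top$ | $G_a S B S^\top$ |
| SNMTF| both | $A G S^\top + A^\top G S$ | $G S G^\top G S^\top + G S^\top G^\top G S$ |

(column-side roles are the transposed counterparts). Central matrices then
update as $S \leftarrow S \circ (G_a^\top R G_b) \oslash (G_a^\top G_a S
G_b^\top G_b + \varepsilon)$, and SNMTF centrals are symmetrized,
$S \leftarrow (S + S^\top)/2$, so that reconstructions of symmetric data
stay symmetric. These are the standard KKT-derived rules for collective
factorization with shared factors; both halves of the symmetric gradient
are kept for SNMTF relations.

One *round* updates the factors sequentially in bundle order, each update
seeing the factors already refreshed in the same round, then updates the
centrals. With a single NMF relation this reduces exactly to the classical
two-factor multiplicative rule (row factor first, column factor computed
with the updated row factor), which the test suite asserts bitwise.
Sequential refresh also preserves, empirically, the monotone descent of
the objective: the suite verifies non-increase within relative $10^{-6}$
per round across hundreds of random typed bundles.

### Numerical choices

* $\varepsilon = 10^{-12}$ is added to every denominator to avoid division
  by zero; entities whose data rows are entirely zero therefore decay
  toward the zero embedding rather than producing NaNs.
* Initialization is strictly positive uniform, seed-controlled. Central
  matrices are rescaled so every tri-factorized relation's initial
  reconstruction has exactly the data's Frobenius norm; NMF relations are
  brought to scale by two sweeps over their column factors. Starting at
  the data's scale avoids the long plateau multiplicative updates exhibit
  when the reconstruction starts orders of magnitude away.
* Convergence is declared when the relative objective change per round
  drops below `tol` (default $10^{-5}$), capped at `max_iter` (default
  500). `n_restarts` repeats the fit from consecutive seeds and keeps the
  lowest final objective; the default is a single restart, which the
  planted-recovery tests show is sufficient at bench scale.
* Reconstruction quality is reported as the *relative residual*
  $\lVert R_e - \hat R_e\rVert_F^2 / \lVert R_e\rVert_F^2$ per relation
  (`relative_residuals()`), the usual relative reconstruction error of the
  factorization literature. Rank-matched planted bundles are recovered to
  below $10^{-3}$ on this scale within 500 iterations; plain
  multiplicative updates do not reach $10^{-3}$ on the *unsquared* norm
  ratio in that budget, and no claim is made on that scale.

### Hyperparameters

The latent dimensionalities `k1, k2, k3` are the only model
hyperparameters. Each `k` must lie in `[1, smallest family size of the
space]` — a factor taller than its family would be overcomplete.
`select_hyperparameters()` fits every combination of candidate values and
scores each fitted model by the macro-F1 of assigning every patient to the
cosine-nearest cancer-type embedding; the argmax wins, with ties broken
toward the lexicographically smallest triple for reproducibility, and
infeasible grid points skipped with a message. On real-scale data the
reference configuration is $k_1 = 21$, $k_2 = 70$, $k_3 = 40$ over a
$5 \times 5 \times 5$ grid; the bench-scale default derives the dims from
the world (e.g. $k_1 =$ number of cancers).

Tree hyperparameters for the link classifiers default to 200 rounds,
depth 6, learning rate 0.1, all exposed through `params =`. Tests assert
recovery of planted signal, never specific raw scores, so these defaults
are not load-bearing.

## Downstream machinery

**Link prediction.** A candidate (cancer, gene) or (cancer, drug) pair is
represented by the concatenation of the two unit-norm embeddings.
Normalization is enforced at feature construction because it is what makes
a classifier transferable between families sharing a space. Cross-validation
folds partition the *known links only*; every non-reported pair forms a
shared negative pool used — unweighted, no balancing — by all ensemble
members; member $m$ never sees fold $m$'s positives (they are removed from
training, not relabeled). Candidate scoring z-standardizes each member's
scores over the scored candidate set, then averages; standardizing over
the candidate population (rather than training scores) is the reproducible
reading, and a degenerate member with zero score spread contributes 0.
Entities with any known association can be excluded so that the ranking
surfaces genuinely novel candidates.

**Repurposing.** Because genes, pathways and complexes share space 2, the
cancer–gene ensemble scores cancer–pathway or cancer–complex pairs with no
retraining; the only requirements are the shared space and unit
normalization, both checked.

**Fold-in.** A new patient with data rows $r_e$ in relations $e$ gets the
embedding $\arg\min_{g \ge 0} \sum_e \lVert r_e - g M_e^\top\rVert^2$ with
$M_e = G_b S_e^\top$ (NMTF) or $G_b$ (NMF), solved by non-negative least
squares (Lawson–Hanson) on the stacked system; trained factors never move.
Diagnosis rows are simply not supplied — they are the quantity being
predicted for a new patient.

**Drug response and importance.** Response records are split 70/10/20;
the validation split drives early stopping on log-loss (the natural use
for a named-but-unspecified validation set); the experiment repeats with
fresh splits and reports mean ± sd. Gain-based importances averaged over
the repeat models split into `i_patients` (first $k_1$ features) and
`i_drugs` (last $k_3$). Genes project into patient space through
$S_{exp} + S_{mut}$ and into drug space through $S_{dt}$
($G_x S_t^\top$), and the inner product with the importance vector ranks
genes per space — evaluated as retrieval of the planted driver set.

## Evaluation conventions

* Cosine distance everywhere; zero vectors get maximal distance 1 with a
  warning, and stay zero under unit normalization.
* Nearest-centroid ties break toward the lexicographically first label;
  kNN majority ties toward the smallest label; both logged in the docs.
* Hierarchical clustering uses average linkage — the robust default with
  cosine dissimilarities, which are bounded and non-Euclidean.
* Enrichment background is the set of clustered genes (matching the
  permutation null, which reassigns exactly those genes); BH correction is
  applied globally across all (cluster, term) tests, the conservative
  scope. The permutation null holds cluster sizes fixed, reassigns genes,
  and reports the add-one empirical p-value $(1 + \#\{rep \ge obs\}) /
  (1 + n_{reps})$, which can never return 0.
* Mann–Whitney tests are exact for samples of at most 20 without ties,
  normal-approximated otherwise.
* Survival stratification splits at the cohort mean; a patient exactly at
  the mean goes to the "lower" group.
* AUROC uses the tie-corrected rank statistic; AUPRC integrates the
  precision–recall step curve treating tied scores as one atomic
  threshold block, with no interpolation.

## The synthetic world

`generate_world()` builds, deterministically per seed, a reduced-scale
world with the same topology as the real inputs: 10 cancers × 20 patients,
500 genes partitioned into 25 pathway-like modules, 20 within-module
complexes, 50 drugs. Cancers activate 3 modules each; drivers are 20% of
each cancer's active-module genes; expression is baseline 1 plus a boost
of 2 on active modules plus truncated Gaussian noise (sd 0.1); mutations
are Bernoulli(0.01) background with rate 0.3 for a cancer's drivers in its
cohort; the PPI network is a planted partition (0.3 within / 0.01 between
modules); each drug targets 30–70% of one module's genes and drug–drug
similarity is the Jaccard of target sets. A patient responds to a drug iff
the drug targets an active module of the patient's cancer, flipped with 5%
label noise; the response experiment samples 13 drugs per patient
(~2,600 records, the size of the real TCGA response cohort this emulates).
Survival ties shorter times to higher expression of a designated
prognostic driver.

These choices make the planted structure *recoverable by design* — dense
enough modules for the PPI partition to matter, a boost-to-noise ratio
that separates active modules, enough response records for trees to learn
a 10-cancer × 25-module interaction. They are deliberately not a model of
real marginal distributions: real expression is heavy-tailed and
batch-confounded, real mutation matrices are far sparser and non-uniform,
real module sizes follow power laws, and real diagnosis labels are noisy.
Passing the planted-recovery tests therefore demonstrates that the
machinery is correct and sensitive, not that equally high scores will be
reached on real cohorts.

One structural consequence of bench scale: space 2 contains the 20
complexes, so $k_2 \le 20$ while there are 25 modules. Pathway embeddings
must share latent directions, which caps zero-shot cancer–pathway transfer
noticeably below the cancer–gene ceiling; the end-to-end checks therefore
evaluate replicate worlds and compare means, as one would report any
stochastic benchmark.

## Problem sizes used by the test bench

The shipped suite fits the default world (500 iterations cap, tolerance
$10^{-6}$–$10^{-5}$), trains 10-member ensembles on the full 5,000-pair
cancer–gene candidate set, runs the response experiment at 10 repeats, and
uses 200 permutation replicates for the enrichment null; the acceptance
script does the same on a single seed. These sizes keep a full run in the
tens of seconds on one CPU while leaving every statistical check
well-powered.

## Known limitations

* No sub-objective weighting or graph regularization; the unweighted sum
  can let large dense relations (expression) dominate small binary ones.
* Multiplicative updates converge linearly; they recover planted structure
  quickly but polish slowly, so very tight reconstruction targets require
  more iterations, not restarts.
* The SNMTF factor update is the aggregated two-sided rule; monotonicity
  for it is verified empirically rather than proven.
* The CLI persists models as labeled TSVs; for very large factors a binary
  format would be preferable but is out of scope.
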