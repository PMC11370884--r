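---
title: "Comparative conservation of gene families and pathways: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative conservation of gene families and pathways: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orthotrace)
```

`orthotrace` implements a comparative ("by descent") analysis of human gene
families and pathways across an animal phylogeny. The pipeline asks, for a
human-anchored collection of orthologous gene families, where in the animal
tree each family originated and where it was lost; whether families linked
to human disease originated deeper than families that are not; whether the
reactions that wire genes into pathways outlast the genes themselves; and
whether curated biomarker gene sets are enriched among the most deeply
conserved families. This vignette describes the models, their assumptions,
and the design choices behind the implementation.

## Data model

All stages share two containers. A **species tree** is a rooted `ape::phylo`
with unique labels on every node (`parse_newick()` auto-names unlabelled
internal nodes `N<preorder index>` so event tables are reproducible across
runs). A **profile matrix** (`profile_matrix()`) holds per-species copy
counts for each family plus a class label (`disease`, `non_disease`,
`mixed`, `unlabeled`). Every family is assumed to contain a gene of the
anchor species (*Homo sapiens* by default): the analysis is about what
humans share with other animals, so families absent from the anchor are a
validation error rather than data. Two reference topologies ship with the
package: `suite1_tree()` (12 species for the gene-family analyses) and
`suite2_tree()` (8 species for the pathway analyses).

Family classification (`classify_families()`) is the all/none/some rule:
a family is *disease* only if every one of its human genes appears in the
morbid-gene list, *non-disease* if none does, *mixed* otherwise. Mixed
families are retained in totals but excluded from disease/non-disease
contrasts.

The nine categories of `conservation_summary()` are literal set
definitions over binary presence. Two of them deserve comment because
their conventional names are looser than their definitions: "in
vertebrate" counts presence in at least one *non-anchor* vertebrate (the
anchor trivially carries every family), and "only in all vertebrates"
means *absent from every invertebrate leaf*. "Only in vertebrate"
additionally requires the present leaves to span at least two children of
the vertebrate clade root — equivalently, the Dollo gain falls exactly on
that node. These are the definitions that make the bundled reference
counts (`disease_family_counts()`) internally consistent across all three
family classes.

## Dollo parsimony

Binary presence profiles are reconstructed under Dollo's irreversibility
assumption: a family is gained exactly once and can only be lost
afterwards. On a rooted tree the minimum-loss single-gain solution is
unique, and it has a closed form: the gain is the most recent common
ancestor of the present leaves, and the losses are the root edges of the
maximal all-absent subtrees inside the gain clade. Sketch: placing the
gain above the MRCA only adds losses (every added branch that leads away
from present leaves must be pruned); placing a loss below the root of an
all-absent subtree splits one loss into several; placing it higher kills a
present leaf. No tie-breaking is therefore needed. The test suite verifies
this closed form against an exhaustive search over all single-gain state
assignments for every rooted binary topology with up to six leaves and
every possible profile, plus multifurcating cases.

A corollary used throughout: the gain falls on the root **iff** the
present leaves span at least two children of the root. On the 12-species
tree this means a family gains at Bilateria exactly when it is present in
at least one vertebrate and at least one ecdysozoan leaf, which ties the
"in vertebrate & invertebrate" count of the conservation summary to the
root-gain count of the event table.

Gains at terminal branches (families private to one species) are allowed
by the implementation even though curated inputs normally exclude them;
they simply appear as leaf-row gains in `branch_event_table()`.

## Subsampling null and branch z-scores

Disease families are compared against size-matched random subsets of the
non-disease pool (`draw_null_replicates()`): each replicate samples
`|disease|` families *without replacement*, replicates being independent
draws (so subsamples may repeat across replicates — the natural reading of
"random sub-samplings"; an exhaustive-partition design would behave
differently only at order `1/n_reps`). For every statistic — per-node
gains, per-branch losses, per-leaf presence — `null_summary()` reports the
null mean, the standard deviation with the `n - 1` denominator, the
standard error `sd/sqrt(n_reps)`, the one-sided 99% upper limit
`mean + 2.326 * se`, and `z = (observed - mean)/sd`. The 2.326 multiplier
(one-sided 99% normal quantile) rather than the two-sided 2.576 is what
reproduces the reference table's printed interval column, which is how the
convention was fixed. A zero-variance statistic with a discrepant
observation yields a signed infinite z with a warning rather than an
error.

Because each family's reconstruction is computed once and replicates only
re-aggregate rows, the default 1000 replicates cost little beyond the
initial Dollo pass.

One caveat stated here because the tests exercise it: the observed class
is an independent draw from the generative process while the null is a
finite-pool subsample, so null spread slightly understates the spread of
an independent sample (by a factor `sqrt(1 - m/M)`), and |z| is mildly
anti-conservative. The calibration test bounds the practical effect (the
share of |z| > 2.58 stays below 5% when both classes share one generative
model).

## The pure-loss content model

Pathway content evolution is modelled as pure loss: the root carries
`N ~ Poisson(lambda)` elements; each element survives each branch `b`
independently with probability `s_b` in (0, 1]; a node's count is the
number of elements surviving its root path. No gains or duplications are
allowed, so the model respects Dollo irreversibility at count level.
Survival probabilities are attached directly to branches — there is no
rate-times-time factorisation because the study trees carry no time
calibration, and only the per-branch survival would be identifiable
anyway.

*Likelihood* (`profile_loglik()`): the child-count transition given a
parent count `m` is `Binomial(m, s_b)`, so a postorder pruning pass over
counts `0..n_max` is exact. The Poisson root prior is truncated at
`n_max = max(observed) + ceiling(6 * sqrt(lambda))`, raised until the
discarded tail mass is below 1e-12; the truncation error is then far below
the optimizer's tolerance. The inner loop is implemented in C++ (the cost
is `branches * n_max^2` per profile and sits inside the optimizer).

*Fitting* (`fit_pure_loss()`): bounded quasi-Newton (`L-BFGS-B`) on
logit-transformed survivals and log-transformed lambda, with multi-start
(default 5; the first start uses moment-based initial values — root mean
from the best-preserved tip, branch survivals spread along root paths —
and the rest jitter them, `sd = 0.7` on the transformed scale). Gradients
are finite-difference. One shared `s_b` per branch is estimated across all
pathways (the standard usage for gene-content likelihood tools); whether
pathway-specific rates would match the original analyses is not decidable
from the published description, and shared rates are the identifiable
choice at these sample sizes.

*Posteriors* (`ancestral_posterior()`): an inside-outside pass gives the
exact conditional count distribution at every node, plus the joint
parent-child distributions per branch. From these, `branch_loss_tally()`
accumulates per-branch expected *losses* (parent count >= 1, child count
0) and *contractions* (parent >= 2, child exactly 1). The verbal notions
of "lost" and "contracted to a single element" admit several
formalisations; the inequalities above are the ones implemented, and they
are also what the enumeration oracle in the tests checks.

*Rate tree* (`rate_tree()`): branch lengths `-log(s_b)`, the expected
per-element loss intensity; `s_b = 1` maps to length 0 and `s_b = 0` is an
error (infinite length). Gene and reaction contents are modelled as two
independent runs over the same tree.

The test suite validates the likelihood, every node posterior and the
branch event probabilities against an enumeration oracle (explicit sums
over root sizes and per-element fates) on all small instances, to absolute
error below 1e-9, and runs a parameter-recovery study (2000 simulated
pathways on the 8-species tree, lambda = 10, survivals drawn in
[0.6, 0.98]) requiring at least 90% of branches within +-0.05 and lambda
within +-10%.

## Pathway conservation and the GLM

Pathway records carry human gene/reaction counts and per-species conserved
counts. `filter_pathways()` keeps terminal pathways with 3 to 1227 human
genes ("elements" are human genes with identifiers; reactions never enter
the size filter). Conservation percentages are `100 * conserved / human`,
group averages are unweighted means over the species group, and the
invertebrate response is the unweighted mean over the two invertebrate
species.

`fit_conservation_glm()` fits
`invertebrate ~ vertebrate + n_genes + vertebrate:n_genes`.
The original description names only "a GLM"; because the response is a
proportion, the default here is binomial family with logit link and the
pathway's human gene count as weights, with a gaussian-identity mode for
sensitivity analysis (both are recorded in the returned object). The
binomial fit silences only the specific non-integer-successes warning that
weighted proportion responses always raise. `predict_surface()` evaluates
the fitted model over a vertebrate-conservation x pathway-size lattice on
the response scale, warning (but not refusing) on extrapolation.

## Shannon ranking and ortholog-set enrichment

`shannon_index()` is `H' = -sum p_i log p_i` with natural log, computed on
**copy counts** (not presence): the quantity ranks families by how evenly
their genes are spread over species, so duplication skew matters as well
as absences. The natural log is the only base consistent with the scale of
the reference summaries (maximum `log(12) = 2.485` for a uniform
single-copy family over 12 species). `rank_families()` sorts descending
with ties broken by ascending family id; ties are massive in real data
(every universal single-copy family shares `H' = log 12`), so a
deterministic tie rule is required for reproducible enrichment scores, and
small sets can shift their scores under a different within-tie order —
a caveat to remember when comparing against other tools.

Gene sets are converted to ortholog sets (`to_ortholog_sets()`) by mapping
gene ids to family ids, keeping unique entries, and applying the usual
size bounds (3 to 500). `preranked_es()` is the weighted running-sum
statistic: increments `|score|^p / sum` at members, decrements
`1/(N - |set|)` at non-members, ES = the signed extremum (positive side on
exact magnitude ties); `p = 1` by default, `p = 0` gives the classic
unweighted form. `permutation_stats()` uses gene-set permutation — random
same-size sets from the ranked universe, the only null available without
sample labels — for nominal p (share of same-sign null scores at least as
extreme), NES (ES over the mean same-sign null magnitude) and FDR q (the
empirical NES-ratio procedure with a monotonicity pass).
`random_panel_experiment()` repeats the analysis for random subsets of a
biomarker panel versus random subsets of the whole gene universe and
reports both p-value vectors and their fractions below 0.05; the subset
size is configurable (default 100, a value the source analyses leave
unstated).

## The synthetic-data generator

`generator_config()` fixes the generating conditions; its defaults *are*
the study conditions and are not tuned per run:

* 10,441 families split 1597 / 7446 / 1398 across disease / non-disease /
  mixed (the reference totals); `scale` shrinks counts (never sizes) for
  desk-scale work, e.g. `scale = 0.1` for tests.
* Origins are drawn on the root-to-anchor path (Bilateria, Vertebrata,
  Tetrapoda, Mammalia), with class-specific probabilities taken from the
  reference gain counts — disease mass 1133/372/33/59 over the four nodes,
  non-disease from the corresponding subsample means. This is what "disease
  labels enriched at deep origins" means operationally.
* Per-branch loss probabilities are back-computed as reference branch
  losses divided by families at risk on that branch (e.g. 0.36 for the
  *Caenorhabditis* terminal, 0.009 for *Mus*). Branches on the
  root-to-anchor path default to probability 0 — human-anchored data
  cannot show a loss there, which is also why reference tables carry no
  loss rows for those branches. The generator nevertheless redraws any
  family that loses the anchor, so user configs with positive anchor-path
  loss remain valid (an anchor-path probability of 1 is rejected as
  infeasible).
* Duplication is a per-branch event (probability 0.08) adding geometric
  extra copies (mean 2) — enough to give the Shannon index real variation
  without a full birth-death model.
* Pathways draw their genes from simulated families; a gene is conserved
  where its family is present, and a reaction is conserved iff at least
  one member gene is. That single rule is what makes reactions
  systematically more conserved than genes, and it is the mechanism the
  pathway-level tests probe. Sizes are log-normal with mean 29 genes and
  11 reactions; the disease-pathway fraction is 351/1508.
* Gene sets are sampled from the top Shannon quartile ("conserved"), the
  bottom quartile ("recent") or uniformly ("neutral"), with truth labels
  returned for calibration and power studies; set sizes default to the
  19-132 range of the curated hallmark collections.

What the generator does **not** emulate: annotation error and ascertainment
(real databases miss genes non-randomly), correlated loss across families,
lineage-specific gene birth, and reaction graphs with shared genes across
pathways. Passing tests therefore demonstrate the internal consistency of
the inference machinery under its own assumptions — not that real
database snapshots would reproduce any particular printed value, which
depend on frozen resource versions.

## Numerical and testing choices

* Percentages are rounded half-up (`percentage()`), the convention that
  matches printed reference tables; base `round()`'s round-half-to-even is
  deliberately avoided.
* The pure-loss optimizer bounds logit survivals at +-9.2 (survival within
  about 1e-4 of the open bounds) and log-lambda in [log 1e-3, log 1e5].
* The enumeration oracle for the pure-loss model lives in the test
  helpers, not the package: it enumerates element fates and convolves
  capped count states, deliberately sharing no structure with the pruning
  implementation it checks.
* Simulation sizes in the test suite (scale 0.07-0.2 generator runs, 200
  null replicates, 200 permutations, 2000 recovery pathways, 20
  calibration datasets) were chosen as the smallest sizes at which the
  statistical assertions have comfortable margins; the assertions
  themselves (calibration bands, recovery tolerances) come from the
  stated study properties, not from the observed runs.

## Known limitations

* The Dollo machinery assumes error-free presence/absence; a single
  spurious absence inside a clade creates a spurious loss, and a spurious
  presence in a distant leaf pulls the gain toward the root. No error
  model is provided.
* The pure-loss model has no gains or duplications by construction;
  content gained inside the tree is mis-attributed to the root and
  compensated by inflated loss rates elsewhere.
* The subsampling z is mildly anti-conservative (finite-pool effect
  discussed above); reference analyses share this property.
* Gene-set permutation nulls test a different hypothesis than
  phenotype-permutation GSEA; q-values are comparable only within one
  ranking.
* `fit_conservation_glm()` treats pathway gene conservation events as
  independent given the predictors; shared families across pathways make
  the effective sample size smaller than the pathway count.
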