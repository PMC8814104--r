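---
title: "Methods: ontology-based phenotype clustering and risk stratification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ontology-based phenotype clustering and risk stratification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenorisk)
```

# Overview

`phenorisk` stratifies a clinical cohort by phenotype and asks whether the
resulting strata differ in prognosis. The pipeline has four stages:

1. **Ontology and information content.** Phenotype terms live in a directed
   acyclic graph (OBO format, `is_a` edges, single root). Annotation counts
   are propagated up the graph and converted to Resnik information content.
2. **Patient similarity.** Pairwise semantic similarity between phenotype
   profiles via the best-match-average construction, converted to a distance.
3. **Clustering.** Complete-linkage agglomeration with a deterministic
   tie-break, cut into `k` clusters (default 3), then per-cluster phenotype
   characterization (term enrichment tests, combination summaries).
4. **Survival.** Kaplan-Meier curves, log-rank tests, landmark analysis at a
   clinically motivated changepoint, and univariable/multivariable Cox
   regression with Benjamini-Hochberg adjustment.

A synthetic-data generator (`simulate_study()`) is a first-class component:
it produces ontologies, phenotype profiles and survival records with known
ground truth, so every statistical claim the pipeline makes can be checked
against a planted answer.

# Model and estimands

## Information content

For term $t$ with propagated annotation count $n_t$ out of a corpus total
$N$ (the root's propagated count), with additive smoothing $s$ (default 1):

$$\mathrm{IC}(t) = -\ln \frac{n_t + s}{N + s}.$$

Logarithms are natural, so IC and all similarities are in **nats**.
Propagation adds each term's raw count once to every inclusive ancestor
(diamond-safe: a term with two paths to an ancestor contributes once).
Smoothing keeps IC finite for terms never annotated in the corpus.

## Term and profile similarity

Resnik similarity between two terms is the IC of their most informative
common ancestor, where the ancestor set is *inclusive* (a term is its own
ancestor), so $\mathrm{Sim}(t, t) = \mathrm{IC}(t)$:

$$\mathrm{Sim}(t_1, t_2) = \max_{v \,\in\, \mathrm{anc}(t_1) \cap \mathrm{anc}(t_2)} \mathrm{IC}(v).$$

Profile similarity between patients with term sets $c_1, c_2$ is the
symmetric best-match average:

$$\mathrm{Sim}(c_1, c_2) = \frac{1}{2|c_1|}\sum_{p \in c_1}\max_{q \in c_2}\mathrm{Sim}(p,q)
 + \frac{1}{2|c_2|}\sum_{q \in c_2}\max_{p \in c_1}\mathrm{Sim}(p,q),$$

so a patient's self-similarity equals the mean IC of their terms.

## Distance and clustering

Similarities convert to distances by
$d_{ij} = \max_{kl}(S_{kl}) - S_{ij}$, where the maximum is over the whole
matrix including the diagonal; the diagonal of $d$ is then set to zero.
This is a global order-reversing shift: ranking of off-diagonal pairs is
exactly inverted, which is all that complete linkage consumes.

Complete linkage is hand-rolled (the merge rule is part of the method's
definition here) with a **deterministic tie-break**: among equally distant
cluster pairs, merge the pair whose smallest member index is smallest,
then whose second key is smallest. `linkage_complete()` agrees with
`stats::hclust(method = "complete")` on tie-free inputs and with an
exhaustive oracle on small inputs; the tie-break makes results reproducible
across platforms where `hclust`'s tie behavior is unspecified. `cut_k()`
numbers clusters by first appearance in input order, so labels are stable
under reruns.

## Cluster characterization

Per-term carriage is compared across clusters with a chi-square test unless
any cluster has fewer than 10 members or any expected cell count is below 5,
in which case Fisher's exact test is used (with a Monte-Carlo fallback,
B = 20000, for tables too large to enumerate). P-values are
Benjamini-Hochberg adjusted within the family of tested terms.

## Survival analysis

* **Endpoints**: `primary` (death), `composite` (death or heart failure,
  earliest event), `reintervention`. Invalid records (negative follow-up,
  component event after follow-up end) are rejected with reasons attached,
  never silently dropped.
* **Kaplan-Meier** uses `survival::survfit` with log-log confidence
  intervals; a $t = 0, S = 1$ row is prepended.
* **Landmark analysis** at `t_landmark` (default 4 years): the *post* set
  is every patient still under observation past the landmark
  (`time > t_landmark`), analyzed on the **original time origin**; the
  *pre* side includes everyone with events censored at the landmark.
  Keeping the original origin preserves interpretability of the hazard
  scale; conditioning on surviving the landmark is what removes the
  pre-landmark information.
* **Cox regression** uses `survival::coxph` with Efron tie handling (the
  default and the better approximation with heavy ties). A coefficient is
  reported non-estimable (HR = NA) when $|\beta| > 15$ or
  $\mathrm{se} > 100$ — the monotone-likelihood signature of perfect
  separation. The multivariable model includes cluster plus every
  covariate with univariable $p < 0.05$; if nothing qualifies, an explicit
  "no multivariable model" result is returned rather than a silent skip.
  BH adjustment is applied within each model family.

# The synthetic generator

`sim_config()` defaults define the package's reference study: 270 patients
in three planted clusters of sizes 21/136/113, a ~120-term ontology, and
piecewise-exponential survival. These sizes were chosen to exercise the
regime the pipeline targets: one small cluster (small enough to trigger the
Fisher rule), two large ones, and events sparse enough that multivariable
models are genuinely at risk of non-estimability.

## Ontology

`make_toy_ontology()` builds a rooted DAG with 8 forced level-1 "family
heads" and geometrically shrinking level sizes; each non-root term gets one
primary parent from the level above and a second parent with probability
0.15 (so diamond patterns occur and must be handled). Annotation counts are
power-law distributed (`ceiling(3/u^1.2)`, capped at 2000), giving the
realistic mix of a few very common and many rare terms.

## Phenotype profiles

Each planted cluster is assigned an **archetype**: a tight ontology branch
(subtree) of 5 terms. Branches are chosen smallest-first among disjoint
subtrees whose head lineages do not overlap (with random-restart greedy
retries when the deterministic choice dead-ends). Within a branch, carriage
probabilities are graded `0.9, 0.7, 0.5, 0.35, 0.2` from the head down —
clinically, a dominant family finding that most members carry, plus
progressively rarer refinements. Background terms are carried with
probability 0.02. Every patient carries **at least one term from their own
family branch**, and profiles are truncated to 1-9 terms (median 3) with a
family term always preserved.

Two design points deserve emphasis because they were forced by failure
analysis, not convenience. First, archetypes are *branches* rather than
random term sets: with random sets, two same-cluster patients frequently
share no informative ancestor, the between/within similarity contrast
collapses, and complete linkage cannot recover the planted structure.
Branch archetypes guarantee shared high-IC ancestors within a cluster.
Second, the mandatory family finding exists because complete linkage is
outlier-sensitive: a handful of patients with only background terms
otherwise become singletons that consume the $k = 3$ cut.

## Survival

Event times are piecewise exponential: baseline yearly hazards
$\lambda_{\text{death}} = 0.0144$, $\lambda_{\text{HF}} = 0.0053$,
$\lambda_{\text{reint}} = 0.021$, chosen so that a 270-patient cohort with
the default censoring yields on the order of 19 deaths, 7 heart-failure
events and 28 reinterventions — realistic event sparsity for a surgical
congenital-heart cohort. After the changepoint $t^{*} = 4$ years, the
death and heart-failure hazards in cluster 3 are multiplied by
`hazard_multiplier` (default 6), planting the late-divergence pattern the
landmark analysis is designed to detect; `hazard_multiplier = 1` gives an
exchangeable null for calibration studies. Censoring is uniform on
0.5-11 years. Covariates: surgical strategy (three levels, 25/55/20%),
sex, and age at surgery (log-normal, median ≈ 5.4 years).

## What the generator does and does not emulate

It emulates: DAG structure with multiple parentage, power-law annotation
frequencies, family-structured phenotypes with graded carriage, sparse
events, late hazard divergence, administrative censoring. It does **not**
emulate: informative censoring, competing risks (reintervention is treated
as a separate endpoint, not a competing event), time-varying covariates,
measurement error in phenotyping, or correlation between phenotype severity
and covariates beyond cluster membership.

# Numerical conventions

* All logs natural; IC and similarity in nats.
* IC smoothing default 1 (Laplace).
* Distance offset is the global similarity maximum including the diagonal.
* Linkage tie-break: lexicographic on (smallest member index, second key).
* Cluster labels: order of first appearance.
* Cox ties: Efron. Non-estimable rule: $|\beta| > 15$ or se > 100.
* Landmark: post set is `time > t_landmark`, original time origin.
* Every random routine takes its seed from configuration; `run_pipeline()`
  reruns are byte-identical (verified via MD5 hashes in `manifest.json`,
  which deliberately contains no timestamps).

# Limitations

* Resnik similarity ignores term multiplicity and profile size beyond the
  averaging; profiles of very different sizes can look more similar than a
  clinician would judge.
* Complete linkage with a global cut is sensitive to outliers; the package
  reports flagged empty profiles and cluster sizes so degenerate cuts are
  visible, but does not automatically re-cut.
* The landmark analysis conditions on survival to the landmark and therefore
  answers a conditional question; it does not model the changepoint.
* The small-sample Fisher rule is a convention, not an optimality result.
* P-value adjustment is within model family only; no global error control
  across endpoints.

# Worked example

```{r example, eval = FALSE}
study <- simulate_study(sim_config(seed = 1))
fit <- phenoclust(study$profiles, study$graph, freq = study$freq_raw, k = 3)
summary(fit)

ep <- build_endpoint(study$survival, "composite")
landmark_analysis(ep$time, ep$event,
                  fit$labels[as.character(ep$patient_id)], t_landmark = 4)
```

Or end to end from a config:

```{r pipeline, eval = FALSE}
run_pipeline(list(simulate = TRUE, seed = 1, out_dir = "results"))
```
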