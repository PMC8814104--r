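# phenorisk

Ontology-based phenotypic risk stratification for congenital heart disease
cohorts.

Patients with complex congenital heart disease — the motivating case is
congenitally corrected transposition of the great arteries — present with
heterogeneous combinations of cardiac findings. Treating the cohort as
homogeneous hides prognostic structure: subgroups defined by coherent
phenotype families can have survival curves that overlap early and diverge
years after surgery. `phenorisk` implements the full analysis chain for
finding and validating such subgroups:

1. **Ontology parsing and information content.** Phenotype terms (e.g. Human
   Phenotype Ontology annotations) are read from OBO files into a rooted DAG.
   Annotation counts are propagated up the graph; term information content is
   Resnik's $\mathrm{IC}(t) = -\ln p(t)$ with Laplace smoothing.
2. **Semantic patient similarity.** Term similarity is the IC of the most
   informative common ancestor,
   $\mathrm{Sim}(t_1,t_2)=\max_{v \in \mathrm{anc}(t_1)\cap\mathrm{anc}(t_2)}\mathrm{IC}(v)$;
   patient similarity is the symmetric best-match average
   $$\mathrm{Sim}(c_1,c_2)=\tfrac{1}{2|c_1|}\sum_{p\in c_1}\max_{q\in c_2}\mathrm{Sim}(p,q)
     +\tfrac{1}{2|c_2|}\sum_{q\in c_2}\max_{p\in c_1}\mathrm{Sim}(p,q).$$
3. **Clustering.** Similarity becomes distance via a global order-reversing
   shift; complete-linkage agglomeration with a deterministic tie-break is
   cut into `k` clusters (default 3). Clusters are characterized by term
   enrichment (chi-square, or Fisher when any cluster has < 10 members or an
   expected count < 5) with Benjamini-Hochberg adjustment, and by phenotype
   combination summaries.
4. **Prognosis.** Kaplan-Meier estimation, log-rank tests, landmark analysis
   at a clinically motivated changepoint (default 4 years), and
   univariable/multivariable Cox regression (Efron ties, p < 0.05 entry rule,
   BH adjustment, explicit non-estimability flags instead of absurd hazard
   ratios).

A synthetic-study generator with planted cluster structure and a
piecewise-exponential hazard changepoint is a first-class part of the
package, so every stage can be validated against known ground truth.

The methods vignette (`vignettes/phenorisk-methods.Rmd`) documents the model,
all numerical conventions, the generator design and its limitations.

## Worked example

Simulate the reference study (270 patients, three planted phenotype clusters
of sizes 21/136/113, hazard divergence in cluster 3 after year 4), fit the
clustering, and test for late survival divergence:

```r
library(phenorisk)

study <- simulate_study(sim_config(seed = 1))
fit <- phenoclust(study$profiles, study$graph, freq = study$freq_raw, k = 3)
fit
#> Ontology-based phenotype clustering (complete linkage)
#>   patients: 270   clusters (k): 3   IC source: corpus
#>   cluster sizes: 21 / 136 / 113

s <- summary(fit)
head(s$term_tests[order(s$term_tests$p_adj),
                  c("term", "n_cluster1", "n_cluster2", "n_cluster3",
                    "test", "p", "p_adj")], 5)
#>          term n_cluster1 n_cluster2 n_cluster3       test            p        p_adj
#> 11 HP:0000022          0          0        102 chi-square 3.489198e-50 1.988843e-48
#> 8  HP:0000013          0        120          0 chi-square 6.108826e-47 1.741016e-45
#> 19 HP:0000043          0          0         83 chi-square 6.988488e-37 1.327813e-35
#> 38 HP:0000090          0        102          0 chi-square 8.449732e-36 1.204087e-34
#> 52 HP:0000113          0          0         59     fisher 4.113710e-28 4.689630e-27

s$combinations
#>   cluster n_patients n_combinations n_unique_patients terms_median terms_min terms_max n_distinct_terms
#> 1       1         21             20                19            4         2         8               23
#> 2       2        136             93                83            3         1         6               45
#> 3       3        113             84                72            4         1         7               42
#> 4 overall        270            197               174            3         1         8               57

ep <- build_endpoint(study$survival, "composite")
landmark_analysis(ep$time, ep$event,
                  fit$labels[as.character(ep$patient_id)], t_landmark = 4)
#> Landmark analysis at t = 4 years
#>   pre- landmark: n = 21/136/113, log-rank chi2 = 0.812 (df 2), p = 0.6663
#>   post- landmark: n = 16/83/71, log-rank chi2 = 29.201 (df 2), p = 4.562e-07
```

The clusters are statistically indistinguishable before the landmark and
sharply divergent after it — the planted late-divergence pattern, recovered
from phenotype data alone.

The whole pipeline (clustering, characterization, KM, log-rank, landmark,
Cox per endpoint, cohort summary, deterministic `manifest.json`) runs from a
single config:

```r
run_pipeline(list(simulate = TRUE, seed = 1, out_dir = "results"))
```

or from files via YAML and the bundled CLI:

```sh
Rscript inst/cli/phenorisk.R simulate --seed 1 --out data/
Rscript inst/cli/phenorisk.R run-all  --config config.yaml
Rscript inst/cli/phenorisk.R summarize --out results/
```

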