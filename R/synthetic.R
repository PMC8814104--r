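#' Configuration for the synthetic study generator
#'
#' Defaults emulate a single-center complex congenital heart disease cohort:
#' 270 patients in three latent phenotype clusters of 21/136/113, each
#' patient annotated with 1-9 cardiovascular terms (median about 3) drawn
#' from 58 informative terms embedded in a ~120-term ontology, and
#' piecewise-exponential survival in which one cluster's hazard diverges
#' after a 4-year changepoint. Baseline hazards are set to plausible
#' single-center rates (about 0.014/y all-cause death, 0.005/y heart
#' failure, 0.021/y reintervention) with uniform administrative censoring on
#' 0.5-11 years.
#'
#' @param seed integer seed driving the whole generator (sub-stages derive
#'   offsets from it).
#' @param n_patients cohort size.
#' @param sizes integer cluster sizes summing to `n_patients`.
#' @param n_terms total terms in the generated ontology (root included).
#' @param n_informative informative (annotatable) terms among them.
#' @param depth,multi_parent_frac ontology shape: number of levels below the
#'   root and the fraction of terms receiving a second parent.
#' @param archetype_size archetype terms per cluster (disjoint across
#'   clusters, sampled within one ontology branch per cluster so that a
#'   cluster's defining anomalies are semantically related, as co-anomaly
#'   families are in real cohorts).
#' @param p_archetype per-term carry probabilities for a patient's own
#'   archetype terms, graded from the cluster-defining anomaly down to
#'   accessory findings (recycled to `archetype_size`); the default mirrors
#'   the carriage gradient of defining terms in published congenital
#'   heart disease clusters (about 0.9 for the top term).
#' @param p_background carry probability for each background term.
#' @param terms_range allowed per-patient term count, inclusive.
#' @param lambda_death,lambda_hf,lambda_reint baseline exponential hazards
#'   (per year).
#' @param hazard_multiplier post-changepoint hazard multiplier `m` applied
#'   to the risk cluster's death and heart-failure hazards.
#' @param risk_cluster index of the cluster whose hazard diverges.
#' @param t_change changepoint time in years.
#' @param censor_window administrative censoring window (uniform draw).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_patients = 270L,
                       sizes = c(21L, 136L, 113L),
                       n_terms = 120L,
                       n_informative = 58L,
                       depth = 4L,
                       multi_parent_frac = 0.15,
                       archetype_size = 5L,
                       p_archetype = c(0.9, 0.7, 0.5, 0.35, 0.2),
                       p_background = 0.02,
                       terms_range = c(1L, 9L),
                       lambda_death = 0.0144,
                       lambda_hf = 0.0053,
                       lambda_reint = 0.021,
                       hazard_multiplier = 6,
                       risk_cluster = 3L,
                       t_change = 4,
                       censor_window = c(0.5, 11)) {
  cfg <- as.list(environment())
  if (sum(cfg$sizes) != cfg$n_patients) {
    stop("cluster sizes must sum to n_patients")
  }
  if (cfg$n_terms < 5L) stop("need at least 5 terms")
  if (any(c(cfg$p_archetype, cfg$p_background) < 0) ||
      any(c(cfg$p_archetype, cfg$p_background) > 1)) {
    stop("carry probabilities must lie in [0, 1]")
  }
  if (cfg$hazard_multiplier <= 0) stop("hazard multiplier must be positive")
  if (any(c(cfg$lambda_death, cfg$lambda_hf, cfg$lambda_reint) <= 0)) {
    stop("baseline hazards must be positive")
  }
  if (cfg$archetype_size * length(cfg$sizes) > cfg$n_informative) {
    stop("archetype sets exceed the informative term pool")
  }
  structure(cfg, class = "sim_config")
}

#' Generate a toy ontology with power-law annotation counts
#'
#' Builds a rooted DAG: terms are assigned to `depth` levels below the root,
#' each term gets one parent from the level above, and a configurable
#' fraction receives a second parent from any higher level (so closures are
#' genuinely DAG-shaped). Raw annotation counts are drawn from a heavy-tail
#' so information content spans from near zero (common terms) to large
#' (rare terms). Output round-trips through [parse_obo()] /
#' [read_freq_tsv()].
#'
#' @param cfg a [sim_config()].
#' @return List with `graph` (an `ontology_graph`) and `freq_raw` (named raw
#'   annotation counts on the non-root terms).
#' @export
make_toy_ontology <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n_terms
  ids <- sprintf("HP:%07d", seq_len(n))
  root <- ids[1]
  # level assignment: root level 0; level sizes grow geometrically so the
  # graph has a few broad families fanning out into many specific terms,
  # the shape of real phenotype ontologies. A fixed floor of top-level
  # family heads mirrors the handful of major anomaly categories directly
  # under a system root.
  n_families <- min(8L, n - 2L)
  lev <- c(0L, rep(1L, n_families),
           sort(sample(seq_len(cfg$depth), n - 1L - n_families,
                       replace = TRUE, prob = 2^seq_len(cfg$depth))))
  parents <- setNames(vector("list", n), ids)
  parents[[root]] <- character(0)
  for (i in 2:n) {
    pool <- ids[lev < lev[i]]
    # primary parent from the level immediately above when available
    above <- ids[lev == lev[i] - 1L]
    p1 <- if (length(above)) sample(above, 1L) else root
    ps <- p1
    if (runif(1) < cfg$multi_parent_frac) {
      extra <- setdiff(pool, p1)
      if (length(extra)) ps <- c(ps, sample(extra, 1L))
    }
    parents[[ids[i]]] <- ps
  }
  g <- new_ontology_graph(ids, setNames(paste("term", seq_len(n)), ids),
                          parents)
  # heavy-tail raw counts on non-root terms: many rare, a few very common
  u <- runif(n - 1L)
  freq_raw <- setNames(pmin(2000, ceiling(3 / u^1.2)), ids[-1])
  list(graph = g, freq_raw = freq_raw)
}

#' Simulate a phenotype cohort with planted clusters
#'
#' Each cluster owns a disjoint archetype set of informative terms sampled
#' from within a single ontology branch, so a cluster's defining anomalies
#' are semantically related (share informative ancestors) the way
#' co-anomaly families are in real cohorts. A patient carries their
#' cluster's archetype terms with graded probabilities `p_archetype`
#' (defining anomaly first) and each background informative term with
#' probability `p_background`. Term counts are truncated into `terms_range`
#' (a patient drawing none receives their cluster's defining term; a patient
#' drawing more than the maximum keeps a random subset), which under the
#' defaults yields a per-patient median of about 3 terms.
#'
#' @param cfg a [sim_config()].
#' @param g the `ontology_graph` the terms live in (typically from
#'   [make_toy_ontology()]).
#' @return List with `profiles` (named list, `P0001`... -> term sets),
#'   `cluster` (named integer planted labels) and `informative`
#'   (list with `archetypes` per cluster and `background` terms).
#' @export
simulate_cohort <- function(cfg, g) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 1L)
  k <- length(cfg$sizes)
  pool <- setdiff(g$terms, g$root)
  if (length(pool) < cfg$n_informative) stop("ontology too small for config")

  # pick k disjoint branches, each large enough to host an archetype set.
  # Candidate branch heads are all non-root terms; greedy smallest-first
  # selection of subtrees that can host an archetype set picks the tightest
  # term families, mirroring how a cluster's defining co-anomalies form one
  # close-knit ontology family. Selected heads may share no ancestor but the
  # root, so the only common ancestry across planted clusters is the
  # (uninformative) root: the planted separation is structural.
  heads <- setdiff(g$terms, g$root)
  branches <- lapply(setNames(heads, heads),
                     function(h) setdiff(descendant_set(g, h), g$root))
  branches <- branches[lengths(branches) >= cfg$archetype_size]
  branches <- branches[order(lengths(branches))]
  # lineage: the branch terms plus the head's own ancestors (root excluded);
  # requiring lineages to be disjoint keeps any two clusters' defining
  # families from sharing an informative ancestor
  lineages <- lapply(names(branches), function(h)
    union(branches[[h]], setdiff(ancestor_closure(g, h), g$root)))
  greedy <- function(ord) {
    chosen <- integer(0); used <- character(0)
    for (i in ord) {
      if (length(chosen) == k) break
      if (length(intersect(lineages[[i]], used))) next
      chosen <- c(chosen, i)
      used <- c(used, lineages[[i]])
    }
    if (length(chosen) == k) chosen else NULL
  }
  chosen <- greedy(seq_along(branches))
  attempt <- 0L
  while (is.null(chosen) && attempt < 200L) {   # smallest-first can dead-end
    chosen <- greedy(sample(seq_along(branches)))
    attempt <- attempt + 1L
  }
  if (is.null(chosen)) stop("ontology has too few disjoint branches for ",
                            k, " archetype sets; regenerate with more terms")
  arch <- lapply(chosen, function(i) sample(branches[[i]], cfg$archetype_size))
  background <- sample(setdiff(pool, unlist(arch)),
                       cfg$n_informative - cfg$archetype_size * k)

  labels <- rep(seq_len(k), cfg$sizes)
  ids <- sprintf("P%04d", seq_len(cfg$n_patients))
  lo <- cfg$terms_range[1]; hi <- cfg$terms_range[2]
  p_arch <- rep_len(cfg$p_archetype, cfg$archetype_size)

  profiles <- vector("list", cfg$n_patients)
  for (i in seq_len(cfg$n_patients)) {
    own <- arch[[labels[i]]]
    carried <- c(own[runif(length(own)) < p_arch],
                 background[runif(length(background)) < cfg$p_background])
    # the latent class always manifests in at least one family finding:
    # a patient drawing no archetype term receives the defining one
    if (!any(own %in% carried)) carried <- c(own[1], carried)
    if (length(carried) > hi) {
      carried <- c(intersect(own, carried)[1],
                   sample(setdiff(carried, intersect(own, carried)[1]),
                          hi - 1L))
    }
    profiles[[i]] <- sort(carried)
  }
  names(profiles) <- ids
  list(profiles = profiles, cluster = setNames(labels, ids),
       informative = list(archetypes = arch, background = background))
}

# Piecewise-exponential sampler by inversion: rate1 before tstar, rate2
# after.
#' @keywords internal
rpwexp <- function(n, rate1, rate2, tstar) {
  h <- stats::rexp(n)                      # cumulative hazard at event
  ifelse(h <= rate1 * tstar, h / rate1, tstar + (h - rate1 * tstar) / rate2)
}

#' Simulate survival outcomes with a hazard changepoint
#'
#' Death and heart-failure times are drawn from independent
#' piecewise-exponential hazards: every cluster shares the baseline rate
#' before the changepoint `t_change`, and the designated risk cluster's
#' rates are multiplied by `hazard_multiplier` afterwards — the mid-term
#' divergence pattern landmark analysis is designed to detect.
#' Reintervention is an independent exponential process. Administrative
#' censoring is uniform on `censor_window`. Follow-up ends at death or
#' censoring; heart failure and reintervention are observed only if they
#' precede the end of follow-up. Surgical strategy, sex and age at surgery
#' are generated as independent covariates.
#'
#' @param cfg a [sim_config()].
#' @param labels named integer cluster labels (e.g. from
#'   [simulate_cohort()]).
#' @return Data frame with one row per patient: `patient_id`, `time_years`,
#'   `death`, `hf`, `hf_time`, `reint`, `reint_time`, `cluster`, `strategy`,
#'   `sex`, `age_surgery`.
#' @export
simulate_survival <- function(cfg, labels) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 2L)
  n <- length(labels)
  risky <- labels == cfg$risk_cluster
  m <- ifelse(risky, cfg$hazard_multiplier, 1)

  t_death <- rpwexp(n, cfg$lambda_death, cfg$lambda_death * m, cfg$t_change)
  t_hf <- rpwexp(n, cfg$lambda_hf, cfg$lambda_hf * m, cfg$t_change)
  t_reint <- stats::rexp(n, cfg$lambda_reint)
  cens <- runif(n, cfg$censor_window[1], cfg$censor_window[2])

  fu <- pmin(t_death, cens)
  death <- as.integer(t_death <= cens)
  hf <- as.integer(t_hf <= fu)
  reint <- as.integer(t_reint <= fu)

  data.frame(
    patient_id = names(labels),
    time_years = fu,
    death = death,
    hf = hf,
    hf_time = ifelse(hf == 1, t_hf, NA_real_),
    reint = reint,
    reint_time = ifelse(reint == 1, t_reint, NA_real_),
    cluster = as.integer(labels),
    strategy = sample(c("anatomic", "physiologic", "Fontan"), n,
                      replace = TRUE, prob = c(0.25, 0.55, 0.20)),
    sex = sample(c("female", "male"), n, replace = TRUE,
                 prob = c(0.4, 0.6)),
    age_surgery = rlnorm(n, meanlog = log(5.4), sdlog = 1.1)
  )
}

#' Simulate a complete synthetic study
#'
#' Runs [make_toy_ontology()], [simulate_cohort()] and
#' [simulate_survival()] under one configuration. Fully deterministic for a
#' fixed `cfg$seed`.
#'
#' @param cfg a [sim_config()].
#' @return List with `graph`, `freq_raw`, `profiles`, `cluster`,
#'   `informative`, `survival` and `config`.
#' @export
simulate_study <- function(cfg = sim_config()) {
  onto <- make_toy_ontology(cfg)
  cohort <- simulate_cohort(cfg, onto$graph)
  surv <- simulate_survival(cfg, cohort$cluster)
  list(graph = onto$graph, freq_raw = onto$freq_raw,
       profiles = cohort$profiles, cluster = cohort$cluster,
       informative = cohort$informative, survival = surv, config = cfg)
}

#' Write annotation counts as TSV (term_id, count)
#' @param freq named numeric vector of counts.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_freq_tsv <- function(freq, path) {
  write.table(data.frame(term_id = names(freq), count = as.integer(freq)),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an annotation-count TSV (term_id, count; header required)
#' @param path TSV path.
#' @return Named numeric vector of counts.
#' @export
read_freq_tsv <- function(path) {
  df <- read.delim(path)
  stopifnot(all(c("term_id", "count") %in% names(df)))
  setNames(as.numeric(df$count), df$term_id)
}

#' Write survival records as TSV
#' @param records survival data frame (see [simulate_survival()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_survival_tsv <- function(records, path) {
  write.table(records, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a survival TSV
#' @param path TSV path.
#' @return Data frame of survival records.
#' @export
read_survival_tsv <- function(path) {
  read.delim(path)
}
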