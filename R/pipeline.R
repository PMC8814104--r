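#' Baseline cohort summary table
#'
#' Summarizes the cohort overall and, when cluster labels are given, per
#' cluster: categorical variables (and phenotype-term carriage from
#' `profiles`) as count (percentage to 1 decimal place) with chi-square /
#' Fisher group comparison under the small-group rule (Fisher when any
#' cluster has fewer than 10 members or any expected count is below 5);
#' continuous variables as mean +/- SD and median (P25-P75) with
#' Kruskal-Wallis comparison. Follow-up retention is reported as
#' followed / eligible when `n_eligible` is supplied. Variables with a zero
#' denominator are skipped with a warning. Every percentage is emitted next
#' to the count and denominator it was computed from.
#'
#' @param records data frame of per-patient rows (one per patient).
#' @param profiles optional named list of phenotype profiles; each carried
#'   term becomes a categorical row.
#' @param labels optional named cluster labels; enables per-cluster columns
#'   and group-comparison p-values.
#' @param categorical,continuous names of `records` columns to summarize.
#' @param n_eligible optional number of patients eligible for follow-up.
#' @return List of class `cohort_summary` with `n`, `retention` (or `NULL`),
#'   `categorical` (data frame) and `continuous` (data frame).
#' @export
cohort_summary <- function(records, profiles = NULL, labels = NULL,
                           categorical = character(0),
                           continuous = character(0),
                           n_eligible = NULL) {
  n <- nrow(records)
  if (n == 0L) stop("empty cohort")
  ids <- as.character(records$patient_id)
  lab <- if (!is.null(labels)) factor(labels[ids]) else NULL
  cluster_n <- if (!is.null(lab)) as.vector(table(lab)) else NULL

  retention <- NULL
  if (!is.null(n_eligible)) {
    if (n_eligible <= 0) stop("n_eligible must be positive")
    retention <- list(followed = n, eligible = n_eligible,
                      pct = round(100 * n / n_eligible, 1))
  }

  pct1 <- function(x, d) round(100 * x / d, 1)

  cat_row <- function(name, carrier) {
    row <- data.frame(variable = name, n = sum(carrier), denominator = n,
                      pct = pct1(sum(carrier), n))
    if (!is.null(lab)) {
      tab <- table(factor(carrier, levels = c(TRUE, FALSE)), lab)
      for (g in seq_along(levels(lab))) {
        row[[paste0("n_cluster", levels(lab)[g])]] <- tab["TRUE", g]
        row[[paste0("pct_cluster", levels(lab)[g])]] <-
          pct1(tab["TRUE", g], cluster_n[g])
      }
      row$p <- group_test_categorical(tab, cluster_n)
    }
    row
  }

  cat_rows <- list()
  for (v in categorical) {
    x <- records[[v]]
    if (is.null(x) || all(is.na(x))) {
      warning("categorical variable skipped (empty): ", v)
      next
    }
    for (lev in sort(unique(as.character(x[!is.na(x)])))) {
      cat_rows[[paste(v, lev)]] <- cat_row(paste0(v, "=", lev),
                                           !is.na(x) & x == lev)
    }
  }
  if (!is.null(profiles)) {
    all_terms <- sort(unique(unlist(profiles[ids], use.names = FALSE)))
    for (tm in all_terms) {
      carrier <- vapply(profiles[ids], function(p) tm %in% p, TRUE)
      cat_rows[[tm]] <- cat_row(tm, carrier)
    }
  }

  cont_rows <- list()
  for (v in continuous) {
    x <- records[[v]]
    if (is.null(x) || all(is.na(x))) {
      warning("continuous variable skipped (empty): ", v)
      next
    }
    q <- quantile(x, c(0.25, 0.5, 0.75), na.rm = TRUE)
    row <- data.frame(variable = v, mean = mean(x, na.rm = TRUE),
                      sd = sd(x, na.rm = TRUE), median = unname(q[2]),
                      p25 = unname(q[1]), p75 = unname(q[3]))
    if (!is.null(lab)) {
      row$p <- kruskal.test(x, lab)$p.value
    }
    cont_rows[[v]] <- row
  }

  structure(list(
    n = n,
    retention = retention,
    categorical = if (length(cat_rows)) do.call(rbind, cat_rows) else NULL,
    continuous = if (length(cont_rows)) do.call(rbind, cont_rows) else NULL
  ), class = "cohort_summary")
}

# chi-square unless a small-group/small-expected-count rule triggers Fisher.
#' @keywords internal
group_test_categorical <- function(tab, cluster_n) {
  if (any(rowSums(tab) == 0L)) return(1)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(cluster_n < 10) || any(expected < 5)) {
    ft <- tryCatch(fisher.test(tab),
                   error = function(e)
                     fisher.test(tab, simulate.p.value = TRUE, B = 20000L))
    ft$p.value
  } else {
    suppressWarnings(chisq.test(tab))$p.value
  }
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("Cohort summary: n =", x$n, "\n")
  if (!is.null(x$retention)) {
    cat(sprintf("  follow-up retention: %d/%d = %.1f%%\n",
                x$retention$followed, x$retention$eligible, x$retention$pct))
  }
  if (!is.null(x$categorical)) {
    cat("\nCategorical variables / phenotype terms:\n")
    print(head(x$categorical, 20), row.names = FALSE)
    if (nrow(x$categorical) > 20) cat("  ...", nrow(x$categorical), "rows\n")
  }
  if (!is.null(x$continuous)) {
    cat("\nContinuous variables:\n")
    print(x$continuous, row.names = FALSE)
  }
  invisible(x)
}

#' Run the full stratification pipeline
#'
#' Orchestrates the stages: load or simulate inputs, restrict the ontology,
#' compute information content, patient similarity and distance, cluster,
#' characterize clusters, and analyze survival per endpoint (whole-cohort
#' KM, cluster log-rank, landmark analysis, univariable + multivariable
#' Cox). All stage outputs are written as TSV under `out_dir` together with
#' a `manifest.json` recording the configuration, seed, package version and
#' MD5 hashes of every output, so a rerun with identical inputs is
#' byte-identical.
#'
#' @param config a list (or path to a YAML file) with entries:
#'   \describe{
#'     \item{simulate}{logical; when TRUE inputs are generated by
#'       [simulate_study()] using `sim` (arguments for [sim_config()]).}
#'     \item{ontology,profiles,frequencies,survival}{input file paths
#'       (OBO / long TSV / count TSV / survival TSV) when `simulate` is
#'       FALSE.}
#'     \item{subontology_root,allowlist}{optional ontology restriction.}
#'     \item{smoothing,k,landmark_time,endpoints,covariates,seed}{analysis
#'       parameters; defaults 1, 3, 4, c("primary","composite"),
#'       c("strategy"), 1.}
#'     \item{out_dir}{output directory (required).}
#'   }
#' @return Invisibly, a list with the fitted `phenoclust`, the cluster
#'   summary, survival results per endpoint, the cohort summary and the
#'   manifest.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- list(simulate = FALSE, smoothing = 1, k = 3, landmark_time = 4,
                   endpoints = c("primary", "composite"),
                   covariates = "strategy", seed = 1L, allowlist = character(0))
  config <- utils::modifyList(defaults, config)
  if (is.null(config$out_dir)) stop("config error: out_dir is required")
  if (config$k < 1) stop("config error: k must be >= 1")
  if (config$landmark_time <= 0) stop("config error: landmark_time must be positive")

  log <- character(0)
  note <- function(...) log <<- c(log, paste0(...))

  if (isTRUE(config$simulate)) {
    cfg <- do.call(sim_config, c(list(seed = as.integer(config$seed)),
                                 config$sim))
    study <- simulate_study(cfg)
    g <- study$graph; freq <- study$freq_raw
    profiles <- study$profiles; surv_records <- study$survival
    note("inputs: simulated study, seed ", cfg$seed)
  } else {
    for (f in c("ontology", "profiles", "survival")) {
      if (is.null(config[[f]]) || !file.exists(config[[f]])) {
        stop("config error: missing input file for stage '", f, "'")
      }
    }
    g <- parse_obo(config$ontology)
    profiles <- read_profiles_tsv(config$profiles)
    freq <- if (!is.null(config$frequencies)) read_freq_tsv(config$frequencies)
    surv_records <- read_survival_tsv(config$survival)
    note("inputs: loaded from disk")
  }

  if (!is.null(config$subontology_root)) {
    n_before <- length(g$terms)
    g <- restrict_to_subontology(g, config$subontology_root, config$allowlist)
    note("ontology restricted: ", n_before, " -> ", length(g$terms), " terms")
  }

  fit <- phenoclust(profiles, g, freq = freq, k = config$k,
                    smoothing = config$smoothing)
  note("clustering: k = ", config$k, ", sizes ",
       paste(table(fit$labels), collapse = "/"),
       ", IC mode ", fit$ic_mode,
       if (length(fit$flagged_empty))
         paste0(", ", length(fit$flagged_empty), " empty profiles flagged")
       else "")
  clus_sum <- summary(fit)

  set.seed(as.integer(config$seed))   # Fisher Monte-Carlo fallback etc.
  ids <- as.character(surv_records$patient_id)
  grp <- fit$labels[ids]
  endpoints <- list()
  for (ep in config$endpoints) {
    te <- build_endpoint(surv_records, ep)
    rej <- attr(te, "rejected")
    if (nrow(rej)) note("endpoint ", ep, ": ", nrow(rej), " records rejected")
    keep <- match(te$patient_id, ids)
    dat <- cbind(te, surv_records[keep, setdiff(names(surv_records),
                                                names(te)), drop = FALSE])
    dat$cluster <- factor(grp[as.character(te$patient_id)])
    endpoints[[ep]] <- list(
      data = te,
      km = km_estimate(te$time, te$event),
      logrank = if (sum(te$event) >= 1)
        logrank_test(te$time, te$event, dat$cluster) else NULL,
      landmark = landmark_analysis(te$time, te$event, dat$cluster,
                                   t_landmark = config$landmark_time),
      cox = cox_multivariable(dat, unique(c("cluster", config$covariates)))
    )
  }

  csum <- cohort_summary(surv_records, profiles = profiles,
                         labels = fit$labels,
                         categorical = intersect(c("strategy", "sex"),
                                                 names(surv_records)),
                         continuous = intersect(c("age_surgery", "time_years"),
                                                names(surv_records)),
                         n_eligible = config$n_eligible)

  # ---- persist outputs -------------------------------------------------
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$out_dir, f)
  wt <- function(df, f) {
    write.table(df, out(f), sep = "\t", quote = FALSE, row.names = FALSE)
    f
  }
  files <- c(
    wt(data.frame(patient_id = names(fit$labels), cluster = fit$labels),
       "labels.tsv"),
    { write_matrix_tsv(fit$sim, out("similarity.tsv")); "similarity.tsv" },
    { write_matrix_tsv(fit$dist, out("distance.tsv")); "distance.tsv" },
    wt(clus_sum$term_tests, "term_tests.tsv"),
    wt(clus_sum$combinations, "combinations.tsv")
  )
  for (ep in names(endpoints)) {
    files <- c(files, wt(endpoints[[ep]]$km, paste0("km_", ep, ".tsv")))
    files <- c(files,
               wt(endpoints[[ep]]$cox$univariable,
                  paste0("cox_univariable_", ep, ".tsv")))
    if (!is.null(endpoints[[ep]]$cox$table)) {
      files <- c(files, wt(endpoints[[ep]]$cox$table,
                           paste0("cox_multivariable_", ep, ".tsv")))
    }
  }
  if (!is.null(csum$categorical)) {
    files <- c(files, wt(csum$categorical, "cohort_summary_categorical.tsv"))
  }
  if (!is.null(csum$continuous)) {
    files <- c(files, wt(csum$continuous, "cohort_summary_continuous.tsv"))
  }

  manifest <- list(
    package = "phenorisk",
    version = as.character(utils::packageVersion("phenorisk")),
    seed = as.integer(config$seed),
    config = config[setdiff(names(config), "out_dir")],
    log = log,
    hashes = as.list(tools::md5sum(file.path(config$out_dir, files)))
  )
  names(manifest$hashes) <- files
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)

  invisible(list(fit = fit, cluster_summary = clus_sum,
                 endpoints = endpoints, cohort_summary = csum,
                 manifest = manifest, log = log))
}
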