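#' Cluster patients by ontology-based phenotype similarity
#'
#' The core fit of the package: computes the pairwise best-match-average
#' Resnik similarity of the patients' phenotype profiles, converts it to a
#' distance matrix (`max(sim) - sim`, diagonal zeroed), runs
#' complete-linkage hierarchical clustering, and cuts the dendrogram into
#' `k` phenotype clusters.
#'
#' Term probabilities come from `freq` (an annotation corpus, e.g. HPO
#' disease-annotation counts) when supplied; otherwise they are estimated
#' from the cohort itself (each patient counted once per carried term,
#' propagated up the ontology). The mode used is recorded in the fit.
#' Patients with an empty term set are assigned the single cohort-root term
#' (the restricted subontology root, or the graph root) so the best-match
#' average is defined; they are flagged in the fit.
#'
#' @param profiles named list of patient phenotype profiles (patient id ->
#'   character vector of term ids).
#' @param g an `ontology_graph` (typically restricted with
#'   [restrict_to_subontology()]).
#' @param freq optional raw annotation counts (named numeric, term -> count)
#'   supplying term probabilities; propagated internally.
#' @param k number of clusters to cut (default 3).
#' @param smoothing pseudo-count for [information_content()] (default 1).
#' @param cohort_root term assigned to patients with empty profiles;
#'   defaults to the selected subontology root if the graph is restricted,
#'   else the graph root.
#' @return An object of class `phenoclust`: list with `labels` (named
#'   cluster assignment), `k`, `sim`, `dist`, `dendrogram` (a
#'   `phenodendro`), `ic`, `profiles` (after the empty-profile rule),
#'   `ic_mode` (`"corpus"` or `"cohort"`), `flagged_empty` and `call`.
#' @examples
#' sim <- simulate_study(sim_config(seed = 1, n_patients = 60,
#'                                  sizes = c(10, 30, 20)))
#' fit <- phenoclust(sim$profiles, sim$graph, freq = sim$freq_raw, k = 3)
#' print(fit)
#' table(fit$labels, sim$cluster)
#' @export
phenoclust <- function(profiles, g, freq = NULL, k = 3, smoothing = 1,
                       cohort_root = NULL) {
  if (is.null(cohort_root)) {
    sel <- attr(g, "selected")
    cohort_root <- if (!is.null(sel)) {
      # the selected term whose closure contains all other selected terms,
      # if one exists; otherwise the graph root
      cand <- sel[vapply(sel, function(t) all(sel %in% descendant_set(g, t)), TRUE)]
      if (length(cand)) cand[1] else g$root
    } else g$root
  }
  empty <- vapply(profiles, length, 1L) == 0L
  profiles[empty] <- list(cohort_root)

  ic_mode <- if (is.null(freq)) "cohort" else "corpus"
  if (is.null(freq)) {
    used <- unlist(lapply(profiles, unique), use.names = FALSE)
    freq <- vapply(split(used, used), length, 1L)
  }
  ic <- information_content(propagate_counts(g, freq), smoothing = smoothing)

  sim <- similarity_matrix(profiles, g, ic)
  dist <- to_distance(sim)
  dend <- linkage_complete(dist)
  labels <- cut_k(dend, k)

  structure(list(labels = labels, k = k, sim = sim, dist = dist,
                 dendrogram = dend, ic = ic, profiles = profiles,
                 ic_mode = ic_mode,
                 flagged_empty = names(profiles)[empty],
                 call = match.call()),
            class = "phenoclust")
}

#' @export
print.phenoclust <- function(x, ...) {
  cat("Ontology-based phenotype clustering (complete linkage)\n")
  cat("  patients:", length(x$labels), "  clusters (k):", x$k,
      "  IC source:", x$ic_mode, "\n")
  cat("  cluster sizes:", paste(table(x$labels), collapse = " / "), "\n")
  if (length(x$flagged_empty)) {
    cat("  patients assigned the cohort-root term:",
        length(x$flagged_empty), "\n")
  }
  invisible(x)
}

#' Summarize a phenotype clustering
#'
#' Runs the per-cluster phenotype-distribution tests and the
#' combination-heterogeneity summary on the fitted partition.
#'
#' @param object a `phenoclust` fit.
#' @param ... passed to [cluster_term_tests()].
#' @return An object of class `summary.phenoclust` with elements
#'   `term_tests` and `combinations`.
#' @export
summary.phenoclust <- function(object, ...) {
  structure(list(
    k = object$k,
    sizes = table(object$labels),
    term_tests = cluster_term_tests(object$profiles, object$labels, ...),
    combinations = combination_summary(object$profiles, object$labels)
  ), class = "summary.phenoclust")
}

#' @export
print.summary.phenoclust <- function(x, ...) {
  cat("Phenotype clusters:", paste(x$sizes, collapse = " / "), "\n")
  sig <- sum(x$term_tests$p_adj < 0.05, na.rm = TRUE)
  cat(sig, "of", nrow(x$term_tests),
      "terms differ across clusters (BH-adjusted p < 0.05)\n\n")
  cat("Combination heterogeneity per cluster:\n")
  print(x$combinations, row.names = FALSE)
  invisible(x)
}

#' @export
plot.phenoclust <- function(x, ...) {
  hc <- as.hclust(x$dendrogram)
  plot(hc, labels = FALSE, main = "Phenotype dendrogram (complete linkage)",
       xlab = "", sub = "", ...)
  stats::rect.hclust(hc, k = x$k)
  invisible(x)
}

#' Re-cut a fitted phenotype clustering at a different k
#' @param object a `phenoclust` fit.
#' @param k new number of clusters.
#' @return Named cluster label vector.
#' @export
recut <- function(object, k) {
  stopifnot(inherits(object, "phenoclust"))
  cut_k(object$dendrogram, k)
}
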