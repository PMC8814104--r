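#' Complete-linkage agglomerative clustering of a distance matrix
#'
#' Agglomerates singletons by the complete (maximum) linkage rule: the
#' distance between two clusters is the largest cross-pair distance. Ties on
#' the minimal merge distance are broken deterministically by merging the
#' candidate pair whose clusters contain the lexicographically smallest
#' (smallest-member-index, second-smallest-member-index) combination, so the
#' dendrogram is a pure function of the distance matrix.
#'
#' @param d symmetric numeric matrix with zero diagonal and no missing
#'   values; rownames are used as observation labels.
#' @return An object of class `phenodendro`: list with `merge` (an
#'   (n-1) x 2 matrix in [stats::hclust()] coding: negative entries are
#'   singleton observations, positive entries earlier merge steps), `height`
#'   (non-decreasing merge distances), `labels` and `method = "complete"`.
#' @seealso [cut_k()], [as.hclust.phenodendro()]
#' @export
linkage_complete <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 2L) stop("need at least two observations")
  if (any(is.na(d)) || any(is.nan(d))) stop("distance matrix contains NA/NaN")
  if (max(abs(d - t(d))) > 1e-8) stop("distance matrix must be symmetric")
  labels <- rownames(d)
  if (is.null(labels)) labels <- as.character(seq_len(n))

  D <- d
  diag(D) <- Inf
  alive <- rep(TRUE, n)
  minmem <- seq_len(n)            # smallest original index in each cluster
  secmem <- rep(Inf, n)           # second smallest (Inf for singletons)
  code <- -seq_len(n)             # hclust merge codes of active clusters
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)

  for (s in seq_len(n - 1L)) {
    Dv <- D
    Dv[!alive, ] <- Inf
    Dv[, !alive] <- Inf
    h <- min(Dv)
    cand <- which(Dv == h, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    # tie-break key: sorted smallest member indices of the candidate pair
    k1 <- pmin(minmem[cand[, 1]], minmem[cand[, 2]])
    k2 <- pmax(minmem[cand[, 1]], minmem[cand[, 2]])
    pick <- order(k1, k2)[1]
    i <- cand[pick, 1]; j <- cand[pick, 2]

    a <- code[i]; b <- code[j]
    merge[s, ] <- if (a < b) c(a, b) else c(b, a)
    height[s] <- h

    upd <- pmax(D[i, ], D[j, ])
    D[i, ] <- upd
    D[, i] <- upd
    D[i, i] <- Inf
    D[i, j] <- D[j, i] <- Inf
    alive[j] <- FALSE
    mm <- sort(c(minmem[i], secmem[i], minmem[j], secmem[j]))[1:2]
    minmem[i] <- mm[1]; secmem[i] <- mm[2]
    code[i] <- s
  }

  structure(list(merge = merge, height = height, labels = labels,
                 method = "complete"),
            class = "phenodendro")
}

#' @export
print.phenodendro <- function(x, ...) {
  n <- length(x$labels)
  cat("Complete-linkage dendrogram:", n, "observations,", n - 1L,
      "merges, heights", format(min(x$height), digits = 4), "-",
      format(max(x$height), digits = 4), "\n")
  invisible(x)
}

#' Convert a phenodendro to an hclust object
#'
#' @param x a `phenodendro`.
#' @param ... unused.
#' @return A [stats::hclust()] object (e.g. for plotting).
#' @export
as.hclust.phenodendro <- function(x, ...) {
  n <- length(x$labels)
  # leaf order by in-order traversal of the merge tree
  walk <- function(code) {
    if (code < 0) return(-code)
    c(walk(x$merge[code, 1]), walk(x$merge[code, 2]))
  }
  structure(list(merge = x$merge, height = x$height,
                 order = walk(n - 1L), labels = x$labels,
                 method = "complete", call = match.call(),
                 dist.method = "ontology"),
            class = "hclust")
}

#' Cut a dendrogram into k clusters
#'
#' Undoes the last `k - 1` merges and labels the resulting clusters `1..k`
#' in order of first patient appearance in the input order (stable
#' relabeling), so labels do not depend on merge bookkeeping.
#'
#' @param dend a `phenodendro` from [linkage_complete()].
#' @param k number of clusters, `1 <= k <= n`.
#' @return Named integer vector of cluster labels (names are observation
#'   labels).
#' @export
cut_k <- function(dend, k) {
  n <- length(dend$labels)
  if (k < 1L || k > n) stop("k must be between 1 and ", n)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  steprep <- integer(n - 1L)
  resolve <- function(code) if (code < 0) -code else steprep[code]
  for (s in seq_len(n - k)) {
    a <- find(resolve(dend$merge[s, 1]))
    b <- find(resolve(dend$merge[s, 2]))
    parent[b] <- a
    steprep[s] <- a
  }
  comp <- vapply(seq_len(n), find, 1L)
  labels <- match(comp, unique(comp))   # 1..k by first appearance
  stats::setNames(labels, dend$labels)
}

#' Per-cluster phenotype distribution tests
#'
#' For each term, builds the carriers-versus-non-carriers by cluster
#' contingency table and tests whether the term's distribution differs
#' across clusters. The chi-square test is used unless any cluster has fewer
#' than 10 members or any expected cell count falls below 5, in which case
#' the Fisher exact test is applied (exact enumeration, falling back to
#' Monte-Carlo with `fisher_B` replicates for tables beyond the enumeration
#' budget). Raw p-values are Benjamini-Hochberg adjusted across terms.
#' Degenerate tables (a term carried by everyone or no variation) get
#' `p = 1`.
#'
#' @param profiles named list of patient term-id vectors.
#' @param labels named integer/character cluster labels covering all
#'   patients in `profiles`.
#' @param terms terms to test; defaults to every term carried by at least
#'   one patient. Terms carried by nobody are excluded with a message.
#' @param fisher_B Monte-Carlo replicates for the Fisher fallback.
#' @return Data frame with one row per term: per-cluster carrier counts and
#'   frequencies, `statistic`, `p`, `p_adj` and `test` used.
#' @export
cluster_term_tests <- function(profiles, labels, terms = NULL,
                               fisher_B = 20000L) {
  ids <- names(profiles)
  stopifnot(!is.null(names(labels)), all(ids %in% names(labels)))
  lab <- factor(labels[ids])
  kk <- nlevels(lab)
  if (kk < 2L) stop("need at least two clusters")
  if (is.null(terms)) terms <- sort(unique(unlist(profiles, use.names = FALSE)))
  cluster_n <- as.vector(table(lab))

  rows <- lapply(terms, function(tm) {
    carrier <- vapply(profiles, function(p) tm %in% p, TRUE)
    if (!any(carrier)) return(NULL)
    tab <- table(factor(carrier, levels = c(TRUE, FALSE)), lab)
    counts <- as.vector(tab["TRUE", ])
    if (all(carrier)) {
      stat <- 0; p <- 1; test <- "degenerate"
    } else {
      expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
      if (any(cluster_n < 10) || any(expected < 5)) {
        ft <- tryCatch(fisher.test(tab),
                       error = function(e)
                         fisher.test(tab, simulate.p.value = TRUE, B = fisher_B))
        stat <- NA_real_; p <- ft$p.value; test <- "fisher"
      } else {
        ct <- suppressWarnings(chisq.test(tab))
        stat <- unname(ct$statistic); p <- ct$p.value; test <- "chi-square"
      }
    }
    out <- data.frame(term = tm, statistic = stat, p = p, test = test)
    for (g in seq_len(kk)) {
      out[[paste0("n_cluster", levels(lab)[g])]] <- counts[g]
      out[[paste0("freq_cluster", levels(lab)[g])]] <- counts[g] / cluster_n[g]
    }
    out$n_total <- sum(counts)
    out
  })
  skipped <- terms[vapply(rows, is.null, TRUE)]
  if (length(skipped)) {
    message("excluded term(s) carried by no patient: ",
            paste(skipped, collapse = ", "))
  }
  res <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  res$p_adj <- bh_adjust(res$p)
  rownames(res) <- NULL
  res
}

#' Phenotype-combination heterogeneity per cluster
#'
#' Summarizes how homogeneous each cluster's phenotype profiles are: the
#' number of distinct term-set combinations, the number of patients whose
#' combination is unique within the cluster, and the per-patient term-count
#' distribution.
#'
#' @inheritParams cluster_term_tests
#' @return Data frame with one row per cluster plus an `overall` row:
#'   `n_patients`, `n_combinations`, `n_unique_patients`, `terms_median`,
#'   `terms_min`, `terms_max`, `n_distinct_terms`.
#' @export
combination_summary <- function(profiles, labels) {
  ids <- names(profiles)
  lab <- as.character(labels[ids])
  key <- vapply(profiles, function(p) paste(sort(unique(p)), collapse = "|"), "")
  one <- function(sel, name) {
    tab <- table(key[sel])
    sizes <- lengths(profiles[sel])
    data.frame(cluster = name,
               n_patients = sum(sel),
               n_combinations = length(tab),
               n_unique_patients = sum(tab == 1L),
               terms_median = median(sizes),
               terms_min = min(sizes),
               terms_max = max(sizes),
               n_distinct_terms = length(unique(unlist(profiles[sel]))))
  }
  per <- lapply(sort(unique(lab)), function(cl) one(lab == cl, cl))
  rbind(do.call(rbind, per), one(rep(TRUE, length(ids)), "overall"))
}
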