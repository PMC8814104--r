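#' Resnik similarity of two ontology terms
#'
#' The similarity of two terms is the information content of their most
#' informative common ancestor (MICA): the maximum of `ic(v)` over the
#' intersection of the two inclusive ancestor closures. With inclusive
#' closures a term is its own ancestor, so `term_similarity(p, p) = ic(p)`.
#'
#' @param p1,p2 term ids present in `g`.
#' @param g an `ontology_graph`.
#' @param ic an `ic_table` from [information_content()].
#' @return Non-negative scalar.
#' @export
term_similarity <- function(p1, p2, g, ic) {
  common <- intersect(ancestor_closure(g, p1), ancestor_closure(g, p2))
  max(ic$ic[common])
}

# Precomputed term-by-term Resnik matrix over a set of terms; the
# workhorse behind similarity_matrix (profiles reuse the same pairs).
#' @keywords internal
term_sim_matrix <- function(terms, g, ic) {
  clo <- all_closures(g)[terms]
  n <- length(terms)
  m <- matrix(0, n, n, dimnames = list(terms, terms))
  for (i in seq_len(n)) {
    for (j in i:n) {
      common <- intersect(clo[[i]], clo[[j]])
      m[i, j] <- m[j, i] <- max(ic$ic[common])
    }
  }
  m
}

#' Best-match-average similarity of two patient phenotype profiles
#'
#' Symmetric between-term-set similarity: each term of one profile is
#' matched to its best-scoring partner in the other profile, the best-match
#' scores are averaged within each direction, and the two directional
#' averages are given equal weight:
#' \deqn{sim(c_1,c_2) = \frac{1}{2|c_1|}\sum_{p\in c_1}\max_{q\in c_2}Sim(p,q)
#'     + \frac{1}{2|c_2|}\sum_{p\in c_2}\max_{q\in c_1}Sim(p,q)}
#' Self-similarity equals the mean information content of the profile's
#' terms.
#'
#' @param c1,c2 non-empty character vectors of term ids (set semantics).
#' @inheritParams term_similarity
#' @param tsim optional precomputed term similarity matrix covering all
#'   terms of both profiles (rows/columns named by term id).
#' @return Non-negative scalar; symmetric in its profile arguments.
#' @export
profile_similarity <- function(c1, c2, g = NULL, ic = NULL, tsim = NULL) {
  c1 <- sort(unique(c1)); c2 <- sort(unique(c2))
  if (!length(c1) || !length(c2)) stop("profiles must be non-empty")
  if (is.null(tsim)) tsim <- term_sim_matrix(union(c1, c2), g, ic)
  block <- tsim[c1, c2, drop = FALSE]
  mean(apply(block, 1, max)) / 2 + mean(apply(block, 2, max)) / 2
}

#' Pairwise patient similarity matrix
#'
#' Computes [profile_similarity()] for every unordered pair of patients and
#' mirrors it into a symmetric matrix. The diagonal holds each patient's
#' self-similarity (mean IC of their terms).
#'
#' @param profiles named list of patient profiles (patient id -> character
#'   vector of term ids); ids must be unique, profiles non-empty.
#' @inheritParams term_similarity
#' @return Symmetric numeric matrix with patient ids as dimnames.
#' @export
similarity_matrix <- function(profiles, g, ic) {
  ids <- names(profiles)
  if (length(profiles) < 2L) stop("need at least two profiles")
  if (is.null(ids) || anyDuplicated(ids)) stop("patient ids must be unique")
  if (any(vapply(profiles, length, 1L) == 0L)) stop("profiles must be non-empty")
  terms <- sort(unique(unlist(profiles, use.names = FALSE)))
  missing <- setdiff(terms, g$terms)
  if (length(missing)) stop("profile term(s) absent from ontology: ",
                            paste(missing, collapse = ", "))
  tsim <- term_sim_matrix(terms, g, ic)
  n <- length(ids)
  sim <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    for (j in i:n) {
      sim[i, j] <- sim[j, i] <-
        profile_similarity(profiles[[i]], profiles[[j]], tsim = tsim)
    }
  }
  sim
}

#' Distance matrix from a similarity matrix
#'
#' Applies the transform `dist = max(sim) - sim`, taking the global maximum
#' over the whole matrix (diagonal included; self-similarities are typically
#' maximal, so the offset is usually a diagonal mean-IC value). The diagonal
#' is then zeroed: agglomerative linkage consumes only off-diagonal
#' dissimilarities, so this cannot change the dendrogram, and it restores
#' the dist convention `d(x, x) = 0`.
#'
#' @param sim symmetric numeric similarity matrix.
#' @return Symmetric non-negative matrix with zero diagonal; attribute
#'   `offset` records the global maximum used.
#' @export
to_distance <- function(sim) {
  m <- max(sim)
  d <- m - sim
  diag(d) <- 0
  attr(d, "offset") <- m
  d
}

#' Read a long-format patient-profile TSV
#'
#' Expects a header row and two columns, `patient_id` and `term_id`, one row
#' per (patient, term) annotation.
#'
#' @param path TSV file path.
#' @return Named list of deduplicated term-id vectors, one per patient, in
#'   the order patients first appear.
#' @export
read_profiles_tsv <- function(path) {
  df <- read.delim(path, colClasses = "character")
  stopifnot(all(c("patient_id", "term_id") %in% names(df)))
  split_ids <- split(df$term_id, factor(df$patient_id, levels = unique(df$patient_id)))
  lapply(split_ids, unique)
}

#' Write patient profiles as a long-format TSV
#' @param profiles named list of term-id vectors.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_profiles_tsv <- function(profiles, path) {
  df <- data.frame(
    patient_id = rep(names(profiles), lengths(profiles)),
    term_id = unlist(profiles, use.names = FALSE)
  )
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a named square matrix (similarity or distance) as TSV
#' @param m matrix with patient ids as dimnames.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(m, path) {
  df <- data.frame(patient_id = rownames(m), m, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
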