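#' Parse an OBO flat file into an ontology graph
#'
#' Reads OBO 1.2/1.4 `[Term]` stanzas (fields `id`, `name`, `is_a`,
#' `is_obsolete`) and returns a rooted directed acyclic graph of is-a
#' relations. Obsolete terms are dropped. The graph is validated on load:
#' every `is_a` target must be a known non-obsolete term, the edge set must
#' be acyclic, and there must be a single root from which every term is
#' reachable via parent links.
#'
#' @param path path to an OBO flat file.
#' @return An object of class `ontology_graph`: a list with elements
#'   `terms` (character vector of term ids), `name` (named character vector
#'   of term labels), `parents` (named list, child -> character vector of
#'   parent ids), `children` (the reverse map) and `root` (the root id).
#' @seealso [ancestor_closure()], [restrict_to_subontology()]
#' @export
parse_obo <- function(path) {
  lines <- readLines(path, warn = FALSE)
  # stanza boundaries: lines equal to "[Term]" start a term, any other
  # "[...]" header (e.g. [Typedef]) ends the scope of the previous term
  header <- grepl("^\\[", lines)
  in_term <- FALSE
  cur <- NULL
  stanzas <- list()
  flush <- function(cur, stanzas) {
    if (!is.null(cur)) stanzas[[length(stanzas) + 1L]] <- cur
    stanzas
  }
  for (ln in lines) {
    if (grepl("^\\[", ln)) {
      stanzas <- flush(cur, stanzas)
      cur <- if (identical(ln, "[Term]")) character(0) else NULL
      next
    }
    if (!is.null(cur) && nzchar(trimws(ln))) cur <- c(cur, ln)
  }
  stanzas <- flush(cur, stanzas)

  get_field <- function(stanza, key) {
    pat <- paste0("^", key, ":\\s*")
    vals <- stanza[grepl(pat, stanza)]
    vals <- sub(pat, "", vals)
    sub("\\s*!.*$", "", vals)           # strip trailing OBO comments
  }

  ids <- character(0); names_ <- character(0); parents <- list()
  for (st in stanzas) {
    id <- trimws(get_field(st, "id"))[1]
    if (is.na(id) || !nzchar(id)) next
    obs <- tolower(trimws(get_field(st, "is_obsolete")))
    if (length(obs) && any(obs == "true")) next
    nm <- trimws(get_field(st, "name"))[1]
    isa <- trimws(get_field(st, "is_a"))
    if (id %in% ids) stop("duplicate term id in OBO file: ", id)
    ids <- c(ids, id)
    names_[id] <- if (is.na(nm)) id else nm
    parents[[id]] <- isa
  }
  if (!length(ids)) stop("no [Term] stanzas found in ", path)

  new_ontology_graph(ids, names_, parents)
}

#' @keywords internal
new_ontology_graph <- function(ids, names_, parents) {
  parents <- parents[ids]
  names(parents) <- ids
  parents <- lapply(parents, function(p) if (is.null(p)) character(0) else p)
  unknown <- setdiff(unlist(parents), ids)
  if (length(unknown)) {
    stop("term(s) reference unknown parent(s): ", paste(unknown, collapse = ", "))
  }
  check_acyclic(ids, parents)
  roots <- ids[vapply(parents, length, 1L) == 0L]
  if (length(roots) != 1L) {
    stop("ontology must have exactly one root; found: ",
         paste(roots, collapse = ", "))
  }
  children <- lapply(stats::setNames(ids, ids), function(i) character(0))
  for (ch in ids) for (pa in parents[[ch]]) {
    children[[pa]] <- c(children[[pa]], ch)
  }
  structure(
    list(terms = ids, name = names_[ids], parents = parents,
         children = children, root = roots),
    class = "ontology_graph"
  )
}

# Kahn topological check on child->parent edges; reports one cycle edge.
#' @keywords internal
check_acyclic <- function(ids, parents) {
  indeg <- vapply(parents, length, 1L)   # edges child -> parent
  names(indeg) <- ids
  children <- new.env(parent = emptyenv())
  for (ch in ids) for (pa in parents[[ch]]) {
    assign(pa, c(mget(pa, children, ifnotfound = list(character(0)))[[1]], ch),
           envir = children)
  }
  queue <- ids[indeg == 0L]
  seen <- 0L
  while (length(queue)) {
    v <- queue[[1]]; queue <- queue[-1]; seen <- seen + 1L
    for (ch in mget(v, children, ifnotfound = list(character(0)))[[1]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (seen < length(ids)) {
    bad <- ids[indeg > 0L][1]
    stop("cycle detected in is-a relations involving edge ", bad, " -> ",
         parents[[bad]][1])
  }
  invisible(TRUE)
}

#' @export
print.ontology_graph <- function(x, ...) {
  n_edges <- sum(vapply(x$parents, length, 1L))
  cat("Ontology graph:", length(x$terms), "terms,", n_edges,
      "is-a edges, root", x$root, paste0("(", x$name[[x$root]], ")"), "\n")
  if (!is.null(attr(x, "selected"))) {
    cat("  restricted:", length(attr(x, "selected")), "selected terms\n")
  }
  invisible(x)
}

#' Inclusive ancestor closure of a term
#'
#' Returns the term itself together with every term reachable through is-a
#' parent links, up to and including the root. Closures are inclusive by
#' convention so that a term is its own most informative common ancestor
#' and self-similarity equals the term's information content.
#'
#' @param g an `ontology_graph`.
#' @param term a term id present in `g`.
#' @return Character vector of term ids (unordered set semantics).
#' @export
ancestor_closure <- function(g, term) {
  if (!term %in% g$terms) stop("unknown term: ", term)
  out <- character(0)
  stack <- term
  while (length(stack)) {
    v <- stack[[length(stack)]]; stack <- stack[-length(stack)]
    if (v %in% out) next
    out <- c(out, v)
    stack <- c(stack, g$parents[[v]])
  }
  out
}

# Closures for all terms at once (memoised bottom-up); named list.
#' @keywords internal
all_closures <- function(g) {
  clo <- vector("list", length(g$terms))
  names(clo) <- g$terms
  order <- topo_order(g)               # parents before children
  for (t in order) {
    up <- unique(unlist(clo[g$parents[[t]]], use.names = FALSE))
    clo[[t]] <- c(t, up)
  }
  clo
}

# Topological order with every parent before its children.
#' @keywords internal
topo_order <- function(g) {
  indeg <- vapply(g$parents, length, 1L)
  queue <- g$terms[indeg == 0L]
  out <- character(0)
  while (length(queue)) {
    v <- queue[[1]]; queue <- queue[-1]
    out <- c(out, v)
    for (ch in g$children[[v]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  out
}

#' Restrict an ontology to a subontology plus an allowlist
#'
#' Keeps the inclusive descendants of `subroot` plus any `allowlist` terms
#' (carried over even though they fall outside the subontology, e.g.
#' pulmonary arterial hypertension kept alongside the cardiovascular
#' branch). Ancestors of all kept terms are retained as connective tissue so
#' the result remains a single-rooted DAG; the set of analysis terms is
#' recorded in the `selected` attribute.
#'
#' @param g an `ontology_graph`.
#' @param subroot term id whose descendants define the subontology.
#' @param allowlist character vector of extra term ids to keep; ids missing
#'   from `g` are skipped with a warning.
#' @return An `ontology_graph` restricted to the kept terms, with attribute
#'   `selected` naming the analysis terms (descendants of `subroot` plus the
#'   retained allowlist terms).
#' @export
restrict_to_subontology <- function(g, subroot, allowlist = character(0)) {
  if (!subroot %in% g$terms) stop("unknown subontology root: ", subroot)
  missing <- setdiff(allowlist, g$terms)
  if (length(missing)) {
    warning("allowlist term(s) absent from ontology, skipped: ",
            paste(missing, collapse = ", "))
    allowlist <- setdiff(allowlist, missing)
  }
  desc <- descendant_set(g, subroot)
  selected <- union(desc, allowlist)
  keep <- unique(unlist(lapply(selected, function(t) ancestor_closure(g, t))))
  ids <- g$terms[g$terms %in% keep]
  parents <- lapply(g$parents[ids], function(p) p[p %in% keep])
  out <- new_ontology_graph(ids, g$name[ids], parents)
  attr(out, "selected") <- selected
  out
}

# Inclusive descendant set of a term.
#' @keywords internal
descendant_set <- function(g, term) {
  out <- character(0)
  stack <- term
  while (length(stack)) {
    v <- stack[[length(stack)]]; stack <- stack[-length(stack)]
    if (v %in% out) next
    out <- c(out, v)
    stack <- c(stack, g$children[[v]])
  }
  out
}

#' Propagate annotation counts up the ontology
#'
#' Converts raw per-term annotation counts into closed counts: each term's
#' propagated count is the total of raw counts over its inclusive descendant
#' set, so an annotation reaches every ancestor exactly once regardless of
#' how many parent paths connect them (true-path rule over a DAG). After
#' propagation counts are monotone non-increasing from root to leaves and
#' the root carries the grand total, which makes the information content
#' monotone and the Resnik maximum well-behaved.
#'
#' @param g an `ontology_graph`.
#' @param raw named numeric vector of raw annotation counts (term id ->
#'   count); terms absent from `raw` count as zero, names absent from `g`
#'   are ignored.
#' @return An object of class `anno_freq`: list with `counts` (named vector
#'   over all terms of `g`) and `total`.
#' @export
propagate_counts <- function(g, raw) {
  counts <- stats::setNames(numeric(length(g$terms)), g$terms)
  raw <- raw[names(raw) %in% g$terms]
  clo <- all_closures(g)
  for (t in names(raw)) {
    if (raw[[t]] < 0) stop("negative annotation count for ", t)
    counts[clo[[t]]] <- counts[clo[[t]]] + raw[[t]]
  }
  structure(list(counts = counts, total = sum(raw)), class = "anno_freq")
}

#' Information content from propagated annotation counts
#'
#' Computes term probabilities `p(t) = (count(t) + smoothing) /
#' (total + smoothing)` and the information content `ic(t) = -log p(t)` in
#' nats. The additive pseudo-count keeps zero-frequency terms at a finite
#' maximal IC; the root (count = total) always has `p = 1`, `ic = 0`.
#'
#' @param freq an `anno_freq` from [propagate_counts()].
#' @param smoothing non-negative pseudo-count (default 1).
#' @return An object of class `ic_table`: list with named vectors `p` and
#'   `ic` and the `smoothing` used.
#' @export
information_content <- function(freq, smoothing = 1) {
  stopifnot(inherits(freq, "anno_freq"))
  if (freq$total <= 0) stop("annotation total must be positive")
  if (smoothing < 0) stop("smoothing must be non-negative")
  p <- (freq$counts + smoothing) / (freq$total + smoothing)
  structure(list(p = p, ic = -log(p), smoothing = smoothing),
            class = "ic_table")
}

#' Map free-text diagnosis labels to ontology terms
#'
#' Resolves diagnosis labels through a user-supplied mapping table. Labels
#' without an entry are collected into a rejects report, never silently
#' dropped; duplicate terms per patient are deduplicated (set semantics).
#' Mappings may be flagged `direct` or `superior` (the label was traced to a
#' superior term because no exact ontology concept exists, e.g. a specific
#' rhythm finding recorded as arrhythmia).
#'
#' @param labels character vector of free-text diagnosis labels for one
#'   patient.
#' @param mapping data frame with columns `label`, `term_id`, `kind`
#'   (`"direct"` or `"superior"`).
#' @param g optional `ontology_graph`; if given, mapped terms must exist in
#'   it (an analysis term when the graph is restricted).
#' @return List with `terms` (deduplicated term ids), `rejects` (unmapped
#'   labels) and `empty` (TRUE when nothing mapped).
#' @export
map_diagnoses <- function(labels, mapping, g = NULL) {
  stopifnot(all(c("label", "term_id", "kind") %in% names(mapping)))
  if (!is.null(g)) {
    bad <- setdiff(mapping$term_id, g$terms)
    if (length(bad)) stop("mapping references term(s) absent from ontology: ",
                          paste(bad, collapse = ", "))
  }
  idx <- match(labels, mapping$label)
  rejects <- labels[is.na(idx)]
  terms <- unique(mapping$term_id[idx[!is.na(idx)]])
  list(terms = terms, rejects = rejects, empty = length(terms) == 0L)
}

#' Write an ontology graph to an OBO flat file
#'
#' Serializes the graph as minimal OBO 1.2 `[Term]` stanzas (id, name, is_a)
#' so generated toy ontologies round-trip through [parse_obo()].
#'
#' @param g an `ontology_graph`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_obo <- function(g, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("format-version: 1.2", ""), con)
  for (t in g$terms) {
    isa <- if (length(g$parents[[t]])) paste0("is_a: ", g$parents[[t]])
    writeLines(c("[Term]",
                 paste0("id: ", t),
                 paste0("name: ", g$name[[t]]),
                 isa,
                 ""), con)
  }
  invisible(path)
}
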