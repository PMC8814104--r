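# Independent brute-force oracles and toy fixtures used across the suite.
# Oracles deliberately avoid the package's internal representations: they
# enumerate paths, ancestor sets and agglomeration steps from scratch.

# --- toy OBO fixtures -------------------------------------------------------

obo_text <- function(stanzas) {
  c("format-version: 1.2", "", unlist(lapply(stanzas, function(s) c(s, ""))))
}

write_temp_obo <- function(stanzas) {
  f <- tempfile(fileext = ".obo")
  writeLines(obo_text(stanzas), f)
  f
}

# chain A <- B <- D plus A <- C (the 4-term toy used in several examples)
toy_chain_obo <- function() {
  write_temp_obo(list(
    c("[Term]", "id: T:A", "name: root"),
    c("[Term]", "id: T:B", "name: b", "is_a: T:A ! root"),
    c("[Term]", "id: T:C", "name: c", "is_a: T:A"),
    c("[Term]", "id: T:D", "name: d", "is_a: T:B")
  ))
}

# diamond A <- B, A <- C, B <- D, C <- D
toy_diamond_obo <- function() {
  write_temp_obo(list(
    c("[Term]", "id: T:A", "name: root"),
    c("[Term]", "id: T:B", "name: b", "is_a: T:A"),
    c("[Term]", "id: T:C", "name: c", "is_a: T:A"),
    c("[Term]", "id: T:D", "name: d", "is_a: T:B", "is_a: T:C"),
    c("[Term]", "id: T:E", "name: e", "is_a: T:B")
  ))
}

# random rooted DAG serialized as OBO: term i picks 1-2 parents among 1..i-1
random_dag_obo <- function(n, seed, p_second = 0.3) {
  set.seed(seed)
  ids <- sprintf("R:%03d", seq_len(n))
  stanzas <- list(c("[Term]", paste0("id: ", ids[1]), "name: root"))
  for (i in 2:n) {
    parents <- sample(ids[seq_len(i - 1L)], 1L)
    if (i > 2 && runif(1) < p_second) {
      parents <- c(parents, sample(setdiff(ids[seq_len(i - 1L)], parents), 1L))
    }
    stanzas[[i]] <- c("[Term]", paste0("id: ", ids[i]),
                      paste0("name: term", i), paste0("is_a: ", parents))
  }
  write_temp_obo(stanzas)
}

# --- brute-force ontology oracles ------------------------------------------

# transitive closure by enumerating every parent path
bf_closure <- function(g, term) {
  out <- term
  frontier <- term
  while (length(frontier)) {
    nxt <- unique(unlist(lapply(frontier, function(t) g$parents[[t]])))
    frontier <- setdiff(nxt, out)
    out <- union(out, frontier)
  }
  out
}

bf_descendants <- function(g, term) {
  g$terms[vapply(g$terms, function(t) term %in% bf_closure(g, t), TRUE)]
}

bf_propagate <- function(g, raw) {
  vapply(g$terms, function(t) {
    sum(raw[names(raw) %in% bf_descendants(g, t)])
  }, 1)
}

bf_term_sim <- function(p1, p2, g, ic) {
  max(ic$ic[intersect(bf_closure(g, p1), bf_closure(g, p2))])
}

bf_profile_sim <- function(c1, c2, g, ic) {
  best <- function(p, other) max(vapply(other, function(q)
    bf_term_sim(p, q, g, ic), 1))
  mean(vapply(c1, best, 1, other = c2)) / 2 +
    mean(vapply(c2, best, 1, other = c1)) / 2
}

# --- brute-force complete-linkage oracle -----------------------------------
# exhaustive agglomeration: cluster distances recomputed from the original
# matrix at every step (no Lance-Williams updates), same lexicographic
# tie-break contract as the implementation
bf_complete_linkage <- function(d) {
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  partitions <- list()                 # partition after each merge
  while (length(clusters) > 1L) {
    best <- NULL
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (i >= j) next
      h <- max(d[clusters[[i]], clusters[[j]]])
      key <- c(h, sort(c(min(clusters[[i]]), min(clusters[[j]]))))
      if (is.null(best) || key[1] < best$key[1] - 1e-12 ||
          (abs(key[1] - best$key[1]) <= 1e-12 &&
           (key[2] < best$key[2] ||
            (key[2] == best$key[2] && key[3] < best$key[3])))) {
        best <- list(i = i, j = j, key = key)
      }
    }
    merged <- c(clusters[[best$i]], clusters[[best$j]])
    clusters <- c(clusters[-c(best$i, best$j)], list(merged))
    heights <- c(heights, best$key[1])
    part <- integer(n)
    for (ci in seq_along(clusters)) part[clusters[[ci]]] <- ci
    partitions[[length(partitions) + 1L]] <- part
  }
  list(heights = heights, partitions = partitions)
}

# canonical form of a partition for label-free comparison
canon_partition <- function(labels) {
  match(labels, unique(labels))
}

# --- direct log-rank statistic (observed-minus-expected form) ---------------
bf_logrank_stat <- function(time, event, group) {
  group <- factor(group)
  k <- nlevels(group)
  times <- sort(unique(time[event == 1]))
  O <- E <- numeric(k)
  V <- matrix(0, k, k)
  for (t in times) {
    at_risk <- time >= t
    n <- sum(at_risk)
    d <- sum(event == 1 & time == t)
    ng <- vapply(levels(group), function(g) sum(at_risk & group == g), 1)
    dg <- vapply(levels(group), function(g)
      sum(at_risk & group == g & event == 1 & time == t), 1)
    O <- O + dg
    E <- E + d * ng / n
    if (n > 1) {
      V <- V + (d * (n - d) / (n - 1)) *
        (diag(ng / n, k) - outer(ng / n, ng / n))
    }
  }
  u <- (O - E)[-1]
  drop(t(u) %*% solve(V[-1, -1, drop = FALSE]) %*% u)
}
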