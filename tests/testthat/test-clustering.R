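named_dist <- function(m) {
  dimnames(m) <- list(sprintf("s%02d", seq_len(nrow(m))),
                      sprintf("s%02d", seq_len(nrow(m))))
  m
}

random_dist <- function(n, seed) {
  set.seed(seed)
  x <- matrix(runif(n * 2), n)
  named_dist(as.matrix(dist(x)))
}

test_that("complete linkage handles the elementary cases", {
  d <- named_dist(matrix(c(0, 3, 3, 0), 2))
  dend <- linkage_complete(d)
  expect_equal(dend$height, 3)
  expect_equal(nrow(dend$merge), 1L)

  # two tight pairs far apart merge first
  d4 <- named_dist(as.matrix(dist(c(0, 0.1, 10, 10.2))))
  dend4 <- linkage_complete(d4)
  expect_equal(dend4$height[1:2], c(0.1, 0.2))
  expect_equal(sort(cut_k(dend4, 2)), sort(setNames(c(1L, 1L, 2L, 2L),
                                                    rownames(d4))))

  dna <- d4; dna[1, 2] <- dna[2, 1] <- NA
  expect_error(linkage_complete(dna), "NA")
})

test_that("merge heights are non-decreasing (complete-linkage monotonicity)", {
  for (seed in 1:6) {
    dend <- linkage_complete(random_dist(sample(5:25, 1), seed = seed))
    expect_true(all(diff(dend$height) >= -1e-12))
  }
})

test_that("linkage matches exhaustive agglomeration for small n", {
  for (seed in 1:10) {
    n <- sample(3:6, 1)
    d <- random_dist(n, seed = 500 + seed)
    dend <- linkage_complete(d)
    oracle <- bf_complete_linkage(d)
    expect_equal(dend$height, oracle$heights, tolerance = 1e-10)
    for (k in seq_len(n - 1)) {
      got <- canon_partition(unname(cut_k(dend, k)))
      want <- canon_partition(oracle$partitions[[n - k]])
      expect_equal(got, want)
    }
  }
})

test_that("linkage agrees with stats::hclust on tie-free matrices", {
  for (seed in 1:5) {
    n <- sample(8:40, 1)
    d <- random_dist(n, seed = 600 + seed)   # continuous -> ties absent
    dend <- linkage_complete(d)
    hc <- hclust(as.dist(d), method = "complete")
    expect_equal(dend$height, hc$height, tolerance = 1e-10)
    for (k in c(2, 3, 5)) {
      if (k > n) next
      expect_equal(canon_partition(unname(cut_k(dend, k))),
                   canon_partition(unname(cutree(hc, k)[rownames(d)])))
    }
  }
})

test_that("tie-breaking is deterministic and lexicographic", {
  # four points, all pairwise distances equal: merges must follow
  # smallest-member order regardless of permutation bookkeeping
  d <- named_dist(matrix(1, 4, 4) - diag(4))
  dend <- linkage_complete(d)
  expect_equal(dend$merge[1, ], c(-2L, -1L))   # pair (1,2) first
  # next tie resolves to ({1,2}, 3), so at k = 2 only s04 stands alone
  expect_equal(unname(cut_k(dend, 2)), c(1L, 1L, 1L, 2L))
  expect_equal(dend$height, rep(1, 3))
})

test_that("cut_k covers the degenerate cuts, refines, and is permutation invariant", {
  d <- random_dist(12, seed = 42)
  dend <- linkage_complete(d)
  expect_equal(unname(cut_k(dend, 1)), rep(1L, 12))
  expect_equal(unname(cut_k(dend, 12)), 1:12)
  expect_error(cut_k(dend, 0), "between")
  expect_error(cut_k(dend, 13), "between")

  # k-cut refines the (k-1)-cut
  for (k in 3:6) {
    fine <- cut_k(dend, k)
    coarse <- cut_k(dend, k - 1)
    expect_true(all(vapply(split(coarse, fine),
                           function(x) length(unique(x)) == 1L, TRUE)))
  }

  # shuffling input order yields the same partition up to relabeling
  perm <- sample(12)
  dp <- d[perm, perm]
  la <- cut_k(linkage_complete(d), 3)
  lb <- cut_k(linkage_complete(dp), 3)
  common <- rownames(d)
  # partition equality: same co-membership relation
  same_a <- outer(la[common], la[common], "==")
  same_b <- outer(lb[common], lb[common], "==")
  expect_equal(same_a, same_b)
})

test_that("planted 3-group toy distances are recovered at k = 3", {
  set.seed(7)
  centers <- c(0, 10, 20)
  x <- c(centers[1] + runif(2, 0, 0.5), centers[2] + runif(2, 0, 0.5),
         centers[3] + runif(2, 0, 0.5))
  d <- named_dist(as.matrix(dist(x)))
  labels <- cut_k(linkage_complete(d), 3)
  expect_equal(canon_partition(unname(labels)),
               canon_partition(rep(1:3, each = 2)))
})

test_that("cluster term tests apply the chi-square/Fisher rule and BH", {
  # 40 patients, 2 clusters of 20; term X perfectly separates
  ids <- sprintf("q%02d", 1:40)
  profiles <- setNames(c(replicate(20, c("X"), simplify = FALSE),
                         replicate(20, c("Y"), simplify = FALSE)), ids)
  labels <- setNames(rep(1:2, each = 20), ids)
  res <- cluster_term_tests(profiles, labels)

  # 20/0 vs 0/20: both clusters >= 10 but expected counts are fine;
  # chi-square applies and detects the separation
  rx <- res[res$term == "X", ]
  expect_lt(rx$p, 1e-6)
  expect_equal(rx$n_cluster1, 20)
  expect_equal(rx$n_cluster2, 0)

  # Fisher exact p on the 20,0/0,20 table equals the hypergeometric tail
  small <- setNames(c(replicate(20, "X", simplify = FALSE),
                      replicate(5, "Y", simplify = FALSE)),
                    sprintf("r%02d", 1:25))
  lab2 <- setNames(rep(1:2, c(20, 5)), names(small))
  res2 <- cluster_term_tests(small, lab2)
  expect_true(all(res2$test == "fisher"))   # one cluster has < 10 members
  # oracle: exact enumeration of the 2x2 table (20,0 / 0,5)
  expect_equal(res2$p[res2$term == "X"],
               fisher.test(matrix(c(20, 0, 0, 5), 2))$p.value,
               tolerance = 1e-12)

  # a term carried by everyone is degenerate with p = 1
  allx <- setNames(replicate(30, "X", simplify = FALSE), sprintf("t%02d", 1:30))
  lab3 <- setNames(rep(1:2, each = 15), names(allx))
  res3 <- cluster_term_tests(allx, lab3)
  expect_equal(res3$p, 1)
  expect_equal(res3$test, "degenerate")

  # BH properties on the adjusted column
  expect_true(all(res$p_adj >= res$p - 1e-12))
  expect_equal(res$p_adj, p.adjust(res$p, "BH"))
})

test_that("combination summary counts distinct and unique phenotype sets", {
  ids <- sprintf("u%d", 1:5)
  profiles <- setNames(list(c("A", "B"), c("B", "A"), c("A"), c("C"), c("C")),
                       ids)
  labels <- setNames(rep(1L, 5), ids)
  cs <- combination_summary(profiles, labels)
  row <- cs[cs$cluster == "1", ]
  expect_equal(row$n_combinations, 3L)       # {A,B}, {A}, {C}
  expect_equal(row$n_unique_patients, 1L)    # only {A}
  expect_equal(row$terms_median, 1)
  expect_equal(row$terms_min, 1)
  expect_equal(row$terms_max, 2)

  # all identical -> 1 combination, 0 unique; all distinct -> n and n
  same <- setNames(replicate(4, c("A", "B"), simplify = FALSE),
                   sprintf("v%d", 1:4))
  cs2 <- combination_summary(same, setNames(rep(1L, 4), names(same)))
  expect_equal(cs2$n_combinations[1], 1L)
  expect_equal(cs2$n_unique_patients[1], 0L)

  distinct <- setNames(list("A", "B", "C"), sprintf("w%d", 1:3))
  cs3 <- combination_summary(distinct, setNames(rep(1L, 3), names(distinct)))
  expect_equal(cs3$n_combinations[1], 3L)
  expect_equal(cs3$n_unique_patients[1], 3L)
})

test_that("phenoclust fit recovers planted clusters and reports structure", {
  s <- simulate_study(sim_config(seed = 2, n_patients = 90,
                                 sizes = c(15, 45, 30)))
  fit <- phenoclust(s$profiles, s$graph, freq = s$freq_raw, k = 3)
  expect_s3_class(fit, "phenoclust")
  expect_equal(length(fit$labels), 90L)
  expect_equal(sort(unique(fit$labels)), 1:3)
  skip_if_not_installed("mclust")
  expect_gte(mclust::adjustedRandIndex(fit$labels, s$cluster), 0.8)

  # summary integrates term tests and combination heterogeneity
  sm <- summary(fit)
  expect_s3_class(sm, "summary.phenoclust")
  expect_true(all(sm$term_tests$n_total <= 90))
  expect_equal(sum(sm$combinations$n_patients[sm$combinations$cluster != "overall"]),
               90)

  # recut is consistent with cut_k on the stored dendrogram
  expect_equal(recut(fit, 5), cut_k(fit$dendrogram, 5))
})
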