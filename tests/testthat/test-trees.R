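test_that("taxon distances are Euclidean between aggregated profiles", {
  ab <- rbind(c(0, 0), c(0, 0), c(3, 4), c(3, 4))
  ft <- tiny_table(ab, taxa = c("A", "A", "B", "B"), transformed = TRUE)
  D <- taxon_distance(ft)
  expect_equal(D["A", "B"], 5)
  expect_equal(diag(D), c(A = 0, B = 0))

  ft2 <- tiny_table(rbind(c(1, 2), c(1, 2)), taxa = c("A", "B"), transformed = TRUE)
  expect_equal(taxon_distance(ft2)["A", "B"], 0)

  # brute-force double loop oracle on a random 4-taxon table
  set.seed(14)
  m <- matrix(rnorm(8 * 6), 8, 6)
  taxa <- rep(c("a", "b", "c", "d"), each = 2)
  D2 <- taxon_distance(m, taxa = taxa)
  prof <- rbind(colMeans(m[1:2, ]), colMeans(m[3:4, ]),
                colMeans(m[5:6, ]), colMeans(m[7:8, ]))
  for (i in 1:4) for (j in 1:4) {
    expect_equal(D2[i, j], sqrt(sum((prof[i, ] - prof[j, ])^2)), tolerance = 1e-12)
  }
})

test_that("complete linkage merges {0,1,5} at heights 1 then 5", {
  D <- labelled_dist(matrix(c(0, 1, 5)), c("A", "B", "C"))
  tr <- complete_linkage_tree(D)
  merges <- attr(tr, "merges")
  expect_equal(merges$height, c(1, 5))
  cm <- cophenetic_matrix(tr)
  expect_equal(cm["A", "B"], 1)
  expect_equal(cm["A", "C"], 5)  # complete linkage takes max(4, 5)
  expect_equal(cm["B", "C"], 5)
  expect_true(is_ultrametric_tree(tr))

  D2 <- labelled_dist(matrix(c(0, 3)), c("X", "Y"))
  tr2 <- complete_linkage_tree(D2)
  expect_equal(cophenetic_matrix(tr2)["X", "Y"], 3)

  Dbad <- D; Dbad[1, 2] <- Dbad[2, 1] <- NaN
  expect_error(complete_linkage_tree(Dbad), "finite")
})

test_that("linkage heights are non-decreasing and match hclust on generic data", {
  set.seed(25)
  for (i in 1:5) {
    X <- matrix(rnorm(14), 7, 2)
    D <- labelled_dist(X, letters[1:7])
    tr <- complete_linkage_tree(D)
    expect_true(all(diff(attr(tr, "merges")$height) >= -1e-12))
    expect_true(is_ultrametric_tree(tr))
    cm <- cophenetic_matrix(tr)
    hc <- stats::cophenetic(stats::hclust(as.dist(D), method = "complete"))
    hm <- as.matrix(hc)[rownames(cm), colnames(cm)]
    expect_equal(cm, hm, tolerance = 1e-9, ignore_attr = TRUE)
  }
})

test_that("equal-distance merges break towards the smallest label pair", {
  # perfect square of side 1: pairs (a,b), (a,c), (b,d), (c,d) all at 1
  X <- rbind(a = c(0, 0), b = c(1, 0), c = c(0, 1), d = c(1, 1))
  D <- labelled_dist(X, rownames(X))
  tr <- complete_linkage_tree(D)
  merges <- attr(tr, "merges")
  expect_equal(merges$left[1], "a")
  expect_equal(merges$right[1], "b")
})

test_that("cophenetic conventions: path length for phylograms, merge height for dendrograms", {
  tr <- read_newick(text = "((A:1,B:1):1,C:2);")
  cm <- cophenetic_matrix(tr)
  expect_equal(cm["A", "B"], 2)
  expect_equal(cm["A", "C"], 4)
  expect_equal(cm["B", "C"], 4)

  # star tree with unit branches: all distances 2
  star <- read_newick(text = "(A:1,B:1,C:1,D:1);")
  expect_true(all(cophenetic_matrix(star)[upper.tri(diag(4))] == 2))

  # fixed point: dendrogram of its own cophenetic matrix reproduces it
  set.seed(33)
  D <- labelled_dist(matrix(rnorm(12), 6, 2), letters[1:6])
  tr1 <- complete_linkage_tree(D)
  c1 <- cophenetic_matrix(tr1)
  tr2 <- complete_linkage_tree(c1)
  expect_equal(cophenetic_matrix(tr2), c1, tolerance = 1e-9)
})

test_that("cophenetic matrix from merge history equals a brute-force re-derivation", {
  set.seed(26)
  D <- labelled_dist(matrix(rnorm(12), 6, 2), letters[1:6])
  tr <- complete_linkage_tree(D)
  merges <- attr(tr, "merges")
  # replay the merge history: members named by smallest label
  members <- setNames(as.list(letters[1:6]), letters[1:6])
  oracle <- matrix(NA_real_, 6, 6, dimnames = dimnames(D)); diag(oracle) <- 0
  for (k in seq_len(nrow(merges))) {
    a <- merges$left[k]; b <- merges$right[k]
    for (x in members[[a]]) for (y in members[[b]]) {
      oracle[x, y] <- oracle[y, x] <- merges$height[k]
    }
    members[[a]] <- c(members[[a]], members[[b]])
    members[[b]] <- NULL
  }
  expect_equal(cophenetic_matrix(tr), oracle, tolerance = 1e-9)
})

test_that("Mantel statistic equals brute-force Pearson and is affine invariant", {
  set.seed(44)
  D1 <- labelled_dist(matrix(rnorm(10), 5, 2))
  expect_equal(mantel_test(D1, D1, n_perm = 0)$M, 1)
  D2 <- 2 * D1 + 5; diag(D2) <- 0
  expect_equal(mantel_test(D1, D2, n_perm = 0)$M, 1, tolerance = 1e-12)

  for (i in 1:5) {
    n <- sample(4:8, 1)
    Da <- labelled_dist(matrix(rnorm(2 * n), n, 2))
    Db <- labelled_dist(matrix(rnorm(2 * n), n, 2))
    got <- mantel_test(Da, Db, n_perm = 0)$M
    v1 <- Da[lower.tri(Da)]; v2 <- Db[lower.tri(Db)]
    oracle <- sum((v1 - mean(v1)) * (v2 - mean(v2))) /
      sqrt(sum((v1 - mean(v1))^2) * sum((v2 - mean(v2))^2))
    expect_equal(got, oracle, tolerance = 1e-12)
  }
  expect_error(mantel_test(D1[1:2, 1:2], D1[1:2, 1:2]), "3 labels")
})

test_that("Mantel agrees with vegan and respects label reordering", {
  skip_if_not_installed("vegan")
  set.seed(45)
  Da <- labelled_dist(matrix(rnorm(12), 6, 2))
  Db <- labelled_dist(matrix(rnorm(12), 6, 2))
  got <- mantel_test(Da, Db, n_perm = 0)$M
  ref <- vegan::mantel(as.dist(Da), as.dist(Db), permutations = 0)$statistic
  expect_equal(got, ref, tolerance = 1e-12)
  # shuffled labels, same underlying assignment
  ord <- sample(6)
  expect_equal(mantel_test(Da[ord, ord], Db, n_perm = 0)$M, got, tolerance = 1e-12)
})

test_that("small-n Mantel p-values are exhaustive over all relabelings", {
  set.seed(46)
  Da <- labelled_dist(matrix(rnorm(8), 4, 2))
  Db <- labelled_dist(matrix(rnorm(8), 4, 2))
  res <- mantel_test(Da, Db, n_perm = 999)
  expect_equal(res$method, "exhaustive")
  expect_equal(res$n_perm_used, 24L)
  v1 <- Da[lower.tri(Da)]
  stats_all <- vapply(perms_oracle(4L), function(pm) {
    Dp <- Db[pm, pm]
    stats::cor(v1, Dp[lower.tri(Dp)])
  }, numeric(1))
  expect_equal(res$p, mean(stats_all >= res$M), tolerance = 1e-12)
})

test_that("cophenetic correlation has its hand-computed values", {
  # ((A,B),C) vs ((A,C),B), merge heights 1 then 2 -> c = -0.5
  ta <- complete_linkage_tree(matrix(c(0, 1, 2, 1, 0, 2, 2, 2, 0), 3,
                                     dimnames = list(c("A", "B", "C"), c("A", "B", "C"))))
  tb <- complete_linkage_tree(matrix(c(0, 2, 1, 2, 0, 2, 1, 2, 0), 3,
                                     dimnames = list(c("A", "B", "C"), c("A", "B", "C"))))
  expect_equal(cophenetic_correlation(ta, tb), -0.5, tolerance = 1e-12)
  expect_equal(cophenetic_correlation(ta, ta), 1)

  # doubling branch lengths leaves c = 1 (affine invariance)
  tb2 <- ta
  tb2$phylo$edge.length <- tb2$phylo$edge.length * 2
  expect_equal(cophenetic_correlation(ta, tb2), 1, tolerance = 1e-12)

  # star tree: zero-variance cophenetic vector -> NA with a message
  star <- read_newick(text = "(A:1,B:1,C:1);")
  expect_message(cc <- cophenetic_correlation(star, ta), "undefined")
  expect_true(is.na(cc))
})

test_that("compare_to_reference is self-congruent and wires the chain together", {
  # taxa placed so their Euclidean distances are ultrametric: d(A,B) = 1,
  # d(A,C) = d(B,C) = 2; the tree built from the table is then an exact
  # representation and comparing the table against it gives M = 1, c = 1
  prof <- rbind(A = c(0, 0), B = c(1, 0), C = c(0.5, sqrt(4 - 0.25)))
  ft <- tiny_table(prof, taxa = rownames(prof), transformed = TRUE)
  self_tree <- complete_linkage_tree(taxon_distance(ft))
  cmp <- compare_to_reference(ft, self_tree, n_perm = 999, seed = 1)
  expect_equal(cmp$report$M, 1, tolerance = 1e-9)
  expect_equal(cmp$report$c, 1, tolerance = 1e-9)
  # exhaustive p over 3! relabelings: identity and the A/B swap tie at M = 1
  expect_equal(cmp$report$mantel_p, 2 / 6, tolerance = 1e-12)

  # against the generating phylogeny: statistics in range, tips shared
  set.seed(51)
  b <- synth_generate(synth_config(seed = 51, n_features = 80, brownian_sd = 1,
                                   replicate_sd = 0.1, n_markers_per_taxon = 0))
  lt <- log_transform(b$feature_table)
  cmp2 <- compare_to_reference(lt, b$true_tree, n_perm = 99, seed = 1)
  expect_true(abs(cmp2$report$M) <= 1)
  expect_true(abs(cmp2$report$c) <= 1)
  expect_equal(cmp2$report$shared_tips, sort(unique(lt$samples$taxon)))
})

test_that("rescaling distances changes neither topology nor M", {
  set.seed(52)
  D <- labelled_dist(matrix(rnorm(10), 5, 2))
  t1 <- complete_linkage_tree(D)
  t2 <- complete_linkage_tree(5 * D)
  expect_equal(ape::dist.topo(ape::unroot(t1$phylo), ape::unroot(t2$phylo))[1], 0)
  ref <- labelled_dist(matrix(rnorm(10), 5, 2))
  expect_equal(mantel_test(5 * D, ref, n_perm = 0)$M,
               mantel_test(D, ref, n_perm = 0)$M, tolerance = 1e-12)
})
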