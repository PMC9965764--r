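#' Euclidean distance matrix between taxon profiles
#'
#' Replicate rows are aggregated per taxon (mean by default), then pairwise
#' Euclidean distances between the aggregated profiles are computed.
#'
#' @param table a [feature_table()] (or any samples x variables matrix given
#'   with a matching `taxa` vector) with >= 2 taxa.
#' @param aggregate `"mean"` or `"median"` across replicates.
#' @param taxa taxon labels per row; defaults to the table's sample
#'   metadata.
#' @return symmetric numeric matrix with taxon labels, zero diagonal.
#' @export
taxon_distance <- function(table, aggregate = c("mean", "median"), taxa = NULL) {
  aggregate <- match.arg(aggregate)
  if (inherits(table, "feature_table")) {
    m <- table$abundance
    taxa <- table$samples$taxon
  } else {
    m <- as.matrix(table)
    chk(!is.null(taxa) && length(taxa) == nrow(m), "taxa must label every row")
  }
  tx <- unique(taxa)
  chk(length(tx) >= 2, "need at least 2 taxa")
  f <- if (aggregate == "mean") colMeans else function(x) apply(x, 2L, stats::median)
  prof <- t(vapply(tx, function(t0) f(m[taxa == t0, , drop = FALSE]),
                   numeric(ncol(m))))
  D <- as.matrix(stats::dist(prof))
  dimnames(D) <- list(tx, tx)
  D
}

#' Complete-linkage dendrogram from a distance matrix
#'
#' Agglomerative clustering with maximum (complete) linkage. Merge heights
#' become node heights, so the cophenetic distance between two tips is the
#' merge height of their lowest common ancestor. Equal-distance merges are
#' broken deterministically towards the lexicographically smallest label
#' pair (each cluster is named by its smallest member label).
#'
#' @param D symmetric distance matrix with labels (or a `dist`).
#' @return an ultrametric [taxon_tree()] of kind `"dendrogram"`, with the
#'   merge history in attribute `"merges"` (data.frame: left, right,
#'   height).
#' @export
complete_linkage_tree <- function(D) {
  if (inherits(D, "dist")) D <- as.matrix(D)
  chk(is.matrix(D) && !is.null(rownames(D)), "D must be a labelled matrix or dist")
  chk(!anyNA(D) && all(is.finite(D)), "distances must be finite (no NaN)")
  chk(nrow(D) >= 2, "need at least 2 labels")
  chk(max(abs(D - t(D))) <= 1e-12 && all(diag(D) == 0), "D must be symmetric with zero diagonal")
  labels <- rownames(D)
  # active clusters: name = smallest member label
  clusters <- stats::setNames(lapply(labels, identity), labels)
  newick <- stats::setNames(as.list(labels), labels)
  height <- stats::setNames(rep(0, length(labels)), labels)
  Dc <- D
  merges <- data.frame(left = character(0), right = character(0), height = numeric(0))
  while (length(clusters) > 1L) {
    nm <- names(clusters)
    # candidate pair: minimal distance, ties -> lexicographically smallest pair
    best <- NULL; best_d <- Inf
    for (i in seq_along(nm)[-length(nm)]) for (j in (i + 1L):length(nm)) {
      a <- min(nm[i], nm[j]); b <- max(nm[i], nm[j])
      d <- Dc[nm[i], nm[j]]
      if (d < best_d - 1e-15 ||
          (abs(d - best_d) <= 1e-15 &&
           (is.null(best) || a < best[1L] || (a == best[1L] && b < best[2L])))) {
        best <- c(a, b); best_d <- d
      }
    }
    a <- best[1L]; b <- best[2L]; h <- Dc[a, b]
    merges <- rbind(merges, data.frame(left = a, right = b, height = h))
    newick[[a]] <- sprintf("(%s:%.15g,%s:%.15g)", newick[[a]], h - height[[a]],
                           newick[[b]], h - height[[b]])
    height[[a]] <- h
    clusters[[a]] <- c(clusters[[a]], clusters[[b]])
    clusters[[b]] <- NULL
    newick[[b]] <- NULL
    keep <- names(clusters)
    Dnew <- Dc[keep, keep, drop = FALSE]
    for (o in setdiff(keep, a)) {
      dmax <- max(D[clusters[[a]], clusters[[o]]])
      Dnew[a, o] <- Dnew[o, a] <- dmax
    }
    Dc <- Dnew
  }
  txt <- paste0(newick[[1L]], ";")
  tree <- taxon_tree(ape::read.tree(text = txt), kind = "dendrogram")
  attr(tree, "merges") <- merges
  tree
}

#' Cophenetic distance matrix of a taxon tree
#'
#' For dendrograms the cophenetic distance of two tips is the merge height
#' of their lowest common ancestor (half the tip-to-tip path length of the
#' ultrametric tree); for phylograms it is the sum of branch lengths along
#' the tip-to-tip path.
#'
#' @param tree a [taxon_tree()] with >= 2 tips and branch lengths.
#' @return symmetric matrix over tip labels.
#' @export
cophenetic_matrix <- function(tree) {
  stopifnot(inherits(tree, "taxon_tree"))
  chk(length(tree$phylo$tip.label) >= 2, "need at least 2 tips")
  chk(!is.null(tree$phylo$edge.length), "branch lengths missing")
  D <- ape::cophenetic.phylo(tree$phylo)
  if (tree$kind == "dendrogram") D <- D / 2
  D[order(rownames(D)), order(colnames(D))]
}

#' Mantel test between two distance matrices
#'
#' The statistic M is the Pearson correlation of the lower-triangle vectors
#' (diagonal excluded) after aligning both matrices by label. Significance
#' is assessed by jointly permuting rows and columns of `D2`: when the
#' number of labels is small enough that all `n!` relabelings fit within
#' `n_perm + 1`, the permutation distribution is enumerated exhaustively
#' and `p = #\{M* >= M\} / n!` (identity included); otherwise `n_perm`
#' random permutations give `p = (1 + #\{M* >= M\}) / (n_perm + 1)`.
#' `n_perm = 0` skips the test (`p = NA`).
#'
#' @param D1,D2 symmetric labelled distance matrices over the same label
#'   set (>= 3 labels).
#' @param n_perm number of permutations (default 999).
#' @param seed RNG seed for random permutations.
#' @return list with `M`, `p`, `n_perm_used` and `method`
#'   (`"exhaustive"`/`"sampled"`/`"none"`).
#' @export
mantel_test <- function(D1, D2, n_perm = 999, seed = 1) {
  D1 <- as.matrix(D1); D2 <- as.matrix(D2)
  chk(!is.null(rownames(D1)) && !is.null(rownames(D2)), "matrices must be labelled")
  chk(setequal(rownames(D1), rownames(D2)), "label sets differ")
  n <- nrow(D1)
  chk(n >= 3, "Mantel needs at least 3 labels")
  lab <- sort(rownames(D1))
  D1 <- D1[lab, lab]; D2 <- D2[lab, lab]
  v1 <- lower_tri_vec(D1)
  M <- stats::cor(v1, lower_tri_vec(D2))
  if (n_perm <= 0) {
    return(list(M = M, p = NA_real_, n_perm_used = 0L, method = "none"))
  }
  if (factorial(n) <= n_perm + 1) {
    perms <- perm_all(n)
    stats_perm <- apply(perms, 1L, function(pm)
      stats::cor(v1, lower_tri_vec(D2[pm, pm])))
    p <- mean(stats_perm >= M - 1e-12)
    list(M = M, p = p, n_perm_used = nrow(perms), method = "exhaustive")
  } else {
    set.seed(seed)
    hits <- 0L
    for (i in seq_len(n_perm)) {
      pm <- sample.int(n)
      if (stats::cor(v1, lower_tri_vec(D2[pm, pm])) >= M - 1e-12) hits <- hits + 1L
    }
    list(M = M, p = (1 + hits) / (n_perm + 1), n_perm_used = as.integer(n_perm),
         method = "sampled")
  }
}

#' Cophenetic correlation between two trees
#'
#' Pearson correlation of the two trees' cophenetic lower-triangle vectors
#' restricted to shared tips (aligned by label), each tree using its own
#' cophenetic convention (see [cophenetic_matrix()]).
#'
#' @param tree1,tree2 [taxon_tree()] objects sharing >= 3 tips.
#' @return correlation c, or `NA` (with a message) when either vector has
#'   zero variance (e.g. a star tree).
#' @export
cophenetic_correlation <- function(tree1, tree2) {
  stopifnot(inherits(tree1, "taxon_tree"), inherits(tree2, "taxon_tree"))
  shared <- sort(intersect(tree1$phylo$tip.label, tree2$phylo$tip.label))
  chk(length(shared) >= 3, "fewer than 3 shared tips")
  d1 <- lower_tri_vec(cophenetic_matrix(tree1)[shared, shared])
  d2 <- lower_tri_vec(cophenetic_matrix(tree2)[shared, shared])
  if (stats::sd(d1) == 0 || stats::sd(d2) == 0) {
    message("cophenetic_correlation: zero-variance cophenetic vector, c undefined")
    return(NA_real_)
  }
  stats::cor(d1, d2)
}

#' Build a chemotaxonomic tree and compare it to a reference phylogeny
#'
#' Chains [taxon_distance()] and [complete_linkage_tree()], then computes
#' the Mantel statistic between the chemical distance matrix and the
#' reference tree's cophenetic distances, and the cophenetic correlation
#' between the two trees.
#'
#' @param table a [feature_table()] (or matrix + `taxa`) whose taxa are all
#'   tips of `reference`.
#' @param reference a [taxon_tree()] (the DNA phylogeny).
#' @param n_perm Mantel permutations (default 999).
#' @param seed RNG seed.
#' @param aggregate replicate aggregation, see [taxon_distance()].
#' @param taxa row labels when `table` is a bare matrix.
#' @return list with `tree` (the chemotaxonomic dendrogram) and `report`
#'   (list: M, mantel_p, c, shared_tips).
#' @export
compare_to_reference <- function(table, reference, n_perm = 999, seed = 1,
                                 aggregate = "mean", taxa = NULL) {
  stopifnot(inherits(reference, "taxon_tree"))
  D <- taxon_distance(table, aggregate = aggregate, taxa = taxa)
  chk(all(rownames(D) %in% reference$phylo$tip.label),
      "table taxa must all be tips of the reference tree")
  chemo <- complete_linkage_tree(D)
  ref_sub <- reference
  if (length(reference$phylo$tip.label) > nrow(D)) {
    ref_sub <- taxon_tree(ape::keep.tip(reference$phylo, rownames(D)),
                          kind = reference$kind)
  }
  refD <- cophenetic_matrix(ref_sub)
  mt <- mantel_test(D, refD, n_perm = n_perm, seed = seed)
  cc <- cophenetic_correlation(chemo, ref_sub)
  list(tree = chemo,
       report = list(M = mt$M, mantel_p = mt$p, c = cc,
                     shared_tips = sort(rownames(D))))
}
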