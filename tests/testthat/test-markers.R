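sep_toy <- function(n_per = 10, seed = 2) {
  # two classes separated on the first coordinate only
  set.seed(seed)
  X <- cbind(sig = rep(c(0, 10), each = n_per) + rnorm(2 * n_per, sd = 0.1),
             n1 = rnorm(2 * n_per))
  list(X = X, y = rep(c("A", "B"), each = n_per))
}

test_that("a linearly separable toy is solved with one component", {
  toy <- sep_toy()
  m <- fit_plsda(toy$X, toy$y, seed = 1)
  expect_equal(m$ncomp, 1L)
  expect_equal(unname(predict(m, toy$X)$class), toy$y)

  # determinism: same data, same seed, same model
  m2 <- fit_plsda(toy$X, toy$y, seed = 1)
  expect_identical(m$W, m2$W)
  expect_identical(m$cv_accuracy, m2$cv_accuracy)

  expect_error(fit_plsda(toy$X[c(1, 11:14), ], toy$y[c(1, 11:14)]), "single sample")
})

test_that("duplicated variables receive identical importances", {
  toy <- sep_toy()
  X <- cbind(toy$X, sig2 = toy$X[, "sig"])
  m <- fit_plsda(X, toy$y, seed = 1)
  imp <- variable_importance(m)
  expect_equal(imp["sig", ], imp["sig2", ], tolerance = 1e-10)
})

test_that("VIP has its closed form and normalization identity", {
  # second variable constant -> scaled to zero -> weights (1, 0) -> VIP (sqrt 2, 0)
  X <- cbind(a = c(1, 2, 3, 10, 11, 12), b = rep(5, 6))
  y <- rep(c("A", "B"), each = 3)
  m <- fit_plsda(X, y, max_components = 1, seed = 1)
  vip <- attr(variable_importance(m), "overall")
  expect_equal(unname(vip), c(sqrt(2), 0), tolerance = 1e-9)

  # sum over variables of VIP^2 equals p, per class column and overall
  set.seed(31)
  for (i in 1:5) {
    Xr <- matrix(rnorm(12 * 20), 12, 20)
    yr <- rep(c("A", "B", "C"), each = 4)
    mr <- fit_plsda(Xr, yr, max_components = 4, seed = i)
    ir <- variable_importance(mr)
    expect_equal(unname(colSums(ir^2)), rep(20, 3), tolerance = 1e-8)
    expect_equal(sum(attr(ir, "overall")^2), 20, tolerance = 1e-8)
  }
})

test_that("component scores are orthogonal", {
  set.seed(41)
  X <- matrix(rnorm(15 * 12), 15, 12)
  y <- rep(c("A", "B", "C"), each = 5)
  m <- fit_plsda(X, y, max_components = 4, seed = 1)
  G <- crossprod(m$T)
  off <- max(abs(G[upper.tri(G)])) / max(diag(G))
  expect_lt(off, 1e-8)
})

test_that("quantile selection takes strict exceedances of the 0.995 quantile", {
  # 1000 distinct importances per class -> exactly 5 selected per class
  set.seed(19)
  imp <- cbind(A = sample(seq_len(1000)) / 7, B = sample(seq_len(1000)) / 3)
  rownames(imp) <- sprintf("v%04d", 1:1000)
  sel <- select_markers(imp, 0.995)
  prov <- attr(sel, "provenance")
  expect_equal(sum(prov$class == "A"), 5L)
  expect_equal(sum(prov$class == "B"), 5L)
  expect_setequal(prov$variable[prov$class == "A"],
                  rownames(imp)[rank(-imp[, "A"]) <= 5])

  # all equal importances -> nothing strictly above the quantile
  flat <- matrix(1, 50, 2, dimnames = list(paste0("v", 1:50), c("A", "B")))
  expect_length(select_markers(flat, 0.995), 0)
})

test_that("selection is invariant to rescaling any variable", {
  toy <- sep_toy(n_per = 5, seed = 23)
  m1 <- fit_plsda(toy$X, toy$y, seed = 2)
  X2 <- toy$X; X2[, "sig"] <- X2[, "sig"] * 1000
  m2 <- fit_plsda(X2, toy$y, seed = 2)
  i1 <- variable_importance(m1); i2 <- variable_importance(m2)
  expect_equal(i1, i2, tolerance = 1e-8)
  expect_equal(select_markers(i1, 0.6), select_markers(i2, 0.6),
               tolerance = 1e-8)
})

test_that("cross-validated evaluation behaves on separable and null data", {
  toy <- sep_toy(n_per = 5, seed = 3)
  m <- fit_plsda(toy$X, toy$y, seed = 1)
  ev <- evaluate_plsda(m, toy$X, toy$y, k_folds = 10, seed = 1)
  expect_equal(ev$accuracy, 1.0)
  expect_equal(ev$auc_macro, 1.0)
  expect_equal(unname(ev$auc_pr_macro), 1.0)
  expect_lte(ev$r2, 1)
  expect_equal(ev$k_used, 10L)

  # permuted labels: accuracy near chance (within 3 binomial SEs)
  set.seed(77)
  Xn <- matrix(rnorm(24 * 10), 24, 10)
  yn <- rep(c("A", "B"), each = 12)
  yperm <- sample(yn)
  mp <- fit_plsda(Xn, yperm, seed = 4)
  evp <- evaluate_plsda(mp, Xn, yperm, k_folds = 10, seed = 4)
  se3 <- 3 * sqrt(0.5 * 0.5 / 24)
  expect_lt(abs(evp$accuracy - 0.5), se3 + 1e-9)
})

test_that("AUC equals the hand-computed Mann-Whitney value", {
  # scores: pos {3, 1.5}, neg {2, 1, 0}; pairs won: 3>2,3>1,3>0,1.5>1,1.5>0 = 5/6
  scores <- c(3, 1.5, 2, 1, 0)
  lab <- c(TRUE, TRUE, FALSE, FALSE, FALSE)
  expect_equal(chemophen:::auc_rank(scores, lab), 5 / 6)
  # tie counts half: pos {2}, neg {2, 0} -> (0.5 + 1)/2
  expect_equal(chemophen:::auc_rank(c(2, 2, 0), c(TRUE, FALSE, FALSE)), 0.75)
  # average precision by hand: order 3,2,1.5,1,0 -> hits at ranks 1,3
  expect_equal(chemophen:::average_precision(scores, lab), (1 + 2 / 3) / 2)
})

test_that("heatmap matrix is z-scored, ordered, and flags degenerate columns", {
  set.seed(55)
  b <- synth_generate(synth_config(seed = 55, n_features = 60,
                                   n_markers_per_taxon = 3, brownian_sd = 0.2))
  lt <- log_transform(b$feature_table)
  y <- lt$samples$taxon
  planted <- unlist(b$planted_markers)
  hm <- heatmap_matrix(lt$abundance, planted, y)
  expect_equal(unname(colMeans(hm)), rep(0, ncol(hm)), tolerance = 1e-9)
  expect_equal(unname(apply(hm, 2, sd)), rep(1, ncol(hm)), tolerance = 1e-9)
  expect_equal(attr(hm, "taxon"), sort(y))

  # a planted marker is overrepresented (positive mean z) in its own taxon
  tx <- names(b$planted_markers)[1]
  f <- b$planted_markers[[tx]][1]
  expect_gt(mean(hm[attr(hm, "taxon") == tx, f]), 0)

  X <- cbind(lt$abundance[, planted], const = rep(1, nrow(lt$abundance)))
  expect_message(hm2 <- heatmap_matrix(X, c(planted, "const"), y), "constant")
  expect_false("const" %in% colnames(hm2))
  expect_error(heatmap_matrix(lt$abundance, character(0), y), "threshold")
})

test_that("selection under marker-dominated conditions returns planted markers", {
  # no Brownian species effects: the planted markers are the only
  # class-discriminating features, and 6 replicates keep chance contrasts of
  # noise features below the marker contrast after autoscaling
  hits <- n_sel <- n_planted <- 0
  for (s in 1:3) {
    b <- synth_generate(synth_config(seed = s, n_features = 200,
                                     n_replicates = 6,
                                     n_markers_per_taxon = 1, brownian_sd = 0,
                                     replicate_sd = 0.3))
    lt <- log_transform(b$feature_table)
    m <- fit_plsda(lt$abundance, lt$samples$taxon, seed = s)
    sel <- select_markers(variable_importance(m), 0.995)
    planted <- unlist(b$planted_markers)
    hits <- hits + length(intersect(sel, planted))
    n_sel <- n_sel + length(sel)
    n_planted <- n_planted + length(planted)
  }
  expect_gte(hits / n_sel, 0.9)      # what is selected is a planted marker
  expect_gte(hits / n_planted, 0.75) # and most planted markers are found
})
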