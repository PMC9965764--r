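px <- function(...) {
  # build a tiny RGB image from a list of (r, g, b) rows on the 0..255 scale
  v <- rbind(...)
  img <- array(0, dim = c(1, nrow(v), 3))
  img[1, , 1] <- v[, 1] / 255; img[1, , 2] <- v[, 2] / 255; img[1, , 3] <- v[, 3] / 255
  img
}

test_that("histograms drop pure black/white and normalize the rest", {
  img <- px(c(0, 0, 0), c(255, 255, 255), c(255, 0, 0), c(255, 0, 0))
  tr <- extract_rgb_histograms(img)
  expect_equal(tr$retained, 2L)
  expect_equal(tr$excluded, 2L)
  expect_equal(tr$hist["red", "bin255"], 1.0)
  expect_equal(tr$hist["green", "bin000"], 1.0)
  expect_equal(tr$hist["blue", "bin000"], 1.0)
  expect_equal(rowSums(tr$hist), c(red = 1, green = 1, blue = 1), tolerance = 1e-9)

  expect_error(extract_rgb_histograms(px(c(0, 0, 0), c(0, 0, 0))), "background")
  # no pure black/white: everything retained
  img2 <- px(c(10, 20, 30), c(200, 100, 50))
  expect_equal(extract_rgb_histograms(img2)$retained, 2L)
})

test_that("histograms are invariant to pixel arrangement", {
  set.seed(61)
  vals <- matrix(sample(1:254, 48, TRUE), 16, 3)
  imgA <- array(vals / 255, dim = c(4, 4, 3))
  perm <- sample(16)
  imgB <- array(vals[perm, ] / 255, dim = c(4, 4, 3))
  # same multiset of pixels in a different arrangement
  imgB <- array(0, dim = c(2, 8, 3))
  for (ch in 1:3) imgB[, , ch] <- matrix(vals[perm, ch] / 255, 2, 8)
  expect_equal(extract_rgb_histograms(imgA)$hist, extract_rgb_histograms(imgB)$hist)
})

test_that("png round trip preserves histograms", {
  b <- synth_generate(synth_config(seed = 63, n_features = 40))
  imgs <- make_reference_images(b, pixels_per_image = 16, seed = 1)
  dir <- withr::local_tempdir()
  write_reference_images(imgs, dir)
  nm <- names(imgs)[1]
  from_file <- extract_rgb_histograms(file.path(dir, paste0(nm, ".png")))
  in_memory <- extract_rgb_histograms(imgs[[nm]])
  expect_equal(from_file$hist, in_memory$hist)
  expect_true(file.exists(file.path(dir, "manifest.tsv")))
})

test_that("dbRDA with Euclidean distance reproduces classical RDA", {
  set.seed(71)
  for (i in 1:5) {
    Y <- matrix(rnorm(20 * 6), 20, 6)
    Z <- matrix(rnorm(20 * 2), 20, 2)
    res <- dbrda_fit(Y, Z)
    Yc <- scale(Y, scale = FALSE); Zc <- scale(Z, scale = FALSE)
    fitted <- qr.fitted(qr(cbind(1, Zc)), Yc)
    rda_frac <- sum(fitted^2) / sum(Yc^2)
    expect_equal(res$constrained_fraction, rda_frac, tolerance = 1e-8)
    expect_true(all(diff(res$eigenvalues) <= 1e-12))
    expect_equal(res$negative_mass, 0, tolerance = 1e-8)
  }
})

test_that("dbRDA agrees with vegan's implementation", {
  skip_if_not_installed("vegan")
  set.seed(72)
  Y <- matrix(rnorm(15 * 5), 15, 5)
  Z <- matrix(rnorm(15 * 2), 15, 2)
  res <- dbrda_fit(Y, Z)
  v <- vegan::dbrda(dist(Y) ~ Z)
  expect_equal(res$constrained_fraction, v$CCA$tot.chi / v$tot.chi,
               tolerance = 1e-8)
})

test_that("dbRDA null and saturated constraint cases", {
  set.seed(73)
  Y <- matrix(rnorm(12 * 4), 12, 4)
  Yc <- scale(Y, scale = FALSE)
  # constraints orthogonal to the response column space
  Q <- qr.Q(qr(cbind(1, Yc)))
  Zorth <- matrix(rnorm(12 * 2), 12, 2)
  Zorth <- Zorth - Q %*% crossprod(Q, Zorth)
  expect_lt(dbrda_fit(Y, Zorth)$constrained_fraction, 1e-8)
  # n - 1 independent constraints explain everything
  Zfull <- matrix(rnorm(12 * 11), 12, 11)
  expect_equal(dbrda_fit(Y, Zfull)$constrained_fraction, 1, tolerance = 1e-8)
  expect_error(dbrda_fit(matrix(1, 10, 3), matrix(rnorm(10), 10, 1)), "constant")
})

test_that("forward selection finds a perfect predictor and planted signal", {
  set.seed(81)
  Y <- matrix(rnorm(20 * 4), 20, 4)
  pc1 <- prcomp(Y)$x[, 1]
  sel <- forward_select(Y, cbind(pc1 = pc1), n_perm = 99, seed = 1)
  expect_equal(sel, "pc1", ignore_attr = TRUE)
  expect_lte(attr(sel, "path")$p[1], 0.05)

  # one informative candidate among noise: picked first in most runs
  first_ok <- 0
  for (s in 1:10) {
    set.seed(s)
    Yb <- matrix(rnorm(18 * 3), 18, 3)
    cand <- cbind(info = drop(Yb %*% c(1, 1, 1)) + rnorm(18, sd = 0.2),
                  matrix(rnorm(18 * 4), 18, 4,
                         dimnames = list(NULL, paste0("noise", 1:4))))
    sel2 <- forward_select(Yb, cand, n_perm = 49, seed = s)
    if (length(sel2) >= 1 && sel2[1] == "info") first_ok <- first_ok + 1
  }
  expect_gte(first_ok, 9)
})

test_that("envfit goodness of fit matches least squares", {
  set.seed(91)
  S <- matrix(rnorm(20 * 2), 20, 2)
  v1 <- S[, 1]
  expect_equal(envfit_r2(S, v1, n_perm = 49, seed = 1)$r2, 1, tolerance = 1e-9)

  # variable orthogonal to both axes (and the intercept)
  Q <- qr.Q(qr(cbind(1, S)))
  v2 <- rnorm(20); v2 <- v2 - Q %*% crossprod(Q, v2)
  expect_lt(envfit_r2(S, drop(v2), n_perm = 0)$r2, 1e-8)

  # hand-computed 4-sample regression
  S4 <- cbind(c(0, 1, 2, 3), c(0, 0, 1, 1))
  v4 <- c(1, 3, 2, 5)
  fit <- lm(v4 ~ S4)
  r2_hand <- 1 - sum(residuals(fit)^2) / sum((v4 - mean(v4))^2)
  expect_equal(envfit_r2(S4, v4, n_perm = 0)$r2, r2_hand, tolerance = 1e-12)
  expect_error(envfit_r2(S4, rep(2, 4)), "zero-variance")
})

test_that("envfit agrees with vegan::envfit on ordination scores", {
  skip_if_not_installed("vegan")
  set.seed(92)
  S <- prcomp(matrix(rnorm(20 * 5), 20, 5))$x[, 1:2]
  v <- rnorm(20)
  got <- envfit_r2(S, v, n_perm = 0)$r2
  ref <- vegan::envfit(S, data.frame(v = v), permutations = 0)$vectors$r
  expect_equal(got, unname(ref), tolerance = 1e-8)
})
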