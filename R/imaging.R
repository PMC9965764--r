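#' RGB channel histograms of a segmented phenotype image
#'
#' Pixels that are exactly pure black (0,0,0) or pure white (255,255,255 on
#' the 8-bit scale) are segmentation background and are dropped; the
#' remaining pixels are histogrammed per channel into 256 bins and
#' normalized to frequencies.
#'
#' @param image an H x W x 3 numeric array in \[0, 1\] (as returned by
#'   [png::readPNG]), or a path to a PNG/TIFF file.
#' @return list of class `spectral_traits` with `hist` (3 x 256 frequency
#'   matrix, rows red/green/blue), `retained` and `excluded` pixel counts.
#' @export
extract_rgb_histograms <- function(image) {
  if (is.character(image)) {
    chk(file.exists(image), "no such file: ", image)
    image <- if (grepl("\\.tiff?$", image, ignore.case = TRUE)) {
      if (!requireNamespace("tiff", quietly = TRUE)) {
        stop("reading TIFF needs the 'tiff' package", call. = FALSE)
      }
      tiff::readTIFF(image)
    } else {
      png::readPNG(image)
    }
  }
  chk(is.array(image) && length(dim(image)) == 3L && dim(image)[3L] >= 3L,
      "image must be an H x W x 3 array")
  q <- round(image[, , 1:3, drop = FALSE] * 255)
  r <- q[, , 1L]; g <- q[, , 2L]; b <- q[, , 3L]
  black <- r == 0 & g == 0 & b == 0
  white <- r == 255 & g == 255 & b == 255
  keep <- !(black | white)
  if (!any(keep)) stop("image entirely background (pure black/white)", call. = FALSE)
  h <- rbind(red = tabulate(r[keep] + 1L, nbins = 256L),
             green = tabulate(g[keep] + 1L, nbins = 256L),
             blue = tabulate(b[keep] + 1L, nbins = 256L))
  h <- h / sum(keep)
  colnames(h) <- sprintf("bin%03d", 0:255)
  structure(list(hist = h, retained = sum(keep), excluded = sum(!keep)),
            class = "spectral_traits")
}

#' Spectral trait matrix for a set of images
#'
#' Concatenates each image's red, green and blue histogram frequencies into
#' one 768-long trait vector per image.
#'
#' @param images named list of image arrays or file paths.
#' @return images x 768 numeric matrix (columns `red_bin000` ...).
#' @export
spectral_trait_matrix <- function(images) {
  rows <- lapply(images, function(im) {
    h <- if (inherits(im, "spectral_traits")) im else extract_rgb_histograms(im)
    as.vector(t(h$hist))
  })
  out <- do.call(rbind, rows)
  colnames(out) <- paste0(rep(c("red", "green", "blue"), each = 256L),
                          sprintf("_bin%03d", 0:255))
  rownames(out) <- names(images)
  out
}

#' Distance-based redundancy analysis (dbRDA)
#'
#' Computes the sample distance matrix, Gower-double-centers it, extracts
#' principal coordinates (negative eigenvalues are dropped and their
#' relative mass recorded), and regresses the coordinates on the centered
#' constraints. With Euclidean distances the constrained-inertia fraction
#' equals the multivariate least-squares R-squared of classical RDA.
#'
#' @param response samples x traits numeric matrix (or a precomputed
#'   `dist`).
#' @param constraints samples x variables numeric matrix (rank >= 1 after
#'   centering; collinear columns are kept with reduced rank and a
#'   warning).
#' @param distance only `"euclidean"` is implemented.
#' @return list of class `dbrda_result`: `constrained_fraction`,
#'   `eigenvalues` (constrained axes, non-increasing), `total_inertia`,
#'   `site_scores` (first constrained axes), `constraint_scores`
#'   (correlations of constraints with those axes), `negative_mass`
#'   (relative magnitude of dropped negative eigenvalues), `rank`.
#' @export
dbrda_fit <- function(response, constraints, distance = "euclidean") {
  chk(identical(distance, "euclidean"), "only euclidean distances are implemented")
  D <- if (inherits(response, "dist")) as.matrix(response)
       else as.matrix(stats::dist(as.matrix(response)))
  n <- nrow(D)
  chk(n >= 3, "need at least 3 samples")
  Z <- as.matrix(constraints)
  chk(nrow(Z) == n, "constraints must cover the same samples")
  # Gower double-centering of -D^2/2
  A <- -0.5 * D^2
  G <- sweep(sweep(A, 1L, rowMeans(A)), 2L, colMeans(A)) + mean(A)
  eg <- eigen(G, symmetric = TRUE)
  tot_abs <- sum(abs(eg$values))
  if (tot_abs == 0) stop("constant response: no inertia", call. = FALSE)
  pos <- eg$values > 1e-10 * max(abs(eg$values))
  negative_mass <- sum(abs(eg$values[eg$values < 0])) / tot_abs
  chk(any(pos), "constant response: no positive inertia")
  coords <- eg$vectors[, pos, drop = FALSE] %*% diag(sqrt(eg$values[pos]),
                                                     nrow = sum(pos))
  total_inertia <- sum(eg$values[pos])
  Zc <- scale(Z, scale = FALSE)
  qrZ <- qr(Zc)
  if (qrZ$rank < ncol(Zc)) {
    warning(sprintf("constraints are collinear: rank %d < %d columns",
                    qrZ$rank, ncol(Zc)), call. = FALSE)
  }
  fitted <- qr.fitted(qrZ, coords)
  constrained <- sum(fitted^2)
  sv <- svd(fitted)
  eigs <- sv$d^2
  eigs <- eigs[eigs > 1e-12 * max(eigs, 1)]
  k <- min(2L, length(eigs))
  if (k > 0) {
    site <- sv$u[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)], nrow = k)
    dimnames(site) <- list(rownames(D), paste0("dbRDA", seq_len(k)))
    cscore <- suppressWarnings(stats::cor(Zc, site))
    cscore[!is.finite(cscore)] <- 0
  } else {
    # constraints explain nothing: no constrained axes to report
    site <- matrix(numeric(0), n, 0, dimnames = list(rownames(D), NULL))
    cscore <- matrix(numeric(0), ncol(Zc), 0)
  }
  structure(list(constrained_fraction = constrained / total_inertia,
                 eigenvalues = eigs, total_inertia = total_inertia,
                 site_scores = site, constraint_scores = cscore,
                 negative_mass = negative_mass, rank = qrZ$rank),
            class = "dbrda_result")
}

#' @export
print.dbrda_result <- function(x, ...) {
  cat(sprintf("dbRDA: constrained fraction %.3f (%d constrained axes, rank %d)\n",
              x$constrained_fraction, length(x$eigenvalues), x$rank))
  invisible(x)
}

#' Forward selection of dbRDA constraints
#'
#' Greedy selection: at each step the candidate giving the largest increase
#' in constrained inertia is tested by permuting the response rows; it is
#' added if its permutation p-value is at most `alpha`, otherwise selection
#' stops.
#'
#' @param response samples x traits matrix.
#' @param candidates samples x candidate-variables matrix.
#' @param alpha inclusion significance level (default 0.05).
#' @param n_perm permutations per inclusion test (default 199).
#' @param seed RNG seed.
#' @return character vector of selected candidate names (possibly empty),
#'   with a data.frame of the selection path in attribute `"path"`.
#' @export
forward_select <- function(response, candidates, alpha = 0.05, n_perm = 199,
                           seed = 1) {
  R <- as.matrix(response)
  Z <- as.matrix(candidates)
  chk(ncol(Z) >= 1, "need at least one candidate")
  if (is.null(colnames(Z))) colnames(Z) <- paste0("cand", seq_len(ncol(Z)))
  if (any(!nzchar(colnames(Z)))) {
    colnames(Z)[!nzchar(colnames(Z))] <- paste0("cand", which(!nzchar(colnames(Z))))
  }
  chk(!anyDuplicated(colnames(Z)), "candidate names must be unique")
  set.seed(seed)
  selected <- character(0)
  path <- data.frame(variable = character(0), gain = numeric(0), p = numeric(0))
  frac <- function(resp, vars) {
    if (length(vars) == 0L) return(0)
    dbrda_fit(resp, Z2 <- Z[, vars, drop = FALSE])$constrained_fraction
  }
  base_frac <- 0
  remaining <- colnames(Z)
  while (length(remaining) > 0L) {
    gains <- vapply(remaining, function(v)
      suppressWarnings(frac(R, c(selected, v))) - base_frac, numeric(1))
    cand <- remaining[which.max(gains)]
    obs <- gains[[cand]]
    hits <- 0L
    for (i in seq_len(n_perm)) {
      pm <- sample.int(nrow(R))
      g <- suppressWarnings(frac(R[pm, , drop = FALSE], c(selected, cand)) -
                              frac(R[pm, , drop = FALSE], selected))
      if (g >= obs - 1e-12) hits <- hits + 1L
    }
    p <- (1 + hits) / (n_perm + 1)
    if (p <= alpha) {
      selected <- c(selected, cand)
      base_frac <- base_frac + obs
      path <- rbind(path, data.frame(variable = cand, gain = obs, p = p))
      remaining <- setdiff(remaining, cand)
    } else {
      break
    }
  }
  attr(selected, "path") <- path
  selected
}

#' Goodness of fit of a variable on ordination axes (envfit style)
#'
#' R-squared of the least-squares regression of the variable on the first
#' two ordination axis scores, with a permutation p-value (fraction of
#' permutations of the variable reaching at least the observed R-squared).
#'
#' @param site_scores samples x 2 matrix of ordination scores.
#' @param variable per-sample numeric values (non-constant).
#' @param n_perm permutations (default 999).
#' @param seed RNG seed.
#' @return list with `r2` and `p`.
#' @export
envfit_r2 <- function(site_scores, variable, n_perm = 999, seed = 1) {
  S <- as.matrix(site_scores)[, 1:2, drop = FALSE]
  chk(nrow(S) >= 4, "need at least 4 samples")
  chk(length(variable) == nrow(S), "variable length must match samples")
  if (stats::sd(variable) == 0) stop("zero-variance variable", call. = FALSE)
  r2_of <- function(v) {
    fit <- stats::lm.fit(cbind(1, S), v)
    1 - sum(fit$residuals^2) / sum((v - mean(v))^2)
  }
  r2 <- r2_of(variable)
  p <- NA_real_
  if (n_perm > 0) {
    set.seed(seed)
    hits <- 0L
    for (i in seq_len(n_perm)) {
      if (r2_of(sample(variable)) >= r2 - 1e-12) hits <- hits + 1L
    }
    p <- (1 + hits) / (n_perm + 1)
  }
  list(r2 = r2, p = p)
}
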