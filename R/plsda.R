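#' Fit a PLS-DA model (NIPALS PLS2 on one-hot class membership)
#'
#' Columns of `X` are centered and unit-variance scaled (constant columns
#' are centered only and receive zero weight); class labels are one-hot
#' encoded and centered. Components are extracted by the NIPALS recurrence.
#' The number of components is chosen in `1..max_components` by stratified
#' cross-validated accuracy, ties resolved towards fewer components.
#'
#' @param X numeric matrix, samples x variables (finite).
#' @param y class labels (>= 2 classes, each with >= 2 samples).
#' @param max_components upper bound on components; default
#'   `min(ncol(X), nrow(X) - 1, 8)`.
#' @param seed RNG seed for the fold assignment in component selection.
#' @return an object of class `plsda_model` with weights `W`, loadings `P`,
#'   scores `T`, response loadings `Q`, per-component per-class explained
#'   response variance `ssy`, coefficients and training metadata.
#' @export
fit_plsda <- function(X, y, max_components = NULL, seed = 1) {
  X <- as.matrix(X)
  chk(all(is.finite(X)), "X must be finite")
  y <- factor(y)
  chk(nlevels(y) >= 2, "need at least 2 classes")
  cls_n <- table(y)
  if (any(cls_n < 2)) {
    stop("class(es) with a single sample cannot be stratified: ",
         paste(names(cls_n)[cls_n < 2], collapse = ", "), call. = FALSE)
  }
  n <- nrow(X); p <- ncol(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(p))
  if (is.null(max_components)) max_components <- min(p, n - 1L, 8L)
  chk(is_count(max_components, 1), "max_components must be a positive integer")
  max_components <- min(max_components, p, n - 1L)

  # component count by stratified CV accuracy
  k_cv <- min(5L, min(cls_n))
  folds <- stratified_folds(y, k_cv, seed)
  acc <- numeric(max_components)
  for (f in seq_len(k_cv)) {
    tr <- folds != f
    if (length(unique(y[tr])) < nlevels(y)) next
    fit <- pls2_core(X[tr, , drop = FALSE], y[tr],
                     ncomp = min(max_components, sum(tr) - 1L))
    for (a in seq_len(max_components)) {
      aa <- min(a, fit$ncomp)
      pred <- pls2_predict(fit, X[!tr, , drop = FALSE], ncomp = aa)
      acc[a] <- acc[a] + sum(pred$class == as.character(y[!tr]))
    }
  }
  ncomp <- which.max(acc)  # which.max takes the first (fewest) on ties

  fit <- pls2_core(X, y, ncomp = ncomp)
  fit$max_components <- max_components
  fit$cv_accuracy <- acc / n
  fit$folds <- k_cv
  fit$seed <- seed
  class(fit) <- "plsda_model"
  fit
}

one_hot <- function(y) {
  Y <- stats::model.matrix(~ y - 1)
  colnames(Y) <- levels(y)
  Y
}

stratified_folds <- function(y, k, seed) {
  set.seed(seed)
  folds <- integer(length(y))
  for (lev in levels(y)) {
    idx <- which(y == lev)
    idx <- idx[sample.int(length(idx))]
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

# NIPALS PLS2 with X autoscaling and centered one-hot Y
pls2_core <- function(X, y, ncomp, tol = 1e-12, max_iter = 500L) {
  y <- factor(y)
  centers <- colMeans(X)
  sds <- apply(X, 2L, stats::sd)
  scales <- ifelse(sds > 0, sds, 1)
  E <- scale(X, center = centers, scale = scales)
  Y <- one_hot(y)
  y_means <- colMeans(Y)
  F0 <- scale(Y, center = y_means, scale = FALSE)
  n <- nrow(E); p <- ncol(E); K <- ncol(Y)
  W <- matrix(0, p, ncomp); P <- matrix(0, p, ncomp)
  TT <- matrix(0, n, ncomp); Q <- matrix(0, K, ncomp)
  ssy <- matrix(0, ncomp, K, dimnames = list(NULL, colnames(Y)))
  FF <- F0
  a <- 0L
  while (a < ncomp) {
    if (sum(FF^2) < tol || sum(E^2) < tol) break
    a <- a + 1L
    u <- FF[, which.max(colSums(FF^2))]
    t_old <- rep(Inf, n)
    for (it in seq_len(max_iter)) {
      w <- drop(crossprod(E, u))
      nw <- sqrt(sum(w^2))
      if (nw < tol) break
      w <- w / nw
      t_sc <- drop(E %*% w)
      q <- drop(crossprod(FF, t_sc)) / sum(t_sc^2)
      u <- drop(FF %*% q) / sum(q^2)
      if (sum((t_sc - t_old)^2) < tol * sum(t_sc^2)) break
      t_old <- t_sc
    }
    pl <- drop(crossprod(E, t_sc)) / sum(t_sc^2)
    W[, a] <- w; P[, a] <- pl; TT[, a] <- t_sc; Q[, a] <- q
    ssy[a, ] <- sum(t_sc^2) * q^2
    E <- E - tcrossprod(t_sc, pl)
    FF <- FF - tcrossprod(t_sc, q)
  }
  ncomp <- a
  W <- W[, seq_len(ncomp), drop = FALSE]; P <- P[, seq_len(ncomp), drop = FALSE]
  TT <- TT[, seq_len(ncomp), drop = FALSE]; Q <- Q[, seq_len(ncomp), drop = FALSE]
  ssy <- ssy[seq_len(ncomp), , drop = FALSE]
  rownames(W) <- rownames(P) <- colnames(X)
  rownames(Q) <- levels(y)
  B <- W %*% solve(crossprod(P, W), t(Q))
  Xs <- scale(X, center = centers, scale = scales)
  fitted <- Xs %*% B
  fitted <- sweep(fitted, 2L, y_means, "+")
  colnames(fitted) <- levels(y)
  list(ncomp = ncomp, W = W, P = P, T = TT, Q = Q, ssy = ssy, B = B,
       centers = centers, scales = scales, y_means = y_means,
       classes = levels(y), y = y, fitted = fitted, variables = colnames(X))
}

pls2_predict <- function(fit, Xnew, ncomp = fit$ncomp) {
  ncomp <- min(ncomp, fit$ncomp)
  W <- fit$W[, seq_len(ncomp), drop = FALSE]
  P <- fit$P[, seq_len(ncomp), drop = FALSE]
  Q <- fit$Q[, seq_len(ncomp), drop = FALSE]
  B <- W %*% solve(crossprod(P, W), t(Q))
  Xs <- scale(as.matrix(Xnew), center = fit$centers, scale = fit$scales)
  scores <- sweep(Xs %*% B, 2L, fit$y_means, "+")
  colnames(scores) <- fit$classes
  list(scores = scores, class = fit$classes[max.col(scores, ties.method = "first")])
}

#' Predict class membership from a PLS-DA model
#' @param object a [fit_plsda()] model.
#' @param newdata samples x variables matrix (same variables as training).
#' @param ... unused.
#' @return list with `scores` (samples x classes) and `class` labels.
#' @export
predict.plsda_model <- function(object, newdata, ...) {
  pls2_predict(object, newdata)
}

#' @export
print.plsda_model <- function(x, ...) {
  cat(sprintf("plsda_model: %d component(s), %d variables, classes: %s\n",
              x$ncomp, nrow(x$W), paste(x$classes, collapse = ", ")))
  invisible(x)
}

#' Variable importance in projection (VIP)
#'
#' `VIP_j = sqrt(p * sum_a SSY_a * w_ja^2 / sum_a SSY_a)` with normalized
#' component weights `w_a` and `SSY_a` the response variance explained by
#' component a. Columns of the returned matrix use each class's own
#' explained-variance weights; the `"overall"` attribute uses the total.
#' For every column `sum_j VIP_j^2 = p` (the VIP normalization identity).
#'
#' @param model a [fit_plsda()] model.
#' @return variables x classes matrix of VIP scores with attribute
#'   `"overall"` (numeric vector).
#' @export
variable_importance <- function(model) {
  stopifnot(inherits(model, "plsda_model"))
  W2 <- model$W^2  # columns already unit norm
  p <- nrow(W2)
  vip_for <- function(wts) {
    s <- sum(wts)
    if (s <= 0) return(rep(0, p))
    sqrt(p * drop(W2 %*% wts) / s)
  }
  imp <- sapply(seq_along(model$classes), function(k) vip_for(model$ssy[, k]))
  dimnames(imp) <- list(model$variables, model$classes)
  attr(imp, "overall") <- stats::setNames(vip_for(rowSums(model$ssy)),
                                          model$variables)
  imp
}

#' Select marker variables by importance quantile
#'
#' For each class column the empirical `quantile_threshold` quantile
#' (linear interpolation, type 7) of the importances is computed and the
#' variables strictly above it are selected; the result is the union over
#' classes. With `pooled = TRUE` a single quantile over the whole matrix is
#' used instead.
#'
#' @param importance variables x classes matrix (see
#'   [variable_importance()]).
#' @param quantile_threshold quantile in (0, 1), default 0.995.
#' @param pooled use one pooled quantile instead of per-class quantiles.
#' @return character vector of selected variable ids, with attribute
#'   `"provenance"`: data.frame (variable, class, importance, cutoff).
#' @export
select_markers <- function(importance, quantile_threshold = 0.995, pooled = FALSE) {
  chk(is.matrix(importance) && !is.null(rownames(importance)),
      "importance must be a matrix with variable rownames")
  chk(is_prob(quantile_threshold) && quantile_threshold > 0 && quantile_threshold < 1,
      "quantile_threshold must be in (0, 1)")
  prov <- list()
  for (k in colnames(importance)) {
    cut_k <- if (pooled) stats::quantile(importance, quantile_threshold, names = FALSE)
             else stats::quantile(importance[, k], quantile_threshold, names = FALSE)
    hit <- importance[, k] > cut_k
    if (any(hit)) {
      prov[[k]] <- data.frame(variable = rownames(importance)[hit], class = k,
                              importance = importance[hit, k], cutoff = cut_k)
    }
  }
  prov <- if (length(prov)) do.call(rbind, prov) else
    data.frame(variable = character(0), class = character(0),
               importance = numeric(0), cutoff = numeric(0))
  rownames(prov) <- NULL
  out <- unique(prov$variable)
  attr(out, "provenance") <- prov
  out
}

#' Cross-validated evaluation of a PLS-DA model
#'
#' Stratified k-fold cross-validation with
#' `k = min(k_folds, smallest class size * n classes, n samples)` (the
#' clamp makes 10-fold requests feasible on small designs; the k used is
#' returned). Accuracy is pooled over held-out folds; AUC (by the
#' rank/Mann-Whitney identity) and PR-AUC (average precision) are one-vs-
#' rest per class on CV-pooled scores, macro-averaged. R-squared is
#' `1 - SSE/SST` of the one-hot responses against the full model's fitted
#' values.
#'
#' @param model a [fit_plsda()] model.
#' @param X,y the data the model was trained on (same shape).
#' @param k_folds requested folds (default 10).
#' @param seed RNG seed for fold assignment.
#' @return list with `accuracy`, `r2`, `auc` (per class), `auc_macro`,
#'   `auc_pr` (per class), `auc_pr_macro`, `k_used`, `roc` and `pr`
#'   (per-class curve points), `cv_class` (pooled predictions).
#' @export
evaluate_plsda <- function(model, X, y, k_folds = 10, seed = 1) {
  stopifnot(inherits(model, "plsda_model"))
  X <- as.matrix(X)
  y <- factor(y, levels = model$classes)
  chk(!anyNA(y), "y contains labels unknown to the model")
  n <- nrow(X)
  cls_n <- table(y)
  k <- min(k_folds, min(cls_n) * nlevels(y), n)
  chk(k >= 2, "fewer than 2 folds after clamping")
  folds <- stratified_folds(y, k, seed)
  scores <- matrix(NA_real_, n, nlevels(y), dimnames = list(rownames(X), model$classes))
  pred <- character(n)
  for (f in seq_len(k)) {
    tr <- folds != f
    fit <- pls2_core(X[tr, , drop = FALSE], droplevels(y[tr]),
                     ncomp = min(model$ncomp, sum(tr) - 1L))
    pr <- pls2_predict(fit, X[!tr, , drop = FALSE])
    scores[!tr, fit$classes] <- pr$scores
    pred[!tr] <- pr$class
  }
  scores[is.na(scores)] <- -Inf  # classes absent from a training fold score lowest
  accuracy <- mean(pred == as.character(y))

  Y <- one_hot(y)
  sst <- sum(scale(Y, scale = FALSE)^2)
  sse <- sum((Y - model$fitted)^2)
  r2 <- 1 - sse / sst

  auc <- auc_pr <- stats::setNames(numeric(nlevels(y)), model$classes)
  roc <- pr_curves <- list()
  for (kk in model$classes) {
    lab <- y == kk
    auc[kk] <- auc_rank(scores[, kk], lab)
    auc_pr[kk] <- average_precision(scores[, kk], lab)
    roc[[kk]] <- roc_points(scores[, kk], lab)
    pr_curves[[kk]] <- pr_points(scores[, kk], lab)
  }
  list(accuracy = accuracy, r2 = r2,
       auc = auc, auc_macro = mean(auc),
       auc_pr = auc_pr, auc_pr_macro = mean(auc_pr),
       k_used = k, cv_class = pred, cv_scores = scores,
       roc = roc, pr = pr_curves)
}

# AUC via the rank-sum (Mann-Whitney) identity; ties get average ranks
auc_rank <- function(scores, positive) {
  n1 <- sum(positive); n0 <- sum(!positive)
  chk(n1 > 0 && n0 > 0, "AUC needs both positives and negatives")
  r <- rank(scores)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# average precision (step-integrated PR curve), ties broken by stable order
average_precision <- function(scores, positive) {
  ord <- order(scores, decreasing = TRUE)
  pos <- positive[ord]
  prec_at <- cumsum(pos) / seq_along(pos)
  sum(prec_at[pos]) / sum(pos)
}

roc_points <- function(scores, positive) {
  ord <- order(scores, decreasing = TRUE)
  pos <- positive[ord]
  data.frame(fpr = c(0, cumsum(!pos) / sum(!pos)),
             tpr = c(0, cumsum(pos) / sum(pos)))
}

pr_points <- function(scores, positive) {
  ord <- order(scores, decreasing = TRUE)
  pos <- positive[ord]
  data.frame(recall = cumsum(pos) / sum(pos),
             precision = cumsum(pos) / seq_along(pos))
}

#' Z-scored matrix of selected markers for heatmap display
#'
#' Columns are the selected variables z-scored across samples (constant
#' variables are dropped with a message); rows are grouped by taxon in a
#' deterministic (taxon, original order) arrangement, and variables are
#' ordered by descending maximal importance when an importance matrix is
#' supplied.
#'
#' @param X samples x variables matrix.
#' @param selected character vector of selected variable ids (non-empty).
#' @param y taxon labels per sample.
#' @param importance optional variables x classes importance matrix used
#'   for column ordering.
#' @return z-scored matrix with reordered rows/columns; row taxa in
#'   attribute `"taxon"`.
#' @export
heatmap_matrix <- function(X, selected, y, importance = NULL) {
  X <- as.matrix(X)
  if (length(selected) == 0L) {
    stop("no variables selected; lower the quantile threshold", call. = FALSE)
  }
  chk(all(selected %in% colnames(X)), "selected variables missing from X")
  M <- X[, selected, drop = FALSE]
  sds <- apply(M, 2L, stats::sd)
  if (any(sds == 0)) {
    message(sprintf("heatmap_matrix: dropped %d constant variable(s)", sum(sds == 0)))
    M <- M[, sds > 0, drop = FALSE]
    chk(ncol(M) > 0, "all selected variables are constant")
  }
  Z <- scale(M)
  if (!is.null(importance)) {
    key <- apply(importance[colnames(Z), , drop = FALSE], 1L, max)
    Z <- Z[, order(-key), drop = FALSE]
  }
  ord <- order(factor(y), seq_along(y))
  Z <- Z[ord, , drop = FALSE]
  attr(Z, "taxon") <- as.character(y)[ord]
  Z
}
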