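#' Richness of an abundance vector
#'
#' Number of entries called present. With `threshold = NULL` any positive
#' entry counts; otherwise entries `>= threshold` count (the same semantics
#' as [presence_absence()], whose `"threshold"` attribute can be passed
#' here).
#'
#' @param x non-negative numeric vector.
#' @param threshold presence threshold or `NULL` (= strictly positive).
#' @return integer count.
#' @export
richness <- function(x, threshold = NULL) {
  chk(is.numeric(x), "x must be numeric")
  if (is.null(threshold)) sum(x > 0) else sum(x >= threshold)
}

#' Shannon diversity index H' (natural log)
#'
#' `H' = -sum(p_i * log(p_i))` over the positive entries, with
#' `p_i = x_i / sum(x)`.
#'
#' @param x non-negative numeric vector with positive sum.
#' @return H' in nats.
#' @export
shannon <- function(x) {
  chk(is.numeric(x) && all(x >= 0), "x must be non-negative")
  s <- sum(x)
  if (s <= 0) stop("shannon undefined for a zero-sum vector", call. = FALSE)
  p <- x[x > 0] / s
  -sum(p * log(p))
}

#' Pielou's evenness J
#'
#' `J = H' / log(richness)`, in \[0, 1\]. Undefined (returned as `NA` with a
#' message) when fewer than 2 entries are present.
#'
#' @inheritParams richness
#' @return J, or `NA_real_` when richness < 2.
#' @export
pielou <- function(x, threshold = NULL) {
  r <- richness(x, threshold)
  if (r < 2) {
    message("pielou: richness < 2, evenness undefined")
    return(NA_real_)
  }
  shannon(x) / log(r)
}

#' Features unique to one taxon
#'
#' Variables present in the given taxon but in no replicate of any other
#' taxon. "Present" means present (per [presence_absence()]) in at least one
#' replicate (`rule = "any"`), or in every replicate of the taxon
#' (`rule = "all"`).
#'
#' @param table a raw [feature_table()] with at least 2 taxa.
#' @param taxon taxon label.
#' @param presence_fraction see [presence_absence()].
#' @param rule `"any"` (default) or `"all"` replicates of `taxon`.
#' @return character vector of feature ids.
#' @export
unique_variables <- function(table, taxon, presence_fraction = 1e-8,
                             rule = c("any", "all")) {
  stopifnot(inherits(table, "feature_table"))
  rule <- match.arg(rule)
  taxa <- unique(table$samples$taxon)
  chk(length(taxa) >= 2, "need at least 2 taxa")
  chk(taxon %in% taxa, "unknown taxon: ", taxon)
  pres <- presence_absence(table, presence_fraction)
  own <- pres[table$samples$taxon == taxon, , drop = FALSE]
  others <- pres[table$samples$taxon != taxon, , drop = FALSE]
  in_own <- if (rule == "any") colSums(own) > 0 else colSums(own) == nrow(own)
  colnames(pres)[in_own & colSums(others) == 0]
}

#' Per-sample and per-taxon diversity summary
#'
#' @param table a raw [feature_table()].
#' @param presence_fraction see [presence_absence()].
#' @return list with `per_sample` (sample_id, taxon, richness, shannon_H,
#'   pielou_J) and `per_taxon` (taxon, n_unique) data.frames; the presence
#'   threshold used is in attribute `"threshold"`.
#' @export
diversity_table <- function(table, presence_fraction = 1e-8) {
  stopifnot(inherits(table, "feature_table"))
  pres <- presence_absence(table, presence_fraction)
  t0 <- attr(pres, "threshold")
  per_sample <- data.frame(
    sample_id = table$samples$sample_id,
    taxon = table$samples$taxon,
    richness = apply(table$abundance, 1L, richness, threshold = t0),
    shannon_H = apply(table$abundance, 1L, shannon),
    pielou_J = suppressMessages(apply(table$abundance, 1L, pielou, threshold = t0)))
  taxa <- unique(table$samples$taxon)
  per_taxon <- data.frame(
    taxon = taxa,
    n_unique = vapply(taxa, function(tx)
      length(unique_variables(table, tx, presence_fraction)), integer(1)))
  out <- list(per_sample = per_sample, per_taxon = per_taxon)
  attr(out, "threshold") <- t0
  out
}

#' One-way ANOVA with Tukey HSD post hoc
#'
#' Compares a per-sample statistic (e.g. richness or H') among taxa.
#'
#' @param values numeric vector of the per-sample statistic.
#' @param groups group labels, same length as `values`.
#' @param alpha significance level for flagging pairs (default 0.05).
#' @return list with `F`, `p`, `df`, and `tukey` (data.frame: pair, diff,
#'   lwr, upr, p_adj, significant).
#' @export
anova_tukey <- function(values, groups, alpha = 0.05) {
  chk(length(values) == length(groups), "values and groups differ in length")
  g <- factor(groups)
  chk(nlevels(g) >= 2, "need at least 2 groups")
  chk(all(table(g) >= 2), "every group needs at least 2 observations")
  sse <- sum(tapply(values, g, function(v) sum((v - mean(v))^2)))
  if (sse == 0) stop("zero within-group variance everywhere; F undefined", call. = FALSE)
  fit <- stats::aov(values ~ g)
  an <- summary(fit)[[1L]]
  tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$g
  tukey <- data.frame(pair = rownames(tk), diff = tk[, "diff"],
                      lwr = tk[, "lwr"], upr = tk[, "upr"],
                      p_adj = tk[, "p adj"],
                      significant = tk[, "p adj"] < alpha,
                      row.names = NULL)
  list(F = an[["F value"]][1L], p = an[["Pr(>F)"]][1L],
       df = c(between = an[["Df"]][1L], within = an[["Df"]][2L]),
       tukey = tukey)
}
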