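## Alpha diversity and nonparametric grouped tests with FDR control.

#' Per-sample alpha diversity
#'
#' Shannon diversity `H = -sum(p_i * ln p_i)`, Simpson index
#' `1 - sum(p_i^2)`, and Simpson evenness `(1 / sum(p_i^2)) / S` (inverse
#' Simpson scaled by observed richness), computed from relative abundances
#' via vegan. Samples with no observed taxa yield `NA`.
#'
#' @param abund An `abundance_table` or a non-negative taxa x samples
#'   matrix.
#' @param metric One of `"shannon"`, `"simpson"`, `"simpson_evenness"`.
#' @return Named numeric vector, one value per sample.
#' @export
alpha_diversity <- function(abund, metric = c("shannon", "simpson",
                                              "simpson_evenness")) {
  metric <- match.arg(metric)
  x <- if (inherits(abund, "abundance_table")) abund$rel else as.matrix(abund)
  m <- t(x)                               # samples x taxa for vegan
  empty <- rowSums(m) == 0
  out <- rep(NA_real_, nrow(m))
  names(out) <- rownames(m)
  if (all(empty)) return(out)
  mm <- m[!empty, , drop = FALSE]
  out[!empty] <- switch(metric,
    shannon = vegan::diversity(mm, index = "shannon"),
    simpson = vegan::diversity(mm, index = "simpson"),
    simpson_evenness = vegan::diversity(mm, index = "invsimpson") /
      vegan::specnumber(mm))
  out
}

#' Dunn's post-hoc test of pairwise stochastic dominance
#'
#' Rank-based multiple-comparison test following a Kruskal-Wallis test:
#' for groups i, j the statistic is
#' `z = (Rbar_i - Rbar_j) / sqrt((N(N+1)/12 - T) (1/n_i + 1/n_j))` with tie
#' correction `T = sum(t^3 - t) / (12 (N - 1))`; two-sided normal p-values
#' are adjusted with Benjamini-Hochberg.
#'
#' @param values Numeric response.
#' @param groups Group labels (>= 3 groups).
#' @return data.frame with one row per group pair: `comparison`, `z`,
#'   `p_value`, `p_adjusted`.
#' @export
dunn_test <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 3) stop("dunn_test requires at least 3 groups")
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]; groups <- droplevels(groups[ok])
  N <- length(values)
  r <- rank(values)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  rbar <- tapply(r, groups, mean)
  n <- tapply(r, groups, length)
  lev <- levels(groups)
  pairs <- utils::combn(lev, 2)
  z <- apply(pairs, 2, function(pr) {
    (rbar[pr[1]] - rbar[pr[2]]) /
      sqrt((N * (N + 1) / 12 - tie_term) * (1 / n[pr[1]] + 1 / n[pr[2]]))
  })
  p <- 2 * stats::pnorm(-abs(z))
  data.frame(comparison = paste(pairs[1, ], pairs[2, ], sep = " - "),
             z = as.numeric(z), p_value = p,
             p_adjusted = stats::p.adjust(p, "BH"),
             stringsAsFactors = FALSE)
}

#' Spearman correlation over jointly nonzero pairs
#'
#' Correlation convention for sparse abundance data: observations where
#' either member is zero (or missing) are excluded before computing the
#' Spearman rank correlation. Both `r` and `r_squared` are reported.
#'
#' @param x,y Numeric vectors of equal length.
#' @return List with `r`, `r_squared`, `p_value`, `n` (pairs used).
#' @export
spearman_nonzero <- function(x, y) {
  keep <- !is.na(x) & !is.na(y) & x != 0 & y != 0
  if (sum(keep) < 3)
    return(list(r = NA_real_, r_squared = NA_real_, p_value = NA_real_,
                n = sum(keep)))
  ct <- suppressWarnings(stats::cor.test(x[keep], y[keep],
                                         method = "spearman"))
  list(r = unname(ct$estimate), r_squared = unname(ct$estimate)^2,
       p_value = ct$p.value, n = sum(keep))
}

#' Nonparametric grouped tests with FDR control
#'
#' Dispatches the test battery used for grouped comparisons of microbiome
#' measurements; every family of p-values is Benjamini-Hochberg adjusted.
#' Degenerate inputs (too few observations, all ties) yield `NA` results
#' with a flag rather than an error.
#'
#' @param values Numeric response (for `"spearman"`, the first variable).
#' @param groups Group labels (for `"spearman"`, the second numeric
#'   variable).
#' @param method One of `"wilcoxon_paired"`, `"wilcoxon_ranksum"`,
#'   `"kruskal_wallis"`, `"dunn_posthoc"`, `"levene"`, `"spearman"`.
#' @param pair_id Pairing identifier, required for `"wilcoxon_paired"`;
#'   values are matched within `pair_id` across the two group levels.
#' @return data.frame with columns `comparison`, `statistic`, `p_value`,
#'   `p_adjusted`, `method`, `flag`.
#' @export
group_tests <- function(values, groups,
                        method = c("wilcoxon_paired", "wilcoxon_ranksum",
                                   "kruskal_wallis", "dunn_posthoc",
                                   "levene", "spearman"),
                        pair_id = NULL) {
  method <- match.arg(method)
  rec <- function(comparison, statistic, p, flag = "ok")
    data.frame(comparison = comparison, statistic = statistic, p_value = p,
               p_adjusted = stats::p.adjust(p, "BH"), method = method,
               flag = flag, stringsAsFactors = FALSE)
  degenerate <- function(comparison, why)
    rec(comparison, NA_real_, NA_real_, flag = why)

  if (method == "spearman") {
    ct <- spearman_nonzero(values, as.numeric(groups))
    if (is.na(ct$r)) return(degenerate("spearman", "insufficient_nonzero"))
    return(rec("spearman", ct$r, ct$p_value))
  }
  groups <- factor(groups)
  if (method == "wilcoxon_paired") {
    if (is.null(pair_id)) stop("wilcoxon_paired requires pair_id")
    if (nlevels(groups) != 2) stop("wilcoxon_paired requires exactly 2 groups")
    lv <- levels(groups)
    a <- values[groups == lv[1]][match(unique(pair_id),
                                       pair_id[groups == lv[1]])]
    b <- values[groups == lv[2]][match(unique(pair_id),
                                       pair_id[groups == lv[2]])]
    keep <- !is.na(a) & !is.na(b)
    cmp <- paste(lv, collapse = " - ")
    if (sum(keep) < 3) return(degenerate(cmp, "too_few_pairs"))
    if (all(a[keep] == b[keep]))
      return(rec(cmp, 0, 1, flag = "all_ties"))
    wt <- suppressWarnings(stats::wilcox.test(a[keep], b[keep],
                                              paired = TRUE, exact = FALSE))
    return(rec(cmp, unname(wt$statistic), wt$p.value))
  }
  if (method == "wilcoxon_ranksum") {
    if (nlevels(groups) != 2) stop("wilcoxon_ranksum requires exactly 2 groups")
    lv <- levels(groups)
    a <- values[groups == lv[1]]; b <- values[groups == lv[2]]
    cmp <- paste(lv, collapse = " - ")
    if (length(a) < 2 || length(b) < 2) return(degenerate(cmp, "too_few"))
    wt <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE))
    return(rec(cmp, unname(wt$statistic), wt$p.value))
  }
  if (method == "kruskal_wallis") {
    if (nlevels(groups) < 2) stop("kruskal_wallis requires >= 2 groups")
    if (length(unique(values[!is.na(values)])) < 2)
      return(degenerate("kruskal_wallis", "all_ties"))
    kt <- stats::kruskal.test(values, groups)
    return(rec("kruskal_wallis", unname(kt$statistic), kt$p.value))
  }
  if (method == "dunn_posthoc") {
    dt <- dunn_test(values, groups)
    return(data.frame(comparison = dt$comparison, statistic = dt$z,
                      p_value = dt$p_value, p_adjusted = dt$p_adjusted,
                      method = method, flag = "ok",
                      stringsAsFactors = FALSE))
  }
  ## levene (Brown-Forsythe: deviations from group medians)
  if (nlevels(groups) < 2) stop("levene requires >= 2 groups")
  if (length(unique(values[!is.na(values)])) < 2)
    return(degenerate("levene", "all_ties"))
  lt <- car::leveneTest(values ~ groups)
  rec("levene", lt[["F value"]][1], lt[["Pr(>F)"]][1])
}
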