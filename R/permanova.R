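## One-way distance-based PERMANOVA and intra/inter-individual distance
## contrasts.

ss_within <- function(D2, groups_idx, sizes) {
  s <- 0
  for (g in seq_along(groups_idx)) {
    idx <- groups_idx[[g]]
    s <- s + sum(D2[idx, idx]) / (2 * sizes[g])
  }
  s
}

#' One-way PERMANOVA on a distance matrix
#'
#' Distance-based permutational multivariate analysis of variance
#' (Anderson's one-way formulation): with total sum of squares
#' `SS_T = sum(d_ij^2) / n` over all pairs and within-group
#' `SS_W = sum_g sum(d_ij^2 within g) / n_g`, the pseudo-F statistic is
#' `((SS_T - SS_W)/(k - 1)) / (SS_W/(n - k))`. Significance comes from
#' permuting group labels; `p = (1 + #{F* >= F}) / (1 + n_permutations)`,
#' so the smallest attainable p-value is `1/(n_permutations + 1)`.
#'
#' @param d A `dist` object or square symmetric distance matrix.
#' @param labels Group labels, one per sample (>= 2 groups).
#' @param n_permutations Number of label permutations (default 999).
#' @param seed Optional integer seed for the permutation stream.
#' @param factor_name Name recorded in the result.
#' @return An object of class `permanova`: `pseudo_F`, `p_value`,
#'   `df_between`, `df_within`, `ss_between`, `ss_within`,
#'   `n_permutations`, `factor`.
#' @export
permanova <- function(d, labels, n_permutations = 999, seed = NULL,
                      factor_name = deparse(substitute(labels))) {
  D <- as.matrix(d)
  n <- nrow(D)
  labels <- factor(labels)
  if (length(labels) != n) stop("labels must have one entry per sample")
  k <- nlevels(labels)
  if (k < 2) stop("permanova requires at least 2 groups")
  sizes <- as.integer(table(labels))
  if (any(sizes < 2))
    warning("group(s) with fewer than 2 samples: ",
            paste(levels(labels)[sizes < 2], collapse = ", "))
  if (!is.null(seed)) set.seed(seed)
  D2 <- D^2
  sst <- sum(D2) / (2 * n)
  lab_int <- as.integer(labels)
  idx <- split(seq_len(n), lab_int)
  ssw <- ss_within(D2, idx, sizes)
  f_obs <- ((sst - ssw) / (k - 1)) / (ssw / (n - k))
  if (!is.finite(f_obs)) {
    warning("degenerate distance matrix (no within-group variation); ",
            "pseudo-F undefined")
    return(structure(list(pseudo_F = NA_real_, p_value = NA_real_,
                          df_between = k - 1, df_within = n - k,
                          ss_between = sst - ssw, ss_within = ssw,
                          n_permutations = n_permutations,
                          factor = factor_name),
                     class = "permanova"))
  }
  exceed <- 0L
  for (b in seq_len(n_permutations)) {
    perm <- sample.int(n)
    idx_p <- split(perm, lab_int)
    ssw_p <- ss_within(D2, idx_p, sizes)
    f_p <- ((sst - ssw_p) / (k - 1)) / (ssw_p / (n - k))
    if (is.finite(f_p) && f_p >= f_obs) exceed <- exceed + 1L
  }
  structure(list(pseudo_F = f_obs,
                 p_value = (1 + exceed) / (1 + n_permutations),
                 df_between = k - 1, df_within = n - k,
                 ss_between = sst - ssw, ss_within = ssw,
                 n_permutations = n_permutations, factor = factor_name),
            class = "permanova")
}

#' @export
print.permanova <- function(x, ...) {
  cat(sprintf("PERMANOVA on '%s': pseudo-F = %.3f (df %d, %d), p = %.4g (%d permutations)\n",
              x$factor, x$pseudo_F, x$df_between, x$df_within, x$p_value,
              x$n_permutations))
  invisible(x)
}

#' Intra- vs inter-individual distance contrast
#'
#' Splits sample pairs into (i) pairs from the same volunteer and (ii)
#' pairs from the same skin type but different volunteers, and compares the
#' two distance populations with a Wilcoxon rank-sum test (BH/FDR-adjusted
#' p returned alongside the raw p; with a single comparison the two
#' coincide).
#'
#' @param d A `dist` or square distance matrix with sample ids.
#' @param metadata data.frame with one row per sample (matched by
#'   `sample_id` to the distance labels) containing volunteer and skin-type
#'   columns.
#' @param volunteer,skin_type Column names in `metadata`.
#' @return An object of class `distance_contrast`: the two distance
#'   vectors, medians, `statistic`, `p_value`, `p_adjusted`, `flag`
#'   (`"ok"`, `"degenerate"` when all distances are zero, or
#'   `"insufficient"`).
#' @export
distance_contrast <- function(d, metadata, volunteer = "volunteer",
                              skin_type = "skin_type") {
  D <- as.matrix(d)
  ids <- rownames(D)
  i <- match(ids, metadata$sample_id)
  if (anyNA(i)) stop("metadata is missing sample(s): ",
                     paste(ids[is.na(i)], collapse = ", "))
  vol <- metadata[[volunteer]][i]
  st <- metadata[[skin_type]][i]
  ut <- upper.tri(D)
  same_vol <- outer(vol, vol, "==") & ut
  same_type_diff_vol <- outer(st, st, "==") & !outer(vol, vol, "==") & ut
  intra <- D[same_vol]
  inter <- D[same_type_diff_vol]
  if (length(intra) < 2 || length(inter) < 2) {
    return(structure(list(intra = intra, inter = inter,
                          statistic = NA_real_, p_value = NA_real_,
                          p_adjusted = NA_real_, flag = "insufficient"),
                     class = "distance_contrast"))
  }
  if (all(c(intra, inter) == 0)) {
    return(structure(list(intra = intra, inter = inter,
                          statistic = NA_real_, p_value = NA_real_,
                          p_adjusted = NA_real_, flag = "degenerate"),
                     class = "distance_contrast"))
  }
  wt <- stats::wilcox.test(intra, inter, exact = FALSE)
  structure(list(intra = intra, inter = inter,
                 median_intra = stats::median(intra),
                 median_inter = stats::median(inter),
                 statistic = unname(wt$statistic), p_value = wt$p.value,
                 p_adjusted = stats::p.adjust(wt$p.value, "BH"),
                 flag = "ok"),
            class = "distance_contrast")
}

#' @export
print.distance_contrast <- function(x, ...) {
  if (x$flag != "ok") {
    cat("Distance contrast:", x$flag, "\n")
    return(invisible(x))
  }
  cat(sprintf("Distance contrast: intra-individual median %.3f (n=%d) vs inter-individual (same skin type) %.3f (n=%d), Wilcoxon p = %.4g\n",
              x$median_intra, length(x$intra), x$median_inter,
              length(x$inter), x$p_value))
  invisible(x)
}
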