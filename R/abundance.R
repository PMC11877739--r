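## Genome-length normalization, filtering, and fusion of compositional
## metagenomics with flow-cytometry cell densities into absolute abundances.

#' Taxon-by-sample read-count table
#'
#' Container for mapped-read counts with per-taxon genome lengths and
#' per-(taxon, sample) genome-coverage fractions.
#'
#' @param counts Non-negative integer matrix, taxa x samples, with
#'   dimnames.
#' @param genome_length Per-taxon genome length in bp (> 0).
#' @param coverage Optional coverage-fraction matrix in `[0, 1]`, same
#'   shape as `counts`; defaults to 1 everywhere.
#' @param contaminant Optional logical per-taxon contaminant flag.
#' @return An object of class `taxon_count_table`.
#' @export
taxon_count_table <- function(counts, genome_length, coverage = NULL,
                              contaminant = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have taxon rownames and sample colnames")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  if (length(genome_length) != nrow(counts) || any(genome_length <= 0))
    stop("genome_length must be positive, one value per taxon")
  if (is.null(coverage)) coverage <- matrix(1, nrow(counts), ncol(counts),
                                            dimnames = dimnames(counts))
  coverage <- as.matrix(coverage)
  if (!identical(dim(coverage), dim(counts)))
    stop("coverage must match the shape of counts")
  if (any(coverage < 0 | coverage > 1)) stop("coverage must lie in [0, 1]")
  if (is.null(contaminant)) contaminant <- rep(FALSE, nrow(counts))
  structure(list(counts = counts, genome_length = stats::setNames(
    as.numeric(genome_length), rownames(counts)),
    coverage = coverage, contaminant = stats::setNames(
      as.logical(contaminant), rownames(counts))),
    class = "taxon_count_table")
}

#' @export
print.taxon_count_table <- function(x, ...) {
  cat(sprintf("Taxon count table: %d taxa x %d samples, %.3g total reads\n",
              nrow(x$counts), ncol(x$counts), sum(x$counts)))
  invisible(x)
}

#' Genome-length (RPKM) normalization
#'
#' `RPKM = count * 1e9 / (genome_length * total_mapped_counts_in_sample)`:
#' reads per kilobase of genome per million mapped reads. Relative
#' abundances are RPKM values renormalized to sum to 1 per sample, removing
#' both depth and genome-length effects from composition. Samples with zero
#' total counts are dropped with a warning.
#'
#' @param tab A [taxon_count_table()].
#' @return An object of class `abundance_table`: list with matrices `rpkm`
#'   and `rel` (taxa x samples), plus `genome_length`.
#' @export
rpkm_normalize <- function(tab) {
  stopifnot(inherits(tab, "taxon_count_table"))
  totals <- colSums(tab$counts)
  if (any(totals == 0)) {
    warning("dropping sample(s) with zero total counts: ",
            paste(colnames(tab$counts)[totals == 0], collapse = ", "))
    tab$counts <- tab$counts[, totals > 0, drop = FALSE]
    totals <- totals[totals > 0]
  }
  rpkm <- sweep(tab$counts * 1e9 / tab$genome_length, 2, totals, "/")
  rel <- sweep(rpkm, 2, colSums(rpkm), "/")
  structure(list(rpkm = rpkm, rel = rel, genome_length = tab$genome_length),
            class = "abundance_table")
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("Abundance table: %d taxa x %d samples (RPKM + relative)\n",
              nrow(x$rpkm), ncol(x$rpkm)))
  invisible(x)
}

#' Genome-coverage filter
#'
#' A taxon's counts in a sample are kept only when its genome-coverage
#' fraction there is at least `min_coverage` (inclusive boundary); counts
#' below the threshold are zeroed, removing spurious assignments from
#' fragmentary alignments.
#'
#' @param tab A [taxon_count_table()].
#' @param min_coverage Coverage threshold, default 0.60.
#' @return A filtered `taxon_count_table`.
#' @export
coverage_filter <- function(tab, min_coverage = 0.60) {
  stopifnot(inherits(tab, "taxon_count_table"))
  tab$counts[tab$coverage < min_coverage] <- 0L
  tab
}

#' Median-relative-abundance taxon filter
#'
#' Retains taxa whose median relative abundance across the given samples
#' exceeds `min_rel` (default 0.05%), returned in descending order of
#' median relative abundance, matching the convention used for displayed
#' taxon panels.
#'
#' @param abund An `abundance_table`.
#' @param min_rel Threshold on the median relative abundance (strict).
#' @param samples Optional subset of sample ids over which to take medians
#'   (e.g. one skin-type group).
#' @return Character vector of retained taxa, most abundant first.
#' @export
abundance_filter <- function(abund, min_rel = 0.0005, samples = NULL) {
  stopifnot(inherits(abund, "abundance_table"))
  rel <- abund$rel
  if (!is.null(samples)) rel <- rel[, samples, drop = FALSE]
  med <- apply(rel, 1, stats::median)
  keep <- med > min_rel
  names(sort(med[keep], decreasing = TRUE))
}

#' Per-taxon absolute abundance
#'
#' Distributes a sample's flow-cytometry cell density (cells/cm2) over taxa
#' according to their RPKM relative abundances, so per-taxon absolute
#' abundances sum to the sample's density.
#'
#' @param abund An `abundance_table`.
#' @param density Named numeric vector of cell densities (cells/cm2),
#'   names = sample ids; samples missing from either input are skipped with
#'   a warning.
#' @param taxa Optional taxon subset (e.g. from [abundance_filter()]);
#'   relative abundances are renormalized over the subset.
#' @return Matrix of cells/cm2, taxa x samples.
#' @export
absolute_abundance <- function(abund, density, taxa = NULL) {
  stopifnot(inherits(abund, "abundance_table"))
  common <- intersect(colnames(abund$rel), names(density))
  missing <- setdiff(union(colnames(abund$rel), names(density)), common)
  if (length(missing))
    warning("skipping unpaired sample(s): ", paste(missing, collapse = ", "))
  rel <- abund$rel[, common, drop = FALSE]
  if (!is.null(taxa)) {
    rel <- rel[taxa, , drop = FALSE]
    tot <- colSums(rel)
    tot[tot == 0] <- 1
    rel <- sweep(rel, 2, tot, "/")
  }
  sweep(rel, 2, density[common], "*")
}

#' Per-taxon live fraction
#'
#' `100 * live / total` percent, unclamped: medians above 100% occur for
#' taxa whose live signal exceeds the total estimate under measurement
#' noise. Entries with zero total abundance are returned as `NA`.
#'
#' @param abs_raw,abs_pma Absolute abundances (cells/cm2) from the
#'   untreated (total) and PMA-treated (live) members of sample pairs;
#'   vectors or matrices of matching shape.
#' @return Live fraction(s) in percent, same shape as the inputs.
#' @export
taxon_live_fraction <- function(abs_raw, abs_pma) {
  out <- ifelse(abs_raw > 0, 100 * abs_pma / abs_raw, NA_real_)
  attr(out, "undefined") <- sum(!(abs_raw > 0))
  out
}

#' PMA index of compositional shift
#'
#' `pma_index = rel_pma / (rel_pma + rel_raw)`: 0.5 exactly when a taxon's
#' relative abundance is unchanged by relic-DNA depletion; above 0.5 the
#' taxon is underestimated by untreated (total-DNA) sequencing, below 0.5
#' it is overestimated. Defined only when at least one input is positive.
#'
#' @param rel_raw,rel_pma Relative abundances in the untreated and
#'   PMA-treated members of a pair; vectorized.
#' @return Values in `[0, 1]`, `NA` where both inputs are zero.
#' @export
pma_index <- function(rel_raw, rel_pma) {
  ifelse(rel_raw + rel_pma > 0, rel_pma / (rel_pma + rel_raw), NA_real_)
}

#' PMA-index table by body site for the top-abundance taxa
#'
#' Ranks taxa by median RPKM across the untreated samples, keeps the top
#' `top_n`, and computes per site the PMA index of the site-median relative
#' abundances of paired raw and PMA-treated samples.
#'
#' @param abund An `abundance_table` holding both treatments.
#' @param pairs data.frame with columns `raw_sample`, `pma_sample`, `site`.
#' @param top_n Number of top-ranked taxa to report.
#' @return Matrix of PMA indices, taxa x sites.
#' @export
pma_index_table <- function(abund, pairs, top_n = 15) {
  stopifnot(all(c("raw_sample", "pma_sample", "site") %in% names(pairs)))
  med_rpkm <- apply(abund$rpkm[, pairs$raw_sample, drop = FALSE], 1,
                    stats::median)
  top <- names(sort(med_rpkm, decreasing = TRUE))[seq_len(min(top_n,
                                                              length(med_rpkm)))]
  sites <- unique(pairs$site)
  out <- matrix(NA_real_, length(top), length(sites),
                dimnames = list(top, sites))
  for (s in sites) {
    p <- pairs[pairs$site == s, , drop = FALSE]
    mr <- apply(abund$rel[top, p$raw_sample, drop = FALSE], 1, stats::median)
    mp <- apply(abund$rel[top, p$pma_sample, drop = FALSE], 1, stats::median)
    out[, s] <- pma_index(mr, mp)
  }
  out
}

#' Relic-DNA portion of per-taxon absolute abundances
#'
#' `relic = max(total - live, 0)` per taxon, the floored difference between
#' untreated and PMA-treated absolute abundances; also returns the
#' column-renormalized relative composition of the relic compartment for
#' ordination.
#'
#' @param abs_raw,abs_pma Absolute-abundance matrices (taxa x paired
#'   samples, matching columns).
#' @return List with matrices `relic` (cells/cm2) and `rel` (relative
#'   composition; columns with no relic signal are `NA`).
#' @export
relic_portion <- function(abs_raw, abs_pma) {
  stopifnot(identical(dim(abs_raw), dim(abs_pma)))
  relic <- pmax(abs_raw - abs_pma, 0)
  tot <- colSums(relic)
  rel <- sweep(relic, 2, ifelse(tot > 0, tot, NA_real_), "/")
  list(relic = relic, rel = rel)
}

#' Live cells per anatomical structure
#'
#' Divides an areal live-cell density by a structure density (for example
#' sebaceous pores per cm2) and rounds up, giving the minimum average
#' number of live cells per structure.
#'
#' @param live_density Live cells per cm2.
#' @param structures_per_cm2 Structures per cm2 (> 0).
#' @return Integer count of live cells per structure (ceiling).
#' @export
live_cells_per_structure <- function(live_density, structures_per_cm2) {
  if (any(structures_per_cm2 <= 0)) stop("structures_per_cm2 must be > 0")
  ceiling(live_density / structures_per_cm2)
}
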