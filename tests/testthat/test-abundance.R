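test_that("count-table construction validates its inputs", {
  m <- matrix(1:4, 2, dimnames = list(c("A", "B"), c("s1", "s2")))
  expect_s3_class(taxon_count_table(m, c(1e6, 2e6)), "taxon_count_table")
  expect_error(taxon_count_table(m, c(1e6, 0)), "genome_length")
  expect_error(taxon_count_table(m - 2, c(1e6, 2e6)), "non-negative")
  expect_error(taxon_count_table(m, c(1e6, 2e6),
                                 coverage = matrix(2, 2, 2)), "\\[0, 1\\]")
})

test_that("RPKM cancels genome length and sequencing depth", {
  # counts proportional to genome length: equal RPKM, equal shares
  ab <- rpkm_normalize(two_taxon_table(c(100, 300)))
  expect_equal(unname(ab$rpkm[, 1]), c(125, 125))
  expect_equal(unname(ab$rel[, 1]), c(0.5, 0.5))

  # single observed taxon: relative abundance 1 regardless of count
  ab1 <- rpkm_normalize(two_taxon_table(c(7, 0)))
  expect_equal(unname(ab1$rel["A", 1]), 1)

  # uniform count scaling leaves relative abundances unchanged
  m <- matrix(c(5, 80, 15, 40, 9, 1), nrow = 3,
              dimnames = list(c("A", "B", "C"), c("s1", "s2")))
  tab <- taxon_count_table(m, c(2e6, 5e6, 1e6))
  tab10 <- taxon_count_table(m * 10, c(2e6, 5e6, 1e6))
  expect_equal(rpkm_normalize(tab)$rel, rpkm_normalize(tab10)$rel)

  # zero-total samples are dropped with a warning
  m0 <- cbind(m, s3 = c(0, 0, 0))
  expect_warning(ab0 <- rpkm_normalize(taxon_count_table(m0, c(2e6, 5e6, 1e6))),
                 "zero total")
  expect_equal(colnames(ab0$rel), c("s1", "s2"))
})

test_that("coverage filter uses an inclusive 60% boundary", {
  cov <- matrix(c(0.59, 0.60), 2, 1, dimnames = list(c("A", "B"), "s1"))
  tab <- two_taxon_table(c(50, 50), coverage = cov)
  out <- coverage_filter(tab)
  expect_equal(unname(out$counts[, 1]), c(0, 50))
  # full coverage leaves the table unchanged
  tab1 <- two_taxon_table(c(50, 50))
  expect_identical(coverage_filter(tab1)$counts, tab1$counts)
})

test_that("planted low-coverage contaminants are exactly the taxa removed", {
  cfg <- tiny_cfg(seq_depth = 3e6, contamination_fraction = 0.005)
  truth <- simulate_cohort(cfg)
  tab <- simulate_count_table(truth)
  filt <- coverage_filter(tab)
  contam <- names(which(tab$contaminant))
  expect_true(all(filt$counts[contam, ] == 0))
  # the dominant community taxa survive
  expect_true(all(filt$counts["Cutibacterium acnes", ] > 0))
})

test_that("median-abundance filter keeps exactly the planted taxa, ranked", {
  set.seed(42)
  n_hi <- 12; n_lo <- 38
  hi <- matrix(rpois(n_hi * 6, 2000) + 500, n_hi, 6)
  lo <- matrix(rpois(n_lo * 6, 1), n_lo, 6)
  m <- rbind(hi, lo)
  dimnames(m) <- list(paste0("t", seq_len(n_hi + n_lo)), paste0("s", 1:6))
  ab <- rpkm_normalize(taxon_count_table(m, rep(2e6, n_hi + n_lo)))
  keep <- abundance_filter(ab, min_rel = 0.0005)
  expect_setequal(keep, paste0("t", seq_len(n_hi)))
  med <- apply(ab$rel[keep, ], 1, median)
  expect_equal(keep, names(sort(med, decreasing = TRUE)))
  # boundary: a taxon sitting below the threshold everywhere is excluded
  rel_lo <- apply(ab$rel[paste0("t", n_hi + 1:n_lo), ], 1, median)
  expect_true(all(rel_lo <= 0.0005))
})

test_that("absolute abundances distribute the density over taxa", {
  m <- matrix(c(30, 30), 2, 1, dimnames = list(c("A", "B"), "s1"))
  ab <- rpkm_normalize(taxon_count_table(m, c(2e6, 2e6)))
  abs1 <- absolute_abundance(ab, c(s1 = 2000))
  expect_equal(unname(abs1[, "s1"]), c(1000, 1000))
  expect_equal(sum(abs1[, "s1"]), 2000)
  abs0 <- absolute_abundance(ab, c(s1 = 0))
  expect_true(all(abs0 == 0))
  expect_warning(absolute_abundance(ab, c(s2 = 10)), "unpaired")
})

test_that("per-taxon live fractions follow the printed worked examples", {
  expect_equal(taxon_live_fraction(100, 100), 100, ignore_attr = TRUE)
  # dominant-taxon reductions at moist and dry sites exceed 90%
  moist <- taxon_live_fraction(1658, 136)
  dry <- taxon_live_fraction(2903, 90)
  expect_equal(as.numeric(moist), 8.2, tolerance = 0.01)
  expect_gt(100 - moist, 90)
  expect_gt(100 - dry, 90)
  expect_equal(as.numeric(taxon_live_fraction(50, 0)), 0)
  expect_true(is.na(taxon_live_fraction(0, 10)))
})

test_that("PMA index: fixed point, extremes, and symmetry", {
  expect_identical(pma_index(0.3, 0.3), 0.5)
  expect_equal(pma_index(0.1, 0), 0)
  expect_equal(pma_index(0.1, 0.3), 0.75)
  expect_true(is.na(pma_index(0, 0)))
  # symmetry: swapping treatments reflects the index around 0.5
  a <- runif(20); b <- runif(20)
  expect_equal(pma_index(a, b), 1 - pma_index(b, a))
})

test_that("relic portion is the floored difference with a relative table", {
  raw <- matrix(c(100, 50), 2, 1, dimnames = list(c("A", "B"), "u1"))
  pma <- matrix(c(90, 10), 2, 1, dimnames = list(c("A", "B"), "u1"))
  rp <- relic_portion(raw, pma)
  expect_equal(unname(rp$relic[, 1]), c(10, 40))
  expect_equal(unname(rp$rel[, 1]), c(0.2, 0.8))
  rp0 <- relic_portion(pma, raw * 2)     # live exceeds total everywhere
  expect_true(all(rp0$relic == 0))
})

test_that("estimated relic composition matches the planted shared draw", {
  cfg <- sim_config(n_volunteers = 6, seq_depth = 5e5, seed = 21)
  truth <- simulate_cohort(cfg)
  dens <- estimate_cohort_densities(truth)
  dvec <- setNames(dens$cells_per_cm2, dens$sample_id)
  ab <- rpkm_normalize(coverage_filter(simulate_count_table(truth)))
  units <- truth$units$unit_id
  raw_id <- paste0(units, "_raw"); pma_id <- paste0(units, "_pma")
  keep <- intersect(rownames(ab$rel), rownames(truth$live))
  rel_raw <- sweep(ab$rel[keep, raw_id], 2, colSums(ab$rel[keep, raw_id]), "/")
  rel_pma <- sweep(ab$rel[keep, pma_id], 2, colSums(ab$rel[keep, pma_id]), "/")
  abs_raw <- sweep(rel_raw, 2, dvec[raw_id], "*")
  abs_pma <- sweep(rel_pma, 2, dvec[pma_id], "*")
  colnames(abs_raw) <- colnames(abs_pma) <- units
  est_rel <- relic_portion(abs_raw, abs_pma)$rel
  true_rel <- sweep(truth$relic[keep, units], 2,
                    colSums(truth$relic[, units]), "/")
  # median estimated relic share per taxon tracks the planted composition
  est_med <- apply(est_rel, 1, median, na.rm = TRUE)
  true_med <- apply(true_rel, 1, median)
  expect_gt(spearman_nonzero(est_med, true_med)$r, 0.85)
  expect_lt(max(abs(est_med - true_med)), 0.1)
})

test_that("PMA-index table ranks taxa by median RPKM and respects sites", {
  truth <- tiny_truth()
  ab <- rpkm_normalize(simulate_count_table(truth))
  units <- truth$units
  pairs <- data.frame(raw_sample = paste0(units$unit_id, "_raw"),
                      pma_sample = paste0(units$unit_id, "_pma"),
                      site = units$site, stringsAsFactors = FALSE)
  pit <- pma_index_table(ab, pairs, top_n = 5)
  expect_equal(dim(pit), c(5, length(unique(units$site))))
  expect_true(all(pit >= 0 & pit <= 1, na.rm = TRUE))
  expect_equal(rownames(pit)[1], "Cutibacterium acnes")
})

test_that("live cells per structure round up the worked division", {
  expect_equal(live_cells_per_structure(2.5e4, 900), 28)
  expect_error(live_cells_per_structure(100, 0), "> 0")
})
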