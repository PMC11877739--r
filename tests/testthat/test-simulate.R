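test_that("invalid configurations are rejected", {
  expect_error(sim_config(n_volunteers = 1), "2 volunteers")
  expect_error(sim_config(body_sites = default_body_sites()[1, ]),
               "2 body sites")
  expect_error(sim_config(taxa = default_taxa()[0, ]), "at least one taxon")
  expect_error(sim_config(contamination_fraction = 1), "\\[0, 1\\)")
  expect_error(sim_config(doublet_rate = -0.1), "\\[0, 1\\)")
  expect_error(sim_config(seq_depth = 0), "> 0")
  expect_error(sim_config(extract_scale = 0.5), ">= 1")
  bs <- default_body_sites(); bs$live_fraction_mean[1] <- 0
  expect_error(sim_config(body_sites = bs), "\\(0, 1\\]")
})

test_that("cohort simulation is deterministic and conserves densities", {
  cfg <- tiny_cfg()
  t1 <- simulate_cohort(cfg)
  t2 <- simulate_cohort(cfg)
  expect_identical(t1, t2)

  # per-taxon live + relic densities sum to the unit totals
  expect_equal(colSums(t1$live), setNames(t1$units$live_density,
                                          t1$units$unit_id))
  expect_equal(colSums(t1$live + t1$relic),
               setNames(t1$units$total_density, t1$units$unit_id))
  expect_true(all(t1$units$live_density <= t1$units$total_density))
  expect_true(all(t1$live >= 0) && all(t1$relic >= 0))

  # per-sample event/count streams are reproducible and order-independent
  sid <- t1$metadata$sample_id[5]
  e1 <- simulate_events(t1, sid)
  simulate_events(t1, t1$metadata$sample_id[2])  # unrelated draw in between
  expect_identical(e1, simulate_events(t1, sid))
  expect_identical(simulate_counts(t1, sid), simulate_counts(t1, sid))
})

test_that("fully live communities have total equal to live density", {
  bs <- default_body_sites()
  bs$live_fraction_mean <- 1
  truth <- simulate_cohort(tiny_cfg(body_sites = bs))
  expect_equal(truth$units$live_density, truth$units$total_density)
  expect_true(all(truth$relic == 0))
})

test_that("zero volunteer effect removes personalization of live composition", {
  truth <- simulate_cohort(tiny_cfg(volunteer_effect_sd = 0))
  rel <- sweep(truth$live, 2, colSums(truth$live), "/")
  for (site in unique(truth$units$site)) {
    cols <- truth$units$unit_id[truth$units$site == site]
    expect_lt(max(apply(rel[, cols], 1, function(r) diff(range(r)))), 1e-12)
  }
})

test_that("per-site median live fractions track the configured means", {
  truth <- simulate_cohort(sim_config(seed = 7))
  med <- tapply(truth$units$live_fraction, truth$units$site, median)
  cfgm <- setNames(default_body_sites()$live_fraction_mean,
                   default_body_sites()$site)
  expect_true(all(abs(med[names(cfgm)] - cfgm) < 0.1))
})

test_that("noise-free samples place all non-bead events inside the gates", {
  truth <- simulate_cohort(tiny_cfg(event_noise = 0, doublet_rate = 0,
                                    debris_rate = 0, human_rate = 0))
  ev <- simulate_events(truth, truth$metadata$sample_id[1])
  g <- gate_events(ev)
  expect_equal(g$cell_events + g$bead_events, nrow(ev))
})

test_that("a blank sample yields beads and background only", {
  truth <- tiny_truth()
  u <- truth$units$unit_id[1]
  truth$units$total_density[1] <- truth$units$live_density[1] <- 0
  truth$live[, u] <- 0
  truth$relic[, u] <- 0
  ev <- simulate_events(truth, paste0(u, "_raw"))
  g <- gate_events(ev)
  expect_equal(g$cell_events, 0)
  expect_gt(g$bead_events, 0)
})

test_that("reads are allocated proportionally to density times genome length", {
  taxa <- data.frame(taxon = c("A", "B"), genome_length_bp = c(2e6, 4e6),
                     w_sebaceous = 1, w_moist = 1, w_dry = 1,
                     contaminant = FALSE, stringsAsFactors = FALSE)
  cfg <- tiny_cfg(taxa = taxa, volunteer_effect_sd = 0,
                  contamination_fraction = 0, seq_depth = 1e6)
  truth <- simulate_cohort(cfg)
  sc <- simulate_counts(truth, truth$metadata$sample_id[1])
  # equal densities, lengths L and 2L: expected read ratio 1:2
  expect_equal(sc$counts[["B"]] / sc$counts[["A"]], 2, tolerance = 0.02)
  # and RPKM ratio 1:1 after normalization
  tab <- taxon_count_table(cbind(s1 = sc$counts), taxa$genome_length_bp)
  ab <- rpkm_normalize(tab)
  expect_equal(unname(ab$rel["A", 1]), 0.5, tolerance = 0.01)
})

test_that("PMA samples carry no reads for taxa with zero live density", {
  truth <- tiny_truth()
  tx <- rownames(truth$live)[2]
  truth$live[tx, ] <- 0
  sid <- truth$metadata$sample_id[truth$metadata$treatment == "pma"][1]
  sc <- simulate_counts(truth, sid)
  expect_equal(sc$counts[[tx]], 0)
  expect_error(simulate_counts(truth, sid, depth = 0), "depth")
})

test_that("coverage grows monotonically and saturates with allocated reads", {
  truth <- tiny_truth()
  sid <- truth$metadata$sample_id[1]
  lo <- simulate_counts(truth, sid, depth = 1e4)
  hi <- simulate_counts(truth, sid, depth = 1e6)
  expect_true(all(hi$coverage >= lo$coverage - 1e-12))
  expect_true(all(lo$coverage >= 0 & hi$coverage <= 1))
})

test_that("gated cell counts track the expected acquisition counts", {
  # Poisson check over the whole cohort: gated count within 3 SE of the
  # acquisition expectation for at least 95% of samples.
  truth <- tiny_truth()
  cfg <- truth$config
  md <- truth$metadata
  ok <- vapply(seq_len(nrow(md)), function(i) {
    sid <- md$sample_id[i]
    u <- md$unit_id[i]
    dens <- if (md$treatment[i] == "raw")
      sum(truth$live[, u] + truth$relic[, u]) else sum(truth$live[, u])
    lam <- dens * md$area_cm2[i] * cfg$acquisition_fraction / cfg$extract_scale
    g <- gate_events(simulate_events(truth, sid))
    abs(g$cell_events - lam) <= 3 * sqrt(lam) + 1
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})

test_that("cohort files round-trip through plain text", {
  dir <- withr::local_tempdir()
  truth <- simulate_cohort(tiny_cfg(seq_depth = 2e4))
  files <- write_cohort(truth, dir)
  md <- read_metadata(files["metadata"])
  expect_equal(nrow(md), nrow(truth$metadata))
  tab <- read_taxon_counts(files["counts"], files["catalog"],
                           files["coverage"])
  expect_equal(tab$counts[, md$sample_id[3]],
               simulate_counts(truth, md$sample_id[3])$counts)
  expect_equal(sum(tab$contaminant), sum(truth$config$taxa$contaminant))
})
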