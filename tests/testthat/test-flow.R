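test_that("gating separates cells, beads, doublets and large events", {
  ev <- rbind(make_cells(1000), make_beads(300), make_doublets(50),
              make_large(20))
  g <- gate_events(ev, gating_config())
  expect_equal(g$cell_events, 1000)
  expect_equal(g$bead_events, 300)
  expect_equal(g$total_events, 1370)

  # beads only
  g2 <- gate_events(make_beads(42))
  expect_equal(g2$cell_events, 0)
  expect_equal(g2$bead_events, 42)

  # empty table: zero counts with a warning flag
  expect_warning(g3 <- gate_events(make_cells(0)), "empty")
  expect_equal(g3$cell_events, 0)
  expect_equal(g3$flag, "empty")

  # missing channel is a format error
  expect_error(gate_events(make_cells(5)[, -3]), "missing channel")
})

test_that("bead gate must not overlap the DNA-positive cell quadrant", {
  expect_error(gating_config(bead_fl4 = c(100, 400)), "disjoint")
  expect_s3_class(gating_config(fl4_max = 700, bead_fl4 = c(800, 5000)),
                  "gating_config")
})

test_that("widening any gate never decreases the cell count", {
  truth <- tiny_truth()
  ev <- simulate_events(truth, truth$metadata$sample_id[2])
  base <- gating_config()
  n0 <- gate_events(ev, base)$cell_events
  wider <- list(
    gating_config(fl1_min = base$fl1_min / 2),
    gating_config(fl4_max = base$fl4_max * 2, bead_fl4 = c(1100, 5000)),
    gating_config(singlet_tol = base$singlet_tol * 2),
    gating_config(fsc_max = base$fsc_max * 2),
    gating_config(bsc_max = base$bsc_max * 2)
  )
  for (cfg in wider) expect_gte(gate_events(ev, cfg)$cell_events, n0)
})

test_that("duplicating every event doubles counts but not the concentration", {
  ev <- rbind(make_cells(500), make_beads(100))
  g1 <- gate_events(ev)
  g2 <- gate_events(rbind(ev, ev))
  expect_equal(g2$cell_events, 2 * g1$cell_events)
  expect_equal(g2$bead_events, 2 * g1$bead_events)
  expect_equal(bead_concentration(g1$cell_events, g1$bead_events, 1e4, 250),
               bead_concentration(g2$cell_events, g2$bead_events, 1e4, 250))
})

test_that("bead concentration formula and guards", {
  expect_equal(bead_concentration(1000, 500, 10000, 250), 80)
  expect_equal(bead_concentration(0, 500, 10000, 250), 0)
  expect_error(bead_concentration(100, 0, 10000, 250), "no beads detected")
  expect_error(bead_concentration(100, 50, 10000, 0), "run_volume")
})

test_that("areal density conversion", {
  expect_equal(cells_per_cm2(80, 250, 10), 2000)
  expect_equal(cells_per_cm2(0, 250, 10), 0)
  expect_equal(cells_per_cm2(80, 250, 10, extract_scale = 2), 4000)
  expect_error(cells_per_cm2(80, 250, 0), "area")
  expect_error(cells_per_cm2(80, 250, 10, extract_scale = 0.5),
               "extract_scale")
})

test_that("a known concentration is recovered within counting error", {
  cfg <- sim_config()
  conc_true <- 40                         # cells/uL
  area <- 10
  density <- conc_true * cfg$run_volume / area
  ev <- simulate_aliquot_events(density, area, cfg, seed = 3)
  g <- gate_events(ev)
  conc <- bead_concentration(g$cell_events, g$bead_events, cfg$beads_added,
                             cfg$run_volume)
  lam_cells <- conc_true * cfg$run_volume * cfg$acquisition_fraction
  lam_beads <- cfg$beads_added * cfg$acquisition_fraction
  se <- conc_true * sqrt(1 / lam_cells + 1 / lam_beads)
  expect_lt(abs(conc - conc_true), 3 * se)
})

test_that("singlet slope is recoverable from bead events", {
  truth <- tiny_truth()
  ev <- simulate_events(truth, truth$metadata$sample_id[1])
  expect_equal(fit_singlet_slope(ev), 1, tolerance = 0.05)
})

test_that("per-sample live fraction arithmetic", {
  expect_equal(live_fraction_sample(5000, 5000), 100)
  # fraction of the printed forehead medians, not the printed median of
  # per-sample fractions
  expect_equal(live_fraction_sample(33508, 29088), 86.81, tolerance = 1e-4)
  expect_equal(live_fraction_sample(5000, 0), 0)
  expect_gt(live_fraction_sample(100, 150), 100)  # unclamped
  expect_warning(out <- live_fraction_sample(0, 10), "zero raw density")
  expect_true(is.na(out))
})

test_that("cell_density flags instead of failing on bad samples", {
  ev <- make_cells(100)                   # no beads at all
  out <- cell_density(ev, sample_id = "s", treatment = "raw",
                      beads_added = 1e4, run_volume = 250, area = 10)
  expect_equal(out$flag, "no_beads")
  expect_true(is.na(out$cells_per_cm2))

  ev2 <- rbind(make_cells(100), make_beads(50))
  out2 <- cell_density(ev2, sample_id = "s", treatment = "raw",
                       beads_added = 1e4, run_volume = 250, area = 10)
  expect_equal(out2$flag, "ok")
  expect_equal(out2$cells_per_cm2, (100 / 50) * (1e4 / 250) * 250 / 10)
})
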