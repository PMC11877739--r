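## Synthetic cohort generator: ground-truth cell densities, flow-cytometry
## event tables and taxon count tables for paired raw / PMA-treated samples.

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) g[which.max(alpha)] <- 1
  g / sum(g)
}

site_weight_col <- function(skin_type) {
  switch(skin_type,
         sebaceous = "w_sebaceous", moist = "w_moist", dry = "w_dry",
         stop("unknown skin type: ", skin_type))
}

## Deterministic per-sample seed stream, independent of call order.
sample_seed <- function(config, index, stream) {
  (abs(config$seed) * 1009L + stream * 97L + index) %% 2147483646L + 1L
}

#' Simulate a paired raw/PMA cohort with planted ground truth
#'
#' Draws, per volunteer-by-site unit: a total cell density (log10-normal per
#' site), a live fraction (logit-normal around the site mean), a live
#' composition (site base weights perturbed by a volunteer-by-taxon
#' log-normal effect) and a relic composition (Dirichlet; one draw per site
#' shared across volunteers when `relic_shared`). Per-taxon live and relic
#' densities sum exactly to the unit's live and relic totals, and every unit
#' yields two samples: `raw` (live + relic measurable) and `pma`
#' (live only).
#'
#' @param config A [sim_config()] object.
#' @return An object of class `cohort_truth`: list with `metadata` (one row
#'   per sample), `units` (one row per volunteer-site pair, with total/live
#'   densities), `live` and `relic` (taxa x unit density matrices,
#'   cells/cm2), and the `config`.
#' @export
simulate_cohort <- function(config = sim_config()) {
  validate_sim_config(config)
  set.seed(config$seed)
  sites <- config$body_sites
  taxa <- config$taxa
  nt <- nrow(taxa)
  comm <- !taxa$contaminant
  if (!any(comm)) stop("simulate_cohort: all taxa are flagged contaminant")

  vols <- sprintf("V%02d", seq_len(config$n_volunteers))
  sexes <- rep(c("female", "male"), length.out = config$n_volunteers)
  names(sexes) <- vols

  ## volunteer-by-taxon multiplicative signature on live composition
  eff <- matrix(exp(stats::rnorm(config$n_volunteers * nt, 0,
                                 config$volunteer_effect_sd)),
                nrow = config$n_volunteers,
                dimnames = list(vols, taxa$taxon))
  eff[, !comm] <- 0

  ## Relic composition: Dirichlet draws around a site-agnostic base (the
  ## cross-microenvironment mean of the live preference weights), modelling
  ## environmentally deposited, non-personalized dead-cell DNA. One draw per
  ## site shared by all volunteers when relic_shared.
  relic_base <- rowMeans(cbind(taxa$w_sebaceous, taxa$w_moist, taxa$w_dry))
  relic_base[!comm] <- 0
  relic_alpha <- config$relic_dirichlet_conc * relic_base / sum(relic_base)
  relic_comp <- matrix(0, nrow = nt, ncol = nrow(sites),
                       dimnames = list(taxa$taxon, sites$site))
  for (s in seq_len(nrow(sites)))
    relic_comp[comm, s] <- rdirichlet1(relic_alpha[comm])

  units <- expand.grid(volunteer = vols, site = sites$site,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  units <- units[order(units$volunteer, units$site), , drop = FALSE]
  units$unit_id <- paste(units$volunteer, units$site, sep = "_")
  srow <- match(units$site, sites$site)
  units$skin_type <- sites$skin_type[srow]
  units$area_cm2 <- sites$area_cm2[srow]

  units$total_density <- 10 ^ stats::rnorm(nrow(units),
                                           sites$biomass_log10_mean[srow],
                                           sites$biomass_log10_sd[srow])
  fmean <- sites$live_fraction_mean[srow]
  f <- ifelse(fmean >= 1, 1,
              stats::plogis(stats::rnorm(nrow(units), stats::qlogis(fmean),
                                         config$live_fraction_logit_sd)))
  units$live_density <- f * units$total_density
  units$live_fraction <- f

  live <- matrix(0, nt, nrow(units), dimnames = list(taxa$taxon, units$unit_id))
  relic <- matrix(0, nt, nrow(units), dimnames = list(taxa$taxon, units$unit_id))
  for (u in seq_len(nrow(units))) {
    st <- units$skin_type[u]
    w <- taxa[[site_weight_col(st)]] * eff[units$volunteer[u], ]
    if (sum(w) == 0) stop("simulate_cohort: zero community weight at ", units$unit_id[u])
    p_live <- w / sum(w)
    live[, u] <- p_live * units$live_density[u]
    rc <- if (config$relic_shared) relic_comp[, units$site[u]] else {
      out <- numeric(nt); out[comm] <- rdirichlet1(relic_alpha[comm]); out
    }
    relic[, u] <- rc * (units$total_density[u] - units$live_density[u])
  }

  metadata <- do.call(rbind, lapply(c("raw", "pma"), function(tr) {
    m <- units[, c("unit_id", "volunteer", "site", "skin_type", "area_cm2")]
    m$treatment <- tr
    m
  }))
  metadata$sample_id <- paste(metadata$unit_id, metadata$treatment, sep = "_")
  metadata$sex <- sexes[metadata$volunteer]
  metadata$run_volume_ul <- config$run_volume
  metadata$beads_added <- config$beads_added
  metadata <- metadata[order(metadata$unit_id, metadata$treatment),
                       c("sample_id", "unit_id", "volunteer", "site",
                         "skin_type", "sex", "treatment", "area_cm2",
                         "run_volume_ul", "beads_added")]
  rownames(metadata) <- NULL
  metadata$index <- seq_len(nrow(metadata))

  structure(list(metadata = metadata, units = units, live = live,
                 relic = relic, config = config),
            class = "cohort_truth")
}

#' @export
print.cohort_truth <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d samples (%d volunteer-site units, raw+pma), %d taxa\n",
              nrow(x$metadata), nrow(x$units), nrow(x$live)))
  cat(sprintf("  total density median %.3g cells/cm2, live fraction median %.2f\n",
              stats::median(x$units$total_density),
              stats::median(x$units$live_fraction)))
  invisible(x)
}

truth_sample_row <- function(truth, sample_id) {
  i <- match(sample_id, truth$metadata$sample_id)
  if (is.na(i)) stop("unknown sample_id: ", sample_id)
  truth$metadata[i, , drop = FALSE]
}

## per-taxon cell densities measurable in a sample (raw: live + relic)
measurable_density <- function(truth, sample_id) {
  m <- truth_sample_row(truth, sample_id)
  lv <- truth$live[, m$unit_id]
  if (m$treatment == "raw") lv + truth$relic[, m$unit_id] else lv
}

## event-class channel centers (arbitrary linear units, documented in the
## methods vignette); gates of gating_config() sit well outside each class.
event_class_centers <- list(
  cell    = c(fsc = 500,  bsc = 400,  fl1 = 1000, fl4 = 60),
  bead    = c(fsc = 1500, bsc = 1200, fl1 = 6000, fl4 = 2000),
  debris  = c(fsc = 100,  bsc = 80,   fl1 = 60,   fl4 = 40),
  doublet = c(fsc = 800,  bsc = 600,  fl1 = 2000, fl4 = 60),
  human   = c(fsc = 8000, bsc = 6000, fl1 = 3000, fl4 = 100)
)

emit_events <- function(n, class, cv, slope = 1) {
  if (n == 0)
    return(data.frame(FSC_A = numeric(0), BSC_A = numeric(0),
                      FL1_A = numeric(0), FL1_H = numeric(0),
                      FL4_A = numeric(0)))
  ctr <- event_class_centers[[class]]
  jit <- function(center) center * exp(stats::rnorm(n, 0, cv))
  fl1 <- jit(ctr["fl1"])
  ## doublets carry twice the area expected from their height signal
  h_slope <- if (class == "doublet") 2 * slope else slope
  fl1_h <- fl1 / h_slope * exp(stats::rnorm(n, 0, cv / 3))
  data.frame(FSC_A = jit(ctr["fsc"]), BSC_A = jit(ctr["bsc"]),
             FL1_A = fl1, FL1_H = fl1_h, FL4_A = jit(ctr["fl4"]))
}

#' Simulate the flow-cytometry event table of one sample
#'
#' Emits counting-bead events (Poisson around `beads_added *
#' acquisition_fraction`), stained-cell events (Poisson around the
#' acquisition expectation of the sample's measurable density: live + relic
#' cells for raw samples, live only for PMA), plus debris (low FL1),
#' large human-like events (high scatter), and doublets (FL1 area about
#' twice the singlet area/height band). Channels are jittered log-normally
#' with CV `event_noise`.
#'
#' @param truth A `cohort_truth`.
#' @param sample_id A sample id from `truth$metadata`.
#' @param config Simulation configuration (defaults to the truth's).
#' @return A data.frame of class `event_table` with columns `FSC_A`,
#'   `BSC_A`, `FL1_A`, `FL1_H`, `FL4_A` and attributes `sample_id`,
#'   `treatment`, `run_volume_ul`, `beads_added`.
#' @export
simulate_events <- function(truth, sample_id, config = truth$config) {
  m <- truth_sample_row(truth, sample_id)
  set.seed(sample_seed(config, m$index, 1L))
  dens <- sum(measurable_density(truth, sample_id))
  lam_cells <- dens * m$area_cm2 * config$acquisition_fraction /
    config$extract_scale
  lam_beads <- config$beads_added * config$acquisition_fraction
  n_cells <- stats::rpois(1, lam_cells)
  n_beads <- stats::rpois(1, lam_beads)
  base <- lam_cells + lam_beads
  n_doub <- stats::rpois(1, config$doublet_rate * base)
  n_debris <- stats::rpois(1, config$debris_rate * base)
  n_human <- stats::rpois(1, config$human_rate * base)

  cv <- config$event_noise
  ev <- rbind(emit_events(n_cells, "cell", cv),
              emit_events(n_beads, "bead", cv),
              emit_events(n_debris, "debris", cv),
              emit_events(n_doub, "doublet", cv),
              emit_events(n_human, "human", cv))
  if (nrow(ev) > 1) ev <- ev[sample.int(nrow(ev)), , drop = FALSE]
  rownames(ev) <- NULL
  attr(ev, "sample_id") <- m$sample_id
  attr(ev, "treatment") <- m$treatment
  attr(ev, "run_volume_ul") <- config$run_volume
  attr(ev, "beads_added") <- config$beads_added
  class(ev) <- c("event_table", "data.frame")
  ev
}

#' Simulate one stained run aliquot of known cell density
#'
#' Standalone event-table generator for calibration studies: emits the same
#' event mix as [simulate_events()] (cells, beads, debris, doublets,
#' human-like events) for an aliquot whose true areal cell density is
#' given, without building a whole cohort.
#'
#' @param density True cell density (cells/cm2) represented by the aliquot.
#' @param area Swabbed area (cm2).
#' @param config A [sim_config()] supplying acquisition constants, noise
#'   and nuisance rates.
#' @param seed Optional seed.
#' @return An `event_table` with acquisition attributes set.
#' @export
simulate_aliquot_events <- function(density, area, config = sim_config(),
                                    seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  lam_cells <- density * area * config$acquisition_fraction /
    config$extract_scale
  lam_beads <- config$beads_added * config$acquisition_fraction
  n_cells <- stats::rpois(1, lam_cells)
  n_beads <- stats::rpois(1, lam_beads)
  base <- lam_cells + lam_beads
  cv <- config$event_noise
  ev <- rbind(emit_events(n_cells, "cell", cv),
              emit_events(n_beads, "bead", cv),
              emit_events(stats::rpois(1, config$debris_rate * base),
                          "debris", cv),
              emit_events(stats::rpois(1, config$doublet_rate * base),
                          "doublet", cv),
              emit_events(stats::rpois(1, config$human_rate * base),
                          "human", cv))
  if (nrow(ev) > 1) ev <- ev[sample.int(nrow(ev)), , drop = FALSE]
  rownames(ev) <- NULL
  attr(ev, "run_volume_ul") <- config$run_volume
  attr(ev, "beads_added") <- config$beads_added
  class(ev) <- c("event_table", "data.frame")
  ev
}

#' Simulate the taxon read-count column of one sample
#'
#' Fragments are multinomially allocated with probability proportional to
#' (measurable cell density x genome length) over community taxa; a
#' `contamination_fraction` of the allocation is split equally among the
#' flagged contaminant taxa. Per-taxon genome coverage follows the
#' saturating Lander-Waterman form
#' `1 - exp(-rate * reads * read_length / genome_length)`, so coverage grows
#' monotonically with allocated reads per bp.
#'
#' @inheritParams simulate_events
#' @param depth Sequencing depth (fragments); defaults to `config$seq_depth`.
#' @return A list with integer vector `counts` and numeric vector
#'   `coverage`, both named by taxon.
#' @export
simulate_counts <- function(truth, sample_id, config = truth$config,
                            depth = config$seq_depth) {
  if (depth <= 0) stop("simulate_counts: sequencing depth must be > 0")
  m <- truth_sample_row(truth, sample_id)
  set.seed(sample_seed(config, m$index, 2L))
  taxa <- config$taxa
  dens <- measurable_density(truth, sample_id)
  w <- dens * taxa$genome_length_bp
  p <- if (sum(w) > 0) w / sum(w) else rep(0, length(w))
  p <- p * (1 - config$contamination_fraction)
  ncon <- sum(taxa$contaminant)
  if (ncon > 0 && config$contamination_fraction > 0)
    p[taxa$contaminant] <- p[taxa$contaminant] +
      config$contamination_fraction / ncon
  if (sum(p) == 0) stop("simulate_counts: no measurable taxa in ", sample_id)
  counts <- as.integer(stats::rmultinom(1, size = depth, prob = p))
  names(counts) <- taxa$taxon
  coverage <- 1 - exp(-config$coverage_rate * counts * config$read_length /
                        taxa$genome_length_bp)
  names(coverage) <- taxa$taxon
  list(counts = counts, coverage = coverage)
}

#' Simulate the full taxon-by-sample count table of a cohort
#'
#' @inheritParams simulate_events
#' @param sample_ids Samples to include (default: all in the cohort).
#' @return A [taxon_count_table()] with counts, genome lengths, per-sample
#'   coverage fractions and the contaminant flag.
#' @export
simulate_count_table <- function(truth, config = truth$config,
                                 sample_ids = truth$metadata$sample_id) {
  cols <- lapply(sample_ids, function(sid) simulate_counts(truth, sid, config))
  counts <- vapply(cols, `[[`, numeric(nrow(config$taxa)), "counts")
  coverage <- vapply(cols, `[[`, numeric(nrow(config$taxa)), "coverage")
  dimnames(counts) <- dimnames(coverage) <-
    list(config$taxa$taxon, sample_ids)
  taxon_count_table(counts, config$taxa$genome_length_bp, coverage,
                    contaminant = config$taxa$contaminant)
}

#' Write a synthetic cohort to plain-text files
#'
#' Emits the sample metadata TSV, the ground-truth TSV (per-unit totals plus
#' per-taxon live/relic densities), the taxon count and coverage TSVs with a
#' genome catalog, and (optionally) one event CSV per sample.
#'
#' @param truth A `cohort_truth`.
#' @param dir Output directory (created if needed).
#' @param events Write per-sample event CSVs (may be large).
#' @return Invisibly, the list of files written.
#' @export
write_cohort <- function(truth, dir, events = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- c(metadata = file.path(dir, "metadata.tsv"),
             units = file.path(dir, "truth_units.tsv"),
             live = file.path(dir, "truth_live.tsv"),
             relic = file.path(dir, "truth_relic.tsv"),
             counts = file.path(dir, "taxon_counts.tsv"),
             coverage = file.path(dir, "taxon_coverage.tsv"),
             catalog = file.path(dir, "genome_catalog.tsv"))
  write_tsv(truth$metadata[, setdiff(names(truth$metadata), "index")],
            files["metadata"])
  write_tsv(truth$units, files["units"])
  write_matrix_tsv(truth$live, files["live"], id_col = "taxon")
  write_matrix_tsv(truth$relic, files["relic"], id_col = "taxon")
  tab <- simulate_count_table(truth)
  write_taxon_counts(tab, files["counts"], files["coverage"], files["catalog"])
  if (events) {
    evdir <- file.path(dir, "events")
    dir.create(evdir, showWarnings = FALSE)
    for (sid in truth$metadata$sample_id) {
      ev <- simulate_events(truth, sid)
      utils::write.csv(as.data.frame(ev),
                       file.path(evdir, paste0(sid, ".csv")),
                       row.names = FALSE)
    }
    files <- c(files, events = evdir)
  }
  invisible(files)
}
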