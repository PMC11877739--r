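#' Default body-site catalog for the synthetic cohort
#'
#' Six skin sites spanning the three canonical microenvironments (sebaceous,
#' moist, dry). Per-site biomass is log10-normal; the location parameters are
#' calibrated to published median total cell densities for these sites, and
#' `live_fraction_mean` is the expected fraction of cells with intact
#' membranes (i.e., surviving PMA treatment). Swabbed areas are free
#' parameters of the design.
#'
#' @return A data.frame with columns `site`, `skin_type`, `area_cm2`,
#'   `biomass_log10_mean`, `biomass_log10_sd`, `live_fraction_mean`.
#' @export
default_body_sites <- function() {
  data.frame(
    site = c("forehead", "upper_back", "antecubital_crease",
             "popliteal_crease", "forearm", "abdomen"),
    skin_type = c("sebaceous", "sebaceous", "moist", "moist", "dry", "dry"),
    area_cm2 = c(25, 50, 25, 25, 50, 50),
    biomass_log10_mean = log10(c(33508, 83508, 10111, 2527, 3729, 5155)),
    biomass_log10_sd = rep(0.55, 6),
    live_fraction_mean = c(0.877, 0.489, 0.126, 0.102, 0.063, 0.165),
    stringsAsFactors = FALSE
  )
}

#' Default taxon catalog for the synthetic cohort
#'
#' A small panel of common skin bacteria with genome lengths (bp) and
#' site-preference weights per skin type; Cutibacterium acnes dominates
#' everywhere, most strongly at sebaceous sites. Three reagent-contaminant
#' taxa are flagged (`contaminant = TRUE`): they carry no community weight
#' and only ever receive contamination reads, so coverage-based filtering
#' can be asserted against them.
#'
#' @return A data.frame with columns `taxon`, `genome_length_bp`,
#'   `w_sebaceous`, `w_moist`, `w_dry`, `contaminant`.
#' @export
default_taxa <- function() {
  tab <- rbind(
    c("Cutibacterium acnes",              2490000, 81.7, 54.2, 54.2),
    c("Staphylococcus epidermidis",       2500000, 17.0, 13.0, 12.0),
    c("Staphylococcus capitis",           2440000,  7.8,  8.8,  6.3),
    c("Staphylococcus hominis",           2220000,  5.0,  7.0,  6.0),
    c("Micrococcus luteus",               2500000,  5.0,  9.5,  6.5),
    c("Corynebacterium tuberculostearicum", 2410000, 4.3, 7.3,  5.3),
    c("Corynebacterium kroppenstedtii",   2450000,  3.5,  3.0,  2.5),
    c("Streptococcus mitis",              2000000,  4.2,  4.7,  7.2),
    c("Cutibacterium granulosum",         2300000,  4.7,  2.7,  2.7),
    c("Staphylococcus aureus",            2800000,  1.7,  2.7,  2.7),
    c("Moraxella osloensis",              2400000,  1.8,  2.8,  3.3),
    c("Dermacoccus nishinomiyaensis",     3000000,  1.5,  2.0,  2.5),
    c("Kocuria palustris",                2900000,  1.3,  1.8,  1.8),
    c("Enhydrobacter aerosaccus",         2600000,  1.5,  2.0,  2.5)
  )
  out <- data.frame(
    taxon = tab[, 1],
    genome_length_bp = as.numeric(tab[, 2]),
    w_sebaceous = as.numeric(tab[, 3]),
    w_moist = as.numeric(tab[, 4]),
    w_dry = as.numeric(tab[, 5]),
    contaminant = FALSE,
    stringsAsFactors = FALSE
  )
  contam <- data.frame(
    taxon = c("Ralstonia pickettii", "Bradyrhizobium japonicum",
              "Cupriavidus metallidurans"),
    genome_length_bp = c(5000000, 7000000, 6900000),
    w_sebaceous = 0, w_moist = 0, w_dry = 0,
    contaminant = TRUE,
    stringsAsFactors = FALSE
  )
  rbind(out, contam)
}

#' Configuration of the synthetic skin-microbiome cohort
#'
#' Bundles every knob of the generator: study design (volunteers, sites,
#' taxa), biological structure (per-site biomass and live fraction,
#' volunteer-specific live composition, shared relic-DNA composition),
#' sequencing (depth, fragment length, contamination), and flow-cytometry
#' acquisition (beads, run volume, acquisition fraction, event noise and
#' nuisance-event rates).
#'
#' The relic (dead-cell / extracellular) compartment is drawn once per site
#' from a Dirichlet distribution and shared by all volunteers when
#' `relic_shared = TRUE`, so only the live compartment carries a volunteer
#' signature; this is the planted contrast that downstream ordination and
#' PERMANOVA recover.
#'
#' @param n_volunteers Number of volunteers (>= 2).
#' @param body_sites Site catalog as from [default_body_sites()] (>= 2 rows).
#' @param taxa Taxon catalog as from [default_taxa()].
#' @param volunteer_effect_sd SD (natural-log scale) of the multiplicative
#'   volunteer-by-taxon effect applied to live composition; 0 removes
#'   personalization.
#' @param live_fraction_logit_sd Spread (logit scale) of per-sample live
#'   fractions around the site mean; the logit-normal median equals the
#'   configured mean.
#' @param relic_shared When TRUE the relic composition is volunteer
#'   independent (one Dirichlet draw per site).
#' @param relic_dirichlet_conc Dirichlet concentration for the relic draw.
#' @param seq_depth Sequenced fragments per sample.
#' @param read_length Effective fragment length (bp) contributing genome
#'   coverage per counted fragment.
#' @param coverage_rate Rate constant of the saturating (Lander-Waterman)
#'   coverage model `1 - exp(-rate * reads * read_length / genome_length)`.
#' @param contamination_fraction Fraction of reads allocated (equally) to the
#'   flagged contaminant taxa, in `[0, 1)`.
#' @param event_noise Channel coefficient of variation for simulated
#'   cytometry events (log-normal jitter); the area/height singlet jitter is
#'   `event_noise / 3`.
#' @param doublet_rate,debris_rate,human_rate Expected nuisance events per
#'   true (cell + bead) event, each in `[0, 1)`.
#' @param beads_added Counting beads spiked into each run aliquot.
#' @param run_volume Run aliquot volume in microliters.
#' @param extract_scale Dimensionless back-calculation multiplier from run
#'   aliquot to whole-swab extract (>= 1).
#' @param acquisition_fraction Fraction of the run aliquot actually acquired
#'   during the timed acquisition; cancels out of the bead-ratio
#'   concentration estimate.
#' @param seed Integer seed; the whole cohort is a deterministic function of
#'   the configuration.
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_volunteers = 12,
                       body_sites = default_body_sites(),
                       taxa = default_taxa(),
                       volunteer_effect_sd = 1.5,
                       live_fraction_logit_sd = 0.15,
                       relic_shared = TRUE,
                       relic_dirichlet_conc = 200,
                       seq_depth = 3e6,
                       read_length = 200,
                       coverage_rate = 1,
                       contamination_fraction = 0.02,
                       event_noise = 0.15,
                       doublet_rate = 0.05,
                       debris_rate = 0.10,
                       human_rate = 0.02,
                       beads_added = 30000,
                       run_volume = 250,
                       extract_scale = 1,
                       acquisition_fraction = 0.02,
                       seed = 7) {
  cfg <- list(
    n_volunteers = as.integer(n_volunteers), body_sites = body_sites,
    taxa = taxa, volunteer_effect_sd = volunteer_effect_sd,
    live_fraction_logit_sd = live_fraction_logit_sd,
    relic_shared = isTRUE(relic_shared),
    relic_dirichlet_conc = relic_dirichlet_conc,
    seq_depth = seq_depth, read_length = read_length,
    coverage_rate = coverage_rate,
    contamination_fraction = contamination_fraction,
    event_noise = event_noise, doublet_rate = doublet_rate,
    debris_rate = debris_rate, human_rate = human_rate,
    beads_added = beads_added, run_volume = run_volume,
    extract_scale = extract_scale,
    acquisition_fraction = acquisition_fraction,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(is.data.frame(cfg$body_sites), is.data.frame(cfg$taxa))
  if (nrow(cfg$taxa) < 1) stop("sim_config: at least one taxon is required")
  if (nrow(cfg$body_sites) < 2 || cfg$n_volunteers < 2)
    stop("sim_config: need >= 2 volunteers and >= 2 body sites")
  fr <- c(cfg$contamination_fraction, cfg$doublet_rate, cfg$debris_rate,
          cfg$human_rate)
  if (any(fr < 0 | fr >= 1))
    stop("sim_config: rates/fractions must lie in [0, 1)")
  if (any(cfg$body_sites$live_fraction_mean <= 0 |
          cfg$body_sites$live_fraction_mean > 1))
    stop("sim_config: live_fraction_mean must lie in (0, 1]")
  if (any(cfg$body_sites$area_cm2 <= 0) || cfg$seq_depth <= 0 ||
      any(cfg$taxa$genome_length_bp <= 0) || cfg$run_volume <= 0 ||
      cfg$beads_added <= 0 || cfg$read_length <= 0)
    stop("sim_config: areas, depths, volumes, bead counts and genome lengths must be > 0")
  if (cfg$extract_scale < 1) stop("sim_config: extract_scale must be >= 1")
  if (cfg$acquisition_fraction <= 0 || cfg$acquisition_fraction > 1)
    stop("sim_config: acquisition_fraction must lie in (0, 1]")
  if (cfg$volunteer_effect_sd < 0 || cfg$event_noise < 0 ||
      cfg$live_fraction_logit_sd < 0)
    stop("sim_config: dispersion parameters must be >= 0")
  invisible(cfg)
}

#' Read a simulation configuration from a YAML file
#'
#' Scalar fields map 1:1 to [sim_config()] arguments; `body_sites` and
#' `taxa` may be given as lists of records (otherwise the package defaults
#' are used).
#'
#' @param path Path to a YAML file.
#' @return A `sim_config` object.
#' @export
sim_config_from_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  for (fld in c("body_sites", "taxa")) {
    if (!is.null(raw[[fld]]) && !is.data.frame(raw[[fld]]))
      raw[[fld]] <- do.call(rbind, lapply(raw[[fld]], function(r)
        as.data.frame(r, stringsAsFactors = FALSE)))
  }
  known <- names(formals(sim_config))
  do.call(sim_config, raw[intersect(names(raw), known)])
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic cohort configuration\n")
  cat(sprintf("  %d volunteers x %d sites (%s)\n", x$n_volunteers,
              nrow(x$body_sites), paste(unique(x$body_sites$skin_type),
                                        collapse = "/")))
  cat(sprintf("  %d taxa (%d contaminant), depth %.3g fragments/sample\n",
              nrow(x$taxa), sum(x$taxa$contaminant), x$seq_depth))
  cat(sprintf("  volunteer effect sd %.2f (log), relic %s, seed %d\n",
              x$volunteer_effect_sd,
              if (x$relic_shared) "shared per site" else "per volunteer",
              x$seed))
  invisible(x)
}
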