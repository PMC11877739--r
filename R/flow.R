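## Flow-cytometry gating and bead-calibrated absolute cell quantification.

EVENT_CHANNELS <- c("FSC_A", "BSC_A", "FL1_A", "FL1_H", "FL4_A")

#' Gating configuration
#'
#' Reproducible numeric gate geometry for the three sequential cell gates
#' and the counting-bead gate:
#' \itemize{
#'   \item DNA-positive quadrant: `FL1_A >= fl1_min` (stain-positive) and
#'     `FL4_A <= fl4_max` (low background emission);
#'   \item singlet band: `|FL1_A - singlet_slope * FL1_H| <=
#'     singlet_tol * FL1_A`, the linear area-vs-height fraction (doublets
#'     carry roughly twice the area per height and fall off the band);
#'   \item size: `FSC_A <= fsc_max` and `BSC_A <= bsc_max` removes large
#'     (human-cell-like) events;
#'   \item bead gate: the high-FL1 x high-FL4 rectangle
#'     `bead_fl1` x `bead_fl4`, required to be disjoint from the
#'     DNA-positive cell quadrant.
#' }
#'
#' @param fl1_min,fl4_max DNA-positive quadrant thresholds.
#' @param singlet_slope Slope of the singlet area/height band (see
#'   [fit_singlet_slope()] to estimate it from bead events).
#' @param singlet_tol Relative half-width of the singlet band.
#' @param fsc_max,bsc_max Large-event exclusion thresholds.
#' @param bead_fl1,bead_fl4 Length-2 ranges of the bead gate rectangle.
#' @return An object of class `gating_config`.
#' @export
gating_config <- function(fl1_min = 200, fl4_max = 500,
                          singlet_slope = 1, singlet_tol = 0.30,
                          fsc_max = 2000, bsc_max = 2000,
                          bead_fl1 = c(3000, 12000),
                          bead_fl4 = c(800, 5000)) {
  cfg <- list(fl1_min = fl1_min, fl4_max = fl4_max,
              singlet_slope = singlet_slope, singlet_tol = singlet_tol,
              fsc_max = fsc_max, bsc_max = bsc_max,
              bead_fl1 = sort(bead_fl1), bead_fl4 = sort(bead_fl4))
  if (any(unlist(cfg) <= 0)) stop("gating_config: all thresholds must be > 0")
  disjoint <- cfg$bead_fl4[1] > cfg$fl4_max || cfg$bead_fl1[2] < cfg$fl1_min
  if (!disjoint)
    stop("gating_config: bead gate must be disjoint from the DNA-positive ",
         "cell quadrant (raise bead_fl4 above fl4_max or keep bead_fl1 below fl1_min)")
  class(cfg) <- "gating_config"
  cfg
}

check_channels <- function(events) {
  miss <- setdiff(EVENT_CHANNELS, names(events))
  if (length(miss))
    stop("event table is missing channel(s): ", paste(miss, collapse = ", "))
  for (ch in EVENT_CHANNELS)
    if (any(!is.finite(events[[ch]])) || any(events[[ch]] < 0))
      stop("channel ", ch, " contains non-finite or negative values")
  invisible(TRUE)
}

#' Gate a flow-cytometry event table
#'
#' Applies, in order, the DNA-positive, singlet and size gates to count
#' microbial cell events, and counts bead events inside the bead gate.
#' Events in the bead gate are never counted as cells.
#'
#' @param events An `event_table` (data.frame with the five channels).
#' @param cfg A [gating_config()].
#' @return A list of class `gate_counts`: `cell_events`, `bead_events`,
#'   `total_events`, per-gate survivor counts (`dna_positive`, `singlet`,
#'   `sized`), and a character `flag` (`"ok"` or `"empty"`).
#' @export
gate_events <- function(events, cfg = gating_config()) {
  if (nrow(events) == 0) {
    warning("empty event table; returning zero counts")
    out <- list(cell_events = 0L, bead_events = 0L, total_events = 0L,
                dna_positive = 0L, singlet = 0L, sized = 0L, flag = "empty")
    class(out) <- "gate_counts"
    return(out)
  }
  check_channels(events)
  fl1 <- events$FL1_A; fl1h <- events$FL1_H; fl4 <- events$FL4_A
  in_bead <- fl1 >= cfg$bead_fl1[1] & fl1 <= cfg$bead_fl1[2] &
    fl4 >= cfg$bead_fl4[1] & fl4 <= cfg$bead_fl4[2]
  dna <- fl1 >= cfg$fl1_min & fl4 <= cfg$fl4_max
  singlet <- abs(fl1 - cfg$singlet_slope * fl1h) <= cfg$singlet_tol * fl1
  sized <- events$FSC_A <= cfg$fsc_max & events$BSC_A <= cfg$bsc_max
  cells <- dna & singlet & sized & !in_bead
  out <- list(cell_events = sum(cells), bead_events = sum(in_bead),
              total_events = nrow(events),
              dna_positive = sum(dna & !in_bead),
              singlet = sum(dna & singlet & !in_bead),
              sized = sum(cells), flag = "ok")
  class(out) <- "gate_counts"
  out
}

#' @export
print.gate_counts <- function(x, ...) {
  cat(sprintf("Gated events: %d cells, %d beads (of %d total; %s)\n",
              x$cell_events, x$bead_events, x$total_events, x$flag))
  invisible(x)
}

#' Estimate the singlet area/height slope from bead events
#'
#' Beads are uniform singlets, so the median `FL1_A / FL1_H` ratio inside
#' the bead gate estimates the slope of the singlet band.
#'
#' @inheritParams gate_events
#' @return A scalar slope estimate.
#' @export
fit_singlet_slope <- function(events, cfg = gating_config()) {
  check_channels(events)
  in_bead <- events$FL1_A >= cfg$bead_fl1[1] & events$FL1_A <= cfg$bead_fl1[2] &
    events$FL4_A >= cfg$bead_fl4[1] & events$FL4_A <= cfg$bead_fl4[2]
  if (!any(in_bead)) stop("no bead events available to fit the singlet slope")
  stats::median(events$FL1_A[in_bead] / events$FL1_H[in_bead])
}

#' Bead-calibrated cell concentration
#'
#' Counting-bead arithmetic: a known number of beads is spiked into the run
#' aliquot, so the cell concentration is
#' `(cell_events / bead_events) * (beads_added / run_volume)` cells/uL.
#'
#' @param cell_events,bead_events Gated event counts.
#' @param beads_added Beads spiked into the aliquot.
#' @param run_volume Aliquot volume in microliters.
#' @return Concentration in cells per microliter.
#' @export
bead_concentration <- function(cell_events, bead_events, beads_added,
                               run_volume) {
  if (run_volume <= 0) stop("run_volume must be > 0")
  if (beads_added <= 0) stop("beads_added must be > 0")
  if (any(bead_events == 0))
    stop("no beads detected: bead_events is 0; sample must be flagged, not quantified")
  (cell_events / bead_events) * (beads_added / run_volume)
}

#' Convert a concentration to an areal cell density
#'
#' `density = concentration * run_volume * extract_scale / area`:
#' the run aliquot concentration scaled back to the whole-swab extract and
#' divided by the swabbed area.
#'
#' @param conc Concentration in cells/uL.
#' @param run_volume Run aliquot volume (uL).
#' @param area Swabbed area (cm2), > 0.
#' @param extract_scale Dimensionless extract back-calculation factor
#'   (>= 1; 1 when the whole extract is run).
#' @return Density in cells/cm2.
#' @export
cells_per_cm2 <- function(conc, run_volume, area, extract_scale = 1) {
  if (any(area <= 0)) stop("area must be > 0")
  if (any(extract_scale < 1)) stop("extract_scale must be >= 1")
  if (any(run_volume <= 0)) stop("run_volume must be > 0")
  conc * run_volume * extract_scale / area
}

#' Gate one sample and estimate its absolute cell density
#'
#' Convenience wrapper: gates the events, applies the bead formula and the
#' areal conversion. A sample with no detected beads (or no events) is
#' flagged and given `NA` estimates rather than failing the batch.
#'
#' @inheritParams gate_events
#' @param sample_id,treatment Sample identity carried into the result.
#' @param beads_added,run_volume,area,extract_scale Acquisition constants.
#' @return A one-row data.frame of class `cell_density`: `sample_id`,
#'   `treatment`, `cell_events`, `bead_events`, `cells_per_ul`,
#'   `cells_per_cm2`, `flag`.
#' @export
cell_density <- function(events, cfg = gating_config(), sample_id = NA,
                         treatment = NA,
                         beads_added = attr(events, "beads_added"),
                         run_volume = attr(events, "run_volume_ul"),
                         area, extract_scale = 1) {
  g <- if (nrow(events) == 0)
    suppressWarnings(gate_events(events, cfg)) else gate_events(events, cfg)
  flag <- g$flag
  if (g$bead_events == 0) {
    conc <- NA_real_; dens <- NA_real_
    flag <- if (flag == "empty") "empty" else "no_beads"
  } else {
    conc <- bead_concentration(g$cell_events, g$bead_events, beads_added,
                               run_volume)
    dens <- cells_per_cm2(conc, run_volume, area, extract_scale)
  }
  data.frame(sample_id = sample_id, treatment = treatment,
             cell_events = g$cell_events, bead_events = g$bead_events,
             cells_per_ul = conc, cells_per_cm2 = dens, flag = flag,
             stringsAsFactors = FALSE)
}

#' Per-sample live fraction from a paired raw/PMA density pair
#'
#' `100 * pma_density / raw_density`, in percent. Values above 100 are
#' possible under measurement noise and are reported as-is. A zero (or
#' missing) raw density yields `NA`.
#'
#' @param raw_density,pma_density Cell densities (cells/cm2) of the
#'   untreated and PMA-treated members of a sample pair; vectorized.
#' @return Live fraction(s) in percent.
#' @export
live_fraction_sample <- function(raw_density, pma_density) {
  out <- ifelse(is.na(raw_density) | is.na(pma_density) | raw_density <= 0,
                NA_real_, 100 * pma_density / raw_density)
  if (any(is.na(out) & !is.na(raw_density) & !is.na(pma_density)))
    warning("live fraction undefined for sample(s) with zero raw density")
  out
}
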