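# Shared fixtures, built in code.

# Small, fast cohort configuration for unit tests.
tiny_cfg <- function(...) {
  args <- list(n_volunteers = 3, seq_depth = 5e4, seed = 11)
  over <- list(...)
  args[names(over)] <- over
  do.call(sim_config, args)
}

# Cached small cohort (simulated once per test run).
tiny_truth_env <- new.env()
tiny_truth <- function() {
  if (is.null(tiny_truth_env$truth))
    tiny_truth_env$truth <- simulate_cohort(tiny_cfg())
  tiny_truth_env$truth
}

# Hand-built noise-free event tables: all values sit exactly on the class
# centers used by the generator, well inside the default gates.
rep_events <- function(row, n) {
  out <- row[rep(1, n), , drop = FALSE]
  rownames(out) <- NULL
  out
}
make_cells <- function(n) {
  rep_events(data.frame(FSC_A = 500, BSC_A = 400, FL1_A = 1000,
                        FL1_H = 1000, FL4_A = 60), n)
}
make_beads <- function(n) {
  rep_events(data.frame(FSC_A = 1500, BSC_A = 1200, FL1_A = 6000,
                        FL1_H = 6000, FL4_A = 2000), n)
}
make_doublets <- function(n, slope = 1) {
  # area = 2 * slope * height: off the singlet band by construction
  rep_events(data.frame(FSC_A = 800, BSC_A = 600, FL1_A = 2000,
                        FL1_H = 2000 / (2 * slope), FL4_A = 60), n)
}
make_large <- function(n) {
  rep_events(data.frame(FSC_A = 5000, BSC_A = 600, FL1_A = 1000,
                        FL1_H = 1000, FL4_A = 60), n)
}

# Two-taxon count table helper.
two_taxon_table <- function(counts, lengths = c(A = 2e6, B = 6e6),
                            coverage = NULL) {
  m <- matrix(counts, nrow = 2, dimnames = list(names(lengths), "s1"))
  taxon_count_table(m, lengths, coverage)
}
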