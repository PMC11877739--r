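## Plain-text readers/writers for the pipeline's tabular interchange formats.

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

write_matrix_tsv <- function(m, path, id_col = "id") {
  df <- data.frame(rownames(m), as.data.frame(m, check.names = FALSE),
                   check.names = FALSE)
  names(df)[1] <- id_col
  write_tsv(df, path)
}

read_matrix_tsv <- function(path) {
  df <- read_tsv(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Read a sample metadata table
#'
#' @param path TSV with one row per sample; must contain `sample_id`,
#'   `treatment`, and the acquisition/area constants used downstream.
#' @return A data.frame.
#' @export
read_metadata <- function(path) {
  md <- read_tsv(path)
  need <- c("sample_id", "treatment")
  if (!all(need %in% names(md)))
    stop("metadata must contain columns: ", paste(need, collapse = ", "))
  md
}

#' Read a flow-cytometry event table from delimited text
#'
#' @param path CSV (or TSV) with one row per event and columns `FSC_A`,
#'   `BSC_A`, `FL1_A`, `FL1_H`, `FL4_A`.
#' @param sep Field separator; `","` by default.
#' @return A data.frame of class `event_table`.
#' @export
read_event_table <- function(path, sep = ",") {
  ev <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  class(ev) <- c("event_table", "data.frame")
  ev
}

#' Write a taxon count table (counts, coverage, genome catalog) as TSV
#'
#' @param tab A [taxon_count_table()].
#' @param counts_path,coverage_path,catalog_path Output file paths.
#' @return Invisibly, the three paths.
#' @export
write_taxon_counts <- function(tab, counts_path, coverage_path,
                               catalog_path) {
  write_matrix_tsv(tab$counts, counts_path, id_col = "taxon")
  write_matrix_tsv(tab$coverage, coverage_path, id_col = "taxon")
  write_tsv(data.frame(taxon = rownames(tab$counts),
                       genome_length_bp = tab$genome_length,
                       contaminant = tab$contaminant),
            catalog_path)
  invisible(c(counts_path, coverage_path, catalog_path))
}

#' Read a taxon count table from TSV (or BIOM) plus a genome catalog
#'
#' @param counts_path Taxon-by-sample counts: TSV with a leading `taxon`
#'   column, or a `.biom` file (requires the biomformat package).
#' @param catalog_path TSV with columns `taxon`, `genome_length_bp` and
#'   optionally `contaminant`.
#' @param coverage_path Optional TSV of per-(taxon, sample) genome-coverage
#'   fractions, same shape as the counts; when absent, coverage defaults to
#'   1 (no coverage filtering possible).
#' @return A [taxon_count_table()].
#' @export
read_taxon_counts <- function(counts_path, catalog_path,
                              coverage_path = NULL) {
  if (grepl("\\.biom$", counts_path)) {
    if (!requireNamespace("biomformat", quietly = TRUE))
      stop("reading .biom files requires the biomformat package")
    counts <- as(biomformat::biom_data(biomformat::read_biom(counts_path)),
                 "matrix")
  } else {
    counts <- read_matrix_tsv(counts_path)
  }
  cat_df <- read_tsv(catalog_path)
  i <- match(rownames(counts), cat_df$taxon)
  if (anyNA(i)) stop("genome catalog is missing taxa: ",
                     paste(rownames(counts)[is.na(i)], collapse = ", "))
  coverage <- if (is.null(coverage_path)) NULL else read_matrix_tsv(coverage_path)
  contaminant <- if ("contaminant" %in% names(cat_df))
    as.logical(cat_df$contaminant[i]) else rep(FALSE, nrow(counts))
  taxon_count_table(counts, cat_df$genome_length_bp[i], coverage,
                    contaminant = contaminant)
}

#' Write a distance matrix as a square TSV
#'
#' @param d A `dist` object or square matrix.
#' @param path Output path.
#' @export
write_distance_tsv <- function(d, path) {
  write_matrix_tsv(as.matrix(d), path, id_col = "sample_id")
}
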