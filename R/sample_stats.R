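#' Per-sample read counts and chromatin masses
#'
#' Assemble the per-sample statistics that every normalization method consumes:
#' deduplicated read counts on the experimental and spike-in genomes, and the
#' wet-lab chromatin amounts. Masses are used internally: the input DNA mass is
#' `input_conc_ng_per_ul * input_volume_ul` (ng), so unequal input volumes are
#' handled correctly; the spike-in chromatin is represented by its mass in ng
#' (only ratios of the two ever enter a factor, so any consistent convention
#' works).
#'
#' @param data A data frame with one row per sample and columns `sample_id`,
#'   `unique_sample_reads`, `unique_spikein_reads`, and either
#'   `input_dna_mass_ng` or the pair `input_conc_ng_per_ul` +
#'   `input_volume_ul`, plus `spikein_mass_ng`. Mass columns may be omitted
#'   when only read-depth methods will be used.
#' @return A tibble of class `sample_stats` with columns `sample_id`,
#'   `unique_sample_reads`, `unique_spikein_reads`, `input_dna_mass_ng`,
#'   `spikein_mass_ng` (mass columns `NA` when not supplied).
#' @examples
#' sample_stats(data.frame(
#'   sample_id = c("rep1", "rep2", "rep3"),
#'   unique_sample_reads = c(4190041, 23728210, 22990981),
#'   unique_spikein_reads = c(142086, 268064, 319773),
#'   input_conc_ng_per_ul = c(29.6, 17.3, 35.6),
#'   input_volume_ul = 20,
#'   spikein_mass_ng = 62.5
#' ))
#' @export
sample_stats <- function(data) {
  stopifnot(is.data.frame(data))
  required <- c("sample_id", "unique_sample_reads", "unique_spikein_reads")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("sample metadata is missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "spikenorm_schema_error")
  }
  out <- as_tibble(data)
  if (!"input_dna_mass_ng" %in% names(out)) {
    if (all(c("input_conc_ng_per_ul", "input_volume_ul") %in% names(out))) {
      out$input_dna_mass_ng <- out$input_conc_ng_per_ul * out$input_volume_ul
    } else {
      out$input_dna_mass_ng <- NA_real_
    }
  }
  if (!"spikein_mass_ng" %in% names(out)) out$spikein_mass_ng <- NA_real_
  out$sample_id <- as.character(out$sample_id)
  if (anyDuplicated(out$sample_id)) {
    abort("duplicated sample_id in metadata", class = "spikenorm_schema_error")
  }
  if (any(out$unique_sample_reads < 0) || any(out$unique_spikein_reads < 0)) {
    abort("read counts must be non-negative",
          class = "spikenorm_degenerate_input_error")
  }
  out <- out[, unique(c(required, "input_dna_mass_ng", "spikein_mass_ng",
                        setdiff(names(out), c(required, "input_dna_mass_ng",
                                              "spikein_mass_ng"))))]
  class(out) <- c("sample_stats", class(out))
  out
}

#' Read per-sample metadata from TSV or JSON
#'
#' The TSV layout mirrors a bench-style sample table: one row per sample with
#' header `sample_id`, `unique_sample_reads`, `unique_spikein_reads`,
#' `input_conc_ng_per_ul`, `input_volume_ul`, `spikein_mass_ng`. A JSON file
#' with the same keys (array of objects, or object of parallel arrays) is also
#' accepted.
#'
#' @param path Path to a `.tsv`/`.txt` or `.json` metadata file.
#' @return A [sample_stats] tibble.
#' @export
read_sample_metadata <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    data <- as.data.frame(jsonlite::fromJSON(path))
  } else {
    data <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  }
  sample_stats(data)
}

check_positive <- function(stats, cols, method) {
  for (col in cols) {
    bad <- !is.finite(stats[[col]]) | stats[[col]] <= 0
    if (any(bad)) {
      abort(sprintf(
        "%s normalization requires %s > 0; violated by sample(s): %s",
        method, col, paste(stats$sample_id[bad], collapse = ", ")),
        class = "spikenorm_degenerate_input_error")
    }
  }
  invisible(stats)
}

check_group_size <- function(stats) {
  if (nrow(stats) < 2) {
    abort("normalization needs at least 2 samples",
          class = "spikenorm_group_size_error")
  }
  invisible(stats)
}
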