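#' Normalization factors for ChIP-seq downsampling
#'
#' Compute per-sample normalization factors (NF) — the fraction of each
#' sample's experimental-genome reads that is randomly retained during
#' downsampling — under one of three read-retention methods, or the CPM
#' display scaling:
#'
#' * `equal_read`: \eqn{NF_i = \min(X)/X_i}, where \eqn{X_i} is the sample's
#'   deduplicated experimental-genome read count. All samples are brought down
#'   to the depth of the shallowest one.
#' * `spikein`: \eqn{NF_i = \min(S)/S_i}, where \eqn{S_i} is the deduplicated
#'   spike-in (exogenous genome) read count. Because an equal mass of spike-in
#'   chromatin was added to every sample, equalizing spike-in reads corrects
#'   for ChIP enrichment, library preparation and sequencing differences.
#' * `input_adjusted_spikein`: the spike-in idea corrected for unequal input
#'   chromatin amounts. The raw factor is
#'   \eqn{(C_{sample,i}/C_{spike,i}) / (X_i/S_i)} — after applying it, the
#'   retained sample-to-spike-in read ratio is proportional to the
#'   sample-to-spike-in DNA mass ratio in every sample. Raw factors are then
#'   rescaled by the group maximum so the reference sample retains all of its
#'   reads and no sample would need up-sampling.
#' * `cpm`: counts-per-million is a display-time scaling of signal tracks
#'   (see [apply_cpm()]); it never triggers downsampling, so its factor set is
#'   all ones with `scale_only = TRUE`.
#'
#' @param stats A [sample_stats] data frame (or anything `sample_stats()`
#'   accepts).
#' @param method One of `"cpm"`, `"equal_read"`, `"spikein"`,
#'   `"input_adjusted_spikein"`.
#' @return A tibble of class `norm_factor_set` with columns `sample_id`,
#'   `factor` (retention fraction in (0, 1]), `expected_retained_reads`
#'   (`factor * unique_sample_reads`), and for the input-adjusted method the
#'   unrescaled `raw_factor`. Attributes: `method`, `reference_sample` (the
#'   sample whose factor is 1), `scale_only` (TRUE for cpm).
#' @examples
#' tbl1 <- sample_stats(data.frame(
#'   sample_id = c("rep1", "rep2", "rep3"),
#'   unique_sample_reads = c(4190041, 23728210, 22990981),
#'   unique_spikein_reads = c(142086, 268064, 319773),
#'   input_conc_ng_per_ul = c(29.6, 17.3, 35.6),
#'   input_volume_ul = 20,
#'   spikein_mass_ng = 62.5
#' ))
#' norm_factors(tbl1, "spikein")
#' norm_factors(tbl1, "input_adjusted_spikein")
#' @export
norm_factors <- function(stats,
                         method = c("cpm", "equal_read", "spikein",
                                    "input_adjusted_spikein")) {
  method <- match.arg(method)
  switch(method,
    cpm = cpm_factors(stats),
    equal_read = equal_read_factors(stats),
    spikein = spikein_factors(stats),
    input_adjusted_spikein = input_adjusted_factors(stats)
  )
}

new_norm_factor_set <- function(stats, factors, method, raw = NULL,
                                scale_only = FALSE) {
  # reference sample determined on the exact arithmetic argmax of the factor,
  # before any floating division can blur ties
  ref <- stats$sample_id[which.max(factors)]
  out <- tibble(
    sample_id = stats$sample_id,
    factor = as.numeric(factors),
    expected_retained_reads = as.numeric(factors) * stats$unique_sample_reads
  )
  if (!is.null(raw)) out$raw_factor <- as.numeric(raw)
  structure(out,
            class = c("norm_factor_set", class(tibble())),
            method = method,
            reference_sample = ref,
            scale_only = scale_only)
}

#' @rdname norm_factors
#' @export
equal_read_factors <- function(stats) {
  stats <- as_sample_stats(stats)
  check_group_size(stats)
  check_positive(stats, "unique_sample_reads", "equal-read")
  x <- stats$unique_sample_reads
  new_norm_factor_set(stats, min(x) / x, "equal_read")
}

#' @rdname norm_factors
#' @export
spikein_factors <- function(stats) {
  stats <- as_sample_stats(stats)
  check_group_size(stats)
  check_positive(stats, "unique_spikein_reads", "spike-in")
  s <- stats$unique_spikein_reads
  new_norm_factor_set(stats, min(s) / s, "spikein")
}

#' @rdname norm_factors
#' @export
input_adjusted_factors <- function(stats) {
  stats <- as_sample_stats(stats)
  check_group_size(stats)
  check_positive(stats,
                 c("unique_sample_reads", "unique_spikein_reads",
                   "input_dna_mass_ng", "spikein_mass_ng"),
                 "input-adjusted spike-in")
  raw <- with(stats, (input_dna_mass_ng / spikein_mass_ng) /
                     (unique_sample_reads / unique_spikein_reads))
  new_norm_factor_set(stats, raw / max(raw), "input_adjusted_spikein",
                      raw = raw)
}

cpm_factors <- function(stats) {
  stats <- as_sample_stats(stats)
  new_norm_factor_set(stats, rep(1, nrow(stats)), "cpm", scale_only = TRUE)
}

as_sample_stats <- function(stats) {
  if (inherits(stats, "sample_stats")) stats else sample_stats(stats)
}

#' CPM scale factor
#'
#' The multiplier that converts raw windowed read counts into counts per
#' million: `1e6 / total_reads`.
#'
#' @param total_reads Total read count of the sample (> 0).
#' @return A positive scalar.
#' @examples
#' cpm_scale_factor(1e6) # 1
#' @export
cpm_scale_factor <- function(total_reads) {
  if (length(total_reads) != 1 || !is.finite(total_reads) || total_reads <= 0) {
    abort("total_reads must be a single positive count",
          class = "spikenorm_degenerate_input_error")
  }
  1e6 / total_reads
}

#' @export
print.norm_factor_set <- function(x, ...) {
  cat(sprintf("<norm_factor_set> method = %s, reference sample = %s%s\n",
              attr(x, "method"), attr(x, "reference_sample"),
              if (isTRUE(attr(x, "scale_only"))) " (display scaling only)" else ""))
  NextMethod()
}

#' @describeIn norm_factors `tidy()` returns the factor table as a plain
#'   tibble with a `method` column.
#' @param x A `norm_factor_set`.
#' @param ... Unused.
#' @export
tidy.norm_factor_set <- function(x, ...) {
  out <- as_tibble(unclass_nfs(x))
  out$method <- attr(x, "method")
  out$is_reference <- out$sample_id == attr(x, "reference_sample")
  out
}

#' @describeIn norm_factors `glance()` returns a one-row summary.
#' @export
glance.norm_factor_set <- function(x, ...) {
  tibble(
    method = attr(x, "method"),
    n_samples = nrow(x),
    reference_sample = attr(x, "reference_sample"),
    min_factor = min(x$factor),
    scale_only = isTRUE(attr(x, "scale_only"))
  )
}

unclass_nfs <- function(x) {
  class(x) <- setdiff(class(x), "norm_factor_set")
  x
}

#' Write a normalization-factor report as JSON
#'
#' @param nfs A `norm_factor_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_norm_report <- function(nfs, path) {
  stopifnot(inherits(nfs, "norm_factor_set"))
  report <- list(
    method = attr(nfs, "method"),
    factors = as.list(setNames(nfs$factor, nfs$sample_id)),
    reference_sample = attr(nfs, "reference_sample"),
    expected_retained_reads =
      as.list(setNames(nfs$expected_retained_reads, nfs$sample_id))
  )
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @describeIn norm_factors `autoplot()` draws the per-sample retention
#'   fractions.
#' @param object A `norm_factor_set`.
#' @export
autoplot.norm_factor_set <- function(object, ...) {
  dat <- tidy(object)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$sample_id, y = .data$factor,
                                    fill = .data$is_reference)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#D55E00", `FALSE` = "grey40")) +
    ggplot2::labs(x = NULL, y = "retention fraction",
                  title = paste0("Normalization factors (", attr(object, "method"), ")")) +
    ggplot2::ylim(0, 1)
}
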