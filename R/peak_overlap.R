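#' Multi-sample peak overlap partition
#'
#' Merges the peaks of k samples into disjoint regions and records which
#' samples contributed to each: peaks whose intervals overlap by at least
#' 1 bp (transitively, across any samples) form one merged region, and every
#' input peak is assigned to exactly one region. The per-region membership is
#' tabulated into the \eqn{2^k - 1} Venn categories used to draw replicate-
#' or method-overlap Venn diagrams.
#'
#' @param peak_sets Named list of k >= 2 peak tibbles (`chrom`, `start`,
#'   `end`). Unsorted input is sorted internally.
#' @return An object of class `overlap_partition`: list with `sample_ids`,
#'   `regions` (tibble: `chrom`, `start`, `end`, one logical column per
#'   sample, `membership` string like `"A+C"`, `n_samples`), and
#'   `venn_counts` (tibble: `membership`, `n_samples`, `n`).
#' @examples
#' a <- tibble::tibble(chrom = "chr1", start = 0, end = 100)
#' b <- tibble::tibble(chrom = "chr1", start = 50, end = 150)
#' overlap_partition(list(A = a, B = b))
#' @export
overlap_partition <- function(peak_sets) {
  stopifnot(is.list(peak_sets), length(peak_sets) >= 2)
  ids <- names(peak_sets)
  if (is.null(ids) || any(ids == "")) {
    ids <- paste0("S", seq_along(peak_sets))
    names(peak_sets) <- ids
  }
  grl <- lapply(peak_sets, function(p) {
    p <- as_tibble(p)
    GenomicRanges::GRanges(p$chrom,
                           IRanges::IRanges(start = p$start + 1L, end = p$end))
  })
  all_gr <- suppressWarnings(do.call(c, unname(grl)))
  if (length(all_gr) == 0) {
    regions <- tibble(chrom = character(), start = integer(), end = integer())
    for (id in ids) regions[[id]] <- logical()
    regions$membership <- character()
    regions$n_samples <- integer()
    return(new_overlap_partition(ids, regions))
  }
  # min.gapwidth = 0: merge only on >= 1 bp overlap, never on abutment
  merged <- GenomicRanges::reduce(GenomicRanges::sort(all_gr),
                                  min.gapwidth = 0L)
  regions <- tibble(
    chrom = as.character(GenomicRanges::seqnames(merged)),
    start = GenomicRanges::start(merged) - 1L,
    end = GenomicRanges::end(merged)
  )
  for (id in ids) {
    regions[[id]] <- IRanges::overlapsAny(merged, grl[[id]])
  }
  memb <- as.matrix(regions[, ids, drop = FALSE])
  regions$membership <- apply(memb, 1L, function(r) paste(ids[r], collapse = "+"))
  regions$n_samples <- rowSums(memb)
  new_overlap_partition(ids, regions)
}

new_overlap_partition <- function(ids, regions) {
  venn <- regions |>
    dplyr::count(.data$membership, .data$n_samples, name = "n") |>
    arrange(dplyr::desc(.data$n_samples), .data$membership)
  structure(list(sample_ids = ids, regions = regions, venn_counts = venn),
            class = "overlap_partition")
}

#' @export
print.overlap_partition <- function(x, ...) {
  cat(sprintf("<overlap_partition> %d merged regions across %d sets (%s)\n",
              nrow(x$regions), length(x$sample_ids),
              paste(x$sample_ids, collapse = ", ")))
  print(x$venn_counts)
  invisible(x)
}

#' @describeIn overlap_partition `tidy()` returns the Venn category counts.
#' @param x An `overlap_partition`.
#' @param ... Unused.
#' @export
tidy.overlap_partition <- function(x, ...) x$venn_counts

#' @describeIn overlap_partition `glance()` returns totals: merged regions,
#'   consensus regions (in all sets), exclusive regions (single set).
#' @export
glance.overlap_partition <- function(x, ...) {
  k <- length(x$sample_ids)
  tibble(
    n_sets = k,
    n_regions = nrow(x$regions),
    n_consensus = sum(x$regions$n_samples == k),
    n_exclusive = sum(x$regions$n_samples == 1)
  )
}

#' Consensus peaks: regions supported by every sample
#'
#' @param partition An `overlap_partition`.
#' @return Tibble of merged regions present in all k samples, ordered by
#'   contig then start.
#' @export
consensus_peaks <- function(partition) {
  stopifnot(inherits(partition, "overlap_partition"))
  k <- length(partition$sample_ids)
  out <- partition$regions[partition$regions$n_samples == k,
                           c("chrom", "start", "end")]
  arrange(out, .data$chrom, .data$start)
}

#' Exclusive (single-sample) region counts
#'
#' Single-sample exclusive regions are the proxy for irreproducible,
#' likely-false-positive peaks when comparing normalization methods.
#'
#' @param partition An `overlap_partition`.
#' @return Named vector: exclusive region count per sample.
#' @export
exclusive_counts <- function(partition) {
  stopifnot(inherits(partition, "overlap_partition"))
  excl <- partition$regions[partition$regions$n_samples == 1, , drop = FALSE]
  vapply(partition$sample_ids, function(id) sum(excl[[id]]), 1L)
}

#' Compare consensus peak sets across normalization methods
#'
#' Applies the same overlap machinery across methods rather than replicates:
#' each element of `consensus_by_method` is the consensus peak set one
#' normalization method produced, and the partition shows which consensus
#' regions are shared between methods and which are method-exclusive.
#'
#' @param consensus_by_method Named list (method -> peak tibble).
#' @return An `overlap_partition` keyed by method name.
#' @export
method_consensus_comparison <- function(consensus_by_method) {
  overlap_partition(consensus_by_method)
}

#' Write Venn category counts as JSON or TSV
#'
#' @param partition An `overlap_partition`.
#' @param path Output path ending in `.json` or `.tsv`.
#' @return `path`, invisibly.
#' @export
write_venn_counts <- function(partition, path) {
  stopifnot(inherits(partition, "overlap_partition"))
  venn <- partition$venn_counts
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(
      list(sample_ids = partition$sample_ids,
           venn_counts = as.list(setNames(venn$n, venn$membership))),
      path, auto_unbox = TRUE, digits = NA)
  } else {
    readr::write_tsv(venn, path, progress = FALSE)
  }
  invisible(path)
}

#' @describeIn overlap_partition `autoplot()` draws the Venn category counts
#'   as a bar chart (an upset-style summary of the Venn diagram).
#' @param object An `overlap_partition`.
#' @export
autoplot.overlap_partition <- function(object, ...) {
  dat <- object$venn_counts
  dat$membership <- factor(dat$membership, levels = dat$membership)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$membership, y = .data$n,
                                    fill = factor(.data$n_samples))) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "set membership", y = "merged regions",
                  fill = "sets", title = "Peak overlap partition") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
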