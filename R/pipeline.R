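#' Run the full normalization-comparison workflow
#'
#' Wires the modules into the end-to-end workflow: per-sample read counting,
#' normalization factors for each requested method, seeded downsampling,
#' windowed coverage tracks, peak calling, per-method replicate overlap
#' partitions and consensus peaks, and a cross-method comparison of the
#' consensus sets — summarized in a bench-table-style tibble (reads before and
#' after each normalization, peaks per method).
#'
#' CPM is a display scaling: its "downsampling" factors are 1, peaks are
#' called on the unnormalized reads, and CPM scaling is applied to the
#' exported tracks only.
#'
#' @param alignments Named list (sample_id -> alignment tibble or SAM/BAM
#'   path) of composite-genome alignments, or a `simulation` object from
#'   [simulate_experiment()] (in which case `metadata` and `chrom_lengths`
#'   default from it).
#' @param metadata A [sample_stats] table. When `NULL` it is derived by
#'   counting the alignments (masses then unavailable, restricting methods).
#' @param chrom_lengths Named contig lengths of the composite genome.
#' @param methods Normalization methods to run.
#' @param seed Integer seed; sample-specific downsampling seeds are derived
#'   from it deterministically.
#' @param window_width,peak_width,fold_min,p_max Track and caller parameters.
#' @param spike_prefix Prefix of spike-in contigs; spike-in reads are never
#'   downsampled and are excluded from tracks and peaks.
#' @param keep_tracks Keep the per-method, per-sample coverage tracks in the
#'   returned object (`FALSE` by default; they dominate memory on large
#'   genomes).
#' @param outdir Optional output directory for tracks (bedGraph), peaks
#'   (narrowPeak), factor reports (JSON), Venn counts (JSON) and the summary
#'   TSV; file names carry the method name.
#' @return A list of class `spikenorm_pipeline`: `summary` (tibble),
#'   `factors` (list of `norm_factor_set`), `peaks` (method -> sample ->
#'   tibble), `partitions` (method -> `overlap_partition`), `consensus`
#'   (method -> tibble), `method_comparison` (`overlap_partition` across
#'   methods), `metadata`.
#' @export
run_pipeline <- function(alignments, metadata = NULL, chrom_lengths = NULL,
                         methods = c("cpm", "equal_read", "spikein",
                                     "input_adjusted_spikein"),
                         seed = 1L, window_width = 20L, peak_width = 200L,
                         fold_min = 4, p_max = 1e-4,
                         spike_prefix = "spikein_", outdir = NULL,
                         keep_tracks = FALSE) {
  methods <- match.arg(methods, several.ok = TRUE)
  if (inherits(alignments, "simulation")) {
    sim <- alignments
    alignments <- sim$alignments
    metadata <- metadata %||% sim$metadata
    chrom_lengths <- chrom_lengths %||% sim$chrom_lengths
  }
  stopifnot(!is.null(chrom_lengths))
  alignments <- lapply(alignments, as_alignments)
  ids <- names(alignments)
  stopifnot(length(ids) >= 2, !is.null(ids))

  if (is.null(metadata)) {
    counts <- purrr::map_dfr(ids, function(id) {
      cc <- classify_and_count(alignments[[id]], spike_prefix = spike_prefix)
      tibble(sample_id = id, unique_sample_reads = cc$unique_sample,
             unique_spikein_reads = cc$unique_spikein)
    })
    metadata <- sample_stats(counts)
  }
  metadata <- as_sample_stats(metadata)
  stopifnot(setequal(metadata$sample_id, ids))
  metadata <- metadata[match(ids, metadata$sample_id), ]

  sample_lengths <- chrom_lengths[!startsWith(names(chrom_lengths),
                                              spike_prefix)]
  sample_aln <- lapply(alignments, function(a) {
    a[!startsWith(a$chrom, spike_prefix) & !a$is_duplicate, ]
  })

  factors <- peaks <- partitions <- consensus <- list()
  tracks_last <- list()
  for (m in methods) {
    nfs <- norm_factors(metadata, m)
    factors[[m]] <- nfs
    f <- setNames(nfs$factor, nfs$sample_id)
    m_peaks <- list()
    m_tracks <- list()
    for (id in ids) {
      ds <- if (isTRUE(attr(nfs, "scale_only")) || f[[id]] == 1) {
        sample_aln[[id]]
      } else {
        downsample_reads(sample_aln[[id]], f[[id]],
                         seed = derive_seed(seed, m, id))
      }
      # peaks are called on 5'-tag counts; overlap-rule tracks serve display
      # and quantification
      tag_trk <- windowed_coverage(ds, sample_lengths, window_width,
                                   count_rule = "start")
      m_peaks[[id]] <- call_peaks(tag_trk, peak_width, fold_min, p_max)
      trk <- NULL
      if (keep_tracks || !is.null(outdir)) {
        trk <- windowed_coverage(ds, sample_lengths, window_width)
      }
      if (keep_tracks) m_tracks[[id]] <- trk
      if (!is.null(outdir)) {
        dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
        out_trk <- if (m == "cpm") apply_cpm(trk) else trk
        write_bedgraph(out_trk, file.path(outdir,
                                          sprintf("%s_%s.bedGraph", id, m)))
        write_peaks(m_peaks[[id]],
                    file.path(outdir, sprintf("%s_%s.narrowPeak", id, m)))
      }
    }
    peaks[[m]] <- m_peaks
    partitions[[m]] <- overlap_partition(m_peaks)
    consensus[[m]] <- consensus_peaks(partitions[[m]])
    tracks_last[[m]] <- m_tracks
    if (!is.null(outdir)) {
      write_norm_report(nfs, file.path(outdir, sprintf("factors_%s.json", m)))
      write_venn_counts(partitions[[m]],
                        file.path(outdir, sprintf("venn_%s.json", m)))
    }
  }
  method_comparison <- if (length(methods) >= 2) {
    method_consensus_comparison(consensus)
  } else {
    NULL
  }

  summary <- pipeline_summary(metadata, factors, peaks, ids)
  if (!is.null(outdir)) {
    readr::write_tsv(summary, file.path(outdir, "summary.tsv"),
                     progress = FALSE)
  }
  structure(list(summary = summary, factors = factors, peaks = peaks,
                 partitions = partitions, consensus = consensus,
                 method_comparison = method_comparison,
                 tracks = tracks_last, metadata = metadata, seed = seed),
            class = "spikenorm_pipeline")
}

derive_seed <- function(seed, method, sample_id) {
  # deterministic, distinct per (method, sample); kept within 32-bit range
  key <- sum(utf8ToInt(paste(method, sample_id, sep = "/")) *
               seq_along(utf8ToInt(paste(method, sample_id, sep = "/"))))
  (as.integer(seed) * 10007L + key) %% 2147483647L
}

pipeline_summary <- function(metadata, factors, peaks, ids) {
  rows <- list(
    tibble(quantity = "unique_sample_reads",
           !!!setNames(as.list(as.numeric(metadata$unique_sample_reads)), ids)),
    tibble(quantity = "unique_spikein_reads",
           !!!setNames(as.list(as.numeric(metadata$unique_spikein_reads)), ids))
  )
  for (m in names(factors)) {
    ret <- setNames(factors[[m]]$expected_retained_reads,
                    factors[[m]]$sample_id)
    rows <- c(rows, list(
      tibble(quantity = paste0("reads_after_", m),
             !!!setNames(as.list(as.numeric(ret[ids])), ids)),
      tibble(quantity = paste0("peaks_", m),
             !!!setNames(as.list(vapply(ids, function(id)
               as.numeric(nrow(peaks[[m]][[id]])), 1.0)), ids))
    ))
  }
  bind_rows(rows)
}

#' @export
print.spikenorm_pipeline <- function(x, ...) {
  cat(sprintf("<spikenorm_pipeline> %d samples, methods: %s\n",
              nrow(x$metadata), paste(names(x$factors), collapse = ", ")))
  print(x$summary)
  invisible(x)
}

#' @describeIn run_pipeline `glance()` returns one row per method with
#'   consensus and exclusive region counts.
#' @param x A `spikenorm_pipeline`.
#' @param ... Unused.
#' @export
glance.spikenorm_pipeline <- function(x, ...) {
  purrr::map_dfr(names(x$partitions), function(m) {
    g <- glance(x$partitions[[m]])
    g$method <- m
    g[, c("method", setdiff(names(g), "method"))]
  })
}
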