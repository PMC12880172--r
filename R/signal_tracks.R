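#' Windowed coverage track from aligned reads
#'
#' Counts reads in fixed-width windows across the genome. Under the default
#' `"overlap"` rule the value of a window is the number of reads overlapping
#' it by at least one base (interval-overlap convention, matching per-bin
#' coverage semantics of standard track tools; a read spanning a window
#' boundary increments both windows). Under the `"start"` rule each read is
#' assigned once, to the window holding its 5' end (tag-count semantics, the
#' appropriate input for Poisson peak calling since window values are then
#' counts of independent read events). Windows tile each contig from 0 in
#' steps of `window_width`; the last window is truncated at the contig end,
#' giving `ceiling(length / window_width)` windows per contig.
#'
#' @param alignments Alignment tibble (or SAM/BAM path); duplicate-flagged
#'   reads are excluded.
#' @param chrom_lengths Named vector of contig lengths (bp). Reads on contigs
#'   absent from it raise an error; reads running past a declared contig end
#'   are clipped with a warning.
#' @param window_width Window size in bp (default 20).
#' @param extend_to Optional fragment extension: each read is extended to this
#'   length in its 3' direction before counting. `NULL` (default) counts the
#'   read as aligned.
#' @param count_rule `"overlap"` (default) or `"start"`; see Details.
#' @return A tibble of class `signal_track` with columns `chrom`, `start`,
#'   `end`, `score`, dense over all windows. Attributes: `window_width`,
#'   `chrom_lengths`, `scale` (`"raw"`), `n_reads` (reads counted).
#' @export
windowed_coverage <- function(alignments, chrom_lengths, window_width = 20L,
                              extend_to = NULL,
                              count_rule = c("overlap", "start")) {
  count_rule <- match.arg(count_rule)
  aln <- as_alignments(alignments)
  stopifnot(window_width >= 1, !is.null(names(chrom_lengths)))
  aln <- aln[!aln$is_duplicate, ]
  bad <- setdiff(unique(aln$chrom), names(chrom_lengths))
  if (length(bad) > 0) {
    abort(paste0("reads on contig(s) absent from chrom_lengths: ",
                 paste(bad, collapse = ", ")),
          class = "spikenorm_classification_error")
  }
  if (!is.null(extend_to)) {
    len <- aln$end - aln$start
    grow <- pmax(extend_to - len, 0L)
    aln$end <- ifelse(aln$strand == "-", aln$end, aln$end + grow)
    aln$start <- ifelse(aln$strand == "-", aln$start - grow, aln$start)
    aln$start <- pmax(aln$start, 0L)
  }
  w <- as.integer(window_width)
  pieces <- lapply(names(chrom_lengths), function(ct) {
    len <- as.integer(chrom_lengths[[ct]])
    nw <- as.integer(ceiling(len / w))
    sub <- aln[aln$chrom == ct, ]
    score <- numeric(nw)
    if (nrow(sub) > 0) {
      if (any(sub$end > len)) {
        warn(sprintf("%d read(s) on %s extend past the contig end; clipped",
                     sum(sub$end > len), ct))
        sub$end <- pmin(sub$end, len)
      }
      sub <- sub[sub$end > sub$start, ]
      if (count_rule == "start") {
        pos5 <- ifelse(sub$strand == "-", sub$end - 1L, sub$start)
        score <- tabulate(pmin(pmax(pos5 %/% w, 0L), nw - 1L) + 1L,
                          nbins = nw)
      } else {
        # difference-array accumulation of "read overlaps window" counts
        wi_from <- pmax(sub$start %/% w, 0L) + 1L
        wi_to <- pmin((sub$end - 1L) %/% w, nw - 1L) + 1L
        add <- tabulate(wi_from, nbins = nw + 1L)
        rem <- tabulate(wi_to + 1L, nbins = nw + 1L)
        score <- cumsum(add - rem)[seq_len(nw)]
      }
    }
    tibble(chrom = ct,
           start = (seq_len(nw) - 1L) * w,
           end = pmin(seq_len(nw) * w, len),
           score = score)
  })
  new_signal_track(bind_rows(pieces), window_width = w,
                   chrom_lengths = chrom_lengths, scale = "raw",
                   n_reads = nrow(aln), count_rule = count_rule)
}

new_signal_track <- function(tbl, window_width, chrom_lengths, scale,
                             n_reads = NA_integer_, count_rule = "overlap") {
  structure(as_tibble(tbl),
            class = c("signal_track", class(tibble())),
            window_width = as.integer(window_width),
            chrom_lengths = chrom_lengths,
            scale = scale,
            n_reads = n_reads,
            count_rule = count_rule)
}

#' @export
print.signal_track <- function(x, ...) {
  cat(sprintf("<signal_track> %d windows of %d bp on %d contig(s), scale = %s\n",
              nrow(x), attr(x, "window_width"),
              length(attr(x, "chrom_lengths")), attr(x, "scale")))
  NextMethod()
}

#' Scale a raw track to counts per million
#'
#' Multiplies every window value by `1e6 / total_reads`. This is the CPM
#' display normalization: it rescales signal for cross-sample visualization
#' and never changes which reads are present.
#'
#' @param track A raw `signal_track`.
#' @param total_reads The sample's total read count (> 0). Defaults to the
#'   number of reads the track was built from.
#' @return The track with scaled values and `scale = "cpm"`.
#' @export
apply_cpm <- function(track, total_reads = attr(track, "n_reads")) {
  stopifnot(inherits(track, "signal_track"))
  k <- cpm_scale_factor(total_reads)
  out <- track
  out$score <- out$score * k
  attr(out, "scale") <- "cpm"
  out
}

#' Peak-centered signal matrix
#'
#' Extracts track values on a fixed grid around each peak center, producing
#' the peaks-by-positions matrix behind heatmaps, average-intensity profiles
#' and cross-sample scatterplots. Column `j` (1-based) holds the track value
#' at `center - flank + (j - 1) * step`, giving `2 * flank / step` columns.
#' Peaks whose flank runs off the contig get zero padding and are flagged.
#'
#' @param track A `signal_track`.
#' @param peaks Peak tibble with `chrom`, `start`, `end` and optionally
#'   `summit` (used as the center when present, else the midpoint).
#' @param flank Half-width of the extracted region in bp (default 2000).
#' @param step Grid spacing in bp (default the track's window width).
#' @return An object of class `signal_matrix`: list with `values` (matrix),
#'   `peaks` (tibble, row order matches), `flank`, `step`, `clipped` (logical
#'   vector flagging padded rows).
#' @export
peak_signal_matrix <- function(track, peaks, flank = 2000L,
                               step = attr(track, "window_width")) {
  stopifnot(inherits(track, "signal_track"))
  peaks <- as_tibble(peaks)
  w <- attr(track, "window_width")
  lens <- attr(track, "chrom_lengths")
  bad <- setdiff(unique(peaks$chrom), names(lens))
  if (length(bad) > 0) {
    abort(paste0("peaks on contig(s) absent from the track: ",
                 paste(bad, collapse = ", ")),
          class = "spikenorm_classification_error")
  }
  ncol <- as.integer(2L * flank / step)
  center <- if ("summit" %in% names(peaks)) {
    as.numeric(peaks$summit)
  } else {
    floor((peaks$start + peaks$end) / 2)
  }
  # per-contig window value lookup
  values <- matrix(0, nrow = nrow(peaks), ncol = ncol)
  clipped <- logical(nrow(peaks))
  offsets <- -flank + (seq_len(ncol) - 1L) * step
  for (ct in unique(peaks$chrom)) {
    scores <- track$score[track$chrom == ct]
    nw <- length(scores)
    rows <- which(peaks$chrom == ct)
    pos <- outer(center[rows], offsets, `+`)
    wi <- pos %/% w + 1L
    ok <- wi >= 1L & wi <= nw
    vals <- matrix(0, nrow = length(rows), ncol = ncol)
    vals[ok] <- scores[wi[ok]]
    values[rows, ] <- vals
    clipped[rows] <- rowSums(!ok) > 0
  }
  if (any(clipped)) {
    inform(sprintf("%d peak(s) closer than %d bp to a contig edge; padded with zeros",
                   sum(clipped), as.integer(flank)))
  }
  structure(list(values = values, peaks = peaks, flank = as.integer(flank),
                 step = as.integer(step), clipped = clipped),
            class = "signal_matrix")
}

#' @export
print.signal_matrix <- function(x, ...) {
  cat(sprintf("<signal_matrix> %d peaks x %d positions (flank %d bp, step %d bp)\n",
              nrow(x$values), ncol(x$values), x$flank, x$step))
  invisible(x)
}

#' @describeIn peak_signal_matrix `tidy()` returns one row per peak-position
#'   pair (`peak`, `position` relative to center, `signal`) plus the per-peak
#'   total over the flank (`peak_total`), the quantity used in cross-sample
#'   scatterplots.
#' @param x A `signal_matrix`.
#' @param ... Unused.
#' @export
tidy.signal_matrix <- function(x, ...) {
  totals <- rowSums(x$values)
  long <- tidyr::expand_grid(
    peak = seq_len(nrow(x$values)),
    position = -x$flank + (seq_len(ncol(x$values)) - 1L) * x$step
  )
  long$signal <- as.vector(t(x$values))
  long$peak_total <- totals[long$peak]
  long
}

#' Per-peak total signal over the flank
#'
#' @param x A `signal_matrix`.
#' @return Tibble with peak coordinates and `peak_total`.
#' @export
peak_totals <- function(x) {
  stopifnot(inherits(x, "signal_matrix"))
  out <- x$peaks
  out$peak_total <- rowSums(x$values)
  as_tibble(out)
}

#' Write / read a signal track as bedGraph
#'
#' Zero-valued windows are dropped on output (bedGraph convention); on input
#' they are restored as zeros, so a round trip reproduces the dense track.
#'
#' @param track A `signal_track`.
#' @param path Output path.
#' @return `path` (write) / a `signal_track` (read), invisibly for write.
#' @export
write_bedgraph <- function(track, path) {
  stopifnot(inherits(track, "signal_track"))
  gr <- GenomicRanges::GRanges(
    seqnames = track$chrom,
    ranges = IRanges::IRanges(start = track$start + 1L, end = track$end),
    score = track$score,
    seqlengths = vapply(attr(track, "chrom_lengths"), as.integer, 1L)
  )
  gr <- gr[gr$score != 0]
  rtracklayer::export.bedGraph(gr, path)
  invisible(path)
}

#' @rdname write_bedgraph
#' @param chrom_lengths Named contig lengths for the restored track.
#' @param window_width Window width of the stored track.
#' @export
read_bedgraph <- function(path, chrom_lengths, window_width = 20L) {
  gr <- rtracklayer::import.bedGraph(path)
  tbl <- tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    score = gr$score
  )
  w <- as.integer(window_width)
  pieces <- lapply(names(chrom_lengths), function(ct) {
    len <- as.integer(chrom_lengths[[ct]])
    nw <- as.integer(ceiling(len / w))
    score <- numeric(nw)
    sub <- tbl[tbl$chrom == ct, ]
    if (nrow(sub) > 0) score[sub$start %/% w + 1L] <- sub$score
    tibble(chrom = ct, start = (seq_len(nw) - 1L) * w,
           end = pmin(seq_len(nw) * w, len), score = score)
  })
  new_signal_track(bind_rows(pieces), window_width = w,
                   chrom_lengths = chrom_lengths, scale = "raw")
}

#' Read a chrom.sizes file
#'
#' @param path Two-column TSV: contig name, length in bp.
#' @return Named integer vector of contig lengths.
#' @export
read_chrom_sizes <- function(path) {
  tbl <- readr::read_tsv(path, col_names = c("chrom", "length"),
                         show_col_types = FALSE, progress = FALSE)
  setNames(as.integer(tbl$length), tbl$chrom)
}
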