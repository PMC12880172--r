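#' Minimal Poisson peak caller
#'
#' Calls enriched regions on a raw windowed coverage track with a
#' threshold-style model: a `peak_width`-bp window slides across the genome in
#' steps of one coverage bin; a position is a candidate when its summed bin
#' counts reach `fold_min` times the global background expectation AND the
#' Poisson upper tail at that expectation is at most `p_max`. Overlapping
#' candidate windows are merged into one peak; the summit is the bin of
#' maximum coverage inside the merged region.
#'
#' The global background rate is `sum(track) / n_windows` per bin (uniform
#' background; no input-chromatin or local-lambda correction). No
#' multiple-testing correction is applied: like threshold-style callers the
#' cutoff is a fixed per-test `p_max`, and the expected number of
#' false-positive tests (`attr(,"expected_fp_tests")`) is reported instead.
#'
#' @param track A raw `signal_track` (integer counts).
#' @param peak_width Sliding-window width in bp (default 200).
#' @param fold_min Minimum fold enrichment over background (default 4).
#' @param p_max Poisson upper-tail cutoff per tested window (default 1e-4).
#' @return Peak tibble: `chrom`, `start`, `end` (0-based half-open), `summit`
#'   (bp of maximum signal), `score` (fold enrichment of the best window),
#'   `p_value` (Poisson upper tail of the best window). Attributes record the
#'   background rate and the effective count threshold.
#' @export
call_peaks <- function(track, peak_width = 200L, fold_min = 4,
                       p_max = 1e-4) {
  stopifnot(inherits(track, "signal_track"))
  if (!identical(attr(track, "scale"), "raw")) {
    abort("call_peaks needs a raw-count track", class = "spikenorm_parameter_error")
  }
  w <- attr(track, "window_width")
  nbin <- max(1L, as.integer(round(peak_width / w)))
  empty <- tibble(chrom = character(), start = integer(), end = integer(),
                  summit = integer(), score = numeric(), p_value = numeric())
  if (nrow(track) == 0 || sum(track$score) == 0) {
    if (nrow(track) > 0 && sum(track$score) == 0) {
      abort("background rate is zero; cannot call peaks",
            class = "spikenorm_degenerate_background_error")
    }
    return(empty)
  }
  lambda_bin <- sum(track$score) / nrow(track)
  mu <- lambda_bin * nbin
  # effective integer count threshold: both the fold and the tail condition
  threshold <- max(ceiling(fold_min * mu), qpois(p_max, mu, lower.tail = FALSE) + 1)
  contigs <- unique(track$chrom)
  pieces <- lapply(contigs, function(ct) {
    v <- track$score[track$chrom == ct]
    nw <- length(v)
    if (nw < nbin) return(NULL)
    cs <- c(0, cumsum(v))
    ssum <- cs[(nbin + 1):(nw + 1)] - cs[1:(nw - nbin + 1)]
    cand <- which(ssum >= fold_min * mu &
                    ppois(ssum - 1, mu, lower.tail = FALSE) <= p_max)
    if (length(cand) == 0) return(NULL)
    ir <- IRanges::reduce(IRanges::IRanges(start = cand, width = nbin))
    starts <- IRanges::start(ir)
    ends <- IRanges::end(ir)
    nr <- length(starts)
    summit_bin <- integer(nr)
    best <- numeric(nr)
    for (k in seq_len(nr)) {
      bins <- starts[k]:ends[k]
      summit_bin[k] <- bins[which.max(v[bins])]
      best[k] <- max(ssum[starts[k]:min(ends[k] - nbin + 1L, length(ssum))])
    }
    tibble(
      chrom = ct,
      start = (starts - 1L) * w,
      end = ends * w,
      summit = as.integer((summit_bin - 1L) * w + w %/% 2L),
      score = best / mu,
      p_value = ppois(best - 1, mu, lower.tail = FALSE)
    )
  })
  out <- bind_rows(pieces)
  if (nrow(out) == 0) out <- empty
  n_tests <- sum(pmax(table(track$chrom)[contigs] - nbin + 1, 0))
  structure(arrange(out, match(.data$chrom, contigs), .data$start),
            background_per_bin = lambda_bin,
            count_threshold = threshold,
            n_tests = as.integer(n_tests),
            expected_fp_tests = n_tests *
              ppois(threshold - 1, mu, lower.tail = FALSE))
}

#' Write / read peak files (BED6 or ENCODE narrowPeak)
#'
#' @param peaks Peak tibble as produced by [call_peaks()].
#' @param path Output path.
#' @param format `"narrowPeak"` (10 columns; summit stored as the relative
#'   offset in column 10) or `"bed"` (6 columns).
#' @return `path` (write) / peak tibble (read).
#' @export
write_peaks <- function(peaks, path, format = c("narrowPeak", "bed")) {
  format <- match.arg(format)
  peaks <- as_tibble(peaks)
  name <- sprintf("peak_%d", seq_len(nrow(peaks)))
  score1k <- as.integer(pmin(round(10 * (peaks$score %||% 0)), 1000))
  if (format == "bed") {
    tbl <- tibble(peaks$chrom, peaks$start, peaks$end, name, score1k, ".")
  } else {
    p <- peaks$p_value %||% rep(NA_real_, nrow(peaks))
    tbl <- tibble(peaks$chrom, peaks$start, peaks$end, name, score1k, ".",
                  signif(peaks$score %||% 0, 6),
                  signif(-log10(pmax(p, 1e-300)), 6),
                  -1,
                  as.integer((peaks$summit %||% floor((peaks$start + peaks$end) / 2)) -
                               peaks$start))
  }
  readr::write_tsv(tbl, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' @rdname write_peaks
#' @export
read_peaks <- function(path) {
  tbl <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE,
                         progress = FALSE)
  out <- tibble(chrom = as.character(tbl$X1),
                start = as.integer(tbl$X2),
                end = as.integer(tbl$X3))
  if (ncol(tbl) >= 10) {
    out$summit <- out$start + as.integer(tbl$X10)
    out$score <- as.numeric(tbl$X7)
    out$p_value <- 10^(-as.numeric(tbl$X8))
  } else if (ncol(tbl) >= 5) {
    out$score <- as.numeric(tbl$X5)
  }
  out
}
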