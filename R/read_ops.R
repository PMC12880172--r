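#' Read aligned reads from SAM/BAM into a tibble
#'
#' Loads mapped, primary alignments into the flat alignment table the rest of
#' the package operates on. Coordinates are converted to the 0-based half-open
#' convention used throughout (`start` inclusive, `end` exclusive).
#'
#' @param path A SAM or BAM file.
#' @return A tibble with columns `qname`, `chrom`, `start`, `end`, `strand`
#'   (`"+"`/`"-"`), `is_duplicate`, `is_paired`.
#' @export
read_alignments <- function(path) {
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  }
  param <- Rsamtools::ScanBamParam(
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE),
    what = c("qname", "flag")
  )
  ga <- GenomicAlignments::readGAlignments(bam, param = param)
  mc <- S4Vectors::mcols(ga)
  tibble(
    qname = as.character(mc$qname),
    chrom = as.character(GenomicAlignments::seqnames(ga)),
    start = GenomicAlignments::start(ga) - 1L,
    end = GenomicAlignments::end(ga),
    strand = as.character(GenomicAlignments::strand(ga)),
    is_duplicate = bitwAnd(mc$flag, 1024L) > 0L,
    is_paired = bitwAnd(mc$flag, 1L) > 0L
  )
}

#' Write an alignment tibble as SAM
#'
#' Emits a minimal valid single-end SAM file (header `@SQ` lines from
#' `chrom_lengths`, one `M`-only CIGAR per record, `*` sequence). This is the
#' sink used by the simulator and the downsampler; records round-trip through
#' [read_alignments()].
#'
#' @param alignments An alignment tibble (see [read_alignments()]).
#' @param path Output `.sam` path.
#' @param chrom_lengths Named vector of contig lengths (bp).
#' @return `path`, invisibly.
#' @export
write_alignments <- function(alignments, path, chrom_lengths) {
  stopifnot(is.data.frame(alignments), !is.null(names(chrom_lengths)))
  header <- c(
    "@HD\tVN:1.6\tSO:coordinate",
    sprintf("@SQ\tSN:%s\tLN:%d", names(chrom_lengths),
            as.integer(chrom_lengths))
  )
  aln <- dplyr::arrange(alignments,
                        match(.data$chrom, names(chrom_lengths)), .data$start)
  flag <- ifelse(aln$strand == "-", 16L, 0L) +
    ifelse(aln$is_duplicate, 1024L, 0L)
  body <- sprintf("%s\t%d\t%s\t%d\t%d\t%dM\t*\t0\t0\t*\t*",
                  aln$qname, flag, aln$chrom, aln$start + 1L, 60L,
                  aln$end - aln$start)
  readr::write_lines(c(header, body), path)
  invisible(path)
}

#' Classify reads by genome of origin and count them
#'
#' Reproduces the count hierarchy of a dual-genome spike-in experiment:
#' total records, mapped records, and deduplicated ("unique") read counts per
#' genome. Classification uses only the contig namespace — either two separate
#' alignment sets (one per genome) or one composite-genome set in which
#' spike-in contigs carry a name prefix.
#'
#' "Unique reads" are mapped, primary, non-duplicate alignments, counted in
#' read units (not fragments). If no record carries a duplicate flag the
#' counts proceed treating all reads as non-duplicate, with a warning.
#'
#' @param alignments Alignment tibble (or SAM/BAM path) for the experimental
#'   genome, or a composite-genome alignment covering both.
#' @param spike_alignments Optional second alignment tibble (or path) holding
#'   the spike-in genome alignment. When supplied, all its contigs are taken
#'   as spike-in.
#' @param spike_prefix Contig-name prefix identifying spike-in contigs in a
#'   composite alignment (default `"spikein_"`). Ignored when
#'   `spike_alignments` is given.
#' @return A one-row tibble: `total`, `mapped`, `unique_sample`,
#'   `unique_spikein`.
#' @examples
#' aln <- tibble::tibble(
#'   qname = paste0("r", 1:6),
#'   chrom = c("chr1", "chr1", "chr1", "chr1", "spikein_2L", "spikein_2L"),
#'   start = c(0, 40, 80, 0, 10, 50), end = c(50, 90, 130, 50, 60, 100),
#'   strand = "+", is_duplicate = c(FALSE, FALSE, FALSE, TRUE, FALSE, FALSE),
#'   is_paired = FALSE
#' )
#' classify_and_count(aln)
#' @export
classify_and_count <- function(alignments, spike_alignments = NULL,
                               spike_prefix = "spikein_") {
  aln <- as_alignments(alignments)
  if (!is.null(spike_alignments)) {
    spk <- as_alignments(spike_alignments)
    aln$.origin <- "sample"
    spk$.origin <- "spikein"
    aln <- bind_rows(aln, spk)
  } else {
    aln$.origin <- ifelse(startsWith(aln$chrom, spike_prefix),
                          "spikein", "sample")
  }
  if (nrow(aln) == 0) {
    return(tibble(total = 0L, mapped = 0L, unique_sample = 0L,
                  unique_spikein = 0L))
  }
  if (!any(aln$is_duplicate)) {
    warn("no duplicate-flagged reads found; counting all reads as non-duplicate")
  }
  uniq <- aln[!aln$is_duplicate, ]
  tibble(
    total = nrow(aln),
    mapped = nrow(aln),
    unique_sample = sum(uniq$.origin == "sample"),
    unique_spikein = sum(uniq$.origin == "spikein")
  )
}

as_alignments <- function(x) {
  if (is.character(x) && length(x) == 1) x <- read_alignments(x)
  stopifnot(is.data.frame(x))
  as_tibble(x)
}

#' Seeded fractional downsampling of reads
#'
#' Retains each read independently with probability `nf`, using a
#' deterministic hash of the read name salted with `seed`: identical
#' `(input, nf, seed)` always yields the identical retained set, and the
#' decision does not depend on record order. With `pair_consistent = TRUE`
#' both mates of a pair (which share a read name) necessarily receive the same
#' decision, so no orphaned mates are created. The retained count is
#' distributed Binomial(N, nf). `nf = 1` returns the input unchanged.
#'
#' @param alignments Alignment tibble (or SAM/BAM path).
#' @param nf Retention fraction in (0, 1].
#' @param seed Integer seed for the retention hash.
#' @param pair_consistent Retained for interface clarity; retention is always
#'   name-keyed, which is intrinsically pair-consistent.
#' @return The retained alignment tibble, with attribute `retained` (count).
#' @export
downsample_reads <- function(alignments, nf, seed = 1L,
                             pair_consistent = TRUE) {
  aln <- as_alignments(alignments)
  check_nf(nf)
  if (nf == 1) {
    attr(aln, "retained") <- nrow(aln)
    return(aln)
  }
  keep <- .retain_by_name(aln$qname, nf, as.double(seed))
  out <- aln[keep, ]
  attr(out, "retained") <- nrow(out)
  out
}

#' Retained-read count of the downsampler at arbitrary scale
#'
#' Applies exactly the retention rule of [downsample_reads()] to `n` synthetic
#' read names and returns how many survive. This exercises the downsampling
#' statistics at full experimental scale (tens of millions of reads) without
#' materializing an alignment table.
#'
#' @param n Number of reads.
#' @param nf Retention fraction in (0, 1].
#' @param seed Integer seed.
#' @return The retained count (length-1 numeric).
#' @examples
#' downsample_count(1e5, 0.5, seed = 7)
#' @export
downsample_count <- function(n, nf, seed = 1L) {
  check_nf(nf)
  stopifnot(length(n) == 1, n >= 0)
  if (nf == 1) return(as.numeric(n))
  .retained_count_synthetic(as.double(n), nf, as.double(seed))
}

check_nf <- function(nf) {
  if (length(nf) != 1 || !is.finite(nf) || nf <= 0 || nf > 1) {
    abort("nf must be a single value in (0, 1]",
          class = "spikenorm_parameter_error")
  }
  invisible(nf)
}
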