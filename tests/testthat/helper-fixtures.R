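# Shared fixtures: the bench-table metadata, tiny alignment builders, a small
# simulation config, and the brute-force overlap oracle used to cross-check
# the interval machinery.

bench_metadata <- function() {
  sample_stats(data.frame(
    sample_id = c("rep1", "rep2", "rep3"),
    unique_sample_reads = c(4190041, 23728210, 22990981),
    unique_spikein_reads = c(142086, 268064, 319773),
    input_conc_ng_per_ul = c(29.6, 17.3, 35.6),
    input_volume_ul = 20,
    spikein_mass_ng = 62.5
  ))
}

make_aln <- function(chrom, start, end = start + 50L, strand = "+",
                     dup = FALSE, qname = NULL) {
  n <- length(chrom)
  tibble::tibble(
    qname = if (is.null(qname)) sprintf("r%d", seq_len(n)) else qname,
    chrom = chrom,
    start = as.integer(start),
    end = as.integer(rep_len(end, n)),
    strand = rep_len(strand, n),
    is_duplicate = rep_len(dup, n),
    is_paired = FALSE
  )
}

# uniform random single-end reads over one contig
random_aln <- function(n, len = 100000L, read_len = 50L, prefix = "r") {
  tibble::tibble(
    qname = sprintf("%s%07d", prefix, seq_len(n)),
    chrom = "chr1",
    start = as.integer(floor(runif(n) * (len - read_len))),
    end = NA_integer_,
    strand = sample(c("+", "-"), n, replace = TRUE),
    is_duplicate = FALSE,
    is_paired = FALSE
  ) |>
    dplyr::mutate(end = start + read_len)
}

small_sim_config <- function(seed = 1L, ...) {
  simulation_config(
    samples = tibble::tibble(
      sample_id = c("s1", "s2", "s3"),
      input_dna_mass_ng = c(592, 346, 712),
      spikein_mass_ng = 62.5,
      chip_efficiency = c(1, 0.245, 0.251),
      depth = c(8000L, 30000L, 29000L),
      duplicate_rate = 0.1
    ),
    sample_genome = c(chr1 = 1500000L, chr2 = 500000L),
    spike_genome = c(`2L` = 100000L),
    n_sites = 40L,
    hotspot_fraction = 0,
    seed = seed,
    ...
  )
}

# Brute-force Venn oracle: pairwise interval overlap + union-find over all
# peaks of all samples, fully independent of the GenomicRanges-based path.
brute_force_venn <- function(peak_sets) {
  ids <- names(peak_sets)
  all <- do.call(rbind, lapply(seq_along(peak_sets), function(i) {
    p <- peak_sets[[i]]
    data.frame(chrom = p$chrom, start = p$start, end = p$end, set = i)
  }))
  n <- nrow(all)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i] <<- parent[parent[i]]
    i
  }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i) next
      if (all$chrom[i] == all$chrom[j] &&
          all$start[i] < all$end[j] && all$start[j] < all$end[i]) {
        parent[find(i)] <- find(j)
      }
    }
  }
  roots <- vapply(seq_len(n), find, 1L)
  memb <- tapply(all$set, roots, function(s) {
    paste(ids[sort(unique(s))], collapse = "+")
  })
  counts <- table(unlist(memb))
  out <- as.integer(counts)
  names(out) <- names(counts)
  out
}

venn_as_vector <- function(partition) {
  v <- partition$venn_counts
  out <- as.integer(v$n)
  # canonicalize membership labels so sample-order permutations compare equal
  names(out) <- vapply(strsplit(v$membership, "+", fixed = TRUE),
                       function(p) paste(sort(p), collapse = "+"), "")
  out[order(names(out))]
}
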