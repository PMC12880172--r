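#' Configuration for a dual-genome spike-in ChIP-seq simulation
#'
#' Builds the parameter set for [simulate_experiment()]. The generative model
#' mirrors the structure of a triplicate tissue ChIP-seq experiment with a
#' fixed exogenous spike-in: per sample \eqn{i}, immunoprecipitated material
#' is a mixture of three pools whose weights are
#'
#' * specific sample signal: \eqn{e_i \cdot C_{m,i}} (split across binding
#'   sites proportionally to site intensity),
#' * nonspecific sample background: \eqn{\beta \cdot C_{m,i}} (mostly uniform
#'   over the experimental genome, with a small fraction concentrated in
#'   sample-specific artifact hotspots — the sticky regions that surface as
#'   irreproducible peaks when many background reads are retained),
#' * spike-in: \eqn{e_i \cdot h \cdot C_{d,i}} (uniform over the spike-in
#'   genome),
#'
#' where \eqn{C_{m,i}} is the input chromatin mass (ng), \eqn{C_{d,i}} the
#' spike-in chromatin mass (ng), \eqn{e_i} the ChIP capture efficiency —
#' which scales the specific capture of *both* genomes equally, the core
#' spike-in assumption — and \eqn{\beta}, \eqn{h} global nonspecific and
#' spike-capture rates. Reads are drawn multinomially from the three pools at
#' the configured sequencing depth; input chromatin amount enters only the
#' sample-side pools. Under this model the sample/spike-in read ratio is
#' \eqn{X_i/S_i = (C_{m,i}/C_{d,i}) (e_i b + \beta)/(e_i h)}: unequal input
#' masses and unequal efficiencies both distort it, which is exactly what
#' input-adjusted spike-in normalization corrects.
#'
#' Defaults emulate the bench-table structure of a real triplicate tissue
#' experiment: three samples with unequal input chromatin mass (592, 346,
#' 712 ng), equal spike-in mass (62.5 ng each), unequal ChIP enrichment
#' efficiency, and unequal sequencing depth, with the deeply sequenced
#' replicates being the poorly enriched ones (the pattern observed in real
#' tissue data). Depths are the real triplicate's unique read counts scaled
#' down 100x to desk scale.
#'
#' @param samples Tibble with one row per sample: `sample_id`,
#'   `input_dna_mass_ng`, `spikein_mass_ng`, `chip_efficiency` in (0, 1],
#'   `depth` (reads emitted), `duplicate_rate` in [0, 1).
#' @param sample_genome,spike_genome Named vectors of contig lengths (bp).
#'   Spike-in contigs are automatically prefixed with `spike_prefix` in the
#'   composite output.
#' @param n_sites Number of planted binding sites.
#' @param site_width Width of each site (bp).
#' @param site_intensity_meanlog,site_intensity_sdlog Log-normal parameters of
#'   the site intensity (relative pull-down weight; clamped to > 1).
#' @param background_rate Nonspecific capture rate \eqn{\beta} per ng of
#'   sample chromatin, relative to specific capture at efficiency 1.
#' @param n_hotspots,hotspot_fraction,hotspot_width,hotspot_sdlog Background
#'   hotspot model: `hotspot_fraction` of each sample's background reads fall
#'   in `n_hotspots` sample-specific artifact regions of `hotspot_width` bp
#'   with log-normal weights (sdlog `hotspot_sdlog`); the rest of the
#'   background is uniform. Set `hotspot_fraction = 0` for a purely uniform
#'   background.
#' @param spike_capture_rate Spike-in capture rate \eqn{h} per ng of spike-in
#'   chromatin at efficiency 1.
#' @param read_length Read length (bp).
#' @param min_gap Minimum gap between planted sites (bp); keeps peak-calling
#'   truth unambiguous.
#' @param spike_prefix Contig-name prefix marking spike-in contigs.
#' @param seed Integer seed; the whole simulation is reproducible from it.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(
    samples = tibble(
      sample_id = c("rep1", "rep2", "rep3"),
      input_dna_mass_ng = c(592, 346, 712),
      spikein_mass_ng = 62.5,
      chip_efficiency = c(1, 0.245, 0.251),
      depth = c(42000L, 237000L, 230000L),
      duplicate_rate = 0.1
    ),
    sample_genome = c(chr1 = 24000000L, chr2 = 16000000L),
    spike_genome = c(`2L` = 200000L),
    n_sites = 500L,
    site_width = 200L,
    site_intensity_meanlog = log(1.5),
    site_intensity_sdlog = 1.2,
    background_rate = 0.82,
    spike_capture_rate = 0.59,
    n_hotspots = 2000L,
    hotspot_fraction = 0.02,
    hotspot_width = 200L,
    hotspot_sdlog = 0.35,
    read_length = 50L,
    min_gap = 2000L,
    spike_prefix = "spikein_",
    seed = 1L) {
  samples <- as_tibble(samples)
  stopifnot(
    all(c("sample_id", "input_dna_mass_ng", "spikein_mass_ng",
          "chip_efficiency", "depth", "duplicate_rate") %in% names(samples)),
    all(samples$input_dna_mass_ng > 0), all(samples$spikein_mass_ng > 0),
    all(samples$chip_efficiency > 0), all(samples$chip_efficiency <= 1),
    all(samples$duplicate_rate >= 0), all(samples$duplicate_rate < 1),
    n_sites >= 1, site_width > read_length, background_rate >= 0,
    spike_capture_rate > 0, hotspot_fraction >= 0, hotspot_fraction < 1,
    n_hotspots >= 0
  )
  out <- structure(list(
    samples = samples, sample_genome = sample_genome,
    spike_genome = spike_genome, n_sites = as.integer(n_sites),
    site_width = as.integer(site_width),
    site_intensity_meanlog = site_intensity_meanlog,
    site_intensity_sdlog = site_intensity_sdlog,
    background_rate = background_rate,
    spike_capture_rate = spike_capture_rate,
    n_hotspots = as.integer(n_hotspots),
    hotspot_fraction = hotspot_fraction,
    hotspot_width = as.integer(hotspot_width),
    hotspot_sdlog = hotspot_sdlog,
    read_length = as.integer(read_length), min_gap = as.integer(min_gap),
    spike_prefix = spike_prefix, seed = as.integer(seed)
  ), class = "simulation_config")
  validate_config(out)
  out
}

validate_config <- function(cfg) {
  if (any(cfg$samples$depth < cfg$n_sites)) {
    abort("config infeasible: depth below the number of sites",
          class = "spikenorm_config_error")
  }
  if (cfg$n_sites * (cfg$site_width + cfg$min_gap) >
        sum(as.numeric(cfg$sample_genome))) {
    abort("config infeasible: sites do not fit the genome at the minimum gap",
          class = "spikenorm_config_error")
  }
  invisible(cfg)
}

#' Simulate a dual-genome spike-in ChIP-seq experiment
#'
#' Draws already-aligned reads for every sample under the generative model of
#' [simulation_config()] and returns them together with the ground truth
#' needed to score every downstream method. Reads are emitted as alignment
#' tibbles on a composite genome (spike-in contigs prefixed); duplicates are
#' injected as flagged coordinate-copies of existing reads, mimicking
#' upstream duplicate marking. Identical config (including its seed) gives
#' identical output.
#'
#' @param config A `simulation_config`.
#' @param dir Optional directory; when given, per-sample SAM files, a
#'   metadata TSV and a truth JSON are written there.
#' @return A list of class `simulation`: `alignments` (named list of
#'   composite-genome alignment tibbles), `truth` (list: `sites` tibble,
#'   `weights` tibble of per-sample pool weights and expected shares,
#'   realized counts), `metadata` (a [sample_stats] tibble with realized
#'   unique read counts), `chrom_lengths` (composite), `config`.
#' @export
simulate_experiment <- function(config, dir = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  validate_config(config)
  set.seed(config$seed)
  cfg <- config
  spike_names <- paste0(cfg$spike_prefix, names(cfg$spike_genome))
  chrom_lengths <- c(cfg$sample_genome,
                     setNames(as.integer(cfg$spike_genome), spike_names))

  sites <- place_sites(cfg)
  site_weight <- sites$intensity / sum(sites$intensity)

  samples <- cfg$samples
  n_samp <- nrow(samples)
  weights <- tibble(
    sample_id = samples$sample_id,
    w_signal = samples$chip_efficiency * samples$input_dna_mass_ng,
    w_background = cfg$background_rate * samples$input_dna_mass_ng,
    w_spikein = samples$chip_efficiency * cfg$spike_capture_rate *
      samples$spikein_mass_ng
  )
  tot <- weights$w_signal + weights$w_background + weights$w_spikein
  weights$signal_share <- weights$w_signal / tot
  weights$background_share <- weights$w_background / tot
  weights$spikein_share <- weights$w_spikein / tot

  alignments <- vector("list", n_samp)
  names(alignments) <- samples$sample_id
  realized <- vector("list", n_samp)
  for (i in seq_len(n_samp)) {
    aln <- draw_sample_reads(cfg, sites, site_weight,
                             depth = samples$depth[i],
                             shares = c(weights$signal_share[i],
                                        weights$background_share[i],
                                        weights$spikein_share[i]),
                             dup_rate = samples$duplicate_rate[i],
                             prefix = samples$sample_id[i],
                             chrom_lengths = chrom_lengths,
                             spike_names = spike_names)
    alignments[[i]] <- aln
    uniq <- aln[!aln$is_duplicate, ]
    realized[[i]] <- tibble(
      sample_id = samples$sample_id[i],
      unique_sample_reads = sum(!uniq$chrom %in% spike_names),
      unique_spikein_reads = sum(uniq$chrom %in% spike_names)
    )
  }
  realized <- bind_rows(realized)
  metadata <- sample_stats(tibble(
    sample_id = samples$sample_id,
    unique_sample_reads = realized$unique_sample_reads,
    unique_spikein_reads = realized$unique_spikein_reads,
    input_dna_mass_ng = samples$input_dna_mass_ng,
    spikein_mass_ng = samples$spikein_mass_ng
  ))
  truth <- list(sites = sites, weights = weights, realized = realized)
  out <- structure(list(alignments = alignments, truth = truth,
                        metadata = metadata, chrom_lengths = chrom_lengths,
                        config = cfg),
                   class = "simulation")
  if (!is.null(dir)) write_simulation(out, dir)
  out
}

place_sites <- function(cfg) {
  # uniform non-overlapping placement with a minimum gap, per contig,
  # sites allocated to contigs proportional to length
  lens <- cfg$sample_genome
  n_per <- diff(round(cfg$n_sites * c(0, cumsum(lens) / sum(lens))))
  pieces <- purrr::map2(names(lens), n_per, function(ct, n) {
    if (n == 0) return(NULL)
    len <- lens[[ct]]
    slot <- cfg$site_width + cfg$min_gap
    if (n * slot > len) {
      abort("config infeasible: sites do not fit the genome at the minimum gap",
            class = "spikenorm_config_error")
    }
    # sorted uniform starts in the compressed coordinate space, then re-expanded
    free <- len - n * slot
    gaps <- sort(sample.int(free + 1, n, replace = TRUE) - 1L)
    start <- gaps + (seq_len(n) - 1L) * slot + cfg$min_gap %/% 2L
    tibble(chrom = ct, start = as.integer(start),
           end = as.integer(start + cfg$site_width))
  })
  sites <- bind_rows(pieces)
  sites$center <- as.integer((sites$start + sites$end) %/% 2)
  sites$intensity <- 1 + rlnorm(nrow(sites), cfg$site_intensity_meanlog,
                                cfg$site_intensity_sdlog)
  sites$site_id <- sprintf("site_%03d", seq_len(nrow(sites)))
  sites
}

draw_sample_reads <- function(cfg, sites, site_weight, depth, shares,
                              dup_rate, prefix, chrom_lengths, spike_names) {
  # `depth` counts emitted reads; a Binomial(depth, dup_rate) subset are
  # duplicates (flagged coordinate-copies of originals), so unique reads are
  # depth * (1 - dup_rate) in expectation
  n_dup <- rbinom(1, depth, dup_rate)
  n_orig <- depth - n_dup
  n_cat <- as.vector(rmultinom(1, n_orig, shares))
  L <- cfg$read_length

  # signal reads: site by intensity, start uniform within the site
  k <- sample.int(nrow(sites), n_cat[1], replace = TRUE, prob = site_weight)
  sig <- tibble(
    chrom = sites$chrom[k],
    start = sites$start[k] +
      as.integer(floor(runif(n_cat[1]) * (cfg$site_width - L + 1)))
  )

  uniform_reads <- function(n, genome, prefix_names = identity) {
    ct <- sample(names(genome), n, replace = TRUE,
                 prob = as.numeric(genome) / sum(as.numeric(genome)))
    tibble(chrom = prefix_names(ct),
           start = as.integer(floor(runif(n) * (genome[ct] - L + 1))))
  }
  # background: mostly uniform, a fraction in sample-specific artifact
  # hotspots whose apparent peaks surface only at high retained depth
  n_hot_reads <- if (cfg$hotspot_fraction > 0 && cfg$n_hotspots > 0) {
    rbinom(1, n_cat[2], cfg$hotspot_fraction)
  } else {
    0L
  }
  bg <- uniform_reads(n_cat[2] - n_hot_reads, cfg$sample_genome)
  if (n_hot_reads > 0) {
    hs <- uniform_reads(cfg$n_hotspots, cfg$sample_genome)
    hs_w <- rlnorm(cfg$n_hotspots, 0, cfg$hotspot_sdlog)
    j <- sample.int(cfg$n_hotspots, n_hot_reads, replace = TRUE,
                    prob = hs_w / sum(hs_w))
    hot <- tibble(
      chrom = hs$chrom[j],
      start = hs$start[j] +
        as.integer(floor(runif(n_hot_reads) *
                           max(cfg$hotspot_width - L + 1, 1)))
    )
    hot$start <- pmin(hot$start,
                      as.integer(cfg$sample_genome[hot$chrom]) - L)
    bg <- bind_rows(bg, hot)
  }
  spk <- uniform_reads(n_cat[3], cfg$spike_genome,
                       function(ct) paste0(cfg$spike_prefix, ct))

  aln <- bind_rows(sig, bg, spk)
  n <- nrow(aln)
  aln$end <- aln$start + L
  aln$strand <- sample(c("+", "-"), n, replace = TRUE)
  aln$is_duplicate <- FALSE
  aln$is_paired <- FALSE

  # duplicates: flagged coordinate-copies of randomly chosen originals
  if (n_dup > 0) {
    src <- sample.int(n, n_dup, replace = TRUE)
    dup <- aln[src, ]
    dup$is_duplicate <- TRUE
    aln <- bind_rows(aln, dup)
  }
  aln$qname <- sprintf("%s:r%07d", prefix, seq_len(nrow(aln)))
  aln[, c("qname", "chrom", "start", "end", "strand", "is_duplicate",
          "is_paired")]
}

write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (id in names(sim$alignments)) {
    write_alignments(sim$alignments[[id]],
                     file.path(dir, paste0(id, ".sam")),
                     sim$chrom_lengths)
  }
  readr::write_tsv(as_tibble(sim$metadata),
                   file.path(dir, "metadata.tsv"), progress = FALSE)
  jsonlite::write_json(
    list(sites = sim$truth$sites, weights = sim$truth$weights,
         realized = sim$truth$realized),
    file.path(dir, "truth.json"), digits = NA, auto_unbox = FALSE)
  invisible(dir)
}

#' Expected per-site signal under the generative model
#'
#' Closed-form expectation of the mean windowed coverage at a planted site,
#' per sample, after downsampling with a given factor set — the oracle behind
#' the cross-sample intensity comparisons. For a site of width \eqn{W},
#' intensity weight \eqn{\lambda_k}, a sample retaining
#' \eqn{N_i = f_i \cdot D_i \cdot signal\_share_i} signal reads, a window of
#' width \eqn{w} fully inside the site is overlapped by an expected
#' \eqn{N_i \frac{\lambda_k}{\sum\lambda} \cdot \frac{L + w - 1}{W - L + 1}}
#' reads (length-\eqn{L} reads placed uniformly in the site).
#'
#' @param truth The `truth` element of a [simulate_experiment()] result (the
#'   full `simulation` object is also accepted).
#' @param factors A `norm_factor_set` (or NULL for unnormalized raw counts).
#' @param window_width Coverage window width (bp).
#' @return Tibble: `sample_id`, `site_id`, `expected_window_signal`, plus the
#'   per-sample mean over sites (`sample_mean`, repeated per row).
#' @export
expected_site_signal <- function(truth, factors = NULL, window_width = 20L) {
  if (inherits(truth, "simulation")) {
    cfg <- truth$config
    truth <- truth$truth
  } else {
    abort("pass the full `simulation` object (the config is needed)",
          class = "spikenorm_parameter_error")
  }
  f <- if (is.null(factors)) {
    setNames(rep(1, nrow(cfg$samples)), cfg$samples$sample_id)
  } else {
    setNames(factors$factor, factors$sample_id)
  }
  W <- cfg$site_width
  L <- cfg$read_length
  w <- window_width
  lam <- truth$sites$intensity / sum(truth$sites$intensity)
  per_sample <- purrr::map_dfr(seq_len(nrow(cfg$samples)), function(i) {
    id <- cfg$samples$sample_id[i]
    n_signal <- cfg$samples$depth[i] * truth$weights$signal_share[i] *
      (1 - cfg$samples$duplicate_rate[i]) * f[[id]]
    tibble(
      sample_id = id,
      site_id = truth$sites$site_id,
      expected_window_signal = n_signal * lam * (L + w - 1) / (W - L + 1)
    )
  })
  per_sample |>
    group_by(.data$sample_id) |>
    mutate(sample_mean = mean(.data$expected_window_signal)) |>
    ungroup()
}
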